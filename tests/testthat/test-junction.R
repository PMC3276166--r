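test_that("rendered junction strings parse and re-render losslessly", {
  jm <- parse_junction("ttaTTAAtgg")
  expect_equal(jm$microhomology, "TTAA")
  expect_equal(jm$left_flank, "tta")
  expect_equal(jm$right_flank, "tgg")
  expect_equal(render_junction(jm), "ttaTTAAtgg")
  blunt <- parse_junction("atat/cctg")
  expect_equal(blunt$microhomology, "")
  expect_equal(render_junction(blunt), "atat/cctg")
  long_mh <- parse_junction("tttTTAATTttt")
  expect_equal(long_mh$microhomology, "TTAATT")
  expect_error(parse_junction("ttaTTAAtggTT"), "malformed")
})

test_that("TA and TTAA motifs are detected in the microhomology only", {
  expect_true(parse_junction("ttaTTAAtgg")$has_TTAA)
  expect_true(parse_junction("ttaTTAAtgg")$has_TA)
  a <- parse_junction("tacATAatc")
  expect_false(a$has_TTAA)
  expect_true(a$has_TA)
  none <- junction_model("tta", "", "tgg")
  expect_false(none$has_TA)
  expect_false(none$has_TTAA)
  gc_only <- junction_model("aaa", "GC", "ttt")
  expect_false(gc_only$has_TA)
})

test_that("microhomology is recovered from raw MIC/MAC boundary sequences", {
  set.seed(12)
  rand <- function(n) paste(sample(c("A","T","G","C"), n, TRUE), collapse = "")
  for (i in 1:25) {
    L <- rand(30); R <- rand(30)
    m <- c("TTAA", "ATA", "TA", "GATC", "")[sample(5, 1)]
    core <- paste0("CCGG", rand(40), "CCGG")  # GC caps block chance extension
    mac <- paste0(L, m, R)
    mic_left <- paste0(L, m, core)           # crosses the left boundary
    mic_right <- paste0(core, m, R)          # crosses the right boundary
    jm <- compute_microhomology(mic_left, mic_right, mac, max_mh = 9)
    oracle <- brute_microhomology(mic_left, mic_right, mac, max_mh = 9)
    expect_equal(jm$microhomology, oracle, info = paste("case", i))
    # chance 1-2 bp homology at the join may extend the call; the planted
    # motif must still be contained in the reported microhomology
    expect_true(m == "" || grepl(m, jm$microhomology, fixed = TRUE),
                info = paste("case", i))
    expect_false(jm$flagged)
  }
})

test_that("junction field concatenation reproduces the MAC sequence", {
  L <- "ATTGCA"; R <- "GGATTC"; m <- "TTAA"
  core <- paste0("CCGG", strrep("ATATTA", 10), "CCGG")
  jm <- compute_microhomology(paste0(L, m, core), paste0(core, m, R),
                              paste0(L, m, R), flank_width = 6)
  expect_equal(paste0(toupper(jm$left_flank), jm$microhomology,
                      toupper(jm$right_flank)),
               paste0(L, m, R))
})

test_that("irreconcilable boundary sequences are flagged", {
  mac <- "AAATTTCCCGGGAAATTT"
  # MIC sides that never reach each other across the junction (erosion gap)
  jm <- compute_microhomology("AAATTTCGCGCGCGCG", "GCGCGCGCGGAAATTT", mac)
  expect_true(jm$flagged)
  expect_equal(jm$microhomology, "")
})

test_that("IES assembly merges overlapping extensions and bounds the rest", {
  set.seed(44)
  core <- paste(sample(c("A","T","G","C"), 260, TRUE), collapse = "")
  lx <- substr(core, 1, 180)     # prefix of the core
  rx <- substr(core, 121, 260)   # suffix, 60 bp overlap
  asm <- assemble_ies(lx, rx, min_olap = 20)
  expect_true(asm$exact)
  expect_equal(asm$seq, core)
  expect_equal(asm$len, 260L)
  # non-overlapping extensions: lower bound only
  asm2 <- assemble_ies(substr(core, 1, 100), substr(core, 201, 260),
                       min_olap = 20)
  expect_false(asm2$exact)
  expect_equal(asm2$len, 100L)
  # one side missing
  asm3 <- assemble_ies(character(), substr(core, 201, 260))
  expect_false(asm3$exact)
  expect_equal(asm3$len, 60L)
})

test_that("tandem-repeat overlaps are reported as ambiguous", {
  rep10 <- strrep("ACGTACGTAC", 12)  # 120 bp of period-10 repeat
  asm <- assemble_ies(rep10, rep10, min_olap = 20)
  expect_true(asm$ambiguous)
  expect_false(asm$exact)
})

test_that("junction heterogeneity is summarized by lengths and sequences", {
  expect_equal(compare_junctions(rep("AATTC", 5))[c("n_lengths", "n_sequences")],
               list(n_lengths = 1L, n_sequences = 1L))
  cj <- compare_junctions(c("AAT", "AAT", "AATT", "ACT"))
  expect_equal(cj$n_lengths, 2L)
  expect_equal(cj$n_sequences, 3L)
  expect_error(compare_junctions(character()), "at least one")
})

test_that("alternative excision boundaries yield bounded junction diversity", {
  cfg <- sim_config(seed = 19, contig_lengths = c(60000L), n_ies = 4,
                    class_mix = 0, n_alt_boundaries = 3L, spacer_len = 500L)
  sim <- simulate_genomes(cfg)
  set.seed(5)
  js <- excision_junctions(sim, sim$truth$ies_id[1L], n_events = 40)
  cj <- compare_junctions(js)
  expect_lte(cj$n_sequences, 3L)
  expect_lte(cj$n_lengths, 3L)
  expect_gte(cj$n_sequences, 2L)  # heterogeneity is actually visible
})

test_that("called win1 sites carry exact microhomology and assembled IES", {
  cfg <- sim_config(seed = 47, contig_lengths = c(80000L), n_ies = 12,
                    class_mix = 1, f = 1, short_len_range = c(100L, 300L),
                    spacer_len = 500L)
  sim <- simulate_genomes(cfg)
  rd <- simulate_reads(sim, mode = "junction")
  res <- run_calling(sim, rd)
  sites <- site_junctions(res$sites, res$evidence, sim$ref)
  w1 <- sites[sites$category == "win1", ]
  expect_gt(nrow(w1), 8L)
  ev <- evaluate_calls(sites, sim)
  expect_equal(ev$mh_accuracy, 1)
  # assembled IES sequences equal the planted excised segments
  tr <- sim$truth
  for (i in seq_len(nrow(w1))) {
    j <- which.min(abs(tr$conmac_junction - w1$window_end[i]))
    if (isTRUE(w1$ies_exact[i])) {
      expect_equal(w1$ies_seq[i], tr$ies_seq[j])
      expect_equal(w1$ies_len[i], tr$ies_len[j])
    } else {
      expect_lte(w1$ies_len[i], tr$ies_len[j])
    }
  }
  expect_true(any(w1$ies_exact))  # short IES are assemblable from clips
})
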