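test_that("with no IES the MIC equals the MAC exactly", {
  sim <- simulate_genomes(sim_config(seed = 2, n_ies = 0,
                                     contig_lengths = c(20000L, 10000L)))
  expect_equal(as.character(sim$mic), as.character(sim$mac))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a fixed seed reproduces genomes and reads byte for byte", {
  cfg <- sim_config(seed = 91, contig_lengths = c(30000L), n_ies = 6,
                    spacer_len = 500L)
  s1 <- simulate_genomes(cfg); s2 <- simulate_genomes(cfg)
  expect_identical(as.character(s1$mac), as.character(s2$mac))
  expect_identical(as.character(s1$mic), as.character(s2$mic))
  expect_identical(s1$truth, s2$truth)
  r1 <- simulate_reads(s1, mode = "uniform")
  r2 <- simulate_reads(s2, mode = "uniform")
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(r1$placement, r2$placement)
})

test_that("base composition matches the configured AT fraction", {
  sim <- simulate_genomes(sim_config(seed = 8, n_ies = 0,
                                     contig_lengths = c(400000L),
                                     at_fraction = 0.75))
  freq <- Biostrings::alphabetFrequency(sim$mac[[1L]])
  at <- sum(freq[c("A", "T")]) / 400000
  sd3 <- 3 * sqrt(0.75 * 0.25 / 400000)
  expect_lt(abs(at - 0.75), sd3)
})

test_that("planted IES satisfy the MIC reconstruction identity", {
  cfg <- sim_config(seed = 23, contig_lengths = c(60000L, 40000L),
                    n_ies = 16, class_mix = 0.5, spacer_len = 500L)
  sim <- simulate_genomes(cfg)
  mac <- as.character(sim$mac); mic <- as.character(sim$mic)
  tr <- sim$truth
  expect_equal(nchar(mic[unique(tr$contig)]) - nchar(mac[unique(tr$contig)]),
               vapply(split(tr$ies_len, tr$contig), sum, 0L)[unique(tr$contig)])
  for (i in seq_len(nrow(tr))) {
    m <- mic[[tr$contig[i]]]
    # excised segment matches the recorded IES sequence (core + mh copy)
    expect_equal(substr(m, tr$mic_start[i], tr$mic_end[i]), tr$ies_seq[i])
    # the MAC junction retains one microhomology copy ending at the junction
    lm <- nchar(tr$microhomology[i])
    if (lm > 0) {
      expect_equal(substr(mac[[tr$contig[i]]],
                          tr$mac_junction[i] - lm + 1L, tr$mac_junction[i]),
                   tr$microhomology[i])
      # duplicated copy sits at the end of the excised segment
      expect_equal(substr(m, tr$mic_end[i] - lm + 1L, tr$mic_end[i]),
                   tr$microhomology[i])
    }
    # removing the excised segment from the MIC restores the MAC locally
    left <- substr(m, tr$mic_start[i] - 50L, tr$mic_start[i] - 1L)
    right <- substr(m, tr$mic_end[i] + 1L, tr$mic_end[i] + 50L)
    expect_equal(paste0(left, right),
                 substr(mac[[tr$contig[i]]], tr$mac_junction[i] - 49L,
                        tr$mac_junction[i] + 50L))
  }
  # short-class microhomologies are 3-4 bp and contain TA when TTAA-drawn
  short <- tr[tr$class == "short_precise", ]
  expect_true(all(nchar(short$microhomology) %in% 3:4))
  expect_true(all(tr$class != "long_heterogeneous" |
                    tr$microhomology == ""))
})

test_that("error-free reads are exact substrings of the MIC (or reverse complement)", {
  cfg <- sim_config(seed = 29, contig_lengths = c(40000L), n_ies = 5,
                    coverage = 0.3, spacer_len = 500L)
  sim <- simulate_genomes(cfg)
  rd <- simulate_reads(sim, mode = "uniform")
  mic <- as.character(sim$mic)
  for (i in seq_len(min(20L, length(rd$reads)))) {
    p <- rd$placement[i, ]
    expected <- substr(mic[[p$contig]], p$mic_start, p$mic_end)
    got <- as.character(rd$reads[[p$read_id]])
    if (p$strand == "-") {
      expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(expected)))
    }
    expect_equal(got, expected)
  }
  expect_equal(sort(unique(mate_tag(names(rd$reads)))), c("b1", "g1"))
})

test_that("substitution errors appear at roughly the configured rate", {
  cfg <- sim_config(seed = 37, contig_lengths = c(40000L), n_ies = 0,
                    coverage = 0.5, error_rate = 0.02, spacer_len = 500L)
  sim <- simulate_genomes(cfg)
  rd <- simulate_reads(sim, mode = "uniform")
  mic <- as.character(sim$mic)
  nerr <- 0L; nbase <- 0L
  for (i in seq_len(nrow(rd$placement))) {
    p <- rd$placement[i, ]
    truth <- substr(mic[[p$contig]], p$mic_start, p$mic_end)
    if (p$strand == "-") {
      truth <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(truth)))
    }
    got <- as.character(rd$reads[[p$read_id]])
    nerr <- nerr + sum(strsplit(got, "")[[1L]] != strsplit(truth, "")[[1L]])
    nbase <- nbase + nchar(got)
  }
  expect_gt(nbase, 10000L)
  sd3 <- 3 * sqrt(0.02 * 0.98 / nbase)
  expect_lt(abs(nerr / nbase - 0.02), sd3)
})

test_that("uniform-mode read yield follows the Lander-Waterman expectation", {
  cfg <- sim_config(seed = 53, contig_lengths = c(120000L), n_ies = 0,
                    coverage = 0.6, spacer_len = 500L)
  sim <- simulate_genomes(cfg)
  rd <- simulate_reads(sim, mode = "uniform")
  realized <- sum(Biostrings::width(rd$reads)) / sum(Biostrings::width(sim$mic))
  expect_lt(abs(realized - 0.6), 0.1)
})

test_that("the evaluator scores perfect and empty call sets correctly", {
  sim <- simulate_genomes(sim_config(seed = 61, contig_lengths = c(50000L),
                                     n_ies = 8, class_mix = 1,
                                     spacer_len = 500L))
  perfect <- data.frame(window_start = sim$truth$conmac_junction,
                        window_end = sim$truth$conmac_junction,
                        category = "win1", n_l = 1L, n_r = 1L,
                        l_reads = "", r_reads = "",
                        stringsAsFactors = FALSE)
  ev <- evaluate_calls(perfect, sim)
  expect_equal(unname(ev$recall["win1"]), 1)
  expect_equal(unname(ev$precision["win1"]), 1)
  empty <- perfect[0L, ]
  ev0 <- evaluate_calls(empty, sim)
  expect_equal(unname(ev0$recall["win1"]), 0)
  expect_true(is.na(ev0$precision["win1"]))
})
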