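ref_600 <- function(seed = 9, len = 6000L) {
  set.seed(seed)
  ctg <- Biostrings::DNAStringSet(c(chr = paste(
    sample(c("A", "T", "C", "G"), len, TRUE,
           prob = c(.375, .375, .125, .125)), collapse = "")))
  build_conmac(ctg, spacer_len = 100L)
}

test_that("a read identical to a reference window aligns full length", {
  ref <- ref_600()
  win <- as.character(ref$contigs[[1L]])
  rds <- make_reads(c(r = substr(win, 2001, 2600)), list(40L))
  rec <- seed_extend_align(rds, ref)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$left_clip, 0L)
  expect_equal(rec$right_clip, 0L)
  expect_equal(rec$ref_start, 2001L)
  expect_equal(rec$ref_end, 2600L)
  expect_equal(rec$strand, "+")
  expect_equal(rec$score, 600L)
  expect_true(rec$is_unique)
})

test_that("a read with a random non-reference tail is clipped near the truth", {
  ref <- ref_600()
  win <- as.character(ref$contigs[[1L]])
  set.seed(33)
  tail300 <- paste(sample(c("A", "C"), 300, TRUE), collapse = "")  # alien
  rds <- make_reads(c(r = paste0(substr(win, 1001, 1300), tail300)),
                    list(40L))
  rec <- seed_extend_align(rds, ref)
  expect_equal(nrow(rec), 1L)
  expect_lte(abs(rec$right_clip - 300L), 5L)
  expect_equal(rec$left_clip, 0L)
})

test_that("reverse-complement reads mirror clips at the same interval", {
  ref <- ref_600()
  win <- as.character(ref$contigs[[1L]])
  fwd <- paste0(substr(win, 3001, 3500), strrep("C", 100))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  rec <- seed_extend_align(make_reads(c(f = fwd, r = rc), list(40L)), ref)
  rec <- rec[order(rec$read_id), ]
  expect_equal(rec$strand, c("+", "-"))
  # clips are reported in reference orientation: identical for both reads
  expect_equal(rec$ref_start[1L], rec$ref_start[2L])
  expect_equal(rec$ref_end[1L], rec$ref_end[2L])
  expect_equal(rec$left_clip[1L], rec$left_clip[2L])
  expect_equal(rec$right_clip[1L], rec$right_clip[2L])
})

test_that("clip arithmetic holds for every record of a simulated run", {
  sim <- simulate_genomes(sim_config(seed = 13, contig_lengths = c(40000L),
                                     n_ies = 10, class_mix = 1,
                                     coverage = 0.8, spacer_len = 1000L))
  rd <- simulate_reads(sim, mode = "uniform")
  rec <- seed_extend_align(rd$reads, sim$ref)
  expect_gt(nrow(rec), 20L)
  expect_true(all(rec$left_clip + (rec$read_end - rec$read_start + 1L) +
                    rec$right_clip == rec$read_len))
  expect_true(all(rec$ref_start <= rec$ref_end))
  expect_true(all(rec$left_clip == rec$read_start - 1L))
})

test_that("error-free reads inside MAC-destined sequence recover the true interval", {
  ref <- ref_600(seed = 17, len = 20000L)
  win <- as.character(ref$contigs[[1L]])
  set.seed(5)
  starts <- sample(1:(20000 - 700), 20)
  ids <- sprintf("r%02d", 1:20)
  rds <- make_reads(setNames(substring(win, starts, starts + 699), ids),
                    list(40L))
  rec <- seed_extend_align(rds, ref)
  expect_equal(nrow(rec), 20L)
  truth <- setNames(starts, ids)
  expect_equal(rec$ref_start, unname(truth[rec$read_id]))
  expect_equal(rec$ref_end, unname(truth[rec$read_id]) + 699L)
  expect_equal(rec$left_clip + rec$right_clip, rep(0L, 20L))
})

test_that("alignment scores match an independent local aligner on mutated reads", {
  ref <- ref_600(seed = 21, len = 8000L)
  win <- as.character(ref$contigs[[1L]])
  set.seed(99)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:5) {
    s <- sample(1:7000, 1L)
    read <- substr(win, s, s + 599)
    v <- strsplit(read, "")[[1L]]
    mut <- sample(600, 6)
    v[mut] <- vapply(v[mut], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    read <- paste(v, collapse = "")
    rec <- seed_extend_align(make_reads(c(r = read), list(40L)), ref)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), ref$contigs[[1L]],
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    expect_equal(rec$score[1L], Biostrings::score(pa), info = paste("case", i))
  }
})

test_that("reads from a duplicated locus are flagged multi, unique reads are not", {
  set.seed(55)
  core <- paste(sample(c("A","T","C","G"), 5000, TRUE,
                       prob = c(.375,.375,.125,.125)), collapse = "")
  dup <- substr(core, 1000, 1399)
  ctg <- Biostrings::DNAStringSet(c(chr = paste0(core, strrep("T", 50), dup)))
  ref <- build_conmac(ctg, spacer_len = 100L)
  rds <- make_reads(c(multi = dup, uniq = substr(core, 3000, 3399)),
                    list(40L))
  rec <- seed_extend_align(rds, ref)
  prim <- rec[rec$segment_index == 1L, ]
  expect_false(prim$is_unique[prim$read_id == "multi"])
  expect_true(prim$is_unique[prim$read_id == "uniq"])
})

test_that("a weak secondary placement leaves the read unique under the margin rule", {
  rec <- rec_row("r1", 100L, 499L, 0L, 0L, 400L, score = 400L,
                 second_score = 200L, is_unique = NA)
  out <- mark_uniqueness(rec, score_margin = 0.95)
  expect_true(out$is_unique)
  rec2 <- rec_row("r2", 100L, 499L, 0L, 0L, 400L, score = 400L,
                  second_score = 399L, is_unique = NA)
  expect_false(mark_uniqueness(rec2, 0.95)$is_unique)
})

test_that("SAM ingestion parses clips, strand normalization and unmapped records", {
  ref <- toy_ref(spacer = 50L)
  sam <- tempfile(fileext = ".sam")
  seq70 <- strrep("ACGTTGCA", 10)  # 80 bp
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:conMAC\tLN:%d", ref$total_length),
    paste("r1", 0, "conMAC", 11, 60, "20S60M", "*", 0, 0, seq70, "*", sep = "\t"),
    paste("r2", 16, "conMAC", 11, 60, "60M20S", "*", 0, 0, seq70, "*", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, seq70, "*", sep = "\t")),
    sam)
  rec <- ingest_sam(sam, ref)
  rec <- rec[order(rec$read_id), ]
  expect_equal(rec$read_id, c("r1", "r2"))
  expect_equal(rec$left_clip, c(20L, 0L))   # reference orientation
  expect_equal(rec$right_clip, c(0L, 20L))
  expect_equal(rec$strand, c("+", "-"))
  expect_equal(rec$ref_start, c(11L, 11L))
  expect_equal(attr(rec, "unmapped"), "r3")
})

test_that("built-in SAM output round-trips through ingestion", {
  ref <- ref_600(seed = 3, len = 10000L)
  win <- as.character(ref$contigs[[1L]])
  rds <- make_reads(c(a = substr(win, 501, 1100),
                      b = paste0(substr(win, 4001, 4400), strrep("G", 80))),
                    list(40L))
  rec <- seed_extend_align(rds, ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(rec, rds, ref, sam)
  back <- ingest_sam(sam, ref)
  m <- merge(rec, back, by = "read_id")
  expect_equal(m$ref_start.x, m$ref_start.y)
  expect_equal(m$left_clip.x, m$left_clip.y)
  expect_equal(m$right_clip.x, m$right_clip.y)
  expect_equal(m$strand.x, m$strand.y)
})
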