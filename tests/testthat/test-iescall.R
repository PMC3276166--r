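ev_row <- function(side, coord, read_id, clip = NA_character_) {
  data.frame(side = side, coord = coord, read_id = read_id, clip_seq = clip,
             stringsAsFactors = FALSE)
}

test_that("breakpoint evidence uses the terminal MAC-matching base", {
  set.seed(3)
  ctg <- Biostrings::DNAStringSet(c(A = paste(
    sample(c("A", "T", "G", "C"), 5000, TRUE), collapse = "")))
  ref <- build_conmac(ctg, spacer_len = 100L)
  rec <- rbind(rec_row("l1", 700L, 1000L, 0L, 399L, 700L),
               rec_row("r1", 2000L, 2300L, 399L, 0L, 700L),
               rec_row("edge", 4650L, 4950L, 0L, 399L, 700L))  # 49 bp from end
  cls <- classify_reads(rec, c("l1", "r1", "edge"), ref, edge_margin = 100L)
  ev <- collect_breakpoints(rec, cls)
  expect_equal(nrow(ev), 2L)  # edge-excluded read contributes nothing
  expect_equal(ev$coord[ev$side == "L"], 1000L)  # last aligned base
  expect_equal(ev$coord[ev$side == "R"], 2000L)  # first aligned base
})

test_that("multi-mapping one-end reads never contribute evidence", {
  set.seed(3)
  ctg <- Biostrings::DNAStringSet(c(A = paste(
    sample(c("A", "T", "G", "C"), 5000, TRUE), collapse = "")))
  ref <- build_conmac(ctg, spacer_len = 100L)
  rec <- rec_row("m1", 700L, 1000L, 0L, 399L, 700L, second_score = 300L,
                 is_unique = FALSE)
  cls <- classify_reads(rec, "m1", ref)
  expect_equal(nrow(collect_breakpoints(rec, cls)), 0L)
})

test_that("convergent L and R evidence within the 9 bp window merges into win1", {
  # 6 bp overlap: L ends at 1001, R starts at 996
  s1 <- call_sites(rbind(ev_row("L", 1001L, "a"), ev_row("R", 996L, "b")))
  expect_equal(s1$category, "win1")
  expect_equal(c(s1$window_start, s1$window_end), c(995L, 1001L))
  # 16 bp overlap: stays two one-sided sites
  s2 <- call_sites(rbind(ev_row("L", 1001L, "a"), ev_row("R", 986L, "b")))
  expect_setequal(s2$category, c("win2", "win3"))
  # exactly 9 bp overlap merges; 10 bp does not
  s3 <- call_sites(rbind(ev_row("L", 1001L, "a"), ev_row("R", 993L, "b")))
  expect_equal(s3$category, "win1")
  s4 <- call_sites(rbind(ev_row("L", 1001L, "a"), ev_row("R", 992L, "b")))
  expect_setequal(s4$category, c("win2", "win3"))
  # the gap side is symmetric: 9 bp gap merges, 10 bp does not
  s5 <- call_sites(rbind(ev_row("L", 1000L, "a"), ev_row("R", 1010L, "b")))
  expect_equal(s5$category, "win1")
  s6 <- call_sites(rbind(ev_row("L", 1000L, "a"), ev_row("R", 1011L, "b")))
  expect_setequal(s6$category, c("win2", "win3"))
})

test_that("a spanning fully mapped read vetoes the site", {
  ev <- rbind(ev_row("L", 1001L, "a"), ev_row("R", 996L, "b"))
  full <- rec_row("f1", 900L, 1100L, 0L, 0L, 201L)
  s <- call_sites(ev, full)
  expect_equal(nrow(s), 0L)
  expect_equal(attr(s, "vetoed")$category, "win1")
  # a full read with less than veto_margin flank does not veto
  near <- rec_row("f2", 990L, 1100L, 0L, 0L, 111L)  # only 5 bp left of window
  s2 <- call_sites(ev, near)
  expect_equal(s2$category, "win1")
})

test_that("same-side breakpoints cluster to their median coordinate", {
  ev <- rbind(ev_row("L", 1000L, "a"), ev_row("L", 1002L, "b"),
              ev_row("L", 1004L, "c"),
              ev_row("R", 999L, "d"))
  s <- call_sites(ev)
  expect_equal(s$category, "win1")
  expect_equal(s$n_l, 3L)
  expect_equal(s$n_r, 1L)
  expect_equal(s$window_end, 1002L)  # median of 1000, 1002, 1004
})

test_that("no breakpoint supports two sites and win1 is bounded by cluster counts", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(5:25, 1L)
    ev <- do.call(rbind, lapply(seq_len(n), function(i) {
      ev_row(sample(c("L", "R"), 1L), sample(1000:4000, 1L),
             sprintf("r%03d", i))
    }))
    s <- call_sites(ev)
    all_reads <- unlist(strsplit(c(s$l_reads, s$r_reads), ","))
    all_reads <- all_reads[nzchar(all_reads)]
    expect_false(any(duplicated(all_reads)))
    expect_setequal(all_reads, ev$read_id)
    n_l_clusters <- sum(s$n_l > 0)
    n_r_clusters <- sum(s$n_r > 0)
    expect_lte(sum(s$category == "win1"),
               min(n_l_clusters, n_r_clusters))
    expect_true(!is.unsorted(s$window_start))
  }
})

test_that("the two-sided coverage model extrapolates the genome-wide count", {
  expect_equal(extrapolate_total(404, 0.25), 6464)
  expect_equal(extrapolate_total(100, 1.0), 100)
  expect_equal(extrapolate_total(0, 0.25), 0)
  expect_error(extrapolate_total(10, 0), "f")
  expect_error(extrapolate_total(10, 1.5), "f")
})

test_that("site BED output is 0-based half-open and loses nothing", {
  s <- call_sites(rbind(ev_row("L", 1001L, "a"), ev_row("R", 996L, "b"),
                        ev_row("L", 3000L, "c")))
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_sites(s, bed, tsv)
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, s$window_start - 1L)
  expect_equal(b$V3, s$window_end)
  expect_equal(b$V4, s$category)
  back <- read.delim(tsv)
  expect_equal(back$window_start, s$window_start)
  expect_equal(back$category, s$category)
})
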