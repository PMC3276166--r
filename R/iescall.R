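#' Extract per-read breakpoint evidence from one-end mappers
#'
#' Each uniquely mapping `ONE_END_L` / `ONE_END_R` read contributes one
#' breakpoint: the conMAC coordinate of its terminal MAC-matching base
#' (last aligned base for L evidence, first aligned base for R evidence),
#' together with the nonmapping extension (clip) sequence, reported in
#' reference orientation so that L clips read into the IES left-to-right
#' and R clips end at the IES/MAC boundary. Edge-excluded and multi-mapping
#' reads contribute nothing.
#'
#' @param records Alignment record data.frame.
#' @param classes Data.frame from [classify_reads()].
#' @param reads Optional read set; when supplied, clip sequences are
#'   attached.
#' @return A data.frame with columns `side` ("L"/"R"), `coord` (1-based
#'   conMAC), `read_id`, `clip_seq`.
#' @export
collect_breakpoints <- function(records, classes, reads = NULL) {
  cl <- setNames(classes$class, classes$read_id)
  prim <- records[records$segment_index == 1L, , drop = FALSE]
  prim$class <- cl[prim$read_id]
  ev <- prim[prim$class %in% c("ONE_END_L", "ONE_END_R") & prim$is_unique, ,
             drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(side = character(), coord = integer(),
                      read_id = character(), clip_seq = character(),
                      stringsAsFactors = FALSE))
  }
  side <- ifelse(ev$class == "ONE_END_L", "L", "R")
  coord <- ifelse(side == "L", ev$ref_end, ev$ref_start)
  clip <- rep(NA_character_, nrow(ev))
  if (!is.null(reads)) {
    seqs <- toupper(as.character(reads))[ev$read_id]
    flip <- ev$strand == "-"
    seqs[flip] <- vapply(seqs[flip], .revcomp_chr, character(1L))
    clip <- ifelse(side == "L",
                   substring(seqs, ev$read_end + 1L, ev$read_len),
                   substring(seqs, 1L, ev$read_start - 1L))
  }
  out <- data.frame(side = side, coord = as.integer(coord),
                    read_id = ev$read_id, clip_seq = clip,
                    stringsAsFactors = FALSE)
  out[order(out$coord), , drop = FALSE]
}

# Cluster same-side breakpoints: coordinates within max_sep of their sorted
# neighbour chain into one cluster; the cluster coordinate is the (lower)
# median breakpoint.
.cluster_side <- function(bp, max_sep) {
  if (nrow(bp) == 0L) {
    return(data.frame(coord = integer(), n = integer(), reads = character(),
                      stringsAsFactors = FALSE))
  }
  bp <- bp[order(bp$coord), , drop = FALSE]
  grp <- cumsum(c(1L, diff(bp$coord) > max_sep))
  do.call(rbind, lapply(split(bp, grp), function(g) {
    data.frame(coord = as.integer(floor(median(g$coord))), n = nrow(g),
               reads = paste(g$read_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Call candidate IES sites from breakpoint evidence
#'
#' Implements the three calling criteria: (1) departure of an L and/or R
#' read from MAC-matching sequence, (2) convergent L and R evidence may
#' overlap by at most `max_sep` bp (allowing for up to `max_sep` bp of
#' IES-flanking microhomology retained in the MAC) or be separated by at
#' most `max_sep` bp of gap, and (3) no uniquely mapped read spans the site.
#' Convergent L+R clusters become `win1` sites; unpaired L clusters `win2`;
#' unpaired R clusters `win3`. Sites spanned by a fully mapped unique read
#' with at least `veto_margin` aligned bp on each side are vetoed and
#' dropped from the site list (returned separately for inspection).
#'
#' The site window is the closed conMAC interval between the two implied
#' junction coordinates: for a win1 site with `o` bp of microhomology the
#' window has width `o + 1` and contains the retained microhomology copy;
#' win2/win3 windows are single positions.
#'
#' @param evidence Breakpoint data.frame from [collect_breakpoints()].
#' @param full_alns Alignment records of uniquely mapping `FULL` reads
#'   (used for the spanning-read veto); may be empty.
#' @param max_sep Convergence window in bp (default 9).
#' @param veto_margin Minimum aligned bp on each side of a window for a
#'   fully mapped read to veto the site (default 10).
#' @return A data.frame of sites (`window_start`, `window_end`, `category`,
#'   `n_l`, `n_r`, `l_reads`, `r_reads`), in conMAC order, with the vetoed
#'   sites in attribute `"vetoed"`.
#' @export
call_sites <- function(evidence, full_alns = NULL, max_sep = 9L,
                       veto_margin = 10L) {
  lc <- .cluster_side(evidence[evidence$side == "L", , drop = FALSE], max_sep)
  rc <- .cluster_side(evidence[evidence$side == "R", , drop = FALSE], max_sep)
  # junction coordinate implied by each side: L reads end on the last
  # MAC-matching base (jL = coord); R reads start on the first (jR = coord-1,
  # the junction sits just left of it). Convergence: |jL - jR| <= max_sep.
  jl <- lc$coord
  jr <- rc$coord - 1L
  pairs <- NULL
  if (length(jl) && length(jr)) {
    cand <- expand.grid(il = seq_along(jl), ir = seq_along(jr))
    cand$d <- abs(jl[cand$il] - jr[cand$ir])
    cand <- cand[cand$d <= max_sep, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_l <- logical(length(jl)); used_r <- logical(length(jr))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_l[cand$il[i]] && !used_r[cand$ir[i]]) {
        keep[i] <- TRUE
        used_l[cand$il[i]] <- TRUE
        used_r[cand$ir[i]] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  sites <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    sites[["win1"]] <- data.frame(
      window_start = pmin(jl[pairs$il], jr[pairs$ir]),
      window_end = pmax(jl[pairs$il], jr[pairs$ir]),
      category = "win1",
      n_l = lc$n[pairs$il], n_r = rc$n[pairs$ir],
      l_reads = lc$reads[pairs$il], r_reads = rc$reads[pairs$ir],
      stringsAsFactors = FALSE)
    lc <- lc[-pairs$il, , drop = FALSE]
    rc <- rc[-pairs$ir, , drop = FALSE]
    jl <- lc$coord
    jr <- rc$coord - 1L
  }
  if (nrow(lc)) {
    sites[["win2"]] <- data.frame(
      window_start = jl, window_end = jl, category = "win2",
      n_l = lc$n, n_r = 0L, l_reads = lc$reads, r_reads = "",
      stringsAsFactors = FALSE)
  }
  if (nrow(rc)) {
    sites[["win3"]] <- data.frame(
      window_start = jr, window_end = jr, category = "win3",
      n_l = 0L, n_r = rc$n, l_reads = "", r_reads = rc$reads,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(window_start = integer(), window_end = integer(),
               category = character(), n_l = integer(), n_r = integer(),
               l_reads = character(), r_reads = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  sites <- sites[order(sites$window_start), , drop = FALSE]

  vetoed <- sites[0L, , drop = FALSE]
  if (nrow(sites) && !is.null(full_alns) && nrow(full_alns)) {
    fa <- full_alns
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(sites$window_start - veto_margin,
                       sites$window_end + veto_margin),
      IRanges::IRanges(fa$ref_start, fa$ref_end),
      type = "within")
    is_vetoed <- seq_len(nrow(sites)) %in% S4Vectors::queryHits(hit)
    vetoed <- sites[is_vetoed, , drop = FALSE]
    sites <- sites[!is_vetoed, , drop = FALSE]
  }
  rownames(sites) <- rownames(vetoed) <- NULL
  attr(sites, "vetoed") <- vetoed
  sites
}

#' Extrapolate the genome-wide IES count from win1 sites
#'
#' Under random read coverage, a given junction is covered by an L read
#' with probability about `f` and independently by an R read with the same
#' probability, so only a fraction `f^2` of all IES junctions acquire the
#' convergent two-sided evidence required for a win1 call. The genome-wide
#' estimate is therefore `n_win1 / f^2`.
#'
#' @param n_win1 Number of win1 sites called.
#' @param f Coverage fraction (probability that a junction is covered by an
#'   L read; equally for R), in (0, 1].
#' @return The rounded estimate of the total number of IES sites.
#' @examples
#' extrapolate_total(404, 0.25)  # 6464
#' @export
extrapolate_total <- function(n_win1, f) {
  if (length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
    stop("'f' must be in (0, 1]")
  }
  if (n_win1 < 0) stop("'n_win1' must be non-negative")
  round(n_win1 / f^2)
}

#' Write called sites as BED plus a companion TSV
#'
#' BED output is 0-based half-open with the category in the name field and
#' the supporting read count in the score field.
#'
#' @param sites Site data.frame from [call_sites()] (optionally augmented
#'   by [site_junctions()]).
#' @param bed Output BED path.
#' @param tsv Optional output TSV path with all columns.
#' @return Invisibly, the paths written.
#' @export
write_sites <- function(sites, bed, tsv = NULL) {
  df <- data.frame(chrom = "conMAC",
                   start = sites$window_start - 1L,  # 0-based half-open
                   end = sites$window_end,
                   name = sites$category,
                   score = pmin(1000L, sites$n_l + sites$n_r),
                   strand = ".")
  write.table(df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv)) {
    write.table(sites, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed, tsv = tsv))
}
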