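#' Read alignment categories
#'
#' Every read receives exactly one of: `FULL` (aligned end to end, at most
#' `min_ext` bp unaligned at either end), `ONE_END_L` (aligned on the
#' browser-left of a putative IES, with a nonmapping extension of more than
#' `min_ext` bp on its right end), `ONE_END_R` (the mirror image),
#' `DISCONTINUOUS` (both ends clipped, or multiple disjoint aligned
#' segments - possible cloned-DNA rearrangement), `EDGE_EXCLUDED` (a
#' one-end mapper whose breakpoint lies near a contig edge or in a spacer,
#' an assembly-edge artifact rather than IES evidence) or `UNMAPPED`.
#'
#' The extension threshold is strict: a clip of exactly `min_ext` bp still
#' counts as fully aligned ("more than 10 bp" of nonmapping sequence is
#' required for IES candidacy).
#'
#' @param records Alignment record data.frame from [seed_extend_align()] or
#'   [ingest_sam()].
#' @param reads The read set that was aligned (used to enumerate unmapped
#'   reads); alternatively a character vector of read ids.
#' @param ref A `ConMacReference`.
#' @param min_ext Clip length in bp that must be exceeded for a read end to
#'   count as a nonmapping extension (default 10).
#' @param edge_margin Breakpoints closer than this to a contig end are
#'   edge-excluded (default 100).
#' @return A data.frame with columns `read_id`, `class`, `is_unique`.
#' @export
classify_reads <- function(records, reads, ref, min_ext = 10L,
                           edge_margin = 100L) {
  ids <- if (is.character(reads)) reads else names(reads)
  cls <- setNames(rep("UNMAPPED", length(ids)), ids)
  uni <- setNames(rep(NA, length(ids)), ids)
  if (nrow(records)) {
    prim <- records[records$segment_index == 1L, , drop = FALSE]
    nseg <- setNames(prim$n_segments, prim$read_id)
    uni[prim$read_id] <- prim$is_unique
    lc <- setNames(prim$left_clip, prim$read_id)
    rc <- setNames(prim$right_clip, prim$read_id)
    mapped <- prim$read_id
    c0 <- ifelse(nseg[mapped] > 1L, "DISCONTINUOUS",
          ifelse(lc[mapped] > min_ext & rc[mapped] > min_ext, "DISCONTINUOUS",
          ifelse(rc[mapped] > min_ext, "ONE_END_L",
          ifelse(lc[mapped] > min_ext, "ONE_END_R", "FULL"))))
    names(c0) <- mapped
    one_end <- names(c0)[c0 %in% c("ONE_END_L", "ONE_END_R")]
    if (length(one_end)) {
      pr <- prim[match(one_end, prim$read_id), , drop = FALSE]
      bp <- ifelse(c0[one_end] == "ONE_END_L", pr$ref_end, pr$ref_start)
      edge <- is_near_contig_edge(ref, bp, edge_margin)
      c0[one_end[edge]] <- "EDGE_EXCLUDED"
    }
    cls[names(c0)] <- c0
  }
  data.frame(read_id = ids, class = unname(cls[ids]),
             is_unique = unname(uni[ids]), stringsAsFactors = FALSE)
}

#' Tally read classes
#'
#' @param classes Data.frame from [classify_reads()].
#' @return A list with `counts` (named vector over all classes), `by_unique`
#'   (class x uniqueness table) and `n` (total reads). Counts always sum to
#'   the number of input reads.
#' @export
tally <- function(classes) {
  lev <- c("FULL", "ONE_END_L", "ONE_END_R", "DISCONTINUOUS",
           "EDGE_EXCLUDED", "UNMAPPED")
  f <- factor(classes$class, levels = lev)
  counts <- table(f)
  u <- factor(ifelse(is.na(classes$is_unique), "unaligned",
                     ifelse(classes$is_unique, "unique", "multi")),
              levels = c("unique", "multi", "unaligned"))
  list(counts = setNames(as.integer(counts), lev),
       by_unique = table(class = f, uniqueness = u),
       n = nrow(classes))
}

#' Write browser-track BED files and a tally report
#'
#' Emits one BED file per read class and uniqueness stratum (the
#' counterparts of "Sanger Reads Left (unique)" style browser tracks) with
#' the aligned span of each record on the conMAC, plus a JSON tally.
#'
#' @param records Alignment record data.frame.
#' @param classes Data.frame from [classify_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tracks <- function(records, classes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- setNames(classes$class, classes$read_id)
  paths <- character()
  if (nrow(records)) {
    records$class <- cl[records$read_id]
    records$strat <- ifelse(records$is_unique, "unique", "multi")
    for (grp in split(records, paste(records$class, records$strat, sep = "_"))) {
      gr <- GenomicRanges::GRanges(
        "conMAC", IRanges::IRanges(grp$ref_start, grp$ref_end),
        strand = grp$strand)
      names(gr) <- grp$read_id
      f <- file.path(dir, paste0("reads_", tolower(grp$class[1L]), "_",
                                 grp$strat[1L], ".bed"))
      rtracklayer::export(gr, f, format = "BED")
      paths <- c(paths, f)
    }
  }
  tj <- file.path(dir, "tally.json")
  tl <- tally(classes)
  jsonlite::write_json(list(counts = as.list(tl$counts), n = tl$n),
                       tj, auto_unbox = TRUE)
  invisible(c(paths, tj))
}
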