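#' Parameters for the built-in seed-and-extend aligner
#'
#' Defaults are a standard local-alignment regime tuned for highly AT-rich
#' (~75% AT) genomes: exact 20-mer seeds sampled along the read, banded
#' affine-gap Smith-Waterman extension around clustered seed diagonals, and
#' a minimum reportable score of 40 (40 matched bases with no penalty).
#'
#' @param seed_len Exact seed length in bp.
#' @param seed_stride Spacing in bp between sampled seed start positions.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (a gap of
#'   length L costs `gap_open + L * gap_extend`; penalties negative).
#' @param min_score Minimum alignment score to report.
#' @param band Half-width in bp of the extension band around the seed
#'   diagonal (bounds the indel budget).
#' @param score_margin A read is multi-mapping when a candidate alignment at
#'   a different locus scores at least `score_margin` times the primary.
#' @param max_loci Maximum candidate loci extended per read.
#' @return A named list of class `align_params`.
#' @export
align_params <- function(seed_len = 20L, seed_stride = 40L,
                         match = 1L, mismatch = -3L,
                         gap_open = -5L, gap_extend = -2L,
                         min_score = 40L, band = 32L,
                         score_margin = 0.95, max_loci = 5L) {
  structure(list(seed_len = as.integer(seed_len),
                 seed_stride = as.integer(seed_stride),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score), band = as.integer(band),
                 score_margin = score_margin,
                 max_loci = as.integer(max_loci)),
            class = "align_params")
}

.empty_records <- function() {
  data.frame(read_id = character(), segment_index = integer(),
             strand = character(), score = integer(),
             ref_start = integer(), ref_end = integer(),
             read_start = integer(), read_end = integer(),
             left_clip = integer(), right_clip = integer(),
             read_len = integer(), n_segments = integer(),
             second_score = integer(), is_unique = logical(),
             stringsAsFactors = FALSE)
}

# Fraction of the shorter of two 1-based closed intervals covered by their
# intersection (vectorized on the second interval).
.olap_frac <- function(s1, e1, s2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  ov / pmin(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Align reads to a conMAC reference with the built-in aligner
#'
#' Samples exact seeds along each read (both orientations), locates them on
#' the reference, clusters seed hits by diagonal, and extends the best
#' candidate loci with a banded affine-gap local alignment. Alignments never
#' extend through the N spacer blocks because N matches nothing. Overlapping
#' candidate alignments on the read are resolved to the higher score; the
#' survivors are the read's segments, numbered `aln1, aln2, ...` in read
#' order. Uniqueness is then assigned with [mark_uniqueness()].
#'
#' Coordinates in the returned table are 1-based and closed. `read_start`,
#' `read_end` and the clip lengths are reported in the reference-normalized
#' read orientation (the read is reverse-complemented first for `-` strand
#' alignments), so that `left_clip == read_start - 1` and
#' `right_clip == read_len - read_end` always hold and clipped tails point
#' left/right on the browser axis.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] or
#'   [Biostrings::DNAStringSet] of trimmed reads (named).
#' @param ref A `ConMacReference` from [build_conmac()].
#' @param params An [align_params()] list.
#' @return A data.frame of alignment records (one row per aligned segment)
#'   with columns `read_id`, `segment_index`, `strand`, `score`,
#'   `ref_start`, `ref_end`, `read_start`, `read_end`, `left_clip`,
#'   `right_clip`, `read_len`, `n_segments`, `second_score`, `is_unique`.
#'   Reads with no alignment are absent (unmapped).
#' @export
seed_extend_align <- function(reads, ref, params = align_params()) {
  seqs <- toupper(as.character(reads))
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named")
  rl <- nchar(seqs)
  p <- params
  usable <- which(rl >= p$seed_len)
  if (length(usable) == 0L) return(.empty_records())

  subj_code <- .encode_seq(ref$sequence)
  nsub <- length(subj_code)

  # --- seed harvest over both orientations -------------------------------
  seed_tab <- list()
  orient_seqs <- list(`+` = seqs[usable],
                      `-` = vapply(seqs[usable], .revcomp_chr, character(1L)))
  for (orient in c("+", "-")) {
    os <- orient_seqs[[orient]]
    starts <- lapply(rl[usable], function(n) {
      unique(c(seq(1L, n - p$seed_len + 1L, by = p$seed_stride),
               n - p$seed_len + 1L))
    })
    nseed <- lengths(starts)
    idx <- rep(seq_along(os), nseed)
    qoff <- unlist(starts)
    seedseq <- substring(os[idx], qoff, qoff + p$seed_len - 1L)
    ok <- !grepl("[^ACGT]", seedseq)
    seed_tab[[orient]] <- data.frame(read = usable[idx][ok],
                                     orient = orient,
                                     qoff = qoff[ok],
                                     seed = seedseq[ok],
                                     stringsAsFactors = FALSE)
  }
  seed_tab <- rbind(seed_tab[["+"]], seed_tab[["-"]])
  if (nrow(seed_tab) == 0L) return(.empty_records())

  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_tab$seed))
  mi <- Biostrings::matchPDict(pd, ref$sequence)
  nhit <- S4Vectors::elementNROWS(mi)
  if (sum(nhit) == 0L) return(.empty_records())
  hit <- data.frame(read = rep(seed_tab$read, nhit),
                    orient = rep(seed_tab$orient, nhit),
                    qoff = rep(seed_tab$qoff, nhit),
                    sstart = unlist(IRanges::start(mi)),
                    stringsAsFactors = FALSE)
  hit$diag <- hit$sstart - hit$qoff

  # --- diagonal clustering per read x orientation ------------------------
  key <- paste(hit$read, hit$orient)
  cand <- do.call(rbind, lapply(split(hit, key), function(h) {
    h <- h[order(h$diag), , drop = FALSE]
    grp <- cumsum(c(1L, diff(h$diag) > p$band %/% 2L))
    agg <- lapply(split(h, grp), function(g) {
      data.frame(read = g$read[1L], orient = g$orient[1L],
                 diag = as.integer(round(median(g$diag))),
                 nseed = nrow(g), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  }))
  rownames(cand) <- NULL
  # rank candidate loci per read by seed support, keep the strongest few
  cand <- cand[order(cand$read, -cand$nseed), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$read),
                        function(i) head(i, p$max_loci)))
  cand <- cand[sort(keep), , drop = FALSE]

  # --- banded extension of each candidate --------------------------------
  qcode <- list(`+` = lapply(orient_seqs[["+"]], .encode_seq),
                `-` = lapply(orient_seqs[["-"]], .encode_seq))
  names(qcode[["+"]]) <- names(qcode[["-"]]) <- as.character(usable)
  pad <- p$band + 8L
  res <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rd <- cand$read[i]
    n <- rl[rd]
    ws <- max(1L, cand$diag[i] + 1L - pad)
    we <- min(nsub, cand$diag[i] + n + pad)
    if (we <= ws) next
    c0 <- cand$diag[i] - ws + 1L
    a <- .sw_band_align(qcode[[cand$orient[i]]][[as.character(rd)]],
                        subj_code[ws:we], c0, p$band,
                        p$match, p$mismatch, p$gap_open, p$gap_extend)
    if (a[1L] < p$min_score) next
    res[[i]] <- data.frame(read = rd, orient = cand$orient[i],
                           score = a[1L],
                           read_start = a[2L], read_end = a[3L],
                           ref_start = ws + a[4L] - 1L,
                           ref_end = ws + a[5L] - 1L,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) return(.empty_records())

  # original-read-frame query interval (for segment resolution across strands)
  res$oq_start <- ifelse(res$orient == "+", res$read_start,
                         rl[res$read] - res$read_end + 1L)
  res$oq_end <- ifelse(res$orient == "+", res$read_end,
                       rl[res$read] - res$read_start + 1L)

  # --- per-read segment selection and alternate bookkeeping --------------
  out <- lapply(split(res, res$read), function(rr) {
    rr <- rr[order(-rr$score), , drop = FALSE]
    kept <- integer()
    second <- 0L
    for (j in seq_len(nrow(rr))) {
      if (length(kept) == 0L) { kept <- j; next }
      qfrac <- .olap_frac(rr$oq_start[j], rr$oq_end[j],
                          rr$oq_start[kept], rr$oq_end[kept])
      if (all(qfrac <= 0.25)) {
        kept <- c(kept, j)  # disjoint on the read: an additional segment
      } else {
        # alternate placement; count it against uniqueness when it sits at
        # a genuinely different reference locus than the primary
        rfrac <- .olap_frac(rr$ref_start[j], rr$ref_end[j],
                            rr$ref_start[kept[1L]], rr$ref_end[kept[1L]])
        qfrac1 <- .olap_frac(rr$oq_start[j], rr$oq_end[j],
                             rr$oq_start[kept[1L]], rr$oq_end[kept[1L]])
        if (qfrac1 > 0.25 && rfrac < 0.5) second <- max(second, rr$score[j])
      }
    }
    sel <- rr[kept, , drop = FALSE]
    sel <- sel[order(sel$oq_start), , drop = FALSE]
    sel$segment_index <- seq_len(nrow(sel))
    sel$n_segments <- nrow(sel)
    sel$second_score <- as.integer(second)
    sel
  })
  out <- do.call(rbind, out)
  n <- rl[out$read]
  records <- data.frame(read_id = ids[out$read],
                        segment_index = out$segment_index,
                        strand = out$orient,
                        score = as.integer(out$score),
                        ref_start = out$ref_start, ref_end = out$ref_end,
                        read_start = out$read_start, read_end = out$read_end,
                        left_clip = out$read_start - 1L,
                        right_clip = n - out$read_end,
                        read_len = n,
                        n_segments = out$n_segments,
                        second_score = out$second_score,
                        is_unique = NA,
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  mark_uniqueness(records, p$score_margin)
}

#' Flag multi-mapping reads
#'
#' A read is unique when no alternate placement of its primary segment at a
#' different reference locus scores at least `score_margin` times the
#' primary score. All segments of a multi-mapping read are flagged together,
#' mirroring the segregation of multi-mapper reads to separate browser
#' tracks.
#'
#' @param records Alignment record data.frame (with `second_score`).
#' @param score_margin Fraction of the primary score at which an alternate
#'   placement makes the read multi-mapping (default 0.95).
#' @return The records with `is_unique` filled in.
#' @export
mark_uniqueness <- function(records, score_margin = 0.95) {
  if (nrow(records) == 0L) return(records)
  prim <- records$segment_index == 1L
  pscore <- setNames(records$score[prim], records$read_id[prim])
  psec <- setNames(records$second_score[prim], records$read_id[prim])
  uni <- psec < score_margin * pscore
  records$is_unique <- unname(uni[records$read_id])
  records
}

#' Ingest alignments from a SAM file
#'
#' Reads standard alignment records produced by an external aligner against
#' either the concatenated reference (sequence name `conMAC`) or the
#' individual contigs (names matching the reference; coordinates are then
#' lifted). Soft and hard clips are parsed from the CIGAR; secondary
#' alignments feed the uniqueness flag; supplementary alignments become
#' additional segments of their read. Unmapped records are excluded and
#' their names returned in the `"unmapped"` attribute.
#'
#' @param path Path to a SAM (or BAM) file with a header.
#' @param ref A `ConMacReference`.
#' @param score_margin Passed to [mark_uniqueness()].
#' @return An alignment record data.frame as from [seed_extend_align()].
#' @export
ingest_sam <- function(path, ref, score_margin = 0.95) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = "AS",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  up <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))[[1L]]$qname

  sq <- as.character(GenomicAlignments::seqnames(ga))
  if (length(ga) > 0L) {
    if (all(sq == "conMAC")) {
      gstart <- GenomicAlignments::start(ga)
    } else if (all(sq %in% names(ref$offsets))) {
      gstart <- lift_to_conmac(ref, sq, GenomicAlignments::start(ga))
    } else {
      stop("SAM reference names match neither 'conMAC' nor the contig names")
    }
  } else gstart <- integer()

  cig <- GenomicAlignments::cigar(ga)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  first_op <- vapply(ops, function(o) if (length(o)) o[1L] else "", "")
  last_op <- vapply(ops, function(o) if (length(o)) o[length(o)] else "", "")
  first_len <- vapply(lens, function(l) if (length(l)) l[1L] else 0L, 0L)
  last_len <- vapply(lens, function(l) if (length(l)) l[length(l)] else 0L, 0L)
  lclip <- ifelse(first_op %in% c("S", "H"), first_len, 0L)
  rclip <- ifelse(last_op %in% c("S", "H"), last_len, 0L)
  hard_l <- ifelse(first_op == "H", first_len, 0L)
  hard_r <- ifelse(last_op == "H", last_len, 0L)
  read_len <- GenomicAlignments::qwidth(ga) + hard_l + hard_r

  flag <- S4Vectors::mcols(ga)$flag
  secondary <- bitwAnd(flag, 256L) > 0L
  qn <- S4Vectors::mcols(ga)$qname
  as_tag <- S4Vectors::mcols(ga)$AS
  aligned_w <- vapply(seq_along(ops), function(i) {
    sum(lens[[i]][ops[[i]] %in% c("M", "=", "X")])
  }, 0L)
  score <- if (!is.null(as_tag) && !all(is.na(as_tag))) {
    ifelse(is.na(as_tag), aligned_w, as_tag)
  } else aligned_w

  df <- data.frame(read_id = qn, strand = as.character(GenomicAlignments::strand(ga)),
                   score = as.integer(score),
                   ref_start = gstart,
                   ref_end = gstart + GenomicAlignments::width(ga) - 1L,
                   left_clip = as.integer(lclip), right_clip = as.integer(rclip),
                   read_len = as.integer(read_len),
                   secondary = secondary, stringsAsFactors = FALSE)
  df$read_start <- df$left_clip + 1L
  df$read_end <- df$read_len - df$right_clip

  out <- lapply(split(df, df$read_id), function(rr) {
    seg <- rr[!rr$secondary, , drop = FALSE]
    if (nrow(seg) == 0L) seg <- rr[1L, , drop = FALSE]
    seg <- seg[order(ifelse(seg$strand == "-",
                            seg$read_len - seg$read_end + 1L,
                            seg$read_start)), , drop = FALSE]
    seg$segment_index <- seq_len(nrow(seg))
    seg$n_segments <- nrow(seg)
    sec <- rr[rr$secondary, , drop = FALSE]
    second <- 0L
    if (nrow(sec)) {
      rfrac <- .olap_frac(sec$ref_start, sec$ref_end,
                          seg$ref_start[1L], seg$ref_end[1L])
      if (any(rfrac < 0.5)) second <- max(sec$score[rfrac < 0.5])
    }
    seg$second_score <- as.integer(second)
    seg
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- .empty_records() else {
    out <- out[, c("read_id", "segment_index", "strand", "score",
                   "ref_start", "ref_end", "read_start", "read_end",
                   "left_clip", "right_clip", "read_len", "n_segments",
                   "second_score")]
    out$is_unique <- NA
    rownames(out) <- NULL
    out <- mark_uniqueness(out, score_margin)
  }
  attr(out, "unmapped") <- unique(up)
  out
}

#' Write alignment records as SAM
#'
#' A minimal SAM writer for interoperability with browser tooling: clip
#' lengths are exact, and any length difference between the read span and
#' the reference span of a segment is collapsed into a single I or D block
#' after the matched block. Secondary placements are not emitted.
#'
#' @param records Alignment record data.frame.
#' @param reads The read set the records refer to (for sequences).
#' @param ref A `ConMacReference` (for the header).
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, reads, ref, path) {
  seqs <- toupper(as.character(reads))
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:conMAC\tLN:%d", ref$total_length))
  if (nrow(records)) {
    qspan <- records$read_end - records$read_start + 1L
    rspan <- records$ref_end - records$ref_start + 1L
    mlen <- pmin(qspan, rspan)
    indel <- ifelse(rspan > qspan, sprintf("%dD", rspan - qspan),
                    ifelse(qspan > rspan, sprintf("%dI", qspan - rspan), ""))
    cigar <- paste0(ifelse(records$left_clip > 0L,
                           sprintf("%dS", records$left_clip), ""),
                    mlen, "M", indel,
                    ifelse(records$right_clip > 0L,
                           sprintf("%dS", records$right_clip), ""))
    oseq <- seqs[records$read_id]
    flip <- records$strand == "-"
    oseq[flip] <- vapply(oseq[flip], .revcomp_chr, character(1L))
    flag <- ifelse(records$strand == "-", 16L, 0L) +
      ifelse(records$segment_index > 1L, 2048L, 0L)
    mapq <- ifelse(records$is_unique, 60L, 0L)
    lines <- c(lines, paste(records$read_id, flag, "conMAC",
                            records$ref_start, mapq, cigar, "*", 0L, 0L,
                            oseq, "*",
                            sprintf("AS:i:%d", records$score), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
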