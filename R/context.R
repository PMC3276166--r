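#' Read gene models from GFF3 and lift them to the conMAC
#'
#' Imports exon features, groups them by gene, applies two plausibility
#' filters approximating manual curation of over-predicted models (a gene
#' with any exon shorter than `min_exon` or any intron longer than
#' `max_intron` is flagged implausible), and lifts exon coordinates to the
#' conMAC axis.
#'
#' @param path GFF3 path (1-based inclusive coordinates, per the format).
#' @param ref A `ConMacReference`; contigs must match the GFF3 seqids.
#' @param min_exon Minimum plausible exon length in bp (default 30).
#' @param max_intron Maximum plausible intron length in bp (default 1000).
#' @return A [GenomicRanges::GRanges] of exons on seqname `conMAC` with
#'   metadata columns `gene_id`, `exon_rank` (5' to 3' on the gene strand),
#'   `n_exons`, `is_plausible`.
#' @export
read_gene_models <- function(path, ref, min_exon = 30L, max_intron = 1000L) {
  gff <- rtracklayer::import(path, format = "gff3")
  ex <- gff[tolower(as.character(gff$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  gene_id <- if (!is.null(ex$gene_id)) as.character(ex$gene_id) else {
    parent <- ex$Parent
    vapply(as.list(parent), function(p) {
      if (length(p)) as.character(p[[1L]]) else NA_character_
    }, "")
  }
  sq <- as.character(GenomicRanges::seqnames(ex))
  if (!all(sq %in% names(ref$offsets))) {
    stop("GFF3 seqids not found among reference contigs: ",
         paste(setdiff(unique(sq), names(ref$offsets)), collapse = ", "))
  }
  gstart <- lift_to_conmac(ref, sq, GenomicRanges::start(ex))
  gr <- GenomicRanges::GRanges(
    "conMAC",
    IRanges::IRanges(gstart, width = GenomicRanges::width(ex)),
    strand = GenomicRanges::strand(ex),
    gene_id = gene_id)
  ord <- order(gr$gene_id, GenomicRanges::start(gr))
  gr <- gr[ord]
  per_gene <- split(seq_along(gr), gr$gene_id)
  rank <- integer(length(gr)); nex <- integer(length(gr))
  plaus <- logical(length(gr))
  for (idx in per_gene) {
    n <- length(idx)
    minus <- as.character(GenomicRanges::strand(gr[idx[1L]])) == "-"
    rank[idx] <- if (minus) rev(seq_len(n)) else seq_len(n)
    nex[idx] <- n
    w <- GenomicRanges::width(gr[idx])
    gaps <- if (n > 1L) {
      GenomicRanges::start(gr[idx[-1L]]) - GenomicRanges::end(gr[idx[-n]]) - 1L
    } else integer()
    plaus[idx] <- all(w >= min_exon) && all(gaps <= max_intron)
  }
  gr$exon_rank <- rank
  gr$n_exons <- nex
  gr$is_plausible <- plaus
  gr
}

# Position label of an exon within its gene, in the Table-style vocabulary.
.exon_position <- function(rank, n) {
  if (n == 1L) "Single"
  else if (rank == 1L) "5'"
  else if (rank == n) "3'"
  else "Mid"
}

#' Annotate called sites against gene models
#'
#' Labels each site window `exon` when it intersects an exon of a plausible
#' gene model, `intron` when it lies inside a gene span without touching an
#' exon, and `intergenic` otherwise. Exonic sites carry the position of the
#' host exon within its gene (`5'`, `3'`, `Mid`, `Single`); a window that
#' straddles an intron/exon boundary is labeled `Jxn <position>`. When a
#' site overlaps several genes, one row per overlapping gene is returned.
#'
#' @param sites Site data.frame from [call_sites()].
#' @param models Exon `GRanges` from [read_gene_models()].
#' @param plausible_only Annotate only against plausible models (default
#'   TRUE).
#' @return A data.frame with one row per site (or per site x gene for
#'   overlaps): all site columns plus `context`, `gene_id`, `exon_position`.
#' @export
annotate_sites <- function(sites, models, plausible_only = TRUE) {
  if (plausible_only) models <- models[models$is_plausible]
  n <- nrow(sites)
  base <- cbind(sites,
                data.frame(context = rep("intergenic", n),
                           gene_id = NA_character_,
                           exon_position = NA_character_,
                           stringsAsFactors = FALSE))
  if (n == 0L || length(models) == 0L) return(base)
  win <- IRanges::IRanges(sites$window_start, sites$window_end)
  exr <- IRanges::ranges(models)
  # gene spans for intron calls
  gene_span <- unlist(range(S4Vectors::split(IRanges::ranges(models),
                                             models$gene_id)))
  rows <- list()
  ex_hit <- IRanges::findOverlaps(win, exr)
  hit_df <- data.frame(site = S4Vectors::queryHits(ex_hit),
                       exon = S4Vectors::subjectHits(ex_hit))
  for (i in seq_len(n)) {
    hits <- hit_df$exon[hit_df$site == i]
    if (length(hits)) {
      for (g in unique(models$gene_id[hits])) {
        e <- hits[models$gene_id[hits] == g][1L]
        pos <- .exon_position(models$exon_rank[e], models$n_exons[e])
        inside <- sites$window_start[i] >= IRanges::start(exr)[e] &&
          sites$window_end[i] <= IRanges::end(exr)[e]
        internal_boundary <-
          (sites$window_start[i] < IRanges::start(exr)[e] &&
             models$exon_rank[e] != 1L) ||
          (sites$window_end[i] > IRanges::end(exr)[e] &&
             models$exon_rank[e] != models$n_exons[e])
        lab <- if (!inside && internal_boundary) paste("Jxn", pos) else pos
        r <- base[i, , drop = FALSE]
        r$context <- "exon"; r$gene_id <- g; r$exon_position <- lab
        rows[[length(rows) + 1L]] <- r
      }
    } else {
      gh <- IRanges::findOverlaps(win[i], gene_span)
      if (length(gh)) {
        for (j in S4Vectors::subjectHits(gh)) {
          r <- base[i, , drop = FALSE]
          r$context <- "intron"; r$gene_id <- names(gene_span)[j]
          rows[[length(rows) + 1L]] <- r
        }
      } else {
        rows[[length(rows) + 1L]] <- base[i, , drop = FALSE]
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference bp covered by unique alignments
#'
#' Length of the union of the aligned reference intervals of uniquely
#' mapping records, with spacer positions excluded (N blocks cannot align,
#' but clipping at a spacer boundary keeps this explicit).
#'
#' @param records Alignment record data.frame.
#' @param ref A `ConMacReference`.
#' @param unique_only Restrict to uniquely mapping reads (default TRUE).
#' @return Covered bp (integer). Invariant to record order and duplication.
#' @export
coverage_bp <- function(records, ref, unique_only = TRUE) {
  if (unique_only && nrow(records)) {
    records <- records[records$is_unique, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(0L)
  cov <- IRanges::reduce(IRanges::IRanges(records$ref_start, records$ref_end))
  sum(IRanges::width(IRanges::intersect(cov, contig_ranges(ref))))
}

#' Histogram of site positions along the conMAC
#'
#' @param sites Site data.frame from [call_sites()].
#' @param ref A `ConMacReference`.
#' @param bin_bp Bin width in bp.
#' @return A data.frame with `bin_start`, `bin_end` (1-based closed),
#'   `count`, and `spacer_only` (TRUE for bins containing no assembly
#'   sequence, which exaggerate apparent genome extent).
#' @export
site_distribution <- function(sites, ref, bin_bp) {
  if (bin_bp <= 0L) stop("'bin_bp' must be positive")
  starts <- seq(1L, ref$total_length, by = bin_bp)
  bins <- IRanges::IRanges(starts,
                           pmin(starts + bin_bp - 1L, ref$total_length))
  count <- IRanges::countOverlaps(
    bins, IRanges::IRanges(sites$window_start, sites$window_end))
  in_contig <- IRanges::countOverlaps(bins, contig_ranges(ref)) > 0L
  data.frame(bin_start = IRanges::start(bins), bin_end = IRanges::end(bins),
             count = count, spacer_only = !in_contig)
}
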