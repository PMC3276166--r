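#' Pipeline configuration
#'
#' Bundles the tunable thresholds of all stages with their defaults:
#' 10 kbp N spacers between contigs, mean read quality Q20, one-end
#' nonmapping extensions must exceed 10 bp, convergent L/R evidence may
#' overlap (or gap) by at most 9 bp, spanning reads veto a site with 10 bp
#' of flank, breakpoints within 100 bp of a contig edge are excluded, and
#' an alternate placement at 95% of the primary score makes a read
#' multi-mapping.
#'
#' @param spacer_len,min_mean_q,min_len,min_ext,max_sep,veto_margin,edge_margin
#'   Stage thresholds (see the stage functions).
#' @param align Alignment parameters from [align_params()].
#' @param seed Seed for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spacer_len = 10000L, min_mean_q = 20,
                            min_len = 50L, min_ext = 10L, max_sep = 9L,
                            veto_margin = 10L, edge_margin = 100L,
                            align = align_params(), seed = 1L) {
  structure(list(spacer_len = spacer_len, min_mean_q = min_mean_q,
                 min_len = min_len, min_ext = min_ext, max_sep = max_sep,
                 veto_margin = veto_margin, edge_margin = edge_margin,
                 align = align, seed = seed),
            class = "pipeline_config")
}

#' Run the IES-detection pipeline end to end
#'
#' Trims reads, aligns them to the conMAC (built here if contigs are
#' given), classifies them, collects one-end breakpoints, calls win1/2/3
#' sites with the spanning-read veto, characterizes junctions, and
#' (optionally) annotates gene context. When `out_dir` is given, writes
#' per-category read tracks (BED), the site BED and TSV, and a JSON
#' summary embedding the configuration.
#'
#' @param contigs MAC contigs (named `DNAStringSet`, character vector, or
#'   FASTA path), or alternatively a prebuilt `ConMacReference` via `ref`.
#' @param reads Reads (a [Biostrings::QualityScaledDNAStringSet] or FASTQ
#'   path).
#' @param ref Optional prebuilt `ConMacReference` (skips `contigs`).
#' @param gff3 Optional gene-model GFF3 path for context annotation.
#' @param sam Optional SAM path of precomputed alignments (skips the
#'   built-in aligner).
#' @param out_dir Optional output directory.
#' @param cfg A [pipeline_config()].
#' @param exclude Contig names to exclude when building the reference.
#' @param skip_trim Set TRUE when reads are already trimmed.
#' @return A list with `ref`, `reads`, `records`, `classes`, `tally`,
#'   `evidence`, `sites` (with junction columns), `annotated` (or NULL)
#'   and `config`.
#' @export
run_pipeline <- function(contigs = NULL, reads = NULL, ref = NULL,
                         gff3 = NULL, sam = NULL, out_dir = NULL,
                         cfg = pipeline_config(), exclude = character(),
                         skip_trim = FALSE) {
  if (is.null(ref)) {
    if (is.null(contigs)) stop("supply 'contigs' or 'ref'")
    if (is.character(contigs) && length(contigs) == 1L &&
        file.exists(contigs)) {
      contigs <- read_contigs(contigs)
    }
    ref <- build_conmac(contigs, spacer_len = cfg$spacer_len,
                        exclude = exclude)
  }
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  n_input <- length(reads)
  if (!skip_trim) {
    qt <- quality_trim(reads, min_mean_q = cfg$min_mean_q,
                       min_len = cfg$min_len)
    reads <- qt$reads
  }
  records <- if (!is.null(sam)) ingest_sam(sam, ref, cfg$align$score_margin)
             else seed_extend_align(reads, ref, cfg$align)
  classes <- classify_reads(records, reads, ref, min_ext = cfg$min_ext,
                            edge_margin = cfg$edge_margin)
  tl <- tally(classes)
  evidence <- collect_breakpoints(records, classes, reads)
  full_ids <- classes$read_id[classes$class == "FULL" & classes$is_unique]
  full_alns <- records[records$read_id %in% full_ids &
                         records$segment_index == 1L, , drop = FALSE]
  sites <- call_sites(evidence, full_alns, max_sep = cfg$max_sep,
                      veto_margin = cfg$veto_margin)
  sites <- site_junctions(sites, evidence, ref)
  annotated <- NULL
  if (!is.null(gff3)) {
    if (file.exists(gff3)) {
      models <- read_gene_models(gff3, ref)
      annotated <- annotate_sites(sites, models)
    } else {
      warning("gene-model file not found, context annotation skipped: ", gff3)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tracks(records, classes, file.path(out_dir, "tracks"))
    write_sites(sites, file.path(out_dir, "sites.bed"),
                file.path(out_dir, "sites.tsv"))
    if (!is.null(annotated)) {
      write.table(annotated, file.path(out_dir, "sites_annotated.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary <- list(
      n_reads_input = n_input,
      n_reads_aligned = length(unique(records$read_id)),
      tally = as.list(tl$counts),
      n_sites = as.list(table(factor(sites$category,
                                     levels = c("win1", "win2", "win3")))),
      covered_bp = coverage_bp(records, ref),
      config = cfg[setdiff(names(cfg), "align")],
      align = unclass(cfg$align))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(ref = ref, reads = reads, records = records, classes = classes,
       tally = tl, evidence = evidence, sites = sites,
       annotated = annotated, config = cfg)
}

#' Curated exon-overlapping IES candidates
#'
#' A small curated table of exon-overlapping IES candidates from the
#' *Tetrahymena thermophila* MIC survey that ships with the package:
#' approximate conMAC browser coordinate, host gene model, supporting read
#' counts, the rendered MAC junction string (lowercase flanks, uppercase
#' retained microhomology, slash for blunt joins), host-exon position, and
#' the determined IES length where PCR could establish one (`length_exact`
#' distinguishes exact lengths from lower bounds).
#'
#' @return A data.frame.
#' @export
exonic_ies_candidates <- function() {
  path <- system.file("extdata", "exonic_ies_candidates.tsv",
                      package = "iesfinder", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA")
}
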