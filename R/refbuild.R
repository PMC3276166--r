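#' Build a concatenated MAC reference (conMAC)
#'
#' Concatenates MAC assembly contigs in order of decreasing length, with
#' blocks of N inserted between consecutive contigs, and records the offset
#' of each contig so that coordinates can be lifted between contig-local and
#' conMAC frames. Placing all contigs on one coordinate axis segregates
#' small, low-coverage scaffolds to the right edge of the reference and
#' gives genome-browser-style tracks a single sequence to live on.
#'
#' Contigs whose names appear in `exclude` (for example, an rDNA
#' minichromosome or the mitochondrial chromosome) are dropped before
#' ordering. Ties in length are broken lexicographically by name so the
#' layout is deterministic.
#'
#' @param contigs A named [Biostrings::DNAStringSet] (or named character
#'   vector) of assembly contigs. Names must be unique.
#' @param spacer_len Length in bp of the N spacer placed between
#'   consecutive contigs (default 10000). No spacer is appended after the
#'   last contig.
#' @param exclude Character vector of contig names to drop.
#' @return An object of class `ConMacReference`: a list with elements
#'   `contigs` (ordered `DNAStringSet`), `offsets` (named integer vector of
#'   1-based start coordinates on the conMAC), `lengths`, `spacer_len`,
#'   `total_length` and `sequence` (the concatenated [Biostrings::DNAString]).
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(A = "ACGTACGTAC", B = "ACGTA"))
#' ref <- build_conmac(ctg, spacer_len = 10)
#' ref$total_length  # 10 + 5 + one 10 bp spacer = 25
#' @export
build_conmac <- function(contigs, spacer_len = 10000L, exclude = character()) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (!is(contigs, "DNAStringSet")) {
    stop("'contigs' must be a named DNAStringSet or character vector")
  }
  nm <- names(contigs)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(nm)) stop("duplicate contig names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (spacer_len < 0) stop("'spacer_len' must be >= 0")
  contigs <- contigs[!(nm %in% exclude)]
  if (length(contigs) == 0L) stop("no contigs left after exclusion")
  len <- Biostrings::width(contigs)
  if (any(len == 0L)) stop("zero-length contig: ",
                           paste(names(contigs)[len == 0L], collapse = ", "))
  ord <- order(-len, names(contigs))
  contigs <- contigs[ord]
  len <- Biostrings::width(contigs)
  n <- length(contigs)
  offsets <- cumsum(c(1L, head(len, -1L) + spacer_len))
  names(offsets) <- names(contigs)
  total <- sum(len) + spacer_len * (n - 1L)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, by = 2L, length.out = n)] <- as.character(contigs)
  if (n > 1L) {
    pieces[seq(2L, by = 2L, length.out = n - 1L)] <-
      strrep("N", spacer_len)
  }
  seq <- Biostrings::DNAString(paste(pieces, collapse = ""))
  stopifnot(length(seq) == total)
  structure(
    list(contigs = contigs,
         offsets = offsets,
         lengths = setNames(len, names(contigs)),
         spacer_len = as.integer(spacer_len),
         total_length = as.integer(total),
         sequence = seq),
    class = "ConMacReference")
}

#' @export
print.ConMacReference <- function(x, ...) {
  cat(sprintf("ConMacReference: %d contigs, %s bp assembly + %s bp spacers = %s bp\n",
              length(x$contigs),
              format(sum(x$lengths), big.mark = ","),
              format(x$spacer_len * (length(x$contigs) - 1L), big.mark = ","),
              format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Contig spans on the conMAC axis
#'
#' @param ref A `ConMacReference`.
#' @return A named [IRanges::IRanges] with one range per contig (1-based,
#'   closed), in conMAC coordinates. Gaps between ranges are spacer.
#' @export
contig_ranges <- function(ref) {
  IRanges::IRanges(start = unname(ref$offsets),
                   width = unname(ref$lengths),
                   names = names(ref$offsets))
}

#' Lift contig-local coordinates to the conMAC
#'
#' @param ref A `ConMacReference`.
#' @param contig Character vector of contig names.
#' @param pos Integer vector of 1-based contig-local positions.
#' @return Integer vector of 1-based conMAC positions.
#' @export
lift_to_conmac <- function(ref, contig, pos) {
  if (length(contig) == 1L && length(pos) > 1L) contig <- rep(contig, length(pos))
  off <- ref$offsets[contig]
  if (anyNA(off)) stop("unknown contig: ",
                       paste(unique(contig[is.na(off)]), collapse = ", "))
  bad <- pos < 1L | pos > ref$lengths[contig]
  if (any(bad)) stop("position outside contig")
  unname(off + pos - 1L)
}

#' Lift conMAC coordinates back to contigs
#'
#' Positions that fall inside an N spacer block are reported with `NA`
#' contig and position and `in_spacer = TRUE`.
#'
#' @param ref A `ConMacReference`.
#' @param pos Integer vector of 1-based conMAC positions.
#' @return A data.frame with columns `conmac_pos`, `contig`, `pos`,
#'   `in_spacer`.
#' @export
lift_to_contig <- function(ref, pos) {
  if (any(pos < 1L | pos > ref$total_length)) {
    stop("conMAC position out of range")
  }
  cr <- contig_ranges(ref)
  hit <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), cr, select = "first")
  contig <- ifelse(is.na(hit), NA_character_, names(cr)[hit])
  local <- ifelse(is.na(hit), NA_integer_, pos - IRanges::start(cr)[hit] + 1L)
  data.frame(conmac_pos = pos, contig = contig, pos = as.integer(local),
             in_spacer = is.na(hit), stringsAsFactors = FALSE)
}

#' Is a conMAC position near a contig edge?
#'
#' One-end-mapping reads whose breakpoint lies near a contig (scaffold) edge
#' are alignment-truncation artifacts, not IES evidence, and are excluded
#' from site calling. Positions inside spacer blocks count as edge.
#'
#' @param ref A `ConMacReference`.
#' @param pos Integer vector of 1-based conMAC positions.
#' @param margin Distance in bp below which a position counts as near an
#'   edge (default 100).
#' @return Logical vector.
#' @export
is_near_contig_edge <- function(ref, pos, margin = 100L) {
  loc <- lift_to_contig(ref, pos)
  out <- rep(TRUE, length(pos))
  i <- !loc$in_spacer
  clen <- ref$lengths[loc$contig[i]]
  dist_edge <- pmin(loc$pos[i] - 1L, clen - loc$pos[i])
  out[i] <- dist_edge < margin
  out
}

#' Read assembly contigs from a multi-FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]. Names are truncated at the
#'   first whitespace, as genome browsers do.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a conMAC reference to FASTA plus an offset table
#'
#' @param ref A `ConMacReference`.
#' @param fasta Output FASTA path for the concatenated sequence (one record
#'   named `conMAC`).
#' @param offsets Output path for a tab-separated table with columns
#'   `contig`, `offset` (1-based conMAC start) and `length`.
#' @return Invisibly, the paths written.
#' @export
write_conmac <- function(ref, fasta, offsets) {
  ss <- Biostrings::DNAStringSet(ref$sequence)
  names(ss) <- "conMAC"
  Biostrings::writeXStringSet(ss, fasta)
  tab <- data.frame(contig = names(ref$offsets),
                    offset = unname(ref$offsets),
                    length = unname(ref$lengths))
  write.table(tab, offsets, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, offsets = offsets))
}
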