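#' Read Sanger-style reads from FASTQ
#'
#' @param path FASTQ path (Sanger/phred+33 quality encoding).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping the (empty) mcols it attaches itself
  # during FASTQ import; that is noise for callers
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns .* dropped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Write reads to FASTQ
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Construct a quality-scaled read set from characters and scores
#'
#' Convenience constructor used by the simulator and in tests.
#'
#' @param seqs Named character vector of read sequences.
#' @param quals List (or single vector, recycled) of integer phred scores,
#'   one per base.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
make_reads <- function(seqs, quals) {
  ss <- Biostrings::DNAStringSet(seqs)
  if (length(ss) == 0L) {
    return(Biostrings::QualityScaledDNAStringSet(
      ss, Biostrings::PhredQuality(character())))
  }
  if (!is.list(quals)) quals <- rep(list(quals), length(ss))
  quals <- mapply(function(q, w) {
    if (length(q) == 1L) rep(q, w) else q
  }, quals, Biostrings::width(ss), SIMPLIFY = FALSE)
  qs <- Biostrings::PhredQuality(
    sapply(quals, function(q) rawToChar(as.raw(pmin(q, 93L) + 33L))))
  Biostrings::QualityScaledDNAStringSet(ss, qs)
}

# Integer phred scores per read, as a plain list.
.qual_list <- function(reads) {
  lapply(as(Biostrings::quality(reads), "IntegerList"), as.integer)
}

#' Mate tag of paired Sanger reads
#'
#' Paired-end Sanger reads from the two ends of a cloned fragment follow a
#' `<clone>.b1` / `<clone>.g1` naming convention. This extracts the tag.
#'
#' @param ids Character vector of read names.
#' @return Character vector of tags (`"b1"`, `"g1"`, or `NA` when the name
#'   has no recognizable suffix).
#' @export
mate_tag <- function(ids) {
  tag <- sub("^.*\\.([bg]1)$", "\\1", ids)
  ifelse(grepl("\\.[bg]1$", ids), tag, NA_character_)
}

# Longest window of `q` with mean >= min_mean_q, leftmost on ties.
# With T[k] = sum(q[1..k]) - min_mean_q * k, the window (i, j] qualifies
# iff T[j] >= T[i]; scan j left to right, binary-searching the prefix
# minima of T (strictly decreasing by construction) for the leftmost
# admissible i. O(n log n).
.best_window <- function(q, min_mean_q) {
  n <- length(q)
  if (n == 0L) return(c(0L, 0L))
  T <- c(0, cumsum(q - min_mean_q))
  cand_idx <- integer(n + 1L)  # positions (0-based k) of strict prefix minima
  cand_val <- numeric(n + 1L)
  nc <- 1L
  cand_idx[1L] <- 0L
  cand_val[1L] <- T[1L]
  best_len <- 0L
  best_i <- 0L
  best_j <- 0L
  for (j in seq_len(n)) {
    tj <- T[j + 1L]
    if (tj < cand_val[nc]) {
      nc <- nc + 1L
      cand_idx[nc] <- j
      cand_val[nc] <- tj
    } else {
      # leftmost candidate with value <= tj; cand_val[1..nc] is decreasing
      lo <- 1L; hi <- nc
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (cand_val[mid] <= tj) hi <- mid else lo <- mid + 1L
      }
      i <- cand_idx[lo]
      if (j - i > best_len) {
        best_len <- j - i
        best_i <- i
        best_j <- j
      }
    }
  }
  c(best_i + 1L, best_j)  # 1-based [start, end]; c(1,0) means empty
}

#' Quality-trim reads to their best high-quality window
#'
#' For each read, retains the longest contiguous sub-read whose mean phred
#' quality is at least `min_mean_q` (leftmost window on ties); reads whose
#' best window is shorter than `min_len` are discarded. Averaging is on the
#' phred scale. When the whole read qualifies it is returned unchanged, so
#' the window criterion reproduces whole-read filtering for good reads.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param min_mean_q Minimum mean phred quality of the retained window
#'   (default 20).
#' @param min_len Minimum retained length in bp (default 50); shorter
#'   fragments cannot support the one-end-mapping logic downstream.
#' @return A list with `reads` (the trimmed, surviving reads) and `log`, a
#'   data.frame with one row per input read (`id`, `kept`, `start`, `end`,
#'   `reason`).
#' @export
quality_trim <- function(reads, min_mean_q = 20, min_len = 50L) {
  quals <- .qual_list(reads)
  win <- t(vapply(quals, .best_window, integer(2L), min_mean_q = min_mean_q))
  len <- win[, 2L] - win[, 1L] + 1L
  keep <- len >= min_len
  log <- data.frame(id = names(reads),
                    kept = keep,
                    start = ifelse(keep, win[, 1L], NA_integer_),
                    end = ifelse(keep, win[, 2L], NA_integer_),
                    reason = ifelse(keep, "",
                                    sprintf("best Q%g window %d bp < %d bp",
                                            min_mean_q, pmax(len, 0L), min_len)),
                    stringsAsFactors = FALSE)
  trimmed <- IRanges::narrow(reads[keep],
                             start = win[keep, 1L], end = win[keep, 2L])
  list(reads = trimmed, log = log)
}

# Longest terminal overlap (>= min_match) between a read end and a vector
# prefix or suffix. `end` is "left" (read prefix) or "right" (read suffix).
.terminal_vector_match <- function(read_chr, vec_chr, min_match, end) {
  kmax <- min(nchar(read_chr), nchar(vec_chr))
  if (kmax < min_match) return(0L)
  best <- 0L
  for (k in kmax:min_match) {
    term <- if (end == "left") substr(read_chr, 1L, k)
            else substr(read_chr, nchar(read_chr) - k + 1L, nchar(read_chr))
    if (term == substr(vec_chr, 1L, k) ||
        term == substr(vec_chr, nchar(vec_chr) - k + 1L, nchar(vec_chr))) {
      best <- k
      break
    }
  }
  best
}

#' Remove cloning-vector sequence from read ends
#'
#' Removes from each read end the longest terminal segment that exactly
#' matches a prefix or suffix of any supplied vector sequence (both
#' orientations of the vector are searched). Reads that still contain an
#' internal vector k-mer after terminal trimming are left unchanged in
#' sequence but flagged, for exclusion or inspection downstream.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param vector_seqs Character vector (or `DNAStringSet`) of vector
#'   sequences.
#' @param min_match Minimum exact terminal match length in bp (default 10;
#'   must be at least 8 to avoid chance hits).
#' @return A list with `reads` (trimmed set, possibly containing
#'   zero-length reads) and `log` (data.frame: `id`, `left_trim`,
#'   `right_trim`, `internal_hit`).
#' @export
trim_vector <- function(reads, vector_seqs, min_match = 10L) {
  if (min_match < 8L) stop("'min_match' must be >= 8")
  vecs <- toupper(as.character(vector_seqs))
  vecs <- unique(c(vecs, vapply(vecs, .revcomp_chr, character(1L))))
  seqs <- as.character(reads)
  n <- length(seqs)
  left <- integer(n); right <- integer(n)
  for (i in seq_len(n)) {
    left[i] <- max(vapply(vecs, .terminal_vector_match, integer(1L),
                          read_chr = seqs[i], min_match = min_match,
                          end = "left"))
    rest <- substr(seqs[i], left[i] + 1L, nchar(seqs[i]))
    right[i] <- max(vapply(vecs, .terminal_vector_match, integer(1L),
                           read_chr = rest, min_match = min_match,
                           end = "right"))
  }
  new_start <- left + 1L
  new_end <- nchar(seqs) - right
  empty <- new_end < new_start   # fully-vector reads collapse to empty
  new_start[empty] <- 1L
  new_end[empty] <- 0L
  trimmed <- IRanges::narrow(reads, start = new_start, end = new_end)
  # internal hits: any vector min_match-mer inside the remaining sequence
  kmers <- unlist(lapply(vecs, function(v) {
    if (nchar(v) < min_match) return(character())
    substring(v, seq_len(nchar(v) - min_match + 1L),
              min_match:nchar(v))
  }))
  kmers <- unique(kmers)
  internal <- rep(FALSE, n)
  if (length(kmers)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    tseq <- Biostrings::DNAStringSet(as.character(trimmed))
    cnt <- Biostrings::vcountPDict(pd, tseq, collapse = 2L)
    internal <- cnt > 0L
  }
  list(reads = trimmed,
       log = data.frame(id = names(reads), left_trim = left,
                        right_trim = right, internal_hit = internal,
                        stringsAsFactors = FALSE))
}
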