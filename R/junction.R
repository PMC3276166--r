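#' Construct a junction model
#'
#' A MAC junction is decomposed into a left flank, the microhomology that
#' was present at both IES boundaries in the MIC and retained as a single
#' copy in the MAC, and a right flank. The MAC junction sequence is always
#' `left_flank + microhomology + right_flank`.
#'
#' @param left_flank,microhomology,right_flank Character scalars (the
#'   microhomology may be empty for blunt joins).
#' @param ies_seq Optional full IES sequence (the excised MIC segment,
#'   including one microhomology copy).
#' @param ies_len Optional IES length in bp; with `ies_exact = FALSE` it is
#'   a lower bound.
#' @param ies_exact Logical; is `ies_len` exact?
#' @param flagged Logical; set when the junction could not be reconstructed
#'   consistently from the reads.
#' @return A list of class `JunctionModel` with additionally `has_TA` and
#'   `has_TTAA` set by [detect_motifs()].
#' @export
junction_model <- function(left_flank, microhomology, right_flank,
                           ies_seq = NA_character_, ies_len = NA_integer_,
                           ies_exact = NA, flagged = FALSE) {
  jm <- structure(list(left_flank = tolower(left_flank),
                       microhomology = toupper(microhomology),
                       right_flank = tolower(right_flank),
                       has_TA = NA, has_TTAA = NA,
                       ies_seq = ies_seq,
                       ies_len = as.integer(ies_len),
                       ies_exact = ies_exact,
                       flagged = flagged),
                  class = "JunctionModel")
  detect_motifs(jm)
}

#' @export
print.JunctionModel <- function(x, ...) {
  cat(render_junction(x),
      if (isTRUE(x$flagged)) " [flagged]" else "",
      sprintf("  TA:%s TTAA:%s", x$has_TA, x$has_TTAA),
      if (!is.na(x$ies_len)) {
        sprintf("  IES %s%d bp", if (isTRUE(x$ies_exact)) "" else ">=",
                x$ies_len)
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Render a junction model as a compact string
#'
#' Flanking MAC-destined sequence is lowercase, retained microhomology
#' uppercase; flanks joined without microhomology are separated by a slash.
#'
#' @param jm A `JunctionModel`.
#' @return A string such as `"ttaTTAAtgg"` or `"atat/cctg"`.
#' @export
render_junction <- function(jm) {
  if (nchar(jm$microhomology) == 0L) {
    paste0(jm$left_flank, "/", jm$right_flank)
  } else {
    paste0(jm$left_flank, jm$microhomology, jm$right_flank)
  }
}

#' Parse a rendered junction string
#'
#' Inverse of [render_junction()]: lowercase runs are flanks, a single
#' uppercase run is the retained microhomology, a slash marks a blunt join.
#'
#' @param x Character vector of junction strings.
#' @return A list of `JunctionModel` objects (a single object when `x` has
#'   length 1).
#' @export
parse_junction <- function(x) {
  one <- function(s) {
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || grepl("[A-Z]", s)) {
        stop("malformed junction string: ", s)
      }
      return(junction_model(parts[1L], "", parts[2L]))
    }
    m <- regmatches(s, regexec("^([acgt]*)([ACGT]+)([acgt]*)$", s))[[1L]]
    if (length(m) != 4L) stop("malformed junction string: ", s)
    junction_model(m[2L], m[3L], m[4L])
  }
  out <- lapply(x, one)
  if (length(out) == 1L) out[[1L]] else out
}

#' Flag TA / TTAA motifs in the retained microhomology
#'
#' The TTAA tetranucleotide is the cleavage motif of domesticated
#' piggyBac-like transposases implicated in precise IES excision; TA is its
#' core dinucleotide.
#'
#' @param jm A `JunctionModel`.
#' @return The model with `has_TA` and `has_TTAA` set.
#' @export
detect_motifs <- function(jm) {
  mh <- toupper(jm$microhomology)
  jm$has_TTAA <- grepl("TTAA", mh, fixed = TRUE)
  jm$has_TA <- grepl("TA", mh, fixed = TRUE)
  jm
}

#' Compute boundary microhomology from MIC and MAC sequences
#'
#' Given the MIC sequence crossing the left IES boundary (`mic_left`,
#' anchored so that it starts at the same position as `mac_junction` and
#' runs into the IES), the MIC sequence crossing the right boundary
#' (`mic_right`, anchored to end with `mac_junction` and running back into
#' the IES), and the MAC junction sequence itself, the microhomology is the
#' longest string (at most `max_mh` bp) that terminates the MAC-matching
#' portion of both boundaries and is retained once in the MAC junction:
#' operationally, the overlap of the longest common prefix of
#' (`mic_left`, `mac_junction`) with the longest common suffix of
#' (`mic_right`, `mac_junction`). An overlap of zero is a blunt join; a
#' negative overlap (the two matching portions do not meet) or an overlap
#' exceeding `max_mh` leaves the junction flagged as not reconstructable.
#'
#' @param mic_left,mic_right,mac_junction Character scalars (case
#'   insensitive).
#' @param max_mh Maximum microhomology length in bp (default 9, matching
#'   the site-calling convergence window).
#' @param flank_width Display width of the flanks in the returned model
#'   (default 3).
#' @return A `JunctionModel`.
#' @export
compute_microhomology <- function(mic_left, mic_right, mac_junction,
                                  max_mh = 9L, flank_width = 3L) {
  ml <- toupper(mic_left); mr <- toupper(mic_right)
  mac <- toupper(mac_junction)
  n <- nchar(mac)
  p <- .lcp_len(ml, mac)   # MAC-matching portion of the left boundary
  s <- .lcs_len(mr, mac)   # MAC-matching portion of the right boundary
  o <- p + s - n           # bp of the MAC junction matched from both sides
  if (o < 0L || o > max_mh) {
    jm <- junction_model(substr(mac, max(1L, p - flank_width + 1L), p), "",
                         substr(mac, p + 1L, min(n, p + flank_width)),
                         flagged = TRUE)
    return(jm)
  }
  mh_start <- n - s + 1L
  mh_end <- p
  mh <- if (o >= 1L) substr(mac, mh_start, mh_end) else ""
  lf <- substr(mac, max(1L, mh_start - flank_width), mh_start - 1L)
  rf <- substr(mac, mh_end + 1L, min(n, mh_end + flank_width))
  junction_model(lf, mh, rf)
}

#' Assemble an IES core from one-end read extensions
#'
#' L-read clip sequences are prefixes of the IES core (the excised segment
#' minus the retained microhomology copy); R-read clips, in reference
#' orientation, are suffixes of it. If a suffix of the longest L extension
#' matches a prefix of the longest R extension over at least `min_olap` bp
#' (allowing a mismatch fraction up to `max_mismatch`), the merge
#' reconstructs the full core exactly; otherwise only a lower bound on the
#' core length is known.
#'
#' @param l_exts,r_exts Character vectors of clip sequences from supporting
#'   L and R reads.
#' @param min_olap Minimum merge overlap in bp (default 20).
#' @param max_mismatch Maximum mismatch fraction tolerated in the overlap
#'   (default 0.05).
#' @return A list: `seq` (assembled core or `NA`), `len` (exact core length
#'   or lower bound), `exact` (logical), `ambiguous` (logical; several
#'   incompatible overlaps).
#' @export
assemble_ies <- function(l_exts, r_exts, min_olap = 20L,
                         max_mismatch = 0.05) {
  l_exts <- l_exts[!is.na(l_exts) & nzchar(l_exts)]
  r_exts <- r_exts[!is.na(r_exts) & nzchar(r_exts)]
  lb <- max(c(nchar(l_exts), nchar(r_exts), 0L))
  if (length(l_exts) == 0L || length(r_exts) == 0L) {
    return(list(seq = NA_character_, len = lb, exact = FALSE,
                ambiguous = FALSE))
  }
  lx <- toupper(l_exts[which.max(nchar(l_exts))])
  rx <- toupper(r_exts[which.max(nchar(r_exts))])
  lv <- strsplit(lx, "")[[1L]]
  rv <- strsplit(rx, "")[[1L]]
  kmax <- min(length(lv), length(rv))
  if (kmax < min_olap) {
    return(list(seq = NA_character_, len = lb, exact = FALSE,
                ambiguous = FALSE))
  }
  valid <- integer()
  for (k in seq(kmax, min_olap)) {
    mm <- sum(lv[(length(lv) - k + 1L):length(lv)] != rv[seq_len(k)])
    if (mm <= max_mismatch * k) valid <- c(valid, k)
  }
  if (length(valid) == 0L) {
    return(list(seq = NA_character_, len = lb, exact = FALSE,
                ambiguous = FALSE))
  }
  if (length(valid) > 1L) {
    return(list(seq = NA_character_, len = lb, exact = FALSE,
                ambiguous = TRUE))
  }
  k <- valid[1L]
  merged <- paste0(lx, substr(rx, k + 1L, nchar(rx)))
  list(seq = merged, len = nchar(merged), exact = TRUE, ambiguous = FALSE)
}

#' Group MAC junction sequences by length and identity
#'
#' Heterogeneous IES boundaries produce several distinct MAC junctions at
#' one locus across excision events; this summarizes the heterogeneity.
#'
#' @param junctions Character vector of junction sequences.
#' @return A list: `n_lengths`, `n_sequences`, `by_length` (table),
#'   `by_sequence` (table).
#' @export
compare_junctions <- function(junctions) {
  if (length(junctions) == 0L) stop("need at least one junction")
  junctions <- toupper(junctions)
  list(n_lengths = length(unique(nchar(junctions))),
       n_sequences = length(unique(junctions)),
       by_length = table(nchar(junctions)),
       by_sequence = table(junctions))
}

#' Characterize the junctions of called sites
#'
#' For each called site, reads the retained microhomology straight off the
#' conMAC (for win1 sites the window between the convergent breakpoints is
#' exactly the retained copy), flags TA/TTAA motifs, renders the junction
#' string, and attempts full IES assembly from the supporting reads' clip
#' sequences.
#'
#' @param sites Site data.frame from [call_sites()].
#' @param evidence Breakpoint data.frame from [collect_breakpoints()] with
#'   clip sequences attached.
#' @param ref A `ConMacReference`.
#' @param flank_width Flank display width in bp (default 3).
#' @param min_olap Passed to [assemble_ies()].
#' @return The `sites` data.frame with added columns `microhomology`,
#'   `junction`, `has_TA`, `has_TTAA`, `ies_len`, `ies_exact`, `ies_seq`.
#' @export
site_junctions <- function(sites, evidence, ref, flank_width = 3L,
                           min_olap = 20L) {
  n <- nrow(sites)
  sites$microhomology <- sites$junction <- sites$ies_seq <- NA_character_
  sites$has_TA <- sites$has_TTAA <- sites$ies_exact <- NA
  sites$ies_len <- NA_integer_
  if (n == 0L) return(sites)
  seq_chr <- as.character(ref$sequence)
  nseq <- nchar(seq_chr)
  for (i in seq_len(n)) {
    ws <- sites$window_start[i]; we <- sites$window_end[i]
    if (sites$category[i] == "win1") {
      # window [jR, jL]: positions ws+1..we are the retained microhomology
      mh <- if (we > ws) substr(seq_chr, ws + 1L, we) else ""
    } else mh <- ""
    lf <- substr(seq_chr, max(1L, ws - flank_width + 1L), ws)
    rf <- substr(seq_chr, we + 1L, min(nseq, we + flank_width))
    jm <- junction_model(lf, mh, rf)
    sites$microhomology[i] <- jm$microhomology
    sites$junction[i] <- render_junction(jm)
    sites$has_TA[i] <- jm$has_TA
    sites$has_TTAA[i] <- jm$has_TTAA
    l_ids <- strsplit(sites$l_reads[i], ",", fixed = TRUE)[[1L]]
    r_ids <- strsplit(sites$r_reads[i], ",", fixed = TRUE)[[1L]]
    lx <- evidence$clip_seq[evidence$read_id %in% l_ids & evidence$side == "L"]
    rx <- evidence$clip_seq[evidence$read_id %in% r_ids & evidence$side == "R"]
    asm <- assemble_ies(lx, rx, min_olap = min_olap)
    if (isTRUE(asm$exact)) {
      # the excised segment is the core plus one microhomology copy
      sites$ies_seq[i] <- paste0(asm$seq, jm$microhomology)
      sites$ies_len[i] <- nchar(sites$ies_seq[i])
      sites$ies_exact[i] <- TRUE
    } else {
      sites$ies_len[i] <- asm$len + nchar(jm$microhomology)
      sites$ies_exact[i] <- FALSE
    }
  }
  sites
}
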