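#' Configuration for the synthetic MIC/MAC simulator
#'
#' The generator emulates the study system: a ~75% AT genome, Sanger-style
#' paired-end reads from ~8 kbp cloned fragments, and two planted IES
#' classes - a short class (100-500 bp) with precise boundaries and 3-4 bp
#' of TTAA-containing microhomology retained in the MAC, and a long class
#' (1-3 kbp) with heterogeneous, blunt boundaries.
#'
#' @param seed Integer seed controlling all randomness.
#' @param contig_lengths MAC contig lengths in bp (descending or not;
#'   ordering happens in [build_conmac()]).
#' @param at_fraction Genome AT fraction (default 0.75).
#' @param spacer_len Spacer length for the conMAC (default 10000).
#' @param n_ies Number of IES to plant.
#' @param class_mix Fraction of IES in the short precise class.
#' @param short_len_range,long_len_range IES length ranges in bp.
#' @param mh_len_range Microhomology length range for the short class.
#' @param p_ttaa Probability that a short-class microhomology is the TTAA
#'   motif.
#' @param n_alt_boundaries Alternative excision boundaries per long-class
#'   IES (used when simulating excision-event junction heterogeneity).
#' @param frag_len_mean,frag_len_sd Cloned fragment length model in bp.
#' @param read_len_mean,read_len_sd,read_len_range Sanger read length model.
#' @param error_rate Per-base substitution error rate (0 = error free).
#' @param coverage Uniform-mode sequence coverage (read bp per genome bp).
#' @param f Junction-mode per-side coverage probability (see
#'   [simulate_reads()]).
#' @param background_depth Junction-mode coverage of fully mapping
#'   background reads.
#' @param min_ies_sep Minimum separation between planted junctions in bp
#'   (must exceed the read length so one-end evidence stays independent).
#' @param edge_buffer Minimum distance of a junction from a contig end.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(200000L, 150000L, 100000L, 50000L),
                       at_fraction = 0.75,
                       spacer_len = 10000L,
                       n_ies = 50L,
                       class_mix = 0.5,
                       short_len_range = c(100L, 500L),
                       long_len_range = c(1000L, 3000L),
                       mh_len_range = c(3L, 4L),
                       p_ttaa = 0.75,
                       n_alt_boundaries = 3L,
                       frag_len_mean = 8000, frag_len_sd = 800,
                       read_len_mean = 750, read_len_sd = 80,
                       read_len_range = c(500L, 1000L),
                       error_rate = 0,
                       coverage = 0.25,
                       f = 0.25,
                       background_depth = 0.3,
                       min_ies_sep = 1500L,
                       edge_buffer = 1200L) {
  cfg <- as.list(environment())
  stopifnot(at_fraction >= 0, at_fraction <= 1,
            class_mix >= 0, class_mix <= 1,
            p_ttaa >= 0, p_ttaa <= 1,
            f > 0, f <= 1,
            short_len_range[1L] <= short_len_range[2L],
            long_len_range[1L] <= long_len_range[2L],
            mh_len_range[1L] <= mh_len_range[2L])
  structure(cfg, class = "sim_config")
}

.random_dna <- function(n, at) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

.random_mh <- function(len_range, p_ttaa, at) {
  if (runif(1L) < p_ttaa) return("TTAA")
  len <- sample(seq(len_range[1L], len_range[2L]), 1L)
  mh <- .random_dna(len, at)
  # the TA core dinucleotide is near-universal at short-IES boundaries
  if (!grepl("TA", mh, fixed = TRUE)) {
    pos <- sample(len - 1L, 1L)
    substr(mh, pos, pos + 1L) <- "TA"
  }
  mh
}

# Draw a g-base guard block with no usable homology to the flank
# continuation. Planted IES boundaries must be locally non-homologous to
# the sequence the junction joins them to: chance homology there (direct or
# shifted by a small indel) lets a maximal local alignment extend past the
# junction, making the true excision position itself ambiguous. The block
# is redrawn until it has at most `max_match` matches against the flank
# continuation at every alignment shift in -3..3, so any extension across
# it is strictly score-negative under the default scoring.
.draw_guard <- function(ref_context, g, at, from = c("start", "end"),
                        max_match = 2L) {
  from <- match.arg(from)
  rv <- strsplit(toupper(ref_context), "", fixed = TRUE)[[1L]]
  pad <- (length(rv) - g) %/% 2L
  ref0 <- rv[(pad + 1L):(pad + g)]          # shift-0 counterpart
  adj <- if (from == "start") 1L else g     # junction-adjacent guard base
  for (try in 1:500) {
    guard <- sample(c("A", "T", "C", "G"), g, replace = TRUE,
                    prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
    if (guard[adj] == ref0[adj]) {
      guard[adj] <- sample(setdiff(c("A", "T", "C", "G"), ref0[adj]), 1L)
    }
    ok <- all(vapply(-pad:pad, function(s) {
      sum(guard == rv[(pad + 1L + s):(pad + g + s)]) <= max_match
    }, logical(1L)))
    if (ok) return(paste(guard, collapse = ""))
  }
  # worst-case fallback: mismatch every shift-0 position
  guard <- vapply(ref0, function(b) {
    sample(setdiff(c("A", "T", "C", "G"), b), 1L)
  }, character(1L))
  paste(guard, collapse = "")
}

#' Simulate a MAC assembly and a MIC genome with planted IES
#'
#' Generates random AT-rich MAC contigs, then derives the MIC by inserting
#' IES: a short-class IES duplicates a 3-4 bp microhomology `m` at both
#' boundaries (`MAC = L m R`, `MIC = L m core m R`) of which the MAC
#' retains a single copy; a long-class IES is inserted bluntly and carries
#' a set of alternative excision boundaries. The first and last core base
#' are redrawn when they would extend the boundary duplication by chance.
#' Junctions are placed with a guaranteed minimum separation and away from
#' contig edges so that planted evidence is attributable to one junction.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ies_sim`: `mac` and `mic` (named
#'   [Biostrings::DNAStringSet]s), `ref` (the `ConMacReference` built from
#'   `mac`), `truth` (data.frame: `ies_id`, `contig`, `mac_junction`
#'   (contig-local, last retained base before the excised segment),
#'   `conmac_junction`, `mic_start`, `mic_end` (excised MIC segment,
#'   contig-local), `ies_len`, `class`, `microhomology`, `ies_seq`,
#'   `alt_boundaries`), and `cfg`.
#' @export
simulate_genomes <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  lens <- sort(as.integer(cfg$contig_lengths), decreasing = TRUE)
  n_ctg <- length(lens)
  ctg_names <- sprintf("scf_%d", seq_len(n_ctg))
  mac <- setNames(vapply(lens, .random_dna, character(1L),
                         at = cfg$at_fraction), ctg_names)

  # apportion IES to contigs by length (largest remainder)
  share <- cfg$n_ies * lens / sum(lens)
  n_per <- floor(share)
  rem <- cfg$n_ies - sum(n_per)
  if (rem > 0L) {
    extra <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }

  truth <- list()
  mic <- character(n_ctg)
  for (ci in seq_len(n_ctg)) {
    G <- lens[ci]
    k <- n_per[ci]
    seq_chr <- mac[[ci]]
    if (k == 0L) { mic[ci] <- seq_chr; next }
    lo <- cfg$edge_buffer
    hi <- G - cfg$edge_buffer
    cw <- (hi - lo) / k
    if (cw < cfg$min_ies_sep + 1) {
      stop("contig ", ctg_names[ci], " too short for ", k,
           " IES at min separation ", cfg$min_ies_sep)
    }
    j <- as.integer(floor(lo + (seq_len(k) - 1L) * cw +
                            runif(k, 0, cw - cfg$min_ies_sep)))
    pieces <- character()
    prev <- 1L
    for (ii in seq_len(k)) {
      short <- runif(1L) < cfg$class_mix
      if (short) {
        mh <- .random_mh(cfg$mh_len_range, cfg$p_ttaa, cfg$at_fraction)
        ies_len <- sample(seq(cfg$short_len_range[1L],
                              cfg$short_len_range[2L]), 1L)
        ies_len <- max(ies_len, nchar(mh) + 30L)
        alt <- "0,0"
      } else {
        mh <- ""
        ies_len <- sample(seq(cfg$long_len_range[1L],
                              cfg$long_len_range[2L]), 1L)
        shifts <- cbind(c(0L, sample(-10:10, cfg$n_alt_boundaries - 1L,
                                     replace = TRUE)),
                        c(0L, sample(-10:10, cfg$n_alt_boundaries - 1L,
                                     replace = TRUE)))
        alt <- paste(apply(shifts, 1L, paste, collapse = ","),
                     collapse = ";")
      }
      lm <- nchar(mh)
      jj <- j[ii]
      if (lm > 0L) {
        substr(seq_chr, jj - lm + 1L, jj) <- mh  # retained copy in the MAC
      }
      core_len <- ies_len - lm
      core <- .random_dna(core_len, cfg$at_fraction)
      # boundary identifiability guards: the first g core bases carry no
      # usable homology to the MAC continuation right of the junction, the
      # last g none to the MAC bases left of the retained microhomology
      g <- min(8L, core_len %/% 2L)
      pad <- 3L
      substr(core, 1L, g) <- .draw_guard(
        substr(seq_chr, jj + 1L - pad, jj + g + pad), g, cfg$at_fraction,
        from = "start")
      substr(core, core_len - g + 1L, core_len) <- .draw_guard(
        substr(seq_chr, jj - lm - g + 1L - pad, jj - lm + pad), g,
        cfg$at_fraction, from = "end")
      truth[[length(truth) + 1L]] <- data.frame(
        contig = ctg_names[ci], mac_junction = jj,
        ies_len = as.integer(ies_len),
        class = if (short) "short_precise" else "long_heterogeneous",
        microhomology = mh, core = core, alt_boundaries = alt,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, substr(seq_chr, prev, jj), core, mh)
      prev <- jj + 1L
    }
    pieces <- c(pieces, substr(seq_chr, prev, G))
    mic[ci] <- paste(pieces, collapse = "")
    mac[[ci]] <- seq_chr  # with retained microhomology copies written in
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(), mac_junction = integer(),
               ies_len = integer(), class = character(),
               microhomology = character(), core = character(),
               alt_boundaries = character(), stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth$ies_id <- sprintf("ies_%03d", seq_len(nrow(truth)))
    # MIC coordinates of the excised segment (core + right microhomology
    # copy): earlier insertions on the same contig shift later ones right
    shift <- stats::ave(truth$ies_len, truth$contig,
                        FUN = function(l) cumsum(c(0L, head(l, -1L))))
    truth$mic_start <- truth$mac_junction + as.integer(shift) + 1L
    truth$mic_end <- truth$mic_start + truth$ies_len - 1L
    truth$ies_seq <- paste0(truth$core, truth$microhomology)
  } else {
    truth$ies_id <- character()
    truth$mic_start <- truth$mic_end <- integer()
    truth$ies_seq <- character()
  }
  mac_set <- Biostrings::DNAStringSet(unlist(mac))
  mic_set <- Biostrings::DNAStringSet(setNames(mic, ctg_names))
  ref <- build_conmac(mac_set, spacer_len = cfg$spacer_len)
  if (nrow(truth)) {
    truth$conmac_junction <- lift_to_conmac(ref, truth$contig,
                                            truth$mac_junction)
  } else truth$conmac_junction <- integer()
  rownames(truth) <- NULL
  structure(list(mac = mac_set, mic = mic_set, ref = ref,
                 truth = truth, cfg = cfg),
            class = "ies_sim")
}

#' @export
print.ies_sim <- function(x, ...) {
  cat(sprintf("ies_sim: %d MAC contigs (%s bp), %d planted IES (%d short, %d long)\n",
              length(x$mac), format(sum(Biostrings::width(x$mac)),
                                    big.mark = ","),
              nrow(x$truth), sum(x$truth$class == "short_precise"),
              sum(x$truth$class == "long_heterogeneous")))
  invisible(x)
}

.trunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, as.integer(round(rnorm(n, mean, sd)))))
}

# Apply substitution errors; returns character vector.
.mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < error_rate)
    if (length(hit)) {
      v <- strsplit(s, "", fixed = TRUE)[[1L]]
      v[hit] <- vapply(v[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1L))
      s <- paste(v, collapse = "")
    }
    s
  }, character(1L), USE.NAMES = FALSE)
}

.read_qual <- function(error_rate) {
  if (error_rate <= 0) 40L else max(2L, as.integer(round(-10 * log10(error_rate))))
}

#' Simulate Sanger-style reads from a MIC genome
#'
#' Two placement modes:
#'
#' * `"uniform"`: paired-end (b1/g1) reads from fragments of length
#'   ~Normal(`frag_len_mean`, `frag_len_sd`) placed uniformly on the MIC,
#'   at total sequence coverage `cfg$coverage`. This is the realistic,
#'   Lander-Waterman placement.
#' * `"junction"`: each planted junction side independently receives one
#'   informative one-end read with probability exactly `cfg$f` (its
#'   MAC-matching anchor and its clip into the IES drawn within the valid
#'   geometry), plus fully mapping background reads at coverage
#'   `cfg$background_depth` placed inside MAC-destined segments. This mode
#'   makes the per-side coverage probability an exact, controllable
#'   quantity, which the two-sided (win1) detection law requires.
#'
#' @param sim An `ies_sim` from [simulate_genomes()].
#' @param mode Placement mode (see above).
#' @param cfg Simulator configuration; defaults to `sim$cfg`.
#' @param seed Optional seed overriding `cfg$seed` (use when drawing
#'   several independent read sets from one genome).
#' @return A list: `reads` (a [Biostrings::QualityScaledDNAStringSet]) and
#'   `placement` (data.frame: `read_id`, `contig`, `mic_start`, `mic_end`,
#'   `strand`).
#' @export
simulate_reads <- function(sim, mode = c("uniform", "junction"),
                           cfg = sim$cfg, seed = NULL) {
  mode <- match.arg(mode)
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  mic <- as.character(sim$mic)
  out_seq <- character(); out_id <- character()
  pl <- list()
  emit <- function(contig, s, e, strand, id) {
    sq <- substr(mic[[contig]], s, e)
    if (strand == "-") sq <- .revcomp_chr(sq)
    out_seq[[length(out_seq) + 1L]] <<- sq
    out_id[[length(out_id) + 1L]] <<- id
    pl[[length(pl) + 1L]] <<- data.frame(
      read_id = id, contig = contig, mic_start = s, mic_end = e,
      strand = strand, stringsAsFactors = FALSE)
  }

  if (mode == "uniform") {
    for (ctg in names(mic)) {
      G <- nchar(mic[[ctg]])
      n_frag <- max(0L, round(cfg$coverage * G / (2 * cfg$read_len_mean)))
      if (n_frag == 0L) next
      fl <- .trunc_norm(n_frag, cfg$frag_len_mean, cfg$frag_len_sd,
                        max(cfg$read_len_range), G)
      fs <- floor(runif(n_frag, 1, G - fl + 1))
      rl1 <- .trunc_norm(n_frag, cfg$read_len_mean, cfg$read_len_sd,
                         cfg$read_len_range[1L], cfg$read_len_range[2L])
      rl2 <- .trunc_norm(n_frag, cfg$read_len_mean, cfg$read_len_sd,
                         cfg$read_len_range[1L], cfg$read_len_range[2L])
      for (i in seq_len(n_frag)) {
        base <- sprintf("%s_frg%05d", ctg, i)
        emit(ctg, fs[i], fs[i] + rl1[i] - 1L, "+", paste0(base, ".b1"))
        emit(ctg, fs[i] + fl[i] - rl2[i], fs[i] + fl[i] - 1L, "-",
             paste0(base, ".g1"))
      }
    }
  } else {
    tr <- sim$truth
    min_anchor <- 100L
    min_clip <- 21L
    for (i in seq_len(nrow(tr))) {
      ctg <- tr$contig[i]
      G <- nchar(mic[[ctg]])
      same <- tr[tr$contig == ctg, , drop = FALSE]
      left_bound <- max(c(1L, same$mic_end[same$mic_end < tr$mic_start[i]] + 1L))
      right_bound <- min(c(G, same$mic_start[same$mic_start > tr$mic_end[i]] - 1L))
      core_len <- tr$ies_len[i] - nchar(tr$microhomology[i])
      jm <- tr$mic_start[i] - 1L  # last MAC-destined base before excision
      if (runif(1L) < cfg$f) {    # L-side informative read
        rl <- .trunc_norm(1L, cfg$read_len_mean, cfg$read_len_sd,
                          cfg$read_len_range[1L], cfg$read_len_range[2L])
        cl <- sample(seq(min_clip, max(min_clip, min(core_len, rl - min_anchor))), 1L)
        a <- min(rl - cl, jm - left_bound + 1L - 10L)
        emit(ctg, jm - a + 1L, jm + cl, sample(c("+", "-"), 1L),
             sprintf("%s_L.b1", tr$ies_id[i]))
      }
      if (runif(1L) < cfg$f) {    # R-side informative read
        rl <- .trunc_norm(1L, cfg$read_len_mean, cfg$read_len_sd,
                          cfg$read_len_range[1L], cfg$read_len_range[2L])
        cl <- sample(seq(min_clip, max(min_clip, min(core_len, rl - min_anchor))), 1L)
        a <- min(rl - cl, right_bound - tr$mic_end[i] - 10L)
        s <- tr$mic_start[i] + core_len - cl
        emit(ctg, s, tr$mic_end[i] + a, sample(c("+", "-"), 1L),
             sprintf("%s_R.b1", tr$ies_id[i]))
      }
    }
    if (cfg$background_depth > 0) {
      for (ctg in names(mic)) {
        G <- nchar(mic[[ctg]])
        same <- tr[tr$contig == ctg, , drop = FALSE]
        segs <- data.frame(
          s = c(1L, same$mic_end + 1L),
          e = c(same$mic_start - 1L, G))
        segs <- segs[segs$e - segs$s + 1L >= cfg$read_len_range[1L] + 2L, ,
                     drop = FALSE]
        if (nrow(segs) == 0L) next
        w <- segs$e - segs$s + 1L
        n_bg <- round(cfg$background_depth * sum(w) / cfg$read_len_mean)
        if (n_bg < 1L) next
        seg_i <- sample(nrow(segs), n_bg, replace = TRUE, prob = w)
        rl <- .trunc_norm(n_bg, cfg$read_len_mean, cfg$read_len_sd,
                          cfg$read_len_range[1L], cfg$read_len_range[2L])
        rl <- pmin(rl, w[seg_i])
        s <- floor(runif(n_bg, segs$s[seg_i], segs$e[seg_i] - rl + 1.0001))
        for (i in seq_len(n_bg)) {
          emit(ctg, s[i], s[i] + rl[i] - 1L, sample(c("+", "-"), 1L),
               sprintf("%s_bg%05d.b1", ctg, i))
        }
      }
    }
  }
  if (length(out_seq) == 0L) {
    return(list(reads = make_reads(setNames(character(), character()),
                                   list()),
                placement = data.frame(read_id = character(),
                                       contig = character(),
                                       mic_start = integer(),
                                       mic_end = integer(),
                                       strand = character(),
                                       stringsAsFactors = FALSE)))
  }
  seqs <- .mutate_seqs(unlist(out_seq), cfg$error_rate)
  names(seqs) <- unlist(out_id)
  reads <- make_reads(seqs, list(.read_qual(cfg$error_rate)))
  list(reads = reads, placement = do.call(rbind, pl))
}

#' Which planted junctions have informative read coverage?
#'
#' Determines, from read placement truth and the planted-IES table alone
#' (independently of the alignment pipeline), which junctions are covered
#' by a geometrically informative L and/or R read: at least `min_anchor`
#' MAC-destined bp on the mapping side, at least `min_clip` bp extending
#' into the excised segment, the clip ending inside it, and the anchor not
#' crossing a neighbouring junction.
#'
#' @param sim An `ies_sim`.
#' @param placement Placement data.frame from [simulate_reads()].
#' @param min_anchor,min_clip Geometry thresholds in bp.
#' @return The truth data.frame with logical columns `covered_l`,
#'   `covered_r` added.
#' @export
truth_side_coverage <- function(sim, placement, min_anchor = 60L,
                                min_clip = 20L) {
  tr <- sim$truth
  tr$covered_l <- tr$covered_r <- FALSE
  for (i in seq_len(nrow(tr))) {
    ctg <- tr$contig[i]
    G <- Biostrings::width(sim$mic)[match(ctg, names(sim$mic))]
    same <- tr[tr$contig == ctg, , drop = FALSE]
    left_bound <- max(c(1L, same$mic_end[same$mic_end < tr$mic_start[i]] + 1L))
    right_bound <- min(c(G, same$mic_start[same$mic_start > tr$mic_end[i]] - 1L))
    p <- placement[placement$contig == ctg, , drop = FALSE]
    jm <- tr$mic_start[i] - 1L
    tr$covered_l[i] <- any(p$mic_start >= left_bound &
                             p$mic_start <= jm - min_anchor + 1L &
                             p$mic_end >= jm + min_clip &
                             p$mic_end <= tr$mic_end[i])
    tr$covered_r[i] <- any(p$mic_end <= right_bound &
                             p$mic_end >= tr$mic_end[i] + min_anchor &
                             p$mic_start <= tr$mic_end[i] - min_clip + 1L &
                             p$mic_start >= tr$mic_start[i])
  }
  tr
}

#' Simulate MAC junction sequences across excision events
#'
#' For a long-class IES with heterogeneous boundaries, each excision event
#' picks one of the alternative boundary pairs; the resulting MAC junction
#' fragment (between fixed flanking anchor points, as a junction PCR clone
#' would capture it) varies in length and sequence across events.
#'
#' @param sim An `ies_sim`.
#' @param ies_id The IES to excise.
#' @param n_events Number of independent excision events.
#' @param anchor Distance of the fixed anchor points from the canonical
#'   boundaries in bp (default 20).
#' @return Character vector of junction fragments, one per event.
#' @export
excision_junctions <- function(sim, ies_id, n_events, anchor = 20L) {
  tr <- sim$truth[sim$truth$ies_id == ies_id, , drop = FALSE]
  if (nrow(tr) != 1L) stop("unknown ies_id: ", ies_id)
  alts <- do.call(rbind, lapply(strsplit(strsplit(tr$alt_boundaries,
                                                  ";")[[1L]], ","),
                                as.integer))
  mic <- as.character(sim$mic[[tr$contig]])
  p1 <- tr$mic_start - anchor          # fixed left anchor (MAC-destined)
  p2 <- tr$mic_end + anchor            # fixed right anchor
  vapply(seq_len(n_events), function(i) {
    k <- sample(nrow(alts), 1L)
    a <- tr$mic_start + alts[k, 1L]    # first excised base this event
    b <- tr$mic_end + alts[k, 2L]      # last excised base this event
    paste0(substr(mic, p1, a - 1L), substr(mic, b + 1L, p2))
  }, character(1L))
}

#' Score called sites against the planted truth
#'
#' A planted IES is recovered when a called site window lies within `tol`
#' bp of its MAC junction. Precision is the fraction of called sites
#' matching some planted junction (NA when nothing was called).
#'
#' @param sites Site data.frame from [call_sites()] (optionally with
#'   junction columns from [site_junctions()]).
#' @param sim An `ies_sim` (or its `truth` data.frame plus `ref`).
#' @param tol Matching tolerance in bp (default 9, the convergence window).
#' @return A list: `n_truth`, `n_called`, `recall` (named: win1, win2,
#'   win3, any), `precision` (named likewise), `positional_error` (signed
#'   bp, win1 matches), `mh_accuracy` (exact microhomology recovery among
#'   matched win1 sites, NA when junction columns are absent).
#' @export
evaluate_calls <- function(sites, sim, tol = 9L) {
  tr <- sim$truth
  jt <- tr$conmac_junction
  cats <- c("win1", "win2", "win3")
  dist_to <- function(ws, we, j) pmax(0L, pmax(ws - j, j - we))
  rec <- setNames(numeric(4L), c(cats, "any"))
  prec <- setNames(rep(NA_real_, 4L), c(cats, "any"))
  matched_mask <- function(sub) {
    if (nrow(sub) == 0L || length(jt) == 0L) return(rep(FALSE, length(jt)))
    vapply(jt, function(j) {
      any(dist_to(sub$window_start, sub$window_end, j) <= tol)
    }, logical(1L))
  }
  for (cc in cats) {
    sub <- sites[sites$category == cc, , drop = FALSE]
    rec[cc] <- if (length(jt)) mean(matched_mask(sub)) else NA_real_
    if (nrow(sub)) {
      prec[cc] <- mean(vapply(seq_len(nrow(sub)), function(s) {
        any(dist_to(sub$window_start[s], sub$window_end[s], jt) <= tol)
      }, logical(1L)))
    }
  }
  rec["any"] <- if (length(jt)) mean(matched_mask(sites)) else NA_real_
  if (nrow(sites)) {
    prec["any"] <- mean(vapply(seq_len(nrow(sites)), function(s) {
      any(dist_to(sites$window_start[s], sites$window_end[s], jt) <= tol)
    }, logical(1L)))
  }
  w1 <- sites[sites$category == "win1", , drop = FALSE]
  pe <- integer(); mh_ok <- logical()
  if (nrow(w1) && length(jt)) {
    for (s in seq_len(nrow(w1))) {
      d <- dist_to(w1$window_start[s], w1$window_end[s], jt)
      if (min(d) <= tol) {
        i <- which.min(d)
        pe <- c(pe, w1$window_end[s] - jt[i])
        if (!is.null(w1$microhomology)) {
          mh_ok <- c(mh_ok, identical(toupper(w1$microhomology[s]),
                                      toupper(tr$microhomology[i])))
        }
      }
    }
  }
  list(n_truth = length(jt), n_called = nrow(sites),
       recall = rec, precision = prec,
       positional_error = pe,
       mh_accuracy = if (length(mh_ok)) mean(mh_ok) else NA_real_)
}
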