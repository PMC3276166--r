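# Shared fixtures: everything is generated in code at test time.

# A tiny deterministic two-contig reference.
toy_ref <- function(spacer = 10000L) {
  set.seed(42)
  ctg <- Biostrings::DNAStringSet(c(
    A = paste(sample(c("A", "T", "C", "G"), 100, TRUE,
                     prob = c(.375, .375, .125, .125)), collapse = ""),
    B = paste(sample(c("A", "T", "C", "G"), 80, TRUE,
                     prob = c(.375, .375, .125, .125)), collapse = "")))
  build_conmac(ctg, spacer_len = spacer)
}

# Brute-force oracle: longest window with mean quality >= q, leftmost on
# ties, by enumerating all O(n^2) substrings.
brute_best_window <- function(quals, q) {
  n <- length(quals)
  best <- c(1L, 0L)
  for (len in n:1) {
    for (s in 1:(n - len + 1L)) {
      if (mean(quals[s:(s + len - 1L)]) >= q) {
        return(c(s, s + len - 1L))
      }
    }
  }
  best
}

# Brute-force oracle for boundary microhomology: enumerate every
# decomposition mac = X m Y with |m| = k (longest k first) and test that
# mic_left starts with X m and then diverges from the MAC, while mic_right
# ends with m Y having diverged just before. Independent of the lcp/lcs
# shortcut used by the implementation.
brute_microhomology <- function(mic_left, mic_right, mac_junction,
                                max_mh = 9L) {
  mac <- toupper(mac_junction)
  ml <- toupper(mic_left); mr <- toupper(mic_right)
  n <- nchar(mac)
  char_at <- function(s, i) substr(s, i, i)
  for (k in max_mh:1) {
    for (a in 0:(n - k)) {
      m <- substr(mac, a + 1L, a + k)
      pl <- a + k  # mic_left must match the MAC over its first pl bases
      left_ok <- substr(ml, 1L, pl) == substr(mac, 1L, pl) &&
        (pl == n || pl == nchar(ml) ||
           char_at(ml, pl + 1L) != char_at(mac, pl + 1L))
      sl <- n - a  # mic_right must match the MAC over its last sl bases
      right_ok <- nchar(mr) >= sl &&
        substr(mr, nchar(mr) - sl + 1L, nchar(mr)) ==
          substr(mac, a + 1L, n) &&
        (sl == n || sl == nchar(mr) ||
           char_at(mr, nchar(mr) - sl) != char_at(mac, a))
      if (left_ok && right_ok) return(m)
    }
  }
  ""
}

# Run the calling stages on a simulated read set; returns everything.
run_calling <- function(sim, rd, cfg = pipeline_config()) {
  rec <- seed_extend_align(rd$reads, sim$ref, cfg$align)
  cls <- classify_reads(rec, rd$reads, sim$ref, min_ext = cfg$min_ext,
                        edge_margin = cfg$edge_margin)
  ev <- collect_breakpoints(rec, cls, rd$reads)
  full_ids <- cls$read_id[cls$class == "FULL" & cls$is_unique]
  full <- rec[rec$read_id %in% full_ids & rec$segment_index == 1L, ,
              drop = FALSE]
  sites <- call_sites(ev, full, max_sep = cfg$max_sep,
                      veto_margin = cfg$veto_margin)
  list(records = rec, classes = cls, evidence = ev, full = full,
       sites = sites)
}

# Minimal alignment-record row for classifier/caller unit tests.
rec_row <- function(read_id, ref_start, ref_end, left_clip, right_clip,
                    read_len, strand = "+", segment_index = 1L,
                    n_segments = 1L, score = NULL, second_score = 0L,
                    is_unique = TRUE) {
  data.frame(read_id = read_id, segment_index = segment_index,
             strand = strand,
             score = if (is.null(score)) ref_end - ref_start + 1L else score,
             ref_start = ref_start, ref_end = ref_end,
             read_start = left_clip + 1L, read_end = read_len - right_clip,
             left_clip = left_clip, right_clip = right_clip,
             read_len = read_len, n_segments = n_segments,
             second_score = second_score, is_unique = is_unique,
             stringsAsFactors = FALSE)
}
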