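---
title: "Detecting programmed DNA elimination sites from split-read alignments"
author: "iesfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting programmed DNA elimination sites from split-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesfinder)
```

## The problem

Ciliates carry two genomes: a germline micronucleus (MIC) and a somatic
macronucleus (MAC) rebuilt from a copy of the MIC in every sexual cycle.
During MAC differentiation, thousands of internal eliminated sequences
(IES) — MIC-specific segments — are excised. The MAC assembly therefore
lacks IES, and a MIC read that crosses an IES boundary aligns to the MAC
with one end only: its nonmapping terminal extension continues into the
eliminated sequence. `iesfinder` turns this signature into a genome-wide
map of elimination sites at nucleotide resolution.

The method is alignment-based, not assembly-based, which suits long,
accurate single reads (Sanger-style reads of roughly 500–1000 bp) at low
genome coverage. With long IES (often beyond a read length), a read rarely
bridges an entire IES, so the one-end-mapping signature is the dominant
observable.

## Reference design: the conMAC

All MAC contigs are concatenated in order of decreasing length, separated
by 10 kbp blocks of N (`build_conmac()`). This gives browser-style tracks a
single axis, and pushes the small, low-coverage scaffolds (which are
enriched for MIC contamination of a MAC assembly) to the right edge of the
coordinate system. The N spacers cannot be matched by any read, so
alignments never leak across contig boundaries; `lift_to_contig()` /
`lift_to_conmac()` convert between the concatenated and contig-local
frames. Contig-length ties are broken lexicographically by name so the
layout is reproducible. Assembly-specific contigs that should not
participate (an rDNA minichromosome, the mitochondrial genome) are excluded
by name.

Coordinates are 1-based and closed everywhere in the R API, following the
Biostrings/IRanges convention; BED output is converted to 0-based half-open
at the I/O boundary and GFF3 input is 1-based as the format requires.
Carrying a 0-based convention internally, against the grain of the host
interval infrastructure, would invite off-by-one errors at every boundary.

## Read preparation

Sanger reads are vector-trimmed (`trim_vector()`: longest exact terminal
match of at least 10 bp against a vector prefix/suffix in either
orientation; internal vector k-mer hits are flagged rather than trimmed)
and quality-trimmed (`quality_trim()`). The quality criterion keeps the
longest contiguous window whose **mean** phred quality is at least Q20
(leftmost window on ties, averaging on the phred scale), discarding reads
whose best window is under 50 bp — too short to support the one-end
evidence logic below.

Two properties of this criterion are worth knowing. When an entire read
qualifies, it is returned unchanged, so the window rule reproduces
whole-read filtering for good reads. Conversely, a mean criterion is weak
against localized garbage: a read of length $w$ at Q40 tolerates a Q3 tail
of up to $w(40-20)/(20-3) \approx 1.18\,w$ bases before the window
shrinks. Tail garbage that survives trimming is not harmful to site
calling — it turns reads into the discontinuous class, which contributes no
evidence — but it is the reason trimming is a read-rescue step, not a
read-surgery step, in this pipeline.

## Alignment

`seed_extend_align()` is a classical seed-and-extend local aligner:
exact 20-mer seeds are sampled every 40 bp along each read (both
orientations), located on the conMAC with `Biostrings::matchPDict()`,
clustered by diagonal, and the strongest candidate loci are extended with a
banded affine-gap Smith–Waterman kernel written in C++ (band half-width
32 bp; alignment endpoints are found exactly by a forward plus reverse
score-only pass). Default scoring is match +1, mismatch −3, gap open −5,
gap extend −2, minimum reported score 40 — a standard local-alignment
regime that behaves well on ~75% AT sequence, where spurious short matches
are common but decay quickly under a −3 mismatch penalty.

Per read, overlapping candidate alignments are resolved to the higher
score; surviving disjoint alignments become the read's segments
(`aln1, aln2, …` in read order). A read is **multi-mapping** when an
alternate placement of its primary segment at a different locus scores at
least 95% of the primary score (`mark_uniqueness()`); all its segments are
flagged together, and multi-mappers are excluded from evidence collection.
The uniqueness rule is a documented stand-in for whatever criterion an
external aligner would supply; when alignments are ingested from SAM
(`ingest_sam()`), secondary records play the same role.

Clip lengths and read coordinates are always reported in the
reference-normalized orientation (the read is reverse-complemented first
for minus-strand alignments), so `left_clip == read_start − 1` holds for
every record and a "left clip" always points left on the browser axis.

## Read classification

Each read receives exactly one class (`classify_reads()`):

* `FULL` — at most 10 bp unaligned at either end.
* `ONE_END_L` / `ONE_END_R` — **more than 10 bp** of nonmapping extension
  at exactly one end (strictly greater: a 10 bp clip is still FULL). An L
  read aligns on the browser-left of a putative IES; an R read on the
  right.
* `DISCONTINUOUS` — both ends clipped, or multiple disjoint segments;
  possible rearrangement in the cloned fragment, never used as evidence.
* `EDGE_EXCLUDED` — a one-end mapper whose breakpoint lies within 100 bp
  of a contig end (or in a spacer); assembly-edge artifacts, not IES
  evidence. The 100 bp default is a conservative buffer above typical
  clip-placement jitter; the original distance is not documented.
* `UNMAPPED` — no alignment at all (candidate MIC-specific content).

## Site calling

Unique one-end reads contribute breakpoints (`collect_breakpoints()`): for
an L read the conMAC coordinate of its **last** aligned base, for an R read
its **first**. Same-side breakpoints within 9 bp chain into one cluster
whose coordinate is the median breakpoint (how the original analysis
reduced multiple read endpoints to one coordinate is unstated; the median
is robust and deterministic).

`call_sites()` applies three criteria: (1) departure of an L and/or R read
from MAC-matching sequence; (2) convergent L and R clusters merge into one
**win1** site when their implied junction coordinates agree within 9 bp —
up to 9 bp of *overlap* between the MAC-matching portions (IES-flanking
microhomology retained once in the MAC) or up to 9 bp of *gap* (endpoint
erosion); (3) no uniquely mapped FULL read spans the site with at least
10 bp of flank on each side (the spanning-read veto: a read mapping across
the locus is direct evidence against an IES there). Unpaired L clusters
become **win2** sites, unpaired R clusters **win3**.

On the overlap side the merge bound is exactly the published rule (no more
than 9 bp of overlap); the gap side is its symmetric completion, since
small alignment-end erosion can separate two endpoints that describe one
junction. For a win1 site with $o$ bp of microhomology, the site window is
the closed interval of width $o + 1$ spanning both implied junctions; the
retained microhomology copy is the window interior, read directly off the
reference by `site_junctions()`.

### Junction anatomy

A precise excision with microhomology $m$ looks like:

    MIC:  L · m · core · m · R        MAC:  L · m · R

Both alignments extend through the retained copy of $m$ — the L alignment
ends at its right edge, the R alignment starts at its left edge — so the
observed overlap between convergent alignments *is* the microhomology, and
the clip sequences expose only the core. `assemble_ies()` therefore merges
an L clip (a prefix of the core) with an R clip (a suffix of it) when they
overlap by at least 20 bp, and the site-level wrapper re-appends the
retained copy: the reported IES sequence is `core + m`, the excised MIC
segment under the convention that the MAC retains the left copy. Junctions
are rendered in the field's compact notation — lowercase flanks, uppercase
microhomology, a slash for blunt joins (`"ttaTTAAtgg"`, `"atat/cctg"`) —
and `detect_motifs()` flags TA and TTAA content of the microhomology, the
piggyBac-associated cleavage motif.

Microhomology search is exact-match only: at the 3–4 bp scale, fuzzy
matching has no meaning. When several equal decompositions exist the
leftmost is reported.

## Genome context and genome-wide extrapolation

`read_gene_models()` imports GFF3 exons and approximates the manual
curation of over-predicted gene models with two filters: a gene having any
exon under 30 bp or any intron over 1 kbp is implausible and ignored by
default. `annotate_sites()` labels each site exon / intron / intergenic,
with the host-exon position (5′, 3′, Mid, Single, or `Jxn` for windows
straddling an intron/exon boundary).

`extrapolate_total()` implements the two-sided detection argument: if a
junction is covered by an L read with probability $f$ and independently by
an R read with the same probability, only a fraction $f^2$ of all sites
acquire win1 evidence, so the genome-wide estimate is
$n_{\mathrm{win1}}/f^2$. At $f \approx 0.25$ (a quarter of the unique MAC
sequence covered), win1 sites represent somewhat less than 1/16 of all
sites:

```{r extrapolate}
extrapolate_total(404, 0.25)
```

## The synthetic genome generator

`simulate_genomes()` builds the study conditions from scratch: random MAC
contigs at 75% AT; planted IES of two classes — a **short precise** class
(100–500 bp) whose 3–4 bp boundary microhomology (the TTAA motif with
probability 0.75, otherwise a TA-containing draw) is duplicated in the MIC
and retained once in the MAC, and a **long heterogeneous** class (1–3 kbp)
inserted bluntly and carrying a small set of alternative excision
boundaries (±10 bp, three per IES by default) from which
`excision_junctions()` samples per-event MAC junctions. Junctions keep a
minimum separation of 1.5 kbp and stay 1.2 kbp from contig edges, so each
read's evidence is attributable to one junction and never edge-excluded.
Reads (`simulate_reads()`) are Sanger-like: ~750 ± 80 bp (truncated to
500–1000 bp), from ~8 kbp ± 0.8 kbp cloned fragments read from both ends
(`.b1`/`.g1` mates), with optional uniform substitution errors and
matching phred qualities.

Two placement modes serve different purposes:

* **uniform** — fragments placed uniformly at a target coverage; the
  realistic Lander–Waterman regime used for the read-partition, coverage
  and end-to-end recovery checks.
* **junction** — each planted junction side independently receives one
  informative one-end read with probability exactly $f$, plus fully
  mapped background reads inside MAC-destined segments. Uniform placement
  cannot reach $f = 1$ (Poisson coverage saturates at $1 - e^{-\lambda}$),
  and the $f^2$ detection law is only exactly testable when $f$ *is* the
  per-side coverage probability; this mode makes $f$ a controlled
  parameter rather than an emergent one.

Two constructions deserve explanation because they are about making the
ground truth well-defined, not about making tests easy:

* **Boundary identifiability guards.** If the first core bases of a
  planted IES happen to resemble the MAC sequence the junction joins to —
  directly, or shifted by a base or two — then a maximal local alignment
  legitimately extends past the planted junction, and the "true" excision
  position is genuinely ambiguous (the same MIC sequence is consistent with
  several junction placements). The generator therefore redraws the first
  and last 8 core bases until they have at most 2 matches against the
  flank continuation at every alignment shift within ±3, with the
  junction-adjacent base always mismatching. Under the default scoring,
  every partial alignment extension across such a block is strictly
  score-negative, so planted junctions are identifiable at single-base
  resolution.
* **Core/boundary conventions.** The recorded IES sequence is
  `core + microhomology` (the excised segment when the MAC retains the
  left copy), and its MIC interval is recorded so that evaluation and
  geometric coverage accounting (`truth_side_coverage()`) are independent
  of the alignment pipeline.

What the simulator does **not** emulate: chromatogram-level basecalling
error structure (errors are uniform substitutions), cloning bias and
library instability, indel sequencing errors, and repetitive multi-copy
IES families (multi-mapper segregation is exercised with duplicated-locus
fixtures instead). Passing the synthetic suite therefore demonstrates the
correctness of the calling logic under clean, identifiable conditions, not
robustness to every pathology of 2000s-era trace archives.

## Numerical and design choices

* Band half-width 32 bp bounds the indel budget per alignment; Sanger
  indel errors are rare and the simulator plants none, so the band is
  generous.
* The strictly-greater-than 10 bp extension rule, the 9 bp convergence
  window, the 10 bp veto margin and the 100 bp edge margin are the
  pipeline defaults (`pipeline_config()`); the win1 merge tolerates the
  window on both the overlap and the gap side.
* Same-side clustering uses single-linkage chaining at 9 bp with the
  (lower) median as the cluster coordinate.
* Greedy nearest-first pairing matches L to R clusters; with junctions
  separated by ≥1.5 kbp, pairing ambiguity does not arise in practice.
* `quality_trim()` runs in $O(n \log n)$ per read via prefix-sum minima;
  the test suite checks it against brute-force enumeration of all windows.
* Degenerate inputs: empty evidence yields an empty, well-typed site
  table; an IES-free simulation yields `MIC == MAC` exactly; vetoed sites
  are returned separately rather than silently dropped.

## Problem sizes used by the test suite

The packaged checks run end-to-end pipelines on 0.35–0.5 Mbp genomes with
40–200 planted IES, ten-seed replicates for the $f^2$ recall law at
$f \in \{0.25, 0.5, 1\}$, and a ~1200-read uniform-coverage run for the
recovery property — sizes at which every property is exercised with
hundreds to thousands of Bernoulli trials while a full `R CMD check`-style
run stays comfortable on a laptop core.

## Known limitations

* The built-in aligner is a generic seeded local aligner, not a
  reimplementation of any specific external tool; on real trace data one
  would ingest SAM from a long-read aligner and keep every downstream
  stage unchanged.
* Mean-quality window trimming cannot remove localized garbage behind a
  long high-quality stretch (see above); such reads degrade to the
  discontinuous class.
* Multi-copy IES present at several MIC loci produce multi-mapping
  one-end reads, which are segregated, never called; the corresponding
  sites are invisible to this method by design.
* win2/win3 sites rest on single-sided evidence and can be artifacts of
  rearranged clones; only win1 sites are treated as high-confidence, and
  the genome-wide extrapolation uses win1 counts alone.
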