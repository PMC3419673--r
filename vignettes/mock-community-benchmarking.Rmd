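---
title: "Benchmarking amplicon community structure with synthetic mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking amplicon community structure with synthetic mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amplicon surveys of microbial communities (16S rRNA gene pyrosequencing
and its successors) estimate *community structure* — which taxa are
present and at what relative abundance — from PCR products. Three
distortions stand between the sequenced library and the truth:

1. **Sequencing depth.** Rare taxa drop out of shallow libraries, which
   depresses membership-based (presence/absence) statistics.
2. **Spurious OTUs.** Sequencing errors and chimeric PCR artifacts that
   survive quality control form clusters containing no real taxon,
   inflating richness.
3. **Multi-template PCR bias.** Templates amplify with different
   efficiencies (GC content being one driver), so relative abundances
   are systematically distorted even in deep, clean libraries.

`ampbias` separates these effects with mock communities: defined
mixtures of known reference sequences. Because the truth is known, every
OTU can be labelled *good* (contains a reference) or *spurious*, every
detected abundance can be compared with its theoretical value, and each
distortion can be switched on or off in the simulator.

## The mock-community design

A reference set holds 33 "bacterial" (or 24 "archaeal") mutually
divergent sequences (<97% pairwise identity, so each founds its own OTU
at a 3% distance cutoff), split into low/medium/high GC clusters of 11
(resp. 8) sequences. Cluster GC means default to the tertiles 51.1 /
55.1 / 59.3% GC for bacteria and 53.1 / 58.3 / 64.9% for archaea over
target regions of 570 and 600 nt.

Three communities are built per domain:

* **m1** — every sequence at equal abundance;
* **m2** — one GC cluster per abundance level, weights (1, 80, 1000)
  per sequence for bacteria and (1, 79, 1000) for archaea;
* **m3** — as m2 but with the high- and low-abundance clusters swapped
  (the medium cluster keeps its level).

Realized as integer "in-silico" communities under the rule that the
lowest level carries exactly one read per sequence, the uneven bacterial
and archaeal communities total 11,891 and 8,640 reads; the even
community is scaled to match. The weight vectors are pinned down by
those totals together with the one-read rule (11·(1+x+y) = 11,891 forces
x+y = 1080), and yield theoretical Morisita-Horn distances of ≈0.442
(m1–m2) and ≈0.992 (m2–m3) for bacteria and ≈0.443 / ≈0.992 for
archaea, while the theoretical Jaccard distance between any pair is 0
(identical membership). These are the package's reference points for
every beta-diversity comparison.

## The simulator

`sim_params()` collects every knob; defaults are the package's study
conditions and are not meant to be tuned per run.

**PCR bias** (`simulate_pcr()`) is a deterministic exponential-growth
model: template *i* finishes `pcr_cycles` (default 15, few cycles being
the standard precaution against artifacts) with weight
$a_i (1+e_i)^{c}$, where
$e_i = \mathrm{clamp}(e_0 + s_{GC} (g_i - \bar g),\,0,\,1)$ with base
efficiency $e_0 = 0.9$ and slope $s_{GC} = -0.4$ per unit GC fraction.
Determinism here is a design choice: the bias itself is reproducible,
and stochasticity enters only through chimera formation and read
sampling.

**Chimeras** divert a `chimera_rate` (default 0.0075) fraction of each
cycle's newly synthesized mass into two-parent joints at uniform
breakpoints, parents drawn proportionally to current weight — including
earlier chimeras, so multi-parent artifacts arise in late cycles and
are exactly the reads a two-parent detector struggles with. The default
leaves roughly 5% chimeric reads after 15 cycles.

**Reads** (`simulate_library()`) are drawn multinomially at the
requested depth. Each read is barcode + reverse primer + the reverse
complement of its template (sequencing proceeds from the distal end of
the region). Substitutions occur at 0.1% per base and indels at 0.15%
per base scaled by $4^{k-1}$ inside homopolymers of length $k$ — the
magnitudes and homopolymer dominance of post-filter pyrosequencing
error profiles. Per-base qualities decay linearly in expectation from
35 to 20 along the read with Gaussian jitter (SD 3), clamped to
[0, 40], emulating the characteristic degradation of quality scores
along long pyrosequencing reads.

**Inter-sample GC yield** (`apply_intersample_gc_yield()`): sample *i*
realizes depth $\propto 1 + s (g_i - \bar g)$. The default slope is
−2 (high-GC amplicon pools under-represented); the sign is deliberately
a free parameter, since the direction of this bias is an empirical
question the package is designed to probe, and
`gc_read_correlation()` recovers it from simulated output.

**Barcodes** (`design_barcodes()`) are length-10 with pairwise
Levenshtein distance ≥3. Candidates containing homopolymer runs longer
than 2 are rejected: a homopolymer is read in a single flow whose
called length is the dominant error mode, and an unscreened run of four
identical bases inside a must-match-exactly barcode can silently
destroy most of a sample's reads under the homopolymer error model.
This mirrors the flow-count screening applied when such codes are
designed for real runs.

All randomness flows from one master seed through per-sample substreams
(`hash(seed, sample_id)`), so any library — and any full report — is
reproducible in isolation.

## Quality control

`run_qc()` applies, in order: exact-length barcode demultiplexing
(0 mismatches by default; equidistant ties are discarded, never
guessed, because binning errors are worse than read loss), reverse
primer screening by Hamming distance over all degenerate-primer
expansions (≤1 mismatch — the primer region is stripped and takes no
further part in analysis, so a lone error there shouldn't cost the
read), sliding-window quality trimming (mean quality ≥25 over 50-bp
windows advancing one base at a time; the read is truncated at the
start of the first failing window so only the high-quality sequencing
end survives), then removal of reads with any ambiguous base or
trimmed below 200 bp (strictly: 200 bp is kept). Reads shorter than
one window are evaluated as a single full-length window rather than
escaping QC. The report conserves reads exactly across pass/reject
categories.

Two conventions the protocol leaves open are fixed here and exposed as
parameters: the window advances by 1 bp (not by window-length jumps),
and "below 200 bp" is read strictly.

## OTU pipeline

Reads are oriented and matched to a seed alignment by shared 8-mers
(both orientations tried), then aligned with a semi-global affine
Needleman–Wunsch (match 1, mismatch −1, gap open 4, extend 1; seed ends
free) implemented in C++. Insertions relative to the seed are dropped
(NAST behaviour), so every read lives in the seed's column coordinates;
consequently the "aligned content equals the read" property is exact
only for insertion-free reads. Because the synthetic references derive
from one backbone by substitutions, the seed alignment is gapless and
trivially consistent.

Reads whose alignment stops more than 5 columns short of the sequenced
end of the region are dropped as mis-spanning. A reference-based bimera
screen then computes, per read, the best single-reference identity
`i1` and the best two-reference split identity `i2` (breakpoints on a
10-column grid, refined ±10); a read is flagged when `i2 − i1 ≥ 0.03`
and `i2 ≥ 0.99` — it must look like two *clean* reference fragments
joined together. Error-laden or multi-parent chimeras evade the screen,
which is precisely how spurious OTUs survive into the tables, as they
do in real pipelines.

Alignment columns containing a terminal gap in any sequence are removed
(so all sequences are compared along the same stretch), as are all-gap
columns. Distances are `(substitutions + gap runs) / compared columns`
with a maximal gap run in one sequence counting as a single event and
mutual gaps skipped — the common convention for OTU work; the protocol
being emulated does not state its gap rule, so this one is fixed and
documented here. Average-neighbor (UPGMA-criterion) clustering merges
while the smallest mean inter-cluster distance is ≤0.03 ("3%
similarity" read as 0.03 distance), with deterministic lexicographic
tie-breaking, so the partition is invariant to input order. OTUs
containing a reference are *good* (named by their reference); the rest
are *spurious*. Reference rows are excluded from counts.

`run_study()` clusters each library separately with the full reference
set included in every distance matrix. The references anchor the good
OTU space, which is therefore identical across libraries; spurious OTUs
are per-library (they are never shared between real libraries either).
This replaces a single pooled mega-clustering: it is linear instead of
quadratic in the number of libraries, and identical reads are
dereplicated before the distance matrix is built.

## Diversity estimators

* `chao1()` — bias-corrected form $S + n_1(n_1-1)/(2(n_2+1))$, defined
  even without doubletons; the classic $S + n_1^2/(2n_2)$ is available
  via `bias_corrected = FALSE`.
* `inverse_simpson()` — unbiased estimator
  $1 / \left[\sum n_i(n_i-1) / (N(N-1))\right]$ by default (note it can
  exceed $S$ for near-even samples; the plug-in $1/\sum p_i^2$, which
  cannot, is available via `unbiased = FALSE`).
* `np_shannon()` — Chao–Shen coverage-adjusted entropy (natural log),
  the standard "non-parametric Shannon".
* `jaccard_distance()` — membership only; `morisita_horn_distance()` —
  structure-weighted and invariant to count rescaling.
* `pcoa()` — classical scaling (via `stats::cmdscale`); negative
  eigenvalues are reported, axes from them suppressed.
* `subsample()` — without replacement (rarefaction-style), exact totals,
  seeded.

The estimator variants behind the historical tool names are
version-dependent; the choices above are fixed, documented, and
switchable where alternatives exist.

## The study orchestrator and its analytics

`run_study()` simulates triplicate libraries of m1/m2/m3 at two depth
tiers whose defaults mirror the benchmarked conditions — a few hundred
reads per sample versus 6–7× more — with per-replicate amplicon-pool GC
offsets (±2% GC) standing in for barcoded reverse primers of differing
GC. It then runs QC and the OTU pipeline and assembles:

* taxa detection frequencies (detected good OTUs / true taxa) against
  95% bands from in-silico subsampling at 1–90% (bands are
  mean ± 1.96 SD over subsampling replicates — the band construction is
  a package convention, with the hypergeometric expectation
  $\sum_i\left[1-\binom{N-n_i}{n}/\binom{N}{n}\right]$ reported
  alongside);
* per-OTU relative-abundance fold errors versus theory (undetected OTUs
  are flagged absent and excluded from fold summaries — their mass
  shifts onto detected OTUs — rather than entered as fold 0);
* rank-abundance Kolmogorov–Smirnov comparisons (asymptotic p-values);
* alpha diversity with and without spurious OTUs;
* pairwise Morisita-Horn and Jaccard between replicate libraries, with
  and without spurious OTUs, against the theoretical values;
* Morisita-Horn distance from each library to theory plus the library
  centroid in PCoA space;
* the depth-versus-pool-GC Pearson correlation across all samples.

Group means are compared by Welch's t (no equal-variance assumption),
variances by a two-sided F test with the larger variance in the
numerator; no multiple-testing correction is applied, matching the
protocol being emulated.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the bacterial study at
depths of 300 (small tier) and 1,920 (large tier, preserving the ≈6.4×
ratio) with triplicate libraries — 18 libraries and ≈20,000 reads per
study — which reproduces every qualitative contrast (richness
inflation, structure-metric stability, depth-bought precision) in a few
minutes on one CPU. The full-scale defaults (520 / 3,328 for bacteria,
306 / 1,865 for archaea) run the same code unchanged. Structure-metric
stability under spurious-OTU removal is evaluated on replicate means
per community and tier — the level at which the diversity bars are
compared — because in a single few-hundred-read library two or three
spurious reads already move the inverse Simpson index by several
percent.

Degenerate inputs fail loudly rather than silently: infeasible GC
targets, empty communities, all-clamped PCR efficiencies, subsample
sizes beyond the total, distance pairs with no comparable columns, and
column filters that would remove everything all raise errors.
Morisita-Horn values are clamped into [0, 1] against floating-point
undershoot; clustering tie-breaks are lexicographic; PCoA axes are
truncated (with a warning) to the positive-eigenvalue count.

## What the simulator does and does not emulate

It emulates: GC-linked multi-template amplification bias, bimera
formation (including higher-order chimeras via chimeric parents),
homopolymer-dominated indel errors with decaying quality, inter-sample
yield bias, barcode/primer read architecture, and the full QC and OTU
pipeline a practitioner would run. It does not emulate: flowgram-level
signal, emulsion-PCR droplet dynamics, template-specific amplification
quirks beyond GC (secondary structure, primer mismatch — references are
built to match their primers perfectly), DNA extraction and chromosomal
context (mock templates are naked inserts), or taxonomy. Passing tests
therefore demonstrate that the *pipeline's statistics behave correctly
under a realistic, controllable error model* — not that any particular
real dataset will show the same effect sizes. In particular, real
communities contain genuinely rare taxa that are statistically
indistinguishable from spurious OTUs; the mock design deliberately
removes that ambiguity.

## Known limitations

* The bimera detector is a split-identity scan against the reference
  seed, not a full de-novo heuristic; its miss modes (near-end
  breakpoints, noisy or multi-parent chimeras) are realistic in kind
  but not calibrated to any specific tool.
* Qualities are drawn independently of the injected errors, so
  quality-aware error correction cannot be studied — only
  quality-threshold filtering.
* Per-library clustering anchored by references assumes the reference
  set is complete; with incomplete references, good/spurious labels
  would be undefined (as they are for real environmental data).
* The unbiased inverse-Simpson estimator can exceed observed richness
  on near-even samples; comparisons across estimator variants should
  fix one variant.
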