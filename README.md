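# ampbias

Mock-community benchmarking of amplicon sequencing bias.

`ampbias` is for microbiome methodologists who want to know how much of
an amplicon survey's apparent community structure is real. It simulates
16S rRNA gene mock communities — defined mixtures of known reference
sequences — through a realistic sequencing chain (multi-template PCR
with GC-dependent efficiency, chimera formation, homopolymer-dominated
sequencing errors, inter-sample GC yield bias), then runs the standard
analysis pipeline on the result (demultiplexing, sliding-window quality
filtering, seed alignment, bimera screening, average-neighbor OTU
clustering at 3% distance) and quantifies three separate distortions:
sequencing depth, spurious OTUs, and errors in mean relative abundance
from PCR bias.

## The core quantities

With truth in hand, every OTU is **good** (contains a reference) or
**spurious**, and the package computes:

* α-diversity: observed richness `R_obs`, bias-corrected Chao1
  `S + n1(n1−1)/(2(n2+1))`, unbiased inverse Simpson
  `1/[Σ n_i(n_i−1)/(N(N−1))]`, and the Chao–Shen non-parametric
  Shannon entropy;
* β-diversity: Jaccard distance `1 − |A∩B|/|A∪B|` (membership) and
  Morisita-Horn distance
  `1 − 2Σx_iy_i / ((Σx_i²/X² + Σy_i²/Y²)XY)` (structure), plus PCoA
  ordination by classical scaling;
* bias analytics: taxa detection frequency (detected / true taxa)
  against hypergeometric subsampling bands, per-OTU fold errors
  (experimental / theoretical relative abundance), rank-abundance
  Kolmogorov–Smirnov comparisons, the Pearson correlation of library
  yield with amplicon-pool GC, and Welch-t / F comparisons across
  depths and spurious-OTU removal.

## Worked example

```r
library(ampbias)

st <- run_study("bacteria", depths = c(small = 150, large = 960),
                seed = 42)
print(st)
#> mock_study (bacteria): 18 libraries, tiers small=150/large=960, seed 42
#>   mean detection frequency: 0.742 | spurious OTUs/library: 4.4
#>   GC-yield correlation r = -1.00 (p = 5.3e-29)

st$theoretical_beta
#>    pair      d_mh d_jaccard
#> 1 m1-m2 0.4419165         0
#> 2 m1-m3 0.4419165         0
#> 3 m2-m3 0.9916534         0

# spurious OTUs inflate richness...
colMeans(st$alpha[, c("r_obs", "r_obs_nospur", "r_chao1", "r_chao1_nospur")])
#>          r_obs   r_obs_nospur        r_chao1 r_chao1_nospur
#>       28.94444       24.50000       35.08889       26.22778

# ...but deeper sequencing buys precision in structure-based beta diversity
sd(st$beta$m1_m2_small$d_mh); sd(st$beta$m1_m2_large$d_mh)
#> [1] 0.05378908
#> [1] 0.01395028
```

The three mock communities share membership (theoretical Jaccard 0) but
differ in structure: the even community m1 sits at Morisita-Horn
distance ≈0.44 from either uneven community, while m2 and m3 — whose
high-abundance GC cluster is the other's low-abundance cluster — are
nearly disjoint in structure (≈0.99). The simulated libraries recover
those contrasts, distorted exactly by the three mechanisms the
simulator injects.

Individual stages are exposed as plain functions
(`generate_reference_set()`, `simulate_pcr()`, `simulate_library()`,
`run_qc()`, `align_to_seed()`, `detect_chimeras()`,
`cluster_average_neighbor()`, `classify_otus()`, `chao1()`,
`morisita_horn_distance()`, `subsample()`, ...); see the vignette in
`vignettes/mock-community-benchmarking.Rmd` for the models, defaults,
and design rationale.

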