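test_that("reference sets hit GC targets, stay mutually divergent, and are seeded", {
  refs <- bact_refs()
  expect_equal(nrow(refs), 33L)
  gm <- tapply(refs$gc_fraction, refs$gc_cluster, mean)
  expect_true(all(abs(gm - c(0.511, 0.551, 0.593)) <= 0.01))
  expect_true(all(diff(gm) > 0))
  expect_true(all(refs$gc_fraction ==
                    gc_fraction(refs$sequence)))
  expect_true(all(grepl("^[ACGT]+$", refs$sequence)))

  im <- pairwise_identity(refs$sequence)
  diag(im) <- 0
  expect_lt(max(im), 0.97)

  expect_identical(refs, bact_refs())   # seeded determinism
  arch <- arch_refs()
  expect_equal(nrow(arch), 24L)
  expect_false(identical(refs$sequence[1], arch$sequence[1]))
})

test_that("infeasible GC targets fail loudly", {
  expect_error(generate_reference_set(2, c(0.001, 0.5, 0.999), 20,
                                      seed = 1),
               "infeasible")
})

test_that("mock designs follow the even/uneven structure and the m2/m3 swap", {
  refs <- bact_refs()
  d1 <- build_mock_design(refs, c(1, 80, 1000), "m1")
  expect_true(all(d1$cluster_to_level == 1))

  d2 <- build_mock_design(refs, c(1, 80, 1000), "m2")
  d3 <- build_mock_design(refs, c(1, 80, 1000), "m3")
  expect_identical(unname(sort(d2$cluster_to_level)),
                   unname(sort(d3$cluster_to_level)))
  # the high-abundance cluster of m2 is the low-abundance cluster of m3
  hi2 <- names(which.max(d2$cluster_to_level))
  expect_identical(names(which.min(d3$cluster_to_level)), hi2)
  lo2 <- names(which.min(d2$cluster_to_level))
  expect_identical(names(which.max(d3$cluster_to_level)), lo2)
  # medium cluster keeps its level
  expect_identical(d2$cluster_to_level[["medium"]],
                   d3$cluster_to_level[["medium"]])

  expect_warning(build_mock_design(refs, c(2, 2, 2), "m2"), "degenerate")
})

test_that("in-silico communities obey the one-read-lowest-level rule", {
  refs <- bact_refs()
  d <- build_mock_design(refs, c(1, 10, 100), "m2")
  p <- build_insilico_community(d)
  expect_equal(sum(p), 11L * 111L)            # 1221
  lows <- names(which.min(d$cluster_to_level))
  low_ids <- refs$id[refs$gc_cluster == lows]
  expect_true(all(unclass(p)[low_ids] == 1L))

  d1 <- build_mock_design(refs, c(1, 10, 100), "m1")
  p1 <- build_insilico_community(d1, match_total = 1221)
  expect_true(all(unclass(p1) == 37L))        # round(1221/33)
  expect_equal(sum(p1), 1221L)
})

test_that("study designs reproduce the published in-silico totals", {
  pb <- theoretical_profiles(bact_refs(), c(1, 80, 1000))
  expect_equal(sum(pb$m2), 11891L)
  expect_equal(sum(pb$m3), 11891L)
  pa <- theoretical_profiles(arch_refs(), c(1, 79, 1000))
  expect_equal(sum(pa$m2), 8640L)
  expect_equal(sum(pa$m1), 8640L)
})

test_that("barcode sets satisfy length and Levenshtein constraints deterministically", {
  bc <- design_barcodes(6, length = 10, min_lev = 3, seed = 3)
  expect_length(bc, 6L)
  expect_true(all(nchar(bc) == 10L))
  d <- utils::adist(bc)
  expect_true(all(d[upper.tri(d)] >= 3))
  expect_identical(as.character(bc),
                   as.character(design_barcodes(6, seed = 3)))
  # single barcode: no pair constraint to satisfy
  expect_length(design_barcodes(1, seed = 1), 1L)
  # infeasible request fails with the achieved count
  expect_error(design_barcodes(50, length = 2, min_lev = 3, seed = 1,
                               max_attempts = 200),
               "could only place")
})

test_that("degenerate primers expand to the full variant set", {
  expect_length(expand_degenerate_primer("CCTACGGGRGGCAGCAG"), 2L)
  v <- expand_degenerate_primer("CCCTAHGGGGYGCASCA")   # H x Y x S
  expect_length(v, 12L)
  expect_length(unique(v), 12L)
  expect_true(all(grepl("^[ACGT]+$", v)))
  expect_identical(expand_degenerate_primer("ATGC"), "ATGC")
  expect_error(expand_degenerate_primer("ATXC"), "position 3")
})

test_that("primer coverage counts per-reference hits on both strands", {
  refs <- c(a = "AAAAACCTACGGGAGGCAGCAGTTTTT",
            b = "GGGGGCCTACGGGGGGCAGCAGAAAAA",
            c = paste(rev(strsplit(
              "AAAAACCTACGGGAGGCAGCAGTTTTT", "")[[1]]), collapse = ""))
  refs <- c(refs, d = revcomp(refs[["a"]]))   # reverse strand hit
  cov0 <- primer_coverage("CCTACGGGRGGCAGCAG", refs, max_mismatch = 0)
  expect_equal(cov0$hits, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(cov0$coverage, 0.75)
  # one mismatch of slack picks up nothing new here
  refs2 <- c(refs[1:2],
             e = sub("CCTACGGGA", "CCTACGGTA",
                     "AAAAACCTACGGGAGGCAGCAGTTTTT"))
  expect_equal(primer_coverage("CCTACGGGRGGCAGCAG", refs2,
                               max_mismatch = 0)$coverage, 2 / 3)
  expect_equal(primer_coverage("CCTACGGGRGGCAGCAG", refs2,
                               max_mismatch = 1)$coverage, 1)
  expect_error(primer_coverage("CCTACGGGRGGCAGCAG", character(0)),
               "empty")
})

test_that("PCR bias model is exact, monotone in GC, and chimera-free when told", {
  refs <- bact_refs()
  prof <- theoretical_profiles(refs, c(1, 80, 1000))$m1
  p0 <- sim_params(gc_efficiency_slope = 0, chimera_rate = 0, seed = 2)
  res <- simulate_pcr(prof, refs, p0)
  expect_equal(nrow(res$chimeras), 0L)
  expect_equal(unname(res$proportions),
               rep(1 / 33, 33), tolerance = 1e-12)  # symmetry preserved

  pneg <- sim_params(gc_efficiency_slope = -0.5, chimera_rate = 0,
                     seed = 2)
  res2 <- simulate_pcr(prof, refs, pneg)
  gcs <- refs$gc_fraction[match(names(res2$proportions), refs$id)]
  ord <- order(gcs)
  # non-increasing in GC, strictly decreasing between distinct GC values
  expect_true(all(diff(res2$proportions[ord]) <= 0))
  expect_true(all(diff(tapply(res2$proportions, gcs, mean)) < 0))

  # uneven input with zero bias keeps proportions exactly
  prof2 <- theoretical_profiles(refs, c(1, 80, 1000))$m2
  res3 <- simulate_pcr(prof2, refs, p0)
  expect_equal(res3$proportions, relative_abundance(prof2),
               tolerance = 1e-12)

  # defensive guard: a (manually corrupted) efficiency model in which
  # every template clamps to zero must fail, not divide by zero
  pbad <- sim_params(gc_efficiency_slope = 0, chimera_rate = 0)
  pbad$base_efficiency <- -1
  expect_error(simulate_pcr(prof, refs, pbad), "clamp")
})

test_that("simulated libraries have exact depth, clean zero-error reads, and seeded output", {
  refs <- tiny_refs()
  prof <- community_profile(stats::setNames(rep(1, nrow(refs)), refs$id))
  p0 <- sim_params(substitution_rate = 0, indel_rate = 0, seed = 9)
  lib <- simulate_library(relative_abundance(prof),
                          stats::setNames(refs$sequence, refs$id),
                          p0, depth = 50, barcode = "ACGT",
                          primer = "GGTT", sample_id = "x")
  expect_equal(nrow(lib$reads), 50L)
  expect_true(all(lengths(lib$quals) == nchar(lib$reads$sequence)))
  # zero error rates: read is exactly barcode + primer + revcomp(template)
  expect_identical(
    lib$reads$sequence,
    paste0("ACGT", "GGTT",
           revcomp(refs$sequence[match(lib$reads$template_id, refs$id)])))
  lib2 <- simulate_library(relative_abundance(prof),
                           stats::setNames(refs$sequence, refs$id),
                           p0, depth = 50, barcode = "ACGT",
                           primer = "GGTT", sample_id = "x")
  expect_identical(lib, lib2)
})

test_that("library read counts are multinomial around the proportions", {
  # 200 seeded replicates at depth 1000 for one focal template
  props <- c(a = 0.2, b = 0.3, c = 0.5)
  seqs <- c(a = strrep("ACGT", 25), b = strrep("TGCA", 25),
            c = strrep("GGAT", 25))
  hits <- vapply(seq_len(200), function(r) {
    lib <- simulate_library(props, seqs,
                            sim_params(substitution_rate = 0,
                                       indel_rate = 0, seed = r),
                            depth = 1000, sample_id = "m")
    mean(lib$reads$template_id == "a")
  }, numeric(1))
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(mean(hits) - 0.2), 4 * se / sqrt(200))
  expect_equal(sd(hits), se, tolerance = 0.25)
})

test_that("inter-sample GC yield shifts depths with the injected sign and size", {
  expect_equal(gc_yield_depths(c(0.5, 0.6), slope = -2, base_depth = 1000),
               c(1100L, 900L))
  expect_equal(gc_yield_depths(c(0.5, 0.6), slope = 0, base_depth = 500),
               c(500L, 500L))
  gc <- seq(0.45, 0.65, length.out = 9)
  for (s in c(-2, 1.5)) {
    d <- gc_yield_depths(gc, slope = s, base_depth = 2000)
    expect_equal(sign(cor(d, gc)), sign(s))
    # regression recovers the injected slope within 10% (noise-free)
    fit <- coef(lm(d ~ gc))
    expect_equal(unname(fit[2]) / (2000 * s), 1, tolerance = 0.1)
  }
  expect_error(gc_yield_depths(c(0.55, 0.55, 0.55), slope = -2,
                               base_depth = 0.2),
               "below one read")
})

test_that("apply_intersample_gc_yield subsamples libraries to realized depths", {
  refs <- tiny_refs()
  props <- relative_abundance(
    community_profile(stats::setNames(rep(1, nrow(refs)), refs$id)))
  seqs <- stats::setNames(refs$sequence, refs$id)
  p0 <- sim_params(substitution_rate = 0, indel_rate = 0, seed = 4)
  libs <- lapply(c("a", "b"), function(s)
    simulate_library(props, seqs, p0, depth = 1200, sample_id = s))
  out <- apply_intersample_gc_yield(libs, pool_gc = c(0.5, 0.6),
                                    slope = -2, base_depth = 1000,
                                    seed = 8)
  expect_equal(vapply(out, function(l) nrow(l$reads), integer(1)),
               c(1100L, 900L))
  expect_error(apply_intersample_gc_yield(libs, c(0.5, 0.6), slope = 2,
                                          base_depth = 1150, seed = 8),
               "realized depth")
})
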