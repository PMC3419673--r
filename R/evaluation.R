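#' Taxa detection frequency
#'
#' Ratio of the number of (good) taxa detected in a sample to the true
#' number of taxa present in it.
#'
#' @param detected_counts named count vector over good OTUs for one
#'   sample (e.g. a column of `drop_spurious(ot)$counts`).
#' @param truth a [community_profile()] listing the true taxa.
#' @return list with `detected`, `true_taxa`, `frequency`.
#' @export
taxa_detection_frequency <- function(detected_counts, truth) {
  true_taxa <- sum(unclass(truth) > 0)
  if (!true_taxa) stopf("truth profile is empty")
  detected <- sum(detected_counts > 0)
  list(detected = detected, true_taxa = true_taxa,
       frequency = detected / true_taxa)
}

#' Theoretical detection-frequency bands from in-silico subsampling
#'
#' Subsamples the in-silico community at each fraction, computes the
#' detection frequency per replicate, and summarizes each fraction as a
#' normal-approximation 95% band (mean +/- 1.96 SD across replicates).
#' The analytic expectation under sampling without replacement is also
#' returned: `E[detected] = sum_i (1 - C(N - n_i, n) / C(N, n))`
#' (hypergeometric zero-draw probability per taxon).
#'
#' @param truth a [community_profile()].
#' @param fractions subsampling fractions (default 1, 5, 10, 20, 50, 70
#'   and 90% of the reads).
#' @param replicates subsample replicates per fraction (3 mirrors the
#'   benchmarked design; use ~1000 for smooth bands).
#' @param seed integer seed.
#' @return data.frame per fraction: `fraction`, `n`, `mean`, `sd`,
#'   `lower`, `upper`, `analytic`.
#' @export
detection_band <- function(truth,
                           fractions = c(.01, .05, .1, .2, .5, .7, .9),
                           replicates = 3L, seed = 1L) {
  counts <- unclass(truth)[unclass(truth) > 0]
  total <- sum(counts)
  s <- length(counts)
  rows <- lapply(seq_along(fractions), function(fi) {
    n <- max(1L, round(fractions[fi] * total))
    subs <- subsample(community_profile(counts), n = n,
                      replicates = replicates,
                      seed = substream_seed(seed, paste0("band:", fi)))
    freq <- vapply(subs, function(p) sum(unclass(p) > 0) / s, numeric(1))
    analytic <- sum(1 - exp(lchoose(total - counts, n) -
                              lchoose(total, n))) / s
    data.frame(fraction = fractions[fi], n = n,
               mean = mean(freq), sd = stats::sd(freq),
               lower = mean(freq) - 1.96 * stats::sd(freq),
               upper = mean(freq) + 1.96 * stats::sd(freq),
               analytic = analytic)
  })
  do.call(rbind, rows)
}

#' Relative-abundance fold errors against the theoretical community
#'
#' Per good OTU: mean relative abundance across replicate libraries,
#' its SD, and the fold error (experimental mean / theoretical).
#' Undetected OTUs are flagged as absent and excluded from the fold
#' summary (their mass shifts onto the detected OTUs) rather than being
#' treated as fold 0.
#'
#' @param replicate_counts list of named count vectors over good OTUs
#'   (one per replicate library).
#' @param truth a [community_profile()] in the same OTU space.
#' @return list with `per_otu` (data.frame: otu, theoretical,
#'   mean_relab, sd_relab, fold_error, detected) and `fold_summary`
#'   (mean and SD of fold errors over detected OTUs).
#' @export
abundance_error <- function(replicate_counts, truth) {
  if (!length(replicate_counts)) stopf("need at least one replicate")
  theo <- relative_abundance(truth)
  relabs <- lapply(replicate_counts, function(x) {
    v <- stats::setNames(rep(0, length(theo)), names(theo))
    shared <- intersect(names(x), names(theo))
    v[shared] <- x[shared]
    v / max(1, sum(x))
  })
  mat <- do.call(rbind, relabs)
  mean_relab <- colMeans(mat)
  sd_relab <- apply(mat, 2, stats::sd)
  detected <- mean_relab > 0
  fold <- ifelse(detected, mean_relab / theo, NA_real_)
  per_otu <- data.frame(otu = names(theo), theoretical = unname(theo),
                        mean_relab = unname(mean_relab),
                        sd_relab = unname(sd_relab),
                        fold_error = unname(fold),
                        detected = unname(detected),
                        stringsAsFactors = FALSE)
  list(per_otu = per_otu,
       fold_summary = c(mean = mean(fold[detected]),
                        sd = stats::sd(fold[detected])))
}

#' Kolmogorov-Smirnov comparison of rank abundance distributions
#'
#' Two-sample KS test on the rank-abundance value distributions
#' (asymptotic p-value).
#'
#' @param ra_a,ra_b [rank_abundance()] profiles (or numeric vectors).
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_rank_abundance <- function(ra_a, ra_b) {
  a <- as.numeric(ra_a); b <- as.numeric(ra_b)
  if (!length(a) || !length(b)) stopf("empty rank abundance profile")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Correlation between library depth and pool GC content
#'
#' Pearson correlation (two-sided p via the t transform) between the
#' number of reads attributed to each sample and the GC content of its
#' amplicon pool -- the inter-sample GC bias diagnostic.
#'
#' @param depths reads per sample.
#' @param pool_gc GC fraction of each sample's amplicon pool.
#' @return list with `r`, `p_value`, `n`.
#' @export
gc_read_correlation <- function(depths, pool_gc) {
  if (length(depths) < 3L) stopf("need at least three samples")
  if (stats::sd(pool_gc) == 0 || stats::sd(depths) == 0) {
    stopf("constant input: correlation undefined")
  }
  ct <- stats::cor.test(depths, pool_gc, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(depths))
}

#' Welch two-sample comparison of means
#'
#' Two-tailed t test without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stopf("each group needs n >= 2")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' F comparison of variances
#'
#' Two-sided F test with the larger variance in the numerator (F >= 1).
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @return list with `F` (>= 1), `p_value`.
#' @export
compare_variances <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stopf("each group needs n >= 2")
  }
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) return(list(F = 1, p_value = 1))
  if (va >= vb) {
    ft <- stats::var.test(values_a, values_b)
  } else {
    ft <- stats::var.test(values_b, values_a)
  }
  list(F = unname(ft$statistic), p_value = ft$p.value)
}

#' Distances from experimental libraries to the theoretical community
#'
#' Computes the chosen beta-diversity distance from every library to the
#' theoretical profile, and the centroid of the libraries in PCoA space
#' over the joint distance matrix.
#'
#' @param library_counts named list of per-library count vectors (shared
#'   OTU name space with the truth).
#' @param truth a [community_profile()].
#' @param metric "morisita_horn" or "jaccard".
#' @return list with `distances` (named per library), `centroid` (PCoA
#'   coordinates of the library centroid), `theoretical_coords`.
#' @export
distance_to_theoretical <- function(library_counts, truth,
                                    metric = c("morisita_horn",
                                               "jaccard")) {
  metric <- match.arg(metric)
  dfun <- if (metric == "morisita_horn") morisita_horn_distance else
    jaccard_distance
  truth_v <- stats::setNames(as.numeric(truth), names(truth))
  dists <- vapply(library_counts, dfun, numeric(1), b = truth_v)
  all_profiles <- c(library_counts, list(theoretical = truth_v))
  n <- length(all_profiles)
  dm <- matrix(0, n, n,
               dimnames = list(names(all_profiles), names(all_profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      dm[i, j] <- dm[j, i] <- dfun(all_profiles[[i]], all_profiles[[j]])
    }
  }
  ord <- pcoa(dm, n_axes = min(2L, n - 1L))
  libs <- seq_len(n - 1L)
  list(distances = dists,
       centroid = colMeans(ord$coordinates[libs, , drop = FALSE]),
       theoretical_coords = ord$coordinates[n, ],
       pcoa = ord)
}
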