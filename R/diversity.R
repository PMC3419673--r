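#' Chao1 richness estimator
#'
#' Bias-corrected form by default:
#' `S_obs + n1 (n1 - 1) / (2 (n2 + 1))`, where `n1` and `n2` are the
#' singleton and doubleton counts; this variant is defined even when no
#' doubletons were seen. The classic form `S_obs + n1^2 / (2 n2)` is
#' available for comparison.
#'
#' @param counts non-negative integer vector of per-OTU read counts.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return estimated richness (>= observed richness).
#' @export
#' @examples
#' chao1(c(rep(1, 3), rep(2, 2), 5, 5, 9, 4, 7))  # S=10, n1=3, n2=2 -> 11
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- counts[counts > 0]
  if (!length(counts)) stopf("empty community")
  s_obs <- length(counts)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
  } else {
    if (n2 == 0) return(s_obs + ifelse(n1 > 0, n1 * (n1 - 1) / 2, 0))
    s_obs + n1^2 / (2 * n2)
  }
}

#' Inverse Simpson diversity
#'
#' Unbiased finite-sample estimator by default:
#' `1 / D` with `D = sum n_i (n_i - 1) / (N (N - 1))`. The plug-in form
#' `1 / sum p_i^2` is available via `unbiased = FALSE`.
#'
#' @param counts non-negative integer vector of per-OTU read counts.
#' @param unbiased use the unbiased estimator (default TRUE).
#' @return inverse Simpson index (1 for a single-OTU community).
#' @export
#' @examples
#' inverse_simpson(c(5, 5))  # 90/40 = 2.25
inverse_simpson <- function(counts, unbiased = TRUE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (unbiased) {
    if (n < 2) stopf("need at least two reads")
    d <- sum(counts * (counts - 1)) / (n * (n - 1))
    if (d == 0) return(Inf)
    1 / d
  } else {
    if (n < 1) stopf("empty community")
    1 / sum((counts / n)^2)
  }
}

#' Non-parametric (Chao-Shen) Shannon diversity
#'
#' Coverage-adjusted Shannon entropy with Horvitz-Thompson correction
#' for unseen species: coverage `C = 1 - n1/N`, adjusted abundances
#' `p_i = C n_i / N`, and
#' `H = -sum p_i log(p_i) / (1 - (1 - p_i)^N)` (natural log).
#'
#' @param counts non-negative integer vector of per-OTU read counts.
#' @return entropy estimate in nats (0 for a single-OTU community).
#' @export
#' @examples
#' np_shannon(c(2, 2))  # log(2) / (1 - 0.5^4)
np_shannon <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stopf("empty community")
  n <- sum(counts)
  n1 <- sum(counts == 1)
  cover <- 1 - n1 / n
  if (cover == 0) stopf("all reads are singletons: coverage is zero")
  p <- cover * counts / n
  -sum(p * log(p) / (1 - (1 - p)^n))
}

#' Per-sample alpha diversity summary
#'
#' @param counts per-OTU read counts for one sample.
#' @return one-row data.frame: `r_obs`, `r_chao1`, `d_invsimp`,
#'   `d_npshannon`, `n1`, `n2`.
#' @export
alpha_diversity <- function(counts) {
  counts <- counts[counts > 0]
  data.frame(r_obs = length(counts), r_chao1 = chao1(counts),
             d_invsimp = inverse_simpson(counts),
             d_npshannon = np_shannon(counts),
             n1 = sum(counts == 1), n2 = sum(counts == 2))
}

#' Jaccard distance (membership based)
#'
#' `1 - |shared OTUs| / |union OTUs|`; abundances are reduced to
#' presence/absence, so communities with identical membership are at
#' distance 0 whatever their structure.
#'
#' @param a,b named non-negative count (or abundance) vectors; names
#'   identify OTUs.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  pa <- names(a)[a > 0]
  pb <- names(b)[b > 0]
  if (!length(pa) && !length(pb)) stopf("both communities are empty")
  1 - length(intersect(pa, pb)) / length(union(pa, pb))
}

#' Morisita-Horn distance (structure based)
#'
#' `1 - 2 sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) X Y)` with
#' totals `X`, `Y`. Invariant to rescaling either community by a
#' positive constant; 0 for identical relative structure, 1 for
#' disjoint support.
#'
#' @param a,b named non-negative count vectors (names identify OTUs;
#'   OTUs absent from one vector count as zero).
#' @return distance in `[0, 1]` (tiny negative rounding is clamped).
#' @export
#' @examples
#' morisita_horn_distance(c(o1 = 1, o2 = 2), c(o1 = 2, o2 = 1))  # 0.2
morisita_horn_distance <- function(a, b) {
  ids <- union(names(a), names(b))
  x <- stats::setNames(rep(0, length(ids)), ids)
  y <- x
  x[names(a)] <- a
  y[names(b)] <- b
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stopf("zero-total community")
  d <- 1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  min(1, max(0, d))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` for positive eigenvalues (axes from
#' negative eigenvalues are reported but suppressed).
#'
#' @param dm symmetric distance matrix with dimnames.
#' @param n_axes number of axes to return (truncated with a warning if
#'   it exceeds the positive-eigenvalue count).
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending),
#'   `prop_explained` (per positive axis).
#' @export
pcoa <- function(dm, n_axes = 2L) {
  n <- nrow(dm)
  cs <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1L, eig = TRUE))
  eig <- cs$eig
  npos <- sum(eig > 1e-8)
  if (n_axes > npos) {
    warnf("only %d positive eigenvalues; returning %d axes", npos, npos)
    n_axes <- npos
  }
  coords <- cs$points[, seq_len(n_axes), drop = FALSE]
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 prop_explained = pmax(eig, 0)[seq_len(npos)] /
                   sum(pmax(eig, 0))),
            class = "pcoa_result")
}

#' Rank abundance profile
#'
#' @param counts non-negative count vector.
#' @return numeric vector of relative frequencies sorted descending
#'   (class `rank_abundance`); sums to 1.
#' @export
rank_abundance <- function(counts) {
  counts <- counts[counts > 0]
  if (!sum(counts)) stopf("empty community")
  structure(sort(unname(counts / sum(counts)), decreasing = TRUE),
            class = "rank_abundance")
}

#' Random subsampling (rarefaction-style, without replacement)
#'
#' Draws `n` reads without replacement from the read multiset of a
#' community profile, in `replicates` independent replicates.
#'
#' @param profile a [community_profile()] (named integer counts).
#' @param n subsample size; alternatively give `fraction` of the total.
#' @param fraction fraction of reads to keep (used when `n` is NULL).
#' @param replicates number of replicate subsamples.
#' @param seed integer seed.
#' @return list of `community_profile`s (zero-count taxa retained with
#'   count 0).
#' @export
subsample <- function(profile, n = NULL, fraction = NULL,
                      replicates = 1L, seed = 1L) {
  counts <- round(unclass(profile))
  total <- sum(counts)
  if (is.null(n)) {
    if (is.null(fraction)) stopf("give n or fraction")
    n <- round(fraction * total)
  }
  if (n < 1 || n > total) stopf("subsample size %d outside 1..%d", n, total)
  pool <- rep(names(counts), counts)
  lapply(seq_len(replicates), function(r) {
    draw <- with_substream(seed, paste0("subsample:", r),
                           sample(pool, n))
    tab <- table(factor(draw, levels = names(counts)))
    community_profile(stats::setNames(as.integer(tab), names(counts)))
  })
}
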