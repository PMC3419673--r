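#' Build a mock-community abundance design
#'
#' Assigns one abundance level (low/medium/high weight) to each GC cluster
#' of a reference set. Variant `m1` is the even community (all weights
#' equal); `m2` and `m3` are the two uneven communities with identical
#' sorted weight vectors but swapped high/low clusters: the cluster given
#' the highest weight in `m2` receives the lowest weight in `m3` and vice
#' versa, while the medium cluster keeps its level.
#'
#' @param refs a [reference_set][generate_reference_set].
#' @param level_weights three positive relative weights (low, medium, high
#'   abundance level). The default (1, 80, 1000) is the uneven design in
#'   which the lowest level contributes one read per sequence when
#'   realized as an in-silico community.
#' @param variant "m1", "m2" or "m3".
#' @return object of class `mock_design` with fields `community_id`,
#'   `level_weights`, `cluster_to_level` (named low/medium/high GC cluster
#'   -> weight), `n_per_cluster`, and `refs`.
#' @export
#' @examples
#' refs <- generate_reference_set(3, c(0.45, 0.50, 0.55), 300, seed = 1)
#' d2 <- build_mock_design(refs, c(1, 80, 1000), "m2")
#' d2$cluster_to_level
build_mock_design <- function(refs, level_weights = c(1, 80, 1000),
                              variant = c("m1", "m2", "m3")) {
  variant <- match.arg(variant)
  if (any(level_weights <= 0) || length(level_weights) != 3L) {
    stopf("level_weights must be three positive weights")
  }
  w <- sort(as.numeric(level_weights))
  if (variant == "m1") {
    cl2lv <- c(low = 1, medium = 1, high = 1)
  } else {
    if (length(unique(w)) == 1L) {
      warnf("uneven variant %s requested with equal weights (degenerate design)",
            variant)
    }
    # m2: low-GC cluster gets the high weight; m3 swaps high/low weights
    cl2lv <- if (variant == "m2") {
      c(low = w[3], medium = w[2], high = w[1])
    } else {
      c(low = w[1], medium = w[2], high = w[3])
    }
  }
  structure(list(
    community_id = variant,
    level_weights = w,
    cluster_to_level = cl2lv,
    n_per_cluster = sum(refs$gc_cluster == "low"),
    refs = refs
  ), class = "mock_design")
}

#' Realize a design as an integer-count in-silico community
#'
#' For uneven designs the weights are normalized so the lowest abundance
#' level contributes exactly one read per sequence; medium and high levels
#' are rounded to the nearest integer. For the even design `m1`,
#' `match_total` grows the community to (approximately) the total read
#' count of the corresponding uneven communities: each sequence receives
#' `round(match_total / n_sequences)` reads.
#'
#' @param design a [mock_design][build_mock_design].
#' @param match_total optional target total (even design only).
#' @return object of class `community_profile`: a named integer vector of
#'   per-sequence read counts with a `total` attribute.
#' @export
#' @examples
#' refs <- generate_reference_set(2, c(0.45, 0.50, 0.55), 300, seed = 1)
#' d <- build_mock_design(refs, c(1, 10, 100), "m2")
#' sum(build_insilico_community(d))  # 2 * (1 + 10 + 100)
build_insilico_community <- function(design, match_total = NULL) {
  refs <- design$refs
  if (design$community_id == "m1") {
    per_seq <- if (is.null(match_total)) 1L else {
      as.integer(round(match_total / nrow(refs)))
    }
    counts <- rep(per_seq, nrow(refs))
  } else {
    if (!is.null(match_total)) {
      stopf("match_total applies to the even design m1 only")
    }
    lv <- design$cluster_to_level[as.character(refs$gc_cluster)]
    scaled <- lv / min(lv)  # lowest level -> exactly 1 read per sequence
    counts <- as.integer(round(scaled))
    if (any(abs(scaled - counts) > 1e-9)) {
      warnf("non-integer level ratios; counts rounded to nearest integer")
    }
  }
  community_profile(stats::setNames(counts, refs$id))
}

#' Community profile constructor
#'
#' @param counts named non-negative numeric vector of per-taxon read
#'   counts (or relative abundances).
#' @return `community_profile` object (named vector with `total`
#'   attribute).
#' @export
community_profile <- function(counts) {
  if (is.null(names(counts)) || any(counts < 0)) {
    stopf("counts must be a named non-negative vector")
  }
  structure(counts, total = sum(counts), class = "community_profile")
}

#' Relative-abundance form of a community profile
#' @param profile a `community_profile` (or named count vector).
#' @return named numeric vector summing to 1.
#' @export
relative_abundance <- function(profile) {
  tot <- sum(profile)
  if (tot <= 0) stopf("profile has zero total")
  v <- unclass(profile)
  attributes(v) <- list(names = names(v))
  v / tot
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("community_profile: %d taxa, %s reads\n",
              length(x), format(attr(x, "total"), big.mark = ",")))
  invisible(x)
}

#' Theoretical profiles for the three mock communities
#'
#' Convenience wrapper returning the integer in-silico community for each
#' of m1/m2/m3 under the "lowest level = one read per sequence" rule, with
#' m1 matched to the uneven total.
#'
#' @param refs a [reference_set][generate_reference_set].
#' @param level_weights three positive weights, see
#'   [build_mock_design()].
#' @return named list of three `community_profile`s (m1, m2, m3).
#' @export
theoretical_profiles <- function(refs, level_weights = c(1, 80, 1000)) {
  d2 <- build_mock_design(refs, level_weights, "m2")
  d3 <- build_mock_design(refs, level_weights, "m3")
  p2 <- build_insilico_community(d2)
  p3 <- build_insilico_community(d3)
  d1 <- build_mock_design(refs, level_weights, "m1")
  p1 <- build_insilico_community(d1, match_total = attr(p2, "total"))
  list(m1 = p1, m2 = p2, m3 = p3)
}
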