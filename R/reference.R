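#' Generate a synthetic reference set with low/medium/high GC clusters
#'
#' Synthesizes `3 * n_per_cluster` reference sequences of equal length,
#' partitioned into three GC clusters whose per-cluster mean GC fraction
#' hits the requested targets to within 0.01. Sequences are built by
#' constrained mutation of one random per-domain backbone: every sequence
#' differs from the backbone at >= 12% of positions, which keeps all
#' pairwise identities below 97% so that each reference seeds its own OTU
#' at a 3% distance cutoff. Homopolymer runs longer than
#' `max_homopolymer` are broken during backbone construction.
#'
#' Because every sequence derives from the same backbone by substitutions
#' only, the set is its own gapless multiple alignment (see
#' [build_seed_alignment()]).
#'
#' @param n_per_cluster sequences per GC cluster (11 for the bacterial
#'   design, 8 for the archaeal design).
#' @param gc_targets strictly increasing vector of three GC fractions in
#'   (0, 1); defaults are the bacterial tertiles (0.511, 0.551, 0.593).
#' @param region_length length of the amplified target region in nt.
#' @param domain_tag "bacteria" or "archaea" (label only).
#' @param seed integer seed; the same call with the same seed is
#'   byte-identical.
#' @param max_homopolymer longest homopolymer run permitted in the
#'   backbone.
#' @return object of class `reference_set`: a data.frame with columns
#'   `id`, `sequence`, `gc_fraction`, `gc_cluster` (low/medium/high) and
#'   `domain_tag`.
#' @export
#' @examples
#' refs <- generate_reference_set(3, c(0.45, 0.5, 0.55), 300, seed = 1)
#' tapply(refs$gc_fraction, refs$gc_cluster, mean)
generate_reference_set <- function(n_per_cluster,
                                   gc_targets = c(0.511, 0.551, 0.593),
                                   region_length = 570L,
                                   domain_tag = c("bacteria", "archaea"),
                                   seed = 1L,
                                   max_homopolymer = 8L) {
  domain_tag <- match.arg(domain_tag)
  if (n_per_cluster < 1L) stopf("n_per_cluster must be >= 1")
  if (length(gc_targets) != 3L || any(diff(gc_targets) <= 0) ||
      any(gc_targets <= 0) || any(gc_targets >= 1)) {
    stopf("gc_targets must be three strictly increasing fractions in (0, 1)")
  }
  L <- as.integer(region_length)
  # feasibility: target GC counts must be representable
  for (t in gc_targets) {
    if (round(t * L) < 1L || round(t * L) > L - 1L) {
      stopf("GC target %.3f is infeasible for region length %d", t, L)
    }
  }

  with_substream(seed, paste0("refset:", domain_tag), {
    backbone <- random_backbone(L, mean(gc_targets), max_homopolymer)
    clusters <- c("low", "medium", "high")
    rows <- vector("list", 3L * n_per_cluster)
    idx <- 1L
    for (ci in seq_along(clusters)) {
      for (j in seq_len(n_per_cluster)) {
        s <- mutate_to_gc(backbone, gc_targets[ci], min_frac = 0.12)
        id <- sprintf("%s_%s_%02d",
                      if (domain_tag == "bacteria") "bact" else "arch",
                      clusters[ci], j)
        rows[[idx]] <- data.frame(
          id = id, sequence = s, gc_fraction = gc_fraction(s),
          gc_cluster = clusters[ci], domain_tag = domain_tag,
          stringsAsFactors = FALSE
        )
        idx <- idx + 1L
      }
    }
    refs <- do.call(rbind, rows)
    refs$gc_cluster <- factor(refs$gc_cluster,
                              levels = c("low", "medium", "high"))
    # enforce the <97% pairwise identity invariant (same-length gapless
    # sequences: identity is the Hamming agreement fraction)
    idmat <- pairwise_identity(refs$sequence)
    diag(idmat) <- 0
    if (any(idmat >= 0.97)) {
      stopf("reference synthesis failed the <97%% pairwise identity bound")
    }
    structure(refs, class = c("reference_set", "data.frame"),
              region_length = L, seed = as.integer(seed))
  })
}

# random backbone at a given GC with homopolymer control
random_backbone <- function(L, gc, max_homopolymer = 8L) {
  pr <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  b <- sample(DNA_BASES, L, replace = TRUE, prob = pr)
  # break runs longer than max_homopolymer
  repeat {
    r <- rle(b)
    long <- which(r$lengths > max_homopolymer)
    if (!length(long)) break
    ends <- cumsum(r$lengths)
    for (i in long) {
      pos <- ends[i]  # replace the run's last base
      b[pos] <- sample(setdiff(DNA_BASES, b[pos]), 1L)
    }
  }
  paste(b, collapse = "")
}

# Mutate >= min_frac of positions so the result has GC count round(gc*L)
# exactly; every mutated position differs from the backbone base.
mutate_to_gc <- function(backbone, gc_target, min_frac = 0.12) {
  b <- strsplit(backbone, "")[[1]]
  L <- length(b)
  g_target <- round(gc_target * L)
  for (frac in c(min_frac, 0.2, 0.3)) {
    m <- ceiling(frac * L)
    pos <- sort(sample.int(L, m))
    outside_gc <- sum(b[-pos] %in% c("G", "C"))
    need <- g_target - outside_gc  # GC bases required among mutated sites
    if (need < 0L || need > m) next
    s <- b
    gc_sites <- sample(seq_len(m), need)
    is_gc <- logical(m); is_gc[gc_sites] <- TRUE
    for (k in seq_len(m)) {
      p <- pos[k]
      cand <- if (is_gc[k]) c("G", "C") else c("A", "T")
      cand <- setdiff(cand, b[p])
      if (!length(cand)) cand <- if (is_gc[k]) c("G", "C") else c("A", "T")
      s[p] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    return(paste(s, collapse = ""))
  }
  stopf("GC target %.3f is infeasible for this backbone", gc_target)
}

#' Pairwise identity matrix for equal-length sequences
#'
#' Agreement fraction per position (sequences are gapless and aligned by
#' construction).
#' @param seqs character vector of equal-length sequences.
#' @return symmetric numeric matrix of identities in `[0, 1]`.
#' @export
pairwise_identity <- function(seqs) {
  n <- length(seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stopf("pairwise_identity expects equal-length sequences")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  out <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      out[i, j] <- out[j, i] <- mean(mat[i, ] == mat[j, ])
    }
  }
  out
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d sequences (%s), region length %d nt\n",
              nrow(x), x$domain_tag[1], attr(x, "region_length")))
  gm <- tapply(x$gc_fraction, x$gc_cluster, mean)
  cat(sprintf("  GC cluster means: low %.3f, medium %.3f, high %.3f\n",
              gm["low"], gm["medium"], gm["high"]))
  invisible(x)
}
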