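#' Average-neighbor (UPGMA-criterion) OTU clustering
#'
#' Agglomerative clustering on a distance matrix: at each step the pair
#' of clusters with the smallest mean inter-cluster distance is merged,
#' and merging stops as soon as that smallest mean exceeds the cutoff.
#' OTUs are therefore defined at average linkage <= `cutoff` (3%
#' distance by default, the usual reading of a "3% similarity cutoff").
#' Ties are broken deterministically: among equally close pairs the one
#' whose (lexicographically smallest member, then second member) label
#' sorts first is merged, so the result does not depend on input order.
#'
#' @param dm symmetric numeric distance matrix with dimnames.
#' @param cutoff linkage cutoff (default 0.03).
#' @return named integer vector: OTU index (1-based, in order of first
#'   appearance) per input label.
#' @export
#' @examples
#' dm <- matrix(c(0, .01, .05, .01, 0, .05, .05, .05, 0), 3,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' cluster_average_neighbor(dm, 0.03)  # A,B together; C alone
cluster_average_neighbor <- function(dm, cutoff = 0.03) {
  labels <- rownames(dm)
  n <- nrow(dm)
  if (is.null(labels) || any(abs(dm - t(dm)) > 1e-12) ||
      any(diag(dm) != 0)) {
    stopf("dm must be a labeled symmetric matrix with zero diagonal")
  }
  # A merge at mean distance <= cutoff requires at least one member pair
  # <= cutoff, so clusters can never straddle two connected components
  # of the <=cutoff graph; running UPGMA per component is exact and
  # avoids the O(n^2) scan over mostly-unmergeable pairs.
  comp <- graph_components(dm <= cutoff)
  otus <- integer(n)
  next_otu <- 0L
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    sub <- upgma_merge(dm[idx, idx, drop = FALSE], labels[idx], cutoff)
    otus[idx] <- sub + next_otu
    next_otu <- next_otu + max(sub)
  }
  # renumber in order of first appearance
  first <- tapply(seq_len(n), otus, min)
  remap <- integer(max(otus))
  remap[as.integer(names(sort(first)))] <- seq_along(first)
  stats::setNames(remap[otus], labels)
}

# connected components of a logical adjacency matrix (diagonal ignored)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# agglomerative mean-linkage within one component; masked in place
upgma_merge <- function(D, labels, cutoff) {
  n <- nrow(D)
  if (n == 1L) return(1L)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  clabel <- labels   # lexicographically smallest member label
  n_active <- n
  while (n_active > 1L) {
    mval <- min(D)
    if (mval > cutoff) break
    cand <- which(D == mval, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(p) {
      paste(sort(c(clabel[p[1]], clabel[p[2]])), collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    # UPGMA update: mean over all member pairs (Inf rows stay Inf)
    newrow <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    newrow[i] <- Inf
    D[i, ] <- newrow; D[, i] <- newrow
    D[j, ] <- Inf; D[, j] <- Inf
    active[j] <- FALSE
    n_active <- n_active - 1L
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    clabel[i] <- min(clabel[i], clabel[j])
  }
  otus <- integer(n)
  live <- which(active)
  live <- live[order(vapply(members[live], min, integer(1)))]
  for (k in seq_along(live)) otus[members[[live[k]]]] <- k
  otus
}

#' Classify OTUs as good or spurious and tabulate per-sample counts
#'
#' An OTU is "good" iff it contains at least one reference sequence; all
#' other OTUs are the footprint of surviving sequencing errors and
#' chimeras and are tagged spurious. Reference sequences themselves are
#' excluded from the counts, so column sums equal the retained reads per
#' sample.
#'
#' @param assignments named integer vector from
#'   [cluster_average_neighbor()] over reads *and* references.
#' @param ref_ids labels in `assignments` that are references.
#' @param sample_of named character vector mapping read label -> sample
#'   id (reads absent from it default to sample "s1").
#' @param cutoff the clustering cutoff used (stored for provenance).
#' @return object of class `otu_table`: list with `counts` (OTU x sample
#'   integer matrix), `status` ("good"/"spurious" per OTU), `ref_ids`
#'   (list of member references per OTU) and `cutoff`.
#' @export
classify_otus <- function(assignments, ref_ids, sample_of = NULL,
                          cutoff = 0.03) {
  labels <- names(assignments)
  if (!any(labels %in% ref_ids)) {
    stopf("no reference sequence present in the clustered matrix")
  }
  is_ref <- labels %in% ref_ids
  read_labels <- labels[!is_ref]
  if (is.null(sample_of)) {
    sample_of <- stats::setNames(rep("s1", length(read_labels)),
                                 read_labels)
  }
  otu_ids <- sort(unique(assignments))
  refs_in <- lapply(otu_ids, function(o) {
    labels[is_ref & assignments == o]
  })
  status <- ifelse(lengths(refs_in) > 0L, "good", "spurious")
  otu_names <- ifelse(status == "good",
                      vapply(refs_in, function(r) sort(r)[1], character(1)),
                      sprintf("spurious_%03d", cumsum(status == "spurious")))
  samples <- sort(unique(unname(sample_of[read_labels])))
  counts <- matrix(0L, length(otu_ids), length(samples),
                   dimnames = list(otu_names, samples))
  if (length(read_labels)) {
    tab <- table(factor(assignments[read_labels], levels = otu_ids),
                 factor(sample_of[read_labels], levels = samples))
    counts[, ] <- as.integer(tab)
  }
  structure(list(counts = counts, status = status, ref_ids = refs_in,
                 cutoff = cutoff),
            class = "otu_table")
}

#' Drop spurious OTUs from an OTU table
#'
#' @param ot an [otu_table][classify_otus].
#' @return the table restricted to good OTUs (counts of good OTUs are
#'   untouched).
#' @export
drop_spurious <- function(ot) {
  keep <- ot$status == "good"
  structure(list(counts = ot$counts[keep, , drop = FALSE],
                 status = ot$status[keep], ref_ids = ot$ref_ids[keep],
                 cutoff = ot$cutoff),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs (%d good, %d spurious) x %d samples at cutoff %.2f\n",
              nrow(x$counts), sum(x$status == "good"),
              sum(x$status == "spurious"), ncol(x$counts), x$cutoff))
  invisible(x)
}
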