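#' Build a seed alignment from a reference set
#'
#' References produced by [generate_reference_set()] share one backbone
#' and differ by substitutions only, so the set is its own gapless
#' multiple alignment: every reference occupies all columns
#' `1..region_length`. The seed carries the expected terminal column of
#' the sequenced (V5) end, used by [screen_alignment_span()].
#'
#' @param refs a [reference_set][generate_reference_set], or a named
#'   character vector of pre-aligned equal-width rows (gaps `-`,
#'   terminal gaps `.`).
#' @return object of class `seed_alignment`: list with `rows` (named
#'   character), `width`, and `region_end` column.
#' @export
build_seed_alignment <- function(refs) {
  rows <- if (inherits(refs, "reference_set")) {
    stats::setNames(refs$sequence, refs$id)
  } else refs
  w <- unique(nchar(rows))
  if (length(w) != 1L) stopf("seed rows must have equal width")
  structure(list(rows = rows, width = w, region_end = w),
            class = "seed_alignment")
}

#' Align reads into seed-alignment coordinates
#'
#' Template selection by shared 8-mers (both read orientations are
#' tried and the better one kept), then semi-global Needleman-Wunsch
#' alignment (affine gaps, seed ends free) of the read against the
#' winning seed row. Read gaps are mapped into seed columns; read
#' insertions relative to the seed are dropped so that every aligned
#' read lives in the common column coordinate system. Columns outside
#' the read's footprint are written as terminal-gap `.` characters.
#'
#' @param reads character vector of QC-passed read sequences (in
#'   sequencing orientation; the aligner reorients them).
#' @param seed a [build_seed_alignment()] object.
#' @param k k-mer size for template search (default 8).
#' @return data.frame with columns `aligned` (row in seed coordinates),
#'   `template` (winning seed row), `orientation` ("forward"/"reverse"),
#'   `unalignable` (no shared k-mer with any row).
#' @export
align_to_seed <- function(reads, seed, k = 8L) {
  stopifnot(inherits(seed, "seed_alignment"))
  ref_ids <- names(seed$rows)
  n_ref <- length(ref_ids)
  # hashed k-mer -> reference-indices dictionary, built once
  dict <- new.env(hash = TRUE, size = 131072L, parent = emptyenv())
  for (r in seq_len(n_ref)) {
    for (km in kmer_set(seed$rows[[r]], k)) {
      dict[[km]] <- c(dict[[km]], r)
    }
  }
  shared_counts <- function(kmers) {
    hits <- unlist(mget(kmers, envir = dict,
                        ifnotfound = list(NULL)), use.names = FALSE)
    if (is.null(hits)) return(integer(n_ref))
    tabulate(hits, nbins = n_ref)
  }
  n <- length(reads)
  tmpl <- character(n); orient <- character(n)
  unalignable <- logical(n)
  oriented <- character(n)
  rc <- revcomp(reads)
  for (i in seq_len(n)) {
    sf <- shared_counts(kmer_set(reads[i], k))
    sr <- shared_counts(kmer_set(rc[i], k))
    if (max(sf, sr) == 0) {
      unalignable[i] <- TRUE
      tmpl[i] <- NA_character_; orient[i] <- NA_character_
      oriented[i] <- NA_character_
    } else if (max(sf) >= max(sr)) {
      tmpl[i] <- ref_ids[which.max(sf)]; orient[i] <- "forward"
      oriented[i] <- reads[i]
    } else {
      tmpl[i] <- ref_ids[which.max(sr)]; orient[i] <- "reverse"
      oriented[i] <- rc[i]
    }
  }
  aligned <- rep(NA_character_, n)
  for (i in which(!unalignable)) {
    aligned[i] <- cpp_nast_align(oriented[i], seed$rows[[tmpl[i]]])
  }
  data.frame(aligned = aligned, template = tmpl, orientation = orient,
             unalignable = unalignable, stringsAsFactors = FALSE)
}

#' Drop reads that do not reach the sequenced end of the region
#'
#' Reads whose alignment footprint ends more than `tolerance` columns
#' before the expected terminal (V5) column of the seed are flagged as
#' poorly aligned and dropped: a read sequenced from the V5 end must
#' terminate there.
#'
#' @param aligned character vector of rows in seed coordinates (from
#'   [align_to_seed()]).
#' @param seed the [build_seed_alignment()] object.
#' @param tolerance permitted deviation in columns (default 5;
#'   `Inf` disables the screen).
#' @return logical vector, `TRUE` = keep.
#' @export
screen_alignment_span <- function(aligned, seed, tolerance = 5) {
  vapply(aligned, function(row) {
    if (is.na(row)) return(FALSE)
    chars <- strsplit(row, "")[[1]]
    covered <- which(chars != ".")
    if (!length(covered)) return(FALSE)
    (seed$region_end - max(covered)) <= tolerance
  }, logical(1), USE.NAMES = FALSE)
}

#' Reference-based bimera detection
#'
#' For each aligned read, `i1` is its best single-reference identity
#' over the columns it covers, and `i2` the best two-reference split
#' identity: the maximum over breakpoints of (matches to reference A on
#' the left + matches to reference B on the right) / columns covered.
#' Breakpoints are scanned on a 10-column grid and refined around the
#' best split. A read is flagged as a chimera when the split model beats
#' the single-parent model by at least `score_threshold` *and* the split
#' identity is near-perfect (`i2 >= min_i2`), i.e. the read looks like
#' two clean reference fragments joined together rather than a noisy
#' copy of one reference.
#'
#' @param aligned character vector of rows in seed coordinates.
#' @param seed the [build_seed_alignment()] object.
#' @param score_threshold minimum `i2 - i1` gain (default 0.03).
#' @param min_i2 minimum split identity (default 0.99).
#' @param step breakpoint grid step in columns (default 10).
#' @return data.frame with `i1`, `i2`, `flagged`.
#' @export
detect_chimeras <- function(aligned, seed, score_threshold = 0.03,
                            min_i2 = 0.99, step = 10L) {
  ref_mat <- do.call(rbind, strsplit(unname(seed$rows), ""))
  n_ref <- nrow(ref_mat)
  out <- data.frame(i1 = rep(NA_real_, length(aligned)),
                    i2 = NA_real_, flagged = FALSE)
  for (i in seq_along(aligned)) {
    row <- aligned[i]
    if (is.na(row)) next
    chars <- strsplit(row, "")[[1]]
    covered <- which(chars != ".")
    m <- length(covered)
    if (m < 2L * step) next
    # per-reference cumulative match counts over covered columns
    # (cum is m x n_ref: row t holds matches in columns 1..t per ref)
    rc <- chars[covered]
    cum <- apply(ref_mat[, covered, drop = FALSE], 1,
                 function(refrow) cumsum(rc == refrow))
    tot <- cum[m, ]
    i1 <- max(tot) / m
    split_score <- function(t) max(cum[t, ]) + max(tot - cum[t, ])
    grid <- seq(step, m - step, by = step)
    sc <- vapply(grid, split_score, numeric(1))
    best <- grid[which.max(sc)]
    fine <- max(1L, best - step):min(m - 1L, best + step)
    i2 <- max(vapply(fine, split_score, numeric(1))) / m
    out$i1[i] <- i1
    out$i2[i] <- max(i1, i2)
    out$flagged[i] <- (out$i2[i] - i1 >= score_threshold) &&
      (out$i2[i] >= min_i2)
  }
  out
}

#' Filter alignment columns (vertical gaps and terminal-gap trump)
#'
#' Removes every column containing a terminal-gap `.` in any row (so all
#' sequences are compared along the same stretch of the gene) and every
#' column that is gap in all rows.
#'
#' @param rows character vector of equal-width alignment rows.
#' @return character vector of filtered rows; attribute `width` holds
#'   the retained width.
#' @export
filter_columns <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  has_dot <- colSums(mat == ".") > 0L
  all_gap <- colSums(mat == "-") == nrow(mat)
  keep <- !(has_dot | all_gap)
  if (!any(keep)) stopf("column filtering removed every column")
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(rows)
  attr(out, "width") <- sum(keep)
  out
}

#' Pairwise distance matrix from filtered alignment rows
#'
#' Distance between two rows = (substitution columns + gap-run events) /
#' compared columns, where a run of contiguous gap columns in one row
#' counts as a single mismatch event (and a single compared column) and
#' columns gapped in both rows are skipped -- the common convention for
#' OTU work at small cutoffs.
#'
#' @param rows named character vector of equal-width filtered rows.
#' @return symmetric numeric `distance matrix` in `[0, 1]`, zero
#'   diagonal, labels as dimnames.
#' @export
pairwise_distance <- function(rows) {
  m <- cpp_dist_onegap(unname(rows))
  if (anyNA(m)) stopf("a sequence pair shares no comparable columns")
  dimnames(m) <- list(names(rows), names(rows))
  m
}
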