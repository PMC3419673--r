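#' Design multiplexing barcodes
#'
#' Greedy-random construction of `n` fixed-length barcodes such that every
#' pair is at Levenshtein distance at least `min_lev` (edit distance via
#' [utils::adist()]). Used for pooled sequencing: barcodes identify the
#' sample each read came from, and a distance-3 code keeps single errors
#' from reassigning reads. Candidates containing homopolymer runs longer
#' than `max_homopolymer` are rejected: pyrosequencing resolves a
#' homopolymer in a single flow whose called length is its dominant error
#' mode, so barcodes -- which must demultiplex exactly -- are kept
#' homopolymer-free (a proxy for the flow-count screening used when such
#' codes are designed for real runs).
#'
#' @param n number of barcodes.
#' @param length barcode length in nt (default 10).
#' @param min_lev minimum pairwise Levenshtein distance (default 3).
#' @param seed integer seed (construction is deterministic given the
#'   seed).
#' @param max_homopolymer longest run of one base allowed within a
#'   barcode (default 2).
#' @param max_attempts candidate draws before giving up.
#' @return object of class `barcode_set`: character vector of barcodes
#'   with `length` and `min_levenshtein` attributes.
#' @export
#' @examples
#' bc <- design_barcodes(4, seed = 1)
#' min(utils::adist(bc)[upper.tri(utils::adist(bc))])  # >= 3
design_barcodes <- function(n, length = 10L, min_lev = 3L, seed = 1L,
                            max_homopolymer = 2L, max_attempts = 10000L) {
  if (n < 1L) stopf("n must be >= 1")
  with_substream(seed, "barcodes", {
    picked <- character(0)
    attempts <- 0L
    while (length(picked) < n && attempts < max_attempts) {
      cand <- paste(sample(DNA_BASES, length, replace = TRUE),
                    collapse = "")
      attempts <- attempts + 1L
      if (max(rle(strsplit(cand, "")[[1]])$lengths) > max_homopolymer) {
        next
      }
      if (!length(picked) ||
          min(utils::adist(cand, picked)) >= min_lev) {
        picked <- c(picked, cand)
      }
    }
    if (length(picked) < n) {
      stopf("could only place %d of %d barcodes after %d attempts",
            length(picked), n, max_attempts)
    }
    structure(picked, length = as.integer(length),
              min_levenshtein = as.integer(min_lev),
              class = "barcode_set")
  })
}

#' Primer specification
#'
#' @param name primer name.
#' @param iupac_sequence sequence over IUPAC degeneracy codes.
#' @param orientation "forward" or "reverse".
#' @return object of class `primer_spec`.
#' @export
#' @examples
#' primer_spec("Bact-338F1", "CCTACGGGRGGCAGCAG", "forward")
primer_spec <- function(name, iupac_sequence,
                        orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  chars <- strsplit(toupper(iupac_sequence), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad)) {
    stopf("invalid IUPAC code '%s' at position %d of primer %s",
          chars[bad[1]], bad[1], name)
  }
  structure(list(name = name, iupac_sequence = paste(chars, collapse = ""),
                 orientation = orientation),
            class = "primer_spec")
}

#' Expand a degenerate primer into its concrete sequences
#'
#' @param primer a [primer_spec()] (or plain IUPAC string).
#' @return character vector of all concrete A/C/G/T sequences; its length
#'   is the product of the per-position degeneracies.
#' @export
#' @examples
#' expand_degenerate_primer("CCTACGGGRGGCAGCAG")  # 2 variants (one R)
expand_degenerate_primer <- function(primer) {
  seq <- if (inherits(primer, "primer_spec")) primer$iupac_sequence else {
    primer_spec("adhoc", primer)$iupac_sequence
  }
  opts <- IUPAC_CODES[strsplit(seq, "")[[1]]]
  grid <- do.call(expand.grid,
                  c(rev(opts), list(stringsAsFactors = FALSE)))
  sort(apply(grid[, rev(seq_along(opts)), drop = FALSE], 1, paste,
             collapse = ""))
}

#' Fraction of references matched by a primer
#'
#' Scans each reference (both strands) for any expanded primer variant
#' within `max_mismatch` substitutions, at any offset.
#'
#' @param primer a [primer_spec()] or IUPAC string.
#' @param refs a [reference_set][generate_reference_set] or character
#'   vector of sequences.
#' @param max_mismatch maximum substitutions tolerated (default 0).
#' @return list with `coverage` (fraction in `[0, 1]`) and `hits`
#'   (logical per reference).
#' @export
primer_coverage <- function(primer, refs, max_mismatch = 0L) {
  seqs <- if (inherits(refs, "reference_set")) refs$sequence else
    as.character(refs)
  if (!length(seqs)) stopf("empty reference set")
  variants <- expand_degenerate_primer(primer)
  plen <- nchar(variants[1])
  if (any(nchar(seqs) < plen)) {
    stopf("references must be longer than the primer")
  }
  hits <- vapply(seqs, function(s) {
    for (target in c(s, revcomp(s))) {
      tc <- strsplit(target, "")[[1]]
      n <- length(tc)
      for (v in variants) {
        vc <- strsplit(v, "")[[1]]
        for (off in 0:(n - plen)) {
          if (sum(tc[off + seq_len(plen)] != vc) <= max_mismatch) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  list(coverage = mean(hits), hits = hits)
}
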