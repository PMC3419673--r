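#' Demultiplex pooled reads by exact-length barcode prefix
#'
#' A read is assigned to a sample iff its leading bases match exactly one
#' barcode within `barcode_mismatch_max` substitutions (default 0). Reads
#' matching two barcodes at the same best distance are discarded rather
#' than guessed, since barcodes decide how sequences are binned. The
#' barcode is stripped from assigned reads.
#'
#' @param lib a [read_library][simulate_library] holding the pooled
#'   reads.
#' @param barcodes named character vector, barcode sequence -> sample
#'   label (all barcodes equal length).
#' @param params a [qc_params()].
#' @return list with `samples` (named list of per-sample `read_library`
#'   objects) and `n_unassigned`.
#' @export
demultiplex <- function(lib, barcodes, params = qc_params()) {
  blen <- unique(nchar(names(barcodes)))
  if (length(blen) != 1L) stopf("barcodes must share one length")
  bmat <- do.call(rbind, strsplit(names(barcodes), ""))
  assign_of <- rep(NA_character_, nrow(lib$reads))
  for (i in seq_len(nrow(lib$reads))) {
    s <- lib$reads$sequence[i]
    if (nchar(s) < blen) next
    pre <- strsplit(substr(s, 1L, blen), "")[[1]]
    d <- rowSums(sweep(bmat, 2, pre, "!="))
    best <- min(d)
    if (best <= params$barcode_mismatch_max && sum(d == best) == 1L) {
      assign_of[i] <- unname(barcodes[which.min(d)])
    }
  }
  samples <- lapply(unique(stats::na.omit(assign_of)), function(smp) {
    idx <- which(assign_of == smp)
    reads <- lib$reads[idx, , drop = FALSE]
    reads$sequence <- substring(reads$sequence, blen + 1L)
    structure(list(sample_id = smp, barcode = NA_character_,
                   primer = lib$primer, reads = reads,
                   quals = lapply(lib$quals[idx],
                                  function(q) q[-seq_len(blen)])),
              class = "read_library")
  })
  names(samples) <- unique(stats::na.omit(assign_of))
  list(samples = samples, n_unassigned = sum(is.na(assign_of)))
}

#' Screen and strip the (reverse) primer from barcode-stripped reads
#'
#' A read is accepted iff the best Hamming distance between its leading
#' bases and any expansion of the degenerate primer is at most
#' `primer_mismatch_max` (default 1, tolerated because the primer region
#' is discarded and takes no part in any downstream analysis). The primer
#' region is removed from accepted reads.
#'
#' @param lib a per-sample [read_library][simulate_library].
#' @param primer a [primer_spec()] or IUPAC string.
#' @param params a [qc_params()].
#' @return list with `lib` (accepted, primer-stripped reads) and
#'   `n_rejected`.
#' @export
check_primer <- function(lib, primer, params = qc_params()) {
  variants <- expand_degenerate_primer(primer)
  plen <- nchar(variants[1])
  vmat <- do.call(rbind, strsplit(variants, ""))
  ok <- logical(nrow(lib$reads))
  for (i in seq_len(nrow(lib$reads))) {
    s <- lib$reads$sequence[i]
    if (nchar(s) < plen) next
    pre <- strsplit(substr(s, 1L, plen), "")[[1]]
    ok[i] <- min(rowSums(sweep(vmat, 2, pre, "!="))) <=
      params$primer_mismatch_max
  }
  lib$reads <- lib$reads[ok, , drop = FALSE]
  lib$reads$sequence <- substring(lib$reads$sequence, plen + 1L)
  lib$quals <- lapply(lib$quals[ok], function(q) q[-seq_len(plen)])
  list(lib = lib, n_rejected = sum(!ok))
}

#' Sliding-window quality trimming
#'
#' Windows of `window_size` bases advance one base at a time from the
#' start of the read. At the first window whose mean quality drops below
#' `q_threshold` the read is truncated at that window's start, so only
#' the (high-quality) sequencing end is retained. Reads shorter than the
#' window are evaluated as a single window over their full length rather
#' than skipping QC.
#'
#' @param sequence read sequence.
#' @param qual integer quality vector, same length.
#' @param params a [qc_params()].
#' @return list with trimmed `sequence` and `qual`.
#' @export
trim_quality <- function(sequence, qual, params = qc_params()) {
  n <- length(qual)
  if (nchar(sequence) != n) stopf("quality length must equal read length")
  w <- params$window_size
  if (n == 0L) return(list(sequence = sequence, qual = qual))
  if (n < w) {
    if (mean(qual) < params$q_threshold) {
      return(list(sequence = "", qual = integer(0)))
    }
    return(list(sequence = sequence, qual = qual))
  }
  cs <- cumsum(c(0, qual))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  bad <- which(means < params$q_threshold)
  if (!length(bad)) return(list(sequence = sequence, qual = qual))
  keep <- bad[1] - 1L  # truncate at the failing window's start
  list(sequence = substr(sequence, 1L, keep), qual = qual[seq_len(keep)])
}

#' Ambiguity and minimum-length filter
#'
#' Removes reads with more than `max_ambiguous` non-ACGT bases or a
#' (post-trimming) length strictly below `min_length`.
#'
#' @param lib a [read_library][simulate_library].
#' @param params a [qc_params()].
#' @return list with `lib` (retained reads), `n_ambiguous`, `n_short`.
#' @export
filter_reads <- function(lib, params = qc_params()) {
  lens <- nchar(lib$reads$sequence)
  n_amb <- vapply(strsplit(lib$reads$sequence, ""),
                  function(b) sum(!b %in% DNA_BASES), integer(1))
  amb_bad <- n_amb > params$max_ambiguous
  short_bad <- !amb_bad & lens < params$min_length
  keep <- !(amb_bad | short_bad)
  lib$reads <- lib$reads[keep, , drop = FALSE]
  lib$quals <- lib$quals[keep]
  list(lib = lib, n_ambiguous = sum(amb_bad), n_short = sum(short_bad))
}

#' Full quality-control pipeline
#'
#' Demultiplexes a pooled library, screens and strips the reverse
#' primer, applies sliding-window quality trimming, and removes
#' ambiguous or short reads. The returned report conserves reads
#' exactly: passed + every rejection reason = input.
#'
#' @param lib pooled [read_library][simulate_library].
#' @param barcodes named character vector, barcode -> sample label.
#' @param primer a [primer_spec()] or IUPAC string (reverse primer, as
#'   it appears at the start of each barcode-stripped read).
#' @param params a [qc_params()].
#' @return object of class `qc_result`: list with `samples` (named list
#'   of cleaned `read_library`s) and `report` (data.frame of counts:
#'   input, passed, reject_barcode, reject_primer, reject_ambiguous,
#'   reject_short, n_trimmed).
#' @export
run_qc <- function(lib, barcodes, primer, params = qc_params()) {
  n_input <- nrow(lib$reads)
  dmx <- demultiplex(lib, barcodes, params)
  n_primer <- 0L; n_amb <- 0L; n_short <- 0L; n_trimmed <- 0L
  samples <- list()
  for (smp in names(dmx$samples)) {
    pr <- check_primer(dmx$samples[[smp]], primer, params)
    n_primer <- n_primer + pr$n_rejected
    slib <- pr$lib
    for (i in seq_len(nrow(slib$reads))) {
      tr <- trim_quality(slib$reads$sequence[i], slib$quals[[i]], params)
      if (nchar(tr$sequence) < nchar(slib$reads$sequence[i])) {
        n_trimmed <- n_trimmed + 1L
      }
      slib$reads$sequence[i] <- tr$sequence
      slib$quals[[i]] <- tr$qual
    }
    fl <- filter_reads(slib, params)
    n_amb <- n_amb + fl$n_ambiguous
    n_short <- n_short + fl$n_short
    samples[[smp]] <- fl$lib
  }
  passed <- sum(vapply(samples, function(x) nrow(x$reads), integer(1)))
  report <- data.frame(
    input = n_input, passed = passed,
    reject_barcode = dmx$n_unassigned, reject_primer = n_primer,
    reject_ambiguous = n_amb, reject_short = n_short,
    n_trimmed = n_trimmed
  )
  stopifnot(report$passed + report$reject_barcode + report$reject_primer +
              report$reject_ambiguous + report$reject_short == n_input)
  structure(list(samples = samples, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "qc_result: %d reads in, %d passed (%d barcode / %d primer / %d ambiguous / %d short rejected; %d trimmed)\n",
    r$input, r$passed, r$reject_barcode, r$reject_primer,
    r$reject_ambiguous, r$reject_short, r$n_trimmed))
  invisible(x)
}
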