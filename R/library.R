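#' Simulate a pyrosequencing read library
#'
#' Draws exactly `depth` reads multinomially from the post-PCR template
#' proportions. Each read is laid out the way the sequencer sees the
#' amplicon when sequencing proceeds from the distal (V5) end: the
#' multiplexing barcode, then the reverse primer, then the reverse
#' complement of the template region. Substitutions and indels are then
#' injected at the configured per-base rates (the indel rate is scaled by
#' `homopolymer_indel_multiplier^(run_length - 1)` inside homopolymer
#' runs, mimicking the dominant pyrosequencing error mode), and per-base
#' Phred qualities are drawn from the linear decay profile, clamped to
#' `[0, 40]`. Full provenance (source template, chimera parents, error
#' ops) is recorded per read.
#'
#' @param proportions named numeric vector of template proportions (e.g.
#'   `simulate_pcr()$proportions`).
#' @param sequences named character vector of template sequences
#'   (chimeras included).
#' @param params a [sim_params()].
#' @param depth number of reads to draw.
#' @param barcode barcode string prefixed to every read.
#' @param primer concrete reverse-primer sequence placed after the
#'   barcode.
#' @param sample_id sample label (also the RNG substream key).
#' @param chimera_ids ids in `sequences` that are chimeric (marks read
#'   truth).
#' @return object of class `read_library`: list with `sample_id`,
#'   `barcode`, `primer`, `reads` (data.frame: read_id, sequence,
#'   template_id, is_chimera, n_sub, n_indel) and `quals` (list of
#'   integer vectors, one per read, same length as the read).
#' @export
simulate_library <- function(proportions, sequences, params = sim_params(),
                             depth = 500L, barcode = "", primer = "",
                             sample_id = "s1",
                             chimera_ids = character(0)) {
  stopifnot(inherits(params, "sim_params"))
  if (depth < 1L) stopf("depth must be >= 1")
  if (!all(names(proportions) %in% names(sequences))) {
    stopf("every proportion needs a template sequence")
  }
  with_substream(params$seed, paste0("lib:", sample_id), {
    counts <- as.integer(stats::rmultinom(1L, depth, proportions))
    template_of <- rep(names(proportions), counts)
    template_of <- sample(template_of)  # shuffle read order
    prefix <- paste0(barcode, primer)
    n <- length(template_of)
    seqs <- character(n)
    n_sub <- integer(n); n_indel <- integer(n)
    quals <- vector("list", n)
    for (i in seq_len(n)) {
      raw <- paste0(prefix, revcomp(sequences[[template_of[i]]]))
      mut <- inject_errors(raw, params)
      seqs[i] <- mut$seq
      n_sub[i] <- mut$n_sub
      n_indel[i] <- mut$n_indel
      quals[[i]] <- draw_qualities(nchar(mut$seq), params)
    }
    reads <- data.frame(
      read_id = sprintf("%s_read%05d", sample_id, seq_len(n)),
      sequence = seqs,
      template_id = template_of,
      is_chimera = template_of %in% chimera_ids,
      n_sub = n_sub, n_indel = n_indel,
      stringsAsFactors = FALSE
    )
    structure(list(sample_id = sample_id, barcode = barcode,
                   primer = primer, reads = reads, quals = quals),
              class = "read_library")
  })
}

# substitutions + homopolymer-scaled indels on one sequence
inject_errors <- function(seq, params) {
  b <- strsplit(seq, "")[[1]]
  n_sub <- 0L; n_indel <- 0L
  if (params$substitution_rate > 0) {
    hit <- which(stats::runif(length(b)) < params$substitution_rate)
    for (p in hit) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1L)
    n_sub <- length(hit)
  }
  if (params$indel_rate > 0) {
    r <- rle(b)
    runlen <- rep(r$lengths, r$lengths)  # homopolymer run length per base
    rate <- pmin(0.5, params$indel_rate *
                   params$homopolymer_indel_multiplier^(runlen - 1))
    hit <- which(stats::runif(length(b)) < rate)
    if (length(hit)) {
      ins <- stats::runif(length(hit)) < 0.5
      out <- vector("list", length(b))
      for (i in seq_along(b)) out[[i]] <- b[i]
      for (k in seq_along(hit)) {
        p <- hit[k]
        out[[p]] <- if (ins[k]) c(b[p], b[p]) else character(0)
      }
      b <- unlist(out)
      n_indel <- length(hit)
    }
  }
  list(seq = paste(b, collapse = ""), n_sub = n_sub, n_indel = n_indel)
}

# linear quality decay with Gaussian jitter, clamped to [0, 40]
draw_qualities <- function(len, params) {
  if (len == 0L) return(integer(0))
  expected <- params$quality_start +
    (params$quality_end - params$quality_start) *
    (seq_len(len) - 1) / max(1L, len - 1L)
  q <- round(expected + stats::rnorm(len, 0, params$quality_sd))
  as.integer(pmin(40, pmax(0, q)))
}

#' Depth adjustment from inter-sample GC yield bias
#'
#' Emulates the observation that a pooled, equimolar set of sample
#' amplicon pools does not return equal read counts: the realized depth
#' of sample `i` is `base_depth * (1 + slope * (gc_i - mean(gc)))`,
#' truncated at a minimum of one read. Libraries are subsampled (without
#' replacement) down to their realized depth, so each input library must
#' hold at least that many reads.
#'
#' @param libraries list of [read_library][simulate_library] objects.
#' @param pool_gc numeric vector, overall GC fraction of each sample's
#'   amplicon pool.
#' @param slope inter-sample GC yield slope (sign free; negative means
#'   high-GC pools are under-represented).
#' @param base_depth target mean depth.
#' @param seed integer seed for the subsampling.
#' @return list of depth-adjusted `read_library` objects.
#' @export
#' @examples
#' # two samples, gc 0.5 / 0.6, slope -2, base 1000 -> depths 1100 / 900
#' gc_yield_depths(c(0.5, 0.6), slope = -2, base_depth = 1000)
apply_intersample_gc_yield <- function(libraries, pool_gc, slope,
                                       base_depth, seed = 1L) {
  if (length(libraries) < 2L) stopf("need at least two libraries")
  if (length(pool_gc) != length(libraries)) {
    stopf("pool_gc must have one value per library")
  }
  depths <- gc_yield_depths(pool_gc, slope, base_depth)
  lapply(seq_along(libraries), function(i) {
    lib <- libraries[[i]]
    n <- nrow(lib$reads)
    if (depths[i] > n) {
      stopf("library %s holds %d reads but realized depth is %d",
            lib$sample_id, n, depths[i])
    }
    keep <- with_substream(seed, paste0("yield:", lib$sample_id),
                           sort(sample.int(n, depths[i])))
    lib$reads <- lib$reads[keep, , drop = FALSE]
    lib$quals <- lib$quals[keep]
    lib
  })
}

#' Realized depths under the inter-sample GC yield model
#'
#' @inheritParams apply_intersample_gc_yield
#' @return integer vector of realized depths (each >= 1).
#' @export
gc_yield_depths <- function(pool_gc, slope, base_depth) {
  d <- round(base_depth * (1 + slope * (pool_gc - mean(pool_gc))))
  if (all(d < 1)) stopf("slope drives all depths below one read")
  as.integer(pmax(1, d))
}
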