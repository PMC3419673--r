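#' Simulation parameters for the amplicon library generator
#'
#' Bundles every knob of the mock-community simulator: the deterministic
#' exponential-growth PCR bias model, per-cycle chimera (bimera) formation,
#' 454-style substitution/indel errors with a homopolymer multiplier, the
#' linear quality-decay profile, and the inter-sample GC yield bias.
#'
#' The defaults emulate the study conditions the package benchmarks:
#' 15 PCR cycles, a mild negative GC-efficiency slope within samples,
#' post-filter pyrosequencing error magnitudes of a few errors per
#' thousand bases dominated by homopolymer indels, expected quality decaying
#' linearly from 35 at the read start to 20 at the read end, and a
#' negative inter-sample GC yield slope so that high-GC amplicon pools are
#' under-represented in the sequencing output.
#'
#' @param pcr_cycles number of PCR cycles (default 15).
#' @param base_efficiency per-cycle amplification efficiency at the mean GC
#'   content, in (0, 1].
#' @param gc_efficiency_slope change in per-cycle efficiency per unit GC
#'   fraction (any sign); efficiencies are clamped to `[0, 1]`.
#' @param chimera_rate probability per extant template per cycle of
#'   spawning a two-parent chimera.
#' @param substitution_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (outside homopolymers).
#' @param homopolymer_indel_multiplier multiplicative increase of
#'   `indel_rate` per extra base of the surrounding homopolymer run
#'   (>= 1).
#' @param quality_start,quality_end expected Phred quality at read start
#'   and read end (linear decay between them).
#' @param quality_sd Gaussian jitter of per-base qualities.
#' @param intersample_gc_yield_slope relative change in realized library
#'   depth per unit deviation of a sample's pool GC from the mean pool GC.
#' @param seed integer master seed for all randomness.
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(pcr_cycles = 15L,
                       base_efficiency = 0.9,
                       gc_efficiency_slope = -0.4,
                       chimera_rate = 0.0075,
                       substitution_rate = 0.001,
                       indel_rate = 0.0015,
                       homopolymer_indel_multiplier = 4,
                       quality_start = 35,
                       quality_end = 20,
                       quality_sd = 3,
                       intersample_gc_yield_slope = -2,
                       seed = 1L) {
  p <- list(
    pcr_cycles = as.integer(pcr_cycles),
    base_efficiency = base_efficiency,
    gc_efficiency_slope = gc_efficiency_slope,
    chimera_rate = chimera_rate,
    substitution_rate = substitution_rate,
    indel_rate = indel_rate,
    homopolymer_indel_multiplier = homopolymer_indel_multiplier,
    quality_start = quality_start,
    quality_end = quality_end,
    quality_sd = quality_sd,
    intersample_gc_yield_slope = intersample_gc_yield_slope,
    seed = as.integer(seed)
  )
  if (p$pcr_cycles < 0L) stopf("pcr_cycles must be >= 0")
  if (p$base_efficiency <= 0 || p$base_efficiency > 1) {
    stopf("base_efficiency must be in (0, 1]")
  }
  for (nm in c("chimera_rate", "substitution_rate", "indel_rate")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stopf("%s must be in [0, 1]", nm)
  }
  if (p$homopolymer_indel_multiplier < 1) {
    stopf("homopolymer_indel_multiplier must be >= 1")
  }
  if (p$quality_end > p$quality_start) {
    stopf("quality profile must be non-increasing along the read")
  }
  structure(p, class = "sim_params")
}

#' Quality-control parameters
#'
#' Defaults implement the stringent filtering protocol benchmarked by the
#' package: no barcode mismatches, at most one mismatch with the reverse
#' primer (the primer region is discarded anyway), no ambiguous bases, a
#' mean quality of 25 over a 50-bp sliding window (step 1), and removal of
#' reads trimmed below 200 bp.
#'
#' @param barcode_mismatch_max maximum barcode mismatches (default 0).
#' @param primer_mismatch_max maximum primer mismatches (default 1).
#' @param max_ambiguous maximum non-ACGT bases tolerated (default 0).
#' @param window_size sliding window width in bases (default 50).
#' @param q_threshold minimum mean quality per window (default 25).
#' @param min_length minimum read length after trimming; shorter reads are
#'   removed (default 200, i.e. a 200-bp read is kept).
#' @return object of class `qc_params`.
#' @export
qc_params <- function(barcode_mismatch_max = 0L,
                      primer_mismatch_max = 1L,
                      max_ambiguous = 0L,
                      window_size = 50L,
                      q_threshold = 25,
                      min_length = 200L) {
  p <- list(
    barcode_mismatch_max = as.integer(barcode_mismatch_max),
    primer_mismatch_max = as.integer(primer_mismatch_max),
    max_ambiguous = as.integer(max_ambiguous),
    window_size = as.integer(window_size),
    q_threshold = q_threshold,
    min_length = as.integer(min_length)
  )
  if (p$window_size < 1L) stopf("window_size must be >= 1")
  if (p$min_length < 1L) stopf("min_length must be >= 1")
  structure(p, class = "qc_params")
}
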