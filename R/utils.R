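#' @useDynLib ampbias, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide degeneracy codes
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' GC fraction of a nucleotide sequence
#'
#' @param x character vector of A/C/G/T sequences.
#' @return numeric vector, (G+C)/length for each sequence.
#' @export
#' @examples
#' gc_fraction("GGCC")   # 1
#' gc_fraction("ACGT")   # 0.5
gc_fraction <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1))
}

#' Reverse complement
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-", `.` = ".")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

# Deterministic substream seed: FNV-style hash of (seed, key), kept < 2^31.
# Gives replicate-level reproducibility without correlated streams.
substream_seed <- function(seed, key) {
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 16777619 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded from (seed, key).
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  expr
}

# k-mer set of a sequence (unique k-mers)
kmer_set <- function(x, k = 8L) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
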