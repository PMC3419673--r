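# Small fixtures shared across test files; everything is generated in
# code under fixed seeds.

tiny_refs <- function(n = 3L, seed = 11L, len = 300L) {
  generate_reference_set(n, c(0.45, 0.50, 0.55), len, "bacteria",
                         seed = seed)
}

bact_refs <- function(seed = 1L) {
  generate_reference_set(11, c(0.511, 0.551, 0.593), 570, "bacteria",
                         seed = seed)
}

arch_refs <- function(seed = 1L) {
  generate_reference_set(8, c(0.531, 0.583, 0.649), 600, "archaea",
                         seed = seed)
}

# a small error-free library of reads drawn from a reference set:
# reverse-complemented suffixes of templates, as the sequencer emits them
clean_reads <- function(refs, n = 20L, span = 350L, seed = 5L) {
  set.seed(seed)
  idx <- sample(nrow(refs), n, replace = TRUE)
  L <- nchar(refs$sequence[1])
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    template_id = refs$id[idx],
    sequence = revcomp(substr(refs$sequence[idx], L - span + 1L, L)),
    stringsAsFactors = FALSE
  )
}

# construct an error-free bimera in seed coordinates from two parents
make_bimera <- function(refs, i, j, bp) {
  paste0(substr(refs$sequence[i], 1, bp),
         substr(refs$sequence[j], bp + 1, nchar(refs$sequence[j])))
}
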