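#' Write a read library as FASTA plus paired quality file
#'
#' @param lib a [read_library][simulate_library].
#' @param fasta_path output FASTA path.
#' @param qual_path output 454-style quality file path (space-separated
#'   integer qualities under the same headers); omitted if `NULL`.
#' @return invisibly, the paths written.
#' @export
write_library_fasta <- function(lib, fasta_path, qual_path = NULL) {
  x <- Biostrings::DNAStringSet(lib$reads$sequence)
  names(x) <- lib$reads$read_id
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(qual_path)) {
    con <- file(qual_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(lib$reads))) {
      writeLines(c(paste0(">", lib$reads$read_id[i]),
                   paste(lib$quals[[i]], collapse = " ")), con)
    }
  }
  invisible(c(fasta_path, qual_path))
}

#' Write a read library as Sanger FASTQ (+33 offset)
#'
#' @inheritParams write_library_fasta
#' @param path output FASTQ path.
#' @export
write_library_fastq <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(lib$reads))) {
    q <- intToUtf8(pmin(93L, lib$quals[[i]]) + 33L)
    writeLines(c(paste0("@", lib$reads$read_id[i]),
                 lib$reads$sequence[i], "+", q), con)
  }
  invisible(path)
}

#' Read a Sanger FASTQ file into a read library
#'
#' @param path FASTQ path.
#' @param sample_id label for the loaded library.
#' @return a `read_library` (without truth columns).
#' @export
read_library_fastq <- function(path, sample_id = basename(path)) {
  # (Biostrings drops fastq metadata columns here; that's expected)
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path))
  reads <- data.frame(
    read_id = names(x),
    sequence = as.character(x),
    template_id = NA_character_,
    is_chimera = NA,
    n_sub = NA_integer_, n_indel = NA_integer_,
    stringsAsFactors = FALSE
  )
  quals <- lapply(as(Biostrings::quality(x), "IntegerList"), as.integer)
  structure(list(sample_id = sample_id, barcode = NA_character_,
                 primer = NA_character_, reads = reads,
                 quals = unname(quals)),
            class = "read_library")
}

#' Read a FASTA plus paired quality file into a read library
#'
#' @param fasta_path FASTA path.
#' @param qual_path 454-style quality file (same headers, space-separated
#'   integer qualities).
#' @param sample_id label for the loaded library.
#' @return a `read_library` (without truth columns).
#' @export
read_library_fasta_qual <- function(fasta_path, qual_path,
                                    sample_id = basename(fasta_path)) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  lines <- readLines(qual_path)
  heads <- grep("^>", lines)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[heads]))
  ends <- c(heads[-1] - 1L, length(lines))
  quals <- lapply(seq_along(heads), function(i) {
    as.integer(strsplit(paste(lines[(heads[i] + 1L):ends[i]],
                              collapse = " "), "\\s+")[[1]])
  })
  names(quals) <- ids
  ord <- match(sub("\\s.*$", "", names(x)), ids)
  if (anyNA(ord)) stopf("quality file is missing reads present in FASTA")
  reads <- data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(unname(x)),
    template_id = NA_character_, is_chimera = NA,
    n_sub = NA_integer_, n_indel = NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(list(sample_id = sample_id, barcode = NA_character_,
                 primer = NA_character_, reads = reads,
                 quals = unname(quals[ord])),
            class = "read_library")
}

#' Write per-read truth (provenance) table as TSV
#'
#' @param lib a simulated [read_library][simulate_library].
#' @param path output TSV path.
#' @export
write_truth_table <- function(lib, path) {
  utils::write.table(lib$reads[, c("read_id", "template_id", "is_chimera",
                                   "n_sub", "n_indel")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an oligos-style barcode and primer table
#'
#' TSV with columns `type` (barcode|primer), `sequence`, `label`
#' (sample label for barcodes, primer name otherwise).
#'
#' @param barcodes named character vector barcode -> sample label.
#' @param primers named character vector primer sequence -> primer name.
#' @param path file path.
#' @return `write_oligos` the path; `read_oligos` a list with `barcodes`
#'   (named vector sequence -> sample) and `primers`.
#' @export
write_oligos <- function(barcodes, primers, path) {
  df <- rbind(
    data.frame(type = "barcode", sequence = names(barcodes),
               label = unname(barcodes), stringsAsFactors = FALSE),
    data.frame(type = "primer", sequence = names(primers),
               label = unname(primers), stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_oligos
#' @export
read_oligos <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  list(
    barcodes = with(df[df$type == "barcode", ],
                    stats::setNames(label, sequence)),
    primers = with(df[df$type == "primer", ],
                   stats::setNames(label, sequence))
  )
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm symmetric numeric matrix with dimnames.
#' @param path output path.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(rownames(dm)[i],
                       sprintf("%.6f", dm[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Read a PHYLIP distance matrix (square or lower-triangle)
#'
#' @param path PHYLIP file path.
#' @return symmetric numeric matrix with labels as dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  toks <- lapply(strsplit(trimws(lines[1 + seq_len(n)]), "\\s+"), identity)
  labels <- vapply(toks, `[`, character(1), 1L)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    vals <- as.numeric(toks[[i]][-1])
    if (length(vals) == n) {
      m[i, ] <- vals
    } else if (length(vals) == i - 1L) {       # lower-triangle dialect
      if (i > 1L) m[i, seq_len(i - 1L)] <- vals
    } else {
      stopf("malformed PHYLIP row %d: %d values", i, length(vals))
    }
  }
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Write an OTU table as TSV
#'
#' Rows are OTUs (with status and reference-id columns), columns samples.
#'
#' @param ot an [otu_table][classify_otus].
#' @param path output path.
#' @export
write_otu_table <- function(ot, path) {
  df <- data.frame(otu = rownames(ot$counts), status = ot$status,
                   reference_ids = vapply(ot$ref_ids, paste,
                                          character(1), collapse = ","),
                   ot$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
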