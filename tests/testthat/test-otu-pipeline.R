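test_that("alignment reproduces the reference row for clean reads, both orientations", {
  refs <- tiny_refs(n = 4L, len = 400L)
  sa <- build_seed_alignment(refs)
  tmpl <- refs$sequence[7]
  frag <- substr(tmpl, 151, 400)
  for (read in c(revcomp(frag), frag)) {     # sequencing + forward
    aln <- align_to_seed(read, sa)
    expect_false(aln$unalignable)
    expect_identical(aln$template, refs$id[7])
    chars <- strsplit(aln$aligned, "")[[1]]
    expect_identical(paste(chars[151:400], collapse = ""), frag)
    expect_true(all(chars[1:150] == "."))
  }
})

test_that("k-mer template choice matches the exhaustive best-identity oracle", {
  refs <- tiny_refs(n = 4L, len = 400L)
  sa <- build_seed_alignment(refs)
  set.seed(21)
  idx <- sample(nrow(refs), 20, replace = TRUE)
  reads <- revcomp(substr(refs$sequence[idx], 101, 400))
  aln <- align_to_seed(reads, sa)
  # oracle: Biostrings global alignment score against every reference
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  for (i in seq_along(reads)) {
    sc <- vapply(refs$sequence, function(r)
      Biostrings::pairwiseAlignment(revcomp(reads[i]), r,
                                    type = "overlap",
                                    substitutionMatrix = submat,
                                    gapOpening = 4, gapExtension = 1,
                                    scoreOnly = TRUE), numeric(1))
    expect_identical(aln$template[i], refs$id[which.max(sc)])
  }
})

test_that("aligned rows agree with the Biostrings aligner on error-laden reads", {
  refs <- tiny_refs(n = 4L, len = 400L)
  sa <- build_seed_alignment(refs)
  set.seed(33)
  tmpl <- refs$sequence[3]
  frag <- substr(tmpl, 101, 400)
  # inject two substitutions
  b <- strsplit(frag, "")[[1]]
  b[50] <- setdiff(c("A", "C", "G", "T"), b[50])[1]
  b[200] <- setdiff(c("A", "C", "G", "T"), b[200])[1]
  read <- revcomp(paste(b, collapse = ""))
  aln <- align_to_seed(read, sa)
  chars <- strsplit(aln$aligned, "")[[1]]
  expect_identical(paste(chars[101:400], collapse = ""),
                   paste(b, collapse = ""))
  # unalignable: garbage sharing no 8-mer
  g <- align_to_seed(strrep("ATATATAT", 10), sa)
  expect_true(g$unalignable || g$template != "")
})

test_that("span screen drops reads that stop short of the sequenced end", {
  refs <- tiny_refs(n = 3L, len = 400L)
  sa <- build_seed_alignment(refs)
  full <- revcomp(substr(refs$sequence[1], 101, 400))
  short <- revcomp(substr(refs$sequence[1], 101, 350))  # ends 50 early
  aln <- align_to_seed(c(full, short), sa)
  keep <- screen_alignment_span(aln$aligned, sa, tolerance = 5)
  expect_identical(keep, c(TRUE, FALSE))
  expect_true(all(screen_alignment_span(aln$aligned, sa,
                                        tolerance = Inf)))
})

test_that("bimera detector is sensitive to mid-breakpoint chimeras and quiet on clean reads", {
  refs <- bact_refs()
  sa <- build_seed_alignment(refs)
  im <- pairwise_identity(refs$sequence)
  set.seed(14)
  pairs <- which(im < 0.9 & upper.tri(im), arr.ind = TRUE)
  pairs <- pairs[sample(nrow(pairs), 40), , drop = FALSE]
  L <- nchar(refs$sequence[1])
  bims <- vapply(seq_len(nrow(pairs)), function(k) {
    bp <- sample(seq(round(0.4 * L), round(0.6 * L)), 1)
    make_bimera(refs, pairs[k, 1], pairs[k, 2], bp)
  }, character(1))
  det <- detect_chimeras(bims, sa)   # already in seed coordinates
  expect_gte(mean(det$flagged), 0.95)
  # zero false positives on the references themselves
  clean <- detect_chimeras(unname(sa$rows), sa)
  expect_true(all(!clean$flagged))
  # bimera of identical "parents" is just the parent
  selfb <- make_bimera(refs, 4, 4, 280)
  expect_false(detect_chimeras(selfb, sa)$flagged)
})

test_that("column filtering removes trump and all-gap columns", {
  rows <- c(a = "A-.C", b = "AG.C")
  out <- filter_columns(rows)
  expect_equal(attr(out, "width"), 3L)
  expect_identical(as.character(out), c("A-C", "AGC"))

  rows2 <- c(a = "A-C", b = "A-C")        # middle column all-gap
  out2 <- filter_columns(rows2)
  expect_identical(as.character(out2), c("AC", "AC"))

  rows3 <- c(a = "ACGT", b = "AGGT")      # nothing to remove
  expect_identical(as.character(filter_columns(rows3)),
                   c("ACGT", "AGGT"))
  expect_error(filter_columns(c(a = "..", b = "AC")), "every column")
})

test_that("pairwise distance counts gap runs as single events", {
  backbone <- strrep("ACGT", 25)
  mut <- backbone
  substr(mut, 13, 13) <- "T"
  d <- pairwise_distance(c(a = backbone, b = mut))
  expect_equal(d["a", "b"], 0.01)                  # 1 sub / 100 columns

  gap3 <- paste0(substr(backbone, 1, 40), "---", substr(backbone, 44, 100))
  d2 <- pairwise_distance(c(a = backbone, b = gap3))
  expect_equal(d2["a", "b"], 1 / 98)               # 1 event / (97 + 1)

  expect_equal(unname(diag(pairwise_distance(c(a = backbone,
                                               b = backbone)))),
               c(0, 0))
  # mutual gaps are skipped entirely
  m1 <- "AC--GT"
  m2 <- "AC--GA"
  expect_equal(pairwise_distance(c(a = m1, b = m2))["a", "b"], 0.25)
  # a pair sharing no comparable columns is an error, not a silent NA
  expect_error(pairwise_distance(c(a = "--", b = "--")), "comparable")
  # a pure gap-vs-gap overlap is all events: distance 1
  expect_equal(pairwise_distance(c(a = "AC--", b = "--GT"))["a", "b"], 1)
})

test_that("average-neighbor clustering matches hand traces and the hclust oracle", {
  dm <- matrix(c(0, .01, .05,
                 .01, 0, .05,
                 .05, .05, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  asg <- cluster_average_neighbor(dm, 0.03)
  expect_equal(unname(asg), c(1L, 1L, 2L))

  # everything farther apart than the cutoff: singletons
  dm2 <- dm; dm2[dm2 > 0] <- 0.5
  expect_equal(unname(cluster_average_neighbor(dm2, 0.03)), 1:3)

  # oracle equivalence on 50 random 10x10 matrices
  set.seed(77)
  for (rep in 1:50) {
    d <- matrix(0, 10, 10)
    d[upper.tri(d)] <- runif(45, 0, 0.08)
    d <- d + t(d)
    dimnames(d) <- list(letters[1:10], letters[1:10])
    mine <- cluster_average_neighbor(d, 0.03)
    orc <- cutree(hclust(as.dist(d), method = "average"), h = 0.03)
    # same partition up to label permutation
    expect_setequal(
      unname(vapply(split(names(mine), mine), paste, "",
                    collapse = ",")),
      unname(vapply(split(names(orc), orc), paste, "",
                    collapse = ",")))
  }
})

test_that("clustering is invariant to input permutation", {
  set.seed(5)
  d <- matrix(0, 8, 8)
  d[upper.tri(d)] <- runif(28, 0, 0.06)
  d <- d + t(d)
  dimnames(d) <- list(letters[1:8], letters[1:8])
  a1 <- cluster_average_neighbor(d, 0.03)
  perm <- sample(8)
  a2 <- cluster_average_neighbor(d[perm, perm], 0.03)[letters[1:8]]
  grp1 <- split(names(a1), a1)
  grp2 <- split(names(a2), a2)
  expect_setequal(unname(vapply(grp1, paste, "", collapse = ",")),
                  unname(vapply(grp2, paste, "", collapse = ",")))
})

test_that("OTU classification separates good from spurious and counts reads only", {
  refs <- tiny_refs(n = 2L, len = 300L)
  sa <- build_seed_alignment(refs)
  # error-free reads from each reference plus one heavily mutated read
  reads <- substr(refs$sequence, 1, 300)
  names(reads) <- paste0("read_", refs$id)
  bad <- strsplit(refs$sequence[1], "")[[1]]
  set.seed(6)
  pos <- sample(300, 15)                     # 5% divergent
  for (p in pos) bad[p] <- setdiff(c("A", "C", "G", "T"), bad[p])[1]
  rows <- c(sa$rows, reads, weird = paste(bad, collapse = ""))
  dm <- pairwise_distance(filter_columns(rows))
  asg <- cluster_average_neighbor(dm, 0.03)
  ot <- classify_otus(asg, refs$id, cutoff = 0.03)
  expect_equal(sum(ot$status == "good"), nrow(refs))
  expect_equal(sum(ot$status == "spurious"), 1L)
  expect_equal(sum(ot$counts), length(reads) + 1L)  # refs excluded
  good_counts <- ot$counts[ot$status == "good", 1]
  expect_true(all(good_counts == 1L))
  expect_error(classify_otus(asg, c("absent1", "absent2")),
               "no reference")
})

test_that("error-free libraries yield exactly the reference OTUs with multinomial abundances", {
  refs <- bact_refs()
  sa <- build_seed_alignment(refs)
  prof <- theoretical_profiles(refs, c(1, 80, 1000))$m2
  p0 <- sim_params(gc_efficiency_slope = 0, chimera_rate = 0,
                   substitution_rate = 0, indel_rate = 0,
                   quality_start = 35, quality_end = 35, quality_sd = 0,
                   seed = 12)
  pcr <- simulate_pcr(prof, refs, p0)
  lib <- simulate_library(pcr$proportions, pcr$sequences, p0,
                          depth = 400, sample_id = "ef")
  aln <- align_to_seed(lib$reads$sequence, sa)
  rows_reads <- stats::setNames(aln$aligned, lib$reads$read_id)
  rows <- c(sa$rows, rows_reads[!duplicated(rows_reads)])
  dm <- pairwise_distance(filter_columns(rows))
  asg_u <- cluster_average_neighbor(dm, 0.03)
  rep_of <- names(rows_reads)[!duplicated(rows_reads)][
    match(rows_reads, rows_reads[!duplicated(rows_reads)])]
  asg <- c(asg_u[refs$id], stats::setNames(asg_u[rep_of],
                                           names(rows_reads)))
  ot <- classify_otus(asg, refs$id)
  expect_equal(sum(ot$status == "spurious"), 0L)
  expect_equal(sum(ot$status == "good"), 33L)
  # per-OTU counts match the post-PCR proportions within 4 binomial SE
  props <- pcr$proportions
  for (id in names(props)[props > 0.01]) {
    se <- sqrt(props[id] * (1 - props[id]) / 400)
    expect_lt(abs(ot$counts[id, 1] / 400 - props[id]), 4 * se + 1e-9)
  }
})

test_that("PHYLIP distance matrices round-trip in square and lower-triangle forms", {
  set.seed(2)
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- runif(6)
  d <- d + t(d)
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  f <- tempfile()
  write_phylip(d, f)
  expect_equal(read_phylip(f), d, tolerance = 1e-6)
  # lower-triangle dialect
  lines <- c("    4", "s1", paste("s2", sprintf("%.6f", d[2, 1])),
             paste("s3", paste(sprintf("%.6f", d[3, 1:2]), collapse = " ")),
             paste("s4", paste(sprintf("%.6f", d[4, 1:3]), collapse = " ")))
  writeLines(lines, f)
  expect_equal(read_phylip(f), d, tolerance = 1e-6)
})
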