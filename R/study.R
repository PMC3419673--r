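#' Run a full synthetic mock-community study
#'
#' End-to-end orchestration of the benchmark on simulated data: builds
#' the reference set and the three mock communities (even m1, uneven
#' m2/m3 with swapped high/low GC clusters), simulates replicate
#' amplicon libraries at two sequencing depths with PCR bias, chimeras,
#' sequencing errors and inter-sample GC yield bias, pushes every
#' library through quality control, seed alignment, chimera screening
#' and average-neighbor OTU clustering, and computes the figure-level
#' analytics: taxa detection frequencies with theoretical subsampling
#' bands, relative-abundance fold errors, rank-abundance KS
#' comparisons, alpha diversity with and without spurious OTUs,
#' pairwise beta diversity against the theoretical values, and the
#' inter-sample GC-yield correlation.
#'
#' All randomness flows from `seed` through per-sample substreams, so a
#' report regenerates byte-identically under a fixed seed.
#'
#' @param domain "bacteria" (33 references, 11 per GC cluster) or
#'   "archaea" (24 references, 8 per cluster); sets the GC tertiles,
#'   region length, abundance levels and default depths.
#' @param depths named vector `c(small = ..., large = ...)`, mean reads
#'   per sample for the two sequencing tiers (defaults mirror the
#'   benchmarked runs: small a few hundred reads, large 6-7 fold more).
#' @param replicates replicate libraries per community (default 3).
#' @param params a [sim_params()]; its seed is overridden by `seed`.
#' @param level_weights abundance-level weights (domain default if
#'   NULL).
#' @param fractions in-silico subsampling fractions for the detection
#'   bands.
#' @param band_replicates subsampling replicates per fraction.
#' @param qc a [qc_params()].
#' @param cutoff OTU distance cutoff (default 0.03).
#' @param span_tolerance columns of slack for the alignment-span screen.
#' @param chimera_threshold,chimera_min_i2 bimera-detector parameters.
#' @param replicate_gc_offsets per-replicate shift of the amplicon-pool
#'   GC fraction (emulating barcoded reverse primers of different GC).
#' @param seed master seed.
#' @return object of class `mock_study`; see Details. Main components:
#'   `samples` (per-library metadata and depths), `alpha` (per-library
#'   diversity with/without spurious OTUs), `detection`, `bands`,
#'   `abundance` (fold-error summaries), `beta` (pairwise
#'   Morisita-Horn/Jaccard summaries per community pair and tier),
#'   `theoretical_beta`, `dist_to_theoretical`, `ks`,
#'   `gc_correlation`, plus the raw `good_counts`/`all_counts` per
#'   library.
#' @export
run_study <- function(domain = c("bacteria", "archaea"),
                      depths = NULL,
                      replicates = 3L,
                      params = sim_params(),
                      level_weights = NULL,
                      fractions = c(.01, .05, .1, .2, .5, .7, .9),
                      band_replicates = 3L,
                      qc = qc_params(),
                      cutoff = 0.03,
                      span_tolerance = 5,
                      chimera_threshold = 0.03,
                      chimera_min_i2 = 0.99,
                      replicate_gc_offsets = c(-0.02, 0, 0.02),
                      seed = 1L) {
  domain <- match.arg(domain)
  cfg <- if (domain == "bacteria") {
    list(n = 11L, gc = c(0.511, 0.551, 0.593), len = 570L,
         weights = c(1, 80, 1000), depths = c(small = 520, large = 3328),
         primer = "CCGTCAATTYHTTTRAGT")    # V5 reverse primer (degenerate)
  } else {
    list(n = 8L, gc = c(0.531, 0.583, 0.649), len = 600L,
         weights = c(1, 79, 1000), depths = c(small = 306, large = 1865),
         primer = "GWGCYCCCCCGYCAATTC")
  }
  if (is.null(depths)) depths <- cfg$depths
  if (is.null(level_weights)) level_weights <- cfg$weights
  params$seed <- as.integer(seed)

  refs <- generate_reference_set(cfg$n, cfg$gc, cfg$len, domain,
                                 seed = seed)
  profiles <- theoretical_profiles(refs, level_weights)
  theo_rel <- lapply(profiles, relative_abundance)
  seedaln <- build_seed_alignment(refs)
  primer <- primer_spec(paste0(domain, "-R"), cfg$primer, "reverse")
  primer_concrete <- expand_degenerate_primer(primer)[1]

  communities <- c("m1", "m2", "m3")
  tiers <- names(depths)
  grid <- expand.grid(replicate = seq_len(replicates),
                      community = communities, tier = tiers,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_r%d_%s", grid$community, grid$replicate,
                            grid$tier)
  barcode_labels <- unique(sprintf("%s_r%d", grid$community,
                                   grid$replicate))
  bcs <- design_barcodes(length(barcode_labels), seed = seed)
  barcode_of <- stats::setNames(as.character(bcs), barcode_labels)

  # amplicon-pool GC per sample: community mean GC + replicate offset
  comm_gc <- vapply(communities, function(cm) {
    sum(theo_rel[[cm]] * refs$gc_fraction[match(names(theo_rel[[cm]]),
                                                refs$id)])
  }, numeric(1))
  grid$pool_gc <- comm_gc[grid$community] +
    replicate_gc_offsets[grid$replicate]

  # realized depths per tier from the inter-sample GC yield model
  grid$depth <- NA_integer_
  for (t in tiers) {
    idx <- grid$tier == t
    grid$depth[idx] <- gc_yield_depths(
      grid$pool_gc[idx], params$intersample_gc_yield_slope, depths[[t]])
  }

  # simulate, pool per tier, and run QC
  clean <- list()
  qc_reports <- list()
  for (t in tiers) {
    libs <- list()
    for (i in which(grid$tier == t)) {
      key <- grid$sample_id[i]
      pcr <- simulate_pcr(profiles[[grid$community[i]]], refs, params,
                          sample_key = key)
      bc <- barcode_of[[sprintf("%s_r%d", grid$community[i],
                                grid$replicate[i])]]
      libs[[key]] <- simulate_library(
        pcr$proportions, pcr$sequences, params,
        depth = grid$depth[i], barcode = bc, primer = primer_concrete,
        sample_id = key, chimera_ids = pcr$chimeras$id)
    }
    pooled <- structure(list(
      sample_id = t, barcode = NA, primer = primer_concrete,
      reads = do.call(rbind, lapply(libs, `[[`, "reads")),
      quals = do.call(c, lapply(libs, `[[`, "quals"))
    ), class = "read_library")
    rownames(pooled$reads) <- NULL
    bc_map <- stats::setNames(
      grid$sample_id[grid$tier == t],
      unname(barcode_of[sprintf("%s_r%d", grid$community[grid$tier == t],
                                grid$replicate[grid$tier == t])]))
    res <- run_qc(pooled, bc_map, primer, qc)
    clean <- c(clean, res$samples)
    qc_reports[[t]] <- res$report
  }

  # per-library OTU pipeline
  otus <- list(); good_counts <- list(); all_counts <- list()
  n_chimera_flagged <- stats::setNames(integer(nrow(grid)),
                                       grid$sample_id)
  for (sid in grid$sample_id) {
    lib <- clean[[sid]]
    if (is.null(lib) || nrow(lib$reads) == 0L) {
      stopf("no reads survived QC for sample %s", sid)
    }
    aln <- align_to_seed(lib$reads$sequence, seedaln)
    keep <- !aln$unalignable & screen_alignment_span(aln$aligned, seedaln,
                                                     span_tolerance)
    chim <- detect_chimeras(aln$aligned[keep], seedaln,
                            chimera_threshold, chimera_min_i2)
    n_chimera_flagged[sid] <- sum(chim$flagged)
    rows_reads <- aln$aligned[keep][!chim$flagged]
    names(rows_reads) <- lib$reads$read_id[keep][!chim$flagged]

    # dereplicate identical aligned reads before the distance matrix
    uniq <- !duplicated(rows_reads)
    rep_of <- names(rows_reads)[uniq][match(rows_reads,
                                            rows_reads[uniq])]
    rows <- c(seedaln$rows, rows_reads[uniq])
    filt <- filter_columns(rows)
    dm <- pairwise_distance(filt)
    asg_uniq <- cluster_average_neighbor(dm, cutoff)
    asg <- c(asg_uniq[names(seedaln$rows)],
             stats::setNames(asg_uniq[rep_of], names(rows_reads)))
    ot <- classify_otus(asg, names(seedaln$rows),
                        stats::setNames(rep(sid, length(rows_reads)),
                                        names(rows_reads)), cutoff)
    # unique spurious names across libraries
    sp <- ot$status == "spurious"
    rownames(ot$counts)[sp] <- sprintf("sp_%s_%02d", sid,
                                       seq_len(sum(sp)))
    otus[[sid]] <- ot
    cv <- stats::setNames(as.integer(ot$counts[, 1]),
                          rownames(ot$counts))
    all_counts[[sid]] <- cv
    good_counts[[sid]] <- cv[ot$status == "good"]
  }
  grid$reads_pass <- vapply(grid$sample_id, function(s)
    sum(all_counts[[s]]), numeric(1))
  grid$n_spurious_otus <- vapply(grid$sample_id, function(s)
    sum(otus[[s]]$status == "spurious"), numeric(1))

  # ---- analytics -------------------------------------------------------
  alpha <- do.call(rbind, lapply(grid$sample_id, function(s) {
    wa <- alpha_diversity(all_counts[[s]])
    wo <- alpha_diversity(good_counts[[s]][good_counts[[s]] > 0])
    names(wo) <- paste0(names(wo), "_nospur")
    cbind(data.frame(sample_id = s), wa, wo)
  }))

  detection <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$sample_id[i]
    td <- taxa_detection_frequency(good_counts[[s]],
                                   profiles[[grid$community[i]]])
    data.frame(sample_id = s, community = grid$community[i],
               tier = grid$tier[i], detected = td$detected,
               true_taxa = td$true_taxa, frequency = td$frequency)
  }))

  bands <- lapply(profiles, detection_band, fractions = fractions,
                  replicates = band_replicates, seed = seed)

  abundance <- list()
  for (cm in communities) for (t in tiers) {
    key <- paste(cm, t, sep = "_")
    reps <- grid$sample_id[grid$community == cm & grid$tier == t]
    abundance[[key]] <- abundance_error(good_counts[reps],
                                        profiles[[cm]])
  }

  # theoretical beta diversity between the mock communities
  pairs <- list(c("m1", "m2"), c("m1", "m3"), c("m2", "m3"))
  theoretical_beta <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(pair = paste(p, collapse = "-"),
               d_mh = morisita_horn_distance(unclass(profiles[[p[1]]]),
                                             unclass(profiles[[p[2]]])),
               d_jaccard = jaccard_distance(unclass(profiles[[p[1]]]),
                                            unclass(profiles[[p[2]]])))
  }))

  beta <- list()
  for (p in pairs) for (t in tiers) {
    ra <- grid$sample_id[grid$community == p[1] & grid$tier == t]
    rb <- grid$sample_id[grid$community == p[2] & grid$tier == t]
    cmb <- expand.grid(a = ra, b = rb, stringsAsFactors = FALSE)
    key <- paste(p[1], p[2], t, sep = "_")
    beta[[key]] <- data.frame(
      a = cmb$a, b = cmb$b,
      d_mh = mapply(function(a, b) morisita_horn_distance(
        good_counts[[a]], good_counts[[b]]), cmb$a, cmb$b),
      d_mh_spur = mapply(function(a, b) morisita_horn_distance(
        all_counts[[a]], all_counts[[b]]), cmb$a, cmb$b),
      d_jaccard = mapply(function(a, b) jaccard_distance(
        good_counts[[a]], good_counts[[b]]), cmb$a, cmb$b),
      d_jaccard_spur = mapply(function(a, b) jaccard_distance(
        all_counts[[a]], all_counts[[b]]), cmb$a, cmb$b))
  }

  dist_theo <- list()
  for (cm in communities) for (t in tiers) {
    reps <- grid$sample_id[grid$community == cm & grid$tier == t]
    # near-coincident replicate libraries can leave a single positive
    # PCoA axis; the truncation is expected here, not worth a warning
    dist_theo[[paste(cm, t, sep = "_")]] <- suppressWarnings(
      distance_to_theoretical(good_counts[reps], profiles[[cm]]))
  }

  mean_good_rel <- function(cm, t) {
    reps <- grid$sample_id[grid$community == cm & grid$tier == t]
    mats <- lapply(reps, function(s) {
      v <- good_counts[[s]]
      full <- stats::setNames(rep(0, nrow(refs)), refs$id)
      full[names(v)] <- v
      full / max(1, sum(v))
    })
    Reduce(`+`, mats) / length(mats)
  }
  ks <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(tiers, function(t) {
      k <- ks_rank_abundance(
        rank_abundance(mean_good_rel(p[1], t)),
        rank_abundance(mean_good_rel(p[2], t)))
      data.frame(pair = paste(p, collapse = "-"), tier = t,
                 D = k$statistic, p_value = k$p_value)
    }))
  }))

  # percent of each tier's reads per sample vs amplicon-pool GC
  pct <- unlist(lapply(tiers, function(t) {
    d <- grid$depth[grid$tier == t]
    100 * d / sum(d)
  }))
  gc_corr <- tryCatch(gc_read_correlation(pct, grid$pool_gc),
                      error = function(e)
                        list(r = NA_real_, p_value = NA_real_,
                             n = nrow(grid)))

  structure(list(
    domain = domain, seed = as.integer(seed), params = params,
    refs = refs, profiles = profiles, depths = depths,
    samples = grid, qc_reports = qc_reports,
    otus = otus, good_counts = good_counts, all_counts = all_counts,
    n_chimera_flagged = n_chimera_flagged,
    alpha = alpha, detection = detection, bands = bands,
    abundance = abundance, theoretical_beta = theoretical_beta,
    beta = beta, dist_to_theoretical = dist_theo, ks = ks,
    gc_correlation = gc_corr
  ), class = "mock_study")
}

#' @export
print.mock_study <- function(x, ...) {
  cat(sprintf("mock_study (%s): %d libraries, tiers %s, seed %d\n",
              x$domain, nrow(x$samples),
              paste(sprintf("%s=%d", names(x$depths),
                            round(unname(x$depths))), collapse = "/"),
              x$seed))
  cat(sprintf("  mean detection frequency: %.3f | spurious OTUs/library: %.1f\n",
              mean(x$detection$frequency),
              mean(x$samples$n_spurious_otus)))
  cat(sprintf("  GC-yield correlation r = %.2f (p = %.2g)\n",
              x$gc_correlation$r, x$gc_correlation$p_value))
  invisible(x)
}
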