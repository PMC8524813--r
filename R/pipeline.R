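## End-to-end orchestration: generate (or load) a dataset, run annotation
## filtering, enrichment, differential testing, multivariate structure and
## the consensus re-mapping stage, and write deterministic TSV outputs with
## a provenance manifest. A thin command-line wrapper around these functions
## ships in `inst/scripts/satrep`.

#' Default analysis parameters
#'
#' Values mirror the pipeline's standard settings: `alpha = 0.05` (two-group
#' significance), `posthoc_alpha_adj = 0.01` (adjusted-p gate for Tukey),
#' `relevance_cutoff = 1.5`, `reciprocal_frac = 0.5`, `min_windows = 50`,
#' `n_perm = 999`, `max_mismatch_rate = 0.1`.
#'
#' @return named list of parameters.
#' @export
default_params <- function() {
  list(alpha = 0.05, posthoc_alpha_adj = 0.01, tukey_alpha = 0.05,
       relevance_cutoff = 1.5, reciprocal_frac = 0.5, min_windows = 50,
       n_perm = 999, max_mismatch_rate = 0.1, fc_min_log2 = 1)
}

#' Run the full analysis on a dataset directory
#'
#' Loads a dataset (as written by [write_dataset()]), applies blocklist and
#' autosome filtering, builds the enrichment matrix, runs the differential
#' analysis appropriate for the scenario (two-group Welch when the metadata
#' has two groups, stage-wise ANOVA otherwise), PCA + PERMANOVA, the
#' consensus re-mapping stage when MAPQ-0 read sets are present, and the
#' overlap analyses. Writes TSV outputs and a manifest to `outdir` and
#' returns the results invisibly.
#'
#' @param data_dir dataset directory.
#' @param outdir output directory (created; must be empty unless `force`).
#' @param params parameter list, see [default_params()].
#' @param seed seed for permutation tests and downsampling.
#' @param force overwrite non-empty `outdir`.
#' @return (invisibly) list of result objects; see the written files.
#' @export
run_pipeline <- function(data_dir, outdir, params = default_params(),
                         seed = 1, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("run_pipeline: ", outdir, " exists and is not empty (use force)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_dataset(data_dir)

  ## annotation filtering
  fb <- filter_blocklist(ds$instances, ds$blocklist)
  kept <- filter_chromosomes(fb$kept, "autosomes_only")
  write_instances(kept, file.path(outdir, "instances_kept.tsv"))
  write_instances(fb$removed, file.path(outdir, "instances_removed.tsv"))

  ## enrichment matrix
  em <- build_enrichment_matrix(kept, ds$samples, ds$tracks)
  write_enrichment_matrix(em, file.path(outdir, "enrichment_matrix.tsv"),
                          file.path(outdir, "samples.tsv"))

  ## differential analysis
  two_group <- length(unique(em$samples$group)) == 2
  if (two_group) {
    diff <- differential_two_group(em, "group", alpha = params$alpha,
                                   relevance_cutoff = params$relevance_cutoff)
    write_tsv(diff, file.path(outdir, "differential_two_group.tsv"))
    diff_ids <- diff$element_id[diff$significant]
  } else {
    st <- differential_stagewise(
      em, "stage", posthoc_alpha_adj = params$posthoc_alpha_adj,
      tukey_alpha = params$tukey_alpha,
      relevance_cutoff = params$relevance_cutoff)
    write_tsv(st$elements, file.path(outdir, "differential_stagewise.tsv"))
    write_tsv(st$pairs, file.path(outdir, "differential_pairs.tsv"))
    diff <- st$elements
    diff_ids <- diff$element_id[diff$differential]
  }
  fam <- family_overrepresentation(kept, diff_ids)
  write_tsv(fam, file.path(outdir, "family_overrepresentation.tsv"))

  ## multivariate
  sc <- scale_rows(em$values)
  pca <- pca_samples(sc[!attr(sc, "zero_variance"), , drop = FALSE])
  write_tsv(data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, 1:min(4, ncol(pca$scores)),
                                  drop = FALSE]),
            file.path(outdir, "pca_scores.tsv"))
  d <- binomial_distance(em$values)
  write_tsv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
            file.path(outdir, "distance_matrix.tsv"))
  pmv <- permanova(d, em$samples$group, n_perm = params$n_perm, seed = seed)
  write_tsv(data.frame(F = pmv$F, R2 = pmv$R2, p = pmv$p,
                       n_perm = pmv$n_perm),
            file.path(outdir, "permanova.tsv"))

  ## mapq0 fractions per replicate file
  if (length(ds$reads)) {
    mq <- do.call(rbind, lapply(names(ds$reads), function(rid) {
      m <- mapq0_fraction(ds$reads[[rid]], kept)
      m$file <- rid
      m
    }))
    write_tsv(mq, file.path(outdir, "mapq0_fractions.tsv"))
  } else mq <- NULL

  ## consensus re-mapping stage
  cons <- NULL
  if (!is.null(ds$mm_reads)) {
    chip <- preprocess_alignments(ds$mm_reads$chip)
    input <- preprocess_alignments(ds$mm_reads$input)
    n <- min(nrow(chip), nrow(input))
    chip <- downsample_reads(chip, n, seed = seed)
    input <- downsample_reads(input, n, seed = seed + 1)
    ac <- align_to_consensus(chip$seq, ds$consensus,
                             max_mismatch_rate = params$max_mismatch_rate)
    ai <- align_to_consensus(input$seq, ds$consensus,
                             max_mismatch_rate = params$max_mismatch_rate)
    cons <- consensus_enrichment(ac$counts, ai$counts, n, n)
    cons$uniformity_flag <- ac$counts$uniformity_flag[
      match(cons$family, ac$counts$family)]
    write_tsv(cons, file.path(outdir, "consensus_enrichment.tsv"))
  }

  ## overlap analyses
  go <- gene_overlap(kept, ds$genes)
  pk <- peak_concordance(kept, ds$peaks, frac = params$reciprocal_frac,
                         log2fc = rowMeans(em$values),
                         fc_min = params$fc_min_log2)
  rn <- lapply(ds$rna, function(cg) rna_level(kept, cg))
  ct <- chromatin_state_tally(kept, ds$segmentation)

  ## summary report
  report <- data.frame(
    n_annotated = length(ds$instances),
    n_blocklisted = length(fb$removed),
    n_analyzed = length(kept),
    n_differential = length(diff_ids),
    mean_log2fc = mean(em$values),
    permanova_p = pmv$p,
    gene_overlap_prop = go$proportion,
    n_peak_matched = sum(pk$peak_matched),
    stringsAsFactors = FALSE
  )
  write_tsv(report, file.path(outdir, "report.tsv"))

  manifest <- data.frame(
    key = c("package", "version", "data_dir", "seed",
            paste0("param_", names(params))),
    value = c("satrep", as.character(packageVersion("satrep")),
              data_dir, as.character(seed),
              vapply(params, function(x) as.character(x), character(1))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  invisible(list(kept = kept, removed = fb$removed, matrix = em,
                 differential = diff, family = fam, pca = pca,
                 permanova = pmv, mapq0 = mq, consensus = cons,
                 gene_overlap = go, peaks = pk, rna = rn,
                 chromatin = ct, report = report))
}
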