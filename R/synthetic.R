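## Seeded synthetic miniature dataset: genome, satellite annotation,
## blocklist, per-sample signal tracks with planted group/stage effects,
## reads (multimappers at clusters, consensus-derived tandem-repeat reads),
## RNA contigs, segmentation, peaks, genes — plus a ground-truth table.
##
## The element-level enrichment model: for element e and sample s a target
## clamped log2 FC is drawn, v_es = max(0, baseline_e + effect_es + N(0, sd)).
## In paired ChIP/input mode the ChIP run value over the element is then set
## so that the measured (median-normalized, +1, clamped-log2) enrichment
## reproduces v_es up to the tiny genome-median shift caused by the element
## runs themselves; in fold-change-track mode the element run is 2^v_es and
## recovery is exact. Background signal between elements is a smoothed
## gamma-tile field, giving realistic piecewise-constant bedGraph runs.

#' Configuration for the synthetic dataset generator
#'
#' Two named scenarios are provided. `"cancer_hypomethylation"` emulates a
#' normal-vs-cancer cell-line panel (13 normal vs 8 cancer samples, paired
#' ChIP/input tracks) with a pericentromeric GSATII-like cluster plus
#' dispersed single elements losing H3K9me3 in the cancer group
#' (delta log2 FC = 1.0, within-group sd 0.3, 20 true positives among 200
#' analyzed elements). `"fetal_wave"` emulates a fetal-development panel
#' (8 stages x 9 tissues = 72 samples, precomputed fold-change tracks) where
#' 20 elements follow a wave trajectory — highest at the earliest stage,
#' sharp drop, partial recovery mid-gestation, low again before and at
#' birth — with transformed-mean stage ratio 2.0, and the MMSAT4-like family
#' over-represented among the true positives.
#'
#' @param scenario `"cancer_hypomethylation"` or `"fetal_wave"`.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @param ... overrides for any config field (see the returned list).
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(scenario = c("cancer_hypomethylation",
                                          "fetal_wave"),
                             seed = 1, ...) {
  scenario <- match.arg(scenario)
  base <- list(
    scenario = scenario,
    seed = seed,
    n_dispersed = 170,          # analyzed autosomal singles
    n_cluster = 30,             # analyzed elements in the satellite cluster
    n_cluster_blocked = 15,     # blocklisted elements at the cluster core
    n_dispersed_blocked = 10,   # blocklisted singles
    n_sex = 10,                 # elements on chrX/chrY (dropped by filters)
    n_other_class = 6,          # non-satellite rmsk rows (class filter test)
    n_true_pos = 20,
    element_meanlog = log(600), element_sdlog = 0.4,
    cluster_element_len = 800, cluster_spacing = c(60, 200),
    baseline_mean = 0.6, baseline_sd = 0.25, baseline_min = 0.05,
    within_sd = 0.3,
    tile = 5000, gamma_shape = 80,
    depth_range = c(0.8, 1.3),
    flank_spread = TRUE,
    read_len = 36,
    mapq0_p_cluster = 0.85, mapq0_p_dispersed = 0.12,
    reads_per_element = 15, background_reads = 800,
    dup_rate = 0.05, unmapped_rate = 0.03,
    consensus_mut_rate = 0.02,
    rna_p = c(polyA_plus = 0.30, polyA_minus = 0.36, short = 0.036),
    gene_p = 0.5,
    peak_n = 50,
    seg_states = c("Repressed", "Heterochrom", "Quiescent", "Active",
                   "Transcribed"),
    seg_tile = 20000, seg_gap_p = 0.05
  )
  if (scenario == "cancer_hypomethylation") {
    base <- c(base, list(
      chrom_sizes = c(chr1 = 1500000L, chr2 = 1200000L,
                      chrX = 400000L, chrY = 200000L),
      cluster_chrom = "chr1", cluster_pos = 700000L,
      cluster_family = "GSATII",
      families = c("GSAT", "GSATX", "ALR/Alpha", "(CACTT)n", "ACRO1",
                   "SST1", "REP522", "HSATII", "(GAATG)n"),
      groups = c(rep("normal", 13), rep("cancer", 8)),
      delta = 1.0,                 # normal minus cancer at true positives
      n_cluster_tp = 12,           # of the 20 TPs, how many in the cluster
      mode = "paired"
    ))
  } else {
    base <- c(base, list(
      chrom_sizes = c(chr1 = 1200000L, chr2 = 1000000L,
                      chrX = 300000L, chrY = 150000L),
      cluster_chrom = "chr1", cluster_pos = 600000L,
      cluster_family = "GSAT_MM",
      families = c("SYNREP_MM", "ZP3AR_MM", "CENSAT_MC", "SATMIN",
                   "(TTTCA)n"),
      overrep_family = "MMSAT4", n_overrep_family = 24, n_overrep_tp = 14,
      stages = c("E10.5", "E11.5", "E12.5", "E13.5", "E14.5", "E15.5",
                 "E16.5", "P0"),
      tissues = c("forebrain", "midbrain", "hindbrain", "heart", "liver",
                  "limb", "EFP", "neural-tube", "intestine"),
      stage_wave = c(1.0, 0.15, 0.5, 0.55, 0.6, 0.35, 0.1, 0.0),
      stage_lo = 0.4, stage_hi = 1.8,   # (hi+1)/(lo+1) = 2.0
      n_cluster_tp = 0,
      mode = "fc",
      n_dispersed_blocked = 5, n_cluster_blocked = 5
    ))
  }
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  structure(base, class = c("SyntheticConfig", "list"))
}

## ---------------------------------------------------------------------------
## element placement

## Place n non-overlapping intervals of the given lengths uniformly on the
## given chromosomes, avoiding `avoid` (GRanges); returns 0-based starts.
place_dispersed <- function(n, lens, chrom_sizes, chroms, avoid) {
  av_chrom <- as.character(seqnames(avoid))
  av_s <- if (length(avoid)) start0(avoid) else integer(0)
  av_e <- if (length(avoid)) end0(avoid) else integer(0)
  p_chrom <- character(0)
  p_s <- integer(0)
  p_e <- integer(0)
  out_chrom <- character(n)
  out_start <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in 1:2000) {
      cs <- sample(chroms, 1, prob = chrom_sizes[chroms])
      s0 <- sample.int(chrom_sizes[[cs]] - lens[i], 1) - 1L
      e0 <- s0 + lens[i]
      hit_a <- any(av_chrom == cs & av_s < e0 & av_e > s0)
      hit_p <- any(p_chrom == cs & p_s < e0 & p_e > s0)
      if (!hit_a && !hit_p) {
        out_chrom[i] <- cs
        out_start[i] <- s0
        p_chrom <- c(p_chrom, cs)
        p_s <- c(p_s, s0)
        p_e <- c(p_e, e0)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("place_dispersed: genome too crowded")
  }
  list(chrom = out_chrom, start = out_start,
       placed = as_granges0(p_chrom, p_s, p_e))
}

## ---------------------------------------------------------------------------
## background signal fields

## Smoothed gamma-tile background as an RleList over the whole genome.
background_field <- function(chrom_sizes, tile, shape, scale = 1) {
  cov <- lapply(names(chrom_sizes), function(cs) {
    len <- chrom_sizes[[cs]]
    nt <- ceiling(len / tile)
    v <- rgamma(nt, shape = shape, rate = shape) * scale
    if (nt >= 3) {  # short-range smoothing (moving average of 3 tiles)
      v <- (c(v[1], v[-nt]) + v + c(v[-1], v[nt])) / 3
    }
    wl <- rep(tile, nt)
    wl[nt] <- len - tile * (nt - 1)
    Rle(values = v, lengths = wl)
  })
  names(cov) <- names(chrom_sizes)
  as(cov, "SimpleRleList")
}

as_signal_track <- function(cov, chrom_sizes) {
  structure(list(cov = cov, seqlengths = chrom_sizes), class = "SignalTrack")
}

## ---------------------------------------------------------------------------
## generator

#' Generate the synthetic dataset bundle
#'
#' Produces every object the pipeline consumes, in memory, plus the
#' ground-truth table. Use [write_dataset()] to serialise the bundle to a
#' directory of plain-text files (rmsk table, BEDs, bedGraphs, SAM, FASTA,
#' TSVs) and [audit_dataset()] to verify file-level consistency.
#'
#' @param config a [synthetic_config()].
#' @return list of class `SyntheticBundle`: `config`, `instances`
#'   (all satellite rows incl. blocklisted/sex), `other_class` (non-satellite
#'   rmsk rows), `blocklist`, `tracks` (per sample), `mnase`, `samples`,
#'   `truth` (per-element table), `planted` (elements x samples matrix of
#'   planted clamped log2 FC), `reads` (mapq0 SAM read sets per replicate),
#'   `consensus` (monomer `DNAStringSet`), `mm_reads` (ChIP/input read sets
#'   for consensus re-mapping), `rna`, `segmentation`, `peaks`, `genes`.
#' @export
simulate_satellite_dataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(config$seed)
  cz <- config$chrom_sizes
  autos <- names(cz)[!names(cz) %in% c("chrX", "chrY")]

  ## ---- cluster elements (tight tandem array at a pericentromere analog)
  ncl <- config$n_cluster + config$n_cluster_blocked
  cl_lens <- rep(config$cluster_element_len, ncl)
  cl_gap <- sample(config$cluster_spacing[1]:config$cluster_spacing[2], ncl,
                   replace = TRUE)
  cl_start <- config$cluster_pos + cumsum(c(0, (cl_lens + cl_gap)[-ncl]))
  ## the first n_cluster_blocked elements form the blocklisted core
  cl_block <- seq_len(ncl) <= config$n_cluster_blocked
  cluster_gr <- as_granges0(rep(config$cluster_chrom, ncl), cl_start,
                            cl_start + cl_lens)

  ## ---- dispersed analyzed + blocklisted + sex-chromosome elements
  nd <- config$n_dispersed
  nb <- config$n_dispersed_blocked
  nx <- config$n_sex
  lens_d <- pmax(80L, as.integer(round(rlnorm(nd + nb, config$element_meanlog,
                                              config$element_sdlog))))
  avoid0 <- range(cluster_gr)
  start(avoid0) <- max(1L, start(avoid0) - 50000L)
  end(avoid0) <- min(cz[[config$cluster_chrom]], end(avoid0) + 50000L)
  pd <- place_dispersed(nd + nb, lens_d, cz, autos, avoid0)
  lens_x <- pmax(80L, as.integer(round(rlnorm(nx, config$element_meanlog,
                                              config$element_sdlog))))
  px <- place_dispersed(nx, lens_x, cz, c("chrX", "chrY"), GRanges())

  ## ---- families
  if (config$scenario == "fetal_wave") {
    fam_d <- sample(c(rep(config$overrep_family, config$n_overrep_family),
                      sample(config$families, nd - config$n_overrep_family,
                             replace = TRUE)))
  } else {
    fam_d <- sample(config$families, nd, replace = TRUE)
  }
  fam_b <- sample(config$families, nb, replace = TRUE)
  fam_x <- sample(config$families, nx, replace = TRUE)

  gr_all <- suppressWarnings(c(   # combined pieces span different seqlevels
    cluster_gr,
    as_granges0(pd$chrom, pd$start, pd$start + lens_d),
    as_granges0(px$chrom, px$start, px$start + lens_x)
  ))
  gr_all$name <- c(rep(config$cluster_family, ncl), fam_d, fam_b, fam_x)
  gr_all$family_class <- "Satellite"
  gr_all$cluster <- c(rep(TRUE, ncl), rep(FALSE, nd + nb + nx))
  gr_all$blocklisted_true <- c(cl_block, rep(FALSE, nd), rep(TRUE, nb),
                               rep(FALSE, nx))
  gr_all$sex_chrom <- as.character(seqnames(gr_all)) %in% c("chrX", "chrY")
  o <- order(as.character(seqnames(gr_all)), start(gr_all))
  gr_all <- gr_all[o]
  gr_all$id <- make_instance_ids(gr_all)
  gr_all$blocklisted <- FALSE

  ## ---- blocklist: cluster core + regions under the planted blocked singles
  bl_core <- reduce(gr_all[gr_all$cluster & gr_all$blocklisted_true],
                    min.gapwidth = 500)
  bl_disp <- gr_all[!gr_all$cluster & gr_all$blocklisted_true]
  bl_disp <- resize(bl_disp, fix = "center", width = width(bl_disp) + 200)
  blocklist <- sort(suppressWarnings(c(granges(bl_core), granges(bl_disp))))

  analyzed <- !gr_all$blocklisted_true & !gr_all$sex_chrom
  n_an <- sum(analyzed)

  ## ---- non-satellite rmsk rows
  no <- config$n_other_class
  lens_o <- sample(150:400, no, replace = TRUE)
  po <- place_dispersed(no, lens_o, cz, autos, c(pd$placed, cluster_gr))
  other <- as_granges0(po$chrom, po$start, po$start + lens_o)
  other$name <- sample(c("AluY", "L1MdA", "MIR"), no, replace = TRUE)
  other$family_class <- sample(c("SINE", "LINE"), no, replace = TRUE)

  ## ---- samples and planted effects
  if (config$scenario == "cancer_hypomethylation") {
    groups <- config$groups
    ns <- length(groups)
    samples <- data.frame(
      sample_id = sprintf("%s%02d", ifelse(groups == "normal", "N", "C"),
                          stats::ave(seq_len(ns), groups, FUN = seq_along)),
      group = groups,
      tissue = sample(c("blood", "lung", "skin", "liver", "muscle"),
                      ns, replace = TRUE),
      stage = NA_character_,
      sex = sample(c("F", "M"), ns, replace = TRUE),
      assay = "H3K9me3",
      stringsAsFactors = FALSE
    )
  } else {
    grid <- expand.grid(tissue = config$tissues, stage = config$stages,
                        stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = paste0(grid$stage, "_", grid$tissue),
      group = grid$stage,
      tissue = grid$tissue,
      stage = grid$stage,
      sex = NA_character_,
      assay = "H3K9me3",
      stringsAsFactors = FALSE
    )
    ns <- nrow(samples)
  }

  baseline <- pmax(config$baseline_min,
                   rnorm(length(gr_all), config$baseline_mean,
                         config$baseline_sd))

  ## choose true positives among analyzed elements
  idx_an <- which(analyzed)
  idx_cl_an <- which(analyzed & gr_all$cluster)
  tp <- logical(length(gr_all))
  if (config$scenario == "cancer_hypomethylation") {
    tp_cl <- sample(idx_cl_an, config$n_cluster_tp)
    tp_disp <- sample(setdiff(idx_an, idx_cl_an),
                      config$n_true_pos - config$n_cluster_tp)
    tp[c(tp_cl, tp_disp)] <- TRUE
    ## blocklisted cluster elements carry the effect too (they are part of
    ## the same differentially methylated region, just not analyzable)
    eff_carrier <- tp | (gr_all$cluster & gr_all$blocklisted_true)
  } else {
    idx_fam <- which(analyzed & gr_all$name == config$overrep_family)
    tp_fam <- sample(idx_fam, config$n_overrep_tp)
    tp_oth <- sample(setdiff(idx_an, idx_fam),
                     config$n_true_pos - config$n_overrep_tp)
    tp[c(tp_fam, tp_oth)] <- TRUE
    eff_carrier <- tp
  }

  ## planted per-sample target values v_es (clamped log2 FC)
  planted <- matrix(0, nrow = length(gr_all), ncol = ns,
                    dimnames = list(gr_all$id, samples$sample_id))
  if (config$scenario == "cancer_hypomethylation") {
    mu <- matrix(baseline, length(gr_all), ns)
    is_cancer <- samples$group == "cancer"
    mu[eff_carrier, !is_cancer] <- mu[eff_carrier, !is_cancer] +
      config$delta / 2
    mu[eff_carrier, is_cancer] <- mu[eff_carrier, is_cancer] -
      config$delta / 2
    true_group_means <- cbind(normal = baseline + ifelse(eff_carrier,
                                                         config$delta / 2, 0),
                              cancer = baseline - ifelse(eff_carrier,
                                                         config$delta / 2, 0))
  } else {
    wave <- config$stage_lo +
      (config$stage_hi - config$stage_lo) * config$stage_wave
    names(wave) <- config$stages
    mu <- matrix(baseline, length(gr_all), ns)
    mu[eff_carrier, ] <- matrix(rep(wave[samples$stage],
                                    each = sum(eff_carrier)),
                                nrow = sum(eff_carrier))
    true_group_means <- NULL
  }
  planted <- pmax(mu + matrix(rnorm(length(gr_all) * ns, 0,
                                    config$within_sd),
                              length(gr_all), ns), 0)
  dimnames(planted) <- list(gr_all$id, samples$sample_id)

  ## ---- tracks
  ## Element runs are overlaid on the background field with vectorised
  ## coverage() arithmetic: ind marks element bases, val carries the target
  ## run value, and the track is bg * (ind == 0) + val.
  tracks <- vector("list", ns)
  names(tracks) <- samples$sample_id
  spread_idx <- if (isTRUE(config$flank_spread)) {
    which(gr_all$cluster)
  } else integer(0)
  gr_sl <- gr_all
  GenomeInfoDb::seqlevels(gr_sl) <- names(cz)
  GenomeInfoDb::seqlengths(gr_sl) <- cz
  ind <- coverage(gr_sl)
  overlay <- function(bg, target) {
    val <- coverage(gr_sl, weight = target)
    bg * (ind == 0) + val
  }
  flank_gr <- if (length(spread_idx)) {
    fl <- gr_sl[spread_idx]
    fs <- pmax(0L, start0(fl) - width(fl))
    fe <- pmin(cz[as.character(seqnames(fl))], end0(fl) + width(fl))
    as_granges0(as.character(seqnames(fl)), fs, fe, seqlengths = cz)
  } else NULL
  for (j in seq_len(ns)) {
    depth_c <- runif(1, config$depth_range[1], config$depth_range[2])
    depth_i <- runif(1, config$depth_range[1], config$depth_range[2])
    if (config$mode == "paired") {
      bg_c <- background_field(cz, config$tile, config$gamma_shape, depth_c)
      bg_i <- background_field(cz, config$tile, config$gamma_shape, depth_i)
      input <- as_signal_track(bg_i, cz)
      med_i <- genome_median(input)
      med_c <- genome_median(as_signal_track(bg_c, cz))
      mean_i <- mean_signal(input, gr_all)
      cov_c <- bg_c
      if (!is.null(flank_gr)) {
        ## flank spreading: halfway (geometric) multiplier around elements
        f <- sqrt(2^(planted[spread_idx, j]))
        mult <- 1 + coverage(flank_gr, weight = f - 1)
        cov_c <- cov_c * mult
      }
      target <- med_c * ((mean_i / med_i + 1) * 2^planted[, j] - 1)
      tracks[[j]] <- list(chip = as_signal_track(overlay(cov_c, target), cz),
                          input = input)
    } else {
      bg <- background_field(cz, config$tile, 120, 1.0)
      tracks[[j]] <- list(fc = as_signal_track(overlay(bg, 2^planted[, j]),
                                               cz))
    }
  }
  mnase <- as_signal_track(background_field(cz, config$tile,
                                            config$gamma_shape, 1.0), cz)

  ## ---- mapq0 read sets (two cell lines x two replicates)
  reads <- list()
  truth_mapq0 <- NULL
  if (config$scenario == "cancer_hypomethylation") {
    rl <- config$read_len
    read_targets <- which(!gr_all$sex_chrom)
    p0 <- ifelse(gr_all$cluster[read_targets] |
                   gr_all$blocklisted_true[read_targets],
                 config$mapq0_p_cluster, config$mapq0_p_dispersed)
    truth_rows <- list()
    for (line in c("lineA", "lineB")) for (rep_i in 1:2) {
      rid <- 0L
      recs <- list()
      for (t in seq_along(read_targets)) {
        i <- read_targets[t]
        nr <- stats::rpois(1, config$reads_per_element)
        if (nr == 0) {
          truth_rows[[length(truth_rows) + 1]] <-
            data.frame(file = paste0(line, "_rep", rep_i),
                       element_id = gr_all$id[i], n_reads = 0L,
                       n_mapq0 = 0L)
          next
        }
        s0 <- start0(gr_all[i]) +
          sample.int(max(1L, width(gr_all)[i] - rl), nr, replace = TRUE) - 1L
        is0 <- runif(nr) < p0[t]
        recs[[length(recs) + 1]] <- data.frame(
          chrom = as.character(seqnames(gr_all))[i], pos = s0,
          mapq = ifelse(is0, 0L, 30L), stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1]] <-
          data.frame(file = paste0(line, "_rep", rep_i),
                     element_id = gr_all$id[i], n_reads = nr,
                     n_mapq0 = sum(is0))
      }
      ## background reads strictly outside elements (batch rejection)
      nbg <- config$background_reads
      bg_chrom <- character(0)
      bg_pos <- integer(0)
      while (length(bg_pos) < nbg) {
        nd2 <- 2L * (nbg - length(bg_pos))
        cs <- sample(names(cz), nd2, replace = TRUE, prob = cz)
        s0 <- vapply(cs, function(x) sample.int(cz[[x]] - rl, 1) - 1L,
                     integer(1))
        cand <- as_granges0(cs, s0, s0 + rl)
        ok <- !overlapsAny(cand, gr_all, ignore.strand = TRUE)
        bg_chrom <- c(bg_chrom, cs[ok])
        bg_pos <- c(bg_pos, s0[ok])
      }
      bg_rec <- data.frame(chrom = bg_chrom[seq_len(nbg)],
                           pos = bg_pos[seq_len(nbg)], mapq = 30L,
                           stringsAsFactors = FALSE)
      all_rec <- rbind(do.call(rbind, recs), bg_rec)
      n <- nrow(all_rec)
      dup <- runif(n) < config$dup_rate
      seqs <- random_dna(n, rl)
      n_un <- stats::rbinom(1, n, config$unmapped_rate)
      rs <- read_set(
        read_id = sprintf("%s_r%d_%06d", line, rep_i, seq_len(n + n_un)),
        chrom = c(all_rec$chrom, rep(NA_character_, n_un)),
        pos = c(all_rec$pos, rep(0L, n_un)),
        mapq = c(all_rec$mapq, rep(0L, n_un)),
        seq = c(seqs, random_dna(n_un, rl)),
        unmapped = c(rep(FALSE, n), rep(TRUE, n_un)),
        duplicate = c(dup, rep(FALSE, n_un)),
        reverse = c(runif(n) < 0.5, rep(FALSE, n_un))
      )
      reads[[paste0(line, "_rep", rep_i)]] <- rs
    }
    truth_mapq0 <- do.call(rbind, truth_rows)
  }

  ## ---- consensus references and tandem-repeat-derived reads
  consensus <- make_consensus_set(config$scenario)
  mm_reads <- make_consensus_reads(consensus, config)

  ## ---- RNA contigs, genes, peaks, segmentation
  neighbor_gaps <- neighbor_gap_table(gr_all, cz)
  rna <- list()
  rna_truth <- matrix(NA_real_, length(gr_all), length(config$rna_p),
                      dimnames = list(gr_all$id, names(config$rna_p)))
  for (lib in names(config$rna_p)) {
    sel <- which(analyzed & runif(length(gr_all)) < config$rna_p[[lib]])
    if (length(sel)) {
      ext1 <- pmin(pmax(1L, neighbor_gaps$prev[sel] - 1L),
                   sample(200:2000, length(sel), replace = TRUE))
      ext2 <- pmin(pmax(1L, neighbor_gaps$nxt[sel] - 1L),
                   sample(200:2000, length(sel), replace = TRUE))
      lev <- rlnorm(length(sel), 0, 1)
      cg <- as_granges0(as.character(seqnames(gr_all))[sel],
                        pmax(0L, start0(gr_all)[sel] - ext1),
                        pmin(cz[as.character(seqnames(gr_all))[sel]],
                             end0(gr_all)[sel] + ext2))
      cg$name <- paste0(lib, "_contig_", seq_along(sel))
      cg$level <- lev
      rna[[lib]] <- cg
      rna_truth[sel, lib] <- lev
    } else {
      rna[[lib]] <- GRanges()
    }
  }

  gene_sel <- which(analyzed & !gr_all$cluster &
                      runif(length(gr_all)) < config$gene_p)
  ge1 <- pmin(pmax(1L, neighbor_gaps$prev[gene_sel] - 1L),
              sample(500:3000, length(gene_sel), replace = TRUE))
  ge2 <- pmin(pmax(1L, neighbor_gaps$nxt[gene_sel] - 1L),
              sample(500:3000, length(gene_sel), replace = TRUE))
  genes <- as_granges0(as.character(seqnames(gr_all))[gene_sel],
                       pmax(0L, start0(gr_all)[gene_sel] - ge1),
                       pmin(cz[as.character(seqnames(gr_all))[gene_sel]],
                            end0(gr_all)[gene_sel] + ge2))
  genes$name <- sprintf("gene%03d", seq_along(gene_sel))
  gene_overlapping <- logical(length(gr_all))
  gene_overlapping[gene_sel] <- TRUE

  peak_sel <- sample(setdiff(idx_an, which(gr_all$cluster)), config$peak_n)
  pk1 <- pmin(pmax(0L, neighbor_gaps$prev[peak_sel] - 1L),
              as.integer(round(width(gr_all)[peak_sel] * 0.15)))
  pk2 <- pmin(pmax(0L, neighbor_gaps$nxt[peak_sel] - 1L),
              as.integer(round(width(gr_all)[peak_sel] * 0.15)))
  peaks <- as_granges0(as.character(seqnames(gr_all))[peak_sel],
                       pmax(0L, start0(gr_all)[peak_sel] - pk1),
                       pmin(cz[as.character(seqnames(gr_all))[peak_sel]],
                            end0(gr_all)[peak_sel] + pk2))
  peaks$name <- sprintf("peak%03d", seq_along(peak_sel))
  peak_matched <- logical(length(gr_all))
  peak_matched[peak_sel] <- TRUE

  segmentation <- make_segmentation(cz, config)

  ## ---- truth table
  truth <- data.frame(
    id = gr_all$id,
    chrom = as.character(seqnames(gr_all)),
    start = start0(gr_all),
    end = end0(gr_all),
    family = gr_all$name,
    cluster = gr_all$cluster,
    blocklisted = gr_all$blocklisted_true,
    sex_chrom = gr_all$sex_chrom,
    analyzed = analyzed,
    true_differential = tp,
    baseline = baseline,
    stringsAsFactors = FALSE
  )
  if (!is.null(true_group_means)) {
    truth$true_mean_normal <- true_group_means[, "normal"]
    truth$true_mean_cancer <- true_group_means[, "cancer"]
  }
  truth$gene_overlapping <- gene_overlapping
  truth$peak_matched <- peak_matched
  truth$rna_level_polyA_plus <- rna_truth[, "polyA_plus"]

  structure(list(
    config = config,
    instances = gr_all,
    other_class = other,
    blocklist = blocklist,
    tracks = tracks,
    mnase = mnase,
    samples = samples,
    truth = truth,
    planted = planted,
    reads = reads,
    truth_mapq0 = truth_mapq0,
    consensus = consensus,
    mm_reads = mm_reads,
    rna = rna,
    segmentation = segmentation,
    peaks = peaks,
    genes = genes
  ), class = "SyntheticBundle")
}

## Gap (bp) to previous/next element on the same chromosome (or to the
## chromosome ends), used to extend contigs/genes without touching neighbors.
neighbor_gap_table <- function(gr, chrom_sizes) {
  n <- length(gr)
  prev <- integer(n)
  nxt <- integer(n)
  chr <- as.character(seqnames(gr))
  for (cs in unique(chr)) {
    idx <- which(chr == cs)
    idx <- idx[order(start(gr)[idx])]
    s <- start0(gr)[idx]
    e <- end0(gr)[idx]
    prev[idx] <- s - c(0L, e[-length(e)])
    nxt[idx] <- c(s[-1], chrom_sizes[[cs]]) - e
  }
  list(prev = pmax(prev, 0L), nxt = pmax(nxt, 0L))
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## Synthetic consensus monomers (random sequence, seeded); IMPB_01-analog
## carries a low-complexity dinucleotide insertion to exercise the coverage
## uniformity flag.
make_consensus_set <- function(scenario) {
  mono <- c(
    GSAT_MM = paste(sample(c("A", "C", "G", "T"), 234, replace = TRUE),
                    collapse = ""),
    SYNREP_MM = paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                      collapse = ""),
    IMPB_01 = paste0(
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
      strrep("CA", 60),
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")),
    ZP3AR_MM = paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                     collapse = ""),
    CENSAT_MC = paste(sample(c("A", "C", "G", "T"), 180, replace = TRUE),
                      collapse = ""),
    SATMIN = paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                   collapse = ""),
    MMSAT4 = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = ""),
    RLTR_SAT = paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
                     collapse = "")
  )
  Biostrings::DNAStringSet(mono)
}

## Draw a read from a consensus dimer with per-base mutation.
consensus_read <- function(dimer_chars, read_len, mut_rate) {
  s0 <- sample.int(length(dimer_chars) - read_len + 1, 1)
  r <- dimer_chars[s0:(s0 + read_len - 1)]
  nm <- rbinom(1, read_len, mut_rate)
  if (nm > 0) {
    at <- sample.int(read_len, nm)
    r[at] <- vapply(r[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(r, collapse = "")
}

## MAPQ-0 read sets for the consensus re-mapping stage. ChIP carries a
## planted 3x excess of major-satellite (GSAT_MM) reads over input, 2x at
## the minor satellite (SYNREP_MM); IMPB_01 reads come only from its
## low-complexity segment; the rest is random (unalignable) sequence.
make_consensus_reads <- function(consensus, config) {
  rl <- config$read_len
  mut <- config$consensus_mut_rate
  dimer_of <- function(f) strsplit(paste0(as.character(consensus[[f]]),
                                          as.character(consensus[[f]])),
                                   "")[[1]]
  gs <- dimer_of("GSAT_MM")
  sy <- dimer_of("SYNREP_MM")
  im <- dimer_of("IMPB_01")
  lc_lo <- 121 + 10  # inside the CA-repeat segment of the IMPB_01 dimer
  lc_hi <- 121 + 120 - 10 - rl
  draw_set <- function(n_gsat, n_syn, n_impb, n_noise, prefix) {
    seqs <- c(
      vapply(seq_len(n_gsat), function(i) consensus_read(gs, rl, mut),
             character(1)),
      vapply(seq_len(n_syn), function(i) consensus_read(sy, rl, mut),
             character(1)),
      vapply(seq_len(n_impb), function(i) {
        s0 <- sample(lc_lo:lc_hi, 1)
        paste(im[s0:(s0 + rl - 1)], collapse = "")
      }, character(1)),
      random_dna(n_noise, rl)
    )
    truth_fam <- c(rep("GSAT_MM", n_gsat), rep("SYNREP_MM", n_syn),
                   rep("IMPB_01", n_impb), rep(NA_character_, n_noise))
    n <- length(seqs)
    rs <- read_set(
      read_id = sprintf("%s_%06d", prefix, seq_len(n)),
      chrom = rep(names(config$chrom_sizes)[1], n),
      pos = rep(0L, n),
      mapq = rep(0L, n),
      seq = seqs
    )
    rs$true_family <- truth_fam
    rs
  }
  ## Planted enrichment is the ratio of library *fractions* (so that it is
  ## what downsampling to equal totals recovers): ChIP totals 3200 with
  ## 480/160/60 consensus-derived reads, input totals 2880 with 144/72/27 —
  ## GSAT_MM 3x, SYNREP_MM 2x, IMPB_01 2x.
  list(
    chip = draw_set(480, 160, 60, 2500, "mmchip"),
    input = draw_set(144, 72, 27, 2637, "mminput"),
    planted_fc = c(GSAT_MM = 3, SYNREP_MM = 2, IMPB_01 = 2)
  )
}

## Alternating-state tiling with occasional unsegmented gaps.
make_segmentation <- function(chrom_sizes, config) {
  states <- config$seg_states
  chrom <- character(0); s0 <- integer(0); e0 <- integer(0); st <- character(0)
  for (cs in names(chrom_sizes)) {
    len <- chrom_sizes[[cs]]
    nt <- ceiling(len / config$seg_tile)
    ts <- (seq_len(nt) - 1L) * config$seg_tile
    te <- pmin(ts + config$seg_tile, len)
    tst <- sample(states, nt, replace = TRUE)
    keep <- runif(nt) >= config$seg_gap_p
    chrom <- c(chrom, rep(cs, sum(keep)))
    s0 <- c(s0, ts[keep]); e0 <- c(e0, te[keep]); st <- c(st, tst[keep])
  }
  gr <- as_granges0(chrom, s0, e0)
  gr$name <- st
  gr
}
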