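## Serialisation of a synthetic bundle to a directory of plain-text files
## (UCSC-style rmsk table, BEDs, bedGraphs, SAM, FASTA, TSVs), the matching
## reader, and the self-audit pass.

#' Write a synthetic bundle to a directory
#'
#' Emits: `rmsk.tsv` (17-column UCSC rmsk table incl. non-satellite rows),
#' `blocklist.bed`, `peaks.bed`, `genes.bed`, `segmentation.bed`,
#' `rna_<library>.bed` (with the expression level in the score column),
#' per-sample `<id>_chip.bedGraph`/`<id>_input.bedGraph` (or
#' `<id>_fc.bedGraph`), `mnase.bedGraph`, per-replicate `<id>.sam`,
#' `mm_chip.sam`/`mm_input.sam` (MAPQ-0 reads for consensus re-mapping),
#' `consensus_synthetic.fa`, `chrom_sizes.tsv`, `samples.tsv`, `truth.tsv`,
#' `truth_mapq0.tsv`. Re-running with the same config and seed yields
#' byte-identical files.
#'
#' @param bundle a `SyntheticBundle`.
#' @param outdir output directory.
#' @param force overwrite a non-empty directory.
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(bundle, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("write_dataset: ", outdir, " exists and is not empty (use force)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cz <- bundle$config$chrom_sizes

  write_rmsk_table(c(bundle$instances, bundle$other_class),
                   file.path(outdir, "rmsk.tsv"))
  write_bed(bundle$blocklist, file.path(outdir, "blocklist.bed"))
  write_bed(bundle$peaks, file.path(outdir, "peaks.bed"))
  write_bed(bundle$genes, file.path(outdir, "genes.bed"))
  write_bed(bundle$segmentation, file.path(outdir, "segmentation.bed"))
  for (lib in names(bundle$rna)) {
    write_bed(bundle$rna[[lib]], file.path(outdir, paste0("rna_", lib, ".bed")),
              score = bundle$rna[[lib]]$level)
  }
  for (sid in names(bundle$tracks)) {
    tr <- bundle$tracks[[sid]]
    if (!is.null(tr$fc)) {
      write_bedgraph(tr$fc, file.path(outdir, paste0(sid, "_fc.bedGraph")))
    } else {
      write_bedgraph(tr$chip, file.path(outdir, paste0(sid, "_chip.bedGraph")))
      write_bedgraph(tr$input,
                     file.path(outdir, paste0(sid, "_input.bedGraph")))
    }
  }
  write_bedgraph(bundle$mnase, file.path(outdir, "mnase.bedGraph"))
  for (rid in names(bundle$reads)) {
    write_sam(bundle$reads[[rid]], cz, file.path(outdir, paste0(rid, ".sam")))
  }
  if (!is.null(bundle$mm_reads)) {
    write_sam(bundle$mm_reads$chip, cz, file.path(outdir, "mm_chip.sam"))
    write_sam(bundle$mm_reads$input, cz, file.path(outdir, "mm_input.sam"))
  }
  Biostrings::writeXStringSet(bundle$consensus,
                              file.path(outdir, "consensus_synthetic.fa"))
  write_tsv(data.frame(chrom = names(cz), size = unname(as.integer(cz))),
            file.path(outdir, "chrom_sizes.tsv"))
  write_tsv(bundle$samples, file.path(outdir, "samples.tsv"))
  write_tsv(bundle$truth, file.path(outdir, "truth.tsv"))
  if (!is.null(bundle$truth_mapq0))
    write_tsv(bundle$truth_mapq0, file.path(outdir, "truth_mapq0.tsv"))
  invisible(outdir)
}

## BED writer (0-based half-open); name/score optional columns.
write_bed <- function(gr, path, score = NULL) {
  n <- length(gr)
  con <- file(path, "w")
  on.exit(close(con))
  if (!n) return(invisible(path))
  nm <- if (!is.null(gr$name)) gr$name else paste0("r", seq_len(n))
  if (is.null(score)) {
    writeLines(paste(as.character(seqnames(gr)), start0(gr), end0(gr), nm,
                     sep = "\t"), con)
  } else {
    writeLines(paste(as.character(seqnames(gr)), start0(gr), end0(gr), nm,
                     trimws(formatC(score, digits = 6, format = "g")),
                     sep = "\t"), con)
  }
  invisible(path)
}

## 17-column UCSC-style rmsk table (with bin column), tab separated.
write_rmsk_table <- function(gr, path) {
  df <- data.frame(
    bin = 0L, swScore = 1000L, milliDiv = 0L, milliDel = 0L, milliIns = 0L,
    genoName = as.character(seqnames(gr)),
    genoStart = start0(gr), genoEnd = end0(gr), genoLeft = 0L,
    strand = ifelse(as.character(strand(gr)) == "-", "-", "+"),
    repName = gr$name, repClass = gr$family_class,
    repFamily = gr$family_class,
    repStart = 0L, repEnd = width(gr), repLeft = 0L,
    id = seq_along(gr),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## Minimal SAM writer (header + 11 mandatory fields).
write_sam <- function(reads, chrom_sizes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(paste0("@SQ\tSN:", names(chrom_sizes), "\tLN:",
                    as.integer(chrom_sizes)), con)
  flag <- ifelse(reads$unmapped, 4L, 0L) +
    ifelse(reads$duplicate, 1024L, 0L) +
    ifelse(!reads$unmapped & reads$reverse, 16L, 0L)
  rname <- ifelse(reads$unmapped | is.na(reads$chrom), "*", reads$chrom)
  pos <- ifelse(reads$unmapped, 0L, reads$pos + 1L)
  cigar <- ifelse(reads$unmapped, "*", paste0(nchar(reads$seq), "M"))
  qual <- strrep("I", nchar(reads$seq))
  writeLines(paste(reads$read_id, flag, rname, pos, reads$mapq, cigar,
                   "*", 0L, 0L, reads$seq, qual, sep = "\t"), con)
  invisible(path)
}

#' Read a written dataset directory back into pipeline inputs
#'
#' Reconstructs the analysis inputs from the plain-text files (exercising
#' the same readers a user would apply to real data).
#'
#' @param dir dataset directory from [write_dataset()].
#' @return list: `chrom_sizes`, `instances` (parsed from the rmsk table,
#'   class-filtered to Satellite), `blocklist`, `tracks`, `mnase`, `samples`,
#'   `peaks`, `genes`, `segmentation`, `rna`, `reads`, `consensus`,
#'   `mm_reads`, `truth`.
#' @export
read_dataset <- function(dir) {
  czdf <- read_tsv(file.path(dir, "chrom_sizes.tsv"))
  cz <- setNames(as.integer(czdf$size), czdf$chrom)
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  tracks <- vector("list", nrow(samples))
  names(tracks) <- samples$sample_id
  for (sid in samples$sample_id) {
    fcp <- file.path(dir, paste0(sid, "_fc.bedGraph"))
    if (file.exists(fcp)) {
      tracks[[sid]] <- list(fc = read_bedgraph(fcp, cz))
    } else {
      tracks[[sid]] <- list(
        chip = read_bedgraph(file.path(dir, paste0(sid, "_chip.bedGraph")),
                             cz),
        input = read_bedgraph(file.path(dir, paste0(sid, "_input.bedGraph")),
                              cz))
    }
  }
  rna_files <- dir(dir, pattern = "^rna_.*\\.bed$", full.names = TRUE)
  rna <- lapply(rna_files, function(f) {
    gr <- read_bed(f)
    gr$level <- as.numeric(gr$score)
    gr
  })
  names(rna) <- sub("^rna_(.*)\\.bed$", "\\1", basename(rna_files))
  sam_files <- dir(dir, pattern = "\\.sam$", full.names = TRUE)
  sam_files <- sam_files[!grepl("^mm_", basename(sam_files))]
  reads <- lapply(sam_files, read_alignments)
  names(reads) <- sub("\\.sam$", "", basename(sam_files))
  mmc <- file.path(dir, "mm_chip.sam")
  mm_reads <- if (file.exists(mmc)) {
    list(chip = read_alignments(mmc),
         input = read_alignments(file.path(dir, "mm_input.sam")))
  } else NULL
  list(
    chrom_sizes = cz,
    instances = read_rmsk(file.path(dir, "rmsk.tsv")),
    blocklist = read_bed(file.path(dir, "blocklist.bed"), label = "blocklist"),
    tracks = tracks,
    mnase = read_bedgraph(file.path(dir, "mnase.bedGraph"), cz),
    samples = samples,
    peaks = read_bed(file.path(dir, "peaks.bed"), label = "peaks"),
    genes = read_bed(file.path(dir, "genes.bed"), label = "genes"),
    segmentation = read_bed(file.path(dir, "segmentation.bed"),
                            label = "segmentation"),
    rna = rna,
    reads = reads,
    consensus = read_consensus_fasta(file.path(dir,
                                               "consensus_synthetic.fa")),
    mm_reads = mm_reads,
    truth = read_tsv(file.path(dir, "truth.tsv"))
  )
}

#' Audit a written dataset against its ground truth
#'
#' File-level consistency checks: every truth element appears in the parsed
#' rmsk table with identical coordinates; blocklist flags match an actual
#' intersection with the written blocklist BED; SAM read counts match the
#' generator's bookkeeping; every sample has its track file(s).
#'
#' @param dir dataset directory.
#' @return list: `ok` (logical) and `violations` (character vector).
#' @export
audit_dataset <- function(dir) {
  v <- character(0)
  ds <- read_dataset(dir)
  truth <- ds$truth
  miss <- setdiff(truth$id, ds$instances$id)
  if (length(miss))
    v <- c(v, paste0("truth elements missing from rmsk table: ",
                     paste(head(miss, 5), collapse = ", ")))
  fb <- filter_blocklist(ds$instances, ds$blocklist)
  flagged <- truth$id[truth$blocklisted]
  got <- fb$removed$id
  if (!setequal(flagged, got))
    v <- c(v, paste0("blocklisted flag mismatch: truth=", length(flagged),
                     " observed=", length(got)))
  if (!is.null(ds$reads) && length(ds$reads) &&
      file.exists(file.path(dir, "truth_mapq0.tsv"))) {
    tm <- read_tsv(file.path(dir, "truth_mapq0.tsv"))
    for (rid in names(ds$reads)) {
      expected <- sum(tm$n_reads[tm$file == rid])
      mapped <- ds$reads[[rid]]
      el <- ds$instances
      got_n <- sum(mapq0_fraction(mapped, el)$n_reads)
      if (got_n != expected)
        v <- c(v, paste0(rid, ": element-overlapping reads ", got_n,
                         " != bookkeeping ", expected))
    }
  }
  for (sid in ds$samples$sample_id) {
    has <- file.exists(file.path(dir, paste0(sid, "_fc.bedGraph"))) ||
      (file.exists(file.path(dir, paste0(sid, "_chip.bedGraph"))) &&
         file.exists(file.path(dir, paste0(sid, "_input.bedGraph"))))
    if (!has) v <- c(v, paste0("missing track file(s) for ", sid))
  }
  list(ok = length(v) == 0, violations = v)
}
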