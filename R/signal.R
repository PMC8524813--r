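## Signal tracks and the normalized, clamped log2 fold-change enrichment.
##
## A SignalTrack is a per-chromosome piecewise-constant non-negative signal
## held as an RleList covering every base of each chromosome; bases not
## covered by any input run have value 0. Enrichment per element is
##   log2( (mean_chip/median_chip + 1) / (mean_input/median_input + 1) )
## clamped at 0, where the medians are genome-wide per-base medians. The +1
## pseudocount avoids division by zero and the clamp discards FC < 1
## (input stronger than ChIP: no true signal).

#' Build a signal track from interval runs
#'
#' @param gr `GRanges` with a numeric `score` column; runs must be disjoint
#'   within each chromosome. Negative scores are floored at 0 (some bigWig
#'   dialects emit them) with a warning.
#' @param seqlengths named integer vector of chromosome lengths covering at
#'   least the chromosomes present in `gr`.
#' @return object of class `SignalTrack`.
#' @export
signal_track <- function(gr, seqlengths) {
  stopifnot(!is.null(gr$score), !is.null(names(seqlengths)))
  if (any(gr$score < 0)) {
    warning("signal_track: ", sum(gr$score < 0),
            " negative run value(s) floored at 0")
    gr$score <- pmax(gr$score, 0)
  }
  if (!all(as.character(seqnames(gr)) %in% names(seqlengths)))
    stop("signal_track: runs on chromosomes absent from seqlengths")
  grl <- split(ranges(gr), factor(as.character(seqnames(gr)),
                                  levels = names(seqlengths)))
  if (any(vapply(grl, function(r) !isDisjoint(r), logical(1))))
    stop("signal_track: overlapping runs within a chromosome")
  gr2 <- gr
  GenomeInfoDb::seqlevels(gr2) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr2) <- seqlengths
  cov <- coverage(gr2, weight = gr2$score)
  structure(list(cov = cov, seqlengths = seqlengths), class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat("SignalTrack over", length(x$seqlengths), "chromosome(s),",
      sum(as.numeric(x$seqlengths)), "bp\n")
  invisible(x)
}

#' Read a 4-column bedGraph file as a SignalTrack
#'
#' @param path bedGraph path (plain text).
#' @param seqlengths named chromosome lengths.
#' @return `SignalTrack`.
#' @export
read_bedgraph <- function(path, seqlengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(gr, seqlengths)
}

#' Write a SignalTrack as bedGraph
#'
#' Zero-valued runs are omitted (implicit zeros), matching common bedGraph
#' practice.
#'
#' @param track `SignalTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    ends <- as.integer(cumsum(runLength(r)))
    starts <- c(0L, head(ends, -1L))
    vals <- runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(paste(chrom, starts[keep], ends[keep],
                       trimws(formatC(vals[keep], digits = 6, format = "g")),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Length-weighted mean signal over intervals
#'
#' Mean of the per-base track value over every base of each interval;
#' uncovered bases count as 0. Intervals extending beyond chromosome bounds
#' are clipped with a warning; intervals on chromosomes absent from the track
#' yield 0 with a warning.
#'
#' @param track `SignalTrack`.
#' @param intervals `GRanges`.
#' @return numeric vector along `intervals`.
#' @export
mean_signal <- function(track, intervals) {
  out <- numeric(length(intervals))
  chr <- as.character(seqnames(intervals))
  for (cs in unique(chr)) {
    idx <- which(chr == cs)
    if (!cs %in% names(track$cov)) {
      warning("mean_signal: chromosome ", cs, " absent from track; 0 returned")
      next
    }
    r <- track$cov[[cs]]
    s <- start(intervals)[idx]
    e <- end(intervals)[idx]
    if (any(s < 1) || any(e > length(r))) {
      warning("mean_signal: interval(s) clipped to chromosome bounds on ", cs)
      s <- pmax(s, 1L)
      e <- pmin(e, length(r))
    }
    v <- IRanges::Views(r, start = s, end = e)
    out[idx] <- IRanges::viewMeans(v)
  }
  out
}

#' Genome-wide per-base median of a track
#'
#' Median of the per-base value distribution over all bases of the given
#' chromosomes, computed from run lengths without expanding to single bases.
#' Bases not covered by any run count as 0 (configurable via
#' `include_zeros = FALSE`, which restricts the distribution to covered,
#' non-zero bases). The even-count convention is the mean of the two central
#' order statistics.
#'
#' @param track `SignalTrack`.
#' @param chroms chromosomes to pool; default all in the track.
#' @param include_zeros count zero-valued bases (default `TRUE`).
#' @return positive scalar; a zero median is an error (degenerate track —
#'   normalization would divide by zero).
#' @export
genome_median <- function(track, chroms = NULL, include_zeros = TRUE) {
  if (is.null(chroms)) chroms <- names(track$cov)
  stopifnot(length(chroms) > 0, all(chroms %in% names(track$cov)))
  vals <- numeric(0)
  lens <- numeric(0)
  for (cs in chroms) {
    r <- track$cov[[cs]]
    vals <- c(vals, runValue(r))
    lens <- c(lens, runLength(r))
  }
  if (!include_zeros) {
    keep <- vals > 0
    vals <- vals[keep]
    lens <- lens[keep]
    if (!length(vals)) stop("genome_median: track empty on chosen chromosomes")
  }
  med <- weighted_median(vals, lens)
  if (med == 0)
    stop("genome_median: median is 0 (degenerate track). Most bases carry no ",
         "signal; check track coverage or use include_zeros = FALSE ",
         "deliberately and document the choice.")
  med
}

#' Median-normalize a mean signal
#'
#' `mean_sig / median + 1`. The +1 pseudocount keeps every normalized value
#' >= 1 so the subsequent ratio is always defined.
#'
#' @param mean_sig non-negative mean signal.
#' @param median positive genome median.
#' @return normalized value >= 1.
#' @export
normalize_value <- function(mean_sig, median) {
  stopifnot(median > 0)
  mean_sig / median + 1
}

#' Clamped log2 fold change
#'
#' `max(0, log2(chip_norm / input_norm))`: loci where input exceeds ChIP are
#' treated as carrying no true signal.
#'
#' @param chip_norm,input_norm normalized values (>= 1).
#' @return non-negative log2 fold change (vectorised).
#' @export
clamped_log2_fc <- function(chip_norm, input_norm) {
  pmax(0, log2(chip_norm / input_norm))
}

#' Per-element enrichment of one ChIP/input pair
#'
#' For each element: the clamped log2 ratio of the median-normalized mean
#' ChIP signal to the median-normalized mean input signal.
#'
#' @param chip,input `SignalTrack`s of the paired sample.
#' @param instances `GRanges` of elements.
#' @param chroms chromosomes over which the genome medians are computed
#'   (default: all chromosomes of each track).
#' @return numeric vector of clamped log2 FC along `instances`.
#' @export
element_enrichment <- function(chip, input, instances, chroms = NULL) {
  med_c <- genome_median(chip, chroms)
  med_i <- genome_median(input, chroms)
  mc <- mean_signal(chip, instances)
  mi <- mean_signal(input, instances)
  clamped_log2_fc(normalize_value(mc, med_c), normalize_value(mi, med_i))
}

#' Per-element mean of a precomputed fold-change track
#'
#' For tracks that already contain the linear ChIP/input fold enrichment
#' (e.g. merged-replicate fold-change tracks), the per-element value is the
#' length-weighted mean FC; no median normalization applies.
#'
#' @param fc_track `SignalTrack` of linear fold changes.
#' @param instances `GRanges`.
#' @return list with `linear` (mean FC) and `log2_clamped`
#'   (`max(0, log2(mean FC))`) vectors; the linear values feed stage-mean
#'   summaries, the clamped values the enrichment matrix.
#' @export
element_fc_from_fc_track <- function(fc_track, instances) {
  lin <- mean_signal(fc_track, instances)
  list(linear = lin, log2_clamped = pmax(0, log2(pmax(lin, .Machine$double.xmin))))
}

#' Assemble an enrichment matrix across samples
#'
#' @param instances `GRanges` of elements (rows; `id` column required).
#' @param samples data.frame of sample metadata with at least `sample_id`;
#'   typical columns: `group`, `tissue`, `stage`, `sex`, `assay`.
#' @param tracks named list along `samples$sample_id`; each entry either
#'   `list(chip = SignalTrack, input = SignalTrack)` or
#'   `list(fc = SignalTrack)` for precomputed fold-change tracks.
#' @param chroms chromosomes for genome medians (paired mode only).
#' @return object of class `EnrichmentMatrix`: list with `values`
#'   (elements x samples matrix of clamped log2 FC), `samples` (metadata) and,
#'   in fc-track mode, `linear` (matrix of linear mean FC).
#' @export
build_enrichment_matrix <- function(instances, samples, tracks,
                                    chroms = NULL) {
  stopifnot(all(samples$sample_id %in% names(tracks)))
  n <- length(instances)
  vals <- matrix(NA_real_, nrow = n, ncol = nrow(samples),
                 dimnames = list(instances$id, samples$sample_id))
  linear <- NULL
  for (j in seq_len(nrow(samples))) {
    tr <- tracks[[samples$sample_id[j]]]
    if (!is.null(tr$fc)) {
      fc <- element_fc_from_fc_track(tr$fc, instances)
      vals[, j] <- fc$log2_clamped
      if (is.null(linear)) linear <- vals * NA_real_
      linear[, j] <- fc$linear
    } else {
      vals[, j] <- element_enrichment(tr$chip, tr$input, instances, chroms)
    }
  }
  stopifnot(all(is.finite(vals)), all(vals >= 0))
  structure(list(values = vals, samples = samples, linear = linear),
            class = "EnrichmentMatrix")
}

#' @export
print.EnrichmentMatrix <- function(x, ...) {
  cat("EnrichmentMatrix:", nrow(x$values), "elements x", ncol(x$values),
      "samples (clamped log2 FC)\n")
  invisible(x)
}

#' Write / read an enrichment matrix as TSV
#'
#' Rows are element ids, columns sample ids; a first column `element_id`
#' carries the row names.
#'
#' @param em `EnrichmentMatrix`.
#' @param path matrix TSV path.
#' @param meta_path optional sample-metadata TSV path.
#' @export
write_enrichment_matrix <- function(em, path, meta_path = NULL) {
  df <- data.frame(element_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(meta_path)) write_tsv(em$samples, meta_path)
  invisible(path)
}

#' @rdname write_enrichment_matrix
#' @export
read_enrichment_matrix <- function(path, meta_path = NULL) {
  df <- read_tsv(path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$element_id
  samples <- if (!is.null(meta_path)) read_tsv(meta_path)
             else data.frame(sample_id = colnames(vals))
  structure(list(values = vals, samples = samples, linear = NULL),
            class = "EnrichmentMatrix")
}

## Integer window boundaries tiling [s0, e0) into n near-equal windows
## (length difference <= 1 bp, widths sum exactly to the region length).
window_bounds <- function(s0, e0, n) {
  L <- e0 - s0
  b <- s0 + floor((0:n) * L / n)
  data.frame(start = b[-(n + 1)], end = b[-1])
}

#' Windowed enrichment profile over an element and its flanks
#'
#' Extends the element by one element-length up- and downstream, divides the
#' extended region into at least `min_windows` equal consecutive
#' non-overlapping windows and computes the clamped log2 FC of normalized
#' window means in each window. Used to visualise signal spreading beyond
#' element boundaries.
#'
#' @param chip,input `SignalTrack`s.
#' @param element single-interval `GRanges`.
#' @param min_windows minimum number of windows (default 50); large clusters
#'   may use more (e.g. 500).
#' @param chroms chromosomes for genome medians.
#' @return data.frame: `window_index`, `start`, `end` (0-based half-open),
#'   `log2fc`; attribute `clipped` records chromosome-boundary clipping.
#' @export
window_profile <- function(chip, input, element, min_windows = 50,
                           chroms = NULL) {
  stopifnot(length(element) == 1)
  cs <- as.character(seqnames(element))
  len <- width(element)
  s0 <- start0(element) - len
  e0 <- end0(element) + len
  clipped <- FALSE
  if (s0 < 0) { s0 <- 0L; clipped <- TRUE }
  clen <- chip$seqlengths[[cs]]
  if (e0 > clen) { e0 <- clen; clipped <- TRUE }
  if (clipped)
    message("window_profile: extended region clipped to chromosome bounds")
  n <- min_windows
  if (e0 - s0 < n) {
    warning("window_profile: region shorter than requested windows; reduced")
    n <- e0 - s0
  }
  wb <- window_bounds(s0, e0, n)
  wgr <- as_granges0(rep(cs, n), wb$start, wb$end)
  med_c <- genome_median(chip, chroms)
  med_i <- genome_median(input, chroms)
  lfc <- clamped_log2_fc(normalize_value(mean_signal(chip, wgr), med_c),
                         normalize_value(mean_signal(input, wgr), med_i))
  out <- data.frame(window_index = seq_len(n), start = wb$start,
                    end = wb$end, log2fc = lfc)
  attr(out, "clipped") <- clipped
  out
}
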