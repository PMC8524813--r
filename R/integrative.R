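## Overlap-based secondary analyses: called-peak concordance, RNA contig
## levels at satellite loci, chromatin-state composition, MNase-based
## nucleosome occupancy with a shuffled null, and gene overlap.

#' Concordance of elements with called peaks
#'
#' Per element: does any called peak reciprocally overlap it at fraction
#' `frac`? Summaries are stratified by an optional per-element enrichment
#' threshold (e.g. only elements with linear FC >= 2, i.e. clamped log2 FC
#' >= 1, counted as confidently enriched).
#'
#' @param elements `GRanges` (with `id`).
#' @param peaks `GRanges` of called peaks for one sample.
#' @param frac reciprocal-overlap fraction (default 0.5).
#' @param log2fc optional per-element clamped log2 FC for this sample.
#' @param fc_min threshold on `log2fc` for the stratified summary
#'   (default 1, i.e. linear FC 2).
#' @return data.frame per element: `element_id`, `peak_matched`,
#'   `passes_fc`; attribute `summary` = c(n_matched, n_matched_fc).
#' @export
peak_concordance <- function(elements, peaks, frac = 0.5, log2fc = NULL,
                             fc_min = 1) {
  matched <- reciprocal_overlap_any(elements, peaks, frac)
  passes <- if (is.null(log2fc)) rep(NA, length(elements))
            else log2fc >= fc_min
  out <- data.frame(element_id = elements$id, peak_matched = matched,
                    passes_fc = passes, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    n_matched = sum(matched),
    n_matched_fc = if (is.null(log2fc)) NA_integer_
                   else sum(matched & passes)
  )
  out
}

#' Transcript level at satellite loci from RNA contigs
#'
#' Per element, the mean expression level (BPKM for long RNA, RPKM for short
#' RNA) over all contigs overlapping it by at least one base. `has_evidence`
#' is `TRUE` iff at least one contig overlaps. Contigs fully contained within
#' the element are book-kept separately (`n_contained`): satellite loci are
#' typically parts of longer transcripts starting/ending outside the element.
#'
#' @param elements `GRanges` (with `id`).
#' @param contigs `GRanges` of RNA contigs with numeric `level` (or `score`)
#'   column.
#' @param weighting `"none"` (unweighted mean, default) or `"overlap_bp"`
#'   (overlap-length weighted).
#' @return data.frame: `element_id`, `n_contigs`, `n_contained`, `level`
#'   (`NA` without evidence), `has_evidence`.
#' @export
rna_level <- function(elements, contigs, weighting = c("none", "overlap_bp")) {
  weighting <- match.arg(weighting)
  lev <- contigs$level
  if (is.null(lev)) lev <- contigs$score
  if (is.null(lev)) stop("rna_level: contigs need a level or score column")
  stopifnot(all(lev >= 0))
  hits <- findOverlaps(elements, contigs, ignore.strand = TRUE)
  n <- countOverlaps(elements, contigs, ignore.strand = TRUE)
  level <- rep(NA_real_, length(elements))
  contained <- integer(length(elements))
  if (length(hits)) {
    q <- queryHits(hits); s <- subjectHits(hits)
    w <- if (weighting == "overlap_bp") {
      width(pintersect(ranges(elements)[q], ranges(contigs)[s]))
    } else rep(1, length(hits))
    sw <- tapply(w * lev[s], q, sum)
    tw <- tapply(w, q, sum)
    level[as.integer(names(sw))] <- sw / tw
    isin <- start(contigs)[s] >= start(elements)[q] &
            end(contigs)[s] <= end(elements)[q]
    tc <- tapply(isin, q, sum)
    contained[as.integer(names(tc))] <- as.integer(tc)
  }
  data.frame(element_id = elements$id, n_contigs = n,
             n_contained = contained, level = level,
             has_evidence = n > 0, stringsAsFactors = FALSE)
}

#' Chromatin-state composition of elements
#'
#' Per state, the total number of element base pairs overlapping genome
#' segments of that state; element bases outside every segment go to the
#' `"unsegmented"` bucket. The genome-wide bp per state is returned alongside
#' for relative-representation comparisons. Overlapping segments within one
#' segmentation violate its contract and are an error.
#'
#' @param elements `GRanges`.
#' @param segments `GRanges` with a state label in `name` (or `state`).
#' @return list: `element_bp` (named bp per state incl. `unsegmented`),
#'   `genome_bp` (named bp per state).
#' @export
chromatin_state_tally <- function(elements, segments) {
  state <- segments$state
  if (is.null(state)) state <- segments$name
  if (is.null(state)) stop("chromatin_state_tally: segments need a state label")
  if (!all(isDisjoint(split(ranges(segments), seqnames(segments)))))
    stop("chromatin_state_tally: overlapping segments within the segmentation")
  hits <- findOverlaps(elements, segments, ignore.strand = TRUE)
  states <- sort(unique(state))
  bp <- setNames(numeric(length(states)), states)
  if (length(hits)) {
    ov <- width(pintersect(ranges(elements)[queryHits(hits)],
                           ranges(segments)[subjectHits(hits)]))
    t1 <- tapply(ov, state[subjectHits(hits)], sum)
    bp[names(t1)] <- as.numeric(t1)
  }
  total_bp <- sum(width(reduce(elements, ignore.strand = TRUE)))
  bp <- c(bp, unsegmented = total_bp - sum(bp))
  genome_bp <- tapply(width(segments), state, sum)
  list(element_bp = bp, genome_bp = setNames(as.numeric(genome_bp),
                                             names(genome_bp)))
}

#' Nucleosome occupancy at elements vs a shuffled null
#'
#' Observed per-element mean MNase signal; a null distribution of mean
#' signals over `n_null` random re-placements of the element coordinates
#' (excluding problematic regions); and the correlation (Pearson and
#' Spearman) between per-element mean MNase signal and mean enrichment, to
#' check whether derived enrichment merely reflects nucleosome occupancy.
#'
#' @param elements `GRanges`.
#' @param mnase_track `SignalTrack`.
#' @param chrom_sizes named chromosome lengths for shuffling.
#' @param exclude `GRanges` excluded from placement (e.g. blocklist).
#' @param fc per-element mean clamped log2 FC (same order as `elements`).
#' @param n_null number of shuffled replicates (default 1).
#' @param seed RNG seed.
#' @return list: `observed` (per-element means), `null` (vector over all
#'   placements), `pearson`, `spearman`.
#' @export
mnase_occupancy <- function(elements, mnase_track, chrom_sizes,
                            exclude = NULL, fc = NULL, n_null = 1,
                            seed = NULL) {
  obs <- mean_signal(mnase_track, elements)
  null <- with_seed(seed, {
    unlist(lapply(seq_len(n_null), function(k) {
      sh <- shuffle_intervals(elements, chrom_sizes, exclude, seed = NULL)
      mean_signal(mnase_track, sh)
    }))
  })
  pe <- sp <- NA_real_
  if (!is.null(fc)) {
    pe <- suppressWarnings(stats::cor(obs, fc, method = "pearson"))
    sp <- suppressWarnings(stats::cor(obs, fc, method = "spearman"))
  }
  list(observed = obs, null = null, pearson = pe, spearman = sp)
}

#' Gene overlap of elements
#'
#' @param elements `GRanges`.
#' @param genes `GRanges`.
#' @return list: `overlapping` (logical per element), `n_overlapping`,
#'   `proportion` (exact fraction).
#' @export
gene_overlap <- function(elements, genes) {
  ov <- overlapsAny(elements, genes, ignore.strand = TRUE)
  list(overlapping = ov, n_overlapping = sum(ov),
       proportion = if (length(elements)) sum(ov) / length(elements) else 0)
}

#' Empirical cumulative distribution table
#'
#' Long-format ECDF of expression levels (or any values) for plotting
#' cumulative-distribution comparisons between groups.
#'
#' @param values numeric vector (NAs dropped).
#' @param group single label attached to the rows.
#' @return data.frame: `group`, `value`, `ecdf`.
#' @export
ecdf_table <- function(values, group = "all") {
  v <- sort(values[!is.na(values)])
  if (!length(v))
    return(data.frame(group = character(0), value = numeric(0),
                      ecdf = numeric(0)))
  data.frame(group = group, value = v, ecdf = seq_along(v) / length(v),
             stringsAsFactors = FALSE)
}
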