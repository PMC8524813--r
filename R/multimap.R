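## Ambiguously mapped reads and the consensus-dimer re-mapping pipeline.
##
## Reads with MAPQ = 0 can be aligned to multiple genomic positions and are
## characteristic of highly repetitive satellite arrays. Their per-element
## fraction diagnoses how much an element's signal rests on ambiguous
## alignments. For satellites too repetitive to analyze positionally, MAPQ-0
## reads are re-mapped end-to-end onto consensus-dimer references (a monomer
## concatenated to itself, so reads spanning the monomer junction can align)
## and enrichment is the ratio of aligned read counts between ChIP and input
## after downsampling both to the same total.

#' Read a SAM alignment file
#'
#' Parses a SAM text file (header + 11 mandatory fields) through
#' `Rsamtools` and returns a `ReadSet`: a data-frame-backed record of read
#' id, position (0-based), MAPQ, FLAG-derived unmapped/duplicate/strand
#' flags and the read sequence.
#'
#' @param path SAM file path.
#' @return object of class `ReadSet`.
#' @export
read_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  read_set(
    read_id = x$qname,
    chrom = as.character(x$rname),
    pos = x$pos - 1L,
    mapq = x$mapq,
    seq = as.character(x$seq),
    unmapped = bitwAnd(x$flag, 4L) > 0L,
    duplicate = bitwAnd(x$flag, 1024L) > 0L,
    reverse = bitwAnd(x$flag, 16L) > 0L
  )
}

#' Construct a ReadSet
#'
#' @param read_id,chrom,pos,mapq,seq,unmapped,duplicate,reverse parallel
#'   vectors describing the reads; `pos` is 0-based.
#' @return `ReadSet` (a classed data.frame).
#' @export
read_set <- function(read_id, chrom, pos, mapq, seq,
                     unmapped = FALSE, duplicate = FALSE, reverse = FALSE) {
  df <- data.frame(read_id = read_id, chrom = chrom, pos = as.integer(pos),
                   mapq = as.integer(mapq), seq = seq,
                   unmapped = unmapped, duplicate = duplicate,
                   reverse = reverse, stringsAsFactors = FALSE)
  class(df) <- c("ReadSet", "data.frame")
  df
}

#' Fraction of zero-mapping-quality reads per element
#'
#' For each element, among reads overlapping it by at least one base:
#' the fraction with MAPQ = 0 and the supporting read count (so that
#' low-support elements can be flagged downstream).
#'
#' @param reads `ReadSet` (mapped reads are used).
#' @param elements `GRanges`.
#' @return data.frame: `element_id`, `n_reads`, `n_mapq0`, `fraction`
#'   (`NA` when no read overlaps).
#' @export
mapq0_fraction <- function(reads, elements) {
  mapped <- reads[!reads$unmapped, , drop = FALSE]
  rgr <- as_granges0(mapped$chrom, mapped$pos,
                     mapped$pos + nchar(mapped$seq))
  hits <- findOverlaps(elements, rgr, ignore.strand = TRUE)
  n <- countOverlaps(elements, rgr, ignore.strand = TRUE)
  n0 <- integer(length(elements))
  if (length(hits)) {
    is0 <- mapped$mapq[subjectHits(hits)] == 0
    t0 <- tapply(is0, queryHits(hits), sum)
    n0[as.integer(names(t0))] <- as.integer(t0)
  }
  data.frame(element_id = if (!is.null(elements$id)) elements$id
                          else as.character(seq_along(elements)),
             n_reads = n, n_mapq0 = n0,
             fraction = ifelse(n > 0, n0 / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Merge replicates, dropping duplicates and unmapped reads
#'
#' @param replicates list of `ReadSet`s.
#' @return single `ReadSet` with duplicate and unmapped reads removed.
#' @export
preprocess_alignments <- function(replicates) {
  if (is(replicates, "ReadSet")) replicates <- list(replicates)
  merged <- do.call(rbind, lapply(replicates, function(r) {
    r[!r$duplicate & !r$unmapped, , drop = FALSE]
  }))
  if (!nrow(merged))
    stop("preprocess_alignments: no reads left after filtering")
  class(merged) <- c("ReadSet", "data.frame")
  merged
}

#' Downsample a read set to an exact count
#'
#' Uniform sampling without replacement; deterministic under `seed`. Used to
#' equalise sequencing depth between samples before counting.
#'
#' @param reads `ReadSet`.
#' @param n target read count (`n <= nrow(reads)`).
#' @param seed RNG seed.
#' @return `ReadSet` of exactly `n` reads (original order preserved).
#' @export
downsample_reads <- function(reads, n, seed = NULL) {
  if (n > nrow(reads))
    stop("downsample_reads: requested ", n, " reads but only ", nrow(reads),
         " available in the limiting sample")
  keep <- with_seed(seed, sort(sample.int(nrow(reads), n)))
  out <- reads[keep, , drop = FALSE]
  class(out) <- c("ReadSet", "data.frame")
  out
}

#' Read satellite consensus monomers and build dimer references
#'
#' @param path FASTA of consensus monomer sequences (one per family).
#' @return list: `monomers`, `dimers` (`DNAStringSet`s named by family).
#' @export
read_consensus_fasta <- function(path) {
  mono <- Biostrings::readDNAStringSet(path)
  dimers <- Biostrings::xscat(mono, mono)
  names(dimers) <- names(mono)
  list(monomers = mono, dimers = dimers)
}

#' Align reads end-to-end onto consensus dimers
#'
#' A built-in ungapped matcher: a read aligns to a family if some end-to-end
#' placement of the full read on the family's dimer (either strand) has a
#' mismatch rate `<= max_mismatch_rate`; `N` bases count as mismatches. Each
#' read is assigned to the family with the fewest mismatches; ties between
#' families leave the read unassigned (counted separately). Per-family
#' per-position coverage along the dimer is accumulated and a uniformity
#' statistic (max/mean positional coverage) flags families whose alignments
#' pile onto a short segment (e.g. low-complexity insertions) rather than
#' covering the repeat.
#'
#' Users running a true external aligner can skip this matcher and feed the
#' resulting SAM through [read_alignments()] + [count_sam_by_reference()].
#'
#' @param seqs character vector or `DNAStringSet` of read sequences (each
#'   shorter than the dimer).
#' @param refs consensus references from [read_consensus_fasta()].
#' @param max_mismatch_rate maximum per-base mismatch rate (default 0.1).
#' @param uniformity_flag_at flag families with max/mean coverage above this
#'   (default 10).
#' @return list: `assignment` (per read: family or `NA`, mismatches),
#'   `counts` (per family: aligned count, uniformity, flag), `n_tied`,
#'   `alignment_rate`.
#' @export
align_to_consensus <- function(seqs, refs, max_mismatch_rate = 0.1,
                               uniformity_flag_at = 10) {
  if (!length(refs$dimers)) stop("align_to_consensus: empty reference set")
  reads <- Biostrings::DNAStringSet(seqs)
  fams <- names(refs$dimers)
  dlen <- Biostrings::width(refs$dimers)
  if (any(Biostrings::width(reads) >= min(dlen)))
    stop("align_to_consensus: reads must be shorter than the dimers")
  nr <- length(reads)
  best_fam <- rep(NA_character_, nr)
  best_mm <- rep(NA_integer_, nr)
  best_pos <- rep(NA_integer_, nr)
  cover <- lapply(fams, function(f) integer(dlen[match(f, fams)]))
  names(cover) <- fams
  rc <- Biostrings::reverseComplement(reads)
  ## Mismatch counts for all end-to-end placements are computed for all
  ## reads of one length at once: with one-hot base encodings R (reads x L)
  ## and W (windows x L), the match-count matrix is sum_b R_b W_b^T, one
  ## matrix product per base (BLAS); N bases encode to all-zero and hence
  ## mismatch everywhere.
  onehot <- function(chars) {
    lapply(c("A", "C", "G", "T"), function(b) (chars == b) * 1)
  }
  for (L in unique(Biostrings::width(reads))) {
    idx <- which(Biostrings::width(reads) == L)
    Rf <- onehot(as.matrix(reads[idx]))
    Rr <- onehot(as.matrix(rc[idx]))
    fam_mm <- matrix(NA_integer_, length(idx), length(fams))
    fam_pos <- matrix(NA_integer_, length(idx), length(fams))
    for (k in seq_along(fams)) {
      d <- strsplit(as.character(refs$dimers[[k]]), "")[[1]]
      m <- dlen[k] - L + 1
      Wc <- matrix(d[outer(0:(m - 1), 1:L, "+")], nrow = m)
      Wb <- onehot(Wc)
      match_f <- Rf[[1]] %*% t(Wb[[1]]) + Rf[[2]] %*% t(Wb[[2]]) +
        Rf[[3]] %*% t(Wb[[3]]) + Rf[[4]] %*% t(Wb[[4]])
      match_r <- Rr[[1]] %*% t(Wb[[1]]) + Rr[[2]] %*% t(Wb[[2]]) +
        Rr[[3]] %*% t(Wb[[3]]) + Rr[[4]] %*% t(Wb[[4]])
      best <- pmax(match_f, match_r)
      pos <- max.col(best, ties.method = "first")
      fam_pos[, k] <- pos
      fam_mm[, k] <- L - as.integer(round(best[cbind(seq_along(idx), pos)]))
    }
    kmax <- floor(max_mismatch_rate * L)
    row_min <- do.call(pmin, as.data.frame(fam_mm))
    for (ii in seq_along(idx)) {
      if (row_min[ii] > kmax) next
      winners <- which(fam_mm[ii, ] == row_min[ii])
      i <- idx[ii]
      if (length(winners) > 1) {
        best_fam[i] <- "TIE"
        next
      }
      k <- winners
      best_fam[i] <- fams[k]
      best_mm[i] <- row_min[ii]
      best_pos[i] <- fam_pos[ii, k]
      span <- fam_pos[ii, k]:(fam_pos[ii, k] + L - 1)
      cover[[fams[k]]][span] <- cover[[fams[k]]][span] + 1L
    }
  }
  n_tied <- sum(best_fam == "TIE", na.rm = TRUE)
  assigned <- !is.na(best_fam) & best_fam != "TIE"
  counts <- do.call(rbind, lapply(fams, function(f) {
    cv <- cover[[f]]
    unif <- if (sum(cv) > 0) max(cv) / mean(cv) else NA_real_
    data.frame(family = f, aligned = sum(best_fam == f, na.rm = TRUE),
               uniformity = unif,
               uniformity_flag = !is.na(unif) && unif > uniformity_flag_at,
               stringsAsFactors = FALSE)
  }))
  list(
    assignment = data.frame(
      family = ifelse(best_fam == "TIE", NA_character_, best_fam),
      mismatches = best_mm, dimer_pos = best_pos,
      tied = !is.na(best_fam) & best_fam == "TIE",
      stringsAsFactors = FALSE),
    counts = counts,
    n_tied = n_tied,
    alignment_rate = sum(assigned) / nr,
    coverage = cover
  )
}

#' Count SAM alignments per reference (external-aligner path)
#'
#' @param reads `ReadSet` from a SAM produced by an external aligner against
#'   the consensus dimers.
#' @return data.frame: `family`, `aligned`.
#' @export
count_sam_by_reference <- function(reads) {
  mapped <- reads[!reads$unmapped, , drop = FALSE]
  tab <- table(mapped$chrom)
  data.frame(family = names(tab), aligned = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Consensus-mapping enrichment per family
#'
#' Fold change of consensus-aligned read counts between a ChIP sample and its
#' input, both downsampled to identical totals beforehand (unequal totals are
#' an error because they defeat the depth normalization). Families with input
#' count 0 but ChIP reads get `fc = NA` with a flag; families with no reads
#' in either sample are reported with status `"no_reads"`.
#'
#' @param chip_counts,input_counts data.frames `family`, `aligned` (as from
#'   [align_to_consensus()]`$counts` or [count_sam_by_reference()]).
#' @param chip_total,input_total total read counts after downsampling.
#' @return data.frame: `family`, `chip_aligned`, `input_aligned`, `fc`,
#'   `status` (`ok`, `no_input`, `no_reads`).
#' @export
consensus_enrichment <- function(chip_counts, input_counts,
                                 chip_total, input_total) {
  if (chip_total != input_total)
    stop("consensus_enrichment: unequal totals (", chip_total, " vs ",
         input_total, "); downsample both samples to the same depth first")
  fams <- union(chip_counts$family, input_counts$family)
  ca <- setNames(rep(0L, length(fams)), fams)
  ia <- ca
  ca[chip_counts$family] <- chip_counts$aligned
  ia[input_counts$family] <- input_counts$aligned
  fc <- ifelse(ia > 0, ca / ia, NA_real_)
  status <- ifelse(ca == 0 & ia == 0, "no_reads",
                   ifelse(ia == 0, "no_input", "ok"))
  data.frame(family = fams, chip_aligned = as.integer(ca),
             input_aligned = as.integer(ia), fc = fc, status = status,
             stringsAsFactors = FALSE)
}
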