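## Repeat annotation parsing, blocklist / chromosome filtering and the
## interval algebra used by every downstream stage. All coordinates are
## 0-based half-open (BED convention); UCSC rmsk genoStart/genoEnd are already
## in that convention and are consumed as-is. Intervals touching end-to-start
## do NOT overlap.

## Column names of the UCSC rmsk table (with leading bin column; 17 columns).
RMSK_COLS <- c("bin", "swScore", "milliDiv", "milliDel", "milliIns",
               "genoName", "genoStart", "genoEnd", "genoLeft", "strand",
               "repName", "repClass", "repFamily", "repStart", "repEnd",
               "repLeft", "id")

#' Parse a UCSC rmsk repeat-annotation table
#'
#' Reads a tab-separated RepeatMasker table as distributed by the UCSC table
#' browser and returns the instances of the requested repeat class as a
#' `GRanges` with metadata columns `name` (repeat name, e.g. `GSATII`),
#' `family_class` (repClass), `id` and `blocklisted` (initialised `FALSE`).
#' The leading `bin` column is auto-detected from the column count (17 with,
#' 16 without). Instances are sorted by (chromosome, start) and each receives
#' a deterministic id `chrom:start-end:name`; rows that would collide get a
#' numeric suffix.
#'
#' @param path path to the rmsk table (plain text, tab separated, no header).
#' @param class_filter repeat class to keep (default `"Satellite"`); `NULL`
#'   keeps all classes.
#' @param on_malformed `"skip"` (report line numbers, drop the rows) or
#'   `"error"`.
#' @return `GRanges` of repeat instances.
#' @export
read_rmsk <- function(path, class_filter = "Satellite",
                      on_malformed = c("skip", "error")) {
  on_malformed <- match.arg(on_malformed)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("read_rmsk: empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  n_expect <- ncols[1]
  if (!n_expect %in% c(16L, 17L))
    stop("read_rmsk: unknown rmsk column count (", n_expect,
         "); expected 16 (no bin) or 17 (with bin)")
  bad <- which(ncols != n_expect)
  if (length(bad)) {
    msg <- paste0("read_rmsk: malformed rows at lines ",
                  paste(head(bad, 10), collapse = ", "))
    if (on_malformed == "error") stop(msg)
    warning(msg, "; skipped")
    fields <- fields[-bad]
  }
  cols <- if (n_expect == 17L) RMSK_COLS else RMSK_COLS[-1]
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  start <- suppressWarnings(as.integer(m[, "genoStart"]))
  end <- suppressWarnings(as.integer(m[, "genoEnd"]))
  bad2 <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad2)) {
    msg <- paste0("read_rmsk: non-numeric or inverted coordinates at rows ",
                  paste(head(bad2, 10), collapse = ", "))
    if (on_malformed == "error") stop(msg)
    warning(msg, "; skipped")
    m <- m[-bad2, , drop = FALSE]
    start <- start[-bad2]
    end <- end[-bad2]
  }
  keep <- if (is.null(class_filter)) rep(TRUE, nrow(m))
          else m[, "repClass"] %in% class_filter
  m <- m[keep, , drop = FALSE]
  start <- start[keep]
  end <- end[keep]
  gr <- as_granges0(m[, "genoName"], start, end, m[, "strand"])
  gr$name <- m[, "repName"]
  gr$family_class <- m[, "repClass"]
  o <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  gr$id <- make_instance_ids(gr)
  gr$blocklisted <- FALSE
  gr
}

## Deterministic instance ids chrom:start-end:name, numeric suffix on collision.
make_instance_ids <- function(gr) {
  ids <- paste0(as.character(seqnames(gr)), ":", start0(gr), "-", end0(gr),
                ":", gr$name)
  dup <- ids %in% ids[duplicated(ids)]
  if (any(dup)) {
    ids[dup] <- paste0(ids[dup], "_", stats::ave(seq_len(sum(dup)),
                                                 ids[dup], FUN = seq_along))
  }
  ids
}

#' Read a BED interval file
#'
#' BED3/BED4/BED6 (and BED with a numeric score column) via `rtracklayer`.
#' The name column, when present, is kept (used as state label for genome
#' segmentations); the score column is kept as `score`.
#'
#' @param path BED file path.
#' @param label free-text label attached as `metadata(gr)$label`.
#' @return `GRanges`.
#' @export
read_bed <- function(path, label = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Remove instances overlapping a blocklist
#'
#' Splits repeat instances into those with zero overlapping bases with any
#' blocklist interval (`kept`) and those with at least one shared base
#' (`removed`, flagged `blocklisted = TRUE`). Touching intervals under the
#' half-open convention share no base and are kept. Chromosomes present in
#' the instances but absent from the blocklist are treated as unblocked.
#'
#' @param instances `GRanges` of repeat instances.
#' @param blocklist `GRanges` of problematic regions.
#' @return list with `kept` and `removed` `GRanges`.
#' @export
filter_blocklist <- function(instances, blocklist) {
  hit <- overlapsAny(instances, blocklist, ignore.strand = TRUE)
  kept <- instances[!hit]
  removed <- instances[hit]
  if (length(removed)) removed$blocklisted <- TRUE
  list(kept = kept, removed = removed)
}

#' Filter instances by chromosome
#'
#' @param instances `GRanges`.
#' @param mode `"assembled_only"` drops chrUn/random/alt scaffolds;
#'   `"autosomes_only"` additionally drops chrX, chrY and chrM;
#'   `"custom"` keeps only chromosomes listed in `keep`.
#' @param keep character vector of chromosomes for `mode = "custom"`.
#' @return filtered `GRanges`, input order preserved.
#' @export
filter_chromosomes <- function(instances,
                               mode = c("autosomes_only", "assembled_only",
                                        "custom"),
                               keep = NULL) {
  mode <- match.arg(mode)
  chr <- as.character(seqnames(instances))
  sel <- switch(mode,
    assembled_only = !grepl("_|chrUn|random|alt", chr),
    autosomes_only = !grepl("_|chrUn|random|alt", chr) &
      !chr %in% c("chrX", "chrY", "chrM", "X", "Y", "MT"),
    custom = {
      if (is.null(keep)) stop("filter_chromosomes: keep required for custom")
      chr %in% keep
    })
  out <- instances[sel]
  if (!length(out)) warning("filter_chromosomes: no instances left")
  out
}

#' Reciprocal overlap between two intervals
#'
#' `TRUE` iff the two intervals share at least `frac` of the length of *each*.
#' Vectorised over pairs; intervals on different chromosomes never overlap.
#'
#' @param a,b `GRanges` of equal length (compared pairwise).
#' @param frac required fraction in (0, 1].
#' @return logical vector.
#' @export
reciprocal_overlap <- function(a, b, frac = 0.5) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("reciprocal_overlap: frac must be in (0, 1]")
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  ov <- pmax(ov, 0L)
  same & ov >= frac * width(a) & ov >= frac * width(b)
}

#' Match elements against an interval set by reciprocal overlap
#'
#' For each element, `TRUE` iff any interval in `set` reciprocally overlaps it
#' at fraction `frac`.
#'
#' @param elements,set `GRanges`.
#' @param frac required fraction in (0, 1].
#' @return logical vector along `elements`.
#' @export
reciprocal_overlap_any <- function(elements, set, frac = 0.5) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("reciprocal_overlap_any: frac must be in (0, 1]")
  hits <- findOverlaps(elements, set, ignore.strand = TRUE)
  if (!length(hits)) return(logical(length(elements)))
  qa <- elements[queryHits(hits)]
  sb <- set[subjectHits(hits)]
  ok <- reciprocal_overlap(qa, sb, frac)
  out <- logical(length(elements))
  out[unique(queryHits(hits)[ok])] <- TRUE
  out
}

#' Randomly re-place intervals over a genome
#'
#' Permutes interval coordinates uniformly over all allowed positions of the
#' genome, preserving each interval's length and avoiding the `exclude`
#' regions, as done for permutation nulls of per-element signal summaries.
#' Placement is by rejection sampling: a chromosome is drawn with probability
#' proportional to its number of valid start positions for the interval
#' length, a start is drawn uniformly, and the placement is rejected if it
#' overlaps `exclude`.
#'
#' @param instances `GRanges` to re-place.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param exclude `GRanges` of forbidden regions (may be empty/`NULL`).
#' @param seed integer seed for determinism (`NULL` = use current RNG state).
#' @param max_attempts attempts per interval before failing.
#' @return `GRanges` of placements (lengths preserved, metadata dropped).
#' @export
shuffle_intervals <- function(instances, chrom_sizes, exclude = NULL,
                              seed = NULL, max_attempts = 1000) {
  ## excluded regions as per-chromosome coordinate vectors (fast rejection)
  ex_s <- ex_e <- list()
  if (!is.null(exclude) && length(exclude)) {
    ex_chr <- as.character(seqnames(exclude))
    for (cs in unique(ex_chr)) {
      ex_s[[cs]] <- start0(exclude)[ex_chr == cs]
      ex_e[[cs]] <- end0(exclude)[ex_chr == cs]
    }
  }
  with_seed(seed, {
    lens <- width(instances)
    chrom <- character(length(instances))
    starts <- integer(length(instances))
    for (i in seq_along(instances)) {
      L <- lens[i]
      avail <- pmax(chrom_sizes - L + 1, 0)
      if (sum(avail) == 0)
        stop("shuffle_intervals: no chromosome can hold an interval of ", L,
             " bp")
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        cs <- sample(names(chrom_sizes), 1, prob = avail)
        s0 <- sample.int(avail[[cs]], 1) - 1L   # 0-based start
        hit <- !is.null(ex_s[[cs]]) &&
          any(ex_s[[cs]] < s0 + L & ex_e[[cs]] > s0)
        if (!hit) {
          chrom[i] <- cs
          starts[i] <- s0
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("shuffle_intervals: interval ", i, " (", L, " bp) could not be ",
             "placed outside the excluded regions after ", max_attempts,
             " attempts")
    }
    as_granges0(chrom, starts, starts + lens)
  })
}

#' Write repeat instances as a TSV table
#'
#' Columns: id, chrom, start, end (0-based half-open), name, blocklisted.
#'
#' @param instances `GRanges` with `id`, `name`, `blocklisted` columns.
#' @param path output path.
#' @export
write_instances <- function(instances, path) {
  df <- data.frame(
    id = instances$id,
    chrom = as.character(seqnames(instances)),
    start = start0(instances),
    end = end0(instances),
    name = instances$name,
    blocklisted = instances$blocklisted,
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
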