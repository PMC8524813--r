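## Internal helpers shared across modules.

#' Write a data frame as a deterministic TSV
#'
#' Numeric columns are printed with 6 significant digits and missing values as
#' "NA", so that re-running a stage with the same inputs yields byte-identical
#' output files.
#'
#' @param df data.frame.
#' @param path output file path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- out[[j]]
      s <- vapply(v, function(x) {
        if (is.na(x)) "NA" else trimws(formatC(x, digits = 6, format = "g"))
      }, character(1))
      out[[j]] <- s
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

## Weighted median of values with positive integer weights, using the
## even-count convention (mean of the two central order statistics).
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  if (!length(values)) stop("weighted_median: no mass")
  o <- order(values)
  v <- values[o]
  w <- weights[o]
  n <- sum(w)
  cw <- cumsum(w)
  lo <- floor((n + 1) / 2)
  hi <- ceiling((n + 1) / 2)
  i1 <- which(cw >= lo)[1]
  i2 <- which(cw >= hi)[1]
  (v[i1] + v[i2]) / 2
}

## Run `expr` under a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_state) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## 0-based half-open (chrom, start, end) -> GRanges (1-based closed internally).
## All user-facing coordinates in satrep are BED-convention 0-based half-open.
as_granges0 <- function(chrom, start, end, strand = "*", seqlengths = NULL) {
  stopifnot(all(end > start), all(start >= 0))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = ifelse(strand %in% c("+", "-"), strand, "*")
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

## GRanges -> 0-based starts / half-open ends
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

message_if <- function(verbose, ...) if (isTRUE(verbose)) message(...)
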