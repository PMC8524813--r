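## Independent brute-force oracles and small fixture builders used across the
## suite. Oracles deliberately use different computation paths from the
## implementation (per-base expansion, textbook formulas, exhaustive
## enumeration).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## GRanges from 0-based half-open coordinates (mirror of the package helper,
## re-stated so fixture construction does not depend on package internals).
gr0 <- function(chrom, start, end, ...) {
  g <- GRanges(chrom, IRanges(start + 1, end))
  dots <- list(...)
  if (length(dots)) mcols(g) <- DataFrame(dots)
  g
}

## Build a SignalTrack from a data.frame of 0-based half-open runs.
toy_track <- function(runs, seqlengths) {
  gr <- GRanges(runs$chrom, IRanges(runs$start + 1, runs$end))
  gr$score <- runs$value
  signal_track(gr, seqlengths)
}

## Random run-length track on 1-2 small chromosomes.
random_track <- function(max_len = 200) {
  nchrom <- sample(1:2, 1)
  sl <- setNames(sample(50:max_len, nchrom, replace = TRUE),
                 paste0("c", seq_len(nchrom)))
  runs <- do.call(rbind, lapply(names(sl), function(cs) {
    bounds <- sort(unique(c(0, sample(0:sl[[cs]], sample(2:8, 1),
                                      replace = TRUE), sl[[cs]])))
    n <- length(bounds) - 1
    keep <- runif(n) < 0.7      # leave gaps (implicit zeros)
    keep[1] <- TRUE             # at least one run per chromosome
    data.frame(chrom = rep(cs, sum(keep)),
               start = bounds[-length(bounds)][keep],
               end = bounds[-1][keep],
               value = round(runif(sum(keep), 0, 10), 3))
  }))
  runs <- runs[runs$end > runs$start, ]
  list(track = toy_track(runs, sl), runs = runs, seqlengths = sl)
}

## Per-base expansion of a SignalTrack chromosome.
expand_track <- function(track, chrom) as.numeric(track$cov[[chrom]])

## Per-base oracle for mean signal over a 0-based half-open interval.
brute_mean <- function(track, chrom, start0, end0) {
  v <- expand_track(track, chrom)
  mean(v[(start0 + 1):end0])
}

## Per-base oracle for the genome median.
brute_median <- function(track, chroms = names(track$cov)) {
  stats::median(unlist(lapply(chroms, function(cs) expand_track(track, cs))))
}

## Base-by-base reciprocal overlap oracle (0-based half-open inputs).
brute_reciprocal <- function(c1, s1, e1, c2, s2, e2, frac) {
  if (c1 != c2) return(FALSE)
  ov <- length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1)))
  ov >= frac * (e1 - s1) && ov >= frac * (e2 - s2)
}

## Tukey-Kramer pairwise p-values from the studentized range distribution.
brute_tukey <- function(values, labels) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  n <- length(values)
  ms <- tapply(values, labels, mean)
  ns <- tapply(values, labels, length)
  mse <- sum(unlist(lapply(levels(labels), function(g) {
    v <- values[labels == g]
    sum((v - mean(v))^2)
  }))) / (n - k)
  cmb <- utils::combn(k, 2)
  data.frame(
    group_a = levels(labels)[cmb[2, ]],
    group_b = levels(labels)[cmb[1, ]],
    p = vapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      se <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
      q <- abs(ms[i2] - ms[i1]) / se
      stats::ptukey(q, k, n - k, lower.tail = FALSE)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

## All permutations of 1..n (n small).
permn <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permn(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

## Exhaustive PERMANOVA oracle: recompute SS partition from scratch for
## every ordering and report the exceedance fraction.
brute_permanova_p <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  sst <- sum(d^2) / (2 * n)
  fstat <- function(g) {
    ssw <- 0
    for (lv in levels(groups)) {
      idx <- which(g == lv)
      if (length(idx) > 1)
        ssw <- ssw + sum(d[idx, idx]^2) / (2 * length(idx))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(groups)
  all_p <- permn(n)
  fs <- apply(all_p, 1, function(o) fstat(groups[o]))
  mean(fs >= f_obs)
}

## Reference line-by-line rmsk parser (independent of read_rmsk).
reference_rmsk_parse <- function(path, class = "Satellite") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) %in% c(16, 17))
  off <- ncol(df) - 16   # 1 when the bin column is present
  out <- data.frame(chrom = df[[5 + off]], start = df[[6 + off]],
                    end = df[[7 + off]], name = df[[10 + off]],
                    class = df[[11 + off]], stringsAsFactors = FALSE)
  out[out$class %in% class, ]
}

## Ungapped all-placements matcher oracle for one read vs a set of dimers.
brute_best_family <- function(read, dimers, max_rate) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(read, "")[[1]]),
                                     collapse = ""))
  L <- nchar(read)
  best <- lapply(names(dimers), function(f) {
    d <- as.character(dimers[[f]])
    mm <- sapply(1:(nchar(d) - L + 1), function(s) {
      w <- substr(d, s, s + L - 1)
      min(sum(strsplit(w, "")[[1]] != strsplit(read, "")[[1]]),
          sum(strsplit(w, "")[[1]] != strsplit(rc, "")[[1]]))
    })
    min(mm)
  })
  names(best) <- names(dimers)
  best <- unlist(best)
  ok <- best <= max_rate * L
  if (!any(ok)) return(NA_character_)
  m <- min(best[ok])
  w <- names(best)[best == m & ok]
  if (length(w) > 1) NA_character_ else w
}

## Small shared dataset bundles (built once per test run).
small_cancer_config <- function(seed = 11) {
  synthetic_config(
    "cancer_hypomethylation", seed = seed,
    chrom_sizes = c(chr1 = 400000L, chr2 = 300000L, chrX = 120000L,
                    chrY = 80000L),
    n_dispersed = 40, n_cluster = 10, n_cluster_blocked = 5,
    n_dispersed_blocked = 5, n_sex = 5, n_other_class = 3,
    n_true_pos = 6, n_cluster_tp = 3,
    cluster_pos = 200000L, peak_n = 12, background_reads = 200,
    reads_per_element = 8
  )
}

cached_small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_satellite_dataset(
      small_cancer_config())
    cache
  }
})
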