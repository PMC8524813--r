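## Sample-level multivariate structure: row scaling, PCA of samples,
## binomial dissimilarity between samples and a permutation PERMANOVA.

#' Center and scale matrix rows
#'
#' Each row (element) is centered to mean 0 and scaled to unit variance.
#' Zero-variance rows are set to all-zero and flagged in the
#' `"zero_variance"` attribute.
#'
#' @param m numeric matrix (elements x samples).
#' @return scaled matrix with attribute `zero_variance` (logical per row).
#' @export
scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  zv <- s == 0
  s[zv] <- 1
  out <- (m - mu) / s
  out[zv, ] <- 0
  attr(out, "zero_variance") <- zv
  out
}

#' PCA of samples on an element matrix
#'
#' Samples are the observations (columns of `m` become rows of the PCA
#' input). SVD-based via [stats::prcomp()], without further scaling (pass the
#' output of [scale_rows()] for scaled input). For determinism the sign of
#' each component is fixed so that its largest-magnitude loading is positive.
#'
#' @param m numeric matrix (elements x samples), e.g. `em$values` after any
#'   autosome-only row filtering.
#' @return list: `scores` (samples x PCs), `loadings` (elements x PCs),
#'   `variance_explained` (sums to 1 over the full rank).
#' @export
pca_samples <- function(m) {
  x <- t(m)
  if (nrow(x) < 2) stop("pca_samples: >= 2 samples required")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, variance_explained = ve)
}

#' Binomial dissimilarity between samples
#'
#' For samples x and y over elements i, with `n_i = x_i + y_i`:
#' `d(x, y) = sum_i [ x_i log(x_i / n_i) + y_i log(y_i / n_i) + n_i log 2 ]`,
#' with `0 log 0 := 0` and elements where both values are 0 contributing
#' nothing. Requires non-negative input (the clamped log2 FC matrix
#' satisfies this).
#'
#' @param m numeric matrix (elements x samples), non-negative.
#' @return `dist`-like symmetric matrix with zero diagonal and sample labels.
#' @export
binomial_distance <- function(m) {
  if (any(m < 0)) stop("binomial_distance: negative values not allowed")
  ns <- ncol(m)
  d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  xlogx <- function(x, n) ifelse(x > 0, x * log(x / n), 0)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      x <- m[, i]; y <- m[, j]
      n <- x + y
      keep <- n > 0
      dij <- sum(xlogx(x[keep], n[keep]) + xlogx(y[keep], n[keep]) +
                 n[keep] * log(2))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared-dissimilarity variation among and within groups
#' (Gower-centered partition) and computes the pseudo-F statistic
#' `F = (SS_A / (a - 1)) / (SS_W / (n - a))`. Significance is assessed by
#' permuting sample labels: `p = (1 + #permutations with F >= F_obs) /
#' (1 + n_perm)`. Supplying an explicit `permutations` matrix (rows =
#' permuted orderings, e.g. the full enumeration for small n) switches to
#' `p = mean(F_perm >= F_obs)` over the supplied set.
#'
#' @param d symmetric dissimilarity matrix (as from [binomial_distance()]).
#' @param groups group label per sample (>= 2 groups).
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param permutations optional integer matrix of orderings overriding random
#'   permutation.
#' @return list: `F`, `R2`, `p`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("permanova: >= 2 groups required")
  a <- nlevels(groups)
  sst <- sum(d^2) / (2 * n)        # sum over i<j of d^2 / n
  ssw_of <- function(g) {
    s <- 0
    for (lv in levels(groups)) {
      idx <- which(g == lv)
      ng <- length(idx)
      if (ng > 1) s <- s + sum(d[idx, idx]^2) / (2 * ng)
    }
    s
  }
  f_of <- function(g) {
    ssw <- ssw_of(g)
    ssa <- sst - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  ssw_obs <- ssw_of(groups)
  r2 <- (sst - ssw_obs) / sst
  if (!is.null(permutations)) {
    fp <- apply(permutations, 1, function(o) f_of(groups[o]))
    p <- mean(fp >= f_obs)
    np <- nrow(permutations)
  } else {
    fp <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) f_of(sample(groups)), numeric(1))
    })
    p <- (1 + sum(fp >= f_obs)) / (1 + n_perm)
    np <- n_perm
  }
  list(F = f_obs, R2 = r2, p = p, n_perm = np)
}

#' Per-group summary for confidence ellipses
#'
#' Mean and covariance of the first two PCA score dimensions per group; a
#' plotting-agnostic table from which 95% ellipses can be drawn.
#'
#' @param scores samples x PCs score matrix.
#' @param groups group labels along samples.
#' @return data.frame: group, n, mean1, mean2, var1, var2, cov12.
#' @export
group_ellipse_stats <- function(scores, groups) {
  groups <- as.factor(groups)
  do.call(rbind, lapply(levels(groups), function(lv) {
    s <- scores[groups == lv, 1:2, drop = FALSE]
    cv <- if (nrow(s) > 1) stats::cov(s) else matrix(NA_real_, 2, 2)
    data.frame(group = lv, n = nrow(s),
               mean1 = mean(s[, 1]), mean2 = mean(s[, 2]),
               var1 = cv[1, 1], var2 = cv[2, 2], cov12 = cv[1, 2],
               stringsAsFactors = FALSE)
  }))
}
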