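## Differential enrichment testing. Two-group mode uses a Welch unequal-
## variance t-test per element; stage mode uses one-way ANOVA per element with
## Bonferroni correction across elements, Tukey HSD post hoc on elements with
## adjusted p < 0.01, and a fold-change relevance filter on (mean + 1) ratios
## between stages (cutoff 1.5, inclusive). The tests run on the clamped log2
## FC values of the enrichment matrix.
##
## The row-wise Welch and ANOVA statistics are computed from the closed-form
## sums-of-squares formulas (vectorised over thousands of elements); the
## generic stats::t.test / stats::aov routes serve as independent oracles in
## the test suite.

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate conventions: if both groups are constant and equal,
#' `t = 0, p = 1`; if both constant but different, `p = 0` with
#' `degenerate = TRUE` (the test statistic diverges).
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list: `t`, `df`, `p`, `degenerate`.
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  r <- row_welch(matrix(a, nrow = 1), matrix(b, nrow = 1))
  list(t = r$t[1], df = r$df[1], p = r$p[1], degenerate = r$degenerate[1])
}

## Vectorised Welch over rows of two group matrices.
row_welch <- function(ma, mb) {
  na <- ncol(ma); nb <- ncol(mb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  va <- rowSums((ma - mean_a)^2) / (na - 1)
  vb <- rowSums((mb - mean_b)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  equal <- degen & (mean_a == mean_b)
  t[equal] <- 0; p[equal] <- 1; df[degen] <- NA_real_
  t[degen & !equal] <- Inf * sign(mean_a - mean_b)[degen & !equal]
  p[degen & !equal] <- 0
  list(t = t, df = df, p = p, degenerate = degen & !equal,
       mean_a = mean_a, mean_b = mean_b)
}

#' One-way ANOVA
#'
#' Standard one-way analysis of variance of `values` across the groups in
#' `labels`. Degenerate conventions: all values identical gives `F = 0,
#' p = 1`; zero within-group variance with distinct group means gives
#' `p = 0` flagged degenerate.
#'
#' @param values numeric vector.
#' @param labels group labels (coerced to factor).
#' @return list: `F`, `df_between`, `df_within`, `p`, `degenerate`.
#' @export
anova_oneway <- function(values, labels) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) >= 2, length(values) == length(labels))
  r <- row_anova(matrix(values, nrow = 1), labels)
  list(F = r$F[1], df_between = r$df_between, df_within = r$df_within,
       p = r$p[1], degenerate = r$degenerate[1])
}

## Vectorised one-way ANOVA over rows of a matrix, columns grouped by f.
row_anova <- function(m, f) {
  f <- as.factor(f)
  stopifnot(ncol(m) == length(f))
  k <- nlevels(f)
  n <- ncol(m)
  counts <- as.vector(table(f))
  grand <- rowMeans(m)
  sst <- rowSums((m - grand)^2)
  group_means <- sapply(levels(f), function(g)
    rowMeans(m[, f == g, drop = FALSE]))
  if (is.null(dim(group_means))) group_means <- matrix(group_means, nrow = 1)
  ssb <- as.vector(group_means^2 %*% counts) - n * grand^2
  ssb <- pmax(ssb, 0)           # guard tiny negatives from cancellation
  ssw <- pmax(sst - ssb, 0)
  dfb <- k - 1
  dfw <- n - k
  F <- (ssb / dfb) / (ssw / dfw)
  p <- pf(F, dfb, dfw, lower.tail = FALSE)
  allsame <- sst < .Machine$double.eps * n
  degen <- !allsame & ssw < .Machine$double.eps * n
  F[allsame] <- 0; p[allsame] <- 1
  F[degen] <- Inf; p[degen] <- 0
  list(F = F, df_between = dfb, df_within = dfw, p = p,
       degenerate = degen, group_means = group_means)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the number of tests (defaults to
#' `length(pvals)`); delegates to [stats::p.adjust()].
#'
#' @param pvals p-values in \[0, 1\].
#' @param m number of tests.
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pmin(1, p.adjust(pvals, method = "bonferroni", n = m))
}

#' Tukey HSD post hoc pairwise comparisons
#'
#' All-pairs comparisons based on the studentized range distribution, with
#' the Tukey-Kramer correction for unequal group sizes (via
#' [stats::TukeyHSD()] on a one-way [stats::aov()] fit).
#'
#' @param values numeric vector.
#' @param labels group labels.
#' @return data.frame: `group_a`, `group_b`, `diff`, `p` (one row per pair).
#' @export
tukey_hsd <- function(values, labels) {
  labels <- as.factor(labels)
  d <- data.frame(y = values, g = labels)
  fit <- aov(y ~ g, data = d)
  tk <- TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group_a = vapply(pairs, `[`, character(1), 1),
    group_b = vapply(pairs, `[`, character(1), 2),
    diff = unname(tk[, "diff"]),
    p = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
}

#' Fold-change relevance filter on transformed stage means
#'
#' Statistically significant differences between stage means that are both
#' close to zero (e.g. mean log2 FC 0.1 vs 0.01) are biologically
#' meaningless. To screen them out, 1 is added to each per-stage mean of the
#' clamped log2 FC and the ratio of the transformed means is taken in both
#' directions; a pair is relevant iff the larger ratio is >= `cutoff`
#' (inclusive).
#'
#' @param stage_means named numeric vector of per-stage mean clamped log2 FC.
#' @param cutoff relevance cutoff (default 1.5).
#' @return data.frame: `stage_a`, `stage_b`, `ratio`, `relevant`.
#' @export
relevance_filter <- function(stage_means, cutoff = 1.5) {
  stopifnot(length(stage_means) >= 2)
  nm <- names(stage_means)
  if (is.null(nm)) nm <- as.character(seq_along(stage_means))
  cmb <- utils::combn(seq_along(stage_means), 2)
  ta <- stage_means[cmb[1, ]] + 1
  tb <- stage_means[cmb[2, ]] + 1
  ratio <- pmax(ta / tb, tb / ta)
  data.frame(stage_a = nm[cmb[1, ]], stage_b = nm[cmb[2, ]],
             ratio = unname(ratio), relevant = unname(ratio >= cutoff),
             stringsAsFactors = FALSE)
}

#' Two-group differential enrichment (Welch)
#'
#' Per element, a Welch t-test of the clamped log2 FC values between the two
#' groups. An element is flagged `significant` at unadjusted `p < alpha`
#' (broad marks yield no sharp peaks and Bonferroni across thousands of
#' elements is very conservative; the adjusted values are reported alongside
#' in `p_adj` and `significant_adj`). Group means and the transformed-mean
#' ratio (as in [relevance_filter()]) are reported per element.
#'
#' @param em `EnrichmentMatrix`.
#' @param grouping named character/factor mapping every sample id to one of
#'   exactly two groups, or the name of a column in `em$samples`.
#' @param alpha significance level (default 0.05).
#' @param relevance_cutoff cutoff for the reported `relevant` flag.
#' @return data.frame, one row per element: `element_id`, `t`, `df`, `p`,
#'   `p_adj`, `significant`, `significant_adj`, `mean_<group>` columns,
#'   `ratio`, `relevant`, `all_zero`, `degenerate`.
#' @export
differential_two_group <- function(em, grouping = "group", alpha = 0.05,
                                   relevance_cutoff = 1.5) {
  g <- resolve_grouping(em, grouping)
  lv <- levels(g)
  if (length(lv) != 2)
    stop("differential_two_group: exactly two groups required, got ",
         length(lv))
  m <- em$values
  r <- row_welch(m[, g == lv[1], drop = FALSE],
                 m[, g == lv[2], drop = FALSE])
  p_adj <- bonferroni(r$p)
  ratio <- pmax((r$mean_a + 1) / (r$mean_b + 1),
                (r$mean_b + 1) / (r$mean_a + 1))
  out <- data.frame(
    element_id = rownames(m),
    t = r$t, df = r$df, p = r$p, p_adj = p_adj,
    significant = r$p < alpha,
    significant_adj = p_adj < alpha,
    mean_a = r$mean_a, mean_b = r$mean_b,
    ratio = ratio, relevant = ratio >= relevance_cutoff,
    all_zero = rowSums(m) == 0,
    degenerate = r$degenerate,
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lv[2])
  attr(out, "groups") <- lv
  out
}

#' Stage-wise differential enrichment (ANOVA + Bonferroni + Tukey + relevance)
#'
#' Per element: one-way ANOVA of the clamped log2 FC values across stages
#' (tissues as replicates), Bonferroni adjustment across elements, Tukey HSD
#' on elements with `p_adj < posthoc_alpha_adj`, and the fold-change
#' relevance filter on per-stage means. An element is reported differential
#' iff at least one stage pair is both Tukey-significant (at `tukey_alpha`)
#' and relevant.
#'
#' @param em `EnrichmentMatrix`.
#' @param stages stage label per sample (name of a metadata column or a
#'   vector along samples).
#' @param posthoc_alpha_adj adjusted-p threshold gating the post hoc test
#'   (default 0.01).
#' @param tukey_alpha significance level for Tukey pairwise p (default 0.05).
#' @param relevance_cutoff transformed-mean ratio cutoff (default 1.5).
#' @return list with `elements` (per-element data.frame: `element_id`, `F`,
#'   `p`, `p_adj`, `posthoc_run`, `differential`, `best_pair`, `best_ratio`,
#'   stage-mean columns) and `pairs` (per significant pair: element, stages,
#'   Tukey p, ratio, relevant).
#' @export
differential_stagewise <- function(em, stages = "stage",
                                   posthoc_alpha_adj = 0.01,
                                   tukey_alpha = 0.05,
                                   relevance_cutoff = 1.5) {
  g <- resolve_grouping(em, stages)
  if (nlevels(g) < 2) stop("differential_stagewise: >= 2 stages required")
  m <- em$values
  an <- row_anova(m, g)
  p_adj <- bonferroni(an$p)
  stage_means <- an$group_means
  colnames(stage_means) <- levels(g)
  run_idx <- which(p_adj < posthoc_alpha_adj)
  pair_rows <- list()
  differential <- logical(nrow(m))
  best_pair <- rep(NA_character_, nrow(m))
  best_ratio <- rep(NA_real_, nrow(m))
  for (i in run_idx) {
    tk <- tukey_hsd(m[i, ], g)
    rel <- relevance_filter(stage_means[i, ], cutoff = relevance_cutoff)
    key_tk <- paste(tk$group_a, tk$group_b)
    key_rel <- paste(rel$stage_a, rel$stage_b)
    key_rel2 <- paste(rel$stage_b, rel$stage_a)
    j <- match(key_tk, key_rel)
    j2 <- match(key_tk, key_rel2)
    j[is.na(j)] <- j2[is.na(j)]
    tab <- data.frame(element_id = rownames(m)[i],
                      stage_a = tk$group_a, stage_b = tk$group_b,
                      tukey_p = tk$p, ratio = rel$ratio[j],
                      relevant = rel$relevant[j],
                      stringsAsFactors = FALSE)
    hit <- tab$tukey_p < tukey_alpha & tab$relevant
    differential[i] <- any(hit)
    if (any(hit)) {
      bh <- tab[hit, ][which.max(tab$ratio[hit]), ]
      best_pair[i] <- paste0(bh$stage_a, "|", bh$stage_b)
      best_ratio[i] <- bh$ratio
      pair_rows[[length(pair_rows) + 1]] <- tab[hit, ]
    }
  }
  el <- data.frame(element_id = rownames(m), F = an$F, p = an$p,
                   p_adj = p_adj,
                   posthoc_run = seq_len(nrow(m)) %in% run_idx,
                   differential = differential,
                   best_pair = best_pair, best_ratio = best_ratio,
                   stringsAsFactors = FALSE)
  sm <- as.data.frame(stage_means)
  names(sm) <- paste0("mean_", names(sm))
  el <- cbind(el, sm)
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows)
           else data.frame(element_id = character(0), stage_a = character(0),
                           stage_b = character(0), tukey_p = numeric(0),
                           ratio = numeric(0), relevant = logical(0))
  list(elements = el, pairs = pairs)
}

#' Satellite-family over-representation among differential elements
#'
#' For each family: with `N` analyzed elements of which `K` belong to the
#' family, and `n` differential elements of which `k` belong to the family,
#' the fold over-representation is `(k/n) / (K/N)` and the p-value is the
#' upper-tail hypergeometric probability `P(X >= k)`.
#'
#' @param instances `GRanges` of all analyzed elements (`name` = family).
#' @param differential_ids ids of differential elements (subset of
#'   `instances$id`).
#' @return data.frame: `family`, `N`, `K`, `n`, `k`, `fold`, `p`, sorted by p.
#' @export
family_overrepresentation <- function(instances, differential_ids) {
  stopifnot(all(differential_ids %in% instances$id))
  n <- length(differential_ids)
  if (n == 0)
    return(data.frame(family = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), fold = numeric(0),
                      p = numeric(0)))
  N <- length(instances)
  fam <- instances$name
  diff_fam <- fam[instances$id %in% differential_ids]
  out <- do.call(rbind, lapply(unique(fam), function(f) {
    K <- sum(fam == f)
    k <- sum(diff_fam == f)
    data.frame(family = f, N = N, K = K, n = n, k = k,
               fold = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out[order(out$p, -out$fold), , drop = FALSE]
}

## Resolve a grouping argument: a metadata column name or a vector/factor
## along samples (optionally named by sample_id).
resolve_grouping <- function(em, grouping) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(em$samples)) {
    g <- em$samples[[grouping]]
  } else if (length(grouping) == ncol(em$values)) {
    g <- grouping
    if (!is.null(names(g))) g <- g[colnames(em$values)]
  } else {
    stop("grouping must be a metadata column name or a vector along samples")
  }
  droplevels(as.factor(g))
}
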