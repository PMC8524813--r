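## Differential testing: Welch, ANOVA, Bonferroni, Tukey, relevance filter,
## per-element pipelines and family over-representation.

test_that("welch_test matches stats::t.test and handles degeneracy", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_test(a, b)
  tt <- t.test(a, b)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  ## identical vectors: t = 0, p = 1
  w2 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w2$t, 0)
  expect_equal(w2$p, 1)
  ## both constant and equal / different
  expect_equal(welch_test(c(2, 2), c(2, 2))$p, 1)
  wd <- welch_test(c(2, 2), c(3, 3))
  expect_equal(wd$p, 0)
  expect_true(wd$degenerate)
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), sd = 2)
    w <- welch_test(a, b); tt <- t.test(a, b)
    expect_equal(w$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("anova_oneway matches a manual sum-of-squares decomposition and aov", {
  v <- c(4.1, 3.9, 4.3, 4.2,  5.0, 5.2, 4.8, 5.1,  6.1, 5.8, 6.0, 6.3)
  g <- rep(c("a", "b", "c"), each = 4)
  an <- anova_oneway(v, g)
  ## manual SS decomposition
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f_manual <- (ssb / 2) / (ssw / 9)
  expect_equal(an$F, f_manual, tolerance = 1e-12)
  fit <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(an$F, fit$`F value`[1], tolerance = 1e-9)
  expect_equal(an$p, fit$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 9)
  ## degenerate conventions
  expect_equal(anova_oneway(rep(1, 9), rep(1:3, 3))$p, 1)
  expect_equal(anova_oneway(rep(1:3, each = 3), rep(1:3, each = 3))$p, 0)
})

test_that("bonferroni caps at one and preserves ordering", {
  expect_equal(bonferroni(0.001, m = 10), 0.01)
  expect_equal(bonferroni(0.5, m = 10), 1)
  set.seed(9)
  p <- runif(50)
  expect_false(is.unsorted(bonferroni(p)[order(p)]))   # monotone (with ties)
  expect_true(all(bonferroni(p) >= p))
})

test_that("tukey_hsd matches an independent studentized-range computation", {
  set.seed(21)
  v <- c(rnorm(5, 0), rnorm(7, 1), rnorm(4, 0.5))   # unequal group sizes
  g <- rep(c("a", "b", "c"), c(5, 7, 4))
  got <- tukey_hsd(v, g)
  ref <- brute_tukey(v, g)
  key <- function(d) paste(pmin(d$group_a, d$group_b),
                           pmax(d$group_a, d$group_b))
  m <- match(key(got), key(ref))
  expect_equal(got$p, ref$p[m], tolerance = 1e-6)
  ## two identical groups
  same <- tukey_hsd(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(same$p, 1, tolerance = 1e-12)
})

test_that("relevance filter uses +1-transformed mean ratios, inclusive at the cutoff", {
  ## means 0.1 and 0.01: tenfold raw ratio but transformed ratio ~1.089
  r <- relevance_filter(c(s1 = 0.1, s2 = 0.01))
  expect_equal(r$ratio, 1.1 / 1.01, tolerance = 1e-12)
  expect_false(r$relevant)
  ## boundary: 2.0 vs 1.0 -> 3/2 = 1.5, inclusive
  r2 <- relevance_filter(c(s1 = 2, s2 = 1))
  expect_equal(r2$ratio, 1.5)
  expect_true(r2$relevant)
  expect_false(relevance_filter(c(a = 1, b = 1))$relevant)
  ## symmetric under swapping stages
  r3 <- relevance_filter(c(a = 0.3, b = 1.9))
  r4 <- relevance_filter(c(a = 1.9, b = 0.3))
  expect_equal(r3$ratio, r4$ratio)
})

make_em <- function(values, samples) {
  structure(list(values = values, samples = samples, linear = NULL),
            class = "EnrichmentMatrix")
}

test_that("two-group differential flags planted effects and stays calibrated on nulls", {
  set.seed(101)
  ns <- c(8, 13)
  samples <- data.frame(sample_id = paste0("s", 1:21),
                        group = rep(c("g1", "g2"), ns))
  ## planted row: delta 1.0, sd 0.3 -> detected in >= 195 of 200 replicates
  hits <- vapply(1:200, function(i) {
    v <- rbind(c(rnorm(8, 1.6, 0.3), rnorm(13, 0.6, 0.3)))
    rownames(v) <- "el1"; colnames(v) <- samples$sample_id
    differential_two_group(make_em(v, samples), "group")$significant
  }, logical(1))
  expect_gte(mean(hits), 0.975)
  ## null matrix: flagged fraction within binomial range of alpha
  v0 <- matrix(rnorm(400 * 21, 1, 0.3), 400,
               dimnames = list(paste0("e", 1:400), samples$sample_id))
  d0 <- differential_two_group(make_em(v0, samples), "group")
  expect_lt(abs(mean(d0$significant) - 0.05),
            3 * sqrt(0.05 * 0.95 / 400) + 0.01)
  ## identical groups in a single row: not flagged
  v1 <- matrix(rep(c(1, 2, 1.5), 7), 1)[, 1:21, drop = FALSE]
  dimnames(v1) <- list("e1", samples$sample_id)
  expect_false(differential_two_group(make_em(v1, samples),
                                      "group")$significant)
  ## all-zero rows are tested but flagged
  vz <- rbind(e1 = rep(0, 21))
  colnames(vz) <- samples$sample_id
  dz <- differential_two_group(make_em(vz, samples), "group")
  expect_true(dz$all_zero)
  expect_false(dz$significant)
})

test_that("stage-wise differential requires both Tukey significance and relevance", {
  set.seed(55)
  stages <- rep(c("s1", "s2", "s3", "s4"), each = 6)
  samples <- data.frame(sample_id = paste0("m", seq_along(stages)),
                        stage = stages)
  n <- 60
  v <- matrix(rnorm(n * length(stages), 0.5, 0.2), n,
              dimnames = list(paste0("e", 1:n), samples$sample_id))
  ## element 1: large, relevant difference ((2.0+1)/(0.5+1) = 2 >= 1.5)
  v[1, stages == "s1"] <- rnorm(6, 2.0, 0.2)
  ## element 2: tiny but ultra-precise difference, ratio (1.02/1.002) < 1.5
  v[2, ] <- rep(0.002, length(stages))
  v[2, stages == "s1"] <- 0.02
  v[2, ] <- v[2, ] + rnorm(length(stages), 0, 1e-4)
  st <- differential_stagewise(make_em(v, samples), "stage")
  expect_true(st$elements$differential[1])
  ## element 2 passes ANOVA at adjusted p < 0.01 yet fails relevance
  expect_true(st$elements$posthoc_run[2])
  expect_false(st$elements$differential[2])
  expect_lt(st$elements$best_ratio[1], Inf)
  ## monotone filtering chain
  expect_true(all(which(st$elements$differential) %in%
                    which(st$elements$posthoc_run)))
  ## null matrix at p_adj < 0.01: expected discoveries < 1
  v0 <- matrix(rnorm(200 * length(stages), 0.5, 0.3), 200,
               dimnames = list(paste0("z", 1:200), samples$sample_id))
  st0 <- differential_stagewise(make_em(v0, samples), "stage")
  expect_equal(sum(st0$elements$differential), 0)
})

test_that("family over-representation matches the exact hypergeometric tail", {
  el <- gr0("chr1", seq(0, 9900, by = 100), seq(50, 9950, by = 100),
            name = c(rep("GSATII", 10), rep("OTHER", 90)),
            id = paste0("e", 1:100), blocklisted = rep(FALSE, 100))
  ## all 10 differential elements are GSATII: fold 10
  fam <- family_overrepresentation(el, paste0("e", 1:10))
  g <- fam[fam$family == "GSATII", ]
  expect_equal(g$fold, 10)
  expect_equal(g$p, choose(10, 10) * choose(90, 0) / choose(100, 10),
               tolerance = 1e-12)
  ## k at expectation -> fold 1
  fam2 <- family_overrepresentation(el, paste0("e", c(1, 11:19)))
  expect_equal(fam2$fold[fam2$family == "GSATII"], 1)
  ## family absent from the differential set
  fam3 <- family_overrepresentation(el, paste0("e", 11:20))
  expect_equal(fam3$fold[fam3$family == "GSATII"], 0)
  expect_equal(fam3$p[fam3$family == "GSATII"], 1)
  ## degenerate: no differential elements
  expect_equal(nrow(family_overrepresentation(el, character(0))), 0)
})
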