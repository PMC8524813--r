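## Repeat annotation parsing and interval algebra.

write_rmsk_fixture <- function(rows, path, bin = TRUE) {
  ## rows: data.frame(chrom, start, end, strand, name, class)
  n <- nrow(rows)
  df <- data.frame(bin = 0L, sw = 1000L, d1 = 0L, d2 = 0L, d3 = 0L,
                   chrom = rows$chrom, start = rows$start, end = rows$end,
                   left = 0L, strand = rows$strand, name = rows$name,
                   class = rows$class, fam = rows$class, rs = 0L,
                   re = rows$end - rows$start, rl = 0L, id = seq_len(n))
  if (!bin) df <- df[, -1]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

test_that("read_rmsk filters by class, uses half-open coordinates, detects bin column", {
  rows <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(100L, 300L, 50L), end = c(200L, 350L, 90L),
                     strand = c("+", "-", "+"),
                     name = c("GSATII", "AluY", "GSAT"),
                     class = c("Satellite", "SINE", "Satellite"))
  f <- write_rmsk_fixture(rows, tempfile())
  inst <- read_rmsk(f)
  expect_length(inst, 2)
  expect_equal(inst$name, c("GSATII", "GSAT"))
  expect_equal(width(inst)[1], 100)            # genoEnd exclusive
  expect_equal(start(inst)[1], 101)            # 0-based start consumed
  ## same table without the bin column parses identically
  f2 <- write_rmsk_fixture(rows, tempfile(), bin = FALSE)
  inst2 <- read_rmsk(f2)
  expect_equal(inst$id, inst2$id)
})

test_that("read_rmsk agrees with a reference line parser; ids unique and sorted", {
  set.seed(42)
  rows <- data.frame(
    chrom = sample(c("chr1", "chr2"), 12, replace = TRUE),
    start = as.integer(sample(0:5000, 12)),
    strand = sample(c("+", "-"), 12, replace = TRUE),
    name = sample(c("GSAT", "GSATII", "(CACTT)n"), 12, replace = TRUE),
    class = sample(c("Satellite", "LINE"), 12, replace = TRUE, prob = c(.8, .2)))
  rows$end <- rows$start + sample(50:500, 12)
  f <- write_rmsk_fixture(rows, tempfile())
  inst <- read_rmsk(f)
  ref <- reference_rmsk_parse(f)
  expect_equal(length(inst), nrow(ref))
  expect_setequal(paste(as.character(seqnames(inst)), start(inst) - 1),
                  paste(ref$chrom, ref$start))
  expect_false(any(duplicated(inst$id)))
  o <- order(as.character(seqnames(inst)), start(inst))
  expect_equal(o, seq_along(inst))             # sorted by (chrom, start)
})

test_that("read_rmsk reports malformed rows and unknown column counts", {
  f <- tempfile()
  writeLines(c(paste(rep("x", 10), collapse = "\t")), f)
  expect_error(read_rmsk(f), "column count")
  rows <- data.frame(chrom = "chr1", start = 0L, end = 10L, strand = "+",
                     name = "GSAT", class = "Satellite")
  f2 <- write_rmsk_fixture(rows, tempfile())
  cat("bad\tline\n", file = f2, append = TRUE)
  expect_warning(inst <- read_rmsk(f2), "malformed")
  expect_length(inst, 1)
  expect_error(read_rmsk(f2, on_malformed = "error"), "malformed")
})

test_that("blocklist filtering excludes any overlap but keeps touching intervals", {
  el <- gr0(c("chr1", "chr1"), c(100, 100), c(200, 200),
            name = c("a", "b"), id = c("a", "b"),
            blocklisted = c(FALSE, FALSE))
  bl1 <- gr0("chr1", 199, 300)    # 1 bp shared
  bl2 <- gr0("chr1", 200, 300)    # touching only
  expect_equal(length(filter_blocklist(el[1], bl1)$removed), 1)
  expect_equal(length(filter_blocklist(el[1], bl2)$kept), 1)
  ## chromosome absent from blocklist is not an error (logged, kept)
  el2 <- gr0("chr9", 0, 10, name = "c", id = "c", blocklisted = FALSE)
  expect_warning(res <- filter_blocklist(el2, bl1), "no sequence levels")
  expect_equal(length(res$kept), 1)
})

test_that("blocklist filtering matches brute force and is idempotent", {
  set.seed(7)
  n <- 50
  s <- sample(0:10000, n)
  el <- gr0(sample(c("chr1", "chr2"), n, replace = TRUE), s, s + 100,
            name = paste0("e", 1:n), id = paste0("e", 1:n),
            blocklisted = rep(FALSE, n))
  ## plant the blocklist over 12 chosen elements
  idx <- sample(n, 12)
  bl <- shift(granges(el[idx]), 10)
  res <- filter_blocklist(el, bl)
  ## brute force all-pairs overlap check
  brute_hit <- vapply(seq_len(n), function(i) {
    any(as.character(seqnames(bl)) == as.character(seqnames(el))[i] &
          start(bl) <= end(el)[i] & end(bl) >= start(el)[i])
  }, logical(1))
  expect_equal(sort(res$removed$id), sort(el$id[brute_hit]))
  expect_true(all(res$removed$blocklisted))
  expect_equal(length(res$kept) + length(res$removed), n)
  ## idempotence and zero residual overlap
  again <- filter_blocklist(res$kept, bl)
  expect_equal(again$kept$id, res$kept$id)
  expect_length(again$removed, 0)
})

test_that("chromosome filtering drops sex chromosomes and honors custom lists", {
  el <- gr0(c(rep("chr1", 5), rep("chr2", 2), "chrX", "chrX", "chrY"),
            seq(0, 900, by = 100), seq(50, 950, by = 100),
            name = letters[1:10], id = letters[1:10],
            blocklisted = rep(FALSE, 10))
  expect_length(filter_chromosomes(el, "autosomes_only"), 7)
  expect_length(filter_chromosomes(el, "custom", keep = "chr1"), 5)
  expect_equal(filter_chromosomes(el, "autosomes_only")$id,
               el$id[1:7])                     # order preserved
  expect_warning(filter_chromosomes(el, "custom", keep = "chr7"), "no instances")
})

test_that("reciprocal overlap matches its definition and a brute-force counter", {
  a <- gr0("chr1", 0, 100)
  b <- gr0("chr1", 50, 150)
  expect_true(reciprocal_overlap(a, b, 0.5))
  expect_false(reciprocal_overlap(a, gr0("chr1", 0, 300), 0.5))
  expect_false(reciprocal_overlap(a, gr0("chr2", 0, 100), 0.5))
  expect_error(reciprocal_overlap(a, b, 0), "frac")
  expect_error(reciprocal_overlap(a, b, 1.2), "frac")
  set.seed(13)
  for (i in 1:1000) {
    c1 <- sample(c("chr1", "chr2"), 1); c2 <- sample(c("chr1", "chr2"), 1)
    s1 <- sample(0:80, 1); e1 <- s1 + sample(1:40, 1)
    s2 <- sample(0:80, 1); e2 <- s2 + sample(1:40, 1)
    fr <- runif(1, 0.05, 1)
    got <- reciprocal_overlap(gr0(c1, s1, e1), gr0(c2, s2, e2), fr)
    expect_equal(got, brute_reciprocal(c1, s1, e1, c2, s2, e2, fr))
    ## symmetry
    expect_equal(got, reciprocal_overlap(gr0(c2, s2, e2), gr0(c1, s1, e1), fr))
  }
})

test_that("interval shuffling preserves lengths, avoids exclusions and is seeded", {
  sizes <- c(chr1 = 10000L, chr2 = 8000L)
  el <- gr0(rep("chr1", 5), c(0, 500, 1200, 3000, 7000),
            c(100, 900, 1300, 3500, 7800))
  sh <- shuffle_intervals(el, sizes, seed = 3)
  expect_equal(sort(width(sh)), sort(width(el)))
  sh2 <- shuffle_intervals(el, sizes, seed = 3)
  expect_identical(as.data.frame(sh), as.data.frame(sh2))
  ## exclusion covering all of chr1 pushes placements to chr2
  excl <- gr0("chr1", 0, 10000)
  sh3 <- shuffle_intervals(el, sizes, exclude = excl, seed = 3)
  expect_true(all(as.character(seqnames(sh3)) == "chr2"))
  ## an interval that cannot be placed is a clear error
  expect_error(
    shuffle_intervals(el, sizes, exclude = gr0(c("chr1", "chr2"), c(0, 0),
                                               c(10000, 8000)),
                      seed = 1, max_attempts = 50),
    "could not be")
})

test_that("shuffled start positions are uniform over allowed placements", {
  sizes <- c(chr1 = 600L, chr2 = 400L)
  el <- gr0("chr1", 0, 10)    # single 10 bp interval, replaced many times
  set.seed(99)
  starts <- replicate(10000, {
    s <- shuffle_intervals(el, sizes)
    paste0(as.character(seqnames(s)), ":", start(s))
  })
  ## chromosome choice proportional to available positions
  p_chr1 <- mean(grepl("^chr1", starts))
  expect_lt(abs(p_chr1 - (600 - 9) / (600 - 9 + 400 - 9)), 0.02)
  ## within chr1, start positions uniform (chi-square over 10 bins)
  pos <- as.integer(sub(".*:", "", starts[grepl("^chr1", starts)]))
  cs <- suppressWarnings(chisq.test(table(cut(pos, 10))))
  expect_gt(cs$p.value, 0.001)
})
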