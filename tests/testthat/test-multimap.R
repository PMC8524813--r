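## MAPQ-0 quantification, read preprocessing, downsampling and the
## consensus-dimer matcher.

toy_reads <- function() {
  read_set(
    read_id = paste0("r", 1:12),
    chrom = rep("chr1", 12),
    pos = c(rep(100L, 9), rep(500L, 3)),
    mapq = c(0L, 0L, 0L, rep(30L, 9)),
    seq = strrep("A", 20),
    unmapped = FALSE, duplicate = FALSE, reverse = FALSE
  )
}

test_that("mapq0 fractions count overlapping reads per element", {
  el <- gr0("chr1", c(90, 480, 900), c(150, 530, 950),
            id = c("e1", "e2", "e3"))
  mq <- mapq0_fraction(toy_reads(), el)
  expect_equal(mq$n_reads, c(9, 3, 0))
  expect_equal(mq$fraction[1], 3 / 9)
  expect_true(is.na(mq$fraction[3]))
  ## all mapq0
  rs <- toy_reads(); rs$mapq <- 0L
  expect_equal(mapq0_fraction(rs, el)$fraction[1:2], c(1, 1))
})

test_that("replicate preprocessing removes duplicates and unmapped reads", {
  r1 <- read_set(paste0("a", 1:5), "chr1", 1:5, 30L, strrep("A", 10),
                 unmapped = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                 duplicate = FALSE, reverse = FALSE)
  r2 <- read_set(paste0("b", 1:5), "chr1", 1:5, 30L, strrep("C", 10),
                 unmapped = FALSE,
                 duplicate = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                 reverse = FALSE)
  merged <- preprocess_alignments(list(r1, r2))
  expect_equal(nrow(merged), 8)
  ## no duplicates: count preserved
  expect_equal(nrow(preprocess_alignments(list(r1[1:4, ]))), 4)
  ## everything filtered away is fatal
  r3 <- read_set("x", "chr1", 1L, 0L, "AAAA", unmapped = TRUE,
                 duplicate = FALSE, reverse = FALSE)
  expect_error(preprocess_alignments(list(r3)), "no reads")
})

test_that("downsampling is exact, seeded and uniform", {
  rs <- read_set(paste0("r", 1:1000), "chr1", 1:1000, 30L, strrep("A", 5),
                 unmapped = FALSE, duplicate = FALSE, reverse = FALSE)
  same <- downsample_reads(rs, 1000, seed = 1)
  expect_equal(sort(same$read_id), sort(rs$read_id))
  d1 <- downsample_reads(rs, 10, seed = 42)
  d2 <- downsample_reads(rs, 10, seed = 42)
  expect_identical(d1$read_id, d2$read_id)
  expect_equal(nrow(d1), 10)
  expect_error(downsample_reads(rs, 1001), "limiting sample")
  ## selection frequencies approximately uniform
  set.seed(5)
  counts <- integer(100)
  small <- rs[1:100, ]
  for (i in 1:2000) {
    sel <- as.integer(sub("r", "", downsample_reads(small, 10)$read_id))
    counts[sel] <- counts[sel] + 1L
  }
  expect_lt(abs(mean(counts) - 200), 1e-9)    # exactly 10/100 of 2000 draws
  cs <- suppressWarnings(chisq.test(counts))
  expect_gt(cs$p.value, 0.001)
})

test_that("SAM files round-trip through the reader", {
  rs <- read_set(
    read_id = c("q1", "q2", "q3", "q4"),
    chrom = c("chr1", "chr1", "chr2", NA),
    pos = c(10L, 20L, 30L, 0L),
    mapq = c(0L, 30L, 12L, 0L),
    seq = c("ACGTACGTAC", "TTTTTTTTTT", "GGGGGGGGGG", "CCCCCCCCCC"),
    unmapped = c(FALSE, FALSE, FALSE, TRUE),
    duplicate = c(FALSE, TRUE, FALSE, FALSE),
    reverse = c(FALSE, TRUE, FALSE, FALSE)
  )
  f <- tempfile(fileext = ".sam")
  satrep:::write_sam(rs, c(chr1 = 1000L, chr2 = 500L), f)
  back <- read_alignments(f)
  back <- back[match(rs$read_id, back$read_id), ]
  expect_equal(back$pos[1:3], rs$pos[1:3])
  expect_equal(back$mapq[1:3], rs$mapq[1:3])
  expect_equal(back$unmapped, rs$unmapped)
  expect_equal(back$duplicate, rs$duplicate)
  ## reverse-strand reads come back reverse-complemented by the BAM layer,
  ## forward reads byte-identical
  expect_equal(back$seq[1], rs$seq[1])
})

test_that("the consensus matcher handles junctions, thresholds and strands", {
  mono <- Biostrings::DNAStringSet(c(
    FAM1 = paste(rep(c("A", "C", "G", "T"), 15), collapse = ""),
    FAM2 = strrep("ACGGT", 12)))
  refs <- list(monomers = mono,
               dimers = setNames(Biostrings::xscat(mono, mono), names(mono)))
  L <- 30
  d1 <- as.character(refs$dimers[[1]])
  ## read spanning the monomer junction aligns thanks to the dimer
  junction_read <- substr(d1, 46, 45 + L)
  got <- align_to_consensus(junction_read, refs, max_mismatch_rate = 0.1)
  expect_equal(got$assignment$family, "FAM1")
  expect_equal(got$assignment$mismatches, 0)
  ## mismatch rate just above the cap -> unaligned
  r <- substr(d1, 1, L)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(k)] <- ifelse(ch[seq_len(k)] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  ok3 <- align_to_consensus(mutate_at(r, 3), refs, max_mismatch_rate = 0.1)
  bad4 <- align_to_consensus(mutate_at(r, 4), refs, max_mismatch_rate = 0.1)
  expect_equal(ok3$assignment$family, "FAM1")
  expect_true(is.na(bad4$assignment$family))
  ## reverse-complement placements are found
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  expect_equal(align_to_consensus(rc, refs)$assignment$family, "FAM1")
  ## N bases count as mismatches
  rn <- paste0(strrep("N", 4), substr(r, 5, L))
  expect_true(is.na(align_to_consensus(rn, refs)$assignment$family))
  expect_error(align_to_consensus(r, list(dimers = Biostrings::DNAStringSet())),
               "empty reference")
})

test_that("the matcher agrees with a brute-force all-placements oracle", {
  set.seed(19)
  mono <- Biostrings::DNAStringSet(c(
    F1 = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = ""),
    F2 = paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE),
               collapse = "")))
  refs <- list(monomers = mono,
               dimers = setNames(Biostrings::xscat(mono, mono), names(mono)))
  reads <- character(40)
  for (i in 1:40) {
    src <- sample(3, 1)
    reads[i] <- if (src == 3) {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    } else {
      d <- as.character(refs$dimers[[src]])
      s <- sample(nchar(d) - 20, 1)
      r <- substr(d, s, s + 19)
      mutate <- sample(0:3, 1)
      if (mutate > 0) {
        ch <- strsplit(r, "")[[1]]
        at <- sample(20, mutate)
        ch[at] <- sapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1))
        r <- paste(ch, collapse = "")
      }
      r
    }
  }
  got <- align_to_consensus(reads, refs, max_mismatch_rate = 0.1)
  ref <- vapply(reads, brute_best_family, character(1),
                dimers = refs$dimers, max_rate = 0.1, USE.NAMES = FALSE)
  expect_equal(got$assignment$family, ref)
})

test_that("generator consensus reads are assigned to their true families", {
  cfg <- synthetic_config(
    "fetal_wave", seed = 4,
    chrom_sizes = c(chr1 = 300000L, chr2 = 200000L, chrX = 80000L,
                    chrY = 60000L),
    n_dispersed = 30, n_cluster = 6, n_cluster_blocked = 2,
    n_dispersed_blocked = 2, n_sex = 3, n_other_class = 2,
    n_true_pos = 4, n_overrep_family = 6, n_overrep_tp = 3,
    cluster_pos = 150000L, peak_n = 6,
    stages = c("E10.5", "E11.5", "P0"),
    tissues = c("forebrain", "liver", "heart"),
    stage_wave = c(1.0, 0.4, 0.0))
  b <- simulate_satellite_dataset(cfg)
  chip <- b$mm_reads$chip
  refs <- list(monomers = b$consensus,
               dimers = setNames(Biostrings::xscat(b$consensus, b$consensus),
                                 names(b$consensus)))
  sub <- chip[!is.na(chip$true_family), ][1:500, ]
  got <- align_to_consensus(sub$seq, refs)
  agree <- mean(got$assignment$family == sub$true_family, na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("consensus enrichment divides aligned counts at equal depth", {
  chip <- data.frame(family = c("A", "B", "C"), aligned = c(200L, 50L, 0L))
  input <- data.frame(family = c("A", "B", "C"), aligned = c(100L, 0L, 0L))
  ce <- consensus_enrichment(chip, input, 1000, 1000)
  expect_equal(ce$fc[ce$family == "A"], 2)
  expect_equal(ce$status[ce$family == "B"], "no_input")
  expect_equal(ce$status[ce$family == "C"], "no_reads")
  expect_error(consensus_enrichment(chip, input, 1000, 900), "unequal")
  ## identical read sets give fc exactly 1
  ce2 <- consensus_enrichment(chip, chip, 500, 500)
  expect_true(all(ce2$fc[ce2$status == "ok"] == 1))
})
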