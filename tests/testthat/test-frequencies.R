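test_that("allele counting applies X dosage: males 1, females 2", {
  tab <- genotype_table(data.frame(
    sample_id = c("m", "f"), sex = c("M", "F"), population = "p",
    L = c("8", "8/9")))
  cnt <- allele_counts(tab, "L")
  expect_identical(as.integer(cnt[c("8", "9")]), c(2L, 1L))
  expect_identical(attr(cnt, "n_chrom"), 3L)
  expect_error(allele_counts(tab, "nope"), "unknown locus")
})

test_that("pooled counts are the sum of sex-specific counts (additivity)", {
  set.seed(7)
  freqs <- lapply(1:3, function(i) {
    p <- rand_simplex(6)
    stats::setNames(p, as.character(7 + seq_along(p)))
  })
  names(freqs) <- paste0("L", 1:3)
  tab <- simulate_population(freqs, n_m = 40, n_f = 30, seed = 13)
  for (l in names(freqs)) {
    pooled <- allele_counts(tab, l)
    m <- allele_counts(tab, l, sex = "M")
    f <- allele_counts(tab, l, sex = "F")
    alleles <- names(pooled)
    get0i <- function(v) ifelse(is.na(v[alleles]), 0L, v[alleles])
    expect_identical(as.integer(pooled), as.integer(get0i(m) + get0i(f)))
    expect_identical(attr(pooled, "n_chrom"),
                     attr(m, "n_chrom") + attr(f, "n_chrom"))
  }
})

test_that("empty selections give n_chrom 0, not an error", {
  tab <- toy_table()
  cnt <- allele_counts(tab, "L1", population = "no-such-pop")
  expect_identical(length(cnt), 0L)
  expect_identical(attr(cnt, "n_chrom"), 0L)
  expect_error(allele_frequencies(cnt), "zero chromosomes")
})

test_that("allele frequencies are exact ratios in allele-key order", {
  fr <- allele_frequencies(c("9" = 1, "8" = 3))
  expect_identical(fr$allele, c("8", "9"))
  expect_identical(fr$frequency, c(0.75, 0.25))
  expect_identical(allele_frequencies(c("8" = 4))$frequency, 1)
  # property: sums to 1, proportional to counts
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    counts <- stats::setNames(sample(0:50, k, TRUE) + 1L,
                              as.character(seq(8, length.out = k)))
    fr <- allele_frequencies(counts)
    expect_equal(sum(fr$frequency), 1, tolerance = 1e-12)
    expect_equal(fr$frequency, fr$count / sum(fr$count), tolerance = 0)
  }
})

test_that("per-locus deletion: missing genotypes drop from that locus only", {
  tab <- genotype_table(data.frame(
    sample_id = c("m1", "f1"), sex = c("M", "F"), population = "p",
    L1 = c(NA, "8/8"), L2 = c("9", "9/10")))
  expect_identical(attr(allele_counts(tab, "L1"), "n_chrom"), 2L)
  expect_identical(attr(allele_counts(tab, "L2"), "n_chrom"), 3L)
})

test_that("haplotype counting matches hand examples and set oracle", {
  # a haplotype seen 12 times among 200 males has frequency 0.0600
  hap <- data.frame(A = "10", B = "21", C = "24.1", frequency = 1)
  males <- simulate_linked_males(hap, n_m = 200, seed = 1)
  hc <- haplotype_counts(males, c("A", "B", "C"))
  expect_identical(hc$count, 200L)
  twelve <- data.frame(
    sample_id = sprintf("s%03d", 1:200), sex = "M", population = "p",
    A = c(rep("10", 12), rep("11", 188)),
    B = "21", C = "24.1")
  hc2 <- haplotype_counts(genotype_table(twelve), c("A", "B", "C"))
  expect_equal(hc2$frequency[hc2$haplotype == "10-21-24.1"], 0.0600,
               tolerance = 1e-12)
  # all males identical -> 1 distinct haplotype at frequency 1
  five <- genotype_table(data.frame(
    sample_id = paste0("s", 1:5), sex = "M", population = "p",
    A = "8", B = "9", C = "10"))
  hc3 <- haplotype_counts(five, c("A", "B", "C"))
  expect_identical(nrow(hc3), 1L)
  expect_identical(hc3$frequency, 1)
  # set oracle: distinct-haplotype count equals cardinality of triple set
  set.seed(5)
  haps <- expand.grid(A = c("8", "9"), B = c("12", "13"),
                      C = c("20", "21.1"), stringsAsFactors = FALSE)
  haps$frequency <- rand_simplex(nrow(haps))
  males <- simulate_linked_males(haps, n_m = 60, seed = 2)
  hc4 <- haplotype_counts(males, c("A", "B", "C"))
  seen <- unique(paste(males$A, males$B, males$C, sep = "-"))
  expect_identical(nrow(hc4), length(seen))
  expect_identical(sum(hc4$count), 60L)
})

test_that("haplotype counting enforces sex and missing-data rules", {
  tab <- toy_table()
  expect_error(haplotype_counts(tab, c("L1", "L2")), "female")
  hc <- haplotype_counts(tab, c("L1", "L2"), males_only = TRUE)
  # m2 is missing L2 and must drop from the group sample size
  expect_identical(attr(hc, "n_males"), 1L)
  expect_error(haplotype_counts(tab, c("L1", "nope"), males_only = TRUE),
               "missing from table")
})

test_that("the four default linkage groups cover the 12 markers", {
  lgs <- linkage_groups()
  expect_identical(names(lgs), c("LG1", "LG2", "LG3", "LG4"))
  expect_identical(sort(unname(unlist(lgs))), sort(c(
    "DXS8378", "DXS10135", "DXS10148", "DXS7132", "DXS10074", "DXS10079",
    "HPRTB", "DXS10103", "DXS10101", "DXS7423", "DXS10134", "DXS10146")))
  expect_true(all(vapply(lgs, function(g) length(unique(g)) == 3L, TRUE)))
})

test_that("haplotype diversity matches hand calculations and properties", {
  expect_equal(haplotype_diversity(c(4))$HD, 0, tolerance = 1e-15)
  expect_equal(haplotype_diversity(c(1, 1))$HD, 1, tolerance = 1e-15)
  hd <- haplotype_diversity(c(2, 1, 1))
  expect_equal(hd$sum_p2, 0.375, tolerance = 1e-15)
  expect_equal(hd$HD, (4 / 3) * 0.625, tolerance = 1e-15)
  expect_error(haplotype_diversity(c(1)), "n >= 2")
  # relabelling invariance and novelty monotonicity
  set.seed(9)
  for (i in 1:10) {
    counts <- sample(1:6, sample(2:6, 1), TRUE)
    expect_equal(haplotype_diversity(counts)$HD,
                 haplotype_diversity(sample(counts))$HD, tolerance = 1e-12)
    dup_idx <- which(counts >= 2)[1]
    if (!is.na(dup_idx)) {
      novel <- counts
      novel[dup_idx] <- novel[dup_idx] - 1L
      novel <- c(novel, 1L)
      expect_gt(haplotype_diversity(novel)$HD,
                haplotype_diversity(counts)$HD)
    }
  }
})
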