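# direct variance-components oracle: explicit sums over chromosomes for a
# two-population, arbitrary-allele count matrix (alleles x pops)
fst_explicit_oracle <- function(m) {
  n_k <- colSums(m)
  N <- sum(n_k)
  r <- ncol(m)
  among <- 0
  within <- 0
  for (al in seq_len(nrow(m))) {
    # indicator data: per chromosome, 1 if it carries allele al
    p_k <- m[al, ] / n_k
    p_bar <- sum(m[al, ]) / N
    ssa <- sum(n_k * (p_k - p_bar)^2)
    ssw <- sum(n_k * p_k * (1 - p_k))
    msa <- ssa / (r - 1)
    msw <- ssw / (N - r)
    n_c <- (N - sum(n_k^2) / N) / (r - 1)
    among <- among + (msa - msw) / n_c
    within <- within + msw
  }
  among / (among + within)
}

counts_df <- function(m, locus = "L1") {
  do.call(rbind, lapply(colnames(m), function(pop) {
    data.frame(population = pop, locus = locus,
               allele = rownames(m), count = m[, pop])
  }))
}

test_that("pairwise Fst: fixation gives 1, identical counts give <= 0", {
  m <- matrix(c(10L, 0L, 0L, 10L), 2,
              dimnames = list(c("8", "9"), c("p1", "p2")))
  fst <- pairwise_fst(counts_df(m))
  expect_equal(fst$multilocus["p1", "p2"], 1, tolerance = 1e-12)
  m2 <- matrix(c(5L, 5L, 5L, 5L), 2,
               dimnames = list(c("8", "9"), c("p1", "p2")))
  fst2 <- pairwise_fst(counts_df(m2))
  expect_lte(fst2$multilocus["p1", "p2"], 0)   # reported, not truncated
})

test_that("pairwise Fst equals the explicit-sums oracle", {
  set.seed(23)
  for (i in 1:10) {
    m <- matrix(rpois(6, 8) + 1L, 3,
                dimnames = list(c("8", "9", "10"), c("p1", "p2")))
    fst <- pairwise_fst(counts_df(m))
    expect_equal(fst$multilocus["p1", "p2"], fst_explicit_oracle(m),
                 tolerance = 1e-12)
  }
})

test_that("Fst input validation", {
  m <- matrix(c(5L, 5L, 0L, 0L), 2,
              dimnames = list(c("8", "9"), c("p1", "p2")))
  expect_error(pairwise_fst(counts_df(m)), "zero chromosomes")
  ok <- matrix(c(5L, 5L, 5L, 5L), 2,
               dimnames = list(c("8", "9"), c("p1", "p2")))
  expect_error(pairwise_fst(counts_df(ok), permutations = -1),
               "permutations")
  one_pop <- counts_df(ok)[counts_df(ok)$population == "p1", ]
  expect_error(pairwise_fst(one_pop), "two populations")
})

test_that("permutation p is deterministic in the seed and detects divergence", {
  set.seed(24)
  freqs <- lapply(1:6, function(i) {
    stats::setNames(rand_simplex(6), as.character(8:13))
  })
  names(freqs) <- paste0("L", 1:6)
  tab <- simulate_divergent_populations(freqs, fst = 0.10, n_pops = 2,
                                        n_m = 80, n_f = 0, seed = 99)
  cnt <- count_table(tab)
  f1 <- pairwise_fst(cnt, permutations = 99, seed = 7)
  f2 <- pairwise_fst(cnt, permutations = 99, seed = 7)
  expect_identical(f1$p_values, f2$p_values)
  expect_lt(f1$p_values["pop1", "pop2"], 0.05)
  # same-source populations: p should not be extreme
  tab0 <- simulate_divergent_populations(freqs, fst = 0, n_pops = 2,
                                         n_m = 80, n_f = 0, seed = 100)
  f0 <- pairwise_fst(count_table(tab0), permutations = 99, seed = 8)
  expect_gt(f0$p_values["pop1", "pop2"], 0.01)
})

test_that("fst significance matrix counts and modes", {
  fst <- list(labels = c("a", "b"),
              per_locus_p = matrix(c(0.01, 0.2, 0.03, 0.8), 1,
                                   dimnames = list("a - b",
                                                   paste0("L", 1:4))))
  # all p = 1 -> nothing significant
  fst1 <- fst
  fst1$per_locus_p[] <- 1
  expect_identical(
    unname(fst_significance_matrix(fst1, 0.05)$n_significant), 0)
  # 4-entry grid with 2 below alpha
  s <- fst_significance_matrix(fst, alpha = 0.05, mode = "raw")
  expect_identical(unname(s$n_significant), 2)
  # bonferroni mode equals bonferroni() applied per pair
  sb <- fst_significance_matrix(fst, alpha = 0.05, mode = "bonferroni")
  expect_identical(unname(sb$flags[1, ]),
                   unname(bonferroni(fst$per_locus_p[1, ],
                                     0.05)$significant))
  expect_error(fst_significance_matrix(list(per_locus_p = NULL)),
               "permutations")
})

test_that("Nei distance: hand value, symmetry, degenerate cases", {
  fx <- list(L = c(a = 0.9, b = 0.1))
  fy <- list(L = c(a = 0.1, b = 0.9))
  d <- nei_unbiased_distance(fx, fy, unbiased = FALSE)
  expect_equal(d, -log(0.18 / 0.82), tolerance = 1e-12)
  expect_equal(d, 1.5163, tolerance = 1e-4)
  # identical populations, correction off -> 0
  expect_equal(nei_unbiased_distance(fx, fx, unbiased = FALSE), 0,
               tolerance = 1e-12)
  # symmetry
  expect_equal(nei_unbiased_distance(fx, fy, unbiased = FALSE),
               nei_unbiased_distance(fy, fx, unbiased = FALSE),
               tolerance = 1e-15)
  # disjoint allele sets -> +Inf flagged
  dz <- nei_unbiased_distance(list(L = c(a = 1)), list(L = c(b = 1)),
                              unbiased = FALSE)
  expect_identical(as.numeric(dz), Inf)
  expect_true(attr(dz, "degenerate"))
  # unbiased correction needs sample sizes and can go slightly negative
  expect_error(nei_unbiased_distance(fx, fy), "sample sizes")
  dneg <- nei_unbiased_distance(fx, fx, n_x = 50, n_y = 50, unbiased = TRUE)
  expect_lt(dneg, 0)
})

test_that("nei_distance_matrix is a valid distance matrix over populations", {
  set.seed(26)
  freqs <- lapply(1:4, function(i) {
    stats::setNames(rand_simplex(5), as.character(8:12))
  })
  names(freqs) <- paste0("L", 1:4)
  tab <- simulate_divergent_populations(freqs, fst = 0.05, n_pops = 3,
                                        n_m = 60, n_f = 0, seed = 33)
  m <- nei_distance_matrix(tab, sex = "M", unbiased = FALSE)
  expect_identical(rownames(m), c("pop1", "pop2", "pop3"))
  expect_true(all(m >= 0))
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_identical(unname(diag(m)), rep(0, 3))
})

test_that("fst_distance_matrix floors negatives for tree building", {
  m2 <- matrix(c(5L, 5L, 5L, 5L), 2,
               dimnames = list(c("8", "9"), c("p1", "p2")))
  fst <- pairwise_fst(counts_df(m2))
  d <- fst_distance_matrix(fst, floor_negative = TRUE)
  expect_gte(min(d), 0)
  d2 <- fst_distance_matrix(fst, mode = "locus_mean", floor_negative = FALSE)
  expect_lte(d2["p1", "p2"], 0)
})
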