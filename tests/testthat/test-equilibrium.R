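test_that("HWE exact test agrees with the matching-enumeration oracle", {
  fixtures <- list(
    c("A/A" = 1, "A/B" = 2, "B/B" = 1),
    c("A/A" = 2, "B/B" = 2),
    c("A/B" = 4),
    c("A/A" = 1, "A/B" = 1, "B/C" = 1, "C/C" = 1),
    c("A/B" = 2, "C/C" = 2)
  )
  for (gt in fixtures) {
    expect_equal(hwe_exact_test(gt)$p_value, hwe_matching_oracle(gt),
                 tolerance = 1e-9)
  }
})

test_that("monomorphic HWE input is degenerate with p = 1", {
  r <- hwe_exact_test(c("A/A" = 10))
  expect_identical(r$p_value, 1.0)
  expect_true(r$degenerate)
  expect_error(hwe_exact_test(integer(0)), "at least one genotype")
})

test_that("HWE Monte-Carlo agrees with enumeration within 3 SE", {
  gt <- c("A/A" = 3, "A/B" = 1, "B/B" = 4, "B/C" = 2, "A/C" = 1, "C/C" = 2)
  exact <- hwe_exact_test(gt)
  expect_identical(exact$method, "exact-enumeration")
  mc <- hwe_exact_test(gt, max_tables = 1, mc_draws = 20000, seed = 101)
  expect_identical(mc$method, "monte-carlo")
  se <- max(mc$se, sqrt(exact$p_value * (1 - exact$p_value) / mc$draws))
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1e-12)
  # deterministic given the seed
  mc2 <- hwe_exact_test(gt, max_tables = 1, mc_draws = 20000, seed = 101)
  expect_identical(mc$p_value, mc2$p_value)
  expect_error(hwe_exact_test(gt, max_tables = 1, mc_draws = 100),
               "seed")
})

test_that("male LD exact test matches the Fisher oracle", {
  # [[5,0],[0,5]] -> two-sided exact p = 2/252
  r <- ld_exact_test_males(rep(c("A", "B"), each = 5),
                           rep(c("x", "y"), each = 5))
  expect_equal(r$p_value, 2 / 252, tolerance = 1e-12)
  # random small tables vs fisher.test (same conditional two-sided rule)
  set.seed(21)
  for (i in 1:10) {
    a <- sample(c("A", "B", "C"), 25, TRUE)
    b <- sample(c("x", "y"), 25, TRUE)
    expect_equal(ld_exact_test_males(a, b)$p_value,
                 stats::fisher.test(table(a, b))$p.value, tolerance = 1e-9)
  }
})

test_that("male LD: monomorphic loci are degenerate, coupling is detected", {
  r <- ld_exact_test_males(rep("A", 20), rep(c("x", "y"), 10))
  expect_identical(r$p_value, 1.0)
  expect_true(r$degenerate)
  # perfectly coupled 2-allele loci at n = 50
  a <- rep(c("A", "B"), each = 25)
  r2 <- ld_exact_test_males(a, a)
  expect_lt(r2$p_value, 1e-4)
})

test_that("population differentiation matches Fisher and handles edge cases", {
  expect_equal(
    exact_population_differentiation(c(A = 5, B = 0), c(A = 0, B = 5))$p_value,
    2 / 252, tolerance = 1e-12)
  r <- exact_population_differentiation(c(A = 5, B = 5), c(A = 5, B = 5))
  expect_identical(r$p_value, 1.0)
  expect_error(exact_population_differentiation(c(A = 0), c(A = 5)),
               "at least one chromosome")
  set.seed(31)
  for (i in 1:5) {
    c1 <- stats::setNames(sample(0:8, 3, TRUE) + c(1L, 0L, 0L), c("8", "9", "10"))
    c2 <- stats::setNames(sample(0:8, 3, TRUE) + c(0L, 1L, 0L), c("8", "9", "10"))
    tab <- cbind(c1, c2)
    keep <- rowSums(tab) > 0
    expect_equal(exact_population_differentiation(c1, c2)$p_value,
                 stats::fisher.test(tab[keep, , drop = FALSE])$p.value,
                 tolerance = 1e-9)
  }
})

test_that("female LD: EM recovers direct counts on unambiguous data", {
  # all double homozygotes: phase known, EM must equal direct counting
  g_a <- c("8/8", "8/8", "9/9", "9/9", "9/9")
  g_b <- c("12/12", "12/12", "12/12", "13/13", "13/13")
  res <- xstrkit:::ld_em_lr(xstrkit:::parse_diploid(g_a),
                            xstrkit:::parse_diploid(g_b))
  h <- res$h
  expect_equal(h["8", "12"], 4 / 10, tolerance = 1e-9)
  expect_equal(h["9", "12"], 2 / 10, tolerance = 1e-9)
  expect_equal(h["9", "13"], 4 / 10, tolerance = 1e-9)
  expect_equal(sum(h), 1, tolerance = 1e-9)
})

test_that("female LD test: errors, degenerate input, determinism, power", {
  expect_error(ld_test_females("8/9", "12/13", seed = 1),
               "at least two females")
  r <- ld_test_females(c("8/8", "8/8"), c("12/13", "12/12"),
                       permutations = 50, seed = 5)
  expect_true(r$degenerate)
  expect_identical(r$p_value, 1.0)
  # strong coupling in females is detected
  set.seed(8)
  hapA <- sample(c("8", "9"), 80, TRUE)
  g_a <- paste(pmin(hapA[1:40], hapA[41:80]),
               pmax(hapA[1:40], hapA[41:80]), sep = "/")
  hapB <- ifelse(hapA == "8", "12", "13")   # fully coupled
  g_b <- paste(pmin(hapB[1:40], hapB[41:80]),
               pmax(hapB[1:40], hapB[41:80]), sep = "/")
  r2 <- ld_test_females(g_a, g_b, permutations = 199, seed = 9)
  expect_lt(r2$p_value, 0.02)
  r3 <- ld_test_females(g_a, g_b, permutations = 199, seed = 9)
  expect_identical(r2$p_value, r3$p_value)
})

test_that("female LD test holds its size on independent loci", {
  # ~200 null simulations at alpha = 0.05; genotypes from independent loci
  set.seed(12)
  n_sim <- 200
  pvals <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    g_a <- paste0(pmin(a1 <- sample(8:10, 30, TRUE),
                       a2 <- sample(8:10, 30, TRUE)), "/",
                  pmax(a1, a2))
    g_b <- paste0(pmin(b1 <- sample(12:14, 30, TRUE),
                       b2 <- sample(12:14, 30, TRUE)), "/",
                  pmax(b1, b2))
    pvals[s] <- ld_test_females(g_a, g_b, permutations = 99,
                                seed = 1000 + s)$p_value
  }
  expect_lte(rejection_rate(pvals, 0.05), 0.08)
})

test_that("bonferroni applies a strict threshold", {
  b <- bonferroni(0.0027, alpha = 0.05, m = 12)
  expect_equal(b$threshold, 0.05 / 12, tolerance = 1e-12)
  expect_true(b$significant)
  # exactly at the threshold is not significant
  expect_false(bonferroni(0.05 / 12, alpha = 0.05, m = 12)$significant)
  expect_equal(bonferroni(1, alpha = 0.05, m = 66)$threshold, 0.05 / 66,
               tolerance = 1e-12)
  expect_lt(abs(bonferroni(1, alpha = 0.05, m = 66)$threshold - 0.000758),
            1e-6)
  expect_error(bonferroni(0.5, m = 0), "m must be")
  b2 <- bonferroni(c(0.001, 0.02, 0.9), alpha = 0.05)
  expect_identical(b2$significant, c(TRUE, FALSE, FALSE))
})
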