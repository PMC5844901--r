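#' Likelihood-ratio LD test for unphased female genotypes
#'
#' Haplotype phase is unknown in diploid females, so two-locus haplotype
#' frequencies are estimated by EM and linkage disequilibrium is measured by
#' the likelihood ratio between the EM solution and the independence model
#' (haplotype frequencies equal to the product of allele frequencies). The
#' null distribution is obtained by permuting one locus's genotypes across
#' individuals, which breaks between-locus association while preserving both
#' single-locus genotype distributions; p uses the standard
#' \eqn{(1 + \#\{LR_{perm} \ge LR_{obs}\}) / (1 + B)} estimator.
#'
#' @param g_a,g_b character vectors of genotype cells (`"a/b"`) at the two
#'   loci, one entry per female; incomplete pairs are dropped.
#' @param permutations number of permutation replicates.
#' @param seed RNG seed (required).
#' @param max_iter,tol EM stopping rule (log-likelihood change below `tol`).
#' @return An `xstr_test` result with `statistic` = observed LR; `converged`
#'   is `FALSE` when the EM hit `max_iter` (best statistic still reported).
#' @export
ld_test_females <- function(g_a, g_b, permutations = 1000, seed = NULL,
                            max_iter = 200, tol = 1e-8) {
  keep <- !(is.na(g_a) | is.na(g_b))
  g_a <- g_a[keep]
  g_b <- g_b[keep]
  if (length(g_a) < 2L) {
    stop("need at least two females with complete two-locus genotypes",
         call. = FALSE)
  }
  pa <- parse_diploid(g_a)
  pb <- parse_diploid(g_b)
  res <- ld_em_lr(pa, pb, max_iter, tol)
  obs <- res$lr
  if (is_degenerate_pair(pa) || is_degenerate_pair(pb)) {
    return(new_test_result(1.0, "degenerate", degenerate = TRUE,
                           statistic = obs))
  }
  hits <- with_seed(seed, {
    h <- 0L
    n <- nrow(pa)
    for (b in seq_len(permutations)) {
      lr_b <- ld_em_lr(pa, pb[sample.int(n), , drop = FALSE],
                       max_iter, tol)$lr
      if (lr_b >= obs - 1e-12) h <- h + 1L
    }
    h
  })
  p <- (1 + hits) / (1 + permutations)
  new_test_result(p, "permutation", seed = seed,
                  draws = as.integer(permutations), statistic = obs,
                  converged = res$converged)
}

parse_diploid <- function(g) {
  parts <- strsplit(g, "/", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) {
    stop("expected diploid genotypes 'a/b', got: ", g[bad][1], call. = FALSE)
  }
  t(vapply(parts, identity, character(2)))
}

is_degenerate_pair <- function(m) length(unique(as.vector(m))) < 2L

# EM haplotype frequencies and LR vs independence for two unphased loci.
# a, b: n x 2 character matrices of allele labels.
ld_em_lr <- function(a, b, max_iter = 200, tol = 1e-8) {
  ua <- order_labels(unique(as.vector(a)))
  ub <- order_labels(unique(as.vector(b)))
  ka <- length(ua)
  kb <- length(ub)
  n <- nrow(a)
  a1 <- match(a[, 1], ua); a2 <- match(a[, 2], ua)
  b1 <- match(b[, 1], ub); b2 <- match(b[, 2], ub)
  p_a <- tabulate(c(a1, a2), ka) / (2 * n)
  p_b <- tabulate(c(b1, b2), kb) / (2 * n)
  hidx <- function(i, j) (i - 1L) * kb + j
  # the two phase configurations per individual (identical unless double het)
  c1h1 <- hidx(a1, b1); c1h2 <- hidx(a2, b2)
  c2h1 <- hidx(a1, b2); c2h2 <- hidx(a2, b1)
  double_het <- (a1 != a2) & (b1 != b2)
  geno_loglik <- function(h) {
    mult1 <- ifelse(c1h1 == c1h2, 1, 2)
    t1 <- mult1 * h[c1h1] * h[c1h2]
    t2 <- ifelse(double_het, 2 * h[c2h1] * h[c2h2], 0)
    sum(log(pmax(t1 + t2, 1e-300)))
  }
  # independence model; hidx is locus-A-major so flatten the transpose
  h0 <- as.vector(t(outer(p_a, p_b)))
  ll0 <- geno_loglik(h0)
  h <- h0
  ll_old <- ll0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    t1 <- ifelse(c1h1 == c1h2, 1, 2) * h[c1h1] * h[c1h2]
    t2 <- ifelse(double_het, 2 * h[c2h1] * h[c2h2], 0)
    w1 <- t1 / pmax(t1 + t2, 1e-300)
    w2 <- (1 - w1) * double_het
    cnt <- numeric(ka * kb)
    sums <- rowsum(c(w1, w1, w2, w2), c(c1h1, c1h2, c2h1, c2h2))
    cnt[as.integer(rownames(sums))] <- sums[, 1]
    h <- cnt / (2 * n)
    ll <- geno_loglik(h)
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(lr = 2 * (geno_loglik(h) - ll0), h = matrix(h, ka, kb, byrow = TRUE,
                                                   dimnames = list(ua, ub)),
       p_a = p_a, p_b = p_b, converged = converged)
}
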