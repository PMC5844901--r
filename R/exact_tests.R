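#' @name exact_tests
#' @title Exact tests for X-STR data
#'
#' @description
#' Conditional exact tests in the Fisher tradition: the p-value is the total
#' null probability of all outcomes (conditional on the observed margins) that
#' are no more probable than the observed one. Small problems are solved by
#' complete enumeration; larger ones by Monte-Carlo sampling from the exact
#' conditional null, with the standard error of the estimated p reported.
#' Monte-Carlo results are deterministic functions of the data, the number of
#' draws and the seed (which must be supplied explicitly).
NULL

new_test_result <- function(p_value, method, se = NA_real_, seed = NULL,
                            draws = NA_integer_, n_tables = NA_integer_,
                            degenerate = FALSE, statistic = NA_real_,
                            converged = TRUE) {
  structure(list(p_value = p_value, method = method, se = se, seed = seed,
                 draws = draws, n_tables = n_tables, degenerate = degenerate,
                 statistic = statistic, converged = converged),
            class = "xstr_test")
}

#' @export
print.xstr_test <- function(x, ...) {
  cat(sprintf("exact test: p = %.6g (%s)", x$p_value, x$method))
  if (!is.na(x$se)) cat(sprintf(", SE = %.2g", x$se))
  if (x$degenerate) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

# --- Hardy-Weinberg -------------------------------------------------------

# parse named genotype counts ("a/b" or "a" = homozygote shorthand) into a
# symmetric count matrix over the allele set
parse_genotype_counts <- function(genotypes) {
  if (length(genotypes) == 0L || sum(genotypes) == 0) {
    stop("at least one genotype observation required", call. = FALSE)
  }
  pairs <- lapply(names(genotypes), function(g) {
    a <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(a) == 1L) a <- c(a, a)
    if (length(a) != 2L) stop("malformed genotype label: ", g, call. = FALSE)
    order_labels(a)
  })
  alleles <- order_labels(unique(unlist(pairs)))
  k <- length(alleles)
  cnt <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (idx in seq_along(pairs)) {
    i <- match(pairs[[idx]][1], alleles)
    j <- match(pairs[[idx]][2], alleles)
    cnt[i, j] <- cnt[i, j] + as.integer(genotypes[idx])
  }
  cnt
}

# log conditional probability of a genotype table given allele counts m:
# P = n! 2^H prod(m_i!) / ((2n)! prod_{i<=j} c_ij!)
hwe_log_prob <- function(cnt) {
  m <- rowSums(cnt) + colSums(cnt)  # upper-triangular storage: margins
  n <- sum(cnt)
  het <- sum(cnt) - sum(diag(cnt))
  lgamma(n + 1) + het * log(2) + sum(lgamma(m + 1)) - lgamma(2 * n + 1) -
    sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1))
}

# enumerate all genotype tables with the given allele margins, calling
# visit(log_prob); aborts via error when more than max_tables are produced
hwe_enumerate <- function(m, max_tables, visit) {
  k <- length(m)
  cnt <- matrix(0L, k, k)
  n_seen <- 0L
  recurse_row <- function(i, rem) {
    if (i > k) {
      n_seen <<- n_seen + 1L
      if (n_seen > max_tables) stop("ENUM_CAP", call. = FALSE)
      visit(hwe_log_prob(cnt))
      return(invisible(NULL))
    }
    fill_cell <- function(j, left) {
      if (j > k) {
        if (left %% 2L == 0L) {
          cnt[i, i] <<- left %/% 2L
          rem2 <- rem
          rem2[i] <- 0L
          recurse_row(i + 1L, rem2)
          cnt[i, i] <<- 0L
        }
        return(invisible(NULL))
      }
      for (v in 0:min(left, rem[j])) {
        cnt[i, j] <<- v
        rem[j] <<- rem[j] - v
        fill_cell(j + 1L, left - v)
        rem[j] <<- rem[j] + v
        cnt[i, j] <<- 0L
      }
    }
    # local copy of rem for this row's mutation
    local_env <- environment()
    fill_cell(i + 1L, rem[i])
  }
  recurse_row(1L, m)
  invisible(NULL)
}

#' Exact test of Hardy-Weinberg equilibrium (female genotypes)
#'
#' X-linked HWE is testable only in females. The test conditions on the
#' observed allele counts: under HWE every way of pairing the 2n observed
#' allele copies into n genotypes is equally likely, giving the Levene/Haldane
#' conditional distribution over genotype tables. The p-value sums the
#' probability of all tables no more probable than the observed one (the
#' Guo-Thompson exact formulation). Small allele sets are enumerated
#' completely; otherwise the null is sampled directly by re-pairing the allele
#' multiset at random `mc_draws` times (i.i.d. draws from the exact
#' conditional null, so `se = sqrt(p(1-p)/B)`).
#'
#' @param genotypes named integer vector of female genotype counts; names are
#'   `"a/b"` (a single label means a homozygote).
#' @param max_tables enumeration bound; beyond it Monte-Carlo is used.
#' @param mc_draws Monte-Carlo sample size.
#' @param seed RNG seed, required when Monte-Carlo is used.
#' @return An `xstr_test` result: `p_value`, `method`, `se`, `degenerate`.
#' @examples
#' hwe_exact_test(c("A/A" = 1, "A/B" = 2, "B/B" = 1))
#' @export
hwe_exact_test <- function(genotypes, max_tables = 2e5, mc_draws = 1e5,
                           seed = NULL) {
  cnt <- parse_genotype_counts(genotypes)
  k <- nrow(cnt)
  if (k == 1L) {
    return(new_test_result(1.0, "degenerate", degenerate = TRUE))
  }
  m <- rowSums(cnt) + colSums(cnt)
  obs <- hwe_log_prob(cnt)
  tol <- 1e-9
  acc <- new.env(parent = emptyenv())
  acc$psum <- 0
  acc$total <- 0
  acc$n <- 0L
  enum_ok <- tryCatch({
    hwe_enumerate(m, max_tables, function(lp) {
      acc$n <- acc$n + 1L
      acc$total <- acc$total + exp(lp)
      if (lp <= obs + tol) acc$psum <- acc$psum + exp(lp)
    })
    TRUE
  }, error = function(e) {
    if (conditionMessage(e) == "ENUM_CAP") FALSE else stop(e)
  })
  if (enum_ok) {
    # normalise against the accumulated total to absorb rounding
    return(new_test_result(min(1, acc$psum / acc$total), "exact-enumeration",
                           n_tables = acc$n, statistic = obs))
  }
  # Monte-Carlo: re-pair the allele multiset uniformly at random
  n <- sum(cnt)
  v <- rep.int(seq_len(k), m)
  # comparable statistic: constants cancel between tables
  stat_of <- function(ii, jj) {
    code <- (pmin(ii, jj) - 1L) * k + pmax(ii, jj)
    cc <- tabulate(code, k * k)
    het <- n - sum(cc[(seq_len(k) - 1L) * k + seq_len(k)])
    het * log(2) - sum(lgamma(cc[cc > 0L] + 1))
  }
  het_obs <- n - sum(diag(cnt))
  stat_obs <- het_obs * log(2) -
    sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1))
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(mc_draws)) {
      perm <- v[sample.int(2L * n)]
      ii <- perm[seq(1L, 2L * n, by = 2L)]
      jj <- perm[seq(2L, 2L * n, by = 2L)]
      if (stat_of(ii, jj) <= stat_obs + tol) h <- h + 1L
    }
    h
  })
  p <- hits / mc_draws
  new_test_result(p, "monte-carlo", se = sqrt(p * (1 - p) / mc_draws),
                  seed = seed, draws = as.integer(mc_draws),
                  statistic = stat_obs)
}

# --- generic R x C conditional exact test ---------------------------------

rxc_log_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

rxc_enumerate <- function(rs, cs, max_tables, visit) {
  r <- length(rs)
  k <- length(cs)
  tab <- matrix(0L, r, k)
  n_seen <- 0L
  recurse <- function(i, colrem) {
    if (i == r) {
      if (any(colrem < 0L)) return(invisible(NULL))
      tab[r, ] <<- colrem
      n_seen <<- n_seen + 1L
      if (n_seen > max_tables) stop("ENUM_CAP", call. = FALSE)
      visit(rxc_log_prob(tab))
      return(invisible(NULL))
    }
    fill <- function(j, left) {
      if (j == k) {
        if (left <= colrem[k]) {
          tab[i, k] <<- left
          colrem[k] <<- colrem[k] - left
          recurse(i + 1L, colrem)
          colrem[k] <<- colrem[k] + left
          tab[i, k] <<- 0L
        }
        return(invisible(NULL))
      }
      for (v in 0:min(left, colrem[j])) {
        tab[i, j] <<- v
        colrem[j] <<- colrem[j] - v
        fill(j + 1L, left - v)
        colrem[j] <<- colrem[j] + v
        tab[i, j] <<- 0L
      }
    }
    fill(1L, rs[i])
  }
  recurse(1L, cs)
  invisible(NULL)
}

rxc_exact_test <- function(tab, max_tables = 2e5, mc_draws = 1e5,
                           seed = NULL) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  tab <- tab[rowSums(tab) > 0L, colSums(tab) > 0L, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(new_test_result(1.0, "degenerate", degenerate = TRUE))
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  obs <- rxc_log_prob(tab)
  tol <- 1e-9
  acc <- new.env(parent = emptyenv())
  acc$psum <- 0
  acc$total <- 0
  acc$n <- 0L
  enum_ok <- tryCatch({
    rxc_enumerate(rs, cs, max_tables, function(lp) {
      acc$n <- acc$n + 1L
      acc$total <- acc$total + exp(lp)
      if (lp <= obs + tol) acc$psum <- acc$psum + exp(lp)
    })
    TRUE
  }, error = function(e) {
    if (conditionMessage(e) == "ENUM_CAP") FALSE else stop(e)
  })
  if (enum_ok) {
    return(new_test_result(min(1, acc$psum / acc$total), "exact-enumeration",
                           n_tables = acc$n, statistic = obs))
  }
  stat_obs <- -sum(lgamma(tab + 1))
  hits <- with_seed(seed, {
    draws <- stats::r2dtable(mc_draws, rs, cs)
    sum(vapply(draws, function(d) -sum(lgamma(d + 1)), 0) <= stat_obs + tol)
  })
  p <- hits / mc_draws
  new_test_result(p, "monte-carlo", se = sqrt(p * (1 - p) / mc_draws),
                  seed = seed, draws = as.integer(mc_draws),
                  statistic = stat_obs)
}

#' Exact test of linkage disequilibrium between two loci in males
#'
#' Males are hemizygous, so each male contributes one fully phased two-locus
#' gamete. Independence of the two loci is tested on the allele-by-allele
#' contingency table with the conditional exact test (Fisher's test
#' generalised to R x C; Monte-Carlo tables are drawn with fixed margins via
#' Patefield's algorithm for large problems).
#'
#' @param a,b allele vectors at the two loci, one entry per male (`NA`
#'   allowed; incomplete pairs are dropped).
#' @inheritParams hwe_exact_test
#' @return An `xstr_test` result. Monomorphic input gives `p = 1` flagged
#'   degenerate.
#' @export
ld_exact_test_males <- function(a, b, max_tables = 2e5, mc_draws = 1e5,
                                seed = NULL) {
  keep <- !(is.na(a) | is.na(b))
  a <- as.character(a)[keep]
  b <- as.character(b)[keep]
  if (length(a) == 0L) stop("no complete male two-locus observations",
                            call. = FALSE)
  tab <- base::table(a, b)
  rxc_exact_test(tab, max_tables = max_tables, mc_draws = mc_draws,
                 seed = seed)
}

#' Exact test of population differentiation from allele counts
#'
#' Raymond-Rousset style exact test on the alleles x populations contingency
#' table: conditional on margins, p is the total probability of tables no
#' more probable than the observed one.
#'
#' @param counts1,counts2 named chromosome counts per allele for the two
#'   populations.
#' @inheritParams hwe_exact_test
#' @return An `xstr_test` result.
#' @export
exact_population_differentiation <- function(counts1, counts2,
                                             max_tables = 2e5,
                                             mc_draws = 1e5, seed = NULL) {
  if (length(counts1) == 0L || sum(counts1) == 0 ||
      length(counts2) == 0L || sum(counts2) == 0) {
    stop("both populations need at least one chromosome", call. = FALSE)
  }
  alleles <- order_labels(unique(c(names(counts1), names(counts2))))
  tab <- cbind(pop1 = as.integer(counts1[alleles]),
               pop2 = as.integer(counts2[alleles]))
  tab[is.na(tab)] <- 0L
  rownames(tab) <- alleles
  rxc_exact_test(tab, max_tables = max_tables, mc_draws = mc_draws,
                 seed = seed)
}

#' Bonferroni correction
#'
#' Flags `p < alpha / m` (strictly): a p-value exactly at the adjusted
#' threshold is not significant.
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @param m number of tests in the family (defaults to `length(p)`).
#' @return list with `threshold` (`alpha/m`), logical `significant`, `alpha`
#'   and `m`.
#' @examples
#' bonferroni(0.0027, alpha = 0.05, m = 12)
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  thr <- alpha / m
  list(threshold = thr, significant = p < thr, alpha = alpha, m = m)
}
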