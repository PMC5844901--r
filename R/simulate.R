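#' @name synthetic_data
#' @title Synthetic X-STR data with known ground truth
#'
#' @description
#' Generators emulating the sampling design of a two-population X-STR study:
#' hemizygous males and diploid females typed at 12 microsatellites, with
#' controllable Hardy-Weinberg distortion, linkage-group haplotype structure
#' and Balding-Nichols divergence at a target Fst. Every generator is a pure
#' function of its parameters and seed.
NULL

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))  # pathological tiny alpha
  g / sum(g)
}

#' Simulate an allele frequency vector
#'
#' Symmetric Dirichlet draw over `k` alleles labelled like STR repeat numbers
#' (consecutive integers starting at 8, the common Argus X-12 range).
#'
#' @param k number of alleles (>= 1).
#' @param concentration Dirichlet concentration per allele (1 = uniform over
#'   the simplex).
#' @param seed RNG seed.
#' @return Named frequency vector summing to 1.
#' @export
simulate_frequencies <- function(k, concentration = 1, seed) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  labels <- as.character(seq(8L, length.out = k))
  if (k == 1L) return(stats::setNames(1, labels))
  p <- with_seed(seed, rdirichlet1(rep(concentration, k)))
  stats::setNames(p, labels)
}

sample_allele <- function(p, n) {
  names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Simulate one population of X-STR genotypes
#'
#' Males draw one allele per locus from the locus frequencies. Females draw
#' genotypes from the inbreeding-distorted HWE model: homozygote `i/i` with
#' probability \eqn{p_i^2 + F p_i (1 - p_i)}, heterozygote `i/j` with
#' probability \eqn{(1 - F) 2 p_i p_j}. `F = 0` is exact HWE.
#'
#' @param freqs named list of per-locus frequency vectors (names = loci).
#' @param n_m,n_f numbers of males and females.
#' @param f_is inbreeding-like distortion parameter in `[0, 1]`.
#' @param seed RNG seed.
#' @param population population label.
#' @return A [genotype_table()].
#' @export
simulate_population <- function(freqs, n_m, n_f, f_is = 0, seed,
                                population = "pop1") {
  if (f_is < 0 || f_is > 1) stop("f_is must lie in [0, 1]", call. = FALSE)
  stopifnot(is.list(freqs), !is.null(names(freqs)))
  with_seed(seed, simulate_population_impl(freqs, n_m, n_f, f_is, population))
}

simulate_population_impl <- function(freqs, n_m, n_f, f_is, population,
                                     id_prefix = population) {
  locs <- names(freqs)
  n <- n_m + n_f
  df <- data.frame(
    sample_id = sprintf("%s_%04d", id_prefix, seq_len(max(n, 0))),
    sex = rep(c("M", "F"), c(n_m, n_f)),
    population = rep(population, n))
  for (l in locs) {
    p <- freqs[[l]]
    cells <- character(n)
    if (n_m > 0) cells[seq_len(n_m)] <- sample_allele(p, n_m)
    if (n_f > 0) {
      a1 <- sample_allele(p, n_f)
      inbred <- stats::runif(n_f) < f_is
      a2 <- ifelse(inbred, a1, sample_allele(p, n_f))
      cells[n_m + seq_len(n_f)] <- mapply(function(x, y) {
        paste(sort_alleles(c(x, y)), collapse = "/")
      }, a1, a2)
    }
    df[[l]] <- cells
  }
  genotype_table(df, locs)
}

#' Simulate males with linked loci from haplotype frequencies
#'
#' Each male draws one whole haplotype (an allele tuple over the group's
#' loci), so marginal locus frequencies equal the haplotype-implied margins
#' in expectation and the specified linkage disequilibrium is exact.
#'
#' @param haplotypes data.frame: one column per locus (allele labels) plus a
#'   `frequency` column summing to 1.
#' @param n_m number of males.
#' @param seed RNG seed.
#' @param population population label.
#' @return A [genotype_table()] of males over the haplotype's loci.
#' @export
simulate_linked_males <- function(haplotypes, n_m, seed,
                                  population = "pop1") {
  stopifnot(is.data.frame(haplotypes), "frequency" %in% names(haplotypes),
            nrow(haplotypes) > 0)
  locs <- setdiff(names(haplotypes), "frequency")
  if (abs(sum(haplotypes$frequency) - 1) > 1e-8) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(haplotypes), n_m, replace = TRUE,
                                    prob = haplotypes$frequency))
  df <- data.frame(
    sample_id = sprintf("%s_%04d", population, seq_len(n_m)),
    sex = rep("M", n_m), population = rep(population, n_m))
  for (l in locs) df[[l]] <- as.character(haplotypes[[l]][idx])
  genotype_table(df, locs)
}

#' Simulate populations diverged at a target Fst
#'
#' Balding-Nichols model: each population's frequency vector at each locus is
#' a Dirichlet draw with parameters \eqn{p_i (1 - F_{st}) / F_{st}} around the
#' ancestral frequencies, giving expected differentiation equal to the target;
#' `fst = 0` copies the ancestral frequencies unchanged. Individuals are then
#' sampled as in [simulate_population()].
#'
#' @param freqs named list of ancestral per-locus frequency vectors.
#' @param fst target divergence in `[0, 1)`.
#' @param n_pops number of populations.
#' @param n_m,n_f per-population sample sizes (recycled).
#' @param seed RNG seed.
#' @param f_is within-population HWE distortion.
#' @return A [genotype_table()] with populations `pop1..popN`.
#' @export
simulate_divergent_populations <- function(freqs, fst, n_pops, n_m, n_f,
                                           seed, f_is = 0) {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  n_m <- rep_len(n_m, n_pops)
  n_f <- rep_len(n_f, n_pops)
  with_seed(seed, {
    tabs <- lapply(seq_len(n_pops), function(k) {
      pf <- if (fst == 0) freqs else lapply(freqs, function(p) {
        stats::setNames(rdirichlet1(p * (1 - fst) / fst), names(p))
      })
      simulate_population_impl(pf, n_m[k], n_f[k], f_is,
                               population = paste0("pop", k))
    })
    df <- do.call(rbind, lapply(tabs, as.data.frame))
    genotype_table(df, loci(tabs[[1]]))
  })
}
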