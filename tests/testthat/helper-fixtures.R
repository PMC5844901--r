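# shared fixtures and independent oracles for the test suite

# random frequency vector on the simplex (uniform Dirichlet)
rand_simplex <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# small canonical genotype table used across io / frequency tests
toy_table <- function() {
  genotype_table(data.frame(
    sample_id = c("m1", "m2", "f1", "f2"),
    sex = c("M", "M", "F", "F"),
    population = c("A", "A", "A", "B"),
    L1 = c("8", "9", "8/9", "9/9"),
    L2 = c("24.1", NA, "24.1/25.1", "24.1/24.1"),
    stringsAsFactors = FALSE))
}

# simulate n female genotype count vectors under HWE at freqs p
sim_female_counts <- function(n, p, labels = names(p)) {
  if (is.null(labels)) labels <- as.character(seq_along(p))
  a1 <- sample(labels, n, TRUE, p)
  a2 <- sample(labels, n, TRUE, p)
  g <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  tab <- table(g)
  stats::setNames(as.integer(tab), names(tab))
}

# --- independent HWE oracle ------------------------------------------------
# Enumerates every perfect matching of the 2n allele copies (all equally
# likely under HWE conditional on allele counts), tallies genotype tables and
# computes the exact p-value as the probability mass of tables no more likely
# than the observed one. Independent of the package's conditional formula.
hwe_matching_oracle <- function(genotype_counts) {
  pairs <- lapply(names(genotype_counts), function(g) {
    a <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(a) == 1L) c(a, a) else a
  })
  alleles <- sort(unique(unlist(pairs)))
  copies <- unlist(mapply(function(pr, cnt) rep(pr, cnt),
                          pairs, genotype_counts, SIMPLIFY = FALSE))
  key_of <- function(v) {
    i <- match(v[seq(1, length(v), 2)], alleles)
    j <- match(v[seq(2, length(v), 2)], alleles)
    paste(sort(paste(pmin(i, j), pmax(i, j))), collapse = "|")
  }
  obs_key <- key_of(copies)
  # explicit enumeration of all (2n-1)!! matchings (fine for 2n <= 10)
  enum <- function(items) {
    if (length(items) == 0L) return(list(character(0)))
    out <- list()
    for (q in 2:length(items)) {
      sub <- enum(items[-c(1, q)])
      for (s in sub) out[[length(out) + 1L]] <- c(items[1], items[q], s)
    }
    out
  }
  matchings <- enum(copies)
  keys <- vapply(matchings, key_of, "")
  tab <- table(keys)
  probs <- as.numeric(tab) / length(matchings)
  names(probs) <- names(tab)
  p_obs <- probs[[obs_key]]
  sum(probs[probs <= p_obs + 1e-12])
}

# empirical rejection rate helper
rejection_rate <- function(p_values, alpha = 0.05) mean(p_values < alpha)
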