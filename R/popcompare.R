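#' Chromosome-level allele count table
#'
#' Builds the long-format count table (population, locus, allele, count) that
#' the between-population statistics operate on. On the X the unit is the
#' chromosome: one per male, two per female.
#'
#' @param table a [genotype_table()].
#' @param sex `"pooled"`, `"M"` or `"F"`.
#' @return data.frame (population, locus, allele, count).
#' @export
count_table <- function(table, sex = c("pooled", "M", "F")) {
  sex <- match.arg(sex)
  ft <- frequency_table(table, sex = sex)
  ft[, c("population", "locus", "allele", "count")]
}

# counts for one locus as an alleles x populations integer matrix
locus_count_matrix <- function(counts, locus) {
  sub <- counts[counts$locus == locus, , drop = FALSE]
  pops <- unique(counts$population)
  alleles <- sort_alleles(unique(sub$allele))
  m <- matrix(0L, length(alleles), length(pops),
              dimnames = list(alleles, pops))
  m[cbind(match(sub$allele, alleles), match(sub$population, pops))] <-
    as.integer(sub$count)
  m
}

# haploid variance components for one locus (alleles x pops count matrix):
# among/within mean squares on allele indicators, Weir-Cockerham style
fst_components <- function(m) {
  n_k <- colSums(m)
  keep <- n_k > 0
  m <- m[, keep, drop = FALSE]
  n_k <- n_k[keep]
  r <- length(n_k)
  if (r < 2) return(c(among = 0, within = 0))
  N <- sum(n_k)
  p_k <- sweep(m, 2, n_k, "/")
  p_bar <- rowSums(m) / N
  msp <- colSums(t((p_k - p_bar)^2) * n_k) / (r - 1)   # per allele, among
  msg <- colSums(t(p_k * (1 - p_k)) * n_k) / (N - r)   # per allele, within
  n_c <- (N - sum(n_k^2) / N) / (r - 1)
  sigma_a <- (msp - msg) / n_c
  c(among = sum(sigma_a), within = sum(msg))
}

#' Pairwise Fst from chromosome-level allele counts
#'
#' Variance-component (AMOVA-style, haploid) estimator. Per locus,
#' \eqn{F_{st} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)} from the among- and
#' within-population components of allele-indicator variance; the multi-locus
#' value pools components over loci before taking the ratio. Negative
#' estimates are reported as computed. The permutation p-value relabels
#' chromosomes between the two populations (realised by resampling each
#' locus table with fixed margins) and is the fraction of replicates with a
#' multi-locus Fst at least the observed one.
#'
#' @param counts count table from [count_table()] (or any data.frame with
#'   columns population, locus, allele, count).
#' @param permutations number of permutation replicates per pair (0 = no
#'   p-values).
#' @param seed RNG seed, required when `permutations > 0`.
#' @return list with `labels`, `per_locus` (pairs x loci matrix),
#'   `multilocus` (symmetric matrix), and when requested `p_values`
#'   (symmetric matrix) and `per_locus_p`.
#' @export
pairwise_fst <- function(counts, permutations = 0, seed = NULL) {
  pops <- unique(counts$population)
  if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
  if (permutations < 0) stop("permutations must be >= 0", call. = FALSE)
  locs <- unique(counts$locus)
  for (pop in pops) {
    if (sum(counts$count[counts$population == pop]) == 0) {
      stop("population '", pop, "' has zero chromosomes", call. = FALSE)
    }
  }
  mats <- lapply(locs, function(l) locus_count_matrix(counts, l))
  names(mats) <- locs
  pair_names <- utils::combn(pops, 2, paste, collapse = " - ")
  pairs <- utils::combn(pops, 2)
  per_locus <- matrix(NA_real_, ncol(pairs), length(locs),
                      dimnames = list(pair_names, locs))
  multi <- matrix(0, length(pops), length(pops),
                  dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, length(pops), length(pops),
                 dimnames = list(pops, pops))
  per_locus_p <- matrix(NA_real_, ncol(pairs), length(locs),
                        dimnames = list(pair_names, locs))
  fst_of <- function(comp_list) {
    a <- sum(vapply(comp_list, `[[`, 0, "among"))
    w <- sum(vapply(comp_list, `[[`, 0, "within"))
    if (a + w == 0) return(0)
    a / (a + w)
  }
  run_pair <- function(p1, p2) {
    sub <- lapply(mats, function(m) m[, c(p1, p2), drop = FALSE])
    comps <- lapply(sub, fst_components)
    per_loc <- vapply(comps, function(cc) {
      if (sum(cc) == 0) 0 else cc[["among"]] / sum(cc)
    }, 0)
    obs <- fst_of(comps)
    res <- list(per_locus = per_loc, multilocus = obs,
                p = NA_real_, per_locus_p = rep(NA_real_, length(sub)))
    if (permutations > 0) {
      perm_multi <- numeric(permutations)
      perm_locus_ge <- rep(0L, length(sub))
      obs_locus <- per_loc
      with_seed(seed, {
        for (b in seq_len(permutations)) {
          comps_b <- lapply(sub, function(m) {
            m2 <- m[rowSums(m) > 0, , drop = FALSE]
            perm <- stats::r2dtable(1, rowSums(m2), colSums(m2))[[1]]
            dimnames(perm) <- dimnames(m2)
            fst_components(perm)
          })
          perm_multi[b] <- fst_of(comps_b)
          loc_b <- vapply(comps_b, function(cc) {
            if (sum(cc) == 0) 0 else cc[["among"]] / sum(cc)
          }, 0)
          perm_locus_ge <- perm_locus_ge + (loc_b >= obs_locus - 1e-12)
        }
      })
      res$p <- mean(perm_multi >= obs - 1e-12)
      res$per_locus_p <- perm_locus_ge / permutations
    }
    res
  }
  for (q in seq_len(ncol(pairs))) {
    p1 <- pairs[1, q]
    p2 <- pairs[2, q]
    r <- run_pair(p1, p2)
    per_locus[q, ] <- r$per_locus
    multi[p1, p2] <- multi[p2, p1] <- r$multilocus
    pmat[p1, p2] <- pmat[p2, p1] <- r$p
    per_locus_p[q, ] <- r$per_locus_p
  }
  out <- list(labels = pops, per_locus = per_locus, multilocus = multi)
  if (permutations > 0) {
    out$p_values <- pmat
    out$per_locus_p <- per_locus_p
  }
  out
}

#' Export a pairwise-Fst result as a distance matrix
#'
#' @param fst result of [pairwise_fst()].
#' @param mode `"multilocus"` (variance-component ratio pooled over loci) or
#'   `"locus_mean"` (arithmetic mean of per-locus Fst values).
#' @param floor_negative set negative entries to 0 (required for UPGMA input).
#' @return Labelled symmetric matrix.
#' @export
fst_distance_matrix <- function(fst, mode = c("multilocus", "locus_mean"),
                                floor_negative = TRUE) {
  mode <- match.arg(mode)
  if (mode == "multilocus") {
    m <- fst$multilocus
  } else {
    pops <- fst$labels
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    pairs <- utils::combn(pops, 2)
    means <- rowMeans(fst$per_locus)
    for (q in seq_len(ncol(pairs))) {
      m[pairs[1, q], pairs[2, q]] <- m[pairs[2, q], pairs[1, q]] <- means[q]
    }
  }
  if (floor_negative) m[m < 0] <- 0
  as_distance_matrix(m)
}

#' Per-locus significance of pairwise differentiation
#'
#' @param fst result of [pairwise_fst()] run with permutations.
#' @param alpha significance level.
#' @param mode `"raw"` compares each p to `alpha`; `"bonferroni"` applies
#'   [bonferroni()] per pair across loci.
#' @return list with logical `flags` (pairs x loci) and integer
#'   `n_significant` per pair.
#' @export
fst_significance_matrix <- function(fst, alpha = 0.05,
                                    mode = c("raw", "bonferroni")) {
  mode <- match.arg(mode)
  if (is.null(fst$per_locus_p)) {
    stop("run pairwise_fst() with permutations > 0 first", call. = FALSE)
  }
  pm <- fst$per_locus_p
  flags <- if (mode == "raw") {
    pm < alpha
  } else {
    t(apply(pm, 1, function(p) bonferroni(p, alpha = alpha)$significant))
  }
  dimnames(flags) <- dimnames(pm)
  list(flags = flags, n_significant = rowSums(flags))
}

#' Nei's (unbiased) genetic distance
#'
#' \eqn{D = -\ln\left(\bar J_{xy} / \sqrt{\bar J_x \bar J_y}\right)} where the
#' bars are arithmetic means over loci of the gene identities
#' \eqn{J_x = \sum_i p_{xi}^2}, \eqn{J_{xy} = \sum_i p_{xi} p_{yi}}. With
#' `unbiased = TRUE` (Nei 1978) the within-population identities use the
#' haploid small-sample correction \eqn{(n \sum p^2 - 1)/(n - 1)}, which can
#' make small distances slightly negative; such values are preserved.
#'
#' @param freqs_x,freqs_y named lists (per locus) of named frequency vectors.
#' @param n_x,n_y chromosome sample sizes per locus (single number or vector
#'   named by locus); required when `unbiased = TRUE`.
#' @param unbiased apply the small-sample correction.
#' @return Distance (scalar). Disjoint allele sets at every locus give `Inf`
#'   with attribute `degenerate = TRUE`.
#' @examples
#' nei_unbiased_distance(list(L = c(a = 0.9, b = 0.1)),
#'                       list(L = c(a = 0.1, b = 0.9)), unbiased = FALSE)
#' @export
nei_unbiased_distance <- function(freqs_x, freqs_y, n_x = NULL, n_y = NULL,
                                  unbiased = TRUE) {
  locs <- intersect(names(freqs_x), names(freqs_y))
  if (length(locs) == 0L) stop("no shared loci", call. = FALSE)
  if (unbiased && (is.null(n_x) || is.null(n_y))) {
    stop("unbiased correction needs sample sizes n_x and n_y", call. = FALSE)
  }
  get_n <- function(n, l) if (length(n) == 1L) n else n[[l]]
  jx <- jy <- jxy <- numeric(length(locs))
  for (i in seq_along(locs)) {
    l <- locs[i]
    px <- freqs_x[[l]]
    py <- freqs_y[[l]]
    alleles <- union(names(px), names(py))
    x <- ifelse(is.na(px[alleles]), 0, px[alleles])
    y <- ifelse(is.na(py[alleles]), 0, py[alleles])
    jx[i] <- sum(x^2)
    jy[i] <- sum(y^2)
    if (unbiased) {
      nx <- get_n(n_x, l)
      ny <- get_n(n_y, l)
      jx[i] <- (nx * jx[i] - 1) / (nx - 1)
      jy[i] <- (ny * jy[i] - 1) / (ny - 1)
    }
    jxy[i] <- sum(x * y)
  }
  jxy_bar <- mean(jxy)
  denom <- sqrt(mean(jx) * mean(jy))
  if (jxy_bar <= 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  -log(jxy_bar / denom)
}

#' Nei distance matrix over populations
#'
#' @param table a [genotype_table()].
#' @param sex which chromosomes to use; male-only is the convention for
#'   haplotype-style comparisons.
#' @param unbiased apply the small-sample correction.
#' @return Labelled symmetric matrix of pairwise distances.
#' @export
nei_distance_matrix <- function(table, sex = c("M", "F", "pooled"),
                                unbiased = TRUE) {
  sex <- match.arg(sex)
  ft <- frequency_table(table, sex = sex)
  pops <- unique(ft$population)
  freqs <- lapply(pops, function(pop) {
    sub <- ft[ft$population == pop, ]
    out <- lapply(split(sub, sub$locus), function(d) {
      stats::setNames(d$frequency, d$allele)
    })
    attr(out, "n") <- vapply(split(sub, sub$locus),
                             function(d) d$n_chrom[1], 0)
    out
  })
  names(freqs) <- pops
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (j <= i) next
      d <- nei_unbiased_distance(freqs[[i]], freqs[[j]],
                                 n_x = attr(freqs[[i]], "n"),
                                 n_y = attr(freqs[[j]], "n"),
                                 unbiased = unbiased)
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}
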