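#' Power sums of an allele frequency vector
#'
#' All closed-form forensic statistics are polynomials in the power sums
#' \eqn{S_k = \sum_i p_i^k}; S5 is needed by the classical trio exclusion
#' formula.
#'
#' @param p numeric frequency vector summing to 1.
#' @return list with `S2`, `S3`, `S4`, `S5`.
#' @export
power_sums <- function(p) {
  p <- check_freqs(p)
  list(S2 = sum(p^2), S3 = sum(p^3), S4 = sum(p^4), S5 = sum(p^5))
}

check_freqs <- function(p, tol = 1e-6) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("empty frequency vector", call. = FALSE)
  if (any(p < 0)) stop("negative allele frequency", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop("allele frequencies sum to ", format(sum(p)), ", not 1",
         call. = FALSE)
  }
  p
}

#' Per-locus forensic efficiency parameters
#'
#' The standard X-STR battery computed from (pooled) allele frequencies, in
#' the conventions of the ChrX reporting tools. With \eqn{S_k = \sum p_i^k}:
#' \itemize{
#'   \item `HOM` \eqn{= S_2}, `HET` \eqn{= 1 - S_2} (expected homo- and
#'     heterozygosity);
#'   \item `PIC` \eqn{= 1 - S_2 - S_2^2 + S_4};
#'   \item `PD_M` \eqn{= 1 - S_2} (two random males differ),
#'     `PD_F` \eqn{= 1 - 2S_2^2 + S_4} (two random females differ under HWE);
#'   \item `PE` \eqn{= HET^2 (1 - 2\,HET\,HOM^2)} (PowerStats power of
#'     exclusion);
#'   \item `PI` \eqn{= HOM / 2} (mean paternity index convention of the ChrX
#'     tool);
#'   \item `MEC_Kruger`: classical autosomal-trio mean exclusion chance,
#'     \eqn{1 - 2S_2 + S_3 - 2(S_2^2 - S_4) + 3(S_2 S_3 - S_5)};
#'   \item `MEC_Kishida`, `MEC_Desmarais`: mean exclusion chance in X trios
#'     involving a daughter; analytically both equal PIC. `MEC_Desmarais` uses
#'     the PIC power-sum form; `MEC_Kishida` is evaluated by explicit
#'     enumeration of mother/daughter configurations (a distinct route to the
#'     same quantity);
#'   \item `MEC_Desmarais_Duo` \eqn{= 1 - 2S_2 + S_3 = \sum p_i (1-p_i)^2}
#'     (father-daughter or mother-son duos).
#' }
#'
#' @param p allele frequency vector (must sum to 1 within 1e-6; all entries
#'   nonnegative). A single-allele locus yields zero discrimination/exclusion
#'   power and `PI = 0.5`.
#' @return Named list of class `forensic_profile`.
#' @examples
#' forensic_profile(c(0.5, 0.5))
#' @export
forensic_profile <- function(p) {
  p <- check_freqs(p)
  s <- power_sums(p)
  hom <- s$S2
  het <- 1 - s$S2
  pic <- 1 - s$S2 - s$S2^2 + s$S4
  pd_f <- 1 - 2 * s$S2^2 + s$S4
  pe <- het^2 * (1 - 2 * het * hom^2)
  kruger <- 1 - 2 * s$S2 + s$S3 - 2 * (s$S2^2 - s$S4) +
    3 * (s$S2 * s$S3 - s$S5)
  duo <- 1 - 2 * s$S2 + s$S3
  structure(list(
    PIC = pic, HOM = hom, HET = het, PE = pe, PI = hom / 2,
    PD_F = pd_f, PD_M = het,
    MEC_Kruger = kruger,
    MEC_Kishida = mec_trio_x_enum(p),
    MEC_Desmarais = pic,
    MEC_Desmarais_Duo = duo
  ), class = "forensic_profile")
}

# X-trio (mother, daughter, alleged father) mean exclusion chance by explicit
# enumeration over mother genotype, transmitted allele and paternal allele.
# P(not excluded) = S2^2 + S2 - S4, so the value equals PIC; kept as an
# independent evaluation path.
mec_trio_x_enum <- function(p) {
  k <- length(p)
  not_excl <- 0
  for (a in seq_len(k)) {
    # mother homozygous aa, transmits a; father f
    for (f in seq_len(k)) {
      oblig <- if (f == a) p[a] else p[f]
      not_excl <- not_excl + p[a]^2 * p[f] * oblig
    }
  }
  if (k > 1) {
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (b == a) next
        # mother ab transmits a (prob p[a]p[b] for the ordered pick)
        for (f in seq_len(k)) {
          oblig <- if (f == a) p[a] else if (f == b) p[a] + p[b] else p[f]
          not_excl <- not_excl + p[a] * p[b] * p[f] * oblig
        }
      }
    }
  }
  1 - not_excl
}

#' @export
print.forensic_profile <- function(x, ...) {
  vals <- unlist(x)
  cat(paste(sprintf("%-18s %.4f", names(vals), round_half_up(vals, 4)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Combined multi-locus forensic parameters
#'
#' For independent loci the combined power of a battery is
#' \eqn{1 - \prod_l (1 - x_l)}; computed in log space via `log1p`/`expm1` so
#' values like 0.9999999999 keep their trailing digits.
#'
#' @param x numeric vector of per-locus values in `[0, 1]`.
#' @return The combined value.
#' @examples
#' combined_parameters(c(0.9, 0.9))
#' @export
combined_parameters <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("at least one locus required", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("per-locus values must lie in [0, 1]",
                               call. = FALSE)
  -expm1(sum(log1p(-x)))
}

#' Table of forensic profiles across loci
#'
#' @param freqs named list of per-locus frequency vectors.
#' @return data.frame with one row per locus, columns in the conventional
#'   report order, plus a `combined` attribute holding cPD_F, cPD_M, cMEC_T
#'   (trio, Desmarais) and cMEC_D (duo).
#' @export
forensic_report <- function(freqs) {
  stopifnot(is.list(freqs), length(freqs) > 0)
  rows <- lapply(freqs, function(p) as.data.frame(unclass(forensic_profile(p))))
  out <- cbind(data.frame(locus = names(freqs)), do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "combined") <- c(
    cPD_F = combined_parameters(out$PD_F),
    cPD_M = combined_parameters(out$PD_M),
    cMEC_T = combined_parameters(out$MEC_Desmarais),
    cMEC_D = combined_parameters(out$MEC_Desmarais_Duo))
  out
}

# --- Monte-Carlo exclusion oracles ----------------------------------------

#' Monte-Carlo paternity exclusion simulations
#'
#' Direct simulations of the exclusion scenarios behind the closed forms, used
#' to validate them independently. All draw parents and unrelated candidates
#' from HWE at the given allele frequencies and return the exclusion rate with
#' its binomial standard error.
#'
#' `mc_exclusion_duo_x()`: father-daughter duo on the X; a random (hemizygous)
#' man is excluded when his allele is absent from the daughter's genotype.
#' Exact value: `MEC_Desmarais_Duo`.
#'
#' `mc_exclusion_trio_x()`: mother-daughter-alleged-father trio on the X; the
#' obligate paternal allele set is deduced from mother and daughter, and a
#' random man is excluded when his single allele is not in it. Exact value:
#' `MEC_Desmarais` (= PIC).
#'
#' `mc_exclusion_trio_autosomal()`: classical autosomal trio
#' (mother/child/alleged father all diploid); a random man is excluded when he
#' carries no allele from the obligate paternal set. Exact value:
#' `MEC_Kruger`.
#'
#' @param p allele frequency vector.
#' @param n number of simulated cases.
#' @param seed RNG seed (required).
#' @return list with `rate`, `se`, `n`.
#' @export
mc_exclusion_duo_x <- function(p, n = 1e5, seed) {
  p <- check_freqs(p)
  k <- length(p)
  with_seed(seed, {
    d1 <- sample.int(k, n, replace = TRUE, prob = p)
    d2 <- sample.int(k, n, replace = TRUE, prob = p)
    x <- sample.int(k, n, replace = TRUE, prob = p)
    excl <- x != d1 & x != d2
    list(rate = mean(excl), se = stats::sd(excl) / sqrt(n), n = n)
  })
}

#' @rdname mc_exclusion_duo_x
#' @export
mc_exclusion_trio_x <- function(p, n = 1e5, seed) {
  p <- check_freqs(p)
  k <- length(p)
  with_seed(seed, {
    m1 <- sample.int(k, n, replace = TRUE, prob = p)
    m2 <- sample.int(k, n, replace = TRUE, prob = p)
    f <- sample.int(k, n, replace = TRUE, prob = p)   # true paternal allele
    tr <- ifelse(stats::runif(n) < 0.5, m1, m2)       # transmitted maternal
    x <- sample.int(k, n, replace = TRUE, prob = p)   # random man
    # daughter is (tr, f); obligate paternal set:
    homo <- tr == f
    mother_has_f <- f == m1 | f == m2
    compatible <- ifelse(homo, x == f,
                         ifelse(mother_has_f, x == f | x == tr, x == f))
    excl <- !compatible
    list(rate = mean(excl), se = stats::sd(excl) / sqrt(n), n = n)
  })
}

#' @rdname mc_exclusion_duo_x
#' @export
mc_exclusion_trio_autosomal <- function(p, n = 1e5, seed) {
  p <- check_freqs(p)
  k <- length(p)
  with_seed(seed, {
    m1 <- sample.int(k, n, replace = TRUE, prob = p)
    m2 <- sample.int(k, n, replace = TRUE, prob = p)
    f1 <- sample.int(k, n, replace = TRUE, prob = p)
    f2 <- sample.int(k, n, replace = TRUE, prob = p)
    cm <- ifelse(stats::runif(n) < 0.5, m1, m2)
    cf <- ifelse(stats::runif(n) < 0.5, f1, f2)
    x1 <- sample.int(k, n, replace = TRUE, prob = p)
    x2 <- sample.int(k, n, replace = TRUE, prob = p)
    # obligate paternal set: child allele a is a candidate iff the other
    # child allele is carried by the mother
    cf_candidate <- cm == m1 | cm == m2        # always TRUE by construction
    cm_candidate <- cf == m1 | cf == m2        # cm possible paternal iff
                                               # mother also carries cf
    man_has_cf <- x1 == cf | x2 == cf
    man_has_cm <- x1 == cm | x2 == cm
    compatible <- (cf_candidate & man_has_cf) |
      (cm_candidate & man_has_cm)
    excl <- !compatible
    list(rate = mean(excl), se = stats::sd(excl) / sqrt(n), n = n)
  })
}
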