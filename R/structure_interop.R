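#' Integer recoding of STR alleles for STRUCTURE export
#'
#' STRUCTURE wants integer alleles. Microvariants are mapped to
#' `10 * repeat + fractional digit` (so `"24.1"` becomes 241 and `"24"`
#' becomes 240), which keeps the numeric ordering of the labels.
#'
#' @param alleles character vector of allele labels.
#' @return Named integer vector (names are the labels).
#' @export
structure_recode_map <- function(alleles) {
  alleles <- sort_alleles(unique(as.character(alleles)))
  key <- allele_key(alleles)
  code <- as.integer(round(key * 10))
  if (anyDuplicated(code)) {
    stop("allele labels collide after integer recoding: ",
         paste(alleles[duplicated(code) | duplicated(code, fromLast = TRUE)],
               collapse = ", "), call. = FALSE)
  }
  stats::setNames(code, alleles)
}

#' Export a genotype table in STRUCTURE input format
#'
#' Two lines per individual, one allele per locus per line. Females place one
#' allele on each line; males (hemizygous) carry their allele on the first
#' line and the missing code on the second — the conventional coding for
#' mixed-ploidy X data. Populations are recoded to consecutive integers. The
#' allele recode map is written alongside as `<path>.map` (tab-separated:
#' locus, allele, code).
#'
#' @param table a [genotype_table()].
#' @param path output file; the map goes to `paste0(path, ".map")`.
#' @param missing_code integer code for missing alleles (default -9).
#' @return Invisibly, a list with `path`, `map` (data.frame) and
#'   `populations` (label -> integer).
#' @export
export_structure_input <- function(table, path, missing_code = -9L) {
  stopifnot(is_genotype_table(table))
  locs <- loci(table)
  maps <- lapply(locs, function(l) {
    alleles <- unlist(lapply(table[[l]], cell_alleles), use.names = FALSE)
    if (length(alleles) == 0L) return(stats::setNames(integer(0),
                                                      character(0)))
    structure_recode_map(alleles)
  })
  names(maps) <- locs
  pops <- stats::setNames(seq_along(unique(table$population)),
                          unique(table$population))
  lines <- character(2L * nrow(table))
  for (i in seq_len(nrow(table))) {
    row1 <- integer(length(locs))
    row2 <- integer(length(locs))
    for (q in seq_along(locs)) {
      a <- cell_alleles(table[[locs[q]]][i])
      if (length(a) == 0L) {
        row1[q] <- row2[q] <- missing_code
      } else {
        codes <- maps[[locs[q]]][a]
        if (anyNA(codes)) stop("unmappable allele at sample '",
                               table$sample_id[i], "', locus ", locs[q],
                               call. = FALSE)
        row1[q] <- codes[1]
        row2[q] <- if (length(codes) == 2L) codes[2] else missing_code
      }
    }
    lab <- table$sample_id[i]
    popi <- pops[[table$population[i]]]
    lines[2L * i - 1L] <- paste(c(lab, popi, row1), collapse = " ")
    lines[2L * i] <- paste(c(lab, popi, row2), collapse = " ")
  }
  header <- paste(locs, collapse = " ")
  writeLines(c(header, lines), path)
  map_df <- do.call(rbind, lapply(locs, function(l) {
    if (length(maps[[l]]) == 0L) return(NULL)
    data.frame(locus = l, allele = names(maps[[l]]),
               code = as.integer(maps[[l]]))
  }))
  utils::write.table(map_df, paste0(path, ".map"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(path = path, map = map_df, populations = pops))
}

#' Re-import a STRUCTURE file written by [export_structure_input()]
#'
#' Round-trip helper (mainly for validation): reconstructs chromosome-level
#' allele counts per locus and population from the exported text.
#'
#' @param path file written by [export_structure_input()]; expects the
#'   companion `.map`.
#' @param missing_code the code used for missing alleles.
#' @return data.frame (population, locus, allele, count) comparable with
#'   [count_table()] output (population labels are the exported integers).
#' @export
read_structure_counts <- function(path, missing_code = -9L) {
  lines <- readLines(path)
  locs <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  map <- utils::read.table(paste0(path, ".map"), header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer"))
  rows <- strsplit(lines[-1], " ", fixed = TRUE)
  out <- list()
  for (r in rows) {
    pop <- r[2]
    codes <- as.integer(r[-(1:2)])
    for (q in seq_along(locs)) {
      if (codes[q] == missing_code) next
      hit <- map$allele[map$locus == locs[q] & map$code == codes[q]]
      out[[length(out) + 1L]] <- data.frame(population = pop,
                                            locus = locs[q], allele = hit)
    }
  }
  long <- do.call(rbind, out)
  agg <- stats::aggregate(list(count = rep(1L, nrow(long))),
                          long[, c("population", "locus", "allele")], sum)
  agg[order(agg$population, agg$locus, allele_key(agg$allele)), ]
}

#' Evanno delta-K from STRUCTURE log-likelihoods
#'
#' Given replicate log-likelihoods L(K) for consecutive K, computes the mean
#' and sd per K, the first difference L'(K) = mean L(K) - mean L(K-1), the
#' absolute second difference |L''(K)| = |mean L(K+1) - 2 mean L(K) +
#' mean L(K-1)| and Evanno's \eqn{\Delta K = |L''(K)| / sd(L(K))}, defined for
#' interior K with positive sd. The most supported K is the argmax of
#' \eqn{\Delta K}.
#'
#' @param runs named list: names are K values, elements numeric vectors of
#'   replicate log-likelihoods.
#' @return data.frame (K, reps, mean_L, sd_L, L1, abs_L2, delta_K) with
#'   attribute `best_K`.
#' @examples
#' evanno_delta_k(list(`1` = -500, `2` = c(-399, -401), `3` = -380,
#'                     `4` = -375))
#' @export
evanno_delta_k <- function(runs) {
  ks <- as.integer(names(runs))
  if (anyNA(ks)) stop("names of `runs` must be integer K values",
                      call. = FALSE)
  o <- order(ks)
  ks <- ks[o]
  runs <- runs[o]
  if (length(ks) < 3L || any(diff(ks) != 1L)) {
    stop("need >= 3 consecutive K values", call. = FALSE)
  }
  mean_l <- vapply(runs, mean, 0)
  sd_l <- vapply(runs, function(x) if (length(x) > 1) stats::sd(x) else NA, 0)
  reps <- vapply(runs, length, 0L)
  nk <- length(ks)
  l1 <- c(NA, diff(mean_l))
  abs_l2 <- rep(NA_real_, nk)
  delta <- rep(NA_real_, nk)
  for (i in 2:(nk - 1L)) {
    abs_l2[i] <- abs(mean_l[i + 1L] - 2 * mean_l[i] + mean_l[i - 1L])
    # delta K needs replicate spread; left NA (flagged) when sd is 0 or
    # unavailable at an interior K
    if (!is.na(sd_l[i]) && sd_l[i] > 0) {
      delta[i] <- abs_l2[i] / sd_l[i]
    }
  }
  out <- data.frame(K = ks, reps = reps, mean_L = mean_l, sd_L = sd_l,
                    L1 = l1, abs_L2 = abs_l2, delta_K = delta,
                    row.names = NULL)
  best <- if (all(is.na(delta))) NA_integer_ else ks[which.max(delta)]
  attr(out, "best_K") <- best
  out
}
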