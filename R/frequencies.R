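#' Allele counting with X-chromosome dosage
#'
#' On the X chromosome each male contributes one chromosome per locus and each
#' female two. Counting is per-locus: an individual missing locus L is dropped
#' from L's counts only (per-locus deletion), so the chromosome total
#' `n_chrom` can differ between loci.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population optional population label filter (`NULL` = all).
#' @param sex `"pooled"` (default), `"M"` or `"F"`.
#' @return Named integer vector of chromosome counts per allele, ordered by
#'   numeric allele key, with attribute `n_chrom` (total chromosomes counted).
#'   An empty selection gives an empty vector with `n_chrom = 0`.
#' @examples
#' tab <- genotype_table(data.frame(
#'   sample_id = c("m1", "f1"), sex = c("M", "F"),
#'   population = "pop", L1 = c("8", "8/9")))
#' allele_counts(tab, "L1")
#' @export
allele_counts <- function(table, locus, population = NULL,
                          sex = c("pooled", "M", "F")) {
  stopifnot(is_genotype_table(table))
  sex <- match.arg(sex)
  if (!locus %in% loci(table)) {
    stop("unknown locus: ", locus, call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  if (!is.null(population)) keep <- keep & table$population %in% population
  if (sex != "pooled") keep <- keep & table$sex == sex
  cells <- table[[locus]][keep]
  alleles <- unlist(lapply(cells, cell_alleles), use.names = FALSE)
  if (length(alleles) == 0L) {
    return(structure(integer(0), n_chrom = 0L))
  }
  tab <- base::table(alleles)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[order(allele_key(names(counts)))]
  structure(counts, n_chrom = sum(counts))
}

#' Allele frequencies from chromosome counts
#'
#' @param counts named count vector as returned by [allele_counts()].
#' @return data.frame with columns `allele`, `count`, `frequency`, ordered by
#'   numeric allele key; frequencies are `count / n_chrom` exactly and sum
#'   to 1.
#' @export
allele_frequencies <- function(counts) {
  n <- sum(counts)
  if (length(counts) == 0L || n == 0) {
    stop("cannot compute frequencies from zero chromosomes", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative allele count", call. = FALSE)
  counts <- counts[order(allele_key(names(counts)))]
  data.frame(allele = names(counts),
             count = as.integer(counts),
             frequency = as.numeric(counts) / n,
             row.names = NULL)
}

#' Long-format allele frequency table
#'
#' Applies [allele_counts()] / [allele_frequencies()] over every locus and
#' population in the table.
#'
#' @inheritParams allele_counts
#' @return data.frame (locus, population, allele, count, frequency, n_chrom).
#' @export
frequency_table <- function(table, sex = c("pooled", "M", "F")) {
  sex <- match.arg(sex)
  pops <- unique(table$population)
  out <- list()
  for (pop in pops) {
    for (l in loci(table)) {
      cnt <- allele_counts(table, l, population = pop, sex = sex)
      if (attr(cnt, "n_chrom") == 0L) next
      fr <- allele_frequencies(cnt)
      out[[length(out) + 1L]] <- cbind(
        data.frame(locus = l, population = pop), fr,
        data.frame(n_chrom = attr(cnt, "n_chrom")))
    }
  }
  do.call(rbind, out) %||% data.frame()
}

#' X-STR linkage groups
#'
#' The 12 Argus X-12 markers cluster into four physically linked triples that
#' are inherited as haplotypes in males: LG1 on Xp22, LG2 on Xq11, LG3 on
#' Xq26 and LG4 on Xq28. The locus order within each group is the conventional
#' haplotype display order.
#'
#' @return Named list of character triples.
#' @export
linkage_groups <- function() {
  list(
    LG1 = c("DXS8378", "DXS10135", "DXS10148"),
    LG2 = c("DXS7132", "DXS10074", "DXS10079"),
    LG3 = c("HPRTB", "DXS10103", "DXS10101"),
    LG4 = c("DXS7423", "DXS10134", "DXS10146")
  )
}

#' Male haplotype counts for a linkage group
#'
#' Males are hemizygous, so their allele triple at a linkage group is an
#' observed haplotype. A male missing any locus of the triple is excluded
#' from that group's sample size.
#'
#' @param table a [genotype_table()] containing only males (any female row is
#'   an error), or a mixed table with `males_only = TRUE` to subset.
#' @param lg character vector of loci defining the group, in display order.
#' @param population optional population filter.
#' @param males_only if `TRUE`, silently drop female rows instead of erroring.
#' @return data.frame (haplotype, count, frequency) sorted by decreasing
#'   count then haplotype label, with attributes `n_males` (males counted)
#'   and `loci`.
#' @export
haplotype_counts <- function(table, lg, population = NULL,
                             males_only = FALSE) {
  stopifnot(is_genotype_table(table))
  if (!all(lg %in% loci(table))) {
    stop("linkage group loci missing from table: ",
         paste(setdiff(lg, loci(table)), collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(table))
  if (!is.null(population)) keep <- keep & table$population %in% population
  sub <- table[keep, , drop = FALSE]
  if (males_only) {
    sub <- sub[sub$sex == "M", , drop = FALSE]
  } else if (any(sub$sex == "F")) {
    stop("haplotype counting requires male rows only; found female sample '",
         sub$sample_id[sub$sex == "F"][1], "'", call. = FALSE)
  }
  cells <- lapply(lg, function(l) sub[[l]])
  complete <- Reduce(`&`, lapply(cells, function(v) {
    !(is.na(v) | v == "" | v == ".")
  })) %||% logical(0)
  n <- sum(complete)
  haps <- if (n > 0) {
    do.call(paste, c(lapply(cells, function(v) v[complete]), list(sep = "-")))
  } else character(0)
  tab <- base::table(haps)
  df <- data.frame(haplotype = names(tab), count = as.integer(tab),
                   row.names = NULL)
  df$frequency <- if (n > 0) df$count / n else numeric(0)
  df <- df[order(-df$count, df$haplotype), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_males = n, loci = lg)
}

#' Haplotype diversity
#'
#' Nei's unbiased gene diversity applied to male haplotypes:
#' \deqn{HD = \frac{n}{n-1}\left(1 - \sum_i \hat p_i^2\right)}
#' where \eqn{\hat p_i} are observed haplotype frequencies among `n` males.
#'
#' @param counts integer vector of haplotype counts, or the data.frame from
#'   [haplotype_counts()].
#' @return list with `HD`, `n`, and `sum_p2` (\eqn{\sum \hat p_i^2}).
#' @examples
#' haplotype_diversity(c(2, 1, 1))
#' @export
haplotype_diversity <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2 observations",
                  call. = FALSE)
  p <- counts / n
  sum_p2 <- sum(p^2)
  hd <- n * (1 - sum_p2) / (n - 1)
  list(HD = hd, n = n, sum_p2 = sum_p2)
}
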