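#' X-STR genotype tables
#'
#' A genotype table holds one row per individual: a unique sample id, sex
#' (`"M"` or `"F"`), a population label, and one column per locus. Males are
#' hemizygous on the X and carry a single allele per locus; females carry an
#' unordered pair. Cells are stored as strings: `"a"` for males, `"a/b"` for
#' females (serialized with the numerically smaller allele first), and `NA`
#' for missing genotypes.
#'
#' @param df data.frame with columns `sample_id`, `sex`, `population` followed
#'   by one character column per locus.
#' @param loci character vector naming the locus columns; defaults to all
#'   columns after the three metadata columns.
#' @return An object of class `genotype_table`: the validated data.frame with
#'   attribute `loci`.
#' @export
genotype_table <- function(df, loci = NULL) {
  meta <- c("sample_id", "sex", "population")
  if (!all(meta %in% names(df))) {
    stop("genotype table needs columns: ", paste(meta, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(loci)) loci <- setdiff(names(df), meta)
  df <- df[, c(meta, loci), drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$sex <- as.character(df$sex)
  df$population <- as.character(df$population)
  for (l in loci) df[[l]] <- as.character(df[[l]])
  validate_genotype_table(df, loci)
  structure(df, loci = loci, class = c("genotype_table", "data.frame"))
}

validate_genotype_table <- function(df, loci) {
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad_sex <- !(df$sex %in% c("M", "F"))
  if (any(bad_sex)) {
    stop("unknown sex code '", df$sex[bad_sex][1], "' for sample '",
         df$sample_id[bad_sex][1], "' (expected M or F)", call. = FALSE)
  }
  for (l in loci) {
    cells <- df[[l]]
    for (i in seq_along(cells)) {
      cell <- cells[i]
      if (is.na(cell) || cell == "" || cell == ".") next
      parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
      if (any(!is_allele_label(parts))) {
        stop("malformed genotype '", cell, "' at sample '", df$sample_id[i],
             "', locus ", l, call. = FALSE)
      }
      n_expect <- if (df$sex[i] == "M") 1L else 2L
      if (length(parts) != n_expect) {
        stop("sample '", df$sample_id[i], "' (sex ", df$sex[i], ") has ",
             length(parts), " allele(s) at locus ", l, "; expected ",
             n_expect, call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' @rdname genotype_table
#' @param x object to test or print.
#' @export
is_genotype_table <- function(x) inherits(x, "genotype_table")

#' Locus names of a genotype table
#' @param table a [genotype_table()].
#' @return Character vector of locus column names.
#' @export
loci <- function(table) attr(table, "loci")

# split a genotype cell into its allele labels (character(0) when missing)
cell_alleles <- function(cell) {
  if (length(cell) != 1L || is.na(cell) || cell == "" || cell == ".") {
    return(character(0))
  }
  strsplit(cell, "/", fixed = TRUE)[[1]]
}

# canonical serialization: female pair ordered by numeric key
canonical_cell <- function(cell) {
  a <- cell_alleles(cell)
  if (length(a) == 0L) return(".")
  paste(sort_alleles(a), collapse = "/")
}

#' Read and write genotype TSV files
#'
#' The on-disk dialect is tab-separated with a header naming `sample_id`,
#' `sex`, `population` and the locus columns. Female cells are `"a/b"`, male
#' cells `"a"`, missing cells `"."`. An amelogenin column (`AMEL` or
#' `Amelogenin`, any case) is dropped with a warning: it is a sex marker, not
#' an STR, and no statistic uses it.
#'
#' @param path file path (or connection) to read from / write to.
#' @param sep field delimiter, tab by default.
#' @return `read_genotype_table()`: a [genotype_table()].
#'   `write_genotype_table()`: the path, invisibly.
#' @export
read_genotype_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "",
                          comment.char = "")
  amel <- grep("^(amel|amelogenin)$", names(df), ignore.case = TRUE)
  if (length(amel)) {
    warning("ignoring amelogenin column(s): ",
            paste(names(df)[amel], collapse = ", "), call. = FALSE)
    df <- df[, -amel, drop = FALSE]
  }
  loci <- setdiff(names(df), c("sample_id", "sex", "population"))
  for (l in loci) df[[l]][df[[l]] %in% c(".", "")] <- NA_character_
  genotype_table(df, loci)
}

#' @rdname read_genotype_table
#' @param table a [genotype_table()].
#' @export
write_genotype_table <- function(table, path, sep = "\t") {
  stopifnot(is_genotype_table(table))
  out <- as.data.frame(table)
  for (l in loci(table)) out[[l]] <- vapply(out[[l]], canonical_cell, "")
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
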