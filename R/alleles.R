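#' STR allele labels
#'
#' X-STR alleles are named by their repeat number, with microvariants carrying
#' a fractional part for incomplete repeats (e.g. `"24.1"` is 24 full repeats
#' plus one extra base). Labels are kept as text so they round-trip unchanged;
#' ordering uses the numeric repeat key.
#'
#' @param x character vector of allele labels.
#' @return `is_allele_label()`: logical vector. `allele_key()`: numeric sort
#'   key (repeat number plus fractional part). `sort_alleles()`: `x` ordered by
#'   numeric key.
#' @examples
#' sort_alleles(c("9", "24.1", "8", "10"))
#' @export
is_allele_label <- function(x) {
  grepl("^[0-9]+(\\.[0-9]+)?$", as.character(x))
}

#' @rdname is_allele_label
#' @export
allele_key <- function(x) {
  x <- as.character(x)
  bad <- !is_allele_label(x)
  if (any(bad)) {
    stop("invalid allele label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  as.numeric(x)
}

#' @rdname is_allele_label
#' @export
sort_alleles <- function(x) {
  x[order(allele_key(x))]
}

# generic ordering: numeric repeat key when every label parses as an STR
# allele, plain lexicographic otherwise (test fixtures may use letters)
order_labels <- function(x) {
  if (all(is_allele_label(x))) x[order(as.numeric(x))] else sort(x)
}
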