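#' Labelled symmetric distance matrices
#'
#' Distances between populations (pairwise Fst, Nei's D) are carried as plain
#' numeric matrices with identical row/column labels, a zero diagonal and
#' symmetry enforced to 1e-8 (tighter asymmetries are averaged away, larger
#' ones rejected).
#'
#' @param m square numeric matrix with dimnames, or a data.frame.
#' @param labels optional label vector overriding dimnames.
#' @return A validated symmetric matrix of class `matrix`.
#' @export
as_distance_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop("distance matrix must be square, got ", nrow(m), "x", ncol(m),
         call. = FALSE)
  }
  mode(m) <- "numeric"
  if (anyNA(m)) stop("distance matrix contains NA/NaN entries", call. = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(m))
    dimnames(m) <- list(labels, labels)
  }
  if (is.null(rownames(m))) {
    stop("distance matrix must carry labels", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    stop("distance matrix asymmetric (max |d_ij - d_ji| = ",
         format(asym), ")", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Read and write distance matrices
#'
#' Two dialects: PHYLIP square (first line the dimension, then one row per
#' label) and labelled CSV (header row of labels, first column labels).
#' `format = "auto"` sniffs PHYLIP by a single leading integer.
#'
#' @param path file path.
#' @param format `"auto"`, `"phylip"` or `"csv"`.
#' @return `read_distance_matrix()`: a labelled symmetric matrix.
#' @export
read_distance_matrix <- function(path, format = c("auto", "phylip", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^\\s*[0-9]+\\s*$", first)) "phylip" else "csv"
  }
  if (format == "phylip") {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    rows <- strsplit(trimws(lines[2:(n + 1L)]), "\\s+")
    labs <- vapply(rows, `[[`, "", 1L)
    m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
    dimnames(m) <- list(labs, labs)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
    m <- as.matrix(df)
    colnames(m) <- rownames(m)
  }
  as_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param m labelled symmetric matrix.
#' @param digits significant digits written.
#' @export
write_distance_matrix <- function(m, path, format = c("phylip", "csv"),
                                  digits = 10L) {
  m <- as_distance_matrix(m)
  format <- match.arg(format)
  if (format == "phylip") {
    rows <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], format(m[i, ], digits = digits, trim = TRUE,
                                     scientific = FALSE)), collapse = "  ")
    }, "")
    writeLines(c(as.character(nrow(m)), rows), path)
  } else {
    df <- as.data.frame(signif(m, digits))
    utils::write.csv(cbind(label = rownames(m), df), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
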