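#' UPGMA clustering of a distance matrix
#'
#' Classic unweighted pair-group method with arithmetic mean: repeatedly join
#' the pair of clusters at minimum distance, placing the new node at height
#' d_min / 2, and update distances to other clusters by the size-weighted
#' arithmetic mean. Ties in the minimum distance are broken by joining the
#' pair whose (sorted) representative labels — the lexicographically smallest
#' leaf label in each cluster — compare smallest, so the output is
#' deterministic and independent of input order.
#'
#' The result is a rooted ultrametric binary tree represented as nested nodes:
#' each node is a list with `label` (leaves only), `height` (0 at leaves) and
#' `children`. Branch lengths are parent height minus child height.
#'
#' @param d labelled symmetric nonnegative matrix (see
#'   [as_distance_matrix()]).
#' @return An object of class `xstr_tree` with elements `root` and `labels`.
#' @examples
#' d <- as_distance_matrix(matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' write_newick(upgma(d))
#' @export
upgma <- function(d) {
  d <- as_distance_matrix(d)
  if (any(d < 0)) stop("UPGMA requires nonnegative distances", call. = FALSE)
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2) stop("UPGMA needs at least two labels", call. = FALSE)
  nodes <- lapply(labs, function(l) list(label = l, height = 0,
                                         children = NULL))
  sizes <- rep(1L, n)
  reps <- labs                      # lexicographically smallest leaf label
  active <- rep(TRUE, n)
  dm <- d
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        dij <- dm[i, j]
        key <- sort(c(reps[i], reps[j]))
        better <- dij < best_d - 1e-15 ||
          (abs(dij - best_d) <= 1e-15 && !is.null(best_key) &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (is.null(best) || better) {
          best <- c(i, j); best_d <- dij; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    # children ordered by representative label so output is canonical
    kids <- if (reps[i] <= reps[j]) list(nodes[[i]], nodes[[j]])
            else list(nodes[[j]], nodes[[i]])
    new_node <- list(label = NULL, height = best_d / 2, children = kids)
    new_size <- sizes[i] + sizes[j]
    # grow the arrays with the merged cluster
    nodes[[length(nodes) + 1L]] <- new_node
    sizes <- c(sizes, new_size)
    reps <- c(reps, min(reps[i], reps[j]))
    active <- c(active, TRUE)
    m <- length(nodes)
    dm <- rbind(cbind(dm, 0), 0)
    for (kk in which(active)) {
      if (kk == m) next
      dm[m, kk] <- dm[kk, m] <-
        (sizes[i] * dm[i, kk] + sizes[j] * dm[j, kk]) / new_size
    }
    active[c(i, j)] <- FALSE
  }
  root <- nodes[[which(active)]]
  structure(list(root = root, labels = labs), class = "xstr_tree")
}

tree_edges <- function(node) {
  if (is.null(node$children)) return(numeric(0))
  unlist(lapply(node$children, function(ch) {
    c(node$height - ch$height, tree_edges(ch))
  }))
}

#' Total branch length of a tree
#'
#' @param tree an `xstr_tree`.
#' @return Sum of all branch lengths (parent height minus child height over
#'   every edge).
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "xstr_tree"))
  sum(tree_edges(tree$root))
}

#' Leaf-pair (cophenetic) distances induced by an ultrametric tree
#'
#' Two leaves are at distance twice the height of their lowest common
#' ancestor.
#'
#' @param tree an `xstr_tree`.
#' @return Labelled symmetric matrix over the tree's leaves.
#' @export
tree_cophenetic <- function(tree) {
  labs <- tree$labels
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  fill <- function(node) {
    if (is.null(node$children)) return(node$label)
    leaf_sets <- lapply(node$children, fill)
    for (a in seq_along(leaf_sets)) {
      for (b in seq_along(leaf_sets)) {
        if (b <= a) next
        m[leaf_sets[[a]], leaf_sets[[b]]] <<- 2 * node$height
        m[leaf_sets[[b]], leaf_sets[[a]]] <<- 2 * node$height
      }
    }
    unlist(leaf_sets)
  }
  fill(tree$root)
  m
}

#' Serialize a tree to Newick text
#'
#' @param tree an `xstr_tree`.
#' @param precision decimal digits for branch lengths (default 6, enough to
#'   round-trip distances on the 1e-8 scale of X-STR Fst trees).
#' @return A Newick string terminated by `";"`.
#' @export
write_newick <- function(tree, precision = 6L) {
  stopifnot(inherits(tree, "xstr_tree"))
  fmt <- function(x) formatC(x, format = "f", digits = precision)
  render <- function(node, parent_height) {
    body <- if (is.null(node$children)) {
      if (is.null(node$label) || !nzchar(node$label)) {
        stop("unnamed leaf in tree", call. = FALSE)
      }
      node$label
    } else {
      paste0("(", paste(vapply(node$children, render, "", node$height),
                        collapse = ","), ")")
    }
    if (is.na(parent_height)) body
    else paste0(body, ":", fmt(parent_height - node$height))
  }
  paste0(render(tree$root, NA_real_), ";")
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower's method: eigendecompose the double-centred matrix
#' \eqn{-\tfrac12 C D^{(2)} C} (with \eqn{C = I - \mathbf{1}\mathbf{1}'/n});
#' coordinates are eigenvectors scaled by the square roots of positive
#' eigenvalues. Distance matrices that are not Euclidean (Fst, Nei D) can
#' produce negative eigenvalues: these are reported but excluded from the
#' percent-variance denominators, GenAlEx-style.
#'
#' @param d labelled symmetric matrix.
#' @param n_axes number of axes to keep (default: all positive-eigenvalue
#'   axes).
#' @return list with `coordinates` (labels x axes), `eigenvalues` (all, in
#'   decreasing order), `percent_variance` (positive axes, sums to 100),
#'   `negative_mass` (sum of negative eigenvalues) and `degenerate` flag for
#'   all-zero input.
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  centre <- diag(n) - matrix(1 / n, n, n)
  b <- centre %*% a %*% centre
  b <- (b + t(b)) / 2
  eg <- eigen(b, symmetric = TRUE)
  ev <- eg$values
  tol <- 1e-9 * max(1, abs(ev[1]))
  pos <- which(ev > tol)
  if (length(pos) == 0L) {
    return(list(coordinates = matrix(0, n, 0, dimnames = list(rownames(d),
                                                              NULL)),
                eigenvalues = ev, percent_variance = numeric(0),
                negative_mass = sum(ev[ev < 0]), degenerate = TRUE))
  }
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes, length(pos)))]
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), length(keep))
  dimnames(coords) <- list(rownames(d), paste0("axis", seq_along(keep)))
  list(coordinates = coords,
       eigenvalues = ev,
       percent_variance = 100 * ev[pos] / sum(ev[pos]),
       negative_mass = sum(ev[ev < tol & ev < 0]),
       degenerate = FALSE)
}
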