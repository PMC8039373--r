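#' Confirmatory Q-matrix
#'
#' A Q-matrix is an item-by-dimension binary matrix whose entry `q[i, k]`
#' indicates that item `i` measures latent dimension `k`. Only between-item
#' multidimensionality is supported: every item loads on exactly one
#' dimension, so each row is one-hot. The same matrix defines both the
#' ability dimensions of the multidimensional Rasch model and the speed
#' factors of the multifactor lognormal response-time model.
#'
#' @param entries numeric or integer matrix of 0/1 loadings, items in rows.
#' @param item_ids optional character vector of item labels (defaults to
#'   rownames or `Item1..ItemI`).
#' @param dim_ids optional character vector of dimension labels (defaults to
#'   colnames or `Dim1..DimK`).
#' @return An object of class `qmatrix`: the binary matrix with label
#'   attributes and a `dim_of_item` attribute mapping each item to its
#'   dimension index.
#' @examples
#' q <- q_matrix(rbind(c(1, 0), c(1, 0), c(0, 1)))
#' dim_of_item(q)
#' @export
q_matrix <- function(entries, item_ids = NULL, dim_ids = NULL) {
  entries <- as.matrix(entries)
  if (!all(entries %in% c(0, 1))) {
    stop("Q-matrix entries must be 0 or 1")
  }
  storage.mode(entries) <- "integer"
  I <- nrow(entries)
  K <- ncol(entries)
  if (I < K) stop("Q-matrix needs at least as many items as dimensions")
  if (K < 1) stop("Q-matrix needs at least one dimension")
  if (!all(rowSums(entries) == 1)) {
    bad <- which(rowSums(entries) != 1)
    stop(
      "between-item multidimensionality requires one-hot rows; offending item(s): ",
      paste(bad, collapse = ", ")
    )
  }
  if (any(colSums(entries) == 0)) {
    stop("every dimension must be measured by at least one item")
  }
  if (is.null(item_ids)) {
    item_ids <- if (!is.null(rownames(entries))) rownames(entries) else paste0("Item", seq_len(I))
  }
  if (is.null(dim_ids)) {
    dim_ids <- if (!is.null(colnames(entries))) colnames(entries) else paste0("Dim", seq_len(K))
  }
  stopifnot(length(item_ids) == I, length(dim_ids) == K)
  dimnames(entries) <- list(item_ids, dim_ids)
  structure(entries,
    dim_of_item = max.col(entries),
    class = c("qmatrix", "matrix", "array")
  )
}

#' Map items to their measured dimension
#'
#' @param q a [q_matrix()].
#' @return Integer vector of length `I` giving, for each item, the index of
#'   the dimension it loads on.
#' @export
dim_of_item <- function(q) {
  stopifnot(inherits(q, "qmatrix"))
  attr(q, "dim_of_item")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(
    "Q-matrix:", nrow(x), "items x", ncol(x),
    "dimensions (between-item)\n"
  )
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Balanced between-item Q-matrix
#'
#' Builds the block-structured Q-matrix used in the simulation design:
#' contiguous blocks of `I / K` items each loading on one dimension
#' (items 1..I/K on dimension 1, the next I/K on dimension 2, and so on).
#'
#' @param I number of items; must be divisible by `K`.
#' @param K number of dimensions.
#' @return A [q_matrix()].
#' @examples
#' build_between_item_q(15, 3)
#' @export
build_between_item_q <- function(I, K) {
  if (I %% K != 0) {
    stop("I = ", I, " is not divisible by K = ", K, "; unsupported design")
  }
  block <- I / K
  entries <- matrix(0L, I, K)
  entries[cbind(seq_len(I), rep(seq_len(K), each = block))] <- 1L
  q_matrix(entries)
}

#' Q-matrix of the PISA 2012 computer-based mathematics items
#'
#' The 9-item, 3-dimension confirmatory structure for the released PISA 2012
#' computer-based mathematics items: change and relationships (dimension 1),
#' space and shape (dimension 2), and uncertainty and data (dimension 3).
#'
#' @return A 9 x 3 [q_matrix()] with the released item identifiers.
#' @examples
#' colSums(pisa_q())
#' @export
pisa_q <- function() {
  items <- c(
    "CM015Q02D", "CM015Q03D", "CM020Q01", "CM020Q02", "CM020Q03",
    "CM020Q04", "CM038Q03T", "CM038Q05", "CM038Q06"
  )
  dims <- rep(1:3, times = c(2, 4, 3))
  entries <- matrix(0L, 9, 3)
  entries[cbind(1:9, dims)] <- 1L
  q_matrix(entries,
    item_ids = items,
    dim_ids = c("theta1", "theta2", "theta3")
  )
}

#' Read / write a Q-matrix as CSV
#'
#' The on-disk format is a CSV with a header row of dimension labels, the
#' first column holding item labels, and 0/1 cells.
#'
#' @param path file path.
#' @return `read_qmatrix()` returns a [q_matrix()]; `write_qmatrix()`
#'   returns `path` invisibly.
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed Q-matrix file: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed Q-matrix file (non-numeric cells): ", path)
  q_matrix(m, item_ids = as.character(df[[1]]), dim_ids = colnames(df)[-1])
}

#' @param q a [q_matrix()].
#' @rdname read_qmatrix
#' @export
write_qmatrix <- function(q, path) {
  stopifnot(inherits(q, "qmatrix"))
  df <- data.frame(item = rownames(q), unclass(q), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
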