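#' Cut a spectrum into a set of fixed-length window vectors
#'
#' Partitions the absorbance trace into `ceiling(N / window)` contiguous
#' non-overlapping windows in wavenumber order; the last window is
#' zero-padded to full length. This is how a 1-D spectrum is presented to
#' the permutation-invariant RepSet head as a vector set while preserving
#' local band structure.
#'
#' @param absorbance Non-empty numeric vector.
#' @param window Window length `d` (>= 1); default 64.
#' @return Numeric matrix with one window per row and `window` columns.
#' @export
#' @examples
#' dim(spectrum_to_set(rnorm(130), 64))  # 3 x 64
spectrum_to_set <- function(absorbance, window = 64) {
  y <- as.numeric(absorbance)
  if (!length(y)) stop("empty spectrum", call. = FALSE)
  if (window < 1 || window != round(window)) {
    stop("`window` must be a positive integer", call. = FALSE)
  }
  n_win <- ceiling(length(y) / window)
  padded <- c(y, numeric(n_win * window - length(y)))
  matrix(padded, nrow = n_win, ncol = window, byrow = TRUE)
}

#' ReLU inner-product score matrix between two vector sets
#'
#' Entry `(i, j)` is `max(0, v_i . u_j)` for input-set vector `v_i` and
#' hidden-set vector `u_j` -- the differentiable pairwise score that the
#' bipartite matching maximizes.
#'
#' @param X Input set: numeric matrix, one vector per row.
#' @param Y Hidden set: numeric matrix, one vector per row, same number
#'   of columns as `X`.
#' @return Nonnegative `nrow(X)` x `nrow(Y)` matrix.
#' @export
score_matrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("input and hidden set vectors must share one dimension",
         call. = FALSE)
  }
  pmax(X %*% t(Y), 0)
}

#' Exact maximum-weight bipartite matching
#'
#' Maximizes `sum x_ij F_ij` over 0/1 assignment variables with each row
#' and each column used at most once (an injective partial assignment for
#' rectangular `F`). Solved exactly by the Hungarian algorithm on the
#' zero-padded square program; the LP relaxation is integral, so the
#' combinatorial solution attains the optimum. The solver is
#' deterministic: equal-value optima always resolve to the same
#' assignment for the same input.
#'
#' @param F Nonnegative finite numeric matrix of pairwise scores.
#' @return A list of class `match_result`: `value` (the maximized
#'   objective) and `assignment`, a two-column integer matrix of matched
#'   `(row, col)` pairs.
#' @export
#' @examples
#' max_matching(rbind(c(3, 1), c(1, 3)))$value  # 6
max_matching <- function(F) {
  F <- as.matrix(F)
  if (!length(F)) stop("empty matrix", call. = FALSE)
  if (!all(is.finite(F))) stop("non-finite entries", call. = FALSE)
  if (any(F < 0)) {
    stop("negative entries: scores must be ReLU-nonnegative", call. = FALSE)
  }
  res <- .hungarian_cpp(F)
  structure(list(value = res$value, assignment = res$assignment),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> value %.6g, %d matched pair(s)\n",
              x$value, nrow(x$assignment)))
  invisible(x)
}

#' Permutation-invariant matching features of an input set
#'
#' Component `k` is the maximum-weight bipartite matching value between
#' the input set and hidden set `k` under the ReLU inner-product score --
#' the representation the RepSet head feeds to its fully connected
#' layers. Invariant under any reordering of the input set's vectors.
#'
#' @param X Input set: numeric matrix, one vector per row.
#' @param H Hidden sets: numeric array of dimension `c(m, c, d)` (m sets
#'   of cardinality c in dimension d), or a `repset_model`'s hidden-set
#'   parameter.
#' @return Numeric vector of length `m`.
#' @export
repset_features <- function(X, H) {
  X <- as.matrix(X)
  H <- as_hidden_matrix(H)
  m <- attr(H, "m"); cc <- attr(H, "c")
  if (ncol(X) != ncol(H)) {
    stop("hidden-set dimension must match input vectors", call. = FALSE)
  }
  S <- pmax(X %*% t(H), 0)
  .match_batch_cpp(S, m, cc)$values
}

# Normalize hidden sets to a (m*c) x d matrix whose rows are grouped by
# hidden set, carrying m and c as attributes.
as_hidden_matrix <- function(H) {
  if (is.matrix(H) && !is.null(attr(H, "m"))) return(H)
  if (is.array(H) && length(dim(H)) == 3L) {
    m <- dim(H)[1]; cc <- dim(H)[2]; d <- dim(H)[3]
    flat <- matrix(aperm(H, c(2, 1, 3)), nrow = m * cc, ncol = d)
    attr(flat, "m") <- m; attr(flat, "c") <- cc
    return(flat)
  }
  stop("`H` must be an m x c x d array of hidden sets", call. = FALSE)
}
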