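#' @useDynLib movefuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

metric_code <- function(metric) {
  switch(metric, euclidean = 0L, manhattan = 1L, sq_euclidean = 2L,
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Local alignment cost between two columns
#'
#' The per-step cost `d[w(k)]` of aligning element `i` of one signal with
#' element `j` of another: the norm of the difference between scalars
#' (vector alignment), columns (matrix alignment) or flattened depth-frames
#' (cuboid alignment).
#'
#' @param x,y Numeric scalars, vectors (matrix columns) or matrices (cuboid
#'   frames) of identical dimension.
#' @param metric `"euclidean"`, `"manhattan"` or `"sq_euclidean"`.
#' @return A single non-negative number.
#' @export
local_cost <- function(x, y, metric = c("euclidean", "manhattan", "sq_euclidean")) {
  metric <- match.arg(metric)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("dimension mismatch between cost arguments", call. = FALSE)
  d <- x - y
  switch(metric,
    euclidean = sqrt(sum(d^2)),
    manhattan = sum(abs(d)),
    sq_euclidean = sum(d^2)
  )
}

as_cost_columns <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    matrix(x, nrow = 1L)
  } else if (is.matrix(x)) {
    x
  } else if (is.array(x) && length(dim(x)) == 3L) {
    cuboid_as_matrix(x)
  } else {
    stop("alignment inputs must be vectors, matrices or 3-d arrays", call. = FALSE)
  }
}

#' Flatten a cuboid into its stacked-frame matrix
#'
#' Stacks the `G` depth-frames of an `M x N x G` cuboid row-wise into an
#' `(M*G) x N` matrix. Column-wise costs on the result equal frame-wise
#' costs on the cuboid, so cuboid alignment can be run as matrix alignment.
#'
#' @param x A 3-d numeric array (or a matrix, returned unchanged).
#' @return An `(M*G) x N` matrix.
#' @export
cuboid_as_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) != 3L) stop("expected a 3-d array", call. = FALSE)
  do.call(rbind, lapply(seq_len(d[3]), function(g) x[, , g, drop = TRUE]))
}

new_dtw_alignment <- function(res, metric, objective) {
  structure(
    list(value = res$value, total = res$total, k = res$k,
         path = tibble::tibble(i = res$i, j = res$j),
         metric = metric, objective = objective),
    class = "dtw_alignment"
  )
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment> discrepancy %.6g (path length K=%d, %s, %s)\n",
              x$value, x$k, x$metric, x$objective))
  invisible(x)
}

#' Dynamic time warping alignment of vectors, matrices or cuboids
#'
#' Aligns two signals under the endpoint, monotonicity and continuity
#' constraints (allowed steps (1,0), (0,1), (1,1)) and returns the
#' discrepancy: the path-length-normalized total local cost
#' `A_XY = (1/K) sum_k d[w(k)]` of the optimal warping path. Vectors use
#' scalar costs, matrices column costs (row counts must match), cuboids
#' frame costs (rows and depth must match). Cuboid pairs are aligned via
#' their stacked-frame matrices, which yields identical costs.
#'
#' With `objective = "normalized"` (default) the normalized cost itself is
#' minimized exactly, by a dynamic program stratified over path lengths;
#' `objective = "sum"` runs the classic recursion that minimizes the
#' unnormalized sum and then divides by the realized path length. Ties are
#' broken deterministically (smaller K, then diagonal-first backtracking).
#'
#' @param x,y Numeric vectors, matrices or 3-d arrays (both of the same kind).
#' @param metric Local cost metric, see [local_cost()].
#' @param objective `"normalized"` or `"sum"`.
#' @return A `dtw_alignment`: list with `value` (the discrepancy), `total`
#'   (unnormalized path cost), `k` (path length) and `path` (tibble of
#'   1-based index pairs).
#' @export
dtw_align <- function(x, y, metric = c("euclidean", "manhattan", "sq_euclidean"),
                      objective = c("normalized", "sum")) {
  metric <- match.arg(metric)
  objective <- match.arg(objective)
  vec_x <- is.numeric(x) && is.null(dim(x))
  vec_y <- is.numeric(y) && is.null(dim(y))
  if (vec_x != vec_y) stop("x and y must both be vectors or both arrays", call. = FALSE)
  if (!vec_x) {
    dx <- dim(x); dy <- dim(y)
    if (length(dx) != length(dy)) {
      stop("x and y must have the same number of dimensions", call. = FALSE)
    }
    if (dx[1] != dy[1]) stop("row counts must be equal for matrix/cuboid alignment", call. = FALSE)
    if (length(dx) == 3L && dx[3] != dy[3]) {
      stop("cuboid depths must be equal", call. = FALSE)
    }
  }
  X <- as_cost_columns(x)
  Y <- as_cost_columns(y)
  if (ncol(X) < 1L || ncol(Y) < 1L) stop("empty sequence", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("alignment inputs must be finite", call. = FALSE)
  }
  C <- cpp_cost_matrix(X, Y, metric_code(metric))
  res <- if (objective == "normalized") cpp_dtw_normalized(C) else cpp_dtw_sum(C)
  new_dtw_alignment(res, metric, objective)
}

#' Exhaustive-search alignment oracle
#'
#' Enumerates every admissible warping path between two short signals and
#' returns the minimizer of the chosen objective. Exponentially expensive;
#' intended as an independent correctness oracle for [dtw_align()] in tests,
#' hence the hard length cap.
#'
#' @inheritParams dtw_align
#' @param max_len Refuse inputs longer than this (default 6).
#' @return A `dtw_alignment`, as from [dtw_align()].
#' @export
brute_force_align <- function(x, y,
                              metric = c("euclidean", "manhattan", "sq_euclidean"),
                              objective = c("normalized", "sum"),
                              max_len = 6L) {
  metric <- match.arg(metric)
  objective <- match.arg(objective)
  X <- as_cost_columns(x)
  Y <- as_cost_columns(y)
  n <- ncol(X); m <- ncol(Y)
  if (n > max_len || m > max_len) {
    stop("brute_force_align refuses sequences longer than max_len", call. = FALSE)
  }
  C <- cpp_cost_matrix(X, Y, metric_code(metric))
  paths <- enumerate_paths(n, m)
  best <- NULL
  for (p in paths) {
    tot <- sum(C[p])
    K <- nrow(p)
    val <- if (objective == "normalized") tot / K else tot
    if (is.null(best) || val < best$score - 1e-15 ||
        (abs(val - best$score) <= 1e-15 && K < best$k)) {
      best <- list(score = val, total = tot, k = K, p = p)
    }
  }
  res <- list(value = best$total / best$k, total = best$total, k = best$k,
              i = best$p[, 1], j = best$p[, 2])
  if (objective == "sum") res$value <- best$total / best$k
  new_dtw_alignment(res, metric, objective)
}

# All admissible warping paths from (1,1) to (n,m), as 2-column matrices.
enumerate_paths <- function(n, m) {
  out <- list()
  walk <- function(i, j, acc) {
    acc[[length(acc) + 1L]] <- c(i, j)
    if (i == n && j == m) {
      out[[length(out) + 1L]] <<- do.call(rbind, acc)
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1L, j + 1L, acc)
    if (i < n) walk(i + 1L, j, acc)
    if (j < m) walk(i, j + 1L, acc)
  }
  walk(1L, 1L, list())
  out
}

#' Verify that a warping path satisfies the alignment constraints
#'
#' Checks the endpoint constraint (path runs from (1,1) to (n, m)),
#' monotonicity, and continuity (every step is (1,0), (0,1) or (1,1)).
#'
#' @param path Tibble or matrix of index pairs (`i`, `j`).
#' @param n,m Lengths of the aligned signals.
#' @return `TRUE` if admissible, otherwise `FALSE`.
#' @export
is_admissible_path <- function(path, n, m) {
  p <- as.matrix(path)
  if (!all(p[1, ] == c(1, 1)) || !all(p[nrow(p), ] == c(n, m))) return(FALSE)
  if (nrow(p) < 2L) return(n == 1 && m == 1)
  di <- diff(p[, 1]); dj <- diff(p[, 2])
  all(di >= 0) && all(dj >= 0) && all(di <= 1) && all(dj <= 1) && all(di + dj >= 1)
}
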