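# Incremental sufficient statistics: O(d^2) add/remove of one cell,
# exactly equivalent to batch recomputation over the modified set.

#' Batch sufficient statistics of a set of cells
#'
#' @param x Numeric matrix (rows = cells) or vector.
#' @return A [component_stats()] with count, mean and scatter
#'   `S2 = (1/n) sum (x - xbar)(x - xbar)'`.
#' @export
batch_stats <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n == 0L) return(component_stats(0, d = ncol(x)))
  m <- colMeans(x)
  xc <- sweep(x, 2L, m)
  component_stats(n, m, crossprod(xc) / n)
}

#' Add one cell to sufficient statistics
#'
#' Updates `(n, mean, scatter)` in place of a full recomputation over the
#' enlarged set; exact up to floating-point rounding.
#'
#' @param stats A [component_stats()].
#' @param x Numeric vector of length `d`.
#' @return Updated [component_stats()].
#' @export
update_stats_add <- function(stats, x) {
  x <- as.numeric(x)
  n0 <- stats$n
  n1 <- n0 + 1
  if (n0 == 0) return(component_stats(1, x, matrix(0, length(x), length(x))))
  m0 <- stats$mean
  m1 <- (n0 * m0 + x) / n1
  s1 <- (n0 * stats$scatter + n0 * tcrossprod(m0) + tcrossprod(x)) / n1 -
    tcrossprod(m1)
  component_stats(n1, m1, (s1 + t(s1)) / 2)
}

#' Remove one cell from sufficient statistics
#'
#' Inverse of [update_stats_add()]; the caller guarantees that `x` was
#' previously added. Removing the last cell yields the empty statistics.
#'
#' @param stats A [component_stats()] with `n >= 1`.
#' @param x Numeric vector of length `d`.
#' @return Updated [component_stats()].
#' @export
update_stats_remove <- function(stats, x) {
  x <- as.numeric(x)
  n0 <- stats$n
  if (n0 < 1) stop("cannot remove a cell from empty statistics (n = 0)")
  if (n0 == 1) return(component_stats(0, d = length(x)))
  n1 <- n0 - 1
  m0 <- stats$mean
  m1 <- (n0 * m0 - x) / n1
  s1 <- (n0 * stats$scatter + n0 * tcrossprod(m0) - tcrossprod(x)) / n1 -
    tcrossprod(m1)
  s1 <- (s1 + t(s1)) / 2
  # rounding can leave tiny negative diagonal entries for near-duplicate data
  diag(s1) <- pmax(diag(s1), 0)
  component_stats(n1, m1, s1)
}
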