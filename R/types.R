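#' Gaussian mixture component
#'
#' A single basis function of a Gaussian mixture: a weight, a mean vector
#' and a covariance matrix over `d` measurement channels.
#'
#' @param weight Component weight in `[0, 1]`.
#' @param mean Numeric vector of length `d` (channel units).
#' @param covariance `d x d` symmetric positive-definite matrix
#'   (channel units squared). A scalar is accepted in one dimension.
#' @return An object of class `gaussian_component`.
#' @examples
#' gaussian_component(1, 0, 1)
#' gaussian_component(0.5, c(0, 0), diag(2))
#' @export
gaussian_component <- function(weight, mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as_covariance(covariance, length(mean))
  stopifnot(is.numeric(weight), length(weight) == 1L)
  if (weight < -1e-12 || weight > 1 + 1e-12)
    stop("component weight must lie in [0, 1], got ", format(weight))
  # Cholesky doubles as the positive-definiteness check
  ch <- tryCatch(chol(covariance), error = function(e)
    stop("component covariance is not positive-definite", call. = FALSE))
  structure(
    list(weight = min(max(weight, 0), 1), mean = mean,
         covariance = covariance, chol = ch),
    class = "gaussian_component"
  )
}

as_covariance <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) == 1L && d == 1L) x <- matrix(x, 1, 1)
    else if (length(x) == d * d) x <- matrix(x, d, d)
    else stop("covariance must be a ", d, "x", d, " matrix")
  }
  x <- as.matrix(x)
  if (nrow(x) != d || ncol(x) != d)
    stop("covariance must be ", d, "x", d, ", got ",
         nrow(x), "x", ncol(x))
  if (max(abs(x - t(x))) > 1e-8 * (1 + max(abs(x))))
    stop("covariance must be symmetric")
  (x + t(x)) / 2
}

#' Gaussian mixture model
#'
#' An ordered set of [gaussian_component()]s over a common dimension, the
#' density representation used for both the target and the noise
#' distribution. Component weights must sum to one.
#'
#' @param components List of `gaussian_component` objects.
#' @param channel_names Optional character vector of channel labels.
#' @return An object of class `mixture_model` with elements `components`,
#'   `dimension` and `channel_names`.
#' @seealso [mixture_logpdf()], [sample_mixture()], [convolve_mixtures()]
#' @export
mixture_model <- function(components, channel_names = NULL) {
  stopifnot(is.list(components), length(components) >= 1L)
  if (!all(vapply(components, inherits, TRUE, "gaussian_component")))
    stop("all components must be gaussian_component objects")
  d <- length(components[[1L]]$mean)
  dims <- vapply(components, function(cp) length(cp$mean), 1L)
  if (any(dims != d))
    stop("all components must share dimension ", d)
  w <- vapply(components, `[[`, 1.0, "weight")
  if (abs(sum(w) - 1) > 1e-12)
    stop("component weights must sum to 1 (got ", format(sum(w), digits = 15), ")")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d))
  stopifnot(length(channel_names) == d)
  structure(
    list(components = components, dimension = d,
         channel_names = as.character(channel_names)),
    class = "mixture_model"
  )
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Gaussian mixture model:", length(x$components), "component(s),",
      x$dimension, "channel(s)\n")
  w <- vapply(x$components, `[[`, 1.0, "weight")
  for (i in seq_along(x$components)) {
    cp <- x$components[[i]]
    cat(sprintf("  [%d] w=%.4f mean=(%s)\n", i, w[i],
                paste(format(cp$mean, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Normal-inverse-Wishart hyperparameters
#'
#' The prior for the mean and covariance of each mixture component, plus
#' the Dirichlet (or Dirichlet-process) concentration. The prior on the
#' mean is normal with center `mu0` and precision scaled by `kappa0`; the
#' prior on the covariance is inverse-Wishart with scale `sigma0` and
#' `nu0` degrees of freedom.
#'
#' @param mu0 Prior mean vector (length `d`).
#' @param kappa0 Positive scalar; confidence in `mu0`.
#' @param sigma0 `d x d` symmetric positive-definite prior scale matrix.
#' @param nu0 Scalar `> d - 1`; confidence in `sigma0`.
#' @param alpha Positive concentration parameter of the mixture weights.
#' @return An object of class `niw_hyperparams`.
#' @seealso [default_hyperparams()]
#' @export
niw_hyperparams <- function(mu0, kappa0 = 1, sigma0, nu0 = NULL, alpha = 1) {
  mu0 <- as.numeric(mu0)
  d <- length(mu0)
  sigma0 <- as_covariance(sigma0, d)
  if (is.null(nu0)) nu0 <- d + 2
  stopifnot(length(kappa0) == 1L, length(nu0) == 1L, length(alpha) == 1L)
  if (kappa0 <= 0) stop("kappa0 must be positive")
  if (alpha <= 0) stop("alpha must be positive")
  if (nu0 <= d - 1) stop("nu0 must exceed d - 1 = ", d - 1,
                         " for the inverse-Wishart prior to be proper")
  chol(sigma0) # positive-definiteness check
  structure(list(mu0 = mu0, kappa0 = kappa0, sigma0 = sigma0,
                 nu0 = nu0, alpha = alpha, d = d),
            class = "niw_hyperparams")
}

#' Per-component sufficient statistics
#'
#' Count, mean and scatter (mean outer-product deviation) of the cells
#' currently assigned to one mixture component. The scatter is the
#' biased covariance `S2 = (1/n) sum (x - xbar)(x - xbar)'`; for `n = 0`
#' both moments are defined as zero.
#'
#' @param n Nonnegative count of assigned cells.
#' @param mean Numeric vector of length `d`.
#' @param scatter `d x d` positive-semidefinite matrix.
#' @return An object of class `component_stats`.
#' @seealso [update_stats_add()], [update_stats_remove()], [batch_stats()]
#' @export
component_stats <- function(n = 0, mean = NULL, scatter = NULL, d = NULL) {
  if (n == 0) {
    if (is.null(d)) d <- if (!is.null(mean)) length(mean) else 1L
    return(structure(list(n = 0, mean = numeric(d),
                          scatter = matrix(0, d, d)),
                     class = "component_stats"))
  }
  mean <- as.numeric(mean)
  d <- length(mean)
  scatter <- if (is.null(scatter)) matrix(0, d, d) else as_covariance(scatter, d)
  if (n < 0) stop("n must be nonnegative")
  structure(list(n = n, mean = mean, scatter = scatter),
            class = "component_stats")
}

#' Event table
#'
#' An `N x d` matrix of per-cell fluorescence intensities with channel
#' labels, the container for both noise (unlabeled-cell) and total-signal
#' (labeled-cell) measurements.
#'
#' @param values Numeric matrix (rows = cells, columns = channels) or a
#'   vector for one channel.
#' @param channel_names Optional character vector of column labels.
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, channel_names = NULL) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("event table must contain at least one cell")
  if (anyNA(values)) stop("event table contains missing values")
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(values)))
  }
  stopifnot(length(channel_names) == ncol(values))
  colnames(values) <- channel_names
  structure(list(values = values, channel_names = as.character(channel_names)),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table:", nrow(x$values), "cells x", ncol(x$values),
      "channels (", paste(x$channel_names, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

n_events <- function(x) nrow(x$values)
n_channels <- function(x) ncol(x$values)
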