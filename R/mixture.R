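# Mixture evaluation, sampling, convolution and JSON serialization.
# All densities are computed in log space; mixture sums use log-sum-exp.

# log N(x | mean, Sigma) for a matrix of rows x, given the Cholesky factor
# of Sigma (upper triangular, as returned by chol()).
mvn_logpdf_chol <- function(x, mean, ch) {
  d <- length(mean)
  x <- matrix(x, ncol = d)
  xc <- sweep(x, 2L, mean)
  # solve R' u = xc' => quadratic form = colSums(u^2)
  u <- backsolve(ch, t(xc), transpose = TRUE)
  q <- colSums(u^2)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * q
}

logsumexp <- function(m) {
  # row-wise log-sum-exp of a matrix
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

#' Log-density of a Gaussian mixture
#'
#' Evaluates `log sum_k w_k N(x | mu_k, Sigma_k)` stably via log-sum-exp.
#'
#' @param x A numeric vector of length `d` (one point) or an `N x d`
#'   matrix of points (an [event_table()] is also accepted).
#' @param model A [mixture_model()].
#' @return A numeric vector of log-densities, one per row of `x`.
#' @examples
#' m <- mixture_model(list(gaussian_component(1, 0, 1)))
#' mixture_logpdf(0, m)  # log(1/sqrt(2*pi))
#' @export
mixture_logpdf <- function(x, model) {
  stopifnot(inherits(model, "mixture_model"))
  d <- model$dimension
  if (inherits(x, "event_table")) x <- x$values
  if (is.null(dim(x))) {
    if (d == 1L) x <- matrix(x, ncol = 1L)
    else if (length(x) == d) x <- matrix(x, nrow = 1L)
    else stop("x has length ", length(x), " but the mixture has dimension ", d)
  }
  x <- as.matrix(x)
  if (ncol(x) != d)
    stop("x has ", ncol(x), " columns but the mixture has dimension ", d)
  K <- length(model$components)
  lp <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    cp <- model$components[[k]]
    lw <- if (cp$weight > 0) log(cp$weight) else -Inf
    lp[, k] <- lw + mvn_logpdf_chol(x, cp$mean, cp$chol)
  }
  logsumexp(lp)
}

#' Density of a Gaussian mixture
#'
#' @inheritParams mixture_logpdf
#' @return Densities `exp(mixture_logpdf(x, model))`.
#' @export
mixture_pdf <- function(x, model) exp(mixture_logpdf(x, model))

#' Draw samples from a Gaussian mixture
#'
#' Draws a component index from the weights, then a multivariate normal
#' deviate from that component.
#'
#' @param model A [mixture_model()].
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return An [event_table()] with `n` rows.
#' @export
sample_mixture <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  d <- model$dimension
  w <- vapply(model$components, `[[`, 1.0, "weight")
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- matrix(0, n, d)
  for (k in unique(idx)) {
    rows <- which(idx == k)
    cp <- model$components[[k]]
    z <- matrix(stats::rnorm(length(rows) * d), length(rows), d)
    out[rows, ] <- sweep(z %*% cp$chol, 2L, cp$mean, `+`)
  }
  event_table(out, model$channel_names)
}

#' Convolution of two Gaussian mixtures
#'
#' The distribution of the sum of independent draws from `target` and
#' `noise`. The convolution of two normal densities is normal, so the
#' result is a mixture with one component per (target, noise) pair:
#' weights multiply, means and covariances add.
#'
#' @param target,noise [mixture_model()]s of equal dimension.
#' @return A [mixture_model()] with `K_T * K_xi` components.
#' @examples
#' t1 <- mixture_model(list(gaussian_component(1, -0.43, 0.36)))
#' n1 <- mixture_model(list(gaussian_component(1, 0, 0.25)))
#' convolve_mixtures(t1, n1)  # N(-0.43, 0.61)
#' @export
convolve_mixtures <- function(target, noise) {
  stopifnot(inherits(target, "mixture_model"), inherits(noise, "mixture_model"))
  if (target$dimension != noise$dimension)
    stop("dimension mismatch: target has d=", target$dimension,
         ", noise has d=", noise$dimension)
  comps <- list()
  for (ct in target$components)
    for (cn in noise$components)
      comps[[length(comps) + 1L]] <- gaussian_component(
        ct$weight * cn$weight, ct$mean + cn$mean,
        ct$covariance + cn$covariance)
  # guard against accumulated rounding in the weight product
  w <- vapply(comps, `[[`, 1.0, "weight")
  if (abs(sum(w) - 1) > 1e-12)
    comps <- lapply(comps, function(cp) {
      cp$weight <- cp$weight / sum(w); cp
    })
  mixture_model(comps, target$channel_names)
}

#' Serialize a mixture model to JSON
#'
#' The layout is `{dimension, channel_names, components: [{weight, mean,
#' covariance}]}` with covariances stored row-major; round-trips at full
#' double precision.
#'
#' @param model A [mixture_model()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
mixture_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  obj <- list(
    dimension = model$dimension,
    channel_names = model$channel_names,
    components = lapply(model$components, function(cp) list(
      weight = cp$weight,
      mean = cp$mean,
      covariance = as.numeric(t(cp$covariance))  # row-major
    ))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a mixture model from JSON
#'
#' @param x A JSON string or a path to a JSON file written by
#'   [mixture_to_json()].
#' @return A [mixture_model()].
#' @export
mixture_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  d <- obj$dimension
  comps <- lapply(obj$components, function(cp)
    gaussian_component(cp$weight, unlist(cp$mean),
                       matrix(unlist(cp$covariance), d, d, byrow = TRUE)))
  mixture_model(comps, unlist(obj$channel_names))
}

#' Mean vector of a mixture model
#' @param model A [mixture_model()].
#' @return Numeric vector of length `d`.
#' @export
mixture_mean <- function(model) {
  w <- vapply(model$components, `[[`, 1.0, "weight")
  Reduce(`+`, Map(function(cp, wi) wi * cp$mean, model$components, w))
}

#' Covariance matrix of a mixture model
#' @param model A [mixture_model()].
#' @return `d x d` matrix.
#' @export
mixture_covariance <- function(model) {
  w <- vapply(model$components, `[[`, 1.0, "weight")
  m <- mixture_mean(model)
  Reduce(`+`, Map(function(cp, wi) {
    dm <- cp$mean - m
    wi * (cp$covariance + tcrossprod(dm))
  }, model$components, w))
}
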