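# Normal-inverse-Wishart conjugate draws and the posterior-predictive
# multivariate t. Parameterization: the inverse-Wishart IW(Psi, nu) has
# density proportional to det(X)^{-(nu + p + 1)/2} exp(-tr(Psi X^{-1})/2),
# so E[X] = Psi / (nu - p - 1) for nu > p + 1.

# One inverse-Wishart draw: X = W^{-1}, W ~ Wishart(df = nu, scale = Psi^{-1}).
riwish1 <- function(psi, nu) {
  p <- nrow(psi)
  psi_inv <- chol2inv(chol(psi))
  psi_inv <- (psi_inv + t(psi_inv)) / 2
  w <- stats::rWishart(1L, df = nu, Sigma = psi_inv)[, , 1L]
  x <- chol2inv(chol(w))
  (x + t(x)) / 2
}

# Positive-definiteness guard: jitter the diagonal only on Cholesky failure.
ensure_spd <- function(m, label = "matrix") {
  m <- (m + t(m)) / 2
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  if (!ok) {
    jit <- 1e-10 * sum(diag(m)) / nrow(m)
    if (!is.finite(jit) || jit <= 0) jit <- 1e-10
    warning(label, " not positive-definite; adding diagonal jitter ",
            format(jit), call. = FALSE)
    m <- m + diag(jit, nrow(m))
  }
  m
}

#' Draw a component mean from its conditional posterior
#'
#' Conditional on the covariance, the mean of a normal component with an
#' NIW prior is normal with center `(n xbar + kappa0 mu0) / (n + kappa0)`
#' and covariance `Sigma / (n + kappa0)`.
#'
#' @param stats A [component_stats()] for the cells assigned to the
#'   component.
#' @param covariance Current `d x d` component covariance.
#' @param prior A [niw_hyperparams()].
#' @param seed Optional integer seed.
#' @return Numeric vector of length `d`.
#' @export
niw_sample_mean <- function(stats, covariance, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- prior$d
  covariance <- as_covariance(covariance, d)
  n <- stats$n
  mu_tilde <- (n * stats$mean + prior$kappa0 * prior$mu0) / (n + prior$kappa0)
  ch <- chol(covariance / (n + prior$kappa0))
  drop(mu_tilde + crossprod(ch, stats::rnorm(d)))
}

#' Draw a component covariance conditional on its mean
#'
#' Inverse-Wishart with `n + nu0 + 1` degrees of freedom and scale
#' `n S2 + n (xbar - mu)(xbar - mu)' + kappa0 (mu - mu0)(mu - mu0)' + Sigma0`.
#'
#' @param stats A [component_stats()].
#' @param mean Current component mean (the value conditioned on).
#' @param prior A [niw_hyperparams()].
#' @param seed Optional integer seed.
#' @return A `d x d` covariance draw.
#' @export
niw_sample_covariance_conditional <- function(stats, mean, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats$n
  mean <- as.numeric(mean)
  dm1 <- stats$mean - mean
  dm2 <- mean - prior$mu0
  psi <- n * stats$scatter + n * tcrossprod(dm1) +
    prior$kappa0 * tcrossprod(dm2) + prior$sigma0
  psi <- ensure_spd(psi, "conditional covariance scale")
  riwish1(psi, n + prior$nu0 + 1)
}

#' Draw a component covariance from its marginal posterior
#'
#' The mean integrated out: inverse-Wishart with `n + nu0 + 1` degrees of
#' freedom and scale
#' `n S2 + (kappa0 n / (kappa0 + n)) (xbar - mu0)(xbar - mu0)' + Sigma0`.
#'
#' @inheritParams niw_sample_covariance_conditional
#' @return A `d x d` covariance draw.
#' @export
niw_sample_covariance_marginal <- function(stats, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats$n
  dm <- stats$mean - prior$mu0
  shrink <- if (n > 0) prior$kappa0 * n / (prior$kappa0 + n) else 0
  psi <- n * stats$scatter + shrink * tcrossprod(dm) + prior$sigma0
  psi <- ensure_spd(psi, "marginal covariance scale")
  riwish1(psi, n + prior$nu0 + 1)
}

# Parameters of the posterior-predictive multivariate t for one component:
# t_nu(y; mu_y, Sigma_y / nu) with nu = n + nu0 + 1 - p. The m1 factor
# simplifies to n kappa0 / (n + kappa0).
predictive_params <- function(stats, prior) {
  n <- stats$n
  k0 <- prior$kappa0
  p <- prior$d
  nu <- n + prior$nu0 + 1 - p
  if (nu <= 0)
    stop("posterior-predictive degrees of freedom nonpositive: n = ", n,
         ", nu0 = ", prior$nu0, ", p = ", p)
  m0 <- (n + k0) / (n + k0 + 1)
  m1 <- n * k0 / (n + k0)
  mu_y <- (n * stats$mean + k0 * prior$mu0) / (n + k0)
  dm <- prior$mu0 - stats$mean
  sigma_y <- (m1 * tcrossprod(dm) + n * stats$scatter + prior$sigma0) / m0
  list(nu = nu, mu = mu_y, sigma = (sigma_y + t(sigma_y)) / 2)
}

#' Posterior-predictive log-density of a new cell
#'
#' The density of a new observation given the cells already assigned to a
#' component, with the component's mean and covariance integrated out
#' under the NIW prior: a multivariate t with `n + nu0 + 1 - p` degrees
#' of freedom, location `(n xbar + kappa0 mu0)/(n + kappa0)` and scale
#' matrix `Sigma_y / nu`.
#'
#' @param y A point (length `d`) or an `N x d` matrix of points.
#' @param stats A [component_stats()].
#' @param prior A [niw_hyperparams()].
#' @return Numeric vector of log-densities.
#' @export
posterior_predictive_logpdf <- function(y, stats, prior) {
  pp <- predictive_params(stats, prior)
  # t_nu(y; mu, Sigma_y/nu): quadratic form (1/nu) * nu * q_{Sigma_y} = q
  p <- prior$d
  y <- matrix(y, ncol = p)
  ch <- chol(pp$sigma)
  yc <- sweep(y, 2L, pp$mu)
  u <- backsolve(ch, t(yc), transpose = TRUE)
  q <- colSums(u^2)
  lgamma((pp$nu + p) / 2) - lgamma(pp$nu / 2) - 0.5 * p * log(pi) -
    sum(log(diag(ch))) - 0.5 * (pp$nu + p) * log1p(q)
}

#' Weakly-informative hyperparameters from the data
#'
#' Centers the prior on the dataset: `mu0` and `Sigma0` are the sample
#' mean and covariance of all cells, `kappa0 = 1`, `nu0 = d + 2` (the
#' smallest integer giving the inverse-Wishart a finite mean). For
#' fat-tailed data the sample covariance is inflated by outliers and the
#' resulting prior is flat; callers may then supply a narrower `sigma0`.
#'
#' @param data An [event_table()] with at least two cells.
#' @param alpha Concentration parameter, passed through.
#' @param kappa0,nu0 Optional overrides of the defaults.
#' @return A [niw_hyperparams()].
#' @export
default_hyperparams <- function(data, alpha = 1, kappa0 = 1, nu0 = NULL) {
  stopifnot(inherits(data, "event_table"))
  x <- data$values
  if (nrow(x) < 2L) stop("need at least 2 cells to set data-driven hyperparameters")
  v <- apply(x, 2L, stats::var)
  if (any(v <= 0))
    stop("channel(s) ", paste(colnames(x)[v <= 0], collapse = ", "),
         " have zero variance; rescale or drop them before fitting")
  niw_hyperparams(mu0 = colMeans(x), kappa0 = kappa0,
                  sigma0 = stats::cov(x), nu0 = nu0, alpha = alpha)
}
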