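# Similarity between an estimated density and a ground truth:
# integrated squared error (MISE) and mean integrated overlap
# (MIO = 1 - 0.5 * integral |p_true - p_est|, i.e. the overlap mass).

#' Wrap a density function with an evaluation window
#'
#' Utility for non-Gaussian ground truths (skewed or heavy-tailed
#' densities): attaches the support window the metrics should integrate
#' over.
#'
#' @param pdf Function mapping an `N x d` matrix (or vector in 1-D) to
#'   densities.
#' @param lower,upper Numeric vectors of length `d`: the evaluation
#'   window, which should contain essentially all of the mass.
#' @param sampler Optional function `n -> N x d` matrix of draws.
#' @return A function of class `density_fn`.
#' @export
density_fn <- function(pdf, lower, upper, sampler = NULL) {
  structure(pdf, class = c("density_fn", "function"),
            window = cbind(lower = lower, upper = upper),
            sampler = sampler)
}

# evaluation window of a density object: d x 2 matrix (lower, upper)
density_window <- function(obj) {
  if (inherits(obj, "mixture_model")) {
    lims <- sapply(seq_len(obj$dimension), function(j) {
      lo <- min(vapply(obj$components, function(cp)
        cp$mean[j] - 8 * sqrt(cp$covariance[j, j]), 1.0))
      hi <- max(vapply(obj$components, function(cp)
        cp$mean[j] + 8 * sqrt(cp$covariance[j, j]), 1.0))
      c(lo, hi)
    })
    return(cbind(lower = lims[1, ], upper = lims[2, ]))
  }
  if (inherits(obj, "density_fn")) return(attr(obj, "window"))
  stop("cannot determine an evaluation window for objects of class ",
       paste(class(obj), collapse = "/"),
       "; supply a mixture_model or a density_fn")
}

density_dim <- function(obj) {
  if (inherits(obj, "mixture_model")) return(obj$dimension)
  nrow(density_window(obj))
}

density_eval <- function(obj, x) {
  if (inherits(obj, "mixture_model")) return(mixture_pdf(x, obj))
  as.numeric(obj(x))
}

# union window of two densities
common_window <- function(a, b) {
  wa <- density_window(a); wb <- density_window(b)
  if (nrow(wa) != nrow(wb))
    stop("densities have different dimensions: ", nrow(wa), " vs ", nrow(wb))
  cbind(lower = pmin(wa[, 1], wb[, 1]), upper = pmax(wa[, 2], wb[, 2]))
}

# integrate h(p_true, p_est) over the common window
integrate_pair <- function(truth, estimate, h, gridsize = 4096L,
                           mc_draws = 1e6, seed = 1L, check_mass = TRUE) {
  d <- density_dim(truth)
  w <- common_window(truth, estimate)
  trapz <- function(v, dx) sum((v[-1L] + v[-length(v)]) / 2) * dx
  if (d == 1L) {
    x <- seq(w[1, 1], w[1, 2], length.out = gridsize)
    f <- density_eval(truth, x)
    g <- density_eval(estimate, x)
    dx <- x[2L] - x[1L]
    if (check_mass) {
      for (m in c(truth = trapz(f, dx), estimate = trapz(g, dx)))
        if (m < 1 - 1e-3)
          stop("evaluation window [", format(w[1, 1]), ", ", format(w[1, 2]),
               "] misses ", format(100 * (1 - m), digits = 3),
               "% of a density's mass; widen the window")
    }
    return(trapz(h(f, g), dx))
  }
  if (d == 2L) {
    n2 <- 512L
    x1 <- seq(w[1, 1], w[1, 2], length.out = n2)
    x2 <- seq(w[2, 1], w[2, 2], length.out = n2)
    grid <- cbind(rep(x1, times = n2), rep(x2, each = n2))
    f <- density_eval(truth, grid)
    g <- density_eval(estimate, grid)
    da <- (x1[2] - x1[1]) * (x2[2] - x2[1])
    if (check_mass && (sum(f) * da < 1 - 1e-3 || sum(g) * da < 1 - 1e-3))
      stop("evaluation window misses more than 0.1% of a density's mass; ",
           "widen the window")
    return(sum(h(f, g)) * da)
  }
  # d >= 3: self-normalized Monte Carlo under the equal mixture of the two
  if (!inherits(truth, "mixture_model") || !inherits(estimate, "mixture_model"))
    stop("Monte-Carlo integration in d >= 3 requires mixture_model inputs")
  set.seed(seed)
  n1 <- ceiling(mc_draws / 2)
  xs <- rbind(sample_mixture(truth, n1)$values,
              sample_mixture(estimate, mc_draws - n1)$values)
  f <- density_eval(truth, xs)
  g <- density_eval(estimate, xs)
  q <- (f + g) / 2
  mean(h(f, g)[q > 0] / q[q > 0])
}

#' Mean integrated squared error between two densities
#'
#' `integral (p_true - p_est)^2 dx`, by composite trapezoid quadrature in
#' one or two dimensions and self-normalized Monte Carlo above.
#'
#' @param truth,estimate [mixture_model()]s or [density_fn()]s (in `d >=
#'   3`, mixtures only).
#' @param gridsize Number of quadrature points per axis in 1-D.
#' @param mc_draws Monte-Carlo sample size for `d >= 3`.
#' @param check_mass Error if the window misses more than 0.1% of either
#'   density's mass (disable when scoring deliberately unnormalized
#'   estimates).
#' @return Nonnegative scalar.
#' @export
mise <- function(truth, estimate, gridsize = 4096L, mc_draws = 1e6,
                 check_mass = TRUE) {
  integrate_pair(truth, estimate, function(f, g) (f - g)^2,
                 gridsize = gridsize, mc_draws = mc_draws,
                 check_mass = check_mass)
}

#' Mean integrated overlap between two densities
#'
#' `1 - 0.5 * integral |p_true - p_est| dx`. For normalized nonnegative
#' densities this equals the overlap mass `integral min(p_true, p_est)`
#' and lies in `[0, 1]`: 1 for identical densities, 0 for disjoint
#' supports. Estimates that are not valid densities (e.g. with negative
#' lobes) can push the value outside `[0, 1]`.
#'
#' @inheritParams mise
#' @return Scalar overlap.
#' @examples
#' a <- mixture_model(list(gaussian_component(1, 0, 1)))
#' b <- mixture_model(list(gaussian_component(1, 1, 1)))
#' mio(a, b)  # 2 * pnorm(-1/2)
#' @export
mio <- function(truth, estimate, gridsize = 4096L, mc_draws = 1e6,
                check_mass = TRUE) {
  1 - 0.5 * integrate_pair(truth, estimate, function(f, g) abs(f - g),
                           gridsize = gridsize, mc_draws = mc_draws,
                           check_mass = check_mass)
}

#' Average the densities of a set of posterior draws
#'
#' Returns the pointwise mean of the draw densities as a [density_fn()],
#' the posterior-mean density estimate scored in the benchmarks.
#'
#' @param draws List of [mixture_model()] posterior draws (or a
#'   `mixture_chain`).
#' @return A [density_fn()].
#' @export
averaged_density <- function(draws) {
  if (inherits(draws, "mixture_chain")) draws <- draws$draws
  stopifnot(length(draws) >= 1L)
  wins <- lapply(draws, density_window)
  lo <- Reduce(pmin, lapply(wins, function(w) w[, 1]))
  hi <- Reduce(pmax, lapply(wins, function(w) w[, 2]))
  pdf <- function(x) {
    acc <- 0
    for (m in draws) acc <- acc + mixture_pdf(x, m)
    acc / length(draws)
  }
  density_fn(pdf, lo, hi)
}

#' Score posterior draws against a ground-truth density
#'
#' Computes the MIO of each stored draw against the truth (summarized as
#' mean and standard deviation) and the MIO of the averaged posterior
#' density.
#'
#' @param draws List of [mixture_model()] draws or a `mixture_chain`.
#' @param truth A [mixture_model()] or [density_fn()].
#' @param gridsize Quadrature points per axis.
#' @return List with `mio_mean`, `mio_sd`, `mio_per_draw` and
#'   `mio_averaged`.
#' @export
score_posterior <- function(draws, truth, gridsize = 4096L) {
  if (inherits(draws, "mixture_chain")) draws <- draws$draws
  per <- vapply(draws, function(m) mio(truth, m, gridsize = gridsize), 1.0)
  list(mio_mean = mean(per), mio_sd = stats::sd(per), mio_per_draw = per,
       mio_averaged = mio(truth, averaged_density(draws), gridsize = gridsize))
}

#' Tabulate a density summary of posterior draws on a grid
#'
#' For each grid point, the mean posterior density and pointwise 5% and
#' 95% quantiles across draws (a credible band for the density).
#'
#' @param draws List of [mixture_model()] draws or a `mixture_chain`.
#' @param grid Numeric vector (1-D) or matrix of evaluation points; if
#'   `NULL`, an equispaced 1-D grid of 512 points over the draw window.
#' @param probs Quantiles for the band.
#' @return A data.frame with the grid, `mean` and one column per
#'   quantile.
#' @export
density_summary <- function(draws, grid = NULL, probs = c(0.05, 0.95)) {
  if (inherits(draws, "mixture_chain")) draws <- draws$draws
  if (is.null(grid)) {
    w <- density_window(averaged_density(draws))
    if (nrow(w) != 1L) stop("supply an explicit grid for d > 1")
    grid <- seq(w[1, 1], w[1, 2], length.out = 512L)
  }
  dens <- vapply(draws, function(m) mixture_pdf(grid, m),
                 numeric(if (is.null(dim(grid))) length(grid) else nrow(grid)))
  qs <- t(apply(dens, 1L, stats::quantile, probs = probs))
  out <- data.frame(grid, mean = rowMeans(dens), qs, check.names = FALSE)
  names(out) <- c(if (is.null(dim(grid))) "x" else paste0("x", seq_len(ncol(grid))),
                  "mean", paste0("q", probs * 100))
  out
}
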