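# Dirichlet-process (infinite) Gaussian mixture Gibbs sampler. Cells are
# reassigned one at a time by the Chinese-restaurant rule: an occupied
# component attracts a cell proportionally to its count times the
# posterior-predictive t density of the cell given the component's other
# members; a new component opens with probability proportional to alpha
# times the prior predictive.

# Predictive log-density of x under one component's collapsed posterior.
# kind = "t" (posterior-predictive Student t), "normal" (normal with the
# prior-predictive location/scale, as sometimes written for the new-basis
# weight), or "uniform" (constant; used for prior-only diagnostics).
component_predictive_logpdf <- function(x, stats, prior, kind = "t") {
  switch(kind,
    t = posterior_predictive_logpdf(x, stats, prior),
    normal = {
      pp <- predictive_params(stats, prior)
      mvn_logpdf_chol(matrix(x, ncol = prior$d), pp$mu, chol(pp$sigma))
    },
    uniform = 0,
    stop("unknown predictive kind: ", kind))
}

#' Chinese-restaurant reassignment probabilities for one cell
#'
#' Given a cell already removed from its component's statistics, returns
#' the normalized probability of joining each occupied component (count
#' times posterior-predictive density) or opening a new one (alpha times
#' the prior predictive).
#'
#' @param x Numeric vector of length `d`; the cell being reassigned.
#' @param state A list with element `stats`: a list of
#'   [component_stats()] for the occupied components (the cell itself
#'   excluded).
#' @param prior A [niw_hyperparams()]; `alpha` is the Dirichlet-process
#'   concentration.
#' @param new_basis `"t"` (default, the `n = 0` prior-predictive Student
#'   t) or `"normal"` (normal density with the prior-predictive location
#'   and scale) for the new-component weight.
#' @param predictive `"t"` for the posterior-predictive t on occupied
#'   components, or `"uniform"` to drop the data term entirely
#'   (prior-only diagnostics).
#' @return Numeric probability vector of length `K_active + 1`; the last
#'   entry is the new-component probability.
#' @export
crp_reassignment_probs <- function(x, state, prior,
                                   new_basis = c("t", "normal"),
                                   predictive = c("t", "uniform")) {
  new_basis <- match.arg(new_basis)
  predictive <- match.arg(predictive)
  stats <- state$stats
  K <- length(stats)
  counts <- vapply(stats, `[[`, 1.0, "n")
  logw <- numeric(K + 1L)
  for (k in seq_len(K)) {
    lk <- if (predictive == "uniform") 0 else
      component_predictive_logpdf(x, stats[[k]], prior, "t")
    logw[k] <- log(counts[k]) + lk
  }
  lnew <- if (predictive == "uniform") 0 else
    component_predictive_logpdf(x, component_stats(0, d = prior$d), prior,
                                kind = new_basis)
  logw[K + 1L] <- log(prior$alpha) + lnew
  w <- exp(logw - max(logw))
  w / sum(w)
}

# ---- fast 1-D sweep ------------------------------------------------------
# Maintains per-component n, mean and M2 = n * S2 as plain vectors so the
# per-cell predictive is vectorized scalar arithmetic.
sweep_1d <- function(x, z, n, m, M2, prior, new_basis, order_idx) {
  mu0 <- prior$mu0; k0 <- prior$kappa0
  s0 <- prior$sigma0[1L, 1L]; nu0 <- prior$nu0; alpha <- prior$alpha
  # prior-predictive (n = 0) constants for the new-component weight
  s_new <- s0 * (k0 + 1) / k0
  lognew <- if (new_basis == "t") {
    function(xi) lgamma((nu0 + 1) / 2) - lgamma(nu0 / 2) - 0.5 * log(pi) -
      0.5 * log(s_new) - 0.5 * (nu0 + 1) * log1p((xi - mu0)^2 / s_new)
  } else {
    function(xi) stats::dnorm(xi, mu0, sqrt(s_new), log = TRUE)
  }
  for (i in order_idx) {
    xi <- x[i]
    j <- z[i]
    # remove cell i from component j
    if (n[j] == 1) {
      n <- n[-j]; m <- m[-j]; M2 <- M2[-j]
      z[z > j] <- z[z > j] - 1L
    } else {
      nj <- n[j] - 1
      mj <- (n[j] * m[j] - xi) / nj
      M2[j] <- max(M2[j] - (xi - mj) * (xi - m[j]), 0)
      n[j] <- nj; m[j] <- mj
    }
    # posterior-predictive t for each occupied component (vectorized)
    nu <- n + nu0
    muy <- (n * m + k0 * mu0) / (n + k0)
    m0f <- (n + k0) / (n + k0 + 1)
    m1f <- n * k0 / (n + k0)
    sy <- (m1f * (mu0 - m)^2 + M2 + s0) / m0f
    logw <- log(n) + lgamma((nu + 1) / 2) - lgamma(nu / 2) -
      0.5 * log(pi) - 0.5 * log(sy) -
      0.5 * (nu + 1) * log1p((xi - muy)^2 / sy)
    logw <- c(logw, log(alpha) + lognew(xi))
    w <- exp(logw - max(logw))
    k <- sample.int(length(w), 1L, prob = w)
    if (k > length(n)) {                  # open a new component
      n <- c(n, 1); m <- c(m, xi); M2 <- c(M2, 0)
    } else {
      nk <- n[k] + 1
      delta <- xi - m[k]
      mk <- m[k] + delta / nk
      M2[k] <- M2[k] + delta * (xi - mk)
      n[k] <- nk; m[k] <- mk
    }
    z[i] <- k
  }
  list(z = z, n = n, m = m, M2 = M2)
}

#' One Chinese-restaurant reassignment sweep
#'
#' Visits every cell, removes it from its component (deleting the
#' component if the cell was its only member), and redraws its label from
#' [crp_reassignment_probs()]. A newly opened component starts with
#' `n = 1`, mean equal to the cell and zero scatter.
#'
#' @param data An [event_table()].
#' @param state Infinite sampler state: list with `assignments` and
#'   `stats` over the active components.
#' @param prior A [niw_hyperparams()].
#' @param seed Optional integer seed.
#' @param new_basis Passed to [crp_reassignment_probs()].
#' @param shuffle If `TRUE`, visit cells in a random order instead of
#'   data order (diagnostic option).
#' @return The updated state.
#' @export
reassign_sweep <- function(data, state, prior, seed = NULL,
                           new_basis = c("t", "normal"), shuffle = FALSE) {
  new_basis <- match.arg(new_basis)
  if (!is.null(seed)) set.seed(seed)
  x <- data$values
  N <- nrow(x)
  ord <- if (shuffle) sample.int(N) else seq_len(N)
  if (ncol(x) == 1L) {
    n <- vapply(state$stats, `[[`, 1.0, "n")
    m <- vapply(state$stats, function(s) s$mean[1L], 1.0)
    M2 <- vapply(state$stats, function(s) s$n * s$scatter[1L, 1L], 1.0)
    res <- sweep_1d(x[, 1L], state$assignments, n, m, M2, prior,
                    new_basis, ord)
    state$assignments <- res$z
    state$stats <- lapply(seq_along(res$n), function(k)
      component_stats(res$n[k], res$m[k],
                      matrix(res$M2[k] / res$n[k], 1, 1)))
    return(state)
  }
  # generic multivariate path
  z <- state$assignments
  stats <- state$stats
  for (i in ord) {
    xi <- x[i, ]
    j <- z[i]
    if (stats[[j]]$n == 1) {
      stats[[j]] <- NULL
      z[z > j] <- z[z > j] - 1L
    } else {
      stats[[j]] <- update_stats_remove(stats[[j]], xi)
    }
    pr <- crp_reassignment_probs(xi, list(stats = stats), prior,
                                 new_basis = new_basis)
    k <- sample.int(length(pr), 1L, prob = pr)
    if (k > length(stats)) {
      stats[[k]] <- component_stats(1, xi, matrix(0, length(xi), length(xi)))
    } else {
      stats[[k]] <- update_stats_add(stats[[k]], xi)
    }
    z[i] <- k
  }
  state$assignments <- z
  state$stats <- stats
  state
}

#' Run the Dirichlet-process mixture Gibbs sampler
#'
#' Alternates a Chinese-restaurant reassignment sweep with parameter
#' draws for each active component: weights from `Dirichlet(n_j +
#' alpha)`, covariance from its marginal (mean-integrated)
#' inverse-Wishart conditional, then the mean conditional on the new
#' covariance. The number of active components varies across draws;
#' `config$n_components` is ignored. The chain starts from
#' `init_components` clusters (default 1): single-cell reassignment
#' splits overpopulated components quickly but merges redundant ones very
#' slowly, so starting small mixes better than starting from many
#' clusters.
#'
#' @inheritParams run_finite_chain
#' @param new_basis Passed to [reassign_sweep()].
#' @param shuffle Visit order per sweep; see [reassign_sweep()].
#' @param init_components Number of initial k-means components.
#' @return A `mixture_chain` with draws of varying component count; also
#'   carries `n_active`, the active-component count per stored draw.
#' @export
run_infinite_chain <- function(data, config = chain_config(),
                               prior = default_hyperparams(data),
                               new_basis = c("t", "normal"),
                               shuffle = FALSE, init_components = 1L) {
  new_basis <- match.arg(new_basis)
  stopifnot(inherits(data, "event_table"))
  set.seed(config$seed)
  K0 <- min(init_components, n_events(data))
  st0 <- init_finite_state(data, K0, config$init_method)
  # drop initial empty components so every active component has n >= 1
  keep <- which(vapply(st0$stats, `[[`, 1.0, "n") > 0)
  relabel <- match(seq_along(st0$stats), keep)
  state <- list(assignments = relabel[st0$assignments],
                stats = st0$stats[keep])
  x_names <- data$channel_names
  draws <- list()
  n_active <- integer(0)
  for (it in seq_len(config$n_iterations)) {
    state <- reassign_sweep(data, state, prior, new_basis = new_basis,
                            shuffle = shuffle)
    K <- length(state$stats)
    counts <- vapply(state$stats, `[[`, 1.0, "n")
    w <- rdirichlet1(counts + prior$alpha)
    comps <- vector("list", K)
    for (k in seq_len(K)) {
      sig <- niw_sample_covariance_marginal(state$stats[[k]], prior)
      mu <- niw_sample_mean(state$stats[[k]], sig, prior)
      comps[[k]] <- gaussian_component(w[k], mu, sig)
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      draws[[length(draws) + 1L]] <- mixture_model(comps, x_names)
      n_active <- c(n_active, K)
    }
  }
  structure(list(draws = draws, config = config, prior = prior,
                 n_active = n_active),
            class = "mixture_chain")
}
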