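# Gibbs sampler for a finite Bayesian Gaussian mixture. This fits the
# noise (autofluorescence) data, and doubles as the "null model" that
# fits the convolved data directly, ignoring the noise.

#' Markov-chain configuration
#'
#' @param n_components Number of mixture components `K` (ignored by the
#'   Dirichlet-process sampler).
#' @param n_iterations Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before storing draws.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed; mandatory for reproducible chains.
#' @param init_method `"kmeans"` (default) or `"random"` initial
#'   assignment of cells to components.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_components = 4, n_iterations = 2000,
                         burn_in = 1000, thin = 10, seed = 1,
                         init_method = c("kmeans", "random")) {
  init_method <- match.arg(init_method)
  stopifnot(n_components >= 1, thin >= 1, n_iterations >= 1)
  if (burn_in >= n_iterations)
    stop("burn_in must be smaller than n_iterations")
  structure(list(n_components = as.integer(n_components),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), init_method = init_method),
            class = "chain_config")
}

# N x K matrix of log(omega_k) + log N(x_i | mu_k, Sigma_k)
assignment_logweights <- function(x, weights, means, chols) {
  K <- length(weights)
  lp <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    lw <- if (weights[k] > 0) log(weights[k]) else -Inf
    lp[, k] <- lw + mvn_logpdf_chol(x, means[[k]], chols[[k]])
  }
  lp
}

# Draw one categorical index per row of a log-weight matrix (Gumbel-max).
# Rows whose weights all underflow take the max log-weight, with a warning.
sample_categorical_rows <- function(logw) {
  bad <- !is.finite(apply(logw, 1L, max))
  if (any(bad)) {
    warning(sum(bad), " cell(s) had fully underflowing assignment weights; ",
            "assigned by maximum log-weight", call. = FALSE)
    logw[bad, ] <- 0
  }
  g <- -log(-log(matrix(stats::runif(length(logw)), nrow(logw), ncol(logw))))
  max.col(logw + g, ties.method = "first")
}

# Per-component batch statistics for an assignment vector (K fixed).
grouped_stats <- function(x, z, K) {
  d <- ncol(x)
  counts <- tabulate(z, nbins = K)
  lapply(seq_len(K), function(k) {
    n <- counts[k]
    if (n == 0) return(component_stats(0, d = d))
    xk <- x[z == k, , drop = FALSE]
    m <- colMeans(xk)
    xc <- sweep(xk, 2L, m)
    component_stats(n, m, crossprod(xc) / n)
  })
}

#' Resample the component indicator of every cell
#'
#' Each cell draws its component from the multinomial with weights
#' proportional to `omega_k N(x_i | mu_k, Sigma_k)`; the per-component
#' sufficient statistics are recomputed to match.
#'
#' @param data An [event_table()].
#' @param state A finite sampler state as produced by the internal
#'   initializer of [run_finite_chain()].
#' @param seed Optional integer seed.
#' @return The updated state.
#' @export
sample_indicators <- function(data, state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- data$values
  means <- lapply(state$components, `[[`, "mean")
  chols <- lapply(state$components, `[[`, "chol")
  logw <- assignment_logweights(x, state$weights, means, chols)
  state$assignments <- sample_categorical_rows(logw)
  state$stats <- grouped_stats(x, state$assignments, length(state$weights))
  state
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(shape))  # degenerate underflow guard
  g / sum(g)
}

#' Resample the mixture weights
#'
#' Weights are drawn from `Dirichlet(n_j + alpha / K)`, the conditional
#' posterior under the symmetric Dirichlet prior.
#'
#' @param state Finite sampler state.
#' @param prior A [niw_hyperparams()] (only `alpha` is used).
#' @param seed Optional integer seed.
#' @return The updated state.
#' @export
sample_weights <- function(state, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(state$weights)
  counts <- vapply(state$stats, `[[`, 1.0, "n")
  state$weights <- rdirichlet1(counts + prior$alpha / K)
  state
}

#' Resample every component's covariance and mean
#'
#' For each component the covariance is drawn conditional on the current
#' mean (inverse-Wishart), then the mean conditional on the new
#' covariance (normal) — covariance first, then mean. Components with no
#' assigned cells draw from the prior-only conditionals.
#'
#' @param data An [event_table()] (unused directly; statistics live in
#'   the state, kept in the signature for symmetry with the other steps).
#' @param state Finite sampler state.
#' @param prior A [niw_hyperparams()].
#' @param seed Optional integer seed.
#' @return The updated state.
#' @export
sample_component_params <- function(data, state, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(state$weights)
  for (k in seq_len(K)) {
    st <- state$stats[[k]]
    mu_cur <- state$components[[k]]$mean
    sig <- niw_sample_covariance_conditional(st, mu_cur, prior)
    mu <- niw_sample_mean(st, sig, prior)
    state$components[[k]] <- gaussian_component(state$weights[k], mu, sig)
  }
  state
}

# Initial state: assign cells (k-means or random), set each component's
# parameters to its empirical statistics and weight to its share of cells.
init_finite_state <- function(data, K, init_method = "kmeans") {
  x <- data$values
  N <- nrow(x)
  if (N < K) stop("need at least as many cells (", N, ") as components (", K, ")")
  z <- if (K == 1L) {
    rep(1L, N)
  } else if (init_method == "kmeans") {
    km <- suppressWarnings(stats::kmeans(x, centers = K, nstart = 3,
                                         iter.max = 50))
    km$cluster
  } else {
    sample.int(K, N, replace = TRUE)
  }
  stats <- grouped_stats(x, z, K)
  counts <- vapply(stats, `[[`, 1.0, "n")
  w <- counts / N
  overall <- batch_stats(x)
  comps <- lapply(seq_len(K), function(k) {
    st <- stats[[k]]
    if (st$n >= 2 && min(eigen(st$scatter, symmetric = TRUE,
                               only.values = TRUE)$values) > 1e-12) {
      gaussian_component(w[k], st$mean, st$scatter)
    } else {
      # empty or degenerate cluster: fall back to overall moments
      gaussian_component(w[k], overall$mean,
                         ensure_spd(overall$scatter, "initial covariance"))
    }
  })
  list(assignments = z, stats = stats, weights = w, components = comps,
       iteration = 0L)
}

# Normalize weights into the stored components and build a mixture_model.
state_to_mixture <- function(state, channel_names) {
  comps <- Map(function(cp, w) gaussian_component(w, cp$mean, cp$covariance),
               state$components, as.list(state$weights / sum(state$weights)))
  mixture_model(comps, channel_names)
}

#' Run the finite-mixture Gibbs sampler
#'
#' Fits a `K`-component Bayesian Gaussian mixture to an event table.
#' Each sweep resamples the indicators, the weights and the component
#' parameters; post-burn-in, thinned states are returned as
#' [mixture_model()] draws. Chains are fully reproducible given
#' `config$seed`.
#'
#' @param data An [event_table()].
#' @param config A [chain_config()].
#' @param prior A [niw_hyperparams()]; defaults to
#'   [default_hyperparams()] of the data.
#' @return A list of class `mixture_chain`: elements `draws` (list of
#'   [mixture_model()]), `config`, `prior`.
#' @examples
#' x <- sample_mixture(mixture_model(list(gaussian_component(1, 0, 1))), 500, seed = 1)
#' fit <- run_finite_chain(x, chain_config(2, 200, 100, 5, seed = 1))
#' length(fit$draws)
#' @export
run_finite_chain <- function(data, config = chain_config(),
                             prior = default_hyperparams(data)) {
  stopifnot(inherits(data, "event_table"), inherits(config, "chain_config"))
  set.seed(config$seed)
  K <- config$n_components
  state <- init_finite_state(data, K, config$init_method)
  draws <- vector("list", (config$n_iterations - config$burn_in) %/% config$thin)
  nd <- 0L
  for (it in seq_len(config$n_iterations)) {
    state <- sample_indicators(data, state)
    state <- sample_weights(state, prior)
    state <- sample_component_params(data, state, prior)
    state$iteration <- it
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      nd <- nd + 1L
      draws[[nd]] <- state_to_mixture(state, data$channel_names)
    }
  }
  structure(list(draws = draws[seq_len(nd)], config = config, prior = prior),
            class = "mixture_chain")
}

#' @export
print.mixture_chain <- function(x, ...) {
  cat("Mixture posterior chain:", length(x$draws), "stored draws\n")
  invisible(x)
}

#' Export a posterior chain to JSON
#'
#' Writes all stored draws in the mixture JSON layout plus a metadata
#' header (seed, configuration, prior).
#'
#' @param chain A `mixture_chain` from [run_finite_chain()] or
#'   [run_infinite_chain()].
#' @param path Optional output file.
#' @return JSON string (invisibly if written to file).
#' @export
chain_to_json <- function(chain, path = NULL) {
  obj <- list(
    config = unclass(chain$config),
    prior = list(mu0 = chain$prior$mu0, kappa0 = chain$prior$kappa0,
                 sigma0 = as.numeric(t(chain$prior$sigma0)),
                 nu0 = chain$prior$nu0, alpha = chain$prior$alpha),
    draws = lapply(chain$draws, function(m)
      jsonlite::fromJSON(mixture_to_json(m), simplifyVector = FALSE))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
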