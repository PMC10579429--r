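# Posterior sampling of the target mixture given noise data and convolved
# data. The posterior factorizes into (i) a plain mixture fit of the noise
# data and (ii) a convolved-mixture Gibbs sampler for the target,
# conditioned on stored noise-posterior draws. The convolved covariance
# conditional has no closed form; it is made inverse-Wishart by the
# correction factor (I - tauhat_jk Sigma_j^xi) applied to each pair's
# scale contribution, where tauhat is the inverse of the pair's effective
# expected covariance.

#' Fit the noise (autofluorescence) distribution
#'
#' Delegates to the finite or Dirichlet-process mixture sampler on the
#' unlabeled-cell data; the stored draws are reused by
#' [run_deconvolution()] as the noise posterior.
#'
#' @param noise_data An [event_table()] of unlabeled-cell events.
#' @param config A [chain_config()].
#' @param prior A [niw_hyperparams()]; defaults to data moments.
#' @param model `"finite"` or `"infinite"`.
#' @return A `mixture_chain`.
#' @export
fit_noise <- function(noise_data, config = chain_config(),
                      prior = default_hyperparams(noise_data),
                      model = c("finite", "infinite")) {
  model <- match.arg(model)
  stopifnot(inherits(noise_data, "event_table"))
  if (n_events(noise_data) < 1) stop("noise data is empty")
  if (model == "finite") run_finite_chain(noise_data, config, prior)
  else run_infinite_chain(noise_data, config, prior)
}

#' Effective expected covariance of a (noise, target) pair
#'
#' `Sigmahat_jk = n_jk S2_jk + kappa0 (xbar_jk - mu0)(xbar_jk - mu0)' +
#' Sigma0`; its inverse is the `tauhat_jk` entering the correction factor
#' `(I - tauhat_jk Sigma_j^xi)`. For an empty pair the data terms vanish
#' and the result is `Sigma0`.
#'
#' @param pair_stats A [component_stats()] for the cells assigned to the
#'   pair.
#' @param prior A [niw_hyperparams()] (the target prior).
#' @return A `d x d` positive-definite matrix.
#' @export
effective_covariance_hat <- function(pair_stats, prior) {
  n <- pair_stats$n
  if (n == 0) return(prior$sigma0)
  dm <- pair_stats$mean - prior$mu0
  s <- n * pair_stats$scatter + prior$kappa0 * tcrossprod(dm) + prior$sigma0
  (s + t(s)) / 2
}

# correction factor (I - tauhat Sigma_xi), symmetrized and eigenvalue-
# floored when the approximation overshoots; returns matrix + clip flag.
# tauhat is the inverse of the pair's expected covariance: the
# inverse-Wishart scale sigma_hat normalized by its posterior-mean
# denominator (n + nu0 - p), so that for well-populated pairs the factor
# shrinks the convolved scale n (Sigma_T + Sigma_xi) to ~ n Sigma_T.
correction_factor <- function(sigma_hat, sigma_xi, denom, floor = 1e-8) {
  d <- nrow(sigma_hat)
  m <- diag(d) - chol2inv(chol(sigma_hat / denom)) %*% sigma_xi
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  clipped <- any(ev$values < floor)
  if (clipped) {
    ev$values <- pmax(ev$values, floor)
    m <- ev$vectors %*% (ev$values * t(ev$vectors))
  }
  # mean eigenvalue = the pair's effective information fraction: the same
  # factor that shrinks the trace term applies to the determinant
  # exponent, so a cell in this pair carries ~fraction degrees of freedom
  # about the target covariance
  list(matrix = m, clipped = clipped,
       fraction = min(mean(pmax(ev$values, floor)), 1))
}

# pair index helpers: pairs laid out with noise j varying slowest
pair_index <- function(j, k, KT) (j - 1L) * KT + k

#' Resample the (noise, target) pair indicator of every cell
#'
#' Each cell draws its pair `(j, k)` with probability proportional to
#' `omega_j^xi omega_k^T N(c_i | mu_j^xi + mu_k^T, Sigma_j^xi +
#' Sigma_k^T)`; pair sufficient statistics are recomputed.
#'
#' @param conv_data An [event_table()] of labeled-cell (total signal)
#'   events.
#' @param state A convolved sampler state (see [run_deconvolution()]).
#' @param seed Optional integer seed.
#' @return The updated state.
#' @export
sample_pair_indicators <- function(conv_data, state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- conv_data$values
  noise <- state$noise
  KT <- length(state$target_components)
  Kxi <- length(noise$components)
  means <- vector("list", Kxi * KT)
  chols <- vector("list", Kxi * KT)
  w <- numeric(Kxi * KT)
  for (j in seq_len(Kxi)) {
    cn <- noise$components[[j]]
    for (k in seq_len(KT)) {
      ct <- state$target_components[[k]]
      p <- pair_index(j, k, KT)
      means[[p]] <- cn$mean + ct$mean
      chols[[p]] <- chol(cn$covariance + ct$covariance)
      w[p] <- cn$weight * state$target_weights[k]
    }
  }
  logw <- assignment_logweights(x, w, means, chols)
  state$pair_assignments <- sample_categorical_rows(logw)
  state$pair_stats <- grouped_stats(x, state$pair_assignments, Kxi * KT)
  state
}

#' Resample the target mixture weights
#'
#' The target counts sum the pair counts over the noise index,
#' `n_k^T = sum_j n_jk`; weights are drawn from
#' `Dirichlet(n^T + alpha / K_T)`.
#'
#' @param state Convolved sampler state.
#' @param prior Target [niw_hyperparams()].
#' @param seed Optional integer seed.
#' @return The updated state.
#' @export
sample_target_weights <- function(state, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  KT <- length(state$target_components)
  nT <- target_counts(state)
  state$target_weights <- rdirichlet1(nT + prior$alpha / KT)
  state
}

target_counts <- function(state) {
  KT <- length(state$target_components)
  Kxi <- length(state$noise$components)
  n_jk <- vapply(state$pair_stats, `[[`, 1.0, "n")
  vapply(seq_len(KT), function(k)
    sum(n_jk[pair_index(seq_len(Kxi), k, KT)]), 1.0)
}

#' Resample the target covariances under the convolved model
#'
#' For each target component `k` the per-pair scale `Sigmatilde_jk` (data
#' scatter around `mu_j^xi + mu_k^T`, plus the prior terms) is corrected
#' by `(I - tauhat_jk Sigma_j^xi)` and summed over the noise components;
#' the covariance is then drawn from an inverse-Wishart with
#' `nu0 + 1 + sum_j n_jk fbar_jk` degrees of freedom, where `fbar_jk` is
#' the mean eigenvalue of the pair's correction factor: the correction
#' applies to the determinant exponent as well as the trace term, so a
#' cell carries only the corrected fraction of a degree of freedom about
#' the target covariance (with no noise, `fbar = 1` and the count reduces
#' to the plain `n_k + nu0 + 1`). Correction factors that lose
#' positive-definiteness are eigenvalue-floored and counted in
#' `state$clip_count`.
#'
#' @inheritParams sample_target_weights
#' @param prior_mode `"single"` (default): the prior terms `kappa0
#'   (mu_k - mu0)(mu_k - mu0)' + Sigma0` enter the aggregated scale once
#'   per target component, outside the noise correction, so sparsely
#'   populated pairs cannot erase the prior when their correction factor
#'   is clipped. `"per-pair"`: the prior terms are repeated inside the
#'   per-pair sum (and corrected with it), i.e. counted once per noise
#'   component.
#' @return The updated state.
#' @export
sample_target_covariance <- function(state, prior, seed = NULL,
                                     prior_mode = c("single", "per-pair")) {
  prior_mode <- match.arg(prior_mode)
  if (!is.null(seed)) set.seed(seed)
  noise <- state$noise
  KT <- length(state$target_components)
  Kxi <- length(noise$components)
  d <- prior$d
  nT <- target_counts(state)
  for (k in seq_len(KT)) {
    mu_k <- state$target_components[[k]]$mean
    dm0 <- mu_k - prior$mu0
    prior_term <- prior$kappa0 * tcrossprod(dm0) + prior$sigma0
    agg <- if (prior_mode == "single") prior_term else matrix(0, d, d)
    df_k <- prior$nu0 + 1
    for (j in seq_len(Kxi)) {
      st <- state$pair_stats[[pair_index(j, k, KT)]]
      if (st$n == 0 && prior_mode == "single") next
      mu_j <- noise$components[[j]]$mean
      s_jk <- if (prior_mode == "per-pair") prior_term else matrix(0, d, d)
      if (st$n > 0) {
        dmn <- st$mean - mu_j - mu_k
        s_jk <- s_jk + st$n * st$scatter + st$n * tcrossprod(dmn)
      }
      hat <- effective_covariance_hat(st, prior)
      cf <- correction_factor(hat, noise$components[[j]]$covariance,
                              max(st$n + prior$nu0 - d, 1))
      if (cf$clipped) state$clip_count <- state$clip_count + 1L
      # Laplace-matched inverse-Wishart: mode f*C and curvature n*f^2 of
      # the exact conditional give scale ~ n C f^3 and df ~ n f^2, so the
      # pair's corrected scatter and count both carry an extra f^2
      agg <- agg + (s_jk %*% cf$matrix) * cf$fraction^2
      df_k <- df_k + st$n * cf$fraction^2
    }
    agg <- (agg + t(agg)) / 2
    ev <- eigen(agg, symmetric = TRUE)
    flo <- 1e-8 * max(sum(abs(ev$values)), 1e-12) / d
    if (any(ev$values < flo)) {
      state$clip_count <- state$clip_count + 1L
      ev$values <- pmax(ev$values, flo)
      agg <- ev$vectors %*% (ev$values * t(ev$vectors))
    }
    sig <- riwish1(agg, max(df_k, d + 0.01))
    cp <- state$target_components[[k]]
    state$target_components[[k]] <- gaussian_component(cp$weight, cp$mean, sig)
  }
  state
}

#' Resample the target means under the convolved model
#'
#' Precision `tautilde_k = sum_j (n_jk + kappa0)(Sigma_j^xi +
#' Sigma_k^T)^{-1}` and mean `mutilde_k = tautilde_k^{-1} sum_j
#' (Sigma_j^xi + Sigma_k^T)^{-1} (n_jk xbar_jk + kappa0 mu0)`; the mean
#' is drawn from the corresponding multivariate normal.
#'
#' @inheritParams sample_target_covariance
#' @return The updated state.
#' @export
sample_target_mean <- function(state, prior, seed = NULL,
                               prior_mode = c("single", "per-pair")) {
  prior_mode <- match.arg(prior_mode)
  if (!is.null(seed)) set.seed(seed)
  noise <- state$noise
  KT <- length(state$target_components)
  Kxi <- length(noise$components)
  d <- prior$d
  k0 <- prior$kappa0
  for (k in seq_len(KT)) {
    sig_k <- state$target_components[[k]]$covariance
    tau <- matrix(0, d, d)
    rhs <- numeric(d)
    pinv_sum <- matrix(0, d, d)
    for (j in seq_len(Kxi)) {
      st <- state$pair_stats[[pair_index(j, k, KT)]]
      pinv <- chol2inv(chol(noise$components[[j]]$covariance + sig_k))
      pinv_sum <- pinv_sum + pinv
      if (prior_mode == "per-pair") {
        tau <- tau + (st$n + k0) * pinv
        rhs <- rhs + pinv %*% (st$n * st$mean + k0 * prior$mu0)
      } else {
        tau <- tau + st$n * pinv
        rhs <- rhs + st$n * (pinv %*% st$mean)
      }
    }
    if (prior_mode == "single") {
      # prior precision counted once, at the weight-averaged pair precision
      tau <- tau + k0 * pinv_sum / Kxi
      rhs <- rhs + k0 * (pinv_sum / Kxi) %*% prior$mu0
    }
    tau <- (tau + t(tau)) / 2
    ch <- tryCatch(chol(tau), error = function(e)
      stop("singular target-mean precision for component ", k))
    cov_mu <- chol2inv(ch)
    mu_tilde <- drop(cov_mu %*% rhs)
    mu <- drop(mu_tilde + crossprod(chol((cov_mu + t(cov_mu)) / 2),
                                    stats::rnorm(d)))
    cp <- state$target_components[[k]]
    state$target_components[[k]] <- gaussian_component(cp$weight, mu,
                                                       cp$covariance)
  }
  state
}

# initial convolved state: k-means clusters of the convolved data, shifted
# and narrowed by the current noise draw's moments
init_convolved_state <- function(conv_data, KT, noise_draw, prior,
                                 init_method = "kmeans") {
  x <- conv_data$values
  d <- ncol(x)
  st0 <- init_finite_state(conv_data, KT, init_method)
  mu_xi <- mixture_mean(noise_draw)
  sig_xi <- mixture_covariance(noise_draw)
  comps <- lapply(seq_len(KT), function(k) {
    cp <- st0$components[[k]]
    sig <- cp$covariance - sig_xi
    ev <- eigen((sig + t(sig)) / 2, symmetric = TRUE)
    flo <- 0.1 * sum(diag(cp$covariance)) / d
    ev$values <- pmax(ev$values, flo)
    gaussian_component(cp$weight, cp$mean - mu_xi,
                       ev$vectors %*% (ev$values * t(ev$vectors)))
  })
  list(noise = noise_draw,
       target_components = comps,
       target_weights = vapply(comps, `[[`, 1.0, "weight"),
       pair_assignments = NULL, pair_stats = NULL,
       clip_count = 0L)
}

#' Data-driven target prior for the convolved model
#'
#' Centers the target prior where the target density should lie: prior
#' mean = convolved-data mean minus noise-data mean; prior scale =
#' convolved covariance minus noise covariance. The moment difference can
#' be arbitrarily small or negative by sampling fluctuation, so its
#' eigenvalues are floored at the larger of 10% of the convolved
#' covariance and the sampling standard error of the difference itself,
#' `sqrt(2/N) (var(c) + var(xi))` per channel — at small N, where the
#' moment estimate is uninformative, the prior widens to match that
#' uncertainty instead of asserting a near-zero target variance; at large
#' N the floor vanishes and the moment difference takes over.
#'
#' @param conv_data,noise_data [event_table()]s.
#' @param alpha,kappa0,nu0 Passed to [niw_hyperparams()].
#' @return A [niw_hyperparams()].
#' @export
target_prior_from_data <- function(conv_data, noise_data, alpha = 1,
                                   kappa0 = 1, nu0 = NULL) {
  xc <- conv_data$values
  xn <- noise_data$values
  d <- ncol(xc)
  covc <- stats::cov(xc)
  covn <- stats::cov(xn)
  dcov <- covc - covn
  ev <- eigen((dcov + t(dcov)) / 2, symmetric = TRUE)
  flo <- max(0.1 * sum(diag(covc)) / d,
             sqrt(2 / nrow(xc)) * sum(diag(covc) + diag(covn)) / d)
  ev$values <- pmax(ev$values, flo)
  sigma0 <- ev$vectors %*% (ev$values * t(ev$vectors))
  niw_hyperparams(mu0 = colMeans(xc) - colMeans(xn), kappa0 = kappa0,
                  sigma0 = sigma0, nu0 = nu0, alpha = alpha)
}

#' Bayesian deconvolution of a target distribution from noisy signal
#'
#' The main entry point. Fits the noise mixture on the unlabeled-cell
#' data, then runs the convolved Gibbs sampler on the labeled-cell data:
#' each iteration refreshes the active noise draw from the stored noise
#' posterior, resamples the per-cell (noise, target) pair indicators, the
#' target weights, the target covariances and the target means.
#'
#' @param noise_data An [event_table()] of unlabeled-cell events.
#' @param conv_data An [event_table()] of labeled-cell events (same
#'   channels).
#' @param config_noise,config_target [chain_config()]s for the two
#'   stages; `config_target$n_components` is the number of target
#'   components `K_T`.
#' @param prior_noise Noise prior; defaults to noise-data moments.
#' @param prior_target Target prior; defaults to
#'   [target_prior_from_data()].
#' @param model `"finite"` (default) or `"infinite"` (Dirichlet-process
#'   reassignment of the target labels, with the noise labels sampled
#'   conditionally).
#' @param noise_model Mixture model used for the noise stage.
#' @param noise_refresh `"cycle"` (default) walks through the stored
#'   noise draws in order; `"resample"` picks one uniformly at random per
#'   iteration.
#' @param prior_mode See [sample_target_covariance()].
#' @return An object of class `deconvolution_posterior` with elements
#'   `noise_draws`, `target_draws`, `clip_count`, `config_noise`,
#'   `config_target`, `prior_noise`, `prior_target`.
#' @examples
#' \donttest{
#' noise <- mixture_model(list(gaussian_component(1, 0, 0.25)))
#' target <- mixture_model(list(
#'   gaussian_component(0.8, -0.43, 0.36),
#'   gaussian_component(0.2, 1.67, 0.36)))
#' xi <- sample_mixture(noise, 2000, seed = 1)
#' tt <- sample_mixture(target, 2000, seed = 2)
#' conv <- event_table(tt$values + xi$values)
#' post <- run_deconvolution(xi, conv,
#'   config_noise = chain_config(2, 300, 150, 5, seed = 3),
#'   config_target = chain_config(2, 300, 150, 5, seed = 4))
#' mio(target, averaged_density(post$target_draws))
#' }
#' @export
run_deconvolution <- function(noise_data, conv_data,
                              config_noise = chain_config(),
                              config_target = chain_config(),
                              prior_noise = default_hyperparams(noise_data),
                              prior_target = target_prior_from_data(conv_data,
                                                                    noise_data),
                              model = c("finite", "infinite"),
                              noise_model = c("finite", "infinite"),
                              noise_refresh = c("cycle", "resample"),
                              prior_mode = c("single", "per-pair")) {
  model <- match.arg(model)
  noise_model <- match.arg(noise_model)
  noise_refresh <- match.arg(noise_refresh)
  stopifnot(inherits(noise_data, "event_table"),
            inherits(conv_data, "event_table"))
  if (n_channels(noise_data) != n_channels(conv_data))
    stop("noise and convolved tables have different channel dimensions: ",
         n_channels(noise_data), " vs ", n_channels(conv_data))
  noise_chain <- fit_noise(noise_data, config_noise, prior_noise,
                           model = noise_model)
  if (model == "finite")
    run_convolved_finite(conv_data, noise_chain, config_target, prior_target,
                         noise_refresh, prior_mode)
  else
    run_convolved_infinite(conv_data, noise_chain, config_target,
                           prior_target, noise_refresh, prior_mode)
}

pick_noise_draw <- function(draws, it, how) {
  if (how == "cycle") draws[[(it - 1L) %% length(draws) + 1L]]
  else draws[[sample.int(length(draws), 1L)]]
}

run_convolved_finite <- function(conv_data, noise_chain, config, prior,
                                 noise_refresh, prior_mode) {
  set.seed(config$seed)
  KT <- config$n_components
  state <- init_convolved_state(conv_data, KT, noise_chain$draws[[1L]],
                                prior, config$init_method)
  target_draws <- list()
  noise_draws <- list()
  for (it in seq_len(config$n_iterations)) {
    state$noise <- pick_noise_draw(noise_chain$draws, it, noise_refresh)
    state <- sample_pair_indicators(conv_data, state)
    state <- sample_target_weights(state, prior)
    state <- sample_target_covariance(state, prior, prior_mode = prior_mode)
    state <- sample_target_mean(state, prior, prior_mode = prior_mode)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      comps <- Map(function(cp, w) gaussian_component(w, cp$mean, cp$covariance),
                   state$target_components,
                   as.list(state$target_weights / sum(state$target_weights)))
      target_draws[[length(target_draws) + 1L]] <-
        mixture_model(comps, conv_data$channel_names)
      noise_draws[[length(noise_draws) + 1L]] <- state$noise
    }
  }
  new_deconvolution_posterior(noise_draws, target_draws, state$clip_count,
                              noise_chain, config, prior)
}

# Dirichlet-process variant: the target labels are reassigned by the
# Chinese-restaurant rule with the cell's current noise component held
# fixed; occupied-component weights use the current parameters (the
# convolved predictive has no closed form), the new-component weight uses
# the prior-predictive t widened by the cell's noise covariance.
run_convolved_infinite <- function(conv_data, noise_chain, config, prior,
                                   noise_refresh, prior_mode) {
  set.seed(config$seed)
  x <- conv_data$values
  N <- nrow(x)
  d <- ncol(x)
  state <- init_convolved_state(conv_data, min(config$n_components, N),
                                noise_chain$draws[[1L]], prior,
                                config$init_method)
  state <- sample_pair_indicators(conv_data, state)
  KT <- length(state$target_components)
  z_t <- (state$pair_assignments - 1L) %% KT + 1L
  z_n <- (state$pair_assignments - 1L) %/% KT + 1L
  target_draws <- list()
  noise_draws <- list()
  for (it in seq_len(config$n_iterations)) {
    state$noise <- pick_noise_draw(noise_chain$draws, it, noise_refresh)
    Kxi <- length(state$noise$components)
    z_n <- pmin(z_n, Kxi)
    # (a) noise labels given target components
    KT <- length(state$target_components)
    logw <- matrix(-Inf, N, Kxi)
    for (j in seq_len(Kxi)) {
      cn <- state$noise$components[[j]]
      lp <- matrix(0, N, KT)
      for (k in seq_len(KT)) {
        ct <- state$target_components[[k]]
        lp[, k] <- mvn_logpdf_chol(x, cn$mean + ct$mean,
                                   chol(cn$covariance + ct$covariance))
      }
      logw[, j] <- log(cn$weight) + lp[cbind(seq_len(N), z_t)]
    }
    z_n <- sample_categorical_rows(logw)
    # (b) CRP sweep over target labels with noise labels fixed
    counts <- tabulate(z_t, nbins = KT)
    for (i in seq_len(N)) {
      k_old <- z_t[i]
      counts[k_old] <- counts[k_old] - 1L
      if (counts[k_old] == 0L) {
        state$target_components[[k_old]] <- NULL
        counts <- counts[-k_old]
        z_t[z_t > k_old] <- z_t[z_t > k_old] - 1L
        KT <- KT - 1L
      }
      cn <- state$noise$components[[z_n[i]]]
      lw <- numeric(KT + 1L)
      for (k in seq_len(KT)) {
        ct <- state$target_components[[k]]
        lw[k] <- log(counts[k]) +
          mvn_logpdf_chol(x[i, , drop = FALSE], cn$mean + ct$mean,
                          chol(cn$covariance + ct$covariance))
      }
      pp <- predictive_params(component_stats(0, d = d), prior)
      lw[KT + 1L] <- log(prior$alpha) +
        posterior_predictive_widened(x[i, ] - cn$mean, pp, cn$covariance)
      w <- exp(lw - max(lw))
      k_new <- sample.int(KT + 1L, 1L, prob = w)
      if (k_new > KT) {
        sig <- riwish1(prior$sigma0, prior$nu0 + 1)
        mu <- prior$mu0 + drop(crossprod(chol(sig / prior$kappa0),
                                         stats::rnorm(d)))
        state$target_components[[k_new]] <- gaussian_component(0, mu, sig)
        counts <- c(counts, 1L)
        KT <- KT + 1L
      } else {
        counts[k_new] <- counts[k_new] + 1L
      }
      z_t[i] <- k_new
    }
    # (c) parameter draws via the convolved conditionals over (j, k) pairs
    state$target_weights <- rep(1 / KT, KT)
    state$pair_assignments <- (z_n - 1L) * KT + z_t
    state$pair_stats <- grouped_stats(x, state$pair_assignments, Kxi * KT)
    w <- rdirichlet1(counts + prior$alpha)
    state$target_weights <- w
    state <- sample_target_covariance(state, prior, prior_mode = prior_mode)
    state <- sample_target_mean(state, prior, prior_mode = prior_mode)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      comps <- Map(function(cp, wi) gaussian_component(wi, cp$mean, cp$covariance),
                   state$target_components, as.list(w / sum(w)))
      target_draws[[length(target_draws) + 1L]] <-
        mixture_model(comps, conv_data$channel_names)
      noise_draws[[length(noise_draws) + 1L]] <- state$noise
    }
  }
  new_deconvolution_posterior(noise_draws, target_draws, state$clip_count,
                              noise_chain, config, prior)
}

# prior-predictive t evaluated with its scale widened by a noise covariance
posterior_predictive_widened <- function(y, pp, sigma_xi) {
  p <- length(pp$mu)
  sig <- pp$sigma + sigma_xi
  ch <- chol(sig)
  u <- backsolve(ch, y - pp$mu, transpose = TRUE)
  q <- sum(u^2)
  lgamma((pp$nu + p) / 2) - lgamma(pp$nu / 2) - 0.5 * p * log(pi) -
    sum(log(diag(ch))) - 0.5 * (pp$nu + p) * log1p(q)
}

new_deconvolution_posterior <- function(noise_draws, target_draws, clip_count,
                                        noise_chain, config, prior) {
  structure(list(noise_draws = noise_draws, target_draws = target_draws,
                 clip_count = clip_count, noise_chain = noise_chain,
                 config_target = config, prior_target = prior),
            class = "deconvolution_posterior")
}

#' @export
print.deconvolution_posterior <- function(x, ...) {
  cat("Deconvolution posterior:", length(x$target_draws),
      "paired target/noise draws;",
      x$clip_count, "covariance-correction clip(s)\n")
  invisible(x)
}

#' Convolved draws implied by a deconvolution posterior
#'
#' Convolves each stored target draw with its paired noise draw,
#' reconstructing the model's fit to the total-signal data.
#'
#' @param posterior A `deconvolution_posterior`.
#' @return List of [mixture_model()]s.
#' @export
convolved_draws <- function(posterior) {
  stopifnot(inherits(posterior, "deconvolution_posterior"))
  Map(convolve_mixtures, posterior$target_draws, posterior$noise_draws)
}

#' Export a deconvolution posterior to JSON
#'
#' All noise and target draws in the mixture JSON layout, plus run
#' metadata (configuration, prior, correction-clip diagnostics).
#'
#' @param posterior A `deconvolution_posterior`.
#' @param path Optional output file.
#' @return JSON string (invisibly if written to file).
#' @export
posterior_to_json <- function(posterior, path = NULL) {
  stopifnot(inherits(posterior, "deconvolution_posterior"))
  as_obj <- function(m) jsonlite::fromJSON(mixture_to_json(m),
                                           simplifyVector = FALSE)
  obj <- list(
    config_target = unclass(posterior$config_target),
    prior_target = list(mu0 = posterior$prior_target$mu0,
                        kappa0 = posterior$prior_target$kappa0,
                        sigma0 = as.numeric(t(posterior$prior_target$sigma0)),
                        nu0 = posterior$prior_target$nu0,
                        alpha = posterior$prior_target$alpha),
    clip_count = posterior$clip_count,
    noise_draws = lapply(posterior$noise_draws, as_obj),
    target_draws = lapply(posterior$target_draws, as_obj)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
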