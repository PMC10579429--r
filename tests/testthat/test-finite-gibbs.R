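# Finite-mixture Gibbs sampler: conditional-step distributions, count
# conservation, determinism, and density recovery.

make_state <- function(data, K, seed = 1) {
  set.seed(seed)
  scdeconv:::init_finite_state(data, K)
}

test_that("indicator resampling follows the responsibility weights", {
  set.seed(201)
  x <- event_table(stats::rnorm(200))
  st <- make_state(x, 1)
  st <- sample_indicators(x, st, seed = 1)
  expect_true(all(st$assignments == 1L))
  expect_equal(st$stats[[1]]$n, 200)

  # well-separated components: misassignment below the Bayes error bound
  xx <- event_table(c(stats::rnorm(3000, -10), stats::rnorm(3000, 10)))
  st2 <- list(assignments = rep(1L, 6000), stats = NULL,
              weights = c(0.5, 0.5),
              components = list(gaussian_component(0.5, -10, 1),
                                gaussian_component(0.5, 10, 1)))
  st2 <- sample_indicators(xx, st2, seed = 2)
  wrong <- sum(st2$assignments[1:3000] == 2L) +
    sum(st2$assignments[3001:6000] == 1L)
  expect_lt(wrong / 6000, 1e-4)
  expect_equal(sum(vapply(st2$stats, `[[`, 1.0, "n")), 6000)

  # identical components: assignments uniform
  st3 <- list(weights = c(0.5, 0.5),
              components = list(gaussian_component(0.5, 0, 1),
                                gaussian_component(0.5, 0, 1)))
  st3 <- sample_indicators(event_table(stats::rnorm(20000)), st3, seed = 3)
  expect_lt(abs(mean(st3$assignments == 1L) - 0.5), 0.02)
})

test_that("weight resampling is Dirichlet with counts plus alpha over K", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  st <- list(weights = c(0.5, 0.5),
             stats = list(component_stats(3, 0, matrix(0)),
                          component_stats(5, 0, matrix(0))))
  set.seed(202)
  draws <- t(replicate(1e5, sample_weights(st, prior)$weights))
  # Dirichlet(3.5, 5.5) moments
  expect_equal(colMeans(draws), c(3.5, 5.5) / 9, tolerance = 0.005)
  v <- 3.5 * 5.5 / (9^2 * 10)
  expect_equal(stats::var(draws[, 1]), v, tolerance = 0.02 * v + 2e-4)

  # empty counts with alpha = 2 give the uniform Dirichlet(1, 1)
  prior2 <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 2)
  st0 <- list(weights = c(0.5, 0.5),
              stats = list(component_stats(0, d = 1), component_stats(0, d = 1)))
  set.seed(203)
  d0 <- replicate(2e4, sample_weights(st0, prior2)$weights[1])
  expect_gt(stats::ks.test(d0, "punif")$p.value, 0.01)
})

test_that("component parameter draws recover generating parameters", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  # empty component draws from the prior conditionals
  x0 <- event_table(stats::rnorm(10))
  st <- list(weights = c(1, 0),
             stats = list(batch_stats(stats::rnorm(10)),
                          component_stats(0, d = 1)),
             components = list(gaussian_component(1, 0, 1),
                               gaussian_component(0, 0, 1)))
  set.seed(204)
  prior_draws <- replicate(4000, {
    s <- sample_component_params(x0, st, prior)
    s$components[[2]]$covariance[1, 1]
  })
  # prior-limit inverse-Wishart(1, nu0 + 1 = 4) has mean 1/2
  expect_equal(mean(prior_draws), 0.5, tolerance = 0.05)

  # single component, large N: posterior concentrates on the truth
  set.seed(205)
  xx <- event_table(stats::rnorm(1e4, 2, 1.5))
  stt <- make_state(xx, 1)
  mus <- sigs <- numeric(300)
  for (i in 1:300) {
    stt <- sample_component_params(xx, stt, prior)
    mus[i] <- stt$components[[1]]$mean
    sigs[i] <- stt$components[[1]]$covariance[1, 1]
  }
  expect_lt(abs(mean(mus) - 2) / 2, 0.02)
  expect_lt(abs(sqrt(mean(sigs)) - 1.5) / 1.5, 0.02)

  # 2-D correlated component: off-diagonal recovered
  set.seed(206)
  z1 <- stats::rnorm(5e3)
  z2 <- 0.8 * z1 + sqrt(1 - 0.64) * stats::rnorm(5e3)
  xy <- event_table(cbind(z1, z2))
  prior2 <- default_hyperparams(xy)
  st2 <- make_state(xy, 1)
  offd <- replicate(200, {
    st2 <<- sample_component_params(xy, st2, prior2)
    st2$components[[1]]$covariance[1, 2]
  })
  expect_lt(abs(mean(offd) - 0.8), 0.05)
})

test_that("the chain is deterministic, conserves counts and recovers densities", {
  set.seed(207)
  truth <- mixture_model(list(gaussian_component(1, 1, 1)))
  x <- sample_mixture(truth, 1e4, seed = 207)
  cfg <- chain_config(4, 400, 200, 10, seed = 9)
  f1 <- run_finite_chain(x, cfg)
  f2 <- run_finite_chain(x, cfg)
  expect_identical(chain_to_json(f1), chain_to_json(f2))

  # over-specified K still recovers the single-normal density
  expect_gte(mio(truth, averaged_density(f1)), 0.95)

  # null-model use: fitting convolved data recovers the convolved density
  conv_truth <- convolve_mixtures(bimodal_target(), narrow_noise())
  xc <- sample_mixture(conv_truth, 1e4, seed = 208)
  fc <- run_finite_chain(xc, chain_config(4, 400, 200, 10, seed = 10))
  expect_gte(mio(conv_truth, averaged_density(fc)), 0.95)

  expect_error(run_finite_chain(event_table(1:3), chain_config(4, 10, 5, 1)),
               "at least as many cells")
})

test_that("density recovery improves with sample size", {
  truth <- bimodal_target()
  mios <- sapply(c(100, 1000, 10000), function(n) {
    x <- sample_mixture(truth, n, seed = 300 + n)
    fit <- run_finite_chain(x, chain_config(4, 400, 200, 10, seed = 11))
    mio(truth, averaged_density(fit))
  })
  expect_true(all(diff(mios) > 0))
  expect_gt(mios[3], 0.95)
})

test_that("prior and posterior-resampling simulators agree (joint test)", {
  # Geweke-style successive-conditional check on a tiny configuration:
  # alternately Gibbs-updating parameters given data and re-drawing data
  # given parameters leaves the prior marginal invariant.
  prior <- niw_hyperparams(0, 2, matrix(2), nu0 = 11, alpha = 2)
  K <- 2; N <- 10
  set.seed(208)
  forward <- replicate(3000, {
    w <- scdeconv:::rdirichlet1(rep(1, K))
    sig <- scdeconv:::riwish1(matrix(2), 11)[1, 1]
    mu <- stats::rnorm(1, 0, sqrt(sig / 2))
    c(mu, sig)
  })
  set.seed(209)
  w <- scdeconv:::rdirichlet1(rep(1, K))
  comps <- lapply(seq_len(K), function(k) {
    sig <- scdeconv:::riwish1(matrix(2), 11)
    gaussian_component(w[k], stats::rnorm(1, 0, sqrt(sig[1, 1] / 2)), sig)
  })
  succ <- matrix(0, 2, 4000)
  state <- NULL
  for (it in seq_len(4000)) {
    m <- mixture_model(Map(function(cp, wk) gaussian_component(wk, cp$mean,
                                                               cp$covariance),
                           comps, as.list(w / sum(w))))
    x <- sample_mixture(m, N)
    state <- list(weights = w, components = comps)
    state <- sample_indicators(x, state)
    state <- sample_weights(state, prior)
    state <- sample_component_params(x, state, prior)
    w <- state$weights
    comps <- state$components
    succ[, it] <- c(comps[[1]]$mean, comps[[1]]$covariance[1, 1])
  }
  succ <- succ[, -(1:500)]
  # compare central moments of mu and Sigma between the two simulators
  expect_lt(abs(mean(succ[1, ]) - mean(forward[1, ])), 0.08)
  expect_lt(abs(stats::median(succ[2, ]) - stats::median(forward[2, ])), 0.05)
})
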