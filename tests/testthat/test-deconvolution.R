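# Convolved-mixture Gibbs sampler: pair bookkeeping, the corrected
# covariance conditional, noise-free reductions, and full-pipeline
# recovery of a known target.

pair_state <- function(noise, target_comps, target_weights, pair_stats) {
  list(noise = noise, target_components = target_comps,
       target_weights = target_weights, pair_stats = pair_stats,
       clip_count = 0L)
}

test_that("the effective pair covariance follows its closed form", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3)
  # empty pair reduces to the prior scale
  expect_equal(effective_covariance_hat(component_stats(0, d = 1), prior),
               matrix(1))
  # n = 10, scatter 1, mean at the prior center: 10 * 1 + 0 + 1 = 11
  st <- component_stats(10, 0, matrix(1))
  expect_equal(effective_covariance_hat(st, prior)[1, 1], 11)
  # the correction factor tends to the identity as the noise vanishes
  cf <- scdeconv:::correction_factor(matrix(11), matrix(1e-12), denom = 12)
  expect_equal(cf$matrix[1, 1], 1, tolerance = 1e-9)
  expect_false(cf$clipped)
  expect_equal(cf$fraction, 1, tolerance = 1e-9)
})

test_that("pair indicators follow the product responsibilities", {
  noise1 <- narrow_noise()
  # single noise x single target: every cell in the unique pair
  tc <- list(gaussian_component(1, 0, 1))
  st <- pair_state(noise1, tc, 1, NULL)
  x <- event_table(stats::rnorm(200))
  st <- sample_pair_indicators(x, st, seed = 1)
  expect_true(all(st$pair_assignments == 1L))
  expect_equal(st$pair_stats[[1]]$n, 200)

  # vanishing noise: assignments match the plain mixture responsibilities
  tiny_noise <- mixture_model(list(gaussian_component(1, 0, 1e-8)))
  tcs <- list(gaussian_component(0.5, -10, 1), gaussian_component(0.5, 10, 1))
  xx <- event_table(c(stats::rnorm(500, -10), stats::rnorm(500, 10)))
  st2 <- pair_state(tiny_noise, tcs, c(0.5, 0.5), NULL)
  st2 <- sample_pair_indicators(xx, st2, seed = 2)
  k <- (st2$pair_assignments - 1L) %% 2L + 1L
  expect_lt(mean(k[1:500] == 2L) + mean(k[501:1000] == 1L), 1e-3)

  # identical targets: symmetric occupancy under target swap
  tsym <- list(gaussian_component(0.5, 0, 1), gaussian_component(0.5, 0, 1))
  st3 <- pair_state(noise1, tsym, c(0.5, 0.5), NULL)
  st3 <- sample_pair_indicators(event_table(stats::rnorm(20000)), st3, seed = 3)
  ksym <- (st3$pair_assignments - 1L) %% 2L + 1L
  expect_lt(abs(mean(ksym == 1L) - 0.5), 0.02)
})

test_that("target counts sum pair counts over the noise index", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  noise2 <- mixture_model(list(gaussian_component(0.6, 0, 1),
                               gaussian_component(0.4, 1, 1)))
  tcs <- list(gaussian_component(0.5, 0, 1), gaussian_component(0.5, 2, 1))
  # pair counts: (j=1,k=1)=3, (j=2,k=1)=2, (j=1,k=2)=5 -> n_T = (5, 5)
  ps <- list(component_stats(3, 0, matrix(0)), component_stats(5, 0, matrix(0)),
             component_stats(2, 0, matrix(0)), component_stats(0, d = 1))
  st <- pair_state(noise2, tcs, c(0.5, 0.5), ps)
  expect_equal(scdeconv:::target_counts(st), c(5, 5))

  # Dirichlet(5.5, 5.5) moments for alpha = 1, K_T = 2
  set.seed(4)
  draws <- t(replicate(2e4, sample_target_weights(st, prior)$target_weights))
  expect_equal(colMeans(draws), c(0.5, 0.5), tolerance = 0.005)
  expect_equal(stats::var(draws[, 1]), 0.25 / 12, tolerance = 0.05)
})

test_that("with vanishing noise the covariance draw matches the plain conditional", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  set.seed(5)
  xs <- stats::rnorm(120, 1, 0.8)
  st_data <- batch_stats(xs)
  tiny_noise <- mixture_model(list(gaussian_component(1, 0, 1e-12)))
  tc <- list(gaussian_component(1, 1, 0.5))
  st <- pair_state(tiny_noise, tc, 1, list(st_data))
  set.seed(6)
  conv_draws <- replicate(4000, {
    s <- sample_target_covariance(st, prior)
    s$target_components[[1]]$covariance[1, 1]
  })
  set.seed(7)
  plain_draws <- replicate(4000, niw_sample_covariance_conditional(
    st_data, mean = 1, prior)[1, 1])
  ks <- suppressWarnings(stats::ks.test(conv_draws, plain_draws))
  expect_gt(ks$p.value, 0.01)
})

test_that("known-noise covariance and mean recovery on a single pair", {
  # target N(1.67, 0.36) convolved with noise N(0, 0.25): the posterior
  # for the target variance should land near 0.36, the mean near 1.67
  set.seed(8)
  n <- 10000
  t_s <- stats::rnorm(n, 1.67, 0.6)
  c_s <- t_s + stats::rnorm(n, 0, 0.5)
  noise1 <- narrow_noise()
  prior <- niw_hyperparams(mean(c_s), 1, matrix(max(var(c_s) - 0.25, 0.05)),
                           nu0 = 3, alpha = 1)
  st <- pair_state(noise1, list(gaussian_component(1, mean(c_s), 0.5)), 1,
                   list(batch_stats(c_s)))
  sig_draws <- mu_draws <- numeric(400)
  set.seed(9)
  for (i in seq_len(400)) {
    st <- sample_target_covariance(st, prior)
    st <- sample_target_mean(st, prior)
    sig_draws[i] <- st$target_components[[1]]$covariance[1, 1]
    mu_draws[i] <- st$target_components[[1]]$mean
  }
  expect_lt(abs(mean(sig_draws) - 0.36) / 0.36, 0.1)
  expect_lt(abs(mean(mu_draws) - 1.67), 3 * stats::sd(mu_draws) + 0.02)
})

test_that("duplicated noise components behave like their merged version", {
  # two identical noise components with half the weight each give the
  # same target conditionals as one merged component (up to Monte Carlo)
  set.seed(10)
  xs <- stats::rnorm(800, 0.5, 1)
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  one <- mixture_model(list(gaussian_component(1, 0, 0.25)))
  two <- mixture_model(list(gaussian_component(0.5, 0, 0.25),
                            gaussian_component(0.5, 0, 0.25)))
  halves <- batch_stats(xs[1:400])
  halves2 <- batch_stats(xs[401:800])
  full <- batch_stats(xs)
  tc <- list(gaussian_component(1, 0.5, 0.75))
  st1 <- pair_state(one, lapply(tc, identity), 1, list(full))
  st2 <- pair_state(two, lapply(tc, identity), 1, list(halves, halves2))
  set.seed(11)
  d1 <- replicate(3000, {
    s <- sample_target_covariance(st1, prior)
    s <- sample_target_mean(s, prior)
    c(s$target_components[[1]]$covariance[1, 1], s$target_components[[1]]$mean)
  })
  set.seed(12)
  d2 <- replicate(3000, {
    s <- sample_target_covariance(st2, prior)
    s <- sample_target_mean(s, prior)
    c(s$target_components[[1]]$covariance[1, 1], s$target_components[[1]]$mean)
  })
  expect_equal(mean(d1[1, ]), mean(d2[1, ]), tolerance = 0.05)
  expect_equal(mean(d1[2, ]), mean(d2[2, ]), tolerance = 0.02)
})

test_that("deconvolution with near-degenerate noise equals the plain fit", {
  truth <- bimodal_target()
  tt <- sample_mixture(truth, 4000, seed = 13)
  # noise three orders of magnitude tighter than the target scale
  xi <- event_table(stats::rnorm(4000, 0, 1e-3))
  conv <- event_table(tt$values + stats::rnorm(4000, 0, 1e-3))
  post <- run_deconvolution(xi, conv,
                            config_noise = chain_config(1, 200, 100, 5, seed = 14),
                            config_target = chain_config(4, 300, 150, 5, seed = 15))
  plain <- run_finite_chain(conv, chain_config(4, 300, 150, 5, seed = 16))
  expect_gte(mio(averaged_density(post$target_draws),
                 averaged_density(plain)), 0.98)
})

test_that("every stored draw is a valid mixture and reruns are identical", {
  ds <- make_synthetic_dataset("asymmetric_bimodal", "normal", 2, 1500, seed = 17)
  cfgn <- chain_config(2, 150, 75, 5, seed = 18)
  cfgt <- chain_config(3, 150, 75, 5, seed = 19)
  post <- run_deconvolution(ds$noise_samples, ds$convolved_samples, cfgn, cfgt)
  expect_length(post$target_draws, 15)
  for (m in post$target_draws) {
    w <- vapply(m$components, `[[`, 1.0, "weight")
    expect_equal(sum(w), 1, tolerance = 1e-9)
    for (cp in m$components) expect_silent(chol(cp$covariance))
  }
  post2 <- run_deconvolution(ds$noise_samples, ds$convolved_samples, cfgn, cfgt)
  expect_identical(posterior_to_json(post), posterior_to_json(post2))

  # convolved draws pair each target draw with its noise draw
  cd <- convolved_draws(post)
  expect_length(cd, length(post$target_draws))
  expect_equal(length(cd[[1]]$components),
               length(post$target_draws[[1]]$components) *
                 length(post$noise_draws[[1]]$components))

  expect_error(run_deconvolution(ds$noise_samples,
                                 event_table(matrix(1:10, 5, 2))),
               "channel dimensions")
})

test_that("the convolved fit explains the data as well as a direct fit", {
  ds <- make_synthetic_dataset("asymmetric_bimodal", "normal", 2, 3000, seed = 20)
  post <- run_deconvolution(ds$noise_samples, ds$convolved_samples,
                            chain_config(2, 200, 100, 10, seed = 21),
                            chain_config(2, 200, 100, 10, seed = 22))
  ll_conv <- mean(vapply(convolved_draws(post), function(m)
    mean(mixture_logpdf(ds$convolved_samples, m)), 1.0))
  direct <- run_finite_chain(ds$convolved_samples,
                             chain_config(4, 200, 100, 10, seed = 23))
  ll_direct <- mean(vapply(direct$draws, function(m)
    mean(mixture_logpdf(ds$convolved_samples, m)), 1.0))
  expect_lt(abs(ll_conv - ll_direct), 0.05)
})

test_that("the Dirichlet-process variant of the convolved sampler runs", {
  ds <- make_synthetic_dataset("asymmetric_bimodal", "normal", 2, 800, seed = 24)
  post <- run_deconvolution(ds$noise_samples, ds$convolved_samples,
                            chain_config(2, 100, 50, 5, seed = 25),
                            chain_config(2, 100, 50, 5, seed = 26),
                            model = "infinite")
  expect_gt(length(post$target_draws), 0)
  for (m in post$target_draws) {
    w <- vapply(m$components, `[[`, 1.0, "weight")
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  expect_gte(mio(ds$target_truth, averaged_density(post$target_draws),
                 check_mass = FALSE), 0.5)
})
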