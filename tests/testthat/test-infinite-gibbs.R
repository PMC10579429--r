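# Dirichlet-process sampler: Chinese-restaurant probabilities, exactness
# of the sweep against the enumerated partition posterior, sweep
# bookkeeping, and density recovery.

test_that("reassignment probabilities follow the Chinese-restaurant rule", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  # equal predictives: counts (2, 1) after removal, n = 4, alpha = 1
  st <- list(stats = list(component_stats(2, 0, matrix(1)),
                          component_stats(1, 0, matrix(1))))
  p <- crp_reassignment_probs(0, st, prior, predictive = "uniform")
  expect_equal(p, c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # vanishing concentration kills the new-component probability
  prior0 <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1e-12)
  p0 <- crp_reassignment_probs(0, st, prior0, predictive = "uniform")
  expect_lt(p0[3], 1e-11)

  # probabilities normalize and stay in (0, 1) for random states
  set.seed(301)
  for (rep in 1:20) {
    K <- sample(1:5, 1)
    sts <- list(stats = lapply(seq_len(K), function(k)
      batch_stats(stats::rnorm(sample(2:30, 1), stats::rnorm(1)))))
    pr <- crp_reassignment_probs(stats::rnorm(1, 0, 3), sts, prior)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0 & pr < 1))
    expect_length(pr, K + 1)
  }
})

test_that("sweep frequencies match the exact partition posterior", {
  # gold-standard check: enumerate all 4140 set partitions of 8 cells,
  # score each by CRP prior times the product of per-cluster marginal
  # likelihoods (predictive chain rule), and compare the exact
  # distribution of the number of clusters with long-run sweep output
  set.seed(77)
  x <- sort(stats::rnorm(8))
  prior <- niw_hyperparams(0, 1, matrix(1.5), nu0 = 3, alpha = 1)
  rgs <- function(prefix, mx) {
    if (length(prefix) == 8) return(list(prefix))
    out <- list()
    for (v in 1:(mx + 1)) out <- c(out, rgs(c(prefix, v), max(mx, v)))
    out
  }
  allp <- rgs(integer(0), 0L)
  expect_length(allp, 4140)
  lml_cluster <- function(xc) {
    st <- component_stats(0, d = 1)
    s <- 0
    for (xi in xc) {
      s <- s + posterior_predictive_logpdf(xi, st, prior)
      st <- update_stats_add(st, xi)
    }
    s
  }
  logcrp <- function(z)
    sum(lgamma(table(z))) - sum(log(1 + seq_along(z) - 1))
  lp <- sapply(allp, function(z)
    logcrp(z) + sum(sapply(split(x, z), lml_cluster)))
  p_exact <- exp(lp - max(lp))
  p_exact <- p_exact / sum(p_exact)
  pk_exact <- tapply(p_exact, sapply(allp, max), sum)

  state <- list(assignments = rep(1L, 8),
                stats = list(batch_stats(matrix(x))))
  xev <- event_table(x)
  set.seed(5)
  n_sweeps <- 2e4
  Ks <- integer(n_sweeps)
  for (i in seq_len(n_sweeps)) {
    state <- reassign_sweep(xev, state, prior)
    Ks[i] <- length(state$stats)
  }
  pk_sweep <- table(factor(Ks[-(1:2000)], levels = 1:8)) / (n_sweeps - 2000)
  for (k in 1:5)
    expect_lt(abs(pk_sweep[k] - pk_exact[as.character(k)]), 0.02)
})

test_that("a reassignment sweep keeps the bookkeeping consistent", {
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1)
  # single cell: exactly one active component with n = 1
  x1 <- event_table(matrix(0.3))
  st1 <- list(assignments = 1L, stats = list(component_stats(1, 0.3, matrix(0))))
  set.seed(302)
  out1 <- reassign_sweep(x1, st1, prior)
  expect_length(out1$stats, 1)
  expect_equal(out1$stats[[1]]$n, 1)

  # identical cells concentrate on one dominant component
  xid <- event_table(rep(2.5, 400))
  stid <- list(assignments = rep(1L, 400),
               stats = list(batch_stats(rep(2.5, 400))))
  set.seed(303)
  for (i in 1:5) stid <- reassign_sweep(xid, stid, prior)
  counts <- vapply(stid$stats, `[[`, 1.0, "n")
  expect_gte(max(counts) / 400, 0.99)
  expect_equal(sum(counts), 400)
  expect_true(all(counts >= 1))

  # incremental statistics along a sweep equal batch recomputation
  set.seed(304)
  xx <- event_table(stats::rnorm(300))
  st <- list(assignments = rep(1L, 300), stats = list(batch_stats(xx$values)))
  for (i in 1:10) st <- reassign_sweep(xx, st, prior)
  for (k in seq_along(st$stats)) {
    ref <- batch_stats(xx$values[st$assignments == k, , drop = FALSE])
    expect_equal(st$stats[[k]]$n, ref$n)
    expect_equal(st$stats[[k]]$mean, ref$mean, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(st$stats[[k]]$scatter, ref$scatter, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("far-separated clusters are dominated by two components", {
  truth <- mixture_model(list(gaussian_component(0.5, -100, 1),
                              gaussian_component(0.5, 100, 1)))
  x <- sample_mixture(truth, 400, seed = 304)
  fit <- run_infinite_chain(x, chain_config(4, 150, 50, 2, seed = 305))
  top2 <- vapply(fit$draws, function(m) {
    w <- sort(vapply(m$components, `[[`, 1.0, "weight"), decreasing = TRUE)
    sum(w[seq_len(min(2, length(w)))])
  }, 1.0)
  expect_true(all(fit$n_active >= 2))
  expect_gte(mean(top2 >= 0.95), 0.95)
  # the two dominant components sit one on each side; no draw mixes cells
  # from both clusters into one component
  for (m in fit$draws) {
    mus <- vapply(m$components, function(cp) cp$mean[1], 1.0)
    ws <- vapply(m$components, `[[`, 1.0, "weight")
    expect_true(any(mus[ws > 0.2] < 0) && any(mus[ws > 0.2] > 0))
    expect_true(all(abs(mus[ws > 0.2]) > 50))
  }
})

test_that("bimodal data are recovered with two dominant components", {
  truth <- mixture_model(list(gaussian_component(0.5, -3, 1),
                              gaussian_component(0.5, 3, 1)))
  x <- sample_mixture(truth, 2000, seed = 306)
  cfg <- chain_config(4, 200, 100, 2, seed = 307)
  fit <- run_infinite_chain(x, cfg)
  top2 <- vapply(fit$draws, function(m) {
    w <- sort(vapply(m$components, `[[`, 1.0, "weight"), decreasing = TRUE)
    sum(w[seq_len(min(2, length(w)))])
  }, 1.0)
  expect_gte(mean(top2), 0.7)
  expect_gte(mio(truth, averaged_density(fit)), 0.9)

  fit2 <- run_infinite_chain(x, cfg)
  expect_identical(chain_to_json(fit), chain_to_json(fit2))
})

test_that("single-normal data keep a dominant component and its density", {
  truth <- mixture_model(list(gaussian_component(1, 0.5, 1.2)))
  x <- sample_mixture(truth, 2000, seed = 308)
  fit <- run_infinite_chain(x, chain_config(4, 200, 100, 2, seed = 309))
  wmax <- vapply(fit$draws, function(m)
    max(vapply(m$components, `[[`, 1.0, "weight")), 1.0)
  expect_gte(mean(wmax), 0.5)
  expect_gte(mio(truth, averaged_density(fit)), 0.95)
})

test_that("prior-only table growth matches the expected occupancy", {
  # sequential seating with the data term switched off: the expected
  # number of occupied components after N cells is sum_i alpha/(alpha+i-1)
  prior <- niw_hyperparams(0, 1, matrix(1), 3, alpha = 1.5)
  N <- 30
  expected <- sum(1.5 / (1.5 + seq_len(N) - 1))
  set.seed(310)
  counts <- replicate(400, {
    st <- list(stats = list(component_stats(1, 0, matrix(0))))
    for (i in 2:N) {
      p <- crp_reassignment_probs(0, st, prior, predictive = "uniform")
      k <- sample.int(length(p), 1, prob = p)
      if (k > length(st$stats))
        st$stats[[k]] <- component_stats(1, 0, matrix(0))
      else
        st$stats[[k]] <- update_stats_add(st$stats[[k]], 0)
    }
    length(st$stats)
  })
  expect_lt(abs(mean(counts) - expected), 3 * stats::sd(counts) / sqrt(400))
})

test_that("the collapsed predictive recovers the bimodal target density", {
  truth <- bimodal_target()
  x <- sample_mixture(truth, 1e4, seed = 311)
  fit <- run_infinite_chain(x, chain_config(4, 150, 75, 3, seed = 312))
  expect_gte(mio(truth, averaged_density(fit)), 0.9)
})
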