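# scdeconv

Bayesian deconvolution of autofluorescence background from single-cell
fluorescence distributions.

## The problem

Flow cytometry reports, per cell, a total signal `c = t + ξ`: the
fluorophore signal `t` of interest plus the cell's intrinsic
autofluorescence `ξ`. Only *distributions* are measurable — `c` from
labeled cells, `ξ` from unlabeled control cells — and they are related by
a convolution, `p_c = p_T ∗ p_ξ`. Subtracting a mean background does not
recover `p_T`; it leaves the noise variance in place and distorts every
population-level statement about the reporter. Anyone quantifying
cell-state heterogeneity from cytometry (or any additive-noise
measurement with a measurable noise channel) faces this deconvolution
problem.

`scdeconv` solves it with a nonparametric Bayesian model: both the
target and the noise densities are Gaussian mixtures

`p_T(x) = Σ_k ω_k^T N(x | μ_k^T, Σ_k^T)`,  `p_ξ(x) = Σ_j ω_j^ξ N(x | μ_j^ξ, Σ_j^ξ)`

so the observed totals follow the mixture with component means
`μ_j^ξ + μ_k^T` and covariances `Σ_j^ξ + Σ_k^T`. Component parameters
carry normal-inverse-Wishart priors, weights a Dirichlet prior, and the
posterior is explored by Gibbs sampling — a finite-`K` sampler and a
Dirichlet-process (Chinese-restaurant) sampler are both provided. The
deconvolution itself runs in two stages: fit the noise mixture on the
unlabeled cells, then sample the target mixture conditioned on stored
noise-posterior draws, with a corrected inverse-Wishart step for the
convolved covariances. The result is a set of posterior draws of the
target distribution: an averaged density with pointwise credible bands,
not a bare point estimate.

The package also ships the evaluation metrics used to validate it (mean
integrated overlap, MIO, and integrated squared error, MISE), a
54-dataset synthetic benchmark generator with known ground truth, and
multichannel preprocessing (spillover-matrix estimation from
single-fluorophore controls, autofluorescence-as-regressor correction,
compensation) so the deconvolution composes with standard cytometry
pipelines. Event tables read from CSV/TSV or FCS 3.0/3.1 files.

## Worked example

A bimodal target (means −0.43 and 1.67, sds 0.6, weights 0.8/0.2)
corrupted by normal noise with sd 0.5; 10,000 cells per table:

```r
library(scdeconv)

target <- mixture_model(list(
  gaussian_component(0.8, -0.43, 0.36),
  gaussian_component(0.2,  1.67, 0.36)))
noise <- mixture_model(list(gaussian_component(1, 0, 0.25)))

conv <- event_table(sample_mixture(target, 10000, seed = 1)$values +
                    sample_mixture(noise,  10000, seed = 2)$values)
xi   <- sample_mixture(noise, 10000, seed = 3)

post <- run_deconvolution(xi, conv,
  config_noise  = chain_config(n_components = 4, n_iterations = 1000,
                               burn_in = 500, thin = 10, seed = 4),
  config_target = chain_config(n_components = 4, n_iterations = 1000,
                               burn_in = 500, thin = 10, seed = 5))
post
#> Deconvolution posterior: 50 paired target/noise draws; 9 covariance-correction clip(s)

null_fit <- run_finite_chain(conv, chain_config(4, 1000, 500, 10, seed = 6))
mio(target, averaged_density(post$target_draws))
#> [1] 0.9608
mio(target, averaged_density(null_fit))
#> [1] 0.8906

score_posterior(post$target_draws, target)[c("mio_mean", "mio_sd")]
#> $mio_mean  0.9552   $mio_sd  0.0077

head(density_summary(post$target_draws, grid = seq(-1, 2, by = 0.5)))
#>      x      mean        q5       q95
#> 1 -1.0 0.3495800 0.3323875 0.3697541
#> 2 -0.5 0.5545819 0.5319455 0.5812059
#> 3  0.0 0.3770154 0.3571292 0.3936549
#> 4  0.5 0.1571455 0.1410585 0.1731039
#> 5  1.0 0.1323557 0.1205739 0.1443368
#> 6  1.5 0.1477785 0.1417774 0.1566085
```

Reading the numbers: the deconvolved averaged density shares 96% of its
probability mass with the true target (MIO 0.96), against 89% for the
"null model" that fits the convolved data directly and ignores the noise
— the deconvolution recovers the sharpness that the noise smeared out.
The per-draw score 0.96 ± 0.01 summarizes the posterior spread;
`density_summary()` tabulates the averaged density with pointwise 5%/95%
credible bands. The "covariance-correction clips" count is a diagnostic
of the convolved-covariance approximation (see the methods vignette);
single-digit counts over 50 stored draws × 16 component pairs are
negligible.

A command-line wrapper around the same functions is installed at
`inst/cli/scdeconv` (subcommands `simulate`, `fit-noise`, `deconvolve`,
`score`, `compensate`).

## Documentation

The methods vignette (`vignettes/deconvolution-methods.Rmd`) describes
the model, the two-stage decomposition, the convolved-covariance
approximation and its stabilizations, hyperparameter defaults, the
benchmark design, and known limitations.
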