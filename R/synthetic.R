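# Synthetic benchmark generator: known ground-truth targets corrupted by
# additive noise at controlled signal-to-noise ratios. Three target
# families (multiple peaks, unequal cluster sizes, skewness) times three
# noise families (one Gaussian, two fat-tailed), two SNRs and three
# sample sizes give the 54-dataset grid.

# --- skew-normal helpers (density 2 phi(z) Phi(shape z), sampled via the
# two-normal representation); delta = shape / sqrt(1 + shape^2)
dskewnorm <- function(x, location = 0, scale = 1, shape = 0) {
  z <- (x - location) / scale
  2 / scale * stats::dnorm(z) * stats::pnorm(shape * z)
}

rskewnorm <- function(n, location = 0, scale = 1, shape = 0) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- stats::rnorm(n)
  v <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * v
  location + scale * z
}

skewnorm_mean <- function(location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  location + scale * delta * sqrt(2 / pi)
}

skewnorm_var <- function(scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  scale^2 * (1 - 2 * delta^2 / pi)
}

#' Default parameters of the synthetic families
#'
#' Frozen package constants defining the benchmark ground truths:
#' `symmetric_bimodal` is an equal-weight pair of normals at -1 and 1
#' with standard deviation 0.5; `asymmetric_bimodal` reuses the worked
#' two-component example (means -0.43 and 1.67, standard deviations 0.6,
#' weights 0.8/0.2); `skew_symmetric` is a skew-normal with shape 4. The
#' noise families are a standard normal, a skew-normal with shape 4, and
#' a Student t with 3 degrees of freedom, each centered and scaled to
#' unit variance before SNR scaling.
#'
#' @return A named list of parameter lists.
#' @export
synthetic_defaults <- function() {
  list(
    symmetric_bimodal = list(means = c(-1, 1), sds = c(0.5, 0.5),
                             weights = c(0.5, 0.5)),
    asymmetric_bimodal = list(means = c(-0.43, 1.67), sds = c(0.6, 0.6),
                              weights = c(0.8, 0.2)),
    skew_symmetric = list(location = 0, scale = 1, shape = 4),
    skewed_noise = list(shape = 4),
    student_noise = list(df = 3)
  )
}

target_families <- c("symmetric_bimodal", "asymmetric_bimodal",
                     "skew_symmetric")
noise_families <- c("normal", "skewed", "student_t")

#' Ground-truth target density with sampler
#'
#' @param family One of `"symmetric_bimodal"`, `"asymmetric_bimodal"`,
#'   `"skew_symmetric"`.
#' @return A [density_fn()] with a `sampler` attribute; bimodal families
#'   also carry the generating [mixture_model()] as attribute `mixture`.
#' @export
make_target <- function(family) {
  defs <- synthetic_defaults()
  if (!family %in% target_families)
    stop("unknown target family '", family, "'; valid families: ",
         paste(target_families, collapse = ", "))
  if (family %in% c("symmetric_bimodal", "asymmetric_bimodal")) {
    p <- defs[[family]]
    m <- mixture_model(Map(function(w, mu, s) gaussian_component(w, mu, s^2),
                           p$weights, p$means, p$sds))
    w <- density_window(m)
    f <- density_fn(function(x) mixture_pdf(x, m), w[, 1], w[, 2],
                    sampler = function(n) sample_mixture(m, n)$values)
    attr(f, "mixture") <- m
    return(f)
  }
  p <- defs$skew_symmetric
  density_fn(function(x) dskewnorm(x, p$location, p$scale, p$shape),
             p$location - 8 * p$scale, p$location + 8 * p$scale,
             sampler = function(n) matrix(
               rskewnorm(n, p$location, p$scale, p$shape), ncol = 1L))
}

#' Ground-truth noise density with sampler
#'
#' All noise families are centered and standardized to unit variance so
#' that [scale_noise_to_snr()] controls the realized noise level alone.
#'
#' @param family One of `"normal"`, `"skewed"`, `"student_t"`.
#' @return A [density_fn()] with a `sampler` attribute.
#' @export
make_noise <- function(family) {
  defs <- synthetic_defaults()
  if (!family %in% noise_families)
    stop("unknown noise family '", family, "'; valid families: ",
         paste(noise_families, collapse = ", "))
  switch(family,
    normal = density_fn(function(x) stats::dnorm(x), -8, 8,
                        sampler = function(n) matrix(stats::rnorm(n), ncol = 1L)),
    skewed = {
      shape <- defs$skewed_noise$shape
      mu <- skewnorm_mean(0, 1, shape)
      s <- sqrt(skewnorm_var(1, shape))
      density_fn(function(x) s * dskewnorm(x * s + mu, 0, 1, shape),
                 -8 / s, 8 / s,
                 sampler = function(n)
                   matrix((rskewnorm(n, 0, 1, shape) - mu) / s, ncol = 1L))
    },
    student_t = {
      df <- defs$student_noise$df
      s <- sqrt(df / (df - 2))  # standardize to unit variance
      density_fn(function(x) s * stats::dt(x * s, df), -30, 30,
                 sampler = function(n) matrix(stats::rt(n, df) / s, ncol = 1L))
    })
}

#' Scale noise samples to a target signal-to-noise ratio
#'
#' SNR is the ratio of target to (scaled) noise variance, measured on the
#' realized samples: the returned scale `s` satisfies
#' `var(target) / var(s * noise) = snr` exactly.
#'
#' @param target_samples,noise_samples Numeric vectors/matrices or
#'   [event_table()]s.
#' @param snr Positive signal-to-noise ratio.
#' @return List with `noise` (scaled samples, same shape as input) and
#'   `scale`.
#' @export
scale_noise_to_snr <- function(target_samples, noise_samples, snr) {
  if (inherits(target_samples, "event_table")) target_samples <- target_samples$values
  if (inherits(noise_samples, "event_table")) noise_samples <- noise_samples$values
  if (snr <= 0) stop("snr must be positive")
  vt <- stats::var(as.numeric(target_samples))
  vn <- stats::var(as.numeric(noise_samples))
  if (!is.finite(vt) || vt <= 0) stop("target samples have zero variance")
  if (!is.finite(vn) || vn <= 0) stop("noise samples have zero variance")
  s <- sqrt(vt / (snr * vn))
  list(noise = noise_samples * s, scale = s)
}

#' Generate one synthetic benchmark dataset
#'
#' Draws `n` target and `n` noise samples, scales the noise to the
#' requested SNR, and returns the additive convolution `c = t + s * xi`
#' row by row, together with the ground truths. A second, independent
#' noise sample of the same size plays the role of the measured
#' unlabeled-cell data.
#'
#' @param target_family,noise_family Family names; see [make_target()],
#'   [make_noise()].
#' @param snr Signal-to-noise ratio (target variance over scaled-noise
#'   variance).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: `spec`,
#'   `target_truth` (a [density_fn()]), `noise_truth` (the scaled noise
#'   density as [density_fn()]), `noise_samples` and `convolved_samples`
#'   ([event_table()]s), `target_samples`, and `noise_scale`.
#' @export
make_synthetic_dataset <- function(target_family, noise_family, snr, n,
                                   seed = 1L) {
  set.seed(seed)
  target <- make_target(target_family)
  noise <- make_noise(noise_family)
  t_s <- attr(target, "sampler")(n)
  xi_raw <- attr(noise, "sampler")(n)     # corrupts the convolved sample
  xi_obs_raw <- attr(noise, "sampler")(n) # measured noise dataset
  sc <- scale_noise_to_snr(t_s, xi_raw, snr)
  s <- sc$scale
  noise_w <- density_window(noise) * s
  noise_truth <- density_fn(function(x) noise(x / s) / s,
                            noise_w[, 1], noise_w[, 2],
                            sampler = function(m) attr(noise, "sampler")(m) * s)
  structure(list(
    spec = list(target_family = target_family, noise_family = noise_family,
                snr = snr, n = n, seed = seed),
    target_truth = target,
    noise_truth = noise_truth,
    target_samples = event_table(t_s),
    noise_samples = event_table(xi_obs_raw * s),
    convolved_samples = event_table(t_s + sc$noise),
    noise_scale = s), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  with(x$spec, cat(sprintf(
    "Synthetic dataset: target=%s noise=%s SNR=%g n=%d seed=%d\n",
    target_family, noise_family, snr, n, seed)))
  invisible(x)
}

#' Generate the full synthetic benchmark
#'
#' Enumerates the 3 target families x 3 noise families x 2 SNRs x 3
#' sample sizes grid (54 datasets), with per-dataset seeds derived
#' deterministically from the master seed.
#'
#' @param master_seed Integer master seed.
#' @param snrs,sizes Optional restrictions of the grid (defaults: SNR in
#'   `{1, 10}`, n in `{100, 1000, 10000}`).
#' @return A list of `synthetic_dataset` objects.
#' @export
generate_benchmark <- function(master_seed = 1L, snrs = c(1, 10),
                               sizes = c(100, 1000, 10000)) {
  grid <- expand.grid(target_family = target_families,
                      noise_family = noise_families,
                      snr = snrs, n = sizes,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    make_synthetic_dataset(grid$target_family[i], grid$noise_family[i],
                           grid$snr[i], grid$n[i],
                           seed = (as.integer(master_seed) * 1009L + i * 97L) %%
                             2147483647L))
}
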