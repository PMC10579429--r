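# Shared fixtures: the worked bimodal example (two normals at -0.43 and
# 1.67, sd 0.6, weights 0.8/0.2) corrupted by N(0, 0.5^2) noise, plus a
# numerical-convolution oracle used to cross-check the analytic mixture
# convolution.

bimodal_target <- function() {
  mixture_model(list(gaussian_component(0.8, -0.43, 0.36),
                     gaussian_component(0.2, 1.67, 0.36)))
}

narrow_noise <- function() {
  mixture_model(list(gaussian_component(1, 0, 0.25)))
}

# density of (f * g) at points cs by trapezoid quadrature over y
numerical_convolution <- function(f, g, cs, lower = -30, upper = 30,
                                  n = 8192L) {
  y <- seq(lower, upper, length.out = n)
  dy <- y[2] - y[1]
  gy <- g(y)
  vapply(cs, function(cc) {
    v <- f(cc - y) * gy
    sum((v[-1] + v[-length(v)]) / 2) * dy
  }, 1.0)
}

# random valid 1-D mixture for property tests
random_mixture_1d <- function(K = 3) {
  w <- stats::runif(K)
  w <- w / sum(w)
  mixture_model(Map(function(wi, mu, s) gaussian_component(wi, mu, s),
                    w, stats::rnorm(K, 0, 2), stats::runif(K, 0.2, 2)))
}
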