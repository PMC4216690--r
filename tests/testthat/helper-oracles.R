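# Shared oracles and fixture builders, independent of the code paths they
# check wherever they serve as a reference.

# central finite differences of a scalar function of (c, k)
fd_grad <- function(f, c0, k0, h = 1e-6) {
  hc <- h * max(1, abs(c0)); hk <- h * max(1, abs(k0))
  c(dk = (f(c0, k0 + hk) - f(c0, k0 - hk)) / (2 * hk),
    dc = (f(c0 + hc, k0) - f(c0 - hc, k0)) / (2 * hc))
}

fd_hess <- function(f, c0, k0, h = 1e-4) {
  hc <- h * max(1, abs(c0)); hk <- h * max(1, abs(k0))
  dkk <- (f(c0, k0 + hk) - 2 * f(c0, k0) + f(c0, k0 - hk)) / hk^2
  dcc <- (f(c0 + hc, k0) - 2 * f(c0, k0) + f(c0 - hc, k0)) / hc^2
  dkc <- (f(c0 + hc, k0 + hk) - f(c0 + hc, k0 - hk) -
            f(c0 - hc, k0 + hk) + f(c0 - hc, k0 - hk)) / (4 * hc * hk)
  matrix(c(dkk, dkc, dkc, dcc), 2, 2, dimnames = list(c("k", "c"), c("k", "c")))
}

# third-order central differences of f(c, k): returns (l30, l03, l12)
# l30 = d3/dk3, l03 = d3/dc3, l12 = d3/(dk dc2)
fd_third <- function(f, c0, k0, h = 5e-3) {
  hc <- h * max(1, abs(c0)); hk <- h * max(1, abs(k0))
  l30 <- (f(c0, k0 + 2 * hk) - 2 * f(c0, k0 + hk) + 2 * f(c0, k0 - hk) -
            f(c0, k0 - 2 * hk)) / (2 * hk^3)
  l03 <- (f(c0 + 2 * hc, k0) - 2 * f(c0 + hc, k0) + 2 * f(c0 - hc, k0) -
            f(c0 - 2 * hc, k0)) / (2 * hc^3)
  dcc <- function(k) (f(c0 + hc, k) - 2 * f(c0, k) + f(c0 - hc, k)) / hc^2
  l12 <- (dcc(k0 + hk) - dcc(k0 - hk)) / (2 * hk)
  c(l30 = l30, l03 = l03, l12 = l12)
}

# a reproducible randomized (scheme, params, sample) instance
random_instance <- function(schemes = list(c(-1, 1), c(0, 1), c(0.5, 2)),
                            n_range = 5:25) {
  mq <- schemes[[sample.int(length(schemes), 1)]]
  n <- sample(n_range, 1)
  c0 <- exp(stats::runif(1, -0.7, 1.3))
  k0 <- exp(stats::runif(1, -0.7, 1.3))
  sch <- dgos_scheme(n, mq[1], mq[2])
  list(sample = rdgos(sch, c0, k0), c0 = c0, k0 = k0, scheme = sch)
}

# the first record sample (from a fixed seed stream) whose MLE exists and
# whose Lindley expansion is proper -- the regime the approximation is
# defined for
first_proper_record_sample <- function(n, c0, k0, prior, seed = 1) {
  set.seed(seed)
  repeat {
    x <- rdgos_records(n, c0, k0)
    f <- burr3_fit(x, prior = prior)
    if (f$converged && !is.null(f$bayes) && f$bayes$proper && !f$bayes$saddle)
      return(list(sample = x, fit = f))
  }
}
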