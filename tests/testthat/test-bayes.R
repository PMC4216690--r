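test_that("gamma prior validates and exposes the log-gradient", {
  expect_error(gamma_prior(0, 1, 1, 1), "positive")
  pr <- gamma_prior(3, 2, 2, 3)
  g <- log_prior_grad(pr, shape1 = 3, shape2 = 2)
  expect_equal(unname(g["p1"]), (3 - 1) / 2 - 1 / 2)      # 0.5
  expect_equal(unname(g["p2"]), (2 - 1) / 3 - 1 / 3)      # 0
  # flat-prior limit: alpha = 1 and huge scale give a vanishing gradient
  g2 <- log_prior_grad(gamma_prior(1, 1e12, 1, 1e12), 3, 2)
  expect_equal(unname(g2["p1"]), 0, tolerance = 1e-11)
})

test_that("Lindley components reuse the observed information at the MLE", {
  set.seed(51)
  x <- rdgos_records(10, 3, 2)
  fit <- burr3_fit(x)
  comp <- lindley_components(x, fit$c_hat, fit$k_hat, gamma_prior(3, 2, 2, 3))
  J <- burr3_obs_info(x, fit$c_hat, fit$k_hat)
  expect_equal(comp$G, J["k", "k"], tolerance = 1e-12)
  expect_equal(comp$H, J["c", "c"], tolerance = 1e-12)
  expect_equal(comp$I, -J["k", "c"], tolerance = 1e-12)
  expect_equal(comp$N, comp$G * comp$H - comp$I^2, tolerance = 1e-12)
  expect_identical(comp$l21, 0)
  expect_equal(comp$G, fit$scheme$n / fit$k_hat^2, tolerance = 1e-12)
})

test_that("Lindley corrections match an independent expansion built from finite differences", {
  # recompute psi1/psi2 through the generic two-parameter expansion
  # (A/B/C terms and the tau matrix) with all derivatives taken by
  # finite differences of the log-likelihood -- an independent route
  set.seed(52)
  pr <- gamma_prior(3, 2, 2, 3)
  for (r in 1:5) {
    x <- rdgos(dgos_scheme(15, 0, 1), 3, 2)
    fit <- burr3_fit(x)
    if (!fit$converged) next
    comp <- lindley_components(x, fit$c_hat, fit$k_hat, pr)

    f <- function(c0, k0) burr3_loglik(x, c0, k0)
    Hfd <- fd_hess(f, fit$c_hat, fit$k_hat)          # (k, c) ordering
    tau <- solve(-Hfd)
    d3 <- fd_third(f, fit$c_hat, fit$k_hat)
    pg <- log_prior_grad(pr, fit$c_hat, fit$k_hat)
    psi_for <- function(U1, U2) {
      B12 <- (U1 * tau[1, 1] + U2 * tau[1, 2]) * tau[1, 1]
      B21 <- (U2 * tau[2, 2] + U1 * tau[2, 1]) * tau[2, 2]
      C12 <- 3 * U1 * tau[1, 1] * tau[1, 2] +
        U2 * (tau[1, 1] * tau[2, 2] + 2 * tau[1, 2]^2)
      C21 <- 3 * U2 * tau[2, 2] * tau[2, 1] +
        U1 * (tau[2, 2] * tau[1, 1] + 2 * tau[2, 1]^2)
      0.5 * (d3["l30"] * B12 + d3["l03"] * B21 + 0 * C12 + d3["l12"] * C21) +
        pg["p1"] * (U1 * tau[1, 1] + U2 * tau[2, 1]) +
        pg["p2"] * (U2 * tau[2, 2] + U1 * tau[1, 2])
    }
    expect_equal(comp$psi1, unname(psi_for(1, 0)),
                 tolerance = 1e-3 * max(1, abs(comp$psi1)))
    expect_equal(comp$psi2, unname(psi_for(0, 1)),
                 tolerance = 1e-3 * max(1, abs(comp$psi2)))
  }
})

test_that("Bayes estimates are the MLE plus the corrections", {
  set.seed(53)
  x <- rdgos_records(12, 3, 2)
  fit <- burr3_fit(x)
  pr <- gamma_prior(5, 1, 2, 5)
  bl <- bayes_lindley(x, fit$c_hat, fit$k_hat, pr)
  comp <- lindley_components(x, fit$c_hat, fit$k_hat, pr)
  expect_equal(bl$k_B, fit$k_hat + comp$psi1)
  expect_equal(bl$c_B, fit$c_hat + comp$psi2)
})

test_that("posterior quadrature recovers prior means when the likelihood is dropped", {
  x <- rdgos_records(5, 3, 2, u = rep(0.4, 5))
  pm <- posterior_mean_quadrature(x, gamma_prior(3, 2, 2, 3),
                                  include_likelihood = FALSE)
  expect_equal(pm$k_mean, 3 * 2, tolerance = 1e-8)
  expect_equal(pm$c_mean, 2 * 3, tolerance = 1e-8)
})

test_that("posterior quadrature agrees with importance sampling", {
  set.seed(54)
  pr <- gamma_prior(3, 2, 2, 3)
  x <- first_proper_record_sample(10, 3, 2, pr, seed = 54)$sample
  pm <- posterior_mean_quadrature(x, pr)
  # proposal: independent normals on log-parameters around the mode
  R <- 40000
  lmu <- log(pm$mode); lsd <- c(0.6, 0.6)
  lk <- rnorm(R, lmu[1], lsd[1]); lc <- rnorm(R, lmu[2], lsd[2])
  lw <- vapply(seq_len(R), function(i) {
    burr3_loglik(x, exp(lc[i]), exp(lk[i])) +
      dgamma(exp(lk[i]), pr$alpha, scale = pr$beta, log = TRUE) +
      dgamma(exp(lc[i]), pr$gamma, scale = pr$delta, log = TRUE) +
      lk[i] + lc[i] -   # Jacobian of the log transform
      dnorm(lk[i], lmu[1], lsd[1], log = TRUE) -
      dnorm(lc[i], lmu[2], lsd[2], log = TRUE)
  }, numeric(1))
  w <- exp(lw - max(lw)); w <- w / sum(w)
  for (par in list(list(v = exp(lk), ref = pm$k_mean),
                   list(v = exp(lc), ref = pm$c_mean))) {
    est <- sum(w * par$v)
    se <- sqrt(sum(w^2 * (par$v - est)^2))
    expect_lt(abs(est - par$ref), 3 * se + 1e-8)
  }
})

test_that("Lindley approaches the exact posterior mean as n grows", {
  pr <- gamma_prior(3, 2, 2, 3)
  set.seed(55)
  x <- rdgos(dgos_scheme(200, 0, 1), 3, 2)
  fit <- burr3_fit(x)
  bl <- bayes_lindley(x, fit$c_hat, fit$k_hat, pr)
  # corrections are small at large n ...
  expect_lt(abs(bl$k_B - fit$k_hat), 0.1)
  expect_lt(abs(bl$c_B - fit$c_hat), 0.1)
  # ... and sit within 2% of the exact posterior means
  pm <- posterior_mean_quadrature(x, pr)
  expect_equal(bl$k_B, pm$k_mean, tolerance = 0.02)
  expect_equal(bl$c_B, pm$c_mean, tolerance = 0.02)
})
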