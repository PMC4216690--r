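test_that("log-likelihood matches hand reductions and a naive recomputation", {
  # single observation at x = 1, q = 1: l = log c + log k - (k+1) log 2
  s1 <- dgos_sample(1, dgos_scheme(1, 0, 1))
  for (ck in list(c(1, 1), c(3, 2), c(0.4, 5)))
    expect_equal(burr3_loglik(s1, ck[1], ck[2]),
                 log(ck[1]) + log(ck[2]) - (ck[2] + 1) * log(2),
                 tolerance = 1e-14)

  # term-by-term naive summation on a fixed sample (no stability tricks)
  x <- c(2.4, 1.1, 0.62, 0.31)
  sch <- dgos_scheme(4, 0.5, 2)
  s <- dgos_sample(x, sch)
  naive <- function(c0, k0) {
    n <- 4; m <- 0.5; q <- 2
    n * log(c0) + n * log(k0) +
      sum((c0 * k0 + c0 * m * k0 - 1) * log(x[1:3]) -
            (k0 + m * k0 + 1) * log(1 + x[1:3]^c0)) +
      (c0 * k0 * q - 1) * log(x[4]) - (k0 * q + 1) * log(1 + x[4]^c0)
  }
  for (ck in list(c(3, 2), c(0.7, 0.9), c(5, 0.2)))
    expect_equal(burr3_loglik(s, ck[1], ck[2]), naive(ck[1], ck[2]),
                 tolerance = 1e-12)

  # likelihood ratios are constant-free: difference of loglik equals the
  # log of the full joint density ratio (constants cancel)
  dens <- function(c0, k0) {
    Fm <- pburr3(x, c0, k0)
    log(sch$q * prod(sch$gamma[1:3])) +
      sum(sch$m * log(Fm[1:3]) + dburr3(x[1:3], c0, k0, log = TRUE)) +
      (sch$q - 1) * log(Fm[4]) + dburr3(x[4], c0, k0, log = TRUE)
  }
  expect_equal(burr3_loglik(s, 3, 2) - burr3_loglik(s, 1.2, 0.8),
               dens(3, 2) - dens(1.2, 0.8), tolerance = 1e-10)
})

test_that("score matches finite differences and hand cases", {
  s1 <- dgos_sample(1, dgos_scheme(1, 0, 1))
  expect_equal(unname(burr3_score(s1, 2, 3)["dl_dk"]), 1 / 3 + log(1 / 2),
               tolerance = 1e-14)
  expect_equal(unname(burr3_score(s1, 2, 1 / log(2))["dl_dk"]), 0,
               tolerance = 1e-12)

  set.seed(31)
  for (r in 1:12) {
    inst <- random_instance()
    f <- function(c0, k0) burr3_loglik(inst$sample, c0, k0)
    fd <- fd_grad(f, inst$c0, inst$k0)
    an <- burr3_score(inst$sample, inst$c0, inst$k0)
    expect_equal(unname(an["dl_dk"]), unname(fd["dk"]),
                 tolerance = 1e-5 * max(1, abs(fd["dk"])))
    expect_equal(unname(an["dl_dc"]), unname(fd["dc"]),
                 tolerance = 1e-5 * max(1, abs(fd["dc"])))
  }
})

test_that("conditional k-MLE has the closed form and kills the k-score", {
  s1 <- dgos_sample(1, dgos_scheme(1, 0, 1))
  expect_equal(burr3_khat(s1, 2), 1 / log(2), tolerance = 1e-14)
  # records, n = 2, x = (2, 1), c = 1: khat = 2 / log 2
  s2 <- dgos_sample(c(2, 1), dgos_scheme(2, -1, 1))
  expect_equal(burr3_khat(s2, 1), 2 / log(2), tolerance = 1e-14)

  set.seed(32)
  for (r in 1:8) {
    inst <- random_instance()
    kk <- burr3_khat(inst$sample, inst$c0)
    expect_equal(unname(burr3_score(inst$sample, inst$c0, kk)["dl_dk"]), 0,
                 tolerance = 1e-12)
  }
})

test_that("profile score equals the c-score at the concentrated k", {
  set.seed(33)
  for (r in 1:10) {
    inst <- random_instance()
    kk <- burr3_khat(inst$sample, inst$c0)
    expect_equal(burr3_profile_score(inst$sample, inst$c0),
                 unname(burr3_score(inst$sample, inst$c0, kk)["dl_dc"]),
                 tolerance = 1e-12)
  }
})

test_that("fit recovers parameters on a large easy sample", {
  set.seed(34)
  x <- rdgos(dgos_scheme(200, 0, 1), 3, 2)
  fit <- burr3_fit(x)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-6)
  expect_lt(abs(burr3_profile_score(x, fit$c_hat)), 1e-8)
  # within 3 asymptotic standard deviations of the truth
  V <- asymptotic_covariance(burr3_expected_fisher(dgos_scheme(1, 0, 1), 3, 2))
  expect_lt(abs(fit$c_hat - 3), 3 * sqrt(V$var_c / 200))
  expect_lt(abs(fit$k_hat - 2), 3 * sqrt(V$var_k / 200))

  # local maximum: the loglik dominates an 11 x 11 grid around the optimum
  grid <- expand.grid(c = fit$c_hat * seq(0.9, 1.1, length.out = 11),
                      k = fit$k_hat * seq(0.9, 1.1, length.out = 11))
  ll <- mapply(function(c0, k0) burr3_loglik(x, c0, k0), grid$c, grid$k)
  expect_true(all(ll <= fit$loglik + 1e-10))
})

test_that("power transforms rescale c and leave k fixed", {
  set.seed(35)
  x <- rdgos(dgos_scheme(60, 0, 1), 3, 2)
  fit <- burr3_fit(x)
  for (a in c(0.5, 2)) {
    fit_a <- burr3_fit(as.numeric(x)^a, m = 0, q = 1)
    expect_equal(fit_a$c_hat, fit$c_hat / a, tolerance = 1e-6)
    expect_equal(fit_a$k_hat, fit$k_hat, tolerance = 1e-6)
  }
})

test_that("fit flags samples without an interior maximum instead of erroring", {
  # all records below 1: the profile likelihood is monotone increasing in c
  x <- dgos_sample(c(0.95, 0.8, 0.55, 0.3) * 0.9, dgos_scheme(4, -1, 1))
  fit <- burr3_fit(x)
  expect_false(fit$converged)
  expect_true(is.na(fit$c_hat))
  expect_error(burr3_fit(dgos_sample(1, dgos_scheme(1, 0, 1))), "two observations")
})

test_that("observed information matches its definition and finite differences", {
  s <- rdgos(dgos_scheme(10, -1, 1), 3, 2)
  expect_equal(burr3_obs_info(s, 3, 2)["k", "k"], 10 / 4, tolerance = 1e-14)

  set.seed(36)
  for (r in 1:8) {
    inst <- random_instance()
    f <- function(c0, k0) burr3_loglik(inst$sample, c0, k0)
    J <- burr3_obs_info(inst$sample, inst$c0, inst$k0)
    expect_identical(J["k", "c"], J["c", "k"])
    Hfd <- -fd_hess(f, inst$c0, inst$k0)
    for (ij in list(c(1, 1), c(1, 2), c(2, 2)))
      expect_equal(J[ij[1], ij[2]], Hfd[ij[1], ij[2]],
                   tolerance = 1e-4 * max(1, abs(Hfd[ij[1], ij[2]])))
  }
})

test_that("third derivatives match their closed forms and finite differences", {
  set.seed(37)
  s <- rdgos(dgos_scheme(10, -1, 1), 3, 2)
  d3 <- burr3_third_derivs(s, 3, 2)
  expect_identical(unname(d3["l21"]), 0)
  expect_equal(unname(d3["l30"]), 2 * 10 / 8, tolerance = 1e-14)

  for (r in 1:8) {
    inst <- random_instance()
    f <- function(c0, k0) burr3_loglik(inst$sample, c0, k0)
    d3 <- burr3_third_derivs(inst$sample, inst$c0, inst$k0)
    fd <- fd_third(f, inst$c0, inst$k0)
    for (nm in c("l30", "l03", "l12"))
      expect_equal(unname(d3[nm]), unname(fd[nm]),
                   tolerance = 1e-3 * max(1, abs(fd[nm])))
  }
})

test_that("MLE error decreases with sample size on reversed order statistics", {
  set.seed(38)
  rmse_c <- sapply(c(25, 100), function(n) {
    err <- replicate(60, {
      fit <- burr3_fit(rdgos(dgos_scheme(n, 0, 1), 3, 2))
      if (fit$converged) (fit$c_hat - 3)^2 else NA_real_
    })
    sqrt(mean(err, na.rm = TRUE))
  })
  expect_lt(rmse_c[2], rmse_c[1])
})
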