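#' Dual-GOS log-likelihood of the Burr III shape parameters
#'
#' For a dual-GOS sample `x_1 > ... > x_n` with scheme `(n, m, q)` the
#' log-likelihood (up to the additive constant `log q + sum log gamma_j`,
#' which does not involve the parameters) is
#' \deqn{\ell = n\log c + n\log k
#'   + \sum_{i=1}^{n-1}\big[(ck + cmk - 1)\log x_i - (k + mk + 1)\log(1 + x_i^c)\big]
#'   + (ckq - 1)\log x_n - (kq + 1)\log(1 + x_n^c).}
#'
#' Throughout the derivative stack the two sample transforms
#' `omega_i = x_i^c / (1 + x_i^c)` and `upsilon_i = log(x_i) / (1 + x_i^c)`
#' appear; both are computed through the logistic function of `c log x_i`
#' for numerical stability at extreme `c`.
#'
#' @param sample a `dgos_sample` (or any decreasing positive vector if
#'   `m`, `q` are supplied to the calling front end).
#' @param shape1,shape2 the Burr III parameters `c`, `k`.
#' @return the log-likelihood value (additive constant omitted).
#' @seealso [burr3_fit()] for maximisation, [burr3_score()] for the
#'   gradient.
#' @export
burr3_loglik <- function(sample, shape1, shape2) {
  s <- attr(sample, "scheme")
  stopifnot(inherits(sample, "dgos_sample"))
  .check_shapes(shape1, shape2)
  n <- s$n; m <- s$m; q <- s$q
  lx <- log(as.numeric(sample))
  L <- .log1p_pow(sample, shape1)    # log(1 + x^c)
  c0 <- shape1; k0 <- shape2
  head <- if (n > 1)
    sum((c0 * k0 + c0 * m * k0 - 1) * lx[-n] - (k0 + m * k0 + 1) * L[-n])
  else 0
  n * log(c0) + n * log(k0) + head + (c0 * k0 * q - 1) * lx[n] - (k0 * q + 1) * L[n]
}

## omega, upsilon and the higher-order sample transforms at a given c.
.sample_stats <- function(x, c0) {
  lx <- log(as.numeric(x))
  w <- stats::plogis(c0 * lx)          # omega = x^c / (1 + x^c)
  s <- stats::plogis(-c0 * lx)         # 1 - omega = 1 / (1 + x^c)
  list(lx = lx,
       w = w,
       logw = stats::plogis(c0 * lx, log.p = TRUE),
       v = lx * s,                     # upsilon
       uwl = lx^2 * w * s,             # upsilon * omega * log x
       t3 = lx^3 * w * s * (s - w))    # omega * upsilon^2 * (1 - x^c) * log x
}

#' Score vector of the dual-GOS Burr III log-likelihood
#'
#' Returns the partial derivatives
#' \deqn{\partial\ell/\partial k = n/k + (1+m)\sum_{i<n}\log\omega_i + q\log\omega_n,}
#' \deqn{\partial\ell/\partial c = n/c - \sum_{i=1}^{n} x_i^c \upsilon_i
#'   + k\big[(1+m)\sum_{i<n}\upsilon_i + q\,\upsilon_n\big].}
#'
#' @inheritParams burr3_loglik
#' @return a named vector `c(dl_dk, dl_dc)`.
#' @export
burr3_score <- function(sample, shape1, shape2) {
  sch <- attr(sample, "scheme")
  stopifnot(inherits(sample, "dgos_sample"))
  .check_shapes(shape1, shape2)
  n <- sch$n; m <- sch$m; q <- sch$q
  st <- .sample_stats(sample, shape1)
  dl_dk <- n / shape2 + (1 + m) * sum(st$logw[-n]) + q * st$logw[n]
  dl_dc <- n / shape1 - sum(st$w * st$lx) +
    shape2 * ((1 + m) * sum(st$v[-n]) + q * st$v[n])
  c(dl_dk = dl_dk, dl_dc = dl_dc)
}

#' Conditional maximum likelihood estimate of k given c
#'
#' The k-score is linear in `1/k`, giving the closed form
#' `k(c) = -n / [(1+m) sum log omega_i + q log omega_n]`. The denominator
#' is strictly negative for valid schemes with `m >= -1`; a non-negative
#' denominator is reported as a numerical error.
#'
#' @inheritParams burr3_loglik
#' @param shape1 the value of `c` at which to profile.
#' @return the conditional MLE of `k`.
#' @export
burr3_khat <- function(sample, shape1) {
  sch <- attr(sample, "scheme")
  stopifnot(inherits(sample, "dgos_sample"))
  n <- sch$n
  st <- .sample_stats(sample, shape1)
  D <- (1 + sch$m) * sum(st$logw[-n]) + sch$q * st$logw[n]
  if (!is.finite(D) || D >= 0)
    stop("conditional k-MLE undefined: denominator of the closed form is not negative",
         call. = FALSE)
  -n / D
}

#' Profile score equation for c
#'
#' The left-hand side of the profile equation obtained by substituting the
#' closed-form `k(c)` into the c-score; its root is the MLE of `c`.
#' Identically equal to `burr3_score(sample, c, burr3_khat(sample, c))[2]`.
#'
#' @inheritParams burr3_khat
#' @return the profile score value at `shape1`.
#' @export
burr3_profile_score <- function(sample, shape1) {
  sch <- attr(sample, "scheme")
  stopifnot(inherits(sample, "dgos_sample"))
  n <- sch$n; m <- sch$m; q <- sch$q
  st <- .sample_stats(sample, shape1)
  D <- (1 + m) * sum(st$logw[-n]) + q * st$logw[n]
  n / shape1 - sum(st$w * st$lx) -
    n * ((1 + m) * sum(st$v[-n]) + q * st$v[n]) / D
}

#' Observed information matrix
#'
#' The negated second derivatives of the log-likelihood, ordered `(k, c)`:
#' \deqn{-\ell_{kk} = n/k^2, \qquad
#'   -\ell_{kc} = -\big[(1+m)\sum_{i<n}\upsilon_i + q\upsilon_n\big],}
#' \deqn{-\ell_{cc} = n/c^2 + (k+mk+1)\sum_{i<n}\upsilon_i\omega_i\log x_i
#'   + (kq+1)\,\upsilon_n\omega_n\log x_n.}
#'
#' @inheritParams burr3_loglik
#' @return a symmetric 2 x 2 matrix with dimnames `(k, c)`.
#' @export
burr3_obs_info <- function(sample, shape1, shape2) {
  sch <- attr(sample, "scheme")
  stopifnot(inherits(sample, "dgos_sample"))
  .check_shapes(shape1, shape2)
  n <- sch$n; m <- sch$m; q <- sch$q
  st <- .sample_stats(sample, shape1)
  Jkk <- n / shape2^2
  Jkc <- -((1 + m) * sum(st$v[-n]) + q * st$v[n])
  Jcc <- n / shape1^2 + (shape2 + m * shape2 + 1) * sum(st$uwl[-n]) +
    (shape2 * q + 1) * st$uwl[n]
  matrix(c(Jkk, Jkc, Jkc, Jcc), 2, 2,
         dimnames = list(c("k", "c"), c("k", "c")))
}

#' Third derivatives of the log-likelihood
#'
#' The four third partials needed by the Lindley approximation, evaluated
#' at `(k, c)`:
#' `l30 = 2n/k^3`, `l21 = 0` (the k-score is free of c-by-k-squared terms),
#' \deqn{l_{12} = -(m+1)\sum_{i<n}\omega_i\upsilon_i\log x_i - q\,\omega_n\upsilon_n\log x_n,}
#' \deqn{l_{03} = 2n/c^3 - \sum_{i=1}^{n} T_i - k(1+m)\sum_{i<n} T_i - kq\,T_n,
#'   \quad T_i = \omega_i\upsilon_i^2(1 - x_i^c)\log x_i.}
#'
#' @inheritParams burr3_loglik
#' @return a named vector `c(l30, l03, l21, l12)`.
#' @export
burr3_third_derivs <- function(sample, shape1, shape2) {
  sch <- attr(sample, "scheme")
  stopifnot(inherits(sample, "dgos_sample"))
  .check_shapes(shape1, shape2)
  n <- sch$n; m <- sch$m; q <- sch$q
  st <- .sample_stats(sample, shape1)
  l30 <- 2 * n / shape2^3
  l12 <- -((m + 1) * sum(st$uwl[-n]) + q * st$uwl[n])
  l03 <- 2 * n / shape1^3 -
    (sum(st$t3) + shape2 * (1 + m) * sum(st$t3[-n]) + shape2 * q * st$t3[n])
  c(l30 = l30, l03 = l03, l21 = 0, l12 = l12)
}
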