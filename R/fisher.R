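#' Exact expectations under the dual-GOS marginal law
#'
#' `expect_upsilon()` returns \eqn{E[\log X_i / (1 + X_i^c)]} and
#' `expect_upsilon_omega_log()` returns
#' \eqn{E[X_i^c (\log X_i)^2 / (1 + X_i^c)^2]} for the i-th dual
#' generalized order statistic of a Burr III parent. These are the two
#' expectations entering the expected Fisher information.
#'
#' Both are evaluated by closed series obtained from the substitution
#' `z = F^{1/k}(x)`, under which `1/(1 + x^c) = 1 - z` and
#' `log x = (log z - log(1-z))/c`, so every required integral reduces to
#' moments of `z^A log z` and `z^A log(1-z)` with `A = k(gamma_i + a(m+1))`.
#' The resulting series have terms of order `n^-3` (log-weighted) and are
#' summed adaptively in chunks until the largest new term falls below
#' `1e-13` of the running total. For `m = -1` the same route yields the
#' record-value series in the scheme constant `kq` directly. An
#' independent adaptive-quadrature oracle over the defining integral is
#' available as [quadrature_expectation()].
#'
#' @param i index of the dual GOS, `1 <= i <= n`.
#' @param scheme a [dgos_scheme()].
#' @param shape1,shape2 Burr III shape parameters `c`, `k`.
#' @return the exact expectation (a scalar).
#' @seealso [burr3_expected_fisher()], [quadrature_expectation()]
#' @export
expect_upsilon <- function(i, scheme, shape1, shape2) {
  .check_expect_args(i, scheme, shape1, shape2)
  c0 <- shape1; k0 <- shape2
  m <- scheme$m; q <- scheme$q
  if (m == -1) {
    K <- k0 * q
    s <- .sum_adapt(function(n) (1 / n) * ((n + K)^(-i) - (n + K + 1)^(-i)))
    i * K^i / (c0 * (K + 1)^(i + 1)) - i / (c0 * K) + K^i / c0 * s
  } else {
    a <- 0:(i - 1)
    A <- k0 * (scheme$gamma[i] + a * (m + 1))
    T1 <- vapply(A, function(AA) {
      1 / (AA + 1)^2 - 1 / AA^2 +
        .sum_adapt(function(n) 1 / (n * (AA + n) * (AA + n + 1)))
    }, numeric(1))
    k0 * scheme$C[i] / (c0 * factorial(i - 1) * (m + 1)^(i - 1)) *
      sum(choose(i - 1, a) * (-1)^a * T1)
  }
}

#' @rdname expect_upsilon
#' @export
expect_upsilon_omega_log <- function(i, scheme, shape1, shape2) {
  .check_expect_args(i, scheme, shape1, shape2)
  c0 <- shape1; k0 <- shape2
  m <- scheme$m; q <- scheme$q
  ## H_{n-1} = digamma(n) + Euler's constant; the n = 1 term of the
  ## double series vanishes with it.
  harm <- function(n) digamma(n) + 0.5772156649015329
  if (m == -1) {
    K <- k0 * q
    s1 <- .sum_adapt(function(n)
      (2 * harm(n) / n) * ((n + K + 1)^(-i) - (n + K + 2)^(-i)))
    s2 <- .sum_adapt(function(n)
      (1 / n) * ((n + K + 2)^(-(i + 1)) - (n + K + 1)^(-(i + 1))))
    K^i / c0^2 *
      (i * (i + 1) * ((K + 1)^(-(i + 2)) - (K + 2)^(-(i + 2))) + s1 + 2 * i * s2)
  } else {
    a <- 0:(i - 1)
    A <- k0 * (scheme$gamma[i] + a * (m + 1))
    T2 <- vapply(A, function(AA) {
      2 / (AA + 1)^3 - 2 / (AA + 2)^3 +
        2 * .sum_adapt(function(n) (1 / n) * ((AA + n + 2)^(-2) - (AA + n + 1)^(-2))) +
        .sum_adapt(function(n)
          (2 * harm(n) / n) * ((AA + n + 1)^(-1) - (AA + n + 2)^(-1)))
    }, numeric(1))
    k0 * scheme$C[i] / (c0^2 * factorial(i - 1) * (m + 1)^(i - 1)) *
      sum(choose(i - 1, a) * (-1)^a * T2)
  }
}

.check_expect_args <- function(i, scheme, shape1, shape2) {
  stopifnot(inherits(scheme, "dgos_scheme"))
  .check_shapes(shape1, shape2)
  if (length(i) != 1L || i < 1 || i > scheme$n || i != round(i))
    stop("'i' must be a single index in 1..n", call. = FALSE)
  invisible(NULL)
}

## Adaptive chunked summation of series with eventually monotone decaying
## terms.  Stops when the largest term of the latest chunk is below `tol`
## relative to the running total; errors at the term cap.
.sum_adapt <- function(term, tol = 1e-13, chunk = 4096L, cap = 2e6) {
  total <- 0; n0 <- 1
  repeat {
    idx <- n0:(n0 + chunk - 1L)
    t <- term(idx)
    total <- total + sum(t)
    if (max(abs(t)) < tol * max(abs(total), 1e-300)) break
    n0 <- n0 + chunk
    if (n0 > cap)
      stop("series did not converge within the term cap", call. = FALSE)
  }
  total
}

#' Quadrature oracle for the dual-GOS expectations
#'
#' Evaluates the defining integral of [expect_upsilon()] or
#' [expect_upsilon_omega_log()] by adaptive quadrature of the integrand
#' against the marginal density [dgos_marginal()], split at `x = 1` to
#' tame the log-weighted tails. Serves as the independent check on the
#' series implementations (and as a slow exact mode).
#'
#' @inheritParams expect_upsilon
#' @param kind `"upsilon"` or `"upsilon_omega_log"`.
#' @param rel.tol quadrature tolerance.
#' @return the expectation by numerical integration.
#' @export
quadrature_expectation <- function(i, kind = c("upsilon", "upsilon_omega_log"),
                                   scheme, shape1, shape2, rel.tol = 1e-10) {
  kind <- match.arg(kind)
  .check_expect_args(i, scheme, shape1, shape2)
  g <- if (kind == "upsilon") {
    function(x) log(x) / (1 + x^shape1)
  } else {
    function(x) x^shape1 * log(x)^2 / (1 + x^shape1)^2
  }
  f <- function(x) g(x) * dgos_marginal(x, i, scheme, shape1, shape2)
  lower <- stats::integrate(f, 0, 1, rel.tol = rel.tol, abs.tol = rel.tol / 10)
  upper <- stats::integrate(f, 1, Inf, rel.tol = rel.tol, abs.tol = rel.tol / 10)
  if (lower$message != "OK" || upper$message != "OK")
    stop("quadrature failed: ", lower$message, " / ", upper$message, call. = FALSE)
  lower$value + upper$value
}

#' Exact expected Fisher information under dual GOS
#'
#' The expected information matrix of `(k, c)` for `n` dual generalized
#' order statistics from a Burr III parent:
#' \deqn{Q_{11} = n/k^2, \qquad
#'   Q_{12} = -(1+m)\sum_{i<n} E(\upsilon_i) - q\,E(\upsilon_n),}
#' \deqn{Q_{22} = n/c^2 + (k+mk+1)\sum_{i<n} E(\upsilon_i\omega_i\log X_i)
#'   + (kq+1)\,E(\upsilon_n\omega_n\log X_n),}
#' with the expectations computed exactly by [expect_upsilon()] and
#' [expect_upsilon_omega_log()].
#'
#' @inheritParams expect_upsilon
#' @return an object of class `"burr3_fisher"`: the 2 x 2 matrix (ordered
#'   `(k, c)`) with the scheme and parameters attached as attributes.
#' @examples
#' Q <- burr3_expected_fisher(dgos_scheme(4, -1, 1), 3, 2)
#' asymptotic_covariance(Q)
#' @export
burr3_expected_fisher <- function(scheme, shape1, shape2) {
  stopifnot(inherits(scheme, "dgos_scheme"))
  .check_shapes(shape1, shape2)
  n <- scheme$n; m <- scheme$m; q <- scheme$q
  Eu <- vapply(seq_len(n), expect_upsilon, numeric(1),
               scheme = scheme, shape1 = shape1, shape2 = shape2)
  Ew <- vapply(seq_len(n), expect_upsilon_omega_log, numeric(1),
               scheme = scheme, shape1 = shape1, shape2 = shape2)
  Q11 <- n / shape2^2
  Q12 <- -((1 + m) * sum(Eu[-n]) + q * Eu[n])
  Q22 <- n / shape1^2 + (shape2 + m * shape2 + 1) * sum(Ew[-n]) +
    (shape2 * q + 1) * Ew[n]
  Q <- matrix(c(Q11, Q12, Q12, Q22), 2, 2,
              dimnames = list(c("k", "c"), c("k", "c")))
  structure(Q, scheme = scheme, shape1 = shape1, shape2 = shape2,
            class = c("burr3_fisher", "matrix"))
}

#' @export
print.burr3_fisher <- function(x, ...) {
  s <- attr(x, "scheme")
  cat(sprintf("Expected Fisher information, Burr III dual GOS (n = %d, m = %g, q = %g) at c = %g, k = %g\n",
              s$n, s$m, s$q, attr(x, "shape1"), attr(x, "shape2")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Asymptotic variance-covariance matrix of the MLE
#'
#' Inverts a 2 x 2 expected (or observed) information matrix:
#' `var_k = Q22/det`, `var_c = Q11/det`, `cov_kc = -Q12/det` with
#' `det = Q11 Q22 - Q12^2`. A non-positive determinant is a singularity
#' error.
#'
#' @param fisher a [burr3_expected_fisher()] result or any symmetric
#'   2 x 2 information matrix ordered `(k, c)`.
#' @return a list with `var_k`, `var_c`, `cov_kc` and the full matrix
#'   `vcov`.
#' @export
asymptotic_covariance <- function(fisher) {
  Q <- unclass(fisher)
  stopifnot(is.matrix(Q), all(dim(Q) == 2))
  det <- Q[1, 1] * Q[2, 2] - Q[1, 2]^2
  if (!is.finite(det) || det <= 0)
    stop("information matrix is singular or indefinite", call. = FALSE)
  V <- matrix(c(Q[2, 2], -Q[1, 2], -Q[1, 2], Q[1, 1]), 2, 2,
              dimnames = dimnames(Q)) / det
  list(var_k = V[1, 1], var_c = V[2, 2], cov_kc = V[1, 2], vcov = V)
}
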