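#' Dual generalized order statistics scheme
#'
#' A dual-GOS scheme is the configuration `(n, m, q)` of the joint density of
#' `n` decreasingly ordered random variables. With a common model parameter
#' `m`, the scheme constants are
#' \deqn{\gamma_r = q + n - r + (n - r)\,m, \qquad r = 1, \dots, n,}
#' all of which must be positive; `gamma[n] = q`. Two special cases matter in
#' practice: `m = 0, q = 1` gives reversed order statistics (an iid sample
#' listed decreasingly) and `m = -1, q = 1` gives lower record values.
#'
#' @param n number of ordered observations (integer, at least 1).
#' @param m common model parameter (real).
#' @param q tail parameter (positive real).
#'
#' @return An object of class `"dgos_scheme"`: a list with elements `n`, `m`,
#'   `q`, `gamma` (the vector of scheme constants) and `C` (the cumulative
#'   products `C[i] = gamma[1] * ... * gamma[i]` entering the marginal
#'   densities).
#'
#' @examples
#' dgos_scheme(4, -1, 1)$gamma   # lower records: 1 1 1 1
#' dgos_scheme(4, 0, 1)$gamma    # reversed order statistics: 4 3 2 1
#' dgos_scheme(3, 0.5, 2)$gamma  # 5.0 3.5 2.0
#' @export
dgos_scheme <- function(n, m, q) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m))
    stop("'m' must be a single finite number", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    stop("'q' must be a single positive number", call. = FALSE)
  n <- as.integer(n)
  r <- seq_len(n)
  gam <- q + n - r + (n - r) * m
  if (any(gam <= 0))
    stop("invalid scheme: gamma_r = q + n - r + (n - r) m must be positive for all r",
         call. = FALSE)
  structure(list(n = n, m = m, q = q, gamma = gam, C = cumprod(gam)),
            class = "dgos_scheme")
}

#' @export
print.dgos_scheme <- function(x, ...) {
  cat(sprintf("Dual GOS scheme: n = %d, m = %g, q = %g\n", x$n, x$m, x$q))
  cat("gamma_r:", paste(format(x$gamma, digits = 6), collapse = " "), "\n")
  invisible(x)
}

#' The g_m weight of the dual-GOS marginal density
#'
#' `gm(u, m)` is `(1 - u^(m+1))/(m+1)` for `m != -1` and `-log(u)` for
#' `m = -1`; the two branches join continuously at `m = -1`.
#'
#' @param u values in `[0, 1)`.
#' @param m the scheme parameter.
#' @return the weight, non-negative on `[0, 1)`.
#' @examples
#' gm(0.5, 0)    # 0.5
#' gm(0.5, -1)   # log(2)
#' @export
gm <- function(u, m) {
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("'u' must lie in [0, 1)", call. = FALSE)
  if (m == -1) -log(u) else (1 - u^(m + 1)) / (m + 1)
}

#' Marginal density of the i-th dual generalized order statistic
#'
#' Under a Burr III parent with shapes `(c, k)`, the i-th dual GOS has
#' density
#' \deqn{f_i(x) = \frac{C_{i-1}}{\Gamma(i)} F(x)^{\gamma_i - 1}
#'   \,g_m(F(x))^{i-1} f(x),}
#' with `F`, `f` the parent cdf/pdf and `C`, `gamma`, `g_m` the scheme
#' quantities of [dgos_scheme()] and [gm()].
#'
#' @param x vector of positive quantiles.
#' @param i index of the dual GOS, `1 <= i <= n`.
#' @param scheme a [dgos_scheme()].
#' @param shape1,shape2 Burr III shape parameters `c`, `k`.
#' @return the marginal density values.
#' @examples
#' s <- dgos_scheme(4, -1, 1)
#' integrate(dgos_marginal, 0, Inf, i = 2, scheme = s, shape1 = 3, shape2 = 2)
#' @export
dgos_marginal <- function(x, i, scheme, shape1, shape2) {
  stopifnot(inherits(scheme, "dgos_scheme"))
  if (length(i) != 1L || i < 1 || i > scheme$n || i != round(i))
    stop("'i' must be a single index in 1..n", call. = FALSE)
  Fv <- pburr3(x, shape1, shape2)
  scheme$C[i] / gamma(i) * Fv^(scheme$gamma[i] - 1) * gm(Fv, scheme$m)^(i - 1) *
    dburr3(x, shape1, shape2)
}

#' Draw one dual-GOS sample
#'
#' Uses the product representation `X(r) = Q(prod_{j<=r} B_j)` with
#' independent `B_j = U_j^{1/gamma_j}`, `U_j` uniform, and `Q` the Burr III
#' quantile function. For `m = -1, q = 1` all `gamma_j = 1`, so the
#' construction reduces exactly to lower record values as cumulative
#' products of plain uniforms. Floating-point ties (measure zero) are
#' rejected and the sample redrawn.
#'
#' @param scheme a [dgos_scheme()].
#' @param shape1,shape2 Burr III shape parameters `c`, `k`.
#' @param u optional matrix/vector of uniforms (one row per sample) for
#'   deterministic construction; mainly for testing.
#' @return a numeric vector of length `n`, strictly decreasing, of class
#'   `"dgos_sample"` with the scheme attached as an attribute.
#' @examples
#' set.seed(1)
#' rdgos(dgos_scheme(4, -1, 1), 3, 2)
#' @export
rdgos <- function(scheme, shape1, shape2, u = NULL) {
  stopifnot(inherits(scheme, "dgos_scheme"))
  repeat {
    uu <- if (is.null(u)) stats::runif(scheme$n) else u
    b <- uu^(1 / scheme$gamma)
    x <- qburr3(cumprod(b), shape1, shape2)
    if (all(diff(x) < 0)) break
    if (!is.null(u)) stop("supplied uniforms produce tied values", call. = FALSE)
  }
  dgos_sample(x, scheme)
}

#' Draw one sequence of lower record values
#'
#' Convenience wrapper for `rdgos(dgos_scheme(n, -1, 1), ...)`: the i-th
#' lower record equals the Burr III quantile of the cumulative product of
#' i iid uniforms.
#'
#' @param n number of records.
#' @param shape1,shape2 Burr III shape parameters `c`, `k`.
#' @param u optional vector of uniforms for deterministic construction.
#' @return a `"dgos_sample"` of `n` lower records.
#' @examples
#' rdgos_records(2, 1, 1, u = c(0.5, 0.5))   # (1, 1/3)
#' @export
rdgos_records <- function(n, shape1, shape2, u = NULL) {
  rdgos(dgos_scheme(n, -1, 1), shape1, shape2, u = u)
}

#' Validate a dual-GOS sample
#'
#' Wraps a decreasing sequence of positive observations together with its
#' scheme. Non-positive values, increasing pairs and exact ties are
#' rejected: the joint dual-GOS density assumes distinct ordered values,
#' and silent acceptance would mask data errors.
#'
#' @param x numeric vector, strictly decreasing, all positive.
#' @param scheme a [dgos_scheme()] with matching `n`.
#' @return `x` with class `"dgos_sample"` and attribute `scheme`.
#' @export
dgos_sample <- function(x, scheme) {
  stopifnot(inherits(scheme, "dgos_scheme"))
  if (!is.numeric(x) || length(x) != scheme$n)
    stop(sprintf("sample length %d does not match scheme n = %d",
                 length(x), scheme$n), call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all observations must be positive and finite", call. = FALSE)
  if (length(x) > 1 && any(diff(x) >= 0))
    stop("observations must be strictly decreasing (x_1 > x_2 > ... > x_n)",
         call. = FALSE)
  structure(as.numeric(x), scheme = scheme, class = "dgos_sample")
}

#' @export
print.dgos_sample <- function(x, ...) {
  s <- attr(x, "scheme")
  cat(sprintf("Dual GOS sample (n = %d, m = %g, q = %g):\n", s$n, s$m, s$q))
  print(as.numeric(x), ...)
  invisible(x)
}

## Coerce user input (vector or dgos_sample) + scheme parameters into a
## validated sample.  Used by the fitting front ends.
.as_dgos_sample <- function(x, m, q) {
  if (inherits(x, "dgos_sample")) return(x)
  dgos_sample(as.numeric(x), dgos_scheme(length(x), m, q))
}
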