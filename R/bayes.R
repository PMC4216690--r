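#' Independent gamma priors for the Burr III parameters
#'
#' The prior is `k ~ Gamma(alpha, scale beta)` independent of
#' `c ~ Gamma(gamma, scale delta)`; the densities are proportional to
#' `k^(alpha-1) exp(-k/beta)` and `c^(gamma-1) exp(-c/delta)`. Note that
#' the second parameter of each pair is a SCALE, not a rate; a shape/rate
#' reading would silently change every Bayes estimate.
#'
#' @param alpha,beta shape and scale of the prior on `k` (both positive).
#' @param gamma,delta shape and scale of the prior on `c` (both positive).
#' @return an object of class `"burr3_prior"`.
#' @examples
#' gamma_prior(3, 2, 2, 3)   # prior means: k 6, c 6
#' @export
gamma_prior <- function(alpha, beta, gamma, delta) {
  v <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all four hyperparameters must be positive", call. = FALSE)
  structure(as.list(v), class = "burr3_prior")
}

#' @export
print.burr3_prior <- function(x, ...) {
  cat(sprintf("Gamma priors: k ~ Gamma(shape %g, scale %g), c ~ Gamma(shape %g, scale %g)\n",
              x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Gradient of the log prior
#'
#' `p1 = d log pi / dk = (alpha - 1)/k - 1/beta` and
#' `p2 = d log pi / dc = (gamma - 1)/c - 1/delta`.
#'
#' @param prior a [gamma_prior()].
#' @param shape1,shape2 the point `(c, k)` of evaluation.
#' @return named vector `c(p1, p2)`.
#' @export
log_prior_grad <- function(prior, shape1, shape2) {
  stopifnot(inherits(prior, "burr3_prior"))
  .check_shapes(shape1, shape2)
  c(p1 = (prior$alpha - 1) / shape2 - 1 / prior$beta,
    p2 = (prior$gamma - 1) / shape1 - 1 / prior$delta)
}

#' Components of Lindley's two-parameter approximation
#'
#' Evaluates, at the MLE `(k_hat, c_hat)`, everything the Lindley expansion
#' of the posterior mean needs: the negated second derivatives
#' `G = -l_kk`, `H = -l_cc`, `I = l_kc`, the determinant `N = GH - I^2`,
#' the third derivatives `(l30, l03, l21, l12)`, the log-prior gradient
#' `(p1, p2)` and the additive corrections
#' \deqn{\psi_1 = \frac{l_{30}H^2 + l_{03}GI + l_{12}(HG + 2I^2)}{2N^2}
#'   + \frac{p_1 H + p_2 I}{N},}
#' \deqn{\psi_2 = \frac{l_{30}HI + l_{03}G^2 + 3 l_{12}GI}{2N^2}
#'   + \frac{p_1 I + p_2 G}{N}.}
#'
#' @param sample a `dgos_sample`.
#' @param shape1,shape2 the MLE `(c_hat, k_hat)` at which to expand.
#' @param prior a [gamma_prior()].
#' @return a list with `G`, `H`, `I`, `N`, `l30`, `l03`, `l21`, `l12`,
#'   `p1`, `p2`, `psi1`, `psi2` and a logical `saddle` flag raised when
#'   `N <= 0` (no proper interior maximum; the corrections are then
#'   unreliable).
#' @export
lindley_components <- function(sample, shape1, shape2, prior) {
  stopifnot(inherits(sample, "dgos_sample"), inherits(prior, "burr3_prior"))
  J <- burr3_obs_info(sample, shape1, shape2)
  G <- J["k", "k"]; H <- J["c", "c"]; I <- -J["k", "c"]
  N <- G * H - I^2
  d3 <- burr3_third_derivs(sample, shape1, shape2)
  pg <- log_prior_grad(prior, shape1, shape2)
  psi1 <- (d3["l30"] * H^2 + d3["l03"] * G * I + d3["l12"] * (H * G + 2 * I^2)) /
    (2 * N^2) + (pg["p1"] * H + pg["p2"] * I) / N
  psi2 <- (d3["l30"] * H * I + d3["l03"] * G^2 + 3 * d3["l12"] * G * I) /
    (2 * N^2) + (pg["p1"] * I + pg["p2"] * G) / N
  list(G = G, H = H, I = I, N = N,
       l30 = unname(d3["l30"]), l03 = unname(d3["l03"]),
       l21 = unname(d3["l21"]), l12 = unname(d3["l12"]),
       p1 = unname(pg["p1"]), p2 = unname(pg["p2"]),
       psi1 = unname(psi1), psi2 = unname(psi2),
       saddle = !is.finite(N) || N <= 0)
}

#' Lindley-approximated Bayes estimates under squared error loss
#'
#' The approximate posterior means are the MLEs plus the Lindley
#' corrections, `k_B = k_hat + psi1` and `c_B = c_hat + psi2`, with all
#' quantities evaluated at the MLE. The corrections can overshoot at very
#' small samples; non-positive estimates are flagged (`proper = FALSE`)
#' but still returned.
#'
#' @inheritParams lindley_components
#' @return a list with `k_B`, `c_B`, the `components` and flags `proper`
#'   and `saddle`.
#' @seealso [posterior_mean_quadrature()] for the exact posterior means.
#' @export
bayes_lindley <- function(sample, shape1, shape2, prior) {
  comp <- lindley_components(sample, shape1, shape2, prior)
  k_B <- shape2 + comp$psi1
  c_B <- shape1 + comp$psi2
  list(k_B = k_B, c_B = c_B, components = comp,
       proper = is.finite(k_B) && is.finite(c_B) && k_B > 0 && c_B > 0,
       saddle = comp$saddle)
}

## Log-likelihood as a function linear in k for fixed c:
## l(c, k) = n log c + n log k + k * ka(c) + kb(c).
.loglik_kc_parts <- function(sample, c0) {
  sch <- attr(sample, "scheme")
  n <- sch$n; m <- sch$m; q <- sch$q
  lx <- log(as.numeric(sample))
  L <- .log1p_pow(sample, c0)
  ka <- if (n > 1)
    sum((c0 + c0 * m) * lx[-n] - (1 + m) * L[-n]) + q * (c0 * lx[n] - L[n])
  else q * (c0 * lx[n] - L[n])
  kb <- if (n > 1) sum(-lx[-n] - L[-n]) - lx[n] - L[n] else -lx[n] - L[n]
  c(ka = ka, kb = kb)
}

#' Exact posterior means by two-dimensional quadrature
#'
#' Computes the posterior means of `k` and `c` under the gamma priors by
#' direct numerical evaluation of the defining integral ratio
#' \deqn{E[U \mid x] = \frac{\iint U(k,c)\,L(c,k\mid x)\,\pi(c,k)\,dc\,dk}
#'   {\iint L(c,k\mid x)\,\pi(c,k)\,dc\,dk}.}
#' This is the oracle against which the Lindley estimates are judged, and
#' a slow exact estimation mode in its own right.
#'
#' The integration box is centred at the posterior mode (found by
#' quasi-Newton ascent on log-parameters) and extends `half_width`
#' posterior-curvature standard deviations per axis, truncated to the
#' positive quadrant; the box is widened by half its width until the
#' normalising mass changes by less than `1e-8` relatively. Integration
#' uses a tensor Gauss-Legendre rule.
#'
#' @param sample a `dgos_sample`.
#' @param prior a [gamma_prior()].
#' @param include_likelihood if `FALSE` the likelihood factor is dropped
#'   and the prior means are recovered (a testing mode: the gamma prior
#'   mean of `k` is `alpha * beta`).
#' @param nodes number of Gauss-Legendre nodes per axis.
#' @param half_width initial box half-width in posterior standard
#'   deviations.
#' @return a list with `k_mean`, `c_mean`, the `mode`, and the final
#'   integration `box`.
#' @export
posterior_mean_quadrature <- function(sample, prior, include_likelihood = TRUE,
                                      nodes = 64, half_width = 8) {
  stopifnot(inherits(sample, "dgos_sample"), inherits(prior, "burr3_prior"))
  sch <- attr(sample, "scheme")
  n <- sch$n
  a <- prior$alpha; b <- prior$beta; g <- prior$gamma; d <- prior$delta

  ## log posterior kernel on (k, c), vectorized over k for fixed c
  lp_fixed_c <- function(c0, kvec) {
    parts <- if (include_likelihood) .loglik_kc_parts(sample, c0) else c(ka = 0, kb = 0)
    nll <- if (include_likelihood) n * (log(c0) + log(kvec)) else 0
    nll + kvec * parts["ka"] + parts["kb"] +
      (a - 1) * log(kvec) - kvec / b + (g - 1) * log(c0) - c0 / d
  }
  lp <- function(par) lp_fixed_c(par[2], par[1])   # par = (k, c)

  ## posterior mode via ascent on log-parameters
  start <- log(c(a * b, g * d))
  opt <- stats::optim(start, function(lpar) -lp(exp(lpar)), method = "BFGS",
                      control = list(maxit = 500))
  mode <- exp(opt$par)
  ## curvature standard deviations by central differences on (k, c)
  h <- pmax(1e-5 * mode, 1e-8)
  hess <- matrix(0, 2, 2)
  for (ii in 1:2) for (jj in 1:2) {
    ei <- ej <- c(0, 0); ei[ii] <- h[ii]; ej[jj] <- h[jj]
    hess[ii, jj] <- (lp(mode + ei + ej) - lp(mode + ei - ej) -
                       lp(mode - ei + ej) + lp(mode - ei - ej)) /
      (4 * h[ii] * h[jj])
  }
  V <- tryCatch(solve(-hess), error = function(e) NULL)
  sd <- if (!is.null(V) && all(diag(V) > 0)) sqrt(diag(V)) else 0.5 * mode

  gl <- pracma::gaussLegendre(nodes, 0, 1)
  integrate_box <- function(w) {
    lo <- pmax(mode - w * sd, 1e-10)
    hi <- mode + w * sd
    kn <- lo[1] + (hi[1] - lo[1]) * gl$x; kw <- (hi[1] - lo[1]) * gl$w
    cn <- lo[2] + (hi[2] - lo[2]) * gl$x; cw <- (hi[2] - lo[2]) * gl$w
    LPM <- vapply(cn, function(c0) lp_fixed_c(c0, kn), numeric(nodes))  # k rows, c cols
    mx <- max(LPM)
    W <- exp(LPM - mx) * outer(kw, cw)
    Z <- sum(W)
    list(Z = Z, k_mean = sum(W * kn) / Z, c_mean = sum(rowSums(t(W) * cn)) / Z,
         lo = lo, hi = hi, mx = mx)
  }
  res <- integrate_box(half_width)
  w <- half_width
  for (pass in 1:4) {
    w2 <- w * 1.5
    res2 <- integrate_box(w2)
    rel <- abs(res2$Z * exp(res2$mx - res$mx) - res$Z) /
      max(res2$Z * exp(res2$mx - res$mx), 1e-300)
    res <- res2; w <- w2
    if (is.finite(rel) && rel < 1e-8) break
  }
  if (!is.finite(res$Z) || res$Z <= 0)
    stop("posterior quadrature failed: normalising mass is not positive",
         call. = FALSE)
  list(k_mean = res$k_mean, c_mean = res$c_mean,
       mode = c(k = mode[1], c = mode[2]),
       box = rbind(lo = res$lo, hi = res$hi))
}
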