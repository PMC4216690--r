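#' Root mean squared error against a known truth
#'
#' `sqrt(mean((truth - estimates)^2))`, the Monte Carlo figure of merit of
#' the recovery study; the divisor is the number of estimates supplied
#' (replicates whose fit failed are excluded upstream and reported).
#'
#' @param truth the true parameter value (scalar).
#' @param estimates vector of per-replicate estimates.
#' @return a non-negative scalar.
#' @examples
#' burr3_rmse(3, c(2, 4))   # 1
#' @export
burr3_rmse <- function(truth, estimates) {
  if (length(estimates) < 1L) stop("no estimates supplied", call. = FALSE)
  sqrt(mean((truth - estimates)^2))
}

#' Monte Carlo parameter-recovery study
#'
#' Repeatedly draws dual-GOS samples (by default lower record values) from
#' a Burr III parent with known parameters, fits the MLE and the
#' Lindley-approximated Bayes estimators for each configured prior, and
#' aggregates root mean squared errors per sample size and estimator.
#'
#' Replicates whose MLE does not exist (no interior maximum of the
#' profile likelihood; see [burr3_fit()]) are excluded from every column
#' of that replicate - the Bayes estimators are expansions around the
#' MLE, so they fail with it - and the exclusion count is reported
#' per sample size. The RMSE divisor is the number of replicates used.
#'
#' `record_construction` selects how the `m = -1, q = 1` samples are
#' generated: `"cumulative_product"` (the default) applies the quantile
#' function to cumulative products of iid uniforms, which is the standard
#' lower-record construction; `"iid_inverse_cdf"` applies it to iid
#' uniforms directly and sorts decreasingly, which yields an ordinary iid
#' sample, not records - the switch exists to quantify how much that
#' (mis)reading changes the study.
#'
#' @param shape1,shape2 true Burr III parameters `c`, `k`.
#' @param m,q scheme parameters of the generated samples.
#' @param n_values sample sizes to study.
#' @param reps Monte Carlo replicates per sample size.
#' @param priors list of [gamma_prior()] objects (possibly empty).
#' @param seed integer seed; per-replicate substream seeds are derived
#'   from it so that any replicate is individually reproducible.
#' @param record_construction see Details.
#'
#' @return An object of class `"burr3_study"`: a list with `table` (a
#'   data.frame of RMSEs: one row per `n`, columns `c_M`, `k_M` and
#'   `c_B`/`k_B` per prior), `failures` (non-converged MLE count per
#'   `n`), `improper` (count of flagged non-positive Bayes estimates),
#'   `estimates` (the raw per-replicate estimates), and the
#'   configuration.
#'
#' @examples
#' p <- list(gamma_prior(3, 2, 2, 3))
#' s <- burr3_study(3, 2, n_values = c(4, 6), reps = 25, priors = p, seed = 1)
#' s$table
#' @export
burr3_study <- function(shape1 = 3, shape2 = 2, m = -1, q = 1,
                        n_values = c(4, 6, 8, 10), reps = 1000,
                        priors = list(gamma_prior(3, 2, 2, 3),
                                      gamma_prior(5, 1, 2, 5)),
                        seed = 1,
                        record_construction = c("cumulative_product",
                                                "iid_inverse_cdf")) {
  record_construction <- match.arg(record_construction)
  .check_shapes(shape1, shape2)
  stopifnot(reps >= 1, all(n_values >= 2))
  for (p in priors) stopifnot(inherits(p, "burr3_prior"))
  np <- length(priors)

  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, length(n_values) * reps)
  dim(subseeds) <- c(length(n_values), reps)

  cols <- c("c_M", "k_M",
            if (np) as.vector(t(outer(seq_len(np), c("c_B", "k_B"),
                                      function(i, s) paste0(s, i)))))
  tab <- matrix(NA_real_, length(n_values), length(cols),
                dimnames = list(NULL, cols))
  failures <- integer(length(n_values))
  improper <- integer(length(n_values))
  estimates <- vector("list", length(n_values))
  names(estimates) <- as.character(n_values)

  for (ni in seq_along(n_values)) {
    n <- n_values[ni]
    scheme <- dgos_scheme(n, m, q)
    est <- matrix(NA_real_, reps, length(cols), dimnames = list(NULL, cols))
    for (r in seq_len(reps)) {
      set.seed(subseeds[ni, r])
      x <- if (record_construction == "iid_inverse_cdf" && m == -1 && q == 1) {
        dgos_sample(sort(rburr3(n, shape1, shape2), decreasing = TRUE), scheme)
      } else {
        rdgos(scheme, shape1, shape2)
      }
      fit <- burr3_fit(x)
      if (!fit$converged) { failures[ni] <- failures[ni] + 1L; next }
      est[r, "c_M"] <- fit$c_hat
      est[r, "k_M"] <- fit$k_hat
      for (pi in seq_len(np)) {
        bl <- bayes_lindley(x, fit$c_hat, fit$k_hat, priors[[pi]])
        est[r, paste0("c_B", pi)] <- bl$c_B
        est[r, paste0("k_B", pi)] <- bl$k_B
        if (!bl$proper) improper[ni] <- improper[ni] + 1L
      }
    }
    used <- !is.na(est[, "c_M"])
    truth <- c(shape1, shape2)[match(substr(cols, 1, 1), c("c", "k"))]
    tab[ni, ] <- vapply(seq_along(cols), function(j)
      burr3_rmse(truth[j], est[used, j]), numeric(1))
    estimates[[ni]] <- est
  }

  structure(list(table = data.frame(n = n_values, tab, check.names = FALSE),
                 failures = stats::setNames(failures, n_values),
                 improper = stats::setNames(improper, n_values),
                 estimates = estimates,
                 config = list(shape1 = shape1, shape2 = shape2, m = m, q = q,
                               n_values = n_values, reps = reps,
                               priors = priors, seed = seed,
                               record_construction = record_construction)),
            class = "burr3_study")
}

#' @export
print.burr3_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte Carlo recovery study: Burr III (c = %g, k = %g), scheme m = %g, q = %g, %d replicates\n",
              cfg$shape1, cfg$shape2, cfg$m, cfg$q, cfg$reps))
  for (pi in seq_along(cfg$priors)) {
    p <- cfg$priors[[pi]]
    cat(sprintf("  prior %d: (alpha, beta, gamma, delta) = (%g, %g, %g, %g)\n",
                pi, p$alpha, p$beta, p$gamma, p$delta))
  }
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.4f", v))
  print(tab, row.names = FALSE)
  cat("non-converged MLE replicates (excluded): ",
      paste(sprintf("n=%s: %d", names(x$failures), x$failures), collapse = ", "),
      "\n", sep = "")
  if (any(x$improper > 0))
    cat("flagged non-positive Bayes estimates (included): ",
        paste(sprintf("n=%s: %d", names(x$improper), x$improper), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
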