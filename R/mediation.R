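#' Quasi-Bayesian Monte Carlo causal mediation
#'
#' Fits the mediator model `m ~ x + mediator covariates` and the outcome
#' model `y ~ x + m + outcome covariates` by ordinary least squares, then
#' draws `n_draws` coefficient vectors from each model's estimated sampling
#' distribution (multivariate normal with mean = estimates, covariance =
#' estimated coefficient covariance, independently for the two models).
#' Per draw, with contrast `delta = treat_value - control_value`:
#' `IDE = a * b * delta`, `DE = c' * delta`, `TE = IDE + DE`, where `a` is
#' the exposure coefficient in the mediator model and `b`, `c'` are the
#' mediator and exposure coefficients in the outcome model. Point estimates
#' are means over draws, intervals are the 2.5/97.5 percentiles, and
#' p-values are `2 * min(Pr(effect <= 0), Pr(effect >= 0))`. Draws use
#' antithetic pairing, which stabilizes point estimates across `n_draws`. The linear
#' product-of-coefficients decomposition is exact because no
#' exposure-by-mediator interaction is modelled; IDE + DE = TE holds per
#' draw and in the point estimates.
#'
#' @param x exposure vector (numeric).
#' @param m mediator vector.
#' @param y outcome vector.
#' @param cov_mediator,cov_outcome optional covariate matrices/data.frames
#'   for the two models.
#' @param treat_value,control_value exposure contrast; the default contrasts
#'   the observed maximum against the observed minimum of `x`, i.e. the
#'   total effect is interpreted at the highest versus lowest exposure.
#' @param n_draws Monte Carlo draws (warning below 100).
#' @param seed RNG seed for the draws (deterministic when supplied).
#' @param conf confidence level for the intervals.
#' @param alpha nominal significance level used for classification.
#' @return object of class `mediation_record`: a list with `estimates`
#'   (data.frame effect/estimate/ci_lower/ci_upper/p for IDE, DE, TE),
#'   `classification`, `proportion_mediated`, `n_draws`, `seed`, `delta`.
#' @export
quasi_bayes_mediate <- function(x, m, y, cov_mediator = NULL,
                                cov_outcome = NULL,
                                treat_value = max(x),
                                control_value = min(x),
                                n_draws = 10000, seed = NULL,
                                conf = 0.95, alpha = 0.05) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (treat_value == control_value) {
    stop("treat_value must differ from control_value", call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (n_draws < 100) warning("n_draws < 100: Monte Carlo summaries unstable")
  delta <- treat_value - control_value

  xm <- cbind(`(Intercept)` = 1, x = x, as_design(cov_mediator, n))
  xo <- cbind(`(Intercept)` = 1, x = x, m = m, as_design(cov_outcome, n))
  med_fit <- fit_ols(xm, m)
  out_fit <- fit_ols(xo, y)

  if (!is.null(seed)) set.seed(seed)
  med_draws <- draw_coefs(n_draws, med_fit)
  out_draws <- draw_coefs(n_draws, out_fit)
  a <- med_draws[, "x"]
  b <- out_draws[, "m"]
  cp <- out_draws[, "x"]
  ide <- a * b * delta
  de <- cp * delta
  te <- ide + de

  summarize <- function(draws) {
    ci <- stats::quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    c(estimate = mean(draws), ci_lower = ci[1], ci_upper = ci[2],
      p = 2 * min(mean(draws <= 0), mean(draws >= 0)))
  }
  est <- as.data.frame(rbind(IDE = summarize(ide), DE = summarize(de),
                             TE = summarize(te)))
  est <- cbind(effect = rownames(est), est)
  rownames(est) <- NULL

  rec <- structure(list(
    estimates = est, n_draws = n_draws, seed = seed, delta = delta,
    point = c(a = unname(med_fit$coef["x"]), b = unname(out_fit$coef["m"]),
              c_prime = unname(out_fit$coef["x"]))
  ), class = "mediation_record")
  rec$classification <- classify_mediation(rec, alpha = alpha)
  rec$proportion_mediated <- proportion_mediated(rec)
  rec
}

as_design <- function(cov, n) {
  if (is.null(cov)) return(NULL)
  cov <- if (is.data.frame(cov)) {
    stats::model.matrix(~ ., data = cov)[, -1, drop = FALSE]
  } else as.matrix(cov)
  stopifnot(nrow(cov) == n)
  cov
}

# Antithetic multivariate-normal coefficient draws: each standard-normal
# row is paired with its negation, which removes first-order Monte Carlo
# error from the linear coefficients and sharply reduces it for products,
# so point estimates are stable in n_draws. Rows are filled draw-by-draw,
# making the first n draws of a longer run identical under the same seed.
draw_coefs <- function(n_draws, fit) {
  k <- length(fit$coef)
  half <- ceiling(n_draws / 2)
  z <- matrix(stats::rnorm(half * k), nrow = half, ncol = k, byrow = TRUE)
  zz <- matrix(0, 2 * half, k)
  zz[seq(1, 2 * half, by = 2), ] <- z
  zz[seq(2, 2 * half, by = 2), ] <- -z
  out <- sweep(zz[seq_len(n_draws), , drop = FALSE] %*% chol(fit$vcov),
               2, fit$coef, "+")
  colnames(out) <- names(fit$coef)
  out
}

fit_ols <- function(x, y) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  sigma2 <- sum(res^2) / (length(y) - ncol(x))
  xtx_inv <- solve(crossprod(x))
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  list(coef = coef, vcov = sigma2 * xtx_inv)
}

#' Classify a mediation record
#'
#' Full mediator: total and indirect effects significant while the direct
#' effect is not. Partial mediator: all three significant. Otherwise none.
#'
#' @param record a `mediation_record` (or anything with an `estimates`
#'   data.frame holding p-values for IDE, DE, TE).
#' @param alpha significance level for the three tests.
#' @return one of `"full"`, `"partial"`, `"none"`.
#' @export
classify_mediation <- function(record, alpha = 0.05) {
  p <- stats::setNames(record$estimates$p, record$estimates$effect)
  stopifnot(all(c("IDE", "DE", "TE") %in% names(p)))
  if (p[["TE"]] < alpha && p[["IDE"]] < alpha) {
    if (p[["DE"]] >= alpha) "full" else "partial"
  } else "none"
}

#' Proportion of the total effect that is mediated
#'
#' Point-estimate ratio `IDE / TE`. Use [format_proportion_mediated()] for
#' the integer-percent display convention.
#'
#' @param record a `mediation_record`.
#' @return numeric fraction, `NA` (flagged) if TE = 0.
#' @export
proportion_mediated <- function(record) {
  est <- stats::setNames(record$estimates$estimate, record$estimates$effect)
  if (est[["TE"]] == 0) {
    warning("total effect is zero; proportion mediated undefined")
    return(NA_real_)
  }
  unname(est[["IDE"]] / est[["TE"]])
}

#' @rdname proportion_mediated
#' @param fraction numeric fraction as returned by [proportion_mediated()].
#' @export
format_proportion_mediated <- function(fraction) {
  if (is.na(fraction)) return(NA_integer_)
  as.integer(round(100 * fraction))
}

#' Probe-wise mediation within a module
#'
#' Re-runs the quasi-Bayesian mediation with each member probe's
#' standardized residual M-value as the mediator, then applies
#' Benjamini-Hochberg jointly over the family of all member-probe IDE and
#' DE p-values (family size = 2 x module size).
#'
#' @param resid probes x samples residualized M-value matrix.
#' @param labels named module label vector.
#' @param module module index to dissect.
#' @param x,y exposure and outcome vectors.
#' @param cov_mediator,cov_outcome covariates for the two models.
#' @param q FDR level for the joint IDE/DE family.
#' @param seed base seed; probe i uses `seed + i`.
#' @inheritParams quasi_bayes_mediate
#' @return data.frame, one row per probe: IDE/DE/TE estimates, CIs,
#'   p-values, BH flags for IDE and DE, classification, proportion
#'   mediated; attribute `m` = BH family size.
#' @export
probewise_mediate <- function(resid, labels, module, x, y,
                              cov_mediator = NULL, cov_outcome = NULL,
                              treat_value = max(x), control_value = min(x),
                              n_draws = 10000, seed = NULL, q = 0.10,
                              alpha = 0.05) {
  probes <- names(labels)[labels == module]
  probes <- intersect(probes, rownames(resid))
  if (!length(probes)) stop("module ", module, " has no probes in the matrix",
                            call. = FALSE)
  recs <- lapply(seq_along(probes), function(i) {
    mv <- zscore(resid[probes[i], ], probes[i])
    rec <- quasi_bayes_mediate(x, mv, y, cov_mediator, cov_outcome,
                               treat_value, control_value, n_draws,
                               seed = if (is.null(seed)) NULL else seed + i,
                               alpha = alpha)
    est <- rec$estimates
    row <- data.frame(probe_id = probes[i], stringsAsFactors = FALSE)
    for (eff in c("IDE", "DE", "TE")) {
      e <- est[est$effect == eff, ]
      row[[paste0(tolower(eff), "_beta")]] <- e$estimate
      row[[paste0(tolower(eff), "_ci_lower")]] <- e$ci_lower
      row[[paste0(tolower(eff), "_ci_upper")]] <- e$ci_upper
      row[[paste0(tolower(eff), "_p")]] <- e$p
    }
    row$classification <- rec$classification
    row$proportion_mediated <- rec$proportion_mediated
    row
  })
  out <- do.call(rbind, recs)
  fam_p <- c(out$ide_p, out$de_p)
  flags <- bh_adjust(fam_p, q = q)
  k <- nrow(out)
  out$ide_bh <- flags[seq_len(k)]
  out$de_bh <- flags[k + seq_len(k)]
  attr(out, "m") <- 2L * k
  out
}
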