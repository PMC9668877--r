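#' @keywords internal
"_PACKAGE"

# z-score a numeric vector; constant input is an error (degenerate design)
zscore <- function(x, label = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant column: ", label, call. = FALSE)
  }
  (x - mean(x)) / s
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
}

assert_simplex <- function(p, label) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop(label, " must be a probability vector summing to 1", call. = FALSE)
  }
  invisible(p)
}

# Sampler for the normal distribution truncated to [lower, upper].
# Inverse CDF in the bulk; shifted-exponential rejection (Robert 1995) when
# the window sits deep in one tail, where pnorm/qnorm round to 1.
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  if (is.finite(b) && b < -5) return(mean - sd * rtruncnorm(n, 0, 1, -b, -a))
  if (is.finite(a) && a > 5) {
    alpha <- (a + sqrt(a^2 + 4)) / 2
    out <- numeric(0)
    while (length(out) < n) {
      m <- 2 * (n - length(out)) + 10
      z <- a + stats::rexp(m, rate = alpha)
      acc <- stats::runif(m) <= exp(-(z - alpha)^2 / 2) & z <= b
      out <- c(out, z[acc])
    }
    return(mean + sd * out[seq_len(n)])
  }
  u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
  mean + sd * stats::qnorm(u)
}

# Mean and sd of a normal(mu, sigma) truncated to [lower, upper].
# Computed on the log scale so the formulas stay finite when the window
# sits many sigmas away from mu.
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  # log Z = log(Phi(b) - Phi(a)), stable in either tail
  if (a > 0) {           # both bounds in the upper tail
    lpa <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lpb <- if (is.finite(b)) stats::pnorm(b, lower.tail = FALSE, log.p = TRUE) else -Inf
    logz <- lpa + log1p(-exp(lpb - lpa))
  } else if (is.finite(b) && b < 0) {  # both bounds in the lower tail
    lpb <- stats::pnorm(b, log.p = TRUE)
    lpa <- if (is.finite(a)) stats::pnorm(a, log.p = TRUE) else -Inf
    logz <- lpb + log1p(-exp(lpa - lpb))
  } else {
    logz <- log(stats::pnorm(b) - stats::pnorm(a))
  }
  ra <- if (is.finite(a)) exp(stats::dnorm(a, log = TRUE) - logz) else 0
  rb <- if (is.finite(b)) exp(stats::dnorm(b, log = TRUE) - logz) else 0
  apa <- if (is.finite(a)) a * ra else 0
  bpb <- if (is.finite(b)) b * rb else 0
  m <- mu + sigma * (ra - rb)
  v <- sigma^2 * (1 + apa - bpb - (ra - rb)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Calibrate a truncated normal to target moments
#'
#' Finds parent parameters `(mu, sigma)` such that the normal distribution
#' truncated to `[lower, upper]` has the requested mean and standard
#' deviation. Used by the cohort generator so that simulated scales
#' reproduce published summary statistics despite range truncation.
#'
#' The mean is always matched exactly. The SD is matched where the family
#' allows it; some printed (mean, SD, range) triples lie outside the
#' truncated-normal moment region (its SD supremum at a given mean is the
#' uniform or shifted-exponential limit), in which case the closest
#' achievable SD is used and reported in the `achieved` field (with a
#' warning if `warn = TRUE`).
#'
#' @param mean,sd target moments of the truncated distribution.
#' @param lower,upper truncation bounds (may be infinite).
#' @param warn warn when the target SD is not attainable.
#' @return list with elements `mu`, `sigma`, `lower`, `upper`, `achieved`
#'   (the calibrated distribution's exact mean and SD).
#' @export
calibrate_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf,
                                warn = TRUE) {
  stopifnot(sd > 0, lower < upper)
  if (!is.finite(lower) && !is.finite(upper)) {
    return(list(mu = mean, sigma = sd, lower = lower, upper = upper,
                achieved = list(mean = mean, sd = sd)))
  }
  # profile solve: for each sigma, mu is pinned by the mean (the truncated
  # mean is strictly increasing in mu); then sigma is searched for the sd.
  mu_for_mean <- function(sigma) {
    f <- function(mu) truncnorm_moments(mu, sigma, lower, upper)$mean - mean
    span <- 1
    while (f(mean - span * sigma) > 0 || f(mean + span * sigma) < 0) {
      span <- span * 2
      if (span > 1e6) stop("truncated-normal mean calibration failed")
    }
    stats::uniroot(f, c(mean - span * sigma, mean + span * sigma),
                   tol = 1e-12)$root
  }
  sd_gap <- function(log_sigma) {
    sigma <- exp(log_sigma)
    mu <- mu_for_mean(sigma)
    truncnorm_moments(mu, sigma, lower, upper)$sd - sd
  }
  opt <- stats::optimize(function(ls) sd_gap(ls)^2,
                         interval = log(sd) + c(-1, 6), tol = 1e-12)
  sigma <- exp(opt$minimum)
  mu <- mu_for_mean(sigma)
  ach <- truncnorm_moments(mu, sigma, lower, upper)
  if (warn && abs(ach$sd - sd) > 0.02 * sd) {
    warning(sprintf(paste0("truncated-normal family cannot reach the target",
                           " sd on [%g, %g]: achieved sd %.3f vs target %.3f",
                           " (mean is matched exactly)"),
                    lower, upper, ach$sd, sd))
  }
  list(mu = mu, sigma = sigma, lower = lower, upper = upper, achieved = ach)
}

# Dirichlet sampler (rows = draws) built on rgamma.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# inverse of the M-value transform: beta = 2^M / (2^M + 1)
m_to_beta <- function(m) 1 / (1 + 2^(-m))

check_matrix <- function(values, probe_ids, sample_ids) {
  stopifnot(is.matrix(values))
  if (anyNA(values)) stop("methylation matrix contains missing values", call. = FALSE)
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}
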