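# Internal weighted binomial ML fit of a cumulative Gaussian choice curve
#   P(right | h) = lapse/2 + (1 - lapse) * pnorm((h - mu) / sigma)
# to per-heading rightward proportions. Used by both the behavioral
# psychometrics and the ROC neurometrics (where the per-heading "successes"
# are ideal-observer P(rightward) values scaled by trial counts, hence k may
# be non-integer).

cg_prob <- function(h, mu, sigma, lapse) {
  lapse / 2 + (1 - lapse) * stats::pnorm((h - mu) / sigma)
}

# box constraints: PSEs beyond these are treated as non-identified
CG_MU_BOX <- 200
CG_SIGMA_BOX <- c(1e-2, 200)

cg_deviance <- function(theta, h, k, n, lapse_fixed) {
  mu <- theta[1]
  sigma <- exp(theta[2])
  lapse <- if (is.na(lapse_fixed)) theta[3] else lapse_fixed
  q <- cg_prob(h, mu, sigma, lapse)
  q <- pmin(pmax(q, 1e-9), 1 - 1e-9)
  -2 * sum(k * log(q) + (n - k) * log(1 - q))
}

cg_deviance_grad <- function(theta, h, k, n, lapse_fixed) {
  mu <- theta[1]
  sigma <- exp(theta[2])
  lapse <- if (is.na(lapse_fixed)) theta[3] else lapse_fixed
  x <- (h - mu) / sigma
  q <- lapse / 2 + (1 - lapse) * stats::pnorm(x)
  q <- pmin(pmax(q, 1e-9), 1 - 1e-9)
  w <- -2 * (k / q - (n - k) / (1 - q))
  phi <- stats::dnorm(x)
  g <- c(sum(w * (-(1 - lapse) * phi / sigma)),
         sum(w * (-(1 - lapse) * phi * x)))
  if (is.na(lapse_fixed)) {
    g <- c(g, sum(w * (0.5 - stats::pnorm(x))))
  }
  g
}

# deterministic starting values: a probit-regression (linearized) start plus
# a fixed grid on mu and sigma
cg_starts <- function(h, k, n) {
  p <- pmin(pmax(k / n, 0.01), 0.99)
  z <- stats::qnorm(p)
  fit <- stats::lm.wfit(cbind(1, h), z, w = n)
  b <- fit$coefficients[2]
  a <- fit$coefficients[1]
  span <- max(diff(range(h)), 1)
  starts <- list()
  if (is.finite(b) && b > 1e-6) {
    starts <- c(starts, list(c(-a / b, log(1 / b))))
  }
  qs <- stats::quantile(h, c(0.25, 0.75), names = FALSE)
  starts <- c(starts, list(
    c(0, log(span / 4)),
    c(stats::weighted.mean(h, n), log(span / 8)),
    c(qs[1], log(span / 4)),
    c(qs[2], log(span / 4))))
  starts[seq_len(min(5, length(starts)))]
}

# h, k, n: per-heading headings, rightward "successes", trial counts.
# lapse_fixed: a value fixes the lapse; NA frees it on [0, lapse_max].
# starts: optional list of c(mu, log sigma) starting points for the
# general optimizer path.
#
# With the lapse fixed at 0 the model is a probit GLM in (intercept, slope)
# = (-mu/sigma, 1/sigma); its log-likelihood is concave, so glm.fit finds
# the global ML solution directly. A non-positive fitted slope means no
# increasing curve fits the data (the neurometric/psychometric curve is
# non-identified); such fits are flagged non-converged. The general
# multi-start quasi-Newton path handles the free/nonzero-lapse model and
# serves as fallback if the GLM fails.
fit_cumgauss <- function(h, k, n, lapse_fixed = 0, lapse_max = 0.1,
                         starts = NULL) {
  stopifnot(length(h) == length(k), length(h) == length(n))
  ord <- order(h)
  h <- h[ord]; k <- k[ord]; n <- n[ord]
  free_lapse <- is.na(lapse_fixed)

  if (!free_lapse && lapse_fixed == 0) {
    glm_fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, h), k / n, weights = n,
                                      family = stats::binomial("probit"))),
      error = function(e) NULL)
    if (!is.null(glm_fit) && all(is.finite(glm_fit$coefficients)) &&
        isTRUE(glm_fit$converged)) {
      b <- glm_fit$coefficients[2]
      if (b > 0) {
        mu <- unname(-glm_fit$coefficients[1] / b)
        sigma <- unname(1 / b)
        dev <- cg_deviance(c(mu, log(sigma)), h, k, n, 0)
        return(list(mu = mu, sigma = sigma, lapse = 0,
                    deviance = dev, logLik = -dev / 2,
                    converged = abs(mu) < CG_MU_BOX &&
                      sigma < CG_SIGMA_BOX[2]))
      }
      # non-increasing unconstrained optimum: no identified PSE
      return(list(mu = NA_real_, sigma = NA_real_, lapse = 0,
                  deviance = NA_real_, logLik = NA_real_,
                  converged = FALSE))
    }
    # glm divergence (e.g. complete separation): fall through to the
    # box-constrained optimizer, which caps sigma from below
  }
  if (is.null(starts)) starts <- cg_starts(h, k, n)

  lower <- c(-CG_MU_BOX, log(CG_SIGMA_BOX[1]))
  upper <- c(CG_MU_BOX, log(CG_SIGMA_BOX[2]))
  if (free_lapse) {
    lower <- c(lower, 0)
    upper <- c(upper, lapse_max)
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(if (free_lapse && length(s) == 2) c(s, 0.02) else s,
                   lower), upper)
    fit <- tryCatch(
      stats::optim(s, cg_deviance, gr = cg_deviance_grad,
                   h = h, k = k, n = n, lapse_fixed = lapse_fixed,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(mu = NA_real_, sigma = NA_real_, lapse = NA_real_,
                deviance = NA_real_, logLik = NA_real_, converged = FALSE))
  }
  mu <- unname(best$par[1])
  sigma <- unname(exp(best$par[2]))
  lapse <- if (free_lapse) best$par[3] else lapse_fixed
  converged <- best$convergence == 0 &&
    abs(mu) < CG_MU_BOX - 1e-6 &&
    sigma < CG_SIGMA_BOX[2] - 1e-6
  list(mu = mu, sigma = sigma, lapse = lapse,
       deviance = best$value, logLik = -best$value / 2,
       converged = converged)
}
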