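# BMD inversion and profile-likelihood lower bounds.

#' Benchmark dose from a fitted model
#'
#' Continuous fits: the BMD is the smallest positive dose at which the mean
#' response departs from the control mean by `bmr` residual standard
#' deviations (`|mu(d) - mu(0)| = bmr * sigma_hat`). Linear, power and hill
#' inversions are closed form; other families use bracketed root finding.
#' Dichotomous fits: the dose at which extra risk
#' `(P(d) - P(0)) / (1 - P(0))` equals `bmr`. Returns `NA` when no crossing
#' exists at or below 10 times the highest tested dose.
#'
#' @param fit a converged [dr_fit()].
#' @param bmr benchmark response: SD multiples (continuous, default 1.349)
#'   or extra risk fraction (dichotomous, default 0.10).
#' @param tol relative root-finding tolerance.
#' @return the BMD (dose scale) or `NA_real_`.
#' @export
bmd_from_fit <- function(fit, bmr = if (fit$type == "continuous") 1.349 else 0.1,
                         tol = 1e-8) {
  if (!fit$converged || is.null(fit$pars)) return(NA_real_)
  dmax <- max(fit$data$dose)
  if (fit$type == "continuous") {
    s <- bmr * fit$sigma
    if (s <= 0) return(NA_real_)
    p <- fit$pars
    if (fit$family == "linear") {
      if (abs(p[["b1"]]) < 1e-300) return(NA_real_)
      b <- s / abs(p[["b1"]])
      return(if (b <= 10 * dmax) b else NA_real_)
    }
    if (fit$family == "power") {
      if (abs(p[["b"]]) < 1e-300) return(NA_real_)
      b <- (s / abs(p[["b"]]))^(1 / p[["delta"]])
      return(if (b <= 10 * dmax) b else NA_real_)
    }
    if (fit$family == "hill") {
      v <- abs(p[["v"]])
      if (v <= s) return(NA_real_)
      b <- p[["k"]] * (s / (v - s))^(1 / p[["n"]])
      return(if (b <= 10 * dmax) b else NA_real_)
    }
    f <- function(d) abs(dr_mean(fit$family, fit$pars, d) -
                           dr_mean(fit$family, fit$pars, 0)) - s
    bmd_root(f, dmax, tol)
  } else {
    p0 <- dr_mean(fit$family, fit$pars, 0)
    f <- function(d) (dr_mean(fit$family, fit$pars, d) - p0) / (1 - p0) - bmr
    bmd_root(f, dmax, tol)
  }
}

# first sign change of f on (0, 10 dmax], grid scan + uniroot
bmd_root <- function(f, dmax, tol = 1e-8) {
  grid <- dmax * 10^seq(-5, 1, length.out = 241)
  fv <- vapply(grid, f, numeric(1))
  fv[!is.finite(fv)] <- -Inf
  idx <- which(fv >= 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(grid[1])
  r <- uniroot(f, lower = grid[i - 1], upper = grid[i], tol = tol * dmax)
  r$root
}

# --- profile likelihood ---------------------------------------------------

# For a fixed candidate BMD b, one model parameter is eliminated by solving
# the BMD-defining equation; the log-likelihood is then maximized over the
# remaining (free) parameters, continuous fits including log(sigma) since
# the SD-based BMR couples sigma to the mean parameters.

# returns list(free0 = start vector, build = function(free, b) -> pars,
#              sigma_free = TRUE/FALSE)
profile_setup <- function(fit, bmr, sgn) {
  fam <- fit$family
  p <- fit$pars
  trans_in  <- function(x, lo, hi) qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-9), 1 - 1e-9))
  trans_out <- function(t, lo, hi) lo + (hi - lo) * plogis(t)
  if (fit$type == "continuous") {
    ls0 <- log(max(fit$sigma, 1e-8))
    switch(fam,
      linear = list(
        free0 = c(p[["b0"]], ls0),
        build = function(fr, b) {
          sig <- exp(fr[2])
          list(pars = c(fr[1], sgn * bmr * sig / b), sigma = sig)
        }),
      poly2 = list(
        free0 = c(p[["b0"]], p[["b2"]], ls0),
        build = function(fr, b) {
          sig <- exp(fr[3])
          b1 <- (sgn * bmr * sig - fr[2] * b^2) / b
          list(pars = c(fr[1], b1, fr[2]), sigma = sig)
        }),
      poly3 = list(
        free0 = c(p[["b0"]], p[["b2"]], p[["b3"]], ls0),
        build = function(fr, b) {
          sig <- exp(fr[4])
          b1 <- (sgn * bmr * sig - fr[2] * b^2 - fr[3] * b^3) / b
          list(pars = c(fr[1], b1, fr[2], fr[3]), sigma = sig)
        }),
      power = list(
        free0 = c(p[["g"]], trans_in(p[["delta"]], 1, 18), ls0),
        build = function(fr, b) {
          sig <- exp(fr[3]); delta <- trans_out(fr[2], 1, 18)
          list(pars = c(fr[1], sgn * bmr * sig / b^delta, delta), sigma = sig)
        }),
      hill = list(
        free0 = c(p[["g"]], log(p[["k"]]), trans_in(p[["n"]], 1, 18), ls0),
        build = function(fr, b) {
          sig <- exp(fr[4]); k <- exp(fr[2]); n <- trans_out(fr[3], 1, 18)
          v <- sgn * bmr * sig * (1 + (k / b)^n)
          list(pars = c(fr[1], v, k, n), sigma = sig)
        }),
      exp4 = list(
        free0 = c(log(max(p[["a"]], 1e-8)), log(max(p[["b"]], 1e-8)), ls0),
        build = function(fr, b) {
          sig <- exp(fr[3]); a <- exp(fr[1]); br <- exp(fr[2])
          den <- a * (1 - exp(-br * b))
          if (den <= 0) return(NULL)
          list(pars = c(a, br, 1 + sgn * bmr * sig / den), sigma = sig)
        }),
      exp5 = list(
        free0 = c(log(max(p[["a"]], 1e-8)), log(max(p[["b"]], 1e-8)),
                  trans_in(p[["gpow"]], 1, 18), ls0),
        build = function(fr, b) {
          sig <- exp(fr[4]); a <- exp(fr[1]); br <- exp(fr[2])
          gp <- trans_out(fr[3], 1, 18)
          den <- a * (1 - exp(-(br * b)^gp))
          if (den <= 0) return(NULL)
          list(pars = c(a, br, 1 + sgn * bmr * sig / den), sigma = sig)
        }),
      stop("profile not implemented for family ", fam))
  } else {
    gq <- function(g) qlogis(pmin(pmax(g, 1e-6), 0.99))
    switch(fam,
      logistic = list(
        free0 = p[["a"]],
        build = function(fr, b) {
          a <- fr[1]; p0 <- plogis(a)
          pt <- p0 + bmr * (1 - p0)
          bb <- (qlogis(pt) - a) / b
          if (bb < 0) return(NULL)
          list(pars = c(a, bb))
        }),
      probit = list(
        free0 = p[["a"]],
        build = function(fr, b) {
          a <- fr[1]; p0 <- pnorm(a)
          pt <- p0 + bmr * (1 - p0)
          bb <- (qnorm(pt) - a) / b
          if (bb < 0) return(NULL)
          list(pars = c(a, bb))
        }),
      loglogistic = list(
        free0 = c(gq(p[["g"]]), log(max(p[["b"]], 1e-2))),
        build = function(fr, b) {
          g <- plogis(fr[1]); bs <- exp(fr[2])
          list(pars = c(g, qlogis(bmr) - bs * log(b), bs))
        }),
      logprobit = list(
        free0 = c(gq(p[["g"]]), log(max(p[["b"]], 1e-2))),
        build = function(fr, b) {
          g <- plogis(fr[1]); bs <- exp(fr[2])
          list(pars = c(g, qnorm(bmr) - bs * log(b), bs))
        }),
      weibull = list(
        free0 = c(gq(p[["g"]]), log(max(p[["a"]], 1))),
        build = function(fr, b) {
          g <- plogis(fr[1]); a <- max(exp(fr[2]), 1)
          list(pars = c(g, a, -log(1 - bmr) / b^a))
        }),
      gamma = list(
        free0 = c(gq(p[["g"]]), log(max(p[["a"]], 1))),
        build = function(fr, b) {
          g <- plogis(fr[1]); a <- max(exp(fr[2]), 1)
          list(pars = c(g, a, qgamma(bmr, a) / b))
        }),
      multistage = list(
        free0 = c(gq(p[["g"]]), log(max(p[["b2"]], 1e-10))),
        build = function(fr, b) {
          g <- plogis(fr[1]); b2 <- exp(fr[2])
          b1 <- (-log(1 - bmr) - b2 * b^2) / b
          if (b1 < 0) return(NULL)
          list(pars = c(g, b1, b2))
        }),
      dhill = list(
        free0 = c(gq(p[["g"]]), qlogis(pmin(pmax(p[["v"]], 0.02), 0.999)),
                  log(max(p[["b"]], 1e-2))),
        build = function(fr, b) {
          g <- plogis(fr[1]); v <- plogis(fr[2]); bs <- exp(fr[3])
          if (v <= g) return(NULL)
          q <- bmr * (1 - g) / (v - g)
          if (q >= 1) return(NULL)
          list(pars = c(g, v, qlogis(q) - bs * log(b), bs))
        }),
      stop("profile not implemented for family ", fam))
  }
}

profile_loglik <- function(fit, setup, b, start) {
  obj <- function(fr) {
    cand <- setup$build(fr, b)
    if (is.null(cand)) return(1e300)
    ll <- if (fit$type == "continuous") {
      sse <- dr_sse(fit$family, cand$pars, fit$data)
      dr_loglik_cont(sse, fit$N, cand$sigma)
    } else dr_loglik_dich(fit$family, cand$pars, fit$data)
    if (!is.finite(ll)) return(1e300)
    -ll
  }
  if (length(start) == 1) {
    res <- tryCatch(optim(start, obj, method = "Brent",
                          lower = start - 20, upper = start + 20),
                    error = function(e) NULL)
  } else {
    res <- tryCatch(optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 600, reltol = 1e-10)),
                    error = function(e) NULL)
  }
  if (is.null(res) || res$value >= 1e299)
    return(list(ll = -Inf, par = start))
  list(ll = -res$value, par = res$par)
}

#' Profile-likelihood lower confidence bound on the BMD
#'
#' Computes the one-sided lower confidence limit as the smallest BMD value
#' `b` whose constrained maximum log-likelihood (subject to the BMD-defining
#' equation holding at `b`) stays within the chi-square threshold
#' `qchisq(2 * level - 1, df = 1) / 2` of the unconstrained maximum. The
#' search steps geometrically down from the BMD and refines the crossing
#' point by bisection with warm-started constrained fits.
#'
#' @inheritParams bmd_from_fit
#' @param level one-sided confidence level (default 0.95).
#' @param rel_tol relative refinement tolerance on the bound.
#' @return the BMDL, or `NA_real_` when the profile cannot bracket a bound
#'   (reported as not computable, never as a number).
#' @export
bmdl_profile <- function(fit, bmr = if (fit$type == "continuous") 1.349 else 0.1,
                         level = 0.95, rel_tol = 1e-4) {
  bmd <- bmd_from_fit(fit, bmr)
  if (!is.finite(bmd)) return(NA_real_)
  cutoff <- qchisq(2 * level - 1, df = 1)
  sgn <- if (fit$type == "continuous") {
    delta <- dr_mean(fit$family, fit$pars, bmd) - dr_mean(fit$family, fit$pars, 0)
    if (delta >= 0) 1 else -1
  } else 1
  setup <- tryCatch(profile_setup(fit, bmr, sgn), error = function(e) NULL)
  if (is.null(setup)) return(NA_real_)

  ll_mle <- fit$loglik
  dev_at <- local({
    warm <- setup$free0
    function(b) {
      pr <- profile_loglik(fit, setup, b, warm)
      if (is.finite(pr$ll)) warm <<- pr$par
      max(2 * (ll_mle - pr$ll), 0)
    }
  })

  # sanity: constrained fit at the MLE's own BMD should reproduce ll_mle
  d0 <- dev_at(bmd)
  if (!is.finite(d0) || d0 > cutoff) return(NA_real_)

  hi <- bmd; lo <- NA_real_
  b <- bmd
  for (i in 1:40) {
    b <- b * 0.7
    dv <- dev_at(b)
    if (dv >= cutoff) { lo <- b; break }
    hi <- b
    if (b < bmd * 1e-6) break
  }
  if (!is.finite(lo)) return(NA_real_)  # profile failed to bracket

  while (hi / lo - 1 > rel_tol) {
    mid <- sqrt(hi * lo)
    if (dev_at(mid) >= cutoff) lo <- mid else hi <- mid
  }
  min(sqrt(hi * lo), bmd)
}
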