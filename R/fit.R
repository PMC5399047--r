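#' @importFrom stats optim lm coef pchisq qchisq uniroot dbinom plogis qlogis
#'   pnorm qnorm pgamma qgamma dnorm var sd setNames quantile median
NULL

# --- data normalization ---------------------------------------------------

# Continuous dose-response data are reduced to per-group sufficient
# statistics (n, mean, sd). The Gaussian constant-variance likelihood
# depends on the data only through these.
dr_summarize <- function(doses, y) {
  if (is.data.frame(y)) {
    stopifnot(all(c("dose", "n", "mean") %in% names(y)))
    sdv <- if ("sd" %in% names(y)) y$sd else rep(0, nrow(y))
    sdv[is.na(sdv)] <- 0
    out <- data.frame(dose = y$dose, n = y$n, mean = y$mean, sd = sdv)
  } else {
    y <- as.numeric(y)
    stopifnot(length(y) == length(doses))
    ds <- sort(unique(doses))
    out <- data.frame(
      dose = ds,
      n = vapply(ds, function(d) sum(doses == d), numeric(1)),
      mean = vapply(ds, function(d) mean(y[doses == d]), numeric(1)),
      sd = vapply(ds, function(d) if (sum(doses == d) > 1) sd(y[doses == d]) else 0,
                  numeric(1))
    )
  }
  out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# SSE(theta) over group summaries; the within-group component is constant.
dr_sse <- function(family, pars, sm) {
  mu <- dr_mean(family, pars, sm$dose)
  sum(sm$n * (sm$mean - mu)^2) + sum(pmax(sm$n - 1, 0) * sm$sd^2)
}

dr_loglik_cont <- function(sse, N, sigma = NULL) {
  if (is.null(sigma)) {
    s2 <- max(sse / N, 1e-300)
    -N / 2 * (log(2 * pi * s2) + 1)
  } else {
    -N / 2 * log(2 * pi * sigma^2) - sse / (2 * sigma^2)
  }
}

dr_loglik_dich <- function(family, pars, dat) {
  p <- dr_mean(family, pars, dat$dose)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dbinom(dat$x, dat$n, p, log = TRUE))
}

# --- optimization helper --------------------------------------------------

# bounded quasi-Newton from each start, then a bound-clamped Nelder-Mead
# polish of the best solution (L-BFGS-B can stop with a line-search error
# at an interior optimum); convergence means the polish stabilized.
multistart_optim <- function(obj, starts, lower, upper, max_iter) {
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e299) return(NULL)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  pol <- tryCatch(
    optim(best$par, function(p) obj(clamp(p)), method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value + 1e-10) {
    best$par <- clamp(pol$par)
    best$value <- pol$value
    best$convergence <- if (pol$convergence == 0 || best$convergence == 0) 0
                        else best$convergence
    best$counts <- best$counts + pol$counts[1]
  }
  best
}

# --- continuous fitting ---------------------------------------------------

fit_cont_ls <- function(family, sm, restrict_power = TRUE, max_iter = 250) {
  N <- sum(sm$n)
  d <- sm$dose
  dmax <- max(d)
  u <- d / dmax
  w <- sm$n
  m <- sm$mean

  if (family %in% c("linear", "poly2", "poly3")) {
    deg <- switch(family, linear = 1, poly2 = 2, poly3 = 3)
    X <- outer(u, 0:deg, `^`)
    f <- stats::lm.wfit(X, m, w)
    beta_u <- f$coefficients
    beta_u[is.na(beta_u)] <- 0
    pars <- beta_u / dmax^(0:deg)
    info <- dr_family_info(family)
    return(list(pars = setNames(pars, info$names), converged = TRUE, iters = 0L))
  }

  info <- dr_family_info(family)
  r0 <- m[1]; rend <- m[length(m)]; amp <- rend - r0
  span <- max(abs(m - r0), 1e-8)

  jit <- c(1, 0.5, 2, 0.8, 1.25)  # fixed deterministic restarts
  starts <- list(); lower <- NULL; upper <- NULL
  if (family == "power") {
    lower <- c(-Inf, -Inf, if (restrict_power) 1 else 1e-2)
    upper <- c(Inf, Inf, 18)
    for (dl in c(1, 2, 3.5)) for (j in jit[1:2])
      starts[[length(starts) + 1]] <- c(r0, amp * j, dl)
  } else if (family == "hill") {
    lower <- c(-Inf, -Inf, 1e-4, if (restrict_power) 1 else 1e-2)
    upper <- c(Inf, Inf, 100, 18)
    for (k0 in c(0.15, 0.5)) for (n0 in c(1, 3)) for (j in jit[1:2])
      starts[[length(starts) + 1]] <- c(r0, amp * (1 + k0^n0) * j, k0, n0)
  } else if (family == "exp4") {
    a0 <- max(r0, 1e-3)
    lower <- c(1e-8, 1e-8, 1e-8); upper <- c(Inf, 1e4, Inf)
    for (b0 in c(1, 3, 0.3)) for (j in jit[1:3])
      starts[[length(starts) + 1]] <- c(a0, b0 * j, max(rend / a0, 1e-3))
  } else if (family == "exp5") {
    a0 <- max(r0, 1e-3)
    lower <- c(1e-8, 1e-8, 1e-8, 1); upper <- c(Inf, 1e4, Inf, 18)
    for (b0 in c(1, 3)) for (g0 in c(1, 2)) for (j in jit[1:2])
      starts[[length(starts) + 1]] <- c(a0, b0 * j, max(rend / a0, 1e-3), g0)
  } else stop("unknown continuous family: ", family)

  smu <- sm; smu$dose <- u
  obj <- function(p) {
    v <- dr_sse(family, p, smu)
    if (!is.finite(v)) 1e300 else v
  }
  best <- multistart_optim(obj, starts, lower, upper, max_iter)
  if (is.null(best)) return(list(pars = NULL, converged = FALSE, iters = NA_integer_))

  # back-transform dose scaling u = d / dmax
  pars <- best$par
  if (family == "power") pars[2] <- pars[2] / dmax^pars[3]
  if (family == "hill")  pars[3] <- pars[3] * dmax
  if (family %in% c("exp4", "exp5")) pars[2] <- pars[2] / dmax
  list(pars = setNames(pars, info$names),
       converged = best$convergence == 0,
       iters = as.integer(best$counts[1]))
}

# --- dichotomous fitting --------------------------------------------------

fit_dich_ml <- function(family, dat, max_iter = 250) {
  info <- dr_family_info(family)
  d <- dat$dose
  dmax <- max(d)
  phat <- (dat$x + 0.5) / (dat$n + 1)
  g0 <- min(max(phat[1], 0.01), 0.6)
  pmaxo <- min(max(phat[length(phat)], g0 + 0.05), 0.98)
  dmid <- stats::median(d[d > 0])

  jit <- c(1, 0.5, 2, 0.8, 1.25)
  starts <- list(); lower <- NULL; upper <- NULL
  if (family %in% c("logistic", "probit")) {
    qf <- if (family == "logistic") qlogis else qnorm
    a0 <- qf(g0); b0 <- max((qf(pmaxo) - a0) / dmax, 1e-6)
    lower <- c(-Inf, 1e-10); upper <- c(Inf, Inf)
    for (j in jit) starts[[length(starts) + 1]] <- c(a0, b0 * j)
  } else if (family %in% c("loglogistic", "logprobit")) {
    qf <- if (family == "loglogistic") qlogis else qnorm
    lower <- c(0, -Inf, 1e-2); upper <- c(0.99, Inf, 18)
    for (b0 in c(0.7, 1.5, 3)) for (j in jit[1:3])
      starts[[length(starts) + 1]] <- c(g0, -b0 * log(dmid) * j, b0)
  } else if (family == "weibull") {
    lower <- c(0, 1, 1e-12); upper <- c(0.99, 18, Inf)
    for (a0 in c(1, 2)) for (j in jit[1:3])
      starts[[length(starts) + 1]] <- c(g0, a0, j * log(2) / dmid^a0)
  } else if (family == "gamma") {
    lower <- c(0, 1, 1e-12); upper <- c(0.99, 18, Inf)
    for (a0 in c(1, 2)) for (j in jit[1:3])
      starts[[length(starts) + 1]] <- c(g0, a0, j * qgamma(0.5, a0) / dmid)
  } else if (family == "multistage") {
    lower <- c(0, 0, 0); upper <- c(0.99, Inf, Inf)
    for (j in jit) starts[[length(starts) + 1]] <- c(g0, j * log(2) / dmid, 1e-8)
  } else if (family == "dhill") {
    lower <- c(0, 0.01, -Inf, 1e-2); upper <- c(0.99, 1, Inf, 18)
    for (b0 in c(1, 2)) for (j in jit[1:2])
      starts[[length(starts) + 1]] <- c(g0, pmaxo, -b0 * log(dmid) * j, b0)
  } else stop("unknown dichotomous family: ", family)

  obj <- function(p) {
    if (family == "dhill" && p[2] <= p[1]) return(1e300)
    v <- -dr_loglik_dich(family, p, dat)
    if (!is.finite(v)) 1e300 else v
  }
  best <- multistart_optim(obj, starts, lower, upper, max_iter)
  if (is.null(best)) return(list(pars = NULL, converged = FALSE, iters = NA_integer_))
  list(pars = setNames(best$par, info$names),
       converged = best$convergence == 0,
       iters = as.integer(best$counts[1]))
}

# --- public fit interface -------------------------------------------------

#' Fit a dose-response model by maximum likelihood
#'
#' Continuous families use a Gaussian likelihood with a single residual
#' variance across dose groups (the variance is profiled out, so the fit
#' minimizes the pooled error sum of squares); dichotomous families use a
#' binomial likelihood. Power exponents (power `delta`, hill `n`) are
#' restricted to be at least 1 by default. Fitting uses bounded
#' quasi-Newton optimization from several deterministic moment-based
#' starting points; non-convergence is reported in the result, never
#' raised.
#'
#' @param doses dose per observation (continuous replicate input) or ignored
#'   when `y` is a per-group summary table.
#' @param y one of: a numeric response vector aligned with `doses`
#'   (continuous replicates); a data frame with columns `dose`, `n`, `mean`,
#'   `sd` (continuous summary); or a data frame with columns `dose`, `n`,
#'   `x` (dichotomous incidence).
#' @param family model family (see [dr_mean()]).
#' @param restrict_power keep power-type exponents >= 1.
#' @param max_iter optimizer iteration cap (default 250).
#' @return an object of class `dr_fit`: family, named parameter estimates,
#'   `sigma` (continuous ML residual SD), `loglik`, `aic`, `npar`,
#'   `converged`, `iters`, and the per-group data summary.
#' @examples
#' d <- rep(c(0, 5, 10, 25, 75), each = 4)
#' y <- 2 + 0.05 * d + rnorm(length(d), 0, 0.2)
#' f <- dr_fit(d, y, "linear")
#' bmd_from_fit(f, bmr = 1.349)
#' @export
dr_fit <- function(doses, y, family, restrict_power = TRUE, max_iter = 250) {
  info <- dr_family_info(family)
  if (info$type == "continuous") {
    sm <- dr_summarize(doses, y)
    if (nrow(sm) < 2) stop("degenerate design: need at least 2 dose groups")
    if (nrow(sm) < info$npar)
      return(dr_fit_failed(family, info, sm, "fewer dose groups than parameters"))
    N <- sum(sm$n)
    f <- fit_cont_ls(family, sm, restrict_power, max_iter)
    if (is.null(f$pars)) return(dr_fit_failed(family, info, sm, "optimization failed"))
    sse <- dr_sse(family, f$pars, sm)
    sigma <- sqrt(max(sse, 0) / N)
    ll <- dr_loglik_cont(sse, N)
    npar <- info$npar + 1L  # mean parameters + sigma
    structure(list(family = family, type = "continuous", pars = f$pars,
                   sigma = sigma, sse = sse, loglik = ll,
                   aic = 2 * npar - 2 * ll, npar = npar,
                   n_mean_par = info$npar, converged = f$converged,
                   iters = f$iters, data = sm, N = N),
              class = "dr_fit")
  } else {
    dat <- if (is.data.frame(y)) y else stop("dichotomous data must be a data frame")
    stopifnot(all(c("dose", "n", "x") %in% names(dat)),
              all(dat$x >= 0 & dat$x <= dat$n))
    dat <- dat[order(dat$dose), , drop = FALSE]
    if (nrow(dat) < 2) stop("degenerate design: need at least 2 dose groups")
    if (nrow(dat) < info$npar)
      return(dr_fit_failed(family, info, dat, "fewer dose groups than parameters"))
    f <- fit_dich_ml(family, dat, max_iter)
    if (is.null(f$pars)) return(dr_fit_failed(family, info, dat, "optimization failed"))
    ll <- dr_loglik_dich(family, f$pars, dat)
    npar <- info$npar
    structure(list(family = family, type = "dichotomous", pars = f$pars,
                   sigma = NA_real_, loglik = ll, aic = 2 * npar - 2 * ll,
                   npar = npar, n_mean_par = info$npar, converged = f$converged,
                   iters = f$iters, data = dat, N = sum(dat$n)),
              class = "dr_fit")
  }
}

dr_fit_failed <- function(family, info, dat, note) {
  structure(list(family = family, type = info$type, pars = NULL,
                 sigma = NA_real_, loglik = -Inf, aic = Inf,
                 npar = info$npar + (info$type == "continuous"),
                 n_mean_par = info$npar, converged = FALSE, iters = NA_integer_,
                 data = dat, N = if ("n" %in% names(dat)) sum(dat$n) else NA,
                 note = note),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("dose-response fit:", x$family,
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (!is.null(x$pars)) print(round(x$pars, 6))
  cat("loglik", format(x$loglik), " AIC", format(x$aic),
      if (x$type == "continuous") paste0(" sigma ", format(x$sigma)), "\n")
  invisible(x)
}

#' Likelihood-ratio goodness of fit against the saturated group-means model
#'
#' Compares the fitted model with the saturated model that assigns each dose
#' group its own mean (continuous, shared variance profiled out) or its own
#' incidence probability (dichotomous). The statistic is twice the
#' log-likelihood difference, referred to a chi-square distribution with
#' degrees of freedom equal to the number of dose groups minus the number of
#' model mean parameters. A saturated model (df = 0) is reported as p = 1;
#' negative df is not testable (p = NA).
#'
#' @param fit a `dr_fit`.
#' @return list with `stat`, `df`, `p`.
#' @export
dr_gof <- function(fit) {
  ngr <- nrow(fit$data)
  df <- ngr - fit$n_mean_par
  if (!fit$converged || is.null(fit$pars))
    return(list(stat = NA_real_, df = df, p = NA_real_))
  if (fit$type == "continuous") {
    sse_sat <- sum(pmax(fit$data$n - 1, 0) * fit$data$sd^2)
    ll_sat <- dr_loglik_cont(max(sse_sat, 1e-300), fit$N)
    stat <- max(2 * (ll_sat - fit$loglik), 0)
  } else {
    p_sat <- fit$data$x / fit$data$n
    ll_sat <- sum(dbinom(fit$data$x, fit$data$n, p_sat, log = TRUE))
    stat <- max(2 * (ll_sat - fit$loglik), 0)
  }
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE)
       else if (df == 0) 1 else NA_real_
  list(stat = stat, df = df, p = p)
}

#' Nested likelihood-ratio selection among linear and polynomial fits
#'
#' Step-up selection: the quadratic replaces the linear fit if the nested
#' likelihood-ratio test rejects at `alpha`; the cubic then replaces the
#' current choice on the same rule. Degrees of freedom equal the parameter
#' count difference.
#'
#' @param fit_lin,fit_poly2,fit_poly3 `dr_fit` objects on the same data.
#' @param alpha per-step test level.
#' @return the chosen `dr_fit`, with attribute `"nested_path"` recording the
#'   decisions.
#' @export
nested_lr_select <- function(fit_lin, fit_poly2, fit_poly3, alpha = 0.05) {
  lr_p <- function(f0, f1) {
    stat <- max(2 * (f1$loglik - f0$loglik), 0)
    df <- f1$n_mean_par - f0$n_mean_par
    pchisq(stat, df, lower.tail = FALSE)
  }
  chosen <- fit_lin
  path <- character()
  if (!is.null(fit_poly2) && fit_poly2$converged &&
      is.finite(fit_poly2$loglik) && lr_p(chosen, fit_poly2) < alpha) {
    chosen <- fit_poly2; path <- c(path, "poly2 over linear")
  }
  if (!is.null(fit_poly3) && fit_poly3$converged &&
      is.finite(fit_poly3$loglik) && lr_p(chosen, fit_poly3) < alpha) {
    chosen <- fit_poly3; path <- c(path, "poly3 accepted")
  }
  attr(chosen, "nested_path") <- path
  chosen
}
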