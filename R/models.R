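#' Dose-response model families
#'
#' The continuous suite (linear, poly2, poly3, power, hill, exp4, exp5)
#' models a Gaussian mean response with constant variance; the dichotomous
#' suite (logistic, probit, loglogistic, logprobit, weibull, gamma,
#' multistage, dhill) models incidence probabilities with background
#' parameter conventions following EPA BMDS.
#'
#' Parameterizations (d = dose):
#' \describe{
#'   \item{linear}{mu = b0 + b1 d}
#'   \item{poly2}{mu = b0 + b1 d + b2 d^2}
#'   \item{poly3}{mu = b0 + b1 d + b2 d^2 + b3 d^3}
#'   \item{power}{mu = g + b d^delta, delta >= 1 when restricted}
#'   \item{hill}{mu = g + v d^n / (k^n + d^n), k > 0, n >= 1 when restricted}
#'   \item{exp4}{mu = a (c - (c - 1) exp(-b d)), a, b > 0}
#'   \item{exp5}{mu = a (c - (c - 1) exp(-(b d)^g)), g >= 1}
#'   \item{logistic}{p = plogis(a + b d)}
#'   \item{probit}{p = pnorm(a + b d)}
#'   \item{loglogistic}{p = g + (1 - g) plogis(a + b log d)}
#'   \item{logprobit}{p = g + (1 - g) pnorm(a + b log d)}
#'   \item{weibull}{p = g + (1 - g) (1 - exp(-b d^a)), a >= 1}
#'   \item{gamma}{p = g + (1 - g) pgamma(b d, shape = a), a >= 1}
#'   \item{multistage}{p = g + (1 - g) (1 - exp(-(b1 d + b2 d^2))), b >= 0}
#'   \item{dhill}{p = g + (v - g) plogis(a + b log d), 0 <= g < v <= 1}
#' }
#'
#' @param family model family name.
#' @param pars named numeric parameter vector.
#' @param d dose vector.
#' @return `dr_mean()` returns the mean response (continuous families) or
#'   incidence probability (dichotomous families) at `d`.
#' @export
dr_mean <- function(family, pars, d) {
  p <- unname(pars)
  switch(family,
    linear = p[1] + p[2] * d,
    poly2  = p[1] + p[2] * d + p[3] * d^2,
    poly3  = p[1] + p[2] * d + p[3] * d^2 + p[4] * d^3,
    power  = p[1] + p[2] * d^p[3],
    hill   = p[1] + ifelse(d > 0, p[2] / (1 + (p[3] / d)^p[4]), 0),
    exp4   = p[1] * (p[3] - (p[3] - 1) * exp(-p[2] * d)),
    exp5   = p[1] * (p[3] - (p[3] - 1) * exp(-(p[2] * d)^p[4])),
    logistic    = stats::plogis(p[1] + p[2] * d),
    probit      = stats::pnorm(p[1] + p[2] * d),
    loglogistic = p[1] + (1 - p[1]) * ifelse(d > 0, stats::plogis(p[2] + p[3] * log(d)), 0),
    logprobit   = p[1] + (1 - p[1]) * ifelse(d > 0, stats::pnorm(p[2] + p[3] * log(d)), 0),
    weibull     = p[1] + (1 - p[1]) * (1 - exp(-p[3] * d^p[2])),
    gamma       = p[1] + (1 - p[1]) * stats::pgamma(p[3] * d, shape = p[2]),
    multistage  = p[1] + (1 - p[1]) * (1 - exp(-(p[2] * d + p[3] * d^2))),
    dhill       = p[1] + (p[2] - p[1]) * ifelse(d > 0, stats::plogis(p[3] + p[4] * log(d)), 0),
    stop("unknown model family: ", family)
  )
}

CONTINUOUS_FAMILIES  <- c("linear", "poly2", "poly3", "power", "hill", "exp4", "exp5")
DICHOTOMOUS_FAMILIES <- c("logistic", "probit", "loglogistic", "logprobit",
                          "weibull", "gamma", "multistage", "dhill")

#' @rdname dr_mean
#' @export
dr_family_info <- function(family) {
  info <- list(
    linear      = list(type = "continuous", npar = 2, names = c("b0", "b1")),
    poly2       = list(type = "continuous", npar = 3, names = c("b0", "b1", "b2")),
    poly3       = list(type = "continuous", npar = 4, names = c("b0", "b1", "b2", "b3")),
    power       = list(type = "continuous", npar = 3, names = c("g", "b", "delta")),
    hill        = list(type = "continuous", npar = 4, names = c("g", "v", "k", "n")),
    exp4        = list(type = "continuous", npar = 3, names = c("a", "b", "c")),
    exp5        = list(type = "continuous", npar = 4, names = c("a", "b", "c", "gpow")),
    logistic    = list(type = "dichotomous", npar = 2, names = c("a", "b")),
    probit      = list(type = "dichotomous", npar = 2, names = c("a", "b")),
    loglogistic = list(type = "dichotomous", npar = 3, names = c("g", "a", "b")),
    logprobit   = list(type = "dichotomous", npar = 3, names = c("g", "a", "b")),
    weibull     = list(type = "dichotomous", npar = 3, names = c("g", "a", "b")),
    gamma       = list(type = "dichotomous", npar = 3, names = c("g", "a", "b")),
    multistage  = list(type = "dichotomous", npar = 3, names = c("g", "b1", "b2")),
    dhill       = list(type = "dichotomous", npar = 4, names = c("g", "v", "a", "b"))
  )[[family]]
  if (is.null(info)) stop("unknown model family: ", family)
  info
}
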