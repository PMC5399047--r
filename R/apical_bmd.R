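# Apical-endpoint benchmark-dose workflow: EPA-style continuous and
# dichotomous model suites, viability classification, recommendation, and
# the highest-dose-drop retry ladder.

APICAL_CONTINUOUS_SUITE  <- c("exp4", "exp5", "hill", "power", "poly2", "linear")
APICAL_DICHOTOMOUS_SUITE <- c("gamma", "dhill", "logistic", "loglogistic",
                              "probit", "logprobit", "weibull", "multistage")

#' Fit the full model suite to an apical endpoint
#'
#' Continuous endpoints (group mean/SD/n) get the exponential-4,
#' exponential-5, hill, power, polynomial and linear models; dichotomous
#' endpoints (affected/n) get gamma, dichotomous-hill, logistic,
#' log-logistic, probit, log-probit, weibull and multistage.
#' Non-convergence is recorded per family, never raised.
#'
#' @param endpoint data frame: continuous columns `dose`, `n`, `mean`, `sd`;
#'   dichotomous columns `dose`, `n`, `x`. At least 3 dose groups including
#'   control.
#' @param type `"continuous"` or `"dichotomous"` (inferred from columns when
#'   missing).
#' @param max_iter optimizer cap per fit.
#' @return named list of `dr_fit` objects, one per family.
#' @export
fit_endpoint <- function(endpoint, type = NULL, max_iter = 250) {
  if (is.null(type))
    type <- if ("x" %in% names(endpoint)) "dichotomous" else "continuous"
  if (nrow(endpoint) < 3)
    stop("need at least 3 dose groups including control")
  suite <- if (type == "continuous") APICAL_CONTINUOUS_SUITE
           else APICAL_DICHOTOMOUS_SUITE
  fits <- lapply(suite, function(fam)
    tryCatch(dr_fit(NULL, endpoint, fam, max_iter = max_iter),
             error = function(e) dr_fit_failed(fam, dr_family_info(fam),
                                               endpoint, conditionMessage(e))))
  stats::setNames(fits, suite)
}

classify_viable <- function(fit, bmr, max_dose, gof_min = 0.1,
                            bmd_bmdl_ratio_max = 20) {
  if (!fit$converged || is.null(fit$pars))
    return(list(viable = FALSE, why = "not converged"))
  g <- dr_gof(fit)
  if (g$df < 1)   # saturated fits leave the fit quality untestable
    return(list(viable = FALSE, why = "goodness of fit not testable"))
  if (is.na(g$p) || g$p < gof_min)
    return(list(viable = FALSE, why = "goodness of fit"))
  bmd <- bmd_from_fit(fit, bmr)
  if (!is.finite(bmd)) return(list(viable = FALSE, why = "no BMD"))
  if (bmd > max_dose) return(list(viable = FALSE, why = "BMD above max dose"))
  bmdl <- bmdl_profile(fit, bmr)
  if (!is.finite(bmdl)) return(list(viable = FALSE, why = "BMDL not computable"))
  if (bmd / bmdl >= bmd_bmdl_ratio_max)
    return(list(viable = FALSE, why = "BMD/BMDL ratio"))
  list(viable = TRUE, bmd = bmd, bmdl = bmdl, aic = fit$aic, gof_p = g$p)
}

#' Recommend an apical BMD with the highest-dose-drop ladder
#'
#' Classifies each fitted model as viable (converged, goodness-of-fit
#' p >= 0.1, computable BMDL, BMD at or below the highest remaining dose,
#' BMD/BMDL < 20). Among viable fits: if the BMDL range spans <= 3-fold,
#' recommend the lowest AIC, otherwise the lowest BMDL. If no model is
#' viable, the highest dose is dropped and the suite refit; the endpoint
#' fails BMD modeling once only three dose groups (including control)
#' remain without a viable model.
#'
#' @param endpoint as in [fit_endpoint()].
#' @param bmr benchmark response: SD multiples for continuous (default 1,
#'   distinct from the transcriptomic 1.349), extra risk for dichotomous
#'   (default 0.10).
#' @param type data type (inferred when missing).
#' @param max_iter optimizer cap.
#' @return list: `status` ("viable"/"failed"), `family`, `bmd`, `bmdl`,
#'   `doses_dropped`, `notes`.
#' @export
recommend_bmd <- function(endpoint, bmr = NULL, type = NULL, max_iter = 250) {
  if (is.null(type))
    type <- if ("x" %in% names(endpoint)) "dichotomous" else "continuous"
  if (is.null(bmr)) bmr <- if (type == "continuous") 1 else 0.1
  dat <- endpoint[order(endpoint$dose), , drop = FALSE]
  dropped <- 0L
  notes <- character()
  while (nrow(dat) >= 3) {
    fits <- fit_endpoint(dat, type, max_iter)
    max_dose <- max(dat$dose)
    cls <- lapply(fits, classify_viable, bmr = bmr, max_dose = max_dose)
    viable <- Filter(function(x) isTRUE(x$viable), cls)
    if (length(viable)) {
      bmdls <- vapply(viable, `[[`, numeric(1), "bmdl")
      pick <- if (max(bmdls) / min(bmdls) <= 3) {
        names(viable)[order(vapply(viable, `[[`, numeric(1), "aic"))][1]
      } else names(viable)[order(bmdls)][1]
      v <- viable[[pick]]
      return(list(status = "viable", family = pick, bmd = v$bmd,
                  bmdl = v$bmdl, doses_dropped = dropped, notes = notes))
    }
    if (nrow(dat) == 3) break
    notes <- c(notes, sprintf("no viable model with %d groups; dropped dose %g",
                              nrow(dat), max_dose))
    dat <- dat[-nrow(dat), , drop = FALSE]
    dropped <- dropped + 1L
  }
  list(status = "failed", family = NA_character_, bmd = NA_real_,
       bmdl = NA_real_, doses_dropped = dropped,
       notes = c(notes, "failed BMD modeling"))
}
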