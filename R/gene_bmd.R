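# Per-gene benchmark-dose workflow: fit the five continuous models, apply
# the nested/AIC/goodness-of-fit selection cascade, the Hill k-flag rule
# with its halving fallback, and the post-filters, producing the gene BMD
# table consumed by the pathway and aggregation stages.

#' Fit the continuous model suite to one gene and select a model
#'
#' Selection cascade: (a) choose among linear/poly2/poly3 by nested
#' likelihood-ratio tests at 0.05; (b) among the chosen polynomial, hill
#' and power fits take the lowest AIC (ties to fewer parameters);
#' (c) require goodness-of-fit p > `gof_cut` (0.1), otherwise the gene has
#' no viable model (subject to Hill-flag handling in
#' [apply_hill_flag()]). BMD and BMDL are computed at `bmr` SD (1.349).
#'
#' @param doses dose per observation.
#' @param y log2 response vector.
#' @param bmr benchmark response in residual SD multiples.
#' @param gof_cut goodness-of-fit gate for the selected model.
#' @param compute_bmdl compute the profile BMDL (slowest step).
#' @param max_iter optimizer iteration cap.
#' @return list: `record` (one-row data frame with gene-level results) and
#'   `fits` (all candidate `dr_fit`s).
#' @export
fit_gene <- function(doses, y, bmr = 1.349, gof_cut = 0.1,
                     compute_bmdl = TRUE, max_iter = 250) {
  fits <- list(
    linear = dr_fit(doses, y, "linear", max_iter = max_iter),
    poly2 = dr_fit(doses, y, "poly2", max_iter = max_iter),
    poly3 = dr_fit(doses, y, "poly3", max_iter = max_iter),
    power = dr_fit(doses, y, "power", max_iter = max_iter),
    hill = dr_fit(doses, y, "hill", max_iter = max_iter)
  )
  chosen_poly <- nested_lr_select(fits$linear, fits$poly2, fits$poly3)
  candidates <- list(chosen_poly, fits$hill, fits$power)
  ok <- vapply(candidates, function(f) f$converged && is.finite(f$aic), logical(1))
  if (!any(ok)) return(list(record = gene_record(NA, "no_viable_model"), fits = fits))
  cand <- candidates[ok]
  aics <- vapply(cand, `[[`, numeric(1), "aic")
  npars <- vapply(cand, `[[`, numeric(1), "npar")
  sel <- cand[[order(aics, npars)[1]]]

  gof <- dr_gof(sel)
  bmd <- bmd_from_fit(sel, bmr)
  bmdl <- if (compute_bmdl && is.finite(bmd)) bmdl_profile(sel, bmr) else NA_real_
  rec <- data.frame(
    family = sel$family, bmd = bmd, bmdl = bmdl,
    gof_p = if (is.null(gof$p)) NA_real_ else gof$p,
    hill_k = if (sel$family == "hill") sel$pars[["k"]] else NA_real_,
    hill_flagged = FALSE, fallback_halved = FALSE,
    excluded_reason = "none", stringsAsFactors = FALSE
  )
  if (!is.na(rec$gof_p) && rec$gof_p <= gof_cut && sel$family != "hill")
    rec$excluded_reason <- "gof_below_0.1"
  list(record = rec, fits = fits, selected = sel, chosen_poly = chosen_poly)
}

gene_record <- function(bmd, reason) {
  data.frame(family = NA_character_, bmd = NA_real_, bmdl = NA_real_,
             gof_p = NA_real_, hill_k = NA_real_, hill_flagged = FALSE,
             fallback_halved = FALSE, excluded_reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply the Hill k-parameter flag rule
#'
#' A Hill fit is flagged when its half-maximum parameter `k` is below one
#' third of the lowest positive dose (an unsupported low-dose plateau). A
#' flagged gene takes the next best (lowest-AIC) non-Hill model with
#' goodness-of-fit p > 0.05; if none qualifies, the dataset-level fallback
#' applies: half of the lowest BMD among unflagged Hill fits
#' (`fallback_bmd * 0.5`, BMDL halved by the same factor); with no such
#' fallback available the gene has no viable model.
#'
#' @param result a [fit_gene()] result whose selected family is hill.
#' @param lowest_positive_dose smallest non-control dose.
#' @param fallback_bmd dataset-level lowest unflagged-Hill BMD (or NULL).
#' @param fallback_bmdl matching BMDL for the fallback (or NULL).
#' @param bmr benchmark response for re-deriving alternatives.
#' @param flag_fraction flag threshold as a fraction of the lowest positive
#'   dose (default 1/3).
#' @param alt_gof_cut goodness-of-fit gate for the substitute model (0.05).
#' @param compute_bmdl compute BMDL for a substituted model.
#' @return updated one-row record.
#' @export
apply_hill_flag <- function(result, lowest_positive_dose, fallback_bmd = NULL,
                            fallback_bmdl = NULL, bmr = 1.349,
                            flag_fraction = 1 / 3, alt_gof_cut = 0.05,
                            compute_bmdl = TRUE) {
  rec <- result$record
  if (is.na(rec$family) || rec$family != "hill") return(rec)
  if (is.na(rec$hill_k) || rec$hill_k >= flag_fraction * lowest_positive_dose) {
    # unflagged hill still subject to the standard GOF gate
    if (!is.na(rec$gof_p) && rec$gof_p <= 0.1 && rec$excluded_reason == "none")
      rec$excluded_reason <- "gof_below_0.1"
    return(rec)
  }
  rec$hill_flagged <- TRUE
  # next-best non-hill candidate with GOF p > alt_gof_cut, by AIC
  alts <- list(result$chosen_poly, result$fits$power)
  alts <- Filter(function(f) !is.null(f) && f$converged && is.finite(f$aic), alts)
  if (length(alts)) {
    aics <- vapply(alts, `[[`, numeric(1), "aic")
    alts <- alts[order(aics)]
    for (f in alts) {
      g <- dr_gof(f)
      if (!is.na(g$p) && g$p > alt_gof_cut) {
        bmd <- bmd_from_fit(f, bmr)
        rec$family <- f$family
        rec$bmd <- bmd
        rec$bmdl <- if (compute_bmdl && is.finite(bmd)) bmdl_profile(f, bmr)
                    else NA_real_
        rec$gof_p <- g$p
        rec$excluded_reason <- "none"
        return(rec)
      }
    }
  }
  if (!is.null(fallback_bmd) && is.finite(fallback_bmd)) {
    rec$bmd <- 0.5 * fallback_bmd
    rec$bmdl <- if (!is.null(fallback_bmdl) && is.finite(fallback_bmdl))
      0.5 * fallback_bmdl else NA_real_
    rec$fallback_halved <- TRUE
    rec$excluded_reason <- "none"
  } else {
    rec$bmd <- NA_real_
    rec$bmdl <- NA_real_
    rec$excluded_reason <- "no_viable_model"
  }
  rec
}

#' Fit the gene BMD table for a filtered gene set
#'
#' Runs [fit_gene()] on each gene, then resolves Hill flags: the
#' dataset-level fallback (lowest unflagged-Hill BMD) is computed in a
#' first pass and applied in a second.
#'
#' @param expr genes x samples log2 matrix.
#' @param dose dose per sample.
#' @param genes gene ids to model (rows of `expr`).
#' @inheritParams fit_gene
#' @return data frame, one row per gene, columns of [fit_gene()] plus `gene`.
#' @export
fit_gene_table <- function(expr, dose, genes = rownames(expr), bmr = 1.349,
                           gof_cut = 0.1, compute_bmdl = TRUE, max_iter = 250) {
  lpd <- min(dose[dose > 0])
  results <- lapply(genes, function(g)
    fit_gene(dose, expr[g, ], bmr, gof_cut, compute_bmdl, max_iter))
  # dataset-level fallback: lowest BMD among unflagged hill selections
  hill_bmds <- hill_bmdls <- numeric(0)
  for (r in results) {
    rec <- r$record
    if (!is.na(rec$family) && rec$family == "hill" && is.finite(rec$bmd) &&
        (is.na(rec$hill_k) || rec$hill_k >= lpd / 3)) {
      hill_bmds <- c(hill_bmds, rec$bmd)
      hill_bmdls <- c(hill_bmdls, rec$bmdl)
    }
  }
  fb <- if (length(hill_bmds)) min(hill_bmds) else NULL
  fbl <- if (length(hill_bmds)) hill_bmdls[which.min(hill_bmds)] else NULL
  recs <- lapply(seq_along(results), function(i) {
    rec <- apply_hill_flag(results[[i]], lpd, fb, fbl, bmr,
                           compute_bmdl = compute_bmdl)
    cbind(gene = genes[i], rec, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Post-filter the gene BMD table
#'
#' Removes promiscuous probes (annotated to more than one gene), records
#' with BMD above the highest dose, and never-flagged records with
#' goodness-of-fit p < 0.1 (flag-substituted and halved-fallback records
#' already passed their own 0.05 gate); then collapses surviving probes to
#' unique genes by averaging BMD and BMDL.
#'
#' @param records output of [fit_gene_table()] (per probe or per gene).
#' @param max_dose highest tested dose.
#' @param probe_annotation optional data frame `probe`, `gene` mapping; when
#'   supplied, `records$gene` is interpreted as probe ids.
#' @param gof_cut removal threshold (0.1).
#' @return list: `table` (gene, bmd, bmdl, family, gof_p), `removed` counts
#'   per reason.
#' @export
postfilter_gene_table <- function(records, max_dose, probe_annotation = NULL,
                                  gof_cut = 0.1) {
  removed <- c(no_viable_model = 0L, promiscuous_probe = 0L,
               bmd_above_max_dose = 0L, gof_below_0.1 = 0L)
  keep <- rep(TRUE, nrow(records))

  bad <- records$excluded_reason %in% c("no_viable_model") | is.na(records$bmd)
  removed["no_viable_model"] <- sum(bad)
  keep <- keep & !bad

  if (!is.null(probe_annotation)) {
    cnt <- table(probe_annotation$probe)
    promiscuous <- names(cnt)[cnt > 1]
    bad <- keep & records$gene %in% promiscuous
    removed["promiscuous_probe"] <- sum(bad)
    keep <- keep & !bad
  }

  bad <- keep & records$bmd > max_dose
  removed["bmd_above_max_dose"] <- sum(bad, na.rm = TRUE)
  keep <- keep & !bad

  bad <- keep & !records$hill_flagged & !records$fallback_halved &
    (!is.na(records$gof_p) & records$gof_p < gof_cut |
       records$excluded_reason == "gof_below_0.1")
  removed["gof_below_0.1"] <- sum(bad, na.rm = TRUE)
  keep <- keep & !bad

  surv <- records[keep, , drop = FALSE]
  if (!is.null(probe_annotation)) {
    gene_of <- probe_annotation$gene[match(surv$gene, probe_annotation$probe)]
    surv$gene <- ifelse(is.na(gene_of), surv$gene, gene_of)
  }
  # collapse probes to unique genes: mean BMD / BMDL
  agg <- stats::aggregate(cbind(bmd, bmdl) ~ gene, data = surv, FUN = mean,
                          na.action = stats::na.pass)
  first <- surv[!duplicated(surv$gene), c("gene", "family", "gof_p")]
  tab <- merge(agg, first, by = "gene", sort = TRUE)
  list(table = tab, removed = removed)
}
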