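# Synthetic dose-response study generator with known ground-truth BMDs.
# Emulates a subchronic rodent transcriptomic design: 6 dose groups
# (control plus 5 treated), 6 replicates per group, log2 expression with
# i.i.d. Gaussian noise, a minority of dose-responsive genes concentrated
# in designated pathways, and matched apical endpoints.

#' Simulation configuration
#'
#' Defaults mirror a subchronic rat design: doses 0, 2.5, 5, 10, 25, 75
#' mg/kg-day and six animals per group. True BMDs of responsive genes are
#' sampled log-uniformly over `bmd_range` so downstream aggregation rules
#' face a spread of sensitivities; the response direction is a random sign
#' per gene.
#'
#' @param doses dose vector, strictly increasing, control 0 first.
#' @param n_reps replicates per dose group (>= 2).
#' @param n_genes total genes on the platform.
#' @param frac_responsive fraction of genes with a dose effect.
#' @param response_model curve families sampled for responsive genes.
#' @param bmd_range (low, high) interval for log-uniform true-BMD sampling.
#' @param sigma residual SD of log2 expression (> 0).
#' @param n_pathways,pathway_size gene-set construction parameters.
#' @param enrichment_frac probability that a member of a designated
#'   "enriched" pathway is drawn from the responsive genes.
#' @param n_regulators number of synthetic upstream regulators.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(doses = c(0, 2.5, 5, 10, 25, 75), n_reps = 6,
                       n_genes = 2000, frac_responsive = 0.15,
                       response_model = c("hill", "linear", "power"),
                       bmd_range = c(2.5, 50), sigma = 0.2,
                       n_pathways = 50, pathway_size = 15,
                       enrichment_frac = 0.7, n_regulators = 30,
                       seed = 1L) {
  stopifnot(length(doses) >= 2, doses[1] == 0, all(diff(doses) > 0),
            n_reps >= 2, frac_responsive >= 0, frac_responsive <= 1,
            sigma > 0, pathway_size >= 1,
            bmd_range[1] > 0, bmd_range[2] >= bmd_range[1])
  if (pathway_size > n_genes) stop("pathway size exceeds gene count")
  structure(list(doses = doses, n_reps = n_reps, n_genes = n_genes,
                 frac_responsive = frac_responsive,
                 response_model = response_model, bmd_range = bmd_range,
                 sigma = sigma, n_pathways = n_pathways,
                 pathway_size = pathway_size,
                 enrichment_frac = enrichment_frac,
                 n_regulators = n_regulators, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate replicate responses for one gene
#'
#' Draws `n_reps` values per dose as `mu(d) + N(0, sigma)`; with
#' `sigma = 0` the values equal the model mean exactly.
#'
#' @param model_spec list with `family` and named `pars` (see [dr_mean()];
#'   Hill `k` must be positive and restricted exponents >= 1).
#' @param doses dose vector.
#' @param n_reps replicates per dose.
#' @param sigma residual SD (>= 0).
#' @return matrix with `n_reps` rows and one column per dose.
#' @export
simulate_gene <- function(model_spec, doses, n_reps, sigma) {
  stopifnot(is.list(model_spec), !is.null(model_spec$family))
  if (sigma < 0) stop("sigma must be non-negative")
  info <- dr_family_info(model_spec$family)
  if (info$type != "continuous") stop("invalid family for expression simulation")
  mu <- dr_mean(model_spec$family, model_spec$pars, doses)
  noise <- if (sigma > 0) matrix(stats::rnorm(n_reps * length(doses), 0, sigma),
                                 n_reps) else 0
  matrix(rep(mu, each = n_reps), n_reps) + noise
}

#' True benchmark dose of a generating model
#'
#' The generating-model BMD is the smallest positive dose at which
#' `|mu(d) - mu(0)| = bmr * sigma`. Linear, power and hill are closed form;
#' other families use bracketed root finding. Returns `NA` ("none") when
#' the crossing does not exist below `10 * max_dose`.
#'
#' @inheritParams simulate_gene
#' @param bmr benchmark response in SD multiples (default 1.349).
#' @param max_dose upper bracket for the numeric search.
#' @return the true BMD, or `NA_real_`.
#' @export
true_bmd <- function(model_spec, sigma, bmr = 1.349, max_dose = NULL) {
  s <- bmr * sigma
  p <- model_spec$pars
  fam <- model_spec$family
  if (fam == "linear") {
    if (abs(p[["b1"]]) < 1e-300) return(NA_real_)
    return(s / abs(p[["b1"]]))
  }
  if (fam == "power") {
    if (abs(p[["b"]]) < 1e-300) return(NA_real_)
    return((s / abs(p[["b"]]))^(1 / p[["delta"]]))
  }
  if (fam == "hill") {
    v <- abs(p[["v"]])
    if (v <= s) return(NA_real_)
    return(p[["k"]] * (s / (v - s))^(1 / p[["n"]]))
  }
  if (is.null(max_dose)) stop("max_dose required for numeric families")
  f <- function(d) abs(dr_mean(fam, p, d) - dr_mean(fam, p, 0)) - s
  bmd_root(f, max_dose)
}

# sample a generating model whose bmr-crossing sits exactly at bmd
sample_gene_model <- function(family, bmd, sigma, bmr, direction) {
  s <- bmr * sigma * direction
  baseline <- stats::runif(1, 6, 12)
  if (family == "linear") {
    list(family = "linear", pars = c(b0 = baseline, b1 = s / bmd))
  } else if (family == "power") {
    delta <- stats::runif(1, 1, 2.5)
    list(family = "power", pars = c(g = baseline, b = s / bmd^delta, delta = delta))
  } else if (family == "hill") {
    n <- stats::runif(1, 1, 3)
    k <- bmd * stats::runif(1, 0.75, 2)
    v <- s * (1 + (k / bmd)^n)
    list(family = "hill", pars = c(g = baseline, v = v, k = k, n = n))
  } else stop("invalid family name: ", family)
}

#' Simulate a complete synthetic study
#'
#' Generates the expression matrix, sample metadata, pathway and regulator
#' gene sets, matched apical endpoints, and a truth table recording each
#' responsive gene's generating model and true BMD. Deterministic given the
#' config seed. Responsive genes are preferentially placed in the first
#' 20\% of pathways ("designed enriched" sets) at rate `enrichment_frac`;
#' regulator target sets are sampled the same way.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_study` list: `expression`, `sample_meta`,
#'   `pathways`, `regulators`, `apical_continuous`, `apical_dichotomous`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  doses <- config$doses
  nrep <- config$n_reps
  genes <- sprintf("g%05d", seq_len(ng))
  n_resp <- round(config$frac_responsive * ng)
  responsive <- if (n_resp > 0) sample(genes, n_resp) else character(0)

  dose_per_sample <- rep(doses, each = nrep)
  samples <- sprintf("s%03d", seq_along(dose_per_sample))
  expr <- matrix(NA_real_, ng, length(samples), dimnames = list(genes, samples))

  truth <- data.frame(gene = genes, responsive = genes %in% responsive,
                      family = NA_character_, true_bmd = NA_real_,
                      direction = NA_real_, stringsAsFactors = FALSE)
  truth$params <- vector("list", ng)

  lb <- log(config$bmd_range)
  for (i in seq_len(ng)) {
    if (truth$responsive[i]) {
      fam <- sample(config$response_model, 1)
      bmd <- exp(stats::runif(1, lb[1], lb[2]))
      dirn <- sample(c(-1, 1), 1)
      spec <- sample_gene_model(fam, bmd, config$sigma, 1.349, dirn)
      truth$family[i] <- fam
      truth$true_bmd[i] <- bmd
      truth$direction[i] <- dirn
      truth$params[[i]] <- spec$pars
    } else {
      spec <- list(family = "linear",
                   pars = c(b0 = stats::runif(1, 6, 12), b1 = 0))
    }
    # simulate_gene returns reps x doses; column-major order matches the
    # dose-major sample layout rep(doses, each = n_reps)
    expr[i, ] <- as.vector(simulate_gene(spec, doses, nrep, config$sigma))
  }

  # enriched sets draw members from the responsive pool at rate
  # enrichment_frac, topping up from the null genes (or anywhere when one
  # pool is exhausted)
  nulls <- setdiff(genes, responsive)
  pick_members <- function(size, enriched) {
    if (enriched && length(responsive)) {
      tr <- min(stats::rbinom(1, size, config$enrichment_frac),
                length(responsive))
      fill <- size - tr
      members <- c(sample(responsive, tr),
                   if (fill > 0 && length(nulls) >= fill) sample(nulls, fill)
                   else sample(genes, fill))
    } else members <- sample(genes, size)
    sort(unique(members))
  }
  n_enr <- max(1L, round(0.2 * config$n_pathways))
  pathways <- list()
  for (j in seq_len(config$n_pathways))
    pathways[[sprintf("PW%03d", j)]] <-
      pick_members(config$pathway_size, j <= n_enr)

  regulators <- list()
  if (config$n_regulators > 0) {
    n_enr_reg <- max(1L, round(0.2 * config$n_regulators))
    for (j in seq_len(config$n_regulators))
      regulators[[sprintf("REG%03d", j)]] <-
        pick_members(config$pathway_size, j <= n_enr_reg)
  }

  apical_cont <- simulate_apical(
    "continuous",
    params = list(family = "hill",
                  pars = c(g = 10, v = 3, k = stats::median(doses[doses > 0]), n = 2),
                  sd = 0.8),
    doses = doses, n_per_group = nrep)
  apical_dich <- simulate_apical(
    "dichotomous",
    params = list(background = 0.05, bmd = stats::median(doses[doses > 0]),
                  bmr = 0.1, slope = 2),
    doses = doses, n_per_group = nrep)

  structure(list(expression = expr,
                 sample_meta = data.frame(sample = samples, dose = dose_per_sample),
                 pathways = pathways, regulators = regulators,
                 apical_continuous = apical_cont,
                 apical_dichotomous = apical_dich,
                 truth = truth, config = config),
            class = "synthetic_study")
}

#' Simulate a matched apical endpoint
#'
#' Continuous endpoints: group means are drawn around a stated mean curve
#' (`mean ~ N(mu(d), sd/sqrt(n))`) with chi-square-distributed group SDs;
#' the recorded true BMD is the `bmr_sd`-SD crossing of the mean curve.
#' Dichotomous endpoints: affected counts are binomial draws from a
#' log-logistic dose-incidence curve anchored so that the extra risk at
#' `params$bmd` equals `params$bmr`; the recorded truth is that dose.
#' Direct per-dose probabilities can be supplied via `params$probs`.
#'
#' @param kind `"continuous"` or `"dichotomous"`.
#' @param params continuous: list(family, pars, sd, bmr_sd = 1.349);
#'   dichotomous: list(background, bmd, bmr = 0.1, slope) or list(probs).
#' @param doses dose vector.
#' @param n_per_group animals per dose group (>= 1).
#' @return data frame of per-dose records with attribute `"true_bmd"`.
#' @export
simulate_apical <- function(kind = c("continuous", "dichotomous"), params,
                            doses, n_per_group) {
  kind <- match.arg(kind)
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (kind == "continuous") {
    bmr_sd <- if (is.null(params$bmr_sd)) 1.349 else params$bmr_sd
    mu <- dr_mean(params$family, params$pars, doses)
    m <- stats::rnorm(length(doses), mu, params$sd / sqrt(n_per_group))
    sdv <- if (n_per_group > 1)
      params$sd * sqrt(stats::rchisq(length(doses), n_per_group - 1) /
                         (n_per_group - 1))
    else rep(0, length(doses))
    out <- data.frame(dose = doses, n = n_per_group, mean = m, sd = sdv)
    tb <- true_bmd(list(family = params$family, pars = params$pars),
                   sigma = params$sd, bmr = bmr_sd, max_dose = max(doses))
    attr(out, "true_bmd") <- tb
    out
  } else {
    if (!is.null(params$probs)) {
      p <- params$probs
      stopifnot(length(p) == length(doses), all(p >= 0 & p <= 1))
      tb <- if (is.null(params$bmd)) NA_real_ else params$bmd
    } else {
      g <- params$background
      stopifnot(g >= 0, g < 1)
      bmr <- if (is.null(params$bmr)) 0.1 else params$bmr
      a <- stats::qlogis(bmr) - params$slope * log(params$bmd)
      Fd <- ifelse(doses > 0, stats::plogis(a + params$slope * log(doses)), 0)
      p <- g + (1 - g) * Fd
      tb <- params$bmd
    }
    x <- stats::rbinom(length(doses), n_per_group, p)
    out <- data.frame(dose = doses, n = n_per_group, x = x, p_true = p)
    attr(out, "true_bmd") <- tb
    out
  }
}

#' Write a synthetic study to plain-text files
#'
#' Expression as tab-delimited text (first column gene id, header sample
#' ids), sample metadata TSV, pathways/regulators as GMT, truth table TSV.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             meta = file.path(dir, "sample_meta.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             regulators = file.path(dir, "regulators.gmt"),
             truth = file.path(dir, "truth.tsv"))
  em <- data.frame(gene = rownames(study$expression), study$expression,
                   check.names = FALSE)
  utils::write.table(em, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$sample_meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(study$pathways, paths["pathways"])
  write_gmt(study$regulators, paths["regulators"])
  tr <- study$truth
  tr$params <- vapply(tr$params, function(p)
    if (is.null(p)) "" else paste(sprintf("%s=%.10g", names(p), p), collapse = ";"),
    character(1))
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
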