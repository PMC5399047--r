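# End-to-end orchestration: screen -> gene BMDs -> pathway results ->
# approaches -> bootstrap, with file-level interfaces and a JSON run
# summary. Every numeric constant of the procedure lives here, in the run
# configuration defaults, not in stage logic.

#' Pipeline run configuration
#'
#' @param fdr_cut,fc_cut conservative filter thresholds (0.05, 1.5).
#' @param p_cut liberal ANOVA threshold (0.05).
#' @param bmr transcriptomic benchmark response in SD multiples (1.349).
#' @param level one-sided confidence level for BMDL (0.95).
#' @param max_iter optimizer iteration cap (250).
#' @param hill_flag_fraction Hill k flag threshold as a fraction of the
#'   lowest positive dose (1/3).
#' @param fallback_factor multiplier for the flagged-Hill fallback (0.5).
#' @param min_pathway_genes minimum BMD-carrying members for a pathway BMD
#'   (4).
#' @param enrich_cut enrichment significance gate (0.05).
#' @param n_permutations permutations for the Fs statistic (1000).
#' @param bootstrap_B bootstrap replicates (2000; the demo scale uses 500).
#' @param seed RNG seed.
#' @param compute_bmdl compute profile BMDLs per gene (slow; TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(fdr_cut = 0.05, fc_cut = 1.5, p_cut = 0.05,
                       bmr = 1.349, level = 0.95, max_iter = 250,
                       hill_flag_fraction = 1 / 3, fallback_factor = 0.5,
                       min_pathway_genes = 4, enrich_cut = 0.05,
                       n_permutations = 1000, bootstrap_B = 2000,
                       seed = 1L, compute_bmdl = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full transcriptomic POD pipeline on one study
#'
#' Stages: gene screening under the conservative (Fs + FDR + fold change)
#' and liberal (ANOVA) filters; per-gene BMD modeling of each filtered set;
#' post-filtering; pathway BMDs and enrichment under both regimes;
#' regulator over-representation; the eleven POD approaches; bootstrap
#' summaries. Deterministic given the config seed.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param dose numeric dose per sample.
#' @param pathways named list of pathway gene sets.
#' @param regulators named list of regulator target sets, or NULL
#'   (approach 8 then reports unavailable).
#' @param config a [run_config()].
#' @param out_dir optional directory for stage TSVs and the JSON summary.
#' @return list with `screen`, `gene_tables`, `pathway_tables`,
#'   `regulator_table`, `approaches`, `bootstrap`, `input`, `config`.
#' @export
run_pipeline <- function(expr, dose, pathways, regulators = NULL,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  universe <- rownames(expr)
  overlap <- length(intersect(universe, unique(unlist(pathways))))
  if (overlap < 0.1 * length(unique(unlist(pathways))))
    warning("expression and pathway gene universes overlap by less than 10%")

  screen <- screen_genes(expr, dose, config$n_permutations, config$seed,
                         config$fdr_cut, config$fc_cut, config$p_cut)

  gene_tables <- list()
  pathway_tables <- list()
  deg_sets <- list(
    conservative = filter_genes(screen, "conservative",
                                config$fdr_cut, config$fc_cut),
    liberal = filter_genes(screen, "liberal", p_cut = config$p_cut)
  )
  for (regime in c("conservative", "liberal")) {
    sel <- deg_sets[[regime]]
    if (length(sel)) {
      raw <- fit_gene_table(expr, dose, sel, config$bmr,
                            compute_bmdl = config$compute_bmdl,
                            max_iter = config$max_iter)
      pf <- postfilter_gene_table(raw, max(dose))
      gene_tables[[regime]] <- pf$table
    } else {
      gene_tables[[regime]] <- data.frame(gene = character(0), bmd = numeric(0),
                                          bmdl = numeric(0))
    }
    pathway_tables[[regime]] <- pathway_bmds(
      gene_tables[[regime]], pathways, universe,
      deg_set = deg_sets[[regime]], min_genes = config$min_pathway_genes)
  }

  regulator_table <- if (!is.null(regulators) && length(regulators))
    regulator_significance(deg_sets$conservative, regulators, universe)
  else NULL

  input <- approach_input(gene_tables, pathway_tables, screen, pathways,
                          regulator_table, regulators, config$enrich_cut)
  approaches <- run_all_approaches(input)
  boot <- bootstrap_all_approaches(input, config$bootstrap_B, config$seed)

  res <- list(screen = screen, deg_sets = deg_sets, gene_tables = gene_tables,
              pathway_tables = pathway_tables,
              regulator_table = regulator_table, approaches = approaches,
              bootstrap = boot, input = input, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$screen, "screen.tsv")
  for (regime in names(res$gene_tables)) {
    wt(res$gene_tables[[regime]], sprintf("gene_bmd_%s.tsv", regime))
    wt(res$pathway_tables[[regime]], sprintf("pathway_bmd_%s.tsv", regime))
  }
  if (!is.null(res$regulator_table)) wt(res$regulator_table, "regulators.tsv")
  wt(res$approaches, "approaches.tsv")
  wt(res$bootstrap, "bootstrap.tsv")
  summary <- list(
    config = res$config[setdiff(names(res$config), "")],
    n_genes_screened = nrow(res$screen),
    n_deg = lapply(res$deg_sets, length),
    n_gene_bmds = lapply(res$gene_tables, nrow),
    n_approaches_available = sum(res$approaches$status == "available")
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
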