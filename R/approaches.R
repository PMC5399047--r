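# The eleven transcriptomic POD derivation rules, dispatched uniformly
# over screen results, gene BMD tables and pathway results.
#
# Filter regimes: approaches 1, 2, 4, 5, 6, 7, 8 consume the conservative
# (FDR + fold change) results; approaches 3, 9, 10, 11 the liberal
# (unadjusted ANOVA) results. Pathway-set approaches aggregate as the
# unweighted mean of the selected pathways' BMDs (each itself a mean over
# member genes); approach 11 takes the median across pathway BMDs.

APPROACH_REGIME <- c("conservative", "conservative", "liberal", "conservative",
                     "conservative", "conservative", "conservative",
                     "conservative", "liberal", "liberal", "liberal")

#' Assemble the input bundle for the approach rules
#'
#' @param gene_tables named list with elements `conservative` and `liberal`:
#'   post-filtered gene BMD tables (`gene`, `bmd`, `bmdl`).
#' @param pathway_tables same structure: [pathway_bmds()] outputs.
#' @param screen the [screen_genes()] table (fold changes for approach 4).
#' @param pathways named list of pathway gene sets.
#' @param regulator_table [regulator_significance()] output, or NULL
#'   (approach 8 then reports unavailable).
#' @param regulator_sets named list of regulator target gene sets (the GMT
#'   contents backing `regulator_table`).
#' @param enrich_cut enrichment gate for "significantly enriched" (0.05).
#' @return an `approach_input` list.
#' @export
approach_input <- function(gene_tables, pathway_tables, screen, pathways,
                           regulator_table = NULL, regulator_sets = NULL,
                           enrich_cut = 0.05) {
  structure(list(gene_tables = gene_tables, pathway_tables = pathway_tables,
                 screen = screen, pathways = pathways,
                 regulator_table = regulator_table,
                 regulator_sets = regulator_sets, enrich_cut = enrich_cut),
            class = "approach_input")
}

approach_unavailable <- function(k, reason) {
  list(approach = k, status = "unavailable", reason = reason,
       entities = character(0), n = 0L, partial = FALSE,
       bmd = NA_real_, bmdl = NA_real_)
}

# selection helper: top n rows by key with deterministic tie-break on id
top_n_by <- function(df, key, n, decreasing = FALSE, tie = "id") {
  ord <- order(df[[key]], df[[tie]], decreasing = c(decreasing, FALSE),
               method = "radix")
  df[ord[seq_len(min(n, nrow(df)))], , drop = FALSE]
}

#' Run one POD-derivation approach
#'
#' The rules: (1) among significantly enriched pathways, the 20 with the
#' lowest pathway BMDs; (2) the 20 most significantly enriched pathways;
#' (3) the 20 pathways with the lowest BMDs under the liberal filter, no
#' enrichment gate; (4) the 20 genes with the largest fold changes; (5)
#' genes with BMDs inside the interquartile band (linear-interpolation
#' quantiles, inclusive); (6) the 20 enriched pathways with the most shared
#' genes; (7) the 20 genes contributing to the most enriched pathways; (8)
#' the union of the top-20 upstream regulators' scored targets; (9) the
#' enriched pathway with the lowest BMD (enrichment on BMD-passing genes);
#' (10) the mean and (11) the median of all pathway BMDs. Fewer than 20
#' available entities are used in full and flagged `partial`; zero
#' available entities gives status `"unavailable"`.
#'
#' @param k approach id 1..11.
#' @param input an [approach_input()].
#' @return list with `approach`, `status`, `entities`, `n`, `bmd`, `bmdl`.
#' @export
run_approach <- function(k, input) {
  if (!k %in% 1:11) stop("unknown approach: ", k)
  regime <- APPROACH_REGIME[k]
  gt <- input$gene_tables[[regime]]
  pt <- input$pathway_tables[[regime]]
  cut <- input$enrich_cut
  scored <- pt[!is.na(pt$bmd), , drop = FALSE]

  pathway_set_result <- function(sel, partial_limit = 20) {
    if (!nrow(sel)) return(approach_unavailable(k, "no qualifying pathways"))
    list(approach = k, status = "available", reason = NA_character_,
         entities = sel$pathway, n = nrow(sel),
         partial = nrow(sel) < partial_limit,
         bmd = mean(sel$bmd), bmdl = mean(sel$bmdl, na.rm = TRUE))
  }
  gene_set_result <- function(genes, partial_limit = 20) {
    rows <- gt[gt$gene %in% genes & is.finite(gt$bmd), , drop = FALSE]
    if (!nrow(rows)) return(approach_unavailable(k, "no qualifying genes"))
    list(approach = k, status = "available", reason = NA_character_,
         entities = rows$gene, n = nrow(rows),
         partial = length(genes) < partial_limit,
         bmd = mean(rows$bmd), bmdl = mean(rows$bmdl, na.rm = TRUE))
  }

  if (k %in% c(1, 2, 6)) {
    enr <- scored[!is.na(scored$p_deg) & scored$p_deg <= cut, , drop = FALSE]
    if (!nrow(enr)) return(approach_unavailable(k, "no enriched pathways"))
    sel <- switch(as.character(k),
      "1" = top_n_by(enr, "bmd", 20, tie = "pathway"),
      "2" = top_n_by(enr, "p_deg", 20, tie = "pathway"),
      "6" = {
        if (nrow(enr) < 2) enr
        else {
          shared <- shared_gene_counts(enr$pathway, input$pathways,
                                       scored_genes = gt$gene)
          enr$shared <- as.integer(shared[enr$pathway])
          top_n_by(enr, "shared", 20, decreasing = TRUE, tie = "pathway")
        }
      })
    return(pathway_set_result(sel))
  }
  if (k == 3) {
    if (!nrow(scored)) return(approach_unavailable(k, "no pathway BMDs"))
    return(pathway_set_result(top_n_by(scored, "bmd", 20, tie = "pathway")))
  }
  if (k == 4) {
    sc <- input$screen
    eligible <- sc[sc$gene %in% gt$gene[is.finite(gt$bmd)], , drop = FALSE]
    if (!nrow(eligible)) return(approach_unavailable(k, "no scored genes"))
    sel <- top_n_by(eligible, "max_abs_fc", 20, decreasing = TRUE, tie = "gene")
    return(gene_set_result(sel$gene))
  }
  if (k == 5) {
    bmds <- gt$bmd[is.finite(gt$bmd)]
    if (!length(bmds)) return(approach_unavailable(k, "no gene BMDs"))
    q <- stats::quantile(bmds, c(0.25, 0.75), type = 7)
    genes <- gt$gene[is.finite(gt$bmd) & gt$bmd >= q[1] & gt$bmd <= q[2]]
    return(gene_set_result(genes, partial_limit = 0))
  }
  if (k == 7) {
    enr <- scored[!is.na(scored$p_deg) & scored$p_deg <= cut, , drop = FALSE]
    if (!nrow(enr)) return(approach_unavailable(k, "no enriched pathways"))
    g <- gt[is.finite(gt$bmd), , drop = FALSE]
    cnt <- gene_membership_counts(g$gene, enr$pathway, input$pathways)
    df <- data.frame(gene = g$gene, count = as.integer(cnt), bmd = g$bmd)
    df <- df[df$count > 0, , drop = FALSE]
    if (!nrow(df)) return(approach_unavailable(k, "no member genes"))
    ord <- order(-df$count, df$bmd, df$gene, method = "radix")
    sel <- df[ord[seq_len(min(20, nrow(df)))], , drop = FALSE]
    return(gene_set_result(sel$gene))
  }
  if (k == 8) {
    rt <- input$regulator_table
    if (is.null(rt) || !nrow(rt))
      return(approach_unavailable(k, "no regulator annotations"))
    top <- top_n_by(rt, "p", 20, tie = "regulator")
    pool <- unique(unlist(input$regulator_sets[top$regulator]))
    return(gene_set_result(intersect(pool, gt$gene)))
  }
  if (k == 9) {
    enr <- scored[!is.na(scored$p_bmd) & scored$p_bmd <= cut, , drop = FALSE]
    if (!nrow(enr)) return(approach_unavailable(k, "no enriched pathways"))
    sel <- top_n_by(enr, "bmd", 1, tie = "pathway")
    return(pathway_set_result(sel, partial_limit = 1))
  }
  if (k %in% c(10, 11)) {
    if (!nrow(scored)) return(approach_unavailable(k, "no pathway BMDs"))
    agg <- if (k == 10) mean else stats::median
    return(list(approach = k, status = "available", reason = NA_character_,
                entities = scored$pathway, n = nrow(scored), partial = FALSE,
                bmd = agg(scored$bmd), bmdl = agg(scored$bmdl, na.rm = TRUE)))
  }
}

#' Run all eleven approaches
#'
#' @param input an [approach_input()].
#' @return data frame, one row per approach in order 1..11: `approach`,
#'   `status`, `n`, `partial`, `bmd`, `bmdl`; the selected entity lists are
#'   kept in attribute `"entities"`.
#' @export
run_all_approaches <- function(input) {
  res <- lapply(1:11, run_approach, input = input)
  out <- data.frame(
    approach = 1:11,
    status = vapply(res, `[[`, character(1), "status"),
    n = vapply(res, function(r) as.integer(r$n), integer(1)),
    partial = vapply(res, function(r) isTRUE(r$partial), logical(1)),
    bmd = vapply(res, `[[`, numeric(1), "bmd"),
    bmdl = vapply(res, `[[`, numeric(1), "bmdl")
  )
  attr(out, "entities") <- lapply(res, `[[`, "entities")
  out
}
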