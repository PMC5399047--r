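# Pathway layer: GMT-backed gene-set membership, Fisher enrichment,
# pathway BMDs and the shared-gene / membership-count statistics.

#' Read and write GMT gene-set files
#'
#' GMT lines are tab-separated: set name, description, then members.
#' Duplicate members are removed; malformed lines (< 3 fields) raise an
#' error naming the line number.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, " (fewer than 3 fields)")
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Right-tailed Fisher exact enrichment test
#'
#' Hypergeometric upper-tail probability `P(X >= overlap)` for the 2x2
#' table (in/out pathway x selected/not selected), with members outside the
#' universe ignored.
#'
#' @param selected selected gene ids (subset of `universe`).
#' @param pathway pathway member gene ids.
#' @param universe analysis universe of gene ids.
#' @return the enrichment p value.
#' @export
fisher_enrichment <- function(selected, pathway, universe) {
  if (!length(universe)) stop("empty universe")
  selected <- intersect(selected, universe)
  pathway <- intersect(pathway, universe)
  q <- length(intersect(selected, pathway))
  stats::phyper(q - 1, length(pathway), length(universe) - length(pathway),
                length(selected), lower.tail = FALSE)
}

#' Pathway-level BMDs and enrichment
#'
#' A pathway's transcriptomic BMD is the mean of its member genes'
#' surviving BMDs, assigned only when at least `min_genes` members carry a
#' BMD; pathway BMDL is the mean of the member BMDLs. Two enrichment p
#' values are reported: `p_deg` tests the DEG set against the platform
#' universe (IPA-style), and `p_bmd` tests the set of genes that passed
#' filtering and carry a BMD against the same platform universe (the
#' conventional analysis with the BMD-passing list in place of the DEG
#' list).
#'
#' @param gene_table post-filtered gene BMD table (columns `gene`, `bmd`,
#'   `bmdl`).
#' @param pathways named list of gene sets.
#' @param universe platform gene ids.
#' @param deg_set differentially expressed gene ids (for `p_deg`), or NULL.
#' @param min_genes minimum BMD-carrying members for a pathway BMD (4).
#' @return data frame: `pathway`, `n_universe`, `n_bmd`, `p_deg`, `p_bmd`,
#'   `bmd`, `bmdl`.
#' @export
pathway_bmds <- function(gene_table, pathways, universe,
                         deg_set = NULL, min_genes = 4) {
  scored <- gene_table$gene
  out <- lapply(names(pathways), function(nm) {
    mem <- intersect(pathways[[nm]], universe)
    mem_bmd <- intersect(mem, scored)
    bmds <- gene_table$bmd[match(mem_bmd, gene_table$gene)]
    bmdls <- gene_table$bmdl[match(mem_bmd, gene_table$gene)]
    data.frame(
      pathway = nm,
      n_universe = length(mem),
      n_bmd = length(mem_bmd),
      p_deg = if (!is.null(deg_set))
        fisher_enrichment(deg_set, mem, universe) else NA_real_,
      p_bmd = fisher_enrichment(intersect(scored, universe), mem, universe),
      bmd = if (length(mem_bmd) >= min_genes) mean(bmds) else NA_real_,
      bmdl = if (length(mem_bmd) >= min_genes) mean(bmdls, na.rm = TRUE)
             else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Shared-gene counts among enriched pathways
#'
#' For each pathway in `enriched`, the number of its scored member genes
#' that also belong to at least one other pathway in `enriched`.
#'
#' @param enriched character vector of pathway ids (>= 2).
#' @param pathways named list of gene sets.
#' @param scored_genes genes carrying BMDs; members outside this set are
#'   ignored (NULL keeps all members).
#' @return named integer vector of counts.
#' @export
shared_gene_counts <- function(enriched, pathways, scored_genes = NULL) {
  stopifnot(length(enriched) >= 2)
  sets <- lapply(pathways[enriched], function(s)
    if (is.null(scored_genes)) s else intersect(s, scored_genes))
  vapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i]))
    sum(sets[[i]] %in% others)
  }, integer(1)) |> stats::setNames(enriched)
}

#' Per-gene enriched-pathway membership counts
#'
#' Number of enriched pathways containing each gene.
#'
#' @param genes gene ids to score.
#' @param enriched enriched pathway ids.
#' @param pathways named list of gene sets.
#' @return named integer vector, one entry per gene.
#' @export
gene_membership_counts <- function(genes, enriched, pathways) {
  sets <- pathways[enriched]
  vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
}

#' Upstream-regulator over-representation
#'
#' Surrogate for knowledge-base upstream analysis: each regulator's target
#' set is tested for overlap with the DEG set by the right-tailed Fisher
#' exact test, and regulators are ranked by p value.
#'
#' @param deg_set differentially expressed gene ids.
#' @param regulators named list of regulator target sets.
#' @param universe platform gene ids.
#' @return data frame `regulator`, `n_targets`, `n_overlap`, `p`, sorted by
#'   `p` then regulator id.
#' @export
regulator_significance <- function(deg_set, regulators, universe) {
  if (is.null(regulators) || !length(regulators))
    stop("no regulator sets loaded")
  out <- data.frame(
    regulator = names(regulators),
    n_targets = vapply(regulators, function(s)
      length(intersect(s, universe)), integer(1)),
    n_overlap = vapply(regulators, function(s)
      length(intersect(intersect(s, universe), deg_set)), integer(1)),
    p = vapply(regulators, function(s)
      fisher_enrichment(deg_set, s, universe), numeric(1)),
    row.names = NULL
  )
  out[order(out$p, out$regulator), , drop = FALSE]
}
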