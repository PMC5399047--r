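# Bootstrap distributions for the approach summary statistics.
#
# Resampling unit: gene BMDs. For pathway-based approaches the selected
# pathway set is held fixed and each pathway's member-gene BMDs are
# resampled with replacement before recomputing the pathway means and the
# across-pathway statistic; for gene-set approaches the selected gene set's
# BMDs are resampled directly.

#' Bootstrap an approach's POD statistic
#'
#' @param k approach id 1..11.
#' @param input an [approach_input()].
#' @param B bootstrap replicates (default 2000).
#' @param seed RNG seed; results are deterministic given `(seed, B)`.
#' @return list: `approach`, `B`, point `estimate`, bootstrap `mean`, `sd`,
#'   `cv`, `percentiles` (2.5, 10, 25, 50, 75, 90, 97.5), `seed`,
#'   `status`; an unavailable approach propagates its status.
#' @export
bootstrap_approach <- function(k, input, B = 2000, seed = 1L) {
  point <- run_approach(k, input)
  if (point$status != "available")
    return(list(approach = k, status = point$status, B = B, seed = seed,
                estimate = NA_real_, mean = NA_real_, sd = NA_real_,
                cv = NA_real_, percentiles = NULL))
  regime <- APPROACH_REGIME[k]
  gt <- input$gene_tables[[regime]]
  pathway_based <- k %in% c(1, 2, 3, 6, 9, 10, 11)
  stat_fun <- if (k == 11) stats::median else mean

  if (pathway_based) {
    member_bmds <- lapply(point$entities, function(pw) {
      mem <- intersect(input$pathways[[pw]], gt$gene)
      b <- gt$bmd[match(mem, gt$gene)]
      b[is.finite(b)]
    })
    member_bmds <- Filter(length, member_bmds)
    draw <- function() {
      pws <- vapply(member_bmds, function(b)
        mean(b[sample.int(length(b), replace = TRUE)]), numeric(1))
      stat_fun(pws)
    }
  } else {
    bmds <- gt$bmd[match(point$entities, gt$gene)]
    bmds <- bmds[is.finite(bmds)]
    draw <- function() mean(bmds[sample.int(length(bmds), replace = TRUE)])
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(B), function(i) draw(), numeric(1))

  m <- mean(reps)
  s <- stats::sd(reps)
  list(approach = k, status = "available", B = B, seed = seed,
       estimate = point$bmd, mean = m, sd = s,
       cv = if (m != 0) s / m else 0,
       percentiles = stats::quantile(reps,
         c(0.025, 0.1, 0.25, 0.5, 0.75, 0.9, 0.975)))
}

#' Bootstrap summaries for all approaches
#'
#' The bootstrap mean is the reported transcriptomic POD for approaches
#' 1-10 (it has lower variance than the median); approach 11 reports the
#' bootstrap mean of its median statistic.
#'
#' @inheritParams bootstrap_approach
#' @return data frame, one row per approach: `approach`, `status`,
#'   `estimate`, `boot_mean`, `boot_sd`, `cv`.
#' @export
bootstrap_all_approaches <- function(input, B = 2000, seed = 1L) {
  res <- lapply(1:11, function(k)
    bootstrap_approach(k, input, B, seed = seed + k))
  data.frame(
    approach = 1:11,
    status = vapply(res, `[[`, character(1), "status"),
    estimate = vapply(res, `[[`, numeric(1), "estimate"),
    boot_mean = vapply(res, `[[`, numeric(1), "mean"),
    boot_sd = vapply(res, `[[`, numeric(1), "sd"),
    cv = vapply(res, `[[`, numeric(1), "cv")
  )
}
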