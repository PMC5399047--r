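# Per-gene workflow: selection cascade, Hill flag rule, fallback halving,
# post-filters.

test_that("a clean linear gene selects linear and lands near its true BMD", {
  spec <- list(family = "linear", pars = c(b0 = 5, b1 = 1.349 * 0.2 / 10))
  dat <- make_gene_data(spec, sigma = 0.1, seed = 41)
  r <- fit_gene(dat$dose, dat$y, compute_bmdl = FALSE)
  expect_equal(r$record$family, "linear")
  expect_equal(r$record$excluded_reason, "none")
  tb <- true_bmd(spec, sigma = 0.1)
  expect_lt(abs(log2(r$record$bmd / tb)), 1)
})

test_that("a flat gene yields no viable model or no BMD", {
  set.seed(55)
  d <- rep(base_doses, each = 6)
  y <- rnorm(length(d), 5, 0.2)
  r <- fit_gene(d, y, compute_bmdl = FALSE)
  expect_true(is.na(r$record$bmd) || r$record$bmd > 75 ||
                r$record$excluded_reason != "none" || r$record$gof_p > 0.1)
})

test_that("the AIC step picks hill when hill clearly wins", {
  spec <- list(family = "hill", pars = c(g = 6, v = 2, k = 5, n = 4))
  dat <- make_gene_data(spec, n_reps = 10, sigma = 0.1, seed = 43)
  r <- fit_gene(dat$dose, dat$y, compute_bmdl = FALSE)
  aics <- vapply(r$fits, `[[`, numeric(1), "aic")
  expect_lt(aics["hill"], aics["linear"] - 2)
  expect_equal(r$record$family, "hill")
})

test_that("Hill flag fires below one third of the lowest positive dose", {
  mk <- function(k) {
    list(record = data.frame(family = "hill", bmd = 3, bmdl = 2, gof_p = 0.5,
                             hill_k = k, hill_flagged = FALSE,
                             fallback_halved = FALSE, excluded_reason = "none",
                             stringsAsFactors = FALSE),
         fits = list(power = NULL), chosen_poly = NULL)
  }
  # lowest positive dose 2.5: threshold 0.8333
  rec <- apply_hill_flag(mk(0.5), 2.5, fallback_bmd = 4.0, fallback_bmdl = 3.0)
  expect_true(rec$hill_flagged)
  expect_true(rec$fallback_halved)
  expect_equal(rec$bmd, 2.0)   # 4.0 * 0.5
  expect_equal(rec$bmdl, 1.5)
  # k above the threshold: untouched
  rec2 <- apply_hill_flag(mk(0.9), 2.5, fallback_bmd = 4.0)
  expect_false(rec2$hill_flagged)
  expect_equal(rec2$bmd, 3)
  # flagged with no alternative and no fallback: no viable model
  rec3 <- apply_hill_flag(mk(0.5), 2.5, fallback_bmd = NULL)
  expect_equal(rec3$excluded_reason, "no_viable_model")
  expect_true(is.na(rec3$bmd))
})

test_that("a flagged hill substitutes the next best model passing GOF 0.05", {
  # construct a gene where hill fits with tiny k but power fits acceptably
  spec <- list(family = "power", pars = c(g = 5, b = 0.05, delta = 1))
  dat <- make_gene_data(spec, sigma = 0.15, seed = 47)
  r <- fit_gene(dat$dose, dat$y, compute_bmdl = FALSE)
  # force the flag path regardless of what was selected
  r$record$family <- "hill"
  r$record$hill_k <- 0.1
  rec <- apply_hill_flag(r, 2.5, fallback_bmd = 99, compute_bmdl = FALSE)
  expect_true(rec$hill_flagged)
  expect_false(rec$fallback_halved)        # alternative found, no halving
  expect_true(rec$family %in% c("power", "linear", "poly2", "poly3"))
  expect_gt(rec$gof_p, 0.05)
})

test_that("post-filters remove the three violation classes and collapse probes", {
  rec <- data.frame(
    gene = sprintf("p%02d", 1:10),
    family = "linear",
    bmd = c(5, 5, 80, 5, 5, 5, 5, 5, 5, 6),
    bmdl = 4,
    gof_p = c(0.5, 0.5, 0.5, 0.05, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    hill_k = NA_real_, hill_flagged = FALSE, fallback_halved = FALSE,
    excluded_reason = "none", stringsAsFactors = FALSE
  )
  ann <- data.frame(probe = c(sprintf("p%02d", 1:10), "p02"),
                    gene = c("gA", "gB", "gC", "gD", "gE", "gF", "gG", "gH",
                             "gI", "gI", "gX"))  # p02 promiscuous
  out <- postfilter_gene_table(rec, max_dose = 75, probe_annotation = ann)
  expect_equal(unname(out$removed[c("promiscuous_probe", "bmd_above_max_dose",
                                    "gof_below_0.1")]), c(1L, 1L, 1L))
  expect_equal(sum(out$removed), 3)
  # p09 (gI, bmd 5) and p10 (gI, bmd 6) collapse to mean 5.5
  expect_equal(out$table$bmd[out$table$gene == "gI"], 5.5)
  expect_false(any(out$table$bmd > 75))
})

test_that("flag-handled records are exempt from the 0.1 GOF removal gate", {
  rec <- data.frame(
    gene = c("a", "b"), family = c("power", "linear"),
    bmd = c(5, 5), bmdl = c(4, 4), gof_p = c(0.07, 0.07),
    hill_k = NA_real_, hill_flagged = c(TRUE, FALSE),
    fallback_halved = FALSE, excluded_reason = "none",
    stringsAsFactors = FALSE
  )
  out <- postfilter_gene_table(rec, max_dose = 75)
  expect_true("a" %in% out$table$gene)    # substituted at the 0.05 gate
  expect_false("b" %in% out$table$gene)   # never flagged: 0.1 gate applies
})

test_that("estimated BMDs track true BMDs across a simulated gene set", {
  cfg <- sim_config(n_genes = 150, frac_responsive = 0.4, sigma = 0.2,
                    bmd_range = c(2.5, 40), seed = 23)
  st <- simulate_study(cfg)
  resp <- st$truth$gene[st$truth$responsive]
  tab <- fit_gene_table(st$expression, st$sample_meta$dose, resp,
                        compute_bmdl = FALSE)
  pf <- postfilter_gene_table(tab, max_dose = 75)
  m <- merge(pf$table, st$truth[, c("gene", "true_bmd")], by = "gene")
  m <- m[is.finite(m$bmd) & is.finite(m$true_bmd), ]
  expect_gt(nrow(m), 30)
  expect_gt(cor(m$bmd, m$true_bmd, method = "spearman"), 0.8)
  expect_false(any(pf$table$bmd > 75))
})
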