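# Synthetic study generator: exactness at zero noise, truth consistency,
# determinism and null calibration.

test_that("zero-noise simulation reproduces the model mean exactly", {
  m <- simulate_gene(list(family = "linear", pars = c(b0 = 2, b1 = 0.5)),
                     doses = c(0, 1, 2), n_reps = 3, sigma = 0)
  expect_equal(unname(m), matrix(rep(c(2, 2.5, 3), each = 3), 3))
  # hill at d = k gives half-maximum
  h <- simulate_gene(list(family = "hill", pars = c(g = 0, v = 1, k = 2, n = 1)),
                     doses = 2, n_reps = 1, sigma = 0)
  expect_equal(as.numeric(h), 0.5)
})

test_that("Monte-Carlo mean matches the analytic mean within 3 SE", {
  set.seed(123)
  m <- simulate_gene(list(family = "linear", pars = c(b0 = 2, b1 = 0.5)),
                     doses = 4, n_reps = 1e4, sigma = 0.4)
  se <- 0.4 / sqrt(1e4)
  expect_lt(abs(mean(m) - 4), 3 * se)
})

test_that("true_bmd matches closed forms and returns none for flat models", {
  expect_equal(true_bmd(list(family = "linear", pars = c(b0 = 0, b1 = 0.5)),
                        sigma = 0.4, bmr = 1.349), 1.0792, tolerance = 1e-4)
  expect_equal(true_bmd(list(family = "hill",
                             pars = c(g = 0, v = 1, k = 2, n = 1)),
                        sigma = 0.1, bmr = 1.349), 0.3119, tolerance = 1e-4)
  expect_true(is.na(true_bmd(list(family = "linear", pars = c(b0 = 1, b1 = 0)),
                             sigma = 0.4)))
})

test_that("simulate_study is deterministic given the seed", {
  cfg <- sim_config(n_genes = 50, n_pathways = 5, pathway_size = 8, seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$truth$true_bmd, s2$truth$true_bmd)
  expect_identical(s1$apical_dichotomous, s2$apical_dichotomous)
})

test_that("study dimensions follow the design and membership is valid", {
  cfg <- sim_config(n_genes = 80, n_pathways = 6, pathway_size = 10, seed = 1)
  st <- simulate_study(cfg)
  expect_equal(ncol(st$expression), 6 * 6)  # 6 doses x 6 reps
  expect_equal(nrow(st$expression), 80)
  expect_true(all(unlist(st$pathways) %in% rownames(st$expression)))
  # every responsive gene has a finite true BMD in (0, max dose]
  tb <- st$truth$true_bmd[st$truth$responsive]
  expect_true(all(is.finite(tb) & tb > 0 & tb <= 75))
  expect_true(all(is.na(st$truth$true_bmd[!st$truth$responsive])))
})

test_that("recorded truth BMDs equal true_bmd recomputed from the model", {
  cfg <- sim_config(n_genes = 100, frac_responsive = 0.5, seed = 17)
  st <- simulate_study(cfg)
  idx <- which(st$truth$responsive)
  for (i in idx) {
    spec <- list(family = st$truth$family[i], pars = st$truth$params[[i]])
    expect_equal(true_bmd(spec, sigma = cfg$sigma, bmr = 1.349),
                 st$truth$true_bmd[i], tolerance = 1e-9)
  }
})

test_that("null studies give uniform ANOVA p values", {
  cfg <- sim_config(n_genes = 500, frac_responsive = 0, seed = 5)
  st <- simulate_study(cfg)
  sc <- screen_genes(st$expression, st$sample_meta$dose,
                     n_permutations = 100, seed = 1)
  ks <- ks.test(sc$p_anova, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("apical generators honor their stated truth", {
  set.seed(3)
  # degenerate dichotomous rates
  ap <- simulate_apical("dichotomous",
                        params = list(probs = c(0, 1, 1, 1), bmd = NULL),
                        doses = c(0, 5, 10, 20), n_per_group = 10)
  expect_equal(ap$x, c(0, 10, 10, 10))
  # extra risk 0.10 at dose 5 by construction
  ap2 <- simulate_apical("dichotomous",
                         params = list(background = 0.05, bmd = 5, bmr = 0.1,
                                       slope = 2),
                         doses = c(0, 2.5, 5, 10, 25), n_per_group = 50)
  expect_equal(attr(ap2, "true_bmd"), 5)
  er5 <- (ap2$p_true[3] - ap2$p_true[1]) / (1 - ap2$p_true[1])
  expect_equal(er5, 0.1, tolerance = 1e-12)
  # continuous zero-effect endpoint has no BMD
  ap3 <- simulate_apical("continuous",
                         params = list(family = "linear",
                                       pars = c(b0 = 10, b1 = 0), sd = 1),
                         doses = c(0, 5, 10), n_per_group = 6)
  expect_true(is.na(attr(ap3, "true_bmd")))
  expect_error(simulate_apical("continuous",
                               params = list(family = "linear",
                                             pars = c(b0 = 1, b1 = 1), sd = 1),
                               doses = c(0, 1), n_per_group = 0), "n_per_group")
})

test_that("write_study round-trips expression and gene sets as text", {
  cfg <- sim_config(n_genes = 30, n_pathways = 3, pathway_size = 5, seed = 2)
  st <- simulate_study(cfg)
  dir <- tempfile("study")
  paths <- write_study(st, dir)
  em <- read.delim(paths["expression"], check.names = FALSE)
  expect_equal(nrow(em), 30)
  expect_equal(as.matrix(em[, -1]), unname(st$expression),
               ignore_attr = TRUE, tolerance = 1e-12)
  pw <- read_gmt(paths["pathways"])
  expect_identical(pw, st$pathways)
})
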