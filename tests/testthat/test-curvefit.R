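# Model fitting engine: identifiability, model selection, goodness of fit,
# and the likelihood identities the downstream cascade relies on.

test_that("noiseless linear data are recovered exactly and sigma is ~0", {
  d <- rep(base_doses, each = 4)
  y <- 2 + 0.5 * d
  f <- dr_fit(d, y, "linear")
  expect_true(f$converged)
  expect_equal(unname(f$pars), c(2, 0.5), tolerance = 1e-6)
  expect_lt(f$sigma, 1e-8)
})

test_that("hill parameters are recovered within 10% on clean simulated data", {
  spec <- list(family = "hill", pars = c(g = 6, v = 2, k = 10, n = 2))
  dat <- make_gene_data(spec, n_reps = 10, sigma = 0.05, seed = 11)
  f <- dr_fit(dat$dose, dat$y, "hill")
  expect_true(f$converged)
  expect_equal(unname(f$pars[["g"]]), 6, tolerance = 0.1)
  expect_equal(unname(f$pars[["v"]]), 2, tolerance = 0.1)
  expect_equal(unname(f$pars[["k"]]), 10, tolerance = 0.1)
})

test_that("logistic dichotomous fit recovers its own curve at large n", {
  doses <- c(0, 10, 50, 200)
  pars <- c(a = -3, b = 0.02)
  p_true <- dr_mean("logistic", pars, doses)
  set.seed(5)
  dat <- data.frame(dose = doses, n = 1000,
                    x = rbinom(length(doses), 1000, p_true))
  f <- dr_fit(NULL, dat, "logistic")
  expect_true(f$converged)
  p_fit <- dr_mean("logistic", f$pars, doses)
  expect_true(all(abs(p_fit - p_true) < 0.02))
})

test_that("AIC identity holds for every fit", {
  dat <- make_gene_data(list(family = "linear", pars = c(b0 = 5, b1 = 0.05)),
                        seed = 3)
  for (fam in c("linear", "poly2", "poly3", "power", "hill")) {
    f <- dr_fit(dat$dose, dat$y, fam)
    expect_equal(f$aic, 2 * f$npar - 2 * f$loglik, tolerance = 1e-10)
  }
})

test_that("nested families satisfy likelihood monotonicity", {
  dat <- make_gene_data(list(family = "hill", pars = c(g = 6, v = 1.5, k = 10, n = 2)),
                        seed = 7)
  fl <- dr_fit(dat$dose, dat$y, "linear")
  f2 <- dr_fit(dat$dose, dat$y, "poly2")
  f3 <- dr_fit(dat$dose, dat$y, "poly3")
  expect_gte(f2$loglik, fl$loglik - 1e-6)
  expect_gte(f3$loglik, f2$loglik - 1e-6)
})

test_that("goodness-of-fit statistic equals the brute-force saturated LR", {
  dat <- make_gene_data(list(family = "linear", pars = c(b0 = 5, b1 = 0.03)),
                        seed = 9)
  f <- dr_fit(dat$dose, dat$y, "linear")
  g <- dr_gof(f)
  # brute force: evaluate both likelihoods directly from replicate data
  groups <- factor(dat$dose)
  gm <- tapply(dat$y, groups, mean)
  N <- length(dat$y)
  sse_sat <- sum((dat$y - gm[as.integer(groups)])^2)
  ll_sat <- -N / 2 * (log(2 * pi * sse_sat / N) + 1)
  mu <- dr_mean("linear", f$pars, dat$dose)
  sse_mod <- sum((dat$y - mu)^2)
  ll_mod <- -N / 2 * (log(2 * pi * sse_mod / N) + 1)
  expect_equal(g$stat, 2 * (ll_sat - ll_mod), tolerance = 1e-6)
  expect_equal(g$df, 6 - 2)
})

test_that("a linear fit to strongly sigmoidal group means is GOF-rejected", {
  doses <- base_doses
  mu <- c(5, 5, 5, 7, 7, 7)  # step shape no line can track
  set.seed(21)
  d <- rep(doses, each = 6)
  y <- rep(mu, each = 6) + rnorm(length(d), 0, 0.1)
  f <- dr_fit(d, y, "linear")
  expect_lt(dr_gof(f)$p, 0.1)
})

test_that("saturated model reports GOF p = 1", {
  # poly3 on 4 dose groups: 4 mean parameters, df = 0
  d <- rep(c(0, 5, 10, 25), each = 5)
  set.seed(2)
  y <- 5 + 0.02 * d + rnorm(length(d), 0, 0.2)
  f <- dr_fit(d, y, "poly3")
  g <- dr_gof(f)
  expect_equal(g$df, 0)
  expect_equal(g$p, 1)
})

test_that("nested LR selection prefers linear on linear data and poly2 on exact quadratic", {
  # exact quadratic, noiseless: infinite LR in favor of poly2
  d <- rep(base_doses, each = 4)
  yq <- 1 + 0.1 * d + 0.05 * d^2
  ch <- nested_lr_select(dr_fit(d, yq, "linear"), dr_fit(d, yq, "poly2"),
                         dr_fit(d, yq, "poly3"))
  expect_true(ch$family %in% c("poly2", "poly3"))
  expect_gt(ch$n_mean_par, 2)

  # LR statistic equals 2 * delta loglik recomputed independently
  dat <- make_gene_data(list(family = "linear", pars = c(b0 = 2, b1 = 0.02)),
                        seed = 13)
  fl <- dr_fit(dat$dose, dat$y, "linear")
  f2 <- dr_fit(dat$dose, dat$y, "poly2")
  stat <- 2 * (f2$loglik - fl$loglik)
  N <- length(dat$y)
  stat_oracle <- N * log(fl$sse / f2$sse)
  expect_equal(stat, stat_oracle, tolerance = 1e-6)

  # selection simulation: linear-generated data keep linear most of the time
  picks <- vapply(1:40, function(i) {
    dat <- make_gene_data(list(family = "linear", pars = c(b0 = 2, b1 = 0.05)),
                          sigma = 0.2, seed = 100 + i)
    nested_lr_select(dr_fit(dat$dose, dat$y, "linear"),
                     dr_fit(dat$dose, dat$y, "poly2"),
                     dr_fit(dat$dose, dat$y, "poly3"))$family
  }, character(1))
  expect_gte(mean(picks == "linear"), 0.8)
})

test_that("dose-scale equivariance and response-shift invariance of the BMD", {
  spec <- list(family = "hill", pars = c(g = 6, v = 2, k = 10, n = 2))
  dat <- make_gene_data(spec, sigma = 0.1, seed = 17)
  f1 <- dr_fit(dat$dose, dat$y, "hill")
  b1 <- bmd_from_fit(f1, 1.349)
  # multiply doses by c
  f2 <- dr_fit(dat$dose * 3, dat$y, "hill")
  b2 <- bmd_from_fit(f2, 1.349)
  expect_equal(b2 / b1, 3, tolerance = 1e-3)
  # add a constant to responses
  f3 <- dr_fit(dat$dose, dat$y + 100, "hill")
  b3 <- bmd_from_fit(f3, 1.349)
  expect_equal(b3, b1, tolerance = 1e-3)
})

test_that("degenerate designs error and non-convergence is flagged not raised", {
  expect_error(dr_fit(rep(0, 6), rnorm(6), "linear"), "degenerate")
  # 3 dose groups cannot support a 4-parameter hill: flagged result
  d <- rep(c(0, 5, 25), each = 4)
  f <- dr_fit(d, 5 + 0.01 * d + rnorm(12, 0, 0.1), "hill")
  expect_false(f$converged)
  expect_s3_class(f, "dr_fit")
})
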