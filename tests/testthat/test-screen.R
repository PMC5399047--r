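# Gene screening: ANOVA, Fs shrinkage statistic, BH adjustment, LS-mean
# fold changes, and the two filter modes.

test_that("one-way ANOVA matches the sums-of-squares oracle and aov", {
  set.seed(4)
  y <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(letters[1:3], each = 3)
  a <- one_way_anova(y, g)
  o <- anova_oracle(y, g)
  expect_equal(a$F, o$F, tolerance = 1e-12)
  expect_equal(a$p, o$p, tolerance = 1e-12)
  ref <- summary(aov(y ~ factor(g)))[[1]]
  expect_equal(a$F, ref[["F value"]][1], tolerance = 1e-10)
})

test_that("two-group ANOVA F equals the squared equal-variance t statistic", {
  set.seed(8)
  y <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  a <- one_way_anova(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("identical values in all groups give F = 0, p = 1", {
  a <- one_way_anova(rep(7, 12), rep(1:3, each = 4))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_error(one_way_anova(c(1, 2), c("a", "b")), "residual")
})

test_that("Fs equals ordinary F when all genes share residual variance", {
  # same within-group deviations for every gene -> identical residual
  # variances -> shrinkage no-op
  g <- rep(1:3, each = 4)
  base_dev <- c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1) * 0.5
  mat <- rbind(5 + base_dev + rep(c(0, 1, 2), each = 4),
               3 + base_dev + rep(c(0, 0.5, 1), each = 4),
               8 + base_dev)
  rownames(mat) <- c("a", "b", "c")
  fs <- fs_statistic(mat, g, n_permutations = 100, seed = 1)
  f_ord <- apply(mat, 1, function(y) one_way_anova(y, g)$F)
  expect_equal(fs$Fs, unname(f_ord), tolerance = 1e-9)
})

test_that("permutation p has the add-one floor for an extreme gene", {
  set.seed(12)
  g <- rep(1:4, each = 5)
  mat <- matrix(rnorm(50 * 20, 0, 0.3), 50)
  mat[1, ] <- mat[1, ] + rep(c(0, 2, 4, 6), each = 5)  # huge effect
  rownames(mat) <- paste0("g", 1:50)
  B <- 200
  fs <- fs_statistic(mat, g, n_permutations = B, seed = 2)
  expect_equal(fs$p_perm[1], 1 / (1 + B))
  expect_true(all(fs$p_perm >= 1 / (1 + B)))
})

test_that("null permutation p values are approximately uniform", {
  set.seed(42)
  g <- rep(1:6, each = 6)
  mat <- matrix(rnorm(400 * 36), 400)
  rownames(mat) <- paste0("g", 1:400)
  fs <- fs_statistic(mat, g, n_permutations = 200, seed = 3)
  frac05 <- mean(fs$p_perm <= 0.05)
  # binomial 99% bounds around 0.05 with n = 400
  expect_lt(abs(frac05 - 0.05), 2.58 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("BH adjustment equals the step-up oracle and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("LS-mean fold changes are group-mean differences on log2 scale", {
  g <- rep(c(0, 5, 10), each = 4)
  y <- c(rep(5, 4), rep(5.585, 4), rep(5, 4))
  fc <- ls_mean_fold_changes(y, g, control = "0")
  expect_equal(fc$l2fc[fc$dose == "5"], 0.585)
  expect_equal(fc$fc[fc$dose == "5"], 2^0.585, tolerance = 1e-9)
  expect_equal(abs(fc$fc[fc$dose == "5"]), 1.5, tolerance = 0.01)
  expect_equal(fc$fc[fc$dose == "10"], 1)  # no change
  # unbalanced design: LS mean still the unweighted group mean; equals the
  # normal-equations solution of the one-factor regression
  y2 <- c(1, 2, 3, 10, 12)
  g2 <- c("0", "0", "0", "5", "5")
  fc2 <- ls_mean_fold_changes(y2, g2, control = "0")
  fit <- lm(y2 ~ factor(g2))
  expect_equal(fc2$l2fc, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("filter thresholds behave as documented at the boundaries", {
  rec <- data.frame(gene = c("a", "b", "c"),
                    p_anova = c(0.01, 0.2, 0.05),
                    fdr_p = c(0.01, 0.01, 0.2),
                    max_abs_fc = c(1.6, 1.4, 3))
  expect_equal(filter_genes(rec, "conservative"), "a")   # b fails FC, c fails FDR
  expect_equal(filter_genes(rec, "liberal"), c("a", "c"))  # <= 0.05 inclusive
})

test_that("a null study retains about 5% of genes under the liberal filter", {
  cfg <- sim_config(n_genes = 600, frac_responsive = 0, seed = 99)
  st <- simulate_study(cfg)
  sc <- screen_genes(st$expression, st$sample_meta$dose,
                     n_permutations = 100, seed = 1)
  frac <- mean(sc$pass_liberal)
  expect_lt(abs(frac - 0.05), 2.58 * sqrt(0.05 * 0.95 / 600) + 0.01)
})

test_that("both filters retain strong true effects", {
  # genes whose effect exceeds 4 sigma at high dose
  cfg <- sim_config(n_genes = 300, frac_responsive = 0.2,
                    bmd_range = c(2.5, 8), sigma = 0.2, seed = 7)
  st <- simulate_study(cfg)
  sc <- screen_genes(st$expression, st$sample_meta$dose,
                     n_permutations = 200, seed = 2)
  resp <- st$truth$gene[st$truth$responsive]
  # restrict to genes with a >= 4 sigma shift at the top dose
  shift <- vapply(which(st$truth$responsive), function(i) {
    sp <- list(family = st$truth$family[i], pars = st$truth$params[[i]])
    abs(dr_mean(sp$family, sp$pars, 75) - dr_mean(sp$family, sp$pars, 0))
  }, numeric(1))
  strong <- resp[shift >= 4 * 0.2]
  cons <- filter_genes(sc, "conservative")
  lib <- filter_genes(sc, "liberal")
  expect_gte(mean(strong %in% cons), 0.95)
  expect_gte(mean(strong %in% lib), 0.95)
})
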