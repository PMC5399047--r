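# Shared fixture builders (all data generated in code).

base_doses <- c(0, 2.5, 5, 10, 25, 75)

# replicate-level continuous data from a generating model
make_gene_data <- function(spec, doses = base_doses, n_reps = 6, sigma = 0.2,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- rep(doses, each = n_reps)
  y <- as.vector(simulate_gene(spec, doses, n_reps, sigma))
  list(dose = d, y = y)
}

# brute-force one-way ANOVA from sums of squares
anova_oracle <- function(y, g) {
  g <- as.factor(g)
  gm <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  k <- nlevels(g); n <- length(y)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# brute-force BH step-up: min over j >= i of m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force right-tail hypergeometric sum
hyper_tail_oracle <- function(q, K, N, n) {
  sum(dhyper(q:min(K, n), K, N - K, n))
}

# small pathway DB for approach tests
toy_gene_table <- function(bmds, bmdls = bmds * 0.8) {
  data.frame(gene = sprintf("g%02d", seq_along(bmds)), bmd = bmds, bmdl = bmdls)
}
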