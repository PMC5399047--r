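---
title: "Deriving transcriptomic points of departure: models, rules and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving transcriptomic points of departure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`txpod` turns a dose–response gene expression study into a candidate point
of departure (POD) for risk assessment. This vignette is the package's own
account of the science: the models and their assumptions, the constants
that matter, what the synthetic generator does and does not emulate, and
the decisions taken where the workflow's published descriptions leave the
design open.

## 1. The per-gene dose–response model

Log2 expression of each screened gene is modeled as Gaussian with a mean
that depends on dose and a single residual variance shared across dose
groups:

* **linear** $\mu(d) = \beta_0 + \beta_1 d$
* **polynomial 2°/3°** $\mu(d) = \beta_0 + \beta_1 d + \beta_2 d^2 (+ \beta_3 d^3)$
* **power** $\mu(d) = \gamma + \beta d^\delta$, $\delta \ge 1$
* **Hill** $\mu(d) = \gamma + \nu d^n / (k^n + d^n)$, $k > 0$, $n \ge 1$

The constant-variance assumption is what makes a standard-deviation-based
benchmark response meaningful: the benchmark dose is the smallest $d$ with
$|\mu(d) - \mu(0)| = \mathrm{BMR}\cdot\hat\sigma$, with BMR = 1.349
residual SDs by default (the conventional value corresponding to a 2%
shift in the tail of a normal population at the 1% level). Linear, power
and Hill inversions are closed form; polynomials use bracketed root
finding with relative tolerance 1e-8, and a crossing beyond ten times the
highest dose is treated as absent.

Because the likelihood is Gaussian with the variance profiled out, fitting
minimizes the pooled error sum of squares. Group summaries (n, mean, SD)
are sufficient statistics, so the same engine fits replicate-level gene
data and summary-level apical endpoints exactly. Optimization is bounded
quasi-Newton (L-BFGS-B, 250-iteration cap) from several moment-based
starting points, followed by a Nelder-Mead polish; the restart table is a
fixed set of multipliers rather than random jitter, so fits are
bit-reproducible without touching the caller's RNG state. Doses are
rescaled to $[0,1]$ internally to keep power/Hill exponents
well-conditioned, and parameters are reported on the original scale.
Non-convergence is recorded in the fit object, never raised.

### Model selection cascade

1. Linear vs polynomial 2° vs 3° by step-up nested likelihood-ratio tests
   at $\alpha = 0.05$.
2. The winner competes with Hill and Power on AIC
   ($\mathrm{AIC} = 2k - 2\ell$, $k$ counting mean parameters plus
   $\sigma$); ties go to fewer parameters.
3. The selected model must pass a goodness-of-fit test against the
   saturated group-means model at $p > 0.1$ (likelihood ratio,
   $\chi^2$ with df = groups − mean parameters; a saturated fit reports
   $p = 1$, negative df is "not testable").

A Hill fit whose half-maximum parameter $k$ falls below one third of the
lowest positive dose is *flagged*: its BMD hinges on curvature below the
observed dose range. A flagged gene takes the next-best (by AIC) non-Hill
model with GOF $p > 0.05$; failing that, the dataset-level fallback
applies — half of the lowest BMD among the study's unflagged Hill fits
(BMDL halved by the same 0.5 factor; the halving factor and the 1/3 flag
fraction are both configurable). The fallback is dataset-level rather than
per-gene because a flagged gene's own Hill fit is exactly the estimate the
rule distrusts. Flag-substituted records already passed their own 0.05
gate and are exempt from the later 0.1 removal filter; this ordering
(flag handling first, the 0.1 gate only for never-flagged records) is one
of the genuinely open corners of the published workflow and is fixed here
by documentation.

Post-filters then remove promiscuous probes (annotated to more than one
gene), BMDs above the highest tested dose, and never-flagged records with
GOF $p < 0.1$; surviving probes collapse to unique genes by averaging BMD
and BMDL (the mean matches the workflow's pervasive use of means; lowest
is available as an option).

### BMDL

The BMDL is a one-sided 95% profile-likelihood lower bound: the smallest
$b$ whose constrained maximum log-likelihood (subject to the BMD equation
holding at $b$) stays within $\chi^2_1(0.90)/2$ of the unconstrained
maximum. One parameter is eliminated analytically per family (e.g. linear
$\beta_1 = \mathrm{BMR}\,\sigma/b$; Hill
$\nu = \mathrm{BMR}\,\sigma\,(1 + (k/b)^n)$), and the remaining
parameters — including $\log\sigma$, since the SD-based BMR couples
$\sigma$ to the mean — are re-optimized at each candidate $b$ with warm
starts while the crossing is bisected to relative tolerance 1e-4. A
profile that cannot bracket the threshold reports "not computable", never
a number. The "confidence interval of 0.95" is read as one-sided 95%
(hence the 0.90 two-sided chi-square cutoff); simulation in the test suite
shows one-sided coverage of the true BMD near the nominal 95%.

## 2. Screening filters

Two pre-filters feed the BMD stage, mirroring common practice:

* **Conservative** (approaches 1, 2, 4, 5, 6, 7, 8): a shrinkage-variance
  *Fs* statistic — between-group mean square over a James–Stein-shrunken
  residual variance, with log variances shrunk toward their ensemble mean
  by weight $B = \min(1, (G-3)\,\psi_1(\nu/2)/\sum_g (x_g-\bar x)^2)$
  where $\psi_1(\nu/2)$ is the sampling variance of a log chi-square
  variance estimate — with permutation p values (pooled within-gene
  residuals shuffled across samples, add-one rule, floor $1/(1+B)$),
  Benjamini–Hochberg adjustment, FDR $\le 0.05$, and max linear fold
  change $\ge 1.5$ from least-squares means. When all genes share a
  residual variance the shrinkage is a no-op and Fs equals ordinary F.
* **Liberal** (approaches 3, 9, 10, 11): unadjusted one-way ANOVA
  $p \le 0.05$.

Threshold semantics are standardized on $\le$ (the source descriptions mix
strict and inclusive forms); all cutoffs are configurable in
`run_config()`.

## 3. Pathways and the eleven rules

Gene sets come from user-supplied GMT files — canonical pathway and
upstream-regulator content is deliberately generic, replacing proprietary
knowledge bases. Two right-tailed Fisher exact tests are reported per
pathway: `p_deg` (DEG set vs the platform universe) and `p_bmd` (the
BMD-carrying gene set vs the same platform universe — the conventional
test with the BMD list in place of the DEG list; restricting the universe
to prefiltered genes removes nearly all contrast, because most prefiltered
genes carry BMDs). A pathway receives a BMD — the mean of its member
genes' BMDs — only with at least four scored members. "Top 20" selections
break ties by identifier (and by smaller BMD first for approach 7's
membership counts) so reruns are deterministic.

The rules: (1) 20 enriched pathways with lowest BMDs; (2) 20 most
significantly enriched; (3) 20 lowest pathway BMDs, liberal filter, no
enrichment gate (the rule's stated rationale is independence from
enrichment); (4) 20 largest-fold-change genes with surviving BMDs; (5)
genes inside the inclusive interquartile BMD band (linear-interpolation
quantiles); (6) 20 enriched pathways with most shared genes (sharing
counted among enriched pathways); (7) 20 genes in the most enriched
pathways; (8) union of the top-20 regulators' scored targets; (9) the
enriched pathway (by `p_bmd`) with the lowest BMD; (10) mean and (11)
median of all pathway BMDs. Pathway-set rules aggregate as the unweighted
mean of the selected pathways' BMDs. Fewer than 20 qualifying entities are
used in full and flagged partial; zero yields an explicit "unavailable"
status (as happens for enrichment-gated rules in studies with no
significant pathways) rather than an error.

## 4. Bootstrap uncertainty

Each rule's statistic is bootstrapped by resampling *gene BMDs* with
replacement — within each selected pathway for pathway rules, within the
selected gene set otherwise — holding the selection itself fixed; 2000
replicates by default, deterministic per seed. The bootstrap mean is the
reported POD (it is less variable than the median); the coefficient of
variation summarizes dispersion. Resampling the selection step too is
exposed as an option but not the default, since the statistic being
summarized is conditional on the selected set.

## 5. Apical endpoints and concordance

Continuous apical endpoints (organ weights) are fit with Exponential 4/5,
Hill, Power, Polynomial and Linear at BMR = 1 SD (distinct from the
transcriptomic 1.349 — the conventional default for apical continuous
data; configurable); incidence data with the eight-model dichotomous suite
at 0.10 extra risk. A fit is *viable* when it converges, has a testable
GOF with $p \ge 0.1$ (saturated fits are not viable), a computable BMDL, a
BMD at or below the highest remaining dose, and BMD/BMDL < 20; among
viable fits the lowest AIC wins when BMDLs span ≤ 3-fold, otherwise the
lowest BMDL. With no viable model the highest dose is dropped and the
suite refit, failing once only three groups remain. These viability rules
reconstruct standard recommendation logic from public guidance; the exact
internal tables of the original wizard software are not public.

Dietary ppm units convert to mg/kg-day via strain/sex food-intake factors
(F344 female 0.113, male 0.1; registry extendable). Concordance of each
rule's PODs with apical PODs across chemicals uses three criteria with
strict boundaries: mean per-chemical ratio < 3; Pearson correlation of
log10 values with $p < 0.05$; and a likelihood-ratio test of the 1:1 line
($y = x$) against the free regression line with $p > 0.05$. The LR
statistic is $n\ln(\mathrm{RSS}_0/\mathrm{RSS}_1)$ with 2 degrees of
freedom. At the $n \approx 6$ chemicals typical of such comparisons the
asymptotic $\chi^2_2$ reference over-rejects badly (~13% at nominal 5% in
simulation), so the default p value uses the exact small-sample reference:
the statistic is a monotone transform of
$F = ((\mathrm{RSS}_0-\mathrm{RSS}_1)/2)/(\mathrm{RSS}_1/(n-2))$, which is
$F(2, n-2)$ exactly under the Gaussian null. The asymptotic p value is
reported alongside as `p_chisq`. Log base cancels in both the correlation
and the LR statistic. Criterion 1 uses the mean of per-chemical ratios
(not the ratio of means); descriptive fold-band counts are two-sided
(1/3 to 3).

## 6. The synthetic-study generator

`simulate_study()` emulates a subchronic rodent transcriptomic design:
doses 0, 2.5, 5, 10, 25, 75 (mg/kg-day scale), six replicates per group,
i.i.d. Gaussian noise on log2 expression (σ = 0.2 default), a minority of
responsive genes (15% default) whose true BMDs are sampled log-uniformly
over `bmd_range` (default 2.5–50, so aggregation rules face a spread of
sensitivities without clustering artifacts), response direction a random
sign per gene (the BMR is defined on the absolute shift), and generating
curves drawn from the same Hill/linear/power families the fitter uses —
with Hill amplitudes anchored so the 1.349σ crossing sits exactly at the
sampled BMD. The first fifth of pathways and regulator target sets are
"designed enriched", drawing members from the responsive pool at rate
`enrichment_frac` (0.7). Matched apical endpoints share the dose design:
continuous group summaries around a Hill mean curve with
chi-square-distributed group SDs, and binomial incidence from a
log-logistic curve anchored so the stated extra risk occurs at the stated
dose; transcriptomic and apical draws are independent given dose, since
within-animal correlation between the two is not characterized.

What the generator does **not** emulate: probe-level microarray artifacts,
batch effects, normalization residue, heteroscedastic or correlated noise,
and gene–gene correlation beyond pathway co-membership. Passing tests
therefore demonstrate that the pipeline recovers truth under its own
statistical assumptions — clean constant-variance Gaussian signal — not
that it is robust to everything real microarray data can do.

## 7. Problem sizes and numerical defaults

The shipped validation suite runs at a demo scale chosen to exercise every
code path: studies of 150–800 genes with 15–30 pathways for pipeline
tests, 200 genes per family for recovery checks, 500 simulations for BMDL
coverage, 10^4 simulations for test calibration, and a six-chemical
end-to-end suite (dose designs scaled 0.5–50×) for concordance. Full-scale
settings (thousands of genes, B = 2000 bootstraps) are one argument away
in `sim_config()`/`run_config()`. Other fixed numerics: BMD root tolerance
1e-8 (relative), BMDL profile refinement 1e-4, optimizer cap 250
iterations, permutation default B = 1000 with the add-one p-value floor.

## 8. Known limitations

* Constant-variance Gaussian likelihood only; no non-constant variance
  modeling for continuous data, no litter effects or covariates.
* No BMDU (upper bound); no Bayesian model averaging.
* Time points are independent runs; no joint time-course modeling.
* The upstream-regulator surrogate is pure overlap enrichment; curated
  activation scores and causal network structure are out of scope.
* The profile BMDL for polynomial fits imposes the BMD equation at the
  candidate dose without re-checking that it is the *smallest* crossing;
  for the monotone fits that dominate in practice the two coincide.
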