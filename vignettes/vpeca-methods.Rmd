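---
title: "vpeca: model, estimation and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vpeca: model, estimation and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpeca)
```

## The problem

Paired ATAC-seq and RNA-seq time courses from two populations — an
adaptive one and a wildtype one exposed to the same stimulus — carry
three kinds of information about gene regulation: which chromatin
regions open and close, which genes respond, and (via whole-genome
sequencing of the two populations) which variants show signatures of
positive selection. `vpeca` links the three: it infers which regulatory
elements (REs) are *active* (they contribute to a target gene's
expression model), which are *active and selected* (their activity is
additionally shifted in the adaptive population by selected variants),
and which TF–RE–target-gene triplets make up the regulatory network.

## Model components and their assumptions

For individual $i$, time $j$, RE $k$, gene $l$ and TF $m$:

$$TG_{ijl} = \beta_{l0} + \sum_{k \in I_l} \beta_{lk}\, Z_{ijk}
  \Big(\sum_{m \in MB_k} \gamma_m B_{km} \, TF_{ijm}\Big) + \varepsilon_l$$

$$Z_{ijk} = O_{ijk} + \alpha_k \delta_i S_k + \varepsilon_{z}, \qquad
  O_{ijk} = \eta_{jk} + \omega_{jk} \delta_i S_k + \varepsilon_{o}$$

$$\mathrm{logit}\, P(S_k = 1 \mid X, Y) = \mu_0 +
  \sum_{q=1}^{4} \mu_q \overline{w X}_{kq} + \mu_5 \overline{w Y}_k$$

where $\delta_i$ indicates the adaptive population, $S_k$ is the RE's
latent selection status, $B_{km}$ the (reference-genome, hence
individual-invariant) summed motif match strength, and
$\overline{w X}_{kq}$ the LD-weighted mean over the SNPs in the RE of
the $q$-th selection statistic (Fst, iHS, XP-EHH, PBS, each a
$-\log_{10} p$), with weights $w_p = 1/r_p$ (reciprocal LD score,
down-weighting redundant correlated SNPs) and $Y$ the derived-allele
frequency difference between the populations.

Key assumptions: activity is openness plus a population-and-selection
shift (never sampled — the plug-in conditional mean is substituted into
the expression model); TF input acts multiplicatively with RE activity;
selection evidence aggregates linearly on the logit scale; and errors
are Gaussian.

## Estimation

1. **Selection status.** Initialise $P(S_k{=}1) = p^0_k = 1 -
   \overline{c_p}$, the complement of the mean composite (Fisher-type)
   p-value of the RE's SNPs. Iterate: clip $P$ to
   $[10^{-6}, 1-10^{-6}]$, regress $\mathrm{logit} P$ on the aggregate
   features by OLS to get $\mu$, set $P$ to the sigmoid of the fitted
   linear predictor; stop when $\max|\Delta\mu| < 10^{-6}$ (at most 100
   iterations; non-convergence is reported, not hidden — it can occur
   when fitted logits sit at the clipping boundary). Calls are strict:
   $S_k = 1$ iff $P > 0.95$. REs without SNPs have $P = 0$ and never
   enter the regression: no evidence is treated as no signal.
2. **Accessibility.** Per (RE, time) with $S_k = 1$, OLS of openness on
   $[1, \delta]$; two-sided t-test on $\omega$ with $n-2$ df, flagged
   at $p < 0.05$ (raw, per the source procedure; BH across REs is
   available through `bh_fdr()` if wanted). For $S_k = 0$ the model
   reduces to the within-time mean. No pooling across time.
3. **Expression, per gene.** Stage 1 — LASSO of $TG$ on the per-RE
   products $O_k \times$ (prior-weighted TF feature), $\lambda$ by
   5-fold CV with folds stratified by (population, time) and assigned
   deterministically from the seed; the parsimonious `lambda.1se` rule
   is used. Stage 2 — with $\beta$ fixed, LASSO over the TFs with
   motifs on surviving REs. Stage 3 — quasi-Newton (BFGS, analytic
   gradient) minimisation of
   $\tfrac12\|r\|^2 - \beta_0^\top\beta - \gamma_0^\top\gamma +
   \tfrac12\|\beta\|^2 + \tfrac12\|\gamma\|^2$, with $\alpha_k$ free
   only where $S_k = 1$. A configurable scalar (default 1) multiplies
   the prior-plus-ridge block, since the source gives no scaling. The
   linear "reward" terms use the cross-context correlation priors
   $\beta_0$ (RE openness vs gene expression) and $\gamma_0$ (TF vs
   gene co-expression) computed over a panel of cellular contexts
   ($\ge 3$ required; constant rows get prior 0 and a flag).
   "Nonzero" means $|x| > 10^{-8}$ throughout.

Classification: ARE = nonzero $\beta$ in at least one gene model;
ASRE = ARE and $P(S{=}1) > 0.95$ and nonzero $\alpha$. Triplets
require nonzero $\beta$ and $\gamma$ plus a motif hit.

### Design choices where the procedure was open

- The intercept/prior name collision in stage 3 is resolved by treating
  the linear reward as the prior *vector* terms; the intercept is free
  and unpenalised.
- The $\mu$ loop never re-anchors to $p^0$ after initialisation.
- Laplacian sparsity on $\alpha$ is *not* added in stage 3: the printed
  objective penalises only $(\beta, \gamma)$, and we implement it as
  printed.
- Candidate boundaries: the $\pm 1$ Mb TSS window intersected with the
  smallest chromatin loop whose span contains the TSS (ties: leftmost
  start); loops wider than the window leave it unchanged. Coordinates
  are 0-based half-open throughout; promoters are the strand-aware 2 kb
  upstream of the TSS and are kept distinct from distal REs (flagged by
  class, never merged).
- Replicate-consistency filtering treats a replicate group with minimum
  0 and maximum > 0 as inconsistent (infinite max/min ratio).
- Missing individual selection scores are imputed as $p = 1$ before
  Fisher combination (flagged); the combination is unweighted; p-values
  are floored at $10^{-300}$.
- The nested individual term in the differential model is only
  estimable when individuals are observed repeatedly; aliased columns
  are dropped with a warning (reference coding), and the term is
  omitted for one-sample-per-individual designs.
- ME levels for the dynamic-TF filter use 7 equal-width bins over the
  observed range (the level scheme for expression is fixed at
  6/12/30/120); both are configurable.

## The synthetic world

`simulate_study()` draws a complete study from the generative equations
above on a 10 Mb toy chromosome: evenly spaced genes (promoter REs) plus
gridded distal REs reconstructed from emitted histone-mark interval
files, loops covering about half the TSSs so the boundary logic is
exercised both ways, sparse motif hits, SNPs placed inside REs with
shifted score distributions for the selected fraction, and a
cross-context panel for the priors. `default_recovery_config()` is the
canonical setting: 200 REs (20% selected), 100 genes, 50 TFs, 400 SNPs,
2 populations × 5 times × 5 individuals, $|\beta| \in [0.5, 1.5]$,
$|\gamma| \in [0.5, 1]$, $\alpha = 1$, $\omega = 2\sigma_o$.

The world is *stated*, and three of its statements deserve emphasis
because they are what a green recovery test does and does not establish:

- **Orientation.** RE effects $\beta$ are positive (activating
  regulatory logic). The bilinear term makes $(\beta, \gamma)$ and
  $(-\beta, -\gamma)$ observationally equivalent; the correlation
  priors anchor the orientation, which is only meaningful when the
  world itself has a consistent one. With mixed-sign $\beta$ per gene
  and a shared $\gamma$, sign recovery is undefined for any method.
- **Candidate restriction.** With only 5 distinct time levels, a false
  candidate RE's openness trajectory aliases the target's by chance
  (null $|cor| \sim 1/\sqrt{5}$), so support recovery on a purely
  positional $\pm$1 Mb candidate map is information-limited. The
  recovery pipeline therefore applies the cross-context prior
  restriction ($|\beta_0| \ge 0.2$ at 200 contexts, i.e. about 2.8 null
  SDs; the gene's own promoter is always kept). The package default for
  `min_abs_prior` remains 0.
- **Calibrated composite evidence.** Per-SNP composite p-values are
  drawn as $c_p = 1 - \sigma(L_k + \epsilon_k)$, a logit-scale
  perturbation (sd 0.5, shared by the SNPs of an RE, which share the
  local sweep) of the RE's true selection probability. This is the
  model's own operating premise — that $p^0_k$ approximates
  $P(S_k{=}1)$. With uncalibrated (e.g. raw Fisher-combined) composite
  p-values, the iteration recovers a monotone transform of $\mu$, not
  $\mu$ itself.

Other stated choices: selection scores for shifted SNPs at
$6 + \Gamma(4, 0.5)$ versus $-\log_{10} U(0,1)$ for neutral ones
(magnitudes comparable to strong sweep signals); LD scores $U(10, 20)$;
$\Delta$DAF shifted positive for selected SNPs; openness baselines
$U(1.5, 3.5)$ with per-time factors $U(0.6, 1.4)$ and $\sigma_o = 0.4$;
TF expression log-normal and deliberately quiet over the time course
(expression lags chromatin — consistent with differential-open-region
proportions several-fold above differential-gene proportions at early
time points); the regulating TF complex binds every RE of a gene's
support; panel TF variation (sdlog 0.25) below panel chromatin
variation (sdlog 0.5). Noise $\sigma_l = 5$ on an FPKM-like scale gives
a moderate-to-high signal-to-noise target-gene model.

What the generator does **not** emulate: read-level data, LD block
structure (LD enters only through scores), mapping/quantification
artefacts, unmodelled confounders (batch, cell-cycle), negative
(repressive) REs, and genes whose regulation violates the activity
model. A green recovery test establishes that the estimation machinery
inverts the stated generative model at the stated sizes — not that the
model is true of any real tissue.

## Numerical notes

- Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before logits;
  p-values floored at $10^{-300}$ before logs.
- The selection OLS falls back to a $10^{-8}$ ridge on rank deficiency.
- glmnet solves the L1 stages (objective $\frac{1}{2n}\|r\|^2 +
  \lambda\|\cdot\|_1$, predictors standardised internally, coefficients
  on the original scale); a closed-form univariate path handles
  single-predictor candidate sets. CV folds come from the seed;
  identical (study, seed) pairs reproduce identical TSV outputs byte
  for byte.
- Stage 3 starts from the stage-1/2 solution; optimiser failure falls
  back to that solution with a flag.
- The openness generator truncates at 0; baselines keep the truncated
  mass around a percent so the accessibility t-test stays calibrated
  (verified at 500 null regressions in the acceptance suite).

## Known limitations

- The likelihood is never marginalised over $(Z, S)$; all inference is
  plug-in/conditional, matching the staged source algorithm, and no
  uncertainty intervals are produced for $\beta, \gamma, \alpha$.
- Empirical-Bayes variance moderation is intentionally not used in
  `differential()`; plain OLS t-tests lose power at small replicate
  counts.
- Support recovery depends on an informative cross-context panel; with
  `min_abs_prior = 0` the candidate sets are purely positional and
  precision drops accordingly.
- The $\omega$ test is per (RE, time) with no multiplicity correction
  by default, mirroring the source procedure; `bh_fdr()` can be applied
  to the tidy output when a corrected call set is wanted.
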