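---
title: "Longitudinal GWAS by eigen-rotated random regression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal GWAS by eigen-rotated random regression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rrgwas` associates SNPs with *test-day* phenotypes: repeated measurements of
the same animal along a time axis (days in milk, DIM). The observation of
individual $n$ in herd-test-date class $j$ and mean-curve group $i$ at time
$t$ is modelled as

$$
y_{ijn}(t) \;=\; \mu_i(t) \;+\; htd_j \;+\; x_{nm}\,SNP_m(t) \;+\; a_n(t)
\;+\; pe_n(t) \;+\; e_{nt},
$$

where every time-dependent term is a regression on a common basis
$\varphi_0(t), \dots, \varphi_k(t)$ (Legendre polynomials on standardized
DIM, or the Wilmink set $1, t, e^{-\lambda t}$):
$\mu_i(t)=\sum_k \beta_{ik}\varphi_k(t)$,
$SNP_m(t)=\sum_k \alpha_{mk}\varphi_k(t)$, and analogously for the additive
genetic trajectory $a_n(t)$ (coefficients $u_n$) and the permanent
environmental trajectory $pe_n(t)$ (coefficients $p_n$). In matrix form
$y = Xb + Qu + Zp + e$ with

$$
u \sim N(0, K \otimes G), \qquad p \sim N(0, I \otimes P), \qquad
e \sim N(0, I\sigma^2_e),
$$

$K$ the VanRaden marker-derived relationship matrix, $G$ and $P$ the
coefficient covariance matrices. The time-dependent variances follow as
$add(t)=\varphi(t)'G\varphi(t)$, $perm(t)=\varphi(t)'P\varphi(t)$,
$phe(t)=add(t)+perm(t)+\sigma^2_e$ (`variance_curves()`).

## Why rotate

A per-SNP generalized least squares fit with
$\mathrm{var}(y)=Q(K\otimes G)Q' + Z(I\otimes P)Z' + I\sigma^2_e$ costs a
dense solve per SNP. The engine instead defines
$W = Q(K\otimes G)Q' + Z(I\otimes P)Z'$, eigendecomposes it **once**
($W = UDU'$), and rotates the whole system by $U'$: the rotated residual
covariance is the diagonal $S = D + I\sigma^2_e$, so each SNP fit is
weighted least squares

$$
\hat b = (X^{*\prime} S^{-1} X^*)^{-1} X^{*\prime} S^{-1} y^*, \qquad
\mathrm{var}(\hat b) = (X^{*\prime} S^{-1} X^*)^{-1},
$$

and the time-varying SNP effect is tested with the Wald statistic
$\hat\alpha' [\mathrm{var}(\hat\alpha)]^{-1} \hat\alpha \sim
\chi^2(n_{f2}+1)$, with one degree of freedom per SNP basis coefficient.
The test suite asserts that this path reproduces direct dense GLS to
machine precision; the identity is exact, not approximate.

Per-SNP work stays linear in the data: `rotate_system()` precomputes, for
each SNP-basis function $k$, the projector
$B_k = U'\,\mathrm{diag}(\varphi_k(t_r))\,Z_{ind}$, so a genotype vector
over individuals maps to its rotated covariate columns by one
matrix-vector product per basis function and $U$ is never touched during a
scan. The base-design cross-products are factored once per scan, and each
SNP block enters through its Schur complement.

## The two-step (P3D) strategy

Variance components are estimated once, without any SNP term, and held
fixed for every test (`reml_estimate()`, or components imported from
external software through the plain-text reader). This mirrors standard
practice for large panels: re-estimating $G$, $P$, $\sigma^2_e$ per SNP is
unnecessary for calibration and prohibitively slow.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| basis family | Legendre | Wilmink available; Legendre decorrelates coefficients and assumes no curve shape |
| basis orders | 2 (all effects) | `order`+1 coefficients per effect; the real-data convention of fourth order is available but desk-scale studies here use order 2 |
| time domain | [5, 305] DIM | standard 305-day lactation, first test at day 5 |
| normalization | on | $\sqrt{(2k+1)/2}\,P_k(s)$; reparameterizes $G$, $P$ only — Wald p-values are invariant (asserted by a test) |
| Wilmink rate | 0.05/day | conventional decay constant; configurable |
| MAF filter | 0.03 | SNPs with minor allele frequency below are removed |
| HWE filter | p < 1e-6 | 1-df chi-squared goodness of fit (the minimal defensible default; exact tests can be substituted) |
| pruning | window 50, step 5, r² 0.5 | the `indep-pairwise`-style effective-test count for Bonferroni |
| REML | tol 1e-6, 200 iterations | EM warm-up plus safeguarded average-information steps |

The pruning threshold deserves a note: descriptions of this procedure
sometimes quote an r² cutoff of 0.2 alongside a command using 0.5. The
command form is taken as authoritative here (default 0.5); the threshold is
a plain argument.

# REML: estimation details

Estimation works on Henderson's mixed model equations with the residual
variance factored out, so one Cholesky factorization per iteration serves
the solutions, the restricted likelihood, and the conditional (co)variance
blocks.

* **EM steps** use the Laird–Ware form: $G \leftarrow (\hat U'K^{-1}\hat U +
  \mathrm{tr}\text{-terms})/n$, $P$ analogously, and $\sigma^2_e \leftarrow
  (\hat e'\hat e + \mathrm{tr}(C^{-1}D'D))/N$. These are monotone in the
  restricted log-likelihood (asserted by a test). The textbook shortcut
  $y'\hat e/(N-p)$ is *not* used: it is only a fixed-point form and loses
  monotonicity.
* **AI acceleration**: after three EM warm-up rounds a Newton step on the
  average-information matrix is attempted, with the gradient computed from
  the same MME quantities. The step is halved up to five times and
  abandoned for a plain EM step whenever it would leave the PSD cone or
  decrease the restricted likelihood. Typical well-posed problems converge
  in about ten iterations.
* **PSD projection**: $G$ and $P$ are symmetrized and eigenvalue-floored
  after every update; the floor is a tiny positive value (not zero) so the
  matrices stay invertible inside the MME.
* **Kinship conditioning**: a VanRaden matrix built with sample allele
  frequencies is exactly singular (centering annihilates the all-ones
  vector). Inverting it with a naive tiny ridge amplifies roundoff in the
  EM trace terms enough to destroy monotonicity. Following genomic
  evaluation practice of blending the genomic relationship matrix toward
  the identity, the REML module floors $K$'s eigenvalues at 1% of its mean
  diagonal, which bounds the condition number of the equations. The scan
  itself uses $K$ unmodified (it only needs $W$ to be PSD).
* **Identifiability**: with $K = I$ and equal basis orders, $G$ and $P$
  enter the likelihood only through their sum; the half-sib family
  structure of the simulated data is what separates them. Estimates of the
  sum, and $\sigma^2_e$, are well determined everywhere.
* Non-convergence within `max_iter` returns the best estimates with
  `converged = FALSE` and a warning, rather than failing: on weakly
  identified ridges (e.g. order-2 components on small family samples) the
  likelihood can remain flat to the tolerance for a long time.

A dense-solver guard (default 20,000 records) protects against accidental
$O(N^3)$ blow-ups; the eigendecomposition of $W$ is the intended
bottleneck of the method.

# Fixed-effect identifiability

`build_design()` drops the first herd-test-date level and lets the
per-group fixed-regression blocks absorb the intercept (no separate global
mean). The resulting design is checked for full column rank and confounded
columns are reported by name — a genuinely confounded layout (e.g. a group
whose records all sit in one herd-test-date class at one day) is a data
problem the user must resolve, not something to silently drop.

# The synthetic study conditions

`sim_config()` fixes the conditions all simulation studies run under:

* 300 cows in 30 paternal half-sib families (sires drawn from the allele
  frequency law, daughters receiving one sire allele and one population
  allele). Half-sib blocks are the minimal structure producing the
  population stratification and cryptic relatedness that the polygenic
  term must absorb.
* 1000 SNPs with frequencies Uniform(0.05, 0.5); the VanRaden matrix is
  built from these same SNPs, so the generative and analysis kinship
  coincide.
* 10 scheduled monthly tests spanning DIM 5–305, jittered by ±10 days per
  cow and thinned by 10% dropout — roughly ten unbalanced records per cow,
  as in routine milk recording.
* Herd-test-date effects of SD 2 across 10 herds (level = herd × test),
  two mean-curve groups with a declining lactation shape, assigned at
  random across herds (a deterministic assignment would confound group
  curves with HTD classes).
* Order-2 normalized Legendre bases; $G$ and $P$ mildly correlated with
  lactation-average additive, permanent and residual variances of about
  2.3, 4.5 and 4, i.e. a lactation-average heritability near 0.2 and
  phenotypic SD near 3.4 — typical of milk-yield-scale traits.

What the generator does **not** emulate: genuine linkage disequilibrium
along the chromosome (SNPs are independent, so LD pruning on simulated
panels removes almost nothing), selection, parity structure beyond a
single lactation, heterogeneous residual variance across DIM, and genotype
missingness patterns of real chips. Passing the calibration and power
suites therefore demonstrates correctness of the statistical machinery
under the model's own assumptions, not robustness to real-data pathologies.

## Type-I error and power studies

`null_scan_study()` scans SNPs against phenotypes simulated *without* any
SNP effect and reports the rejection rate at $\alpha=0.05$ and a
Kolmogorov–Smirnov uniformity check. With `with_polygenic = FALSE` the
additive-genetic covariance is dropped and the permanent-environment and
residual variances are re-estimated, reproducing the comparator model
without time-varying polygenic effects; under family structure its null
rejection rate inflates well above the nominal level, which is the
qualitative behaviour that motivates carrying the polygenic term.

`power_study()` injects a time-varying QTN effect into the phenotypes one
SNP at a time: the per-day allele substitution effect starts at 10.0 on
day 5 and performs a random walk with Uniform(−1, 1) daily increments
(fresh trajectory per SNP), then is scaled to an effect size of $k$
phenotypic SDs for $k \in \{0.04, \dots, 0.20\}$. Detection is counted at
the *empirical* threshold — the 5th percentile of the null p-values — so
models are compared at identical realized type-I error.

Two scaling conventions needed a decision, and both are isolated in one
function each:

* **Trajectory scaling** (`scale_qtn()`): "scaled to $k$ × phenotypic SD"
  is read as the trajectory's *root-mean-square* over the schedule days
  equalling $k \sigma_p$ (`method = "rms"`, the default). Under RMS
  scaling the variance fraction explained by the QTN matches the closed
  form $\pi = 2p(1-p)k^2 / (1 + 2p(1-p)k^2)$ exactly in expectation.
  Scaling the *time-average* instead (`method = "mean"`) makes the
  realized variance exceed $\pi$ by the trajectory's mean-square to
  squared-mean ratio (roughly 1.2–1.5 for this random walk), breaking the
  formula's self-consistency; it is kept as an option but not used.
* **Variance accounting**: the injected effect $x_n s(t)$ has a nonzero
  genotype mean, and $2p\,s(t)$ is a population mean-curve shift that the
  model's $\mu(t)$ absorbs. The genetic variance contributed by the QTN is
  that of the *centered* genotype, $\mathrm{var}((x_n - 2p)\,s(t)) =
  2p(1-p)\,\overline{s^2}$, and that is what the consistency check
  measures. $\sigma_p$ itself is taken as
  $\sqrt{\overline{phe(t)}}$ over the schedule (the model-based pooled
  phenotypic SD).

# Numerical choices

* Eigenvalues of $W$ within $-10^{-8}\max(D)$ of zero are clamped to zero;
  $W$ is PSD in exact arithmetic and small negatives are noise.
* All WLS solves go through QR of the row-scaled design; no cross-product
  matrix is explicitly inverted on the solution path.
* SNPs monomorphic among the scanned individuals are emitted with a
  `monomorphic` flag and missing p-value — a genome scan never aborts on a
  degenerate column. A singular SNP information matrix (confounded
  covariates) is flagged `singular` likewise.
* Missing genotypes are mean-imputed: centered zero inside the kinship
  matrix, $2p_m$ inside a scan; LD r² uses pairwise-complete individuals.
  Ties in pruning (equal MAF) remove the later position.
* Pruning operates greedily within each window on the currently retained
  set, window by window along each chromosome, matching the stepped-window
  procedure of the reference implementation.

# Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
50 cows / 500 records for the rotation-equivalence identity, the 300-cow
default population (~2700 records) for calibration (1000 null SNPs) and
power (200 SNPs per effect size), 60 Monte-Carlo replicates for the
variance-fraction check, and 20 replicates of 300 cows for REML recovery.
These sizes make the full suite complete in minutes on one core while
leaving the binomial/Monte-Carlo error bars tight enough for the stated
acceptance bands.

# Known limitations

* The dense eigendecomposition limits a single analysis to tens of
  thousands of records; the documented guard refuses more.
* Only additive SNP effects are modelled (no dominance/epistasis), one
  trait and one parity at a time.
* The HWE filter is the 1-df chi-squared approximation, not an exact test.
* The enrichment module reports the density-ratio coefficient and the
  expected-by-chance count; it attaches no p-value, since the choice of a
  null (permutation scheme, LD-aware or not) is analysis-specific. A
  permutation option is a natural extension.
* Group assignment ("season × age" classes) is taken as a user-supplied
  column; the package does not construct it from calving dates.
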