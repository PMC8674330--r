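---
title: "Likelihood-based trio association testing with partially missing omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based trio association testing with partially missing omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`omictrio` tests whether a trio — a gene's expression $E$, a cis-SNP
genotype $G$ and a cis-CpG methylation value $M$ — is jointly associated
with a binary phenotype $Y \in \{-1, +1\}$, on data where $M$ and/or $E$
may be missing for subsets of individuals while $Y$, covariates $X$ and
$G$ are always observed. The joint model is a chain of three regressions:

$$P(Y_i = 1) = \sigma\big(y_i(\beta_0 + \beta_e E_i + \beta_m M_i +
\beta_g G_i + \beta_x' X_i)\big), \qquad
\sigma(v) = \frac{1}{1 + e^{-v}},$$
$$M_i = \alpha_0 + \alpha_g G_i + \epsilon_{1i}, \qquad
E_i = \gamma_0 + \gamma_g G_i + \gamma_m M_i + \epsilon_{2i},$$

with independent Gaussian errors ($\sigma_1^2$, $\sigma_2^2$) and
$G_i \sim \mathrm{Binomial}(2, p)$. The chain factorizes the joint law as
$[Y \mid E, M, G, X]\,[E \mid M, G]\,[M \mid G]\,[G]$, which is what makes
missing layers tractable: any unobserved layer can be integrated out of
its own conditional. A residual correlation between $\epsilon_1$ and
$\epsilon_2$ beyond what $\gamma_m$ captures is *not* a free parameter:
the conditional-regression structure absorbs the (M, E) dependence
through $\gamma_m$, and the likelihood contains no separate correlation
term.

Key assumptions: omics values are continuous and roughly Gaussian after
the usual transformation/normalization; the genotype is biallelic, coded
as the minor-allele count; missingness is ignorable (independent of the
unobserved values given the observed data — MCAR/MAR); and the phenotype
model is logistic with no interactions between omics layers.

## Marginalizing a missing layer

Exact logistic-Gaussian integrals have no closed form, so the logistic
CDF is approximated by a normal CDF with scale $\beta = \pi/\sqrt{3}$
(variance matching): $\sigma(v) \approx \Phi(v / \beta)$. The sup-norm
error of this approximation is about $0.023$ (computed by dense grid
evaluation in the test suite). Under it, every marginalization is the
integral of a product of two normal densities,

$$\int \phi\!\Big(\frac{ax - b}{\sigma_1}\Big)
\phi\!\Big(\frac{c - dx}{\sigma_2}\Big)\,dx
= \phi\!\Big(\frac{ac - bd}{\sqrt{a^2\sigma_2^2 + d^2\sigma_1^2}}\Big)
\frac{1}{\sqrt{a^2/\sigma_1^2 + d^2/\sigma_2^2}},$$

and each missing pattern yields a probit-style probability whose
denominator inflates by the marginal variance of the integrated-out
linear predictor:

- expression missing: plug in $\mu_0 = \gamma_0 + \gamma_g G + \gamma_m M$
  and inflate by $\beta_e^2 \sigma_2^2$;
- methylation missing: plug in the bivariate-normal conditional mean of
  $M \mid E, G$ and inflate by $\beta_m^2 \sigma_1^2 \sigma_2^2 /
  (\sigma_2^2 + \gamma_m^2 \sigma_1^2)$; the observed $E$ contributes its
  genotype-marginal density $N(\gamma_0 + \gamma_g G + \gamma_m(\alpha_0 +
  \alpha_g G),\ \sigma_2^2 + \gamma_m^2 \sigma_1^2)$;
- both missing: plug in the genotype-implied means and inflate by
  $\beta_e^2\sigma_2^2 + (\beta_e\gamma_m + \beta_m)^2\sigma_1^2$.

Each closed form is tested against brute-force quadrature of the
probit-approximated model on randomized configurations
(`test-kernels.R`, `test-acceptance.R`). Complete individuals keep the
*exact* logistic term — the approximation is used only where an integral
requires it — so the likelihood follows the printed conditional forms
rather than harmonizing everything to the probit scale.

## Fitting and testing

The log-likelihood and its analytic gradient are implemented in C++ and
maximized by `optim(method = "L-BFGS-B")` with box constraints
($\sigma^2 \in [10^{-6}, 10^6]$, $p \in [10^{-6}, 1 - 10^{-6}]$,
coefficients in $[-50, 50]$ — generous bounds whose only role is keeping
the objective finite). Starting values are deterministic and cheap:
least squares for the two omics layers on the rows that observe them, a
logistic GLM on complete cases (coefficients clamped to $[-5, 5]$ to
tame separation) for the phenotype layer, the sample allele frequency
for $p$, and residual variances for the $\sigma^2$. On non-convergence
one deterministic jittered restart is attempted. The analytic gradient
is pinned to a central finite-difference oracle in the tests.

The trio test constrains $\beta_e = \beta_m = \beta_g = 0$ under the
null and refers $\Lambda = 2(\hat\ell_{alt} - \hat\ell_{null})$ to
$\chi^2_3$; duo and single-omic tests constrain the corresponding subset
and use the matching degrees of freedom. The null fit starts from the
alternative optimum with the tested coefficients zeroed, and if the
alternative ever lands below the null it is refitted from the null
optimum, so the nesting inequality $\Lambda \ge 0$ holds up to optimizer
noise; anything in $(-10^{-6}, 0)$ is clamped to zero. p-values rely on
the asymptotic null only — fast asymptotics over permutation is the
point of the method — and batch screens apply Benjamini–Hochberg across
all trios of the screen.

## What the synthetic-data generator emulates

`sim_config()` defaults encode the study conditions of the simulation
harness: minor-allele frequency $0.2$ under Hardy–Weinberg equilibrium in
controls; case genotypes from an additive penetrance model (relative risk
$1.2$ per minor-allele copy, anchored at prevalence $0.1$, inverted by
Bayes' rule); $\alpha_0 = 1.3$, $\alpha_g = 2.4$, $\gamma_0 = 1.9$,
$\gamma_g = 0.6$, $\gamma_m = 2.3$, $\sigma_1^2 = \sigma_2^2 = 1$; a
case–control separation of $0.3$ in the (M, E) pair; phenotype
coefficients $\beta_0 = 1$, $\beta_x = (0.01, 0.01)$, $\beta_g = 0.1$,
$\beta_m = 0.2$, $\beta_e = 0.3$; covariates age $\sim N(40, \mathrm{sd}\ 6)$
(we read the second argument as a standard deviation, the conventional
notation) and sex $\sim \mathrm{Bernoulli}(0.5)$. Missingness is injected
completely at random, balanced across the case and control strata, in
three disjoint sets (both missing / methylation only / expression only).

Two design questions were genuinely open and we resolved them by
measurement against the reference operating characteristics, once,
before freezing the harness:

**How the 0.3 separation enters.** "Case and control (M, E) means differ
by 0.3" admits several readings. Adding $0.3$ to both values after
generation shifts each marginal mean by exactly $0.3$ but makes the
*conditional* expression signal $0.3 - \gamma_m \cdot 0.3 = -0.39$,
and the complete-data power it implies (about $0.85/0.97/0.99$ at
$n = 100/150/200$ per stratum) overshoots the reference column
($0.697/0.878/0.950$). Shifting methylation by $0.3$ and generating
expression *from the shifted methylation* plus its own $0.3$
("conditional" reading) gives $0.75/0.83/0.97$ — consistent within
Monte-Carlo error — and is the default (`shift_mode = "conditional"`);
the marginal reading stays available as `shift_mode = "marginal"`.

**Where the phenotype comes from.** The generator supports three modes.
`retrospective` (default): labels are fixed by design quota and case
features follow the shifted laws — this is the reading whose type I
error ($\approx 0.053$) and power match the reference tables, and the
per-individual logistic probability is recorded as a diagnostic
attribute. `prospective`: individuals are drawn from the population law
and labelled by a Bernoulli draw from the logistic model; with the
default coefficients this separates cases and controls so strongly that
the trio test saturates (power $\approx 1$ at every sample size), so it
cannot be the process behind the power tables. `rejection`: intended
cases and controls are drawn from their stratum laws and kept only when
the Bernoulli phenotype draw matches the intent — the only reading
under which *all* of the stated generation steps operate. The
classification studies (cross-validation, ROC) use the rejection mode:
under the retrospective mode the Bayes accuracy given $(X, G, M, E)$ is
only about $0.60$ (the class separation is a fraction of a standard
deviation by construction), so classification accuracies near $0.80$
are attainable only when the Bernoulli phenotype step participates in
the labels.

## Evaluation protocol

Type I error is the rejection rate of the asymptotic 5% test over
simulated null datasets (2000 replicates by default at desk scale;
Monte-Carlo standard errors are always reported). Power uses the
*empirical* 5% cutoff — the 95th percentile of the simulated null
$\Lambda$ for the same scheme and sample size — so the comparison holds
type I error fixed by construction. Tenfold cross-validation splits the
*complete* individuals into ten case/control-stratified folds; each test
fold is scored with the model fitted on everything else (incomplete
individuals included, through the marginalized likelihood), classifying
at threshold $0.5$; ROC curves sweep a 101-point threshold grid over the
out-of-fold probabilities. Baselines: complete-case analysis, mean
imputation, and a $k = 5$ nearest-neighbour imputation over standardized
always-observed features.

Problem sizes in the shipped tests and acceptance script are chosen for
a desk-scale run: 2000 null / 500 alternative replicates per scheme,
100 replicates for parameter recovery, 20 datasets per scheme for the
cross-validation grid.

## Numerical choices and degenerate inputs

- All probability terms are composed on the log scale; the probit terms
  use `pnorm(..., log.p = TRUE)` and a stable Mills-ratio form in the
  gradient, so extreme linear predictors do not underflow.
- The closed-form integral requires $a$ and $d$ not both zero; that
  degenerate call errors explicitly.
- A dataset whose omics are entirely missing in both layers is rejected
  at the I/O boundary as carrying no information; a monomorphic genotype
  triggers a boundary warning for $\hat p$.
- Variance estimates are floored at $10^{-6}$ by the optimizer box; the
  likelihood internally guards finite-difference probes a hair outside
  the box.
- Phenotypes are stored as $\pm 1$; $0/1$ and `"case"/"control"` are
  recoded at the boundary. Cis-window coordinates are 1-based inclusive
  and the window is closed on both ends, strand ignored.

## What passing tests do and do not show

The generator emulates a single trio under the stated parametric laws.
It does not simulate population structure, batch effects, probe-level
measurement error, non-Gaussian omics distributions, linkage between
SNPs, or informative (non-ignorable) missingness — so green simulation
results certify the method's behaviour under its own assumptions, not
on any particular real dataset.

Known limitations found while calibrating the harness, left honest
rather than tuned away:

- Under the conditional shift reading, blanking 40% of expression
  values costs our generator less power (rate $\approx 0.93$) than the
  reference table's $0.866$; no reading of the separation statement
  matches both the complete-data power column and that cell
  simultaneously, suggesting the reference generator allocated more of
  the class separation to the conditional expression signal than any
  reading we admit.
- Rejection-mode cross-validated accuracy averages $0.76$–$0.80$ per
  scheme (pooled mean about $0.787$; lowest at 80% both-missing), so
  the "above 80% everywhere" reference claim is reproduced only
  directionally, not uniformly.
- The finite-sample null of the statistic is slightly right-shifted
  relative to $\chi^2_3$ at these sample sizes (empirical 95th
  percentile about $8.1$ versus $7.81$; a two-sided
  Kolmogorov–Smirnov check on 2000 null replicates rejects with
  $D \approx 0.04$), mirroring the mild inflation visible in the
  reference type I table, whose complete-data rate $0.0533$ at 10000
  replicates is itself significantly above $0.05$. The empirical-cutoff
  power protocol removes this shift by construction.
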