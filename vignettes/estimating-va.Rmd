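---
title: "Estimating the additive genetic variance for fitness from allele-frequency change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the additive genetic variance for fitness from allele-frequency change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vafit)
```

## The estimand and the identities behind it

The additive genetic variance for relative fitness, $V_A$, is the variance
of breeding values for relative fitness $w$, and by Fisher's fundamental
theorem the partial per-generation increase in mean fitness caused by
selection.  With $c$ the vector of reference-allele dosages of a diploid
individual (entries $0, \tfrac12, 1$) and $L = \mathrm{VAR}(c)$ the
genome-wide dosage covariance matrix, the average effects are
$\alpha = L^{-}\,\mathrm{COV}(c, w)$ and

$$V_A \;=\; \alpha^\top L \alpha \;=\; E[\Delta p]^\top L^{-} E[\Delta p],$$

because the expected allele-frequency change due to selection is
Robertson's covariance $E[\Delta p] = \mathrm{COV}(c, w) = L\alpha$.  These
identities are exact for the population at one time point; no assumption
about dominance, epistasis or mating is needed for them.  They make $V_A$
estimable from genome-wide frequency changes *without* estimating any
individual locus effect, which is hopeless at realistic scales.

`compute_dosages()`, `compute_L()`, `average_effects_exact()`,
`va_from_alpha()` and `va_from_deltap()` implement these objects on a fully
observed population; `genic_decomposition()` splits the response and the
variance into per-locus (genic, $\alpha^\top B^2 \alpha$ with $B$ the
diagonal of dosage standard deviations) and linkage-disequilibrium parts.

## From one population to a replicated experiment

Real experiments observe noisy changes $\Delta p_m$ in $M$ replicate
populations founded from a common base (generation 0).  Three model layers
connect them to $V_A(0)$:

**Decay of L.**  L in later generations is predicted from the base value
by Hadamard decay: writing $L_0 = L_0' + L_0''$ for the gametic/nongametic
split (covariances over haploid gametic genomes versus between the two
gametic contributions of a diploid, both centred on the pooled allele
frequency so the split is exact), the predictable part is
$\mathcal{L}_t = N_t \circ \tilde L_0$ with
$\tilde L_0 = L_0' + \tfrac{r}{1-r} \circ L_0''$ and
$N_{t,ij} = (1-r_{ij})^t \prod_{k<t} (1 - \tfrac{1}{2N_{e,k}})$.
The $r/(1-r)$ weight makes nongametic associations dissolve in one round
of random mating and leaves the diagonal untouched ($r_{ii}=0$); an
alternative algebraic reading of the same quantity gives $(1-r)/r$, which
diverges on the diagonal, so the first form is used.  Without phased data
the package falls back to $\tilde L_0 = L_0$ (with a warning), which
biases estimates slightly downward.

**Drift covariance.**  The drift covariance of $\Delta p_m$ accumulated
between the first and last observed generations $t_m, \tau_m$ has
expectation $\tilde L_0 \circ M^{(m)}$,
$M^{(m)} = \sum_{t=t_m}^{\tau_m-1} \tfrac{(1-r)}{N_{E,t}} \circ N_t$.
Two effective sizes appear: $N_e$ governs the decay of LD, $N_E = 4N/(2+V_o)$
the drift variance, with $V_o$ the offspring-number variance absent
additive genetic fitness variance.  They are exposed separately
(`drift_design()`), defaulting to equality.

**Projection.**  Only the non-null subspace of $L_0$ (rank at most the
number of sequenced base individuals) carries information.  With $U_L$ the
retained eigenvectors of $L_0$ and $U_2 D_2^2 U_2^\top$ the
eigendecomposition of the reduced drift matrix, the projection
$P = D_2^{-1} U_2^\top U_L^\top$ makes projected changes i.i.d. standard
normal under pure drift.  Every fit asserts the whitening invariant
$P(\tilde L_0 \circ M)P^\top = I$ to $10^{-8}$.

## The mixed model

Treating the time-and-replicate-averaged average effects as random with

$$\mu_{\bar\alpha} = \beta^{(1)}_{\bar\alpha} (p_0 - q_0), \qquad
  V_{\bar\alpha} = \sigma^2_{\bar\alpha}\, \mathrm{diag}(L_0)^{p_{\bar\alpha}},$$

the projected changes follow a linear mixed model: fixed-effect column
$P\,\mathcal{L}_m (p_0 - q_0)$, random-effect factor
$Z_m = P\,\mathcal{L}_m\,\mathrm{diag}(L_0)^{p_{\bar\alpha}/2}$ shared
across replicates (inducing the between-replicate covariance
$\sigma^2_{\bar\alpha} Z_m Z_n^\top$), residual variance $\varphi$ with
expectation 1 when drift is correctly modelled, and — for pool-seq data —
per-replicate error blocks
$E_m = 2\sigma^2_o P(\mathcal{L}_{t_m} \circ Q_{t_m} +
\mathcal{L}_{\tau_m} \circ Q_{\tau_m})P^\top$ where $Q_{ij}$ is the
read-span statistic (reads spanning $i$ and $j$ over the product of
coverages; $1/\text{coverage}$ on the diagonal).  Only the diagonal of the
Hadamard terms is used by default, which keeps the blocks cheap; the dense
variant is available in `poolseq_error_structure()`.

$V_{\bar\alpha}$ uses the *diagonal* of $L_0$ only — a power function of
the diversities; $p_{\bar\alpha} = 0$ means effects independent of
diversity, $p_{\bar\alpha} = -1$ means effects scaling inversely with it
(then $\sigma^2_{\bar\alpha}$ is the mean per-locus contribution to the
additive genic variance).

**REML.**  `reml_fit()` profiles $\beta$ by GLS and the overall scale
$\varphi$ analytically, optimizes the variance ratios
$\sigma^2_{\bar\alpha}/\varphi$ (and $\sigma^2_o/\varphi$) numerically,
and maximizes over $p_{\bar\alpha} \in [-2, 1]$ in an outer Brent search —
the model is linear-mixed conditional on $p_{\bar\alpha}$, so the problem
separates.  When all replicates share one design and there is no pool-seq
block, replicates are exchangeable and the likelihood splits into a
replicate-average mode plus pure-noise contrast modes; one
eigendecomposition per $p_{\bar\alpha}$ then makes inner iterations $O(K)$
(solver chosen automatically; both solvers agree to numerical tolerance
and are cross-checked in the tests).  The $\sigma^2_{\bar\alpha} = 0$
boundary is always evaluated explicitly and reported as such.

**The estimate.**  Averaging $\bar\alpha^\top L_0 \bar\alpha$ over the
fitted distribution,

$$\widehat{V_A}(0) = \sigma^2_{\bar\alpha} \sum_i L_{0,ii}^{\,p_{\bar\alpha}+1}
 \;+\; \hat\beta^2 (p_0-q_0)^\top L_0 (p_0-q_0)
 \;-\; S_{\bar\alpha} (p_0-q_0)^\top L_0 (p_0-q_0),$$

where $S_{\bar\alpha}$, the sampling variance of $\hat\beta$ from the
information matrix, corrects the upward bias of the plug-in quadratic
form.  The correction uses the unprojected column $p_0 - q_0$, since the
quadratic form lives on the $L_0$ scale rather than the whitened scale.  A
corrected quadratic term can be negative and is reported as-is (alongside
the raw term), keeping the estimator unbiased in the mean rather than
truncating.

## What the simulator emulates

`run_experiment()` generates the whole study: standing variation from a
forward-time neutral Wright–Fisher burn-in with infinite-sites mutation
(run for `burnin_factor * N0 = 4 N0` generations, close to mutation–drift
equilibrium; an import hook `panel_from_matrix()` accepts externally
generated, e.g. coalescent, haplotypes), fitness effects from a point
mass at zero plus reflected-gamma/gamma tails (shape 0.3; mean absolute
effect `shape * scale`), log-additive fitness with the within-locus
dominance scheme ($0$, $(1+\kappa)\eta/2$, $\eta$ for 0/1/2 reference
copies; $|\kappa| = 0.5, 0.9$ correspond to $h = 0.25, 0.05$), standard
normal environmental noise on log fitness, fitness-proportional parent
sampling with selfing, and Poisson crossovers on the genetic map (no
interference, consistent with Haldane's mapping function used for the
$r$ matrix).

Two history modes set the relationship between effects and frequencies:
`"neutral-simplified"` attaches effects at random with respect to allele
(null relationship: $p_{\bar\alpha} = \beta^{(1)}_{\bar\alpha} = 0$),
while `"selected-burnin"` appends a forward phase with selection and
non-neutral mutation on derived alleles, driving the population toward
mutation–selection–drift balance where $p_{\bar\alpha} < 0$ and
$\beta^{(1)}_{\bar\alpha} > 0$.  Replicates are founded from the base by
one selection-free reproduction ($t_m = 1$); no mutation occurs during
the experiment.  True $V_A$ is bookkept exactly: $\alpha$ from the exact
regression of expected (noise-free) relative fitness on dosages in the
base population, $V_A = \alpha^\top L_0 \alpha$.

**Effective size of simulated replicates.**  The environmental noise
$\varepsilon \sim N(0, v)$, $v = 1$, makes relative fitness lognormal with
$\mathrm{Var}(w) = e^v - 1$, so the neutral offspring-number variance is
$V_o = 2 + 4(e^v - 1)$ and $N_E = 4N/(2+V_o) = N e^{-v} \approx N/e$.
`experiment_effective_size()` computes this; with it the whitened residual
variance of pure-drift simulations is 1.00 within Monte-Carlo error
(asserted in the tests).  Supplying the census size instead simply inflates
the fitted residual variance by the same factor — which is why the fit
also reports `NE_implied = NE_assumed / residual_variance`.

What the simulator does *not* emulate: epistasis, nonrandom mating,
overlapping generations, migration, balancing or frequency-dependent
selection, sequencing error or mapping bias in pool-seq reads.  Passing
tests therefore validate the estimator under drift–recombination–selection
dynamics with the stated fitness model, not under arbitrary real-data
pathologies.

## Study conditions of the validation suite

Validation runs at desk scale, with conditions fixed once:

* **Null calibration** (`study_null_calibration()`): 500 loci, $N_0 = N = 200$,
  5 replicates, 3 generations, mean absolute effect 0.03, effects detached
  from alleles, with the non-neutral fraction swept over $[0.15, 1]$ so
  the 20 runs pool true $V_A$ across roughly 0.01–0.1, as the full-sized
  histogram study they mirror does.  Checks: mean fitted $p_{\bar\alpha}$
  and $\beta^{(1)}_{\bar\alpha}$ within two Monte-Carlo standard errors of
  0, mean residual variance in $[0.9, 1.2]$.  Pooling across the range
  matters: $p_{\bar\alpha}$ is weakly identified when $V_A \lesssim 0.02$
  at this scale, and its REML point estimate then skews negative (the
  $[-2, 1]$ power range offers far more flexibility at the negative end);
  fitting data simulated from the package's own mixed model reproduces
  that skew, so it is a small-sample property of the estimand, not a
  defect of the drift model.
* **Recovery** (`study_recovery()`): same base scale with the reference
  10 replicates, mean absolute effect 0.03 and the non-neutral fraction
  swept over $[0.1, 1]$, spanning true $V_A$ of roughly 0.005–0.1; 24
  runs; regression of estimated on true $V_A$ should have slope in
  $[0.8, 1.2]$.  At 500 loci a mean effect of 0.02 cannot produce
  $V_A = 0.1$ even with every locus selected, and a mean effect of 0.06
  triggers the known downward bias from rare large-effect variants losing
  genic variance during the experiment, so 0.03 is the scale at which the
  full range is reachable without leaving the estimator's intended regime.
* **Pool-seq correction** (`study_poolseq()`): 300 loci on 100 kb
  (2.4 segregating sites per 800-bp read, matching the survey density of
  about 2.5 sites per 150-bp read at full scale), $N = 100$, 5 replicates,
  coverage 10×.  Coverage scales with $N_E$: the full-scale regime of
  100× on populations of 1,000 has sampling-error-to-drift variance ratio
  $\approx 2.45$, and 10× on populations of 100 reproduces exactly that
  ratio.  Checks: fitting the error covariance recovers the $V_A$ that
  omitting it wipes out.
* **Selected history** (`study_selected()`): scaled-down selected burn-in
  (1,000 generations of selection after neutral equilibration), 10 runs;
  checks the signs $p_{\bar\alpha} < 0$, $\beta^{(1)}_{\bar\alpha} > 0$.

## Numerical choices and degenerate inputs

* All inverses of $L_0$ are Moore–Penrose pseudoinverses restricted to
  eigenvalues above $10^{-10}$ of the largest; the inference lives
  entirely in that subspace, where the identity
  $\alpha^\top L \alpha = (L\alpha)^\top L^{-}(L\alpha)$ is exact.
* Directions of the reduced drift matrix that are numerically singular are
  dropped with a reported count.
* Monomorphic loci contribute nothing and are excluded from the random
  structure (and from simulated experiments at the outset); pool-seq loci
  with zero coverage are masked everywhere to keep locus sets aligned.
* Frequency-change components outside the column space of $L$ are
  projected away with a warning.
* The outer search for $p_{\bar\alpha}$ uses interval $[-2, 1]$ with
  tolerance $10^{-2}$; variance ratios are optimized on the log scale with
  an explicit boundary check at zero.
* Dense $n_L \times n_L$ matrices throughout: the practical ceiling is
  roughly $10^4$ loci on a desktop; no sparse approximations.
* Replicates founded later than generation 1 ($t_m > 1$) are accepted with
  a warning, because LD changes accumulated before $t_m$ are shared across
  replicates and violate the independence of residuals.

## Known limitations

The residual variance absorbs every unmodelled source — unpredictable
selection response, misspecified $N_E$, environment-by-time interactions —
so a residual variance far from 1 flags model misfit without localizing
it.  Estimates are noticeably upward-biased when power is low (few
replicates, small $V_A$), as the truncated-at-zero variance component and
the weakly identified power exponent both push upward at small scale.
Multi-time-point covariance chains (more than start/end per replicate) are
not modelled, nor is the covariance of the unpredictable response to
selection, which has no tractable closed form; both follow the modelling
choices the estimator was designed around.
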