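---
title: "Estimating LQ radiosensitivity parameters from grouped outcome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating LQ radiosensitivity parameters from grouped outcome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqtcp)
```

## The model

Each row of an arm table is one published treatment arm: `n` patients
treated with total dose $D$ (Gy) in $N$ fractions (equivalently with dose
per fraction $d = D/N$), and an observed 5-year biochemical relapse-free
survival (bRFS) proportion $p$.  The arm-level control proportion is
modelled with the Poisson tumour control probability derived from the
linear-quadratic cell-kill model:

$$P = \exp\!\left(-\exp\!\left(k - \alpha D - \beta D^2/N\right)\right)
    = \exp\!\left(-\exp\!\left(k - \alpha D - \beta D d\right)\right),$$

where $k$ is the natural logarithm of the effective clonogenic target cell
number, $\alpha$ (Gy$^{-1}$) measures unrepairable one-track lethal damage
and $\beta$ (Gy$^{-2}$) repairable two-track damage.  The ratio
$\alpha/\beta$ (Gy) is the dose at which both contributions are equal and
governs fractionation sensitivity.  Internally the canonical
parameterisation is $(k, \alpha, r = \alpha/\beta)$, with $\beta = \alpha/r$
always derived; the two displayed forms are algebraically identical and the
code evaluates both through the quadratic dose $C = D^2/N = Dd$, so arms
specified either way are handled uniformly.

Assumptions worth keeping in view:

* arm-level outcomes are binomial draws at the model TCP — there is no
  between-study heterogeneity term;
* no time/repopulation factor is modelled, appropriate for slow-growing
  tumours treated over conventional overall times;
* no covariates enter the likelihood: risk group, androgen deprivation and
  the bRFS definition (Phoenix vs ASTRO) are carried in the data model and
  reported, but subgroup analysis means fitting subgroup tables separately.

## Data model and packaged tables

The CSV dialect is fixed (UTF-8, comma-separated, mandatory header, empty
cell = absent):

```
study,author,n,brfs_5y,total_dose,n_fractions,dose_per_fraction,c,definition,risk_group,subset_of_pooled
```

`read_arm_table()` fills the dose per fraction from $D/N$ and the quadratic
dose from $D^2/N$ (or $Dd$) when absent, and enforces the invariants
$0 \le p \le 1$, $D > 0$, and consistency of derived columns within 0.5%
(published tables round the quadratic dose, so exact equality cannot be
demanded).  `validate_arm_table()` additionally reports soft findings:
rounded derived columns, fraction sizes that disagree with the table's
regimen label, duplicated arms, and suspected pooled-cohort overlap (an arm
whose patient count equals the sum of the same author's other arms).

Three transcribed groups ship with the package: conventional fractionation
(1.8–2.1 Gy per fraction; 22 arms, 7793 patients), moderate
hypofractionation (2.19–3.5 Gy; 31 arms, 6822 patients) and SBRT
($\ge$ 6.5 Gy; 11 printed arms).  The SBRT table contains one pooled
multi-institution cohort of 1100 patients together with three of its
risk-stratified subsets (385/589/126 patients); the subsets are flagged
`subset_of_pooled`, fitting defaults to the table as printed, and
`drop_pooled_subsets = TRUE` removes the flagged rows (patient total 1827
when the pooled study is counted once).  Fraction sizes in the definitional
gaps (2.11–2.18 Gy, 3.51–6.49 Gy) are deliberately `"unclassified"` rather
than silently assigned.

## Estimation

The grouped binomial log-likelihood is

$$\ell(k, \alpha, r) = \sum_i n_i p_i \log P_i + n_i (1 - p_i) \log(1 - P_i),$$

with fractional successes $n_i p_i$ used exactly as published (no rounding
to integer counts).  Model probabilities are clamped to
$[10^{-12}, 1 - 10^{-12}]$ only inside likelihood evaluation, so an arm
with $p_i = 1$ contributes only its first term and the model math elsewhere
stays exact.

`fit_mle()` runs a quasi-Newton optimiser (with analytic gradient) from
every start of a 72-point grid ($k \in \{-5, 0, 5, 10\}$,
$\alpha \in \{0.01, 0.05, 0.1\}$, $r \in \{0.5, 1.5, 3, 5, 10, 20\}$), keeps
the best final log-likelihood, breaks ties (within $10^{-8}$) by the
smallest $|r|$, and polishes the winner with a derivative-free simplex pass.
The multi-start guards against the multi-modality that flat designs can
produce.  Convergence tolerances are $10^{-10}$ on the log-likelihood and
$10^{-8}$ on parameters.  A fit is refused when fewer than 3 arms or fewer
than 2 distinct doses per fraction are available, since $\alpha/\beta$ is
then structurally unidentifiable.  With `nonnegative = TRUE` the
optimisation is bound-constrained at $\alpha \ge 0$, $r \ge 0$ (not
transformed), so an estimate exactly at the boundary is representable and
active bounds are reported.

Standard errors come from the inverse observed information (numerically
differentiated at the optimum) with Wald p-values; these are diagnostics,
honest about the local curvature, not reproduction targets.

## Identifiability: the ratio rides a flat ridge

Within each fractionation group the dose per fraction spans a narrow range,
so the data constrain $k$ and $\alpha$ far more strongly than
$\alpha/\beta$.  `profile_alpha_beta()` makes this visible: on the packaged
conventional table the profile log-likelihood changes by only a few
hundredths over several tenths of a Gy around the optimum, and on the SBRT
table it is flat to about $10^{-4}$ across a 1-Gy stretch.  Two practical
consequences follow.  First, any two well-behaved optimisers can stop at
ratio values a few tenths of a Gy apart at essentially the same likelihood,
and published point estimates obtained with other software can sit on the
same ridge without being the exact argmax of the transcribed data; this
package always reports its own fully converged maximum.  Second,
uncertainty statements for $\alpha/\beta$ inherit the flatness: the Wald
and jackknife standard errors for the ratio are large, and the resampling
intervals computed here are much wider than the corresponding intervals for
$k$ and $\alpha$.  That width is a property of the estimation problem, not
an implementation artefact, and narrower published intervals for the ratio
should be read with this in mind.

## Resampling uncertainty

`jackknife()` removes one arm at a time (the study arm is the resampling
unit throughout; patients are never resampled individually), refits, and
applies the standard jackknife formula
$\widehat{se} = \sqrt{\tfrac{m-1}{m} \sum_i (\theta_i - \bar\theta)^2}$.
Replicate refits are warm-started from the full-sample optimum plus a
coarse safety grid, which is a pure speed optimisation: every refit is run
to the same tolerances.  The interval construction behind grouped-data
jackknives is often under-documented, so `jackknife_interval()` makes the
choices explicit: the default is the full-sample estimate $\pm$
$z_{(1+\gamma)/2}\,\widehat{se}$, with a Student-$t$ flavour
(`flavor = "t"`) and centring on the jackknife mean
(`center = "jack_mean"`) available as flags.

`bca_interval()` implements the standard Efron bias-corrected and
accelerated bootstrap: arms resampled with replacement, bias correction
$z_0$ from the fraction of bootstrap replicates below the point estimate,
acceleration from jackknife influence values.  Resamples that violate the
identifiability precondition (all drawn arms sharing one fraction size) are
redrawn from the same deterministic stream, so results are reproducible
under a fixed seed, which is mandatory.  A degenerate bootstrap
distribution falls back to the percentile interval with a warning, and
forcing $z_0 = a = 0$ (testing hooks) reduces BCa to the percentile
interval exactly.

## Verification by chi-square

`chi_square_gof()` computes the proportion-based statistic

$$X^2 = \sum_i \frac{(P^{model}_i - p^{obs}_i)^2}{p^{obs}_i},$$

in which the observed study proportion plays the expected-frequency role in
the denominator, and refers it to the upper chi-square tail.  Two features
are deliberately preserved and flagged rather than silently corrected:
the statistic operates on proportions (not counts, so sample sizes do not
weight it), and the default degrees of freedom are $m - 1$ with no
subtraction of the three fitted parameters (`df_rule = "m_minus_3"` is
available; for these tables both rules give p-values far above 0.995, so
the choice does not affect the qualitative conclusion).  The statistically
conventional count-based Pearson test is provided separately as
`chi_square_counts()` and is labelled as such; it is a different statistic
with a much larger value on these data.  Note that the maximum-likelihood
fit need not minimise $X^2$ — on the packaged tables it sits within about
0.05 of the best value over a $\pm 5\%$ perturbation grid.

## BED re-analysis

`bed()` is the closed form $BED = D(1 + d/(\alpha/\beta))$, refusing
non-positive ratios (a restriction-free fit can produce them; the BED is
undefined there).  `run_bed_reanalysis()` applies it to the packaged
schedules of three randomised trials comparing moderate hypofractionation
with conventional fractionation, once under the classical low prostate
ratio (1.5 Gy) and once with each arm's ratio chosen by its fraction size
via `classify_regimen()` (defaults: the published per-regimen reference
ratios shipped with the package, overridable with any fitted values).  The
trial schedules are protocol constants packaged as an editable JSON
configuration; they are inputs, not outputs, of any fit.  Under the low
ratio the hypofractionated arms appear dose-escalated; under the
regimen-specific ratios the ordering reverses — the point of the
re-analysis.

## Synthetic cohorts and parameter recovery

`synthetic_design()` + `generate_table()` simulate exactly the data the
likelihood assumes: per-arm relapse-free counts drawn as
$\mathrm{Binomial}(n_i, P_i)$ at stated true parameters, with observed
proportions stored as the exact rationals successes$/n$.  Sub-seeds are
derived counter-style from (seed, replicate, arm), so adding arms or
replicates never perturbs existing draws and every granularity is
deterministic.  The generator's default design copies the conventional
table's $(n, D, N)$ structure with truth
$(k, \alpha, \alpha/\beta) = (5.35, 0.043, 1.78)$ — the published
conventional-group estimates — so that recovery experiments probe the
estimator under a realistic meta-analytic design.

What the generator does **not** emulate: patient-level censoring and
follow-up, PSA dynamics and the differing failure clocks of the
ASTRO/Phoenix definitions, androgen deprivation, dose heterogeneity within
arms, and between-study heterogeneity beyond binomial noise.  Passing
recovery tests therefore demonstrate correctness of the estimator under its
own sampling model, not robustness to real-data violations of it.

`recovery_experiment()` reports per-parameter bias, RMSE and empirical
coverage of the jackknife-normal intervals.  The packaged checks use 200
replicates at the conventional design (the suite's heaviest computation, a
few minutes of refits), where the median recovered ratio is unbiased within
Monte-Carlo error and interval coverage lands inside 90–99%; a companion
check at 100-fold patient counts verifies the $1/\sqrt{n}$ shrinkage of the
RMSE.

## Numerical choices, in one place

* likelihood clamp $[10^{-12}, 1 - 10^{-12}]$, applied only where logs are
  taken;
* multi-start tie-break: log-likelihoods within $10^{-8}$ are ties, the
  smallest $|r|$ wins;
* derived-column consistency tolerance 0.5% (printed tables are rounded);
* regimen interval edges carry an absolute guard of $10^{-9}$ Gy against
  binary representation of decimal doses (e.g. $73.8/41$);
* counter-derived sub-seeds stay below $2^{31}$;
* reported estimates are full precision; `paper_round()` formats $k$ and
  $\alpha/\beta$ to 2 decimals and $\alpha$ to 3, matching the precision of
  the published reference tables.

## Known limitations

The model is the standard LQ/TCP form only: no lethal-potentially-lethal,
modified-LQ, universal-survival-curve or generalised-LQ variants, no
EQD2 utilities, and no time factor.  The likelihood treats arms as
independent binomial samples, which understates uncertainty when cohorts
overlap (hence the pooled-subset flag and the overlap finding in
validation).  And as discussed above, $\alpha/\beta$ is intrinsically
weakly identified by grouped within-regimen data; the package reports that
weakness honestly rather than hiding it.
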