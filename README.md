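# lqtcp

Estimation of linear-quadratic (LQ) radiosensitivity parameters of prostate
cancer from grouped clinical outcome data.

## The problem

Prostate cancer is widely treated with hypofractionated radiotherapy on the
strength of a low α/β ratio (classically 1.5–3 Gy), yet randomised trials of
hypofractionation have not shown the expected superiority.  One way to probe
this is to estimate the LQ parameters separately for cohorts treated with
different fraction sizes and ask whether the ratio is stable.  `lqtcp` is
built for exactly that analysis: each published treatment arm contributes a
patient count `n`, an observed 5-year biochemical relapse-free survival
(bRFS) proportion `p`, and a dose schedule (total dose `D` in Gy, fraction
number `N` or dose per fraction `d`), and the arm-level control proportion
is modelled with the Poisson tumour control probability

    P = exp(−exp(k − αD − βD²/N)) = exp(−exp(k − αD − βDd))

where `k` is the natural logarithm of the effective clonogenic target cell
number, `α` (Gy⁻¹) the one-track lethal-damage coefficient and `β` (Gy⁻²)
the two-track coefficient.  The triple `(k, α, α/β)` is estimated by
maximising the grouped binomial log-likelihood

    ℓ = Σᵢ nᵢpᵢ log Pᵢ + nᵢ(1 − pᵢ) log(1 − Pᵢ)

with a multi-start quasi-Newton optimiser.  Uncertainty comes from the
leave-one-arm-out jackknife and the BCa bootstrap over arms; fits are
verified with a proportion-based chi-square comparison of calculated and
observed bRFS; and biologically effective doses, BED = D(1 + d/(α/β)),
convert schedules between fraction sizes.  Three transcribed multi-arm
tables ship with the package (conventional fractionation, moderate
hypofractionation, SBRT), along with a synthetic-cohort generator and a
parameter-recovery harness.

The intended audience is radiation oncology researchers and biostatisticians
doing dose-response meta-analysis of grouped (arm-level) outcome data.

## Worked example

```r
library(lqtcp)

tab <- load_fixture("conventional")   # 22 arms, 7793 patients
fit <- fit_mle(tab)
fit
#> LQ/TCP maximum-likelihood fit: 'conventional' (22 arms, 7793 patients)
#>                 estimate       se   wald_p
#> k                5.32200 0.376900 2.82e-45
#> alpha (Gy^-1)    0.04204 0.006833 7.62e-10
#> alpha/beta (Gy)  1.72400 0.454800 1.49e-04
#> log-likelihood -3867.6765; converged: TRUE
```

`k` and `α` are sharply determined; the α/β ratio is not — its likelihood is
nearly flat over several tenths of a Gy (see the vignette), which the
jackknife makes explicit:

```r
jk <- jackknife(tab, point = fit)
jackknife_interval(jk)
#>    parameter      point       lower     upper level           method
#> 1          k 5.32180279  0.86874932 9.7748563  0.95 jackknife_normal
#> 2      alpha 0.04204282 -0.02696283 0.1110485  0.95 jackknife_normal
#> 3 alpha_beta 1.72444918 -2.06262209 5.5115204  0.95 jackknife_normal
```

The verification step substitutes the fitted parameters back into the TCP
formula and compares calculated with observed proportions:

```r
chi_square_gof(tab$brfs_5y, predicted_brfs(fit$params, tab), labels = tab$author)
#> Proportion-based chi-square: X^2 = 0.0997, df = 21 (m_minus_1), p = 1
```

so the fitted curve passes essentially through the observed proportions.
Finally, the BED re-analysis of three hypofractionation trials shows why the
ratio matters: under the classical α/β = 1.5 Gy the hypofractionated arms
look dose-escalated, while under regimen-specific ratios the ordering flips:

```r
run_bed_reanalysis()[, c("trial", "arm", "total_dose", "n_fractions", "bed_low", "bed_regimen")]
#>       trial              arm total_dose n_fractions bed_low bed_regimen
#> 1 RTOG 0415 hypofractionated       70.0          28   186.7       120.6
#> 2 RTOG 0415     conventional       73.8          41   162.4       148.4
#> 3     HYPRO hypofractionated       64.6          19   211.0       128.1
#> 4     HYPRO     conventional       78.0          39   182.0       165.6
#> 5 Fox Chase hypofractionated       70.2          26   196.6       125.0
#> 6 Fox Chase     conventional       76.0          38   177.3       161.4
```

`reproduce_main_tables()` runs the whole pipeline (fit, jackknife, BCa,
chi-square) for all three fixture groups and tabulates the rounded estimates
against the packaged published reference values with per-cell deltas.  A
thin command-line wrapper with `fit`, `ci`, `gof`, `bed`, `simulate`,
`recover` and `reproduce` subcommands lives at
`inst/scripts/lqtcp-cli.R`.

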