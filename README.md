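# ifnpkpd

Population PK-PD modelling of a sustained-release subcutaneous
interferon-α (IFN-α) formulation, with serum **neopterin** — an
immune-activation marker released by monocytes/macrophages — as the
pharmacodynamic readout.

## Who this is for

Pharmacometricians and clinical-pharmacology analysts who want a fully
scripted, testable re-implementation of this analysis chain: structural
model, trial simulation, nonlinear mixed-effects estimation, NCA,
bootstrap and VPC — with no dependence on NONMEM or on the original
(unavailable) raw data.

## The model

**PK** — one-compartment disposition, first-order elimination
(k<sub>e</sub> = CL/F ÷ V/F), and a *mixed* absorption input that
reproduces the double-peak profiles seen after dosing:

* zero-order input of a fraction f<sub>z</sub> = 1/(1+e<sup>−RF</sup>) of
  the dose over D2 hours (first peak, ~24 h), in parallel with
* a lagged first-order input (rate KA, onset ALAG ≈ 86 h) of the
  remainder (second rise, ~100 h).

Solved in closed form; dA1/dt = −KA·A1, dA2/dt = KA·A1 + r0(t) − Ke·A2.

**PD** — turnover (indirect-response) model with one transit
compartment:

    dA3/dt = Kin·E(C) − Ktr·A3
    dA4/dt = Ktr·A3 − Kout·A4          (A4 = neopterin, nmol/L)

with sigmoid stimulation E(C) = 1 + Emax·C^γ / (EC50(t)^γ + C^γ) and a
**time-increasing EC50**, EC50(t) = ECB·(1 + CA·(1 − e^(−CB·t))), the
phenomenological description of the tolerance that makes the neopterin
response almost dose-flat over a 4× dose range.  Identifiability
constraints: Kin = Kout·BASE, Ktr = 1/MTT.

Estimation is an approximate marginal-likelihood (Laplace with
interaction, FOCE-I-style Gauss-Newton Hessians) with log-normal
between-subject variability, additive/proportional residual error, and
sequential PK→PD coupling through per-subject empirical Bayes PK
parameters.  See the methods vignette
(`vignettes/ifn-neopterin-pkpd.Rmd`) for every numerical choice.

## Worked example

Simulate the reference trial (4 dose groups × 6 subjects, 9–36 MIU),
run the NCA, and refit the PK model:

```r
library(ifnpkpd)

ds <- simulate_study(seed = 101)   # 864 records, 24 subjects
run_nca(ds)$groups[, c("group", "n", "cmax_mean", "tmax_median",
                       "auclast_mean")]
#>   group n cmax_mean tmax_median auclast_mean
#> 1     9 6  28.74374          21     2.291441
#> 2    18 6  55.56858          21     3.973995
#> 3    27 6  93.63566          18     8.243623
#> 4    36 6 122.11987          27     9.057647

fit <- fit_pk(ds, control = fit_control(se = FALSE))
round(fit$theta, 4)
#>     cl_f      v_f       d2       ka     alag       rf 
#>  12.0212 663.8887  18.4806   0.0081  84.5434   0.0950
```

AUClast grows with dose while the neopterin stage (below) does not; the
refitted apparent clearance (12.2 L/h generated, 12.0 recovered here)
shows the estimator recovering the generating values from one synthetic
study.  The full sequential experiment (11 replicate studies by
default, PK + PD) is one call:

```r
rec <- recovery_experiment(seed = 1)
print(rec)   # median estimates vs truth, pass/fail at the 20% tier
```

The neopterin saturation property itself is a model invariant you can
verify in seconds — PK exposure scales exactly 4× from 9 to 36 MIU while
the neopterin AUC ratio stays far below 4:

```r
tt <- seq(0, 264, 0.5)
auc <- function(x) sum(diff(tt) * (head(x, -1) + x[-1]) / 2)
pk <- default_pk_parameters(); pd <- default_pd_parameters()
auc(pk_concentration(pk, dose_event(36), tt)) /
  auc(pk_concentration(pk, dose_event(9), tt))
#> [1] 4
auc(pd_trajectory(pk, pd, dose_event(36), tt)) /
  auc(pd_trajectory(pk, pd, dose_event(9), tt))
#> [1] 1.861708
```

## Command line

```sh
Rscript -e 'ifnpkpd::cli_dispatch()' simulate --seed 1 --out out/
Rscript -e 'ifnpkpd::cli_dispatch()' pipeline --seed 1 --out out/
```

Stages: `simulate`, `fit-pk`, `fit-pd`, `nca`, `vpc`, `bootstrap`,
`pipeline`; each writes CSV/JSON artifacts plus a provenance block
(seed, config hash, versions).

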