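# rsbuffer

Deterministic kinetic modelling of **mRNA buffering** — the homeostasis
of mRNA concentration achieved by compensatory coupling of the mRNA
production and degradation rates — through the **releasing-shuttling
(RS) mechanism**. The package is for systems biologists who want to
simulate, perturb, and fit this class of compartmental
transcription/export/degradation models: the seven-state ODE core with
a conservation-aware steady-state solver, seven mechanistic variants,
the standard in-silico perturbation protocols (genome-wide screens,
volume scans, acute decay-factor depletion, Pol II depletion,
transcription shutoff, host shutoff, two gene groups), a staged
nonlinear least-squares parameter-estimation pipeline for fold-change
time courses, and synthetic-data generators with known ground truth.

## The model

Two proteins are released from the preinitiation complex at every
transcription initiation. X cycles nucleus → cytoplasm → nucleus
(released `Xn` → decay factor `Xc` → transcription factor `Xp`); Y
alternates between an export-factor state `Yn` and a TF state `Yp`.
With export and degradation proportional to the `Yn` and `Xc`
concentrations,

```
dNmn/dt = kn − αm (NYn/Vn) Nmn           dNXn/dt = kn − αx NXn
dNmc/dt = αm (NYn/Vn) Nmn − βm (NXc/Vc) Nmc
dNXc/dt = αx NXn − βx NXc                dNXp/dt = βx NXc − kn
dNYn/dt = kn − αy NYn                    dNYp/dt = αy NYn − kn
```

and a production law `kn = k0 · Vn/(Vn+Kv) · Km/(cmn+Km) ·
cXp/(cXp+Kx) · cYp/(cYp+Ky)`, the steady state pins both mRNA
concentrations to rate-constant ratios,

```
cmn = αy/αm        cmc = βx/βm
```

independent of the production rate and of every production-law
parameter — which is exactly the buffering seen in genome-wide
perturbation screens. The per-mRNA degradation rate is
`δm = βm·NXc/Vc`, so degradation tracks production through the size of
the `Xc` pool.

## Worked example

```r
library(rsbuffer)

p <- rs_params()          # basic parameter set (copies, fL, minutes)
ss <- rs_steady_state(p)
ss
#> <rs_steady>  kn* = 450.759 molecules/min, delta_m* = 0.0536618 /min
#>        Nmn        Nmc        NXn        NXc        NXp        NYn        NYp
#>  44390.200   8400.000   4507.590 201232.000  24260.700    866.844  10133.200
#> converged: TRUE  residual: 1.756462e-11
```

The self-consistent production rate is ~451 molecules/min and the mRNA
lifetime `1/δm*` ~19 min. `Nmc/Vc = 8400/37.2 = 225.8 /fL` equals
`βx/βm = 2.24e-3/9.92e-6` — the buffered cytoplasmic concentration.

Acutely removing 80% of the cytoplasmic decay factor reproduces the
three-phase transcription response:

```r
dep <- acute_depletion_timecourse(p, fdep = 0.8)
dep$phases[, c("Tacc", "Tadp", "Trev", "Tacc_approx", "Trev_approx",
               "plateau_kn_fold", "peak_mrna_fold")]
#>    Tacc  Tadp  Trev Tacc_approx Trev_approx plateau_kn_fold peak_mrna_fold
#> 1  52.7  35.3  49.1        65.9        55.8           0.334           1.25
autoplot(dep)
```

Total mRNA accumulates to a 1.25-fold peak while production holds, then
production collapses to a 0.33 plateau and the excess mRNA reverts with
a ~49-min relaxation time — within 30% of the closed-form
approximations `(NXp*−Kx·Vn)/(0.8·kn*)` and `Vc/(βm·NXc_rev)`.

A noisy genome-wide screen (1000 lognormal parameter draws, Poisson
copy noise, 5% rate noise) shows buffering statistically:

```r
scr <- run_perturbation_screen(update_params(p, k0 = p$k0 / 8),
                               screen_config(n_samples = 1000, seed = 1))
scr$summary
#>   r_kn_cmn r_kn_cmc slope_dm_kn slope_dm_kn_linear n_rejected
#> 1   -0.303   0.0300       0.926               1.25          0
autoplot(scr)                      # cytoplasmic fold vs production fold
autoplot(scr, y = "delta_m_fold")  # degradation tracks production (y = x)
```

The production fold spans orders of magnitude yet is uncorrelated with
the cytoplasmic concentration fold (|r| = 0.03), and the
degradation-vs-production log-fold slope is ~1: the y = x signature.

Fitting a synthetic depletion time course recovers the generator:

```r
syn <- synth_depletion_dataset(p, noise = noise_spec(FALSE, 0, 0))
st  <- staged_initial_estimates(syn$dataset)
fit <- optimize_parameters(syn$dataset, st$params, fdep = 0.8)
glance(fit)   # objective ~1e-12 on noiseless data
tidy(fit)     # the 14 parameters
```

See `vignette("rs-model")` for the model variants, the experiment
protocols, the staged estimation scheme, and the design decisions.

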