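---
title: "The releasing-shuttling model of mRNA concentration homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The releasing-shuttling model of mRNA concentration homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsbuffer)
```

## The problem: mRNA buffering

Eukaryotic cells hold their total mRNA concentration remarkably constant.
Knock down a transcription factor and the production rate drops — but the
degradation rate drops with it; impair the decay machinery and production
falls in compensation. The same homeostasis holds across cell volumes:
bigger cells make more mRNA but degrade each molecule more slowly, keeping
the concentration fixed. This phenomenon is called **mRNA buffering**, and
single-species feedback models (mRNA repressing its own production, or
promoting its own degradation) cannot reproduce its most striking feature:
a production rate that varies over orders of magnitude with *zero*
correlation to the concentration.

`rsbuffer` implements a mechanistic explanation, the **releasing-shuttling
(RS) model**. Two proteins are released from the preinitiation complex at
every transcription initiation event:

* **X** — released in the nucleus (`Xn`), exported to the cytoplasm at
  rate `alpha_x` where it becomes the decay factor (`Xc`) that degrades
  cytoplasmic mRNA, then shuttles back at `beta_x` to rejoin the
  preinitiation complex as a transcription factor (`Xp`). In budding
  yeast, Xrn1 (the major 5'→3' exonuclease) behaves like a component of X.
* **Y** — released as the export factor (`Yn`) that carries nuclear mRNA
  to the cytoplasm, reverting to its transcription-factor state (`Yp`) at
  rate `alpha_y`.

Because one copy of each is released per initiation, the sizes of the
`Yn` and `Xc` pools *encode the production rate itself* and synchronize
export and degradation to it.

## State, dynamics, and the production law

The state holds seven copy numbers: nuclear and cytoplasmic mRNA
(`Nmn`, `Nmc`), three X pools (`NXn`, `NXc`, `NXp`) and two Y pools
(`NYn`, `NYp`). With production rate $k_n$:

$$
\begin{aligned}
\dot N_{mn} &= k_n - \alpha_m \tfrac{N_{Yn}}{V_n} N_{mn}, &
\dot N_{mc} &= \alpha_m \tfrac{N_{Yn}}{V_n} N_{mn}
             - \beta_m \tfrac{N_{Xc}}{V_c} N_{mc}, \\
\dot N_{Xn} &= k_n - \alpha_x N_{Xn}, &
\dot N_{Xc} &= \alpha_x N_{Xn} - \beta_x N_{Xc}, \\
\dot N_{Xp} &= \beta_x N_{Xc} - k_n, &
\dot N_{Yn} &= k_n - \alpha_y N_{Yn}, \qquad
\dot N_{Yp} = \alpha_y N_{Yn} - k_n.
\end{aligned}
$$

The X rows and Y rows each sum to zero, so the totals
$N_{Xt} = N_{Xn}+N_{Xc}+N_{Xp}$ and $N_{Yt} = N_{Yn}+N_{Yp}$ are
conserved exactly. The production rate is a product of four
Michaelis–Menten factors,

$$
k_n = k_0\,
\frac{V_n}{V_n + K_v}\,
\frac{K_m}{c_{mn} + K_m}\,
\frac{c_{Xp}}{c_{Xp} + K_x}\,
\frac{c_{Yp}}{c_{Yp} + K_y},
$$

where the volume factor proxies limiting Pol II (its copy number scales
with nuclear volume), the second factor is negative feedback of nuclear
mRNA on transcription, and the last two are promoter occupancies of the
TF states of X and Y.

At steady state the flux balances give `NXn = kn/alpha_x`,
`NXc = kn/beta_x`, `NYn = kn/alpha_y`, and — the central result —

$$
c_{mn} = \frac{N_{mn}}{V_n} = \frac{\alpha_y}{\alpha_m},
\qquad
c_{mc} = \frac{N_{mc}}{V_c} = \frac{\beta_x}{\beta_m}:
$$

both mRNA concentrations are ratios of rate constants, independent of
$k_n$ and of every production-law parameter. That *is* buffering.

```{r}
p <- rs_params()   # the basic parameter set (copies, fL, minutes)
ss <- rs_steady_state(p)
glance(ss)
c(cmn = ss$state[["Nmn"]] / p$Vn, cmc = ss$state[["Nmc"]] / p$Vc)
```

## Numerical choices

**Steady-state solver.** Substituting the conservation laws into the
production law with $c_{mn}$ fixed at $\alpha_y/\alpha_m$ turns the
steady-state problem into a one-dimensional fixed point $k_n = F(k_n)$
with $F$ strictly decreasing on $[0, k_n^{\max}]$, where
$k_n^{\max} = N_{Xt}/(1/\alpha_x + 1/\beta_x)$ is the production ceiling
imposed by the X budget. `rs_steady_state()` brackets and bisects to a
relative tolerance of 1e-12; tests cross-check the root against a damped
fixed-point iteration and a dense sign-change scan.

**Integrator.** `rs_simulate()` uses the stiff-capable `lsoda` from
deSolve (the production collapse after an acute depletion is sharp) with
`rtol = 1e-8`, `atol = 1e-10` copies, both overridable. Copy numbers
more negative than −1e-9 abort the run; round-off negatives above that
threshold are clipped to zero with a warning. These tolerances are this
package's own defaults, chosen so conservation drift stays below 1e-8
over the longest protocols.

**Degenerate inputs.** Infeasible parameter sets (production ceiling
non-positive, TF pools driven negative across the whole bracket) raise
errors rather than returning clipped states; screen draws that land
there are rejected, counted, and redrawn.

## Model variants

Seven modifications probe which ingredients are essential
(`rs_variant()`, `variant_steady_state()`, `variant_relax()`):

| kind | change | buffering |
|---|---|---|
| `nonessential_x` | transcription proceeds without Xp (coarse rates `k1 < k2`) | **breaks** — $c_{mc}$ depends on $N_{Xp}$ and $V_n$ |
| `shuttling_y` | Y exits the nucleus and returns at `beta_y` | holds |
| `exosome` | nuclear decay/TF factor Z (`alpha_z`, `alpha_d`, `Kz`) | holds |
| `dropoff` | premature termination with probability `delta` | holds, scaled by $1-\delta$ |
| `imprinting` | released X binds nascent mRNA and is co-exported | holds |
| `pabpc1` | protein P released on mRNA decay represses transcription | host-shutoff regime |
| `two_group` | two fully independent RS systems | holds per group |

For the exosome variant the nuclear degradation flux removes a fraction
$\alpha_d\alpha_y/(\alpha_m\alpha_z+\alpha_d\alpha_y)$ of produced mRNA
before export, so the cytoplasmic steady pool carries the complementary
factor $\alpha_m\alpha_z/(\alpha_m\alpha_z+\alpha_d\alpha_y)$ relative
to the core model; the implementation uses this self-consistent form
(it reduces to the core expression as $\alpha_d \to 0$) because it is
what the variant's own ODEs relax to, and the test suite checks
closed form against relaxation to 1e-6.

The two feedback-only null models (`feedback_steady_state()`) are kept
as the negative control: their steady concentration tracks the
production parameters, so they cannot buffer. The negative-feedback
production term is parsed as $a/(c_m + b)$ — inhibition of production by
the mRNA itself.

Variant extras with no externally fixed values are package defaults
chosen once
for biological plausibility: `beta_p = 0.05`/min, `Kp = 2e4`/fL,
`NPt = 6e4` (P shuttles slowly and its free nuclear pool sits near its
MM constant so repression is engaged but not saturated), and
`alpha_z = 0.5`/min, `alpha_d = 1e-5` fL/min, `Kz = 100`/fL, `NZt = 1e4`
(Y-like magnitudes; nuclear decay a minor flux next to export). The
two-group variant duplicates the full parameter set per group with no
shared resources — that independence is exactly what makes the
unperturbed group invariant.

## In-silico experiments

All protocols start from a verified steady state and are exposed as
seeded, deterministic functions:

* `run_perturbation_screen()` — genome-wide perturbations: every
  parameter drawn from a *mean-preserving* lognormal
  ($\sigma^2 = \log(1+\mathrm{CV}^2)$, $\mu = \log(\text{mean}) -
  \sigma^2/2$), CV 0.5 for production-law parameters and totals, 0.2
  for the other rates; Poisson noise on mRNA copy numbers and 5%
  multiplicative Gaussian noise on reported rates. The degradation-vs-
  production alignment along $y=x$ is summarized as the through-origin
  slope in log-fold space, which is symmetric in the two axes; the
  linear-fold slope is also reported but is inflated by the reciprocal
  moments of the sampled lognormals ($E[1/V_c^{\text{fold}}] = 1.25$ at
  CV 0.5).
* `run_alpha_m_screen()` — export impairment: `alpha_m` at CV 1
  dominant; nuclear concentration anti-correlates with production while
  the cytoplasmic concentration is untouched.
* `volume_scan()` — steady states across cell volumes with totals
  scaling proportionally, under the MM volume law or the superlinear
  ($10^{-5} V_n^{1.5}$) and oscillating ($0.05 V_n(\sin 5V_n + 2)$)
  alternatives; concentrations are volume-invariant under all three.
* `acute_depletion_timecourse()` — removes 80% of `Xc` at $t=0$
  (nuclear X untouched, total X reduced accordingly) and measures the
  three phases. Phase boundaries are operationalized as the first
  crossing of $0.95\,k_n^{\text{bf}}$ (accumulation → adaptation) and
  first sustained entry into a 1% band around the final plateau
  (adaptation → reversion); closed-form approximations
  $T_{acc} \approx (N_{Xp}^* - K_x V_n)/(f_{dep} k_n^*)$ and
  $T_{rev} \approx V_c/(\beta_m N_{Xc}^{rev})$ are reported alongside.
* `polII_depletion_decay()` — focal-gene decay under control vs doubled
  `Kv` (halved Pol II). The focal pools are passive species in the
  constant global fields, a two-exponential closed form whose terminal
  slope is the *slower* of the export coefficient
  $\alpha_m N_{Yn}/V_n$ and $\delta_m$; at the basic parameters that is
  the export coefficient, and the depleted curve lies above the control
  at every $t>0$.
* `transcription_shutoff()`, `recovery_time()`,
  `viral_infection_timecourse()` (PABPC1 variant, `alpha_m`×20 preset,
  `beta_m`×10 step), `two_group_timecourse()`.

### The recovery-time landscape

`recovery_time()` halves `k0`, shifts/normalizes the mRNA fold so the
pre-step value is 1 and the minimum 0, and reports the first re-crossing
of 0.9 after the minimum. Mapping this across the total X budget reveals
two regimes. X-replete cells show a deep dip whose recovery is limited
by the slow X redistribution between `Xp` and `Xc` (timescale
$\sim 1/\beta_x$, independent of $N_{Xt}$). As $N_{Xt}$ falls the
production rate becomes budget-limited and *more* strongly buffered
against `k0`, so the dip nearly vanishes — and only below a few percent
of the basic budget does the vanishing degradation rate
($1/\delta_m \propto 1/N_{Xt}$) take over and the recovery time diverge.
The divergence in the small-budget limit is the biologically meaningful
statement (a cell whose entire X is one knocked-out protein cannot
re-equilibrate); between the two regimes the recovery time is
*non-monotone* in $N_{Xt}$, which is worth knowing before treating any
single pair of budgets as representative.

## Staged parameter estimation

`staged_initial_estimates()` reconstructs a full parameter start point
from one depletion time course (total-mRNA fold and nascent fold, both
normalized at $t=0$), following the anchor-by-anchor scheme:

1. the nascent plateau over the reversion window gives
   $k_n^{rev}/k_n^{bf}$, and — because the cytoplasmic pool returns to
   the same level — the same ratio for $\delta_m$;
2. the reversion fit $FC(t) = 1 + a e^{-bt}$
   (`fit_reversion_decay()`, window $t \ge 95$ min) gives
   $\delta_m^{rev} = b$, hence $\delta_m^{bf}$ and
   $N_{mc}^{bf} = k_n^{bf}/\delta_m^{bf}$ with the assumed
   $k_n^{bf} = 500$/min;
3. phase durations are read from the nascent curve; production and the
   Xc→Xp replenishment rate are approximated as piecewise-linear, giving
   the TF-pool drops $N_{Xp}$ at the phase boundaries;
4. the three-point Michaelis–Menten system
   $k_{n,i} = k_0' N_{Xp,i}/(N_{Xp,i} + K_x')$ is solved for
   $k_0'$, $K_x'$, $N_{Xp}^{bf}$ (reduced to one root-find);
5. integrating the cytoplasmic balance under the linear approximations
   yields the accumulated mRNA at the end of adaptation; the dataset's
   measured peak fold then fixes $N_{mn}$ (the peak fold is read from
   the data, not hard-coded, so the pipeline runs on any synthetic
   table);
6. the remaining constants are backed out from the steady-state
   relations using the assumed seed copy numbers
   ($k_0 = 6000$/min, $K_y = 100$/fL, $N_{Yp} = 10^4$, $N_{Xn} = 5000$,
   $N_{Xc} = 2\times10^5$, $N_{Yn} = 1000$; note
   $N_{Yn} + N_{Yp} = 1.1\times10^4$, the basic-set total).

Because a normalized series inherits the noise of its single reference
measurement, the nascent baseline is re-estimated as the median of the
early running-median-smoothed points and divides all nascent anchors;
phase crossings are likewise detected on the smoothed series so that
measurement noise cannot trip them.

`optimize_parameters()` then minimizes the equal-weighted MSE between
the model's two fold curves and the data by Levenberg–Marquardt
(`minpack.lm::nls.lm`) on the logarithms of the 11 free parameters
(`Vn`, `Vc`, `Kv` fixed, positivity by construction). Equal weights are
the declared default — there is no canonical weighting for these two
series — and a `weights` argument exposes alternatives. Individual parameters are
only jointly identifiable from a single time course (the model is
sloppy); the pipeline's contract is the *objective*, which reaches
~1e-12 on noiseless synthetic data and the injected-noise floor on noisy
data. `fit_volume_scaling()` recovers the volume MM constant from
production-fold-vs-volume data by one-parameter least squares, flagging
the unidentifiable linear regime at its upper bound.

## Synthetic data: what it emulates, and what it does not

`synth_depletion_dataset()`, `synth_screen_dataset()` and
`synth_volume_dataset()` emulate the *statistical structure* of the
deposited empirical tables (depletion time courses, perturbation
screens, volume series) — fold-change normalization at a reference
point, Poisson copy-number noise, multiplicative Gaussian rate noise at
CV 0.05 (0.5/0.2 lognormal parameter spreads for screens) — and return
their generating ground truth alongside, so every pipeline stage is
testable without downloads. Recovery tests consume only the dataset,
never the truth. The depletion grid default is 0–300 min at 1-min
resolution, covering accumulation through reversion at the basic
parameter scales.

What passing these tests does *not* show: the generators draw from the
model itself, so they cannot detect model misspecification against real
cells; they contain no batch structure, no correlated measurement error,
no gene-to-gene regulatory heterogeneity, and the screen tables carry
one perturbation per record rather than a CRISPR library's guide-level
structure. Conclusions about real datasets require the real tables
(`read_timecourse_table()`, `read_screen_table()` accept column-mapping
overrides for the deposited layouts).

## Known limitations

* Bulk, deterministic description of an averaged cell: no single-cell
  stochasticity (no Gillespie path), no explicit cell-volume dynamics
  beyond parametric scans, no splicing.
* Pol II is proxied by the nuclear-volume MM factor; its copy number is
  not tracked.
* The basic parameter set is treated as a fixture, not re-derived
  here; the staged pipeline recovers composite
  quantities, not all 14 constants individually.
* The viral protocol reduces endonuclease kinetics to a step in
  `beta_m`.
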