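---
title: "Spectral inequality indices for depth-of-consciousness monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral inequality indices for depth-of-consciousness monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(docgini)
library(dplyr)
```

## The problem

General anesthesia suppresses consciousness, and the EEG tracks that
suppression: as the effect-site concentration of a hypnotic such as propofol
rises, broadband cortical activity gives way to large, slow delta
oscillations while high-frequency power fades. A depth-of-consciousness
(DOC) index compresses this spectral reorganization into a single number
that an anesthesiologist can follow in real time.

`docgini` implements a family of such indices built on a simple
observation: anesthesia makes the power spectrum *unequal*. Awake, in-band
power is spread relatively evenly across frequencies, with only a mild
8--12 Hz (alpha) concentration; deep, it piles up below 3 Hz. Inequality of
a distribution is exactly what the Gini coefficient of economics measures,
so the package's core indices are:

* **SpG** (spectral Gini index): the Gini coefficient of the in-band power
  spectrum values,
  $$\mathrm{SpG} = \frac{\sum_i \sum_j |\check X(f_i) - \check X(f_j)|}
  {2 N \sum_i \check X(f_i)},$$
  0 for a flat spectrum, approaching 1 as power concentrates in few bins.
* **BSpG** (binarized spectral Gini index): the same statistic after each
  bin is thresholded against a baseline-derived power level $\alpha$. For a
  0/1 spectrum the double sum collapses to $M/N$ --- the fraction of
  sub-threshold bins --- which makes BSpG essentially free to compute
  (sorting is not even needed) while preserving the inequality
  interpretation.

Five established comparator indices are provided under the same epoching
pipeline: spectral entropy (SpE), permutation entropy (PE), approximate
entropy (AE), the detrended-fluctuation-analysis exponent (DFA), and the
bispectral SynchFastSlow (SFS). SpG/BSpG *rise* with hypnotic depth;
SpE/PE/AE *fall*; DFA and SFS rise.

## Processing pipeline

The defaults in `doc_config()` reproduce the reference protocol end to end:

| parameter | default | meaning |
|---|---|---|
| `filter.order`, `filter.cutoff_hz` | 9, 48 | Butterworth low-pass before analysis |
| `epoch.length_s`, `epoch.step_s` | 10, 5 | 10 s epochs, 50% overlap: one value per 5 s |
| `window` | blackman | epoch taper before the DFT |
| `indices.band_hz` | 0.8--47 | analysis band for SpE, SpG, BSpG |
| `bspg.threshold_fraction` | 0.02 | $\alpha$ = 2% of mean pre-infusion in-band bin power |
| `smoothing_s` | 30 | trailing moving average of each index series |
| `ae.n`, `ae.m`, `ae.r_factor` | 1024, 2, 0.2 | AE on the last 4 s of each epoch, $r = 0.2\,\mathrm{SD}$ |
| `pe.m` | 3 | ordinal patterns of 3 samples at lags 1 and 2 |
| `dfa.range_ms` | 6.7--157.8 | DFA segment lengths |
| `sfs.subepoch_s` | 2 | SFS bispectrum averaged over 2 s sub-epochs (50% overlap) |

Design choices where the protocol leaves room, and why:

* **Frequency indexing.** DFT bin $k$ (1-based) sits at $(k-1) f_s / N$ and
  a band is the *closed* interval of bin frequencies. This convention is
  pinned by the printed example that 13--40 Hz at $f_s = 256$, 5 s epochs
  corresponds to bins $L = 66$ to $H = 201$; `band_indices()` reports both
  the 1-based indices and 0-based offsets.
* **Zero-phase filtering.** The low-pass is applied forward--backward by
  default so that filtering adds no group delay to index timestamps
  (`filter.zero_phase = FALSE` gives the single-pass causal filter).
  Mirror padding absorbs the start-up transients; point-symmetric (odd)
  reflection was rejected because a zero-phase filter passes an
  antisymmetric neighbourhood through its centre unchanged, pinning raw
  endpoint values into the output.
* **Epoch stamps.** An epoch's value is stamped at its *end* (the causal
  choice for a monitor); `timestamp = "center"` is available.
* **Smoothing** is a trailing (causal) moving average over the values of
  the last 30 s --- 6 values at the default stepping; at the start of a
  series the average runs over the values available so far.
* **Degenerate inputs.** An all-zero band is an error by default
  (`gini.degenerate = "na"` lets a pipeline carry on with `NA`). An
  all-sub-threshold binarized spectrum is a 0/0 in the $M/N$ closed form;
  it is defined as 1 --- the limit of total suppression --- with a warning.
  Bins exactly at the threshold binarize to 0.
* **Gini evaluation.** The default path uses the sorted-array identity
  ($O(N \log N)$); the defining double sum is kept as `method = "pairwise"`
  and as the oracle in the test suite. A tiny negative result from
  cancellation on near-equal inputs is clamped to 0.
* **PE normalization.** The two-lag entropy sum is divided by
  $2\log m!$, which guarantees PE $\le 1$; the alternative literal
  normalizer $\log((m{+}1)!/2)$ is selectable
  (`pe.normalization = "log_mp1fact_half"`) but is not bounded. Ordinal
  patterns use the standard $m$-point embedding spanning $(m-1)\tau$
  samples; ties rank by order of occurrence. An extended $m{+}1$-point
  reading of the embedding is available behind `pe.embedding`.
* **AE.** Classic Pincus approximate entropy with self-matches, Chebyshev
  distance, and $r$ tied to the SD of the analyzed window. Because the
  protocol fixes $N = 1024$ samples (4 s) inside a 10 s epoch, the *final*
  1024 samples are used: the most recent data best reflect the current
  state.
* **DFA.** Segment lengths are log-spaced integers within the configured
  range; $n = 2$ is excluded because a line interpolates two points exactly
  (zero residual). At the default 6.7--157.8 ms range the segment lengths
  (3--40 samples at 256 Hz) sit in the small-scale regime where
  first-order DFA of white noise follows the exact law
  $F^2(n) = \sigma^2 (n^2 - 4)/(15 n)$ rather than the asymptotic
  $n^{1/2}$; the test suite verifies that law directly and checks the
  0.5/1.5 white-noise/random-walk exponents on larger scales
  (16--128 samples) where the asymptote holds.
* **SFS.** The bispectrum is averaged over 2 s sub-epochs with 50% overlap
  tiled across the analysis epoch, giving 0.5 Hz resolution so the
  0.5--47 Hz band edge lands on a bin. The 40--47 Hz denominator grid is
  the subset of pairs with *both* frequencies in 40--47 Hz (the sum
  frequency is only constrained to stay below Nyquist). Natural logarithms
  throughout.
* **BSpG threshold.** $\alpha$ is 2% of the mean per-bin in-band power
  averaged over all complete pre-infusion epochs (per-bin mean, not total
  band power over bin count --- the two differ by a constant factor and the
  protocol does not distinguish them; the choice is explicit in
  `calibrate_threshold()`).
* **Sampling schedule.** `select_index_samples()` reads the two clinical
  schedule clauses as anchored to infusion start and end respectively:
  30 s spacing for 10 min then 1 min for 60 min after start; 30 s for
  30 min, 1 min for 20 min, 2 min for 20 min after termination. Instants
  beyond the series are dropped with a warning (the default synthetic
  course ends 60 min after infusion stop, so the final 10 min of the
  70 min post-termination schedule is always truncated).
* **Stage statistics** pool all samples inside each window (median and
  2.5/97.5 percentiles, linear-interpolation definition); whether to pool
  samples or subject-level summaries is left open by the protocol, and
  pooling is the choice here.

## PK/PD harness

The propofol disposition model is a mammillary three-compartment model with
central elimination and the covariate structure
$V_1 = 10.3 + (\mathrm{LBM}/45)^{6.63}$ L and
$\mathrm{Cl} = 0.217 + (\mathrm{WT}/W_{\mathrm{ref}})^{1.02}$ L/min
(remaining point estimates $V_2 = 75.3$, $V_3 = 846$ L, $Q_1 = 0.928$,
$Q_2 = 0.679$ L/min). The published model states the weight reference
inconsistently (58 kg in the final parameter table, 63 kg in the equation
text); both are supported via `pk.weight_ref`, with 58 as the default
because the final-model table is the authoritative fit. Only the
point-estimate structural model is implemented --- population
interindividual variability, objective-function model selection and
bootstrap validation are deliberately out of scope.

`simulate_pk()` solves the linear system piecewise-analytically through its
eigendecomposition: exact to machine precision on each constant-rate
interval, with cumulative eliminated mass carried as a fourth state so mass
balance is verifiable to solver precision. The test suite cross-checks
against `deSolve` and the one-compartment closed form. Units: mg, L and
minutes give plasma concentration in mg/L, identically ug/mL.

The effect site follows $dC_e/dt = k_{e0}(C_p - C_e)$, integrated exactly
for linear (default) or stepwise plasma interpolation between grid points.
The concentration--effect link is the sigmoid Emax model
$E = E_0 + (E_{\max} - E_0) C_e^\gamma / (C_{e50}^\gamma + C_e^\gamma)$.
`fit_emax()` is additive-error nonlinear least squares; when $k_{e0}$ is
unknown, `fit_emax_with_ke0()` profiles the residual sum of squares over a
log-spaced grid (0.01--1 /min, 50 points --- the physiologically plausible
range for EEG effects of propofol) and refines the minimum by univariate
search, mirroring the sequential PK-then-PD strategy in which the plasma
course is fixed before the PD fit.

```{r emax-demo}
pd <- list(E0 = 0.037, Emax = 0.367, Ce50 = 2.88, gamma = 3.85)
conc <- pk_concentration_series(infusion_regimen(12, 60, 70),
                                covariate_pk(55, 70), ke0 = 0.081,
                                seq(0, 130, by = 0.25))
set.seed(1)
obs <- tibble(time_min = seq(1, 130, by = 1),
              e = emax_effect(approx(conc$time_min, conc$ce,
                                     seq(1, 130, by = 1))$y, pd) +
                rnorm(130, 0, 0.02))
fit <- fit_emax_with_ke0(conc[, c("time_min", "cp")], obs)
tidy(fit)
```

## Evaluation statistics

Prediction probability $P_K$ rescales Somers' $D$ of the index (dependent)
on effect-site concentration (independent):
$P_K = 1 - (1 - |D|)/2$, the probability that the index correctly orders
two randomly chosen anesthetic states. $D$ is computed by direct pair
enumeration on untied-in-$C_e$ pairs; concentrations enter as continuous
values without binning. The standard error is $\mathrm{se}(D)/2$ with
$\mathrm{se}(D)$ from a seeded nonparametric bootstrap (1000 resamples by
default) --- a deliberate substitution for the asymptotic cross-tabulation
SE of legacy statistical packages, which assumes a binned table this
package never forms. Spearman's $\rho$ is the Pearson correlation of
mid-ranks.

`sensitivity_curves()` contrasts how SpE and SpG react when one component
of a uniform $N$-bin spectrum is amplified by $A$ and the spectrum
renormalized. Both closed forms are derived exactly from the definitions
(the SpE algebra keeps the $A x_a \log A$ and $(A-1) x_a \log x_a$ terms,
and the SpG form is $(N-1)|A-1| / (N(N+A-1))$); the tests verify them
against direct evaluation of the index definitions on the perturbed
spectrum. SpG responds near-proportionally over decades of $A$ while SpE
saturates --- the core argument for an inequality measure over an entropy.

```{r sensitivity, fig.alt = "SpE and SpG sensitivity curves"}
plot_sensitivity()
```

## The synthetic anesthesia course

No public recordings accompany the clinical study, so `generate_subject()`
fabricates a complete, seeded anesthesia course on which every stage of the
package is testable:

1. the reference regimen (12 mg/kg/h for 60 min into a 70 kg, 55 kg-LBM
   subject, 5 min baseline, 60 min recovery) is pushed through the PK model
   and effect-site link ($k_{e0} = 0.081$ /min);
2. $C_e$ maps to a depth variable $e \in [0,1]$ through a sigmoid with
   $C_{e50} = 2.88$ ug/mL and $\gamma = 3.85$ (the steepest estimated index
   response); LOC/ROC events are placed where $e$ crosses 0.5;
3. the EEG is a sum of five band-limited Gaussian components (delta
   0.5--3, theta 4--7, alpha 8--12, beta 13--30, gamma 30--47 Hz): white
   noise through zero-phase 4th-order Butterworth band-passes, each
   calibrated so its in-band power equals the template, with per-sample
   envelopes interpolating each band's power geometrically between the
   awake and deep templates as $e(t)$ moves.

The awake template (densities 16/10/18/3/1.5 uV^2/Hz) shows the mild alpha
concentration over a broadband floor of resting wakefulness; the deep
template (200/12/8/2/0.006) concentrates power below 3 Hz (a > 12-fold
delta rise) and pushes gamma power below the 2% binarization threshold.
Splitting the high band into beta and gamma components --- rather than one
13--47 Hz block --- lets 30--47 Hz power sink in deep hypnosis while
13--30 Hz persists, reproducing the gradual high-frequency rundown seen in
propofol spectrograms and giving BSpG a deep plateau near the clinically
reported range.

What the generator does *not* model: burst suppression, spindles, artifact,
nonstationarity beyond the concentration-driven power trajectory, or any
phase coupling beyond what band-limited Gaussian noise provides. The
indices under test are spectral-distribution statistics, so second-order
structure is the right level of fidelity --- but passing tests on this
corpus demonstrates correct *mechanics and directionality*, not clinical
performance. In particular the bispectral SFS sees Gaussian data whose
coupling is incidental, and DFA sees a spectrum with a hard 47 Hz edge.

Because the observed indices reach the latent depth variable only through
the spectrum, fitting the sigmoid link to a computed index series recovers
the *kinetic* parameters well ($k_{e0}$, $C_{e50}$) while $E_0$ and
$E_{\max}$ reflect the measured index range and the apparent $\gamma$
steepens (a sigmoid composed with a sigmoid): the test suite asserts
exactly that, and full five-parameter recovery is demonstrated where it is
well-posed --- on index observations generated from the sigmoid itself.

```{r course, fig.alt = "Synthetic course with SpG and BSpG series"}
subj <- generate_subject(subject_scenario(seed = 1))
report <- run_full_pipeline(subj, indices = c("SpE", "SpG", "BSpG"),
                            n_boot = 0)
plot_index_series(report$series, events = subj$events)
report$metrics
```

## Problem sizes used in the shipped checks

The test suite and acceptance script favour the smallest sizes that pin
each property: worked examples are exact and instantaneous; oracle
equivalences run over exhaustive bit vectors to $N = 12$ plus 1000 random
draws; Monte-Carlo limits use $10^4$--$10^5$ samples; the Emax/ke0
recovery study uses 100 replicates of a 160-point sampling schedule; and
the end-to-end direction checks run five full 125 min synthetic subjects
at 256 Hz through the complete pipeline.

## Known limitations

* The clinical stage values, correlation coefficients and population PK/PD
  estimates of the source study require its 15-subject recordings, which
  were never deposited; this package reproduces the printed worked
  examples, limits and model structure, and validates everything else by
  construction on synthetic data.
* EDF input is not supported; recordings travel as CSV (`# fs:` header plus
  a `value` column). Multi-channel montages, artifact rejection and online
  operation are out of scope.
* BSpG requires a pre-infusion baseline (`t_I` event) to calibrate its
  threshold; without it the index is undefined by design.
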