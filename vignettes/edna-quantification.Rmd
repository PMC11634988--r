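---
title: "Bayesian quantification of eDNA from qPCR and ddPCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian quantification of eDNA from qPCR and ddPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eDNAquant)
```

## The problem

Environmental DNA surveys quantify trace amounts of species-specific DNA
in water or soil. At the concentrations that matter (often 10⁻²–10⁰
copies/μL of reaction volume) both instruments become stochastic: qPCR
reactions fail to amplify even when template is present, and ddPCR wells
may contain zero positive droplets. A point estimate from a single well is
then nearly meaningless; what is needed is a posterior distribution for
each sample's concentration that pools technical replicates and borrows
strength from the standard dilution series run on the same plates. That is
what this package provides, for both platforms, with matched outputs so
the platforms and model variants can be compared on precision.

## Models and assumptions

Everything is parameterised on `log10(C)` with C in copies/μL of reaction
volume, because all three calibration relationships (detection logit, Ct
mean, cloglog of droplet positivity) are linear on that scale and the
dilution series is decade-spaced.

**qPCR.** A reaction at concentration C amplifies with probability
`plogis(phi0 + phi1 * log10(C))`; conditional on amplification the Ct is
Normal with mean `beta0 + beta1 * log10(C)` and standard deviation
`exp(gamma0 + gamma1 * log10(C))`. The two-step structure is a hurdle
model: non-detected replicates are not discarded, they contribute the
Bernoulli factor `1 - theta`, which is exactly where the extra precision
at low concentration comes from. Assumptions worth stating:

- Detected Ct values are modelled as exact Normal draws. The instrument's
  cycle cap (42/45/52 depending on plate) is *not* entered as a truncation
  term in the continuous likelihood; a run that would have crossed
  threshold beyond the cap simply appears as a non-detect and is absorbed
  by the detection component. A right-truncated Normal would be the next
  refinement; at realistic parameter values the probability mass beyond
  the cap is negligible except at concentrations where detection is
  already rare.
- One shared detection curve (phi) serves standards and environmental
  samples alike. If field samples carry inhibitors, their effective phi
  differs from the standards' and this assumption biases low-concentration
  posteriors; inhibition covariates are out of scope.
- Technical replicates of a sample are conditionally independent given
  its single latent `log10(C)`.

**ddPCR.** Positive-droplet counts are
`W ~ Binomial(U, invCloglog(kappa0 + kappa1 * log10(C)))`. This is the
Poisson-partitioning physics rewritten as a regression: if every droplet
of volume V captures template as Poisson with mean `C * V`, then
`cloglog(omega) = log(V) + log(10) * log10(C)`, so a 100%-efficient assay
has `kappa0 = log(V)` and `kappa1 = log(10)`. Estimating (kappa0, kappa1)
from the standards instead of fixing them is the point: the deviation of
`exp(kappa0)` from the manufacturer droplet volume and of
`kappa1 / log(10)` from 1 are interpretable diagnostics of degraded
standards or anomalous assay chemistry. Replicates are aggregated through
the shared latent concentration — information pooling that the default
single-well formula `C = -log(1 - W/U) / V` does not have. Consistency
between the two is a package invariant: with kappa fixed at
`(log(V), log(10))`, the single-well binomial MLE equals the default
formula to numerical precision.

## Priors

The study data these models were built for state no priors, so the
package's defaults are its own choice: weakly informative, centred on PCR
physics, wide enough to cover 10⁻³–10⁶ copies/μL.

| parameter | prior | rationale |
|---|---|---|
| phi0 | Normal(0, 5) | uninformative intercept |
| phi1 | Normal(1, 2), > 0 | detection must rise with concentration |
| beta0 | Normal(40, 10) | typical qPCR intercepts 35–45 cycles |
| beta1 | Normal(−3.32, 2), < 0 | centred on 100% efficiency |
| gamma0 | Normal(0, 2) | Ct SD scale free over ~e⁻⁴–e⁴ |
| gamma1 | Normal(0, 1) | allows rising or flat scatter |
| kappa0 | Normal(log 0.00085, 1) | manufacturer droplet volume |
| kappa1 | Normal(log 10, 0.5), > 0 | centred on 100% efficiency |
| latent log10 C | Normal(0, 3) | spans 10⁻⁶–10⁶ at 2 SD |

A consequence users should understand: a sample with *no* signal at all
(all qPCR replicates non-detect, or zero positive droplets everywhere)
has a posterior driven by the prior below the platform's sensitivity
floor. The likelihood only removes mass *above* that floor — for ddPCR
the floor sits near 10⁻² copies/μL with triplicate ~20,000-droplet wells,
so the posterior median drops below the 10⁻³ non-detect threshold; for
the qPCR detection component the floor is the 50%-detection point (about
10⁻⁰·⁷ at the default parameters), which leaves the median near 10⁻²·⁸ —
far below the single-copy limit (0.05 copies/μL) but not automatically
below 10⁻³. The non-detect classification (`is_detect`, median below
10⁻³ copies/μL, ties counting as detect) should therefore be read
together with `ci_width`; truly empty samples are recognisable by their
prior-scale interval widths. In `continuous_only` mode such samples have
*no* likelihood term at all and are returned as the prior quantiles with
`prior_driven = TRUE`.

## Sampling and numerics

Fitting uses JAGS (≥4 chains, each with its own seeded RNG so the same
seed and data reproduce draws exactly; defaults 500 adaptation + 500
burn-in + 2000 retained draws per chain). Convergence is declared only
when every monitored parameter has potential scale reduction below 1.05
and effective sample size of at least 400; failure flags the fit rather
than erroring.

The one non-obvious numerical choice is the sampling parameterisation.
Intercept/slope pairs on a decade-spaced design are strongly correlated
in the posterior, and one-at-a-time Gibbs updates then mix poorly. Each
pair is therefore sampled as (centered intercept, slope), with the
centering constant chosen where that component's information actually
sits: the mean detected-standard concentration for the Ct line, the
`theta * (1 - theta)`-weighted mean for the detection pair, and the
binomial-cloglog Fisher-information-weighted mean
(`U * t^2 * exp(-t) / (1 - exp(-t))`, t the expected copies per droplet)
for the ddPCR line, whose information concentrates near the saturation
knee. The conditional prior on the centered intercept is chosen so the
independent Normal priors above are preserved *exactly*; the centering
changes nothing about the model, only the sampler's geometry.

Other numerics and edge rules:

- Saturated ddPCR wells (`W = U`) carry no finite concentration
  information upward and are excluded from the likelihood with a warning
  (conservative and visible, rather than silently fitted).
- `cloglog()` refuses p outside (0, 1); the model code clamps omega just
  below 1 so high-concentration latents cannot produce an invalid
  binomial probability during sampling.
- Degenerate inputs error early: fewer than two distinct standard
  concentrations, all-non-detect standards, all-zero ddPCR standards, a
  detection fit from a single concentration.
- Fixing the calibration parameters (`fixedParams`) drops their priors
  and samples only the latents — used by the oracle tests to compare the
  samplers against an exhaustive grid posterior.

## The synthetic-data generator

`simulateQpcr()`/`simulateDdpcr()` draw plates from exactly the generative
structure the models assume, under a design mirroring the study
conditions: decade dilution series (10⁻¹–10⁶ copies/μL for qPCR,
10⁻³–10⁴ for ddPCR), technical triplicates, ~20,000 droplets per reaction
(Normal with 5% CV, floored at 1,000), 20 μL reactions, environmental
unknowns with `log10(C) ~ Normal(-1, 1.5)` (the low-concentration eDNA
regime), plus true absences and no-template controls. Default truths are
`phi0 = 1.5, phi1 = 2.2, beta0 = 38, beta1 = -3.32, gamma0 = -1.2,
gamma1 = -0.25` and `kappa0 = log(0.00085), kappa1 = log(10)`: plausible
field-like values with a 100%-efficiency slope and Ct scatter growing as
template falls. One deliberate generator detail: a detected Ct draw
landing beyond the assay's cycle cap is recorded as a non-detect,
mimicking instrument censoring, rather than redrawn.

Because generator and model share their structure, passing
parameter-recovery and coverage tests demonstrates that the inference
machinery is correct and calibrated — not that the model is right for any
particular field dataset. The generator deliberately omits inhibition,
pipetting error in the dilution series, between-assay droplet-volume
variability, contamination, and plate/batch effects; on real data those
appear as lack of fit (e.g. an implied droplet volume off the
manufacturer value), not as anything the tests certify.

The detection simulator uses the model's own logistic form, not the
mechanistic Poisson alternative `theta = 1 - exp(-C * v)`; fidelity to
the fitted model was preferred over mechanistic realism so that recovery
tests have a well-defined truth.

## Verification strategy and problem sizes

The test suite checks, in increasing depth: closed-form identities
(limits, diagnostics, c50 equivariance); likelihood decomposition against
independently coded per-replicate oracles; single-well binomial MLE
against the Poisson formula (200 random wells, 10⁻⁶ relative); full
posteriors against a 2,000-point grid evaluation with parameters fixed at
truth (total variation below 0.02, 40,000 draws); 95% credible-interval
coverage of all eight calibration parameters over 20 independent
simulated plates per platform (8 standards × 3 replicates, 20 unknowns ×
3 replicates; at least 17/20 coverage per parameter); and the qualitative
precision orderings on matched simulations (30 unknowns × 3 replicates,
20 seeds): ddPCR intervals narrower than qPCR below 1 copy/μL, the
two-step model at least as precise as continuous-only below 10²
copies/μL, and the two qPCR variants equivalent (mean absolute width
difference under 0.1 orders of magnitude) at abundant template. These
sizes keep a full run in a few minutes on one core while leaving the
binomial/coverage margins comfortably away from their thresholds.

## Known limitations

- No multi-assay hierarchy: each assay is fitted separately
  (`fitQpcr`/`fitDdpcr` take one assay's records at a time).
- No truncation term for detected Cts at the cycle cap, and no
  harmonisation of plates run with different caps beyond their effect on
  detection.
- The upper ddPCR limit uses the all-but-one-droplet reading of the
  one-negative-droplet definition, `exp(cloglog((U-1)/U) - log(V))`; the
  replicate-pooled lower limit multiplies droplets (`n * U`) rather than
  averaging per-replicate limits, treating droplets as independent
  end-point reactions.
- A nonlinear low-concentration slope correction (an `x * log(x)`-type
  substitution for the cloglog slope) has been suggested in the field but
  lacks a precise definition; it is intentionally not implemented.
- Negative controls are read, stored and simulated but excluded from all
  fits by default (`includeControls = TRUE` treats them as unknowns);
  contamination modelling is out of scope.
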