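---
title: "Methods: operator scanning and BLI kinetics for CopR-CopY repressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operator scanning and BLI kinetics for CopR-CopY repressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coperator)
```

# Scope

Gram-positive bacteria repress their copper-export (*cop*) operon with a
copper-sensitive repressor of the CopR-CopY family. The repressor binds a
DNA operator near the promoter; Cu(I) releases it. Two questions shape the
analyses in this package:

1. **Which DNA is the operator?** The historical answer was the 10-base
   palindromic core `TACANNTGTA` (generalised here as `KACANNTGTA`); the
   refined answer is a 16-base site with conserved purine-N-pyrimidine
   flanks. `coperator` ships the consensus strings as presets
   (`operator_presets()`), compiles arbitrary IUPAC strings, scans both
   strands of promoter sequences with optional mismatches, and summarises
   operator counts, inter-operator spacings and palindromy.
2. **How tightly does the repressor bind?** Affinities are measured by
   biolayer interferometry (BLI): a DNA-loaded biosensor dipped into
   protein solutions yields a response-versus-time *sensorgram* per
   concentration. `coperator` preprocesses such traces and estimates the
   association rate constant $k_a$, dissociation rate constant $k_d$ and
   equilibrium dissociation constant $K_d = k_d/k_a$ with a global 1:1
   Langmuir fit.

A synthetic-data module generates both kinds of input with known ground
truth, so every stage of the pipeline is testable end to end without any
external download.

# The 1:1 binding model

For a ligand site loaded on the sensor and analyte at constant molar
concentration $C$, complex formation follows pseudo-first-order kinetics.
During association the response follows

$$Y(t) = Y_0 + A\,(1 - e^{-k_\mathrm{obs} t}),
  \qquad k_\mathrm{obs} = k_a C + k_d,$$

and during dissociation

$$Y(t) = Y_0 + A\,e^{-k_d t}.$$

At equilibrium the association amplitude is
$R_\mathrm{eq} = R_\mathrm{max}\, C / (C + K_d)$, where $R_\mathrm{max}$
is the response at analyte saturation. The affinity is the identity
$K_d = k_d / k_a$; the two-stage route derives
$k_a = (k_\mathrm{obs} - k_d)/C$ from per-trace fits
(`derive_ka()`, `derive_equilibrium_kd()`).

## Simulated sensorgrams

`simulate_sensorgram()` reproduces the five-phase Octet-style protocol
with default durations 60 s (primary baseline), 150 s (loading), 180 s
(secondary baseline), 180 s (association) and 270 s (dissociation), and
the default two-fold concentration series 1000, 500, 250, 125, 62.5,
31.3 nM plus one zero-concentration reference sensor
(`simulate_set()`). Choices that the protocol leaves open:

* **Sampling interval** 0.2 s: dense enough to resolve
  $k_\mathrm{obs} \approx 1\,\mathrm{s}^{-1}$, the fastest rate arising in
  the default series at nanomolar affinities.
* **Loading-phase shape**: a saturating ramp to a fixed load level. Its
  kinetics never enter the fits; only its plateau (the loaded-sensor
  baseline) matters downstream, which is why the loading dilution used in
  the wet protocol is treated as a free plumbing parameter.
* **Noise model** (`noise_model()`): per-sample Gaussian noise (default
  SD 0.01, i.e. 1% of the default $R_\mathrm{max} = 1$), a random offset
  at each phase boundary (default SD 0.02) emulating interstep artifacts,
  and optional common-mode linear drift. These defaults produce
  Octet-like traces while keeping recovery tolerances meaningful.

# Preprocessing

`preprocess_set()` applies, in order:

1. **Savitzky-Golay smoothing** (`smooth_savgol()`), window 11 samples,
   polynomial order 3, applied per phase segment so no information leaks
   across boundaries. At 0.2 s sampling this preserves exponentials up to
   roughly $2\,\mathrm{s}^{-1}$ and reproduces polynomials up to order 3
   exactly; segments shorter than the window shrink it to the largest
   valid odd size with a warning.
2. **Reference-baseline subtraction**
   (`subtract_reference_baseline()`): the secondary-baseline segment is
   averaged pointwise across sensors, summarised as a linear trend in
   time, and that trend is subtracted from every sensor over the full
   trace. This zeroes a shared constant baseline exactly and removes
   common-mode linear drift. Averaging across sensors (rather than
   per-sensor correction) follows the instrument-software convention of
   applying one secondary-baseline average to the set.
3. **Interstep alignment** (`interstep_align()`): each phase is shifted
   by a constant so that its first sample meets the last sample of the
   preceding phase. "Alignment to the dissociation step" is read as
   offset-continuity at every phase boundary — the only reading that
   makes association-dissociation continuous and removes simulated step
   artifacts exactly on clean data.

None of these steps changes segment lengths or time stamps.

# The global fit

`global_fit_1to1()` fits all positive-concentration sensors jointly:
shared $k_a$ and $k_d$, one $R_\mathrm{max}$ per sensor, and one nuisance
baseline offset $Y_0$ per sensor per segment. Numerical choices:

* Rates are optimised as $\log_{10} k_a$ and $\log_{10} k_d$
  (Levenberg-Marquardt, `minpack.lm`), which enforces positivity and
  conditions the problem across the $10^4$–$10^7\,\mathrm{M^{-1}s^{-1}}$
  range.
* Initial values come from per-trace segment fits: $k_d$ from the
  highest-concentration dissociation, $k_a$ from the slope of the
  $k_\mathrm{obs}$-versus-$C$ line, $R_\mathrm{max}$ from amplitude over
  predicted occupancy.
* The per-segment $Y_0$ offsets are the $Y_0$ terms of the segment
  equations above. They are identically zero on clean data (noiseless
  recovery is exact to better than 0.1%), but they matter on noisy data:
  first-sample interstep alignment carries the noise of a single smoothed
  sample into a segment-wide offset, and with the offsets fixed at zero
  that alignment noise dominated the $K_d$ spread (about 9% per seed for
  the weakest construct, versus under 1% with the offsets free).
* Standard errors are 1-SE values from the covariance at the optimum
  (residual variance times the inverse Gauss-Newton Hessian, delta method
  for the back-transformed rates and for $K_d$). The printed
  uncertainties of the original affinity table are not reproduced — the
  raw sensorgrams are not available and the table's error definition is
  unstated — so only recovery of the central $K_d$ values is claimed.
* $R^2$ pools all fitted association and dissociation points, matching
  the convention of one model statistic per construct.
* Each sensor of a replicated concentration keeps its own
  $R_\mathrm{max}$; whether instrument software shares
  $R_\mathrm{max}$ across replicates of one concentration is not
  documented, and per-sensor amplitudes are the safer assumption.

## Binding categories

`classify_binding()` renders a fit as the three-level call used in
cross-species binding matrices: `++` (strong) for a converged fit with
$K_d < 250\,\mathrm{nM}$, `+` (weak) for $K_d$ up to the highest assayed
protein concentration (3 µM), `-` (none) otherwise. The cut-offs are
editorial: the published matrix gives categories, not thresholds; 250 nM
separates the observed strong interactions (tens of nM) from weak ones,
and 3 µM is anchored to the assay ceiling.

A fit must additionally show signal above background: the fitted
association amplitude at the top concentration must exceed 5 pooled
residual SDs, otherwise the call is `-` regardless of the nominal
$K_d$. This implements "no binding greater than the negative controls".
The guard is needed because the assay design itself cannot identify
affinities a few-fold above its 1 µM top concentration: with per-sensor
free $R_\mathrm{max}$, the equilibrium information degenerates along the
$R_\mathrm{max}/K_d$ ridge, and fits to a simulated true
$K_d = 5{-}10\,\mu\mathrm{M}$ interaction return essentially arbitrary
$K_d$ point estimates (with deceptively small local SEs). Consequently a
"none" construct is simulated as a true non-binder (background-level
signal, e.g. $K_d = 1\,\mathrm{mM}$), and the intermediate
3–30 µM regime is declared unidentifiable rather than classified. The
5-SD default (rather than a conventional 3) reflects that a fitted
amplitude is an extreme-value-prone quantity: under pure background noise
with about twenty free parameters, 3-SD amplitudes occur by chance.

# Operator scanning

`compile_pattern()` turns an IUPAC string into per-position allowed base
sets; `scan_operators()` reports every window whose mismatch count is at
most `max_mismatch`, on either strand. Conventions:

* **Coordinates** are 0-based, half-open, always on the forward strand;
  reverse-strand hits are found by scanning with the reverse-complemented
  pattern, so a hit's `matched` field is the forward-strand subsequence.
* **Subject sequences must be pure A/C/G/T**; ambiguity codes in subjects
  are rejected rather than guessed.
* **Overlap collapsing**: `count_operators()` collapses overlapping
  windows to the leftmost hit — two overlapping windows are one physical
  site. A perfectly palindromic site matches both strands at one
  position and is counted once.
* **Spacing** is the end-to-start gap (bases *between* operators); the
  start-to-start alternative is available via `start_to_start = TRUE`.
  Counts and spacings here are defined on the 16-base consensus hits, not
  on the 21-base repeats produced by de novo motif discovery in the
  original pipeline, which can offset spacing histograms by a constant.
* **Count classes** cap at 2 ("two or more"), mirroring the
  two/one/none panel classification; modal gaps break ties toward the
  smaller gap for determinism.

Five consensus presets are shipped; the published record prints four
non-identical 16-base degenerate strings in different places (abstract,
results, discussion), so all are kept as named presets and none is
asserted as canonical: `OLD_CORE` (`KACANNTGTA`), `MINIMAL_16`
(`ATTGACAAATGTAGAT`), `PNEUMO_16` (`RNYKACAAATGTMRNY`),
`INTERMEDIATE_16` (`RNYKACANNTGTARNY`) and `FAMILY_16`
(`RNYKACANNYGTMRNY`). The family consensus `FAMILY_16` is the scanning
default: hit-presence under it agrees with the experimental binding
outcome for all 18 printed candidate fragments (`candidate_operator_sites()`), 9
binders and 9 non-binders.

## Synthetic promoter panels

`generate_promoter()` plants 0, 1 or 2 concrete operator instances
(drawn uniformly within the pattern's allowed sets, reverse-complemented
on the minus strand) into a uniform-random background of default length
100 bases — the upstream-region length used for promoter extraction. The
whole record is rejection-sampled until a both-strand scan recovers
exactly the planted sites (no spurious matches; capped at 10,000
attempts), so panel ground truth is exact by construction rather than
probabilistic. For a 16-base degenerate pattern in a 100-base background,
a spurious match occurs in roughly 1 in 800 records, so rejections are
rare.

Two-operator gaps default to a discrete triangular distribution on 24–39
bases peaked at 26 (`triangular_gap_sampler()`), emulating the observed
spacing of paired operators; the published analysis gives only the range
and the mode, and a triangular is the simplest unimodal shape fixed by
those two facts. One consequence is worth stating: any triangular on
that support has nearly equal weight at 26 and 27 (13/14), so the modal
gap recovered from 67 draws equals 26 in only about a third of panels —
the mode is recovered as a plurality vote across panels (it is the most
frequent recovered mode, about 35% versus 21% for the runner-up), not
per panel.

# What the synthetic data does and does not show

The generators emulate: phase structure and durations, 1:1 binding
kinetics at the printed concentration series, instrument-like Gaussian
noise, interstep offsets and drift; promoter length, operator counts,
strands, and gap geometry. They deliberately do not model:
mass-transport limitation, avidity or bivalent binding, loading-density
artifacts (such as reduced apparent affinity when the biotin anchor abuts
the binding site), biosensor regeneration, cooperative binding, or any
sequence composition bias of real promoters. Passing recovery tests
therefore demonstrates the correctness of the estimators under the 1:1
model and the scanning logic — not robustness to the full range of
instrument or genomic artifacts.

# Problem sizes and determinism

Analyses in the test-suite and in `scripts/acceptance.R` use: 3 noise
seeds per affinity construct at the six-concentration series (18 fitted
sensorgrams per construct); an 88-promoter panel (67/14/7); and 100
panel seeds of 67 two-operator promoters for the spacing-mode vote.
Every stochastic routine takes an explicit integer seed and derives
per-member sub-seeds deterministically, so identical seeds give
bit-identical sensorgrams, panels and output files.

# Known limitations

* Affinities above the top assay concentration are reported but not
  identifiable (see the binding-call section); only the category "none"
  is meaningful there.
* The Savitzky-Golay defaults attenuate rates much faster than about
  2 s^-1 at 0.2 s sampling; for faster kinetics, reduce the window or the
  sampling interval together.
* `k_a` values at the upper end of the tested range (10^7 1/M/s) put the
  top-concentration association rise within a handful of samples of the
  default grid; estimates remain exact on clean data but degrade quickly
  with noise.
* The scanner is a consensus matcher, not a motif-discovery or PWM
  scoring engine; it answers "where does this degenerate site occur",
  not "what motif is enriched".
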