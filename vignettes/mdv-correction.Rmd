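---
title: "Correcting mass isotopomer distributions for flux analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting mass isotopomer distributions for flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdvflux)
```

mdvflux turns raw mass-spectrometric intensity matrices from stable-isotope
labeling experiments into corrected, replicate-aggregated mass isotopomer
distribution vectors (MDVs) ready for metabolic flux analysis software.
This vignette explains the underlying models, the assumptions they make,
the parameters that matter, and the design decisions taken where the
problem leaves genuine freedom.

## The data model

A measurement file is a tab-separated matrix: analyte identifiers in the
first column, the nominal mass of each mass isotopomer in the second, one
column of intensities per chromatogram; an optional title row precedes the
chromatogram-identifier row, and every file carries a single data type
(intensities, retention times, ...).  Rows are assembled into MDVs by
walking consecutive masses: a row matching a library fragment's M+0 (minus
the configured leading-boundary count) starts a fragment of length
`num_c + 1` plus boundary masses.  A mass missing *inside* an MDV is never
assumed to be zero — the fragment is marked incomplete, excluded from
correction, and reported, and the remaining masses are treated as the start
of a possible new fragment.  Boundary counts are global configuration
settings, so all fragments necessarily carry the same number of boundary
masses.

## Pre-correction data checks

Automation is only safe on verified data, so three checks can run before
any correction: missing values (blank or non-numeric cells; text such as
`n.d.` counts as missing, never as zero), detector-range thresholds applied
to *all* masses including boundary masses, and retention-time outliers
flagged when a value lies more than `rt_sd_multiplier` standard deviations
from the mean.  Feedback is written as a mask in the exact layout of the
input file so flagged cells can be overlaid on the data in any spreadsheet.
Any flag terminates the run before correction unless it is forced.

Retention-time statistics are computed per fragment across chromatograms by
default.  The pooled alternative (one mean and SD over all fragments and
chromatograms of the table) is available via `rt_pooled = TRUE`; we default
to per-fragment because a pooled SD mixes analytes that elute at entirely
different times, which either drowns genuine shifts or flags everything.

## The corrections

Corrections are applied per MDV and per chromatogram, in exactly the order
listed in the configuration; each correction rescales its result and the
final MDV is normalized to fractions (percent scaling is applied only in
human-readable output).  An empty correction list just normalizes.

### Natural abundance

For a fragment with full elemental formula (metabolite backbone plus
derivatization atoms) the probability that natural heavy isotopes shift the
mass by $+k$ is the convolution of the per-atom isotope vectors; the
probability of one specific isotope assignment over $N$ atoms of an element
is the multinomial $N!\prod_i p(I_i)^{f(I_i)}/f(I_i)!$.  Per-element
vectors are truncated at shift $+2$ (heavier natural isotopes are
negligible at these fragment sizes), and the correction matrix is truncated
to the square $(numC+1)\times(numC+1)$ window of measured masses.  Column
$j$ removes $j$ tracer atoms from the natural-isotope pool before
convolving — a position that carries the experimental label cannot also
acquire a natural heavy isotope.  The cruder alternative (leaving all
tracer atoms in the pool for every column) double-counts label and is not
offered.

The inversion of `measured = C · true` uses non-negative least squares
(`pracma::lsqnonneg`) rather than triangular back-substitution: on
noise-free data the two agree (asserted by test), but with noise plain
inversion produces negative fractions that propagate into downstream flux
fits.  A matrix with reciprocal condition number below $10^{-12}$ is
rejected with an error naming the fragment.

The shipped abundances are 13C 1.1 %, 2H 0.0115 %, 17O 0.038 %, 18O 0.2 %,
15N 0.366 %, 34S 4.2 %, 29Si 4.7 %, 30Si 3.1 %, light isotopes by
complement; 33S is set to 0.75 %.  Published tables differ in the third
digit (1.07 % vs 1.1 % for 13C), which measurably moves corrected values
for large fragments — the TSV override (`read_isotope_table()`) exists for
laboratories that calibrate their own fractions.

### Proton loss and gain

A fixed fraction $\alpha$ of all molecules of a fragment — independent of
labeling — loses one hydrogen during ionisation (or gains one, typical for
the McLafferty ion of fatty acid methyl esters):

$$M_k^{meas} = (1-\alpha)\,M_k' + \alpha\,M_{k+1}'.$$

Estimating $\alpha$ requires the adjacent boundary mass (M−1 for loss,
M+numC+1 for gain) and assumes the *true* boundary intensity is negligible,
so that boundary$^{meas} = \alpha M_0'$.  The scaling factor is found by
fixed-point iteration: start at $\alpha_0 =$ boundary / adjacent measured
value, invert the equation set at the current $\alpha$, update $\alpha$ to
boundary / adjacent recovered value, stop when successive values differ by
less than $10^{-9}$ (at most 100 iterations).  Tolerance, cap and starting
point are our choices; the iteration typically converges in under 20
steps.  When no stable $\alpha \in [0,1)$ is found the data are left
uncorrected for this step and the failure is reported — a boundary that is
not actually negligible inflates $\alpha$ or prevents convergence.

**A genuine identifiability limit.**  The equation set has $numC+2$
measurements and $numC+2$ unknowns and is nonlinear in $\alpha$; it can
possess several exact solutions with fully non-negative MDVs.  Two
different (true MDV, $\alpha$) pairs can therefore generate *identical*
measurements, and no per-fragment estimator — ours or any other — can
distinguish them.  In simulations with flat random MDVs and
$\alpha \le 0.3$ roughly 2–5 % of fragments are affected: the iteration
either locks onto an alternative exact interpretation or fails to
converge.  The package's property tests assert exactly this: every
converged estimate solves the equations exactly, and recovery of the
simulated truth holds whenever the estimate matches the simulated factor.
In practice the ambiguity concentrates where M+0 is small relative to the
shifted masses; real proton-loss factors of a few percent with a dominant
M+0 are far from this regime.  Estimating one $\alpha$ jointly across
fragments of a chromatogram would disambiguate almost surely, but would
change the per-fragment contract and is left out of scope.

### Original biomass

Biomass present before tracer feeding is unlabeled and dilutes the
labeling.  Given its fraction $f$ per chromatogram, the correction
subtracts $f$ times the unlabeled fragment's distribution $d$ and rescales:
$(m - f\,d)/(1-f)$, clamping small negatives to zero before
renormalization.  What $d$ is depends on where the correction sits in the
order: before natural-abundance correction the unlabeled biomass is spread
over the masses by the fragment's (truncated, renormalized)
natural-abundance distribution; after it, unlabeled biomass is simply M+0,
so $d = (1, 0, \ldots, 0)$.  Both orders are honored and both are exact
inverses of the corresponding forward model.

### Scale bookkeeping across corrections

Intensities are only meaningful relative to the measured mass window, and
boundary masses must stay on the same scale as the MDV for a later
proton-shift estimate to be valid.  Every correction therefore rescales the
boundary intensities by the same divisor it applies to the MDV when
normalizing.  With this convention each configured correction order is the
exact inverse of its forward model; without it, orders that estimate the
proton shift after another correction would see boundary and MDV on
different scales and bias $\alpha$.  (Whether normalization happens between
corrections or once at the end is then immaterial, which is why the
package normalizes after each step.)

## Post-correction diagnostics and aggregation

The average labeling of a corrected MDV,
$\sum_i i\,m_i / (numC \sum_i m_i)$, is reported per MDV, per chromatogram,
per replicate group and over the whole dataset.  Run on unlabeled control
samples it should sit at zero; deviations expose contamination or residual
correction bias.  Dataset-level values are unweighted means over MDVs —
corrected MDVs are normalized, so intensity weighting would only
re-introduce detector effects.

Replicate groups occupy consecutive columns in configuration order.  Per
mass, the group mean and the sample ($n-1$) standard deviation of the
corrected fractions are reported; a single-replicate group gets the
conventional default deviation of five percent (0.05) so downstream flux
software that requires an error value always receives one.

Exports: TSV matrices in the input layout (percent), 13CFLUX FTBL
`MASS_SPECTROMETRY` or `LABEL_MEASUREMENTS` sections (fractions;
tab-indented rows, one file per replicate group or injected into an
existing model file with all other lines preserved byte-identically), and a
flat OpenFLUX-style CSV (fraction mean and deviation per fragment and mass
weight).  The FTBL column layout is pinned by golden-file tests and easy to
adjust.

## The synthetic-data generator

`simulate_dataset()` is the package's test bed: it pushes known true MDVs
through the distortions the corrections undo — natural-abundance
convolution with the fragment's correction matrix, the proton-shift forward
equations (populating boundary masses), original-biomass admixture — in the
reverse of the configured correction order, scales to ion counts, and adds
multiplicative Gaussian detector noise.  The default scenario is a small
GC-MS amino-acid experiment: two analytes, three TMS-derivatized fragments,
six chromatograms in two replicate groups, $\alpha_{loss} = 0.1$, 20 %
original biomass, $10^6$ total ion counts, noise-free.  True MDVs default
to flat Dirichlet draws; noise is multiplicative because MS detector error
scales roughly with signal.  For scale tests, `benchmark_fragments()`
builds a 65-fragment / 412-mass library (43 fragments with four backbone
carbons, 22 with five, one trailing boundary row each), which with 128
chromatograms mirrors the shape of a large multi-plate experiment; the
acceptance script processes it in well under a minute.

What the generator does *not* emulate: chromatographic peak shape and
integration error, retention-time drift beyond normal jitter, correlated
noise between masses, isotopic impurity of the tracer substrate, and
detector saturation.  Passing round-trip tests therefore demonstrate the
algebraic correctness of the corrections, not robustness to every
real-world artifact — the data checks exist precisely because real data
violate assumptions in ways simulation does not.

## Numerical choices and degenerate inputs

* NNLS for the natural-abundance solve; rcond $< 10^{-12}$ is an error.
* Proton-shift iteration: tolerance $10^{-9}$ on successive $\alpha$,
  100-iteration cap, failure leaves data uncorrected with feedback.
* Negative fractions after original-biomass subtraction are clamped to
  zero; a signal removed entirely (possible only for unnormalized or
  pathological input) is an error.
* All-zero MDVs cannot be normalized and error out.
* Missing values inside an MDV skip that MDV with feedback rather than
  guessing.
* Ties and ordering: fragments are matched on (analyte, M+0 mass); the
  first matching library entry wins.

## Known limitations

* Single proton loss/gain only; multi-proton events are out of scope.
* The proton-shift ambiguity described above is inherent to per-fragment
  estimation from one boundary mass.
* Isotope vectors stop at shift +2; for very large fragments (many dozens
  of Si/S atoms) the truncation error becomes visible.
* Vendor file formats are not read; export chromatogram tables to TSV with
  the extraction software of your choice.
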