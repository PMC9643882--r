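---
title: "Methods: simulated FT-NIR authentication of blood-based foods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated FT-NIR authentication of blood-based foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `bloodspec`, the parameters that
matter, the numerical decisions taken where the workflow left room, and what
the simulated results do and do not say about real spectra.

## The problem

Duck blood tofu (DBT) commands a higher price than gels made from cow (CBG)
or pig (PBG) blood, which makes binary and ternary adulteration of DBT
economically attractive and hard to spot visually. FT-NIR diffuse
reflectance gives a fast, non-destructive fingerprint of the gel's organic
composition; chemometrics turns that fingerprint into (a) a six-way class
decision — raw DBT, pure CBG, pure PBG, DBT+CBG, DBT+PBG, ternary — and
(b) a quantitative estimate of the adulterant mass fraction.

## The spectral simulator

No public spectra exist for this product class, so the package ships a
generator that produces data with the statistical structure the analysis
pipeline assumes, and the whole pipeline is exercised end-to-end against it.

**Endmembers.** Each species is a flat baseline plus twelve Gaussian
absorption bands at fixed centers (4,108; 4,405; 5,238; 5,326; 5,477;
5,774; 6,241; 6,931; 7,189; 8,015; 9,399; 9,997 cm⁻¹) — the hydrogen-bond
combination/overtone positions at which blood-food species differ. Band
sigmas grow from 50 cm⁻¹ (combination region) to 120 cm⁻¹ (second
overtones), the broad shapes typical of NIR. The species amplitude tables
(see `bloodspec:::endmember_defaults()`) are fixed constants chosen so that
relative band strengths qualitatively track the compositional differences
between the species: CBG, the fattiest gel, is strongest at the 4,108/4,405
cm⁻¹ C–H bands; PBG, highest in protein and sugar, at the 5,238–5,477 cm⁻¹
C=O region; DBT, richest in methionine and aromatic/basic amino acids, at
5,774 (S–H), 6,241 (Ar–CH) and the 9,399/9,997 cm⁻¹ N–H overtones. No
absorbance magnitudes are published for this matrix, so the amplitudes
(0.05–0.70 AU over baselines of 0.30–0.40 AU) are stated constants in the
plausible range of diffuse-reflectance gel spectra, not calibrated values.

**Mixing.** A mixture with mass fractions `(f_DBT, f_CBG, f_PBG)` on the
unit simplex has the Beer–Lambert spectrum `Σ f_s e_s(ν)`. This linearity is
what makes MSC meaningful and adulteration levels recoverable; it ignores
every matrix interaction (water activity shifts, protein–lipid binding,
temperature).

**Artifacts.** Each replicate scan multiplies the spectrum by
`exp(N(0, 0.08))`, adds an offset `N(0, 0.04 AU)`, a linear tilt
`N(0, 1e-5 AU/cm⁻¹) · (ν − ν̄)` and white noise `N(0, 0.003 AU)` per
channel; three replicates are averaged, as in triplicate-scan acquisition.
The slope+offset pair is exactly the distortion MSC models; the magnitudes
are typical of FT-NIR diffuse reflectance on soft solids. These defaults are
the package's study conditions and are not tuned per experiment.

**Design.** `generate_design()` emits the full factorial: 30 samples each of
the three pure materials, 30 per level × 5 levels for each binary series,
and 30 per level × 5 levels for the ternary series with an equal CBG/PBG
split — 540 samples on 1,557 equally spaced wavenumbers over 4,000–10,000
cm⁻¹. Per-sample random substreams are derived from the master seed, so any
subset of the design is reproducible in isolation.

**What the simulator does not emulate.** Instrument line-shape, detector
nonlinearity, water-band dominance, batch effects between slaughterhouses,
or nonlinear matrix interactions. Consequently the simulated spectra have
low chemical rank (three endmembers plus smooth artifacts), which shows up
downstream: SWDA needs only ~4–18 variables where real spectra needed ~27,
and CARS retains hundreds of near-equivalent variables. Passing the
end-to-end suites demonstrates that the pipeline's algorithms are correct
and well-coupled, not that the same accuracies would be reached on real
gels.

## Pretreatments

- **Centering** subtracts training-set column means.
- **SNV** standardizes each spectrum to mean 0, sd 1, using the sample
  (n−1) standard deviation — the convention is documented because both
  denominators appear in practice.
- **MSC** regresses each spectrum on a reference by ordinary least squares
  (`x ≈ a + b·ref`) and returns `(x − a)/b`. The reference is the mean of
  the *training* split only, so no test information leaks into the
  transform.
- **Derivatives** are Savitzky–Golay (window 15 points, polynomial order 2,
  scaled by the grid spacing so units are AU·cm). SG is the NIR standard
  because plain differencing amplifies noise. Edges are handled by
  `signal::sgolayfilt`, which fits the local polynomial at the ends of the
  spectrum; this keeps the derivative exact on polynomials up to the chosen
  order over the whole support, whereas reflect-padding would force the
  first derivative toward zero at the edges.

All pretreatments follow a fit-on-training / apply-to-anything contract and
never change the number of rows.

## Sample partitioning

Kennard–Stone (max–min Euclidean distance, ties to the lowest index) selects
one third of every class as the *prediction* set — KS more commonly picks
calibration sets, but selecting the hold-out this way keeps the
training/test membership fixed across all pretreatments and variable
subsets, which is the property the comparison grid needs. KS runs on raw
absorbance over all 1,557 variables precisely so that no pretreatment can
influence the split. For regression tasks the strata are the adulteration
levels rather than the six classes, matching how level-balanced hold-outs
are built for calibration models.

## Variable selection

**SWDA** (identification): forward entry with backward removal on Wilks'
Λ; partial F statistics are computed for all candidates per step via Schur
complements of the within/total scatter matrices, so each step costs
O(k²p). Thresholds default to the classical F-to-enter 3.84 and F-to-remove
2.71; the variable just entered is never the one removed, which prevents
cycling. Constant variables are skipped silently.

**CARS** (quantification): 50 Monte-Carlo runs, 80% sampling, PLS1
coefficients as weights, exponentially decreasing enforced retention from
all p variables down to 2, followed by adaptive reweighted sampling — a
weighted bootstrap of size p whose distinct draws survive. Drawing p times
(not `r_i · p` times) matters: a draw of the retained-set size loses ~37%
of variables per run to sampling alone and collapses the set within a dozen
runs regardless of the data. The per-run PLS component count and the
evaluation RMSE both come from 5-fold cross-validation (components capped
at 10). Selection always runs on the training split only.

The PLS1 primitive is the NIPALS recursion, which for a univariate response
is deterministic and returns coefficients for every truncation from one
fit — this is what makes the CARS inner cross-validation cheap.

## Classification models

PCA (3 components, warning if they explain <99% of training variance)
decorrelates the SWDA-selected variables; when SWDA returns fewer than
three variables the component count is capped at the selection size.
Fisher LDA takes the eigenvectors of `W⁻¹B` (computed via a Cholesky
whitening for symmetry; a diagonal ridge of `1e-8·mean(diag(W))` is applied
if W is singular) and classifies by the nearest class centroid in
discriminant-score space. With six classes and three PCs this yields
exactly three discriminant functions.

The ELM draws input weights and biases uniformly on [−1, 1] and solves the
output layer by SVD pseudoinverse. The sweep trains one fresh draw per
(activation, neuron-count) cell from seeded substreams and selects the best
*test-set* accuracy — the cut-and-trial criterion; it mildly leaks the test
set into model choice, which is flagged here and accepted as the workflow's
own selection rule. The empirical bracket
`N_h = N_s/(α(N_i+N_0)), α ∈ [2,10]` (e.g. [9, 45] for 360 training
samples, 3 inputs, 1 output) is reported alongside the full 1–50 sweep.

**Class coding.** The classifier codes classes as one-hot targets with
argmax decoding by default. A single-output coding (classes 1..6, nearest
code) is also provided, matching a one-output-neuron network, but on this
design it is structurally inadequate: the six classes tile a
two-dimensional mixing simplex, and least-squares regression onto an
arbitrary one-dimensional class code cannot carve that layout — it peaks
near 74% hold-out accuracy and *degrades* as neurons are added, while the
one-hot coding reaches ~95%. The package therefore defaults to one-hot and
keeps `coding = "code"` for comparison.

## Quantification models

Four ELMR tasks: CBG in DBT+CBG, PBG in DBT+PBG, and CBG resp. PBG in the
ternary mixtures (responses 10–50% for the binary tasks, 5–25% per gel for
the ternary ones; each ternary task is an independent single-output model).
Inputs are the CARS-selected pretreated variables — no PCA, matching the
identification/quantification asymmetry of the workflow — standardized with
training statistics and scaled by `1/sqrt(n_selected)` so the random
projection arguments `x'w` stay O(1); without that scaling a few hundred
standardized inputs push the sine activation through dozens of periods and
the hidden layer retains no signal. The sine activation is used throughout
the regression sweep (1–50 neurons, minimum prediction-set RMSE wins), and
`run_quantification()` also lets each ternary task inherit the matching
binary task's pretreatment and selection, keeping whichever predicts
better.

Metrics are implemented exactly as printed in the field's reports:
`RMSE = sqrt(mean((y − ŷ)²))`; `r = 1 − SSE/SST` (note: despite the name
"correlation coefficient" this is the coefficient-of-determination form —
it is implemented verbatim, and can be negative for a bad fit);
`RPD = Std(training reference)/RMSE_p` (≥3 satisfactory, ≥5 quality
control); `RER = (Max − Min)/RMSE_t` (>10 good predictive ability; note the
training RMSE in the denominator, where RMSEP is the more common
convention — also kept verbatim).

## Numerical choices and degeneracies

- SNV errors on zero-variance spectra; MSC errors when the fitted slope
  magnitude falls below 1e-12.
- Kennard–Stone breaks distance ties by lowest index; duplicate rows are
  allowed.
- The ELM pseudoinverse truncates singular values below
  `sqrt(.Machine$double.eps)` relative to the largest.
- All randomness (simulator, CARS, ELM draws) descends from one master seed
  via stable integer hashes of stage names, so any stage is reproducible in
  isolation and a full re-run from an archived `run_config()` is
  bit-identical.

## Problem sizes used by the test-suite

The unit suites run on a reduced design (6 samples per cell, 300-point
grid) chosen to exercise every code path quickly; the end-to-end suite runs
the full 540 × 1,557 design once for identification and once per
quantification task, and the CARS recovery study uses twenty 60 × 50
planted-signal instances. These sizes are the package's own trade-off
between coverage and turnaround.

## Known limitations

- The simulator's low chemical rank makes selection counts incomparable to
  real-spectra studies (see above).
- Selecting the ELM by test-set performance biases the reported best
  accuracy upward; a cross-validated criterion would be the defensible
  alternative for real deployments.
- `r = 1 − SSE/SST` and `RER`'s training-RMSE denominator are kept verbatim
  for comparability, not because they are the best-practice definitions.
- No wavelength registration or instrument transfer: all inputs are assumed
  on a common grid (the readers re-sort descending grids but do not
  interpolate).
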