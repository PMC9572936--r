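---
title: "Screening antibiotics in milk by LC-HRMS: models, validation statistics, and the synthetic-data generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening antibiotics in milk by LC-HRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkscreen)
```

## The screening problem

Official food-control laboratories screen milk for residues of veterinary
antibiotics against the maximum residue limits (MRLs) of EU food law. A
*screening* method does not need to quantify accurately; it needs to sort
samples into *compliant* and *suspect* with a false-compliant (false
negative) rate below 5% at the concentration of interest, and to do so for
many analytes at once. `milkscreen` implements such a pipeline for a
57-compound panel (penicillins, cephalosporins, tetracyclines and their
4-epimers, pleuromutilins, macrolides, lincosamides, quinolones,
sulfonamides) measured by liquid chromatography coupled to a
high-resolution Orbitrap mass spectrometer in positive-mode full scan with
targeted fragmentation.

Each analyte is characterised by its molecular formula, an adduct species
(`[M+H]+`, `[M+Na]+`, `[M+2H]2+`, or the ammonia-loss ion `[M+H-NH3]+`),
an expected retention time, two product-ion m/z values, an MRL where the
substance is authorised in milk, and a screening target concentration
(STC): the level at which the method is validated, equal to the MRL for
penicillins and to a class-wise fraction of the MRL (or a minimum
achievable level) elsewhere. STCs ship as configured data rather than a
computed fraction, because the panel's class policy does not reduce to a
single formula.

## Mass arithmetic

Theoretical precursor m/z values are computed from IUPAC monoisotopic
atomic masses with electron-mass correction:

$$ m/z = \frac{M + \sum_i n_i\, m_i - z\, m_e}{z} $$

where `M` is the monoisotopic mass of the neutral molecule, the sum runs
over added (or lost, negative) atoms, `z` is the charge and `m_e` the
electron mass. Display is rounded to 4 decimals; all comparisons use full
precision. Three spelling conventions in the source panel required an
interpretation: the sulfanilamide species is read as the ammonia-loss ion
`[M+H-NH3]+` (the only reading that reproduces the tabulated 156.0114),
and `[M+2H]+` for cefquinome, tilmicosin and spiramycin is read as the
doubly charged `[M+2H]2+` (only `(M + 2 m_p)/2` reproduces the tabulated
values).

On loading, the database recomputes every precursor m/z and compares it
with the tabulated value. 52 of the 57 rows agree exactly at 4 decimals
(two more differ by one unit in the last decimal, consistent with
last-digit rounding of a slightly different atomic-mass table). Five rows
deviate by more than 0.5 ppm and are loaded but flagged as transcription
discrepancies: penicillin G (−0.8 ppm), cefquinome (+1.1 ppm), doxycycline
(−3.6 ppm, which carries tetracycline's formula but a different printed
mass), azithromycin (−1.7 ppm) and sulfamonomethoxine (−2.5 ppm, which
shares sulfamethoxypyridazine's formula). The recomputed value is
authoritative for matching; flags are reported, never silently corrected.

```{r}
db <- load_compound_db()
db$compounds[db$compounds$mass_flag,
             c("name", "precursor_mz", "ppm_vs_tabulated")]
```

## Identification

A feature matches an analyte's precursor when its mass error is within
±5 ppm (inclusive), and its retention time when the relative deviation is
within ±2.5% — the instrumental specificity tolerances of the method.
Product ions match within ±0.05 Th (the panel tabulates fragments to one
decimal; the tolerance is configurable), each observation consumed at most
once. Evidence is scored as identification points: 1.0 for chromatographic
separation, 1.5 for the high-resolution precursor, 2.5 per product ion.
Confirmation requires ≥4 points for authorised substances and ≥5 for
unauthorised ones; a fully detected analyte scores
1.0 + 1.5 + 2 × 2.5 = 7.5.

Candidate selection was a genuinely open design point. When several
features fall in one m/z window, we prefer features inside the analyte's
retention-time window, then the smallest |ppm error|, then the smallest RT
deviation, then m/z. The RT-window preference is not cosmetic: four
tetracycline-family analytes share the formula C22H24N2O8 and hence an
identical theoretical m/z, so a pure smallest-ppm rule would routinely
assign an epimer's peak at the wrong retention time. Preferring the RT
window is exactly how an analyst reads the extracted-ion chromatogram at
the expected retention time. A retention-time coincidence without a
precursor match identifies nothing: candidates only come from the m/z
window. All tolerance comparisons are inclusive (≤), following the
regulation's wording.

## Quantification and screening decisions

Semi-quantification uses an unweighted ordinary-least-squares line through
the five solvent calibration standards (0.1, 0.5, 1.0, 5.0, 10.0 µg/L);
weighting is deliberately not applied because the acceptance criterion on
the curve is an R² threshold, not a bias profile at the extremes. The
extraction procedure fixes the dilution arithmetic: 1.0 g of milk into
4.1 mL of extract, of which an aliquot is diluted tenfold, so

$$ c_{\text{sample}}\ [\text{µg/kg}] = c_{\text{vial}}\ [\text{µg/L}]
   \times \frac{4.1\ \text{mL}}{1.0\ \text{g}} \times 10 = 41\, c_{\text{vial}}. $$

This maps every STC on the panel (4–75 µg/kg) to 0.098–1.83 µg/L, inside
the calibration range. Responses below the intercept back-calculate to a
clamped 0 µg/kg — a blank reads "not detected", never a negative amount —
and the clamp is applied before any blank statistics, so T ≥ B ≥ 0.

A sample is *suspect* for an analyte when the analyte is identified and
its back-calculated concentration strictly exceeds the cut-off factor Fm;
a concentration exactly at the cut-off stays compliant ("above which"
is read strictly). A sample as a whole is suspect when any analyte is.
Batch quality control requires the negative control (blank milk) to screen
compliant as a sample, the screen positive control (milk spiked at STC) to
screen suspect as a sample, and the four isotope-labelled internal
standards (sulfanilamide-13C6, cefadroxil-d4, enrofloxacin-d5,
penicillin G-d7, 10 µg/kg each) to be present within the mass and RT
tolerances in both controls. The sample-level reading of the control
verdicts matters statistically: each individual analyte in the positive
control has, by construction of Fm, about a 5% chance of reading below its
cut-off, so demanding all 57 simultaneously would fail most well-behaved
batches; demanding the *sample* to be suspect is the check a laboratory
actually performs. Internal standards are modelled as presence/RT checks
only — no isotope-dilution correction.

## Validation statistics

With concentration readings from 25 blank and 25 STC-spiked milk samples
(10 sheep, 10 cow, 5 goat):

* threshold value: $T = B + 1.64\,S_B$ from the blanks,
* cut-off factor: $F_m = M - 1.64\,SD$ from the spikes,

both with the sample (n−1) standard deviation — the divisor is not
specified by the source guidance and small-n validation sets argue for the
unbiased form — and the factor 1.64 used verbatim (not 1.645, not a t
quantile). Detection capability passes when $F_m > T$ strictly: the
false-negative rate at STC is then below the nominal 5%
($\Phi(-1.64) \approx 5.05\%$ is the exact reading of the same quantile).
When $F_m \le T$ the verdict is fail and the method defers to new
experiments at a higher level; no numeric re-determination is attempted.

Precision is summarised as the within-laboratory reproducibility CV,
$CV_R = 100\,SD/M$, compared against guide limits applied exactly as
printed in the regulation: 30% below 10 µg/kg, 25% from 10 up to (not
including) 120 µg/kg, and the Horwitz value
$CV = 2^{(1 - 0.5 \log_{10} C)}$ above that, with `C` the dimensionless
mass fraction. The guide values intentionally differ from the Horwitz
function evaluated at the same mass fractions; the function is exposed as
its own operation.

Stability of standard solutions is monitored through the calibration line:
R² ≥ 0.999 and an intercept/slope ratio (y/x) within ±20% relative of the
first curve's ratio. Ruggedness uses a two-sided two-sample t-test between
the two levels of each procedural factor (centrifuge temperature and
speed, HLB conditioning, EDTA amount); Welch's unequal-variance form is
the default since the source states only "t-test", with the pooled option
available. Groups that are both exactly constant are handled explicitly
(t = 0, p = 1 when equal) because the standard test refuses constant data.

## What the synthetic-data generator emulates

No instrument data accompany the method, so the generator produces feature
tables with the statistical structure the validation assumes:

* **Mass error**: normal, SD 1.5 ppm, truncated at ±5 ppm.
* **RT jitter**: relative, normal, SD 0.8%, truncated at ±2.5%.
* **Response dispersion**: per-analyte normal concentration noise using the
  panel's published within-laboratory CVs (2.7–18.5%) as defaults,
  truncated at 4 SD so responses stay positive. Normal rather than
  lognormal, because the T/Fm formulas presume symmetric normal-like
  dispersion.
* **Blank background**: false features per analyte window with Poisson
  count (rate 0.02/run), uniform position in the m/z and RT windows,
  exponential response with mean 5% of the STC response, and no product
  ions. The source reports no blank-response distribution — these
  parameters are free modelling choices exposed in the noise model, not
  claims about the instrument.
* **Ground-truth response model**: per-compound slope (log-normal around
  5000 area units per µg/L) and near-zero intercept, shared between
  calibration series and milk runs so that back-calculation recovers the
  generated concentrations.
* **Internal standards**: always present in milk runs; solvent blanks are
  empty.
* Species labels (bovine/ovine/goat) are metadata only by default — the
  procedure is applied identically to the three milks — with an optional
  per-species response scale for ruggedness-style experiments.

Truncation at the matching tolerances means a true spike can never be lost
on tolerance grounds, so the 100% true-positive identification rate at STC
holds exactly when background features are disabled. With background
enabled, a fragment-less false feature occasionally (≈1–2% of
analyte-runs) wins the candidate choice and produces a low concentration
reading — realistic interference that slightly inflates the recovered CV
of an affected study, and the reason strict tolerance-monotonicity of the
identified set holds only in the interference-free setting.

Because everything is seeded (run seeds derived deterministically from a
master seed), every generated object is a pure function of its parameters
and seed, bit for bit.

What the generator does **not** emulate: chromatographic peak shapes, raw
spectra, matrix effects and recovery, ion suppression, carry-over, and
between-day drifts. Passing tests on synthetic data therefore demonstrate
the correctness of the decision logic and statistics under the method's
stated assumptions — not the chemical performance of the extraction on
real milk.

## Numerical and scale choices

* Calibration standards carry a small multiplicative response noise
  (CV 0.5%) so that default fits satisfy R² ≥ 0.999 as solvent standards
  do; zero-noise fits give R² = 1 exactly.
* Degenerate inputs error early and informatively: identical calibration
  levels, zero slope, fewer than two replicates, nonpositive theoretical
  m/z or retention time, unknown element symbols (named in the message).
* The cefadroxil-d4 internal standard's retention time (9.50 min) is a
  modelling choice — cefadroxil is not on the 57-compound panel — and is
  self-consistent between the generator and the QC check.
* Default validation studies use the published design (25 + 25 runs).
  Distribution-level checks use 10^5 draws (false-negative rate) and
  200–500 seeded studies of 25 replicates (CV recovery); these sizes put
  the Monte-Carlo error well inside the tolerances being checked.

## Known limitations

* Isotope-pattern scoring, negative-mode ionisation, adducts beyond the
  four observed, and in-silico fragmentation are out of scope.
* The cut-off verdict is binary; when Fm ≤ T the package reports fail and
  does not estimate a numeric detection capability.
* Quantification is semi-quantitative screening support: no measurement
  uncertainty, recovery correction, or matrix-matched calibration.
* The fragment-match tolerance (±0.05 Th) is a package default chosen to
  be generous against one-decimal tabulated fragments; the source does not
  state one.
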