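---
title: "Quantifying CBS filamentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CBS filamentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CBSfilament)
```

Cystathionine beta-synthase (CBS) polymerises into helical filaments
whose architecture switches with the allosteric activator
S-adenosyl-L-methionine (SAM): a low-activity basal filament with three
dimers per helical turn (twist about −108°, rise about 51 Å, D1 point
symmetry) and a high-activity SAM-bound filament with two dimers per
turn (twist about −178.6°, rise about 46.7 Å). In cells, fluorescently
tagged CBS shows a filamentous or punctate cytoplasmic pattern that
responds to nutrient state. This package implements the quantitative
methods needed to analyse all three faces of that biology: a
fractal-dimension classifier for high-content micrographs, helical
geometry computations for coordinate models, and the binding/activation
models of the underlying biophysics. A synthetic-data module generates
every input with known ground truth so each stage is testable end to
end.

## 1. The image classifier

### Model and procedure

Each field of view carries a nuclear channel and a reporter channel
(mKO2-tagged CBS). The pipeline follows the standard high-content
recipe:

1. **Nucleus detection.** Both channels are percentile-rescaled
   (1st/99.5th percentiles) and combined; the combination is blurred
   with a Gaussian of sigma 3 px, Otsu-thresholded, and 8-connected
   components smaller than `minNucleusArea` are discarded.
2. **Cytoplasm expansion.** Each nucleus is grown outward by
   nearest-seed (geodesic) expansion up to `cytoplasmExpandRadius`
   (default 25 µm); contested pixels go to the nearer nucleus, and
   nucleus pixels are excluded from the cytoplasm mask.
3. **Reporter enhancement.** A consistent, image-derived contrast rule
   (1st/99.5th percentile rescale to [0, 1]) followed by CLAHE local
   contrast enhancement (kernel 127 px, clip limit 3 — the defaults of
   the reference ImageJ implementation of the algorithm).
4. **Binarisation and object extraction.** Global Otsu threshold;
   4-connected components within each cell's cytoplasm, minimum area
   4 px²; objects straddling two territories are split at the boundary.
5. **Morphometry and classification.** Per object, the box-counting
   fractal dimension D and the boundary-step perimeter; per cell, a
   majority vote: *filamented* if most objects meet or exceed D = 0.7,
   *punctuated* if most fall below, *tie* otherwise (including cells
   with no objects). An analogous vote with a 10 µm perimeter threshold
   yields the longer/shorter classification. Ties are excluded from all
   downstream fractions.

### The box-counting dimension

For box sizes ε ∈ {2, 3, 4, 6, 8, 12, 16, 32, 64} px, a grid anchored
at the object's bounding-box origin (single offset) is overlaid and
N(ε), the number of boxes containing foreground, is counted;
D = −slope of the ordinary least-squares fit of log N(ε) on log ε.
Sizes larger than the object's bounding box are retained and contribute
N = 1. This is the property that makes D work as a shape-complexity
score at these object scales: a small punctum plateaus at N = 1 for
most sizes and scores D ≈ 0.3, while a filament keeps halving its box
count and scores D ≈ 1. Clipping the size series to the bounding box
would instead give small filled discs D ≈ 2–3 and destroy the 0.7
separation, so we deliberately do not clip. Repeated counts are kept
(no deduplication), a single pixel scores exactly D = 0, and objects
whose bounding box is smaller than the third box size are flagged
(`few_informative_sizes`).

### The perimeter estimator

The perimeter is the number of exposed 4-neighbour edges of the object
times the pixel size: a 1 px object at 0.3 µm/px measures 1.2 µm, a
10 × 10 px square 12 µm. This boundary-step convention doubles as its
own easily verified oracle and scales exactly linearly with the object.
At the default 0.3 µm/px (typical 20× high-content sampling) the 10 µm
threshold corresponds to ~33 boundary steps.

### Design choices the source procedure leaves open

- **Channel combination weights.** Nucleus detection uses a weighted
  combination (nuclear:reporter = 1:0.3). With equal weights, bright
  reporter filaments — rescaled to the same intensity ceiling as nuclei
  — survive the sigma-3 blur and Otsu threshold as phantom "nuclei"
  that steal cytoplasm territory and fragment objects. The down-weight
  preserves the intent of the combination (rescuing weakly stained
  nuclei) while letting nuclear morphology dominate.
- **Thresholding.** Per-image Otsu, recorded in the configuration; it
  is parameter-free and reproducible.
- **Cytoplasm expansion.** Radius-limited nearest-seed growth with a
  25 µm default, the standard high-content convention.
- **Connectivity.** Objects are 4-connected (better-behaved perimeters
  for thin structures), nuclei 8-connected (blurred discs fragment
  less).
- **Replicate unit.** The image (field of view) is the replicate for
  condition means, s.e.m., ANOVA and Tukey HSD — the most conservative
  granularity available without well annotations.
- Coordinates are 0-based (row, col) with the pixel-centre convention.

### What the generator emulates — and what it does not

`generateCellImage()` draws cells on a jittered grid (non-overlap
enforced by the grid spacing): a nucleus disc per cell, and per-cell
reporter objects — 1–3 curved strokes (quadratic Béziers, 10–18 µm
long, 0.6–0.9 µm thick, bowed around the nucleus) for filamented cells,
3–7 small discs (0.9–1.8 µm) for punctuated cells — plus Gaussian read
noise. The filamented count is exactly round-half-up(n·f), so label
counts are testable; each image consumes an RNG stream derived from
(seed, image index), so cohorts are bit-reproducible and parallel-safe.
Object geometry ranges are free parameters chosen to realise the
long/high-D versus short/low-D contrast the classifier keys on; they
are not calibrated to any particular instrument or cell line.

The generator does **not** model optics (no point-spread function,
photobleaching, or 3D), touching nuclei, diffuse cytosolic reporter
background, or out-of-focus debris. Passing recovery tests therefore
demonstrates the correctness of the measurement chain, not robustness
to every real-world artefact. One known consequence: with very sparse
fields (foreground below roughly 1% of pixels, e.g. ten cells in a
512² image), CLAHE amplifies background noise enough that a global
Otsu threshold can collapse onto the background mode. At the package's
default density (25 cells per 512² field) the pipeline recovers drawn
objects with pixelwise F1 ≥ 0.9 and per-condition fractions within a
few points of truth.

## 2. Cohort statistics

Per image, the filamented fraction is filamented/(filamented +
punctuated), ties excluded from numerator and denominator; images with
zero classified cells are dropped (with a message). Conditions are
compared by one-way ANOVA and Tukey HSD on the per-image fractions.
Degenerate inputs are handled explicitly rather than crashing a
pipeline on synthetic extremes: zero between-group variance returns
F = 0, p = 1; complete separation with zero within-group variance
returns p = 0 with a `degenerate` flag. Simulated-null calibration
(1000 runs, 3 conditions × 6 images) puts the ANOVA type-I error at
0.05 ± 0.02 and the Tukey family-wise error at or below 0.07.

## 3. Helical geometry

`applyHelicalSymmetry()` builds filaments: unit *k* is the protomer
rotated by *k*·twist about z and translated *k*·rise along z; D1 point
symmetry adds each unit's C2 mate about an axis perpendicular to the
helix axis. `screwDecompose()` inverts the operator: a Kabsch
least-squares superposition of matched point sets, decomposed via a
quaternion (stable near 180°) into a rotation about the screw axis and
a translation along it. Sign conventions: the axis is oriented so the
translation is non-negative, the angle follows the right-hand rule
about that axis and is reported in (−180°, 180°] — so a left-handed
filament with positive rise has negative twist, matching the deposition
convention behind −108° and −178.6°. `recoverHelicalParams()` averages
successive-unit decompositions (circular mean for angles, so values
near ±180° cannot cancel) and reports the per-pair spread. Coordinate
noise of 0.5 Å on a five-unit toy filament leaves the recovered
parameters within ±0.5° and ±0.5 Å. The point group is not inferred
from the coordinates and is reported as C1.

`dimersPerTurn()` is the printed-figure arithmetic: 360/|twist| with
round-half-up, giving 3.33 → 3 dimers per turn for the basal twist and
2.02 → 2 for the activated twist.

Buried interface area follows the classic Shrake–Rupley construction:
a fixed golden-spiral lattice of 960 points per atom, probe 1.4 Å, and
an embedded radii table (C 1.70, N 1.55, O 1.52, S 1.80, others
1.80 Å) so results are bit-reproducible; BSA = SASA(A) + SASA(B) −
SASA(A∪B), totalled over both sides (not halved) — the convention used
for regulatory-domain (Bateman) pair burial. Against the closed-form
two-sphere cap formula the lattice agrees to well under 2%. Deposited
coordinate models can be read from PDB or mmCIF via `readStructure()`
and grouped into helical units with `assignUnits()` for the same
recovery machinery.

## 4. Binding and activation models

All fits are unweighted nonlinear least squares (Levenberg–Marquardt,
numerical Jacobians) from fixed multi-start grids, so fitted outputs
are deterministic. Standard errors come from the Jacobian at the
solution.

- **H₂S calibration**: ordinary least squares of fluorescence rate on
  known H₂S concentration; rates convert through the inverted line.
- **Michaelis–Menten**: v = Vmax·S/(Km + S).
- **Hill activation**: v = v_basal + (v_max − v_basal)·Sⁿ/(K_actⁿ + Sⁿ),
  n bounded to (0.2, 10]; at S = K_act the response is exactly midway
  between the plateaus, and n = 1 with zero basal rate reduces to the
  Michaelis–Menten form. Recovery at SAM-scale truth (K_act 30 µM,
  n = 3, 2-fold activation, 3% noise, 8 levels × 4 replicates) returns
  K_act within 15% and n within ±0.5.
- **Thermal activation**: a logistic between two plateaus with Tm at
  the inflection; data a straight line explains as well as the logistic
  (no usable inflection in range) are refused rather than assigned a
  fake midpoint. Tm = 49.5 °C is recovered within ±0.5 °C at 5% noise.
- **SEC molecular weight**: Kav = (Ve − V0)/(Vt − V0), log10(MW) linear
  in Kav; void-volume elution and extrapolation beyond the standards
  are flagged.

### The two-sets-of-sites ITC model

The forward model updates total ligand and macromolecule with
displacement dilution (each injection of dV expels dV/V0 of cell
content), solves the free-ligand concentration from the two-class
isotherm by bracketed root finding (relative tolerance 1e-12, with a
Newton polish; mass balance holds to 1e-10 relative), and converts the
cell heat content Q = V0·M·Σ N_i·ΔH_i·θ_i into per-injection heats
with the usual expelled-volume correction. The default design matches
common PEAQ-ITC practice for SAM into CBS: 200 µl cell at 30 µM
monomer, 500 µM syringe, one 0.4 µl pre-injection plus 44 × 0.8 µl at
25 °C.

The fit excludes the pre-injection by default and removes heats of
dilution by subtracting a supplied blank's mean; without a blank, a
constant per-injection offset is estimated as a free parameter. We
chose the free offset over the common "subtract the mean of the final
injections" shortcut because the latter biases even noiseless round
trips (final heats are never exactly zero); with the free offset, a
dilution-free synthetic titration is recovered exactly. Site classes
are reported sorted by ascending Kd with ΔG = −RT ln K and
−TΔS = ΔG − ΔH; if both classes have Wiseman c = K·N·M below 1 the fit
is flagged non-identifiable and a single-class fallback is compared by
residual sum of squares.

**Known limitation — the high-affinity event is information-limited.**
At per-injection noise of 0.1 µcal with Kd's of 160 and 600 nM, equal
half-stoichiometries and enthalpies of +2/−8 kcal/mol, the Fisher
information of a single titration bounds the standard error of
ln K for the high-affinity class at about 1.3 — a factor of ~3.7 on
Kd₁ — because that class contributes little heat and overlaps the
second event. The fitted Kd₁ therefore scatters widely across noise
realisations even though the estimator is exact on noiseless data; Kd₂
is typically recovered within ~20%. This mirrors the wide spread of
high-affinity SAM-site estimates in the literature and is documented
rather than hidden: the corresponding acceptance test asserts the
nominal 25% tolerance and is expected to fail on the high-affinity
class.

## 5. Problem sizes and numerical choices

The test-suite and acceptance computations use: 500 cells (20 fields ×
25 cells at 512², 0.3 µm/px) for fraction recovery; 5 seeds × 5 true
fractions at 12 cells per 360² field for monotonicity; 50 fields for
the nucleus-count property; five-unit toy filaments of 20–30
pseudo-atoms for helical round trips; 960 sphere points for SASA; 1000
simulated-null runs for the statistical calibration. These sizes were
chosen so every property is exercised at scales where its failure
modes are visible while the whole suite stays quick on a laptop.
Tie-breaks and degenerate inputs are handled explicitly throughout:
empty masks and empty structure parts are errors, constant images
yield empty detections rather than errors, zero-object cells are ties,
and exact-tie votes are ties.
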