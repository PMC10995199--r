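# CBSfilament

Quantitative analysis of cystathionine beta-synthase (CBS)
filamentation. Human CBS polymerises into helical filaments whose
architecture switches with the allosteric activator
S-adenosyl-L-methionine (SAM): a low-activity basal filament with three
dimers per turn (twist ≈ −108°, rise ≈ 51 Å, D1 symmetry) and a
high-activity SAM-bound filament with two dimers per turn
(twist ≈ −178.6°, rise ≈ 46.7 Å). In cells, fluorescently tagged CBS
shows filamentous or punctate cytoplasmic patterns that respond to
nutrient state.

The package is for structural biologists and cell biologists who need
the three quantitative layers of this system in one tested toolbox:

1. **High-content image classifier** — nucleus detection, nearest-seed
   cytoplasm expansion, CLAHE enhancement, Otsu binarisation, and
   per-object **box-counting fractal dimension**
   *D* = −d log *N*(ε)/d log ε with per-cell majority votes
   (filamented if most objects have *D* ≥ 0.7; longer if most
   perimeters ≥ 10 µm; ties excluded), plus per-condition fractions
   with one-way ANOVA and Tukey HSD.
2. **Helical geometry** — build filaments from a protomer and
   (twist, rise, point group); recover parameters from coordinates by
   Kabsch superposition + screw-axis decomposition; dimers per turn
   = 360/|twist|; Shrake–Rupley buried interface area
   BSA = SASA(A) + SASA(B) − SASA(A∪B).
3. **Binding and activation models** — H₂S-rate calibration,
   Michaelis–Menten, Hill activation
   v = v_b + (v_max − v_b)·Sⁿ/(K_actⁿ + Sⁿ), thermal-activation
   sigmoid (Tm), the two-sets-of-sites ITC forward model and fit
   (N_i, K_i, ΔH_i with ΔG = −RT ln K and −TΔS = ΔG − ΔH), and SEC
   K_av molecular-weight estimation.

A synthetic-data module generates micrographs with known per-cell
labels, toy helical filaments, and noisy assay datasets, so every
stage has ground truth. See the vignette
(`vignettes/cbs-filament-analysis.Rmd`) for the methods and design
decisions.

## Worked example

Simulate two culture conditions (65% vs 25% truly filamented cells),
classify every cell, and compare conditions:

```r
library(CBSfilament)

conds <- list(
  complete = imageSimConfig(nCells = 25, fracFilamented = 0.65, seed = 101),
  depleted = imageSimConfig(nCells = 25, fracFilamented = 0.25, seed = 202))
cells <- simulateCohort(conds, nImages = 4)
s <- summarizeCondition(cells)
print(s$summary, digits = 3)
#>   condition n_images n_cells_classified frac sem
#> 1  complete        4                100 0.64   0
#> 2  depleted        4                100 0.24   0

a <- oneWayAnova(s$perImage$frac, s$perImage$condition)
sprintf("one-way ANOVA: F = %.1f, p = %.2g", a$F, a$p)
#> "one-way ANOVA: F = Inf, p = 0"
```

The recovered fractions (0.64, 0.24) match the generating truth to one
cell: the generator fixes the filamented count per field at
round-half-up(25 × 0.65) = 16, i.e. 0.64. Because recovery here is
exact, the per-image fractions have zero within-condition variance and
the ANOVA reports the complete-separation case (F = Inf, p = 0 with a
`degenerate` flag) instead of NaN.

Helical geometry round trip and the printed-figure arithmetic:

```r
basal <- dimersPerTurn(-108)
sprintf("basal: %.2f units/turn -> %d dimers per turn",
        basal$unitsPerTurn, basal$nearestInteger)
#> "basal: 3.33 units/turn -> 3 dimers per turn"

p <- makeToyProtomer(20, 10, seed = 2)
fil <- applyHelicalSymmetry(p, helicalParams(-108, 51, "D1"), 5)
r <- recoverHelicalParams(fil)
sprintf("recovered twist %.3f deg, rise %.3f A",
        twist(r$params), rise(r$params))
#> "recovered twist -108.000 deg, rise 51.000 A"
```

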