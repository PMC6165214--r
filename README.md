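# fibreXRD

Quantitative analysis of small-angle X-ray fiber diffraction patterns
from striated muscle, for muscle biophysicists who want the standard
reduction-and-fitting chain — and a fully verifiable synthetic testbed —
in R.

Muscle diffraction patterns encode myosin head configurations in a few
measurable features:

* the **equatorial intensity ratio** I<sub>1,1</sub>/I<sub>1,0</sub> of
  the hexagonal myofilament lattice, a proxy for head mass shifting from
  the thick filaments toward the thin filaments, fitted here as five
  lattice-constrained Gaussians whose widths follow the disorder
  decomposition σ<sub>hk</sub> = √(σ<sub>c</sub>² +
  σ<sub>d</sub>²θ<sub>hk</sub>² + σ<sub>s</sub>²θ<sub>hk</sub>⁴) with
  θ<sub>hk</sub> = √(h² + k² + hk);
* the **myosin layer lines** on the 43 nm repeat, whose integrated
  intensity scales with the *square* of the quasi-helically ordered head
  fraction and whose first radial maximum gives the head radius
  R<sub>m</sub> = x*<sub>n</sub>/(2π r<sub>max</sub>), with
  x*<sub>n</sub> the first maximum of J<sub>n</sub>²;
* derived physiology: ordered head fraction √(I/I₀), recruited fraction
  ΔR/ΔR<sub>rigor</sub>, intensity–tension regressions and a
  Hill-versus-linear model comparison, cross-sectional area and specific
  tension.

The package contains five parts: a synthetic 2D pattern generator with
known ground truth (`latticeModel`, `renderPattern`, state presets for
resting / contracting / rigor / blebbistatin / BTS), image reduction
(`quadrantFold`, `estimateCircularBackground`, `normalizeByDiffuse`,
`projectBand`), equatorial fitting (`analyzeEquator`, `fitEquator`,
`widthModel`, `convexHullBaseline`), layer-line fitting
(`analyzeLayerLine`, `fitLayerLine`, `besselFirstMax`,
`rmFromFirstMax`), and physiology (`orderedHeadFraction`,
`recruitedFraction`, `hillVsLinear`, ...).  See the methods vignette
(`vignettes/fiber-diffraction-methods.Rmd`) for the models and the
numerical choices.

## Worked example

Render a resting pattern at the default study conditions (d10 = 36 nm,
resting ratio calibrated to 0.421, R<sub>m</sub> = 12.53 nm, 10⁶ counts)
and run both analysis pipelines:

```r
library(fibreXRD)

model <- latticeModel()
geom  <- detectorGeometry()
rest  <- renderPattern(model, geom, "resting", seed = 1)

analyzeEquator(rest)
#> EquatorFit: d10 = 35.9981 nm | I11/I10 = 0.4229
#>   widths (nm^-1): sigma_c 0.00084 (fixed), sigma_d 0.00136 , sigma_s 0.000546
#>   areas: 1,0 50.76 | 1,1 21.47 | 2,0 2.833 | 2,1 0.4893 | 3,0 0.4976
#>   R^2 = 0.99993

fold <- quadrantFold(rest)
bg   <- estimateCircularBackground(fold)
ll   <- analyzeLayerLine(rest, background = bg)
ll
#> LayerLineFit: first maximum at 0.06782 nm^-1 | area 3.5903
#>   diffuse-normalized intensity: 8.367e-06
#>   Rm = 12.48 nm (Bessel order 4 )
#>   R^2 = 0.96895
```

The fitted lattice spacing (35.998 nm), intensity ratio (0.423),
disorder widths (1.36×10⁻³ and 0.55×10⁻³ nm⁻¹) and head radius
(12.48 nm) recover the generator's ground truth (36 nm, 0.421,
1.36×10⁻³, 0.54×10⁻³, 12.53 nm) to ~1%.  Pairing with a contracting
pattern gives the residual layer-line intensity and, through the
mass-squared rule, the fraction of heads still in the ordered resting
configuration:

```r
contr <- renderPattern(model, geom, "contracting", seed = 2)
llc   <- analyzeLayerLine(contr,
           background = estimateCircularBackground(quadrantFold(contr)))
r <- residualIntensityRatio(llc, ll)
round(r, 3)                        #> 0.277
round(orderedHeadFraction(r), 3)   #> 0.526
```

About half the myosin heads remain ordered during full activation — the
physiological headline this analysis chain exists to measure.

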