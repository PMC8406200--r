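# filadyn

Coarse-grained dynamics and geometry of enzyme filamentation, built around
the bacteriophage T3 SAMase / *E. coli* methionine S-adenosyltransferase
(MAT) heteropolymer system.

## The scientific problem

Bacteriophage T3 SAMase inactivates the host enzyme MAT not by blocking its
active site but by cross-linking MAT tetramers into head-to-tail filaments
(two MAT tetramers joined at each junction by two SAMase dimers). The free
and filament-bound tetramers superpose almost perfectly, so the inhibition
must be *dynamic*: entrapment in the filament restrains the junction
interface and redistributes the enzyme's soft collective motions into modes
that deform the active-site pockets. `filadyn` implements the computational
pipeline with which that mechanism is interrogated:

- **Gō-model discrete molecular dynamics** (event-driven square-well
  potentials on C-alpha beads) with the pocket-deformation statistic

  d_rms = sqrt( (1/N) Σ_{i<j} (d_ij − d⁰_ij)² ),  N = n(n−1)/2

  over all pairs of a residue set;
- **Gaussian network model** normal modes (Kirchhoff-matrix
  eigendecomposition, amplitudes 1/λ) with per-mode inter-residue dynamic
  correlations c_ij = u_i u_j / √(u_i u_i × u_j u_j) and their set means
  C_pocket and C_interface;
- **PISA-style buried interface areas** (half the accessible-surface-area
  difference between isolated and complexed partners, Shrake–Rupley
  quadrature) with a per-residue interface census;
- **filament reconstruction** by iterative replication of the asymmetric
  unit, with screw parameters (twist, rise, repeats per turn, handedness)
  and the junction kink angle;
- selections exactly as the analysis defines them: native contacts at
  7.5 Å, pockets as a 6 Å expansion around bound substrates, junction
  interfaces within 0.75 nm;
- a **synthetic-structure generator** that plants ground truth (pockets,
  junction patches, screw/kink parameters, and an allosteric
  filamentation signature true by construction), so the whole pipeline is
  testable offline.

It is aimed at structural biologists and biophysicists studying
filamentation-borne regulation, and at anyone needing a self-contained,
deterministic Gō-DMD / GNM / interface-area toolkit in R.

## Worked example

```r
library(filadyn)

rep <- runAnalysis(analysisConfig(seed = 1))

# planted filamentation contrast: pocket deformation in DMD
rep$dmd$drmsMeanTetramer
#> [1] 0.5241387
rep$dmd$drmsMeanOctamer
#> [1] 0.8208723

# ... and in the GNM low modes (mean C_pocket over the 5 softest modes)
rep$gnm$cPocketLowTetramer
#> [1] 1
rep$gnm$cPocketLowOctamer
#> [1] 0.8666667

# filament geometry recovered from the helical fixture
unlist(rep$filament[c("twist", "rise", "repeatsPerTurn", "kink")])
#>          twist           rise repeatsPerTurn           kink
#>             40             50              9             30
```

The free-tetramer pockets stay coherent (C_pocket = 1) and tight
(d_rms ≈ 0.52 Å), while the filament-entrapped octamer's pockets deform in
the soft junction modes (C_pocket ≈ 0.87) and fluctuate further from their
native geometry (d_rms ≈ 0.82 Å) — the qualitative signature of allosteric
inactivation by filamentation, here true by construction in the synthetic
pair. The screw decomposition of the filament's generating transform (40°
twist, 50 Å rise) gives exactly 9 repeats per helical turn, and the planted
30° junction kink is recovered to numerical precision.

Individual stages are plain functions: `readStructure()`, `extractCA()`,
`superpose()`, `nativeContacts()`, `pocketResidues()`,
`interfaceResidues()`, `buildGoModel()`, `runDMD()`, `computeDrms()`,
`gnmModes()`, `correlationProfile()`, `sasa()`, `buriedInterfaceArea()`,
`unitTransform()`, `screwDecompose()`, `replicateFilament()`,
`kinkAngle()`, `makeTetramerAnalog()`, `makeOctamerAnalog()`. A thin
command-line wrapper lives at `inst/scripts/filadyn.R`.

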