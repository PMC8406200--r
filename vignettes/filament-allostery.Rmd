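---
title: "Coarse-grained dynamics of enzyme filamentation: models and methods"
author: "filadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained dynamics of enzyme filamentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filadyn)
```

## The question the package addresses

Several metabolic enzymes are regulated by polymerizing into filaments.  A
striking viral example is the bacteriophage T3 S-adenosylmethionine lyase
(SAMase), which cross-links tetramers of the host's methionine
S-adenosyltransferase (MAT) into open-ended head-to-tail heteropolymers:
two MAT tetramers joined at each junction by two SAMase dimers.  The free
and filament-bound MAT tetramers superpose almost perfectly (about 2 Å
C-alpha RMSD), yet the filament-bound enzyme is inactive, so the mechanism
of inhibition must be dynamic rather than a static conformational change.

`filadyn` implements the computational machinery with which such an
allosteric, dynamics-borne inhibition can be interrogated:

1. **Structure handling** — PDB/mmCIF input, C-alpha extraction,
   least-squares (Kabsch) superposition.
2. **Selections** — native contacts at a 7.5 Å cutoff, active-site
   ("pocket") residues as a 6 Å expansion around bound substrates, and
   junction-interface residues within 0.75 nm of the partner molecules.
3. **Gō-model discrete molecular dynamics (DMD)** with the
   pocket-deformation statistic $d_\mathrm{rms}$.
4. **Gaussian network model (GNM)** normal modes with per-mode
   inter-residue dynamic correlations $C_\mathrm{pocket}$ and
   $C_\mathrm{interface}$.
5. **PISA-style buried interface areas** from Shrake–Rupley accessible
   surface areas.
6. **Filament reconstruction** by iterative replication of the asymmetric
   unit, with helical screw parameters (twist, rise, repeats per turn,
   handedness) and the junction kink angle.
7. A **synthetic-structure generator** that plants ground truth for every
   stage, so the entire pipeline is testable without any external
   coordinate file.

## Coarse-grained DMD

Each residue is one C-alpha bead of unit mass; energies are measured in
units of the native-contact well depth $\varepsilon$ and temperatures in
$\varepsilon/k_B$.  Pairs are partitioned exactly once:

* **Bonds** (sequence neighbours of a chain) are confined to a hard window
  $[0.98, 1.02]$ times the native bond length.
* **Native contacts** (pairs within 7.5 Å in the native structure,
  intra-chain pairs at sequence separation ≥ 2) feel a single square well
  of depth $\varepsilon = 1$ spanning $[0.85, 1.15]$ times the native
  distance, with a hard core at the inner boundary.
* **All other pairs** are hardcore-repulsive at 3.6 Å.

The published description of this class of model cites prior DMD work
without restating well depths or widths; the values above are the minimal
standard Gō-DMD choices and every one of them is an exposed argument of
`buildGoModel()`.

Dynamics are event-driven: beads move ballistically between events, and at
each event (hardcore collision, well-boundary crossing, bond-window wall)
the radial component of the relative velocity is updated by exact
energy/momentum conservation for equal masses.  A well exit succeeds only
when the radial kinetic energy in the reduced-mass frame exceeds
$\varepsilon$; otherwise the pair reflects and stays bound.  One *DMD step*
is one processed event (the source description does not define its step
unit; this definition makes step counts exactly reproducible).  An
Andersen-style thermostat redraws the velocity of a uniformly chosen bead
from the Maxwell–Boltzmann distribution at Poisson rate
`thermostatRate` per bead per reduced time unit (default 1); with the
thermostat off the run is microcanonical and conserves total energy to
round-off (measured drift is below $10^{-17}$ per event, far inside the
$10^{-9}$ budget asserted by the tests).  All randomness comes from an
internal 64-bit generator, so a fixed seed yields a bit-identical
trajectory.

The default temperature is $T = 0.5\,\varepsilon/k_B$, well below the
unfolding regime of these parameters: a 40-bead compact chain retains more
than 90 % of its native contacts over $10^5$ events.  The contrast studied
(free tetramer vs. linked octamer) is about *relative* pocket deformation
and is preserved across moderate temperatures.

### The deformation statistic

For a residue set of size $n$ (all $N = n(n-1)/2$ pairs, not only native
contacts),
$$d_\mathrm{rms} \;=\; \sqrt{\tfrac1N \sum_{i<j} \bigl(d_{ij} - d^0_{ij}\bigr)^2},$$
where $d^0_{ij}$ are the distances in the system's own native coordinates
and $d_{ij}$ those in a trajectory frame.  It is zero at the native frame
and invariant under rigid motion.  `drmsProfile()` evaluates it on every
retained frame, discarding the first third of each trajectory as burn-in
(mirroring a production protocol that analyzes the last two thirds) and
pooling across replicas.

### Production scale and the scaled-down default

The production protocol behind the published comparison is 39 independent
trajectories of 6 million steps per system.  The package default —
`analysisConfig()` — runs 8 replicas of $2\times10^5$ steps with snapshots
every $10^3$ steps, which resolves the planted contrast in well under a
minute per system on one core; `analysisConfig(paperScale = TRUE)`
restores the full 39 × 6 M protocol.  Replica $k$ uses seed
`baseSeed + k - 1`, and velocities are initialized from the
Maxwell–Boltzmann distribution with the net momentum removed.

## GNM normal modes and the correlation statistic

The Kirchhoff (connectivity) matrix $\Gamma$ has $\Gamma_{ij} = -1$ for
nodes within the spring cutoff and node degree on the diagonal, so rows sum
to zero.  The cutoff defaults to 7.5 Å, matching the native-contact
definition used by the DMD stage (10 Å is another common GNM choice and is
a single argument away).  Eigenvalues are sorted ascending; modes below
$10^{-10}$ are zero modes — exactly one per connected network component —
and internal mode 1 is the lowest non-zero mode.  The amplitude of mode $k$
is $1/\lambda_k$.

For one mode with shape $u$, the inter-residue dynamic correlation is
$$c_{ij} \;=\; \frac{u_i u_j}{\sqrt{u_i u_i \times u_j u_j}},$$
which for a single scalar mode is the *sign concordance* of the two
components.  $C$ is the mean of $c_{ij}$ over distinct pairs of the set:
$C = 1$ means the set moves fully in phase (no deformation in that mode);
negative values mean anti-correlated, deforming motion.

Two numerical guards apply.  Components below $10^{-9}$ of the mode's
largest component are numerical zeros and are excluded.  Separately,
`minParticipation` (used at 0.05 by the pipeline) excludes residues whose
component is below that fraction of the mode's largest component: the
*sign* of a component that is orders of magnitude smaller than the mode's
actual motion carries no information about deformation — it is round-off
noise — and without the floor a pocket sitting on an essentially static
chain can read as "deformed" because two near-zero components happen to
have opposite signs.  A set with fewer than two participating members does
not deform in that mode and reads $C = 1$.  This floor is a deliberate
design choice of this package; setting `minParticipation = 0` recovers the
bare sign-concordance statistic.

Profiles (`correlationProfile()`) report mode index, $\lambda$,
$1/\lambda$ and $C$ for the first $M$ internal modes (default 20; the
pipeline uses 12 and summarizes the lowest 5 as the "low-mode" value).
When several pockets are present, `pooledCorrelationProfile()` emits both
the per-pocket profiles and their per-mode mean (4 pockets in a tetramer,
8 in the linked octamer).

## Buried interface areas

Accessible surface areas use the Shrake–Rupley construction: the solvent
probe (1.4 Å) is rolled over van der Waals spheres (C 1.70, N 1.55,
O 1.52, S 1.80 Å, plus other common elements) by testing 960 points per
atom placed on a deterministic golden-spiral lattice — no randomness, so
areas are exactly reproducible, and doubling the point count moves totals
by less than 1 %.  The buried interface area between chain groups $A$ and
$B$ is the PISA-style half-difference
$$\mathrm{area} = \tfrac12\bigl(\mathrm{SASA}(A) + \mathrm{SASA}(B) -
\mathrm{SASA}(A \cup B)\bigr),$$
with per-residue buried areas (isolated minus complexed) for both
partners; residues burying more than a 0.1 Å² noise floor form the
interface census.  Waters and ligands are excluded by default.  The exact
radii PISA uses are not published alongside the reference areas, so
comparisons against areas computed with other radii sets should allow
roughly ±15 %.

## Filament geometry

`unitTransform()` superposes one oligomer of the asymmetric unit onto the
adjacent equivalent oligomer (chains paired in the given order,
residues by sequence order), producing the generating transform of the
filament.  `screwDecompose()` factors any proper rigid motion into a twist
about a unique axis plus a rise along it: the twist magnitude comes from
the rotation-matrix trace, the axis from the antisymmetric part (or the
+1-eigenvector near 180°), the rise is the translation component along the
axis, and the axis point solves $(I - R)\,p = t_\perp$ by pseudoinverse.
The axis sign is chosen so the rise is non-negative; the handedness is the
sign of the twist about that axis (+1 = right-handed), and
`repeatsPerTurn = 360 / twist` exactly.  Decompose-then-recompose is exact
to $10^{-12}$ over random transforms; transforms with twist below 0.1° are
rejected as near-pure translations (the axis is ill-defined).

The kink angle between adjacent oligomers is the angle between their
designated molecular axes, reported in $[0°, 90°]$ since axes are lines.
Two axis rules are available, because the published ~30° bend is not
accompanied by a definition: `"inertia"` (default) uses the principal axis
with the smallest inertia moment — the long molecular axis — and
`"plane"` uses the normal of the best-fit plane.  On the synthetic
fixtures both recover a planted kink; on real oligomers the two rules can
differ and both should be reported.

`replicateFilament()` applies the generating transform iteratively (copy
$k$ is $t^k$ applied to the unit) and reports the minimum inter-copy
C-alpha distance as a clash check; reconstruction is purely geometric, with
no clash filtering, since observed filaments (2–7 tetramers) are much
shorter than a full helical turn.

## The synthetic generator and what it plants

`makeCompactChain()` grows a self-avoiding C-alpha chain (3.8 Å bonds,
non-bonded beads ≥ 4.0 Å apart) confined to a sphere of radius
$3\,n^{1/3}$ Å, giving compact folds with 3–4 native contacts per residue.
`makeTetramerAnalog()` packs four copies in a C4 arrangement with the
radial offset tuned so neighbouring chains approach to 4.4–6.0 Å (contacts
but no clashes), and plants one substrate pseudo-atom per chain.  Pocket
sites are chosen on internally *rigid* faces — candidate placements are
scored by the coherence of their members in the low modes of the free
assembly — because the reference side of the planted contrast is an intact
free-state pocket.

`makeOctamerAnalog()` joins two tetramer analogs head-to-tail through two
short linker chains and plants the filamentation signature by
construction, in two independent ways:

* **Junction-straddling active sites.**  The substrate pseudo-atoms of the
  two junction-facing chains sit in the cleft between the tetramers, so
  their 6 Å pockets contain residues of both tetramers (and of the linkers
  running through the cleft).  The sparsest cut of the octamer's elastic
  network is the junction, so the lowest internal modes move the two
  tetramers against each other — and a pocket that straddles the junction
  is deformed by exactly those high-amplitude modes.  This is what drives
  the low-mode pocket correlation of the octamer below the tetramer's.
* **Entrapment strain.**  Every pocket of the assembled unit is pried open
  by ~0.6 Å (halved automatically if that would create clashes), while the
  accompanying Gō contact list keeps the *relaxed* free-tetramer reference
  distances for tetramer-internal pairs and the *assembled* distances for
  junction pairs.  The octamer's energy landscape is therefore frustrated
  precisely at its pockets: junction wells hold the pried state,
  intra-tetramer wells pull back, and the pocket geometry fluctuates
  between the two.  Measured against the octamer's own native (assembled)
  coordinates, pocket $d_\mathrm{rms}$ is then systematically larger than
  in the free tetramer.

Both effects are synthetic surrogates: they guarantee the qualitative
signature (higher pocket $d_\mathrm{rms}$ and lower low-mode
$C_\mathrm{pocket}$ upon filamentation) for testing purposes, and they
encode a physically sensible story (binding strains the enzyme; soft
junction modes run through the active sites), but they are *constructions*,
not biological claims.  Consequently, a passing end-to-end test shows that
the pipeline detects a planted allosteric signature of realistic magnitude
in a realistic-size assembly — it does not by itself validate the
mechanism in the real SAMase–MAT system, which requires the deposited
structures.

What the fixtures deliberately do not emulate: real secondary structure,
side chains and rotamers, sequence effects, solvent, and the detailed
symmetry of a dihedral (dimer-of-dimers) tetramer.

```{r generator, eval = FALSE}
tet <- makeTetramerAnalog(seed = 1)   # 4 x 40 beads, 4 planted pockets
oct <- makeOctamerAnalog(seed = 1)    # + mirror copy, 2 linkers, strain
```

## End-to-end pipeline

`runAnalysis(analysisConfig(seed))` executes selections → GNM (both
systems) → replicated DMD (both systems) with pooled pocket
$d_\mathrm{rms}$ → junction buried areas → filament reconstruction, and is
deterministic given the seed.  The DMD stage of the octamer uses the
generator's frustrated contact list; everything else derives from the
structures alone.  Problem sizes per run: 160-bead tetramer and 330-bead
octamer, 8 replicas × 2 × 10⁵ events each, 12 GNM modes, 960 SASA points
per atom — about 40 s on one core in total.

## Reproducing the deposited-structure comparisons

The comparisons against the deposited SAMase–MAT filament unit and the
free MAT tetramer (C-alpha superposition RMSD ≈ 2.16 Å; screw
decomposition of the tetramer-to-tetramer transform ≈ 9 repeats per turn
with a ≈ 30° kink; buried areas ≈ 1000 Å² for the SAMase–SAMase dimer
interface, ≈ 600–700 Å² for MAT–SAMase and ≈ 170 Å² for the inter-tetramer
MAT–MAT contact; ≈ 21 MAT interface residues including Asp132 and Trp26)
require the wwPDB coordinate files `1p7l.pdb` and `7ock.cif`.  They are too
large to ship with the package: download them from the PDB and place them
under `inst/extdata/deposited/` (or the installed
`extdata/deposited/` directory), after which the corresponding blocks in
`tests/testthat/test-acceptance.R` run the full comparisons.  Without the
files those three checks fail loudly rather than pass silently; all
synthetic-data checks are self-contained.

For the 2.16 Å check the superposition uses C-alpha atoms of matched
residues (the published number is quoted for "atomic positions" without an
atom list; all-atom superposition is available by superposing the full
coordinate sets), and both candidate tetramer pairings within the filament
unit are tried, reporting the better one.

## Numerical choices and degenerate inputs

* Distances are Euclidean with inclusive (≤) cutoffs throughout; the
  junction-interface cutoff (0.75 nm) and the native-contact cutoff
  (7.5 Å) are numerically identical but remain independent parameters.
* Residue identity is (chain, author residue number, insertion code);
  author numbering is preserved from the input.  Altloc records keep the
  highest-occupancy conformer.
* Kabsch reflections are corrected by flipping the smallest singular
  vector; coincident or collinear point sets are rejected.
* Superposition of fewer than 3 points, empty ligand lists, overlapping
  chain groups, cutoffs ≤ 0, burn-in ≥ trajectory length, and mode indices
  beyond the spectrum all raise immediate errors.
* DMD initialization rejects bead pairs that start inside a hard core, and
  a system with no future events (all beads at rest, thermostat off) is
  reported as event-queue starvation rather than looping.

## Known limitations

* The Gō parameterization (well widths, hardcore diameter, thermostat
  rate) is a standard minimal choice, not fitted to the real enzyme.
* Single-mode GNM correlations are sign statistics; magnitude-weighted
  cross-correlations over mode combinations are not implemented.
* SASA has no analytic derivatives and no solvation-energy model; the
  PISA ΔG, hydrogen-bond and salt-bridge predictions are out of scope.
* Filament reconstruction assumes a single generating transform; polymorphic
  or curved filaments are not modelled.
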