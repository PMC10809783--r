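---
title: "Quantifying surfactant monolayer biophysics with monosurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying surfactant monolayer biophysics with monosurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monosurf)
```

## The problem

Pulmonary surfactant is the lipid-protein film at the alveolar
air-liquid interface. A functional film drives the surface tension
$\gamma$ far below that of clean water during exhalation-like
compression, resists lateral compression (a high compressibility
modulus), and cycles with little compression-expansion hysteresis.
Inhaled chemicals - for example flavoring aldehydes from vaping
aerosols and their acetal byproducts - can partition into this film and
degrade all three properties.

monosurf implements the quantitative machinery for both sides of such a
study:

* **Surfactometry traces** from a Langmuir-Blodgett trough (LBT;
  surface pressure $\Pi$ vs. area in cm$^2$, quasi-static barrier
  cycling) or a constrained sessile drop (CSD; surface tension
  $\gamma$ vs. drop area in mm$^2$, physiological-rate oscillation) are
  segmented into compression-expansion iso-cycles and reduced to
  per-cycle functional metrics.
* **Monolayer coordinate frames** (GRO/PDB, as produced by molecular
  simulations) are reduced to structural observables: leaflet
  assignment, area per lipid, liquid-condensed packing fraction, acyl
  chain tilt, density profiles, and partner-normalized contacts.
* A **synthetic-data generator** produces ground-truth-labeled traces,
  decay series and coordinate frames, so every analysis stage is tested
  end to end against constructions whose answers are known exactly.

Running molecular dynamics itself, instrument control, drop-shape
fitting and cross-condition inferential statistics (ANOVA-type
comparisons) are out of scope.

## Trace model and iso-cycle metrics

A trace is a time series $(t_i, A_i, v_i)$ with $v$ either $\Pi$ or
$\gamma$ (mN/m). The two are interconvertible through the clean-water
reference, $\Pi = \gamma_0 - \gamma$ with $\gamma_0 = 72.8$ mN/m at
20 °C (`convertMeasure()`).

**Segmentation** (`segmentCycles()`) finds area reversals on a centered
moving-median smoothed copy of $A(t)$ (window 5 points) using a
zig-zag rule: a running extremum becomes a cycle boundary once the
series retreats from it by at least `minAmplitudeFraction` (default
0.02) of the global area range, which makes the boundary count immune
to jitter below that threshold. Because the moving median flattens
sharp reversal tips, each boundary is then snapped to the raw-area
extremum within half a smoothing window. A trailing cycle whose
expansion recovers less than half its compression amplitude is kept but
flagged incomplete (CSD records end mid-cycle at the fixed 120 s mark);
window summaries skip incomplete cycles. A constant-area trace yields
zero cycles and a warning, not an error.

**Per-cycle metrics**:

* Extrema (`cycleExtrema()`): max $\Pi$ (LBT) or min $\gamma$ (CSD) per
  cycle, taken from raw samples without interpolation, with the area at
  which they occur.
* Compressibility modulus (`modulusCurve()`):
  $\kappa = -A\,\partial\Pi/\partial A$, the reciprocal of the
  compressibility $C$. The derivative uses centered finite differences
  (one-sided at branch ends) on the first-cycle compression branch -
  the branch where the modulus is best defined - after collapsing
  duplicate-area plateau samples. The curve is reported against $\Pi$
  raw and Savitzky-Golay smoothed. The filter window is 9 points; the
  polynomial order is not fixed by the instrument convention, so we
  default to 3 and expose both. No installed R package provides this
  filter, so it is implemented directly (least-squares polynomial
  convolution with exact polynomial edge handling).
* Global compressibility (`globalCompressibility()`): CSD iso-cycles
  are too sparse for a pointwise modulus, so a single slope
  $\Delta\gamma/\Delta A$ between the minimum- and maximum-tension
  points of the compression branch is used. The magnitude is reported
  (relative comparisons are the use case); the signed slope rides along
  as an attribute.
* Hysteresis (`hysteresis()`): the area difference between compression
  and expansion branches at half the cycle's maximum surface measure,
  located on each branch by linear interpolation;
  $\Delta A = A_\mathrm{comp} - A_\mathrm{exp}$, positive when the
  expansion branch lies inside the compression branch. We use the
  whole-cycle maximum as "the maximum"; for well-formed cycles this
  equals the compression-branch maximum.
* Window summaries (`summarizeWindows()`): means ± standard errors of
  the first/last $n$ complete cycles; `relativeToControl()` forms the
  ratios used to compare against an untreated first cycle.

## Decay kinetics of the cycle minima

Across consecutive CSD cycles the per-cycle minimum tension relaxes
toward a plateau. `fitDecay()` fits

$$y(t) = y_\infty + \sum_{i} a_i\, 2^{-t/t_{1/2,i}}, \qquad a_i \ge 0$$

with one (mono) or two (bi) phases. The base-2 parameterization makes
the printed half-lives the parameters themselves;
`halfLifeToRate()`/`rateToHalfLife()` convert to $e$-folding rates. The
fit is deterministic: half-life starting values come from a fixed
log-spaced grid spanning the sampling interval to 10× the record
length; at each start the plateau and amplitudes are solved by linear
least squares with nonnegativity enforced by an exact active-set drop;
the best start is refined by bounded quasi-Newton iterations. The
biexponential multi-start includes the fitted monoexponential as a
degenerate start, so $\mathrm{rss}_{bi} \le \mathrm{rss}_{mono}$ always
holds. `model = "auto"` compares the two by the extra-sum-of-squares F
test at $\alpha = 0.05$ (the convention of the commercial fitting
package such curves are usually analyzed in); AICc is available as an
alternative. A constant series degrades gracefully to a zero-amplitude
monoexponential.

A note on identifiability: with 600 uniform samples and noise at 5% of
the initial decay amplitude, the exact least-squares estimator recovers
the half-life pair 44.5/253 s within 15% in only about three quarters
of replicates - we verified that `fitDecay()` reproduces a
truth-started optimizer to machine precision, so this is the Fisher
information of such records, not an optimizer artifact. Noiseless
recovery is better than 0.1%.

## Monolayer structural analysis

Frames are read from GRO or PDB files (`loadFrames()`); residue names
resolve to a closed species vocabulary (DPPC, POPC, POPG, CHOL,
PROTEIN, CHEMICAL, WATER, ION) through a species map whose default
covers CHARMM-style naming and the synthetic builder; unknown residues
are reported by name. Boxes are orthorhombic, periodic in the membrane
plane; triclinic cells are out of scope. Coordinates are nm internally;
area per lipid is reported in Å$^2$ at a single conversion point.

* `assignLeaflets()`: the simulated systems hold two monolayers facing
  a central water slab; each lipid's head marker (phosphate P, or the
  cholesterol O3) is compared with the water-slab center (or an
  explicit midplane). An exact tie goes to the upper leaflet with a
  warning.
* `areaPerLipid()`: in-plane box area over leaflet lipid count.
* `packingFraction()`: DBSCAN over the in-plane positions of the 10th
  acyl carbon of every phospholipid chain and the cholesterol C14, with
  cutoff $\varepsilon = 0.71$ nm and 6 required neighbors, under
  periodic minimum-image distances. "6 neighbors" is read as six
  *other* points (`includeSelf = TRUE` gives the alternative reading),
  and border points attached to a cluster count as condensed
  (`countBorder = FALSE` restricts to cores). Any clustered chain or
  sterol is assigned to the liquid-condensed ($L_c$) phase; the
  fraction is over all chain/sterol entities. `packingFractionSeries()`
  averages over frames with a standard deviation. The implementation is
  queue-expansion DBSCAN on the core graph (no R DBSCAN package is
  available here); the test suite checks it against an independent
  brute-force oracle built on graph components.
* `chainTilt()`: the angle between each chain's C1→C16 vector and the
  monolayer normal (z), folded to [0°, 90°] so leaflet orientation and
  chain direction conventions cannot flip signs; chains crossing the
  periodic boundary are unwrapped by minimum image. Cholesterol is
  excluded; the mean is over chains (two per phospholipid).
* `densityProfile()`: per-species number densities along z, each frame
  centered so the leaflet's mean phosphate z sits at 0 (per-frame
  centering removes drift), accumulated over frames and divided by each
  species' maximum so occupied profiles peak at exactly 1. Bin width
  defaults to 0.1 nm. An absent species gives an all-zero flagged
  profile.
* `contactCount()`: heavy-atom pairs across two disjoint groups within
  0.6 nm under 3-D minimum image, divided by
  $N_\mathrm{heavy}(A)\,N_\mathrm{heavy}(B)$ - the most literal reading
  of normalizing by the number of possible interaction partners;
  per-molecule-pair normalization is an option.
  `contactsVsArea()` evaluates the per-frame APL and contact value over
  a compression series and averages within APL bins;
  `replicaAggregate()` implements the duplicate-simulation convention
  (mean as the value, half the absolute difference as the error).

## The synthetic generator: a stated world

The generator's defaults are the instruments' and simulation systems'
stated operating points, chosen once:

* **LBT traces**: 10 triangular cycles at 150 cm$^2$/min between 215
  and 56 cm$^2$, 1 Hz sampling, pressure output, $\kappa_0$-exponential
  isotherm $\Pi = \kappa_0 \ln(A_{max}/A)$ with $\kappa_0 = 100$ mN/m
  capped at 60 mN/m, optional kink plateaus.
* **CSD traces**: sinusoidal oscillation, 20 cycles/min, 20% area
  reduction around a 30 mm$^2$ drop, 120 s at 5 frames/s (600
  samples), tension output. The stiffness default is $\kappa_0 = 280$
  mN/m: within a 20% area excursion a functional film must reach low
  tension ($\gamma_{min} \approx 8$-11 mN/m), which an LBT-like
  $\kappa_0 = 100$ cannot do - with it, $\gamma$ would never cross the
  half-maximum level and hysteresis would be undefined.
* **Hysteresis** is constructed by rigidly shifting the expansion
  branch's effective area, which makes the half-maximum area difference
  equal the shift at every level. On the triangular LBT schedule with a
  grid-commensurate shift the analysis recovers it to 1e-9; on the
  sinusoidal CSD schedule linear interpolation leaves an
  $O(0.005\ \mathrm{mm}^2)$ residual, and the sampled extremum misses
  the exact reversal phase by up to $\kappa_0 \Delta A_{vertex}/A
  \approx 0.8$ mN/m in $\gamma_{min}$; the tests carry these bounds.
* **Monolayer frames** (`buildMonolayerFrame()`): lipids are coarse
  marker-bearing rods - P plus two C1/C10/C16 chains for a
  phospholipid, O3 + C14 for cholesterol - because every analysis
  consumes only marker atoms and heavy-atom positions. Compositions are
  apportioned by largest remainder (`apportionComposition()`; 149
  lipids at 68:20:10:2 gives 101/30/15/3). The condensed patch is a
  hexagonal lattice strip (default spacing 0.48 nm, a typical condensed
  chain spacing) that wraps the box in x, so under the
  0.71 nm/6-neighbor rule every patch entity is core or border; patches
  thinner than three wrapped rows are refused because their corners
  would be DBSCAN noise and break the exact ground-truth contract.
  Chain C10 markers sit exactly on their sites, so the clustering
  geometry is exact by construction. Patch chains share the requested
  tilt with a common azimuth (collective tilt); disordered chains draw
  a random tilt up to 60° and random azimuth. The achieved entity
  fraction and the realized mean tilt are recorded as the ground truth,
  so noiseless recovery is exact rather than approximate.
* **Disordered placement.** At realistic areas per lipid the chain
  density (2-4 entities/nm$^2$) exceeds what any point set with minimum
  spacing 0.8 nm can reach, so Poisson-disk placement at that radius is
  geometrically impossible. Disordered entities therefore sit on a
  lightly jittered triangular lattice with minimum spacing 0.72 nm
  (still strictly above $\varepsilon = 0.71$ nm, so ground-truth
  membership stays unambiguous), and the builder raises a geometry
  error when even that density is infeasible. This is also why the
  builder's default APL is 100 Å$^2$, the expanded end of the
  physiological 50-100 Å$^2$ band: it is the regime where a fully
  disordered leaflet is constructible under the spacing guarantee.
* **Compression series** (`simulateCompressionSeries()`): the box and
  all in-plane positions are rescaled affinely so the APL falls
  linearly from 110 to 54.5 Å$^2$; z is preserved. A probe line of
  protein atoms plus chemical particles is added with constructed
  placements - in frame $i$ exactly $k_i$ chemicals sit 0.45 nm above
  distinct probes and the rest are parked out of range - so the
  normalized contact series has the closed form
  $k_i/(n_{probe} n_{chem})$ and rises toward low area.

What the generator does **not** emulate: thermal disorder in condensed
packing, realistic chain conformations, protein structure, chemical
aggregation physics, squeeze-out, or any energetics. A green round-trip
test therefore establishes that the analysis measures what it claims to
measure on inputs with known answers - not that the physics of a real
trajectory is reproduced.

## Pipeline, seeds, and provenance

`runPipeline()` drives three modes (trace, monolayer, validate) from a
single configuration - an R list or a JSON file (`readRunConfig()`;
JSON rather than YAML because this environment ships no R YAML parser).
Every run writes tidy CSV tables, a JSON summary, a log, and a
provenance record (config echo, config MD5, seed, package and R
versions) sufficient to re-execute it. All randomness derives from the
single top-level seed via fixed offsets per stage; two runs with the
same config and seed produce identical tables. A thin `Rscript` wrapper
lives in `inst/scripts/monosurf.R`.

```{r example, eval = FALSE}
g <- generateTrace(traceSpec("LBT", hysteresisShift = 3,
                             samplingRate = 2.5))
cycles <- segmentCycles(g$trace)
cycleMetrics(g$trace, cycles)

b <- buildMonolayerFrame(monolayerSpec(lcPatchFraction = 0.5))
packingFraction(b$frame)
chainTilt(b$frame)
```

## Numerical choices and known limitations

* Branch index ranges are stored disjoint; interpolation-based metrics
  re-attach the shared turning-point sample internally.
* `modulusCurve()` requires a strictly monotone branch after collapsing
  duplicate areas and names the first violation; the Savitzky-Golay
  window must fit the branch.
* At noise levels comparable to the per-sample pressure increment, the
  pointwise finite-difference modulus is noise-dominated; the 9-point
  smoother roughly halves the worst-case deviation and centers the
  curve, but pointwise accuracy requires either denser sampling or
  smoothing before differentiation, which we deliberately do not do
  (the smoothed curve is defined as the filter of the raw modulus).
* DBSCAN border points between two eligible clusters join whichever
  cluster's expansion reaches them first; membership in the condensed
  phase (the quantity of interest) is unaffected.
* GRO output carries 3 decimals (0.001 nm); analyses on written-out
  frames agree with in-memory frames to that precision.
* The decay fit's half-life grid spans fixed bounds derived from the
  record; pathological records (all mass decayed between two samples)
  hit the bounds and are reported at them rather than diverging.
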