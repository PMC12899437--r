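---
title: "Methods: pucker mathematics, eABF/CZAR estimation, and landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pucker mathematics, eABF/CZAR estimation, and landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gagfes` implements the analysis chain for studying how iduronate ring
pucker and sulfation shape glycosidic-linkage free-energy surfaces
ΔG(φ, ψ) in glycosaminoglycan (GAG) carbohydrates. This vignette records
the models, conventions, numerical choices and limitations behind each
stage, in the order data flows through the pipeline.

## Ring puckering: Cremer–Pople transforms and conventions

A six-membered ring's out-of-plane conformation is parameterized by the
Cremer–Pople construction: displacements z_j of the six ring atoms
perpendicular to the unique mean plane are decomposed into the m = 2
harmonic (amplitude q₂, phase ϕ) and the m = 3 alternating mode (q₃),
giving a total amplitude Q = √(q₂² + q₃²) (Å) and spherical-polar
direction θ = atan2(q₂, q₃) ∈ [0°, 180°], ϕ ∈ [0°, 360°).

Conventions the package pins (the mathematics itself leaves them free):

- **Atom order** O5, C1, C2, C3, C4, C5, with the mean-plane normal
  chosen so the ⁴C₁ chair maps to θ = 0 and ¹C₄ to θ = 180. With this
  orientation ²S_O sits at (90°, 150°) and B₃,O at (90°, 180°), the
  standard pyranose chart.
- **Hexagon handedness** in `inverse_cremer_pople()` is chosen so that
  ring dihedral signs agree with pyranose geometry: the ¹C₄ ring gives
  the alternating (−, +, −, +, −, +) pattern of Φ₁…Φ₆ (Φ₁ =
  O5–C1–C2–C3, cyclic), matching the reference dihedrals of the
  restraint targets. The projected hexagon radius is 1.46 Å (typical
  pyranose); only the harmonic content matters for round trips.
- **Planarity**: Q < 10⁻⁴ Å is rejected ("planar ring"); q₂ below the
  same tolerance marks ϕ undefined (pure chair).
- **Naming** uses great-circle distance on the (θ, ϕ) sphere to the 38
  canonical IUPAC vertices (2 chairs, 6 boats + 6 skews on the equator
  every 30°, 6 envelopes + 6 half-chairs on each tropic at
  θ = 54.74°/125.26°). When ϕ is undefined, only the chairs are
  resolvable; θ within [45°, 135°] then raises an error rather than
  guessing an equatorial form.
- **Idealness** is scored as (θ − θ_ideal)² for the chairs and
  (θ − θ_ideal)² + (ϕ − ϕ_ideal)² for the equatorial targets, with the
  ϕ difference taken as the minimal image on the circle (θ is not
  periodic on [0°, 180°], so its difference is plain). The two-term
  score applies to ²S_O and B₃,O: these are the two equatorial
  restraint targets, the only ones for which an azimuthal term is
  meaningful.

Reversing the ring traversal direction maps θ → 180° − θ; this is
asserted in the tests so the convention cannot drift silently.

## Glycosidic torsions

φ ≡ O5ᵢ–C1ᵢ–OXᵢ₋₁–CXᵢ₋₁ and ψ ≡ C1ᵢ–OXᵢ₋₁–CXᵢ₋₁–C(X−1)ᵢ₋₁, the IUPAC
heavy-atom definitions, with X = 3 or 4 by linkage type. Signs follow
the IUPAC convention (clockwise positive viewed along the central
bond); angles are wrapped to (−180°, 180°], matching conformational
maps spanning −180…180. The bridging oxygen is resolved geometrically —
an oxygen within 1.7 Å of both the anomeric and the attachment carbon —
because PDB dialects disagree about which residue owns it. A
proton-based convention (H1/HX replacing O5/C(X−1)), used in NMR work,
is available via `convention = "nmr"`; IUPAC is the default throughout.

## Ring restraint

The restraining potential E = ½ k Σᵢ₌₁⁶ ((Φᵢ − Φ₀,ᵢ)/w)², with defaults
k = 1 kcal/mol and w = 5°, holds the iduronate ring in a chosen pucker
state while permitting moderate deformation. Differences are wrap-aware:
the published formula is silent on wrapping, but reference dihedrals
near ±180° make the minimal image the only self-consistent choice (a
raw difference would see a 358° violation where the geometry moved 2°).
The gradient is analytic (k·Δᵢ/w²) and is verified against central
finite differences at 10⁻⁶.

Retention is quantified as the fraction of (θ, ϕ) samples within a
great-circle radius of the target's ideal point; the default radius of
30° is the largest value that still separates the four restraint
targets (²S_O and B₃,O are exactly 30° apart; all other pairs are
farther). Because the six ring dihedrals of a closed ring are not
independent coordinates, the restrained ensemble used for testing is
generated by Metropolis Monte Carlo on (Q, θ, ϕ): each proposal is
materialized as a ring via the inverse Cremer–Pople map, scored with
the restraint energy, and accepted by the Boltzmann criterion at 298 K.
This has the same stationary distribution a restrained dynamics over
those coordinates would have, which is all the retention check needs.

## The synthetic landscape and sampler

All sampling-dependent stages are exercised against analytic ground
truth rather than molecular dynamics. The landscape is a sum of
von-Mises-like wells, U(x, y) = offset − Σ depthⱼ ·
exp(κⱼ(cos(x−xⱼ) + cos(y−yⱼ) − 2)) — smooth, periodic, with analytic
gradient. `design_two_basin()` builds a two-well landscape whose escape
barrier (measured as a minimax saddle on a dense 144² grid) hits a
requested target within 0.1 kcal/mol by bisecting the shared κ: for
fixed depths, larger κ narrows the basins and raises the saddle toward
the flat background, so the barrier is monotone in κ. Default centers
put the global basin at (−77.5°, 132.5°) and the secondary basin at
(−97.5°, −80°) — the upper-left/lower-left quadrant arrangement seen for
IdoA2S-GlcNS-type linkages — with the secondary minimum +1.3 kcal/mol
above the global one, a typical offset for a highly sulfated
heparin-type disaccharide.

The sampler is overdamped Langevin (Euler–Maruyama) for the coordinate
pair z = (φ, ψ) on U plus a harmonic spring to an extended pair λ, and
for λ on the spring plus (when biased) the adaptive bias force. Choices:

- **Overdamped dynamics**: the simplest process with the correct
  stationary density; inertial MD realism is out of scope and unneeded
  for testing estimators.
- **Units**: degrees, kcal/mol; k_BT = 0.5922 kcal/mol at the default
  298 K. Time is measured in steps; only dt/friction and k_BT enter.
- **dt = 2, friction = 1**: RMS thermal step √(2k_BT·dt) ≈ 1.5° per
  axis, well under one 2.5° bin, while the Euler–Maruyama
  stationary-density bias (≈ dt·U″/2) stays below a few percent for
  every well curvature used here; verified against Boltzmann
  quadrature in the tests.
- **k_ext = 0.01 kcal/mol/deg²**: spring fluctuation
  σ = √(k_BT/k_ext) ≈ 7.7°, keeping λ within about two bins of z.
- **eABF bias**: per λ-bin running mean of the spring force scaled by
  the ramp min(1, N/N_full), N_full = 200 by default (the customary
  collective-variables default; the source protocol does not print its
  value).

Trajectories and all bias statistics are bit-reproducible for a fixed
seed. For transition counting, a dwell filter (default 10 stored
frames) requires persistence in the new basin before a transition
registers, suppressing barrier recrossings; the underlying definition
of "a single transition" in the source material is not stated, so the
filter is exposed and documented rather than hidden.

## CZAR estimation and Poisson integration

The free-energy gradient is reconstructed by the corrected z-averaged
restraint (CZAR) estimator, ∇A(z) = −k_BT ∇ln ρ̃(z) + k_ext(⟨λ⟩_z − z),
with ρ̃ the biased histogram of z and the log-density gradient taken by
central differences on the periodic grid. The spring displacement is
accumulated as the minimal-image mean of (λ − z) per z-bin, which is
the same quantity and immune to wrap artifacts at ±180°. Bins without
samples are flagged and, before integration, filled by iterative
averaging of finite neighbors (the only place interpolation occurs; the
filled bins are far above the region of interest whenever coverage is
adequate).

Integration solves the discrete periodic Poisson problem ∇²A = ∇·G
spectrally: both the divergence and the Laplacian are built from the
same central-difference operator, so the discrete operators are
adjoint-consistent and the solution is the least-squares potential of
G. Consequences worth recording: (i) if G is exactly the
central-difference gradient of a surface, that surface is recovered to
machine precision up to an additive constant (asserted at 10⁻⁹); (ii)
for noisy G the residual ‖G − ∇Â‖ can never exceed the perturbation;
(iii) the four modes where the central-difference symbol vanishes (DC
and the pure Nyquist lines) are pinned to zero — central differences
are blind to Nyquist content, which is absent from any surface smooth
on the grid scale. Surfaces are min-zero normalized, and point values
are reported by nearest bin (no interpolation), matching how minima are
quoted on a 2.5° lattice.

**Grid convention.** Bins are 2.5° wide with centers at −180° + j·2.5°,
so reported minima such as (−77.5°, 132.5°) are bin centers; the lower
cell edge is center − 1.25°. Grid files use the Colvars-style
multicolumn text layout (`# 2` header, per-axis
`# lower_edge width nbins periodic` lines, rows of bin centers plus
values) written with 17 significant digits so write→read round trips
are bit-exact.

## Landscape analysis

Minima are bins strictly below all eight periodic neighbors (plateaus
whose entire boundary is higher collapse to their lexicographically
smallest bin); segmentation assigns each bin below the ceiling to a
minimum by steepest descent with deterministic (value, index)
tie-breaks; 8-connectivity with periodic wrap is used throughout. The
default segmentation ceiling of 15 kcal/mol matches the conventional
contour-plot ceiling for these maps, and reported minima default to a
3 kcal/mol ceiling, the threshold used to call a secondary minimum
"low".

Pairwise barrier heights are minimax saddles: the lowest level at which
two minima join in the sublevel-set filtration, computed by a
union-find sweep over bins sorted by free energy (equivalent to the
widest-path/Dijkstra formulation but O(n log n) and exact). Escape
barriers are directional — saddle minus the starting minimum — so the
two directions differ by exactly the minima offset. Basin extents are
the tightest periodic intervals covering a basin's sub-level bins, with
wrap-straddling intervals reported as a single range crossing ±180°.
Replicate convergence is summarized by the RMS deviation over the
region where all surfaces are ≤ 5 kcal/mol and by argmin agreement
(within 15° periodic distance, or falling in one shared basin); both
thresholds are package choices calibrated to the qualitative language
they operationalize, and are exposed as arguments.

## Structures and fixtures

PDB files are parsed via bio3d (multi-model aware) behind a pre-scan
that reports malformed fixed-column records with their line numbers.
Residue rings are located through an atom-name synonym table
(case-insensitive, prime/star variants); linkages are discovered by
covalent-distance search (C–O within 1.85 Å) rather than trusting
residue bookkeeping. Fixture builders construct disaccharides — and an
alternating IdoA2S/GlcNS6S dodecasaccharide — with idealized internal
coordinates (C–C 1.52 Å, C–O 1.43 Å, tetrahedral angles), the iduronate
ring placed by inverse Cremer–Pople at a requested pucker, and the
glycosidic torsions set exactly by natural-extension-reference-frame
placement, so built torsions round-trip through measurement to 10⁻⁶.
The two-model dodecamer is a **synthetic stand-in** assembled at the
published per-model pucker states and consensus torsions of the NMR
heparin dodecamer; it exercises the parse → classify → measure pipeline
end to end but carries no experimental information beyond those
published values. Sulfation codes follow the biologically motivated
four-per-template scheme (heparin/HS n = 1–4 tracking the biosynthetic
order N-S → IdoA-2-O-S → 6-O-S → 3-O-S; dermatan sulfate x = a/b/d/e
for the iA/iB/iD/iE sulfoforms).

Four-atom superposition uses the Kabsch construction via SVD with an
explicit singular-value degeneracy check (near-collinear atom sets are
rejected rather than silently fit); the default alignment atoms are the
reducing-end C1, O1, C2, O5, and the default highlighted bond is the
non-reducing-end C4–O4 (C3–O3 for 1→3 contexts), both configurable.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the problem: periodic
two-basin ΔG(φ, ψ) landscapes with prescribed barriers, harmonically
coupled extended coordinates at 298 K, metastable trapping of unbiased
runs started in a secondary basin, and ring ensembles with thermal
pucker jitter. It does not reproduce solvent, force-field energetics,
inertial dynamics, or the coupling of ring pucker to torsion
preferences — so passing tests certify the estimators and analyses, not
any chemical prediction. MD-derived quantities (absolute ΔG values of
specific sulfoforms, convergence tallies across 64 systems) require
cluster-scale simulation and are outside what this package can check;
they are covered instead by the property-based recovery, barrier and
metastability checks on synthetic ground truth.

## Problem sizes used in the checks

The standard recovery study uses three seeded replicates of 2×10⁶ steps
each on the 144² grid (a few seconds of compute per replicate); the
metastability study uses 4×10⁵-step runs, with the biased runs
accumulating on a 5° (72-bin) grid with N_full = 100 — a coarser bias
grid is the standard way to make a short exploratory run's bias build
quickly, and the analysis itself still runs on the fine grid. Barrier
oracle equivalence is exhaustively checked on random periodic grids up
to 7×7, where enumeration is feasible.

## Known limitations

- The Euler–Maruyama integrator has O(dt) stationary bias; at the
  default step it is below the statistical noise of the standard
  budgets, but very stiff user-supplied wells (κ·depth ≫ 10³) would
  need a smaller dt.
- CZAR needs occupied bins; surfaces far above the sampled region are
  reconstructed only through the neighbor-fill policy and should not be
  interpreted quantitatively.
- The fixture geometry is idealized: suitable for torsion/pucker logic
  and alignment tests, not for energetic or steric analysis.
- `find_glycosidic_linkages` is purely distance-based; exotic covalent
  geometry (bond lengths outside 1.85 Å) or overlapping models in one
  coordinate set will confuse it, and ambiguous bridges are warned
  about and resolved to the nearest candidate.
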