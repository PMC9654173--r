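---
title: "Methods: characterizing polymer-brush surfaces under foulant adsorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing polymer-brush surfaces under foulant adsorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushfoul)
```

## The problem

Zwitterionic polymer brushes — here a sulfobetaine-like chemistry whose
side groups carry a quaternary ammonium cation and a sulfonate anion —
are grafted onto surfaces to resist non-specific protein adsorption
(fouling). Molecular-dynamics studies of such systems ask how grafting
density and the initial orientation of a charged foulant protein decide
between three fates: the foulant **detaches** from the brush, **anchors**
on top of it, or **penetrates** into it. `brushfoul` implements the
trajectory post-processing that answers those questions, together with a
synthetic-trajectory generator that scripts each fate with known ground
truth so every analysis stage can be validated end to end.

## The surface model

A brush surface is a rectangular grafting lattice. Two density regimes
are built in:

* **low density** — chains every 32 Å over a ~100 Å square domain,
  giving a 4 × 4 lattice of 16 chains;
* **high density** — chains every 16 Å, 56 chains. The literature states
  the chain count and spacing but not the lattice shape; we use 7 × 8,
  the only small rectangular factorization of 56 whose footprint
  (96 × 112 Å before periodic closure) stays at the ~100 Å scale.

The periodic box closes the lattice (`box = n · spacing` per axis), so
the surface tiles in x and y; z is aperiodic — solvent above, grafting
plane below. A degenerate case: when the spacing equals the domain side,
the grid is a single chain, because a second lattice point would be the
periodic image of the first.

Each chain has four repeat units, R0 (free end) through R3 (grafted
end), represented coarsely: per unit one backbone carbon (the C_TR or
C_IN marker where the height metrics need one), a carbonyl ester oxygen,
an ammonium nitrogen, and three sulfonate oxygens; plus one buried
methylene carbon fixed at the grafting plane. The analyses consume only
these roles, so finer chemistry would add cost without changing any
output. Syndiotactic alternation of the backbone is recorded as metadata
(and as the sign of a small lateral offset) but has no analytical
consequence. Default marker heights (30, 25, 10 Å for R0/R1/R3) give
every chain a reference brush height of 20 Å.

The foulant is a rigid BSA-like blob: C-alpha atoms on a sphere
(radius 12 Å — a deliberately scaled-down globular protein), charged
surface atoms in the exact positive:negative ratio of the chosen
adsorption orientation (A 1.0:1.6, B 1.0:1.9, C 1.0:2.0; realized as
10:16, 10:19, 10:20 atoms), and polar hydrogens as hydrogen-bond
donors. Orientation presets are fixed rotations (A identity, B 90°
about x, C 90° about y): the source study defines its orientations only
in an appendix unavailable to us, so these are conventions, not
reproductions; all downstream statistics are orientation-generic. The
foulant is centred over the grid and dropped to an `initial_gap` of
2.5 Å above the highest brush atom, mirroring the solvent-clash removal
distance used when solvating such systems.

## The synthetic trajectory generator

`generate_trajectory()` produces frames with the statistical structure
the analyses assume — it is a stand-in for MD, not a simulation:

* **Anchoring contract.** Anchored atoms are bit-identical across
  frames.
* **Chain noise.** `chain_fluctuation_sigma` (default 0.8 Å, a typical
  side-chain RMSF scale) is the *target per-atom RMS displacement*:
  marker atoms get z-only Gaussian noise of that standard deviation (so
  scripted heights stay analytically known), all other non-anchored
  polymer atoms get isotropic noise with per-coordinate standard
  deviation sigma/sqrt(3). Every atom's 3D RMSF therefore equals sigma
  in expectation, which is what makes exact parameter-recovery tests
  possible.
* **Foulant motion.** The rigid foulant is translated vertically by a
  per-frame schedule. Presets: *detach* rises monotonically by 40 Å;
  *anchor* settles exponentially to within 2 Å of its start while an
  ammonium–(negative foulant atom) contact is scheduled; *penetrate*
  descends 25 Å — below the 20 Å mean brush height — with a
  sulfonate–(positive foulant atom) contact. Scheduled contact atoms
  are placed at exactly their scripted separation (default 3.9 Å,
  0.1 Å inside the 4 Å electrostatic cutoff) in their scheduled frames,
  leaving the rigid body for those frames only.
* **Waters.** Three-point waters (fixed O–H 0.9572 Å, H–O–H 104.52°
  geometry) are placed uniformly, rejecting oxygens within 2.5 Å
  (minimum image) of any solute atom, and are *static* across frames:
  hydration ground truth is then exact. The default `water_count = 100`
  is deliberately sparse — enough to exercise the counting machinery,
  far below bulk density; tests that need specific hydration numbers
  script waters into shells explicitly.
* **Frame interval** defaults to 10 ps, the only value under which a
  100 ns analysis window contains exactly 10,000 snapshots.
* **Determinism.** The seed fully determines the trajectory; the
  global RNG state is saved and restored.

What a green test on this generator does **not** establish: physical
realism. There are no forces, no water dynamics, no chain–foulant
coupling; the generator states the world the analyses must recover, and
the tests verify the recovery, not the world.

## The per-chain characterizations

**Height.** Per frame, `h1 = z(C_TR, R0) − z(C_TR, R3)` and
`h2 = z(C_IN, R1) − z(C_TR, R3)`; negative values are clamped to zero
and the larger candidate is the frame height; the chain value is the
window mean. Three window styles are supported (the first *n* converged
frames, the last 100 frames ≈ last 1 ns, and the trailing 100 ns),
because the conventional descriptions of the "first snapshot" window
are ambiguous between one frame and one hundred.

**RMSF.** For each non-anchored side-group atom, the RMS of its 3D
displacement from its own window-mean position, averaged (unweighted)
over the chain's atoms. No superposition is applied: the chains are
grafted, so fluctuations are meaningful in the lab frame. The reduction
to one value per chain is not specified in the source methodology; the
unweighted atom mean is the simplest defensible choice and is what the
sigma-recovery test pins down.

**Hydration.** Water hydrogens within 3 Å (minimum image, inclusive) of
any ester or sulfonate oxygen of the chain, counted per frame and
averaged. A hydrogen near several oxygens of the *same* chain counts
once — the statistic is "hydrogens in the shell", not "pairs" — and the
per-side-group breakdown counts it once per group. Zero waters in the
topology is an error rather than a zero, to guard against silent
misconfiguration.

## Foulant metrics and classification

The detachment height series is `min_CA z(t) − min_CA z(0)`. Component
RMSDs (foulant, polymer, combined) superpose each frame on the
reference with a Kabsch least-squares fit *per component* — whether the
original analyses fit per component or reuse the combined fit is
unstated; per-component fitting is the stricter convergence measure. A
rolling-mean convergence flag (20 ns span, < 5 % change) is
informational only.

Classification thresholds are ours (the source gives qualitative labels
only): terminal mean height over the last 10 % of frames above **+10 Å**
is detached, below **−5 Å** is penetrated, otherwise anchored if any
foulant–polymer contact survives the 5 % occurrence floor, else
detached. The ±(5–10) Å separation is an order of magnitude above brush
fluctuation scales (sigma ≈ 1 Å), which is why recovery is 60/60 across
seeds rather than probabilistic.

## Occurrence statistics

A pair is in contact when its minimum-image distance is ≤ the cutoff —
**inclusive**, since "within a cutoff" is boundary-ambiguous; the
convention is boundary-tested. Cutoffs: 4 Å for oppositely-charged
electrostatic pairs, 2.4 Å for polar-H → carbonyl/sulfonate-oxygen
hydrogen bonds (distance-only; an angle filter exists but defaults off,
matching the distance-only criterion of the CHARMM-style occupancy
analyses this mirrors). Occurrence = 100 × (frames in contact)/(window
frames); rows strictly below 5 % are neglected, rows at exactly 5 %
retained. The source's "divide the total by the number of polymer
chains" normalization cannot be attached unambiguously to per-pair
percentages, so it is emitted as a separate per-surface statistic
(`mean_contacts_per_chain`) alongside the per-pair table — both are
reported, neither is mixed into the other.

## Topography maps

Chain values enter a matrix at their lattice cells; each cavity between
a 2 × 2 chain neighbourhood takes the arithmetic mean of its four
surrounding chains, with **periodic wrap-around** supplying the missing
neighbours at grid edges. Cells between two adjacent chains along one
axis take the mean of those two (the degenerate neighbourhood); this is
also what bilinear interpolation would produce there. "Interpolation
every 5 pixels" is read as 5 pixels per inter-node interval, bilinear;
"smoothed 5 times" as 5 passes of a span-5 moving average along each
axis with symmetrically shrinking edge windows (the default behaviour
of the Matlab `smooth` routine the original workflow names). Both
readings are conventions where the source names routines but not modes;
the invariants that matter — chain cells preserved exactly before
interpolation, constants invariant, extrema never amplified, cyclic
grid permutations commuting with the map — are all tested. Maps are
rendered over the grafting grid only; the expanded foulant-region
footprint of the original figures is not gridded, a deliberate
divergence since its gridding is unspecified.

## Numerical choices and degenerate inputs

* PDB interchange quantizes coordinates to 0.001 Å (fixed `%8.3f`
  columns); round-tripping a written file is byte-identical.
* Anchored atoms are written with occupancy and B-factor 0.00, echoing
  the beta-zero fixing convention; the sidecar file is authoritative
  for roles.
* Kabsch superposition refuses components with fewer than 3
  non-collinear atoms; the reflection case is handled by the
  determinant sign correction.
* Single-frame windows are an error for RMSF (fluctuation undefined),
  not a zero.
* Minimum-image wrapping uses `round(d/L)`, correct for displacements
  of any magnitude, not just within one box length.

## Limitations

* The generator's waters are static and sparse; hydration numbers are
  internally consistent but not comparable to bulk-water simulations.
* The foulant is rigid and featureless apart from role flags; no
  residue-level chemistry, no internal dynamics.
* Orientation presets and classification thresholds are package
  conventions (documented above), not reproductions of the original
  study's unavailable appendix.
* Nothing here validates against real MD output; the package analyses
  any conforming multi-model PDB + annotation pair, but its tests
  establish correctness of the *analyses*, not of any simulation.

## A worked run

```{r example, eval = FALSE}
topo <- place_foulant(instantiate_chains(build_grid(100, 32)),
                      make_foulant("A"))
sim <- generate_trajectory(topo, mechanism_preset("penetrate",
                                                  n_frames = 200,
                                                  seed = 7))
hs <- detachment_height(sim$trajectory, sim$topology)
contacts <- electrostatic_contacts(sim$trajectory, sim$topology)
classify_mechanism(hs, contacts)
prof <- chain_profile(sim$trajectory, sim$topology, "height")
map <- interpolate_and_smooth(build_matrix(prof, topo$grid))
render_map(map, "map_height", metric = "height")
```
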