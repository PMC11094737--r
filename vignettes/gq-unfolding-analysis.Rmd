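---
title: "Quantifying mechanical unfolding of tetrameric parallel G-quadruplexes"
author: "gqmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mechanical unfolding of tetrameric parallel G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqmech)
```

## The system and the problem

A tetramolecular parallel G-quadruplex (GQ) is four separate DNA strands,
all oriented 5'→3' the same way, whose guanines stack into planar
G-quartets around a central channel of K⁺ ions. Each quartet is a cyclic
arrangement in which every guanine donates two hydrogen bonds from its
Watson–Crick edge (N1–H···O6, N2–H···N7) to the Hoogsteen edge of the next
strand's guanine. Constant-velocity pulling experiments and steered
simulations unfold such stems through a reproducible repertoire of
transitions — single-base unzipping, strand slippage (register shift),
opening of one strand–strand interface, full strand detachment, transient
helically wound "spiral" intermediates, and cross-like rotations — and the
forces and geometries along the way carry the mechanical signature of the
stem.

`gqmech` implements the quantitative machinery for analyzing such
trajectories: quartet-plane geometry, reconstruction and decomposition of
the pulling force, force–edge alignment, H-bond-based event classification,
and channel-cation occupancy. Because real pulling trajectories are
expensive and noisy, the package also ships a synthetic-trajectory
generator that produces ideal stems, scheduled elastic deformations,
scripted unfolding pathways and harmonic force traces with complete ground
truth; every analysis stage is validated by round-tripping against that
truth.

## Geometry descriptors

For each frame and quartet, the best-fit plane of the heavy base atoms
(ring atoms plus exocyclic O6 and N2; sugar and phosphate excluded, as they
would corrupt the plane) is computed by singular value decomposition of the
centered coordinates. The descriptors are:

* **Planarity** — the RMSD of the atoms from their best-fit plane, which
  equals σ₃/√N for the third singular value σ₃. A flat quartet scores 0; a
  buckled base raises it.
* **Tilt** — the angle between the normals of adjacent quartet planes,
  after co-orienting all normals along the 5'→3' axis (SVD normals carry an
  arbitrary sign).
* **Rise** — the vertical separation of adjacent quartets: the sum of the
  distances of the two quartet centroids from the quartets' average
  best-fit plane. By default the average plane is the single plane fitted
  to the pooled base atoms of both quartets, which stays well defined when
  the quartets tilt against each other; a bisector-plane alternative
  (`rise(..., method = "bisector")`) averages the two individual normals
  instead. The two readings agree for stacked, nearly parallel quartets;
  the pooled fit is the default because it never needs a convention for
  averaging misaligned normals.
* **Twist** — the signed rotation, about the stem axis, of a per-quartet
  in-plane reference vector (quartet centroid → glycosidic N9 of the same
  strand's guanine) between adjacent quartets. Positive values are
  right-handed advancing 5'→3'; the total twist (sum over steps; the
  rotation of the 3'-quartet relative to the 5'-quartet) gives the
  handedness of the helix by its sign. The reference-atom choice shifts all
  step angles by a common constant only for ideal geometry, so relative
  changes — the quantity of interest during unwinding — are
  convention-free.
* **Stem axis** — the principal direction through the quartet centroids,
  oriented 5'→3'. With two quartets this degenerates, by construction, to
  the normalized centroid difference.

All angles are reported in degrees and distances in Å; arccosine arguments
are clamped to [−1, 1]; fits with fewer than three points or collinear
points raise a degenerate-geometry error naming the offense.

```{r geometry}
stem <- build_ideal_stem(stem_blueprint(n_quartets = 4))
geom <- stem_geometry(stem$traj, stem$topology)
geom
```

## Pulling-force reconstruction and decomposition

The pulling device is a moving harmonic distance restraint between two
anchors — the geometric centers of the C2, C4 and C6 atoms of the terminal
thymines — with force constant k = 180 kJ mol⁻¹ nm⁻² and restraint center
c(t) = d₀ + vt at pull speed v ≈ 5.4 nm/μs. The scalar spring force is
k(c(t) − d) for anchor distance d, converted to piconewton with
1 kJ mol⁻¹ nm⁻¹ = 1.660539 pN (fixed via the Avogadro constant so outputs
are bit-reproducible). The sign convention is positive for extension
(restraint center beyond the anchors); compressive dips are negative and
magnitudes are used in averages.

Relative to the average quartet plane (mean of the co-oriented per-quartet
normals), the force is decomposed through its out-of-plane angle β:
F_horizontal = F cos β, F_vertical = F sin β, and the vertical-to-horizontal
ratio equals tan β, inheriting β's sign (the sign flips when the anchor
geometry puts the 5'/3' anchors "upside down" relative to the reference
plane). A vanishing force leaves β undefined (`NA`), not an error, since
the spring force crosses zero mid-trajectory. β uses the instantaneous
per-frame average plane rather than the starting structure's plane: the
deformed stem, not its history, sets the geometry the force acts against.

The **force–edge overlap** quantifies which H-bond edge of a guanine the
force is aligned with: feo = (|F·u_wc| − |F·u_h|)/|F|, where u_wc and u_h
are unit vectors along the mean donated (Watson–Crick-edge) and accepted
(Hoogsteen-edge) H-bond directions of the designated guanine. It lies in
[−1, 1]; positive means better alignment with the Watson–Crick edge.

```{r forces}
sched <- pulling_schedule(force_constant = 180, pull_speed = 5.4)
spring_force(0, 1, sched, center = 2)$force_pN   # 180 kJ/mol/nm -> pN
decompose_force(300, beta = 35)
force_edge_overlap(c(3, 4, 0), list(u_wc = c(1, 0, 0), u_h = c(0, 1, 0)))
```

**Rupture force** is the maximum running-average force magnitude (2 ns
window) over windows lying entirely before the first H-bond-altering stem
event; terminal-T unstacking does not count as a stem event. The window is
centered by default with a trailing alternative
(`rupture_force(..., align = "trailing")`), since the original averaging
alignment is a convention, not a physical choice. Subsequent
transition-inducing forces are trailing 2 ns averages ending at each event
time, annotated with the number of quartets still intact before the event.

## Event classification

The classifier works from two per-frame layers:

1. **H-bond state** — every Watson–Crick-edge → Hoogsteen-edge bond between
   cyclically adjacent strands, evaluated at *every* level pairing so
   register-shifted states remain visible. A bond is present when the
   donor–acceptor distance is ≤ 3.4 Å (inclusive); with hydrogens present a
   3.5 Å / 135° donor–H–acceptor criterion is available. The distance-only
   default serves hydrogen-free models.
2. **A register-aware level ladder** — each bonded guanine is assigned to
   the physical level where it currently bonds (its partner's native index
   plus the partner strand's register offset, modal over its bonds). Row
   centroids over assigned guanines give the quartet ladder; the stem axis
   is the mean of co-oriented level-plane normals (robust to a missing
   strand, which would drag a centroid-line fit sideways), and the ladder's
   global register is kept continuous across frames so a change of the
   best-bonded reference strand cannot shift every level by one.

Register offsets per strand are modal H-bond level shifts, anchored at the
best-bonded strand and propagated around the strand cycle through the most
strongly bonded interfaces first, so a few incidental contacts of a
displaced strand cannot outvote intact interfaces.

Each transition has an explicit operational rule, and a candidate state
must hold for a persistence window (default 10 frames) before it commits as
an event stamped at its onset frame:

| event | rule |
|---|---|
| unzip | one G holds zero quartet H-bonds while ≥2 bonds among the rest of its quartet persist, its strand is otherwise bonded, and its register keeps it inside the stem |
| strand_slippage | the strand's register offset changes by ±1 with ≥2 bonds re-formed on each interface |
| opening | one strand–strand interface has zero bonds while both of its strands keep their other neighbor |
| detachment | a strand has zero inter-strand H-bonds and no heavy atom within 6 Å of another strand; terminal for that strand |
| spiral_form / resolve | monotone per-residue ladder offsets (≥1 full level) plus cumulative backbone winding beyond 45° per slipped level; the winding sign gives the handedness |
| rotation_crosslike | the strand's 5'→3' end-to-end vector exceeds 120° from the stem axis while inter-strand contacts persist |
| refold | the complete native H-bond set returns after a prior stem event |
| anchorT_unstack | a flanking thymine's base centroid moves beyond 5.5 Å (along the axis) from its terminal quartet level |

At coincident onsets, strand-level events take precedence over per-G
unzips of the same strand; nothing involving a strand is reported after its
detachment; a spiral suppresses unzip/T-unstack reports for the strand it
winds (the wound guanine's broken bonds and the carried T *are* the
spiral); and a spiral resolving back to the native state is not
double-reported as a refold. For the first unzip, the classifier also
reports which edge's bonds broke first (Watson–Crick vs Hoogsteen, from the
pulled-out G's perspective, with a debounced scan so single-frame noise
flicker cannot fake a tie) and joins the contemporaneous feo value.

```{r events}
script <- list(
  list(type = "unzip", frame = 60, strand = 4, level = 4, edge = "wc"),
  list(type = "detachment", frame = 160, strand = 4))
u <- make_unfolding_traj(stem_blueprint(4), script, n_frames = 200,
                         noise_sd = 0.1, seed = 42)
detect_events(u$traj, u$topology)
```

## Channel occupancy

A channel site (between two adjacent quartets) is occupied in a frame when
a K⁺ ion's projection on the stem axis falls strictly between the two
quartet-centroid projections and the ion lies within 2.5 Å of the axis (the
channel-radius scale). Occupancy is reported as the percentage of frames,
per site; the per-frame boolean matrix is returned for exact bookkeeping.

## The synthetic generator: what it emulates and what it does not

`build_ideal_stem()` constructs an idealized parallel all-*anti* stem: four
strands related by 90° rotations, quartet k rotated by k·30° (right-handed)
and raised by k·3.4 Å, flanking anchor thymines, and channel K⁺ midway
between adjacent quartets. Base geometry uses standard planar heavy-atom
templates, and the in-plane quartet placement is solved numerically so the
cyclic H-bond register is exact. Two subtleties are worth knowing:

* With rigid standard bases, requiring both quartet H-bonds to equal
  2.9 Å fixes the quartet geometry up to rotation — the C1′ radius is then
  *derived* (≈8.2 Å), not free. The blueprint therefore defaults to the
  derived radius; requesting an explicit radius keeps the two bond lengths
  equal and lets their common value float, with an error outside a
  physical 2.5–3.35 Å band.
* Backbone is represented minimally (C1′ plus full heavy-atom bases); all
  analyses in the package depend only on base atoms, the glycosidic N9 and
  the anchor-T C2/C4/C6.

`make_deformation_traj()` realizes per-frame twist/rise schedules and base
buckling with seeded Gaussian coordinate noise; `make_unfolding_traj()`
realizes an ordered event script as step transitions at the scripted frames
(an unzip with a declared first-breaking edge is staged: an edge-selective
displacement a few frames ahead, then full ejection at the scripted frame);
`make_force_trace()` writes COLVAR-style sawtooth traces whose bias column
is exactly consistent with the spring reconstruction. Identical inputs and
seed give bit-identical output.

The generator's defaults are the study conditions: 3–5 quartets, +30°/step,
3.4 Å rise, k = 180 kJ mol⁻¹ nm⁻², ≈5.4 nm/μs, 2 ns averaging windows.
Coordinate noise of 0.1–0.2 Å models thermal jitter around a conformer; it
does **not** model correlated solvent fluctuations, partial/fuzzy
intermediates, force-field-specific artifacts, or the microsecond-scale
conformational kinetics of real simulations. Passing the round-trip suite
therefore demonstrates that the estimators and the classifier are correct
and noise-robust for well-separated transitions; it does not certify
classification of marginal, overlapping events in real trajectories, where
the exposed thresholds (distance cutoff, persistence, winding and contact
thresholds) may need tuning.

## Numerical choices and degenerate inputs

* Plane fits require ≥3 non-collinear finite points; σ₂ below 10⁻⁶ of σ₁
  triggers a collinearity error. Twist is undefined when a reference
  vector is (near-)parallel to the axis (projection < 10⁻⁶).
* Running averages require uniform sampling (checked); the rupture window
  must fit inside the pre-event span (error otherwise), and
  transition-force windows truncated at the trajectory start warn.
* Restart-duplicated COLVAR blocks are deduplicated keeping the later
  block; files lacking a bias column are reconstructed from the schedule
  with a warning; missing time/distance columns are fatal.
* Trajectories without time metadata need an explicit `dt` — there is no
  silent default.
* Problem sizes used by the validation suite: 25-frame deformation
  trajectories per grid point, 100 random clouds for the planarity oracle,
  10⁵ random decompositions for the force identities, and four scripted
  pathway families × two noise levels (≈300–340 frames each) for the
  classifier — sizes at which every check is exact or tightly bounded while
  the whole suite runs in about a minute and a half.

## Known limitations

* Single-stem scope: multimeric/interlocked species and cross-stem
  stacking are out of scope, as are duplex-style 6-parameter base-pair step
  analytics, groove geometry and backbone torsions.
* The classifier's transition rules are declared operational
  approximations; taxonomies in the literature are often described
  qualitatively, and borderline intermediates (partial slippage of a single
  guanine, incomplete openings) map onto the nearest rule or none.
* Event choreography in the generator is kinematic interpolation — its
  contract is label fidelity, not physical realism; no free-energy or
  kinetic claims attach to the synthetic pathways.
* Force vectors from scalar COLVAR records are directional only when anchor
  coordinates are available; otherwise analyses that need a 3-vector
  (β, feo) must be driven from trajectory frames.
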