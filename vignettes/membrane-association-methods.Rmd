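---
title: "Quantifying lipid-anchored membrane association in coarse-grained ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid-anchored membrane association in coarse-grained ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membanchor)
```

## The problem

Peripheral membrane proteins that carry an s-palmitoylated cysteine — for
example the ankyrin-repeat membrane-binding stack of ankyrin-G, whose
palmitoylation site sits between the first two repeats — associate with the
bilayer in two regimes: transient, orientationally unspecific surface
contacts, and a stable, effectively irreversible state in which the acyl
chain is buried among the lipids. Ensembles of coarse-grained molecular
dynamics trajectories can sample both regimes, but turning hundreds of
trajectories into defensible statements ("the protein inserted in 72 of 100
runs", "these residues form the interface") requires a small set of
carefully specified statistics. `membanchor` implements those statistics,
their file plumbing, and a synthetic trajectory generator that provides
ground truth to validate every stage.

## The statistics

All distances are minimum-image Euclidean distances in an orthorhombic
periodic box, computed between coarse-grained beads, in nm.

**Contact.** A snapshot is a *contact* when the minimum distance between any
protein bead and any membrane bead is strictly below the contact threshold
`d_c` (default 0.6 nm, i.e. 6 Å). The inequality is strict: a snapshot at
exactly 0.6 nm is not a contact. By default "membrane" means all lipid
beads; a bead-name restriction is available.

**Insertion event.** The anchor residue (the palmitoylated cysteine;
residue 70 in the default numbering) has its own contact mask against the
lipid beads. The insertion event is the first run of at least `L` successive
anchor-contact snapshots (default `L = 3`). Two readings of "the first time
contact was observed in `L` successive snapshots" are possible — the first
or the `L`-th snapshot of the run — so the reported index is configurable
(`insertion_report`), defaulting to the run's first snapshot. A trajectory
with an insertion event is classified *inserted*; otherwise *contact_only*
if it has any contact, else *no_contact*.

Insertion is only meaningful for a protein that carries an insertable
anchor. For unmodified or disulfide-dimerized variants (where the cysteine
is occupied by the cross-link) the analysis disables the insertion
classification (`insertable = FALSE`); otherwise a protein merely resting
its anchor-side surface on the membrane for three snapshots would be
counted as inserted.

**Ensemble curves.** Over an ensemble of records on a common snapshot grid:

* *cumulative contact*: fraction of trajectories with at least one contact
  at or before `t` (monotone non-decreasing);
* *subtotal contact*: fraction with at least one contact in the trailing
  half-open window `(t - W, t]`, default `W = 10` ns — five snapshots at
  the 2 ns analysis interval. The half-open convention makes every snapshot
  contribute to exactly `W / Δt` windows. A window at least as long as the
  trajectory reduces the subtotal to the cumulative curve, which is used as
  a property test;
* *cumulative inserted*: fraction whose insertion event is at or before
  `t`, normalized either over the whole ensemble or over the inserted
  subset (both conventions appear in the literature; a flag selects one).

**Residue contact probability.** For each protein residue, the fraction of
in-window snapshots — pooled over trajectories — in which the residue has at
least one bead within the threshold of a lipid *head-group* bead (Martini
names C1A, C1B, NH3, PO4). The head-group restriction applies only here;
the global contact and insertion definitions use all lipid beads. One
threshold governs both definitions by default since "interaction" is
defined once; `residue_contact_threshold` can decouple them. Three phase
windows are supported per trajectory: after the insertion event
(`insertion_frame..end`, inserted trajectories only), between first contact
and insertion, and after the first contact (any contacting trajectory).
Pooling is snapshot-weighted; trajectory-weighted averaging is available
(`per_trajectory = TRUE`), and the two differ when window lengths vary
strongly. An empty pooled window is an error, never a silent zero profile.

**Snapshot bookkeeping.** Trajectories are analyzed on a fixed interval
(default 2 ns). The subsampling grid starts at `t = interval` and excludes
the initial frame, so a 1 μs trajectory yields exactly 500 analysis
snapshots, not 501. Off-grid frames are matched by nearest time with ties
to the earlier frame, each source frame used at most once; intervals below
the native spacing are refused rather than upsampled.

## The distance kernel

`min_group_distance()` offers two exact kernels: an all-pairs scan and a
cell-list search that bins one bead set on a grid and explores Chebyshev
shells of cells outward, stopping when the best distance found cannot be
beaten by the next shell (shell `s` cannot contain a pair closer than
`(s-1)` times the smallest cell edge). Wrapped duplicate cells are skipped
with a stamp array; every cell is first reached through its canonical
minimum-image offset, for which the bound is valid, so the binned kernel
returns exactly the all-pairs result — an equality the test suite checks on
hundreds of random frames to 1e-9 nm. Grids too coarse for shell
bookkeeping (< 3 cells along an axis) fall back to the scan. Whether input
frames are wrapped or whole-molecule-reconstructed is immaterial: the
minimum image is applied per pair along each axis.

## The synthetic generator

The generator is a phenomenological Brownian-dynamics surrogate, not a
coarse-grained force-field re-implementation: no energetics, thermostat, or
lipid dynamics, only the observable event structure the analysis consumes —
diffusive approach, transient surface contacts, and irreversible anchor
insertion. Its value is ground truth: every trajectory comes with the true
first-contact and insertion snapshots and the per-snapshot anchored state.

* **Membrane**: a static single leaflet of `n_lipids` (default 410) on a
  jittered square lattice; four head beads per lipid within 0.2 nm of the
  surface plane and eight tail beads strictly below. A single leaflet
  suffices because the protein only ever touches one side, and the
  heads-above-tails construction guarantees that the nearest lipid bead
  seen from above is a head bead — which makes head-bead capture and
  all-lipid contact coincide at equal thresholds.
* **Protein**: a rigid bead cloud (backbone random walk plus side-chain
  beads, rescaled to a target radius of gyration, default 1.6 nm for the
  163-residue five-repeat stack at two beads per residue). The anchor
  residue is placed at the most surface-exposed position so insertion is
  geometrically possible. Dimer mode concatenates a 180°-rotated copy with
  the two anchor side chains adjacent, mimicking a disulfide-linked dimer
  (which is therefore non-anchorable).
* **Dynamics**: per snapshot, an isotropic Gaussian center-of-mass step
  (variance `2 D_t Δt` per axis) plus a downhill drift from an exponential
  surface well, and a Gaussian rotation about a random axis (variance
  `2 D_r Δt`); periodic x–y wrap, reflecting walls at the box top and the
  membrane plane. With the well off, the z mean-squared displacement
  follows `2 D_t t`, a closed form the tests verify to 10%.
* **Insertion**: while the anchor is within `anchor_capture_distance` of a
  head bead, insertion fires with probability `anchor_capture_hazard` per
  snapshot; under forced proximity the inserted fraction after `N`
  snapshots follows the geometric law `1 - (1-p)^N`, a second closed-form
  check. Once fired (irreversible mode) the anchor side chain is pinned to
  the head-bead plane — a rigid limit of a harmonic tether, chosen so that
  post-insertion contact is exact rather than approximate, since that is
  the property the analysis needs downstream.

Default parameters were chosen once, as a physically plausible setting
that reproduces the qualitative phenomenology of the reference ensembles
(an approach within the microsecond for nearly all runs, repeated
make-and-lose contact before insertion, a majority of anchored runs
inserting): `D_t = 0.05` nm²/ns and `D_r = 0.02` rad²/ns (a ~19 kDa
protein in a coarse-grained solvent, orientation decorrelating over tens
of ns), well depth 0.05 nm/ns with 1 nm range (binds weakly enough to
allow escape), capture distance 0.6 nm with a capture hazard of 1.
The capture criterion deliberately equals the contact threshold and
capture fires on the first anchor contact: at a 2 ns snapshot interval,
burial of an exposed acyl chain that has reached the head-group layer is
effectively sub-snapshot, and in the reference systems sustained anchor
contact is precisely what defines the insertion event. A sub-unity
hazard (available for stochastic waiting-time studies, and used by the
geometric-law validation) instead generates anchor-contact runs that are
not insertions; that event structure decouples the detected event from
the physical one and is not what those systems show, which is why it is
not the default. Initial orientations are uniform random rotations — the reference
ensembles vary the starting pose but do not state a distribution, so
uniformity is the recorded assumption.

**Ground truth versus detection.** The detector reports the first
≥3-snapshot anchor-contact run; the generator's truth is the capture
snapshot. At the default (deterministic capture at the contact threshold)
the first anchor contact, the capture, and the start of the pinned run
provably coincide, so detection recovers the ground truth exactly — the
exact-recovery validation runs under exactly these conditions. With a
sub-unity hazard the two can disagree legitimately (an anchor-contact run
can precede capture when the hazard draws miss), so under those configs
the detector is validated only for irreversibility — every post-insertion
snapshot remains a contact — and for the waiting-time law, not for exact
frame agreement.

## What the tests do and do not show

Validation problem sizes were chosen to preserve geometry while staying
desk-scale: ensembles of 100 (recovery) and 5 × 24/8 (profiles)
trajectories of 500 snapshots use a 96-lipid patch in a 6 × 6 × 14 nm box —
the same 0.6 nm head-bead lattice spacing as the 410-lipid default, so a
pinned anchor is within the contact threshold of a head bead everywhere on
the surface. Unit tests use a still smaller 36-lipid patch with the same
guarantee.

Passing tests show that the *statistics* are computed correctly on
trajectories whose event structure is known, and that the generator's
event structure behaves as designed (diffusion law, geometric insertion
law, irreversibility, concentration of the after-insertion interface on
the pinned side against diffuse pre-insertion profiles — the generator's
pre-insertion and non-anchored maxima stay well under 0.5 at default
diffusivity). They do not show anything about force-field realism:
real bilayers fluctuate, lipids diffuse and tilt, the protein is flexible,
and insertion kinetics are not a single-hazard process. Conclusions about
a real system require real trajectories; the file readers (multi-model
GRO, a whitespace XYZ dialect) and `assign_groups()` are the intended
entry point for those.

## Degenerate inputs and numerical choices

* Boxes must be orthorhombic; triclinic box lines are rejected, not
  truncated. GRO times (`t=` in ps) are converted to ns on read; frames
  without time tokens get order-based times.
* Empty selections, missing anchor residues, empty lipid groups, and empty
  pooled phase windows raise errors naming the offender.
* Contact comparisons are strict `<`; run detection uses run-length
  encoding and is validated against exhaustive scanning over all 4096
  masks of length 12.
* All randomness is seed-derived; ensembles are reproducible bit-for-bit
  from `(config, base_seed)`, and the pipeline manifest records the seed
  and a config hash.

## Limitations

* The generator's membrane is static and single-leaflet; lipid mixing,
  curvature, and leaflet asymmetry are out of scope.
* Insertion is modeled as pin-to-plane; acyl-chain conformational dynamics
  are not represented.
* The residue-profile cutoff separating "high-contact" interface residues
  has no canonical value and must be chosen per analysis
  (`high_contact_residues()` takes it explicitly).
* Compressed binary trajectory formats (XTC/DCD) are not read; convert to
  multi-model GRO first so the analysis path stays free of binary-format
  dependencies.
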