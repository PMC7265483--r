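---
title: "Burr diagrams and the ancestral reconstruction of antler branching"
author: "antlerphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burr diagrams and the ancestral reconstruction of antler branching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antlerphy)
```

## The problem

Deer antlers are the richest morphological character system in Cervidae,
but their branching structure has resisted use in phylogenetics because
there was no anatomical procedure for deciding which tine of one species
corresponds to which tine of another. `antlerphy` implements such a
procedure: the surface grooves of an antler (growth streaks and parallel
arterial impressions) are treated as a flow field that connects every
point of the antler surface to the burr, the bony ring at the antler
base. Projecting the branching directions of tines and the positions of
forks down this field onto the burr cross-section turns each antler into
a circular *burr diagram* — a rotation-invariant, side-invariant summary
of its entire branching topology and of its orientation on the skull.
Diagrams can then be compared across species to decide homology, homology
gives characters, and characters are optimised on a fixed molecular
phylogeny to reconstruct ancestral antlers.

## Projection geometry

All positions for one antler live on a single burr-aligned coordinate
circle (circumference 360 by default, so positions read as degrees). The
convention is a left antler viewed along the pedicle axis from distal:
0° at the supraorbital ridge on the pedicle (SR), angles increasing
toward the temporal ridge (TR) on the lateral side. Right antlers are
mirrored on input so all diagrams are directly comparable.

Three primitives build the diagram:

* **Branching direction** (`opposite_point`): the direction of a tine is
  the point opposite its fork ridge on the tine's own cross-section,
  `(ridge + C/2) mod C`, drawn down the grooves to the burr.
* **Fork positions** (`project_fork`): each fork reaches the burr twice,
  once traced on each side (the ridge-side and groove-boundary-side
  traces). These marks bound the *zones* — the angular sectors of the
  burr circle whose grooves feed each element. Zones partition the
  circle, and every element's branching direction falls inside its own
  zone; `compute_zones` errors on geometry that violates this.
* **Proration across an overlapping proximal tine**
  (`remap_across_tine`): when a descending point lands on a more
  proximal tine instead of reaching the burr, it is carried across by
  proportional allotment centred on the groove-boundary:
  `x : y = X : Y`, where `x`/`y` are the arcs from the fork ridge to the
  point and from the point to the groove-boundary, and `X`/`Y` the
  corresponding arcs from the ridge's opposite point. The
  groove-boundary is the fixed point of the map, the ridge maps to its
  opposite point, and the map is strictly monotone — so it is a
  continuous bijection from the covered arc onto the uncovered "shadow"
  arc. The degenerate case `x + y = 0` (ridge on the boundary) returns
  the boundary, the continuity limit.

The proration exists so that the projected position of a structure does
not depend on whether a more proximal tine happens to be present. The
package formalises this as a *groove-consistency* model: in an antler
whose proximal tine never grew, the observed coordinates of the distal
structures are exactly the prorated images of their covered positions.
`delete_proximal_tine()` constructs that tine-free antler (splicing out
the fork and baking its proration into the surviving coordinates), and
the test suite verifies over randomised geometries that every projected
burr position is unchanged by the deletion. The invariance is exact when
the deleted fork is the innermost overlap on the descent path, which is
the configuration the construction models; stacked overlaps compose in
descent order.

Cross-sections of different sizes are related by piecewise-linear
arc-length interpolation — the simplest contract that preserves the
proration invariance — so the shared coordinate circle loses no
generality.

## Homology from diagram signatures

Homology is decided on *positional order*, not on measured angles: two
tines are homologous when they occupy the same position on the diagram.
`extract_signature` reduces an element to (i) the cyclic order of its
branching direction among all reference marks (skull indices, other
branching directions, fork traces), with marks closer than a coincidence
tolerance merged into one group; (ii) its branching hierarchy depth
(fork count from the antler base); and (iii) its fork partner.
`match_elements` declares homology when the orders restricted to shared
marks, the depths, and the partner positions all agree, and otherwise
reports the violated order relations. Because only cyclic order enters,
verdicts are invariant under rotation of the whole diagram and under
uniform scaling of the geometry — both verified property-style in the
tests.

The coincidence tolerance defaults to 5°. The source descriptions use
qualitative phrases ("slightly lateral", "at the same position") rather
than a number, so the default is a package decision: wide enough to
absorb specimen noise in the packaged fixtures, narrow enough that
distinct landmarks (which sit tens of degrees apart) never merge. It is
a per-call argument. A species' canonical signature
(`canonical_signature`) is the weighted majority of its specimen
signatures, ties broken toward the largest sample — typical antlers, not
anomalies, carry the comparison. Elements are called "-tine"/"-beam"
when length exceeds twice the basal diameter and "-process" otherwise
(`classify_category`; the boundary is strict).

## Character coding

`species_percentages` converts a specimen matrix (one row per antler;
left and right counted separately; adults only — juvenile and
unknown-age rows are kept for diagram work but never enter coding) into
per-species element percentages. `code_state` maps a percentage to the
three-state scheme: state 2 at 80% or more, state 1 strictly between 0
and 80%, state 0 only at exactly 0. The lower breakpoint is literal: one
observation in any sample size forces state 1, which matters for rare
elements. Percentages are carried at full precision internally.

The packaged frequency registry stores, per species and element, either
a printed percentage or a qualitative token resolved by the fixed table
`all→100, almost_all→95, common→50, rare→10, very_rare→2, absent→0`,
chosen so that coding the resolved values reproduces every explicit
state statement in the source descriptions; unlisted pairs are absent.
The water deer (*Hydropotes inermis*), which grows no antlers, is coded
0 throughout. Elements described as plural sets (pre-cacuminal tines,
frontal-posterior tines, terminal-posterior-anterior tines) are single
characters. The marsh deer (*Blastocerus dichotomus*) is coded
lower-beam-present, following the statement that only its brow tine was
lost and that the lower beam occurs in all species with more than
two-tined antlers; this keeps the structural dependency of the frontal
tine and upper beam on the lower beam satisfiable at the tips.

## Ancestral state reconstruction

Reconstruction is a two-layer hybrid on the fixed rooted topology (no
branch lengths; parsimony only):

1. **Presence (0 vs {1,2}) by Dollo parsimony** (`dollo_presence`): a
   complex homologous tine is gained exactly once and may be lost any
   number of times. The gain goes on the stem edge of the MRCA of all
   present tips (the standard convention that makes "gained at clade X"
   well-defined); inside that clade a node is present iff its subtree
   retains a present tip, and each maximal absent subtree costs one loss
   on its stem. This placement is forced, so the minimal loss set is
   unique — the tests confirm minimality against brute-force enumeration
   of all single-gain histories on every tree shape up to six leaves.

2. **Grade (1 vs 2) by Fitch/ACCTRAN** (`acctran_refine`) on the present
   subtree, state-0 tips pruned first (absent taxa are never graded;
   their stems are losses). The down-pass gives a node its parent's
   grade whenever the Fitch preliminary set allows it, else its forced
   grade, which places changes as close to the root as any
   minimum-change solution permits (verified exhaustively against the
   brute-force minimum and its shallowest change edge). Ambiguity at the
   subtree root resolves to grade 2: a newly gained adaptive tine is
   presumed to sweep through the population immediately after the gain,
   so the 1→2 step is accelerated onto the gain edge. A character seen
   in a single species at state 1 is gained on that terminal edge at
   grade 1 — the scheme's one uncovered corner, decided here as the
   literal reading. When pruning leaves a degree-two node on a
   lineage (its other child lost the element), a grade change on that
   lineage is reported on the uppermost edge of the path, per the
   nearest-root rule.

`assemble_ancestral_antler` turns the per-element node states into an
ancestral antler: an element is drawn at a node when its state exceeds 0
*and* all its structurally required elements are present (a trez tine
cannot attach without a lower beam); violations are diagnostics, never
silently repaired. Both state layers are kept — state 1 elements are
present but flagged as low-frequency. `count_points` counts terminal
tips of tines and beams only; processes add no point, which is what
keeps a brow process from inflating a three-pointed ancestor to four.

## The packaged fixtures and the fixed topology

The registry ships the element catalogue (33 elements with structural
dependencies), the seven skull indices, the species table (25 species in
16 genera with adult antler counts), the curated frequency registry, and
the fixed topology with labelled clades. The topology's named-clade
structure is fixed by the source; within-genus resolutions not decidable
from it (the packaged default resolves Cervini as
(Axis, (Rucervus, (Dama, ((Elaphurus, Panolia), (Rusa, Cervus))))), with
Rusa as (unicolor, (timorensis, marianna)) and Cervus as
(nippon, (elaphus, canadensis))) do not affect the named-clade
reconstructions, and the tree is user-replaceable via Newick as long as
its leaves match the species table.

## Simulators and what the tests show

`simulate_dollo_character` draws histories under exactly the
assumptions the reconstruction makes — single gain, per-edge loss
probability (default 0.1), grade upgrades (default 0.9, acceleration)
and downgrades (default 0.1) where present. `simulate_specimens` is the
coding step's inverse: each antler carries each element independently
with a state-dependent frequency (defaults 2 → 0.95, 1 → 0.3, 0 → 0; a
package choice — within-species frequency given a state is not modelled
in the source — that makes coding recovery well-conditioned at museum
sample sizes). `synthetic_antler` generates geometry by recursive arc
subdivision, so every generated antler satisfies the zone partition by
construction. All randomness flows from one explicit seed; the global
RNG state is saved and restored.

The simulations are structural, not biological: no allometry, no growth,
no measurement error on angles, no within-species correlation between
elements. Passing tests therefore show that the pipeline's inference is
correct *under its own model* — lossless gain edges are recovered
exactly, parsimony loss counts never exceed the true count, coding
recovers generating frequencies within binomial error — not that real
specimen series satisfy the model.

Problem sizes in the test suite are chosen for exactness at desk scale:
parsimony properties are checked on *every* labelled rooted binary
topology up to five leaves and every shape at six (larger trees add no
new local configurations for these algorithms), projection properties on
1,000 random geometries, and recovery on 1,000 seeded replicates over
the packaged 25-species tree.

## Known limitations

* Groove geometry is an input (per-fork ridge and boundary positions);
  the package does not trace grooves from photographs or 3D scans, and
  takes a single groove field as given where arterial impressions run
  oblique to fine streaks.
* The curated frequency registry is an approximation assembled from
  explicit frequency statements; per-species percentages for minor
  elements are not published in the main text, so reconstructions of
  minor elements inherit that coarseness. The headline clades (root,
  Cervini, Capreolinae) depend only on robustly stated frequencies.
* The arterial impression IFST is treated as an optional landmark in
  signatures: it is described as often present on the pedicle yet was
  not observed in the photographed series, so no signature requires it.
* Homology matching assumes both diagrams present the same landmark
  vocabulary; elements with no shared reference marks compare as
  trivially homologous at equal depth, so comparisons should include the
  skull indices.
* No likelihood or Bayesian reconstruction, no DELTRAN, no branch
  lengths: the method is defined as topology-only parsimony.
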