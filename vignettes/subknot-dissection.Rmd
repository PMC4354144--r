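---
title: "Dissecting polygonal knots into subknots: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting polygonal knots into subknots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A closed polygonal curve in space has a well-defined knot type.  Its
subchains — open arcs of consecutive segments — do not, yet both knotted
proteins and circular polymers clearly contain "knotted parts".
`knotdissect` makes that intuition quantitative.  It assigns a knot-type
*spectrum* to every open subchain through a stochastic closure protocol,
summarizes the spectra of all subchains of a circular chain in a polar *disk
matrix* (and of a linear chain in a triangular matrix), and derives from the
matrix the host's *subknots*: the knot types its subchains form.  These are
compared against *predecessor knots*, the types obtained by switching single
crossings in minimal diagrams — a purely diagrammatic notion that turns out
to predict the subknot inventory of geometrically tight configurations
remarkably well.

## The closure protocol

An open chain is closed by attaching two long parallel rays at its endpoints
along a direction $d$ and joining their tips.  If both tips lie beyond every
vertex in direction $d$, the result is isotopic to the closure at infinity
in that direction, so only the direction matters.  We take the ray length to
be the chain's span along $d$ plus three bounding-box diameters times
$(1 + \mathrm{hull\_margin})$; the classified type is independent of the
margin (property-tested), and `hull_margin` defaults to 0.5.

Directions are drawn from a weighted *direction set*:

* `dodecahedron_directions()` — the 20 vertices of a regular dodecahedron,
  each with weight exactly 0.05.  This is the default used throughout the
  test suite: it is perfectly uniform, antipodally closed, and cheap.
* `uniform_directions(n, seed)` — a Fibonacci sphere lattice under a seeded
  random rotation, with each direction weighted by the fractional area of
  its spherical Voronoi cell.  Cell areas are computed exactly (gnomonic
  half-plane clipping, then L'Huilier spherical excess) and validated to
  tile the sphere; for `n = 100` the weight ratio is about 1.12.

The spectrum of a subchain is the weighted distribution of closure types;
its *dominant* type is the heaviest (ties broken by smaller crossing number,
then lexicographically), and a *majority* type is one holding at least half
the weight.  With the tie-break rule an exact 0.5/0.5 split still yields a
single majority type, keeping the majority call single-valued per cell.

## Knot identification

Closed polygons are identified in four stages:

1. **Projection.**  A seeded random view direction (never a coordinate axis:
   regular fixtures are degenerate there) maps the polygon to a signed Gauss
   code.  Genericity is enforced with tolerance $10^{-9}$ after rescaling to
   unit bounding radius; non-generic views (grazed vertices, tangencies,
   coincident passages, collinear overlaps) are retried along directions
   perturbed toward seeded random axes with angles growing from $10^{-6}$
   radians.
2. **Simplification.**  Reidemeister I/II reduction to a fixed point,
   interleaved with a breadth-first Reidemeister III search (budgeted, by
   default 1000 visited diagrams at the API surface and 200 inside matrix
   loops, stopping early once the diagram is small) that restarts whenever a
   III move unlocks further reduction.  The result is an upper bound on the
   crossing number, never a minimality certificate.
3. **HOMFLYPT.**  Skein recursion in the $(l, m)$ convention
   $l\,P(L_+) + l^{-1}P(L_-) + m\,P(L_0) = 0$ with unknot $= 1$; the first
   crossing met as an underpass is switched and smoothed, descending
   diagrams are unlinks with $P = (-(l + l^{-1})/m)^{k-1}$.  Subdiagrams are
   R1/R2-reduced and memoized on canonical Gauss codes; small subdiagrams
   (at most 12 crossings) share a persistent memo across calls, which is
   what makes disk matrices with hundreds of thousands of closures
   tractable.  Mirrors correspond to $l \mapsto l^{-1}$; connected sums
   multiply.
4. **Table lookup.**  The polynomial is looked up in a table generated from
   the embedded DT codes of all prime knots through 10 crossings, with both
   chiralities and all composites of total crossing number at most 10.
   Candidates with minimal crossing number above the simplified diagram's
   crossing count are discarded; remaining ambiguity returns the
   lowest-crossing candidate flagged `ambiguous`.  Polynomials outside the
   table become `unknown:<hash>` — a stable fingerprint label, treated as a
   distinct type in set comparisons.

Chirality names are an internal convention: each DT code is realized by the
planar embedding (rotation-system search over transversal crossings,
planarity by Euler's formula) with maximal writhe, and that realization
carries the plain name; its mirror gets the `-` prefix.  The convention is
globally consistent, but whether our `9_19` is the paper-figure's positive
or negative representative is not determined — mirror-paired statements are
the convention-free content, and the tests compare up to an overall mirror
where that matters.

## Disk matrices, cores, trimming, generations

The disk matrix evaluates the dominant type and frequency of every proper
subchain `(start, nseg)`; latitude is the length, longitude the midpoint
`(start + nseg/2) mod n`, whose half-integer grid gives the brick-wall
pattern.  An `n`-segment host has exactly `n(n-1)` cells; cells with at most
4 segments are always unknots (their closures have at most 7 edges).  The
*knot core* is the set of minimal-latitude cells carrying the global type.
*Trimming paths* from a scission report the dominant types as the opened
chain is shortened segment by segment from either end; classifying each
scission by the first non-global type on its two paths (`both_via_K`,
`both_direct`, `mixed`) partitions the scissions into circular arcs.

Subknot *generations* come from the region graph: maximal connected
same-type cell regions (adjacency along latitudes plus the trimming steps
`(s,k) -> (s,k-1), (s+1,k-1)`), with directed edges along trimming steps.
The generation of a type is its hop distance from the global-type rim
region.  Cells touching only diagonally (brick corners) are not adjacent;
this matches the trimming relation that defines the spiral paths.

`extract_subknot()` realizes a cell's nontrivial type as a standalone closed
polygon — rays cut just outside the subchain's hull, then joined — enabling
the *distributive* search: dissecting the extracted subknot reveals its own
subknots, which processive trimming of the host alone can miss.

## Predecessors and the census

`first_generation()` switches each crossing of a minimal diagram in turn and
classifies the results; the diagram comes from the embedded DT table
(mirrored for `-` names; plumbed connected sums for composites).  The
restriction to alternating knots is essential: their minimal diagrams are
unique up to flypes, making the outcome set diagram-independent.
`generational_closure()` iterates breadth-first, labelling each type with
its first generation; the closure is *defined* only while every reached
type is alternating (or unknot, or a composite of alternating primes) —
reaching a non-alternating type makes further predecessors
diagram-dependent, so such types are recorded and not expanded.  The census
over alternating primes (`defined_census()`) counts the types whose whole
closure stays defined; at 9 crossings the six failures all occur by
reaching one of the non-alternating 8-crossing knots.  This
whole-closure interpretation of "defined" (rather than gating only on the
first generation) is what `scripts/acceptance.R` recomputes.

## The embedded knot table

No machine-readable knot census was available to this project, so the
DT-code table shipped in `inst/extdata/dt_codes.tsv` was generated by the
package's own machinery and frozen: all-positive DT codes enumerated per
crossing number, filtered to reduced (every chord interleaved), prime (no
proper interval closed under the pairing), planar-realizable codes,
canonicalized under dihedral relabelling, and deduplicated at knot level by
HOMFLYPT (mirror-invariant key).  By Tait's theorem these are exactly the
alternating knots of each crossing number, and the stratum sizes reproduce
the census (1, 1, 2, 3, 7, 18, 41 for 3-9 crossings; determinant sequences
and amphichirality patterns match the classical tables).  Non-alternating
knots were obtained by sweeping all crossing switchings of the alternating
shadows and keeping polynomials new to the lower strata (3, 8 at 8 and 9
crossings).  Names follow Rolfsen numbering where an invariant fingerprint
pins them (torus and twist knots, determinants, amphichirality, Alexander
degree); remaining 9- and 10-crossing names are provisional det-ordered
assignments — nothing downstream depends on them.

Known identification limits, inherited from HOMFLYPT itself: at 10
crossings two alternating and three non-alternating mutant pairs share
polynomials and are merged into single entries (so the 10-crossing strata
hold 121 + 39 entries rather than 123 + 42); the chirality of `9_42` is
invisible to the polynomial and it is stored as a single entry; and one
prime/composite coincidence (`9_12` with `4_1#5_2`, both alternating) is
resolved by the crossing-bound rule and flagged ambiguous when it cannot
be.

## The random-polygon generator

`random_equilateral_polygon(n, seed)` emulates closed equilateral chains —
idealized ring polymers: `n/2` directions drawn uniformly on the sphere and
emitted with their antipodes (closure is then exact by construction), the
`2(n/2)` edge vectors randomly permuted, and `10n` random crankshaft
rotations applied.  Crankshaft moves preserve edge lengths and closure
exactly, preserve the uniform measure on equilateral polygon space, and are
ergodic on it, so the sampler approximates the uniform equilateral ensemble;
runs with 10- and 200-fold more moves give statistically identical knot
spectra, indicating convergence at the default.

What this generator does *not* emulate: excluded volume, bending stiffness,
or any protein-like geometry — and, notably, the ensemble behind the
published absolute counts of complex knots in 100-edge polygons.  Under the
uniform measure the knot spectrum decays with crossing number (we observe
roughly 71% unknots, 17% trefoils, and 0.6-0.7% eight-crossing primes at
`n = 100`, in line with published equilateral-polygon statistics), whereas
the reported count of eight-crossing configurations corresponds to about
3.3% — more than the seven-crossing fraction, which no decaying spectrum can
produce.  The unmixed antipodal-pair construction itself is geometrically
degenerate (adjacent antipodal edges create coincident vertices), so any
usable variant perturbs the ensemble; the one used for the published counts
is not specified and evidently differs from the uniform measure.  The
desk-scale binomial gate against those absolute rates therefore fails under
this generator, and we report that disagreement rather than tune the
sampler toward the published numbers; the structural results (which types
appear as subknots, containment of predecessor types in random hosts) are
insensitive to this normalization and do reproduce.

## Numerical choices

* Tolerances: all genericity tests at $10^{-9}$ after rescaling to unit
  bounding radius; Voronoi areas validated to $4\pi$ within $10^{-6}$
  relative; spectrum weights sum to 1 within $10^{-9}$.
* Degenerate closures: a closure whose rays or tip-joining segment pass
  within tolerance of the chain (grazed vertices, or a genuine ray-edge
  intersection, which no projection can make generic) triggers
  deterministic perturbation of the closure direction (angles growing from
  $10^{-6}$ radians about a fixed axis), recorded per direction.  Symmetric
  hosts do hit these coincidences: several dodecahedral directions of a
  12-segment torus polygon send a closure ray exactly through a chain edge.
* Skein budget: recursion aborts past a node cap (default $2\times 10^5$
  inside matrix loops, $2\times 10^6$ for whole-polygon classification);
  a capped run escalates — deeper III-move simplification, then one more
  projection — before the closure is declared unclassifiable.  In the
  matrix protocol such failures redistribute that direction's weight
  proportionally and increment a failure counter; fixture suites require
  the counter to be zero.
* Ties: dominance breaks ties by crossing number then name; unknown types
  sort last.
* Degenerate inputs: coincident consecutive vertices, non-even random
  polygon sizes, non-coprime torus parameters, non-realizable DT codes, and
  non-alternating predecessor requests all raise errors rather than
  guessing.

## Problem sizes in the shipped tests

The suites run at desk scale by design: torus fixtures with 18-47 segments
(disk matrices of up to 2,162 cells at 20 closure directions), a
100-segment host for the grid-structure checks, 5,000 random 100-edge
polygons for the spectrum study, and predecessor containment on 20 random
eight-crossing hosts with an early-exit containment scan.  The full-scale
published study (100,000 polygons, 100-direction closures) is reproducible
with the same functions by raising these numbers.

## Worked example

```{r}
library(knotdissect)

p <- torus_knot_polygon(2, 5, 40)
as.character(classify(p))         # "-5_1" (internal chirality convention)

dm <- disk_matrix(p)              # 40 * 39 cells, 20 closures each
subknot_report(dm)                # subknots: 0_1, -3_1, -5_1
region_graph(dm)$generations      # -5_1: 0, -3_1: 1, 0_1: 2
knot_core(dm)

generational_closure("7_5")       # gen 1: 3_1, 5_1, 5_2; gen 2: 0_1
defined_census(8)                 # all 18 defined
```
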