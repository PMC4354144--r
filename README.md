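# knotdissect

Dissecting closed polygonal knots into their subknots.

A closed polygonal chain — a circular polymer model, the closure of a
protein backbone, a random equilateral polygon — has a single global knot
type, but its *subchains* carry a rich inner structure: shortened pieces of
a 7_5 knot form 5_2, 5_1 and 3_1 knots before they untie completely.
`knotdissect` quantifies that structure for people who study knotted
biopolymers and random knots:

* **Uniform closure protocol.** An open subchain is closed by two parallel
  rays joined outside its convex hull, once per direction of a weighted
  direction set (the 20 dodecahedron vertices, or *n* spherical-Voronoi
  weighted directions).  The resulting distribution over knot types is the
  subchain's spectrum; its heaviest type is the *dominant* type, a type with
  at least half the weight a *majority* type.
* **Knot identification.** Each closure is projected to a signed crossing
  code, simplified by Reidemeister moves, and identified through its
  HOMFLYPT polynomial, computed by the skein recursion
  `l P(L+) + l⁻¹ P(L−) + m P(L0) = 0` (unknot = 1, mirror image = `l ↔ l⁻¹`)
  against a table generated from embedded DT codes of all prime knots
  through 10 crossings, both chiralities, plus composites.
* **Disk and triangular matrices.** The dominant type of every subchain
  `(start, nseg)` of a circular chain, arranged by subchain length
  (latitude) and midpoint (longitude) in a brick-wall polar grid; the
  triangular analogue serves open, protein-like chains.  Derived analyses:
  knot cores, trimming paths from a scission, scission classification,
  subknot reports, region-graph generations, and distributive subknot
  extraction.
* **Predecessor knots.** The types obtained by switching one crossing in a
  minimal diagram, iterated into generations; censuses of the alternating
  knots whose predecessor closure stays within the alternating world.
* **Random equilateral polygons.** A seeded antipodal-pair sampler with
  crankshaft decorrelation, for studying subknots of random hosts.

## Worked example

```r
library(knotdissect)

p <- torus_knot_polygon(2, 5, 40)   # 40-segment (2,5) torus polygon
as.character(classify(p))
#> [1] "-5_1"

dm <- disk_matrix(p)                # 40 x 39 = 1560 cells, 20 closures each
subknot_report(dm)
#> <subknot_report> global -5_1
#>   all:      -3_1, -5_1, 0_1
#>   majority: -3_1, -5_1, 0_1

region_graph(dm)$generations
#> # A tibble: 3 x 2
#>   type  generation
#>   <chr>      <int>
#> 1 -3_1           1
#> 2 -5_1           0
#> 3 0_1            2

generational_closure("7_5")
#> <predecessor_set> 7_5 (defined)
#>   gen 1 : 3_1, 5_1, 5_2
#>   gen 2 : 0_1
```

Reading: the torus polygon is a (left-handed, in the package's internal
chirality convention) 5_1 knot; every one of its 1,560 subchains closes to
the unknot, the trefoil, or the global 5_1; and the trefoil territory
separates the 5_1 territory from the unknot territory (generations 0 → 1 →
2), mirroring the fact that the 5_1 has unknotting number two.  The 7_5
predecessor closure lists exactly the types seen as subknots of regular 7_5
configurations: 3_1, 5_1, 5_2, then the unknot.

A thin command-line front end over the same functions is installed with the
package (`system.file("cli", "knotdissect", package = "knotdissect")`) with
subcommands `classify`, `spectrum`, `diskmatrix`, `trimatrix`, `subknots`,
`predecessors`, `census`, `randomgen`, `fixtures`, reading xyz / Geomview
VECT / PDB (C-alpha) chains.

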