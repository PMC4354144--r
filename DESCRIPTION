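Package: knotdissect
Title: Dissecting Polygonal Knots into Subknots with Disk Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting closed polygonal knots into their subknots.
    Implements the stochastic uniform closure protocol for assigning knot types
    to open polygonal chains (dodecahedral and Voronoi-weighted direction sets,
    ray closure outside the convex hull), knot identification through projection
    to a signed crossing code, Reidemeister simplification and the HOMFLYPT
    polynomial computed by skein recursion against a generated table of prime
    and composite knots through 10 crossings, disk matrices reporting the
    dominant knot type of every subchain of a circular chain (and triangular
    matrices for open, protein-like chains), knot cores, trimming paths and
    scission classification, subknot reports with region-graph generations,
    predecessor knots obtained by single crossing changes in minimal diagrams,
    and random equilateral polygon sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
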