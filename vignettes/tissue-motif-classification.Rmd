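---
title: "Classifying tissues by primary tissue motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tissues by primary tissue motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftumotifs)
```

## The model

Solid tissue is organised around its blood supply: diffusion is only an
effective transport mechanism over roughly 100 micrometres, so every viable
cell sits within about 50 um of a capillary, and any paracrine exchange
between two cells is bounded by the same ~100-um span. A **functional
tissue unit (FTU)** is the natural unit this constraint carves out: a
cylindrical block of cells whose long axis is the feeding capillary, small
enough that every cell can exchange metabolites and signals with every
other.

The **primary tissue motif (PTM)** of an FTU is a deliberately minimal
knowledge representation of it: the non-redundant *set* of cell-type
ontology terms the unit contains, plus the anatomical region it came from.
Two FTUs can then be compared through their motifs in direct analogy to
primary protein sequence comparison, with a cell-type term-similarity
matrix `c()` playing the role of the amino-acid substitution matrix:

1. compute pairwise semantic similarity `c()` between cell-type terms over
   the ontology graph;
2. align two motifs by an *exclusive best-match* pairing `p{}`: repeatedly
   pair the most similar unused terms, one from each motif, until the
   smaller motif is exhausted;
3. score the comparison, `s = sum of pair scores / normaliser`;
4. cluster the motif collection on the distance `1 - s` into a binary
   tree.

Because motifs are sets (not sequences), the "alignment" is a one-to-one
matching with no order or gap structure, and the package also provides the
plain set algebra of motifs: equivalence, subsumption, overlap,
disjointness, and unions (the motif of a compound tissue region).

## Term similarity

`term_similarity()` offers three measures, all in [0, 1]:

* **simUI** (default): the Jaccard index of the two terms' reflexive
  ancestor sets. It needs nothing but the graph topology, which is why it
  is the default: no annotation corpus is attached to a bare cell-type
  ontology.
* **resnik_norm**: information content (IC) of the most informative common
  ancestor, scaled by the graph's maximum IC.
* **lin**: `2 IC(MICA) / (IC(a) + IC(b))`.

IC is topology-based with +1 smoothing, `-log((descendants(t) + 1) /
(N + 1))`. Two deliberate conventions:

* *Identity is exact match.* All three measures return exactly 1 for
  `a == b`. Raw normalised Resnik would give `IC(t)/IC_max < 1` for
  internal terms, which would break the unit diagonal of the similarity
  matrix and the self-score `s(x, x) = 1`; the identity case is therefore
  defined, not computed.
* *Relations traversed* default to `is_a` only, because cell-type
  subsumption is `is_a`-dominated; `part_of` (or any other label) can be
  added via the `relations` argument of `load_obo()`.

The five-tissue worked example (`table1_fixture()`) does **not** recompute
its `c()` values: the published numbers came from an external calculation
over a specific 2013 ontology release and only the best-pair entries were
ever printed. The fixture matrix therefore holds every published pair
value, a unit diagonal, and a filler of 0.05 for all unprinted cross
pairs. The filler sits strictly below the smallest published pair score
(0.17), so it cannot displace any published pair during matching; it is a
documented reconstruction, not data. Correctness of the similarity
measures themselves is established by oracle properties (brute-force
ancestor-set Jaccard on random DAGs), not by reproducing those historical
values.

## Alignment and scoring

`align_motifs()` implements two strategies. The default, `greedy`,
repeatedly takes the highest-scoring unused cross pair -- the direct
reading of "highest possible score" -- with ties broken lexicographically
on `(term_x, term_y)` so every run and every input ordering gives the same
pairing. `optimal` computes a maximum-weight bipartite matching of the
same size (weights shifted by a constant so maximum weight implies maximum
cardinality). On realistic similarity matrices the two rarely differ --
they agree on all ten comparisons of the worked example -- but on
adversarial weight patterns greedy can be blocked into a lower total, so
the guarded variant is kept available; the test suite verifies `optimal`
against exhaustive enumeration on small instances and logs the observed
greedy/optimal agreement rate on random matrices rather than asserting
one.

`score_motifs()` normalises the summed pair scores. The prose definition
of the published method divides by the *average* motif size, but the
published score column is arithmetically consistent only with dividing by
the *number of pairs* (`min(|X|, |Y|)`): for the hepatic-cardiac
comparison the pair scores sum to 2.54, and 2.54/4 = 0.635 -> 0.64 as
printed, whereas 2.54/4.5 = 0.56. The package default is therefore
`divisor_mode = "pair_count"`, which reproduces the published scores and
keeps `s` in [0, 1] with `s(x, x) = 1`; `"average_size"` is retained
behind a flag for the literal prose definition (it penalises size
mismatch: an identical pair of motifs still scores 1, but a subsumed motif
scores below 1).

Scores are kept at full precision internally; `round_half_up()` (round
half away from zero) is applied only at presentation, because the
published two-decimal values follow that convention (0.635 prints as
0.64). Three of the ten published scores differ from recomputation by
0.006-0.008 (hepatic-gastric, cardiac-gastric, pulmonary-colonic); the
published `c()` inputs are themselves rounded to two decimals, so this is
irreducible input-rounding noise and the tests assert those three at
+/-0.01 and the other seven exactly.

## Classification

`cluster_motifs()` runs agglomerative clustering on `d = 1 - s` with
UPGMA (average linkage) by default; single and complete linkage are flags.
The similarity-to-distance transform is fixed at `1 - s` because scores
are bounded by 1. Labels are sorted lexicographically before clustering,
making the topology invariant under input permutation and tie-breaks
deterministic.

On the worked example every linkage first merges the cardiac-pulmonary
pair (d = 0.2775, driven by the 0.64 smooth/cardiac muscle cell match) and
then the colonic-gastric pair (d = 0.2875, driven by the 0.52 goblet-cell
match), leaving the hepatic motif as the only leaf in neither pair -- the
published "two tissue pairs and a hepatic out-group". One subtlety the
linkage choice does affect: under average linkage the hepatic leaf
attaches to the cardiac-pulmonary cluster (mean distance 0.3835) before
the final merge of the two clusters (0.3934), whereas under single linkage
the two pairs merge first and the hepatic motif joins last. The published
description constrains only the pairs-plus-out-group structure, which
holds either way; the package keeps the conventional UPGMA default and
tests exactly that structure.

`to_newick()` writes branch lengths as height differences (a cherry merged
at height 0.3 is `(A:0.3,B:0.3);`), quoting labels that contain
Newick-special characters; round-trip fidelity is checked in the tests
against the independent parser in `ape`.

## Geometry

`optimal_cylinder(d_max)` solves the FTU sizing problem: maximise
`pi (d/2)^2 L` subject to `sqrt(d^2 + L^2) <= d_max`, the constraint that
the two farthest points of the cylinder (diametrically opposite rim
corners) stay within diffusion distance. The optimum lies on the
constraint boundary at `d = d_max sqrt(2/3)`, `L = d_max / sqrt(3)`; for
`d_max = 100` um this is 81.65 um by 57.74 um, the canonical "about 80 by
60 um" block. Tests confirm global optimality against a 200 x 200 grid
search and first-order optimality under +/-1% perturbation along the
constraint.

Spatial extraction (`cells_in_ftu()`) models the capillary axis as a 3D
polyline (straight vessels being the 2-point case), computes each cell's
distance to the axis and arc-length projection, and keeps cells with
radial distance at most `d/2` inside the axial window. Conventions, chosen
once:

* all distance thresholds are **closed** (a cell exactly on the wall is a
  member) -- the boundary convention is not dictated by the biology and a
  closed rule is the one that makes the generator/extractor round trip
  exact;
* a cell is a point (its nucleus centroid); no cell volumes;
* coordinates are continuous micrometres -- no voxel grid;
* a cell may belong to several overlapping FTUs; no exclusivity is
  enforced, since capillary fields genuinely overlap;
* connectivity of the selected block is implied by the cylinder predicate
  rather than checked as a separate graph condition.

`validate_diffusion()` reports (never silently fixes) all cell pairs
beyond `d_max`; for cells selected by the optimal cylinder the report is
empty by construction. `diffusive_field()` reproduces the image-annotation
dilation: membership within a fixed radius (40 um in the colon
demonstration, 50 um as the canonical capillary proximity) of the vessel
axis.

Default parameters, all in micrometres: `d_max = 100` (diffusion span),
`capillary_proximity = 50` (= `d_max/2`, the distance within which most
cells sit of a capillary), `dilation_radius = 40` (the demonstration's
annotation radius, deliberately inside the 50-um bound).

## Synthetic data

Two seeded generators make every component testable offline; seeds are
explicit arguments and never global state.

* `gen_dag_ontology(n, max_parents, seed)` grows a rooted random DAG by
  letting each new term draw parents among earlier terms -- acyclic by
  construction. It emulates the *shape* of a cell-type ontology
  (single-rooted, sparse, shallow), not its content: term labels,
  realistic branching statistics and multiple relation types are not
  modelled, so passing tests show algorithmic correctness on DAGs, not
  fidelity to any real ontology release.
* `gen_ftu_pointcloud(motif, n_cells, cylinder, noise_frac, seed)` places
  member cells uniformly in the cylinder around a straight capillary
  (every motif type at least once, a 0.01-um wall inset so coordinate
  rounding cannot flip membership) and `noise_frac` of cells radially
  outside the wall within the same axial window. It emulates an annotated
  capillary neighbourhood with known ground truth; it does **not** emulate
  curved vessels, anisotropic cell packing, motif composition drift along
  the arteriolar-venular axis, or segmentation error, so recovery tests
  demonstrate the selection geometry, not robustness to imaging noise.

Test problem sizes were chosen as the smallest that exercise each
property meaningfully: 25-50-term DAGs for similarity oracles, 3 x 4 to
5 x 5 matrices for exhaustive matching enumeration (brute force grows
factorially), 35-150-cell point clouds for geometry oracles, and 10 cells
per motif type for "high-density" recovery (at that density the chance of
a motif type going unsampled is negligible, and the round trip is exact
for the shipped seeds).

## Known limitations

* The five-tissue similarity matrix is a reconstruction (see above);
  analyses needing true `c()` values for other term sets should compute
  them from a current ontology with `build_matrix()`.
* `s()` comes with no significance model; the package deliberately does
  not attach p-values to scores or bootstrap support to trees.
* Motifs ignore cell multiplicity, spatial arrangement and extracellular
  matrix by design -- they are the *primary* level of a motif hierarchy;
  contact-level (secondary) and advection-level (tertiary) enrichments are
  out of scope.
* Ontology IC is topology-based; with an annotation corpus the
  Resnik/Lin variants would be better calibrated.
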