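---
title: "Inferring the nitrogenase active-site metal cofactor: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the nitrogenase active-site metal cofactor: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcof)
```

# The scientific problem

Nitrogenase reduces N~2~ to ammonia at an iron–sulfur cluster whose variable
heterometal defines three enzyme families: molybdenum-dependent (NifD,
FeMo-co), vanadium-dependent (VnfD, FeV-co) and iron-only (AnfD, FeFe-co).
Several anaerobic methanogens, archaeal methanotrophs and firmicutes encode
catalytic D-subunit homologs that have never been biochemically
characterized, and their metal dependence cannot be read directly from a
genome. `metcof` infers the likely cofactor of such a homolog from three
independent lines of evidence:

1. **Global structure similarity** — contact-set similarity between the
   query and reference D-subunit structures, clustered with the
   complete-link (furthest neighbor) method;
2. **Active-site pocket volume** — grid volumetrics of the cofactor-binding
   cavity after removing the cluster in silico, with a 1.4 Å water probe
   (Mo-type cavities run roughly twice the volume of V/Fe-type ones);
3. **Active-site sequence fingerprint** — position-specific scoring of the
   nine conserved sequence areas that surround the cofactor, plus a small
   set of diagnostic residues.

The pipeline combines whatever lines are available by majority vote and
reports ties as `"ambiguous"` rather than resolving them silently.

# The residue shell and its motif regions

The active-site environment is defined geometrically: every residue with at
least one atom within 5 Å (atom center to atom center) of any cofactor atom
— the cluster plus its homocitrate ligand — belongs to the shell. We use
center-to-center distance rather than van der Waals surface distance
because it is the simplest reproducible reading and needs no radii
assumptions; the cutoff is a parameter (`cutoff`, Å, default 5). Waters are
excluded by default. Neighbor search runs on a cell list whose results are
tested to be identical to brute force.

Shell residues are grouped into contiguous sequence regions with a **gap
rule**: two shell residues join one region when their author-numbering
separation is at most `gap` (default 3). The rule itself is our
operationalization — no published delimitation rule exists for these
"sequence areas" — and the default was chosen because the anchors of the
known motif regions sit ≥ 20 positions apart while each region spans about
7–13 contiguous positions, so any gap in 2–10 yields the same partition; 3
is the most conservative value in that plateau. On a D-subunit active site
this produces nine regions, two of which contain the cluster-coordinating
residues Cys275 and His442 (A. vinelandii NifD numbering).

Coordination ligands are detected chemically: a residue counts when a
*side-chain* S or N atom lies within `bond_cutoff` (default 2.6 Å, spanning
Fe–S and Fe–N bond lengths) of a cluster metal (Fe, Mo or V). Backbone
amide nitrogens never qualify.

# Pocket volumetrics

The cavity method is a grid re-implementation of the *intent* of
alpha-shape pocket servers: "pocket volume at a 1.4 Å probe", not
bit-compatibility with any server. Space is discretized at `spacing`
(default 0.5 Å; 0.1 < spacing ≤ 1):

* a voxel is **occupied** when its center lies within the van der Waals
  radius of a retained heavy atom (hydrogens are excluded; radii come from
  a bundled Bondi-style table with common metals added, user-overridable);
* a voxel is **blocked** when within vdW + probe — probe centers cannot
  enter it;
* the **exterior** is the flood fill (6-connected, conservative against
  diagonal leaks) of unblocked space from the grid boundary, computed after
  morphological closing of the blocked mask with a `closure_probe` ball
  (default 4 Å) that seals pocket mouths;
* the **pocket** is the unblocked connected component containing the seed
  (by default the centroid of the removed cofactor), minus the exterior;
* the reported **re-entrant volume** is that component dilated by the probe
  and intersected with unoccupied voxels.

One numerical subtlety: dilation is computed from surface-voxel centers,
which sit up to one voxel inside the continuous region boundary, so raw
volumes converge from below with a half-voxel "skin" missing. The dilation
radius therefore carries a midpoint compensation of +0.5 voxel. With it, a
synthetic enclosed sphere of radius 4 Å (analytic volume 268.1 ų)
measures with 10.0 / 7.2 / 4.6 / 0.6 % error at spacings of
0.8 / 0.5 / 0.4 / 0.25 Å — monotone convergence, within 10 % at 0.4 Å, and
invariant within 5 % under rigid-body transforms.

When the seed's component never reaches the grid boundary the pocket is
fully enclosed and mouth closing is skipped (it cannot change the answer).
If the component still merges with the exterior after closing, the result
is flagged `open_to_solvent` and the volume of the capped region is
reported. A seed falling in blocked space snaps to the nearest accessible
voxel within 3 Å, else errors.

Per-class summaries report the mean and the **mean absolute deviation**
from the mean ("average deviation"); the published per-lineage tables do
not state which dispersion measure they use, and MAD is the most common
reading of "average deviation".

# Superposition

Structure pairs are superposed on CA atoms through the Kabsch algorithm
(SVD of the covariance of centered paired coordinates, determinant
correction to enforce a proper rotation). Pairing comes from a sequence
alignment (aligned non-gap columns whose residues both carry a CA) or from
identical author numbering. CA-only superposition is deliberate: homology
models carry unreliable side chains. Distance-matrix structure alignment
(DALI-style) is out of scope, so RMSDs against references are indicative,
not reproductions of published elastic-alignment values. With ≥ 3
non-collinear pairs the fit is exact for rigid copies (RMSD ≤ 1e-6 Å) and
matches the √3·σ expectation for isotropic Gaussian coordinate noise.

# Contact-set similarity and clustering

True Voronoi tessellation contacts are replaced by a standard, testable
surrogate: residues are in contact when their CB atoms (CA for glycine)
lie within 8 Å and their sequence separation exceeds 2. The similarity of
two aligned structures is the sum over aligned residue pairs of the
Jaccard index between the first residue's contact set (mapped through the
alignment) and the second's; a structure against itself scores the number
of residues with at least one contact. The similarity is standardized by
the geometric mean of the self-scores,

$$D(a,b) = 1 - \frac{S(a,b)}{\sqrt{S(a,a)\,S(b,b)}},$$

giving a distance in [0, 1] with zero diagonal. The exact published
V-score and its standardization are unpublished server internals; both the
contact rule and the standardization are documented as our choices and are
configuration knobs.

Complete-link agglomeration is implemented directly so tie-breaking is
deterministic (merge the lexicographically smallest pair of cluster
representative labels among minimal-distance pairs); `stats::hclust` and a
from-scratch furthest-neighbor recomputation serve as independent oracles
in the tests. Merge heights are non-decreasing (complete linkage is
monotone), trees export as ultrametric Newick (a node of height *h* puts
leaves at depth *h*/2), and dendrograms convert to `hclust` objects for
cutting and plotting. Class assignment of a query cuts the tree at half
the root height and takes the majority label among co-clustered
references.

# The motif fingerprint classifier

Nine sequence areas surround the cofactor; their per-class conservation
patterns are encoded in `motif_profiles()`, expressed in *A. vinelandii*
NifD author numbering. Pattern case encodes conservation: uppercase =
conserved within the class (+2 exact match / −2 mismatch), lowercase =
strongly similar (+1 when the query residue shares a Gonnet PAM250 strong
group — STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW — with the
pattern residue, −1 otherwise), `x` = variable (0). Gaps score as
mismatches. Single-organism exceptions recorded in the source conservation
table are encoded as permitted alternatives at their positions (scored as
matches, never penalized).

Window boundaries are not printed anywhere; they are fixed here from each
anchor residue (G66, R96, Q191, N230, G356, H383, G424, plus the ligand
positions C275 and H442) and the pattern length. The placement was
cross-validated internally: with the windows anchored this way, every
diagnostic residue the literature names (Ala65 vs Cys65, Gly69 vs
His69/Leu69, Arg96 vs Lys96, Glu380 vs Lys380, Lys428 vs Gly428, and the
Cys275 tetrad Cys-Tyr/Gln/His-Arg-Ser vs Cys-Ala-Arg-Ser) lands on its
stated number in every class row, which also identifies the table's second
numbering row as an alternate display numbering.

Diagnostic rules at positions 65, 69, 96, 276, 380 and 428 add weighted
votes (weight 3 per rule, configurable). Position 70 (Val) is conserved in
*all* classes' patterns and therefore carries no discriminating power; it
is deliberately not a rule. The class with the highest motif-plus-vote
total wins; the margin to the runner-up is the confidence. NifD-A, NifD-B
and the uncharacterized class map to FeMo-co, VnfD to FeV-co, AnfD to
FeFe-co. Sequences lacking *both* ligand positions (no Cys at 275 and no
His at 442) are flagged "Nif-like, unclassifiable" — such proteins are
known not to bind the cofactor at all. The `CXRS` ligand-environment
pattern check used for sequence pre-filtering is available as
`phi_pattern_check()`. C-terminal overhangs (an AnfD signature) and
internal insertions (a NifD-B signature) are read off the alignment with
`detect_extensions()`.

The score weights (+2/−2/+1/−1, rule weight 3) are our calibration of a
qualitative conservation description; they live in function arguments, not
constants.

# Synthetic data: what it emulates and what it does not

All tests run without downloads, on generators whose defaults are the
study conditions used throughout:

* `make_cavity_shell()` — pseudo-atom spherical shells with analytically
  known inner volume (default wall 4 Å thick, lattice 1 Å; both validated
  leak-proof against the probe);
* `perturb()` — rigid transform plus i.i.d. Gaussian noise with recorded
  ground truth;
* `make_planted_classes()` — per-class random smooth CA/CB backbones
  confined to a globule of protein-like density (~134 ų per residue),
  members as noised copies (default σ 0.3 Å, 3 members, 60 residues);
* `make_motif_family()` — class motif rows placed at their reference
  windows over a shared 460-residue scaffold, `x` positions drawn per
  member, point mutations at the requested rate (uppercase positions at
  one fifth of it); Mo-type members draw a Tyr/Gln/His tetrad residue at
  276 and uncharacterized members an uncharged Thr/Leu/Met at 380;
* `make_synthetic_site()` — a geometric nitrogenase-like active site: a
  Mo/7Fe/9S pseudo-cluster plus homocitrate-like group with the nine motif
  regions placed around it at their author numbers, Cys275 donating a
  thiolate S at 2.3 Å and His442 an imidazole N at 2.2 Å, and decoy
  residues outside the shell.

All randomness flows from one seed per invocation, split per sub-generator
so adding a call does not perturb earlier outputs; same seed means
byte-identical output.

These fixtures validate geometry, scoring and recovery logic. They do
**not** emulate real protein packing, crystallographic disorder,
alternative conformations, alignment errors from real aligners, or
homology-model bias — so passing tests demonstrate correctness of the
procedures, not field accuracy on real homologs. The synthetic reference
scaffold carries the true motif content at the true author numbers but is
not the deposited NifD sequence, and the synthetic site is a geometric
stand-in, not deposited coordinates. Absolute pocket volumes of real
structures depend on the structure source and are not comparable across
methods; only relative (per-class) contrasts are used as evidence.

# Problem sizes and numerical choices

Default problem sizes: clustering demonstrations use 2 planted classes ×
3 members of 60 residues; volumetrics use spacings 0.8–0.25 Å on ~25 Å
grids; classifier robustness uses 200 sequences per class at mutation rate
0.05. These sizes resolve every effect the methods claim while keeping a
full run to a couple of minutes on one core.

Degenerate inputs are handled explicitly: empty cofactor selections and
empty shells error or warn; fewer than 3 or collinear superposition pairs
error; zero self-similarity errors; non-symmetric distance matrices error;
equidistant volume classes and tied evidence votes surface as ties, never
as silent winners.

# Known limitations

* Distance contacts approximate Voronoi contacts; heavily distorted models
  can shift the standardized distances.
* The gap rule is a heuristic; unusual insertions inside a motif region
  could split it.
* The classifier assumes the query aligns to the reference numbering; it
  consumes an external aligner's output and does not build alignments.
* mmCIF, assembly expansion and structure prediction are out of scope.
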