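---
title: "Disentangling aligned residue associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling aligned residue associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arassoc)
```

## The model

An aligned pattern cluster (APC) is an M × N table: M sequences from a
protein family, N aligned sites from one conserved region, cells holding
amino-acid symbols. Optionally each sequence carries a class label
(taxon, functional subgroup). The analysis asks two questions: *which*
pairs of events — a residue at one site, a residue at another site, or a
class label — co-occur more or less often than chance, and *which
subgroup story* each such association belongs to when several subgroups
are mixed in the same cluster.

Every attribute contributes its distinct observed values as events; with
`I` events in total, the co-occurrence counts `o_ij` between events of
different attributes form an `I × I` frequency matrix. Under
independence the expected count is `e_ij = occ_i · occ_j / M`, where
`occ` are the marginal occurrence counts. Each count becomes a
statistical residual:

* standardized (Pearson): `SR_ij = (o_ij − e_ij) / √e_ij`;
* adjusted (Haberman; the default): the standardized residual divided by
  `√((1 − occ_i/M)(1 − occ_j/M))`.

The adjusted form is approximately standard normal under independence,
so a fixed two-sided threshold of 1.96 marks 95% significance; the
standardized form is biased toward zero for high-margin events, which is
why the adjustment is the default. Both modes are available
(`compute_srv(mode = )`) because the two are common in the contingency-table
literature and users may want either reading; the mode is recorded in every
output. The inequalities are strict: a residual of exactly 1.96 is not
significant. No multiple-testing correction is applied; the threshold is a
per-cell significance rule, not a family-wise error control, and should be
read as such.

The residual matrix is viewed as a vector space (SRV): row i is the
*a-vector* of event i, its coordinates the residuals against every other
event. Entangled subgroup structure means several independent contrast
patterns are superimposed in this one matrix.

## Disentanglement by decomposition and re-projection

Principal-component decomposition of the SRV separates those patterns.
The components are the right singular vectors of the **uncentered** SRV;
eigenvalues are the squared singular values in descending order. Not
centering is a deliberate choice: only then do the re-projection
identity `RSRV_k = SRV · PC_k · PC_kᵀ` and the completeness property
`Σ_k RSRV_k = SRV` hold exactly, so the retained RSRVs are an additive
decomposition of the original residual structure. A `center = TRUE`
option exists for exploration and is clearly non-default; with it the
identities hold only for the centered matrix. Because the SRV puts all
attributes on one statistical scale, the decomposition is not distorted
by the scaling differences that make PCA on raw counts unstable.

Components are retained when their eigenvalue exceeds the mean
eigenvalue (a Kaiser-style rule on the uncentered spectrum; `top_n` is
available when the user wants a fixed count). Each retained component is
re-projected to residual scale, and two summaries are extracted:

* **Salient events on the component**: events whose projection magnitude
  exceeds `stdev_factor` (default 1.0) times the standard deviation of
  all projections. The factor is our parameter — selection "far from the
  center" needs a scale, and one standard deviation of the projection
  distribution is the natural unit; it is exported in the manifest so
  any other choice is visible. Events at opposite extremes are reported
  with opposite poles, which is how two alternative residues at one site,
  each tied to a different class, appear.
* **AR clusters in the RSRV**: the graph on events with edges where
  `|RSRV residual| > 1.96` (same threshold as the SRV — the RSRVs are on
  the same residual scale, being an additive decomposition of it;
  rescaling per component would break comparability across components),
  restricted to pairs of different attributes; connected components of
  size ≥ 2 are the clusters. Connected components are the minimal
  deterministic reading of "events sharing strong associations"; no
  cluster count or distance parameter is introduced.

Determinism is enforced throughout: the event order is the radix-sorted
value order per attribute (so results are invariant to row order), the
SVD backend is deterministic LAPACK, and each component's sign is fixed
by making its largest-magnitude loading positive. Degenerate input — an
all-zero SRV, as produced by perfectly independent columns — yields zero
eigenvalues with an identity basis and a warning rather than an error.

## Mixed-mode tables and property expansion

To analyse physicochemical structure, `expand_to_appc()` replaces each
residue by a 5-tuple: side-chain polarity class, acidity/basicity,
Kyte–Doolittle hydropathy, molecular weight (Da), isoelectric point
(pH). The first two are categorical, the last three numeric, so the
expanded table is mixed-mode. The built-in table covers the 20 standard
residues with the standard scales; because numeric results at the
property level depend on the exact table used, the table is
user-overridable (`read_property_table()`). Attribute keys are
structured `(site, property_index)` pairs rendered as concatenated
display labels (`"721"` = property 1 of site 72); the structured key is
authoritative, avoiding the parsing ambiguity of labels like `"1043"`.
A gap symbol without a property row expands to missing cells, and rows
with missing cells are excluded from the pairwise counts involving those
attributes (each attribute pair is a complete-case contingency table,
with margins and M taken per pair).

Numeric attributes are discretized before analysis
(`maybe_discretize()`): attributes with fewer than three distinct values
pass through as categorical; the rest are cut into `bins` interval
events (default 3 — with the small per-class sample sizes typical of
APCs, three bins keep expected cell counts large enough for the normal
approximation behind the 1.96 rule while still resolving
class-enriched sub-ranges; configurable). Equal-frequency quantile
cuts are the default because equal-width bins are fragile to outliers;
`max_entropy` is the equal-probability partition maximizing occupancy
entropy, which coincides with equal-frequency cuts on tie-free data and
is provided under its own name. Cut points are placed midway between
distinct values, and a quantile falling inside a run of ties sends the
whole run to the lower bin: ties never split, and the scheme is
deterministic and total. Class-driven discretization is not
implemented; the CLI rejects `--discretize ocdd`, and the unsupervised
methods are the supported path.

Bin labels (`"[lo,hi)"`, last bin closed) are normative strings: event
identity downstream is string-keyed, so the rendering (8 significant
digits) is part of the contract and schemes are serialized to JSON with
every run.

## The synthetic benchmark

`generate_table2(seed)` generates the reference benchmark: 300 rows in
three equal classes (the total is fixed by design; the equal split is
our choice, configurable via `rows_per_class`), five categorical
attributes. Classes carry deterministic site patterns — C1: A1=A, A2=C,
A3=E; C2: A1=A, A2=D, A3=F; C3: A1=B, A2=D, A3=E — plus stochastic
attributes A4 (uniform H/G for C1 and C2, fixed H for C3) and A5
(uniform M/N everywhere). The entanglement is the point: A1=A is shared
by C1 and C2, A2=D by C2 and C3, A3=E by C1 and C3, so no single
attribute separates the classes, and in the undecomposed SRV the class
contrasts overlap. After decomposition, one retained RSRV carries the
C3-versus-rest contrast (A1=B against A1=A) and others the C1-versus-C2
contrast (A2=C against A2=D, A3=E against A3=F) — the designed
disentanglement.

`generate_generic()` generalizes this: arbitrary class sizes, background
alphabets (uniform draws; our choice of `{A..H}` per attribute where a
background is needed, since only uniformity is specified), embedding
probabilities below 1, and numeric attributes with class-enriched
sub-intervals to exercise the discretizer. The generator is seeded
(Mersenne-Twister, recorded in the ground truth), restores the session
RNG state, and exports ground truth sufficient to score recovery
without reference to any external description.

What the generator does *not* emulate: phylogenetic correlation between
sequences (rows are i.i.d. within class), position-specific
conservation gradients, gaps, and alignment error. Passing the
synthetic recovery tests therefore shows the machinery recovers planted
associations under clean sampling; it does not show robustness to the
dependence structure of real alignments.

## Numerical and testing choices

* Residuals are validated against an independent contingency-table
  oracle (`chisq.test` expected counts, Pearson residuals and adjusted
  residuals) on hundreds of random small tables, to 1e-9.
* The decomposition is validated for completeness (`Σ_k RSRV_k = SRV`,
  Frobenius 1e-8, matrices up to I = 100), orthonormality (1e-8), and
  against a power-iteration eigen-oracle on small matrices (1e-6,
  sign-free comparison).
* Recovery, RSRV separation of the two class-pair patterns, and
  supervised-versus-unsupervised agreement (Jaccard on cluster
  membership restricted to residue events, ≥ 0.8) are checked over 20
  seeded replicates of the benchmark; the false-positive rate of the
  1.96 rule on pattern-free tables is checked against its nominal 5%
  over 50 replicates (band 3–7%, allowing Monte-Carlo error and count
  discreteness at expected cells near 5). These problem sizes — 300-row
  tables, I ≤ 100 matrices, 20–50 replicates — were chosen as the
  smallest at which the statistical claims are meaningfully testable.

## Limitations

* Significance is per association at a fixed threshold; with many
  events, some suprathreshold cells are expected by chance (the null
  calibration quantifies how many).
* Components are linear contrasts; subgroup structure that is not
  expressible as a linear combination of residual columns will not
  isolate into a single RSRV.
* The adjusted-residual normal approximation degrades for very small
  expected counts (rare events at small M); interpret borderline
  residuals accordingly.
* Cluster extraction by connected components can chain distinct
  sub-stories through a shared hub event; inspect the per-edge
  residuals (`clusters.tsv` exports each member's strongest partner).
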