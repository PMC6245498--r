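# arassoc

Discovery and disentanglement of aligned residue associations in aligned
pattern clusters.

## The problem

A conserved region of a protein family can be represented as an **aligned
pattern cluster (APC)**: a table whose rows are sequences and whose columns
are aligned sites holding amino-acid symbols. Residues at different sites
co-occur non-randomly — an **aligned residue association (ARA)** — and these
associations carry subgroup structure: different taxonomic classes or
functional subgroups favour different residue combinations. When several
subgroups are mixed in one APC their associations *entangle*: a single
association table superimposes several subgroup stories, and no one view
shows which association belongs to which subgroup.

`arassoc` is for sequence analysts who have an APC (with or without class
labels) and want to know which residue—residue and residue—class
associations are statistically significant, and which subgroup each one
belongs to. It also works one level deeper, on **aligned residue property
tuples**: each residue replaced by five physicochemical properties
(side-chain polarity, acidity/basicity, Kyte–Doolittle hydropathy,
molecular weight, isoelectric point), giving a mixed-mode table whose
numeric columns are discretized before analysis.

## The method

1. **Events.** Each attribute (site, site-property, or the class column)
   contributes its distinct values as events; numeric attributes with at
   least three distinct values are first cut into interval events
   (equal-frequency quantile bins by default). With `I` events in total:
2. **Frequency matrix.** An `I x I` matrix of co-occurrence counts
   `o_ij` between events of different attributes.
3. **Statistical-residual vector space (SRV).** Each count becomes a
   residual against independence, `e_ij = occ_i * occ_j / M`:

   - standardized: `SR_ij = (o_ij - e_ij) / sqrt(e_ij)`
   - adjusted (default): additionally divided by
     `sqrt((1 - occ_i/M)(1 - occ_j/M))`, the Haberman adjustment, so each
     entry is approximately N(0,1) under independence.

   `|SR| > 1.96` marks an association significant at the 95% level. Each
   row of the SRV is the *a-vector* of one event.
4. **Decomposition.** Principal components of the *uncentered* SRV
   (right singular vectors; eigenvalues are squared singular values,
   descending). Components whose eigenvalue exceeds the mean are retained.
5. **Re-projection.** For each retained component,
   `RSRV_k = SRV %*% PC_k %*% t(PC_k)` maps the component back to
   residual scale. Associations belonging to different subgroups separate
   into different RSRVs.
6. **Clusters.** Within each RSRV, events connected by suprathreshold
   residuals form AR clusters (connected components), each member carrying
   the sign of its projection (its pole).

## Worked example

The built-in generator reproduces a 300-row, three-class benchmark with
deliberately entangled patterns: `A1=A` is shared by classes C1 and C2,
`A2=D` by C2 and C3, `A3=E` by C1 and C3.

```r
library(arassoc)
synth <- generate_table2(seed = 1)
res   <- run_pipeline(synth$apc)
res
#> disentangled_result: M = 300, I = 13 events, mode = adjusted
#>   retained components: 1, 2, 3, 4, 5
#>   PC1: 1 cluster(s), 48 significant association(s)
#>   PC2: 1 cluster(s), 12 significant association(s)
#>   PC3: 1 cluster(s), 12 significant association(s)
#>   PC4: 1 cluster(s), 16 significant association(s)
#>   PC5: 1 cluster(s), 12 significant association(s)

head(significant_associations(res))
#>   component event_i  event_j   residual
#> 1         1    A1=A Class=C3 -11.038983
#> 2         1    A1=B Class=C3  11.038983
#> 3         1    A4=G Class=C3  -7.847483
#> 4         1    A4=H Class=C3   7.847483
#> 5         1    A1=A     A4=G   7.119176
#> 6         1    A1=B     A4=G  -7.119176
```

The first component opposes `A1=B`/C3 against `A1=A` (shared by C1 and
C2): a residual of +11.0 says B at site A1 co-occurs with class C3 far
more often than independence predicts, while −11.0 says A at that site
avoids C3 — the C3-versus-rest contrast isolated in one RSRV. Other
retained components carry the C1-versus-C2 contrast (`A2=C`/`A2=D`,
`A3=E`/`A3=F` with opposite poles). `format_report(res)` renders the
clusters and their edge residuals as text, `write_result_bundle(res, dir)`
exports `result.json`, per-component `rsrv_k.csv`, `pc_coordinates.csv`
and `clusters.tsv`.

A shell entry point wraps the same functions:

```sh
Rscript inst/cli/arassoc.R synth --seed 1 --out apc.tsv
Rscript inst/cli/arassoc.R run --input apc.tsv --class-column class --out out/
Rscript inst/cli/arassoc.R report --input apc.tsv --class-column class
```

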