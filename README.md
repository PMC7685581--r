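# pathpls

Coupling microbial community structure and metabolic potential to
geochemistry in hot-spring "oil site" habitats.

## The problem

Hydrothermal petroleum seeps — hot springs whose waters carry freshly
formed oil — host microbial communities shaped by steep, heterogeneous
physicochemical gradients (temperature up to ~97 °C, pH swings, Eh,
total dissolved solids, major ions, trace elements). Two questions
recur in 16S rRNA surveys of such systems:

1. Does the community carry the *metabolic potential* to degrade the
   hydrocarbons it lives on? 16S data gives taxonomy, not genes, so
   potential must be inferred: each detected taxon contributes its known
   protein repertoire (collapsed to KEGG Orthology identifiers), and a
   pathway's **completeness** in a sample is the fraction of its
   required KOs present in the community-wide non-redundant KO set:

   `completeness(sample, pathway) = |KO_sample ∩ KO_pathway| / |KO_pathway|`

2. Do geochemical gradients *structure* the community and its
   potential? This is a two-table association problem, answered here by
   **two-block partial least squares** (2B-PLS, also known as PLS-SVD or
   co-inertia analysis): the singular decomposition of the cross-covariance
   matrix `C = XᵀY/(n−1)` of the paired, column-centered blocks yields
   paired axes `(u_k, v_k)` maximizing `cov(Xu_k, Yv_k)`; the Pearson
   correlation `r_k` of the paired axis scores is the headline statistic,
   and its significance comes from a permutation test with the add-one
   estimator `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`.

`pathpls` implements this entire desk-analysis chain for microbial
ecologists: table I/O with field-data semantics ("b.d.l." / "n.d."
censoring tokens, the ICP-MS detection-limit formula
`DL = 3σ·c_std/(S−B)`, Greengenes lineage strings, BIOM-JSON), alpha
diversity (Shannon in nats, inverse Simpson, richness), the
completeness statistic, Hellinger-transformed ordination (PCA, 2B-PLS),
permutation inference, and a seeded generator of coupled synthetic
datasets with known ground truth so every stage is testable without any
database download.

## Worked example

The `analysis/` directory is a numbered workflow over the package
functions. Stage 1 simulates a survey at study scale (10 samples, 200
OTUs, read depths 12,000–29,000, 20 geochemical variables, one latent
gradient with coupling κ = 0.8 driving both blocks):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diversity.R
Rscript analysis/03_completeness.R
Rscript analysis/04_ordination.R
Rscript analysis/05_reproduce_sweep.R
```

Stage 4 prints (this exact run is reproducible from the committed
seeds):

```
community PCA: PC1 71.6%, PC2 7.1% of variance
taxa~geochem: axis-1 r = 0.991, d = 1.222, p = 0.0001 (9999 perms)
completeness~geochem: axis-1 r = 0.983, d = 2.971, p = 0.0001 (9999 perms)
ground truth rho = 0.997; estimated taxa r1 = 0.991
```

Reading: the first 2B-PLS axis pairs a geochemical gradient with a
community gradient correlated at r = 0.991 across the 10 samples; no
permutation among 9999 reached the observed statistic, so p = 10⁻⁴, the
smallest value that many permutations can report. The estimate sits
within 0.01 of the generator's ground-truth axis correlation
(ρ = 0.997). The same axis structure holds for the pathway-completeness
block: samples high on the latent gradient detect more hydrocarbon
degraders, hence more degradation-pathway KOs. Stage 3 shows the
functional side — degradation pathways average 0.49 completeness with
strong between-sample spread, while housekeeping pathways sit at 1.0,
and the ≥90% list contains exactly the 5 housekeeping pathways.

The same functions run on real tables:

```r
library(pathpls)
otu  <- read_otu_table("otu.tsv")                  # or dialect = "biom_json"
geo  <- read_geochem_table("geochem.tsv", bdl_policy = "half_dl",
                           dl_map = c("As (µg/l)" = 0.02))
db   <- read_annotation_db("taxon_ko.tsv")
cat_ <- read_pathway_catalog("pathways.tsv")
bundle <- run_pipeline(run_config(simulate = NULL, otu = "otu.tsv",
  geochem = "geochem.tsv", annotations = "taxon_ko.tsv",
  pathways = "pathways.tsv", n_perm = 9999, seed = 1))
```

## Scope

Upstream read processing (QC, chimera removal, OTU picking), UniFrac
beta diversity, and live UniProt/KEGG retrieval are out of scope: the
package starts from OTU tables and flat-file taxon→KO / pathway→KO
contracts, and ships a synthetic generator in their place. See
`vignettes/pathway-completeness-coupling.Rmd` for the model, parameter
and design discussion.
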