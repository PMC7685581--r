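---
title: "Pathway completeness and geochemistry coupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway completeness and geochemistry coupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpls)
```

# The analysis chain

`pathpls` implements a desk-scale analysis of hot-spring oil-seep
microbial surveys with three stages: alpha diversity of OTU tables,
taxonomy-driven KEGG-pathway completeness, and two-block PLS coupling of
each of those community descriptions to a geochemical block, with
permutation inference. This vignette records the models, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open.

## Alpha diversity

For a relative-abundance vector $p$ (renormalized to sum to 1, zeros
dropped):

* Shannon $H = -\sum_i p_i \ln p_i$, in **nats**. Natural log is the
  deliberate choice: with per-sample richness up to roughly 200 OTUs,
  observed index values of at most about 4.1 are consistent with $\ln$
  ($\ln 206 \approx 5.3$), whereas base-2 logs would allow values above
  7. Reports print 1 decimal.
* Inverse Simpson $D = 1/\sum_i p_i^2$, the effective number of equally
  abundant OTUs; printed at 2 decimals.
* Richness: count of entries strictly above a presence threshold
  (default 0).

Renormalization before computing the indices is the package's
reproduction convention for *truncated* published tables, whose rows sum
to less than 1 after a display cutoff (conventionally 0.05%). Because
the original indices may have been computed before truncation,
`diversity_variants()` reports two bracketing conventions — renormalize
over the shown OTUs, or pool the undisplayed mass into one pseudo-OTU —
together with their discrepancy. The pooled variant treats the hidden
tail as a single taxon, so it bounds that tail's contribution from
below; with a 0.05% cutoff the two conventions typically agree at print
precision, and the report makes any disagreement visible rather than
silently picking one.

The abundance cutoff itself (`filter_min_abundance`) removes entries
*strictly below* the threshold — a value exactly at the cutoff survives,
matching the convention "values below X not shown" — and does not
renormalize rows, mirroring the shape of truncated supplementary tables.

## Pathway completeness

The functional statistic is presence/absence at the KEGG Orthology
level. For sample $s$ with community-wide non-redundant KO set $K_s$ and
a pathway requiring KO set $P$:

$$\mathrm{completeness}(s, P) = \frac{|K_s \cap P|}{|P|} \in \{0, \tfrac1{|P|}, \dots, 1\}.$$

$K_s$ is the union of the KO sets of the taxa detected in $s$. Design
decisions:

* **"Enzyme" means KO identifier.** The catalog defines each pathway as
  a KO set; whether those KOs are restricted to EC-bearing entries is a
  catalog-construction choice upstream of the package.
* **Matching rank: genus by default.** 16S OTUs rarely resolve species,
  so OTU lineages are collapsed to `g__` labels before matching the
  annotation database; species-first matching with genus/family
  fallback (`rank_fallback = TRUE`) is available when full lineage
  strings are supplied. Labels match exactly after lowercasing with the
  rank prefix kept — no fuzzy matching, ever.
* **Detection threshold: any positive abundance by default**
  (`min_rel_abund = 0`); the pipeline default raises it to the 0.05%
  display-cutoff convention (`5e-4`) so that "detected" matches what a
  truncated published table shows. There is no principled universal
  cutoff; both are parameters.
* The statistic is monotone (adding taxa or KOs can only increase it),
  exactly rational with the pathway size as denominator, and
  deterministic under row/column reordering — all property-tested, with
  a brute-force set-enumeration oracle on small catalogs.

A sample whose taxa all miss the database yields an all-zero row plus a
warning and a per-taxon match report (matched / fallback / unmatched),
rather than an error: partially annotated databases are the norm.

## Geochemistry semantics

Field geochemistry tables carry censoring tokens: `n.d.` (not
determined) always becomes a missing value; `b.d.l.` (below detection
limit) becomes, per policy, zero, NA, or DL/2 — the standard
left-censoring substitution — with the cell's status kept in a parallel
mask either way. DL/2 requires a per-parameter detection-limit map; the
ICP-MS detection limit itself is computed as
$DL = 3\sigma \cdot c_{std} / (S - B)$ (blank-signal SD, standard
concentration, net standard signal), with $S \le B$ rejected as a
domain error.

## Block preparation and two-block PLS

Blocks are samples × variables matrices. Defaults, all configurable:

* **Geochemistry**: log10 on concentration variables (their unit
  strings contain `g/l`; spanning orders of magnitude), then z-scoring —
  the block mixes °C, pH units, mV, g/l and µg/l, so unit variance is
  the only defensible common scale. The log floor added before log10
  defaults to half the smallest positive value of the column;
  a literal machine-epsilon floor would map censored zeros to
  $\approx -308$ and destroy the z-scale.
* **Community**: Hellinger transform (square root of relative
  abundances, via `vegan::decostand`), then column centering. Hellinger
  downweights dominant OTUs without overweighting rare ones and makes
  Euclidean ordination appropriate.
* **Completeness**: column centering only — the values already share the
  [0,1] scale, and z-scoring would inflate near-constant pathways.

2B-PLS is the SVD of $C = X^\top Y/(n-1)$: unit weight vectors
$(u_k, v_k)$ maximize $\mathrm{cov}(Xu_k, Yv_k) = d_k$, and the per-axis
score correlation $r_k$ is the reported association. Numerical
conventions, chosen to make outputs byte-stable across linear-algebra
backends:

* Each $(u_k, v_k)$ pair is jointly sign-flipped so the
  largest-magnitude entry of $u_k$ is positive. A joint flip leaves
  $d_k$ and $r_k$ untouched. Because blocks are centered before
  decomposition, $d_1 = \mathrm{cov}(Xu_1, Yv_1) \ge 0$ already forces
  $r_1 \ge 0$; flipping only one side of the pair would negate $d_1$
  and break the decreasing-nonnegative spectrum, so the sign convention
  operates on pairs.
* Rank truncation at $10^{-12} d_1$; requesting more axes truncates.
* $\sum_k d_k^2 = \|C\|_F^2$ (co-inertia conservation) is tested to
  $10^{-10}$; axis-1 is tested to $10^{-6}$ against an independent
  brute-force covariance maximizer (random multi-start over the unit
  sphere, Nelder–Mead + BFGS polish, with the optimal $v$ given $u$ in
  closed form).

## Permutation inference

Rows of $Y$ are permuted uniformly (under exchangeability this is
equivalent to permuting either block), the decomposition is recomputed
from scratch each time, and

$$p = \frac{1 + \#\{\text{perm} \ge \text{observed}\}}{1 + n_{perm}},$$

the add-one estimator, with ties counted as exceedances (conservative).
Consequences worth stating: $p \in [1/(n_{perm}+1), 1]$, so reporting
$p < 10^{-4}$ requires at least $10^4$ permutations; and with few
samples the identity permutation is occasionally drawn, so on perfectly
correlated blocks the add-one minimum is only attained when $n!$ is
large relative to $n_{perm}$. Permutations are drawn over *id-sorted*
positions, which makes the p-value exactly invariant under jointly
relabeling (reordering) the samples of both blocks. The seed is a
mandatory argument. The two pipeline analyses report raw p-values with
$n_{perm}$ stated; no multiplicity correction is applied across the two
tests.

## PCA

`pca_block` wraps `stats::prcomp` on the centered block and applies the
same deterministic sign convention (largest-|loading| entry positive).
Explained-variance fractions are reported over the full spectrum;
requesting components beyond the numerical rank truncates with a
warning.

# The synthetic-data generator

`generate_coupled_dataset()` is first-class, tested code: it stands in
for the study's raw data in every test, so its defaults *are* the study
conditions — 10 samples, 200 OTUs, read depths uniform on
12,000–29,000, 20 geochemical variables (temperature, pH, Eh, TDS,
major ions, trace elements), and a catalog of 12 pathways (7
hydrocarbon-degradation, 5 housekeeping) of 10 KOs each.

One latent standard-normal gradient $z_i$ per sample drives everything
(rank-1 coupling, strength $\kappa \in [0,1]$, default 0.8 — chosen once
to emulate the strong community–geochemistry associations such systems
exhibit):

* Concentrations are log-normal,
  $\log x_{ij} = \log b_j + a_j \kappa z_i + \sigma_j \varepsilon$, with
  heteroscedastic $\sigma_j$ (multipliers 0.5–1.5 on the base noise SD)
  to stress the z-scoring path; temperature, pH and Eh respond linearly
  on their natural scales, pH clipped to its physical range. Trace
  elements below a detection limit (default 10% of baseline) are
  censored to `b.d.l.` semantics with the DL map stored.
* Taxon log relative abundances are
  $\lambda_{ik} = \mu_k + b_k \kappa z_i + \tau \eta$, softmaxed per
  sample, with multinomial read sampling at the drawn depth —
  the simplest model yielding integer OTU tables at realistic depth; a
  Dirichlet-multinomial overdispersion switch exists but defaults off.
* A quarter of taxa are designated degraders: strictly positive
  responses $b_k$, baselines $\mu_k$ centered just *below* the 0.05%
  detection convention, and KO sets drawn sparsely from one degradation
  pathway each (35% of its KOs, plus a sprinkling of housekeeping KOs).
  Non-degraders carry housekeeping KOs with a 5% chance of one stray
  degradation KO. Degradation-pathway completeness therefore co-varies
  with $z$ *emergently*, through which degraders cross the detection
  threshold — nothing about the completeness–geochemistry association is
  hard-coded.

Baseline spreads ($\mu_k$ SD 1.6 for non-degraders) were set so the
generated surveys match the observed ranges of such systems: per-sample
richness within 50–210 and Shannon/inverse Simpson values in the
low-single-digit / tens range. The generator stores its ground truth
($z$, $a$, $b$, degrader flags, $\kappa$, seed) plus the population
axis correlation $\rho$, recomputed on demand by
`population_axis_correlation()`: a large-$n$ (default 2000 draws)
noise-free construction — exact softmax abundances instead of reads,
zero measurement noise — pushed through the standard block preparation
and 2B-PLS. For $\kappa = 0$, $\rho = 0$ exactly and
`generate_null_dataset()` provides the decoupled case for type-I-error
suites.

What the generator deliberately does **not** emulate: phylogenetic
structure among OTUs (taxa are exchangeable), PCR/primer bias and
chimeras, multi-gradient geochemistry (coupling is rank-1), database
incompleteness patterns (every synthetic taxon is annotated), and
geochemical speciation constraints beyond the pH range. Passing tests
on synthetic data therefore demonstrate correctness of the statistical
machinery and recoverability of a known gradient — not that any real
system has such a gradient, nor that a real annotation database is
adequate.

# Problem sizes and budgets in the test suite

The suite runs everything at desk scale, chosen as the package's own
trade-off between statistical resolution and a test run of a few
minutes: type-I error uses 200 decoupled replicates (20 samples, 40
taxa, 8 geochemical variables) at 199 permutations; ground-truth
recovery uses $\kappa = 0.9$, $n = 50$, low noise (SDs 0.15) with a
±0.05 acceptance band against $\rho$; monotonicity in $\kappa$ averages
5 seeds per grid point over $\{0, 0.3, 0.6, 0.9\}$; the
supplement-style preprocessing sweep runs its full 8-variant grid at
$10^4$ permutations. The analysis scripts use 9999 permutations at the
10-sample study scale.

# Known limitations

* Completeness is presence/absence: gene abundance, expression and
  enzyme promiscuity are invisible, and a pathway can score 1.0 in a
  community none of whose members individually encodes it end-to-end.
* Genus-level matching inherits the database's genus-level
  annotations; a database built from sequenced relatives of the
  observed taxa can over- or under-state repertoires.
* With ~10 samples, 2B-PLS axis correlations are optimistically biased
  (weights are fit and evaluated on the same samples); the permutation
  test accounts for this under the null, but the point estimate $r_1$
  should be read with that bias in mind — the null-data estimate in the
  test suite is substantially positive even when blocks are
  independent.
* DL/2 substitution and column-median imputation are pragmatic, not
  model-based; heavily censored variables deserve proper
  censored-likelihood treatment before ordination.
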