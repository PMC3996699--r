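---
title: "Methods and design of the dysbiosr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dysbiosr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiosr)
```

# Scope

dysbiosr reconstructs, as a tested and reusable pipeline, the derived-table
analysis layer of a longitudinal DSS-colitis microbiome study: community
profiling of rRNA-derived taxon tables and amplicon OTU tables, functional
profiling of annotated mRNA reads, qPCR quantification and expression
statistics, and a multi-omic Pearson correlation network for biomarker
discovery. Upstream steps — sequencing, read merging, taxonomic and
functional annotation, OTU picking — are out of scope: the package starts
from feature-by-sample count tables and per-sample metadata, the products
those tools emit.

Because the raw animal data are archived externally and are not desk-scale
reproducible, the package ships a first-class synthetic-data generator
whose defaults emulate the study conditions, with known ground truth. All
calibration, power and recovery claims in the test suite refer to that
generator, not to real sequencing data.

# Community profiling

**Rarefaction** (`rarefy()`) subsamples each sample's reads without
replacement to a common depth (default 3500 in the pipeline configuration,
the conventional depth for moderately sized amplicon libraries). It is a
single recorded draw per sample under an explicit seed; a `replicates`
argument in `alpha_diversity()` averages over draws when smoother richness
estimates are wanted. Samples below depth are dropped, never scaled —
scaling would fabricate reads and bias richness.

**Alpha diversity** reports observed richness at depth and Pielou's
evenness J = H / ln(S) with Shannon entropy H in natural-log units. The
evenness convention matters: QIIME-era "equitability" uses log2. We fix the
natural log and state it, and the tests are metric-explicit. For a
single-feature sample J is undefined and returned as `NA`, never coerced
to 0.

**Rank aggregation** pools features lacking an assignment at the target
rank into `"unclassified <parent>"` groups rather than discarding them, so
per-sample totals are conserved exactly at every rank.

# Dissimilarity and ordination

**Bray–Curtis** is computed as sum(|x−y|)/sum(x+y) on relative abundances,
or on presence/absence indicators (equal to Sørensen dissimilarity) in
binary mode. The matrix route delegates to `vegan::vegdist`; the scalar
`bray_curtis()` implements the formula directly and the test suite checks
the two against each other entry by entry. Feature subsets (e.g. the
phylotypes of one family) are re-normalized within the subset before
abundance-mode computation, so within-group shifts are measured
compositionally.

**PCA** is eigendecomposition of the variable correlation matrix:
variables (taxa, families or categories) are standardized with sd
denominator n−1, the correlation matrix is decomposed with a symmetric
eigensolver, and scores are the standardized data projected on the
eigenvectors. Correlation (not covariance) PCA is deliberate: relative
abundances of dominant and rare groups differ by orders of magnitude, and
the correlation form weights them equally. Eigenvector sign is arbitrary,
so it is pinned — each loading column's largest-magnitude entry is made
positive — which makes scores reproducible across platforms. The tests
verify the spectral invariants (eigenvalue sum = number of variables,
orthonormal loadings, score covariance = eigenvalue diagonal, full
reconstruction) and agreement with an SVD oracle (`prcomp`).

# qPCR quantification and expression statistics

**Standard curves** are ordinary least squares of Ct on log10 copies.
Efficiency is expressed as fold-amplification per cycle, E = 10^(−1/slope),
so E = 2 is perfect doubling; percent efficiency E−1 is reported alongside.
Curves require at least 3 points spanning 2 log10 units, and a
non-negative slope is rejected as non-amplifying.

**Copy numbers** are normalized both per µg of template nucleic acid and
per µl of preparation from the same raw estimate. The **flagellin
expression index** is the per-mouse log10 ratio of transcript to gene
copies in the same preparation (per-µl values by default, matching how
such ratios are formed when DNA and RNA come from one extraction). The
ratio separates transcriptional downregulation from a decline of the
flagellated population, and is invariant under joint rescaling of both
copy estimates.

**Expression ratios** follow the efficiency-corrected, housekeeping-
normalized form R = E_t^ΔCt_t / E_r^ΔCt_r with ΔCt = mean Ct(control) −
mean Ct(treatment). Per-assay efficiencies from the standard curve are
supported; E = 2 is the default when none is supplied. A plate-wide Ct
offset cancels exactly.

**The fixed reallocation randomization test** reallocates group labels
across samples, keeping each sample's target and reference measurements
paired, recomputes the ratio, and uses the two-sided statistic |log R|
with the add-one correction p = (1 + #extreme)/(1 + n_reallocations).
Reallocations are drawn uniformly with replacement (2000 by default, which
at small n exceeds the number of distinct labelings; duplicates are
expected and harmless). The published tool this reconstructs does not
document its exact internal statistic, so the suite calibrates the test's
type-I error rather than matching another implementation output-for-output.

One property deserves emphasis: **at equal group sizes the test is
conservative by construction**. With n = 4 vs 4 there are choose(8,4) = 70
labelings, and the two-sided statistic is identical for each labeling and
its complement, so exact p-values live on {2/70, 4/70, …}. The largest
attainable size below 0.05 is 2/70 ≈ 0.029 — no correct implementation can
reject 5% of null datasets at α = 0.05. The acceptance suite therefore
checks the empirical size against an exact-enumeration oracle of the
attainable size, plus a validity bound (never anti-conservative) and
super-uniformity of the null p-value distribution over a grid of levels.

**Group tests** offer the unpaired pooled t-test and one-way ANOVA with the
Student–Newman–Keuls stepwise procedure. SNK critical values come from the
studentized range distribution (`qtukey`), ranges are tested from widest to
narrowest, non-significant ranges close all their sub-ranges, and the
result is summarized as a compact letter display. Ties in means are broken
by group order. With two groups the procedure reduces exactly to the
pooled t-test decision (q = t·sqrt(2)), which the tests exploit as an
independent check.

# Functional categories

Counts are summed up a user-supplied 3-level hierarchy (level 1 ≈ broad
subsystem). The denominator for "relative abundance of transcripts" is all
functionally annotated reads per sample; a taxon-restricted denominator
(e.g. fraction of the Firmicutes metatranscriptome) is available because
within-taxon profiles answer a different question than whole-community
ones, and the two are easy to conflate. Per-category day contrasts use
plain unpaired t-tests with **no multiple-testing correction by default** —
this mirrors the per-category testing convention of the study design the
package reconstructs; Benjamini–Hochberg is available behind a flag for
users who prefer family-wise control.

Gene panels (mucin degradation, butyrate pathway) ship as editable YAML
files under `inst/extdata/panels/`; they are conventions to be curated per
annotation vocabulary, not hard-coded constants.

# Correlation networks

Blocks — host markers (log-scale expression ratios), OTU relative
abundances, level-1 category fractions — are inner-joined on samples;
abundance features must reach ≥ 1% relative abundance in at least one
sample (inclusive at the boundary: "did not reach 1%" excludes only
features strictly below it everywhere). Host markers are not abundances
and are exempt. Samples missing from any block are dropped entirely, so a
single n underlies every edge (no pairwise-complete estimation).

Log-normalization is x → log10(x + pseudocount). The pseudocount default
is half the smallest nonzero value of each abundance block — scale-aware,
keeps zeros finite, preserves rank order — with a fixed constant available
when cross-dataset comparability matters; the value used is recorded on
the object. Host markers are already log-scale and pass through.

Edges require r > threshold or r < −threshold, strictly, with r stored on
the edge and sign(r) as the edge sign; the default threshold is 0.6. No
multiple-testing adjustment alters the edge set — the method thresholds r
only. Neighbourhood queries (`neighborhood()`, order 1 or 2) return the
induced sub-network around seed nodes, the operation used to nominate
candidate phylotype biomarkers around host markers. Networks export to
GraphML (typed nodes, signed weighted edges) and round-trip losslessly.

Plain Pearson correlation on log-normalized relative abundances is used
deliberately, including its known compositional caveats (see Limitations).

# The synthetic-data generator

`simulate_study(design, effects)` emits every table the pipeline consumes,
plus ground truth. The defaults encode a moderate-to-severe colitis course
over days 1/5/8/14/25 with 4 mice per day:

* **Taxa.** Two dominant orders (Clostridiales + Bacteroidales) jointly
  ~95% of rRNA reads in health; a Clostridiales dip and Bacteroidales
  expansion at peak inflammation (day 8); low-abundance bloomers
  (Enterobacteriaceae, Verrucomicrobiaceae, Erysipelotrichaceae,
  Deferribacteraceae) during the acute phase. Per-sample compositions are
  Dirichlet-perturbed day means (concentration 200) drawn into multinomial
  counts at a library size sampled from 80–120k reads.
* **OTUs.** Families split into phylotypes with fixed geometric weights
  (Dirichlet concentration 100; libraries 5–26k reads); the residual mass
  is emitted as an explicit unclassified phylotype pool so totals stay at
  the drawn library size.
* **Function genes.** Level-1 category day trajectories (with the
  'Motility and Chemotaxis' fraction planted at −21%/−49% of baseline on
  days 5/8) are split into genes by fixed catalog weights; the simplex
  remainder becomes an explicit Miscellaneous pool so level-1 fractions
  partition every annotated read. Per-gene rates get multiplicative gamma
  noise (shape 200) and are drawn conditional on the sampled library size
  (100–200k) — negative-binomial-type overdispersion at a controlled
  total, chosen because the module must simultaneously keep per-sample
  totals inside the declared range. The mucin-degradation panel is carved
  out of the carbohydrate share so that its fraction of
  Bacteroidetes-attributed reads follows 1.36/1.39/2.03/1.31/1.33% over
  the five days.
* **Host markers** are simulated directly as log2 expression ratios vs
  day 1 (cytokines up at day 8, IL-10 dip at day 5, TLR5 down), with
  matched Ct-level measurements (E = 2 chemistry, GAPDH reference) for the
  qPCR entry point.
* **Flagellin qPCR** draws per-mouse gene copies and transcript:gene log10
  ratios with day means 0.09/0.05/−0.34/−0.10/−0.25 and sds
  0.18/0.20/0.31/0.35/0.25 — healthy near 0.09 ± 0.18, peak colitis near
  −0.34 ± 0.31, and deliberately large replicate spread at day 14.
* **Planted correlations** act through shared latent Gaussian factors on
  the log scale. Edges sharing a feature form one factor (and must share
  |ρ|); modules of mutually correlated features are supported. For planted
  phylotypes the latent factor *replaces* the Dirichlet perturbation, so
  the intended log-scale correlation survives count sampling without
  attenuation by compositional noise. Ground truth records the latent
  values; their empirical correlations match ρ within ±0.05 at ≥200
  samples (oversampled validation).

Noise levels were fixed once, at design time: gamma dispersion 200 and a
category factor sd of 0.02 (log10) give per-sample category-fraction
coefficients of variation of ~5–7%, so that day-mean percent changes at
n = 4 mice recover the planted −21/−49% within a few percentage points;
the OTU factor sd of 0.3 keeps planted ρ = 0.9 biomarker edges above the
0.6 threshold after count noise. These are the study conditions for every
calibration claim and are not tuned per test.

What the generator does **not** emulate: sequencing error and chimeras,
read-level data, phylogenetic structure, batch effects, zero-inflation
beyond what Dirichlet-multinomial sampling produces, and annotation
ambiguity. Passing tests on synthetic data therefore demonstrate that the
pipeline's arithmetic, statistics and recovery behave as specified under a
known truth — not that any biological conclusion transfers to a particular
real dataset.

`simulate_null_dataset()` provides mutually independent Gaussian features
for calibrating the randomization test's size and the network's chance
edge rate; `simulate_qpcr_dataset()` provides two-group Ct panels with an
optional planted fold change for power analysis.

# Compositional closure

Relative abundances sum to one, so a genuinely blooming taxon mechanically
depresses every other taxon's relative abundance. Two consequences are
worth knowing. First, plain Pearson networks on relative abundances can
contain closure-induced edges among high-abundance features; the planted
biomarker scenarios in the acceptance suite therefore use low-abundance
(1–5%) phylotypes, where closure is negligible — also the biologically
sensible case for bloomer biomarkers. Second, compositionally aware
estimators (SparCC-type, proportionality) exist precisely for this reason;
they are out of scope here because the reconstructed method uses plain
Pearson, but the network module's surface would accommodate them.

# Numerical and procedural conventions

* Every stochastic step takes an explicit integer seed; the pipeline
  config refuses to run without a master seed, and `run_pipeline()` writes
  a YAML report with the fully resolved configuration and MD5 hashes of
  every stage output. Identical configs reproduce outputs bit for bit.
* Zero-variance variables are removed (PCA, network assembly) with a
  recorded log entry; constant features have no defined correlation.
* Division contracts are explicit: zero-sum samples are an error in
  `relative_abundance()`, a zero taxon-ratio denominator is flagged
  infinite (not an error), a zero baseline mean yields `NA` percent
  change, and degenerate randomization inputs return p = 1 with a warning.
* Problem sizes in the suite (e.g. 1000 null datasets × 2000 reallocations
  for size calibration; 5–40 replicate cohorts for mean-recovery checks;
  10⁵ Monte-Carlo draws for the null edge probability) were chosen so that
  Monte-Carlo error is small relative to each tolerance.

# Known limitations

* Bray–Curtis + correlation PCA stand in for β-diversity; UniFrac/PCoA
  need a phylogeny the pipeline does not model.
* The randomization test reconstructs the published procedure's interface
  and calibrates its size; bit-level agreement with the original tool is
  not claimed, since its internal statistic is not published.
* The SNK letter display assumes contiguous homogeneous ranges in the
  sorted means (a property of the SNK procedure itself); unequal group
  sizes use the harmonic-style standard error, the usual extension.
* Networks are plain Pearson on log-normalized data: compositional and
  indirect-correlation artefacts are inherited from the method by design.
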