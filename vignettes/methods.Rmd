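---
title: "Methods: models, parameters and design choices in beescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in beescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beescape)
```

# Scope

`beescape` implements a comparative landscape-genomics workflow for wild bee
populations sampled along an urbanisation gradient: variant QC, genetic
diversity and differentiation, landscape regression, genotype–environment
association (GEA), a haplotype-based selection scan, and cross-species
functional convergence. This vignette documents the statistical models, the
parameters that matter, the numerical conventions, and the design decisions
that were genuinely open.

# The filtering ladder

Three presets mirror common practice for whole-genome SNP data from
non-model insects. `initial` keeps biallelic SNPs genotyped in at least half
of the individuals, with Phred site quality ≥ 30 (the boundary is
inclusive), minor allele *count* ≥ 3, and masks genotypes supported by fewer
than 3 reads *before* any site statistic is computed. `strict` (diversity,
structure, differentiation) additionally requires a 95% call rate,
MAF ≥ 0.05, mean depth in [5, 100], removes indels, drops sites whose
observed heterozygosity exceeds 0.6 — a screen against collapsed paralogs,
where reads from two loci stack onto one and produce excess apparent
heterozygosity — and prunes linkage disequilibrium (pairwise r² > 0.5 in
50-SNP windows advanced by 5). `relaxed` (GEA and sweep scans) lowers the
call-rate requirement to 75% and skips LD pruning, since both downstream
methods want dense markers.

The order of the rules is not externally fixed; we apply them in the order
thresholds are conventionally listed (depth masking → indels → QUAL → MAC →
missingness → MAF → mean depth → heterozygosity) and report per-rule removal
counts so order effects are auditable. Masking low-depth genotypes before
computing site statistics is the stricter of the two possible conventions;
it is flagged in the report. Individuals missing more than 50% of genotypes
are removed (strictly greater; an individual at exactly 50% stays).

Relatedness is screened with the KING-robust estimator,
$\hat\varphi_{ij} = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa}(i) + N_{Aa}(j))$,
computed over the sites called in both individuals. The flagging threshold
defaults to φ ≥ 0.177, the conventional second-degree boundary; it is a
parameter because the appropriate cutoff depends on the sampling design
(nest aggregations can legitimately contain close kin).

# Diversity, differentiation, structure

Expected heterozygosity per population is averaged over polymorphic sites
and then adjusted by the fraction of callable sites that are polymorphic,
`adjHe = He × n_polymorphic / n_callable`, which makes values comparable
across datasets whose monomorphic fraction differs. For real data the
callable-site count comes from all-sites VCF accounting; synthetic runs take
it from the generator's truth record, avoiding an all-sites emission.

Pairwise differentiation uses the Weir–Cockerham (1984) variance-components
estimator, combined across loci as θ = Σa / Σ(a+b+c). Percentile 95%
confidence intervals and a one-sided bootstrap p-value P(θ ≤ 0) come from
resampling loci with replacement (1000 replicates by default). The
one-sided orientation is our choice — the scientific question is whether
differentiation exceeds zero — and is documented in the output.

Isolation by distance is a Mantel correlation between linearised FST,
θ/(1−θ), and log great-circle distance (haversine, Earth radius 6371 km);
p-values count permutations with r at least the observed value, with the
+1 correction. For n ≤ 8 an exact enumeration over all n! relabelings is
available and is used as the oracle in the tests.

The cluster search mean-imputes 0/1/2 dosages, reduces them to the
principal components carrying ≥ 90% of variance, runs k-means for
K = 1..K_max with 20 restarts, and scores
BIC(K) = n·ln(WSS/n) + K·ln(n). This penalty is known to overfit when the
number of retained dimensions approaches the number of individuals — our
tests therefore probe it at realistic sizes (tens of individuals, hundreds
of loci), where it cleanly identifies both planted two-cluster structure
and its absence. PCoA is classical metric scaling (double-centring +
eigendecomposition) of Euclidean genotype distances, which for this input
is equivalent to genotype PCA up to scaling.

# Landscape models

The landscape layer regresses diversity (or differentiation) on landscape
covariates: impervious surface cover (the urban-intensity proxy), urban
green space, semi-natural cover and edge density, measured per site in
percent (edge density in m/m²). Collinearity is screened with VIFs
(flag at 5); spatial autocorrelation with Moran's I using inverse-distance
weights (note the engine, `ape::Moran.I`, row-standardises the weight
matrix). Model selection fits every model with at most two predictors
(1 + p + C(p,2) candidates), ranks by AIC, and averages the ΔAIC < 2 set
with Akaike weights. Averaging is *conditional* (each term averaged only
over the models containing it, weights renormalised), with
Burnham–Anderson adjusted standard errors
$SE_j = \sum_m w_m \sqrt{SE_{jm}^2 + (\beta_{jm} - \bar\beta_j)^2}$ and
two-sided normal p-values on z = |β̄|/SE. AIC (not AICc) is the default to
match the workflow being reproduced; AICc is available by flag. WLS weights
for cross-species comparisons are caller-supplied, since no principled
default exists for pairwise-FST responses.

# Genotype–environment association

Analyses run on population allele frequencies; missing genotypes are first
imputed with the most common genotype at each SNP (computed over all
individuals, so an entirely missing population inherits the global mode).

The core model is a latent factor mixed model fitted by ridge-penalised
least squares: Y = X B′ + U V′ + E, with Y the populations × SNPs frequency
matrix, X the standardised environmental variable and K latent factors
absorbing residual structure. The solution is the SVD algorithm of the
ridge LFMM: with X = QΣR′, the latent part is the best rank-K approximation
of D_λ Q′Y, where D_λ shrinks the directions spanned by X
(d = √(λ/(λ+σ²)) on those directions, 1 elsewhere); the environmental
effects then come from the ridge normal equations on Y − UV′. Tests regress
each SNP on [1, X, U] by OLS; z-scores are calibrated by the genomic
inflation factor, `gif = median(z²)/0.456` (0.456 is the median of χ²₁),
and calibrated p-values are `pchisq(z²/gif, 1, lower = FALSE)`. With K = 0
the whole construction reduces to per-SNP simple regression — a degeneracy
the tests assert to 1e-8.

Significance is empirical: the environmental vector is randomly reshuffled
(unconstrained permutations) 1000 times, the *full* model — including
factor re-estimation and recalibration — is refitted each time, and all
null calibrated p-values are pooled. The threshold is the 0.1st percentile
of that pooled distribution. Pooling (rather than per-SNP nulls) is the
variant that produces thresholds of the order 10⁻⁷–10⁻⁶ on genome-scale
data: the calibrated null is strongly sub-uniform in its extreme tail, so
the 0.1st percentile falls far below the naive 0.001. On our ~5000-SNP
null simulations the procedure flags ≈ 0.1% of SNPs, as it should.

The forest-based ranking regresses each SNP's frequencies on the
environment with a 500-tree random forest; the reported importance is the
node-impurity importance weighted by out-of-bag R², with non-positive R²
mapped to zero. With a single environmental axis the cumulative-importance
ranking of the multi-predictor machinery collapses to this per-SNP
quantity. Candidates are the top ⌈1%⌉ of SNPs by importance among SNPs
with positive importance ("top 1%" is read as a SNP count, not an
importance mass; ties at the boundary break by SNP id order). Robust
candidates are the intersection of both methods, tested against a
hypergeometric null.

# The nSL sweep scan

For each focal SNP the phased haplotypes split into ancestral (REF) and
derived (ALT) carriers — REF is *assumed* ancestral, as no outgroup
polarisation is available; only |z| is used downstream, so the convention
is internal. For every within-group haplotype pair, the identity tract
spanning the focal site is the maximal run of agreeing sites containing it,
measured in number of segregating sites, focal site included. SL_A and SL_D
are the group mean tract lengths and nSL = ln(SL_A/SL_D); a sweep around
the derived allele drives nSL negative. Focal sites need ≥ 2 carriers per
allele and MAF ≥ 0.05.

Tracts are truncated at contig ends. A focal SNP is dropped when more than
5% of either group's tracts are truncated — the pairwise analogue of a
haplotype scan skipping loci whose homozygosity has not decayed at a
chromosome edge. (Dropping a locus because a *single* pair among thousands
touches the edge would discard nearly everything on short contigs; the
fraction rule is the defensible middle ground, and the brute-force oracle
in the test suite encodes the same contract.)

Raw nSL depends on allele frequency, so scores are standardised within 100
equal-width derived-allele-frequency bins: z = (nSL − bin mean)/bin SD,
using the moment (n-denominator) standard deviation, as scan normalisation
utilities do. Bins with fewer than two SNPs merge into the nearest occupied
bin (logged on the result). Outliers are |z| ≥ 2; under approximate
normality ≈ 4.6% of SNPs qualify, and our full-scale synthetic scans land
within 2 points of that. Outlier SNPs within 50 kb of each other merge into
candidate sweep regions spanning first to last member (singletons give
width-0 regions).

Overlap between GEA candidates and sweep regions counts candidates within
±10 kb of any region (inclusive bounds). The permutation null reassigns the
candidate labels uniformly at random over the observed SNP positions within
each contig — exactly preserving the SNP position set, per-contig SNP
density, and per-contig candidate counts — and p = (#{k* ≥ k}+1)/(n+1).

# Functional convergence

Candidate SNPs map to genes whose intervals (0-based half-open on disk)
intersect ±10 kb windows around the SNPs. GO enrichment uses the elim
algorithm: terms are processed leaves-to-root; each term gets a one-sided
Fisher exact test on propagated annotations minus genes already eliminated
at that term; when a term is significant below the elimination cutoff, its
genes are removed from all ancestors before those are tested. The
elimination cutoff defaults to 0.01 (the algorithm's customary default, and
deliberately distinct from the 0.05 reporting threshold); terms with fewer
than 5 annotated background genes are skipped. With the cutoff at 0 the
procedure equals the classic term-by-term Fisher test exactly — a test in
the suite.

Cross-species overlap is hypergeometric over an explicit orthologous-pair
universe. We replace sequence-alignment-based region matching with an
orthology-table input: the downstream statistics need only the mapping, and
the table's provenance (alignment, synteny, curated orthologs) is the
caller's concern. The universe parameter is exposed rather than guessed,
because "shared regions between species" admits several readings.

Semantic similarity uses the Wang measure (edge weights 0.8 for `is_a`, 0.6
for `part_of` — the measure's standard constants, configurable), combined
across term sets with best-match averaging per ontology, and ontology
values averaged into one score. The convergence permutation test draws term
sets of matching per-ontology sizes uniformly from the shared universe
(10,000 permutations by default); pairwise similarities over the universe
are cached once, so the permutations are lookups.

# The synthetic-data generator

The generator emulates the study design the package targets: 10 populations
of 7 diploid females sampled along an impervious-cover gradient, multiple
contigs, weak background structure, clinal loci, and soft-sweep-like loci.
Specifics:

* **Environment.** Impervious cover is evenly spaced across `env_range`
  (default 5–70% — the empirical per-site range is not reported, so this is
  a fixed design choice spanning city centre to outskirts) and jittered by
  up to a quarter of the spacing; correlated urban-green, semi-natural and
  edge-density covariates are added with realistic signs.
* **Neutral loci.** Ancestral frequencies from Beta(0.8, 0.8) truncated to
  [0.05, 0.95]; population frequencies from the Balding–Nichols beta model
  at background FST 0.02, matching the weak differentiation of the target
  system. Frequencies are simulated directly rather than through a
  coalescent because every downstream statistic consumes frequencies and
  haplotype tracts, not genealogies.
* **Clinal loci.** Population frequency
  p_k = clamp(p₀ + effect·z_k, 0.01, 0.99) with z_k the standardised
  environment; default effect 0.4 per SD.
* **Sweep loci.** Each haplotype carries the derived allele with
  probability `sweep_freq` (default 0.4); all carriers then receive one
  donor haplotype copied over `sweep_halo_bp` (default 100 kb) around the
  focal site. This haplotype-copying construction produces exactly the
  SL asymmetry the scan detects at negligible cost, instead of forward
  simulation of selection. Focal sites are placed so the halo fits inside
  the contig: a clipped halo leaves every derived tract truncated at the
  contig end, making the planted sweep undetectable by construction and
  the run uninformative.
* **Plumbing.** SNP positions uniform per contig (duplicates dropped),
  depth Poisson(15) matching typical re-sequencing depth, GQ near 45,
  genotypes missing independently at 2%.

What the generator does *not* emulate: recombination-map heterogeneity,
demographic history (bottlenecks, expansions), linked background selection,
sequencing-error structure, and reference bias. Passing tests therefore
demonstrate that the statistics behave as designed under their own
assumptions — calibration under the null, recovery of planted signal —
not that real urban bee data will show such signal.

# Problem sizes and numerical conventions

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the distributional claims are
meaningful: ~5000 SNPs for GEA calibration (1000 environment permutations)
and candidate recovery (200 permutations per seed across seeded
replicates), ~4000-SNP haplotype scans for the outlier-share check, ten
seeded replicates for sweep recovery, and enumeration-scale fixtures
(≤ 12 haplotypes × 40 SNPs; ≤ 30 GO terms) wherever a brute-force oracle
defines the contract. Quantile computations use R's default type-7;
the Mantel and permutation p-values all use the (count+1)/(n+1)
convention; ties in candidate ranking break by SNP id order; all
stochastic stages take explicit seeds and are bit-reproducible.

# Known limitations

* The ridge LFMM tests use the estimated factors as if known; with very
  few populations the GIF calibration absorbs most, but not all, of the
  optimism. The empirical permutation threshold is the primary control.
* Per-SNP forests with one predictor are a deliberately reduced reading of
  gradient-forest importance; multi-predictor turnover curves are out of
  scope.
* The k-means BIC is a scoring heuristic; at near-degenerate sizes
  (individuals ≈ retained PCs) it can overfit, which is why K grids should
  stay small relative to sample size.
* The sweep scan assumes correct phase; no statistical phasing is
  implemented, and phase errors shorten apparent tracts symmetrically.
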