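---
title: "Models and methods in camelroutes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in camelroutes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

camelroutes implements a complete inference chain for reduced-representation
(ddRAD) SNP surveys of population structure and effective migration in
dromedaries: hybrid screening, PLINK-style quality control, diversity and
differentiation statistics, model-based ancestry, Bayesian FST-outlier
scanning, effective-migration-surface estimation, and the preparation of
calibrated multi-locus inputs for Extended Bayesian Skyline demography.
This vignette explains each model, its assumptions, and the numerical and
design choices behind the implementation. Every empirical claim below is a
property the package's test suite or `scripts/acceptance.R` computes; none
is quoted from elsewhere.

## The synthetic cohort generators

All downstream stages are validated against data simulated with known
ground truth, so the generators are first-class, tested code.

**Island model (`simulate_island_genotypes`).** K populations diverge from
a shared ancestral pool under the Balding–Nichols model: a SNP's ancestral
frequency is uniform on `maf_range` (default 0.05–0.5), each population's
frequency is Beta-distributed with mean p and variance `F p (1 - p)`, and
diploid genotypes are binomial. The single parameter `F` is the expected
Wright fixation index between the populations, which is what makes the
model the right oracle for FST-estimator recovery: at 5,000 SNPs and two
populations of 200 the multi-locus Weir–Cockerham estimate lands within
±0.02 of the target for F between 0.01 and 0.1. `F = 0` short-circuits the
Beta draw (its parameterization would divide by zero) and gives identical
frequencies. After genotype draws every SNP is re-oriented to its realized
minor allele, so the written PED/MAP files read back to an identical
matrix. Missingness is uniform at random — per entry
(`geno_missing_rate`) and per individual (`ind_missing_rate`) — because
no structured missingness mechanism is part of the study design; tests
that need specific QC violations plant them explicitly.

The generator does *not* emulate linkage disequilibrium, inbreeding, or a
skewed site-frequency spectrum: its uniform ancestral spectrum yields a
mean expected heterozygosity around 0.36, higher than typical empirical
ddRAD panels (~0.27), and its AMOVA within-individual share is near 99%
rather than the mid-90s seen with real inbreeding. Passing tests therefore
demonstrate estimator correctness under the model's assumptions, not
robustness to those real-data features.

**Spatial model (`simulate_grid_genotypes`).** Latent per-deme logit
allele frequencies are one draw of a Gaussian Markov random field whose
precision is the migration-weighted graph Laplacian of the deme grid plus
a diagonal `1/q`: high migration couples neighbouring demes, the `1/q`
term bounds marginal variance. Logistic transform and binomial sampling
produce genotypes. Two properties matter and are tested: dissimilarity
grows with graph distance (faster under low migration), and a low-m band
raises cross-band dissimilarity relative to same-side pairs at equal graph
distance. One subtlety found during development and documented here
because it constrains fixture design: the GMRF's latent dissimilarity is a
*damped* resistance — it saturates near `2q` — so it approximates the pure
resistance distance the inference stage assumes only while resistances are
well below `q`. Fixtures therefore use migration rates large relative to
`1/q`; in that regime the latent deme dissimilarity is numerically
indistinguishable from a scaled resistance distance (correlation ≈ 0.999
in the development checks reproduced by the test suite's barrier
property).

**Read-assignment simulator (`simulate_read_assignments`).** Total mapped
reads per individual are Poisson (default mean 1e5 — the study design
does not fix a depth, so the default is an arbitrary but realistic HiSeq
ddRAD yield); the count assigned to the alternate (Bactrian camel)
reference is binomial with fraction `baseline_frac` (default 1%, a small
cross-mapping rate) or `hybrid_frac` for designated hybrids (default 20%,
an F1-backcross-scale signal).

**RAD loci (`simulate_rad_loci`).** Per locus: a random 110 bp reference,
a chosen number of segregating sites with both alleles guaranteed present
among the ingroup, IUPAC-coded diploid consensus sequences, and an
outgroup differing from the reference at `Binomial(L, d)` sites. `d` is
divergence from the *reference*; measured ingroup-to-outgroup divergence
additionally includes the polymorphic sites, which mirrors how divergence
is counted on real data.

A single user seed expands into fixed per-component child seeds, so every
generator is bit-reproducible and independent of call order.

## Hybrid screen

The statistic is the percentage of unambiguously mapped reads assigned to
the alternate reference, `100 a / (p + a)`. A sample is flagged when its
percentage is a Tukey far-out value: strictly greater than Q3 + 3 × IQR
computed over all samples jointly. Quartiles use linear interpolation on
order statistics (R type 7, the default of the major scientific stacks);
the quartile convention is reported alongside the threshold so alternate
conventions can be audited. The screen runs on raw counts before genotype
QC, and the flag set is invariant to rescaling all read totals at fixed
fractions. On 200 simulated cohorts of 50 with one planted hybrid at 20×
baseline, sensitivity is 1.0 with a false-flag rate well under 2% — the
binomial noise at 1% cross-mapping and 2 × 10^4 reads is far too small to
reach a far-out threshold.

## Quality-control cascade

Filters apply in the study's order: individual missingness, minor allele
frequency, per-SNP missingness, then relatedness pruning; the report
records every removal, which makes the order auditable (a crafted fixture
in the tests shows the order is observable). Boundary semantics follow
PLINK: "more than" for the missingness filters (exactly 25% is kept),
keep-at-equality for MAF. MAF is computed on non-missing calls only.

The identity-by-state distance between two individuals is one minus the
mean shared-allele fraction `(2 - |g_i - g_j|) / 2` over
pairwise-complete SNPs. Pairs closer than the cutoff (default 0.05,
read as a *distance*: near-duplicates) are pruned greedily, removing the
member with higher missingness (ties: lexicographically later id) until no
pair remains — one removal per duplicate pair, two per triangle. The
cascade is idempotent and monotone in its thresholds (both tested).

## Diversity and differentiation

Observed heterozygosity is the heterozygote fraction among non-missing
calls; expected heterozygosity is the unbiased gene diversity
`(2n/(2n-1)) (1 - p² - q²)`; `FIS = 1 - Ho/He` with He = 0 undefined and
excluded from group means. Group summaries are means ± SD over SNPs.
Allelic richness uses Hurlbert rarefaction to a common allele draw `g`
(default: the smallest group's non-missing allele count); both `AR` (in
[1, 2] for biallelic SNPs) and `AR - 1` are reported, since rescaled
variants of this quantity circulate and values below 1 in the literature
are best read as `AR - 1`. Note the fixed-`g` limit: with `g = 2`, a
balanced SNP tops out at AR = 1.5; AR approaches 2 only as `g` grows.

Between-group differentiation is the Weir–Cockerham (1984) θ with the a,
b, c variance components combined as a ratio of sums over loci;
per-locus components with undefined estimators (fewer than two groups
with data) are skipped, and negative estimates are reported as computed.
Significance comes from permuting individuals between the two groups,
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, 1000 permutations by default.
Pairs with a group below three individuals are skipped and reported.

AMOVA decomposes squared allele differences at three levels (among
populations, among individuals within populations, within individuals),
with sums of squares computed from the `k (n - k) / n` identity for 0/1
allele sets and variance components from the standard moment equations
with allele-count coefficients. The implementation route (pairwise
distances) is checked to 1e-10 against an independent nested-ANOVA
(mean-deviation) computation on small instances. Percentages sum to 100
by construction when the total is positive; a zero total is an error.
Welch's t test is `stats::t.test`, re-exported in tidy form.

## PCA and model-based ancestry

PCA mean-imputes missing genotypes per SNP, centers columns without
variance scaling (the convention under which small leading-axis
percentages like those of genome-wide panels arise), and fixes each
axis's sign by making its largest-magnitude loading positive, so results
are invariant to individual order. Percent variance per axis is its
eigenvalue over the total, summing to 100 across all axes.

The ancestry model maximizes the binomial likelihood of allele counts
given per-individual ancestry fractions Q and per-cluster allele
frequencies F, by EM over the multinomial responsibilities of each of an
individual's two allele draws. The log-likelihood is non-decreasing by
construction (asserted per iteration in tests), K = 1 has the closed-form
solution (Q = 1, F = observed frequencies) reproduced exactly, and three
random starts (best likelihood kept) guard the nested-likelihood property
that the optimum for K is at least that for K - 1. Cluster labels are
arbitrary; comparisons in tests use best-permutation alignment.

The number of clusters is chosen by fivefold cross-validation at the
genotype-entry level: non-missing entries are partitioned into folds,
each fold masked, the model refit, and the error defined as the RMSE
between masked genotypes and their expectation `2 Σ_k q_ik f_kj`. This
masked-prediction RMSE is this package's definition of CV error — it
need not equal other tools' internal definitions, but selects the same K
in the regimes tested: K = 1 on unstructured cohorts and K = 3 on strong
three-population structure in at least 9 of 10 seeds.

## FST-outlier scan

The F-model decomposes each locus-by-group FST on the logistic scale,
`logit(F_ij) = α_i + β_j`, with a locus effect α (selection when
non-zero) and a group effect β (shared drift). Group allele counts follow
a beta-binomial likelihood given the locus's ancestral frequency, with
`θ_ij = 1/F_ij - 1`. A reversible-jump MCMC toggles each α's inclusion
with prior odds for neutrality (default 10:1); the jump proposal is the
α prior itself, so the acceptance ratio reduces to the likelihood ratio
times the prior inclusion odds — a deliberate simplification that keeps
the sampler exact. Ancestral frequencies and included effects move by
vectorized random-walk Metropolis (valid componentwise because the
likelihood factorizes over loci given β); pilot runs tune proposal
scales toward mid-range acceptance.

The q-value of locus i is the mean posterior neutrality probability over
all loci with inclusion probability at least locus i's (ties share a
value); outliers are loci with q below the FDR threshold (default 0.05).
Diagnostics flag a chain whose inclusion probabilities all sit at the
prior. Properties exercised by tests: a planted fixed difference among
999 neutral loci is top-ranked and declared with positive α; a planted
homogenizing locus in a differentiated genome gets negative α; neutral
data yields essentially no declarations; prior odds → ∞ empties the
outlier set; fixed seeds reproduce the scan exactly. Default chain
lengths in the package are desk-scale (a few thousand iterations); they
are smaller than the cited desktop tool's defaults and are documented as
such, with the planted-signal regime insensitive to this choice in the
seeds tested.

Outlier annotation reports every gene whose interval overlaps the closed
window `[max(1, pos - 200000), pos + 200000]` by at least one base,
never crossing scaffolds.

## Effective migration surface

The stepping-stone surface is approximated by an explicit
resistance-distance model: the expected dissimilarity between demes is
the effective resistance on the grid graph (edge conductance = mean of
the incident demes' rates) plus the mean of their within-deme
diversities. Closed forms anchor the tests: a single deme returns q, two
demes return 1/conductance + mean q, a uniform path grows linearly with
hops, and the expectation is monotone decreasing in any single deme's
rate.

Observed dissimilarity is the mean squared genotype difference over
pairwise-complete SNPs, averaged within deme pairs; the Gaussian
likelihood compares its between-deme upper triangle with the model
expectation. Relative to the cited method this implementation makes three
declared simplifications: a Gaussian smoothing prior on neighbouring
demes' log10 rates replaces the Voronoi-tile prior; a Gaussian likelihood
with an estimated noise scale replaces the Wishart; and the noise scale
is profiled — estimated once from the flat-field fit at initialization
and held fixed — rather than sampled. The last choice matters twice
over: sampling the scale couples a slow global mode into the field and
wrecks replicate agreement, while re-estimating it after the field has
absorbed noise understates it and produces overconfident intervals (the
uniform-field coverage test fails both ways; the profiled scheme passes).

The sampler is random-walk Metropolis with four move types per sweep:
single-deme updates, patch moves (a deme and its lattice neighbours
shifted together), moves along the eigenvectors of the smoothing-prior
precision scaled by their prior standard deviations, and global shifts of
the whole field. The global level of log10 m is only weakly identified
(rescaling all rates rescales all resistances), so it carries a broad
prior, is located by a coarse 1-D scan before sampling, and is removed by
normalizing every retained draw to zero mean — zero is the overall mean
migration rate, matching how such surfaces are read. Per-deme diversities
initialize at the observed within-deme dissimilarities. Defaults are
desk-scale: 2,000 sweeps, two chains, burn-in half, smoothing sd 0.35 and
deviation prior sd 1 (in log10 units); the acceptance checks use 8,000 to
10,000 sweeps on 16-deme grids, where two independent chains' per-deme
posterior means correlate above 0.9 and a 20× low-rate band is flagged
as a barrier while uniform data leaves essentially all credible intervals
covering zero. Corridors and barriers are declared at posterior
probability 0.9 (tests use 0.8) of the normalized rate being above or
below zero.

Sample-to-deme assignment uses great-circle distance. The habitat polygon
is user-supplied (ordered lon/lat vertices, auto-closed, orientation
normalized, self-intersections rejected); fixtures use synthetic
rectangles because no real polygon is bundled.

## Demographic preparation

EBSP input selection draws `n` loci uniformly without replacement among
those with 4–6 segregating sites and at least 75% of individuals present.
The locus-specific clock rate is calibrated by counting differences
between each ingroup consensus and the outgroup (IUPAC heterozygotes
count half when one allele matches), dividing by locus length, averaging
within SNP class (4, 5, 6) and then across classes, and dividing by the
split time (default 4.4 million years) times the generation time (default
5 years). Two counting conventions are deliberate: heterozygote
half-counting (the counting rule is not otherwise fixed by the workflow
this mirrors), and *no* halving of divergence between the two lineages —
the calibration divides by the split time alone, following the procedure
it reproduces verbatim; correcting it would change the rate by 2×.
Alignments are exported as one NEXUS DATA block per locus via ape, with a
TSV manifest carrying the calibrated rate; absent individuals are omitted
unless all-missing rows are requested.

## Pipeline

`run_pipeline()` chains the stages in the study's order from a plain YAML
config — hybrid screen, filter cascade, statistics, structure, outlier
scan, migration surface, demographic prep — with each stage consuming the
previous stage's outputs, every table written under the output directory,
and a run report (package version, seed, config, per-stage status and
wall time) sufficient to reproduce the run. Deterministic stages are
bit-identical across reruns with the same config. Problem sizes in the
bundled tests are chosen to keep the whole suite in the minutes range:
cohorts of tens to hundreds of individuals, hundreds to thousands of
SNPs, 16-deme grids.
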