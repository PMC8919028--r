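---
title: "Community-state dynamics and assembly processes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-state dynamics and assembly processes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commstate)
```

`commstate` analyzes longitudinal, multi-body-site 16S amplicon data from
low-diversity host environments — its motivating setting is the gut, oral
cavity and skin of extremely low birthweight infants (ELBWI, birth weight
< 1000 g) sampled repeatedly over their first weeks in intensive care. This
vignette explains the models the package implements, the assumptions they
make, the tunable parameters that matter, and what the bundled synthetic
cohort generator does and does not emulate.

## The analysis model

The pipeline treats a cohort as a set of patient-site time series of ASV
(amplicon sequence variant) count vectors and proceeds in five stages.

**Pre-processing.** Negative-control-informed contaminant removal applies
three rules in order: genera with more than `read_threshold` (default 10)
reads in pooled negative controls; genera whose genus-aggregated
relative-abundance profile across all samples has Pearson r above
`r_threshold` (default 0.9) with a rule-one genus; and an explicit reagent
contaminant list. Correlation is computed on relative abundances — the rule
is meant to catch taxa that co-vary with reagent load, and raw counts would
confound that with library size. Unassigned genera (`g__unclassified`) are
exempt from the correlation rule, because that bucket aggregates all unknown
taxa and removing it wholesale would discard genuine signal. Run-level
cross-contamination cannot be inferred from a single dataset, so it is
supported only as an explicit ASV exclusion list. Tables are then rarefied
to `depth` reads per sample (default 600) by multivariate hypergeometric
subsampling without replacement; shallower samples are dropped and logged,
and Good's coverage (1 − singletons/reads) is reported per sample so users
can confirm the depth does not underestimate richness.

**Community states.** Samples are clustered on Bray–Curtis dissimilarities.
k-means cannot consume a dissimilarity matrix directly, so the package runs
it in full principal-coordinates space (all positive-eigenvalue axes), with
PAM on the dissimilarity matrix available via `method = "pam"`; with
well-separated states both give the same partition. The number of states is
chosen by maximizing the mean silhouette width (computed on the original
dissimilarities, never the embedding), with the Calinski–Harabasz criterion
(which needs coordinates) breaking ties. Clusters are named after their
dominant taxon: if the top ASV's in-cluster mean relative abundance reaches
`dominance` (default 0.4), the state is named by the genus initial plus "C"
(SC for a *Staphylococcus*-dominated state, EC for *Escherichia/Shigella*,
LC for *Lactobacillus*); otherwise it is the mixed "IC" state. The 0.4
threshold sits well below mono-dominated cluster means (≈0.6–0.9) and well
above what a genuinely even community can give its top taxon.

**Markov dynamics.** Within each body site, each patient's state sequence is
treated as a realization of a site-level first-order Markov chain: the next
community state depends only on the current one. This memorylessness is a
modeling assumption justified by the frequent disturbances (antibiotics,
ventilation, handling) these patients experience. Sampling occasions are
treated as equally spaced steps even though nominal days are 1/3/7/14 —
transitions are per occasion, not per day, and the nominal day is kept as
metadata only. Transition counts are pooled across patients within a site,
which is the maximum-likelihood estimate of a shared site chain; per-patient
count matrices are retained for inspection. States with no observed
departures get uniform rows with a loud warning so the stationary
distribution stays computable. Stationary frequencies solve πP = π (one
extremal solution per closed communicating class, found via strongly
connected components of the positive-transition digraph), and states are
recurrent exactly when they lie in a closed class. Stationary solutions are
verified internally against a residual bound of 1e-10.

**Cross-site colonization.** For each ASV and ordered site pair, the package
estimates the probability of detection (count > 0 after rarefaction) at one
site given detection at another, over occasions matched on patient and time
point. The estimate is computed twice — directly and through Bayes' rule
P(s1|s2) = P(s2|s1)P(s1)/P(s2) — and the two are asserted equal to machine
precision. ASVs never detected at the conditioning site are reported missing
rather than zero. Aggregates over ASVs are unweighted by default; an
abundance-weighted variant is available because the right weighting is a
judgment call.

**Assembly processes.** Pairwise turnover within each body site is
partitioned into the five standard categories. βMNTD (abundance-weighted by
default) measures the mean phylogenetic distance of each taxon to its
nearest neighbor in the paired community; its standardized effect size
against a null that shuffles the ASV-to-tip mapping across the whole tree
(999 replicates, one shared permutation per replicate across all pairs) is
βNTI. |βNTI| > 2 flags deterministic turnover (variable selection above +2,
homogeneous selection below −2). Stochastic pairs are split by the
Raup–Crick index on Bray–Curtis: each community is probabilistically
reassembled preserving its richness and depth — species drawn by
metacommunity occupancy, each seeded with one read, remaining reads
distributed by metacommunity relative abundance — and
RC = 2·((#null < obs) + ½·ties)/n_null − 1. RC > 0.95 indicates dispersal
limitation, RC < −0.95 homogenizing dispersal, |RC| ≤ 0.95 drift. Ties count
half so the index is centered under its own null; within a replicate, null
reassemblies are shared across pairs, the usual metacommunity-null
construction (it leaves each pair's RC distribution unchanged and makes the
computation linear rather than quadratic in pairs per replicate). Both null
loops are implemented in compiled code driven by R's RNG, so results are
reproducible from the seed. Per-site chi-square tests compare process
composition across sites on pair counts, and per-state odds ratios
(deterministic pairs × pairs involving the state, with Haldane–Anscombe 0.5
correction on zero cells and log-normal 95% CIs) attribute deterministic
turnover to community states. "Involving" means the state appears at either
endpoint by default; a both-endpoints variant is a flag.

**Co-occurrence networks.** Per community state, Spearman correlations
(average ranks on ties) among ASVs present in at least `min_prevalence`
(default 2) of the state's samples are tested against a null that shuffles
each ASV's abundances across samples independently, 1000 times; per-pair
p-values use the +1 rule and are BH-corrected. The retention threshold
(default 0.01) can be applied to adjusted values (default) or raw p-values —
both readings of the usual practice are supported because published
descriptions are often ambiguous on this point.

Throughout, permutation p-values include the observed statistic in numerator
and denominator, p = (1 + #{T_perm ≥ T_obs})/(n_perm + 1), so p = 0 is
impossible and validity holds at finite permutation counts. PERMANOVA is
single-factor (marginal fits per variable), with permutations optionally
restricted to blocks — labels are shuffled within each patient only, which
is the correct exchangeability unit for repeated measures. `envfit`-style
fits use the first two ordination axes by default (a flag raises this);
axis count is a presentation choice, not a statistical one.

## The synthetic cohort generator

The generator exists so every downstream stage can be validated against
known truth. Its defaults encode the study design it emulates: 15 patients ×
3 body sites × 4 occasions (nominal days 1, 3, 7, 14), 300 ASVs, four latent
states — SC, EC, LC with dominant-ASV Dirichlet means 0.61, 0.60 and 0.91,
and a high-evenness IC — and per-site transition matrices calibrated, before
any testing, to the qualitative site dynamics the package is designed to
detect: a stable gut (mean self-transition 0.62, EC/LC/IC sticky, SC
near-uniform), an oral cavity with a stable SC, elevated IC→SC flow and LC
leaving only toward EC or IC, and a volatile skin (mean self-transition
≈ 0.22) funneling toward SC with a stationary SC frequency of ≈ 0.70.

Counts are Dirichlet-multinomial: a state's mean profile spreads its
non-dominant mass geometrically over satellite ASVs, and the per-state
concentration parameters (100/100/200/120 for SC/EC/LC/IC) were fixed at
design time so that clusters are as well-supported as in the kind of cohort
emulated (mean silhouette roughly 0.5–0.6 at 600-read depth); the
concentrations control within-state compositional noise, not the state
means, so dominant-ASV means stay at their configured values regardless.
Library sizes are negative-binomial (mean 2000, dispersion 4) truncated at
650 so that, after contaminant removal, default rarefaction at 600 drops
nothing; setting `min = 0` deliberately produces droppable samples for
testing. Contamination is injected at genus level with one shared rate per
genus scaling both expected pooled negative-control reads and the relative
abundance added to real samples, modulated by a per-sample lognormal
"reagent load" common to all contaminant genera — that shared factor is what
makes the correlation-removal rule exercisable. Default rates (45, 28, 16,
7, 4) straddle the 10-read threshold on purpose. Planted ASV pairs share a
mean-one lognormal factor per sample, giving strong monotone coupling
(Spearman ρ ≳ 0.9) without biasing mean abundances. The phylogeny is a
birth–death tree over all emitted ASVs (contaminants included, as an
inferred tree over observed sequences would be); `habitat_signal` s ∈ [0, 1]
interpolates between a fully exchangeable ASV-to-tip assignment (s = 0, the
null-calibration regime) and state-affiliated taxa clustered into clades
(s = 1). Because satellite taxa have weak state affinity, intermediate
signal mostly structures the dominant ASVs; the generator is not intended as
a faithful model of phylogenetic habitat conservatism.

One master seed drives everything through named sub-streams
(`substream_seed()`, a Lehmer-multiplier derivation), so stages are
independently reproducible and two runs with one seed are byte-identical.

What the generator does *not* emulate: read-level error, chimeras, or PCR
bias; compositional correlation induced by sequencing itself; strain-level
dynamics; irregular or missing sampling; covariate-dependent transitions
(clinical covariates are generated as plausible decoration, uncorrelated
with community structure). Tests passing on synthetic cohorts therefore
demonstrate correctness of the estimators and calibration of the null
models — not that real neonatal microbiomes satisfy the generative
assumptions.

## Numerical choices and degenerate inputs

- Stationary distributions are solved by least squares on the augmented
  system (πᵀ(P − I) = 0, Σπ = 1) per closed class; residuals above 1e-10
  are an internal error, and tiny negative components (< 1e-12) are clipped.
- βNTI with zero null standard deviation is 0 when the observed βMNTD
  equals the null exactly (e.g. a star phylogeny, where tip shuffling is a
  no-op) and missing otherwise; missing pairs are counted and excluded from
  partitions.
- Bray–Curtis on an all-zero sample, clustering on an all-zero distance
  matrix, correlation on a constant ASV, and conditional probabilities with
  an undetected conditioning ASV are all refused or reported missing rather
  than silently coerced.
- k-means uses `n_init` restarts (default 100) with the best
  within-cluster sum of squares; PAM is deterministic given the seed. Tie
  handling in Spearman uses average ranks.
- Rarefaction requires an explicit seed; the pipeline logs every stage's
  derived seed in its run report.

## Problem sizes and defaults

The package defaults — 999 null replicates for βNTI/RC, 1000 permutations
for PERMANOVA/envfit/networks, rarefaction depth 600 — follow the
conventions of the frameworks these methods come from. On the default
synthetic cohort (180 samples, ~5300 within-site pairs, 305 ASVs) a full
pipeline run takes well under a minute on one core, with the βNTI and
Raup–Crick null models dominating. The test suite validates statistical
calibration at reduced sizes (99–999 permutations, hundreds of replicates)
chosen so each property is tested with meaningful Monte-Carlo resolution;
the calibration checks for βNTI pool pairs across several independently
generated cohorts because all pairs within one cohort share a single
realized tip assignment, making the single-cohort mean a noisy estimate of
the null center.

## Known limitations

- Pooling transitions across patients assumes a shared site-level chain;
  patient heterogeneity shows up only in the retained per-patient count
  matrices, not in the pooled estimates.
- The discrete-occasion Markov model ignores unequal real-time intervals;
  transition probabilities are per occasion and not comparable across
  designs with different sampling grids.
- The βNTI null shuffles tips across the whole tree; alternative nulls
  (within-clade shuffles, abundance-constrained swaps) are not implemented.
- Conditional detection matches occasions at the same time index only
  (an any-time variant is a flag) and treats detection as binary at the
  rarefied depth, so rare-taxon conditional probabilities are
  depth-dependent.
- The co-occurrence null preserves each ASV's marginal distribution but not
  compositional closure; for strongly compositional data a log-ratio-aware
  method would be more appropriate.
- The Raup–Crick reassembly null is not the same stochastic process as
  multinomial resampling of a shared community profile: at a 600-read depth
  its one-read seeding per drawn species and occupancy-weighted species
  selection give presence patterns with different variance than multinomial
  sampling, so RC computed on data that are merely iid multinomial draws
  from one profile concentrates near ±1 rather than spreading over the
  interval. RC answers "does this pair share species as expected under the
  reassembly null", not "was the data multinomial". The package's
  calibration tests therefore check self-consistency against the null's own
  generative process (communities regenerated by the reassembly scheme at a
  fixed point of its metacommunity statistics), where RC is near-uniform.
  Interpretations of |RC| ≤ 0.95 as "drift" inherit this null-model
  definition of chance.
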