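# commstate

Community-state dynamics and ecological assembly processes for
longitudinal, multi-body-site microbiome cohorts.

## The problem

In hospitalized preterm neonates — and in many other host environments —
microbial communities are low-diversity, volatile, and sampled repeatedly
at several body sites (gut, oral cavity, skin). Two questions dominate:
*what discrete compositional states do these communities occupy and how do
they move between them*, and *which ecological processes (selection,
dispersal, drift) drive the turnover*? `commstate` implements a coherent
pipeline for both, for anyone with an ASV count table, sample metadata and
a rooted phylogeny.

The core models:

- **Community states.** Samples are clustered on Bray–Curtis
  dissimilarities (k-means in full PCoA space or PAM), with the number of
  states chosen by mean silhouette width and the Calinski–Harabasz
  criterion, and states named by their dominant genus (e.g. SC =
  *Staphylococcus*-dominated, IC = mixed).
- **Markov dynamics.** Per body site, state sequences are modeled as a
  first-order Markov chain: transition matrix **P** estimated from pooled
  patient series, stationary frequencies **π** solving **πP = π**, and
  recurrent/transient classification from the closed communicating classes.
- **Cross-site colonization.** Conditional detection probabilities
  P(s₁|s₂) = P(s₂|s₁)·P(s₁)/P(s₂) per ASV and ordered site pair, matched on
  patient and occasion.
- **Assembly processes.** βMNTD/βNTI against a tip-shuffling phylogenetic
  null and Raup–Crick on Bray–Curtis under a richness- and
  abundance-preserving reassembly null, partitioned by the standard
  thresholds: βNTI > +2 variable selection, βNTI < −2 homogeneous
  selection, then RC > 0.95 dispersal limitation, RC < −0.95 homogenizing
  dispersal, |RC| ≤ 0.95 drift; plus per-state odds ratios for contribution
  to deterministic turnover.
- **Supporting statistics.** Contaminant filtering against negative
  controls, rarefaction, Good's coverage, alpha diversity,
  restricted-permutation PERMANOVA and ordination fitting, and
  permutation-null Spearman co-occurrence networks with BH correction.

A fully seeded synthetic cohort generator (`generate_cohort()`) with known
latent states, transition matrices, phylogeny, planted correlations and
contamination provides ground truth for every stage.

## Worked example

```r
library(commstate)

cohort <- generate_cohort(synth_config(seed = 7))
filt   <- filter_contaminants(cohort$counts,
                              neg_controls = cohort$truth$negative_controls)
rare   <- rarefy(filt$table, depth = 600, seed = 7)

d   <- bray_curtis(rare)
sel <- select_k(d, k_range = 2:8, seed = 7, n_init = 50)
sel$k
#> [1] 4

states <- assign_states(d, rare, k = sel$k, seed = 7, n_init = 50)
states
#> Community-state assignment: k = 4 (kmeans)
#>   mean silhouette = 0.560, Calinski-Harabasz = 165.0
#> # A tibble: 4 x 6
#>   state cluster     n dominant_asv dominant_genus       dominant_mean
#>   <chr>   <int> <int> <chr>        <chr>                        <dbl>
#> 1 EC          1    44 ASV_1        Escherichia/Shigella         0.599
#> 2 LC          2    29 ASV_2        Lactobacillus                0.915
#> 3 IC          3    39 ASV_1        Escherichia/Shigella         0.185
#> 4 SC          4    68 ASV_3        Staphylococcus               0.606

gut <- estimate_transitions(states, cohort$metadata, site = "gut")
glance(gut)[, c("mean_self_transition", "pi_SC", "pi_EC", "pi_LC", "pi_IC")]
#> # A tibble: 1 x 5
#>   mean_self_transition  pi_SC pi_EC pi_LC pi_IC
#>                  <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1                0.534 0.0412 0.412 0.392 0.155
```

The four recovered states are the three mono-dominated community types
(each named by its dominant genus, whose in-cluster means sit near the
configured 0.60/0.60/0.91) and the mixed IC state. The gut model's mean
self-transition (0.53 from this 45-step sample) says gut communities tend
to stay in their state from one occasion to the next, and `pi_*` are the
long-run state frequencies implied by the fitted chain.

Assembly processes on the same cohort:

```r
pairs <- turnover_pairs(rare, cohort$metadata, within_site = TRUE)
turn  <- beta_nti(rare, cohort$truth$tree, pairs, n_null = 999, seed = 7)
turn  <- raup_crick_bray(rare, turn, n_null = 999, seed = 8)
part  <- partition_processes(annotate_states(turn, states), by = "body_site")
autoplot(part)   # stacked process fractions per site
```

Or run everything at once, with per-stage TSV outputs and a JSON run
report:

```r
res <- run_pipeline(pipeline_config(seed = 7, outdir = "out"))
```

A thin command-line wrapper is installed at
`system.file("cli", "commstate", package = "commstate")` with subcommands
`simulate`, `preprocess`, `diversity`, `states`, `markov`, `processes`,
`networks`, and `run`.

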