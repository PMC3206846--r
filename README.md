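# symprofiler

Profiling of host-associated bacterial communities from 16S rRNA gene
data: replicated clone libraries, T-RFLP fingerprints, and the bridge
between them.

## What it does, and for whom

Microbial ecologists studying symbionts of marine invertebrates (sponges,
tunicates) classically combine small replicated clone libraries — which
identify phylotypes — with terminal restriction fragment length
polymorphism (T-RFLP) profiles, which scale cheaply to many samples but
report only fragment sizes. This package implements that complete
workflow:

* **Clone libraries** — greedy-centroid OTU clustering at 99% global
  alignment identity (`cluster_otus`), sample × OTU tables, alpha
  diversity (S_obs, Chao1, Shannon H′, evenness J), analytic rarefaction,
  and likelihood-ratio G tests on taxonomic composition.
* **In-silico digestion** — predicted 5′-terminal fragments per phylotype
  for HaeIII, MspI and RsaI (`build_reference_db`), with a 100–500 bp
  detection window.
* **T-RFLP processing** — variable-percentage-threshold standardization
  of raw peak profiles (`variable_threshold_standardize`) and greedy
  running-mean alignment of T-RFs across samples (`align_trfs`,
  0.5 bp window).
* **Matching** — empirical T-RFs matched to predictions under
  size-dependent tolerance bins (1.0 bp ≤ 200 bp, 1.5 bp for 201–400 bp,
  4.0 bp > 400 bp), per-phylotype T-RFLP signatures and their resolution
  classes (`match_trfs`, `build_signatures`).
* **Community statistics** — Bray–Curtis with square-root transform,
  non-metric MDS (Kruskal stress-1), ANOSIM
  (R = (r̄_B − r̄_W)/(M/2), permutation p), with pairwise
  Bonferroni-corrected post-hocs.
* **Phylogenetic metrics** — Tajima–Nei (1984) distances, AMOVA
  (hierarchical F_ST with sample-level permutation), LIBSHUFF coverage
  statistics (ΔC = Σ (C_X − C_XY)²), the parsimony P-test (Fitch/Hartigan),
  and NRI/NTI against a tip-shuffle null.
* **Symbiont classification** — host-exclusive OTUs with ≤ 98% identity
  to free-living references are specialists (dominant / common / rare by
  prevalence and abundance); seawater-shared or environment-like OTUs are
  generalists (`classify_all`).
* **Synthetic data** — a generator (`simulate_community`,
  `simulate_sequences`, `simulate_electropherograms`, `simulate_tree`,
  `simulate_dataset`) reproducing the study design the statistics assume:
  4 sources with 9/3/3/9 replicate samples, 15 clones each, planted
  dominant host-specific phylotypes, a seawater-shared generalist pool,
  singleton-rich tails, and electropherograms with size-dependent
  systematic T-RF drift plus baseline noise.

See the methods vignette (`vignettes/community-profiling.Rmd`) for the
models, parameter defaults and design rationale.

## Worked example

Simulate a full study and run the pipeline end to end:

```r
library(symprofiler)

p   <- simulation_params()                      # 9/3/3/9 design, 15 clones
com <- simulate_community(p, seed = 42)
sq  <- simulate_sequences(com, p, seed = 42)
pk  <- simulate_electropherograms(build_reference_db(sq$ancestors),
                                  com, p, seed = 42)

res <- profile_communities(sq$clones, sq$sample_of,
                           com$table$metadata, pk)
res$clustering
#> OTU clustering: 360 sequences -> 104 OTUs at 99 % identity
res$db
#> Reference T-RF database: 104 phylotypes x 3 enzymes
#> Detection window: 100 - 500 bp  primer offset: 0 bp
#>  enzyme n_in_window frac_in_window
#>  HaeIII          77      0.7403846
#>    MspI          76      0.7307692
#>    RsaI          73      0.7019231
#> In-window for >=1 enzyme: 99 of 104 (95.2%)
res$signatures
#> T-RFLP signatures for 104 phylotypes:
#>   unique      98 (94.2%)
#>   shared       0 (0.0%)
#>   undetected   6 (5.8%)

classify_all(res$table)
#> Symbiont classification
#>   Hymeniacidon : dominant specialist 1 (40.7% of clones); common specialist 10 (38.5% ...
#>   Haliclona    : dominant specialist 1 (64.4% of clones); ...
#>   Didemnum     : dominant specialist 0 (0.0% of clones); ...

src <- com$table$metadata$source
rel <- t(res$table$counts) / colSums(res$table$counts)
anosim(bray_curtis(rel, "sqrt"), src, n_perm = 999, seed = 42)
#> ANOSIM: R = 0.942, P = 0.001 (999 permutations)
nmds(bray_curtis(rel, "sqrt"), seed = 42)
#> NMDS: 24 samples, k = 2, stress = 0.1282 (excellent)
```

Reading: the 360 simulated clones cluster into 104 phylotypes; about
three quarters carry an in-window predicted fragment per enzyme and 95%
for at least one enzyme; each sponge host carries exactly one dominant
specialist (the tunicate none, by design); and community structure
separates the four sources almost perfectly (ANOSIM R near 1 at the
smallest attainable p), with a trustworthy 2-d ordination (stress below
0.15).

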