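---
title: "Profiling host-associated bacterial communities: clone libraries and T-RFLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling host-associated bacterial communities: clone libraries and T-RFLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symprofiler)
```

## The problem

Marine sponges and other benthic invertebrates host bacterial consortia
that can be dense, diverse and highly host-specific. Characterizing such
communities classically combines two data types:

* **replicated 16S rRNA clone libraries** — a modest number of sequenced
  clones (here 15 per sample) from each of several replicate samples per
  source (host species or ambient seawater), clustered into phylotypes
  (OTUs) at a 99% identity threshold; and
* **T-RFLP fingerprints** — community profiles obtained by digesting
  fluorescently end-labeled 16S amplicons with restriction enzymes and
  sizing the labeled terminal fragment (T-RF) of every template on a
  capillary sequencer.

Clone libraries identify *who* is there; T-RFLP scales to many samples but
only yields fragment sizes. The workflow implemented here connects the
two: it predicts each phylotype's T-RF per enzyme by in-silico digestion,
matches empirical fragments to those predictions under size-dependent
tolerances, and quantifies how much of the community each technique
resolves. Around that core sit the community statistics used to compare
sources: alpha diversity, rarefaction, Bray-Curtis/NMDS/ANOSIM, G tests on
taxonomic composition, phylogenetic dispersion and distance-based variance
analyses, and a rule-based classification of symbionts as host specialists
or generalists.

## Clone-library analysis

**OTU clustering.** `cluster_otus()` uses greedy centroid clustering:
sequences are dereplicated, ordered by decreasing duplicate abundance
(ties lexicographic by id), and each joins the first centroid with global
alignment identity at or above the threshold (default 0.99), else founds a
new OTU. Identity is computed from a Needleman-Wunsch alignment (match 1,
mismatch 0, linear gap −1) as matching columns over aligned columns, with
terminal gap columns excluded — clone sequences are uniformly trimmed, so
end overhangs carry no signal — and internal gaps counted as mismatches.
The greedy-centroid choice makes the procedure deterministic and is the
standard de novo approach; assembly-style tools can group slightly
differently, so absolute OTU counts are comparable only within a pipeline.

**Alpha diversity.** `alpha_diversity()` reports observed richness,
Shannon H′ (natural log), Pielou evenness J = H′/ln S, and Chao1 in the
classic form S + F1²/(2 F2), falling back to the bias-corrected
S + F1(F1−1)/(2(F2+1)) when no doubletons exist. `rarefaction_curve()` is
the analytic hypergeometric expectation, not a resampling average.

**Composition tests.** `gtest_independence()` is the likelihood-ratio
(G) test on source × taxon count tables; `taxonomic_bias_gtest()` is its
goodness-of-fit form for comparing taxa recovered by fingerprinting
against the full library (expected frequencies from library proportions,
df = categories − 1).

## In-silico digestion

`build_reference_db()` predicts, for every OTU representative and enzyme
(built-ins HaeIII GG^CC, MspI C^CGG, RsaI GT^AC), the labeled-fragment
length: (first site position − 1) + bases of the site retained 5′ of the
cut + an optional `primer_offset` reconciling trimmed sequences with the
labeled-primer coordinate frame (default 0). Degenerate IUPAC codes
expand in the *recognition* sequence but never match in the *scanned*
sequence (an N could otherwise fabricate sites). Only fragments inside
the accurate sizing range — 100–500 bp, both ends inclusive — are
considered detectable. All three built-in sites are palindromic, so a
sense-strand scan is sufficient; non-palindromic custom enzymes trigger a
dual-strand search.

## T-RFLP processing

**Standardization.** Electropherograms carry baseline noise whose peak
count scales with loaded DNA. `variable_threshold_standardize()` removes
it with a percentage-of-total-fluorescence threshold applied iteratively
to a fixed point per profile, scanning a grid of percentages (default 0
to 5% in 0.01% steps) and keeping the smallest at which retained peak
count no longer correlates with total fluorescence (two-sided Pearson
test, α = 0.05; an undefined correlation counts as decoupled). Peaks
outside the sizing window are removed first; the alternative order
(threshold before windowing) would let sub-100 bp noise inflate the
totals that set the thresholds. If no candidate on the grid decouples the
two — the procedure's premise has then failed for that data set — the
function warns and applies no threshold at all, rather than the grid
maximum, which would discard genuine community signal.

**Cross-sample alignment.** `align_trfs()` pools all profiles of one
enzyme, sorts peaks by size, and bins them greedily with a running-mean
consensus window (default 0.5 bp, ties joining the open bin). Sorting
first makes the result invariant to profile order. Rows are normalized to
relative fluorescence or presence/absence. One profile per sample-enzyme
is assumed (replicate PCRs are pooled before digestion).

## Matching predictions to fragments

Measured sizes drift from sequence-predicted sizes, increasingly so for
longer fragments, so `match_trfs()` uses tolerance bins: 1.0 bp for
predictions up to 200 bp, 1.5 bp for 201–400 bp, 4.0 bp above 400 bp
(boundary sizes take the smaller tolerance). A phylotype matches the
nearest qualifying consensus bin (exact ties to the smaller size);
matching is study-wide rather than per-sample, since composite profiles
are assembled across the full sample set. `build_signatures()` collects
each phylotype's matched (enzyme, T-RF) set — its T-RFLP signature — and
classes it `unique`, `shared` (another phylotype has the identical set)
or `undetected` (no in-window matches). `shared_signature_divergence()`
quantifies how related co-migrating phylotypes are.

## Community comparison

`bray_curtis()` (optional square-root transform, the variance-stabilizing
default for relative abundances), `nmds()` (Kruskal stress-1 via
isotonic-regression NMDS, best of 20 seeded random starts, 500 iteration
cap, stress tolerance 1e−7) and `anosim()` (mid-rank ties;
R = (r̄B − r̄W)/(M/2); add-one permutation p, with an exact exhaustive
mode for small designs) compare communities on OTU or T-RF matrices.
Pairwise post-hoc comparisons get a Bonferroni family correction.

## Phylogenetic metrics

* `tajima_nei_distance()` — the 1984 base-composition-corrected distance,
  with pairwise deletion of gap/ambiguity columns and an infinite-distance
  saturation flag; feeds `amova()`.
* `amova()` — hierarchical decomposition of squared distances
  (sources / samples / sequences), F_ST = among-source variance over
  total, significance by permuting whole samples among sources; designs
  with single-sample sources fall back to two levels with a warning.
  Negative intermediate components are truncated at zero, a standard
  convention.
* `ptest()` — Fitch parsimony length of the source character
  (Hartigan's set recurrence on multifurcations), compared against random
  tip-label permutations; small trees can be enumerated exhaustively.
* `nri_nti()` — standardized effect sizes of MPD and MNTD against a
  tip-shuffle null (communities redrawn from the supplied pool; sample
  standard deviation with n − 1), positive values meaning phylogenetic
  clustering; degenerate nulls (zero sd) are flagged rather than
  reported as numbers.
* `libshuff()` — homologous vs heterologous coverage curves on a 0–0.50
  distance grid (step 0.01), ΔC as the squared-difference sum, p by
  shuffling sequences between libraries.

## Symbiont classification

`classify_otu()` applies the host-specificity rules: presence in any
seawater sample, or >98% identity to a free-living environmental
reference, makes a generalist; otherwise a specialist, sub-classified
dominant (all host samples and more than a quarter of the host's clones),
common (≥2 samples) or rare (1 sample). Exactly 98% identity (2%
divergence) stays specialist. OTUs lacking an environmental-identity
annotation are specialist-eligible and flagged, and OTUs shared between
two hosts but absent from seawater are specialists of each host with a
`multi_host` flag. Clone fractions are host-relative. Environmental
identities are consumed as annotations; this package performs no
database searches.

## The synthetic-data generator

`simulate_community()` and its companions generate data with the
structure the analysis assumes, so every stage is testable without
external downloads: four sources with 9/3/3/9 replicate samples and 15
clones each; one dominant host-exclusive phylotype per sponge host
(expected clone fractions 0.34 and 0.51; the tunicate community is even,
with none), present in every host sample by construction; a generalist
fraction per host (0.22 / 0.40 / 0.53) drawn from a pool shared with
seawater; host specialist pools with log-series rank weights x^k/k
(x = 0.9), giving the dominated, low-evenness profile of sponge
symbiont libraries; and a seawater pool with a near-even geometric tail
(ratio 0.985 over 150 phylotypes), reproducing the high per-sample
richness and singleton-rich character of bacterioplankton clone
libraries. With these settings the per-sample observed richness averages
about 7.5 (sponges) versus about 12 (seawater, tunicate), matching the
regime the statistics are meant to separate.

`simulate_sequences()` plants one 600 bp ancestor per phylotype, at least
2.8% divergent from every other ancestor, and derives clones with at most
2 substitutions (<1% within-OTU divergence), so clustering at 99%
provably recovers the planted partition. Restriction sites are cleared
and re-planted per enzyme (in-window with probability 0.7, out-of-window
0.15, absent otherwise), making predicted T-RFs controllable.
`simulate_electropherograms()` adds size-dependent Gaussian drift as a
*systematic* per-fragment offset (one draw per OTU and enzyme,
sd = 0.2 + 0.004·L bp, capped by default at half the applicable matching
tolerance, mirroring the rationale for size-increasing tolerance bins)
shared by all samples — electrophoretic drift is reproducible for a given
fragment, which is why predicted-vs-empirical tolerances reach 4 bp while
a 0.5 bp cross-sample alignment window suffices — plus small per-sample
sizing jitter (sd 0.15 bp),
abundance-proportional fluorescence, and uniform noise peaks (some below
the sizing window) whose count scales with the profile's total
fluorescence — the dependence of spurious peak number on loaded DNA that
the variable-threshold standardization exists to remove. `simulate_tree()` grafts each host's specialists as a
clade onto a coalescent backbone (planted phylogenetic clustering), with
an unstructured mode for null calibration.

What the generator does **not** emulate: PCR and cloning bias, chimeras,
realistic 16S evolution (divergences are controlled, not modeled),
pseudo-peaks from partial digestion, or multi-dye sizing error beyond
Gaussian drift. Tests passing on these data therefore demonstrate the
pipeline's internal correctness and recovery properties, not robustness
to every artifact of real electropherograms.

## Numerical and test-scale choices

Sizes are stored at 0.01 bp precision; all text I/O is UTF-8 with "." as
the decimal point. Determinism: every stochastic routine takes an
explicit seed (R's Mersenne-Twister), and the reference-database JSON is
key-sorted so identical inputs give byte-identical files. Permutation
tests use the add-one convention with ≥ in the tail count; exhaustive
modes replace it with the exact fraction. Property tests run at sizes
chosen to finish in minutes on one core while keeping estimates sharp:
the digestion oracle uses 10^4 random sequences; ANOSIM calibration uses
1000 null simulations at 199 permutations with 6+6 samples (large enough
that permutation ties with the observed labeling are rare — smaller
designs make the test visibly conservative); AMOVA calibration uses 200
simulations; end-to-end recovery uses 20 seeds of the full 9/3/3/9
design. Small permutation designs (3+3) have an exact-test floor near
p = 0.1, which the tests acknowledge rather than fight.

## Known limitations

Greedy clustering reproduces printed OTU counts only up to tool
differences; Chao1 variant choices differ between programs at F2 = 0;
PRIMER-style tie handling in ANOSIM ranks is assumed to be mid-ranks; the
variable-threshold procedure is reconstructed from its published
description (grid, α and correlation type are configurable for that
reason); and matching is resolution-limited — phylotypes under ~2–6%
divergence frequently share T-RFs across all enzymes and can only be
reported as shared signatures, never separated.
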