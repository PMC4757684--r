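---
title: "Scoring metabolic pathway availability from 16S community profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolic pathway availability from 16S community profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commpath)
library(dplyr)
```

## The problem

Activated sludge is a self-assembled microbial community whose job is to
degrade the organic load, toxicants and xenobiotics arriving in wastewater.
Whether a given degradation route is *available* to the community is a
question about the joint capabilities of its members: most multi-step
degradations are distributed across taxa, and no single organism carries the
whole cascade. Full metagenome sequencing answers this directly but is too
expensive for routine bioreactor monitoring. `commpath` instead infers a
community's metabolic potential from the cheap assay plants already run —
16S rRNA amplicon profiling — combined with a reaction–organism–pathway
database.

## The availability score

A pathway is modelled as an ordered chain of stages; each stage is either a
single reaction or a parallel block of alternative sub-pathways. A reaction
is annotated with the set of organisms (lineages) able to perform it.

Within a sample, the **capacity** $n_i$ of serial stage $i$ is the summed
read count of the profile taxa matched to that stage's capable organisms.
The **availability score** composes capacities harmonically:

$$ S_A = \left( \sum_{i=1}^{P} n_i^{-1} \right)^{-1} $$

so the score is throttled by the weakest serial stage ($S_A \le \min_i n_i$)
and is zero as soon as any stage has no capable taxon. A parallel block is
scored by applying the same rule to each branch and summing the branch
scores into the enclosing stage's capacity — alternative routes add capacity
exactly the way additional capable organisms do. This mirrors a
rate-limiting-step view of a metabolic cascade in which per-organism rate
constants and metabolite transport are deliberately dropped: with those
factors unknowable from 16S data alone, $S_A$ is a relative score, suited to
comparing the same pathway across communities and not to comparing different
pathways or converting to fluxes.

Two modelling choices deserve emphasis:

* **Organism matching.** 16S classification typically stops at genus, while
  databases list species. Each capable organism is therefore matched to the
  deepest profile lineage that is an ancestor-or-equal of it. When several
  capable species collapse onto one genus entry, that entry is counted once
  per reaction (`dedup = TRUE`, the default) — otherwise a reaction listing
  five congeneric species would count the genus reads five times. This rank
  mismatch is the most consequential free choice in the method, so it is
  exposed as a flag.
* **Zero stages.** $1/0$ is taken as $\infty$, hence $S_A = 0$: a pathway
  with an uncovered serial step is unavailable, however abundant the other
  steps' organisms.

Counts should be copy-number adjusted and normalised before scoring so that
scores are comparable across sequencing depths; raw counts remain available
for within-sample work.

## From reads to profiles

`read_profiles()` ingests the classifier-export TSV (one row per sample and
lineage). Lineages are canonical `rank:name` chains from domain downward;
reads that fail classification below some rank simply truncate there and
are retained at the deepest classified level rather than being turned into
synthetic "unclassified" taxa. The processing order is:

1. `adjust_copy_numbers()` — divide by the mean 16S gene copy number
   (nearest-ancestor fallback, then 1), correcting the over-representation
   of multi-copy genomes;
2. `merge_replicates()` — technical replicates taken minutes apart are
   summed (keeping merging additive is why adjustment precedes it);
3. `normalize_profiles()` — convert to within-sample proportions.

`all_rank_matrix()` expands each sample into the concatenated all-rank
vector: a read contributes to every taxon on its classification path, so a
family-level read is visible at family and above but at no genus. Community
comparisons (distance, PCA) run on these vectors, which is what "taking all
taxonomic levels into account" means operationally.

## Community comparison

The between-sample distance is $d = 1 - r$ with $r$ the Pearson correlation
of the square-root transformed all-rank vectors; the square root raises the
weight of low-abundance taxa. $d$ lives in $[0, 2]$ and values above 1
(anti-correlation) are kept as-is rather than clipped. Ward's
minimum-variance clustering runs the Lance–Williams update on squared
dissimilarities; merge heights are reported on the distance scale by
default (`heights = "squared"` keeps the squared scale — the topology is
identical, only the height units change). PCA runs on the centred
square-root matrix, with component signs fixed by forcing each component's
largest loading positive so coordinates reproduce across platforms.

The temporal-stability question — is sludge compositionally stable while
incoming wastewater drifts? — is answered by pooling, for each plant and
compartment, the distances between samples taken at different months
(replicates merged first), concatenating the activated-sludge pools and the
incoming-wastewater pools, and comparing the two groups with a two-sided
Mann–Whitney U test. The exact null is used whenever both groups have at
most 12 values and no ties — the study design of 3 plants × 3 months gives
9 values per group, squarely in exact territory — and the normal
approximation with tie correction otherwise.

## Differential pathway representation

`differential_pathways()` compares availability across sample groups (the
three plants, in the motivating design). Scores are transformed first —
$\sqrt{S_A}$ by default, matching the display convention, with `none` and
`log1p` available — then each pathway gets every pairwise Welch test plus a
one-way ANOVA, and the ANOVA p-values are Benjamini–Hochberg adjusted
across tested pathways. Raw p-values are reported alongside q-values since
the motivating analysis was uncorrected. Pathways with all-zero scores, or
zero variance after transform, are flagged and skipped rather than fed to
degenerate tests; Welch (not pooled) is the default because group variances
of scores have no reason to be equal (a pooled flag exists).

## The synthetic study generator

`sim_design()` / `make_toy_db()` / `simulate_profiles()` generate a complete
study with known ground truth, sized like the field design they emulate:
3 plants, activated sludge and incoming wastewater, 3 monthly dates,
duplicate sampling 15 minutes apart, ~3000 reads per sample over 40 genera.
Counts are Dirichlet-multinomial: one log-normal base composition
(meanlog 0, sdlog 1.5), a per-plant tilt (log-sd 0.25) shared by both
compartments of a plant, a monthly Dirichlet redraw at a
compartment-specific concentration, a high-concentration replicate redraw
(200) and multinomial reads. The temporal concentrations
(`conc_time = c(AS = 150, IW = 25)`) and the replicate concentration were
chosen so the simulated distances land on the magnitudes reported for real
plants — replicate pairs near 0.02, sludge month-to-month distances of a
few hundredths, incoming-wastewater distances several times larger — and
were fixed before any recovery experiments were run. The planted
differential truth is one target pathway whose reactions draw capable
organisms exclusively from a designated taxon set; those taxa are pinned to
the upper quartile of the base abundance law (the real analogues of such
shifts are abundant families, and rare planted taxa would vanish below read
depth), excluded from all other reactions, and multiplied by the effect
size (default 4) in the last plant.

What the generator does *not* emulate: classifier error, chimeras, strain
heterogeneity, compositional correlations between taxa, or any real
taxonomy — so green recovery tests certify the statistical machinery, not
robustness to those real-data features.

## Numerical and design notes

* Canonical JSON serialisation (sorted keys, sorted organism and keyword
  lists) makes database saves byte-stable, so fixtures diff cleanly.
* MetaCyc-style flat files encode pathway order as a predecessor DAG, which
  need not be series-parallel. The parser attempts a two-terminal
  series-parallel reduction (contract degree-(1,1) vertices, merge parallel
  edges); on failure the reaction list is treated as purely serial and the
  pathway flagged in `source_note`. Extra serial constraints can only
  lower $S_A$, so the fallback errs conservative.
* The interchange JSON schema, not MetaCyc, is the canonical input: the
  package must build and test without the license-restricted database, and
  headline counts tied to a specific MetaCyc release (total pathways,
  keyword subsets) are not reproducible here by construction.
* Keyword filtering is case-insensitive substring matching over the pathway
  name and keyword list; the empty string matches everything.
* Degenerate inputs fail loudly by name: all-zero samples cannot be
  normalised, constant (zero-variance) abundance vectors cannot enter the
  correlation distance, and dangling reaction references are reported with
  their ids.
* Absolute-abundance fold changes multiply proportions by per-sample CFU/mL
  and report presence/absence flips as ±Inf sentinels rather than inventing
  a pseudocount (one is available but off by default). CFU counts carry
  cultivation bias, so these are indicative estimates only.

## Known limitations

* The pooled stability test inherits a structural inflation of its type-I
  error: the three distances in a pool share the three monthly draws
  (d(Oct,Nov), d(Oct,Dec), d(Nov,Dec)), and for correlation-type distances
  over many taxa a pairwise distance decomposes almost additively into
  per-month effects, pushing intra-pool correlation toward 0.5. Simulations
  with equal compartment dispersions put the realised size near 0.10 at a
  nominal 0.05, and Monte-Carlo on the idealised additive model shows no
  count-based generator can push it below ~0.07. Pooled p-values near the
  threshold should therefore be read cautiously; the dispersion contrast
  the design actually targets is detected essentially always at the
  calibrated effect sizes.
* Benjamini–Hochberg step-up routinely assigns one shared q-value to the
  few leading pathways; "the most significant pathway" should be read as
  attaining the minimal q, possibly tied.
* $S_A$ says a route is covered, not active: substrate absence, transport
  limits and strain-level capability differences are all invisible to 16S
  data.

## Problem sizes used in the test suite

Property checks run on 1000 random series-parallel pathways (≤ 12
reactions) against an independent reducer, 500 random instances for the
analytic properties, exhaustive Mann–Whitney enumeration up to 7 per group,
and 200 simulated studies each for stability power/level and differential
recovery; these sizes make the Monte-Carlo rates stable to a few percent.
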