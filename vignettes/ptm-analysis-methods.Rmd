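---
title: "Methods: residue-level PTM metrics, sequence architecture and enzyme stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue-level PTM metrics, sequence architecture and enzyme stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmatlas)
```

## Scope and model

Metabolic enzymes are regulated by many kinds of post-translational
modification (PTM) — phosphorylation, acetylation, ubiquitination,
methylation and rarer chemistries — and curated databases report these at
residue resolution but in inconsistent dialects. `ptmatlas` harmonizes such
annotations onto reference sequences and asks whether enzyme-level PTM
features stratify a cohort into distinct regulatory groups.

The pipeline has four layers:

1. **Harmonization** (`read_ptm_table()`, `harmonize_sites()`): raw records
   are keyed to one canonical site per (accession, position, type). A site's
   *detection count* is the number of independent reports supporting it,
   summed across sources (at least one per contributing record, so a site is
   kept irrespective of how many studies support it). Records whose annotated
   residue disagrees with the reference sequence are excluded and itemized,
   never remapped: the position may refer to a different sequence release,
   and silently shifting coordinates would corrupt every downstream window
   statistic.
2. **Enzyme-level metrics** (`enzyme_metrics()`):
   * *PTM density* = unique sites / sequence length (sites per residue).
   * *Per-type density*: the same, per modification type; the per-type values
     partition the total exactly.
   * *PTM potentiality rate (PPR)* = unique sites of a type / residues
     chemically eligible for that type. The numerator uses unique sites, not
     cumulative detections, for consistency with the density numerator. When
     a sequence has no eligible residue the value is undefined and propagates
     as missing — it is only imputed (as zero capacity) when the clustering
     matrix must be complete.
   * *Predominant sites*: per enzyme and type, sites ranked by detection
     count (ties broken by ascending position) and accumulated until their
     cumulative count first reaches a threshold fraction (default 60%) of all
     detections; the crossing site is included. The resulting set is monotone
     in the threshold, and `sensitivity_scan()` quantifies robustness at
     50/60/70%.
3. **Sequence architecture** (`detect_hotspots()`, `detect_crosstalk()`,
   `localize_sites()`, `overlap_variants()`): a *hotspot* window is the ±7
   residues around a site containing at least five further PTM records
   (excluding only the central record, so another modification of the same
   residue counts); overlapping qualifying windows are merged into maximal
   regions. A window counts unique (position, type) records, so a
   dual-modified residue contributes two; `count_unique_positions = TRUE`
   gives the residue-counting alternative. *Crosstalk* residues carry two or
   more distinct types at one position (residue mode, the headline
   definition); window mode instead asks whether a ±7 neighborhood mixes
   types, for the looser "within or near one window" reading. Region
   localization is multi-label with no precedence, and a site inside no
   annotation is `unannotated`.
4. **Statistics and stratification** (`spearman_matrix()`,
   `cohort_contrasts()`, `hypergeom_enrich()`, `build_feature_matrix()`,
   `cluster_enzymes()`): PTM features are non-normal and right-skewed, so all
   contrasts are two-sided Mann–Whitney tests and all summaries lead with
   medians; families of tests are Benjamini–Hochberg adjusted per analysis
   family. Enzymes are clustered on a multi-block feature matrix and each
   cluster is characterized by feature contrasts and background-aware
   hypergeometric pathway enrichment (background = the full cohort, the one
   defensible choice when the cohort itself defines the universe).

## Feature matrix conventions

* Numeric block: total and per-type densities, per-type PPR, and the
  predominant/hotspot/crosstalk/mutation-overlap counts; z-scored after
  filtering. Missing PPR values are imputed as 0 with a per-column
  missingness report, because a protein with no eligible residue has no
  modification capacity and Ward linkage needs a complete matrix.
* Text block: TF-IDF over the enzyme's free-text descriptors plus its region
  names. Convention (held fixed; conventions differ across software):
  lowercase, tokenize on non-alphanumerics, drop tokens with document
  frequency < 2, tf = raw count, idf = ln((1 + N)/(1 + df)) + 1, rows
  L2-normalized.
* Categorical block: 0/1 pathway and EC-class indicators.
* Filtering drops zero-variance columns and columns nonzero in < 1% of rows,
  logging every drop. Only the numeric block is z-scored: the text rows are
  already unit-norm and the indicators are meaningful on their 0/1 scale
  (a `scale_all` flag covers the alternative).

Clustering runs on the full filtered matrix — PCA is strictly a
visualization device. Ward agglomeration uses `hclust(method = "ward.D2")`
on Euclidean distances; k-means uses `stats::kmeans` with 10 random restarts
under a fixed seed (a k-means++ initializer would be a reasonable
alternative; with 10 restarts on cohorts of this size the best-inertia
solution is stable, and the headline method is the Ward solution anyway).
k is selected by the mean silhouette width over k = 2..10; a k at or above
the number of rows is reported as undefined rather than an error. Component
signs in the PCA projection are arbitrary, as for any eigendecomposition.

## Statistical conventions

* Spearman correlations use midranks; p-values come from the large-sample t
  approximation t = ρ√((n−2)/(1−ρ²)) with pairwise deletion of missing
  values; pairs with a constant margin or fewer than 3 complete pairs are
  undefined and excluded from the BH family.
* Mann–Whitney U counts pairs (a > b) plus half-ties, so identical groups
  give U = n_a·n_b/2. For combined n ≤ 16 the two-sided p comes from
  complete enumeration of all group assignments over the pooled midranks
  (valid under ties; the permutation distribution of U is symmetric about
  its midpoint). Above 16 a normal approximation with midrank tie correction
  and continuity correction is used. The switch point is a documented
  implementation constant: enumeration at 16 costs at most choose(16,8) =
  12,870 evaluations, while the normal approximation is accurate from these
  sizes upward.
* BH adjustment is `stats::p.adjust(method = "BH")` behind a validated
  wrapper, applied within each analysis family (one correlation matrix; one
  contrast family per dichotomy; one enrichment run per cluster).
* Hypergeometric enrichment is the upper-tail `phyper` against the full
  cohort background.
* Quartiles use linear interpolation between order statistics (R type 7),
  stated because quartile conventions differ across software.

## The synthetic cohort generator

Real multi-database PTM catalogs cannot be redistributed, so every stage is
exercised against a seeded generator (`generate_cohort()`) whose defaults
define the package's reference study conditions:

* **Density**: each enzyme draws a propensity λ from a gamma with mean 1
  (shape 10), and each residue is modified with probability λ · (sum of
  per-type base rates eligible at that residue), capped at 0.95. Per-type
  base rates mirror the field's coverage hierarchy (phosphorylation >
  ubiquitination/methylation/acetylation > minor types). A planted
  PTM-enriched group (15% of enzymes) has its density, burst and crosstalk
  rates multiplied by 3. At the cohort level the density distribution is
  right-skewed — a low-density majority plus a markedly elevated subset —
  which is exactly the mixture shape the generator is meant to emulate. The
  within-group dispersion (the gamma shape) is a free choice: it was fixed
  at 10 so that the planted groups remain recoverable by the downstream
  clustering, which is the generator's stated purpose as a positive control;
  smaller shapes blur the planted boundary with propensity noise rather than
  adding scientific realism.
* **Types and eligibility**: one type per modified residue, drawn
  proportionally to the base rates eligible for that residue; multi-type
  co-annotation arises *only* through the crosstalk mechanism, so
  `crosstalk_rate = 0` guarantees zero multi-type residues and the injected
  positions are exact ground truth.
* **Bursts**: Poisson-many bursts per enzyme place ≥ 6 records inside one
  15-residue window, always anchoring a site at the eligible position
  nearest the window center. The anchor guarantees that a realized burst
  carries a window satisfying the hotspot rule, making bursts usable as
  planted positive controls with known locations.
* **Detection counts**: shifted geometric (1 + Geom(0.35)) for a heavy tail
  of highly recurrent sites over a mass of singletons.
* **Regions and variants**: 1–3 non-overlapping domains covering ~40% of
  each sequence (so ~40% of sites fall inside domains under uniform
  placement), an optional disordered segment that may overlap them, variants
  on 15% of PTM positions plus a 0.5% background.
* **Annotations**: the enriched group preferentially carries a `core`
  pathway label (0.9 vs 0.05), holds all planted rate-limiting flags, and
  leans mitochondrial (0.45 vs 0.25); text descriptors mix shared vocabulary
  with group-linked terms.

What passing tests on this cohort do **not** show: real catalogs have
non-uniform residue composition, study-coverage bias correlated with enzyme
fame, isoform mapping drift, and PTM-type-specific detection platforms.
The generator makes no claim to match any real cohort's parameters — it
provides known ground truth at realistic scale (presets of 200 and 771
enzymes, the latter matching the size of the human metabolic enzyme
complement).

## Calibration and recovery checks

The test suite verifies, among others (problem sizes chosen to keep the
default run in the minutes range while leaving the statistics
well-powered):

* hotspot detection equals an exhaustive all-windows + interval-merge oracle
  on every enzyme of a 200-enzyme cohort;
* under a null generator (enrichment multiplier 1), the pooled rejection
  rate of the Mann–Whitney contrast layer at nominal p < 0.05 stays within
  the binomial 99% band of 0.05 across 500 seeded replicates of 200 enzymes
  — the band is applied at replicate level because the ~58 contrasts within
  one replicate share a cohort and are dependent;
* exact Mann–Whitney p-values equal exhaustive enumeration at 4 + 4; the BH
  step-up and hypergeometric tails equal closed forms;
* on the 771-enzyme preset with multiplier 3 and its shipped seed, the
  silhouette scan selects k = 2, Ward clustering recovers the planted groups
  with adjusted Rand index ≥ 0.8, the enriched cluster shows significantly
  higher density/hotspot/crosstalk medians, and the planted `core` label
  enriches at q < 0.05.

## Degenerate inputs and edge rules

* Empty site lists: hotspot/crosstalk detection return empty tables;
  predominant calling errors (there is nothing to rank).
* Regions beyond the sequence are clipped with a warning; inverted regions
  are rejected with a report entry.
* PPR > 1 (a site on a residue outside its type's alphabet) is reported as
  computed with a warning, never clamped — it flags an eligibility/catalog
  mismatch the user must resolve.
* Windows are closed 1-based intervals clipped to [1, length], matching the
  UniProt coordinate convention of every supported source dialect.
* Qualifying hotspot windows merge only when they share residues; adjacent
  but non-overlapping windows remain distinct regions.

## Known limitations

* Functional notes from conflicting sources are all kept, pipe-joined; no
  reconciliation is attempted.
* No isoform-aware coordinate lift-over: records that disagree with the
  reference sequence are dropped, not rescued.
* The silhouette of a real cohort's two-group solution is expected to be
  moderate (high-dimensional heterogeneous features); the package reports it
  but does not threshold on it.
* Enrichment uses the cohort as background; results are not comparable to
  web tools that default to a genome-wide background.
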