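# ptmatlas

Residue-level integration and enzyme-level analysis of post-translational
modifications (PTMs) on protein cohorts, written for the setting of human
metabolic enzymes: harmonize multi-database site annotations onto reference
sequences, quantify each enzyme's regulatory burden, derive its sequence
architecture (hotspots, crosstalk, region localization, mutation overlap),
test group contrasts and pathway enrichment, and stratify the cohort by
clustering a multi-block feature matrix.

## Who this is for

Proteomics / systems-biology analysts who have residue-level PTM tables (in
PhosphoSitePlus-, dbPTM-, qPTM-like or generic TSV dialects), reference
FASTA sequences, and optional region/variant/pathway annotations, and who
want reproducible enzyme-level metrics and stratification rather than
manual spreadsheet merges. A seeded synthetic-cohort generator with planted
structure makes the whole pipeline testable without access to licensed
database snapshots.

## The quantities at the core

For an enzyme of length `L` with harmonized site set `S` (unique
(position, type) records, each with a cumulative detection count):

- **PTM density** `= |S| / L` — modification burden per residue.
- **Per-type density** `= |S_t| / L` for each modification type `t`; these
  partition the total density.
- **PTM potentiality rate (PPR)** `= |S_t| / (# residues eligible for t)` —
  composition-corrected propensity (e.g. K for acetylation; S/T/Y for
  phosphorylation); undefined when the sequence has no eligible residue.
- **Predominant sites** — per enzyme and type, the top detection-ranked
  sites whose cumulative detection count first reaches 60% of all
  detections (threshold-sensitivity scan at 50/60/70%).
- **Hotspot regions** — maximal merges of ±7-residue windows containing ≥ 5
  PTM records besides the central site.
- **Crosstalk residues** — positions carrying ≥ 2 distinct PTM types.
- **Statistics** — Spearman correlations (t approximation, BH-adjusted),
  two-sided Mann–Whitney contrasts (exact by enumeration for combined
  n ≤ 16, tie-corrected normal approximation above), hypergeometric pathway
  enrichment against the cohort background.
- **Stratification** — Ward (or k-means) clustering of a z-scored numeric +
  TF-IDF text + one-hot categorical feature matrix, with silhouette-based
  selection of k over 2..10 and PCA projection for display only.

## Worked example

```r
library(ptmatlas)

co <- generate_cohort(cohort_config("cohort_small"), seed = 42)
m  <- enzyme_metrics(co$sites, co$enzymes, co$regions, co$variants)
m[1:3, c("accession", "length", "n_sites_total", "ptm_density",
         "n_predominant", "n_hotspot_regions")]
#> # A tibble: 3 x 6
#>   accession length n_sites_total ptm_density n_predominant n_hotspot_regions
#> 1 SYN0001      330            45      0.136             19                 2
#> 2 SYN0002      900            94      0.104             35                 2
#> 3 SYN0003      612            47      0.0768            26                 0

summarize_distribution(m$ptm_density)$summary
#> # A tibble: 1 x 9
#>       n    min     q1 median    q3   max  mean skewness right_skewed
#> 1   200 0.0284 0.0935  0.113 0.150 0.308 0.130     1.29 TRUE
```

`SYN0001` carries 45 unique sites on 330 residues (density 0.136, i.e. one
site per ~7 residues), of which 19 are predominant — recurrently detected —
and two sequence segments are dense enough to qualify as hotspot regions.
Across the cohort the density distribution is right-skewed (mean 0.130 above
the median 0.113): most enzymes are sparsely modified, a minority heavily.

The full pipeline (metrics → architecture → statistics → clustering →
characterization) runs from one config and writes a hashed artifact
manifest:

```r
rep <- run_pipeline(pipeline_config(cohort_config("cohort_small")),
                    out_dir = "ptm_run", seed = 1)
rep
#> <ptm_run_report> 200 enzymes | 15608 sites | k = 2 | silhouette = 0.447
#>   outputs in ptm_run ( 17 files )
```

Plot helpers, given
`fm <- filter_features(build_feature_matrix(m, co$enzymes, co$regions))`:
`plot_density_distribution(m)`, `autoplot(silhouette_scan(fm))`,
`plot_pca(pca_project(fm), cluster_enzymes(fm, 2))`.

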