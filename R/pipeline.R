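#' Pipeline configuration
#'
#' Builds (and validates) the single configuration object driving
#' [run_pipeline()]. Inputs are either a synthetic cohort preset or a set of
#' file paths readable by the loaders. Defaults mirror the analysis
#' conventions used throughout the package: predominant threshold 0.60 with
#' a 0.50/0.60/0.70 sensitivity set, hotspot windows of +/-7 residues with
#' at least 5 co-occurring records, residue-mode crosstalk, sparsity
#' threshold 0.01, silhouette scan over k = 2..10, Ward clustering, q-value
#' highlight threshold 0.05.
#'
#' @param input either a `ptm_cohort_config` (synthetic run), a `ptm_cohort`,
#'   or a named list of paths (`fasta`, `ptm`, `ptm_dialect`, `regions`,
#'   `variants`, `annotations`).
#' @param ... overrides of any default parameter below.
#' @return list of class `ptm_pipeline_config`.
#' @export
pipeline_config <- function(input = cohort_config("cohort_small"), ...) {
  cfg <- list(
    input = input,
    predominant_threshold = 0.60,
    sensitivity_thresholds = c(0.50, 0.60, 0.70),
    half_window = 7L,
    min_neighbors = 5L,
    crosstalk_mode = "residue",
    eligibility = default_eligibility(),
    min_df = 2L,
    sparsity_threshold = 0.01,
    k_range = 2:10,
    cluster_method = "ward",
    q_threshold = 0.05,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) stop("unknown pipeline config field(s): ",
                            paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$predominant_threshold > 0, cfg$predominant_threshold <= 1,
    all(cfg$sensitivity_thresholds > 0 & cfg$sensitivity_thresholds <= 1),
    cfg$half_window >= 1, cfg$min_neighbors >= 1,
    cfg$crosstalk_mode %in% c("residue", "window"),
    cfg$sparsity_threshold >= 0, cfg$sparsity_threshold < 1,
    all(cfg$k_range >= 2),
    cfg$cluster_method %in% c("ward", "kmeans"),
    cfg$q_threshold > 0, cfg$q_threshold <= 1
  )
  structure(cfg, class = "ptm_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar parameters are read from the YAML mapping; an `input` mapping with
#' a `preset` key selects a synthetic cohort preset (any other keys of that
#' mapping override generator fields), and an `input` mapping with file
#' paths is passed through for loading.
#'
#' @param path YAML file.
#' @return a `ptm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (!is.null(input$preset)) {
    args <- input[setdiff(names(input), "preset")]
    input <- do.call(cohort_config, c(list(preset = input$preset), args))
  }
  y$input <- NULL
  if (!is.null(y$k_range) && length(y$k_range) == 2) {
    y$k_range <- y$k_range[1]:y$k_range[2]
  }
  do.call(pipeline_config, c(list(input = input), y))
}

load_pipeline_input <- function(input, seed) {
  if (inherits(input, "ptm_cohort")) return(input)
  if (inherits(input, "ptm_cohort_config")) {
    return(generate_cohort(input, seed = seed))
  }
  if (is.list(input) && !is.null(input$fasta)) {
    enz <- read_enzyme_fasta(input$fasta)
    if (!is.null(input$annotations)) {
      enz <- read_enzyme_annotations(enz, input$annotations)
    }
    raw <- read_ptm_table(input$ptm,
                          dialect = input$ptm_dialect %||% "generic_tsv")
    harm <- harmonize_sites(raw, enz)
    regions <- if (!is.null(input$regions)) {
      read_region_table(input$regions, enzymes = enz)
    } else NULL
    variants <- if (!is.null(input$variants)) {
      read_variant_table(input$variants)
    } else NULL
    return(structure(list(enzymes = enz, sites = harm$sites,
                          regions = regions, variants = variants,
                          truth = NULL, harmonization_report = harm$report),
                     class = "ptm_cohort"))
  }
  stop("unrecognized pipeline input")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or generate the cohort, harmonize,
#' enzyme-level metrics, sequence architecture, sensitivity scan,
#' correlation and group-contrast statistics, feature-matrix construction,
#' clustering with silhouette-based k selection, PCA projection, cluster
#' characterization — writing every table to `out_dir` and returning a run
#' report with a content-hash manifest. Given the same config and seed, the
#' run (and every file hash) is reproducible.
#'
#' @param config a `ptm_pipeline_config` (or path to a YAML config).
#' @param out_dir output directory.
#' @param seed integer; overrides `config$seed`.
#' @return list of class `ptm_run_report`: `manifest` (file, md5), `summary`
#'   (headline statistics), `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ptmrun"),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "ptm_pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cohort <- load_pipeline_input(config$input, seed)
  metrics <- enzyme_metrics(
    cohort$sites, cohort$enzymes, cohort$regions, cohort$variants,
    eligibility = config$eligibility,
    predominant_threshold = config$predominant_threshold,
    half_window = config$half_window, min_neighbors = config$min_neighbors,
    crosstalk_mode = config$crosstalk_mode)

  hotspots <- detect_hotspots(cohort$sites, cohort$enzymes,
                              half_window = config$half_window,
                              min_neighbors = config$min_neighbors)
  crosstalk <- detect_crosstalk(cohort$sites, mode = config$crosstalk_mode,
                                half_window = config$half_window)
  predominant <- call_predominant(cohort$sites, config$predominant_threshold)
  scan <- sensitivity_scan(cohort$sites, config$sensitivity_thresholds)
  overlaps <- if (!is.null(cohort$variants) && nrow(cohort$variants) > 0) {
    overlap_variants(cohort$sites, cohort$variants)
  } else NULL
  localization <- if (!is.null(cohort$regions) && nrow(cohort$regions) > 0) {
    localize_sites(cohort$sites, cohort$regions)
  } else NULL

  corr <- spearman_matrix(metrics, features = intersect(
    c("ptm_density", "n_sites_total", "n_predominant", "n_hotspot_regions",
      "n_crosstalk_residues", "n_mutated_ptm_sites",
      "n_domain_localized_sites", "length"), names(metrics)))
  contrasts <- cohort_contrasts(metrics)

  fm <- build_feature_matrix(metrics, cohort$enzymes, cohort$regions,
                             min_df = config$min_df)
  fm <- filter_features(fm, sparsity_threshold = config$sparsity_threshold)
  kscan <- silhouette_scan(fm, k_range = config$k_range,
                           method = config$cluster_method, seed = seed)
  k_best <- selected_k(kscan)
  clustering <- cluster_enzymes(fm, k = k_best, method = config$cluster_method,
                                seed = seed)
  scores <- pca_project(fm, 2L)
  sets <- pathway_sets(cohort$enzymes)
  characterization <- characterize_clusters(clustering, metrics, sets)

  # ---- write artifacts ----
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    p
  }
  files <- c(
    w(cohort$sites, "site_catalog.tsv"),
    w(metrics, "enzyme_metrics.tsv"),
    w(predominant, "predominant_sites.tsv"),
    w(scan$counts, "sensitivity_counts.tsv"),
    w(scan$agreement, "sensitivity_agreement.tsv"),
    w(hotspots, "hotspots.tsv"),
    w(crosstalk, "crosstalk.tsv"),
    w(corr, "correlations.tsv"),
    w(contrasts, "contrasts.tsv"),
    w(clustering$labels, "cluster_assignments.tsv"),
    w(tibble::as_tibble(kscan), "silhouette_scan.tsv"),
    w(scores, "pca_scores.tsv"),
    w(characterization$contrasts, "cluster_contrasts.tsv"),
    w(characterization$enrichment, "cluster_enrichment.tsv")
  )
  if (!is.null(overlaps)) files <- c(files, w(overlaps, "mutation_overlap.tsv"))
  if (!is.null(localization)) files <- c(files, w(localization, "site_localization.tsv"))
  files <- c(files, write_feature_matrix(fm, file.path(out_dir, "feature_matrix.tsv")))
  if (!is.null(clustering$tree)) {
    files <- c(files, write_linkage_tree(clustering, file.path(out_dir, "linkage_tree.tsv")))
  }
  if (!is.null(cohort$harmonization_report)) {
    files <- c(files, write_harmonization_report(
      cohort$harmonization_report, file.path(out_dir, "harmonization_report.json")))
  }
  summary <- list(
    n_enzymes = nrow(cohort$enzymes),
    n_sites = nrow(cohort$sites),
    median_density = stats::median(metrics$ptm_density),
    n_hotspot_enzymes = dplyr::n_distinct(hotspots$accession),
    n_crosstalk_residues = nrow(crosstalk),
    selected_k = k_best,
    silhouette = clustering$silhouette,
    cluster_sizes = as.integer(table(clustering$labels$cluster)),
    seed = seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "run_summary.json"))
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  structure(list(
    manifest = manifest, summary = summary, out_dir = out_dir,
    results = list(cohort = cohort, metrics = metrics, hotspots = hotspots,
                   crosstalk = crosstalk, predominant = predominant,
                   sensitivity = scan, correlations = corr,
                   contrasts = contrasts, feature_matrix = fm,
                   silhouette_scan = kscan, clustering = clustering,
                   pca = scores, characterization = characterization)
  ), class = "ptm_run_report")
}

#' @export
print.ptm_run_report <- function(x, ...) {
  cat("<ptm_run_report>", x$summary$n_enzymes, "enzymes |",
      x$summary$n_sites, "sites | k =", x$summary$selected_k,
      sprintf("| silhouette = %.3f", x$summary$silhouette), "\n")
  cat("  outputs in", x$out_dir, "(", nrow(x$manifest), "files )\n")
  invisible(x)
}
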