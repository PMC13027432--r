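#' Per-enzyme PTM density
#'
#' PTM density is the number of unique observed PTM sites — unique
#' (position, type) records — divided by the protein sequence length, i.e.
#' sites per residue. It is a sequence-normalized measure of modification
#' burden for relative comparison across enzymes of different sizes.
#'
#' @param sites harmonized site tibble (one row per unique
#'   accession/position/type; see [harmonize_sites()]).
#' @param enzymes enzyme tibble with `accession` and `length`.
#' @return tibble with one row per enzyme: `accession`, `n_sites_total`,
#'   `ptm_density`. Enzymes without sites get density 0.
#' @export
#' @examples
#' enz <- tibble::tibble(accession = "E1", length = 10L)
#' s <- tibble::tibble(accession = "E1", position = 1:5,
#'                     ptm_type = "phosphorylation")
#' ptm_density(s, enz)  # 0.5
ptm_density <- function(sites, enzymes) {
  if (any(is.na(enzymes$length)) || any(enzymes$length < 1)) {
    stop("all enzyme lengths must be >= 1")
  }
  counts <- sites |>
    dplyr::distinct(.data$accession, .data$position, .data$ptm_type) |>
    dplyr::count(.data$accession, name = "n_sites_total")
  enzymes |>
    dplyr::select("accession", "length") |>
    dplyr::left_join(counts, by = "accession") |>
    dplyr::mutate(
      n_sites_total = dplyr::coalesce(.data$n_sites_total, 0L),
      ptm_density = .data$n_sites_total / .data$length
    ) |>
    dplyr::select("accession", "n_sites_total", "ptm_density")
}

#' Modification-specific PTM density
#'
#' Unique-site count of each PTM type divided by sequence length. Over all
#' types these densities partition the total: their sum equals the enzyme's
#' [ptm_density()].
#'
#' @inheritParams ptm_density
#' @param zero_fill if `TRUE`, every enzyme x observed-type combination is
#'   emitted with density 0 where absent; otherwise absent types are omitted.
#' @return tibble with columns `accession`, `ptm_type`, `n_sites`, `density`.
#' @export
per_type_density <- function(sites, enzymes, zero_fill = FALSE) {
  if (any(enzymes$length < 1)) stop("all enzyme lengths must be >= 1")
  out <- sites |>
    dplyr::distinct(.data$accession, .data$position, .data$ptm_type) |>
    dplyr::count(.data$accession, .data$ptm_type, name = "n_sites")
  if (zero_fill) {
    out <- out |>
      tidyr::complete(accession = enzymes$accession,
                      ptm_type = unique(sites$ptm_type),
                      fill = list(n_sites = 0L))
  }
  out |>
    dplyr::inner_join(dplyr::select(enzymes, "accession", "length"),
                      by = "accession") |>
    dplyr::mutate(density = .data$n_sites / .data$length) |>
    dplyr::select("accession", "ptm_type", "n_sites", "density")
}

# residues of each type actually observed in the catalog: eligibility
# fallback for types absent from the configured map
observed_eligibility <- function(sites) {
  sp <- split(sites$residue, sites$ptm_type)
  lapply(sp, function(r) sort(unique(r[!is.na(r)])))
}

#' PTM potentiality rate (PPR)
#'
#' For each enzyme and PTM type, the number of unique observed sites divided
#' by the number of residues chemically eligible for that modification in the
#' sequence (e.g. lysines for acetylation; S/T/Y for phosphorylation). PPR is
#' a composition-corrected modification propensity. When a sequence has no
#' eligible residue the rate is undefined and reported as `NA`, which is
#' distinct from 0 and propagates as missing downstream (never imputed here).
#'
#' "Observed PTM events" in the numerator are unique sites, not cumulative
#' detection counts, for consistency with the density numerator. Types not in
#' the eligibility map fall back to the residues observed for that type in
#' the catalog; a type with neither is an error.
#'
#' @inheritParams ptm_density
#' @param enzymes enzyme tibble with `accession` and `sequence`.
#' @param eligibility named list mapping type to residue alphabet; see
#'   [default_eligibility()].
#' @param types PTM types to evaluate (default: all types in `sites`).
#' @return tibble with columns `accession`, `ptm_type`, `n_sites`,
#'   `n_eligible`, `ppr`. A warning is raised if any site sits on a residue
#'   outside its type's alphabet (PPR can then exceed 1; values are reported
#'   as computed, never clamped).
#' @export
ptm_potentiality <- function(sites, enzymes,
                             eligibility = default_eligibility(),
                             types = NULL) {
  if (is.null(types)) types <- sort(unique(sites$ptm_type))
  obs <- observed_eligibility(sites)
  alph <- lapply(stats::setNames(types, types), function(t) {
    a <- eligibility[[t]]
    if (is.null(a)) a <- obs[[t]]
    if (is.null(a) || length(a) == 0) {
      stop("unknown ptm_type with no eligibility and no observed residues: ", t)
    }
    a
  })

  counts <- sites |>
    dplyr::filter(.data$ptm_type %in% types) |>
    dplyr::distinct(.data$accession, .data$position, .data$ptm_type) |>
    dplyr::count(.data$accession, .data$ptm_type, name = "n_sites")

  # residue composition per enzyme, computed once
  letters_seen <- sort(unique(c(AA_ALPHABET, unlist(alph))))
  comp <- t(vapply(strsplit(enzymes$sequence, ""), function(ch) {
    tabulate(factor(ch, levels = letters_seen), nbins = length(letters_seen))
  }, integer(length(letters_seen))))
  colnames(comp) <- letters_seen
  grid <- purrr::map_dfr(types, function(t) {
    tibble::tibble(accession = enzymes$accession, ptm_type = t,
                   n_eligible = as.integer(rowSums(
                     comp[, alph[[t]], drop = FALSE])))
  }) |> dplyr::arrange(.data$accession, .data$ptm_type)

  out <- grid |>
    dplyr::left_join(counts, by = c("accession", "ptm_type")) |>
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      ppr = ifelse(.data$n_eligible == 0, NA_real_,
                   .data$n_sites / .data$n_eligible)
    ) |>
    dplyr::select("accession", "ptm_type", "n_sites", "n_eligible", "ppr")
  bad <- !is.na(out$ppr) & out$ppr > 1
  if (any(bad)) {
    warning("PPR > 1 for ", sum(bad),
            " enzyme/type combination(s): sites occur on residues outside ",
            "the eligibility alphabet")
  }
  out
}

#' Call predominant (recurrently detected) PTM sites
#'
#' For each enzyme and PTM type, sites are ranked by detection count
#' (descending; ties broken by ascending position for determinism) and
#' accumulated until their cumulative detection count first reaches the
#' stated fraction of all detections for that enzyme and type. The crossing
#' site is included. At the default 60% threshold these are the sites that
#' carry the bulk of independent experimental support.
#'
#' The predominant set is monotone in the threshold: the set at threshold t
#' is a subset of the set at any t' > t.
#'
#' @param sites harmonized site tibble (needs `detection_count`).
#' @param threshold cumulative detection fraction in (0, 1].
#' @return tibble with columns `accession`, `ptm_type`, `position`,
#'   `residue`, `rank`, `detection_count`, `cum_count`, `cum_fraction`,
#'   `threshold` — one row per predominant site.
#' @export
#' @examples
#' s <- tibble::tibble(accession = "E1", ptm_type = "phosphorylation",
#'                     position = 1:4, residue = "S",
#'                     detection_count = c(10L, 5L, 3L, 2L))
#' call_predominant(s, 0.6)$position  # 1 2
call_predominant <- function(sites, threshold = 0.60) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  if (nrow(sites) == 0) stop("empty site list")
  if (!"residue" %in% names(sites)) sites$residue <- NA_character_
  df <- sites[order(sites$accession, sites$ptm_type,
                    -sites$detection_count, sites$position), ]
  nr <- nrow(df)
  new_grp <- !duplicated(df[c("accession", "ptm_type")])
  start_idx <- which(new_grp)
  sizes <- diff(c(start_idx, nr + 1L))
  gid <- rep(seq_along(start_idx), sizes)
  cs <- cumsum(as.numeric(df$detection_count))
  base <- (cs[start_idx] - df$detection_count[start_idx])[gid]
  cum <- cs - base
  end_idx <- c(start_idx[-1] - 1L, nr)
  tot <- (cs[end_idx] - cs[start_idx] + df$detection_count[start_idx])[gid]
  keep <- (cum - df$detection_count) < threshold * tot
  rk <- seq_len(nr) - rep(start_idx, sizes) + 1L
  tibble::tibble(
    accession = df$accession[keep],
    ptm_type = df$ptm_type[keep],
    position = df$position[keep],
    residue = df$residue[keep],
    rank = rk[keep],
    detection_count = df$detection_count[keep],
    cum_count = cum[keep],
    cum_fraction = cum[keep] / tot[keep],
    threshold = threshold
  )
}

#' Threshold sensitivity of predominant-site calling
#'
#' Recomputes predominant calls at several cumulative-frequency thresholds
#' and reports, per enzyme, the predominant-site count at each threshold,
#' plus robustness statistics: Spearman rank correlation of the per-enzyme
#' count ordering between every threshold pair and the overlap (Jaccard) of
#' top-decile enzymes.
#'
#' @param sites harmonized site tibble.
#' @param thresholds numeric vector of fractions in (0, 1].
#' @return list with `counts` (tibble: accession, one `n_predominant_<t>`
#'   column per threshold) and `agreement` (tibble: threshold pair, Spearman
#'   rho, top-decile Jaccard overlap).
#' @export
sensitivity_scan <- function(sites, thresholds = c(0.50, 0.60, 0.70)) {
  if (any(thresholds <= 0 | thresholds > 1)) stop("thresholds must be in (0, 1]")
  thresholds <- sort(thresholds)
  per_thr <- lapply(thresholds, function(t) {
    call_predominant(sites, t) |>
      dplyr::count(.data$accession, name = paste0("n_predominant_", t))
  })
  counts <- Reduce(function(a, b) dplyr::full_join(a, b, by = "accession"),
                   per_thr) |>
    dplyr::mutate(dplyr::across(-"accession", ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::arrange(.data$accession)

  pairs <- utils::combn(thresholds, 2, simplify = FALSE)
  agreement <- purrr::map_dfr(pairs, function(pr) {
    a <- counts[[paste0("n_predominant_", pr[1])]]
    b <- counts[[paste0("n_predominant_", pr[2])]]
    top_k <- max(1L, ceiling(0.1 * nrow(counts)))
    top_a <- counts$accession[order(-a)][seq_len(top_k)]
    top_b <- counts$accession[order(-b)][seq_len(top_k)]
    tibble::tibble(
      threshold_a = pr[1], threshold_b = pr[2],
      spearman_rho = spearman_rho(a, b),
      top_decile_jaccard = length(intersect(top_a, top_b)) /
        length(union(top_a, top_b))
    )
  })
  list(counts = counts, agreement = agreement)
}

#' Summarize a feature distribution
#'
#' Quartile statistics (linear interpolation between order statistics — R
#' quantile type 7; this convention is held fixed because quartiles are
#' convention-sensitive), fixed-width histogram counts, and right-skew
#' indicators. The median is the headline summary used throughout the
#' package, as PTM features are non-normal and right-skewed.
#'
#' @param values numeric vector with at least one finite value.
#' @param bins number of fixed-width histogram bins.
#' @return list with `summary` (one-row tibble: n, min, q1, median, q3, max,
#'   mean, skewness, right_skewed) and `histogram` (tibble: bin_left,
#'   bin_right, count).
#' @export
summarize_distribution <- function(values, bins = 20) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to summarize")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  m <- mean(values)
  s <- stats::sd(values)
  skew <- if (length(values) > 2 && isTRUE(s > 0)) {
    mean(((values - m) / s)^3)
  } else 0
  breaks <- seq(q[1], q[5], length.out = bins + 1)
  if (q[1] == q[5]) breaks <- c(q[1] - 0.5, q[1] + 0.5)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  list(
    summary = tibble::tibble(
      n = length(values), min = q[1], q1 = q[2], median = q[3], q3 = q[4],
      max = q[5], mean = m, skewness = skew,
      right_skewed = m > q[3]
    ),
    histogram = tibble::tibble(
      bin_left = utils::head(h$breaks, -1),
      bin_right = utils::tail(h$breaks, -1),
      count = h$counts
    )
  )
}

#' Assemble the per-enzyme metrics table
#'
#' One row per enzyme combining total and per-type densities, per-type PPR
#' (wide columns `density_<type>`, `ppr_<type>`), the predominant-site count
#' at `predominant_threshold`, and — when region/variant tracks are given —
#' the architecture counts (hotspot regions, crosstalk residues,
#' mutation-bearing PTM positions, domain-localized sites). This is the
#' canonical input to the statistics and clustering layers.
#'
#' @param sites harmonized site tibble.
#' @param enzymes enzyme tibble.
#' @param regions optional region tibble.
#' @param variants optional variant tibble.
#' @param eligibility eligibility map for PPR.
#' @param predominant_threshold cumulative-detection fraction for
#'   [call_predominant()].
#' @param half_window,min_neighbors hotspot parameters, see
#'   [detect_hotspots()].
#' @param crosstalk_mode `"residue"` or `"window"`, see [detect_crosstalk()].
#' @return a wide tibble, one row per enzyme, carrying enzyme annotations
#'   (`ec_class`, flags) alongside all numeric metrics.
#' @export
enzyme_metrics <- function(sites, enzymes, regions = NULL, variants = NULL,
                           eligibility = default_eligibility(),
                           predominant_threshold = 0.60,
                           half_window = 7L, min_neighbors = 5L,
                           crosstalk_mode = "residue") {
  dens <- ptm_density(sites, enzymes)
  ptd <- per_type_density(sites, enzymes, zero_fill = TRUE) |>
    dplyr::select("accession", "ptm_type", "density") |>
    tidyr::pivot_wider(names_from = "ptm_type", values_from = "density",
                       names_prefix = "density_", values_fill = 0)
  ppr <- ptm_potentiality(sites, enzymes, eligibility) |>
    dplyr::select("accession", "ptm_type", "ppr") |>
    tidyr::pivot_wider(names_from = "ptm_type", values_from = "ppr",
                       names_prefix = "ppr_")
  pred <- call_predominant(sites, predominant_threshold) |>
    dplyr::count(.data$accession, name = "n_predominant")

  hs <- detect_hotspots(sites, enzymes, half_window = half_window,
                        min_neighbors = min_neighbors) |>
    dplyr::count(.data$accession, name = "n_hotspot_regions")
  # count-only equivalent of detect_crosstalk() in residue mode (the paste
  # of type sets is skipped); window mode falls back to the full scan
  uniq <- dplyr::distinct(sites, .data$accession, .data$position,
                          .data$ptm_type)
  ct <- if (crosstalk_mode == "residue") {
    uniq |>
      dplyr::count(.data$accession, .data$position) |>
      dplyr::filter(.data$n >= 2) |>
      dplyr::count(.data$accession, name = "n_crosstalk_residues")
  } else {
    detect_crosstalk(sites, mode = crosstalk_mode,
                     half_window = half_window) |>
      dplyr::count(.data$accession, name = "n_crosstalk_residues")
  }

  out <- enzymes |>
    dplyr::select("accession", "length", dplyr::any_of(c(
      "ec_class", "is_rate_limiting", "is_mitochondrial"))) |>
    dplyr::left_join(dens, by = "accession") |>
    dplyr::left_join(ptd, by = "accession") |>
    dplyr::left_join(ppr, by = "accession") |>
    dplyr::left_join(pred, by = "accession") |>
    dplyr::left_join(hs, by = "accession") |>
    dplyr::left_join(ct, by = "accession")

  if (!is.null(variants) && nrow(variants) > 0) {
    # positions with >= 1 PTM and >= 1 variant: count form of overlap_variants()
    mo <- dplyr::distinct(sites, .data$accession, .data$position) |>
      dplyr::semi_join(variants, by = c("accession", "position")) |>
      dplyr::count(.data$accession, name = "n_mutated_ptm_sites")
    out <- dplyr::left_join(out, mo, by = "accession")
  } else {
    out$n_mutated_ptm_sites <- 0L
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    # count form of localize_sites(): unique records inside a domain interval
    dom <- regions[regions$region_type == "domain",
                   c("accession", "start", "end")]
    dl <- uniq |>
      dplyr::inner_join(dom, by = "accession",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$position >= .data$start,
                    .data$position <= .data$end) |>
      dplyr::distinct(.data$accession, .data$position, .data$ptm_type) |>
      dplyr::count(.data$accession, name = "n_domain_localized_sites")
    out <- dplyr::left_join(out, dl, by = "accession")
  } else {
    out$n_domain_localized_sites <- 0L
  }
  out |>
    dplyr::mutate(dplyr::across(
      dplyr::any_of(c("n_predominant", "n_hotspot_regions",
                      "n_crosstalk_residues", "n_mutated_ptm_sites",
                      "n_domain_localized_sites")),
      ~ dplyr::coalesce(.x, 0L)))
}
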