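#' Detect PTM hotspot regions by sliding-window scan
#'
#' Around every PTM site at position p, the closed window
#' `[p - half_window, p + half_window]` (clipped to the sequence) is scanned
#' for co-occurring PTM records. A window qualifies when it contains at least
#' `min_neighbors` PTM records besides the central site record itself — other
#' records at the central position do count. Qualifying windows that overlap
#' are merged, and each maximal merged interval is reported as one hotspot
#' region.
#'
#' By default a "PTM record" is a unique (position, type) pair, so a residue
#' carrying two modification types contributes two records;
#' `count_unique_positions = TRUE` switches to counting modified residues.
#'
#' @param sites harmonized site tibble.
#' @param enzymes enzyme tibble (`accession`, `length`) for window clipping.
#' @param half_window residues scanned on each side of a site (default 7).
#' @param min_neighbors minimum co-occurring records, central site excluded
#'   (default 5).
#' @param count_unique_positions count modified positions instead of
#'   (position, type) records.
#' @return tibble with columns `accession`, `start`, `end`, `n_sites`
#'   (unique records inside the merged region), `n_windows` (qualifying
#'   windows merged), `seed_positions` (semicolon-joined window centers).
#' @export
detect_hotspots <- function(sites, enzymes, half_window = 7L,
                            min_neighbors = 5L,
                            count_unique_positions = FALSE) {
  stopifnot(half_window >= 1, min_neighbors >= 1)
  if (nrow(sites) == 0) {
    return(tibble::tibble(accession = character(0), start = integer(0),
                          end = integer(0), n_sites = integer(0),
                          n_windows = integer(0), seed_positions = character(0)))
  }
  len_map <- stats::setNames(enzymes$length, enzymes$accession)
  uniq <- dplyr::distinct(sites, .data$accession, .data$position, .data$ptm_type)
  pos_by_acc <- split(uniq$position, uniq$accession)
  res <- purrr::imap(pos_by_acc, function(positions, acc) {
      L <- unname(len_map[acc])
      rec_pos <- sort(positions)                      # one entry per record
      unit_pos <- if (count_unique_positions) unique(rec_pos) else rec_pos
      centers <- unique(rec_pos)
      lo <- pmax(centers - half_window, 1L)
      hi <- pmin(centers + half_window, if (is.na(L)) max(rec_pos) else L)
      n_in <- findInterval(hi, unit_pos) - findInterval(lo - 1L, unit_pos)
      # exclude exactly the central site record (or central position)
      qual <- (n_in - 1L) >= min_neighbors
      if (!any(qual)) return(NULL)
      qs <- lo[qual]; qe <- hi[qual]; qc <- centers[qual]
      # merge overlapping qualifying windows into maximal regions
      grp <- cumsum(c(TRUE, qs[-1] > cummax(qe)[-length(qe)]))
      s0 <- as.integer(tapply(qs, grp, min))
      e0 <- as.integer(tapply(qe, grp, max))
      tibble::tibble(
        accession = acc, start = s0, end = e0,
        n_sites = findInterval(e0, rec_pos) - findInterval(s0 - 1L, rec_pos),
        n_windows = as.integer(tabulate(grp)),
        seed_positions = vapply(split(qc, grp), paste, "", collapse = ";")
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble::tibble(accession = character(0), start = integer(0),
                          end = integer(0), n_sites = integer(0),
                          n_windows = integer(0), seed_positions = character(0)))
  }
  dplyr::arrange(res, .data$accession, .data$start)
}

#' Detect PTM crosstalk residues
#'
#' In `"residue"` mode (the default, used for all headline counts) a
#' crosstalk residue is a single position annotated with two or more distinct
#' PTM types. In `"window"` mode a position qualifies when its
#' `half_window`-neighborhood carries two or more distinct types (the
#' position's own type counts) — an interpretation of type co-occurrence
#' "within or near" a window.
#'
#' @param sites harmonized site tibble.
#' @param mode `"residue"` or `"window"`.
#' @param half_window neighborhood half-width for window mode.
#' @return tibble with columns `accession`, `position`, `ptm_types`
#'   (semicolon-joined, sorted), `n_types`, `mode`.
#' @export
detect_crosstalk <- function(sites, mode = c("residue", "window"),
                             half_window = 7L) {
  mode <- match.arg(mode)
  uniq <- dplyr::distinct(sites, .data$accession, .data$position, .data$ptm_type)
  if (mode == "residue") {
    multi <- uniq |>
      dplyr::count(.data$accession, .data$position, name = "n_types") |>
      dplyr::filter(.data$n_types >= 2)
    out <- uniq |>
      dplyr::semi_join(multi, by = c("accession", "position")) |>
      dplyr::group_by(.data$accession, .data$position) |>
      dplyr::summarise(
        ptm_types = paste(sort(unique(.data$ptm_type)), collapse = ";"),
        n_types = dplyr::n_distinct(.data$ptm_type), .groups = "drop")
  } else {
    out <- uniq |>
      dplyr::group_by(.data$accession) |>
      dplyr::group_map(function(df, key) {
        pos <- df$position; typ <- df$ptm_type
        upos <- sort(unique(pos))
        hits <- purrr::map_dfr(upos, function(p) {
          sel <- pos >= p - half_window & pos <= p + half_window
          tt <- sort(unique(typ[sel]))
          tibble::tibble(position = p,
                         ptm_types = paste(tt, collapse = ";"),
                         n_types = length(tt))
        })
        hits$accession <- key$accession[[1]]
        hits
      }) |>
      dplyr::bind_rows() |>
      dplyr::filter(.data$n_types >= 2) |>
      dplyr::select("accession", "position", "ptm_types", "n_types")
  }
  if (nrow(out) == 0) {
    return(tibble::tibble(accession = character(0), position = integer(0),
                          ptm_types = character(0), n_types = integer(0),
                          mode = character(0)))
  }
  out |>
    dplyr::mutate(mode = mode) |>
    dplyr::arrange(.data$accession, .data$position)
}

#' Localize PTM sites to annotated protein regions
#'
#' Each site receives every region-type label whose interval contains its
#' position (multi-label, no precedence hierarchy); sites inside no
#' annotated region are labelled `"unannotated"`, which never co-occurs with
#' another label.
#'
#' @param sites harmonized site tibble.
#' @param regions validated region tibble.
#' @return tibble with columns `accession`, `position`, `ptm_type`, `labels`
#'   (semicolon-joined, sorted unique region types).
#' @export
localize_sites <- function(sites, regions) {
  uniq <- dplyr::distinct(sites, .data$accession, .data$position, .data$ptm_type)
  hits <- uniq |>
    dplyr::inner_join(
      dplyr::select(regions, "accession", "region_type", "start", "end"),
      by = "accession", relationship = "many-to-many") |>
    dplyr::filter(.data$position >= .data$start, .data$position <= .data$end) |>
    dplyr::group_by(.data$accession, .data$position, .data$ptm_type) |>
    dplyr::summarise(
      labels = paste(sort(unique(.data$region_type)), collapse = ";"),
      .groups = "drop")
  uniq |>
    dplyr::left_join(hits, by = c("accession", "position", "ptm_type")) |>
    dplyr::mutate(labels = dplyr::coalesce(.data$labels, "unannotated")) |>
    dplyr::arrange(.data$accession, .data$position, .data$ptm_type)
}

#' Region-type PTM enrichment table
#'
#' For every region type and PTM type: the number of sites falling inside
#' regions of that type, the residues covered by that region type across the
#' cohort (per-enzyme union of intervals), and the sites-per-covered-residue
#' versus sites-per-uncovered-residue ratio.
#'
#' @param sites harmonized site tibble.
#' @param regions validated region tibble.
#' @param enzymes enzyme tibble (for total lengths).
#' @return tibble with columns `region_type`, `ptm_type`, `n_sites_inside`,
#'   `n_sites_outside`, `residues_covered`, `residues_uncovered`, `rate_inside`,
#'   `rate_outside`, `rate_ratio`.
#' @export
region_enrichment <- function(sites, regions, enzymes) {
  total_len <- sum(enzymes$length)
  loc <- localize_sites(sites, regions)
  cov_by_type <- regions |>
    dplyr::group_by(.data$region_type, .data$accession) |>
    dplyr::group_map(function(df, key) {
      # merged coverage within one enzyme
      o <- order(df$start)
      s <- df$start[o]; e <- df$end[o]
      grp <- cumsum(c(TRUE, s[-1] > cummax(e)[-length(e)]))
      covered <- sum(vapply(split(seq_along(s), grp), function(i) {
        max(e[i]) - min(s[i]) + 1L
      }, 0L))
      tibble::tibble(region_type = key$region_type[[1]], covered = covered)
    }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$region_type) |>
    dplyr::summarise(residues_covered = sum(.data$covered), .groups = "drop")

  n_sites <- nrow(dplyr::distinct(sites, .data$accession, .data$position,
                                  .data$ptm_type))
  purrr::map_dfr(unique(regions$region_type), function(rt) {
    inside <- loc[grepl(rt, loc$labels, fixed = TRUE), ]
    per_ptm <- dplyr::count(inside, .data$ptm_type, name = "n_sites_inside")
    all_ptm <- dplyr::count(
      dplyr::distinct(sites, .data$accession, .data$position, .data$ptm_type),
      .data$ptm_type, name = "n_total")
    cov <- cov_by_type$residues_covered[cov_by_type$region_type == rt]
    per_ptm |>
      dplyr::right_join(all_ptm, by = "ptm_type") |>
      dplyr::mutate(
        region_type = rt,
        n_sites_inside = dplyr::coalesce(.data$n_sites_inside, 0L),
        n_sites_outside = .data$n_total - .data$n_sites_inside,
        residues_covered = cov,
        residues_uncovered = total_len - cov,
        rate_inside = .data$n_sites_inside / .data$residues_covered,
        rate_outside = .data$n_sites_outside / .data$residues_uncovered,
        rate_ratio = .data$rate_inside / .data$rate_outside
      ) |>
      dplyr::select("region_type", "ptm_type", "n_sites_inside",
                    "n_sites_outside", "residues_covered",
                    "residues_uncovered", "rate_inside", "rate_outside",
                    "rate_ratio")
  })
}

#' Overlap variants with PTM-bearing residues
#'
#' Reports every PTM-bearing position that carries at least one variant,
#' with the modification types at that position, the variant classes, and a
#' missense flag. A variant at a position with no PTM yields no record.
#'
#' @param sites harmonized site tibble.
#' @param variants validated variant tibble.
#' @return tibble with columns `accession`, `position`, `ptm_types`,
#'   `n_variants`, `variant_classes`, `any_missense`.
#' @export
overlap_variants <- function(sites, variants) {
  ptm_pos <- sites |>
    dplyr::semi_join(variants, by = c("accession", "position")) |>
    dplyr::group_by(.data$accession, .data$position) |>
    dplyr::summarise(
      ptm_types = paste(sort(unique(.data$ptm_type)), collapse = ";"),
      residue = .data$residue[1], .groups = "drop")
  variants |>
    dplyr::inner_join(ptm_pos, by = c("accession", "position")) |>
    dplyr::group_by(.data$accession, .data$position) |>
    dplyr::summarise(
      ptm_types = .data$ptm_types[1],
      residue = .data$residue[1],
      n_variants = dplyr::n(),
      variant_classes = paste(sort(unique(.data$variant_class)), collapse = ";"),
      any_missense = any(.data$variant_class == "missense"),
      .groups = "drop") |>
    dplyr::arrange(.data$accession, .data$position)
}

#' @rdname overlap_variants
#' @param overlaps result of `overlap_variants()`.
#' @return `variant_overlap_summary()`: list with total overlapped positions,
#'   per-variant-class counts and per-residue identity counts.
#' @export
variant_overlap_summary <- function(overlaps) {
  class_counts <- overlaps |>
    tidyr::separate_rows("variant_classes", sep = ";") |>
    dplyr::count(.data$variant_classes, name = "n")
  residue_counts <- overlaps |>
    dplyr::count(.data$residue, name = "n", sort = TRUE)
  list(
    n_overlapped_positions = nrow(overlaps),
    by_class = class_counts,
    by_residue = residue_counts
  )
}
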