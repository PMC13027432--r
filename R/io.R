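#' Read reference protein sequences from FASTA
#'
#' Parses a FASTA file of canonical protein sequences into the enzyme catalog
#' skeleton used throughout the package. Both UniProt-style headers
#' (`sp|P07954|FUMH_HUMAN ...`) and bare-accession headers are accepted; the
#' accession is the second `|`-delimited field when present, otherwise the
#' first whitespace-delimited token.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param strict if `TRUE`, sequences containing characters outside the 20
#'   canonical one-letter codes are an error; otherwise they are retained
#'   with a warning.
#' @return a tibble with columns `accession`, `gene_symbol`, `sequence`,
#'   `length`, plus empty annotation columns (`ec_class`, `pathways`,
#'   `is_rate_limiting`, `is_mitochondrial`, `text_descriptors`) to be filled
#'   by [read_enzyme_annotations()].
#' @export
read_enzyme_fasta <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  first_tok <- sub("\\s.*$", "", headers)
  has_pipes <- grepl("|", first_tok, fixed = TRUE)
  acc <- ifelse(has_pipes,
                vapply(strsplit(first_tok, "|", fixed = TRUE),
                       function(p) if (length(p) >= 2) p[2] else p[1], ""),
                first_tok)
  gene <- ifelse(has_pipes,
                 vapply(strsplit(first_tok, "|", fixed = TRUE),
                        function(p) if (length(p) >= 3) sub("_.*$", "", p[3]) else NA_character_, ""),
                 NA_character_)
  if (any(acc == "" | is.na(acc))) stop("FASTA record with empty accession")
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- unname(toupper(as.character(aa)))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for accession(s): ",
         paste(acc[nchar(seqs) == 0], collapse = ", "))
  }
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    msg <- paste0("non-canonical residue characters in: ",
                  paste(acc[bad], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  tibble::tibble(
    accession = unname(acc),
    gene_symbol = unname(gene),
    sequence = unname(seqs),
    length = nchar(seqs),
    ec_class = NA_character_,
    pathways = NA_character_,
    is_rate_limiting = NA,
    is_mitochondrial = NA,
    text_descriptors = NA_character_
  )
}

#' Write an enzyme catalog back to FASTA
#'
#' @param enzymes enzyme tibble (needs `accession`, `sequence`).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_enzyme_fasta <- function(enzymes, path) {
  aa <- Biostrings::AAStringSet(enzymes$sequence)
  names(aa) <- enzymes$accession
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Split a joint residue+position token like "S293" into residue + position.
parse_joint_site <- function(site) {
  residue <- toupper(substr(trimws(site), 1, 1))
  position <- suppressWarnings(as.integer(sub("^[A-Za-z]", "", trimws(site))))
  list(residue = residue, position = position)
}

#' Read a residue-level PTM annotation table
#'
#' Reads one source table of raw PTM site annotations in one of the supported
#' dialects and returns standardized raw records. PTM type spellings are
#' normalized through the shipped synonym table ([normalize_ptm_type()]).
#' Rows whose position cannot be parsed to a positive integer are dropped and
#' counted in the load report (attribute `load_report`).
#'
#' Dialect column expectations (TSV unless the file ends in `.csv`):
#' \describe{
#'   \item{generic_tsv}{`accession`, `position`, `residue`, `ptm_type`;
#'     optional `source`, `study_count`, `functional_note`.}
#'   \item{psp_like}{`accession`, `site` (joint residue+position, e.g.
#'     "S293"), `modification`; optional `lt_lit`, `ms_lit` literature counts
#'     (summed into `study_count`), `functional_note`.}
#'   \item{dbptm_like}{`accession`, `position`, `ptm_type`; optional
#'     `residue`, `pmids` (semicolon-joined; the count of entries becomes
#'     `study_count`).}
#'   \item{qptm_like}{`accession`, `site` (joint), `ptm_type`; optional
#'     `n_studies`.}
#' }
#' A `study_count` absent from a dialect is treated as 1 per row, so a site
#' is retained irrespective of the number of supporting studies.
#'
#' @param path path to the table.
#' @param dialect one of `"generic_tsv"`, `"psp_like"`, `"dbptm_like"`,
#'   `"qptm_like"`.
#' @param source_tag database tag recorded on each record; defaults to the
#'   dialect name.
#' @return tibble of raw records with columns `accession`, `position`,
#'   `residue`, `ptm_type`, `source`, `study_count`, `functional_note`;
#'   attribute `load_report` is a list counting parsed and dropped rows.
#' @export
read_ptm_table <- function(path,
                           dialect = c("generic_tsv", "psp_like",
                                       "dbptm_like", "qptm_like"),
                           source_tag = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  need <- switch(dialect,
    generic_tsv = c("accession", "position", "residue", "ptm_type"),
    psp_like    = c("accession", "site", "modification"),
    dbptm_like  = c("accession", "position", "ptm_type"),
    qptm_like   = c("accession", "site", "ptm_type"))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("dialect '", dialect, "' requires missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(source_tag)) source_tag <- sub("_like$", "", dialect)

  if (dialect %in% c("psp_like", "qptm_like")) {
    js <- parse_joint_site(tab$site)
    position <- js$position
    residue <- js$residue
  } else {
    position <- suppressWarnings(as.integer(tab$position))
    residue <- if ("residue" %in% names(tab)) toupper(tab$residue) else NA_character_
  }
  type_col <- if (dialect == "psp_like") tab$modification else tab$ptm_type
  ptm_type <- normalize_ptm_type(type_col)
  nonstandard <- attr(ptm_type, "nonstandard")

  study_count <- rep(1L, nrow(tab))
  if (dialect == "psp_like") {
    lt <- if ("lt_lit" %in% names(tab)) dplyr::coalesce(as.integer(tab$lt_lit), 0L) else 0L
    ms <- if ("ms_lit" %in% names(tab)) dplyr::coalesce(as.integer(tab$ms_lit), 0L) else 0L
    study_count <- pmax(lt + ms, 1L)
  } else if (dialect == "dbptm_like" && "pmids" %in% names(tab)) {
    study_count <- pmax(lengths(strsplit(dplyr::coalesce(tab$pmids, ""), ";", fixed = TRUE)), 1L)
  } else if (dialect == "qptm_like" && "n_studies" %in% names(tab)) {
    study_count <- pmax(dplyr::coalesce(as.integer(tab$n_studies), 1L), 1L)
  } else if ("study_count" %in% names(tab)) {
    study_count <- pmax(dplyr::coalesce(as.integer(tab$study_count), 1L), 1L)
  }

  note <- if ("functional_note" %in% names(tab)) as.character(tab$functional_note) else NA_character_
  out <- tibble::tibble(
    accession = as.character(tab$accession),
    position = position,
    residue = as.character(residue),
    ptm_type = as.character(ptm_type),
    source = source_tag,
    study_count = as.integer(study_count),
    functional_note = note
  )
  bad_pos <- is.na(out$position) | out$position < 1L
  report <- list(
    n_rows = nrow(out),
    n_dropped_bad_position = sum(bad_pos),
    nonstandard_types = nonstandard
  )
  out <- out[!bad_pos, , drop = FALSE]
  attr(out, "load_report") <- report
  out
}

#' Harmonize raw PTM records into a deduplicated site catalog
#'
#' Consolidates raw records from any number of sources into exactly one site
#' per (accession, position, PTM type). Detection counts are summed across
#' contributing records (each record contributes at least 1), sources are
#' unioned, and conflicting functional notes are all kept, pipe-joined.
#' Records referencing unknown accessions, positions beyond the sequence, or
#' an annotated residue that disagrees with the reference sequence character
#' at that position are excluded and itemized in the report — the sequence is
#' authoritative and mismatches are never remapped.
#'
#' The operation is idempotent (a harmonized catalog passes through
#' unchanged) and order-independent (permuting input rows gives an identical
#' catalog).
#'
#' @param raw tibble of raw records from [read_ptm_table()] (or a previously
#'   harmonized catalog: `detection_count`/`sources` columns are accepted in
#'   place of `study_count`/`source`).
#' @param enzymes enzyme tibble from [read_enzyme_fasta()].
#' @return a list with `sites` — tibble with columns `accession`, `position`,
#'   `residue`, `ptm_type`, `detection_count`, `sources` (semicolon-joined),
#'   `functional_note` — and `report`, a list of rejection tallies with
#'   reason codes.
#' @export
harmonize_sites <- function(raw, enzymes) {
  stopifnot(is.data.frame(raw), is.data.frame(enzymes))
  raw <- tibble::as_tibble(raw)
  if (!"study_count" %in% names(raw) && "detection_count" %in% names(raw)) {
    raw$study_count <- raw$detection_count
  }
  if (!"source" %in% names(raw) && "sources" %in% names(raw)) {
    raw$source <- raw$sources
  }
  if (!"study_count" %in% names(raw)) raw$study_count <- 1L
  if (!"source" %in% names(raw)) raw$source <- "unspecified"
  if (!"functional_note" %in% names(raw)) raw$functional_note <- NA_character_
  raw$study_count <- pmax(dplyr::coalesce(as.integer(raw$study_count), 1L), 1L)

  seq_map <- stats::setNames(enzymes$sequence, enzymes$accession)
  len_map <- stats::setNames(enzymes$length, enzymes$accession)

  known <- raw$accession %in% enzymes$accession
  pos_ok <- known & !is.na(raw$position) & raw$position >= 1L &
    raw$position <= dplyr::coalesce(unname(len_map[raw$accession]), 0L)
  seq_res <- rep(NA_character_, nrow(raw))
  seq_res[pos_ok] <- substr(seq_map[raw$accession[pos_ok]],
                            raw$position[pos_ok], raw$position[pos_ok])
  res_ok <- pos_ok & (is.na(raw$residue) | raw$residue == seq_res)

  rejected <- dplyr::bind_rows(
    dplyr::mutate(raw[!known, c("accession", "position", "ptm_type")],
                  reason = "unknown_accession"),
    dplyr::mutate(raw[known & !pos_ok, c("accession", "position", "ptm_type")],
                  reason = "position_out_of_bounds"),
    dplyr::mutate(raw[pos_ok & !res_ok, c("accession", "position", "ptm_type")],
                  reason = "residue_mismatch")
  )

  kept <- raw[res_ok, , drop = FALSE]
  kept$residue <- seq_res[res_ok]

  join_unique <- function(x) {
    x <- unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE))
    if (length(x) == 0) return(NA_character_)
    paste(sort(unique(x)), collapse = ";")
  }
  join_notes <- function(x) {
    x <- unlist(strsplit(x[!is.na(x) & x != ""], "|", fixed = TRUE))
    if (length(x) == 0) return(NA_character_)
    paste(sort(unique(x)), collapse = "|")
  }
  sites <- kept |>
    dplyr::group_by(.data$accession, .data$position, .data$ptm_type) |>
    dplyr::summarise(
      residue = .data$residue[1],
      detection_count = sum(.data$study_count),
      sources = join_unique(.data$source),
      functional_note = join_notes(.data$functional_note),
      .groups = "drop"
    ) |>
    dplyr::select("accession", "position", "residue", "ptm_type",
                  "detection_count", "sources", "functional_note") |>
    dplyr::arrange(.data$accession, .data$position, .data$ptm_type)

  report <- list(
    n_input = nrow(raw),
    n_accepted_records = nrow(kept),
    n_sites = nrow(sites),
    n_rejected = nrow(rejected),
    rejected = dplyr::count(rejected, .data$reason, name = "n"),
    rejected_records = tibble::as_tibble(rejected)
  )
  list(sites = sites, report = report)
}

#' Read and validate a region annotation table
#'
#' Expects a TSV with columns `accession`, `region_type`, `start`, `end`,
#' `name`. Region types are restricted to domain, family, conserved_site,
#' repeat and disordered. When `enzymes` is supplied, regions extending
#' beyond the sequence are clipped to `[1, length]` with a warning, and
#' regions with `start > end` or on unknown accessions are rejected (listed
#' in the `rejected` attribute).
#'
#' @param path path to the TSV.
#' @param enzymes optional enzyme tibble for bounds validation.
#' @return tibble of validated region annotations.
#' @export
read_region_table <- function(path, enzymes = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("accession", "region_type", "start", "end", "name")
  if (length(setdiff(need, names(tab))) > 0) {
    stop("region table requires columns: ", paste(need, collapse = ", "))
  }
  tab <- tibble::tibble(
    accession = as.character(tab$accession),
    region_type = as.character(tab$region_type),
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    name = as.character(tab$name)
  )
  validate_regions(tab, enzymes)
}

#' @rdname read_region_table
#' @param regions region tibble to validate in-memory.
#' @export
validate_regions <- function(regions, enzymes = NULL) {
  allowed <- c("domain", "family", "conserved_site", "repeat", "disordered")
  bad_type <- !regions$region_type %in% allowed
  bad_order <- is.na(regions$start) | is.na(regions$end) | regions$start > regions$end
  reject <- bad_type | bad_order
  if (!is.null(enzymes)) {
    len_map <- stats::setNames(enzymes$length, enzymes$accession)
    known <- regions$accession %in% enzymes$accession
    reject <- reject | !known
    lens <- unname(len_map[regions$accession])
    clip <- !reject & (regions$start < 1L | regions$end > lens)
    if (any(clip)) {
      warning(sum(clip), " region(s) clipped to sequence bounds")
      regions$start[clip] <- pmax(regions$start[clip], 1L)
      regions$end[clip] <- pmin(regions$end[clip], lens[clip])
    }
  }
  out <- regions[!reject, , drop = FALSE]
  attr(out, "rejected") <- regions[reject, , drop = FALSE]
  out
}

#' Read a variant table
#'
#' Expects a TSV with columns `accession`, `position`, `ref_residue`,
#' `alt_residue`, `variant_class` (missense, nonsense, synonymous,
#' engineered, other) and optional `source`. Missense rows where the
#' reference and alternate residues are identical violate the record
#' contract and are rejected (listed in attribute `rejected`).
#'
#' @param path path to the TSV.
#' @return tibble of validated variant records.
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("accession", "position", "ref_residue", "alt_residue", "variant_class")
  if (length(setdiff(need, names(tab))) > 0) {
    stop("variant table requires columns: ", paste(need, collapse = ", "))
  }
  out <- tibble::tibble(
    accession = as.character(tab$accession),
    position = as.integer(tab$position),
    ref_residue = toupper(as.character(tab$ref_residue)),
    alt_residue = toupper(as.character(tab$alt_residue)),
    variant_class = as.character(tab$variant_class),
    source = if ("source" %in% names(tab)) as.character(tab$source) else "unspecified"
  )
  bad <- is.na(out$position) | out$position < 1L |
    (out$variant_class == "missense" & out$ref_residue == out$alt_residue)
  res <- out[!bad, , drop = FALSE]
  attr(res, "rejected") <- out[bad, , drop = FALSE]
  res
}

#' Merge enzyme-level annotations into the catalog
#'
#' Reads a TSV with column `accession` plus any of `ec_class`, `pathways`
#' (semicolon-joined), `is_rate_limiting`, `is_mitochondrial`,
#' `text_descriptors` (semicolon-joined) and merges them into the enzyme
#' tibble. Enzymes absent from the annotation file keep default values
#' (`ec_class` "unknown", flags `FALSE`).
#'
#' @param enzymes enzyme tibble from [read_enzyme_fasta()].
#' @param path path to the annotation TSV.
#' @return enzyme tibble with annotation columns filled.
#' @export
read_enzyme_annotations <- function(enzymes, path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"accession" %in% names(ann)) stop("annotation table requires 'accession'")
  keep <- intersect(c("accession", "ec_class", "pathways", "is_rate_limiting",
                      "is_mitochondrial", "text_descriptors"), names(ann))
  ann <- ann[keep]
  out <- enzymes |>
    dplyr::select(-dplyr::any_of(setdiff(keep, "accession"))) |>
    dplyr::left_join(ann, by = "accession")
  out$ec_class <- dplyr::coalesce(out$ec_class, "unknown")
  out$is_rate_limiting <- dplyr::coalesce(as.logical(out$is_rate_limiting), FALSE)
  out$is_mitochondrial <- dplyr::coalesce(as.logical(out$is_mitochondrial), FALSE)
  out
}

#' Write the harmonized site catalog and report
#'
#' @param sites harmonized site tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_site_catalog
#' @param report harmonization report list from [harmonize_sites()].
#' @export
write_harmonization_report <- function(report, path) {
  report$rejected <- as.list(stats::setNames(report$rejected$n, report$rejected$reason))
  report$rejected_records <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
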