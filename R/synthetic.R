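#' Configuration for the synthetic PTM cohort generator
#'
#' Builds the parameter list consumed by [generate_cohort()]. Two presets are
#' shipped: `"cohort_small"` (200 enzymes; used by the test suite) and
#' `"cohort_paper_scale"` (771 enzymes; the scale of the real human metabolic
#' enzyme catalog). Any field can be overridden through `...`.
#'
#' The generator emulates the statistical shape of curated multi-database PTM
#' catalogs: a right-skewed per-enzyme modification density (gamma-distributed
#' per-enzyme propensity driving Bernoulli placement over chemically eligible
#' residues), multiple PTM types with residue-specific eligibility, burst-like
#' clustered placement producing hotspots, residue-level multi-type
#' co-annotation (crosstalk), heavy-tailed per-site detection counts (shifted
#' geometric), domain/disordered region tracks, variant tracks, and two
#' planted enzyme groups — a PTM-enriched group (density, burst and crosstalk
#' rates multiplied by `enrichment_multiplier`) versus a sparse group — with
#' group-linked pathway labels and rate-limiting flags.
#'
#' @param preset `"cohort_small"` or `"cohort_paper_scale"`.
#' @param ... named overrides of any config field.
#' @return a list of class `ptm_cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config("cohort_small", seed = 7)
#' cfg$n_enzymes
cohort_config <- function(preset = c("cohort_small", "cohort_paper_scale"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_enzymes = if (preset == "cohort_small") 200L else 771L,
    length_range = c(150L, 1200L),
    # per-type residue eligibility and per-eligible-residue base modification
    # probability (scaled by the per-enzyme gamma propensity)
    ptm_types = tibble::tribble(
      ~ptm_type,                ~residues, ~base_rate,
      "phosphorylation",        "STY",     0.28,
      "methylation",            "KR",      0.18,
      "ubiquitination",         "K",       0.30,
      "acetylation",            "K",       0.20,
      "sumoylation",            "K",       0.06,
      "succinylation",          "K",       0.04,
      "malonylation",           "K",       0.04,
      "o_linked_glycosylation", "ST",      0.03,
      "n_linked_glycosylation", "N",       0.04,
      "s_nitrosylation",        "C",       0.03,
      "sulfoxidation",          "M",       0.05
    ),
    density_shape = 10,           # gamma shape of per-enzyme propensity (mean 1)
    burst_rate = 0.5,             # expected hotspot bursts per enzyme (base)
    burst_width = 15L,            # residues spanned by one burst window
    burst_extra_sites = 1,        # Poisson mean added to the 6-site burst floor
    crosstalk_rate = 0.10,        # P(second PTM type on a modified residue)
    detection_geom_p = 0.35,      # detection_count = 1 + Geom(p): heavy tail
    enriched_fraction = 0.15,
    enrichment_multiplier = 3,
    pathway_labels = list(
      enriched = c("glycolysis", "tca_cycle", "pentose_phosphate", "fatty_acid_oxidation"),
      sparse = c("lipid", "amino_acid", "nucleotide", "xenobiotic", "cofactor", "steroid")
    ),
    core_label = "core",
    core_prob = c(enriched = 0.9, sparse = 0.05),
    rate_limiting_prob = 0.5,     # within the enriched group
    mitochondrial_prob = c(enriched = 0.45, sparse = 0.25),
    domain_coverage = 0.40,       # fraction of each sequence covered by domains
    disorder_prob = 0.3,
    variant_overlap_rate = 0.15,
    background_variant_rate = 0.005,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_cohort_config(cfg)
  structure(cfg, class = "ptm_cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_enzymes >= 1,
    cfg$length_range[1] >= 30, cfg$length_range[2] >= cfg$length_range[1],
    cfg$enriched_fraction > 0, cfg$enriched_fraction < 1,
    cfg$enrichment_multiplier >= 1,
    cfg$crosstalk_rate >= 0, cfg$crosstalk_rate <= 1,
    cfg$variant_overlap_rate >= 0, cfg$variant_overlap_rate <= 1,
    cfg$domain_coverage >= 0, cfg$domain_coverage < 1
  )
  if (any(nchar(cfg$ptm_types$residues) == 0)) {
    stop("eligibility alphabet empty for an active PTM type")
  }
  invisible(cfg)
}

DOMAIN_VOCAB <- c("lyase_fold", "kinase_fold", "rossmann_fold", "tim_barrel",
                  "beta_clamp", "hydrolase_core", "transferase_core",
                  "dehydrogenase_core")
SHARED_TERMS <- c("catalytic", "binding", "metal", "dimer", "cytosolic",
                  "nadh", "atp", "substrate_channel", "conserved")
ENRICHED_TERMS <- c("flux_control", "central_carbon", "kinase_substrate",
                    "allosteric", "regulatory_node")
SPARSE_TERMS <- c("membrane", "transport", "detoxification", "peripheral")

#' Generate a seeded synthetic PTM cohort with planted structure
#'
#' Draws a full cohort — enzyme sequences, a harmonized-style PTM site
#' catalog, region and variant tracks, enzyme-level annotations — together
#' with the planted ground truth (group labels, realized burst intervals,
#' injected crosstalk positions) against which downstream recovery is tested.
#' Runs are fully reproducible: the same config and seed yield byte-identical
#' outputs.
#'
#' Bursts are planted by sampling a burst center and placing at least six
#' unique (position, type) site records inside the surrounding
#' `burst_width`-residue window, always including a site at the eligible
#' position closest to the center, so every realized burst is a positive
#' control carrying a detectable hotspot signal at the default detection
#' parameters.
#'
#' @param config a `ptm_cohort_config` from [cohort_config()].
#' @param seed integer; overrides `config$seed` when given.
#' @return a list of class `ptm_cohort` with elements `enzymes`, `sites`,
#'   `regions`, `variants`, `truth` (list: `groups`, `bursts`, `crosstalk`,
#'   `config`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)

  n <- as.integer(config$n_enzymes)
  if (n < 1) stop("n_enzymes must be >= 1")
  type_tab <- config$ptm_types
  type_res <- strsplit(type_tab$residues, "")
  names(type_res) <- type_tab$ptm_type
  hw <- (as.integer(config$burst_width) - 1L) %/% 2L

  # per-letter total base rate and the eligible types (with weights) carried
  # by that letter; one PTM type is placed per modified residue, so residue
  # co-annotation is governed exclusively by crosstalk_rate
  letter_types <- lapply(stats::setNames(AA_ALPHABET, AA_ALPHABET), function(a) {
    sel <- vapply(type_res, function(r) a %in% r, TRUE)
    list(types = type_tab$ptm_type[sel], w = type_tab$base_rate[sel],
         total = sum(type_tab$base_rate[sel]))
  })
  letter_rate <- vapply(letter_types, `[[`, 0, "total")

  n_enr <- max(1L, round(config$enriched_fraction * n))
  group <- sample(c(rep("enriched", n_enr), rep("sparse", n - n_enr)))
  acc <- sprintf("SYN%04d", seq_len(n))

  lens <- sample(config$length_range[1]:config$length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) paste(sample(AA_ALPHABET, L, replace = TRUE),
                                         collapse = ""), "")
  lambda <- stats::rgamma(n, shape = config$density_shape,
                          rate = config$density_shape)

  site_list <- vector("list", n)
  burst_list <- vector("list", n)
  ct_list <- vector("list", n)
  var_list <- vector("list", n)
  reg_list <- vector("list", n)

  draw_types <- function(chars, positions) {
    # one type per modified residue, chosen proportional to per-type base rates
    out <- character(length(positions))
    for (a in unique(chars[positions])) {
      idx <- which(chars[positions] == a)
      lt <- letter_types[[a]]
      out[idx] <- if (length(lt$types) == 1) lt$types else
        sample(lt$types, length(idx), replace = TRUE, prob = lt$w)
    }
    out
  }

  for (i in seq_len(n)) {
    L <- lens[i]
    chars <- strsplit(seqs[i], "")[[1]]
    mult <- if (group[i] == "enriched") config$enrichment_multiplier else 1
    rate_pos <- unname(letter_rate[chars])

    # base placement: Bernoulli per residue with rate scaled by the
    # per-enzyme gamma propensity (right-skewed density across enzymes)
    p_mod <- pmin(0.95, lambda[i] * mult * rate_pos)
    pos <- which(stats::runif(L) < p_mod)

    # planted bursts: >= 6 modified residues inside one burst_width window,
    # always anchored at the eligible position nearest the window center
    n_bursts <- stats::rpois(1, config$burst_rate * mult)
    b_start <- integer(0); b_end <- integer(0); b_n <- integer(0)
    if (n_bursts > 0 && L > 2 * hw + 2) {
      centers <- sample((hw + 1L):(L - hw), n_bursts, replace = TRUE)
      for (ctr in centers) {
        win <- (ctr - hw):(ctr + hw)
        avail <- win[rate_pos[win] > 0]
        if (length(avail) < 6) next
        n_take <- min(length(avail), 6L + stats::rpois(1, config$burst_extra_sites))
        anchor <- avail[which.min(abs(avail - ctr))]
        take <- c(anchor, sample(setdiff(avail, anchor), n_take - 1L))
        pos <- c(pos, take)
        b_start <- c(b_start, min(take))
        b_end <- c(b_end, max(take))
        b_n <- c(b_n, n_take)
      }
    }

    pos <- sort(unique(pos))
    typ <- draw_types(chars, pos)

    # crosstalk injection: a second, distinct eligible type on modified residues
    ct_pos <- integer(0); ct_typ <- character(0)
    if (length(pos) > 0 && config$crosstalk_rate > 0) {
      p_ct <- min(1, config$crosstalk_rate * mult)
      cand <- which(stats::runif(length(pos)) < p_ct)
      for (j in cand) {
        lt <- letter_types[[chars[pos[j]]]]
        new_types <- setdiff(lt$types, typ[j])
        if (length(new_types) == 0) next
        ct_pos <- c(ct_pos, pos[j])
        ct_typ <- c(ct_typ, new_types[sample.int(length(new_types), 1)])
      }
    }
    pos <- c(pos, ct_pos)
    typ <- c(typ, ct_typ)

    ord <- order(pos, typ)
    pos <- pos[ord]; typ <- typ[ord]
    site_list[[i]] <- list(position = pos, ptm_type = typ,
                           residue = chars[pos])
    burst_list[[i]] <- list(start = b_start, end = b_end, n_sites = b_n)
    ct_list[[i]] <- ct_pos

    # regions: 1-3 non-overlapping domains covering ~domain_coverage of the
    # sequence, placed one per equal-width block; optional disordered segment
    k_dom <- sample.int(3L, 1)
    tot <- round(config$domain_coverage * L)
    dl <- diff(as.integer(round(seq(0, tot, length.out = k_dom + 1))))
    blocks <- as.integer(round(seq(0, L, length.out = k_dom + 1)))
    r_start <- integer(0); r_end <- integer(0); r_type <- character(0); r_name <- character(0)
    for (j in seq_len(k_dom)) {
      bs <- blocks[j] + 1L; be <- blocks[j + 1]
      len_j <- min(dl[j], be - bs + 1L)
      if (len_j < 3) next
      len_j <- as.integer(len_j)
      s0 <- if (be - len_j + 1L > bs) sample(bs:(be - len_j + 1L), 1) else bs
      s0 <- as.integer(s0)
      r_start <- c(r_start, s0); r_end <- c(r_end, s0 + len_j - 1L)
      r_type <- c(r_type, "domain")
      r_name <- c(r_name, sample(DOMAIN_VOCAB, 1))
    }
    if (stats::runif(1) < config$disorder_prob) {
      dlen <- sample(20:60, 1)
      if (L > dlen) {
        s0 <- sample.int(L - dlen, 1)
        r_start <- c(r_start, s0); r_end <- c(r_end, as.integer(s0 + dlen - 1L))
        r_type <- c(r_type, "disordered"); r_name <- c(r_name, "disordered_segment")
      }
    }
    reg_list[[i]] <- list(start = r_start, end = r_end,
                          region_type = r_type, name = r_name)

    # variants: on PTM positions at variant_overlap_rate, background elsewhere
    upos <- unique(pos)
    v_pos <- integer(0)
    if (length(upos) > 0) {
      v_pos <- upos[stats::runif(length(upos)) < config$variant_overlap_rate]
    }
    non_ptm <- setdiff(seq_len(L), upos)
    n_bg <- stats::rbinom(1, length(non_ptm), config$background_variant_rate)
    if (n_bg > 0) v_pos <- c(v_pos, sample(non_ptm, n_bg))
    v_pos <- sort(v_pos)
    if (length(v_pos) > 0) {
      cls <- sample(c("missense", "nonsense", "synonymous", "engineered", "other"),
                    length(v_pos), replace = TRUE,
                    prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
      refs <- chars[v_pos]
      alts <- vapply(seq_along(v_pos), function(j) {
        if (cls[j] == "synonymous") refs[j] else sample(setdiff(AA_ALPHABET, refs[j]), 1)
      }, "")
      var_list[[i]] <- list(position = v_pos, ref = refs, alt = alts, class = cls)
    } else {
      var_list[[i]] <- list(position = integer(0), ref = character(0),
                            alt = character(0), class = character(0))
    }
  }

  n_sites_per <- vapply(site_list, function(s) length(s$position), 0L)
  sites <- tibble::tibble(
    accession = rep(acc, n_sites_per),
    position = unlist(lapply(site_list, `[[`, "position")),
    residue = unlist(lapply(site_list, `[[`, "residue")),
    ptm_type = unlist(lapply(site_list, `[[`, "ptm_type")),
    detection_count = 1L + stats::rgeom(sum(n_sites_per), config$detection_geom_p),
    sources = "synthetic",
    functional_note = NA_character_
  )

  n_reg_per <- vapply(reg_list, function(r) length(r$start), 0L)
  regions <- tibble::tibble(
    accession = rep(acc, n_reg_per),
    region_type = unlist(lapply(reg_list, `[[`, "region_type")),
    start = unlist(lapply(reg_list, `[[`, "start")),
    end = unlist(lapply(reg_list, `[[`, "end")),
    name = unlist(lapply(reg_list, `[[`, "name"))
  )

  n_var_per <- vapply(var_list, function(v) length(v$position), 0L)
  variants <- tibble::tibble(
    accession = rep(acc, n_var_per),
    position = unlist(lapply(var_list, `[[`, "position")),
    ref_residue = unlist(lapply(var_list, `[[`, "ref")),
    alt_residue = unlist(lapply(var_list, `[[`, "alt")),
    variant_class = unlist(lapply(var_list, `[[`, "class")),
    source = "synthetic"
  )

  # enzyme-level annotations
  is_rl <- group == "enriched" & stats::runif(n) < config$rate_limiting_prob
  is_mt <- stats::runif(n) < config$mitochondrial_prob[group]
  ec <- sample(c("oxidoreductase", "transferase", "hydrolase",
                 "lyase", "isomerase", "ligase"), n, replace = TRUE,
               prob = c(0.25, 0.30, 0.15, 0.10, 0.10, 0.10))
  pathways <- vapply(seq_len(n), function(i) {
    pool <- config$pathway_labels[[group[i]]]
    lab <- sample(pool, sample.int(min(2L, length(pool)), 1))
    if (stats::runif(1) < config$core_prob[[group[i]]]) lab <- c(config$core_label, lab)
    paste(sort(unique(lab)), collapse = ";")
  }, "")
  txt <- vapply(seq_len(n), function(i) {
    gterms <- if (group[i] == "enriched") ENRICHED_TERMS else SPARSE_TERMS
    toks <- c(sample(SHARED_TERMS, sample(2:4, 1)),
              sample(gterms, sample(1:2, 1)))
    paste(sort(unique(toks)), collapse = ";")
  }, "")

  enzymes <- tibble::tibble(
    accession = acc,
    gene_symbol = paste0("GENE", seq_len(n)),
    sequence = seqs,
    length = lens,
    ec_class = ec,
    pathways = pathways,
    is_rate_limiting = is_rl,
    is_mitochondrial = is_mt,
    text_descriptors = txt
  )

  n_burst_per <- vapply(burst_list, function(b) length(b$start), 0L)
  truth <- list(
    groups = tibble::tibble(accession = acc, group = group, propensity = lambda),
    bursts = tibble::tibble(
      accession = rep(acc, n_burst_per),
      start = unlist(lapply(burst_list, `[[`, "start")),
      end = unlist(lapply(burst_list, `[[`, "end")),
      n_sites = unlist(lapply(burst_list, `[[`, "n_sites"))
    ),
    crosstalk = tibble::tibble(
      accession = rep(acc, lengths(ct_list)),
      position = unlist(ct_list)
    ),
    config = config,
    seed = seed
  )

  structure(list(enzymes = enzymes, sites = sites, regions = regions,
                 variants = variants, truth = truth),
            class = "ptm_cohort")
}

#' @export
print.ptm_cohort <- function(x, ...) {
  cat("<ptm_cohort>", nrow(x$enzymes), "enzymes,", nrow(x$sites), "PTM sites,",
      nrow(x$regions), "regions,", nrow(x$variants), "variants\n")
  invisible(x)
}

#' Write a synthetic cohort to disk in the formats the loaders read
#'
#' Writes `sequences.fasta`, `ptm_sites.tsv` (generic dialect),
#' `regions.tsv`, `variants.tsv`, `annotations.tsv` and `truth.json` into
#' `out_dir`. The written file set round-trips: [read_cohort()] on the
#' directory reproduces the in-memory cohort exactly.
#'
#' @param cohort a `ptm_cohort` from [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
cohort_to_files <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_enzyme_fasta(cohort$enzymes, file.path(out_dir, "sequences.fasta"))
  ptm_tab <- cohort$sites |>
    dplyr::transmute(.data$accession, .data$position, .data$residue,
                     .data$ptm_type, source = .data$sources,
                     study_count = .data$detection_count,
                     functional_note = .data$functional_note)
  readr::write_tsv(ptm_tab, file.path(out_dir, "ptm_sites.tsv"), progress = FALSE)
  readr::write_tsv(cohort$regions, file.path(out_dir, "regions.tsv"), progress = FALSE)
  readr::write_tsv(cohort$variants, file.path(out_dir, "variants.tsv"), progress = FALSE)
  ann <- cohort$enzymes |>
    dplyr::select("accession", "ec_class", "pathways", "is_rate_limiting",
                  "is_mitochondrial", "text_descriptors")
  readr::write_tsv(ann, file.path(out_dir, "annotations.tsv"), progress = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$config$ptm_types <- as.list(truth$config$ptm_types)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @rdname cohort_to_files
#' @param dir directory written by [cohort_to_files()].
#' @return `read_cohort()`: a `ptm_cohort` list rebuilt through the package
#'   loaders ([read_enzyme_fasta()], [read_ptm_table()], [harmonize_sites()],
#'   [read_region_table()], [read_variant_table()],
#'   [read_enzyme_annotations()]).
#' @export
read_cohort <- function(dir) {
  enz <- read_enzyme_fasta(file.path(dir, "sequences.fasta"))
  enz <- read_enzyme_annotations(enz, file.path(dir, "annotations.tsv"))
  raw <- read_ptm_table(file.path(dir, "ptm_sites.tsv"), "generic_tsv",
                        source_tag = "synthetic")
  harm <- harmonize_sites(raw, enz)
  regions <- read_region_table(file.path(dir, "regions.tsv"), enzymes = enz)
  variants <- read_variant_table(file.path(dir, "variants.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    list(groups = tibble::as_tibble(tr$groups),
         bursts = tibble::as_tibble(tr$bursts),
         crosstalk = tibble::as_tibble(tr$crosstalk),
         seed = tr$seed)
  } else NULL
  structure(list(enzymes = enz, sites = harm$sites, regions = regions,
                 variants = variants, truth = truth,
                 harmonization_report = harm$report),
            class = "ptm_cohort")
}
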