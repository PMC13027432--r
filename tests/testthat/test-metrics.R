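test_that("PTM density is unique sites over sequence length", {
  enz <- tibble::tibble(accession = c("FH", "E0", "E5"),
                        length = c(510L, 300L, 10L))
  sites <- dplyr::bind_rows(
    make_sites("FH", 1:99),
    make_sites("E5", 1:5))
  d <- ptm_density(sites, enz)
  # fumarase-scale worked example: 99 sites on 510 residues prints as 0.19
  expect_equal(round(d$ptm_density[d$accession == "FH"], 2), 0.19)
  expect_equal(d$ptm_density[d$accession == "E0"], 0)
  expect_equal(d$ptm_density[d$accession == "E5"], 0.5)
  # dual-modified residues count once per (position, type) record
  dup <- dplyr::bind_rows(make_sites("E5", c(1, 1)), make_sites("E5", 1, "acetylation"))
  d2 <- ptm_density(dup, enz[enz$accession == "E5", ])
  expect_equal(d2$n_sites_total, 2L)
  expect_error(ptm_density(sites, tibble::tibble(accession = "X", length = 0L)),
               "length")
})

test_that("per-type densities partition the total density", {
  enz <- tibble::tibble(accession = "E1", length = 10L)
  sites <- dplyr::bind_rows(
    make_sites("E1", 1:3, "phosphorylation"),
    make_sites("E1", 4:5, "acetylation", residue = "K"))
  ptd <- per_type_density(sites, enz)
  expect_equal(ptd$density[ptd$ptm_type == "phosphorylation"], 0.3)
  expect_equal(ptd$density[ptd$ptm_type == "acetylation"], 0.2)
  # absent types omitted unless zero-filled
  expect_equal(nrow(ptd), 2)

  co <- test_cohort()
  total <- ptm_density(co$sites, co$enzymes)
  per <- per_type_density(co$sites, co$enzymes) |>
    dplyr::group_by(accession) |>
    dplyr::summarise(s = sum(density))
  j <- dplyr::left_join(total, per, by = "accession") |>
    dplyr::mutate(s = dplyr::coalesce(s, 0))
  expect_equal(j$s, j$ptm_density, tolerance = 1e-12)
})

test_that("PPR divides unique sites by eligible residues and is NA when undefined", {
  enz <- tibble::tibble(accession = c("K3", "NOK"),
                        sequence = c("KAKAK", "AAAAA"),
                        length = c(5L, 5L))
  sites <- make_sites("K3", 1, "acetylation", residue = "K")
  p <- ptm_potentiality(sites, enz)
  expect_equal(p$ppr[p$accession == "K3"], 1 / 3)
  expect_true(is.na(p$ppr[p$accession == "NOK"]))
  expect_error(ptm_potentiality(sites, enz, eligibility = list(),
                                types = "unheard_of_mod"),
               "no observed residues|unknown")
})

test_that("PPR equals a brute-force per-residue scan on a synthetic cohort", {
  co <- test_cohort()
  elig <- default_eligibility()
  p <- ptm_potentiality(co$sites, co$enzymes, elig,
                        types = c("phosphorylation", "acetylation"))
  idx <- sample.int(nrow(p), 50)
  for (i in idx) {
    row <- p[i, ]
    chars <- strsplit(co$enzymes$sequence[co$enzymes$accession == row$accession],
                      "")[[1]]
    n_el <- 0L
    for (ch in chars) if (ch %in% elig[[row$ptm_type]]) n_el <- n_el + 1L
    n_s <- sum(co$sites$accession == row$accession &
                 co$sites$ptm_type == row$ptm_type)
    expect_equal(row$n_eligible, n_el)
    expect_equal(row$ppr, if (n_el == 0) NA_real_ else n_s / n_el)
  }
})

test_that("predominant calling follows the cumulative-detection rule", {
  s <- make_sites("E1", 1:4, detection_count = c(10L, 5L, 3L, 2L))
  # cumulative 10 (50%) then 15 (75%): the 60% threshold is crossed at site 2
  expect_equal(call_predominant(s, 0.6)$position, c(1L, 2L))
  # five equal sites: 3/5 of detections reach exactly 60%, tie-break by position
  s5 <- make_sites("E1", c(30L, 10L, 50L, 20L, 40L), detection_count = 1L)
  expect_equal(call_predominant(s5, 0.6)$position, c(10L, 20L, 30L))
  # a single site is always predominant
  expect_equal(nrow(call_predominant(make_sites("E1", 7, detection_count = 1L), 0.6)), 1)
  expect_error(call_predominant(s, 0))
  expect_error(call_predominant(s[0, ], 0.6), "empty")
})

test_that("predominant sets are monotone in the threshold", {
  co <- test_cohort()
  key <- function(d) paste(d$accession, d$ptm_type, d$position)
  p50 <- key(call_predominant(co$sites, 0.5))
  p60 <- key(call_predominant(co$sites, 0.6))
  p70 <- key(call_predominant(co$sites, 0.7))
  expect_true(all(p50 %in% p60))
  expect_true(all(p60 %in% p70))
  # at threshold 1 every site is predominant
  expect_equal(nrow(call_predominant(co$sites, 1)), nrow(co$sites))
})

test_that("sensitivity scan reports monotone counts and rank agreement", {
  co <- test_cohort()
  sc <- sensitivity_scan(co$sites)
  expect_true(all(sc$counts$n_predominant_0.5 <= sc$counts$n_predominant_0.6))
  expect_true(all(sc$counts$n_predominant_0.6 <= sc$counts$n_predominant_0.7))
  # rank agreement equals an independent rank-then-correlate computation
  a <- sc$counts$n_predominant_0.5
  b <- sc$counts$n_predominant_0.6
  expect_equal(
    sc$agreement$spearman_rho[sc$agreement$threshold_a == 0.5 &
                                sc$agreement$threshold_b == 0.6],
    stats::cor(oracle_midranks(a), oracle_midranks(b)),
    tolerance = 1e-12)
  expect_true(all(sc$agreement$spearman_rho > 0.8))
})

test_that("distribution summaries use linear-interpolation quartiles", {
  s <- summarize_distribution(c(1, 2, 3, 4, 5), bins = 5)
  expect_equal(s$summary$q1, 2)
  expect_equal(s$summary$median, 3)
  expect_equal(s$summary$q3, 4)
  expect_equal(sum(s$histogram$count), 5)
  cst <- summarize_distribution(rep(2.5, 10))
  expect_equal(cst$summary$q1, cst$summary$q3)
  # gamma-mixture densities are right-skewed: mean above median
  co <- test_cohort()
  d <- ptm_density(co$sites, co$enzymes)
  sd <- summarize_distribution(d$ptm_density)
  expect_gt(sd$summary$mean, sd$summary$median)
  expect_true(sd$summary$right_skewed)
  expect_error(summarize_distribution(numeric(0)))
})

test_that("the metrics table matches the per-operation counts", {
  co <- test_cohort()
  m <- test_metrics()
  expect_equal(m$n_crosstalk_residues,
               dplyr::left_join(m["accession"],
                                dplyr::count(detect_crosstalk(co$sites),
                                             accession, name = "n"),
                                by = "accession")$n |> (\(x) dplyr::coalesce(x, 0L))())
  ov <- dplyr::count(overlap_variants(co$sites, co$variants), accession, name = "n")
  expect_equal(m$n_mutated_ptm_sites,
               dplyr::coalesce(dplyr::left_join(m["accession"], ov,
                                                by = "accession")$n, 0L))
  loc <- localize_sites(co$sites, co$regions) |>
    dplyr::filter(grepl("domain", labels)) |>
    dplyr::count(accession, name = "n")
  expect_equal(m$n_domain_localized_sites,
               dplyr::coalesce(dplyr::left_join(m["accession"], loc,
                                                by = "accession")$n, 0L))
  expect_equal(m$ptm_density, m$n_sites_total / m$length)
})
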