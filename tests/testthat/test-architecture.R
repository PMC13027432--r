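enz1 <- function(L = 100L, acc = "E1") {
  tibble::tibble(accession = acc, length = L)
}

test_that("hotspot windows qualify, clip and merge as specified", {
  # six single-type sites at 10..15: the +/-7 window of each covers all six,
  # giving 5 neighbors besides the center -> one merged region
  s <- make_sites("E1", 10:15)
  h <- detect_hotspots(s, enz1())
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 3L)       # 10 - 7
  expect_equal(h$end, 22L)        # 15 + 7
  expect_equal(h$n_sites, 6L)
  expect_equal(h$n_windows, 6L)

  # sites spaced >= 15 apart: no window can hold 5 neighbors
  far <- make_sites("E1", seq(1, 100, by = 16))
  expect_equal(nrow(detect_hotspots(far, enz1())), 0)

  # windows are clipped at the sequence end
  edge <- make_sites("E1", 95:100)
  he <- detect_hotspots(edge, enz1())
  expect_equal(he$end, 100L)

  # two qualifying windows sharing residues merge into one region
  s2 <- make_sites("E1", c(10:15, 24:29))
  h2 <- detect_hotspots(s2, enz1())
  expect_equal(nrow(h2), 1)       # [3,22] and [17,36] overlap
  expect_equal(c(h2$start, h2$end), c(3L, 36L))

  # a dual-modified residue contributes two records to the window load
  dual <- dplyr::bind_rows(make_sites("E1", c(10, 11, 12)),
                           make_sites("E1", c(10, 11), "acetylation"),
                           make_sites("E1", 13, "methylation"))
  expect_equal(nrow(detect_hotspots(dual, enz1())), 1)
  expect_equal(nrow(detect_hotspots(dual, enz1(),
                                    count_unique_positions = TRUE)), 0)
})

test_that("hotspot detection equals the exhaustive all-windows oracle", {
  co <- test_cohort()
  got <- detect_hotspots(co$sites, co$enzymes)
  uniq <- dplyr::distinct(co$sites, accession, position, ptm_type)
  for (acc in unique(co$enzymes$accession)) {
    L <- co$enzymes$length[co$enzymes$accession == acc]
    want <- oracle_hotspots_one(uniq$position[uniq$accession == acc], L)
    have <- got[got$accession == acc, c("start", "end", "n_sites")]
    expect_equal(as.data.frame(have), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("hotspot count is monotone as min_neighbors decreases", {
  co <- test_cohort()
  h5 <- detect_hotspots(co$sites, co$enzymes, min_neighbors = 5)
  h4 <- detect_hotspots(co$sites, co$enzymes, min_neighbors = 4)
  h3 <- detect_hotspots(co$sites, co$enzymes, min_neighbors = 3)
  # qualifying windows and covered residues can only grow as the load
  # requirement relaxes (merged-region counts may shrink through merging)
  win <- function(h) sum(h$n_windows)
  cov <- function(h) sum(h$end - h$start + 1)
  expect_gte(win(h4), win(h5))
  expect_gte(win(h3), win(h4))
  expect_gte(cov(h4), cov(h5))
  expect_gte(cov(h3), cov(h4))
})

test_that("planted bursts are recovered as hotspot regions", {
  co <- test_cohort()
  hs <- detect_hotspots(co$sites, co$enzymes)
  bursts <- co$truth$bursts |>
    dplyr::filter(n_sites >= 6, end - start + 1 <= 15)
  hit <- vapply(seq_len(nrow(bursts)), function(i) {
    b <- bursts[i, ]
    any(hs$accession == b$accession & hs$start <= b$end & hs$end >= b$start)
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("crosstalk residues carry at least two distinct PTM types", {
  s <- dplyr::bind_rows(
    make_sites("E1", 100, "phosphorylation"),
    make_sites("E1", 100, "o_linked_glycosylation"),
    make_sites("E1", 50, "phosphorylation", detection_count = 3L),
    make_sites("E1", 50, "phosphorylation", detection_count = 9L))
  ct <- detect_crosstalk(s)
  expect_equal(ct$position, 100L)
  expect_equal(ct$ptm_types, "o_linked_glycosylation;phosphorylation")
  # a single type reported twice is not crosstalk
  expect_false(50L %in% ct$position)
})

test_that("residue-mode crosstalk equals a brute-force per-position tally", {
  co <- generate_cohort(cohort_config("cohort_small", n_enzymes = 80L,
                                      crosstalk_rate = 0.2), seed = 13)
  ct <- detect_crosstalk(co$sites)
  tall <- table(paste(co$sites$accession, co$sites$position))
  expect_equal(nrow(ct), sum(tall >= 2))
  # every injected crosstalk position is detected
  inj <- co$truth$crosstalk
  expect_true(all(paste(inj$accession, inj$position) %in%
                    paste(ct$accession, ct$position)))
})

test_that("window-mode crosstalk sees types in the neighborhood", {
  s <- dplyr::bind_rows(make_sites("E1", 10, "phosphorylation"),
                        make_sites("E1", 14, "acetylation"),
                        make_sites("E1", 40, "phosphorylation"))
  cw <- detect_crosstalk(s, mode = "window")
  expect_setequal(cw$position, c(10L, 14L))
  expect_equal(nrow(detect_crosstalk(s, mode = "residue")), 0)
})

test_that("site localization is multi-label with unannotated fallback", {
  regions <- tibble::tibble(
    accession = "E1",
    region_type = c("domain", "disordered"),
    start = c(40L, 50L), end = c(60L, 70L), name = c("d1", "idr"))
  s <- make_sites("E1", c(50L, 45L, 90L))
  loc <- localize_sites(s, regions)
  expect_equal(loc$labels[loc$position == 50], "disordered;domain")
  expect_equal(loc$labels[loc$position == 45], "domain")
  expect_equal(loc$labels[loc$position == 90], "unannotated")
})

test_that("domain-localized site fraction matches the generator's coverage", {
  co <- test_cohort()
  loc <- localize_sites(co$sites, co$regions)
  in_dom <- grepl("domain", loc$labels)
  # true per-site probability is the realized domain coverage of the cohort
  dom <- co$regions[co$regions$region_type == "domain", ]
  coverage <- sum(dom$end - dom$start + 1) / sum(co$enzymes$length)
  expect_equal(coverage, 0.40, tolerance = 0.02)
  p <- mean(in_dom)
  se <- sqrt(coverage * (1 - coverage) / nrow(loc))
  # bursts and eligibility make placement only approximately uniform; allow
  # a small systematic margin beyond pure binomial noise
  expect_lt(abs(p - coverage), 3 * se + 0.02)
})

test_that("region enrichment reports per-region-type site rates", {
  co <- test_cohort()
  er <- region_enrichment(co$sites, co$regions, co$enzymes)
  expect_true(all(c("domain", "disordered") %in% er$region_type))
  phos_dom <- er[er$region_type == "domain" & er$ptm_type == "phosphorylation", ]
  expect_equal(phos_dom$n_sites_inside + phos_dom$n_sites_outside,
               sum(dplyr::distinct(co$sites, accession, position,
                                   ptm_type)$ptm_type == "phosphorylation"))
  expect_true(all(er$rate_inside >= 0))
})

test_that("variant overlap reports PTM-bearing positions only", {
  s <- make_sites("E1", c(10L, 20L))
  v <- tibble::tibble(
    accession = "E1", position = c(10L, 10L, 30L),
    ref_residue = c("S", "S", "A"), alt_residue = c("A", "D", "V"),
    variant_class = c("engineered", "missense", "missense"),
    source = "test")
  ov <- overlap_variants(s, v)
  expect_equal(nrow(ov), 1)                    # position 30 has no PTM
  expect_equal(ov$n_variants, 2L)
  expect_true(ov$any_missense)
  expect_equal(ov$variant_classes, "engineered;missense")
  sm <- variant_overlap_summary(ov)
  expect_equal(sm$n_overlapped_positions, 1)
  # engineered-only site: no missense flag
  ov2 <- overlap_variants(s, v[v$variant_class == "engineered", ])
  expect_false(ov2$any_missense)
})
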