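# fixture builders and independent oracles shared across test files

write_test_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(h) c(paste0(">", h), records[[h]])))
  writeLines(lines, path)
  path
}

fh_like_sequence <- function() {
  # 510-residue sequence standing in for a canonical fumarase-sized enzyme
  paste(rep("ACDEFGHIKL", 51), collapse = "")
}

make_sites <- function(accession, position, ptm_type = "phosphorylation",
                       detection_count = 1L, residue = "S") {
  tibble::tibble(accession = accession, position = as.integer(position),
                 residue = residue, ptm_type = ptm_type,
                 detection_count = as.integer(detection_count),
                 sources = "test", functional_note = NA_character_)
}

# memoized small synthetic cohort shared by read-only tests
.test_env <- new.env(parent = emptyenv())
test_cohort <- function() {
  if (is.null(.test_env$cohort)) {
    .test_env$cohort <- generate_cohort(cohort_config("cohort_small"), seed = 42)
  }
  .test_env$cohort
}
test_metrics <- function() {
  if (is.null(.test_env$metrics)) {
    co <- test_cohort()
    .test_env$metrics <- enzyme_metrics(co$sites, co$enzymes, co$regions,
                                        co$variants)
  }
  .test_env$metrics
}

# exhaustive all-windows + interval-merge hotspot oracle (O(n^2) per enzyme)
oracle_hotspots_one <- function(positions, L, half_window = 7L,
                                min_neighbors = 5L) {
  pos <- sort(positions)                 # one entry per (position, type) record
  centers <- unique(pos)
  qual <- list()
  for (p in centers) {
    lo <- max(1L, p - half_window); hi <- min(L, p + half_window)
    n_in <- sum(pos >= lo & pos <= hi) - 1L   # exclude the central record
    if (n_in >= min_neighbors) qual[[length(qual) + 1L]] <- c(lo, hi)
  }
  if (length(qual) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          n_sites = integer(0)))
  }
  # brute-force merge of the qualifying interval list (merge on overlap)
  ivs <- do.call(rbind, qual)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  merged <- list(ivs[1, ])
  if (nrow(ivs) > 1) for (i in 2:nrow(ivs)) {
    last <- merged[[length(merged)]]
    if (ivs[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], ivs[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- ivs[i, ]
    }
  }
  m <- do.call(rbind, merged)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2])) |>
    dplyr::mutate(n_sites = vapply(seq_along(start), function(i) {
      sum(pos >= start[i] & pos <= end[i])
    }, 0L))
}

# independent midrank computation (no call to rank())
oracle_midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  sorted <- x[o]
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && sorted[j + 1] == sorted[i]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# exhaustive two-sided Mann-Whitney oracle over all group assignments
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n_a <- length(x)
  u_of <- function(a, b) {
    sum(vapply(a, function(ai) sum(ai > b) + 0.5 * sum(ai == b), 0))
  }
  u_obs <- u_of(x, y)
  mid <- n_a * (n - n_a) / 2
  idx <- utils::combn(n, n_a)
  us <- apply(idx, 2, function(sel) u_of(pooled[sel], pooled[-sel]))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# naive O(n^3) Ward agglomeration via Lance-Williams on squared distances
oracle_ward_partition <- function(mat, k) {
  n <- nrow(mat)
  d2 <- as.matrix(stats::dist(mat))^2
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  while (length(active) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      a <- active[ii]; b <- active[jj]
      if (d2[a, b] < bestd) { bestd <- d2[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (c0 in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[c0]
      d2[a, c0] <- d2[c0, a] <-
        ((na + nc) * d2[a, c0] + (nb + nc) * d2[b, c0] - nc * d2[a, b]) /
        (na + nb + nc)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  lab <- integer(n)
  for (i in seq_along(active)) lab[members[[active[i]]]] <- i
  lab
}

# chance-corrected partition agreement (adjusted Rand)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
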