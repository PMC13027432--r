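#' Spearman rank correlation with midrank ties
#'
#' `spearman_rho()` computes the Spearman coefficient for one pair of
#' vectors; `spearman_matrix()` computes it for every pair of numeric
#' features in a table, with pairwise deletion of missing values, a
#' large-sample t approximation for the p-value
#' (t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom) and
#' Benjamini-Hochberg adjustment across all tested pairs.
#'
#' Pairs with fewer than 3 complete observations or with a constant feature
#' have undefined rho and are reported with `NA` (excluded from the BH
#' family).
#'
#' @param x,y numeric vectors.
#' @return `spearman_rho()`: a single correlation value.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman_rho
#' @param data data frame of features.
#' @param features columns to correlate (default: all numeric columns).
#' @return `spearman_matrix()`: tibble with one row per unordered feature
#'   pair: `feature_a`, `feature_b`, `rho`, `n`, `p_value`, `q_value`.
#' @export
spearman_matrix <- function(data, features = NULL) {
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  if (length(features) < 2) stop("need at least two features")
  pairs <- utils::combn(features, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    rho <- spearman_rho(x, y)
    p <- if (is.na(rho) || n < 3 || abs(rho) == 1) {
      if (is.na(rho)) NA_real_ else 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
    tibble::tibble(feature_a = pr[1], feature_b = pr[2],
                   rho = rho, n = n, p_value = p)
  })
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: q-values
#' are monotone non-decreasing in sorted p order, capped at 1, elementwise
#' at least the input p, and invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# exact two-sided Mann-Whitney p by complete enumeration of group
# assignments over the pooled midranks (valid with ties; the permutation
# distribution of U is symmetric about n_a * n_b / 2)
mw_exact_p <- function(pooled_ranks, n_a, u_obs) {
  n <- length(pooled_ranks)
  mid <- n_a * (n - n_a) / 2
  combs <- utils::combn(n, n_a)
  w <- colSums(matrix(pooled_ranks[combs], nrow = n_a))
  u_all <- w - n_a * (n_a + 1) / 2
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from midranks and counts, for each pair (a, b), the events
#' a > b (plus 1/2 per tie), so `U = n_a * n_b` means group a entirely above
#' group b and `U = 0` entirely below; identical groups give
#' `U = n_a * n_b / 2`. For combined sample sizes up to `exact_limit` the
#' two-sided p-value is computed by complete enumeration of all group
#' assignments (valid under ties); above it, a normal approximation with
#' midrank tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact_limit switch point on n_a + n_b between the exact and the
#'   approximate branch (default 16).
#' @return one-row tibble: `n_a`, `n_b`, `statistic` (U for x vs y),
#'   `p_value`, `method`, `median_a`, `median_b`, `direction`
#'   (sign of median_a - median_b).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic  # 4.5
mann_whitney <- function(x, y, exact_limit = 16L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n_a <- length(x); n_b <- length(y)
  if (n_a == 0 || n_b == 0) stop("both groups must be nonempty")
  n <- n_a + n_b
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n <= exact_limit) {
    p <- mw_exact_p(r, n_a, u)
    method <- "exact_enumeration"
  } else {
    ties <- table(r)
    sigma2 <- (n_a * n_b / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    mid <- n_a * n_b / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mid) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approximation"
  }
  med_a <- stats::median(x); med_b <- stats::median(y)
  tibble::tibble(n_a = n_a, n_b = n_b, statistic = u, p_value = p,
                 method = method, median_a = med_a, median_b = med_b,
                 direction = sign(med_a - med_b))
}

#' Mann-Whitney contrasts of enzyme features between two groups
#'
#' Runs [mann_whitney()] for each feature between the two levels of a
#' grouping column and applies Benjamini-Hochberg adjustment across the
#' feature family. An empty stratum skips the whole contrast family with a
#' warning.
#'
#' @param data per-enzyme feature table.
#' @param group name of a two-level grouping column (logical or two-valued).
#' @param features feature columns to contrast (default: all numeric columns
#'   except the group).
#' @return tibble with one row per feature: `feature`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p_value`, `q_value`, `median_a`, `median_b`,
#'   `direction`.
#' @export
group_contrasts <- function(data, group, features = NULL) {
  g <- data[[group]]
  if (is.null(g)) stop("grouping column not found: ", group)
  lv <- sort(unique(stats::na.omit(g)), decreasing = TRUE)
  if (length(lv) != 2) {
    warning("grouping column '", group, "' does not have two non-empty levels; skipped")
    return(tibble::tibble())
  }
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                        c(group, "length"))
  }
  out <- purrr::map_dfr(features, function(f) {
    res <- mann_whitney(data[[f]][g == lv[1] & !is.na(g)],
                        data[[f]][g == lv[2] & !is.na(g)])
    tibble::tibble(feature = f, group_a = as.character(lv[1]),
                   group_b = as.character(lv[2]),
                   n_a = res$n_a, n_b = res$n_b, statistic = res$statistic,
                   p_value = res$p_value, median_a = res$median_a,
                   median_b = res$median_b, direction = res$direction)
  })
  out$q_value <- bh_adjust(out$p_value)
  dplyr::relocate(out, "q_value", .after = "p_value")
}

#' Standard group contrasts of the metrics table
#'
#' Contrasts every enzyme-level PTM metric (total and per-type densities,
#' PPR, predominant / hotspot / crosstalk / mutation-overlap counts) across
#' the standard enzyme dichotomies — rate-limiting versus not, mitochondrial
#' versus not — with BH adjustment within each dichotomy's feature family.
#'
#' @param metrics table from [enzyme_metrics()].
#' @param dichotomies names of logical columns to contrast on.
#' @return tibble of contrasts with a `dichotomy` column.
#' @export
cohort_contrasts <- function(metrics,
                             dichotomies = c("is_rate_limiting",
                                             "is_mitochondrial")) {
  purrr::map_dfr(dichotomies, function(d) {
    if (!d %in% names(metrics)) {
      warning("dichotomy column missing: ", d)
      return(tibble::tibble())
    }
    res <- group_contrasts(metrics, d)
    if (nrow(res) > 0) res$dichotomy <- d
    res
  })
}

#' Hypergeometric pathway enrichment with BH adjustment
#'
#' Upper-tail hypergeometric test of each annotation set against a selection
#' drawn from a background (the full enzyme cohort): with N background
#' enzymes, K of them in the set, and a selection of n enzymes of which k
#' are in the set, p = P(X >= k) for X hypergeometric(N, K, n). q-values are
#' BH-adjusted across the sets tested.
#'
#' @param selection character vector of selected identifiers (must be a
#'   subset of `background`).
#' @param background character vector: the full cohort.
#' @param sets named list of identifier sets (each intersected with the
#'   background before testing).
#' @return tibble sorted by q then p: `set_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`.
#' @export
#' @examples
#' hypergeom_enrich(letters[1:5], letters[1:10], list(s = letters[1:5]))
hypergeom_enrich <- function(selection, background, sets) {
  selection <- unique(selection)
  background <- unique(background)
  if (!all(selection %in% background)) {
    stop("selection must be a subset of the background")
  }
  N <- length(background)
  n <- length(selection)
  out <- purrr::imap_dfr(sets, function(s, id) {
    s <- intersect(unique(s), background)
    K <- length(s)
    k <- length(intersect(s, selection))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_id = id, k = k, K = K, n = n, N = N, p_value = p)
  })
  out$q_value <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$q_value, .data$p_value)
}

#' Pathway sets from the enzyme annotation table
#'
#' Splits the semicolon-joined `pathways` column into a named list of
#' accession sets, suitable for [hypergeom_enrich()].
#'
#' @param enzymes enzyme tibble with `accession` and `pathways`.
#' @return named list of character vectors.
#' @export
pathway_sets <- function(enzymes) {
  long <- enzymes |>
    dplyr::select("accession", "pathways") |>
    tidyr::separate_rows("pathways", sep = ";") |>
    dplyr::filter(!is.na(.data$pathways), .data$pathways != "")
  split(long$accession, long$pathways)
}
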