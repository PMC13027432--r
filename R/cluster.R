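#' Build the multi-block enzyme feature matrix
#'
#' Assembles one row per enzyme from three blocks, each tagged with its
#' provenance:
#' \describe{
#'   \item{numeric}{all numeric metric columns of the metrics table (total
#'     and per-type density, per-type PPR, total/predominant/hotspot/
#'     crosstalk/mutation-overlap counts). Missing values (e.g. undefined
#'     PPR where a sequence has no eligible residue) are imputed as 0 —
#'     absence of eligible residues is no modification capacity — and
#'     tallied in a per-column missingness report.}
#'   \item{tfidf}{term frequency-inverse document frequency encoding of the
#'     enzyme's concatenated free-text descriptors and region names.
#'     Convention, held fixed: lowercase, tokenized on non-alphanumerics,
#'     tokens kept at document frequency >= `min_df`; tf = raw count;
#'     idf = ln((1 + N_docs) / (1 + df)) + 1; rows L2-normalized.}
#'   \item{onehot}{0/1 pathway-membership and EC-class indicator columns.}
#' }
#'
#' @param metrics per-enzyme table from [enzyme_metrics()].
#' @param enzymes enzyme tibble (`pathways`, `ec_class`, `text_descriptors`).
#' @param regions optional region tibble; region names join the text corpus.
#' @param min_df minimum document frequency for a TF-IDF token.
#' @return object of class `ptm_feature_matrix`: list with `matrix` (rows
#'   named by accession), `blocks` (tibble column -> block), `missingness`,
#'   and `filter_log` (empty until [filter_features()]).
#' @export
build_feature_matrix <- function(metrics, enzymes, regions = NULL,
                                 min_df = 2L) {
  acc <- metrics$accession
  stopifnot(!anyDuplicated(acc))
  enz <- enzymes[match(acc, enzymes$accession), ]
  if (any(is.na(enz$accession))) stop("metrics rows not aligned with enzymes")

  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                      c("length"))
  num <- as.matrix(metrics[num_cols])
  rownames(num) <- acc
  missingness <- tibble::tibble(
    column = num_cols,
    n_missing = unname(colSums(is.na(num)))
  ) |> dplyr::filter(.data$n_missing > 0)
  num[is.na(num)] <- 0

  # --- TF-IDF text block ---
  region_text <- if (!is.null(regions) && nrow(regions) > 0) {
    regions |>
      dplyr::group_by(.data$accession) |>
      dplyr::summarise(txt = paste(.data$name, collapse = " "), .groups = "drop")
  } else tibble::tibble(accession = character(0), txt = character(0))
  docs_tbl <- tibble::tibble(accession = acc,
                             base = dplyr::coalesce(enz$text_descriptors, "")) |>
    dplyr::left_join(region_text, by = "accession") |>
    dplyr::mutate(doc = paste(.data$base, dplyr::coalesce(.data$txt, "")))
  tokens <- lapply(tolower(docs_tbl$doc), function(d) {
    t <- strsplit(d, "[^a-z0-9]+")[[1]]
    t[t != ""]
  })
  df_counts <- table(unlist(lapply(tokens, unique)))
  vocab <- sort(names(df_counts)[df_counts >= min_df])
  if (length(vocab) > 0) {
    n_docs <- length(tokens)
    idf <- log((1 + n_docs) / (1 + as.numeric(df_counts[vocab]))) + 1
    tf <- matrix(0, nrow = n_docs, ncol = length(vocab),
                 dimnames = list(acc, paste0("tfidf_", vocab)))
    for (i in seq_len(n_docs)) {
      tt <- table(factor(tokens[[i]], levels = vocab))
      tf[i, ] <- as.numeric(tt)
    }
    tfidf <- sweep(tf, 2, idf, `*`)
    norms <- sqrt(rowSums(tfidf^2))
    norms[norms == 0] <- 1
    tfidf <- tfidf / norms
  } else {
    tfidf <- matrix(0, nrow = length(acc), ncol = 0, dimnames = list(acc, NULL))
  }

  # --- one-hot block ---
  pw_long <- tibble::tibble(accession = acc,
                            pathways = dplyr::coalesce(enz$pathways, "")) |>
    tidyr::separate_rows("pathways", sep = ";") |>
    dplyr::filter(.data$pathways != "")
  pw_levels <- sort(unique(pw_long$pathways))
  onehot_pw <- matrix(0, nrow = length(acc), ncol = length(pw_levels),
                      dimnames = list(acc, paste0("pathway_", pw_levels)))
  if (nrow(pw_long) > 0) {
    onehot_pw[cbind(match(pw_long$accession, acc),
                    match(pw_long$pathways, pw_levels))] <- 1
  }
  ec <- dplyr::coalesce(enz$ec_class, "unknown")
  ec_levels <- sort(unique(ec))
  onehot_ec <- matrix(0, nrow = length(acc), ncol = length(ec_levels),
                      dimnames = list(acc, paste0("ec_", ec_levels)))
  onehot_ec[cbind(seq_along(acc), match(ec, ec_levels))] <- 1

  mat <- cbind(num, tfidf, onehot_pw, onehot_ec)
  blocks <- tibble::tibble(
    column = colnames(mat),
    block = c(rep("numeric", ncol(num)), rep("tfidf", ncol(tfidf)),
              rep("onehot", ncol(onehot_pw) + ncol(onehot_ec)))
  )
  structure(list(matrix = mat, blocks = blocks, missingness = missingness,
                 filter_log = tibble::tibble(column = character(0),
                                             reason = character(0)),
                 normalized = FALSE),
            class = "ptm_feature_matrix")
}

#' @export
print.ptm_feature_matrix <- function(x, ...) {
  tab <- table(x$blocks$block)
  cat("<ptm_feature_matrix>", nrow(x$matrix), "enzymes x", ncol(x$matrix),
      "features (", paste(names(tab), tab, collapse = ", "), ")\n")
  if (x$normalized) cat("  numeric block z-scored; filtered\n")
  invisible(x)
}

#' Filter and normalize the feature matrix
#'
#' Drops zero-variance columns and columns nonzero in fewer than
#' `sparsity_threshold` of rows, then z-scores the numeric block (the TF-IDF
#' block is already row-L2-normalized and the one-hot block is left on its
#' 0/1 scale unless `scale_all = TRUE`). Every dropped column is listed with
#' its reason in the `filter_log`.
#'
#' @param fm a `ptm_feature_matrix`.
#' @param sparsity_threshold minimum fraction of rows in which a column must
#'   be nonzero.
#' @param scale_all also z-score the tfidf and onehot blocks.
#' @return the filtered, normalized `ptm_feature_matrix`.
#' @export
filter_features <- function(fm, sparsity_threshold = 0.01, scale_all = FALSE) {
  mat <- fm$matrix
  v <- apply(mat, 2, stats::var)
  zero_var <- v == 0 | is.na(v)
  nonzero_frac <- colMeans(mat != 0)
  sparse <- nonzero_frac < sparsity_threshold
  drop <- zero_var | sparse
  log <- tibble::tibble(
    column = colnames(mat)[drop],
    reason = as.character(ifelse(zero_var[drop], "zero_variance", "sparse"))
  )
  if (all(drop)) stop("all feature columns dropped by filtering")
  mat <- mat[, !drop, drop = FALSE]
  blocks <- fm$blocks[!drop, , drop = FALSE]
  scale_cols <- if (scale_all) rep(TRUE, ncol(mat)) else
    blocks$block == "numeric"
  if (any(scale_cols)) {
    mat[, scale_cols] <- scale(mat[, scale_cols, drop = FALSE])
  }
  fm$matrix <- mat
  fm$blocks <- blocks
  fm$filter_log <- dplyr::bind_rows(fm$filter_log, log)
  fm$normalized <- TRUE
  fm
}

fm_matrix <- function(fm) {
  if (inherits(fm, "ptm_feature_matrix")) fm$matrix else as.matrix(fm)
}

#' Cluster enzymes on the feature matrix
#'
#' Ward agglomerative clustering (`hclust` with Ward linkage on Euclidean
#' distance over the full filtered matrix — no dimensionality reduction) or
#' k-means (seeded, 10 random restarts, best within-cluster sum of squares
#' kept). The mean silhouette width over the same matrix is attached.
#'
#' @param fm a filtered `ptm_feature_matrix` (or plain matrix).
#' @param k number of clusters, `2 <= k < n`.
#' @param method `"ward"` or `"kmeans"`.
#' @param seed RNG seed for k-means restarts.
#' @return object of class `ptm_clustering`: list with `method`, `k`,
#'   `labels` (tibble accession/cluster), `silhouette`, `tree` (`hclust`,
#'   Ward only), `fit` (`kmeans` only), `seed`.
#' @export
cluster_enzymes <- function(fm, k, method = c("ward", "kmeans"), seed = 1L) {
  method <- match.arg(method)
  mat <- fm_matrix(fm)
  n <- nrow(mat)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
  d <- stats::dist(mat)
  tree <- NULL; fit <- NULL
  if (method == "ward") {
    tree <- stats::hclust(d, method = "ward.D2")
    cl <- stats::cutree(tree, k = k)
  } else {
    set.seed(seed)
    fit <- stats::kmeans(mat, centers = k, nstart = 10, iter.max = 100)
    cl <- fit$cluster
  }
  sil <- mean(cluster::silhouette(cl, d)[, "sil_width"])
  structure(list(
    method = if (method == "ward") "agglomerative_ward" else "kmeans",
    k = k,
    labels = tibble::tibble(accession = rownames(mat), cluster = unname(cl)),
    silhouette = sil,
    tree = tree, fit = fit, seed = seed
  ), class = "ptm_clustering")
}

#' @export
print.ptm_clustering <- function(x, ...) {
  cat("<ptm_clustering>", x$method, "k =", x$k,
      sprintf("silhouette = %.3f", x$silhouette), "\n")
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Broom-style accessors for clustering results
#'
#' `tidy()` returns one row per cluster (size and, for k-means, the
#' within-cluster sum of squares); `glance()` returns a one-row model
#' summary; `augment()` attaches cluster labels to a per-enzyme table.
#'
#' @param x a `ptm_clustering` object.
#' @param ... unused.
#' @method tidy ptm_clustering
#' @export
tidy.ptm_clustering <- function(x, ...) {
  out <- x$labels |>
    dplyr::count(.data$cluster, name = "size")
  if (!is.null(x$fit)) out$withinss <- x$fit$withinss
  out
}

#' @rdname tidy.ptm_clustering
#' @method glance ptm_clustering
#' @export
glance.ptm_clustering <- function(x, ...) {
  tibble::tibble(method = x$method, k = x$k, n = nrow(x$labels),
                 silhouette = x$silhouette)
}

#' @rdname tidy.ptm_clustering
#' @param data per-enzyme table keyed by `accession` to attach labels to.
#' @method augment ptm_clustering
#' @export
augment.ptm_clustering <- function(x, data, ...) {
  dplyr::left_join(data, x$labels, by = "accession")
}

#' Silhouette scan over a range of k
#'
#' Clusters the matrix at every k in `k_range` and reports the mean
#' silhouette width per k; the selected k is the argmax. Configurations
#' where k is not below the number of rows are reported as `NA` rather than
#' an error.
#'
#' @inheritParams cluster_enzymes
#' @param k_range integer vector of candidate k.
#' @return tibble of class `ptm_silhouette_scan` with columns `k`,
#'   `silhouette`; attributes `selected_k` and `method`.
#' @export
silhouette_scan <- function(fm, k_range = 2:10, method = c("ward", "kmeans"),
                            seed = 1L) {
  method <- match.arg(method)
  mat <- fm_matrix(fm)
  n <- nrow(mat)
  d <- stats::dist(mat)
  tree <- if (method == "ward") stats::hclust(d, method = "ward.D2") else NULL
  scores <- purrr::map_dbl(k_range, function(k) {
    if (k < 2 || k >= n) return(NA_real_)
    cl <- if (method == "ward") {
      stats::cutree(tree, k = k)
    } else {
      set.seed(seed + k)
      stats::kmeans(mat, centers = k, nstart = 10, iter.max = 100)$cluster
    }
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  })
  out <- tibble::tibble(k = as.integer(k_range), silhouette = scores)
  sel <- out$k[which.max(out$silhouette)]
  structure(out, selected_k = sel, method = method,
            class = c("ptm_silhouette_scan", class(out)))
}

#' @rdname silhouette_scan
#' @param scan a `ptm_silhouette_scan`.
#' @return `selected_k()`: the k with the highest mean silhouette.
#' @export
selected_k <- function(scan) attr(scan, "selected_k")

#' PCA projection of the feature matrix for visualization
#'
#' Centered principal component scores, for plotting only — clustering always
#' runs on the full unreduced matrix. Component signs are arbitrary (a
#' property of any eigendecomposition).
#'
#' @param fm a filtered `ptm_feature_matrix` (or plain matrix).
#' @param n_components number of components to return; reduced with a
#'   warning if above the matrix rank.
#' @return tibble with `accession` and `PC1..PCn`; attribute
#'   `explained_variance` holds the per-component variance fractions.
#' @export
pca_project <- function(fm, n_components = 2L) {
  mat <- fm_matrix(fm)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_components > rank) {
    warning("n_components reduced to matrix rank ", rank)
    n_components <- rank
  }
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(accession = rownames(mat)), scores)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(scores, "explained_variance") <- ev[seq_len(n_components)]
  scores
}

#' Characterize clusters by feature contrasts and pathway enrichment
#'
#' For a two-cluster solution, a single family of per-feature Mann-Whitney
#' contrasts between the clusters; for k > 2, all cluster pairs with BH
#' across the whole family. Each cluster is also tested for pathway
#' enrichment against the full cohort background (hypergeometric, BH), and
#' rate-limiting representation per cluster is tallied when the flag is
#' present.
#'
#' @param clustering a `ptm_clustering`.
#' @param metrics per-enzyme metrics table (with `accession`).
#' @param sets named list of pathway sets (see [pathway_sets()]); `NULL`
#'   skips enrichment.
#' @return list with `contrasts`, `enrichment` (with `cluster` column) and
#'   `rate_limiting` tibbles.
#' @export
characterize_clusters <- function(clustering, metrics, sets = NULL) {
  joined <- augment(clustering, metrics)
  ks <- sort(unique(joined$cluster))
  prs <- utils::combn(ks, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(prs, function(pr) {
    sub <- joined |>
      dplyr::filter(.data$cluster %in% pr) |>
      dplyr::mutate(.in_a = .data$cluster == pr[1])
    res <- group_contrasts(sub, ".in_a",
                           features = setdiff(
                             names(metrics)[vapply(metrics, is.numeric, TRUE)],
                             c("length", "cluster")))
    res$cluster_a <- pr[1]; res$cluster_b <- pr[2]
    res
  })
  # one BH family across all pairwise feature contrasts
  contrasts$q_value <- bh_adjust(contrasts$p_value)

  enrichment <- NULL
  if (!is.null(sets)) {
    enrichment <- purrr::map_dfr(ks, function(kk) {
      sel <- clustering$labels$accession[clustering$labels$cluster == kk]
      res <- hypergeom_enrich(sel, clustering$labels$accession, sets)
      res$cluster <- kk
      res
    })
  }
  rate_limiting <- NULL
  if ("is_rate_limiting" %in% names(joined)) {
    rate_limiting <- joined |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(n = dplyr::n(),
                       n_rate_limiting = sum(.data$is_rate_limiting),
                       fraction = .data$n_rate_limiting / .data$n,
                       .groups = "drop")
  }
  list(contrasts = contrasts, enrichment = enrichment,
       rate_limiting = rate_limiting)
}

#' Export the feature matrix and linkage tree
#'
#' `write_feature_matrix()` writes the (filtered) matrix as a dense TSV with
#' an `accession` key column, plus a companion `<path>.blocks.tsv` recording
#' each column's block provenance. `write_linkage_tree()` writes the Ward
#' merge sequence as a parent-child table: one row per internal node, with
#' negative child ids referring to leaves (`-i` is the i-th accession in the
#' leaf table order) and positive ids to earlier merge rows, alongside the
#' merge height.
#'
#' @param fm a `ptm_feature_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  mat <- fm_matrix(fm)
  tab <- dplyr::bind_cols(tibble::tibble(accession = rownames(mat)),
                          tibble::as_tibble(mat))
  readr::write_tsv(tab, path, progress = FALSE)
  if (inherits(fm, "ptm_feature_matrix")) {
    readr::write_tsv(fm$blocks, paste0(path, ".blocks.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param clustering a `ptm_clustering` fitted with the Ward method.
#' @export
write_linkage_tree <- function(clustering, path) {
  if (is.null(clustering$tree)) stop("no linkage tree: not a Ward clustering")
  h <- clustering$tree
  tab <- tibble::tibble(
    node = seq_len(nrow(h$merge)),
    child_a = h$merge[, 1],
    child_b = h$merge[, 2],
    height = h$height
  )
  readr::write_tsv(tab, path, progress = FALSE)
  leaves <- tibble::tibble(leaf = -seq_along(h$labels), accession = h$labels)
  readr::write_tsv(leaves, paste0(path, ".leaves.tsv"), progress = FALSE)
  invisible(path)
}
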