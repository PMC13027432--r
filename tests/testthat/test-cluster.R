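mini_inputs <- function(docs, pathways = NULL, ec = NULL) {
  n <- length(docs)
  acc <- paste0("E", seq_len(n))
  metrics <- tibble::tibble(accession = acc, ptm_density = seq_len(n) / 10)
  enzymes <- tibble::tibble(
    accession = acc,
    pathways = pathways %||% rep("p1", n),
    ec_class = ec %||% rep("lyase", n),
    text_descriptors = docs)
  list(metrics = metrics, enzymes = enzymes)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TF-IDF block follows the documented convention", {
  mi <- mini_inputs(c("alpha;beta", "alpha;gamma", "alpha;beta"))
  fm <- build_feature_matrix(mi$metrics, mi$enzymes, min_df = 2L)
  tf <- fm$matrix[, fm$blocks$column[fm$blocks$block == "tfidf"], drop = FALSE]
  # gamma (df 1) is below min_df; alpha in every doc gets the minimal idf (1)
  expect_setequal(colnames(tf), c("tfidf_alpha", "tfidf_beta"))
  idf_beta <- log((1 + 3) / (1 + 2)) + 1
  v <- c(1, idf_beta) / sqrt(1 + idf_beta^2)
  expect_equal(unname(tf["E1", ]), v, tolerance = 1e-12)
  expect_equal(unname(tf["E2", ]), c(1, 0))
  # identical descriptors give identical rows
  expect_equal(unname(tf["E1", ]), unname(tf["E3", ]))
})

test_that("one-hot block encodes pathway and EC membership", {
  mi <- mini_inputs(c("a;b", "a;b", "a;b"),
                    pathways = c("core;tca", "core", "lipid"),
                    ec = c("lyase", "ligase", "lyase"))
  fm <- build_feature_matrix(mi$metrics, mi$enzymes)
  oh <- fm$matrix[, fm$blocks$column[fm$blocks$block == "onehot"]]
  expect_equal(unname(oh[, "pathway_core"]), c(1, 1, 0))
  expect_equal(unname(oh[, "pathway_tca"]), c(1, 0, 0))
  expect_equal(unname(oh[, "ec_ligase"]), c(0, 1, 0))
})

test_that("filtering drops zero-variance and sparse columns, then z-scores", {
  n <- 120L
  acc <- sprintf("E%03d", seq_len(n))
  metrics <- tibble::tibble(accession = acc,
                            ptm_density = rgamma(n, 4),
                            n_sites_total = rpois(n, 20),
                            flat = rep(3.3, n))
  enzymes <- tibble::tibble(
    accession = acc,
    pathways = c("rare", rep("common", n - 1L)),  # 1/120 < 1% threshold
    ec_class = "lyase",
    text_descriptors = rep(c("alpha;beta", "alpha"), length.out = n))
  fm <- build_feature_matrix(metrics, enzymes)
  ff <- filter_features(fm, sparsity_threshold = 0.01)
  expect_false("flat" %in% colnames(ff$matrix))
  expect_false("pathway_rare" %in% colnames(ff$matrix))
  expect_false("ec_lyase" %in% colnames(ff$matrix))     # constant indicator
  expect_true(all(c("flat", "pathway_rare") %in% ff$filter_log$column))
  num <- ff$matrix[, ff$blocks$column[ff$blocks$block == "numeric"]]
  expect_true(all(abs(colMeans(num)) < 1e-9))
  expect_equal(unname(apply(num, 2, stats::sd)), rep(1, ncol(num)))
  all_const <- enzymes
  all_const$pathways <- "common"
  all_const$text_descriptors <- "alpha;beta"
  expect_error(filter_features(build_feature_matrix(
    metrics[, c("accession", "flat")], all_const)), "dropped")
})

test_that("missing numeric values are imputed as zero and reported", {
  metrics <- tibble::tibble(accession = c("E1", "E2"),
                            ppr_acetylation = c(NA, 0.5))
  enzymes <- tibble::tibble(accession = c("E1", "E2"), pathways = "p",
                            ec_class = "lyase", text_descriptors = "a;b")
  fm <- build_feature_matrix(metrics, enzymes)
  expect_equal(unname(fm$matrix[, "ppr_acetylation"]), c(0, 0.5))
  expect_equal(fm$missingness$column, "ppr_acetylation")
  expect_equal(fm$missingness$n_missing, 1)
})

blob_matrix <- function(centers, n_per = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  mat <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), ncol = ncol(centers),
           byrow = TRUE) + matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(mat) <- paste0("E", seq_len(nrow(mat)))
  mat
}

test_that("well-separated planted blobs are recovered exactly", {
  mat <- blob_matrix(rbind(c(0, 0), c(20, 20)))
  truth <- rep(1:2, each = 10)
  for (method in c("ward", "kmeans")) {
    cl <- cluster_enzymes(mat, 2, method = method, seed = 3)
    expect_equal(ari(cl$labels$cluster, truth), 1)
    expect_gt(cl$silhouette, 0.8)
  }
})

test_that("duplicated rows always share a label", {
  mat <- blob_matrix(rbind(c(0, 0), c(8, 8)))
  mat[2, ] <- mat[1, ]
  cl <- cluster_enzymes(mat, 2)
  expect_equal(cl$labels$cluster[1], cl$labels$cluster[2])
})

test_that("Ward clustering equals a naive Lance-Williams agglomeration", {
  set.seed(9)
  mat <- matrix(rnorm(18 * 3), ncol = 3)
  rownames(mat) <- paste0("E", 1:18)
  h <- stats::hclust(stats::dist(mat), method = "ward.D2")
  for (k in 2:5) {
    expect_equal(ari(stats::cutree(h, k), oracle_ward_partition(mat, k)), 1)
  }
})

test_that("the silhouette scan selects the planted number of blobs", {
  two <- blob_matrix(rbind(c(0, 0), c(20, 20)))
  s2 <- silhouette_scan(two, k_range = 2:6)
  expect_equal(selected_k(s2), 2L)
  three <- blob_matrix(rbind(c(0, 0), c(20, 0), c(10, 17.3)), seed = 2)
  s3 <- silhouette_scan(three, k_range = 2:6)
  expect_equal(selected_k(s3), 3L)
  expect_true(all(s2$silhouette >= -1 & s2$silhouette <= 1, na.rm = TRUE))
  # k beyond the number of rows is reported as NA, not an error
  tiny <- blob_matrix(rbind(c(0, 0)), n_per = 4)
  st <- silhouette_scan(tiny, k_range = 2:6)
  expect_true(all(is.na(st$silhouette[st$k >= 4])))
})

test_that("clustering is deterministic and column-order invariant", {
  mat <- blob_matrix(rbind(c(0, 0, 1), c(5, 5, 2)), n_per = 12)
  a <- cluster_enzymes(mat, 2, method = "kmeans", seed = 11)
  b <- cluster_enzymes(mat, 2, method = "kmeans", seed = 11)
  expect_identical(a$labels, b$labels)
  perm <- mat[, c(3, 1, 2)]
  cw <- cluster_enzymes(mat, 2)
  cp <- cluster_enzymes(perm, 2)
  expect_equal(cw$labels$cluster, cp$labels$cluster)
  expect_equal(cw$silhouette, cp$silhouette)
})

test_that("PCA projection explains bounded variance and flags rank deficits", {
  mat <- blob_matrix(rbind(c(0, 0, 0, 0), c(6, 6, 6, 6)))
  sc <- pca_project(mat, 2)
  ev <- attr(sc, "explained_variance")
  expect_lte(sum(ev), 1)
  expect_gt(mean(cluster::silhouette(rep(1:2, each = 10),
                                     dist(as.matrix(sc[, c("PC1", "PC2")])))[, 3]),
            0)
  rank1 <- outer(rnorm(10), c(1, 2, 3))
  rownames(rank1) <- paste0("E", 1:10)
  expect_warning(s1 <- pca_project(rank1, 2), "rank")
  expect_equal(attr(s1, "explained_variance")[1], 1, tolerance = 1e-12)
})

test_that("tidy, glance and augment expose the clustering result", {
  mat <- blob_matrix(rbind(c(0, 0), c(9, 9)))
  cl <- cluster_enzymes(mat, 2)
  td <- tidy(cl)
  expect_equal(sum(td$size), 20)
  gl <- glance(cl)
  expect_equal(gl$k, 2)
  expect_equal(gl$method, "agglomerative_ward")
  ag <- augment(cl, tibble::tibble(accession = rownames(mat)))
  expect_equal(ag$cluster, cl$labels$cluster)
})

test_that("cluster characterization recovers the planted contrast and pathway", {
  co <- test_cohort()
  m <- test_metrics()
  fm <- filter_features(build_feature_matrix(m, co$enzymes, co$regions))
  cl <- cluster_enzymes(fm, 2)
  ch <- characterize_clusters(cl, m, pathway_sets(co$enzymes))
  # identify the PTM-enriched cluster by median density
  ag <- augment(cl, m)
  meds <- tapply(ag$ptm_density, ag$cluster, median)
  enr_cluster <- as.integer(names(which.max(meds)))
  dens <- ch$contrasts[ch$contrasts$feature == "ptm_density", ]
  expect_lt(dens$q_value, 0.001)
  core <- ch$enrichment[ch$enrichment$set_id == "core" &
                          ch$enrichment$cluster == enr_cluster, ]
  expect_lt(core$q_value, 0.05)
  # rate-limiting enzymes concentrate in the enriched cluster
  rl <- ch$rate_limiting
  expect_gt(rl$fraction[rl$cluster == enr_cluster],
            rl$fraction[rl$cluster != enr_cluster])
})
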