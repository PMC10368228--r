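test_that("IDF weights, variance filter and document norms match their
           definitions", {
  f <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(idf_weights(f), c(0, 1))

  # site open in 1 of 8 nuclei has IDF 3
  f8 <- rbind(rep(1, 8), c(1, rep(0, 7)))
  expect_equal(idf_weights(f8), c(0, 3))
  expect_error(idf_weights(rbind(f8, 0)), class = "atacmod_validation_error")

  # p = 0.5, g = 1: variance 0.25 -> dropped at 0.4, kept at 0.1
  f2 <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  g2 <- idf_weights(f2)
  expect_equal(g2[1], 1)
  expect_false(1 %in% variance_filter(f2, g2, 0.4))
  expect_true(1 %in% variance_filter(f2, g2, 0.1))
  # p = 1/8, g = 3: variance 9 * 7/64 = 0.984, kept at both thresholds
  v <- 3^2 * (1 / 8) * (7 / 8)
  expect_equal(v, 0.984375)
  expect_true(2 %in% variance_filter(f8, idf_weights(f8), 0.4))
  # constant site (p = 1) has variance 0 and is dropped
  expect_false(1 %in% variance_filter(f8, idf_weights(f8), 0.1))

  expect_equal(document_norm(cbind(c(1, 1, 1, 1), c(1, 0, 0, 0))), c(1 / 4, 1))
  expect_equal(document_norm(cbind(c(1, 1, 1, 1)), norm = "l2"), 1 / 2)
  expect_error(document_norm(cbind(c(1, 0), c(0, 0))),
               class = "atacmod_validation_error")
})

test_that("idf/variance/d/gamma match brute-force recomputation", {
  for (seed in 1:3) {
    f <- random_binary(20, 30, seed)
    n <- ncol(f)
    g_brute <- vapply(seq_len(20), function(i) log2(n / sum(f[i, ])),
                      numeric(1))
    expect_equal(idf_weights(f), g_brute, tolerance = 1e-12)

    p <- rowSums(f) / n
    expect_equal(sort(variance_filter(f, g_brute, 0.1)),
                 sort(which(g_brute^2 * p * (1 - p) > 0.1)))

    d_brute <- vapply(seq_len(n), function(j) 1 / sum(f[, j]^2), numeric(1))
    expect_equal(document_norm(f), d_brute, tolerance = 1e-12)

    sample <- rep(c("a", "b"), length.out = n)
    gam <- batch_correction(f, d_brute, sample, cap = FALSE)
    df <- sweep(f, 2, d_brute, `*`)
    for (i in c(1, 7, 20)) {
      for (j in c(1, 2, 30)) {
        den <- mean(df[i, sample == sample[j]])
        expected <- if (den == 0) 1 else mean(df[i, ]) / den
        expect_equal(gam[i, j], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("batch correction handles single samples, planted depth and caps", {
  f <- random_binary(30, 20, 4)
  d <- document_norm(f)
  # single sample: numerator equals denominator everywhere
  expect_true(all(batch_correction(f, d, rep("s", 20)) == 1))

  # planted 2x depth: sample B's d*f means are half the global means of
  # sample-A-only sites ... construct duplicated nuclei with halved d
  f2 <- cbind(f, f)
  d2 <- c(d, d / 2)  # as if sample B nuclei had twice the open sites
  sample2 <- rep(c("A", "B"), each = 20)
  gam <- batch_correction(f2, d2, sample2, cap = FALSE)
  open <- f[, 1] > 0
  expect_equal(unname(gam[open, 21]),
               rep(0.75 / 0.5, sum(open)), tolerance = 1e-12)

  # capping bound: post-cap gamma <= Q3^2/Q2 per nucleus
  gam_capped <- batch_correction(f2, d2, sample2, cap = TRUE)
  for (j in seq_len(ncol(gam_capped))) {
    q <- quantile(gam[, j], c(0.5, 0.75), names = FALSE)
    if (q[1] > 0) expect_true(all(gam_capped[, j] <= q[2]^2 / q[1] + 1e-12))
  }
})

test_that("embedding is centred, rank-aware and order-invariant", {
  toy <- toy_binary()
  emb <- embed_lsi(toy$f, n_components = 5)
  expect_true(all(diff(emb$d) <= 1e-9))
  expect_equal(nrow(emb$coords), ncol(toy$f))

  # two distinct column patterns: the row-centred weighted matrix is rank 1
  pat_a <- rep(1, 10)
  pat_b <- c(rep(1, 5), rep(0, 5))
  f1 <- cbind(matrix(pat_a, 10, 6), matrix(pat_b, 10, 6))
  emb1 <- embed_lsi(f1, n_components = 3)
  expect_lt(emb1$d[2] / emb1$d[1], 1e-8)

  # row centring: the decomposed matrix has zero row means by construction
  x <- sweep(toy$f, 2, document_norm(toy$f), `*`) * idf_weights(toy$f)
  x <- x - rowMeans(x)
  expect_lt(max(abs(rowSums(x))), 1e-9 * ncol(x))

  # permutation of nuclei permutes coordinates (up to sign)
  perm <- rev(seq_len(ncol(toy$f)))
  emb_p <- embed_lsi(toy$f[, perm], n_components = 5)
  agree <- abs(diag(cor(emb$coords[perm, 1:2], emb_p$coords[, 1:2])))
  expect_true(all(agree > 1 - 1e-6))

  expect_error(embed_lsi(toy$f, n_components = 1000),
               class = "atacmod_validation_error")
})

test_that("outlier detection flags a planted distant point", {
  set.seed(5)
  coords <- matrix(rnorm(200, sd = 0.5), 100, 2)
  coords[7, ] <- c(20, 20)  # ~10x the cluster radius away
  flags <- remove_outliers(coords)
  expect_true(flags[7])
  expect_equal(sum(flags), 1L)

  # all identical points: no flags
  expect_false(any(remove_outliers(matrix(1, 50, 2))))

  # equidistant point score is 5 r^2: verify on a ring of 6 neighbours
  r <- 2
  ring <- rbind(c(0, 0),
                t(vapply(0:5, function(k) {
                  r * c(cos(k * pi / 3), sin(k * pi / 3))
                }, numeric(2))))
  d <- as.matrix(dist(ring))
  score0 <- sum(sort(d[1, ])[2:6]^2)
  expect_equal(score0, 5 * r^2)
})

test_that("SNN-Leiden separates blobs and collapses at low resolution", {
  set.seed(6)
  blob <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  cl <- cluster_snn_leiden(blob, k = 20, seed = 2)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 50)), 1)
  # resolution -> 0 merges everything within a connected component
  one_cloud <- matrix(rnorm(200), 100, 2)
  cl0 <- cluster_snn_leiden(one_cloud, k = 20, resolution = 1e-4, seed = 2)
  expect_equal(length(unique(cl0)), 1L)
  expect_error(cluster_snn_leiden(blob, k = 200),
               class = "atacmod_validation_error")
})

test_that("two-pass pipeline recovers planted cell types and batch
           correction reduces sample separation", {
  cfg <- synth_config(n_cell_types = 3, n_samples = 2,
                      n_nuclei_per_sample = 400, n_tiles = 1200,
                      depth_batch_sd = 0.6, seed = 21)
  bm <- generate_binary_matrix(cfg)
  res <- two_pass_pipeline(bm$f, bm$sample, variance_threshold = 0.1,
                           seed = 5)
  keep <- res$nuclei$retained
  truth <- bm$truth$cell_type[match(res$nuclei$barcode, bm$truth$barcode)]
  expect_gte(adjusted_rand_index(res$nuclei$cluster[keep], truth[keep]),
             0.95)

  # cell-type-aware batch correction mixes samples better within cell type
  # than no correction: mean between-sample centroid distance within type
  f <- bm$f[rowSums(bm$f) > 0, ]
  g <- idf_weights(f)
  keep_sites <- variance_filter(f, g, 0.1)
  fs <- f[keep_sites, ]
  g <- idf_weights(fs); d <- document_norm(fs)
  gam <- batch_correction(fs, d, bm$sample,
                          cell_type = bm$truth$cell_type)
  emb_cor <- embed_lsi(fs, g, d, gam, n_components = 8)
  emb_raw <- embed_lsi(fs, g, d, NULL, n_components = 8)
  sep <- function(coords) {
    mean(vapply(unique(bm$truth$cell_type), function(ct) {
      in_ct <- bm$truth$cell_type == ct
      c1 <- colMeans(coords[in_ct & bm$sample == "S1", , drop = FALSE])
      c2 <- colMeans(coords[in_ct & bm$sample == "S2", , drop = FALSE])
      sqrt(sum((c1 - c2)^2)) / mean(apply(coords[in_ct, ], 2, sd))
    }, numeric(1)))
  }
  expect_lt(sep(emb_cor$coords), sep(emb_raw$coords))
})

test_that("coarse merging of a single fine cluster is the identity", {
  coords <- matrix(rnorm(40), 20, 2)
  expect_equal(atacmod:::merge_coarse_clusters(rep(1L, 20), coords),
               rep(1L, 20))
})

test_that("cell-type assignment follows marker activity", {
  set.seed(9)
  genes <- c("Stab2", "Alb", "Csf1r")
  gs <- matrix(rnorm(3 * 30, 0, 0.1), 3, 30, dimnames = list(genes, NULL))
  clusters <- rep(1:3, each = 10)
  gs["Stab2", clusters == 1] <- 5
  gs["Alb", clusters == 2] <- 5
  gs["Csf1r", clusters == 3] <- 5
  res <- suppressWarnings(assign_cell_types(clusters, gs))
  expect_equal(res$cell_type[res$cluster == 1], "endothelial")
  expect_equal(res$cell_type[res$cluster == 2], "hepatocyte")
  expect_equal(res$cell_type[res$cluster == 3], "macrophage")

  # equal marker activity everywhere: all ambiguous
  flat <- matrix(1, 3, 30, dimnames = list(genes, NULL))
  res2 <- suppressWarnings(assign_cell_types(clusters, flat))
  expect_true(all(res2$cell_type == "ambiguous"))

  # absent markers are skipped with a warning
  expect_warning(assign_cell_types(clusters, gs), "absent")
})
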