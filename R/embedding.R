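#' Inverse document frequency weights per site
#'
#' Treating the binary site-by-nucleus matrix as a term-document matrix,
#' the IDF of site i is `log2(n / sum_j f_ij)` with n the number of nuclei.
#' Rarely open sites are up-weighted; a site open in every nucleus gets 0.
#'
#' @param f binary matrix, sites x nuclei.
#' @return numeric vector, one weight per site.
#' @export
idf_weights <- function(f) {
  rs <- rowSums(f)
  am_validate(all(rs >= 1), "every site must be open in at least one nucleus")
  log2(ncol(f) / rs)
}

#' Variance filter on IDF-weighted sites
#'
#' The variance of IDF-weighted site i is `g_i^2 p_i (1 - p_i)` with
#' `p_i = sum_j f_ij / n`. Sites with variance at or below the threshold are
#' dropped (conventional thresholds: 0.4 for 500-bp tile matrices, 0.1 for
#' peak matrices).
#'
#' @param f binary matrix, sites x nuclei.
#' @param g IDF weights from [idf_weights()] on the same matrix.
#' @param threshold keep sites with IDF-weighted variance strictly above it.
#' @return integer vector of retained site indices.
#' @export
variance_filter <- function(f, g, threshold = 0.4) {
  p <- rowSums(f) / ncol(f)
  which(g^2 * p * (1 - p) > threshold)
}

#' Document normalization factor per nucleus
#'
#' `d_j = 1 / sum_i f_ij^2`; for a binary matrix this is the reciprocal of
#' the nucleus's open-site count. (An L2 variant, `1 / sqrt(sum f^2)`, is the
#' usual LSI document norm and is available via `norm = "l2"`.)
#'
#' @param f binary matrix, sites x nuclei.
#' @param norm `"sum"` (reciprocal open-site count, the default) or `"l2"`.
#' @return numeric vector, one factor per nucleus.
#' @export
document_norm <- function(f, norm = c("sum", "l2")) {
  norm <- match.arg(norm)
  cs <- colSums(f^2)
  am_validate(all(cs > 0), "every nucleus must have at least one open site")
  if (norm == "sum") 1 / cs else 1 / sqrt(cs)
}

#' Per-sample (optionally per-cell-type) batch correction factors
#'
#' Tn5:DNA ratios and other library conditions shift the average normalized
#' accessibility of a site between samples; the difference is treated as a
#' batch effect and corrected by scaling. For nucleus j of sample s the
#' factor on site i is the mean of `d * f` on site i over all nuclei divided
#' by the mean over the nuclei of sample s; when coarse cell-type labels are
#' supplied, both means are restricted to the nucleus's cell type. A zero
#' denominator gives a factor of 1. To avoid inflation under small
#' denominators, each nucleus's factors are capped above at Q3^2 / Q2 of its
#' own factor quartiles.
#'
#' @param f binary matrix, sites x nuclei.
#' @param d document norms from [document_norm()].
#' @param sample character vector, sample label per nucleus.
#' @param cell_type optional coarse cell-type label per nucleus.
#' @param cap cap each nucleus's factors at Q3^2/Q2 (default TRUE).
#' @return matrix of factors, sites x nuclei.
#' @export
batch_correction <- function(f, d, sample, cell_type = NULL, cap = TRUE) {
  am_validate(length(sample) == ncol(f), "one sample label per nucleus")
  am_validate(!anyNA(sample), "unknown (NA) sample label")
  df <- sweep(f, 2, d, `*`)
  n <- ncol(f)
  gamma <- matrix(1, nrow(f), n)
  groups <- if (is.null(cell_type)) rep("all", n) else as.character(cell_type)
  for (ct in unique(groups)) {
    in_ct <- groups == ct
    num <- rowMeans(df[, in_ct, drop = FALSE])
    for (s in unique(sample[in_ct])) {
      cols <- which(in_ct & sample == s)
      den <- rowMeans(df[, cols, drop = FALSE])
      fac <- ifelse(den > 0, num / den, 1)
      gamma[, cols] <- fac
    }
  }
  if (cap) {
    for (j in seq_len(n)) {
      q <- quantile(gamma[, j], c(0.5, 0.75), names = FALSE)
      if (q[1] > 0) gamma[, j] <- pmin(gamma[, j], q[2]^2 / q[1])
    }
  }
  gamma
}

#' IDF-weighted, batch-corrected truncated SVD embedding
#'
#' Builds the matrix with entries `g_i * d_j * f_ij * gamma_ij`, subtracts
#' each row's mean, and takes the truncated SVD `U D V'`. Nucleus coordinates
#' are `V D`.
#'
#' @param f binary matrix (already site-filtered), sites x nuclei.
#' @param g,d,gamma weights from [idf_weights()], [document_norm()] and
#'   [batch_correction()] (pass `gamma = NULL` for no correction).
#' @param n_components number of singular values to retain.
#' @return list of class `atac_embedding`: `coords` (nuclei x components),
#'   `d` (singular values), `u`, `n_components`.
#' @export
embed_lsi <- function(f, g = idf_weights(f), d = document_norm(f),
                      gamma = NULL, n_components = 30) {
  am_validate(n_components <= min(dim(f)),
              "n_components exceeds matrix dimensions")
  x <- sweep(f, 2, d, `*`)
  if (!is.null(gamma)) x <- x * gamma
  x <- x * g
  x <- x - rowMeans(x)
  sv <- truncated_svd(x, n_components)
  coords <- sv$v %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- colnames(f)
  structure(list(coords = coords, d = sv$d, u = sv$u,
                 n_components = n_components),
            class = "atac_embedding")
}

#' Flag outlier nuclei in a 2-D embedding
#'
#' The outlier score of a nucleus is the sum of squared Euclidean distances
#' to its five nearest neighbors in the top-2 component coordinates; nuclei
#' with scores above the given percentile are flagged. Fewer than 6 nuclei:
#' nothing is flagged.
#'
#' @param coords numeric matrix, nuclei x 2 (more columns are ignored).
#' @param k number of nearest neighbors (default 5).
#' @param percentile flag scores above this percentile (default 99.5).
#' @return logical vector, `TRUE` for outliers.
#' @export
remove_outliers <- function(coords, k = 5, percentile = 99.5) {
  n <- nrow(coords)
  if (n < k + 1) return(rep(FALSE, n))
  dmat <- as.matrix(dist(coords[, 1:2, drop = FALSE]))
  score <- apply(dmat, 1, function(r) sum(sort(r)[2:(k + 1)]^2))
  score > quantile(score, percentile / 100)
}

#' Shared-nearest-neighbor Leiden clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding coordinates, weights
#' edges by the Jaccard similarity of neighbor sets (pruning weights below
#' `prune`), and optimizes modularity with the Leiden algorithm.
#'
#' @param coords numeric matrix, nuclei x components.
#' @param k number of nearest neighbors (default 20).
#' @param resolution Leiden resolution parameter.
#' @param prune drop SNN edges with Jaccard weight below this (default 1/15).
#' @param seed random seed for the Leiden optimizer.
#' @return integer vector of cluster labels (contiguous from 1).
#' @export
cluster_snn_leiden <- function(coords, k = 20, resolution = 1, prune = 1 / 15,
                               seed = 1L) {
  n <- nrow(coords)
  am_validate(k < n, "k must be smaller than the number of nuclei")
  dmat <- as.matrix(dist(coords))
  nn <- t(apply(dmat, 1, function(r) order(r)[2:(k + 1)]))
  # Jaccard similarity of neighbor sets via the shared-neighbor count
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- as.matrix(shared) / (2 * k - as.matrix(shared))
  diag(jac) <- 0
  jac[jac < prune] <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  labels <- igraph::membership(cl)
  as.integer(factor(labels, levels = unique(sort(labels))))
}

# agglomerate fine clusters whose centroid distance in the top-2 components
# is below `merge_fraction` of the global coordinate spread
merge_coarse_clusters <- function(fine, coords2, merge_fraction = 0.25,
                                  override = NULL) {
  if (!is.null(override)) {
    return(as.integer(factor(override[as.character(fine)])))
  }
  ids <- sort(unique(fine))
  if (length(ids) == 1) return(rep(1L, length(fine)))
  centroids <- t(vapply(ids, function(cl) {
    colMeans(coords2[fine == cl, 1:2, drop = FALSE])
  }, numeric(2)))
  spread <- sqrt(sum(apply(coords2[, 1:2, drop = FALSE], 2, var)))
  hc <- stats::hclust(dist(centroids), method = "average")
  coarse_of_fine <- stats::cutree(hc, h = merge_fraction * spread)
  as.integer(coarse_of_fine[match(fine, ids)])
}

#' Two-pass batch-corrected embedding and clustering
#'
#' The full dimensionality-reduction and clustering procedure. Pass 1:
#' sample-only batch correction, a 30-component embedding, outlier removal in
#' the top-2 components, re-embedding, SNN-Leiden clustering, and
#' agglomeration of the fine clusters into coarse (cell-type level) groups.
#' Pass 2: batch correction refined within the coarse groups, re-embedding,
#' and final clustering. Retained component counts default to 10 (pass 1)
#' and 8 (pass 2).
#'
#' @param f binary matrix, sites x nuclei (QC-passed).
#' @param sample sample label per nucleus.
#' @param variance_threshold site filter threshold (0.4 for tiles, 0.1 for
#'   peaks).
#' @param n_components_pass1,n_components_pass2 retained singular values in
#'   each pass.
#' @param outlier_percentile passed to [remove_outliers()].
#' @param k,resolution,prune SNN-Leiden parameters.
#' @param merge_fraction centroid-distance fraction for coarse merging.
#' @param coarse_override optional named vector mapping fine cluster ids to
#'   coarse labels (manual merge map).
#' @param norm document-norm variant, see [document_norm()].
#' @param seed random seed.
#' @return list of class `atac_clustering`: `nuclei` tibble (barcode,
#'   sample, retained, coarse, cluster), `embedding` (pass-2
#'   `atac_embedding`), `embedding_pass1`, `retained_sites`.
#' @export
two_pass_pipeline <- function(f, sample, variance_threshold = 0.4,
                              n_components_pass1 = 10,
                              n_components_pass2 = 8,
                              outlier_percentile = 99.5, k = 20,
                              resolution = 1, prune = 1 / 15,
                              merge_fraction = 0.25, coarse_override = NULL,
                              norm = "sum", seed = 1L) {
  nonzero <- which(rowSums(f) > 0)
  fnz <- f[nonzero, , drop = FALSE]
  g_all <- idf_weights(fnz)
  keep <- variance_filter(fnz, g_all, variance_threshold)
  keep_sites <- nonzero[keep]
  am_validate(length(keep_sites) >= n_components_pass1,
              "too few sites pass the variance filter")
  fs <- fnz[keep, , drop = FALSE]
  ok <- colSums(fs) > 0
  fs <- fs[, ok, drop = FALSE]
  sample <- sample[ok]

  # pass 1: sample-only correction
  g <- idf_weights(fs)
  d <- document_norm(fs, norm)
  gam <- batch_correction(fs, d, sample)
  emb30 <- embed_lsi(fs, g, d, gam, n_components = min(30, min(dim(fs)) - 1))
  out <- remove_outliers(emb30$coords[, 1:2, drop = FALSE],
                         percentile = outlier_percentile)
  f1 <- fs[, !out, drop = FALSE]
  s1 <- sample[!out]
  keep2 <- rowSums(f1) > 0
  f1 <- f1[keep2, , drop = FALSE]
  g1 <- idf_weights(f1)
  d1 <- document_norm(f1, norm)
  gam1 <- batch_correction(f1, d1, s1)
  emb1 <- embed_lsi(f1, g1, d1, gam1, n_components = n_components_pass1)
  fine1 <- cluster_snn_leiden(emb1$coords, k = k, resolution = resolution,
                              prune = prune, seed = seed)
  coarse <- merge_coarse_clusters(fine1, emb1$coords,
                                  merge_fraction = merge_fraction,
                                  override = coarse_override)

  # pass 2: cell-type aware correction
  gam2 <- batch_correction(f1, d1, s1, cell_type = coarse)
  emb2 <- embed_lsi(f1, g1, d1, gam2, n_components = n_components_pass2)
  fine2 <- cluster_snn_leiden(emb2$coords, k = k, resolution = resolution,
                              prune = prune, seed = seed)

  nuclei <- tibble(barcode = colnames(fs), sample = sample,
                   retained = !out, coarse = NA_integer_,
                   cluster = NA_integer_, cluster_pass1 = NA_integer_)
  nuclei$coarse[!out] <- coarse
  nuclei$cluster[!out] <- fine2
  nuclei$cluster_pass1[!out] <- fine1
  structure(list(nuclei = nuclei, embedding = emb2, embedding_pass1 = emb1,
                 retained_sites = keep_sites),
            class = "atac_clustering")
}

#' Assign cell types to clusters from marker-gene activity
#'
#' Standardizes each marker gene's score across nuclei, averages within
#' clusters, and labels each cluster with the cell type whose markers have
#' the highest mean standardized score. A margin below `tie_tol` yields
#' "ambiguous"; exact ties break lexicographically on the cell-type name.
#'
#' @param clusters integer/character cluster label per nucleus.
#' @param gene_scores genes x nuclei matrix.
#' @param markers named list: cell type -> character vector of marker genes.
#'   Defaults to a liver panel (hepatocyte Alb/Apoc3/Cyp2e1/Cyp2f4,
#'   endothelial Stab2, stellate Dcn/Des/Lrat/Acta2, macrophage Csf1r,
#'   inflammatory vs noninflammatory macrophage Lyz2/Marco, T cell
#'   Cd3g/Gata3, B cell Ebf1).
#' @param tie_tol score margin below which a cluster is called "ambiguous".
#' @return tibble: `cluster`, `cell_type`, `score`, `margin`.
#' @export
assign_cell_types <- function(clusters, gene_scores,
                              markers = liver_markers(), tie_tol = 1e-9) {
  present <- lapply(markers, intersect, rownames(gene_scores))
  missing <- unlist(lapply(markers, setdiff, rownames(gene_scores)))
  if (length(missing) > 0) {
    warn(paste("markers absent from matrix, skipped:",
               paste(missing, collapse = ", ")))
  }
  present <- present[lengths(present) > 0]
  am_validate(length(present) > 0, "no marker genes found in the matrix")
  z <- t(scale(t(gene_scores[unique(unlist(present)), , drop = FALSE])))
  z[is.na(z)] <- 0
  ids <- sort(unique(clusters))
  purrr::map_dfr(ids, function(cl) {
    in_cl <- clusters == cl
    type_scores <- vapply(present, function(gs) {
      mean(z[gs, in_cl, drop = FALSE])
    }, numeric(1))
    # order by score, ties lexicographically on name, for determinism
    type_scores <- type_scores[order(-type_scores, names(type_scores))]
    margin <- if (length(type_scores) > 1)
      type_scores[1] - type_scores[2] else Inf
    tibble(cluster = cl,
           cell_type = if (margin < tie_tol) "ambiguous"
                       else names(type_scores)[1],
           score = unname(type_scores[1]), margin = unname(margin))
  })
}

#' Default liver marker panel
#' @return named list of marker genes per cell type.
#' @export
liver_markers <- function() {
  list(hepatocyte = c("Alb", "Apoc3", "Cyp2e1", "Cyp2f4"),
       cholangiocyte = c("Epcam", "Krt19"),
       endothelial = "Stab2",
       stellate = c("Dcn", "Des", "Lrat", "Acta2"),
       macrophage = "Csf1r",
       macrophage_inflammatory = "Lyz2",
       macrophage_noninflammatory = "Marco",
       t_cell = c("Cd3g", "Gata3"),
       b_cell = "Ebf1")
}
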