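#' Raw gene activity scores from Tn5 insertions
#'
#' Per gene and nucleus, counts Tn5 insertions (both fragment ends) falling
#' within the gene body extended by `window` bp on both sides. Chromatin
#' opening of the gene, not mRNA abundance, is the targeted signal.
#' Overlapping genes each receive the insertion (no arbitration).
#'
#' @param fragments fragments tibble.
#' @param genes tibble with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open gene bodies).
#' @param window extension in bp (default 2000).
#' @return genes x nuclei integer matrix.
#' @export
gene_score_counts <- function(fragments, genes, window = 2000) {
  barcodes <- sort(unique(fragments$barcode))
  mat <- matrix(0L, nrow(genes), length(barcodes),
                dimnames = list(genes$gene, barcodes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    fi <- which(fragments$chrom == ch)
    if (length(fi) == 0) next
    ins_pos <- c(fragments$start[fi], fragments$end[fi] - 1L)
    ins_bc <- match(rep(fragments$barcode[fi], 2), barcodes)
    gr <- IRanges::IRanges(start = genes$start[gi] - window,
                           end = genes$end[gi] - 1L + window)
    ir <- IRanges::IRanges(start = ins_pos, width = 1L)
    hits <- IRanges::findOverlaps(ir, gr)
    if (length(hits) == 0) next
    idx <- cbind(gi[S4Vectors::subjectHits(hits)],
                 ins_bc[S4Vectors::queryHits(hits)])
    tab <- table(idx[, 1], idx[, 2])
    mat[as.integer(rownames(tab)), as.integer(colnames(tab))] <-
      mat[as.integer(rownames(tab)), as.integer(colnames(tab))] +
      as.integer(tab)
  }
  mat
}

#' Post-process a raw gene score matrix
#'
#' The fixed processing chain: (1) scale each nucleus to the median library
#' size; (2) impute zeros by k-nearest-neighbor smoothing in PCA space, then
#' floor all values at 0.001; (3) drop low-expression genes whose value sits
#' at the floor in at least `floor_gene_fraction` of nuclei; (4) log2;
#' (5) quantile normalization across nuclei; (6) subtract the rank-2 SVD
#' approximation, which absorbs the dominant sample batch effect.
#'
#' @param raw genes x nuclei nonnegative matrix.
#' @param k neighbors for imputation (default 15).
#' @param n_pcs PCA dimensions used to find neighbors.
#' @param floor_value imputation floor (default 0.001).
#' @param floor_gene_fraction drop genes at the floor in at least this
#'   fraction of nuclei (default 0.01).
#' @param n_svd_remove leading SVD components to subtract (default 2).
#' @return processed matrix (possibly fewer genes), with attribute `state`
#'   recording the chain.
#' @export
process_gene_scores <- function(raw, k = 15, n_pcs = 10,
                                floor_value = 0.001,
                                floor_gene_fraction = 0.01,
                                n_svd_remove = 2) {
  am_validate(all(raw >= 0), "raw gene scores must be nonnegative")
  lib <- colSums(raw)
  empty <- lib == 0
  if (any(empty)) {
    warn(sprintf("%d empty nuclei dropped", sum(empty)))
    raw <- raw[, !empty, drop = FALSE]
    lib <- lib[!empty]
  }
  x <- sweep(raw, 2, median(lib) / lib, `*`)

  if (any(x == 0)) {
    x <- knn_impute_zeros(x, k = k, n_pcs = n_pcs)
  }
  x <- pmax(x, floor_value)

  at_floor <- rowMeans(x == floor_value)
  x <- x[at_floor < floor_gene_fraction, , drop = FALSE]

  x <- log2(x)
  x <- quantile_normalize(x)$v
  if (n_svd_remove > 0) x <- subtract_svd_components(x, n_svd_remove)
  attr(x, "state") <- "svd-corrected"
  x
}

# replace zero entries by the mean over the k nearest nuclei in PCA space
knn_impute_zeros <- function(x, k = 15, n_pcs = 10) {
  n <- ncol(x)
  k <- min(k, n - 1)
  n_pcs <- min(n_pcs, n - 1, nrow(x))
  pc <- prcomp(t(log1p(x)), rank. = n_pcs, center = TRUE, scale. = FALSE)
  dmat <- as.matrix(dist(pc$x))
  for (j in seq_len(n)) {
    zr <- which(x[, j] == 0)
    if (length(zr) == 0) next
    nb <- order(dmat[j, ])[seq_len(k + 1)]  # includes self
    x[zr, j] <- rowMeans(x[zr, nb, drop = FALSE])
  }
  x
}

# subtract the rank-r SVD approximation (deflation of leading components)
subtract_svd_components <- function(x, r) {
  sv <- truncated_svd(x, r)
  x - sv$u %*% (diag(sv$d, nrow = r) %*% t(sv$v))
}

#' Motif deviation z-scores per TF and nucleus
#'
#' For each TF, the observed count of open peaks carrying its motif in a
#' nucleus is compared with the expectation under the nucleus's depth and
#' the peaks' population accessibility; the raw deviation
#' `(obs - exp) / exp` is standardized against `n_background` random peak
#' sets matched on accessibility deciles. The z-score matrix then receives
#' the same quantile normalization and rank-2 SVD subtraction as the gene
#' score matrix.
#'
#' @param peaks_by_nuclei binary peaks x nuclei matrix.
#' @param motif_match binary peaks x TFs match matrix.
#' @param n_background background sets per TF (default 50).
#' @param min_peaks TFs matching fewer peaks are dropped with a warning.
#' @param normalize apply the quantile + SVD correction (default TRUE).
#' @param seed seed for background sampling.
#' @return TFs x nuclei matrix of deviation z-scores.
#' @export
motif_deviation_zscores <- function(peaks_by_nuclei, motif_match,
                                    n_background = 50, min_peaks = 10,
                                    normalize = TRUE, seed = 1L) {
  am_validate(nrow(peaks_by_nuclei) == nrow(motif_match),
              "peak sets of the two matrices must match")
  keep <- colSums(motif_match) >= min_peaks
  if (!all(keep)) {
    warn(sprintf("%d TFs matched < %d peaks and were dropped",
                 sum(!keep), min_peaks))
  }
  motif_match <- motif_match[, keep, drop = FALSE]
  set.seed(seed)
  depth <- colSums(peaks_by_nuclei)
  p_i <- rowSums(peaks_by_nuclei) / sum(peaks_by_nuclei)
  decile <- cut(rank(p_i, ties.method = "first"),
                breaks = 10, labels = FALSE)
  peaks_by_decile <- split(seq_along(p_i), decile)

  dev_of_sets <- function(match_mat) {
    # expected count per nucleus = depth_j * sum_{i in set} p_i
    obs <- t(match_mat) %*% peaks_by_nuclei
    expd <- outer(colSums(match_mat * p_i), depth)
    as.matrix((obs - expd) / expd)
  }
  raw <- dev_of_sets(motif_match)

  n_tf <- ncol(motif_match)
  bg_mean <- matrix(0, n_tf, ncol(peaks_by_nuclei))
  bg_m2 <- matrix(0, n_tf, ncol(peaks_by_nuclei))
  tf_deciles <- lapply(seq_len(n_tf), function(m) {
    decile[motif_match[, m] > 0]
  })
  for (b in seq_len(n_background)) {
    bg_match <- matrix(0, nrow(motif_match), n_tf)
    for (m in seq_len(n_tf)) {
      picks <- unlist(lapply(split(tf_deciles[[m]], tf_deciles[[m]]),
                             function(d) {
        pool <- peaks_by_decile[[as.character(d[1])]]
        pool[sample.int(length(pool), length(d), replace = TRUE)]
      }), use.names = FALSE)
      bg_match[picks, m] <- 1
    }
    dv <- dev_of_sets(bg_match)
    bg_mean <- bg_mean + dv
    bg_m2 <- bg_m2 + dv^2
  }
  bg_mean <- bg_mean / n_background
  bg_sd <- sqrt(pmax(bg_m2 / n_background - bg_mean^2, 0) *
                  n_background / (n_background - 1))
  z <- (raw - bg_mean) / bg_sd
  z[!is.finite(z)] <- 0
  rownames(z) <- colnames(motif_match)
  colnames(z) <- colnames(peaks_by_nuclei)
  if (normalize) {
    z <- quantile_normalize(z)$v
    z <- subtract_svd_components(z, 2)
  }
  z
}

#' Wilcoxon rank-sum z-scores for differential activity
#'
#' Per gene, the continuity-corrected normal approximation of the Wilcoxon
#' rank-sum statistic comparing nuclei of each condition against the
#' reference condition; the sign is positive when the condition exceeds the
#' reference. Constant genes get z = 0.
#'
#' @param x genes x nuclei matrix (processed scores).
#' @param condition label per nucleus.
#' @param reference reference condition.
#' @return tibble: `gene`, `condition`, `z`.
#' @export
dge_zscores <- function(x, condition, reference) {
  am_validate(reference %in% condition, "reference condition absent")
  conds <- setdiff(unique(condition), reference)
  ref_cols <- condition == reference
  purrr::map_dfr(conds, function(cn) {
    cols <- condition == cn
    am_validate(sum(cols) >= 2 && sum(ref_cols) >= 2,
                "need >= 2 nuclei per compared group")
    sub <- x[, cols | ref_cols, drop = FALSE]
    grp1 <- condition[cols | ref_cols] == cn
    z <- apply(sub, 1, function(row) wilcox_z(row[grp1], row[!grp1]))
    tibble(gene = rownames(x), condition = cn, z = z)
  })
}

# continuity-corrected normal approximation of the rank-sum test, with the
# tie correction of the normal approximation
wilcox_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for group 1
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(0)
  (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
}

#' Sample-permutation gene-set enrichment with overlap down-weighting
#'
#' Tests, per gene set, whether its member genes carry larger moderated
#' |t|-statistics (condition vs reference across nuclei) than expected,
#' using group-label permutations. Genes appearing in many sets are
#' down-weighted: `w_g = 1 + sqrt((max_f - f_g) / (max_f - min_f))` with
#' `f_g` the number of sets containing gene g. The permutation count is
#' `max(10000 * scale, 20 * n_sets)`; `scale` trades precision for time.
#' P-values are `(1 + #exceedances) / (n_perm + 1)` with Benjamini-Hochberg
#' FDR across sets.
#'
#' @param x genes x nuclei matrix (processed scores).
#' @param condition label per nucleus (exactly two groups used).
#' @param reference reference condition.
#' @param gene_sets named list of member vectors.
#' @param scale multiplier on the 10,000 base permutation count.
#' @param prior_df prior degrees of freedom of the variance moderation.
#' @param seed permutation seed.
#' @return tibble: `set`, `n_members`, `score`, `p_value`, `fdr`,
#'   `significant` (FDR < 0.05).
#' @export
gs_enrichment_sample_perm <- function(x, condition, reference, gene_sets,
                                      scale = 1, prior_df = 4, seed = 1L) {
  grp <- condition == reference
  am_validate(length(unique(condition)) == 2, "exactly two groups expected")
  present <- lapply(gene_sets, intersect, rownames(x))
  skipped <- lengths(present) == 0
  if (any(skipped)) {
    warn(sprintf("%d sets have no genes in the matrix; skipped",
                 sum(skipped)))
  }
  present <- present[!skipped]
  n_sets <- length(present)
  am_validate(n_sets > 0, "no scorable gene sets")
  n_perm <- gs_perm_count(n_sets, scale)

  f_g <- setNames(rep(0, nrow(x)), rownames(x))
  tab <- table(unlist(present))
  f_g[names(tab)] <- as.numeric(tab)
  rng <- range(f_g[unique(unlist(present))])
  w_g <- if (diff(rng) == 0) rep(1, nrow(x)) else
    1 + sqrt((rng[2] - f_g) / (rng[2] - rng[1]))
  names(w_g) <- rownames(x)

  member_idx <- lapply(present, match, rownames(x))
  set_matrix <- Matrix::sparseMatrix(
    i = rep(seq_len(n_sets), lengths(member_idx)),
    j = unlist(member_idx), x = 1, dims = c(n_sets, nrow(x)))

  score_of <- function(assignment) {
    wt <- w_g * abs(moderated_t_rows(x, assignment, prior_df))
    as.vector(set_matrix %*% wt) / unname(lengths(member_idx))
  }
  observed <- score_of(grp)

  set.seed(seed)
  n <- ncol(x)
  n_ref <- sum(grp)
  exceed <- rep(0, n_sets)
  # permutations are evaluated in blocks via matrix products
  block <- 200
  done <- 0
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    perm_scores <- vapply(seq_len(nb), function(b) {
      score_of(seq_len(n) %in% sample.int(n, n_ref))
    }, numeric(n_sets))
    exceed <- exceed + rowSums(perm_scores >= observed)
    done <- done + nb
  }
  p <- (1 + exceed) / (n_perm + 1)
  fdr <- p.adjust(p, "BH")
  out <- tibble(set = names(present), n_members = lengths(present),
                score = observed, p_value = p, fdr = fdr,
                significant = fdr < 0.05)
  attr(out, "n_perm") <- n_perm
  out
}

#' Permutation count rule for the sample-permutation set test
#'
#' The base count of 10,000 (scaled by `scale`) or 20 permutations per gene
#' set, whichever is larger.
#'
#' @param n_sets number of scorable gene sets.
#' @param scale multiplier on the base 10,000.
#' @return integer permutation count.
#' @export
gs_perm_count <- function(n_sets, scale = 1) {
  max(round(10000 * scale), 20 * n_sets)
}

# moderated t per row: pooled two-group t with the gene-wise variance shrunk
# toward the mean variance with `prior_df` prior degrees of freedom
moderated_t_rows <- function(x, grp1, prior_df = 4) {
  n1 <- sum(grp1); n2 <- sum(!grp1)
  m1 <- rowMeans(x[, grp1, drop = FALSE])
  m2 <- rowMeans(x[, !grp1, drop = FALSE])
  v1 <- rowSums((x[, grp1, drop = FALSE] - m1)^2)
  v2 <- rowSums((x[, !grp1, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (v1 + v2) / df
  s2_shrunk <- (prior_df * mean(s2) + df * s2) / (prior_df + df)
  t <- (m1 - m2) / sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  t[!is.finite(t)] <- 0
  t
}
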