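#' Regulator-regulatee importance matrix from per-gene random forests
#'
#' For every gene, a regression forest predicts its activity score from all
#' TF motif deviations plus condition indicator rows; the importance of a
#' predictor is its total impurity (variance) reduction, normalized so the
#' per-gene column sums to the forest's out-of-bag explained-variance
#' proportion (floored at 0). The number of candidate predictors per split
#' defaults to the square root of the number of predictors.
#'
#' @param gene_scores genes x nuclei matrix (responses).
#' @param motif_dev TFs x nuclei matrix (predictors).
#' @param condition optional condition label per nucleus; indicator rows are
#'   added as predictors and kept in the output with `row_kind`
#'   "condition".
#' @param n_trees trees per forest (default 100).
#' @param mtry candidate predictors per split; default
#'   `round(sqrt(n_predictors))`.
#' @param seed base seed (per-gene seeds derive from it).
#' @return regulators x genes matrix with attribute `row_kind`
#'   ("tf"/"condition") and class `regulator_matrix`.
#' @export
regulator_importances <- function(gene_scores, motif_dev, condition = NULL,
                                  n_trees = 100, mtry = NULL, seed = 1L) {
  am_validate(ncol(gene_scores) == ncol(motif_dev),
              "matrices must share nuclei")
  predictors <- motif_dev
  row_kind <- rep("tf", nrow(motif_dev))
  if (!is.null(condition)) {
    lv <- sort(unique(condition))
    ind <- t(vapply(lv, function(cv) as.numeric(condition == cv),
                    numeric(length(condition))))
    rownames(ind) <- paste0("condition:", lv)
    predictors <- rbind(predictors, ind)
    row_kind <- c(row_kind, rep("condition", length(lv)))
  }
  p <- nrow(predictors)
  if (is.null(mtry)) mtry <- max(1, round(sqrt(p)))
  xmat <- t(predictors)
  R <- matrix(0, p, nrow(gene_scores),
              dimnames = list(rownames(predictors), rownames(gene_scores)))
  for (gi in seq_len(nrow(gene_scores))) {
    y <- gene_scores[gi, ]
    if (var(y) == 0) next
    rf <- ranger::ranger(x = xmat, y = y, num.trees = n_trees, mtry = mtry,
                         importance = "impurity", num.threads = 1,
                         seed = seed + gi)
    imp <- pmax(rf$variable.importance, 0)
    r2 <- max(rf$r.squared, 0)
    if (sum(imp) > 0) R[, gi] <- imp / sum(imp) * r2
  }
  attr(R, "row_kind") <- row_kind
  class(R) <- c("regulator_matrix", class(R))
  R
}

# nonnegative double SVD initialization (Boutsidis & Gallopoulos)
nndsvd_init <- function(V, rank) {
  sv <- svd(V, nu = rank, nv = rank)
  W <- matrix(0, nrow(V), rank)
  H <- matrix(0, rank, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(rank)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
    n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
    if (n_up * n_vp >= n_un * n_vn) {
      scale <- sqrt(sv$d[j] * n_up * n_vp)
      if (n_up > 0) W[, j] <- scale * up / n_up
      if (n_vp > 0) H[j, ] <- scale * vp / n_vp
    } else {
      scale <- sqrt(sv$d[j] * n_un * n_vn)
      if (n_un > 0) W[, j] <- scale * un / n_un
      if (n_vn > 0) H[j, ] <- scale * vn / n_vn
    }
  }
  floor_val <- mean(V) * 1e-4
  W[W < floor_val] <- floor_val
  H[H < floor_val] <- floor_val
  list(W = W, H = H)
}

#' Nonnegative matrix factorization by KL multiplicative updates
#'
#' Factorizes a nonnegative matrix into `W %*% H` by the Brunet
#' multiplicative updates minimizing generalized Kullback-Leibler
#' divergence. Multiple random nonnegative initializations (plus an
#' optional NNDSVD start) are run and the factorization with the lowest
#' objective kept. Convergence: relative objective change below `tol` or
#' `max_iter` iterations.
#'
#' @param R nonnegative matrix (regulators x genes).
#' @param rank number of factors (modules).
#' @param n_starts random starts (default 100).
#' @param seed integer seed.
#' @param max_iter,tol convergence controls.
#' @param nndsvd also try a nonnegative-double-SVD start (default TRUE).
#' @return list of class `nmf_fit`: `W`, `H`, `rank`, `objective`, `trace`
#'   (objective values of the winning run), `seed`.
#' @export
nmf_brunet <- function(R, rank, n_starts = 100, seed = 1L, max_iter = 2000,
                       tol = 1e-6, nndsvd = TRUE) {
  am_validate(all(R >= 0), "matrix must be nonnegative")
  am_validate(rank >= 1 && rank <= min(dim(R)),
              "rank must lie in [1, min(dim(R))]")
  scale0 <- sqrt(mean(R) / rank)
  best <- NULL
  starts <- seq_len(n_starts)
  for (s in starts) {
    set.seed(seed + s)
    W0 <- matrix(runif(nrow(R) * rank, 1e-4, 1), nrow(R), rank) * scale0
    H0 <- matrix(runif(rank * ncol(R), 1e-4, 1), rank, ncol(R)) * scale0
    fit <- nmf_kl_run(R, W0, H0, max_iter, tol, 10L)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (nndsvd) {
    init <- nndsvd_init(R, rank)
    fit <- nmf_kl_run(R, init$W, init$H, max_iter, tol, 10L)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  dimnames(best$W) <- list(rownames(R), paste0("module", seq_len(rank)))
  dimnames(best$H) <- list(paste0("module", seq_len(rank)), colnames(R))
  structure(list(W = best$W, H = best$H, rank = rank,
                 objective = best$objective, trace = best$trace,
                 seed = seed),
            class = "nmf_fit")
}

#' Choose the NMF rank at the inflection of the residual curve
#'
#' Fits each rank in the grid (with a reduced number of starts), records the
#' final KL objective, and picks the rank where the log-residual curve bends
#' most sharply — the maximum discrete second difference of the log
#' residuals, equivalently the rank after which the relative improvement
#' collapses. A curve with no positive curvature has no elbow; the smallest
#' rank is returned with a warning.
#'
#' @param R nonnegative matrix.
#' @param ranks consecutive rank grid (default 2:10, >= 4 values).
#' @param n_starts starts per rank (default 20).
#' @param seed,max_iter,tol passed to [nmf_brunet()].
#' @return list: `rank` (chosen), `residuals` tibble (rank, objective,
#'   curvature).
#' @export
select_rank <- function(R, ranks = 2:10, n_starts = 20, seed = 1L,
                        max_iter = 2000, tol = 1e-6) {
  am_validate(length(ranks) >= 4 && all(diff(ranks) == 1),
              "need a grid of >= 4 consecutive ranks")
  resid <- vapply(ranks, function(r) {
    nmf_brunet(R, r, n_starts = n_starts, seed = seed + 1000L * r,
               max_iter = max_iter, tol = tol)$objective
  }, numeric(1))
  curvature <- residual_curvature(resid)
  if (all(is.na(curvature)) || max(curvature, na.rm = TRUE) <= 0) {
    warn("residual curve has no elbow; returning the smallest rank")
    chosen <- ranks[1]
  } else {
    chosen <- ranks[which.max(curvature)]  # which.max takes the first tie
  }
  list(rank = chosen,
       residuals = tibble(rank = ranks, objective = resid,
                          curvature = curvature))
}

# second difference of log residuals at interior grid points; the floor
# keeps exactly-factorizable (zero-residual) fits finite
residual_curvature <- function(resid) {
  lr <- log(pmax(resid, max(resid) * 1e-12 + 1e-300))
  n <- length(lr)
  curv <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  curv[idx] <- lr[idx - 1] - 2 * lr[idx] + lr[idx + 1]
  curv
}

#' Representative regulators and genes of each module
#'
#' Per module, members are ranked by their factor weight; representatives
#' are those ranked in the top `top_n` whose weight also exceeds
#' `weight_fraction` of the module's top weight. Condition indicator rows
#' are excluded from the reporting.
#'
#' @param fit an [nmf_brunet()] result.
#' @param row_kind optional row-kind vector of the factorized matrix
#'   ("tf"/"condition"); condition rows are dropped from regulator tables.
#' @param top_n,weight_fraction the membership reporting rule.
#' @return list of tibbles `regulators` and `genes` with columns `module`,
#'   `symbol`, `weight`, `rank`, `representative`.
#' @export
module_membership <- function(fit, row_kind = NULL, top_n = 5,
                              weight_fraction = 0.5) {
  rank_table <- function(mat, margin) {
    purrr::map_dfr(seq_len(fit$rank), function(m) {
      w <- if (margin == 1) mat[, m] else mat[m, ]
      ord <- order(-w)
      tibble(module = m, symbol = names(w)[ord], weight = unname(w[ord]),
             rank = seq_along(w)) |>
        dplyr::mutate(representative = .data$rank <= top_n &
                        .data$weight > weight_fraction * .data$weight[1])
    })
  }
  W <- fit$W
  if (!is.null(row_kind)) W <- W[row_kind == "tf", , drop = FALSE]
  list(regulators = rank_table(W, 1), genes = rank_table(fit$H, 2))
}

#' Gene-set enrichment of module gene weights with permutation FWER
#'
#' Per module and gene set, a Welch t-statistic compares the module weights
#' of member genes against non-members. The null distribution permutes gene
#' names `n_perm` times, recording per permutation the maximum t across all
#' sets (per module); the FWER-adjusted p-value is
#' `(1 + #exceedances) / (n_perm + 1)`.
#'
#' @param fit an [nmf_brunet()] result (uses its `H`).
#' @param gene_sets named list of member vectors.
#' @param n_perm gene-name permutations (default 100).
#' @param min_overlap sets with fewer member genes in the universe are
#'   skipped.
#' @param seed permutation seed.
#' @return tibble: `module`, `set`, `n_members`, `t`, `fwer_p`,
#'   `significant` (FWER p < 0.05).
#' @export
module_gs_enrichment <- function(fit, gene_sets, n_perm = 100,
                                 min_overlap = 3, seed = 1L) {
  genes <- colnames(fit$H)
  member <- lapply(gene_sets, function(gs) genes %in% gs)
  keep <- vapply(member, sum, numeric(1)) >= min_overlap
  am_validate(any(keep), "no gene set overlaps the gene universe")
  member <- member[keep]

  t_for <- function(h) {
    vapply(member, function(m) welch_t_scalar(h[m], h[!m]), numeric(1))
  }
  set.seed(seed)
  purrr::map_dfr(seq_len(fit$rank), function(mod) {
    h <- fit$H[mod, ]
    observed <- t_for(h)
    max_null <- vapply(seq_len(n_perm), function(b) {
      max(t_for(setNames(h, sample(names(h)))[names(h)]))
    }, numeric(1))
    fwer <- vapply(observed, function(t0) {
      (1 + sum(max_null >= t0)) / (n_perm + 1)
    }, numeric(1))
    tibble(module = mod, set = names(member),
           n_members = vapply(member, sum, numeric(1)),
           t = observed, fwer_p = fwer, significant = fwer < 0.05)
  })
}

welch_t_scalar <- function(a, b) {
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (!is.finite(se) || se == 0) return(0)
  (mean(a) - mean(b)) / se
}

#' Split-half consistency of module discovery
#'
#' Randomly halves the nuclei, infers the regulator-regulatee matrix in each
#' half, approximates each by NMF at the chosen rank, and reports the
#' Pearson correlation between the two NMF approximations. The noise floor
#' repeats the procedure with the gene-matrix nucleus labels randomly
#' permuted (motif matrix intact).
#'
#' @param gene_scores,motif_dev,condition as in [regulator_importances()].
#' @param rank NMF rank.
#' @param n_floor_trials permuted-label trials for the noise floor
#'   (default 5).
#' @param n_trees,n_starts,seed pipeline controls.
#' @return tibble: `trial` ("observed" or "permuted_k"), `correlation`.
#' @export
split_half_consistency <- function(gene_scores, motif_dev, condition = NULL,
                                   rank = 4, n_floor_trials = 5,
                                   n_trees = 50, n_starts = 5, seed = 1L) {
  n <- ncol(gene_scores)
  am_validate(n >= 200, "need >= 200 nuclei for a meaningful split")
  half_correlation <- function(gs, md, cond, seed0) {
    set.seed(seed0)
    half <- sample.int(n, floor(n / 2))
    approx_of <- function(cols) {
      R <- regulator_importances(gs[, cols, drop = FALSE],
                                 md[, cols, drop = FALSE],
                                 condition = cond[cols],
                                 n_trees = n_trees, seed = seed0)
      fit <- nmf_brunet(unclass(R), rank, n_starts = n_starts, seed = seed0)
      fit$W %*% fit$H
    }
    a1 <- as.vector(approx_of(half))
    a2 <- as.vector(approx_of(setdiff(seq_len(n), half)))
    # an all-zero importance approximation (no predictive signal) has no
    # consistency with anything
    if (sd(a1) == 0 || sd(a2) == 0) return(0)
    cor(a1, a2)
  }
  if (is.null(condition)) condition <- rep("all", n)
  observed <- half_correlation(gene_scores, motif_dev, condition, seed)
  floors <- vapply(seq_len(n_floor_trials), function(k) {
    set.seed(seed + 100L * k)
    shuffled <- gene_scores[, sample.int(n), drop = FALSE]
    colnames(shuffled) <- colnames(gene_scores)
    half_correlation(shuffled, motif_dev, condition, seed + 100L * k)
  }, numeric(1))
  tibble(trial = c("observed", paste0("permuted_", seq_len(n_floor_trials))),
         correlation = c(observed, floors))
}
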