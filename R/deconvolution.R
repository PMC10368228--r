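#' Pseudo-bulk counts per (cell type, sample) group
#'
#' Sums per-nucleus peak counts within each (cell type, sample) group and
#' records the group sizes `a_jk`.
#'
#' @param counts peaks x nuclei count matrix.
#' @param cell_type,sample labels per nucleus.
#' @return list of class `pseudo_bulk`: `u` (peaks x groups), `groups`
#'   tibble (`cell_type`, `sample`, `a`).
#' @export
pseudo_bulk <- function(counts, cell_type, sample) {
  am_validate(length(cell_type) == ncol(counts) &&
                length(sample) == ncol(counts),
              "one cell type and sample label per nucleus")
  key <- paste(cell_type, sample, sep = ".")
  groups <- tibble(cell_type = cell_type, sample = sample, key = key) |>
    dplyr::count(.data$cell_type, .data$sample, .data$key, name = "a") |>
    dplyr::arrange(.data$cell_type, .data$sample)
  u <- vapply(groups$key, function(k) {
    rowSums(counts[, key == k, drop = FALSE])
  }, numeric(nrow(counts)))
  colnames(u) <- groups$key
  structure(list(u = u, groups = dplyr::select(groups, -"key")),
            class = "pseudo_bulk")
}

#' Assemble a pseudo-bulk set from precomputed group counts
#'
#' For workflows where the per-group count matrix is already available
#' (e.g. from the synthetic generator), wraps it in the container
#' [pseudo_bulk()] produces.
#'
#' @param u peaks x groups count matrix.
#' @param groups tibble with `cell_type`, `sample`, `a` (one row per column
#'   of `u`).
#' @return a `pseudo_bulk` object.
#' @export
as_pseudo_bulk <- function(u, groups) {
  am_validate(ncol(u) == nrow(groups),
              "one group row per column of the count matrix")
  am_validate(all(c("cell_type", "sample", "a") %in% names(groups)),
              "groups needs cell_type, sample and a columns")
  structure(list(u = u, groups = groups), class = "pseudo_bulk")
}

#' Quantile normalization against a stored reference distribution
#'
#' The reference distribution is the mean of the sorted values across the
#' input vectors (computed once, typically from the pseudo-bulk library
#' vectors, and reused for bulk vectors so single-sample deconvolution is
#' well defined). Each vector's sorted values are replaced by the reference;
#' ties receive the mean of their assigned reference values.
#'
#' @param x matrix whose columns are the vectors to normalize.
#' @param reference optional previously stored reference distribution; when
#'   `NULL` it is computed from `x`.
#' @return list: `v` (normalized matrix), `reference` (sorted numeric
#'   vector).
#' @export
quantile_normalize <- function(x, reference = NULL) {
  if (is.null(reference)) {
    reference <- rowMeans(apply(x, 2, sort))
  }
  v <- qn_to_reference(x, reference)
  dimnames(v) <- dimnames(x)
  list(v = v, reference = sort(reference))
}

#' Nuclei equivalents of normalized pseudo-bulk libraries
#'
#' Quantile normalization is not linear, but the effective number of nuclei
#' in the normalized vector can be tracked as
#' `b_jk = (sum_i v_ijk / sum_i u_ijk) * a_jk`.
#'
#' @param u,v raw and quantile-normalized peaks x groups matrices.
#' @param a group sizes (nuclei counts), one per column.
#' @return numeric vector `b`, one per group.
#' @export
nuclei_equivalents <- function(u, v, a) {
  tot_u <- colSums(u)
  am_validate(all(tot_u > 0), "group with zero total counts")
  colSums(v) / tot_u * a
}

#' Factorize nuclei equivalents into cell-type and sample scalars
#'
#' Fits `b_jk ~ c_j * d_k` by ordinary least squares on `log b` with
#' cell-type and sample indicators, then exponentiates; `d` is normalized so
#' the designated reference sample has `d = 1`. Optionally, cell types
#' flagged as higher ploidy have their fitted `c_j` divided by
#' `ploidy_divisor` (with the doubled DNA content already present in the
#' counts, the fitted `c_j` is itself halved, so the manual adjustment is
#' off unless flags are passed).
#'
#' @param b numeric vector of nuclei equivalents.
#' @param cell_type,sample labels per element of `b`.
#' @param reference_sample sample whose `d` is fixed at 1 (default: first).
#' @param ploidy_flags optional logical per element or named per cell type;
#'   flagged types get `c` divided by `ploidy_divisor`.
#' @param ploidy_divisor divisor applied to flagged cell types (default 2).
#' @return list: `c` (named per cell type), `d` (named per sample),
#'   `fitted` (c_j * d_k per input element).
#' @export
factorize_b <- function(b, cell_type, sample,
                        reference_sample = sample[1],
                        ploidy_flags = NULL, ploidy_divisor = 2) {
  am_validate(all(b > 0), "nuclei equivalents must be positive")
  ct <- factor(cell_type)
  sm <- factor(sample)
  am_validate(nlevels(ct) >= 1 && nlevels(sm) >= 1, "empty design")
  if (nlevels(sm) == 1) {
    cf <- vapply(split(log(b), ct), mean, numeric(1))
    c_log <- setNames(cf, levels(ct))
    d_log <- setNames(0, levels(sm))
  } else {
    fit <- lm(log(b) ~ 0 + ct + sm)
    if (anyNA(coef(fit))) {
      am_abort("disconnected design: some cell type is not identifiable",
               class = "atacmod_validation_error")
    }
    cf <- coef(fit)
    c_log <- cf[paste0("ct", levels(ct))]
    d_log <- c(0, cf[paste0("sm", levels(sm)[-1])])
  }
  names(c_log) <- levels(ct)
  names(d_log) <- levels(sm)
  # re-anchor so the reference sample has d = 1
  shift <- d_log[as.character(reference_sample)]
  d <- exp(d_log - shift)
  cc <- exp(c_log + shift)
  if (!is.null(ploidy_flags)) {
    if (!is.null(names(ploidy_flags))) {
      flagged <- names(ploidy_flags)[ploidy_flags]
    } else {
      flagged <- unique(as.character(cell_type)[ploidy_flags])
    }
    cc[intersect(flagged, names(cc))] <-
      cc[intersect(flagged, names(cc))] / ploidy_divisor
  }
  list(c = cc, d = d,
       fitted = unname(cc[as.character(cell_type)] * d[as.character(sample)]))
}

#' Select marker peaks distinguishing cell types
#'
#' Per cell type, peaks are ranked by the Welch t-statistic of that type's
#' normalized pseudo-bulk samples against all others; for each candidate
#' count m in `grid`, the top-m peaks per type are pooled and the condition
#' number of the resulting signature matrix is computed; the set minimizing
#' the condition number is returned. Cell types with fewer than two samples
#' fall back to log-fold-change ranking with a warning.
#'
#' @param v quantile-normalized peaks x groups matrix.
#' @param cell_type label per column of `v`.
#' @param grid candidate marker counts per cell type.
#' @return list: `peaks` (integer indices), `per_type` ranking tibble,
#'   `condition_numbers` tibble over the grid.
#' @export
select_marker_peaks <- function(v, cell_type,
                                grid = seq(20, 200, by = 20)) {
  types <- unique(cell_type)
  am_validate(length(types) >= 2, "need >= 2 cell types")
  stat <- vapply(types, function(tj) {
    in_t <- cell_type == tj
    if (sum(in_t) < 2 || sum(!in_t) < 2) {
      warn(sprintf("cell type %s has < 2 samples; using fold-change ranking",
                   tj))
      return(log1p(rowMeans(v[, in_t, drop = FALSE])) -
               log1p(rowMeans(v[, !in_t, drop = FALSE])))
    }
    welch_t_rows(v[, in_t, drop = FALSE], v[, !in_t, drop = FALSE])
  }, numeric(nrow(v)))
  order_by_type <- apply(stat, 2, order, decreasing = TRUE)

  build_w <- function(peaks) {
    vapply(types, function(tj) {
      rowMeans(v[peaks, cell_type == tj, drop = FALSE])
    }, numeric(length(peaks)))
  }
  kappa_of <- vapply(grid, function(m) {
    peaks <- sort(unique(as.vector(order_by_type[seq_len(min(m, nrow(v))), ])))
    w <- build_w(peaks)
    kappa(w, exact = TRUE)
  }, numeric(1))
  if (!any(is.finite(kappa_of)) || min(kappa_of, na.rm = TRUE) > 1e12) {
    am_abort(paste("signature matrix is (near-)singular for every candidate",
                   "size; cell types are not identifiable"),
             class = "atacmod_validation_error")
  }
  best_m <- grid[which.min(kappa_of)]
  peaks <- sort(unique(as.vector(
    order_by_type[seq_len(min(best_m, nrow(v))), ])))
  list(peaks = peaks,
       condition_numbers = tibble(m = grid, kappa = kappa_of),
       chosen_m = best_m)
}

# Welch t-statistic per row of x1 (group 1) vs x2 (group 2)
welch_t_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

#' Build the deconvolution reference from selected peaks
#'
#' The signature `w_ij` is the mean of the normalized pseudo-bulk values
#' over samples of cell type j; the per-peak error variance is
#' `e_i^2 = mean_j var_k(v_ijk)`. For use as regression weights a capped
#' copy of `e^2` is stored, bounded to \[Q1^2/Q2, Q3^2/Q2\] of its own
#' quartiles.
#'
#' @param v_sel normalized pseudo-bulk matrix restricted to selected peaks.
#' @param cell_type label per column.
#' @return list of class `decon_reference`: `W` (peaks x types), `e2`,
#'   `e2_capped`, `cell_types`.
#' @export
build_reference <- function(v_sel, cell_type) {
  types <- unique(cell_type)
  W <- vapply(types, function(tj) {
    rowMeans(v_sel[, cell_type == tj, drop = FALSE])
  }, numeric(nrow(v_sel)))
  colnames(W) <- types
  vars <- vapply(types, function(tj) {
    cols <- which(cell_type == tj)
    if (length(cols) < 2) return(rep(NA_real_, nrow(v_sel)))
    apply(v_sel[, cols, drop = FALSE], 1, var)
  }, numeric(nrow(v_sel)))
  e2 <- rowMeans(vars, na.rm = TRUE)
  e2[is.nan(e2)] <- 0
  structure(list(W = W, e2 = e2, e2_capped = quartile_cap(e2),
                 cell_types = types),
            class = "decon_reference")
}

# cap x into [Q1^2/Q2, Q3^2/Q2] of its own quartiles (no-op when Q2 == 0)
quartile_cap <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (q[2] <= 0) return(x)
  pmin(pmax(x, q[1]^2 / q[2]), q[3]^2 / q[2])
}

#' Synthesize the pseudo-bulk mixture of a matched sample
#'
#' `x_k = sum_j a_jk / (sum_j' a_j'k) * (1 / c_j) * w_j`, the expected
#' chromatin accessibility of the sample's nucleus mixture scaled to one
#' nucleus.
#'
#' @param W signature matrix (peaks x cell types).
#' @param a_k named vector of nuclei counts for the sample (by cell type).
#' @param c_j named vector of nuclei-equivalent scalars.
#' @return numeric vector over peaks.
#' @export
synthesize_mixture <- function(W, a_k, c_j) {
  types <- colnames(W)
  prop <- a_k[types] / sum(a_k[types])
  as.vector(W %*% (prop / c_j[types]))
}

#' Per-peak platform factors from matched sample pairs
#'
#' `f_i = exp(mean_k log(y_ik / x_ik))` over matched (bulk, synthesized
#' single-nucleus) pairs, capped to \[Q1^2/Q2, Q3^2/Q2\] of its own
#' quartiles to avoid overcorrection. Non-positive entries are excluded
#' pairwise with a warning; a peak with no positive pair gets f = 1.
#'
#' @param x matrix of synthesized mixtures (peaks x matched samples).
#' @param y matrix of matched normalized bulk vectors (same shape).
#' @return list: `f` (capped factors), `f_raw`.
#' @export
platform_correction <- function(x, y) {
  am_validate(all(dim(x) == dim(y)), "x and y must be matched (same shape)")
  lr <- log(y / x)
  lr[!is.finite(lr)] <- NA
  if (anyNA(lr)) warn("non-positive matched entries excluded pairwise")
  f_raw <- exp(rowMeans(lr, na.rm = TRUE))
  none <- !is.finite(f_raw)
  if (any(none)) {
    warn(sprintf("%d peaks had no positive matched pair; factor set to 1",
                 sum(none)))
    f_raw[none] <- 1
  }
  list(f = quartile_cap(f_raw), f_raw = f_raw)
}

#' Deconvolve a bulk sample against the reference
#'
#' Solves `F^-1 y = W theta + eps`, `eps_i ~ N(0, e_i^2 sigma^2)`, by Huber
#' M-estimation with inverse-variance weights from the capped `e^2`
#' (all-equal weights when `e^2` is identically 0). Negative elements of the
#' estimate are set to zero and the composition is
#' `c_j theta_j / sum_j c_j theta_j`.
#'
#' @param y normalized bulk vector restricted to the selected peaks.
#' @param reference a [build_reference()] result.
#' @param c_j named nuclei-equivalent scalars per cell type.
#' @param f platform factors (default 1).
#' @param method `"huber"` (default), `"bisquare"`, or `"nnls"`-style
#'   non-negative least squares for comparison.
#' @param k_huber Huber tuning constant.
#' @return tibble: `cell_type`, `theta`, `composition`, plus attributes
#'   `sigma` (robust scale), `n_clamped`, `residual_norm`.
#' @export
deconvolve <- function(y, reference, c_j, f = 1,
                       method = c("huber", "bisquare", "nnls"),
                       k_huber = 1.345) {
  method <- match.arg(method)
  W <- reference$W
  am_validate(length(y) == nrow(W), "bulk vector does not match the reference")
  yc <- y / f
  e2 <- reference$e2_capped
  wts <- if (all(e2 == 0)) rep(1, length(e2)) else {
    e2pos <- pmax(e2, min(e2[e2 > 0]))
    1 / e2pos
  }
  if (method == "nnls") {
    # projected-gradient NNLS on the weighted problem
    theta <- nnls_pg(W * sqrt(wts), yc * sqrt(wts))
    sigma <- NA_real_
  } else if ({
    wls <- stats::lm.wfit(W, yc, wts)
    max(abs(wls$residuals)) <= 1e-8 * max(abs(yc))
  }) {
    # (near-)exact linear case: the M-estimator reduces to weighted OLS and
    # a MAD scale of 0 would stall it
    theta <- setNames(wls$coefficients, colnames(W))
    sigma <- 0
  } else {
    fit <- suppressWarnings(
      MASS::rlm(x = W, y = yc, weights = wts, intercept = FALSE,
                psi = if (method == "huber") MASS::psi.huber else
                  MASS::psi.bisquare,
                k = k_huber, maxit = 100))
    theta <- coef(fit)
    sigma <- fit$s
  }
  n_clamped <- sum(theta < 0)
  theta <- pmax(theta, 0)
  if (all(theta <= 0)) {
    am_abort("deconvolution failed: all coefficients non-positive",
             class = "atacmod_estimation_error")
  }
  cth <- c_j[colnames(W)] * theta
  comp <- cth / sum(cth)
  out <- tibble(cell_type = colnames(W), theta = unname(theta),
                nuclei_fraction = unname(cth),
                composition = unname(comp))
  attr(out, "sigma") <- sigma
  attr(out, "n_clamped") <- n_clamped
  attr(out, "residual_norm") <- sqrt(sum((yc - W %*% theta)^2))
  out
}

# simple projected-gradient non-negative least squares
nnls_pg <- function(A, b, max_iter = 2000, tol = 1e-10) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  L <- norm(AtA, "2")
  x <- pmax(qr.solve(AtA + diag(1e-8, ncol(A)), Atb), 0)
  for (i in seq_len(max_iter)) {
    x_new <- pmax(x - (AtA %*% x - Atb) / L, 0)
    if (max(abs(x_new - x)) < tol * (1 + max(abs(x)))) {
      x <- x_new
      break
    }
    x <- x_new
  }
  setNames(as.vector(x), colnames(A))
}

#' Full reference-based deconvolution of bulk samples
#'
#' Convenience wrapper running the whole chain: joint quantile normalization
#' of the pseudo-bulk libraries, nuclei-equivalent bookkeeping and
#' factorization, marker-peak selection, reference construction, platform
#' factor estimation from matched pairs, and robust deconvolution of each
#' bulk vector.
#'
#' @param pb a [pseudo_bulk()] result (or a list with `u` and `groups`).
#' @param y_bulk peaks x bulk-samples count matrix.
#' @param matched named vector mapping bulk sample names (columns of
#'   `y_bulk`) to single-nucleus sample labels, for the matched pairs used
#'   in platform-factor estimation; `NULL` disables the correction.
#' @param ploidy_flags,ploidy_divisor passed to [factorize_b()].
#' @param grid marker-count grid, see [select_marker_peaks()].
#' @param method robust estimator, see [deconvolve()].
#' @param bulk_normalization `"reference"` quantile-normalizes each bulk
#'   vector to the stored pseudo-bulk reference distribution (the default);
#'   `"scale"` only matches its total mass to the reference total, a linear
#'   alternative that preserves exactness when the inputs are noise-free.
#' @return list of class `decon_result`: `composition` tibble (bulk sample x
#'   cell type), `reference`, `c`, `d`, `f`, `selected_peaks`, `b`.
#' @export
deconvolve_bulk <- function(pb, y_bulk, matched = NULL, ploidy_flags = NULL,
                            ploidy_divisor = 2, grid = seq(20, 200, by = 20),
                            method = "huber",
                            bulk_normalization = c("reference", "scale")) {
  bulk_normalization <- match.arg(bulk_normalization)
  qn <- quantile_normalize(pb$u)
  v <- qn$v
  b <- nuclei_equivalents(pb$u, v, pb$groups$a)
  fac <- factorize_b(b, pb$groups$cell_type, pb$groups$sample,
                     ploidy_flags = ploidy_flags,
                     ploidy_divisor = ploidy_divisor)
  sel <- select_marker_peaks(v, pb$groups$cell_type, grid = grid)
  ref <- build_reference(v[sel$peaks, , drop = FALSE], pb$groups$cell_type)

  y_qn <- if (bulk_normalization == "reference") {
    qn_to_reference(y_bulk, qn$reference)
  } else {
    sweep(y_bulk, 2, sum(qn$reference) / colSums(y_bulk), `*`)
  }
  dimnames(y_qn) <- dimnames(y_bulk)
  y_sel <- y_qn[sel$peaks, , drop = FALSE]

  f <- rep(1, length(sel$peaks))
  if (!is.null(matched)) {
    x_mat <- vapply(names(matched), function(bk) {
      sn <- matched[[bk]]
      rows <- pb$groups$sample == sn
      a_k <- setNames(pb$groups$a[rows], pb$groups$cell_type[rows])
      synthesize_mixture(ref$W, a_k, fac$c)
    }, numeric(length(sel$peaks)))
    f <- platform_correction(x_mat, y_sel[, names(matched), drop = FALSE])$f
  }

  comps <- purrr::map(colnames(y_bulk), function(bk) {
    deconvolve(y_sel[, bk], ref, fac$c, f = f, method = method) |>
      dplyr::mutate(bulk_sample = bk, .before = 1)
  })
  composition <- dplyr::bind_rows(comps)
  structure(list(composition = composition, reference = ref, c = fac$c,
                 d = fac$d, f = f, selected_peaks = sel$peaks, b = b,
                 groups = pb$groups, quantile_reference = qn$reference),
            class = "decon_result")
}

#' Compare cell-type compositions among conditions
#'
#' Per cell type, ordinary least squares of the inferred composition on
#' condition indicators (reference condition as baseline), with two-sided
#' t-tests per coefficient and a Bonferroni significance threshold of
#' `alpha / (n_types * n_non_reference_conditions)`.
#'
#' @param composition tibble with columns `bulk_sample`, `cell_type`,
#'   `composition`.
#' @param condition named vector: bulk sample -> condition label.
#' @param reference reference condition.
#' @param alpha family-wise significance level (default 0.05).
#' @return tibble: `cell_type`, `condition`, `estimate`, `p_value`,
#'   `threshold`, `significant`.
#' @export
compare_compositions <- function(composition, condition, reference,
                                 alpha = 0.05) {
  cond <- condition[composition$bulk_sample]
  am_validate(!anyNA(cond), "condition missing for some bulk samples")
  lv <- c(reference, setdiff(unique(condition), reference))
  types <- unique(composition$cell_type)
  n_tests <- length(types) * (length(lv) - 1)
  threshold <- alpha / n_tests
  purrr::map_dfr(types, function(tj) {
    rows <- composition$cell_type == tj
    df <- tibble(y = composition$composition[rows],
                 cond = factor(cond[rows], levels = lv))
    fit <- lm(y ~ cond, data = df)
    if (anyNA(coef(fit))) {
      am_abort("singular design in composition comparison",
               class = "atacmod_validation_error")
    }
    sm <- summary(fit)$coefficients
    rows_keep <- grep("^cond", rownames(sm))
    tibble(cell_type = tj,
           condition = sub("^cond", "", rownames(sm)[rows_keep]),
           estimate = sm[rows_keep, 1], p_value = sm[rows_keep, 4],
           threshold = threshold,
           significant = !is.na(sm[rows_keep, 4]) &
             sm[rows_keep, 4] < threshold)
  })
}
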