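test_that("pseudo-bulk sums match a brute-force loop", {
  set.seed(1)
  counts <- matrix(rpois(10 * 30, 2), 10, 30)
  ct <- sample(c("x", "y"), 30, replace = TRUE)
  sm <- sample(c("s1", "s2"), 30, replace = TRUE)
  pb <- pseudo_bulk(counts, ct, sm)
  for (g in seq_len(nrow(pb$groups))) {
    cols <- ct == pb$groups$cell_type[g] & sm == pb$groups$sample[g]
    expect_identical(unname(pb$u[, g]), rowSums(counts[, cols, drop = FALSE]))
    expect_identical(pb$groups$a[g], sum(cols))
  }
  # one nucleus per group: u equals the nucleus counts
  pb1 <- pseudo_bulk(counts[, 1:2], c("x", "y"), c("s", "s"))
  expect_equal(unname(pb1$u[, 1]), as.double(counts[, 1]))
})

test_that("quantile normalization follows the sorted-mean definition", {
  x <- cbind(c(1, 2, 3), c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn$v), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical vectors are unchanged
  same <- cbind(c(2, 1, 5), c(2, 1, 5))
  expect_equal(unname(quantile_normalize(same)$v), same)
  # all columns share sorted values afterwards
  set.seed(2)
  y <- matrix(rexp(50), 10, 5)
  v <- quantile_normalize(y)$v
  expect_equal(apply(v, 2, sort), matrix(sort(v[, 1]), 10, 5))
  # ties get the mean of the assigned reference values
  tied <- cbind(c(1, 1, 3), c(4, 5, 6))
  vt <- quantile_normalize(tied)$v
  expect_equal(vt[1, 1], vt[2, 1])
  # stored reference must match in length
  expect_error(atacmod:::qn_to_reference(y, 1:3),
               class = "atacmod_validation_error")
})

test_that("nuclei equivalents and their factorization behave as printed", {
  u <- cbind(a = c(2, 2), b = c(1, 3))
  v <- cbind(a = c(4, 4), b = c(2, 6))  # totals doubled
  expect_equal(nuclei_equivalents(u, v, c(3, 5)), c(a = 6, b = 10))
  # total-preserving normalization gives b = a
  expect_equal(nuclei_equivalents(u, u, c(3, 5)), c(a = 3, b = 5))

  # exact c_j * d_k structure is recovered to machine precision
  c_true <- c(t1 = 2, t2 = 0.5, t3 = 1.3)
  d_true <- c(s1 = 1, s2 = 3)
  grid <- expand.grid(ct = names(c_true), sm = names(d_true),
                      stringsAsFactors = FALSE)
  b <- c_true[grid$ct] * d_true[grid$sm]
  fac <- factorize_b(b, grid$ct, grid$sm, reference_sample = "s1")
  expect_equal(fac$c, c_true, tolerance = 1e-9)
  expect_equal(fac$d, d_true, tolerance = 1e-9)

  # all-equal b gives c = d = 1
  fac1 <- factorize_b(rep(1, 6), grid$ct, grid$sm, reference_sample = "s1")
  expect_equal(unname(fac1$c), rep(1, 3), tolerance = 1e-12)

  # flagged double-ploidy type has its c halved relative to the plain fit
  fac2 <- factorize_b(b, grid$ct, grid$sm, reference_sample = "s1",
                      ploidy_flags = c(t1 = TRUE, t2 = FALSE, t3 = FALSE))
  expect_equal(unname(fac2$c["t1"]), unname(fac$c["t1"]) / 2)
  expect_equal(fac2$c[c("t2", "t3")], fac$c[c("t2", "t3")])
})

test_that("marker selection favours well-conditioned signatures", {
  # orthogonal signatures: each type has private peaks
  set.seed(3)
  n_types <- 3
  v <- matrix(0.01, 90, 6)
  ct <- rep(paste0("t", 1:n_types), each = 2)
  for (j in seq_len(n_types)) {
    rows <- ((j - 1) * 30 + 1):(j * 30)
    v[rows, ct == paste0("t", j)] <- 5 + matrix(rnorm(60, 0, 0.1), 30)
  }
  sel <- select_marker_peaks(v, ct, grid = c(10, 20))
  W <- vapply(unique(ct), function(tj) {
    rowMeans(v[sel$peaks, ct == tj, drop = FALSE])
  }, numeric(length(sel$peaks)))
  expect_lt(kappa(W, exact = TRUE), 1.5)

  # identical profiles across types are not identifiable
  same <- matrix(rep(rexp(50), 6), 50, 6)
  expect_error(select_marker_peaks(same, ct, grid = c(10, 20)),
               class = "atacmod_validation_error")

  # grid bookkeeping: one value m keeps at most m * n_types rows
  sel2 <- select_marker_peaks(v, ct, grid = 15)
  expect_lte(length(sel2$peaks), 15 * n_types)
})

test_that("reference construction matches brute-force means and variances", {
  set.seed(4)
  v <- matrix(rexp(20 * 6), 20, 6)
  ct <- rep(c("x", "y"), each = 3)
  ref <- build_reference(v, ct)
  for (i in c(1, 10, 20)) {
    expect_equal(unname(ref$W[i, "x"]), mean(v[i, 1:3]), tolerance = 1e-12)
    expect_equal(ref$e2[i], mean(c(var(v[i, 1:3]), var(v[i, 4:6]))),
                 tolerance = 1e-12)
  }
  # two samples with values 0 and 2 on one peak: sample variance 2
  v2 <- rbind(c(0, 2), c(1, 1))
  ref2 <- build_reference(v2, c("x", "x"))
  expect_equal(ref2$e2[1], 2)
  # identical replicates: e2 = 0, handled as equal weights downstream
  ref3 <- build_reference(cbind(c(1, 2), c(1, 2)), c("x", "x"))
  expect_equal(ref3$e2, c(0, 0))

  # capped e2 stays within the quartile bounds
  e2 <- rexp(100)
  capped <- atacmod:::quartile_cap(e2)
  q <- quantile(e2, c(0.25, 0.5, 0.75), names = FALSE)
  expect_true(all(capped >= q[1]^2 / q[2] - 1e-12))
  expect_true(all(capped <= q[3]^2 / q[2] + 1e-12))
})

test_that("mixture synthesis follows the scaled formula", {
  W <- cbind(a = c(2, 4), b = c(6, 2))
  expect_equal(synthesize_mixture(W, c(a = 5, b = 0), c_j = c(a = 2, b = 1)),
               c(1, 2))
  expect_equal(synthesize_mixture(W, c(a = 3, b = 3), c_j = c(a = 1, b = 1)),
               c((2 + 6) / 2, (4 + 2) / 2))
  # hand-computed 3-type case
  W3 <- cbind(a = c(1, 0), b = c(0, 2), c = c(4, 4))
  x <- synthesize_mixture(W3, c(a = 1, b = 1, c = 2),
                          c_j = c(a = 1, b = 2, c = 4))
  expect_equal(x, c(0.25 * 1 + 0.5 * 1, 0.25 * 2 / 2 + 0.5 * 1))
})

test_that("platform factors are per-peak geometric means with capping", {
  x <- matrix(rexp(40), 20, 2)
  p <- platform_correction(x, x)
  expect_equal(p$f_raw, rep(1, 20))
  # ratios {1, 4} give geometric mean 2 before capping
  y <- x
  y[1, ] <- x[1, ] * c(1, 4)
  expect_equal(platform_correction(x, y)$f_raw[1], 2)
  # capped within quartile bounds
  set.seed(5)
  y2 <- x * exp(matrix(rnorm(40, 0, 1), 20, 2))
  f <- platform_correction(x, y2)$f
  q <- quantile(platform_correction(x, y2)$f_raw, c(0.25, 0.5, 0.75),
                names = FALSE)
  expect_true(all(f >= q[1]^2 / q[2] - 1e-12 & f <= q[3]^2 / q[2] + 1e-12))
})

test_that("deconvolution is exact in the linear case and on pure types", {
  set.seed(6)
  W <- matrix(rexp(200 * 4, 0.2), 200, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  ref <- build_reference(W, colnames(W))  # single replicate: e2 = 0
  c_j <- setNames(c(1, 2, 0.5, 1), colnames(W))
  theta <- c(0.3, 0.1, 0.5, 0.1)
  y <- as.vector(W %*% theta)
  est <- deconvolve(y, ref, c_j)
  expect_equal(est$theta, theta, tolerance = 1e-9)
  expect_equal(est$composition, unname(c_j * theta / sum(c_j * theta)),
               tolerance = 1e-6)

  # pure type: unit composition
  pure <- deconvolve(as.vector(W[, 2]), ref, c_j)
  expect_equal(pure$composition, c(0, 1, 0, 0), tolerance = 1e-6)

  # scale equivariance of the full chain: quantile normalization maps any
  # scalar multiple of a bulk vector to the same normalized vector
  qn <- quantile_normalize(W)
  y1 <- atacmod:::qn_to_reference(cbind(y), qn$reference)
  y2 <- atacmod:::qn_to_reference(cbind(7 * y), qn$reference)
  expect_equal(unname(y1), unname(y2), tolerance = 1e-12)
})

test_that("end-to-end noise-free deconvolution recovers proportions and the
           fitted ploidy scalar is halved", {
  cfg <- synth_config(seed = 31, platform_sd = 0, n_peaks = 600)
  sim <- generate_mixture_experiment(cfg, noise_free = TRUE)
  pb <- structure(list(u = sim$u, groups = sim$groups),
                  class = "pseudo_bulk")
  res <- suppressWarnings(
    deconvolve_bulk(pb, sim$y, bulk_normalization = "scale"))
  ct <- unique(res$composition$cell_type)
  inferred <- matrix(res$composition$composition, nrow = length(ct))
  truth <- sim$truth$mixture_proportions[ct, ]
  expect_lt(max(abs(inferred - truth)), 1e-6)

  # double-ploidy type emits twice the counts per nucleus, so its fitted
  # nuclei-equivalent scalar comes out at half the diploid level
  ratio <- res$c["T1"] / mean(res$c[setdiff(ct, "T1")])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("composition comparison applies the Bonferroni rule", {
  set.seed(7)
  types <- paste0("t", 1:7)
  samples <- paste0("b", 1:16)
  cond <- setNames(rep(c("normal", "hf4", "hf8", "wash"), each = 4), samples)
  comp <- tidyr::expand_grid(bulk_sample = samples, cell_type = types) |>
    dplyr::mutate(composition = 1 / 7 + rnorm(dplyr::n(), 0, 0.01))
  res <- compare_compositions(comp, cond, reference = "normal")
  expect_equal(unique(res$threshold), 0.05 / 21, tolerance = 1e-12)
  expect_equal(nrow(res), 21L)

  # identical compositions in all groups: nothing flagged
  comp0 <- dplyr::mutate(comp, composition = 1 / 7)
  res0 <- suppressWarnings(compare_compositions(comp0, cond,
                                                reference = "normal"))
  expect_false(any(res0$significant))

  # planted +0.2 shift is detected with high power
  hits <- vapply(1:60, function(s) {
    set.seed(100 + s)
    shifted <- comp |>
      dplyr::mutate(composition = 1 / 7 + rnorm(dplyr::n(), 0, 0.02) +
                      ifelse(cell_type == "t3" &
                               cond[bulk_sample] == "hf8", 0.2, 0))
    r <- compare_compositions(shifted, cond, reference = "normal")
    r$significant[r$cell_type == "t3" & r$condition == "hf8"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
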