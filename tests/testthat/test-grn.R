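test_that("random-forest importances recover single-predictor structure", {
  set.seed(21)
  n_nuc <- 250
  motif <- matrix(rnorm(6 * n_nuc), 6, n_nuc,
                  dimnames = list(paste0("TF", 1:6), NULL))
  genes <- rbind(copy = motif[2, ],
                 noise = rnorm(n_nuc))
  # with every predictor available at each split, the exact copy of TF2
  # takes essentially all the importance mass
  R <- regulator_importances(genes, motif, n_trees = 100, mtry = 6, seed = 2)
  expect_gt(R["TF2", "copy"] / sum(R[, "copy"]), 0.95)
  # pure-noise gene: little explained variance
  expect_lt(sum(R[, "noise"]), 0.1)
  # zero-variance gene yields a zero column
  gz <- rbind(flat = rep(1, n_nuc))
  expect_equal(unname(regulator_importances(gz, motif, seed = 2)[, 1]),
               rep(0, 6))
  # default mtry is the square root of the predictor count: 529 -> 23
  expect_equal(max(1, round(sqrt(529))), 23)
})

test_that("importance columns equal a tree-walk oracle re-computation", {
  set.seed(22)
  n <- 50; p <- 5
  xmat <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("TF", 1:p)))
  y <- 2 * xmat[, 1] - xmat[, 3] + rnorm(n, 0, 0.5)
  rf <- ranger::ranger(x = xmat, y = y, num.trees = 10, mtry = 2,
                       importance = "impurity", keep.inbag = TRUE,
                       seed = 7, num.threads = 1)
  # walk every tree, routing the in-bag sample and summing the decrease in
  # residual sum of squares attributed to each split variable
  imp_oracle <- setNames(numeric(p), colnames(xmat))
  for (t in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, t)
    idx <- rep(seq_len(n), rf$inbag.counts[[t]])
    members <- list(`0` = idx)
    ssq <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
    for (r in seq_len(nrow(ti))) {
      mem <- members[[as.character(ti$nodeID[r])]]
      if (ti$terminal[r] || is.null(mem)) next
      sv <- ti$splitvarID[r] + 1
      left <- mem[xmat[mem, sv] <= ti$splitval[r]]
      right <- mem[xmat[mem, sv] > ti$splitval[r]]
      imp_oracle[sv] <- imp_oracle[sv] +
        ssq(y[mem]) - ssq(y[left]) - ssq(y[right])
      members[[as.character(ti$leftChild[r])]] <- left
      members[[as.character(ti$rightChild[r])]] <- right
    }
  }
  imp_oracle <- imp_oracle / rf$num.trees
  expect_equal(rf$variable.importance, imp_oracle, tolerance = 1e-10)

  # and the packaged normalization divides by the total and scales by the
  # out-of-bag explained variance
  # per-gene seeds derive from the base seed as base + gene index
  R <- regulator_importances(rbind(g = y), xmat |> t(), n_trees = 10,
                             mtry = 2, seed = 6)
  manual <- pmax(imp_oracle, 0) / sum(pmax(imp_oracle, 0)) *
    max(rf$r.squared, 0)
  expect_equal(unname(R[, "g"]), unname(manual), tolerance = 1e-10)
})

test_that("KL-NMF converges monotonically and fits realizable matrices", {
  set.seed(23)
  W0 <- matrix(runif(20 * 2), 20, 2)
  H0 <- matrix(runif(2 * 30), 2, 30)
  V <- W0 %*% H0
  dimnames(V) <- list(paste0("r", 1:20), paste0("c", 1:30))
  fit2 <- nmf_brunet(V, 2, n_starts = 5, seed = 1)
  fit1 <- nmf_brunet(V, 1, n_starts = 5, seed = 1)
  expect_lt(fit2$objective, 1e-6 * fit1$objective)
  # objective trace is nonincreasing within the winning run
  expect_true(all(diff(fit2$trace) <= 1e-8 * (1 + abs(fit2$trace[-1]))))
  # residual is nonincreasing in rank (best-of-starts)
  fit3 <- nmf_brunet(V, 3, n_starts = 5, seed = 1)
  expect_lte(fit3$objective, fit2$objective + 1e-8)
  expect_error(nmf_brunet(V, 25), class = "atacmod_validation_error")
  expect_error(nmf_brunet(-V, 2), class = "atacmod_validation_error")
})

test_that("rank selection finds the elbow of the residual curve", {
  # worked curve over ranks 2..7: the log-curvature peaks at rank 4
  curve <- c(100, 40, 12, 10.5, 10.2, 10.1)
  curv <- atacmod:::residual_curvature(curve)
  expect_equal((2:7)[which.max(curv)], 4)

  # planted 4-module matrix: chosen rank is 4
  sim <- simulate_regulator_matrix(synth_config(n_tfs = 40, n_genes = 200,
                                                seed = 24))
  sel <- select_rank(sim$R, ranks = 2:7, n_starts = 3, max_iter = 300,
                     tol = 1e-5, seed = 3)
  expect_equal(sel$rank, 4)

  # a monotone-linear curve has no elbow: smallest rank with a warning
  lin <- atacmod:::residual_curvature(c(40, 30, 20, 10))
  expect_true(all(lin[!is.na(lin)] <= 0.3))
})

test_that("NMF assigns planted TFs to modules", {
  sim <- simulate_regulator_matrix(synth_config(n_tfs = 50, n_genes = 300,
                                                seed = 25))
  fit <- nmf_brunet(sim$R, 4, n_starts = 8, seed = 4)
  assign <- apply(fit$W, 1, which.max)
  expect_gte(adjusted_rand_index(assign, sim$truth$module_of_tf), 0.9)
})

test_that("membership reporting follows the top-5 and half-of-top rule", {
  W <- cbind(m1 = c(10, 6, 4.9, 1, 0.5, 0.1))
  rownames(W) <- paste0("TF", 1:6)
  fit <- structure(list(W = W, H = matrix(1, 1, 3,
                                          dimnames = list("m1", letters[1:3])),
                        rank = 1), class = "nmf_fit")
  mm <- module_membership(fit)
  reps <- mm$regulators$symbol[mm$regulators$representative]
  expect_equal(reps, c("TF1", "TF2"))  # 4.9 < 5 excluded by half-of-top

  # all weights equal: the whole top-5 qualifies
  W2 <- cbind(m1 = rep(2, 8)); rownames(W2) <- paste0("TF", 1:8)
  fit2 <- structure(list(W = W2, H = fit$H, rank = 1), class = "nmf_fit")
  expect_equal(sum(module_membership(fit2)$regulators$representative), 5L)

  # single nonzero weight: exactly one representative
  W3 <- cbind(m1 = c(3, 0, 0)); rownames(W3) <- paste0("TF", 1:3)
  fit3 <- structure(list(W = W3, H = fit$H, rank = 1), class = "nmf_fit")
  expect_equal(sum(module_membership(fit3)$regulators$representative), 1L)

  # condition rows are excluded from regulator reporting
  W4 <- rbind(W, `condition:C1` = 100)
  fit4 <- structure(list(W = W4, H = fit$H, rank = 1), class = "nmf_fit")
  mm4 <- module_membership(fit4, row_kind = c(rep("tf", 6), "condition"))
  expect_false("condition:C1" %in% mm4$regulators$symbol)
})

test_that("module gene-set enrichment flags the planted set only", {
  sim <- simulate_regulator_matrix(synth_config(n_tfs = 30, n_genes = 120,
                                                seed = 26))
  fit <- nmf_brunet(sim$R, 4, n_starts = 5, seed = 5)
  mod_genes <- names(sim$truth$module_of_gene)[
    sim$truth$module_of_gene == 2]
  set.seed(6)
  sets <- list(planted = mod_genes,
               decoy = sample(colnames(sim$R), length(mod_genes)))
  enr <- module_gs_enrichment(fit, sets, n_perm = 100, seed = 7)
  matching <- enr$module[enr$set == "planted"][
    which.min(enr$fwer_p[enr$set == "planted"])]
  expect_equal(unname(enr$fwer_p[enr$set == "planted" &
                                   enr$module == matching]),
               1 / 101)
  expect_false(any(enr$significant[enr$set == "decoy"]))

  # permutation leaves the weight multiset intact: null t's centre on 0
  h <- fit$H[1, ]
  perm_t <- vapply(1:50, function(i) {
    atacmod:::welch_t_scalar(sample(h, 20), sample(h, 50))
  }, numeric(1))
  expect_lt(abs(mean(perm_t)), 0.5)
})
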