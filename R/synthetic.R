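#' Configuration for the synthetic-data generators
#'
#' Bundles the sizes and noise levels shared by all generators. Defaults
#' mirror the study design the pipeline targets: 5 single-nucleus libraries,
#' 7 liver cell types, 4 dietary conditions, 4 planted TF-regulation modules.
#' Noise families are the simplest ones matching the data: Poisson counts,
#' log-normal depth/platform multipliers, Gaussian residuals.
#'
#' @param n_cell_types,n_nuclei_per_sample,n_samples,n_peaks,n_tiles,n_genes,n_tfs,n_conditions,n_modules
#'   problem sizes (all >= 1).
#' @param depth_batch_sd log-scale SD of the per-sample depth multiplier.
#' @param platform_sd log-scale SD of the per-peak platform factor applied to
#'   bulk measurements.
#' @param noise_sd residual SD for gene-score and motif-deviation rows.
#' @param seed integer seed; every generator is deterministic given
#'   `(config, seed)`.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cell_types = 7, n_nuclei_per_sample = 400,
                         n_samples = 5, n_peaks = 1000, n_tiles = 2000,
                         n_genes = 300, n_tfs = 50, n_conditions = 4,
                         n_modules = 4, depth_batch_sd = 0.3,
                         platform_sd = 0.3, noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_cell_types = n_cell_types,
              n_nuclei_per_sample = n_nuclei_per_sample,
              n_samples = n_samples, n_peaks = n_peaks, n_tiles = n_tiles,
              n_genes = n_genes, n_tfs = n_tfs, n_conditions = n_conditions,
              n_modules = n_modules, depth_batch_sd = depth_batch_sd,
              platform_sd = platform_sd, noise_sd = noise_sd,
              seed = as.integer(seed))
  counts <- cfg[c("n_cell_types", "n_nuclei_per_sample", "n_samples",
                  "n_peaks", "n_tiles", "n_genes", "n_tfs", "n_conditions",
                  "n_modules")]
  if (!all(vapply(counts, function(x) is.numeric(x) && length(x) == 1 &&
                    x >= 1 && x == round(x), logical(1)))) {
    am_abort("all counts in synth_config must be integers >= 1",
             class = "atacmod_config_error")
  }
  if (depth_batch_sd < 0 || platform_sd < 0 || noise_sd < 0) {
    am_abort("SD parameters must be >= 0", class = "atacmod_config_error")
  }
  if (n_modules > min(n_tfs, n_genes)) {
    am_abort("n_modules must not exceed min(n_tfs, n_genes)",
             class = "atacmod_config_error")
  }
  structure(cfg, class = "synth_config")
}

#' Synthetic genome used by the fragment generator
#'
#' A deliberately small genome that still exercises per-chromosome logic:
#' 21 chromosomes (matching a rat-like autosome + X count, which the
#' chromosome-deviation filter's default threshold presumes) with decreasing
#' lengths, and a TSS every 100 kb.
#'
#' @param n_chrom number of chromosomes (>= 2).
#' @param lengths optional integer vector of chromosome lengths.
#' @return list with `chrom_sizes` (named vector) and `tss` tibble
#'   (`chrom`, `pos`).
#' @export
synthetic_genome <- function(n_chrom = 21,
                             lengths = round(seq(8e5, 4e5,
                                                 length.out = n_chrom))) {
  am_validate(n_chrom >= 2, "need >= 2 chromosomes")
  chrom <- paste0("chr", seq_len(n_chrom))
  sizes <- setNames(as.integer(lengths), chrom)
  tss <- purrr::map_dfr(seq_len(n_chrom), function(c) {
    pos <- seq(50000L, sizes[c] - 50000L, by = 100000L)
    tibble(chrom = chrom[c], pos = as.integer(pos))
  })
  list(chrom_sizes = sizes, tss = tss)
}

# fragment-size mixture: sub-nucleosomal exponential plus nucleosome-periodic
# Gaussians at 200 and 400 bp
draw_fragment_sizes <- function(n, periodic_weight) {
  comp <- sample(1:3, n, replace = TRUE,
                 prob = c(1 - periodic_weight, 0.7 * periodic_weight,
                          0.3 * periodic_weight))
  size <- numeric(n)
  size[comp == 1] <- 30 + rexp(sum(comp == 1), rate = 1 / 50)
  size[comp == 2] <- rnorm(sum(comp == 2), 200, 25)
  size[comp == 3] <- rnorm(sum(comp == 3), 400, 35)
  pmax(20L, pmin(990L, as.integer(round(size))))
}

#' Generate per-nucleus Tn5 fragments with known ground truth
#'
#' Emulates the raw substrate of single-nucleus ATAC-seq QC: each nucleus
#' receives fragments whose sizes follow a sub-nucleosomal/nucleosomal
#' mixture, a configurable fraction pile up within 1 kb of TSS, and fragments
#' are allocated to chromosomes proportionally to length. A configurable
#' fraction of "contaminated" nuclei (free-DNA admixture) have their
#' chromosome allocation perturbed by `contamination_sd` multinomial standard
#' deviations.
#'
#' @param config a [synth_config()].
#' @param genome a [synthetic_genome()].
#' @param depth expected fragments per nucleus (Poisson).
#' @param tss_fraction fraction of fragments centred within 1 kb of a TSS.
#' @param periodic_weight weight of the nucleosome-periodic size components.
#' @param contaminated_fraction fraction of nuclei with perturbed chromosome
#'   allocation.
#' @param contamination_sd perturbation magnitude in units of the multinomial
#'   SD of a chromosome proportion at the given depth.
#' @return list with `fragments` (tibble: chrom, start, end, barcode, count),
#'   `genome`, and `truth` (tibble per nucleus: barcode, sample,
#'   contaminated, periodic_weight).
#' @export
generate_fragments <- function(config = synth_config(),
                               genome = synthetic_genome(),
                               depth = 2000, tss_fraction = 0.5,
                               periodic_weight = 0.5,
                               contaminated_fraction = 0,
                               contamination_sd = 3) {
  if (!inherits(config, "synth_config")) {
    am_abort("config must be a synth_config", class = "atacmod_config_error")
  }
  set.seed(config$seed)
  n_nuc <- config$n_samples * config$n_nuclei_per_sample
  barcodes <- sprintf("N%05d", seq_len(n_nuc))
  samples <- rep(paste0("S", seq_len(config$n_samples)),
                 each = config$n_nuclei_per_sample)
  # plant exactly the nominal number of contaminated nuclei so the recorded
  # truth matches the configured rate
  contaminated <- rep(FALSE, n_nuc)
  contaminated[sample.int(n_nuc, round(contaminated_fraction * n_nuc))] <-
    TRUE
  chrom_p <- genome$chrom_sizes / sum(genome$chrom_sizes)
  tss_by_chrom <- split(genome$tss$pos, genome$tss$chrom)

  frag_list <- vector("list", n_nuc)
  for (j in seq_len(n_nuc)) {
    nf <- max(1L, rpois(1, depth))
    p <- chrom_p
    if (contaminated[j]) {
      # balanced +- signs keep the shift vector near zero-sum, so the
      # renormalization does not dilute the planted per-chromosome deviation
      signs <- sample(rep(c(-1, 1), length.out = length(p)))
      shift <- signs * contamination_sd * sqrt(p * (1 - p) / depth)
      p <- pmax(1e-6, p + shift)
      p <- p / sum(p)
    }
    chrom_idx <- sample.int(length(p), nf, replace = TRUE, prob = p)
    chrom <- names(genome$chrom_sizes)[chrom_idx]
    size <- draw_fragment_sizes(nf, periodic_weight)
    near_tss <- runif(nf) < tss_fraction
    center <- integer(nf)
    for (c in unique(chrom_idx)) {
      sel <- which(chrom_idx == c)
      len <- genome$chrom_sizes[c]
      tss <- tss_by_chrom[[names(genome$chrom_sizes)[c]]]
      center[sel] <- ifelse(
        near_tss[sel],
        tss[sample.int(length(tss), length(sel), replace = TRUE)] +
          as.integer(round(runif(length(sel), -1000, 1000))),
        as.integer(round(runif(length(sel), 1, len - 1000))))
    }
    start <- pmax(0L, as.integer(center - size %/% 2L))
    frag_list[[j]] <- tibble(chrom = chrom, start = start,
                             end = start + size,
                             barcode = barcodes[j], count = 1L)
  }
  fragments <- dplyr::bind_rows(frag_list) |>
    dplyr::arrange(.data$chrom, .data$start, .data$barcode)
  truth <- tibble(barcode = barcodes, sample = samples,
                  contaminated = contaminated,
                  periodic_weight = periodic_weight)
  list(fragments = fragments, genome = genome, truth = truth)
}

#' Generate a binary site-by-nucleus accessibility matrix
#'
#' Each cell type has its own site-open-probability profile (a shared
#' baseline plus elevated probabilities on a type-specific marker subset);
#' each sample has a log-normal depth multiplier emulating Tn5:DNA batch
#' variation; entries are independent Bernoulli draws.
#'
#' @param config a [synth_config()].
#' @param baseline_shape1,baseline_shape2 Beta parameters of the baseline
#'   open probability per site.
#' @param marker_fraction fraction of sites elevated in each cell type.
#' @param signal additive open-probability elevation on marker sites.
#' @return list with `f` (binary matrix, sites x nuclei), `sample` (label per
#'   nucleus) and `truth` (tibble: barcode, sample, cell_type;
#'   `depth_multiplier` per sample as an attribute-free column in
#'   `sample_truth`).
#' @export
generate_binary_matrix <- function(config = synth_config(),
                                   baseline_shape1 = 2, baseline_shape2 = 20,
                                   marker_fraction = 0.1, signal = 0.3) {
  if (!inherits(config, "synth_config")) {
    am_abort("config must be a synth_config", class = "atacmod_config_error")
  }
  set.seed(config$seed + 1L)
  n_nuc <- config$n_samples * config$n_nuclei_per_sample
  n_sites <- config$n_tiles
  base_p <- stats::rbeta(n_sites, baseline_shape1, baseline_shape2)
  type_p <- matrix(base_p, n_sites, config$n_cell_types)
  marker_sites <- vector("list", config$n_cell_types)
  for (t in seq_len(config$n_cell_types)) {
    ms <- sample.int(n_sites, round(marker_fraction * n_sites))
    type_p[ms, t] <- pmin(0.95, type_p[ms, t] + signal)
    marker_sites[[t]] <- ms
  }
  depth_mult <- exp(rnorm(config$n_samples, 0, config$depth_batch_sd))
  samples <- rep(paste0("S", seq_len(config$n_samples)),
                 each = config$n_nuclei_per_sample)
  cell_type <- sample(paste0("T", seq_len(config$n_cell_types)), n_nuc,
                      replace = TRUE)
  p_mat <- type_p[, as.integer(sub("T", "", cell_type)), drop = FALSE]
  p_mat <- sweep(p_mat, 2,
                 depth_mult[rep(seq_len(config$n_samples),
                                each = config$n_nuclei_per_sample)], `*`)
  p_mat <- pmin(1, p_mat)
  f <- matrix(rbinom(length(p_mat), 1L, p_mat), n_sites, n_nuc)
  # guarantee every nucleus has at least one open site
  empty <- which(colSums(f) == 0)
  for (j in empty) f[sample.int(n_sites, 1), j] <- 1L
  barcodes <- sprintf("N%05d", seq_len(n_nuc))
  dimnames(f) <- list(paste0("site", seq_len(n_sites)), barcodes)
  list(f = f, sample = samples,
       truth = tibble(barcode = barcodes, sample = samples,
                      cell_type = cell_type),
       sample_truth = tibble(sample = paste0("S", seq_len(config$n_samples)),
                             depth_multiplier = depth_mult),
       marker_sites = marker_sites)
}

#' Generate a matched single-nucleus / bulk mixture experiment
#'
#' Emulates the validation design in which the same samples are assayed both
#' in single nuclei and in bulk. Per-cell-type peak-intensity profiles are
#' drawn once; pseudo-bulk counts are Poisson around `a_jk` nuclei times the
#' profile; true proportions are Dirichlet(1); bulk vectors are the
#' proportion-weighted intensity sums distorted by per-peak log-normal
#' platform factors and Poisson-sampled. One designated cell type is flagged
#' "double-ploidy": each of its nuclei carries twice the genome copies and
#' therefore emits twice the counts, so the fitted nuclei-equivalent scalar
#' c_j for that type comes out halved.
#'
#' @param config a [synth_config()].
#' @param nuclei_per_sample total nuclei per matched single-nucleus sample.
#' @param intensity_shape,intensity_rate Gamma parameters of the per-peak
#'   base intensity (mean counts per diploid nucleus), shared across cell
#'   types: real ATAC peaks have an intrinsic accessibility propensity, and
#'   cell types modulate it.
#' @param type_sd log-scale SD of the per-(peak, type) modulation of the
#'   base intensity; larger values make cell types easier to distinguish.
#' @param bulk_scale bulk sequencing depth as a multiple of the one-nucleus
#'   mixture intensity.
#' @param ploidy_type index of the cell type flagged double-ploidy (0 = none).
#' @param noise_free bypass all sampling and return expectations, and draw
#'   the per-type profiles as permutations of one common intensity multiset
#'   so that quantile normalization is exactly linear on them; together with
#'   `platform_sd = 0` this makes the whole deconvolution chain linear and
#'   enables exact-recovery tests.
#' @return list with `u` (peaks x groups count matrix), `groups` (tibble
#'   cell_type, sample, a), `y` (peaks x samples bulk counts), and `truth`
#'   (list: mixture_proportions matrix, platform_factors, ploidy_flags).
#' @export
generate_mixture_experiment <- function(config = synth_config(),
                                        nuclei_per_sample = 2000,
                                        intensity_shape = 2,
                                        intensity_rate = 0.02,
                                        type_sd = 0.8,
                                        bulk_scale = 20,
                                        ploidy_type = 1,
                                        noise_free = FALSE) {
  if (!inherits(config, "synth_config")) {
    am_abort("config must be a synth_config", class = "atacmod_config_error")
  }
  set.seed(config$seed + 2L)
  np <- config$n_peaks; nt <- config$n_cell_types; ns <- config$n_samples
  types <- paste0("T", seq_len(nt))
  samples <- paste0("S", seq_len(ns))
  ploidy_flags <- setNames(seq_len(nt) == ploidy_type, types)
  mult <- ifelse(ploidy_flags, 2, 1)

  base_intensity <- rgamma(np, intensity_shape, intensity_rate)
  if (noise_free) {
    common <- base_intensity * exp(rnorm(np, 0, type_sd))
    lambda <- vapply(seq_len(nt), function(j) common[sample.int(np)],
                     numeric(np))
    dimnames(lambda) <- list(paste0("peak", seq_len(np)), types)
  } else {
    lambda <- base_intensity *
      matrix(exp(rnorm(np * nt, 0, type_sd)), np, nt,
             dimnames = list(paste0("peak", seq_len(np)), types))
  }
  # true proportions: Dirichlet(1) per sample, realized as nucleus counts
  props <- matrix(rexp(nt * ns), nt, ns)
  props <- sweep(props, 2, colSums(props), `/`)
  a <- round(props * nuclei_per_sample)
  a[a < 1] <- 1
  true_prop <- sweep(a, 2, colSums(a), `/`)
  dimnames(a) <- dimnames(true_prop) <- list(types, samples)

  groups <- tidyr::expand_grid(sample = samples, cell_type = types) |>
    dplyr::mutate(a = purrr::map2_dbl(.data$cell_type, .data$sample,
                                      ~ a[.x, .y]))
  mean_u <- vapply(seq_len(nrow(groups)), function(g) {
    j <- match(groups$cell_type[g], types)
    groups$a[g] * mult[j] * lambda[, j]
  }, numeric(np))
  u <- if (noise_free) mean_u else
    matrix(rpois(length(mean_u), mean_u), np, nrow(groups))
  dimnames(u) <- list(rownames(lambda),
                      paste(groups$cell_type, groups$sample, sep = "."))

  platform <- exp(rnorm(np, 0, config$platform_sd))
  mix_intensity <- vapply(seq_len(ns), function(k) {
    rowSums(sweep(lambda, 2, true_prop[, k] * mult, `*`))
  }, numeric(np))
  mean_y <- bulk_scale * platform * mix_intensity
  y <- if (noise_free) mean_y else matrix(rpois(length(mean_y), mean_y), np, ns)
  dimnames(y) <- list(rownames(lambda), samples)

  list(u = u, groups = groups, y = y, lambda = lambda,
       truth = list(mixture_proportions = true_prop,
                    platform_factors = platform,
                    ploidy_flags = ploidy_flags))
}

#' Generate motif-deviation and gene-score matrices with planted modules
#'
#' `n_modules` latent activity factors are drawn per nucleus, with condition
#' labels shifting the factor means; member TF rows equal a loading times
#' their module's factor plus Gaussian noise, member gene rows likewise;
#' non-members are pure noise. One gene set per module contains a fraction of
#' that module's genes plus random decoy genes; matched-size decoy sets are
#' added. PPI edge scores are high between genes sharing a module and low
#' otherwise.
#'
#' @param config a [synth_config()].
#' @param tf_member_fraction,gene_member_fraction fraction of TFs / genes
#'   assigned to a module.
#' @param gs_member_fraction fraction of a module's genes included in its
#'   gene set.
#' @param gs_decoy_fraction decoy members added to each module set, as a
#'   fraction of its true members.
#' @param condition_effect shift of a module's factor mean in its associated
#'   condition.
#' @param ppi_in,ppi_out mean PPI score within / between modules.
#' @return list with `motif_dev` (TFs x nuclei), `gene_scores`
#'   (genes x nuclei), `gene_sets`, `ppi`, `nuclei` (tibble: barcode, sample,
#'   condition) and `truth` (module_of_tf, module_of_gene, factors,
#'   gs_membership).
#' @export
generate_regulatory_dataset <- function(config = synth_config(),
                                        tf_member_fraction = 0.6,
                                        gene_member_fraction = 0.7,
                                        gs_member_fraction = 0.6,
                                        gs_decoy_fraction = 0.2,
                                        condition_effect = 1,
                                        ppi_in = 0.9, ppi_out = 0.05) {
  if (!inherits(config, "synth_config")) {
    am_abort("config must be a synth_config", class = "atacmod_config_error")
  }
  set.seed(config$seed + 3L)
  n_nuc <- config$n_samples * config$n_nuclei_per_sample
  nm <- config$n_modules
  barcodes <- sprintf("N%05d", seq_len(n_nuc))
  samples <- rep(paste0("S", seq_len(config$n_samples)),
                 each = config$n_nuclei_per_sample)
  condition <- sample(paste0("C", seq_len(config$n_conditions)), n_nuc,
                      replace = TRUE)
  # module m is elevated in condition (m - 1) %% n_conditions + 1
  cond_of_module <- ((seq_len(nm) - 1) %% config$n_conditions) + 1
  factors <- vapply(seq_len(nm), function(m) {
    mu <- ifelse(condition == paste0("C", cond_of_module[m]),
                 condition_effect, 0)
    rnorm(n_nuc, mu, 1)
  }, numeric(n_nuc))  # nuclei x modules

  assign_members <- function(n, frac, prefix) {
    labels <- rep(NA_integer_, n)
    member <- sample.int(n, round(frac * n))
    labels[member] <- rep_len(seq_len(nm), length(member))
    names(labels) <- paste0(prefix, seq_len(n))
    labels
  }
  module_of_tf <- assign_members(config$n_tfs, tf_member_fraction, "TF")
  module_of_gene <- assign_members(config$n_genes, gene_member_fraction, "G")

  build_rows <- function(labels) {
    t(vapply(labels, function(m) {
      if (is.na(m)) return(rnorm(n_nuc, 0, 1))
      loading <- runif(1, 0.8, 1.2) * sample(c(1, 1, 1, -1), 1)
      loading * factors[, m] + rnorm(n_nuc, 0, config$noise_sd)
    }, numeric(n_nuc)))
  }
  motif_dev <- build_rows(module_of_tf)
  gene_scores <- build_rows(module_of_gene)
  colnames(motif_dev) <- colnames(gene_scores) <- barcodes

  gene_names <- names(module_of_gene)
  gene_sets <- list()
  for (m in seq_len(nm)) {
    members <- gene_names[which(module_of_gene == m)]
    core <- sample(members, max(2, round(gs_member_fraction * length(members))))
    decoys <- sample(setdiff(gene_names, members),
                     max(1, round(gs_decoy_fraction * length(core))))
    gene_sets[[paste0("GS_module", m)]] <- c(core, decoys)
  }
  set_sizes <- lengths(gene_sets)
  for (m in seq_len(nm)) {
    gene_sets[[paste0("GS_decoy", m)]] <- sample(gene_names, set_sizes[m])
  }

  # PPI: dense high-score edges within modules, sparse low-score background
  ppi_edges <- purrr::map_dfr(seq_len(nm), function(m) {
    members <- gene_names[which(module_of_gene == m)]
    if (length(members) < 2) return(NULL)
    pairs <- utils::combn(members, 2)
    tibble(node1 = pairs[1, ], node2 = pairs[2, ],
           score = pmin(1, pmax(0, rnorm(ncol(pairs), ppi_in, 0.05))))
  })
  n_bg <- 4 * config$n_genes
  bg1 <- sample(gene_names, n_bg, replace = TRUE)
  bg2 <- sample(gene_names, n_bg, replace = TRUE)
  keep <- bg1 != bg2
  bg <- tibble(node1 = bg1[keep], node2 = bg2[keep],
               score = pmin(1, pmax(0, rnorm(sum(keep), ppi_out, 0.03))))
  ppi <- validate_ppi(dplyr::bind_rows(ppi_edges, bg))

  list(motif_dev = motif_dev, gene_scores = gene_scores,
       gene_sets = gene_sets, ppi = ppi,
       nuclei = tibble(barcode = barcodes, sample = samples,
                       condition = condition),
       truth = list(module_of_tf = module_of_tf,
                    module_of_gene = module_of_gene,
                    factors = factors,
                    cond_of_module = cond_of_module,
                    gs_membership = gene_sets[seq_len(nm)]))
}

#' Generate a regulator-regulatee importance matrix with planted modules
#'
#' Builds the nonnegative importance matrix directly from a planted
#' block structure (module TFs load on module genes) plus half-normal noise,
#' for testing rank selection and factorization without running the
#' random-forest stage.
#'
#' @param config a [synth_config()].
#' @param importance_noise SD of the half-normal background importance.
#' @return list with `R` (TFs x genes), `truth` (module_of_tf,
#'   module_of_gene).
#' @export
simulate_regulator_matrix <- function(config = synth_config(),
                                      importance_noise = 0.02) {
  if (!inherits(config, "synth_config")) {
    am_abort("config must be a synth_config", class = "atacmod_config_error")
  }
  set.seed(config$seed + 4L)
  nm <- config$n_modules
  module_of_tf <- rep_len(seq_len(nm), config$n_tfs)
  module_of_gene <- rep_len(seq_len(nm), config$n_genes)
  W0 <- matrix(0, config$n_tfs, nm)
  H0 <- matrix(0, nm, config$n_genes)
  for (m in seq_len(nm)) {
    W0[module_of_tf == m, m] <- runif(sum(module_of_tf == m), 0.5, 1)
    H0[m, module_of_gene == m] <- runif(sum(module_of_gene == m), 0.5, 1)
  }
  R <- W0 %*% H0 + abs(matrix(rnorm(config$n_tfs * config$n_genes, 0,
                                    importance_noise),
                              config$n_tfs, config$n_genes))
  # per-gene importance mass behaves like a share of explained variance
  R <- sweep(R, 2, pmax(colSums(R), 1), `/`) * 0.8
  dimnames(R) <- list(paste0("TF", seq_len(config$n_tfs)),
                      paste0("G", seq_len(config$n_genes)))
  names(module_of_tf) <- rownames(R)
  names(module_of_gene) <- colnames(R)
  list(R = R, truth = list(module_of_tf = module_of_tf,
                           module_of_gene = module_of_gene))
}
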