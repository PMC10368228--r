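#' Per-nucleus gene-set activity score
#'
#' Rows of the motif-deviation and gene-score matrices belonging to the gene
#' set are standardized (mean 0, SD 1 across nuclei), stacked, and the first
#' right-singular vector of the stack is the activity score — the dominant
#' shared pattern of the set's TFs and genes across nuclei, as if it were
#' the expression of one representative gene. The sign is fixed so the score
#' correlates positively with the mean of the standardized member rows.
#'
#' @param gene_scores genes x nuclei matrix.
#' @param motif_dev TFs x nuclei matrix (a symbol present in both
#'   contributes both rows).
#' @param gene_set character vector of member symbols.
#' @return list of class `gs_activity`: `score` (named per nucleus, unit
#'   norm), `singular_value`, `orientation`, `members` tibble
#'   (`symbol`, `kind`).
#' @export
gs_activity_score <- function(gene_scores, motif_dev, gene_set) {
  stack <- member_stack(gene_scores, motif_dev, gene_set)
  score_from_stack(stack)
}

member_stack <- function(gene_scores, motif_dev, gene_set) {
  tf_rows <- intersect(rownames(motif_dev), gene_set)
  gene_rows <- intersect(rownames(gene_scores), gene_set)
  m <- rbind(motif_dev[tf_rows, , drop = FALSE],
             gene_scores[gene_rows, , drop = FALSE])
  kind <- c(rep("tf", length(tf_rows)), rep("gene", length(gene_rows)))
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance member rows excluded", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
    kind <- kind[sds > 0]
  }
  am_validate(nrow(m) >= 2,
              "need >= 2 set members present across the matrices")
  z <- t(scale(t(m)))
  attr(z, "kind") <- kind
  z
}

score_from_stack <- function(z) {
  sv <- truncated_svd(z, 1)
  score <- as.vector(sv$v)
  orientation <- sign(cor(score, colMeans(z)))
  if (is.na(orientation) || orientation == 0) orientation <- 1
  score <- orientation * score
  names(score) <- colnames(z)
  structure(list(score = score, singular_value = sv$d[1],
                 orientation = orientation,
                 members = tibble(symbol = rownames(z),
                                  kind = attr(z, "kind"))),
            class = "gs_activity")
}

#' Permutation significance of a gene-set activity score
#'
#' The score is meaningless when the set's TFs/genes are not co-expressed.
#' The null distribution of the first singular value is obtained by
#' permuting the TF weight vector and the gene weight vector (independently,
#' within their blocks) — i.e. drawing random same-size row subsets from
#' each matrix — `n_perm` times; the empirical p-value is
#' `(1 + #exceedances) / (n_perm + 1)`. Sets with p >= `alpha` are flagged
#' not co-expressed.
#'
#' @param gene_scores,motif_dev,gene_set as in [gs_activity_score()].
#' @param n_perm permutations (default 100).
#' @param alpha flag threshold (default 0.05).
#' @param joint permute the stacked weight vector jointly across the two
#'   blocks instead of within blocks (default FALSE).
#' @param seed permutation seed.
#' @return list: `activity` (the observed [gs_activity_score()] result),
#'   `p_value`, `coexpressed` (p < alpha), `null_singular_values`.
#' @export
gs_activity_significance <- function(gene_scores, motif_dev, gene_set,
                                     n_perm = 100, alpha = 0.05,
                                     joint = FALSE, seed = 1L) {
  observed <- gs_activity_score(gene_scores, motif_dev, gene_set)
  n_tf <- sum(rownames(motif_dev) %in% gene_set)
  n_gene <- sum(rownames(gene_scores) %in% gene_set)
  set.seed(seed)
  null_sv <- vapply(seq_len(n_perm), function(b) {
    if (joint) {
      total <- nrow(motif_dev) + nrow(gene_scores)
      pick <- sample.int(total, n_tf + n_gene)
      tf_pick <- pick[pick <= nrow(motif_dev)]
      gene_pick <- pick[pick > nrow(motif_dev)] - nrow(motif_dev)
    } else {
      tf_pick <- sample.int(nrow(motif_dev), n_tf)
      gene_pick <- sample.int(nrow(gene_scores), n_gene)
    }
    set_b <- c(rownames(motif_dev)[tf_pick], rownames(gene_scores)[gene_pick])
    z <- suppressWarnings(tryCatch(
      member_stack(gene_scores, motif_dev, set_b), error = function(e) NULL))
    if (is.null(z)) return(0)
    truncated_svd(z, 1)$d[1]
  }, numeric(1))
  p <- (1 + sum(null_sv >= observed$singular_value)) / (n_perm + 1)
  list(activity = observed, p_value = p, coexpressed = p < alpha,
       null_singular_values = null_sv)
}

#' AUROC of an activity score between conditions
#'
#' Mann-Whitney AUROC of the score for each condition against the reference:
#' the probability that a random nucleus of the condition outranks a random
#' reference nucleus. Flags: `"*"` for AUROC > 0.75 or < 0.25, `"**"` for
#' > 0.9 or < 0.1.
#'
#' @param score named numeric vector per nucleus (or a `gs_activity`).
#' @param condition label per nucleus.
#' @param reference reference condition.
#' @return tibble: `condition`, `n`, `auroc`, `direction`, `flag`.
#' @export
condition_auroc <- function(score, condition, reference) {
  if (inherits(score, "gs_activity")) score <- score$score
  am_validate(reference %in% condition, "reference condition absent")
  ref <- score[condition == reference]
  am_validate(length(ref) >= 2, "reference group has < 2 nuclei")
  purrr::map_dfr(setdiff(unique(condition), reference), function(cn) {
    grp <- score[condition == cn]
    if (length(grp) < 2) {
      warn(sprintf("condition %s has < 2 nuclei; skipped", cn))
      return(NULL)
    }
    r <- rank(c(grp, ref))
    auroc <- (sum(r[seq_along(grp)]) -
                length(grp) * (length(grp) + 1) / 2) /
      (length(grp) * length(ref))
    up <- auroc >= 0.5
    extreme <- if (up) auroc else 1 - auroc
    tibble(condition = cn, n = length(grp), auroc = auroc,
           direction = ifelse(up, "increase", "decrease"),
           flag = dplyr::case_when(extreme > 0.9 ~ "**",
                                   extreme > 0.75 ~ "*",
                                   TRUE ~ ""))
  })
}

#' Total protein-protein interaction score with a gene set
#'
#' For each symbol, the sum of PPI edge scores between it and the members of
#' the gene set (self-edges excluded); symbols absent from the network get
#' 0.
#'
#' @param symbols character vector to score.
#' @param gene_set member symbols.
#' @param ppi tibble with `node1`, `node2`, `score` (see [read_ppi()]).
#' @return named numeric vector of totals.
#' @export
ppi_totals <- function(symbols, gene_set, ppi) {
  in_gs1 <- ppi$node2 %in% gene_set & ppi$node1 != ppi$node2
  in_gs2 <- ppi$node1 %in% gene_set & ppi$node1 != ppi$node2
  edges <- dplyr::bind_rows(
    tibble(symbol = ppi$node1[in_gs1], score = ppi$score[in_gs1]),
    tibble(symbol = ppi$node2[in_gs2], score = ppi$score[in_gs2]))
  totals <- setNames(rep(0, length(symbols)), symbols)
  agg <- edges |>
    dplyr::filter(.data$symbol %in% symbols) |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(total = sum(.data$score), .groups = "drop")
  totals[agg$symbol] <- agg$total
  totals
}

#' Core-gene table from activity correlations and PPI totals
#'
#' A symbol is "core" for a biological process when its activity correlation
#' is strong (|r| at or above `cor_threshold`) and its total PPI with the
#' set is within the top `ppi_top_fraction` across all scored symbols
#' (dense ranking: everything tied with the boundary value is included).
#' In-set and out-of-set symbols are reported together with an `in_gs` flag;
#' novel candidates are core symbols outside the set.
#'
#' @param activity a `gs_activity` result (scores over nuclei of one cell
#'   type).
#' @param gene_scores,motif_dev matrices over the same nuclei; all their
#'   rows are scored.
#' @param gene_set member symbols.
#' @param ppi PPI tibble.
#' @param cor_threshold minimum |correlation| (default 0.3).
#' @param ppi_top_fraction PPI total percentile rule (default 0.05).
#' @return tibble: `symbol`, `kind`, `correlation`, `ppi_total`, `in_gs`,
#'   `top_ppi`, `core`.
#' @export
core_gene_table <- function(activity, gene_scores, motif_dev, gene_set, ppi,
                            cor_threshold = 0.3, ppi_top_fraction = 0.05) {
  score <- activity$score
  cors <- function(m, kind) {
    cc <- suppressWarnings(as.vector(cor(t(m), score)))
    cc[is.na(cc)] <- 0
    tibble(symbol = rownames(m), kind = kind, correlation = cc)
  }
  tab <- dplyr::bind_rows(cors(motif_dev, "tf"), cors(gene_scores, "gene"))
  totals <- ppi_totals(tab$symbol, gene_set, ppi)
  tab$ppi_total <- unname(totals[tab$symbol])
  k <- max(1, floor(ppi_top_fraction * nrow(tab)))
  boundary <- sort(tab$ppi_total, decreasing = TRUE)[k]
  tab |>
    dplyr::mutate(in_gs = .data$symbol %in% gene_set,
                  top_ppi = .data$ppi_total >= boundary & boundary > 0,
                  core = .data$top_ppi &
                    abs(.data$correlation) >= cor_threshold)
}
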