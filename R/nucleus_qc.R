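#' Per-nucleus TSS enrichment metrics
#'
#' For each barcode, counts fragments overlapping any TSS +/- 1 kb window and
#' compares per-bp Tn5 insertion rates near versus far from TSS. Each
#' fragment contributes two insertions (its two ends). The near window is
#' \[TSS - 25, TSS + 25\] (51 bp); the far window is the pair of flanks at
#' distance 1,900-2,000 bp (202 bp in total); both rates are normalized per
#' bp so their ratio is scale-free.
#'
#' @param fragments fragments tibble (see [read_fragments()]).
#' @param tss tibble with columns `chrom`, `pos` of transcription start
#'   sites.
#' @param ratio_cap value reported when the far-window rate is zero while the
#'   near-window rate is positive.
#' @return tibble per barcode: `n_fragments`, `tss_fragment_count`,
#'   `tss_fraction`, `tss_insertion_ratio`. A barcode with zero fragments is
#'   impossible here (it has no rows); downstream filters treat absent
#'   metrics as failure.
#' @export
tss_metrics <- function(fragments, tss, ratio_cap = 1e6) {
  am_validate(nrow(tss) > 0, "TSS list must be non-empty")
  barcodes <- sort(unique(fragments$barcode))

  # fragment overlap with TSS windows, per chromosome
  frag_hit <- logical(nrow(fragments))
  near_ins <- far_ins <- 0
  ins_near_by_bc <- ins_far_by_bc <- setNames(numeric(length(barcodes)),
                                              barcodes)
  for (ch in unique(fragments$chrom)) {
    fi <- which(fragments$chrom == ch)
    tp <- sort(tss$pos[tss$chrom == ch])
    if (length(tp) == 0) next
    windows <- IRanges::IRanges(start = tp - 1000L, end = tp + 1000L)
    fr <- IRanges::IRanges(start = fragments$start[fi],
                           end = fragments$end[fi] - 1L)
    frag_hit[fi] <- IRanges::countOverlaps(fr, windows) > 0
    # insertions: both fragment ends
    ins_pos <- c(fragments$start[fi], fragments$end[fi] - 1L)
    ins_bc <- rep(fragments$barcode[fi], 2)
    d <- nearest_distance(ins_pos, tp)
    near <- d <= 25
    far <- d >= 1900 & d <= 2000
    if (any(near)) {
      tab <- table(ins_bc[near])
      ins_near_by_bc[names(tab)] <- ins_near_by_bc[names(tab)] + as.numeric(tab)
    }
    if (any(far)) {
      tab <- table(ins_bc[far])
      ins_far_by_bc[names(tab)] <- ins_far_by_bc[names(tab)] + as.numeric(tab)
    }
  }
  per_bc <- fragments |>
    dplyr::mutate(hit = frag_hit) |>
    dplyr::group_by(barcode = .data$barcode) |>
    dplyr::summarise(n_fragments = dplyr::n(),
                     tss_fragment_count = sum(.data$hit), .groups = "drop")
  per_bc |>
    dplyr::mutate(
      tss_fraction = .data$tss_fragment_count / .data$n_fragments,
      near_rate = unname(ins_near_by_bc[.data$barcode]) / 51,
      far_rate = unname(ins_far_by_bc[.data$barcode]) / 202,
      tss_insertion_ratio = dplyr::case_when(
        far_rate > 0 ~ pmin(near_rate / far_rate, ratio_cap),
        near_rate > 0 ~ ratio_cap,
        TRUE ~ 0)) |>
    dplyr::select(-"near_rate", -"far_rate")
}

# distance from each position to its nearest value in sorted vector `ref`
nearest_distance <- function(pos, ref) {
  idx <- findInterval(pos, ref)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ref))
  pmin(abs(pos - ref[lo]), abs(pos - ref[hi]))
}

#' Chromosome deviation score per nucleus
#'
#' Detects droplets contaminated by free DNA from broken nuclei: the
#' proportion of a nucleus's fragments on each chromosome should be
#' approximately proportional to chromosome length. The nuclei-by-chromosome
#' proportion matrix is column-standardized (subtract mean, divide by SD) and
#' the score is the row sum of absolute standardized values. Columns with
#' zero SD carry no contamination signal and contribute 0. The score depends
#' only on proportions, so it is invariant to per-nucleus depth.
#'
#' @param fragments fragments tibble.
#' @return tibble per barcode: `chrom_deviation_score`.
#' @export
chromosome_deviation_score <- function(fragments) {
  counts <- fragments |>
    dplyr::count(.data$barcode, .data$chrom) |>
    tidyr::pivot_wider(names_from = "chrom", values_from = "n",
                       values_fill = 0)
  am_validate(ncol(counts) >= 3, "need >= 2 chromosomes")
  am_validate(nrow(counts) >= 2, "need >= 2 nuclei for column standardization")
  m <- as.matrix(counts[, -1])
  prop <- m / rowSums(m)
  mu <- colMeans(prop)
  sdev <- apply(prop, 2, sd)
  z <- sweep(prop, 2, mu)
  z <- sweep(z, 2, ifelse(sdev > 0, sdev, Inf), `/`)  # zero-SD column -> 0
  tibble(barcode = counts$barcode,
         chrom_deviation_score = rowSums(abs(z)))
}

#' Fragment-size periodicity score per nucleus
#'
#' Nucleosome-associated DNA gives ATAC fragment-size distributions a ~200 bp
#' periodicity. Fragment sizes are histogrammed on 1-bp bins over
#' \[1, 1000\], the histogram is mean-subtracted, and the score is the
#' periodogram power summed over periods of 100-300 bp as a fraction of the
#' total spectral power. The relative form is what discriminates
#' periodicity: absolute band power is dominated by the sheer sharpness of
#' any feature of the size distribution, whereas the band share is maximal
#' for a 200-bp-period comb and invariant to scaling all counts.
#'
#' @param fragments fragments tibble.
#' @param min_fragments minimum fragments required for a defined score;
#'   below it the score is `NA` (flagged for removal downstream).
#' @return tibble per barcode: `n_fragments`, `periodicity_score`.
#' @export
fragment_size_spectrum <- function(fragments, min_fragments = 100) {
  sizes <- fragments$end - fragments$start
  keep <- sizes >= 1 & sizes <= 1000
  split_sizes <- split(sizes[keep], fragments$barcode[keep])
  all_bc <- sort(unique(fragments$barcode))
  score <- vapply(all_bc, function(bc) {
    s <- split_sizes[[bc]]
    if (is.null(s) || length(s) < min_fragments) return(NA_real_)
    periodogram_band_power(tabulate(s, nbins = 1000))
  }, numeric(1))
  tibble(barcode = all_bc,
         n_fragments = as.integer(table(fragments$barcode)[all_bc]),
         periodicity_score = score)
}

# share of periodogram power of a length-1000 histogram at periods in
# [100, 300] bp (frequency indices k = 4..10, i.e. 1000/k in [100, 250])
periodogram_band_power <- function(h, period_range = c(100, 300)) {
  x <- h - mean(h)
  p <- Mod(fft(x))^2
  n <- length(h)
  k <- seq_len(floor(n / 2))
  band <- k[n / k >= period_range[1] & n / k <= period_range[2]]
  total <- sum(p[k + 1])
  if (total == 0) return(0)
  sum(p[band + 1]) / total
}

#' QC thresholds
#'
#' Container for the per-nucleus filter thresholds. Set an element to `NULL`
#' to disable that filter. `min_tss_fraction` may be a single value or a
#' named vector with one entry per sample (the study design this package
#' targets used 7.5% for three libraries and 15% for two).
#'
#' @param min_tss_fragments minimum fragments within 1 kb of TSS.
#' @param min_tss_fraction minimum proportion of fragments within 1 kb of
#'   TSS (scalar or named per-sample vector).
#' @param min_insertion_ratio minimum near/far TSS insertion-rate ratio.
#' @param max_deviation_score nuclei at or above this chromosome deviation
#'   score are removed.
#' @param spectrum_alpha tail fraction removed at each end of the
#'   within-sample periodicity-score distribution.
#' @return a named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_tss_fragments = 1000,
                          min_tss_fraction = 0.075,
                          min_insertion_ratio = 4,
                          max_deviation_score = 40,
                          spectrum_alpha = 0.01) {
  structure(list(min_tss_fragments = min_tss_fragments,
                 min_tss_fraction = min_tss_fraction,
                 min_insertion_ratio = min_insertion_ratio,
                 max_deviation_score = max_deviation_score,
                 spectrum_alpha = spectrum_alpha),
            class = "qc_thresholds")
}

#' Apply the per-nucleus QC filters
#'
#' Combines the TSS, chromosome-deviation and fragment-size-spectrum metrics
#' into per-filter pass flags and an overall pass (pure conjunction, so the
#' outcome is order-independent). Externally supplied removal flags (e.g. an
#' 8n ploidy class or a doublet call from upstream tools) are honored as
#' additional filters.
#'
#' @param metrics tibble with one row per barcode holding any of the metric
#'   columns produced by [tss_metrics()], [chromosome_deviation_score()] and
#'   [fragment_size_spectrum()], plus a `sample` column when per-sample
#'   thresholds or the spectrum filter are used.
#' @param thresholds a [qc_thresholds()] object.
#' @param external optional tibble with `barcode` plus logical columns where
#'   `TRUE` marks the nucleus for removal.
#' @return tibble per barcode: one `pass_*` column per enabled filter and an
#'   overall `pass`.
#' @export
apply_qc_filters <- function(metrics, thresholds = qc_thresholds(),
                             external = NULL) {
  am_validate(inherits(thresholds, "qc_thresholds"),
              "thresholds must be built with qc_thresholds()")
  out <- tibble(barcode = metrics$barcode)

  need <- function(col, filter) {
    if (!col %in% names(metrics)) {
      am_abort(sprintf("filter '%s' is enabled but metrics lack column '%s'",
                       filter, col), class = "atacmod_config_error")
    }
    metrics[[col]]
  }
  if (!is.null(thresholds$min_tss_fragments)) {
    x <- need("tss_fragment_count", "min_tss_fragments")
    out$pass_tss_fragments <- !is.na(x) & x >= thresholds$min_tss_fragments
  }
  if (!is.null(thresholds$min_tss_fraction)) {
    x <- need("tss_fraction", "min_tss_fraction")
    thr <- thresholds$min_tss_fraction
    if (length(thr) > 1 || !is.null(names(thr))) {
      s <- need("sample", "min_tss_fraction (per sample)")
      if (!all(unique(s) %in% names(thr))) {
        am_abort("per-sample tss_fraction threshold missing for some samples",
                 class = "atacmod_config_error")
      }
      thr <- unname(thr[s])
    }
    out$pass_tss_fraction <- !is.na(x) & x >= thr
  }
  if (!is.null(thresholds$min_insertion_ratio)) {
    x <- need("tss_insertion_ratio", "min_insertion_ratio")
    out$pass_insertion_ratio <- !is.na(x) & x >= thresholds$min_insertion_ratio
  }
  if (!is.null(thresholds$max_deviation_score)) {
    x <- need("chrom_deviation_score", "max_deviation_score")
    out$pass_deviation <- !is.na(x) & x < thresholds$max_deviation_score
  }
  if (!is.null(thresholds$spectrum_alpha)) {
    x <- need("periodicity_score", "spectrum_alpha")
    s <- if ("sample" %in% names(metrics)) metrics$sample else
      rep("all", nrow(metrics))
    out$pass_spectrum <- !tail_flags(x, s, thresholds$spectrum_alpha)
  }
  if (!is.null(external)) {
    ext <- external[match(out$barcode, external$barcode), , drop = FALSE]
    for (col in setdiff(names(ext), "barcode")) {
      out[[paste0("pass_", col)]] <- !dplyr::coalesce(ext[[col]], FALSE)
    }
  }
  flag_cols <- setdiff(names(out), "barcode")
  out$pass <- if (length(flag_cols) == 0) rep(TRUE, nrow(out)) else
    Reduce(`&`, out[flag_cols])
  out
}

# rank-based two-sided tail flagging within groups: the ceiling(alpha * n)
# smallest and largest defined scores are flagged; NA scores are flagged too
tail_flags <- function(score, group, alpha) {
  flag <- is.na(score)
  for (g in unique(group)) {
    idx <- which(group == g & !is.na(score))
    if (length(idx) == 0) next
    k <- ceiling(alpha * length(idx))
    ord <- idx[order(score[idx])]
    flag[head(ord, k)] <- TRUE
    flag[utils::tail(ord, k)] <- TRUE
  }
  flag
}
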