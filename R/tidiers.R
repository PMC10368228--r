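#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a deconvolution result
#'
#' @param x a `decon_result` from [deconvolve_bulk()].
#' @param ... unused.
#' @return tibble with one row per (bulk sample, cell type):
#'   `bulk_sample`, `cell_type`, `theta`, `nuclei_fraction`, `composition`.
#' @method tidy decon_result
#' @export
tidy.decon_result <- function(x, ...) {
  x$composition
}

#' One-row summary of a deconvolution result
#'
#' @param x a `decon_result`.
#' @param ... unused.
#' @return tibble: `n_bulk_samples`, `n_cell_types`, `n_selected_peaks`,
#'   `kappa` (condition number of the signature matrix).
#' @method glance decon_result
#' @export
glance.decon_result <- function(x, ...) {
  tibble(n_bulk_samples = length(unique(x$composition$bulk_sample)),
         n_cell_types = length(x$c),
         n_selected_peaks = length(x$selected_peaks),
         kappa = kappa(x$reference$W, exact = TRUE))
}

#' Tidy an NMF fit into long regulator/gene weight tables
#'
#' @param x an `nmf_fit` from [nmf_brunet()].
#' @param matrix `"W"` (regulator weights, default) or `"H"` (gene
#'   weights).
#' @param ... unused.
#' @return tibble: `module`, `symbol`, `weight`.
#' @method tidy nmf_fit
#' @export
tidy.nmf_fit <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    as_tibble(x$W, rownames = "symbol") |>
      tidyr::pivot_longer(-"symbol", names_to = "module",
                          values_to = "weight")
  } else {
    as_tibble(t(x$H), rownames = "symbol") |>
      tidyr::pivot_longer(-"symbol", names_to = "module",
                          values_to = "weight")
  }
}

#' One-row summary of an NMF fit
#' @param x an `nmf_fit`.
#' @param ... unused.
#' @return tibble: `rank`, `objective`, `iterations_traced`.
#' @method glance nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(rank = x$rank, objective = x$objective,
         iterations_traced = length(x$trace))
}

#' Tidy a gene-set activity result
#' @param x a `gs_activity`.
#' @param ... unused.
#' @return tibble: `barcode`, `score`.
#' @method tidy gs_activity
#' @export
tidy.gs_activity <- function(x, ...) {
  tibble(barcode = names(x$score), score = unname(x$score))
}

#' One-row summary of a gene-set activity result
#' @param x a `gs_activity`.
#' @param ... unused.
#' @return tibble: `n_members`, `singular_value`, `orientation`.
#' @method glance gs_activity
#' @export
glance.gs_activity <- function(x, ...) {
  tibble(n_members = nrow(x$members), singular_value = x$singular_value,
         orientation = x$orientation)
}

#' Tidy a two-pass clustering result
#' @param x an `atac_clustering` from [two_pass_pipeline()].
#' @param ... unused.
#' @return the per-nucleus tibble with embedding coordinates attached.
#' @method tidy atac_clustering
#' @export
tidy.atac_clustering <- function(x, ...) {
  out <- x$nuclei
  coords <- x$embedding$coords
  out$lsi1 <- NA_real_
  out$lsi2 <- NA_real_
  out$lsi1[out$retained] <- coords[, 1]
  out$lsi2[out$retained] <- coords[, 2]
  out
}
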