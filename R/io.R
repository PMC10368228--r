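#' Read a 10x-style fragments file
#'
#' Parses a (optionally gzipped) tab-separated fragments file with columns
#' chromosome, start, end, barcode and an optional duplicate count. Coordinates
#' are 0-based half-open, the convention of the 10x fragments ecosystem.
#' Comment lines starting with `#` are skipped. When the count column is
#' absent every record gets count 1.
#'
#' @param path path to the fragments file (plain or `.gz`).
#' @param sample_map optional tibble with columns `barcode`, `sample` mapping
#'   each barcode to the library it came from; attached as the `sample`
#'   column (NA for unmapped barcodes).
#' @return a tibble with columns `chrom`, `start`, `end`, `barcode`, `count`
#'   (and `sample` if a map was given).
#' @export
read_fragments <- function(path, sample_map = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    frags <- tibble(chrom = character(), start = integer(), end = integer(),
                    barcode = character(), count = integer())
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 4 | nf > 5)
    if (length(bad) > 0) {
      am_abort(sprintf("malformed fragment line %d: expected 4 or 5 fields, got %d",
                       bad[1], nf[bad[1]]), class = "atacmod_parse_error")
    }
    m <- matrix("", nrow = length(parts), ncol = 5)
    for (i in seq_along(parts)) m[i, seq_len(nf[i])] <- parts[[i]]
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    count <- ifelse(nf == 5, suppressWarnings(as.integer(m[, 5])), 1L)
    badnum <- which(is.na(start) | is.na(end) | is.na(count))
    if (length(badnum) > 0) {
      am_abort(sprintf("malformed fragment line %d: non-numeric coordinate or count",
                       badnum[1]), class = "atacmod_parse_error")
    }
    frags <- tibble(chrom = m[, 1], start = start, end = end,
                    barcode = m[, 4], count = count)
  }
  validate_fragments(frags)
  if (!is.null(sample_map)) {
    frags$sample <- sample_map$sample[match(frags$barcode, sample_map$barcode)]
  }
  frags
}

validate_fragments <- function(frags) {
  am_validate(all(frags$start < frags$end),
              "fragment with start >= end (coordinates are 0-based half-open)")
  am_validate(all(frags$start >= 0), "negative fragment coordinate")
  am_validate(all(nzchar(frags$barcode)), "empty barcode")
  am_validate(all(frags$count >= 1), "fragment count must be >= 1")
  invisible(frags)
}

#' Write fragments as gzipped TSV
#'
#' @param frags tibble as returned by [read_fragments()].
#' @param path output path; use a `.gz` suffix for compression.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  validate_fragments(frags)
  readr::write_tsv(frags[, c("chrom", "start", "end", "barcode", "count")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One gene set per line: name, description, then member symbols, all
#' tab-separated. Duplicate members are dropped.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors (members), with a `description`
#'   attribute per element.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      am_abort(sprintf("GMT line %d has %d fields; need name, description and >=1 member",
                       i, length(fields)), class = "atacmod_parse_error")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    set <- members
    attr(set, "description") <- fields[2]
    out[[fields[1]]] <- set
  }
  out
}

#' Write gene sets in GMT format
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(seq_along(gene_sets), function(i) {
    desc <- attr(gene_sets[[i]], "description") %||% ""
    paste(c(names(gene_sets)[i], desc, gene_sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a named matrix from MatrixMarket plus name sidecars
#'
#' @param path_mtx MatrixMarket file.
#' @param path_rows,path_cols sidecar text files, one name per line.
#' @param dense return a base dense matrix (default) or a sparse `dgCMatrix`.
#' @return matrix with dimnames.
#' @export
read_named_matrix <- function(path_mtx, path_rows, path_cols, dense = TRUE) {
  m <- Matrix::readMM(path_mtx)
  rn <- readr::read_lines(path_rows)
  cn <- readr::read_lines(path_cols)
  am_validate(length(rn) == nrow(m),
              "row-name sidecar length does not match matrix rows")
  am_validate(length(cn) == ncol(m),
              "column-name sidecar length does not match matrix columns")
  dimnames(m) <- list(rn, cn)
  if (dense) as.matrix(m) else methods::as(m, "CsparseMatrix")
}

#' Write a named matrix as MatrixMarket plus name sidecars
#'
#' Integer matrices round-trip bit-exactly through [read_named_matrix()].
#'
#' @param x matrix with dimnames.
#' @param path_mtx,path_rows,path_cols output paths.
#' @return `path_mtx`, invisibly.
#' @export
write_named_matrix <- function(x, path_mtx, path_rows, path_cols) {
  am_validate(!is.null(rownames(x)) && !is.null(colnames(x)),
              "matrix must have row and column names")
  Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
                  path_mtx)
  readr::write_lines(rownames(x), path_rows)
  readr::write_lines(colnames(x), path_cols)
  invisible(path_mtx)
}

#' Read a STRING-style protein-protein interaction table
#'
#' Three tab-separated columns: node1, node2, score in \[0, 1\]. Self-loops
#' are dropped (they carry no between-protein information for set
#' aggregation); duplicate undirected edges keep their maximum score.
#'
#' @param path path to the TSV (a header line is auto-detected).
#' @return tibble with columns `node1`, `node2`, `score`.
#' @export
read_ppi <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- length(first) == 1 &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][3])))
  ppi <- readr::read_tsv(path, col_names = c("node1", "node2", "score"),
                         skip = as.integer(has_header),
                         col_types = readr::cols("c", "c", "d"))
  validate_ppi(ppi)
}

validate_ppi <- function(ppi) {
  am_validate(all(ppi$score >= 0 & ppi$score <= 1),
              "PPI scores must lie in [0, 1]")
  ppi <- dplyr::filter(ppi, .data$node1 != .data$node2)
  key <- ifelse(ppi$node1 < ppi$node2,
                paste(ppi$node1, ppi$node2), paste(ppi$node2, ppi$node1))
  ppi |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".key")
}

#' Write a PPI table as 3-column TSV
#' @param ppi tibble with `node1`, `node2`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(ppi, path) {
  readr::write_tsv(ppi[, c("node1", "node2", "score")], path, col_names = FALSE)
  invisible(path)
}
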