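# shared small fixtures, built in code

toy_fragments <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 300L, 950L, 40L, 500L),
    end = c(300L, 520L, 1150L, 240L, 700L),
    barcode = c("A", "A", "B", "B", "B"),
    count = 1L)
}

# deterministic binary matrix with two planted cell types
toy_binary <- function(n_sites = 60, n_nuclei = 40, seed = 7) {
  set.seed(seed)
  p <- matrix(0.1, n_sites, 2)
  p[1:20, 1] <- 0.8
  p[21:40, 2] <- 0.8
  type <- rep(1:2, each = n_nuclei / 2)
  f <- matrix(rbinom(n_sites * n_nuclei, 1, p[, type]), n_sites, n_nuclei)
  f[1, colSums(f) == 0] <- 1L
  dimnames(f) <- list(paste0("s", seq_len(n_sites)),
                      paste0("n", seq_len(n_nuclei)))
  list(f = f, type = type)
}

random_binary <- function(n_sites, n_nuclei, seed) {
  set.seed(seed)
  f <- matrix(rbinom(n_sites * n_nuclei, 1, 0.3), n_sites, n_nuclei)
  f[1, colSums(f) == 0] <- 1L
  f[rowSums(f) == 0, 1] <- 1L
  f
}
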