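# Independent brute-force mutual information oracle: explicit double
# loop over the joint contingency table of two pre-discretized vectors.
brute_force_mi <- function(dx, dy, n_bins, base = exp(1)) {
  n <- length(dx)
  mi <- 0
  for (a in seq_len(n_bins)) {
    for (b in seq_len(n_bins)) {
      nab <- sum(dx == a & dy == b)
      if (nab == 0) next
      pab <- nab / n
      pa <- sum(dx == a) / n
      pb <- sum(dy == b) / n
      mi <- mi + pab * log(pab / (pa * pb), base = base)
    }
  }
  mi
}

# tiny named expression matrix with reproducible values
toy_expr <- function(genes, samples, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(length(genes) * length(samples)),
           nrow = length(genes),
           dimnames = list(genes, samples))
  })
}

# small fully wired toy world: 10 genes, 2 miRNAs, 12 samples
toy_world <- function(seed = 11) {
  genes <- sprintf("g%02d", 1:10)
  samples <- sprintf("s%02d", 1:12)
  withr::with_seed(seed, {
    mirna <- matrix(rnorm(2 * 12), 2, 12,
                    dimnames = list(c("mirA", "mirB"), samples))
    mrna <- matrix(rnorm(10 * 12), 10, 12,
                   dimnames = list(genes, samples))
    # g01 strongly repressed by mirA; g02 is g01's co-expressed partner
    mrna["g01", ] <- -mirna["mirA", ] + rnorm(12, sd = 0.1)
    mrna["g02", ] <- mrna["g01", ] + rnorm(12, sd = 0.1)
    # g03 positively coupled to mirA (must be filtered out)
    mrna["g03", ] <- mirna["mirA", ] + rnorm(12, sd = 0.1)
  })
  fpi <- tibble::tibble(from = c("g01", "g02", "g03", "g05"),
                        to = c("g02", "g04", "g04", "g06"))
  list(genes = genes, samples = samples, mirna = mirna, mrna = mrna,
       fpi = fpi)
}

small_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(seed = seed, ...))
}

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
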