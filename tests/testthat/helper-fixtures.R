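# Programmatic fixtures shared across test files.

# Two well-separated Gaussian blobs in d dimensions.
make_blobs <- function(n_pos, n_neg, d = 5, sep = 4, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    p <- matrix(rnorm(n_pos * d, mean = 0, sd = sd), n_pos, d)
    n <- matrix(rnorm(n_neg * d, mean = sep, sd = sd), n_neg, d)
    list(p = p, n = n)
  })
}

# Tiny FASTA + annotation files written to a temp dir; returns the paths.
write_tiny_dataset <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "tiny.fasta")
  writeLines(c(
    ">p1 first protein",
    "MKVAKLPKWT",
    ">p2",
    "KKAYDE"
  ), fasta)
  ann <- file.path(dir, "tiny_sites.tsv")
  writeLines(c("protein_id\tsite", "p1\t2", "p2\t1"), ann)
  list(fasta = fasta, annotations = ann)
}

# Small simulated dataset for pipeline tests (cheap: few proteins).
small_sim <- function(seed = 11, n_proteins = 20) {
  simulate_proteome(simulation_config(n_proteins = n_proteins, seed = seed))
}

# A fast config for tests: tiny tuning grids, fewer folds.
fast_config <- function(seed = 1, tuning_folds = 5, ...) {
  pu_config(cost_grid = c(1, 10), gamma_grid = c(0.01, 0.1, 1),
            tuning_folds = tuning_folds, seed = seed, ...)
}

# Brute-force 2x2 chi-square (no continuity correction) for feature oracle.
chisq2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (den == 0) return(0)
  n * (a * d - b * c_)^2 / den
}
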