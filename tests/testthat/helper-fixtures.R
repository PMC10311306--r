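# Small fixtures built in code, shared across test files.

tiny_genotypes <- function() {
  genotype_matrix(
    matrix(c(0, 1, 2, 0,
             1, 1, 0, 2,
             2, 0, 1, 1), nrow = 3, byrow = TRUE),
    sample_ids = c("s1", "s2", "s3"),
    snp_ids = c("rs1", "rs2", "rs3", "rs4")
  )
}

random_genotypes <- function(n, m, seed = 1, prefix = "s") {
  withr::with_seed(seed, {
    genotype_matrix(matrix(sample(0:2, n * m, replace = TRUE), n, m),
                    sample_ids = paste0(prefix, seq_len(n)),
                    snp_ids = sprintf("snp%03d", seq_len(m)))
  })
}

# one small aligned federation reused by several tests: 3 populations,
# researchers hold pop1/pop2, public panel has all three
small_federation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_populations(
        synthetic_config(3, 40, 600, fst = 0.1, seed = 314))
      fed <- split_federation(g, list(Ra = c(pop1 = 15), Rb = c(pop2 = 15)))
      al <- align_snp_sets(c(list(qc_filter(fed$public)), fed$locals))
      cache <<- list(g = g, public = al[[1]],
                     locals = list(Ra = al[[2]], Rb = al[[3]]))
    }
    cache
  }
})

# brute-force PCA oracle: eigendecomposition of the covariance matrix of
# the standardized dosages (independent of the SVD code path)
oracle_pca <- function(g, d) {
  z <- scale(unclass(g))
  ev <- eigen(stats::cov(z), symmetric = TRUE)
  q <- ev$vectors[, seq_len(d), drop = FALSE]
  list(q = q, scores = z %*% q)
}

# agreement up to per-column sign
expect_equal_up_to_sign <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    d_same <- max(abs(a[, j] - b[, j]))
    d_flip <- max(abs(a[, j] + b[, j]))
    expect_lt(min(d_same, d_flip), tol)
  }
}
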