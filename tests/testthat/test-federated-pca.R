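test_that("fit_pca_model matches a brute-force covariance eigendecomposition", {
  for (seed in 1:3) {
    g <- random_genotypes(20, 10, seed = seed)
    g <- qc_filter(g, maf_min = 0, missing_max = 1)  # keep all; no-op
    model <- fit_pca_model(g, 3)
    oracle <- oracle_pca(g, 3)
    expect_equal_up_to_sign(model$q_matrix, oracle$q, tol = 1e-8)
    scores <- scores_matrix(project_samples(model, g))
    expect_equal_up_to_sign(scores, oracle$scores, tol = 1e-8)
  }
})

test_that("factor scores equal P Delta from the SVD", {
  g <- random_genotypes(12, 8, seed = 4)
  model <- fit_pca_model(g, 4)
  zs <- scale(unclass(g))
  sv <- svd(zs)
  f_svd <- sv$u[, 1:4] %*% diag(sv$d[1:4])
  f_model <- scores_matrix(project_samples(model, g))
  expect_equal_up_to_sign(f_model, f_svd, tol = 1e-8)
})

test_that("the dominant variance direction is recovered", {
  # points on a line through both axes plus tiny isotropic jitter: after
  # per-axis standardization the line is the diagonal v = (1, -1)/sqrt(2)
  withr::with_seed(2, {
    t_ <- stats::rnorm(100, sd = 3)
    pts <- cbind(2 * t_, -5 * t_) +
      matrix(stats::rnorm(200, sd = 1e-4), ncol = 2)
  })
  sv <- svd(scale(pts))
  q1 <- sv$v[, 1]
  v <- c(1, -1) / sqrt(2)
  expect_lt(min(max(abs(q1 - v)), max(abs(q1 + v))), 1e-3)
  # PC1 explains essentially all variance
  expect_gt(sv$d[1]^2 / sum(sv$d^2), 1 - 1e-6)
})

test_that("training rejects degenerate panels", {
  g <- tiny_genotypes()
  expect_error(fit_pca_model(g, 4), "too small")
  m <- unclass(g)
  m[, 2] <- 1
  g2 <- genotype_matrix(m)
  expect_error(fit_pca_model(g2, 2), "zero-variance")
})

test_that("compute_sensitivity is the per-component score range", {
  fake_scores <- tibble::tibble(sample_id = c("a", "b", "c"),
                                PC1 = c(-2, 0, 3), PC2 = c(0, 5, 10))
  model <- structure(list(n_components = 2L), class = "pca_model")
  s <- compute_sensitivity(model, fake_scores)
  expect_equal(unname(s), c(5, 10))

  fake_scores$PC1 <- c(1, 1, 1)
  expect_error(compute_sensitivity(model, fake_scores), "degenerate")

  two <- tibble::tibble(sample_id = c("a", "b"),
                        PC1 = c(-1, 1), PC2 = c(0, 10))
  expect_equal(unname(compute_sensitivity(model, two)), c(2, 10))
})

test_that("both sensitivity estimators are exposed on the trained model", {
  fed <- small_federation()
  m_load <- fit_pca_model(fed$public, 2, sensitivity = "loadings")
  m_score <- fit_pca_model(fed$public, 2, sensitivity = "scores")
  expect_equal(unname(m_load$sensitivities),
               unname(apply(m_load$q_matrix, 2, function(v) max(v) - min(v))))
  f <- scores_matrix(project_samples(m_score, fed$public))
  expect_equal(unname(m_score$sensitivities),
               unname(apply(f, 2, function(v) max(v) - min(v))))
  # identical projection geometry either way
  expect_identical(m_load$q_matrix, m_score$q_matrix)
})

test_that("projection standardizes with the model parameters", {
  model <- structure(list(
    q_matrix = matrix(c(0.6, 0.8), 2, 1,
                      dimnames = list(c("a", "b"), "PC1")),
    n_components = 1L, snp_ids = c("a", "b"),
    means = c(a = 0, b = 0), scales = c(a = 1, b = 1),
    sensitivities = c(PC1 = 1)), class = "pca_model")
  g <- genotype_matrix(matrix(c(1, 2), 1, 2), "s1", c("a", "b"))
  expect_equal(project_samples(model, g)$PC1, 2.2)

  # identity projection returns the dosages
  id_model <- structure(list(
    q_matrix = diag(2), n_components = 2L, snp_ids = c("a", "b"),
    means = c(a = 0, b = 0), scales = c(a = 1, b = 1),
    sensitivities = c(PC1 = 1, PC2 = 1)), class = "pca_model")
  dimnames(id_model$q_matrix) <- list(c("a", "b"), c("PC1", "PC2"))
  g2 <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2),
                        c("s1", "s2"), c("a", "b"))
  sc <- project_samples(id_model, g2)
  expect_equal(unname(scores_matrix(sc)), unname(unclass(g2)[, ]))

  # missing dosage imputes to the training mean (0 after standardization)
  g3 <- genotype_matrix(matrix(c(NA, 2), 1, 2), "s1", c("a", "b"))
  expect_equal(project_samples(model, g3)$PC1, 1.6)

  colnames(g2) <- c("a", "zz")
  expect_error(project_samples(model, g2), "discrepancy")
})

test_that("projecting the training panel reproduces the training factor scores", {
  fed <- small_federation()
  model <- fit_pca_model(fed$public, 2)
  s1 <- project_samples(model, fed$public)
  s2 <- project_samples(model, fed$public)
  expect_identical(s1, s2)
  zs <- scale(unclass(fed$public))
  expect_equal(unname(scores_matrix(s1)), unname(zs %*% model$q_matrix))
})

test_that("row permutation of the local data permutes scores identically", {
  fed <- small_federation()
  model <- fit_pca_model(fed$public, 2)
  loc <- fed$locals$Ra
  perm <- withr::with_seed(1, sample(n_samples(loc)))
  s_orig <- project_samples(model, loc)
  s_perm <- project_samples(model, loc[perm, ])
  expect_equal(s_perm, s_orig[perm, ])
})

test_that("Laplace noise has the prescribed per-dimension scale", {
  # d = 2, s1 = 5, epsilon = 1: lambda_1 = 5 / (1/2) = 10
  scores <- tibble::tibble(sample_id = sprintf("s%06d", 1:50000),
                           PC1 = 0, PC2 = 0)
  noisy <- perturb_projection(scores, epsilon = 1,
                              sensitivities = c(5, 8), seed = 123)
  draws1 <- noisy$PC1
  lambda1 <- 5 * 2 / 1
  n <- length(draws1)
  expect_lt(abs(mean(draws1)), 3 * lambda1 * sqrt(2) / sqrt(n))
  expect_lt(abs(mean(abs(draws1)) - lambda1) / lambda1, 0.02)
  lambda2 <- 8 * 2 / 1
  expect_lt(abs(mean(abs(noisy$PC2)) - lambda2) / lambda2, 0.02)
})

test_that("rlaplace moments match the distribution at 1e5 draws", {
  x <- withr::with_seed(9, rlaplace(1e5, scale = 10))
  expect_lt(abs(mean(x)), 3 * 10 * sqrt(2) / sqrt(1e5))
  expect_lt(abs(mean(abs(x)) - 10) / 10, 0.02)
  expect_lt(abs(stats::var(x) - 200) / 200, 0.05)
})

test_that("the infinite-budget sentinel passes scores through bit-exactly", {
  fed <- small_federation()
  model <- fit_pca_model(fed$public, 2)
  sc <- project_samples(model, fed$locals$Ra)
  expect_identical(perturb_projection(sc, Inf, model$sensitivities), sc)
  expect_error(perturb_projection(sc, 0, model$sensitivities), "epsilon")
  expect_error(perturb_projection(sc, -1, model$sensitivities), "epsilon")
})

test_that("sample id hashing is standard SHA-256", {
  expect_identical(
    hash_sample_ids("abc"),
    "ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad")
  expect_identical(hash_sample_ids("abc"), hash_sample_ids("abc"))
  expect_false(hash_sample_ids("abc") == hash_sample_ids("abd"))
  expect_error(hash_sample_ids(c("a", "a")), "duplicate")
  h <- hash_sample_ids(c("a", "b"))
  expect_true(all(grepl("^[0-9a-f]{64}$", h)))
})

test_that("metadata payloads couple hashed ids with coordinates", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"),
                       PC1 = c(0.1, 0.2, 0.3), PC2 = c(-1, 0, 1))
  meta <- build_metadata(sc, epsilon = 3)
  expect_identical(nrow(meta), 3L)
  expect_identical(names(meta), c("hashed_id", "coord_1", "coord_2"))
  expect_true(all(grepl("^[0-9a-f]{64}$", meta$hashed_id)))
  expect_identical(attr(meta, "epsilon"), 3)
  expect_error(build_metadata(sc[0, ], 3), "empty")
})

test_that("metadata files round-trip bit-exactly", {
  sc <- tibble::tibble(sample_id = c("a", "b"),
                       PC1 = c(pi, -exp(1)), PC2 = c(1 / 3, sqrt(2)))
  meta <- build_metadata(sc, epsilon = 2.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_identical(back$coord_1, meta$coord_1)
  expect_identical(back$coord_2, meta$coord_2)
  expect_identical(back$hashed_id, meta$hashed_id)
  expect_identical(attr(back, "epsilon"), 2.5)

  inf_meta <- build_metadata(sc, epsilon = Inf)
  write_metadata(inf_meta, path)
  expect_identical(attr(read_metadata(path), "epsilon"), Inf)
})

test_that("model serialization round-trips bit-exactly", {
  fed <- small_federation()
  model <- fit_pca_model(fed$public, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(model, path)
  back <- read_pca_model(path)
  expect_identical(back$q_matrix, model$q_matrix)
  expect_identical(back$means, model$means)
  expect_identical(back$scales, model$scales)
  expect_identical(back$sensitivities, model$sensitivities)
  expect_identical(back$n_components, model$n_components)
})

test_that("tidy and glance summarize a model", {
  fed <- small_federation()
  model <- fit_pca_model(fed$public, 2)
  td <- tidy(model)
  expect_identical(nrow(td), length(model$snp_ids) * 2L)
  gl <- glance(model)
  expect_identical(gl$n_components, 2L)
})
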