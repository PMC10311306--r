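make_payload <- function(n, d = 2, seed = 1, eps = 3, prefix = "p") {
  sc <- withr::with_seed(seed, tibble::tibble(
    sample_id = paste0(prefix, seq_len(n)),
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n))[, c(1, seq_len(d) + 1)])
  build_metadata(sc, eps)
}

test_that("aggregate_metadata concatenates payloads with source tags", {
  pa <- make_payload(20, seed = 1, prefix = "a")
  pb <- make_payload(18, seed = 2, prefix = "b")
  pts <- aggregate_metadata(list(Ra = pa, Rb = pb))
  expect_identical(nrow(pts), 38L)
  expect_identical(unique(pts$source), c("Ra", "Rb"))
  expect_identical(pts$coord_1[1:20], pa$coord_1)

  one <- aggregate_metadata(list(pa))
  expect_identical(one$coord_1, pa$coord_1)
  expect_identical(unique(one$source), "researcher_1")

  # same individual released by two researchers: both rows kept
  dup <- aggregate_metadata(list(A = pa, B = pa))
  expect_identical(nrow(dup), 40L)

  p1 <- make_payload(5, d = 1, seed = 3)
  expect_error(aggregate_metadata(list(pa, p1)), "disagree")
  expect_error(aggregate_metadata(list()), "payload")
})

test_that("WCSS is zero at k = n and the curve is non-increasing", {
  pts <- withr::with_seed(4, matrix(stats::rnorm(24), ncol = 2))
  curve <- wcss_curve(pts, k_min = 1, k_max = 12, seed = 2)
  expect_equal(curve$wcss[12], 0)
  expect_true(all(diff(curve$wcss) <= 1e-10))
})

test_that("WCSS curves are non-increasing on many random point sets", {
  for (s in 1:100) {
    pts <- withr::with_seed(s, matrix(stats::rnorm(30), ncol = 2))
    curve <- wcss_curve(pts, k_min = 1, k_max = 8, seed = s, restarts = 3)
    expect_true(all(diff(curve$wcss) <= 1e-10))
  }
})

test_that("well-separated clusters produce a sharp WCSS elbow", {
  centers <- rbind(c(0, 0), c(50, 0), c(0, 50))
  pts <- withr::with_seed(8, centers[rep(1:3, each = 30), ] +
                            matrix(stats::rnorm(180, sd = 1), ncol = 2))
  curve <- wcss_curve(pts, k_min = 1, k_max = 8, seed = 1)
  w <- stats::setNames(curve$wcss, curve$k)
  expect_lt(w["3"], w["2"] / 10)
  expect_gt(w["4"], w["3"] / 2)
  expect_identical(choose_k_elbow(curve), 3L)
})

test_that("choose_k_elbow maximizes normalized distance to the chord", {
  expect_identical(
    choose_k_elbow(tibble::tibble(k = 1:4, wcss = c(100, 10, 9, 8.5))), 2L)
  expect_warning(
    k <- choose_k_elbow(tibble::tibble(k = 1:4, wcss = c(5, 5, 5, 5))),
    "flat")
  expect_identical(k, 1L)
  expect_warning(
    k2 <- choose_k_elbow(tibble::tibble(k = 2:6, wcss = c(50, 40, 30, 20, 10))),
    "no elbow")
  expect_identical(k2, 2L)
  expect_error(choose_k_elbow(tibble::tibble(k = 1:2, wcss = c(2, 1))))
})

test_that("cluster_kmeans is deterministic, canonical, and exact when separable", {
  two <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  rep2 <- cluster_kmeans(two, k = 2, seed = 1)
  expect_setequal(rep2$assignments$cluster, 1:2)
  expect_equal(rep2$wcss_curve$wcss, 0)

  centers <- rbind(c(0, 0), c(100, 0), c(0, 100))
  sizes <- c(40, 30, 20)
  pts <- withr::with_seed(5, centers[rep(1:3, sizes), ] +
                            matrix(stats::rnorm(180, sd = 1), ncol = 2))
  truth <- stats::setNames(rep(c("a", "b", "c"), sizes),
                           as.character(1:90))
  rep3 <- cluster_kmeans(pts, k = 3, seed = 7)
  expect_equal(score_accuracy(rep3, truth), 1)
  # canonical labels: cluster 1 is the largest
  expect_identical(rep3$cluster_sizes$size, c(40L, 30L, 20L))
  expect_identical(rep3$cluster_sizes$cluster, 1:3)

  again <- cluster_kmeans(pts, k = 3, seed = 7)
  expect_identical(rep3$assignments, again$assignments)
  expect_error(cluster_kmeans(pts, k = 91, seed = 1), "k")
})

test_that("the centralized benchmark pools datasets order-invariantly", {
  fed <- small_federation()
  b1 <- centralized_benchmark(fed$locals, fed$public, 2, k = 3, seed = 2)
  b2 <- centralized_benchmark(rev(fed$locals), fed$public, 2, k = 3, seed = 2)
  m <- match_cluster_labels(b1, stats::setNames(b2$assignments$cluster,
                                                b2$assignments$id))
  expect_identical(sum(m$overlap), nrow(b1$assignments))

  # no locals: benchmark is PCA + k-means on the public panel alone
  b3 <- centralized_benchmark(list(), fed$public, 2, k = 3, seed = 2)
  expect_setequal(b3$assignments$id, sample_ids(fed$public))
})

test_that("no-noise federation is bit-identical to pooled projection", {
  fed <- small_federation()
  model <- fit_pca_model(fed$public, 2)
  payloads <- lapply(fed$locals, function(g) {
    build_metadata(perturb_projection(project_samples(model, g), Inf,
                                      model$sensitivities), Inf)
  })
  pts <- aggregate_metadata(payloads)
  pooled <- bind_genotypes(fed$locals)
  pooled_scores <- project_samples(model, pooled)
  expect_identical(pts$coord_1, pooled_scores$PC1)
  expect_identical(pts$coord_2, pooled_scores$PC2)
  expect_identical(pts$hashed_id, hash_sample_ids(pooled_scores$sample_id))

  # hence identical cluster reports on identical coordinates
  r_fed <- cluster_kmeans(pts, k = 2, seed = 3)
  r_pool <- cluster_kmeans(pooled_scores, k = 2, seed = 3)
  expect_identical(r_fed$assignments$cluster, r_pool$assignments$cluster)
})

test_that("Hungarian matching agrees with a brute-force permutation oracle", {
  brute_force_overlap <- function(tab) {
    n <- max(dim(tab))
    padded <- matrix(0, n, n)
    padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    max(vapply(perms(seq_len(n)),
               function(p) sum(padded[cbind(seq_len(n), p)]), numeric(1)))
  }
  for (s in 1:5) {
    labs <- withr::with_seed(s, list(
      p = sample(1:3, 40, replace = TRUE),
      t = sample(letters[1:4], 40, replace = TRUE)))
    pred <- tibble::tibble(id = as.character(1:40), cluster = labs$p)
    truth <- stats::setNames(labs$t, as.character(1:40))
    m <- match_cluster_labels(pred, truth)
    expect_equal(sum(m$overlap),
                 brute_force_overlap(table(labs$p, labs$t)))
  }

  # the spec'd 2x2 example: contingency [[9,1],[2,8]]
  pred <- tibble::tibble(id = as.character(1:20),
                         cluster = rep(c(0, 1), c(10, 10)))
  truth <- stats::setNames(rep(c("x", "y", "y", "x"), c(9, 1, 8, 2)),
                           as.character(1:20))
  m <- match_cluster_labels(pred, truth)
  expect_identical(m$truth_cluster[m$predicted_cluster == "0"], "x")
  expect_identical(m$truth_cluster[m$predicted_cluster == "1"], "y")
  expect_identical(sum(m$overlap), 17L)
})

test_that("matching is identity-equivalent on identical or relabeled partitions", {
  labs <- rep(1:3, c(5, 7, 9))
  pred <- tibble::tibble(id = as.character(1:21), cluster = labs)
  truth <- stats::setNames(labs, as.character(1:21))
  m <- match_cluster_labels(pred, truth)
  expect_identical(sum(m$overlap), 21L)
  permuted <- stats::setNames(c("C", "A", "B")[labs], as.character(1:21))
  m2 <- match_cluster_labels(pred, permuted)
  expect_identical(sum(m2$overlap), 21L)
  expect_equal(score_accuracy(pred, permuted), 1)
  expect_error(match_cluster_labels(
    pred, stats::setNames(labs, paste0("z", 1:21))), "no sample ids")
})

test_that("accuracy, precision and recall follow their definitions", {
  labs <- rep(c("a", "b"), each = 5)
  pred <- tibble::tibble(id = as.character(1:10), cluster = labs)
  truth <- stats::setNames(labs, as.character(1:10))
  expect_equal(score_accuracy(pred, truth), 1)
  pr <- score_precision_recall(pred, truth)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  # one of ten misassigned
  flipped <- labs
  flipped[10] <- "a"
  pred2 <- tibble::tibble(id = as.character(1:10), cluster = flipped)
  expect_equal(score_accuracy(pred2, truth), 0.9)

  # predicted cluster X = {8 true-X, 2 true-Y}, both clusters of size 10
  p3 <- rep(c("X", "Y"), each = 10)
  t3 <- c(rep("X", 8), "Y", "Y", rep("Y", 8), "X", "X")
  pred3 <- tibble::tibble(id = as.character(1:20), cluster = p3)
  truth3 <- stats::setNames(t3, as.character(1:20))
  pr3 <- score_precision_recall(pred3, truth3)
  expect_equal(pr3$precision, 0.8)
  expect_equal(pr3$recall, 0.8)
})

test_that("metrics stay within [0, 1] on random partitions", {
  for (s in 1:10) {
    withr::with_seed(s, {
      pred <- tibble::tibble(id = as.character(1:30),
                             cluster = sample(1:4, 30, replace = TRUE))
      truth <- stats::setNames(sample(letters[1:3], 30, replace = TRUE),
                               as.character(1:30))
    })
    pr <- score_precision_recall(pred, truth)
    acc <- score_accuracy(pred, truth)
    expect_true(acc >= 0 && acc <= 1)
    expect_true(pr$precision >= 0 && pr$precision <= 1)
    expect_true(pr$recall >= 0 && pr$recall <= 1)
  }
})
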