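#' Combine metadata payloads from several researchers
#'
#' Row-concatenates the payloads in the order given, tagging every row with
#' its source researcher. Because every researcher projected through the
#' same trained model, the combined coordinates are directly comparable —
#' this is the server-side "combined PCA". The same hashed id may appear
#' under two sources (both rows are kept); within one payload ids are
#' unique by construction.
#'
#' @param payloads named list of `noisy_metadata` payloads (names become
#'   source tags; unnamed lists get `researcher_1`, ...).
#' @return A `combined_points` tibble: `hashed_id`, `source`,
#'   `coord_1` ... `coord_d`.
#' @export
aggregate_metadata <- function(payloads) {
  if (!is.list(payloads) || length(payloads) == 0) {
    stop("need at least one metadata payload", call. = FALSE)
  }
  ds <- vapply(payloads, function(p) attr(p, "n_components"), integer(1))
  if (length(unique(ds)) != 1) {
    stop("payloads disagree on the number of components: ",
         paste(ds, collapse = ", "), call. = FALSE)
  }
  tags <- names(payloads)
  if (is.null(tags) || any(!nzchar(tags))) {
    tags <- paste0("researcher_", seq_along(payloads))
  }
  out <- purrr::map2(payloads, tags, function(p, tag) {
    tibble::as_tibble(p) |>
      tibble::add_column(source = tag, .after = "hashed_id")
  }) |>
    purrr::list_rbind()
  structure(out,
            n_components = ds[1],
            class = c("combined_points", class(tibble::tibble())))
}

points_matrix <- function(points) {
  if (is.matrix(points)) return(points)
  cols <- grep("^(coord|PC)_?[0-9]+$", names(points), value = TRUE)
  if (length(cols) == 0) {
    stop("no coordinate columns (coord_* or PC*) found", call. = FALSE)
  }
  as.matrix(points[cols])
}

points_ids <- function(points) {
  if (is.matrix(points)) {
    if (!is.null(rownames(points))) rownames(points)
    else as.character(seq_len(nrow(points)))
  } else if ("hashed_id" %in% names(points)) points$hashed_id
  else if ("sample_id" %in% names(points)) points$sample_id
  else as.character(seq_len(nrow(points)))
}

# squared distance from every row of x to every row of centers
dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(sweep(-2 * cross, 2, rowSums(centers^2), "+"), 1, rowSums(x^2), "+")
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# data points with probability proportional to squared distance to the
# nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        stop("fewer distinct points than requested clusters", call. = FALSE)
      }
      idx <- sample.int(n, 1, prob = pmax(d2, 0))
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

# best of `restarts` Lloyd runs from k-means++ seeds (plus optional extra
# candidate center sets); returns list(labels, centers, wcss)
best_kmeans_fit <- function(x, k, restarts = 10, extra_inits = list()) {
  if (k >= nrow(x)) {
    if (k > nrow(x)) stop("more clusters than points", call. = FALSE)
    return(list(labels = seq_len(nrow(x)), centers = x, wcss = 0))
  }
  best <- NULL
  consider <- function(fit) {
    if (!is.null(fit) && (is.null(best) || fit$wcss < best$wcss)) best <<- fit
  }
  for (r in seq_len(restarts)) {
    init <- tryCatch(kmeanspp_centers(x, k), error = function(e) NULL)
    if (is.null(init)) next
    fit <- tryCatch({
      km <- stats::kmeans(x, centers = init, iter.max = 300,
                          algorithm = "Lloyd")
      list(labels = km$cluster, centers = km$centers,
           wcss = km$tot.withinss)
    }, error = function(e) NULL, warning = function(w) {
      km <- suppressWarnings(stats::kmeans(x, centers = init, iter.max = 300,
                                           algorithm = "Lloyd"))
      list(labels = km$cluster, centers = km$centers, wcss = km$tot.withinss)
    })
    consider(fit)
  }
  for (init in extra_inits) {
    # assignment-only evaluation of a candidate center set: its WCSS is an
    # upper bound on the Lloyd result from the same seed, and is always
    # well-defined even when Lloyd would empty a cluster
    d2 <- dist2_to_centers(x, init)
    labels <- max.col(-d2, ties.method = "first")
    consider(list(labels = labels, centers = init,
                  wcss = sum(d2[cbind(seq_len(nrow(x)), labels)])))
    fit <- tryCatch({
      km <- suppressWarnings(stats::kmeans(x, centers = init, iter.max = 300,
                                           algorithm = "Lloyd"))
      list(labels = km$cluster, centers = km$centers, wcss = km$tot.withinss)
    }, error = function(e) NULL)
    consider(fit)
  }
  if (is.null(best)) stop("k-means failed for k = ", k, call. = FALSE)
  best$wcss <- max(best$wcss, 0)
  best
}

#' Within-cluster sum of squares over a range of k
#'
#' For each `k` in `k_min:k_max`, the best WCSS over `restarts` seeded
#' k-means++ Lloyd runs. A deterministic warm start (the best centers for
#' `k - 1` plus the point worst served by them) is always among the
#' candidates, which guarantees the curve is non-increasing in `k`.
#'
#' @param points a `combined_points` tibble, factor-score tibble, or
#'   numeric matrix.
#' @param k_min,k_max range of cluster counts (`1 <= k_min <= k_max <= n`).
#' @param seed integer seed; the curve is deterministic given it.
#' @param restarts k-means++ restarts per `k`.
#' @return A tibble with columns `k` and `wcss`.
#' @export
wcss_curve <- function(points, k_min = 1, k_max = NULL, seed = 1L,
                       restarts = 10) {
  x <- points_matrix(points)
  if (is.null(k_max)) k_max <- min(10, nrow(x) - 1)
  stopifnot(k_min >= 1, k_min <= k_max, k_max <= nrow(x))
  withr::with_seed(seed, {
    prev <- NULL
    rows <- vector("list", k_max - k_min + 1)
    for (k in k_min:k_max) {
      extra <- list()
      if (!is.null(prev)) {
        d2 <- dist2_to_centers(x, prev$centers)
        mind2 <- d2[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))]
        extra <- list(rbind(prev$centers, x[which.max(mind2), ]))
      }
      fit <- best_kmeans_fit(x, k, restarts = restarts, extra_inits = extra)
      rows[[k - k_min + 1]] <- tibble::tibble(k = k, wcss = fit$wcss)
      prev <- fit
    }
    purrr::list_rbind(rows)
  })
}

#' Pick the number of clusters at the elbow of a WCSS curve
#'
#' Normalizes both axes to \[0, 1\] and returns the `k` whose point lies
#' farthest (perpendicular distance) from the chord joining the curve's
#' endpoints — a deterministic formulation of the visual elbow rule. Ties
#' break toward the smaller `k`; a flat curve returns the smallest `k`
#' with a warning.
#'
#' @param curve a tibble with columns `k` and `wcss` (as from
#'   [wcss_curve()]) or a numeric vector named by `k`.
#' @return The selected number of clusters (integer).
#' @export
#' @examples
#' choose_k_elbow(tibble::tibble(k = 1:4, wcss = c(100, 10, 9, 8.5)))
choose_k_elbow <- function(curve) {
  if (is.numeric(curve) && !is.null(names(curve))) {
    curve <- tibble::tibble(k = as.integer(names(curve)), wcss = unname(curve))
  }
  stopifnot(all(c("k", "wcss") %in% names(curve)), nrow(curve) >= 3)
  curve <- dplyr::arrange(curve, .data$k)
  k <- curve$k
  w <- curve$wcss
  if (diff(range(w)) == 0) {
    warning("flat WCSS curve: no elbow, returning smallest k", call. = FALSE)
    return(k[1])
  }
  u <- (k - k[1]) / (k[length(k)] - k[1])
  v <- (w - min(w)) / (max(w) - min(w))
  # distance from (u, v) to the chord between the first and last points
  p1 <- c(u[1], v[1]); p2 <- c(u[length(u)], v[length(v)])
  dvec <- p2 - p1
  dist <- abs(dvec[2] * (u - p1[1]) - dvec[1] * (v - p1[2])) /
    sqrt(sum(dvec^2))
  if (max(dist) < 1e-12) {
    warning("WCSS curve has no elbow (collinear points), returning smallest k",
            call. = FALSE)
    return(k[1])
  }
  k[which.max(dist)]
}

#' Cluster combined points with k-means
#'
#' Lloyd's algorithm from k-means++ seeds, best of `restarts` runs by
#' WCSS, deterministic given `seed`. Cluster labels are canonicalized by
#' decreasing cluster size (ties by first appearance) so reports are
#' stable across runs.
#'
#' @inheritParams wcss_curve
#' @param k number of clusters, or `"auto"` to select it with
#'   [choose_k_elbow()] on a `k_min:k_max` WCSS curve (the curve starts at
#'   `k = 1` so that a two-cluster elbow is detectable; the reported
#'   number of clusters is never below 2).
#' @return A `cluster_report`: list with `assignments` (tibble `id`,
#'   `source`, `cluster`), `cluster_sizes` (tibble `cluster`, `size`),
#'   `chosen_k`, and `wcss_curve` (tibble `k`, `wcss`; a single row when
#'   `k` was fixed).
#' @export
cluster_kmeans <- function(points, k, seed = 1L, restarts = 10,
                           k_min = 1, k_max = NULL) {
  x <- points_matrix(points)
  ids <- points_ids(points)
  src <- if (!is.matrix(points) && "source" %in% names(points)) {
    points$source
  } else rep(NA_character_, nrow(x))

  if (identical(k, "auto")) {
    curve <- wcss_curve(points, k_min = k_min, k_max = k_max, seed = seed,
                        restarts = restarts)
    # the chord-distance rule cannot return an endpoint, so the curve
    # starts at k = 1; at least two population clusters are always reported
    k <- max(choose_k_elbow(curve), 2L)
  } else {
    stopifnot(is.numeric(k), k >= 1, k <= nrow(x))
    curve <- NULL
  }
  fit <- withr::with_seed(seed + 1L,
                          best_kmeans_fit(x, k, restarts = restarts))
  if (is.null(curve)) curve <- tibble::tibble(k = k, wcss = fit$wcss)

  # canonical labels: 1 = largest cluster
  sizes <- tabulate(fit$labels, nbins = k)
  rank_map <- order(order(-sizes, seq_len(k)))
  labels <- rank_map[fit$labels]
  structure(list(
    assignments = tibble::tibble(id = ids, source = src, cluster = labels),
    cluster_sizes = tibble::tibble(cluster = seq_len(k),
                                   size = sort(sizes, decreasing = TRUE)),
    chosen_k = as.integer(k),
    wcss_curve = curve
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d samples in %d clusters (sizes: %s)\n",
              nrow(x$assignments), x$chosen_k,
              paste(x$cluster_sizes$size, collapse = ", ")))
  invisible(x)
}

#' @rdname cluster_kmeans
#' @param x a `cluster_report`.
#' @param ... ignored.
#' @export
tidy.cluster_report <- function(x, ...) x$assignments

#' @rdname cluster_kmeans
#' @export
glance.cluster_report <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$assignments),
    chosen_k = x$chosen_k,
    wcss = x$wcss_curve$wcss[match(x$chosen_k, x$wcss_curve$k)]
  )
}

#' Centralized PCA + k-means benchmark
#'
#' The evaluation ground truth: pools every local dataset with the public
#' panel, fits PCA on the pooled standardized matrix, and clusters the
#' pooled factor scores with k-means — exactly what the federation
#' approximates without ever pooling genotypes. Samples are sorted by id
#' before fitting so the result does not depend on the order the datasets
#' are supplied in.
#'
#' @param locals list of [genotype_matrix] local datasets (may be empty).
#' @param public the public [genotype_matrix] panel.
#' @param n_components number of principal components.
#' @param k number of clusters, or `"auto"`.
#' @param seed integer seed for the clustering.
#' @param restarts k-means++ restarts.
#' @return A `cluster_report` whose assignment ids are raw sample ids.
#' @export
centralized_benchmark <- function(locals, public, n_components = 2, k = "auto",
                                  seed = 1L, restarts = 10) {
  mats <- c(locals, list(public))
  pooled <- bind_genotypes(mats)
  pooled <- pooled[order(sample_ids(pooled)), ]
  model <- fit_pca_model(pooled, n_components)
  scores <- project_samples(model, pooled)
  cluster_kmeans(scores, k = k, seed = seed, restarts = restarts)
}

#' Stack genotype matrices that share a SNP set
#'
#' @param matrices list of [genotype_matrix] objects with identical
#'   `snp_ids` (use [align_snp_sets()] first) and disjoint samples.
#' @return A single [genotype_matrix].
#' @export
bind_genotypes <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- snp_ids(matrices[[1]])
  ok <- vapply(matrices, function(m) identical(snp_ids(m), ref), logical(1))
  if (!all(ok)) stop("matrices do not share an aligned SNP set", call. = FALSE)
  values <- do.call(rbind, lapply(matrices, unclass))
  labs <- unlist(lapply(matrices, function(m) {
    l <- population_labels(m)
    if (is.null(l)) rep(NA_character_, n_samples(m)) else l
  }))
  if (all(is.na(labs))) labs <- NULL
  genotype_matrix(values,
                  sample_ids = unlist(lapply(matrices, sample_ids)),
                  snp_ids = ref,
                  population_labels = labs)
}

#' Match predicted clusters to reference clusters
#'
#' One-to-one assignment between predicted and reference cluster labels
#' maximizing total overlap on the contingency table (Hungarian
#' algorithm). When the partitions have different numbers of clusters, the
#' surplus clusters map to `NA`.
#'
#' @param predicted a `cluster_report`, or a tibble/data frame with
#'   columns `id` and `cluster`.
#' @param truth reference labels: a named vector (names = ids) or a tibble
#'   with columns `id` and `cluster` (or `label`).
#' @return A tibble `predicted_cluster`, `truth_cluster`, `overlap`.
#' @export
match_cluster_labels <- function(predicted, truth) {
  pred <- as_assignment(predicted)
  ref <- as_assignment(truth)
  common <- intersect(pred$id, ref$id)
  if (length(common) == 0) {
    stop("predicted and reference partitions share no sample ids",
         call. = FALSE)
  }
  p <- pred$cluster[match(common, pred$id)]
  t_ <- ref$cluster[match(common, ref$id)]
  tab <- table(factor(p), factor(t_))
  np <- nrow(tab); nt <- ncol(tab)
  n <- max(np, nt)
  padded <- matrix(0, n, n)
  padded[seq_len(np), seq_len(nt)] <- tab
  sol <- clue::solve_LSAP(padded, maximum = TRUE)
  tibble::tibble(
    predicted_cluster = c(rownames(tab), rep(NA_character_, n - np)),
    truth_cluster = {
      cols <- as.integer(sol)
      ifelse(cols <= nt, colnames(tab)[pmin(cols, nt)], NA_character_)
    },
    overlap = as.integer(padded[cbind(seq_len(n), as.integer(sol))])
  ) |>
    dplyr::filter(!is.na(.data$predicted_cluster))
}

as_assignment <- function(x) {
  if (inherits(x, "cluster_report")) {
    tibble::tibble(id = x$assignments$id,
                   cluster = as.character(x$assignments$cluster))
  } else if (is.data.frame(x)) {
    cl <- if ("cluster" %in% names(x)) x$cluster else x$label
    tibble::tibble(id = as.character(x$id), cluster = as.character(cl))
  } else if (!is.null(names(x))) {
    tibble::tibble(id = names(x), cluster = as.character(unname(x)))
  } else {
    stop("cannot interpret labels: supply a cluster_report, a data frame ",
         "with id/cluster, or a named vector", call. = FALSE)
  }
}

#' Clustering agreement metrics against reference labels
#'
#' `score_accuracy()` is the fraction of shared samples whose predicted
#' cluster, after Hungarian matching, agrees with the reference label.
#' `score_precision_recall()` computes, per matched cluster pair,
#' precision (correct members of the predicted cluster over its size) and
#' recall (correct members over the reference cluster's size), then
#' averages both weighted by reference cluster size. A reference cluster
#' with no matched predicted cluster contributes 0 to both. All three
#' metrics are invariant to relabeling of either partition.
#'
#' @inheritParams match_cluster_labels
#' @return `score_accuracy()`: a single fraction.
#'   `score_precision_recall()`: a one-row tibble `precision`, `recall`.
#' @export
score_accuracy <- function(predicted, truth) {
  pred <- as_assignment(predicted)
  ref <- as_assignment(truth)
  common <- intersect(pred$id, ref$id)
  mapping <- match_cluster_labels(predicted, truth)
  p <- pred$cluster[match(common, pred$id)]
  t_ <- ref$cluster[match(common, ref$id)]
  mapped <- mapping$truth_cluster[match(p, mapping$predicted_cluster)]
  mean(!is.na(mapped) & mapped == t_)
}

#' @rdname score_accuracy
#' @export
score_precision_recall <- function(predicted, truth) {
  pred <- as_assignment(predicted)
  ref <- as_assignment(truth)
  common <- intersect(pred$id, ref$id)
  mapping <- match_cluster_labels(predicted, truth)
  p <- pred$cluster[match(common, pred$id)]
  t_ <- ref$cluster[match(common, ref$id)]

  truth_clusters <- sort(unique(t_))
  per <- purrr::map(truth_clusters, function(tc) {
    size_true <- sum(t_ == tc)
    pc <- mapping$predicted_cluster[match(tc, mapping$truth_cluster)]
    if (is.na(pc)) {
      return(tibble::tibble(truth_cluster = tc, size = size_true,
                            precision = 0, recall = 0))
    }
    size_pred <- sum(p == pc)
    correct <- sum(p == pc & t_ == tc)
    tibble::tibble(
      truth_cluster = tc, size = size_true,
      precision = if (size_pred == 0) as.numeric(size_true == 0)
                  else correct / size_pred,
      recall = if (size_true == 0) 1 else correct / size_true
    )
  }) |> purrr::list_rbind()
  tibble::tibble(
    precision = stats::weighted.mean(per$precision, per$size),
    recall = stats::weighted.mean(per$recall, per$size)
  )
}
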