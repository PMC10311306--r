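#' Train the server-side PCA model on a public genotype panel
#'
#' Standardizes the public dosage matrix per SNP (mean 0, sd 1; missing
#' dosages mean-imputed first), takes the top `n_components` right singular
#' vectors of the standardized matrix as the projection matrix `Q`, and
#' calibrates per-component sensitivities as the range (max - min) of the
#' public panel's own factor scores, the quantities later used to scale the
#' Laplace noise. The model is everything a collaborator needs to project
#' local data into the same coordinate system: `Q`, the standardization
#' parameters, the SNP order, and the sensitivities.
#'
#' Each column of `Q` is sign-fixed so its largest-magnitude entry is
#' positive, making training deterministic up to the SVD's numerical
#' tolerance.
#'
#' Two estimators of the per-component sensitivity are supported, because
#' "the range of each principal component over the public panel" admits
#' two readings. `"loadings"` (the default) takes the range of each
#' eigenvector's entries — the principal component itself, in the
#' eigenvector sense; it is nearly invariant to which populations the
#' public panel contains and yields noise on the scale of the projection
#' weights. `"scores"` takes the range of the public panel's factor
#' scores via [compute_sensitivity()]; it is on the scale of the
#' projected coordinates themselves and therefore of the between-population
#' separation, so the resulting noise at practical budgets overwhelms the
#' cluster structure. The vignette discusses the choice.
#'
#' @param public a [genotype_matrix]: the public panel.
#' @param n_components number of principal components `d` to retain.
#' @param sensitivity `"loadings"` or `"scores"` (see above).
#' @return A `pca_model` object.
#' @seealso [project_samples()], [perturb_projection()], [write_pca_model()]
#' @export
fit_pca_model <- function(public, n_components = 2,
                          sensitivity = c("loadings", "scores")) {
  sensitivity <- match.arg(sensitivity)
  stopifnot(inherits(public, "genotype_matrix"), n_components >= 1)
  if (n_samples(public) < n_components + 1 || n_snps(public) < n_components) {
    stop("public panel too small for ", n_components, " components",
         call. = FALSE)
  }
  z <- unclass(public)
  attr(z, "population_labels") <- NULL
  if (anyNA(z)) {
    mu_fill <- colMeans(z, na.rm = TRUE)
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- mu_fill[idx[, 2]]
  }
  means <- colMeans(z)
  scales <- apply(z, 2, stats::sd)
  if (any(scales == 0)) {
    stop("zero-variance SNP(s) in the public panel (e.g. ",
         snp_ids(public)[which(scales == 0)[1]],
         "); run qc_filter() first", call. = FALSE)
  }
  zs <- scale(z, center = means, scale = scales)
  sv <- svd(zs, nu = 0, nv = n_components)
  rank_tol <- max(dim(zs)) * max(sv$d) * .Machine$double.eps
  if (sum(sv$d > rank_tol) < n_components) {
    stop("requested n_components exceeds the rank of the standardized panel",
         call. = FALSE)
  }
  q <- sv$v
  # deterministic sign: largest-magnitude loading positive in each column
  for (j in seq_len(ncol(q))) {
    piv <- which.max(abs(q[, j]))
    if (q[piv, j] < 0) q[, j] <- -q[, j]
  }
  dimnames(q) <- list(snp_ids(public), paste0("PC", seq_len(n_components)))

  model <- structure(list(q_matrix = q,
                          n_components = as.integer(n_components),
                          snp_ids = snp_ids(public),
                          means = stats::setNames(means, snp_ids(public)),
                          scales = stats::setNames(scales, snp_ids(public)),
                          sensitivities = NULL),
                     class = "pca_model")
  model$sensitivities <- switch(sensitivity,
    loadings = {
      s <- apply(q, 2, function(v) max(v) - min(v))
      if (any(s == 0)) {
        stop("degenerate model: constant loading vector", call. = FALSE)
      }
      stats::setNames(s, colnames(q))
    },
    scores = compute_sensitivity(model, project_samples(model, public))
  )
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d SNPs -> %d components\n",
              length(x$snp_ids), x$n_components))
  cat("sensitivities:", format(x$sensitivities, digits = 4), "\n")
  invisible(x)
}

#' Per-component sensitivities from public factor scores
#'
#' The sensitivity of component `j` is estimated as the range
#' `max_i F_ij - min_i F_ij` of that component's factor scores over the
#' public panel. It is the scale reference for the Laplace mechanism: a
#' larger spread of the public scores means more noise is needed per unit
#' of privacy budget.
#'
#' @param model a `pca_model`.
#' @param public_scores factor scores of the public panel, as returned by
#'   [project_samples()].
#' @return Named numeric vector of `d` sensitivities, all strictly positive.
#' @export
compute_sensitivity <- function(model, public_scores) {
  coords <- scores_matrix(public_scores, model$n_components)
  if (nrow(coords) == 0) stop("empty public scores", call. = FALSE)
  s <- apply(coords, 2, function(v) max(v) - min(v))
  if (any(s == 0)) {
    stop("degenerate model: component ", which(s == 0)[1],
         " is constant on the public panel", call. = FALSE)
  }
  stats::setNames(s, paste0("PC", seq_along(s)))
}

#' Project local genotypes through a trained PCA model
#'
#' Standardizes each local sample with the model's training means and
#' scales (never with local statistics, so projections from different
#' parties live in the same coordinate system) and multiplies by the
#' projection matrix `Q`. Missing dosages are imputed with the model's
#' training mean, i.e. 0 after standardization. The local SNP set must
#' equal the model's in order; use [align_snp_sets()] beforehand.
#'
#' @param model a `pca_model`.
#' @param local a [genotype_matrix].
#' @return A tibble of factor scores: `sample_id`, `PC1` ... `PCd`.
#' @export
project_samples <- function(model, local) {
  stopifnot(inherits(model, "pca_model"), inherits(local, "genotype_matrix"))
  if (!identical(snp_ids(local), model$snp_ids)) {
    diff <- which(snp_ids(local) != model$snp_ids[seq_len(n_snps(local))])
    stop("local SNPs do not match the model (first discrepancy at column ",
         if (length(diff)) diff[1] else n_snps(local) + 1, ")", call. = FALSE)
  }
  z <- unclass(local)
  attr(z, "population_labels") <- NULL
  zs <- sweep(sweep(z, 2, model$means, "-"), 2, model$scales, "/")
  zs[is.na(zs)] <- 0
  coords <- zs %*% model$q_matrix
  tibble::as_tibble(coords) |>
    tibble::add_column(sample_id = sample_ids(local), .before = 1)
}

scores_matrix <- function(scores, d = NULL) {
  cols <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  if (!is.null(d)) {
    stopifnot(length(cols) == d)
  }
  as.matrix(scores[cols])
}

#' Laplace random deviates
#'
#' Inverse-CDF sampler for the Laplace distribution with density
#' `pdf(x | mu, lambda) = exp(-|x - mu| / lambda) / (2 lambda)`.
#'
#' @param n number of draws.
#' @param scale scale parameter `lambda` (> 0).
#' @param location location parameter `mu`.
#' @return Numeric vector of `n` draws.
#' @export
rlaplace <- function(n, scale = 1, location = 0) {
  stopifnot(scale > 0)
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log1p(-2 * abs(u))
}

#' Perturb factor scores to achieve epsilon-local differential privacy
#'
#' Adds independent Laplace noise to every coordinate before it leaves the
#' researcher. The total privacy budget `epsilon` is split evenly over the
#' `d` components (each dimension gets `epsilon / d`; for the usual `d = 2`
#' that is `epsilon / 2` per axis), so component `j` receives noise of
#' scale `lambda_j = s_j / (epsilon / d) = s_j d / epsilon`, where `s_j` is
#' the server-provided sensitivity. `epsilon = Inf` is the no-noise
#' sentinel: the scores pass through bit-exactly.
#'
#' @param scores factor scores from [project_samples()].
#' @param epsilon total privacy budget (> 0, or `Inf` for no noise).
#' @param sensitivities per-component sensitivities, usually
#'   `model$sensitivities`.
#' @param seed optional integer seed for the noise draws; by default the
#'   current RNG state is used (deployments should leave this unset so the
#'   noise is unpredictable).
#' @return A tibble with the same shape as `scores`.
#' @export
perturb_projection <- function(scores, epsilon, sensitivities, seed = NULL) {
  if (!(is.infinite(epsilon) || epsilon > 0)) {
    stop("epsilon must be > 0 (or Inf for the no-noise sentinel)",
         call. = FALSE)
  }
  coords <- scores_matrix(scores)
  d <- ncol(coords)
  stopifnot(length(sensitivities) == d)
  if (is.infinite(epsilon)) return(scores)
  lambda <- sensitivities * d / epsilon
  add_noise <- function() {
    for (j in seq_len(d)) {
      coords[, j] <- coords[, j] + rlaplace(nrow(coords), scale = lambda[j])
    }
    coords
  }
  noisy <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  out <- scores
  out[, colnames(coords)] <- tibble::as_tibble(noisy)
  out
}

#' Pseudonymize sample identifiers with SHA-256
#'
#' @param ids character vector of non-empty, unique sample identifiers.
#' @return Character vector of 64-character lowercase hex digests of the
#'   UTF-8 encoded identifiers.
#' @export
#' @examples
#' hash_sample_ids("abc")
hash_sample_ids <- function(ids) {
  stopifnot(is.character(ids), all(nzchar(ids)))
  if (anyDuplicated(ids)) {
    stop("duplicate sample identifiers cannot be pseudonymized into one payload",
         call. = FALSE)
  }
  vapply(enc2utf8(ids), digest::digest,
         FUN.VALUE = character(1), algo = "sha256", serialize = FALSE,
         USE.NAMES = FALSE)
}

#' Assemble the researcher's shared metadata payload
#'
#' Couples the SHA-256 hashed sample identifiers with the noisy factor
#' scores: this payload (hashed id plus `d` noisy coordinates) is the only
#' thing a researcher shares with the server.
#'
#' @param noisy noisy factor scores from [perturb_projection()].
#' @param epsilon the privacy budget that produced them (`Inf` allowed).
#' @return A `noisy_metadata` tibble with columns `hashed_id`,
#'   `coord_1` ... `coord_d`, carrying `epsilon` and `n_components`
#'   attributes.
#' @export
build_metadata <- function(noisy, epsilon) {
  coords <- scores_matrix(noisy)
  if (nrow(coords) == 0) stop("empty factor scores", call. = FALSE)
  if (!(is.infinite(epsilon) || epsilon > 0)) {
    stop("epsilon must be > 0 or Inf", call. = FALSE)
  }
  out <- tibble::tibble(hashed_id = hash_sample_ids(noisy$sample_id))
  colnames(coords) <- paste0("coord_", seq_len(ncol(coords)))
  out <- dplyr::bind_cols(out, tibble::as_tibble(coords))
  new_noisy_metadata(out, epsilon = epsilon, n_components = ncol(coords))
}

new_noisy_metadata <- function(df, epsilon, n_components) {
  structure(df,
            epsilon = epsilon,
            n_components = as.integer(n_components),
            class = c("noisy_metadata", class(tibble::tibble())))
}

#' @export
print.noisy_metadata <- function(x, ...) {
  cat(sprintf("<noisy_metadata> %d samples, d = %d, epsilon = %s\n",
              nrow(x), attr(x, "n_components"),
              format(attr(x, "epsilon"))))
  NextMethod()
}

#' Serialize a PCA model to JSON
#'
#' Writes all model fields (SNP ids, `Q` row-major, standardization means
#' and scales, sensitivities) at full double precision so that
#' `read_pca_model(write_pca_model(m, path))` reproduces the model
#' bit-exactly.
#'
#' @param model a `pca_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  payload <- list(
    format_version = 1L,
    snp_ids = model$snp_ids,
    n_components = model$n_components,
    q_matrix = as.vector(t(model$q_matrix)),
    means = unname(model$means),
    scales = unname(model$scales),
    sensitivities = unname(model$sensitivities)
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(payload$n_components)
  m <- length(payload$snp_ids)
  q <- matrix(payload$q_matrix, nrow = m, ncol = d, byrow = TRUE,
              dimnames = list(payload$snp_ids, paste0("PC", seq_len(d))))
  structure(list(q_matrix = q,
                 n_components = d,
                 snp_ids = payload$snp_ids,
                 means = stats::setNames(payload$means, payload$snp_ids),
                 scales = stats::setNames(payload$scales, payload$snp_ids),
                 sensitivities = stats::setNames(payload$sensitivities,
                                                 paste0("PC", seq_len(d)))),
            class = "pca_model")
}

#' Write and read a metadata payload
#'
#' The payload travels as a CSV (`hashed_id, coord_1, ..., coord_d`) with
#' coordinates serialized at 17 significant digits (bit-exact round-trip
#' for doubles) plus a JSON sidecar `<path>.json` recording the epsilon
#' used and `d`.
#'
#' @param meta a `noisy_metadata` payload.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly (`read_metadata` returns the payload).
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "noisy_metadata"))
  coord_cols <- setdiff(names(meta), "hashed_id")
  lines <- c(paste(c("hashed_id", coord_cols), collapse = ","),
             vapply(seq_len(nrow(meta)), function(i) {
               paste(c(meta$hashed_id[i],
                       sprintf("%.17g", as.numeric(meta[i, coord_cols]))),
                     collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  eps <- attr(meta, "epsilon")
  jsonlite::write_json(list(epsilon = if (is.infinite(eps)) "Inf" else eps,
                            n_components = attr(meta, "n_components")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    hashed_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eps <- if (identical(side$epsilon, "Inf")) Inf else as.numeric(side$epsilon)
  new_noisy_metadata(tibble::as_tibble(df), epsilon = eps,
                     n_components = as.integer(side$n_components))
}

#' Tidy and summarize a PCA model
#'
#' `tidy()` returns one row per SNP per component with the loading;
#' `glance()` returns a one-row summary (SNP count, components,
#' sensitivities).
#'
#' @param x a `pca_model`.
#' @param ... ignored.
#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    snp_id = rep(x$snp_ids, times = x$n_components),
    component = rep(colnames(x$q_matrix), each = length(x$snp_ids)),
    loading = as.vector(x$q_matrix)
  )
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_snps = length(x$snp_ids),
    n_components = x$n_components,
    min_sensitivity = min(x$sensitivities),
    max_sensitivity = max(x$sensitivities)
  )
}
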