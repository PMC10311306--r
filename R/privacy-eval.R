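#' Minimum Euclidean distance from a target to a released payload
#'
#' The attacker's test statistic: the distance from the target's (noise
#' free) projection to the nearest of the released noisy coordinates. A
#' small minimum distance suggests the target is one of the released
#' samples.
#'
#' @param target numeric vector of length `d` (one projected sample), or a
#'   matrix / factor-score tibble of many targets.
#' @param released a `noisy_metadata` payload (or anything
#'   [points_matrix()] accepts).
#' @return One minimum distance per target row.
#' @export
#' @examples
#' rel <- tibble::tibble(coord_1 = c(3, 6), coord_2 = c(4, 8))
#' min_euclidean_distance(c(0, 0), rel)  # 5
min_euclidean_distance <- function(target, released) {
  rel <- points_matrix(released)
  if (nrow(rel) == 0) stop("empty released payload", call. = FALSE)
  tgt <- if (is.numeric(target) && is.null(dim(target))) {
    matrix(target, nrow = 1)
  } else {
    points_matrix(target)
  }
  if (ncol(tgt) != ncol(rel)) {
    stop("dimension mismatch: target has ", ncol(tgt),
         " coordinates, payload has ", ncol(rel), call. = FALSE)
  }
  d2 <- dist2_to_centers(tgt, rel)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Calibrate the attack's distance threshold at a target false-positive rate
#'
#' Given minimum distances of a control set of known non-members, the
#' threshold gamma is the `floor(fpr_target * |G|)`-th smallest control
#' distance, so that at most an `fpr_target` fraction of controls fall
#' strictly below gamma (i.e. at least `1 - fpr_target` of non-members are
#' correctly called out). With fewer than `1 / fpr_target` controls the
#' order statistic degenerates to the minimum and a warning is issued.
#'
#' @param control_min_distances numeric vector of control minimum distances.
#' @param fpr_target target false-positive rate, default 0.05.
#' @return The threshold gamma.
#' @export
calibrate_threshold <- function(control_min_distances, fpr_target = 0.05) {
  stopifnot(fpr_target > 0, fpr_target < 1)
  n <- length(control_min_distances)
  if (n == 0) stop("no control distances", call. = FALSE)
  r <- floor(fpr_target * n)
  if (r < 1) {
    warning("fewer than 1/fpr_target controls; using the minimum distance ",
            "as threshold", call. = FALSE)
    r <- 1
  }
  sort(control_min_distances)[r]
}

#' Membership-inference power of the Euclidean-distance attack
#'
#' Plays the honest-but-curious server: projects known non-members
#' (controls) and true members through the *same* trained model the
#' defenders used — without noise, since the attacker holds the raw
#' genomes — computes each one's minimum distance to the released noisy
#' payload, calibrates the threshold gamma on the controls at
#' `fpr_target`, and reports the fraction of members falling strictly
#' below gamma (the power).
#'
#' @param model the `pca_model` the defenders projected through.
#' @param released the defender's `noisy_metadata` payload.
#' @param member_genotypes [genotype_matrix] of true members of the
#'   released dataset.
#' @param control_genotypes [genotype_matrix] of non-members (disjoint
#'   from the members).
#' @param fpr_target target false-positive rate for the calibration.
#' @return An `attack_result`: list with `threshold`, `power`,
#'   `empirical_fpr`, `fpr_target`, and both distance vectors.
#' @export
mi_power <- function(model, released, member_genotypes, control_genotypes,
                     fpr_target = 0.05) {
  stopifnot(inherits(model, "pca_model"))
  if (length(intersect(sample_ids(member_genotypes),
                       sample_ids(control_genotypes))) > 0) {
    stop("member and control sets must be disjoint", call. = FALSE)
  }
  ctl <- min_euclidean_distance(project_samples(model, control_genotypes),
                                released)
  mem <- min_euclidean_distance(project_samples(model, member_genotypes),
                                released)
  gamma <- calibrate_threshold(ctl, fpr_target)
  structure(list(
    threshold = gamma,
    power = mean(mem < gamma),
    empirical_fpr = mean(ctl < gamma),
    fpr_target = fpr_target,
    control_min_distances = ctl,
    member_min_distances = mem
  ), class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("<attack_result> power %.3f at threshold %.4g (FPR %.3f, target %.2f)\n",
              x$power, x$threshold, x$empirical_fpr, x$fpr_target))
  invisible(x)
}

#' @rdname mi_power
#' @param x an `attack_result`.
#' @param ... ignored.
#' @export
tidy.attack_result <- function(x, ...) {
  tibble::tibble(
    set = rep(c("control", "member"),
              c(length(x$control_min_distances),
                length(x$member_min_distances))),
    min_distance = c(x$control_min_distances, x$member_min_distances),
    flagged = .data$min_distance < x$threshold
  )
}

#' @rdname mi_power
#' @export
glance.attack_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, power = x$power,
                 empirical_fpr = x$empirical_fpr,
                 fpr_target = x$fpr_target,
                 n_controls = length(x$control_min_distances),
                 n_members = length(x$member_min_distances))
}

#' Log-likelihood-ratio statistic over released allele frequencies
#'
#' Contrasts, SNP by SNP, the dataset's minor allele frequencies `a_s`
#' (the released GWAS-style statistics) against a reference population's
#' frequencies `pop_s` at the target's genotype. The default
#' `mode = "per_allele"` treats the two alleles of a diploid genotype as
#' independent Bernoulli draws, contributing
#' `z log(a/pop) + (2 - z) log((1-a)/(1-pop))` for dosage `z` in
#' \{0, 1, 2\}. `mode = "verbatim"` instead weights the second term by
#' `(1 - z)` — the classic single-allele form applied to dosages as-is.
#' Frequencies are clamped away from 0 and 1 by a pseudocount
#' `1 / (2 n + 1)` before taking logs.
#'
#' @param genotype_row dosage vector for the target over the released SNPs.
#' @param dataset_maf per-SNP MAF in the protected dataset (`a_s`).
#' @param reference_maf per-SNP MAF in the reference population (`pop_s`).
#' @param mode `"per_allele"` (default) or `"verbatim"`.
#' @param n_clamp effective sample count for the pseudocount clamp.
#' @return The LRT statistic (a real number; larger = more member-like).
#' @export
lrt_statistic <- function(genotype_row, dataset_maf, reference_maf,
                          mode = c("per_allele", "verbatim"),
                          n_clamp = 100) {
  mode <- match.arg(mode)
  stopifnot(length(dataset_maf) == length(genotype_row),
            length(reference_maf) == length(genotype_row))
  eps <- 1 / (2 * n_clamp + 1)
  a <- pmin(pmax(dataset_maf, eps), 1 - eps)
  p <- pmin(pmax(reference_maf, eps), 1 - eps)
  z <- genotype_row
  keep <- !is.na(z)
  z <- z[keep]; a <- a[keep]; p <- p[keep]
  w2 <- if (mode == "per_allele") 2 - z else 1 - z
  sum(z * log(a / p) + w2 * log((1 - a) / (1 - p)))
}

#' Membership-inference power of the LRT baseline
#'
#' The baseline risk of releasing `l` per-SNP MAF statistics from a
#' dataset: computes the LRT statistic for disjoint member and control
#' sets over the first `l` SNPs in canonical order (or an explicit SNP
#' selection), sets the decision threshold as the `floor(fpr_target * n)`-th
#' largest control statistic (at most `fpr_target` of controls fall
#' strictly above it), and reports the fraction of members strictly above.
#'
#' @param members [genotype_matrix] of individuals in the dataset whose
#'   statistics were released.
#' @param controls [genotype_matrix] of non-members.
#' @param dataset_maf per-SNP MAF of the protected dataset, aligned with
#'   its `snp_ids` (defaults to MAFs estimated from `members`).
#' @param reference_maf per-SNP reference-population MAF, same alignment.
#' @param l number of SNP statistics released.
#' @param fpr_target target false-positive rate.
#' @param snps optional explicit SNP ids to use instead of the first `l`.
#' @param mode passed to [lrt_statistic()].
#' @return An `attack_result` (distances replaced by LRT statistics, with
#'   members above-threshold counted as flagged).
#' @export
lrt_power <- function(members, controls, dataset_maf = NULL, reference_maf,
                      l = 10, fpr_target = 0.05, snps = NULL,
                      mode = "per_allele") {
  if (length(intersect(sample_ids(members), sample_ids(controls))) > 0) {
    stop("member and control sets must be disjoint", call. = FALSE)
  }
  if (is.null(dataset_maf)) {
    dataset_maf <- stats::setNames(snp_stats(members)$maf, snp_ids(members))
  }
  if (l == 0) {
    warning("no statistics released (l = 0): power is 0 by convention",
            call. = FALSE)
    return(structure(list(threshold = 0, power = 0, empirical_fpr = 0,
                          fpr_target = fpr_target,
                          control_min_distances = numeric(0),
                          member_min_distances = numeric(0)),
                     class = "attack_result"))
  }
  sel <- if (is.null(snps)) snp_ids(members)[seq_len(l)] else snps
  stopifnot(all(sel %in% snp_ids(members)), all(sel %in% snp_ids(controls)))
  a <- dataset_maf[sel]
  p <- reference_maf[sel]
  n_clamp <- n_samples(members)
  stat_for <- function(g) {
    cols <- match(sel, snp_ids(g))
    apply(unclass(g)[, cols, drop = FALSE], 1, lrt_statistic,
          dataset_maf = a, reference_maf = p, mode = mode, n_clamp = n_clamp)
  }
  ctl <- stat_for(controls)
  mem <- stat_for(members)
  r <- floor(fpr_target * length(ctl))
  if (r < 1) {
    warning("fewer than 1/fpr_target controls; thresholding at the maximum",
            call. = FALSE)
    r <- 1
  }
  thr <- sort(ctl, decreasing = TRUE)[r]
  structure(list(threshold = thr,
                 power = mean(mem > thr),
                 empirical_fpr = mean(ctl > thr),
                 fpr_target = fpr_target,
                 control_min_distances = ctl,
                 member_min_distances = mem),
            class = "attack_result")
}
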