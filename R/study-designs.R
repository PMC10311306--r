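#' Reference synthetic study designs
#'
#' Four pre-registered end-to-end experiments on Balding-Nichols cohorts,
#' mirroring the evaluation designs the framework is built for. Each runs
#' the full pipeline (simulate, split, QC, align, train, project, perturb,
#' aggregate, cluster, attack) at a scale a laptop handles in seconds to a
#' few minutes; the methods vignette motivates every fixed parameter.
#' All randomness derives from `seed` via [substream_seed()].
#'
#' `study_benchmark_agreement()`: five populations with the two researcher
#' populations dominant in the cohort (as in a public panel whose
#' substructure was defined by its own PCA); researchers hold samples of
#' populations 1 and 2, the public panel contains all five, no noise is
#' added. Returns the clustering accuracy of the federated result against
#' the centralized PCA + k-means benchmark (expected: 1 when the panel
#' covers the local populations).
#'
#' `study_no_noise_power()`: a researcher releases 100 samples without
#' noise; 100 disjoint fresh controls calibrate the Euclidean-attack
#' threshold at 5% FPR. Returns the attack power (expected: exactly 1 —
#' every member's own released point sits at distance 0).
#'
#' `study_elbow_consistency()`: three populations split across two
#' researchers, protocol run at epsilon in \{1, 3, 5\}, WCSS curve over
#' k = 2..10, chord-distance elbow. Returns the per-run selected k and the
#' majority choice (expected: 3, the number of populations).
#'
#' `study_fpr_calibration()`: threshold calibrated on 1000 non-member
#' control distances, then evaluated on 1000 fresh non-members. Returns
#' the empirical false-positive percentage (expected: about 5).
#'
#' @param seed master integer seed.
#' @param n_replicates replicates for the elbow consistency study.
#' @return A list; see each design above. All contain the problem size `n`.
#' @name study_designs
NULL

#' @rdname study_designs
#' @export
study_benchmark_agreement <- function(seed = 1L) {
  cfg <- experiment_config(
    n_populations = 5, samples_per_population = c(60, 60, 20, 20, 20),
    n_snps = 2000, fst = 0.1,
    researchers = list(Ra = c(pop1 = 10, pop2 = 10),
                       Rb = c(pop1 = 9, pop2 = 9)),
    epsilon_grid = Inf, d = 2, k = "auto", n_replicates = 1,
    truth = "benchmark", n_controls = 100,
    seed = substream_seed(seed, "benchmark-agreement"))
  res <- run_experiment(cfg)$results
  list(accuracy = res$accuracy, chosen_k = res$chosen_k, n = 38L)
}

#' @rdname study_designs
#' @export
study_no_noise_power <- function(seed = 1L) {
  g <- simulate_populations(synthetic_config(
    2, c(130, 60), 1000, fst = 0.1,
    seed = substream_seed(seed, "no-noise-power", "sim")))
  fed <- split_federation(g, list(Ra = c(pop1 = 100)))
  controls <- withr::with_seed(
    substream_seed(seed, "no-noise-power", "controls"),
    simulate_from_freqs(attr(g, "allele_freqs")[, 1, drop = FALSE], 100,
                        prefix = "control"))
  al <- align_snp_sets(c(list(qc_filter(fed$public)), fed$locals,
                         list(controls)))
  model <- fit_pca_model(al[[1]], 2)
  released <- build_metadata(
    perturb_projection(project_samples(model, al[[2]]), Inf,
                       model$sensitivities), Inf)
  atk <- mi_power(model, released, member_genotypes = al[[2]],
                  control_genotypes = al[[3]], fpr_target = 0.05)
  list(power = atk$power, empirical_fpr = atk$empirical_fpr, n = 100L)
}

#' @rdname study_designs
#' @export
study_elbow_consistency <- function(seed = 1L, n_replicates = 100) {
  eps_grid <- c(1, 3, 5)
  chosen <- purrr::map(seq_len(n_replicates), function(rep_i) {
    g <- simulate_populations(synthetic_config(
      3, 50, 2000, fst = 0.1,
      seed = substream_seed(seed, "elbow", "sim", rep_i)))
    fed <- split_federation(g, list(Ra = c(pop1 = 15, pop2 = 15),
                                    Rb = c(pop2 = 15, pop3 = 15)))
    al <- align_snp_sets(c(list(qc_filter(fed$public)), fed$locals))
    model <- fit_pca_model(al[[1]], 2)
    vapply(seq_along(eps_grid), function(e_i) {
      eps <- eps_grid[e_i]
      payloads <- list(
        Ra = build_metadata(perturb_projection(
          project_samples(model, al[[2]]), eps, model$sensitivities,
          seed = substream_seed(seed, "elbow", "noise", rep_i, e_i, 1)), eps),
        Rb = build_metadata(perturb_projection(
          project_samples(model, al[[3]]), eps, model$sensitivities,
          seed = substream_seed(seed, "elbow", "noise", rep_i, e_i, 2)), eps))
      pts <- aggregate_metadata(payloads)
      curve <- wcss_curve(pts, k_min = 2, k_max = 10,
                          seed = substream_seed(seed, "elbow", "km",
                                                rep_i, e_i))
      choose_k_elbow(curve)
    }, integer(1))
  })
  ks <- unlist(chosen)
  tab <- sort(table(ks), decreasing = TRUE)
  list(selected_k = as.integer(names(tab)[1]),
       fraction_modal = unname(tab[1]) / length(ks),
       choices = ks, n = length(ks))
}

#' @rdname study_designs
#' @export
study_fpr_calibration <- function(seed = 1L) {
  g <- simulate_populations(synthetic_config(
    2, c(120, 120), 1000, fst = 0.1,
    seed = substream_seed(seed, "fpr", "sim")))
  fed <- split_federation(g, list(Ra = c(pop1 = 60, pop2 = 60)))
  freqs <- attr(g, "allele_freqs")
  nonmembers <- withr::with_seed(
    substream_seed(seed, "fpr", "controls"),
    simulate_from_freqs(freqs, c(1000, 1000), prefix = "nm"))
  al <- align_snp_sets(c(list(qc_filter(fed$public)), fed$locals,
                         list(nonmembers)))
  model <- fit_pca_model(al[[1]], 2)
  eps <- 3
  released <- build_metadata(perturb_projection(
    project_samples(model, al[[2]]), eps, model$sensitivities,
    seed = substream_seed(seed, "fpr", "noise")), eps)
  dists <- min_euclidean_distance(project_samples(model, al[[3]]), released)
  half <- withr::with_seed(substream_seed(seed, "fpr", "split"),
                           sample(length(dists), 1000))
  gamma <- calibrate_threshold(dists[half], fpr_target = 0.05)
  fresh <- dists[-half][seq_len(1000)]
  list(fpr_percent = 100 * mean(fresh < gamma), threshold = gamma,
       n = 1000L)
}
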