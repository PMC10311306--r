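#' Derive a reproducible sub-stream seed
#'
#' Hashes a stage name and any indices into a 31-bit integer seed, so each
#' stage of an experiment gets its own independent, reproducible RNG
#' stream and adding stages never perturbs existing ones.
#'
#' @param seed master integer seed.
#' @param stage stage name (e.g. `"simulate"`).
#' @param ... further indices (replicate number, epsilon index, ...).
#' @return An integer in `[0, 2^28)`.
#' @export
substream_seed <- function(seed, stage, ...) {
  key <- paste(c(seed, stage, ...), collapse = "/")
  hex <- substr(digest::digest(key, algo = "sha256", serialize = FALSE), 1, 7)
  strtoi(hex, base = 16L)
}

#' Configure an end-to-end federation experiment
#'
#' Describes one synthetic study: the generating populations, how samples
#' are split between the researchers and the public panel, the privacy
#' budgets to sweep, and the evaluation settings. Population names are
#' `pop1 ... popN`; each researcher entry is a named count vector just as
#' in [split_federation()]. Samples left over after the researchers take
#' theirs form the server's public training panel.
#'
#' @param n_populations,samples_per_population,n_snps,fst,maf_range
#'   passed to [synthetic_config()] (per-population counts must cover the
#'   researchers' requests plus a non-empty public remainder).
#' @param researchers named list of named count vectors,
#'   e.g. `list(Ra = c(pop1 = 20), Rb = c(pop2 = 18))`.
#' @param epsilon_grid privacy budgets to sweep (positive, `Inf` allowed).
#' @param d number of principal components.
#' @param k `"auto"` (elbow selection) or a fixed cluster count.
#' @param n_replicates independent replicates per epsilon.
#' @param truth `"benchmark"` scores against the centralized PCA + k-means
#'   partition; `"labels"` against the generator's population labels.
#' @param n_controls non-member controls for the membership attack.
#' @param fpr_target attack false-positive-rate target.
#' @param seed master seed; everything downstream derives from it via
#'   [substream_seed()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_populations, samples_per_population, n_snps,
                              fst = 0.1, maf_range = c(0.05, 0.5),
                              researchers, epsilon_grid = c(1, 3, 5, Inf),
                              d = 2, k = "auto", n_replicates = 10,
                              truth = c("benchmark", "labels"),
                              n_controls = 100, fpr_target = 0.05,
                              seed = 1L) {
  truth <- match.arg(truth)
  stopifnot(length(researchers) >= 1, !is.null(names(researchers)),
            all(epsilon_grid > 0), n_replicates >= 1, d >= 1)
  structure(list(n_populations = n_populations,
                 samples_per_population = samples_per_population,
                 n_snps = n_snps, fst = fst, maf_range = maf_range,
                 researchers = researchers, epsilon_grid = epsilon_grid,
                 d = d, k = k, n_replicates = n_replicates, truth = truth,
                 n_controls = n_controls, fpr_target = fpr_target,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run one replicate of the federation protocol
#'
#' The full protocol on given data: train the PCA model on the public
#' panel, project every researcher's local data, perturb at `epsilon`,
#' build the pseudonymized payloads, aggregate at the server, and cluster.
#'
#' @param public public [genotype_matrix] panel.
#' @param locals named list of local [genotype_matrix] datasets.
#' @param epsilon privacy budget (total, split over the `d` components).
#' @param d number of components.
#' @param k `"auto"` or a fixed count.
#' @param seed integer seed (noise and clustering substreams derive from it).
#' @param model optional pre-trained `pca_model` to reuse.
#' @return List with `model`, `payloads`, `points` (`combined_points`) and
#'   `report` (`cluster_report`).
#' @export
run_protocol <- function(public, locals, epsilon, d = 2, k = "auto",
                         seed = 1L, model = NULL) {
  if (is.null(model)) model <- fit_pca_model(public, d)
  payloads <- purrr::imap(locals, function(g, name) {
    scores <- project_samples(model, g)
    noisy <- perturb_projection(scores, epsilon, model$sensitivities,
                                seed = substream_seed(seed, "noise", name))
    build_metadata(noisy, epsilon)
  })
  points <- aggregate_metadata(payloads)
  report <- cluster_kmeans(points, k = k,
                           seed = substream_seed(seed, "cluster"))
  list(model = model, payloads = payloads, points = points, report = report)
}

#' Sweep a federation experiment over epsilon and replicates
#'
#' For every replicate, simulates a fresh Balding-Nichols cohort, splits
#' it into researcher datasets and a public panel, trains the model once,
#' and then runs the protocol at every epsilon in the grid; each run is
#' scored for clustering utility (accuracy, precision, recall against the
#' configured truth) and privacy (Euclidean-attack power against the first
#' researcher's payload, using fresh non-member controls drawn from the
#' same populations). All randomness derives from `cfg$seed` through named
#' sub-streams, so the same config reproduces the same table exactly.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, the per-run table is
#'   written as `results.tsv` and the epsilon-averaged summary as
#'   `summary.json`.
#' @return An `experiment_result`: list of tibbles `results` (one row per
#'   replicate x epsilon) and `summary` (replicate-averaged per epsilon).
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- purrr::map(seq_len(cfg$n_replicates), function(rep_i) {
    sim_cfg <- synthetic_config(
      cfg$n_populations, cfg$samples_per_population, cfg$n_snps,
      fst = cfg$fst, maf_range = cfg$maf_range,
      seed = substream_seed(cfg$seed, "simulate", rep_i))
    g <- simulate_populations(sim_cfg)
    fed <- split_federation(g, cfg$researchers)

    # controls: random non-members of the attacked researcher's dataset,
    # drawn from the whole simulated cohort (other researchers' samples and
    # the public panel included, as in a finite study population)
    r1 <- names(cfg$researchers)[1]
    pool <- setdiff(sample_ids(g), sample_ids(fed$locals[[r1]]))
    if (length(pool) < cfg$n_controls) {
      stop("only ", length(pool), " non-members available for ",
           cfg$n_controls, " controls", call. = FALSE)
    }
    ctl_ids <- withr::with_seed(substream_seed(cfg$seed, "controls", rep_i),
                                sample(pool, cfg$n_controls))
    controls <- g[match(ctl_ids, sample_ids(g)), ]

    # server-side QC on the public panel, then all parties agree on the
    # filtered, canonically ordered SNP set
    aligned <- align_snp_sets(c(list(qc_filter(fed$public)), fed$locals,
                                list(controls)))
    fed$public <- aligned[[1]]
    fed$locals <- stats::setNames(aligned[2:(1 + length(fed$locals))],
                                  names(fed$locals))
    controls <- aligned[[length(aligned)]]
    model <- fit_pca_model(fed$public, cfg$d)

    truth_labels <- switch(cfg$truth,
      labels = {
        ids <- unlist(lapply(fed$locals, sample_ids))
        labs <- unlist(lapply(fed$locals, population_labels))
        stats::setNames(labs, hash_sample_ids(ids))
      },
      benchmark = {
        bench <- centralized_benchmark(
          fed$locals, fed$public, n_components = cfg$d, k = cfg$k,
          seed = substream_seed(cfg$seed, "benchmark", rep_i))
        local_ids <- unlist(lapply(fed$locals, sample_ids))
        keep <- bench$assignments$id %in% local_ids
        stats::setNames(as.character(bench$assignments$cluster[keep]),
                        hash_sample_ids(bench$assignments$id[keep]))
      })

    purrr::map(seq_along(cfg$epsilon_grid), function(e_i) {
      eps <- cfg$epsilon_grid[e_i]
      run <- run_protocol(fed$public, fed$locals, epsilon = eps,
                          d = cfg$d, k = cfg$k,
                          seed = substream_seed(cfg$seed, "protocol",
                                                rep_i, e_i),
                          model = model)
      pr <- score_precision_recall(run$report, truth_labels)
      atk <- mi_power(model, run$payloads[[r1]],
                      member_genotypes = fed$locals[[r1]],
                      control_genotypes = controls,
                      fpr_target = cfg$fpr_target)
      tibble::tibble(
        replicate = rep_i, epsilon = eps, chosen_k = run$report$chosen_k,
        accuracy = score_accuracy(run$report, truth_labels),
        precision = pr$precision, recall = pr$recall,
        power = atk$power, attack_threshold = atk$threshold,
        attack_fpr = atk$empirical_fpr)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  summary <- rows |>
    dplyr::group_by(.data$epsilon) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "precision", "recall", "power", "chosen_k"),
      mean), .groups = "drop")

  res <- structure(list(results = rows, summary = summary, config = cfg),
                   class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(rows, file.path(out_dir, "results.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         digits = NA, dataframe = "rows")
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d runs (%d replicates x %d epsilon values)\n",
              nrow(x$results), max(x$results$replicate),
              length(unique(x$results$epsilon))))
  print(x$summary)
  invisible(x)
}

#' @rdname run_experiment
#' @param x an `experiment_result`.
#' @param ... ignored.
#' @export
tidy.experiment_result <- function(x, ...) x$results

#' @rdname run_experiment
#' @export
glance.experiment_result <- function(x, ...) x$summary
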