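#' Configuration for the Balding-Nichols genotype simulator
#'
#' Under the Balding-Nichols model each SNP has an ancestral minor allele
#' frequency `q` drawn uniformly from `maf_range`; population `k`'s
#' frequency is drawn from `Beta(q (1 - fst) / fst, (1 - q)(1 - fst) / fst)`,
#' so `fst` controls the divergence of the populations from the ancestral
#' pool; each individual's dosage is `Binomial(2, q_k)`.
#'
#' @param n_populations number of populations (>= 1).
#' @param samples_per_population integer vector of per-population sample
#'   counts; recycled to `n_populations` if scalar.
#' @param n_snps number of SNPs.
#' @param fst divergence parameter, strictly between 0 and 1.
#' @param maf_range ancestral-frequency interval, a sub-interval of (0, 0.5].
#' @param missing_rate fraction of dosages set missing, for QC testing;
#'   0 by default.
#' @param seed integer seed making the simulation fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_populations, samples_per_population, n_snps,
                             fst, maf_range = c(0.05, 0.5),
                             missing_rate = 0, seed = 1L) {
  if (length(samples_per_population) == 1) {
    samples_per_population <- rep(samples_per_population, n_populations)
  }
  stopifnot(n_populations >= 1,
            length(samples_per_population) == n_populations,
            all(samples_per_population >= 1),
            n_snps >= 1,
            fst > 0, fst < 1,
            length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_populations = as.integer(n_populations),
                 samples_per_population = as.integer(samples_per_population),
                 n_snps = as.integer(n_snps),
                 fst = fst,
                 maf_range = maf_range,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a structured multi-population genotype matrix
#'
#' Draws a samples x SNPs minor-allele dosage matrix under the
#' Balding-Nichols model described in [synthetic_config()]. Population
#' labels (`"pop1"`, `"pop2"`, ...) are attached as ground truth for
#' evaluation. The per-population allele frequencies and the ancestral
#' frequencies are kept as attributes `allele_freqs` (SNPs x populations)
#' and `ancestral_freqs`, so additional members or non-member controls can
#' be drawn from the same populations with [simulate_from_freqs()].
#'
#' @param cfg a [synthetic_config()].
#' @return A [genotype_matrix] with `population_labels` set.
#' @export
#' @examples
#' g <- simulate_populations(synthetic_config(2, 10, 50, fst = 0.1, seed = 4))
#' table(population_labels(g))
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    q <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    a <- q * (1 - cfg$fst) / cfg$fst
    b <- (1 - q) * (1 - cfg$fst) / cfg$fst
    freqs <- vapply(seq_len(cfg$n_populations),
                    function(k) stats::rbeta(cfg$n_snps, a, b),
                    numeric(cfg$n_snps))
    freqs <- matrix(freqs, nrow = cfg$n_snps)
    colnames(freqs) <- paste0("pop", seq_len(cfg$n_populations))
    g <- draw_genotypes(freqs, cfg$samples_per_population, prefix = "sample")
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(length(g)) < cfg$missing_rate
      m <- unclass(g)
      m[miss] <- NA_real_
      g <- genotype_matrix(m, population_labels = population_labels(g))
    }
    attr(g, "allele_freqs") <- freqs
    attr(g, "ancestral_freqs") <- q
    g
  })
}

#' Draw further genotypes from known population allele frequencies
#'
#' Samples new individuals as `Binomial(2, q_k)` per SNP from the
#' population frequencies of an existing simulation, e.g. to create
#' non-member control sets from the same generating distribution. Uses the
#' current RNG state (seed it with `withr::with_seed()` or `set.seed()`).
#'
#' @param freqs SNPs x populations allele-frequency matrix, as in the
#'   `allele_freqs` attribute of [simulate_populations()].
#' @param samples_per_population per-population counts, aligned with the
#'   columns of `freqs`.
#' @param prefix prefix for the generated sample identifiers.
#' @return A [genotype_matrix] with `population_labels` set.
#' @export
simulate_from_freqs <- function(freqs, samples_per_population,
                                prefix = "extra") {
  stopifnot(is.matrix(freqs),
            length(samples_per_population) == ncol(freqs))
  draw_genotypes(freqs, samples_per_population, prefix = prefix)
}

draw_genotypes <- function(freqs, samples_per_population, prefix) {
  m <- nrow(freqs)
  pops <- colnames(freqs)
  if (is.null(pops)) pops <- paste0("pop", seq_len(ncol(freqs)))
  rows <- purrr::map(seq_along(pops), function(k) {
    n_k <- samples_per_population[k]
    matrix(stats::rbinom(n_k * m, size = 2, prob = rep(freqs[, k], each = n_k)),
           nrow = n_k)
  })
  values <- do.call(rbind, rows)
  labels <- rep(pops, samples_per_population)
  genotype_matrix(values,
                  sample_ids = sprintf("%s_%04d", prefix,
                                       seq_len(nrow(values))),
                  snp_ids = sprintf("snp_%05d", seq_len(m)),
                  population_labels = labels)
}

#' Split a genotype matrix into a federation
#'
#' Partitions the samples of one matrix into disjoint local datasets for
#' each researcher plus a public panel for the server. Each researcher's
#' request is a named integer vector `population -> count`; the public
#' panel receives all remaining samples (optionally restricted to
#' `public_populations`) and must be non-empty.
#'
#' @param g a [genotype_matrix] with `population_labels`.
#' @param researchers named list, one named count vector per researcher,
#'   e.g. `list(Ra = c(pop1 = 20), Rb = c(pop2 = 18))`.
#' @param public_populations optional labels to keep in the public panel;
#'   default keeps every remaining sample.
#' @return A list with elements `public` (a [genotype_matrix]) and
#'   `locals` (named list of [genotype_matrix], one per researcher).
#' @export
split_federation <- function(g, researchers, public_populations = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  labs <- population_labels(g)
  if (is.null(labs)) stop("g must carry population_labels", call. = FALSE)
  available <- split(seq_len(n_samples(g)), labs)

  locals <- list()
  for (r in names(researchers)) {
    want <- researchers[[r]]
    idx <- integer(0)
    for (pop in names(want)) {
      pool <- available[[pop]]
      if (is.null(pool) || length(pool) < want[[pop]]) {
        stop(sprintf("researcher %s requests %d samples of population %s; %d available",
                     r, want[[pop]], pop, length(pool)), call. = FALSE)
      }
      take <- pool[seq_len(want[[pop]])]
      available[[pop]] <- setdiff(pool, take)
      idx <- c(idx, take)
    }
    locals[[r]] <- g[idx, ]
  }

  rest <- sort(unlist(available, use.names = FALSE))
  if (!is.null(public_populations)) {
    rest <- rest[labs[rest] %in% public_populations]
  }
  if (length(rest) == 0) {
    stop("public panel is empty after assigning researcher samples",
         call. = FALSE)
  }
  list(public = g[rest, ], locals = locals)
}
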