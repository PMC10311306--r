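#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds a samples x SNPs minor-allele dosage matrix:
#' every non-missing entry is 0, 1 or 2 (the number of minor alleles the
#' sample carries at that SNP), rows are samples, columns are SNPs in a
#' canonical order shared by all parties of a federation. Optional
#' population labels are carried along for evaluation only and never leave
#' a party.
#'
#' @param values numeric matrix of dosages in \{0, 1, 2\} or `NA`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row. Defaults to existing rownames.
#' @param snp_ids character vector of unique SNP identifiers, one per
#'   column. Defaults to existing colnames.
#' @param population_labels optional character vector of ground-truth
#'   population labels, one per sample.
#'
#' @return An object of class `genotype_matrix`: the dosage matrix with
#'   `sample_ids`/`snp_ids` as dimnames and the labels as an attribute.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0), 2, 2),
#'                      sample_ids = c("s1", "s2"),
#'                      snp_ids = c("rs1", "rs2"))
#' n_samples(g)
genotype_matrix <- function(values, sample_ids = rownames(values),
                            snp_ids = colnames(values),
                            population_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) && nrow(values) == 0) sample_ids <- character(0)
  if (is.null(snp_ids) && ncol(values) == 0) snp_ids <- character(0)
  if (is.null(sample_ids) || is.null(snp_ids)) {
    stop("sample_ids and snp_ids are required (or supply dimnames)",
         call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(snp_ids) != ncol(values)) {
    stop("length(snp_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("duplicate snp_ids", call. = FALSE)
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; first offending value: ",
         values[which(bad)[1]], call. = FALSE)
  }
  if (!is.null(population_labels)) {
    population_labels <- as.character(population_labels)
    if (length(population_labels) != nrow(values)) {
      stop("population_labels must have one entry per sample", call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(values,
            population_labels = population_labels,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  labs <- population_labels(x)
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs", nrow(x), ncol(x)))
  if (!is.null(labs)) {
    tab <- table(labs)
    cat(sprintf("; populations: %s",
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
  nm <- sum(is.na(x))
  if (nm > 0) cat(sprintf("; %d missing dosages", nm))
  cat("\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g,x a `genotype_matrix`.
#' @export
n_samples <- function(g) nrow(g)

#' @rdname genotype_matrix
#' @export
n_snps <- function(g) ncol(g)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(g) rownames(g) %||% character(0)

#' @rdname genotype_matrix
#' @export
snp_ids <- function(g) colnames(g) %||% character(0)

#' @rdname genotype_matrix
#' @export
population_labels <- function(g) attr(g, "population_labels")

#' Subset a genotype matrix, keeping class and labels aligned
#'
#' @param x a `genotype_matrix`.
#' @param i,j row (sample) and column (SNP) indices.
#' @param ... ignored.
#' @param drop ignored; the result is always a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  labs <- population_labels(x)
  m <- unclass(x)
  attr(m, "population_labels") <- NULL
  out <- m[i, j, drop = FALSE]
  if (!is.null(labs)) {
    keep <- seq_len(nrow(m))
    names(keep) <- rownames(m)
    labs <- labs[keep[rownames(out)]]
  }
  genotype_matrix(out, population_labels = labs)
}

#' Per-SNP minor allele frequency and missingness
#'
#' MAF is computed over non-missing genotypes only, as the folded allele
#' frequency `min(f, 1 - f)` where `f` is the mean dosage divided by 2.
#'
#' @param g a `genotype_matrix`.
#' @return A tibble with one row per SNP: `snp_id`, `maf`, `missing_rate`.
#' @export
snp_stats <- function(g) {
  f <- colMeans(g, na.rm = TRUE) / 2
  tibble::tibble(
    snp_id = snp_ids(g),
    maf = pmin(f, 1 - f),
    missing_rate = colMeans(is.na(unclass(g)))
  )
}

#' Tidy a genotype matrix into long form
#'
#' @param x a `genotype_matrix`.
#' @param ... ignored.
#' @return A tibble with columns `sample_id`, `snp_id`, `dosage` and, when
#'   labels are present, `population`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(sample_ids(x), times = ncol(x)),
    snp_id = rep(snp_ids(x), each = nrow(x)),
    dosage = as.vector(unclass(x))
  )
  labs <- population_labels(x)
  if (!is.null(labs)) {
    out$population <- rep(labs, times = ncol(x))
  }
  out
}
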