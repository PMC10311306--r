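#' Read a genotype matrix from VCF or TSV
#'
#' The TSV dialect is the package's own plain-text exchange format: a header
#' row `sample_id` followed by SNP identifiers, then one row per sample with
#' integer dosages (0/1/2) or `NA` for missing. VCF input (4.x, read via
#' vcfR) must carry diploid GT fields; genotypes are converted to
#' minor-allele dosage, where the minor allele of each SNP is determined
#' from the data at hand: if the ALT allele frequency exceeds 0.5 the ALT
#' allele is the major allele and the dosage is flipped to `2 - alt_count`.
#' Ties (frequency exactly 0.5) count ALT as minor. Non-biallelic records
#' are skipped with a warning; `./.` genotypes become `NA`.
#'
#' SNP identity is the VCF ID field, falling back to `CHROM:POS` where ID
#' is missing; genomic coordinates are not used downstream, only a shared
#' ordered SNP list matters.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"vcf"`; inferred from the extension by default.
#' @return A [genotype_matrix].
#' @seealso [write_genotypes()], [qc_filter()], [align_snp_sets()]
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, tsv = read_genotypes_tsv(path), vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!identical(names(df)[1], "sample_id")) {
    stop("malformed genotype TSV: first column must be 'sample_id'",
         call. = FALSE)
  }
  snp_cols <- setdiff(names(df), "sample_id")
  values <- as.matrix(df[snp_cols])
  genotype_matrix(values, sample_ids = df$sample_id, snp_ids = snp_cols)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = dimnames(vcfR::getFIX(vcf)))
  biallelic <- vcfR::is.biallelic(vcf)
  if (any(!biallelic)) {
    warning(sum(!biallelic), " non-biallelic VCF record(s) skipped",
            call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  if (nrow(gt) == 0) stop("no biallelic SNPs in VCF", call. = FALSE)

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])

  # count ALT alleles in each diploid GT (phased or unphased)
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_real_, {
      alleles <- strsplit(x, "[/|]")
      vapply(alleles, function(a) sum(a == "1"), numeric(1))
    })
  }
  dos <- t(apply(gt, 1, alt_count))
  if (ncol(gt) == 1) dos <- matrix(dos, ncol = 1, dimnames = dimnames(gt))

  # orient to the minor allele: flip SNPs where ALT is the major allele
  alt_freq <- rowMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  dos[flip, ] <- 2 - dos[flip, ]

  genotype_matrix(t(dos), sample_ids = colnames(gt), snp_ids = unname(ids))
}

#' Write a genotype matrix as TSV
#'
#' Writes the dialect read by [read_genotypes()]: header
#' `sample_id<TAB>snp...`, one row per sample, dosages as integers and
#' missing entries as the token `NA`. Round-trips bit-identically.
#'
#' @param g a [genotype_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- tibble::as_tibble(unclass(g), .name_repair = "minimal")
  names(df) <- snp_ids(g)
  df <- tibble::add_column(df, sample_id = sample_ids(g), .before = 1)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Quality-control filter on SNPs
#'
#' Keeps only SNPs whose sample minor allele frequency is at least
#' `maf_min` and whose missing fraction is at most `missing_max`; the
#' sample set and the relative SNP order are unchanged. These are the two
#' standard pre-stratification filters (the conventional thresholds are
#' MAF < 0.01 and missingness > 5%). MAF is computed over non-missing
#' genotypes only.
#'
#' @param g a [genotype_matrix].
#' @param maf_min minimum minor allele frequency, in \[0, 0.5\].
#' @param missing_max maximum missing fraction, in \[0, 1\].
#' @return The filtered [genotype_matrix].
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 1, 2, 0, 0, 0, 0), 4, 2),
#'                      sample_ids = paste0("s", 1:4),
#'                      snp_ids = c("keep", "drop"))
#' snp_ids(qc_filter(g))
qc_filter <- function(g, maf_min = 0.01, missing_max = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1)
  st <- snp_stats(g)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$missing_rate <= missing_max
  if (!any(keep)) stop("no SNPs remain after QC filtering", call. = FALSE)
  g[, which(keep)]
}

#' Restrict genotype matrices to their shared SNPs
#'
#' All parties of a federation must agree on the set of SNPs and their
#' order before projecting through a common PCA model. This restricts each
#' matrix to the intersection of their SNP sets and reorders columns to a
#' canonical (lexicographic) order.
#'
#' @param matrices a list of [genotype_matrix] objects (at least two).
#' @return A list of matrices with identical `snp_ids`, same length and
#'   order as the input.
#' @export
align_snp_sets <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  shared <- Reduce(intersect, lapply(matrices, snp_ids))
  if (length(shared) == 0) {
    stop("no SNPs shared by all matrices", call. = FALSE)
  }
  shared <- sort(shared)
  lapply(matrices, function(g) g[, match(shared, snp_ids(g))])
}
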