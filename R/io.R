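# Plain-text interchange: the TSV dosage dialect, protein/covariate
# tables, FUSION-style summary statistics, weight files and truth records.

#' Write and read genotypes in the TSV dosage dialect
#'
#' Two files per prefix: `<prefix>.dosage.tsv` (sample_id column plus one
#' column per SNP, header row of SNP ids, missing as `NA`) and
#' `<prefix>.snps.tsv` (per-SNP metadata).
#'
#' @param G A `genotype_matrix`.
#' @param prefix File path prefix.
#' @return `write_genotypes()` returns the prefix invisibly;
#'   `read_genotypes()` returns a `genotype_matrix`.
#' @export
write_genotypes <- function(G, prefix) {
  d <- data.frame(sample_id = G$samples, G$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, paste0(prefix, ".dosage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(G$snps, paste0(prefix, ".snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(prefix) {
  d <- read.delim(paste0(prefix, ".dosage.tsv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  snps <- read.delim(paste0(prefix, ".snps.tsv"), stringsAsFactors = FALSE)
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- d$sample_id
  new_genotype_matrix(M, snps, d$sample_id)
}

#' Read and write FUSION-style summary statistics
#'
#' Four tab-separated columns `SNP A1 A2 Z`.
#'
#' @param ss A `sumstats` data frame (`snp_id, a1, a2, z`).
#' @param path File path.
#' @return `read_sumstats()` returns a `sumstats` data frame.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp_id, A1 = ss$a1, A2 = ss$a2, Z = ss$z)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  stopifnot(all(c("snp", "a1", "a2", "z") %in% names(d)))
  out <- data.frame(snp_id = d$snp, a1 = d$a1, a2 = d$a2, z = d$z,
                    stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write and read a weight model (TSV + JSON sidecar)
#'
#' The weights go to `<prefix>.weights.tsv`
#' (`snp_id chrom pos a1 a2 weight`); method, cross-validation R-squared,
#' cis/trans counts and gene anchor go to `<prefix>.json`.
#'
#' @param model A `weight_model`.
#' @param prefix File path prefix.
#' @return `read_weight_model()` returns a `weight_model`.
#' @export
write_weight_model <- function(model, prefix) {
  write.table(model$weights, paste0(prefix, ".weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- model[c("aptamer_id", "method", "cv_r2", "n_cis", "n_trans",
                  "gene_chrom", "tss")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_weight_model
#' @export
read_weight_model <- function(prefix) {
  w <- read.delim(paste0(prefix, ".weights.tsv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(c(list(weights = w), meta), class = "weight_model")
}
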