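#' Simulation configuration for the synthetic two-cohort pQTL study
#'
#' Describes the world the generators draw from: a training cohort and an
#' independent validation cohort measured on the same SNP panel, plus an
#' external reference panel used only for LD estimation.  Defaults match the
#' scale of the study the package emulates: 2481 training samples, 820
#' validation samples, and a 1000-Genomes-sized European reference panel
#' (503 samples).
#'
#' SNPs are organized in LD blocks.  Within a block, standardized dosages
#' have correlation `ld_rho^|i-j|`; blocks are mutually independent.  All
#' SNPs in a block share one minor allele frequency drawn from `maf_range`,
#' which keeps the AR(1) correlation target exact for the haplotype Markov
#' chain used by [simulate_genotypes()].
#'
#' @param n_train,n_valid,n_ref Cohort sample sizes (all >= 1).
#' @param n_blocks Number of independent LD blocks.
#' @param n_snps Number of SNPs per block.
#' @param ld_rho AR(1) correlation between adjacent SNPs within a block,
#'   in `[0, 1)`.
#' @param maf_range Length-2 numeric in `(0, 0.5]`; each block's minor
#'   allele frequency is drawn uniformly from this interval.
#' @param seed Integer master seed; every generator derives its stream
#'   from it deterministically.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_train = 100, n_valid = 50, n_ref = 50,
#'                   n_blocks = 2, n_snps = 10, seed = 1)
#' @export
sim_config <- function(n_train = 2481, n_valid = 820, n_ref = 503,
                       n_blocks = 10, n_snps = 50, ld_rho = 0.5,
                       maf_range = c(0.05, 0.5), seed = 1) {
  cfg <- list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
              n_ref = as.integer(n_ref), n_blocks = as.integer(n_blocks),
              n_snps = as.integer(n_snps), ld_rho = as.numeric(ld_rho),
              maf_range = as.numeric(maf_range), seed = as.integer(seed))
  counts <- c(cfg$n_train, cfg$n_valid, cfg$n_ref, cfg$n_blocks, cfg$n_snps)
  if (any(!is.finite(counts)) || any(counts < 1L)) {
    stop("all counts in a sim_config must be >= 1", call. = FALSE)
  }
  if (!is.finite(cfg$ld_rho) || cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    stop("`ld_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("`maf_range` must be an increasing pair within (0, 0.5]",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Planted genetic architecture for one synthetic protein
#'
#' Records the ground truth the proteome generator plants, so recovery tests
#' can compare estimates against it: the causal cis and trans SNPs with
#' their effects on the standardized latent scale, the cis/trans
#' heritability shares, and (for summary-statistic generation) the
#' protein-to-disease effect `gamma` per SD of predicted protein together
#' with the GWAS effective sample size.
#'
#' @param aptamer_id Identifier of the synthetic aptamer.
#' @param causal_cis,causal_trans Data frames with columns `snp_id` and
#'   `effect` (standardized scale); either may have zero rows.
#' @param h2_cis,h2_trans Variance shares in `[0, 1)` with
#'   `h2_cis + h2_trans < 1`.
#' @param gamma Protein-to-disease log-odds-scale slope per SD of
#'   genetically predicted protein (0 under the null).
#' @param gwas_n Effective GWAS sample size.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(aptamer_id, causal_cis, causal_trans,
                         h2_cis, h2_trans, gamma = 0, gwas_n = 4e5) {
  empty <- data.frame(snp_id = character(), effect = numeric())
  causal_cis <- causal_cis %||% empty
  causal_trans <- causal_trans %||% empty
  stopifnot(all(c("snp_id", "effect") %in% names(causal_cis)),
            all(c("snp_id", "effect") %in% names(causal_trans)))
  if (h2_cis < 0 || h2_trans < 0 || h2_cis + h2_trans >= 1) {
    stop("heritability shares must be non-negative with h2_cis + h2_trans < 1",
         call. = FALSE)
  }
  structure(list(aptamer_id = as.character(aptamer_id),
                 causal_cis = causal_cis, causal_trans = causal_trans,
                 h2_cis = as.numeric(h2_cis), h2_trans = as.numeric(h2_trans),
                 gamma = as.numeric(gamma), gwas_n = as.numeric(gwas_n)),
            class = "truth_record")
}
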