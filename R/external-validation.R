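# External validation: apply trained weights to an independent cohort and
# gate models on predicted-vs-measured correlation.

#' Predict protein levels in a new cohort from a weight model
#'
#' `prediction = sum_j w_j * dosage(a1_j)` over the model SNPs found in the
#' cohort.  SNPs stored with swapped alleles contribute the flipped dosage
#' `2 - d`; SNPs with mismatched alleles, strand-ambiguous alleles, or
#' absent from the cohort are dropped.  Missing dosages are mean-imputed
#' per SNP.
#'
#' @param G2 Target-cohort `genotype_matrix`.
#' @param model A `weight_model`.
#' @return Named numeric prediction vector with attribute `n_snps_used`,
#'   or `NULL` (with a message) when no model SNP is usable.
#' @export
predict_protein <- function(G2, model) {
  w <- model$weights
  i <- match(w$snp_id, G2$snps$snp_id)
  pred <- numeric(nrow(G2$dosage))
  used <- 0L
  for (k in seq_len(nrow(w))) {
    j <- i[k]
    if (is.na(j)) next
    b1 <- G2$snps$a1[j]; b2 <- G2$snps$a2[j]
    if (is_ambiguous(w$a1[k], w$a2[k]) || is_ambiguous(b1, b2)) next
    d <- G2$dosage[, j]
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    if (b1 == w$a1[k] && b2 == w$a2[k]) {
      pred <- pred + w$weight[k] * d
    } else if (b1 == w$a2[k] && b2 == w$a1[k]) {
      pred <- pred + w$weight[k] * (2 - d)
    } else {
      next  # allele mismatch
    }
    used <- used + 1L
  }
  if (used == 0L) {
    message("no usable SNP for model ", model$aptamer_id,
            ": validation skipped")
    return(NULL)
  }
  names(pred) <- G2$samples
  attr(pred, "n_snps_used") <- used
  pred
}

#' Validate predictions against measured levels
#'
#' Pearson correlation between predicted and measured adjusted phenotype
#' over paired samples.  The gate uses the signed correlation: a model
#' predicting with the wrong sign fails regardless of magnitude.
#'
#' @param pred Named prediction vector (from [predict_protein()]).
#' @param y2 Named measured adjusted phenotype in the validation cohort.
#' @param r_min Retention gate on the correlation coefficient.
#' @param aptamer_id Identifier carried into the result.
#' @return List `aptamer_id, r, r2, n_used, pass` (class
#'   `validation_result`); `r` is `NA` and `pass` is `FALSE` with a
#'   `reason` when the prediction has zero variance.
#' @export
validate_model <- function(pred, y2, r_min = 0.1,
                           aptamer_id = NA_character_) {
  common <- intersect(names(pred), names(y2))
  if (length(common) < 10L) {
    stop("need at least 10 paired samples for validation", call. = FALSE)
  }
  p <- as.numeric(pred[common])
  m <- as.numeric(y2[common])
  if (sd(p) == 0) {
    return(structure(list(aptamer_id = aptamer_id, r = NA_real_,
                          r2 = NA_real_, n_used = length(common),
                          pass = FALSE, reason = "zero_variance_prediction"),
                     class = "validation_result"))
  }
  r <- cor(p, m)
  structure(list(aptamer_id = aptamer_id, r = r, r2 = r^2,
                 n_used = length(common), pass = r >= r_min),
            class = "validation_result")
}
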