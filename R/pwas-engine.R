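# Summary-statistic association engine: allele harmonization against GWAS
# sumstats, LD matrix estimation from a reference panel, and the
# Z = w'Z / sqrt(w' Sigma w) statistic with missingness and Bonferroni
# rules.

#' Harmonize a weight model against GWAS summary statistics
#'
#' Per model SNP: an exact allele match keeps the summary z; swapped
#' alleles (model a1/a2 equal to sumstats a2/a1) negate it;
#' strand-ambiguous, allele-mismatched or absent SNPs are dropped.
#'
#' @param model A `weight_model`.
#' @param ss Summary statistics data frame `snp_id, a1, a2, z`.
#' @return List with `z` and `w` (aligned over usable SNPs, named by
#'   snp_id), `missing_frac` (dropped / model size) and `disposition`
#'   (per-SNP outcome: `match`, `swap`, `absent`, `ambiguous`,
#'   `mismatch`).
#' @export
harmonize <- function(model, ss) {
  w <- model$weights
  if (nrow(w) == 0L) stop("empty weight model", call. = FALSE)
  i <- match(w$snp_id, ss$snp_id)
  disposition <- character(nrow(w))
  z <- rep(NA_real_, nrow(w))
  for (k in seq_len(nrow(w))) {
    if (is.na(i[k])) {
      disposition[k] <- "absent"
      next
    }
    if (is_ambiguous(w$a1[k], w$a2[k])) {
      disposition[k] <- "ambiguous"
      next
    }
    b1 <- ss$a1[i[k]]; b2 <- ss$a2[i[k]]
    if (b1 == w$a1[k] && b2 == w$a2[k]) {
      disposition[k] <- "match"
      z[k] <- ss$z[i[k]]
    } else if (b1 == w$a2[k] && b2 == w$a1[k]) {
      disposition[k] <- "swap"
      z[k] <- -ss$z[i[k]]
    } else {
      disposition[k] <- "mismatch"
    }
  }
  keep <- !is.na(z)
  list(z = stats::setNames(z[keep], w$snp_id[keep]),
       w = stats::setNames(w$weight[keep], w$snp_id[keep]),
       missing_frac = 1 - sum(keep) / nrow(w),
       disposition = data.frame(snp_id = w$snp_id,
                                disposition = disposition,
                                stringsAsFactors = FALSE))
}

#' Estimate the LD matrix of a SNP set from a reference panel
#'
#' Pearson correlation of mean-imputed dosages over the panel samples.
#' The matrix is repaired to be usable downstream: eigenvalues floored at
#' `floor_ev`, re-symmetrized, and rescaled back to unit diagonal.  SNPs
#' absent from the panel (or with zero dosage variance) are dropped and
#' reported.
#'
#' @param G_ref Reference-panel `genotype_matrix`.
#' @param snp_ids SNPs to include, in the desired order.
#' @param floor_ev Eigenvalue floor for the PSD repair.
#' @return List with `Sigma` (correlation matrix over retained SNPs),
#'   `snp_id`, `sd` (panel dosage standard deviations, used to put
#'   per-allele weights on the standardized scale), and `dropped`.
#' @export
ld_from_panel <- function(G_ref, snp_ids, floor_ev = 1e-8) {
  i <- match(snp_ids, G_ref$snps$snp_id)
  present <- !is.na(i)
  D <- impute_mean(G_ref$dosage[, i[present], drop = FALSE])
  sds <- apply(D, 2, sd)
  ok <- sds > 0
  dropped <- c(snp_ids[!present], snp_ids[present][!ok])
  if (length(dropped) > 0L) {
    message("dropped from LD panel: ", paste(dropped, collapse = ", "))
  }
  D <- D[, ok, drop = FALSE]
  ids <- snp_ids[present][ok]
  if (length(ids) == 0L) {
    return(list(Sigma = matrix(numeric(0), 0, 0), snp_id = character(),
                sd = numeric(), dropped = dropped))
  }
  S <- cor(D)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) < floor_ev) {
    vals <- pmax(ev$values, floor_ev)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    S <- (S + t(S)) / 2
    d <- sqrt(diag(S))
    S <- S / outer(d, d)       # restore unit diagonal
    diag(S) <- 1
  }
  dimnames(S) <- list(ids, ids)
  list(Sigma = S, snp_id = ids, sd = stats::setNames(sds[ok], ids),
       dropped = dropped)
}

#' The summary-statistic association Z score
#'
#' `z_pwas = w'z / sqrt(w' Sigma w)`: the Wald statistic of the
#' genetically predicted protein against the outcome, built from the SNP
#' z-vector and the reference-panel LD matrix.  `w` must be on the same
#' (standardized-dosage) scale as `Sigma`.
#'
#' @param w Weight vector.
#' @param z SNP association z-vector, aligned with `w`.
#' @param Sigma SNP correlation matrix, aligned with `w`.
#' @return The association Z score (scalar).
#' @export
pwas_z <- function(w, z, Sigma) {
  w <- as.numeric(w); z <- as.numeric(z)
  Sigma <- as.matrix(Sigma)
  if (length(w) != length(z) || nrow(Sigma) != length(w) ||
      ncol(Sigma) != length(w)) {
    stop("dimension mismatch among w, z and Sigma", call. = FALSE)
  }
  denom2 <- as.numeric(t(w) %*% Sigma %*% w)
  if (!is.finite(denom2) || denom2 <= 1e-12) {
    stop("degenerate predicted-protein variance (w' Sigma w <= 1e-12)",
         call. = FALSE)
  }
  sum(w * z) / sqrt(denom2)
}

#' Two-sided p-value from an association Z score
#'
#' `p = 2 * (1 - Phi(|z|))`, floored at 1e-300.
#'
#' @param z Z score(s).
#' @return Two-sided p-value(s).
#' @export
pvalue_from_z <- function(z) {
  stopifnot(all(is.finite(z)))
  z_to_p(z)
}

#' Run the association scan over a set of retained models
#'
#' For each model: harmonize against the summary statistics; skip when
#' strictly more than half of the model SNPs are unusable (absent from
#' the sumstats, ambiguous, mismatched, or absent from the LD panel);
#' otherwise estimate the LD matrix over the used SNPs, put the
#' per-allele weights on the standardized scale using panel dosage SDs,
#' and compute the Z score and p-value.  A model is significant when
#' `p < alpha / m` with `m` the number of models actually tested (or when
#' `p <= p_threshold` if an absolute threshold is supplied).
#'
#' @param models List of `weight_model` objects.
#' @param ss Summary statistics (`snp_id, a1, a2, z`).
#' @param panel Reference-panel `genotype_matrix`.
#' @param alpha Family-wise error target for the Bonferroni rule.
#' @param p_threshold Optional absolute significance threshold used
#'   instead of `alpha / m`.
#' @return A `pwas_result` data frame: `aptamer_id, method, n_model_snps,
#'   n_used, missing_frac, z_pwas, p, significant, skip_reason`, with
#'   attributes `n_tested` and `p_cutoff`.
#' @export
run_pwas <- function(models, ss, panel, alpha = 0.05, p_threshold = NULL) {
  if (length(models) == 0L) stop("no model to test", call. = FALSE)
  rows <- lapply(models, function(model) {
    out <- data.frame(aptamer_id = model$aptamer_id,
                      method = model$method %||% NA_character_,
                      n_model_snps = nrow(model$weights),
                      n_used = NA_integer_, missing_frac = NA_real_,
                      z_pwas = NA_real_, p = NA_real_, significant = NA,
                      skip_reason = NA_character_,
                      stringsAsFactors = FALSE)
    h <- harmonize(model, ss)
    ld <- ld_from_panel(panel, names(h$w))
    used <- ld$snp_id
    miss <- 1 - length(used) / nrow(model$weights)
    out$n_used <- length(used)
    out$missing_frac <- miss
    if (miss > 0.5) {                # strictly greater: half is still tested
      out$skip_reason <- "missing_frac_gt_half"
      return(out)
    }
    w_std <- h$w[used] * ld$sd[used]
    z_try <- try(pwas_z(w_std, h$z[used], ld$Sigma), silent = TRUE)
    if (inherits(z_try, "try-error")) {
      out$skip_reason <- "degenerate_variance"
      return(out)
    }
    out$z_pwas <- z_try
    out$p <- pvalue_from_z(z_try)
    out
  })
  res <- do.call(rbind, rows)
  tested <- is.na(res$skip_reason)
  m <- sum(tested)
  cutoff <- if (!is.null(p_threshold)) p_threshold else alpha / max(m, 1L)
  res$significant[tested] <- if (!is.null(p_threshold)) {
    res$p[tested] <= cutoff
  } else {
    res$p[tested] < cutoff
  }
  attr(res, "n_tested") <- m
  attr(res, "p_cutoff") <- cutoff
  class(res) <- c("pwas_result", "data.frame")
  res
}
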