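# Protein preprocessing: log transform, covariate adjustment, rank-based
# inverse normal transformation.

#' Covariate-adjust a raw protein abundance vector
#'
#' Regresses `log(raw)` on an intercept plus age, sex, duration between
#' blood draw and processing, and the first three ancestry principal
#' components, returning the ordinary least-squares residuals.  Samples
#' with any missing covariate are dropped listwise (count reported via the
#' `n_dropped` attribute).
#'
#' @param raw Named positive abundance vector (names are sample ids
#'   matching `covs$sample_id`).
#' @param covs Covariate data frame with columns `sample_id`, `age`, `sex`,
#'   `duration`, `pc1`, `pc2`, `pc3`.
#' @return Named residual vector over retained samples, with attribute
#'   `n_dropped`.
#' @export
adjust_covariates <- function(raw, covs) {
  if (is.null(names(raw))) stop("`raw` must be named by sample id",
                                call. = FALSE)
  bad <- !is.finite(raw) | raw <= 0
  if (any(bad)) {
    stop("non-positive abundance for sample(s): ",
         paste(head(names(raw)[bad], 5), collapse = ", "), call. = FALSE)
  }
  cols <- c("age", "sex", "duration", "pc1", "pc2", "pc3")
  stopifnot(all(c("sample_id", cols) %in% names(covs)))
  i <- match(names(raw), covs$sample_id)
  if (anyNA(i)) stop("samples absent from the covariate table",
                     call. = FALSE)
  C <- covs[i, cols, drop = FALSE]
  ok <- complete.cases(C)
  n_dropped <- sum(!ok)
  y <- log(raw[ok])
  Cm <- as.matrix(C[ok, , drop = FALSE])
  # constant covariates carry no information beyond the intercept; drop
  # them (all constant -> plain centering of log(raw))
  keep_col <- apply(Cm, 2, function(v) diff(range(v)) > 0)
  X <- cbind(`(Intercept)` = 1, Cm[, keep_col, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    sv <- svd(X, nu = 0, nv = 0)$d
    stop(sprintf(
      "rank-deficient covariate design (rank %d of %d, condition %.3g)",
      qrX$rank, ncol(X), max(sv) / max(min(sv), .Machine$double.eps)),
      call. = FALSE)
  }
  res <- qr.resid(qrX, y)
  names(res) <- names(raw)[ok]
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Rank-based inverse normal transformation
#'
#' Maps values through `qnorm((rank - c) / (n - 2c + 1))` with the Blom
#' offset `c = 3/8` and average ranks for ties.  The output preserves the
#' input order, has mean ~0, and its sorted values depend only on `n`.
#'
#' @param x Numeric vector, length >= 3, not all identical.
#' @param offset Rank offset `c` (Blom 3/8 by default).
#' @return Transformed numeric vector (names preserved).
#' @examples
#' rank_inverse_normal(c(5, 2, 9))
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  if (diff(range(x)) == 0) stop("all values identical: ranks degenerate",
                                call. = FALSE)
  r <- rank(x, ties.method = "average")
  out <- qnorm((r - offset) / (n - 2 * offset + 1))
  names(out) <- names(x)
  out
}

#' Prepare adjusted, inverse-normalized phenotypes for a protein panel
#'
#' Runs [adjust_covariates()] then [rank_inverse_normal()] per aptamer
#' column, the transformation every downstream model consumes.
#'
#' @param proteins Samples x aptamers matrix of raw (positive) abundances
#'   with dimnames set.
#' @param covs Covariate table (see [adjust_covariates()]).
#' @param offset INT rank offset.
#' @return Samples x aptamers matrix of adjusted phenotypes.
#' @export
prepare_phenotypes <- function(proteins, covs, offset = 3 / 8) {
  stopifnot(is.matrix(proteins), !is.null(rownames(proteins)))
  out <- apply(proteins, 2, function(col) {
    names(col) <- rownames(proteins)
    rank_inverse_normal(adjust_covariates(col, covs), offset = offset)
  })
  rownames(out) <- rownames(proteins)
  out
}
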