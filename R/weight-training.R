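# Predictor selection and model fitting: marginal scan, cis-FDR / trans
# genome-wide seed selection, 100 kb windows on a pseudo chromosome, and
# the four learners (top1, LASSO, elastic net, BLUP/ridge) with outer
# cross-validation.

#' Marginal single-SNP association scan
#'
#' Simple linear regression of the adjusted phenotype on each SNP's
#' mean-imputed dosage (intercept included).  `z = beta / se`, and the
#' two-sided p uses the large-sample normal, floored at 1e-300.
#' Monomorphic SNPs (zero dosage variance after imputation) are returned
#' with `NA` statistics and reported in the `skipped` attribute.
#'
#' @param G A `genotype_matrix` (optionally subset).
#' @param y Named adjusted phenotype vector; names must match `G$samples`.
#' @return Data frame `snp_id, beta, se, z, p` with attribute `skipped`.
#' @export
marginal_scan <- function(G, y) {
  if (is.null(names(y))) stop("`y` must be named by sample id", call. = FALSE)
  i <- match(G$samples, names(y))
  if (anyNA(i)) stop("samples of G and y are not aligned", call. = FALSE)
  y <- as.numeric(y[i])
  X <- impute_mean(G$dosage)
  n <- length(y)
  sx <- apply(X, 2, sd)
  mono <- sx == 0
  r <- rep(NA_real_, ncol(X))
  r[!mono] <- as.numeric(cor(X[, !mono, drop = FALSE], y))
  r2 <- pmin(r^2, 1 - 1e-12)
  z <- r * sqrt((n - 2) / (1 - r2))
  beta <- r * sd(y) / sx
  se <- beta / z
  se[!is.finite(se)] <- NA_real_
  out <- data.frame(snp_id = G$snps$snp_id, beta = beta, se = se, z = z,
                    p = ifelse(is.na(z), NA_real_, z_to_p(z)),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- G$snps$snp_id[mono]
  out
}

#' Select seed SNPs for one protein
#'
#' Cis SNPs (within 1 Mb of the encoding gene's TSS, on its chromosome)
#' are screened by Benjamini-Hochberg FDR < `cis_fdr` computed over this
#' protein's cis SNPs only; all other SNPs are screened at the
#' genome-wide bound `p <= trans_p` (both comparisons inclusive).
#'
#' @param scan Output of [marginal_scan()].
#' @param snps SNP metadata aligned with `scan` (needs `chrom`, `pos`).
#' @param gene_chrom,tss Encoding gene chromosome and transcription start
#'   site (1-based).
#' @param cis_fdr BH q-value threshold for cis SNPs.
#' @param trans_p P-value threshold for trans SNPs.
#' @param cis_window Half-width of the cis region in bp.
#' @return Data frame `snp_id, chrom, pos, region` (region in
#'   `{"cis","trans"}`); zero rows when nothing passes (the protein is
#'   unmodellable).
#' @export
select_seed_snps <- function(scan, snps, gene_chrom, tss, cis_fdr = 0.05,
                             trans_p = 5e-8, cis_window = 1e6) {
  if (is.na(gene_chrom) || is.na(tss)) {
    stop("unknown TSS: protein cannot be scanned for cis SNPs",
         call. = FALSE)
  }
  stopifnot(identical(scan$snp_id, snps$snp_id))
  usable <- !is.na(scan$p)
  is_cis <- snps$chrom == gene_chrom & abs(snps$pos - tss) <= cis_window
  keep <- logical(nrow(scan))
  ci <- which(is_cis & usable)
  if (length(ci) > 0L) {
    # step-up rule: reject p_(1..k) for the largest k with
    # p_(k) <= k/m * q, i.e. BH-adjusted q-value <= threshold
    q <- p.adjust(scan$p[ci], method = "BH")
    keep[ci] <- q <= cis_fdr
  }
  ti <- which(!is_cis & usable)
  keep[ti] <- scan$p[ti] <= trans_p
  out <- data.frame(snp_id = scan$snp_id[keep], chrom = snps$chrom[keep],
                    pos = snps$pos[keep],
                    region = ifelse(is_cis[keep], "cis", "trans"),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Build merged predictor windows and the pseudo-chromosome map
#'
#' Each seed SNP contributes the half-open interval
#' `[pos - width, pos + width)` (clipped at 1); overlapping or adjacent
#' intervals on one chromosome are merged.  Window blocks, ordered by
#' `(chrom, start)`, are laid end-to-end on a single pseudo chromosome
#' with a 1 Mb spacer between blocks, preserving within-window order and
#' pairwise distances.
#'
#' @param seeds Seed data frame from [select_seed_snps()] (non-empty).
#' @param width Window half-width in bp.
#' @param spacer Gap between pseudo-chromosome blocks in bp.
#' @return Data frame `chrom, start, end, pseudo_start` of class
#'   `selection_windows`.
#' @export
build_windows <- function(seeds, width = 1e5, spacer = 1e6) {
  if (nrow(seeds) == 0L) stop("empty seed set", call. = FALSE)
  per_chrom <- split(seeds, seeds$chrom)
  merged <- do.call(rbind, lapply(per_chrom, function(s) {
    s <- s[order(s$pos), , drop = FALSE]
    start <- pmax(s$pos - width, 1)
    end <- s$pos + width
    keep_start <- start[1]
    out_start <- c(); out_end <- c()
    cur_end <- end[1]
    if (nrow(s) > 1L) {
      for (k in 2L:nrow(s)) {
        if (start[k] <= cur_end) {
          cur_end <- max(cur_end, end[k])
        } else {
          out_start <- c(out_start, keep_start)
          out_end <- c(out_end, cur_end)
          keep_start <- start[k]
          cur_end <- end[k]
        }
      }
    }
    data.frame(chrom = s$chrom[1], start = c(out_start, keep_start),
               end = c(out_end, cur_end))
  }))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  len <- merged$end - merged$start
  merged$pseudo_start <- 1 + cumsum(c(0, head(len + spacer, -1)))
  class(merged) <- c("selection_windows", "data.frame")
  merged
}

#' Map genomic coordinates to the pseudo chromosome (and back)
#'
#' @param windows A `selection_windows` object.
#' @param chrom,pos Coordinates to map.
#' @return `pseudo_position()` returns pseudo coordinates (`NA` outside
#'   every window); `genomic_position()` inverts the map.
#' @export
pseudo_position <- function(windows, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (k in seq_len(nrow(windows))) {
    hit <- chrom == windows$chrom[k] & pos >= windows$start[k] &
      pos < windows$end[k]
    out[hit] <- windows$pseudo_start[k] + (pos[hit] - windows$start[k])
  }
  out
}

#' @rdname pseudo_position
#' @param pseudo Pseudo coordinates to invert.
#' @export
genomic_position <- function(windows, pseudo) {
  chrom <- rep(NA, length(pseudo))
  pos <- rep(NA_real_, length(pseudo))
  for (k in seq_len(nrow(windows))) {
    len <- windows$end[k] - windows$start[k]
    hit <- pseudo >= windows$pseudo_start[k] &
      pseudo < windows$pseudo_start[k] + len
    chrom[hit] <- windows$chrom[k]
    pos[hit] <- windows$start[k] + (pseudo[hit] - windows$pseudo_start[k])
  }
  data.frame(chrom = chrom, pos = pos)
}

#' Extract the predictor submatrix for a set of windows
#'
#' Keeps QC-passing, non-strand-ambiguous SNPs whose position falls inside
#' any window (half-open `[start, end)`), re-addressed on the pseudo
#' chromosome via a `pseudo_pos` metadata column.
#'
#' @param G A `genotype_matrix`.
#' @param windows A `selection_windows` object.
#' @param kept Optional character vector of QC-passing snp_ids (from
#'   [filter_snps()]); defaults to all SNPs in `G`.
#' @return A `genotype_matrix` restricted to the predictors, or `NULL`
#'   with a message when no predictor survives.
#' @export
extract_predictors <- function(G, windows, kept = NULL) {
  snps <- G$snps
  pseudo <- pseudo_position(windows, snps$chrom, snps$pos)
  sel <- !is.na(pseudo) & !is_ambiguous(snps$a1, snps$a2)
  if (!is.null(kept)) sel <- sel & snps$snp_id %in% kept
  if (!any(sel)) {
    message("no usable predictor SNP in the selection windows")
    return(NULL)
  }
  sub <- snps[sel, , drop = FALSE]
  sub$pseudo_pos <- pseudo[sel]
  sub <- sub[order(sub$pseudo_pos), , drop = FALSE]
  new_genotype_matrix(G$dosage[, sub$snp_id, drop = FALSE], sub, G$samples)
}

# Deterministic outer-fold assignment: derived from the seed after sorting
# the sample ids, so the folds are invariant to input sample order.
make_folds <- function(samples, folds, seed) {
  ord <- order(samples)
  ids <- with_seed(derive_seed(seed, 81L), {
    sample(rep_len(seq_len(folds), length(samples)))
  })
  out <- integer(length(samples))
  out[ord] <- ids
  out
}

# Maximum-likelihood h2 of the single-variance-component model
# y = g + e, g ~ N(0, h2 * XX'/m), on standardized X, via the SVD of X
# (m x m workload).  Returns h2-hat and a boundary flag.
estimate_h2_ml <- function(X, y, grid = seq(0.01, 0.99, by = 0.01)) {
  n <- nrow(X); m <- ncol(X)
  sv <- svd(X, nv = 0)
  d2 <- sv$d^2 / m                      # nonzero eigenvalues of XX'/m
  uty2 <- as.numeric(crossprod(sv$u, y))^2
  rss0 <- sum(y^2) - sum(uty2)          # component orthogonal to col(X)
  r <- length(d2)
  ll <- vapply(grid, function(h2) {
    vals <- h2 * d2 + (1 - h2)
    s2 <- (sum(uty2 / vals) + rss0 / (1 - h2)) / n
    -0.5 * (n * log(s2) + sum(log(vals)) + (n - r) * log(1 - h2) + n)
  }, numeric(1))
  best <- which.max(ll)
  list(h2 = grid[best], boundary = best == 1L || best == length(grid))
}

# Ridge solution on standardized X with penalty lambda (SNP-space solve).
ridge_weights <- function(X, y, lambda) {
  m <- ncol(X)
  XtX <- crossprod(X) + diag(lambda, m)
  as.numeric(solve(XtX, crossprod(X, y)))
}

# Fit one learner on (standardized) training data; returns standardized
# weights (named) or NULL when the method cannot produce a model.
fit_one_method <- function(method, X, y, inner_foldid) {
  m <- ncol(X)
  w <- switch(method,
    top1 = {
      sx <- apply(X, 2, sd)
      usable <- sx > 0
      if (!any(usable)) return(NULL)
      r <- rep(NA_real_, m)
      r[usable] <- as.numeric(cor(X[, usable, drop = FALSE], y))
      n <- nrow(X)
      r2 <- pmin(r^2, 1 - 1e-12)
      z <- r * sqrt((n - 2) / (1 - r2))
      p <- z_to_p(z)
      # ties: smallest p, then largest |z|, then lexicographic snp_id
      ord <- order(p, -abs(z), colnames(X), na.last = TRUE)
      j <- ord[1L]
      if (is.na(p[j])) return(NULL)
      w <- numeric(m)
      w[j] <- as.numeric(cor(X[, j], y)) * sd(y) / sd(X[, j])
      w
    },
    lasso = ,
    enet = {
      if (m < 2L) return(NULL)          # glmnet requires >= 2 columns
      alpha <- if (method == "lasso") 1 else 0.5
      fit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = inner_foldid,
                               standardize = FALSE)
      as.numeric(coef(fit, s = "lambda.min"))[-1L]
    },
    blup = {
      est <- estimate_h2_ml(X, y)
      if (est$boundary) {
        if (m < 2L) return(NULL)
        fit <- glmnet::cv.glmnet(X, y, alpha = 0, foldid = inner_foldid,
                                 standardize = FALSE)
        as.numeric(coef(fit, s = "lambda.min"))[-1L]
      } else {
        ridge_weights(X, y, m * (1 - est$h2) / est$h2)
      }
    }
  )
  if (is.null(w) || all(w == 0)) return(NULL)
  names(w) <- colnames(X)
  w
}

#' Fit the four prediction learners with outer cross-validation
#'
#' Fits top1 (single most significant marginal SNP), LASSO, elastic net
#' (mixing 0.5) and BLUP (ridge with shrinkage from a one-component ML
#' variance estimate, falling back to CV-chosen ridge at the grid
#' boundary) on standardized dosages, and reports each method's
#' out-of-fold R-squared: the squared correlation between the phenotype
#' and predictions assembled over `folds` outer folds with a fold
#' assignment derived deterministically from `seed` and the sorted sample
#' ids.  Final weights are refit on the full data.
#'
#' @param G A predictor `genotype_matrix` (e.g. from
#'   [extract_predictors()]).
#' @param y Named adjusted phenotype.
#' @param folds Number of outer folds.
#' @param seed Integer seed (outer and inner fold assignment).
#' @return List per method with `weights_std` (standardized-dosage scale),
#'   `weights` (per-allele scale, training-sd converted), `cv_r2`, or
#'   `NULL` for methods that produced no model; plus attributes
#'   `snps` and `folds`.
#' @export
fit_models <- function(G, y, folds = 5, seed = 1) {
  i <- match(G$samples, names(y))
  if (anyNA(i)) stop("samples of G and y are not aligned", call. = FALSE)
  y <- as.numeric(y[i])
  n <- length(y)
  if (n <= folds) stop("need more samples than folds", call. = FALSE)
  X0 <- impute_mean(G$dosage)
  methods <- c("top1", "lasso", "enet", "blup")
  fold_id <- make_folds(G$samples, folds, seed)
  inner_all <- make_folds(G$samples, folds, derive_seed(seed, 91L))
  oof <- matrix(NA_real_, n, length(methods),
                dimnames = list(NULL, methods))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    mu <- colMeans(X0[tr, , drop = FALSE])
    sx <- apply(X0[tr, , drop = FALSE], 2, sd)
    usable <- sx > 0
    if (!any(usable)) next
    std <- function(M) {
      sweep(sweep(M[, usable, drop = FALSE], 2, mu[usable]), 2,
            sx[usable], "/")
    }
    Xtr <- std(X0[tr, , drop = FALSE])
    Xte <- std(X0[!tr, , drop = FALSE])
    inner <- make_folds(G$samples[tr], folds, derive_seed(seed, 91L + f))
    for (mth in methods) {
      w <- fit_one_method(mth, Xtr, y[tr], inner)
      # a fold where the learner selects nothing predicts the constant 0
      # (the centered training mean), not a dropped sample block
      oof[!tr, mth] <- if (is.null(w)) 0 else as.numeric(Xte %*% w)
    }
  }
  cv_r2 <- vapply(methods, function(mth) {
    pr <- oof[, mth]
    if (all(is.na(pr)) || sd(pr, na.rm = TRUE) == 0) return(0)
    ok <- !is.na(pr)
    cor(pr[ok], y[ok])^2
  }, numeric(1))
  # final fits on the full data
  mu <- colMeans(X0)
  sx <- apply(X0, 2, sd)
  usable <- sx > 0
  Xf <- sweep(sweep(X0[, usable, drop = FALSE], 2, mu[usable]), 2,
              sx[usable], "/")
  out <- lapply(methods, function(mth) {
    w <- fit_one_method(mth, Xf, y, inner_all)
    if (is.null(w)) return(NULL)
    w_allele <- w / sx[usable][names(w)]
    list(method = mth, weights_std = w, weights = w_allele,
         cv_r2 = unname(cv_r2[mth]))
  })
  names(out) <- methods
  for (mth in methods) {
    if (!is.null(out[[mth]])) out[[mth]]$cv_r2 <- unname(cv_r2[mth])
  }
  attr(out, "snps") <- G$snps
  attr(out, "folds") <- fold_id
  attr(out, "cv_r2") <- cv_r2
  out
}

#' Choose the best learner and gate on prediction performance
#'
#' Returns the method with maximal out-of-fold R-squared; ties are broken
#' by the fixed order top1 < lasso < enet < blup (sparser preferred).
#' When the maximum is below `r2_min` the protein is rejected.
#'
#' @param fits Output of [fit_models()].
#' @param r2_min Retention gate on cross-validated R-squared.
#' @param aptamer_id,gene_chrom,tss Metadata stored on the model.
#' @return A `weight_model` (list: `aptamer_id`, `method`, `weights` data
#'   frame `snp_id, chrom, pos, a1, a2, weight` on the per-allele scale,
#'   `cv_r2`, `n_cis`, `n_trans`), or a rejection list
#'   (`rejected = TRUE`, `reason`, `cv_r2`).
#' @export
choose_best <- function(fits, r2_min = 0.01, aptamer_id = NA_character_,
                        gene_chrom = NA, tss = NA) {
  methods <- c("top1", "lasso", "enet", "blup")
  avail <- methods[!vapply(fits[methods], is.null, logical(1))]
  if (length(avail) == 0L) {
    return(list(rejected = TRUE, reason = "no_method_fit", cv_r2 = NA_real_,
                aptamer_id = aptamer_id))
  }
  r2 <- vapply(fits[avail], function(f) f$cv_r2, numeric(1))
  best <- avail[which.max(r2)]          # which.max keeps the first on ties
  if (max(r2) < r2_min) {
    return(list(rejected = TRUE, reason = "cv_r2_below_threshold",
                cv_r2 = max(r2), aptamer_id = aptamer_id))
  }
  f <- fits[[best]]
  snps <- attr(fits, "snps")
  nz <- f$weights[f$weights != 0]
  i <- match(names(nz), snps$snp_id)
  wdf <- data.frame(snp_id = names(nz), chrom = snps$chrom[i],
                    pos = snps$pos[i], a1 = snps$a1[i], a2 = snps$a2[i],
                    weight = as.numeric(nz), stringsAsFactors = FALSE)
  is_cis <- if (is.na(gene_chrom) || is.na(tss)) {
    rep(NA, nrow(wdf))
  } else {
    wdf$chrom == gene_chrom & abs(wdf$pos - tss) <= 1e6
  }
  structure(list(aptamer_id = aptamer_id, method = best, weights = wdf,
                 cv_r2 = f$cv_r2,
                 n_cis = if (all(is.na(is_cis))) NA_integer_ else sum(is_cis),
                 n_trans = if (all(is.na(is_cis))) NA_integer_
                           else sum(!is_cis),
                 gene_chrom = gene_chrom, tss = tss),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("weight_model %s: %s, %d SNPs (%s cis / %s trans), cv R2 = %.3f\n",
              x$aptamer_id, x$method, nrow(x$weights),
              x$n_cis, x$n_trans, x$cv_r2))
  invisible(x)
}

#' Train a prediction model for one protein, end to end
#'
#' Marginal scan, cis-FDR / trans genome-wide seed selection, 100 kb
#' window construction on the pseudo chromosome, predictor extraction
#' (QC-passing, non-ambiguous), four-learner fitting and best-model
#' selection.
#'
#' @param G Training `genotype_matrix` (post-QC metadata available).
#' @param y Named adjusted phenotype for one aptamer.
#' @param gene_chrom,tss Encoding gene chromosome and TSS.
#' @param kept QC-passing snp_ids (default all).
#' @param aptamer_id Identifier stored on the model.
#' @param folds,seed Cross-validation controls.
#' @param cis_fdr,trans_p,window_width,r2_min Selection and retention
#'   parameters.
#' @return A `weight_model`, or a rejection list whose `reason` is one of
#'   `no_seed_snps`, `no_predictors`, `no_method_fit`,
#'   `cv_r2_below_threshold`.
#' @export
train_protein <- function(G, y, gene_chrom, tss, kept = NULL,
                          aptamer_id = "protein", folds = 5, seed = 1,
                          cis_fdr = 0.05, trans_p = 5e-8,
                          window_width = 1e5, r2_min = 0.01) {
  scan <- marginal_scan(G, y)
  seeds <- select_seed_snps(scan, G$snps, gene_chrom, tss,
                            cis_fdr = cis_fdr, trans_p = trans_p)
  if (nrow(seeds) == 0L) {
    return(list(rejected = TRUE, reason = "no_seed_snps",
                aptamer_id = aptamer_id, cv_r2 = NA_real_))
  }
  windows <- build_windows(seeds, width = window_width)
  pred <- extract_predictors(G, windows, kept = kept)
  if (is.null(pred)) {
    return(list(rejected = TRUE, reason = "no_predictors",
                aptamer_id = aptamer_id, cv_r2 = NA_real_))
  }
  fits <- fit_models(pred, y, folds = folds, seed = seed)
  choose_best(fits, r2_min = r2_min, aptamer_id = aptamer_id,
              gene_chrom = gene_chrom, tss = tss)
}
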