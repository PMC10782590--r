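# Per-SNP quality control: Hardy-Weinberg exact test, summary statistics,
# and the variant filters applied before model training.

#' Hardy-Weinberg exact test
#'
#' Exact (conditional) test of Hardy-Weinberg proportions from genotype
#' counts: conditional on the observed allele counts, the p-value is the
#' sum of probabilities of all heterozygote configurations no more probable
#' than the observed one.  Computed with the numerically stable
#' mode-outward recurrence on hard-call counts; no mid-p correction.
#'
#' The chi-square approximation is anticonservative at low minor allele
#' frequency in the tail where the filtering threshold (5e-6) lives, which
#' is why the exact test is used.
#'
#' @param n_hom1 Count of homozygotes for the first allele.
#' @param n_het Count of heterozygotes.
#' @param n_hom2 Count of homozygotes for the second allele.
#' @return The exact-test p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(1, 2, 1)   # modal configuration: p = 1
#' hwe_exact_test(2, 0, 2)   # 6/70
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero", call. = FALSE)
  rare <- as.integer(2 * min(n_hom1, n_hom2) + n_het)
  obs_het <- as.integer(n_het)
  het_max <- min(rare, 2L * n - rare)
  if (het_max == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, het_max, by = 2L)
  probs <- numeric(length(hets))
  names(probs) <- hets
  # start at (an even-shifted neighbour of) the expected het count
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  mid <- min(max(mid, hets[1L]), het_max)
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # downward: P(h-2) = P(h) * h(h-1) / (4 (homr+1)(homc+1))
  h <- mid
  homr <- (rare - h) / 2
  homc <- n - h - homr
  if (i_mid > 1L) {
    for (i in seq(i_mid - 1L, 1L)) {
      probs[i] <- probs[i + 1L] * h * (h - 1) /
        (4 * (homr + 1) * (homc + 1))
      h <- h - 2L
      homr <- homr + 1
      homc <- homc + 1
    }
  }
  # upward: P(h+2) = P(h) * 4 homr homc / ((h+2)(h+1))
  h <- mid
  homr <- (rare - h) / 2
  homc <- n - h - homr
  if (i_mid < length(hets)) {
    for (i in seq(i_mid + 1L, length(hets))) {
      probs[i] <- probs[i - 1L] * 4 * homr * homc / ((h + 2) * (h + 1))
      h <- h + 2L
      homr <- homr - 1
      homc <- homc - 1
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(obs_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Is a SNP strand-ambiguous?
#'
#' A/T and C/G pairs cannot be strand-resolved from alleles alone; they are
#' excluded from predictors and dropped during harmonization.
#'
#' @param a1,a2 Allele characters (vectorized); must be A, C, G or T.
#' @return Logical vector.
#' @export
is_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  ok <- a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("unsupported allele code: ",
         paste(unique(c(a1, a2)[!c(ok, ok)]), collapse = ", "),
         call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(a2 == comp[a1])
}

#' Compute per-SNP summary statistics
#'
#' Populates `maf`, `missing_rate` and `hwe_p` in the SNP metadata from the
#' dosage matrix.  MAF is computed on non-missing entries; the HWE exact
#' test is run on hard calls (dosages rounded to the nearest integer).
#' SNPs with every entry missing are flagged (`all_missing = TRUE`) with
#' undefined MAF rather than dropped.
#'
#' @param G A `genotype_matrix`.
#' @return `G` with updated `snps` metadata (adds an `all_missing` column).
#' @export
compute_snp_stats <- function(G) {
  D <- G$dosage
  n <- nrow(D)
  miss <- colMeans(is.na(D))
  all_missing <- miss >= 1
  freq <- suppressWarnings(colMeans(D, na.rm = TRUE) / 2)
  maf <- pmin(freq, 1 - freq)
  maf[all_missing] <- NA_real_
  hwe <- vapply(seq_len(ncol(D)), function(j) {
    if (all_missing[j]) return(NA_real_)
    hc <- round(pmin(pmax(D[, j], 0), 2))
    hc <- hc[!is.na(hc)]
    hwe_exact_test(sum(hc == 0), sum(hc == 1), sum(hc == 2))
  }, numeric(1))
  G$snps$maf <- as.numeric(maf)
  G$snps$missing_rate <- as.numeric(miss)
  G$snps$hwe_p <- hwe
  G$snps$all_missing <- as.logical(all_missing)
  G
}

#' Default variant-filter thresholds
#'
#' The filters applied to imputed variants before training: imputation
#' info >= 0.7, MAF >= 0.05, HWE exact p >= 5e-6, missing rate < 0.05, and
#' presence in the LD reference panel.
#'
#' @param info,maf,hwe_p,missing Threshold values.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(info = 0.7, maf = 0.05, hwe_p = 5e-6,
                          missing = 0.05) {
  list(info = info, maf = maf, hwe_p = hwe_p, missing = missing)
}

#' Filter SNPs on the standard variant criteria
#'
#' A SNP is kept iff `info >= 0.7` and `maf >= 0.05` and `hwe_p >= 5e-6`
#' and `missing_rate < 0.05` and it is present in the reference panel (all
#' thresholds configurable).  Exclusion counts attribute each dropped SNP
#' to every criterion it fails, so the per-criterion counts can exceed the
#' number of dropped SNPs when violations overlap.
#'
#' @param snps SNP metadata data frame with populated statistics (see
#'   [compute_snp_stats()]).
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `kept` (character vector of kept snp_ids), `counts`
#'   (named integer vector of per-criterion exclusion counts) and `flags`
#'   (per-SNP pass/fail data frame).
#' @export
filter_snps <- function(snps, thresholds = qc_thresholds()) {
  need <- c("snp_id", "info", "maf", "hwe_p", "missing_rate",
            "in_reference_panel")
  missing_cols <- setdiff(need, names(snps))
  if (length(missing_cols) > 0L) {
    stop("SNP metadata lacks: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_stats <- !is.finite(snps$maf) | !is.finite(snps$hwe_p)
  if (any(bad_stats & !(snps$all_missing %||% FALSE))) {
    stop("uncomputed statistics for SNP(s): ",
         paste(head(snps$snp_id[bad_stats], 5), collapse = ", "),
         call. = FALSE)
  }
  fail <- data.frame(
    snp_id = snps$snp_id,
    fail_info = snps$info < thresholds$info,
    fail_maf = !(snps$maf >= thresholds$maf) | bad_stats,
    fail_hwe = !(snps$hwe_p >= thresholds$hwe_p) | bad_stats,
    fail_missing = !(snps$missing_rate < thresholds$missing),
    fail_panel = !snps$in_reference_panel,
    stringsAsFactors = FALSE
  )
  crit <- c("fail_info", "fail_maf", "fail_hwe", "fail_missing",
            "fail_panel")
  keep <- !Reduce(`|`, fail[crit])
  counts <- vapply(fail[crit], sum, integer(1))
  names(counts) <- sub("^fail_", "", names(counts))
  list(kept = snps$snp_id[keep], counts = counts,
       flags = cbind(fail, keep = keep))
}
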