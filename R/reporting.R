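# Reporting: association summaries, risk-SNP distance annotation, and
# consistency checks on the packaged published association table.

#' Summarize an association result table
#'
#' Counts tested, skipped and significant models, and splits the
#' significant set by the sign of the association Z score.
#'
#' @param results A `pwas_result` data frame (see [run_pwas()]) or any
#'   data frame with `z_pwas`, `significant` and `skip_reason` columns.
#' @return List `n_tested, n_skipped, n_significant, n_positive,
#'   n_negative`.
#' @export
summarize_associations <- function(results) {
  if (nrow(results) == 0L) stop("empty result table", call. = FALSE)
  skipped <- !is.na(results$skip_reason)
  sig <- !skipped & !is.na(results$significant) & results$significant
  list(n_tested = sum(!skipped), n_skipped = sum(skipped),
       n_significant = sum(sig),
       n_positive = sum(sig & results$z_pwas > 0),
       n_negative = sum(sig & results$z_pwas < 0))
}

#' Distance from a gene's TSS to the closest known risk SNP
#'
#' Minimum `|pos - tss| / 1000` over the risk SNPs on the gene's
#' chromosome, reported to two decimals; `NA` when no risk SNP was
#' reported on that chromosome.
#'
#' @param gene_chrom,tss Gene chromosome and transcription start site.
#' @param risk Risk-SNP data frame with columns `snp_id`, `chrom`, `pos`.
#' @return Distance in kb (2 decimals) or `NA`.
#' @export
annotate_distance <- function(gene_chrom, tss, risk) {
  stopifnot(all(c("chrom", "pos") %in% names(risk)))
  on_chrom <- risk$pos[risk$chrom == gene_chrom]
  if (length(on_chrom) == 0L) return(NA_real_)
  round(min(abs(on_chrom - tss)) / 1000, 2)
}

#' Load the packaged published association table
#'
#' The 69 significant protein-AD associations shipped with the package
#' (SOMAmer id, encoding gene, modeling method, SNP counts, internal and
#' external R-squared, association Z score, p-value, distance to the
#' nearest risk SNP).  Rows whose p-value was published only as an upper
#' bound carry `p_censored = TRUE`.
#'
#' @return Data frame with 69 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_associations.tsv",
                      package = "protwas", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Consistency checks on the published association table
#'
#' Verifies, per row, that the printed p-value matches
#' `2 * (1 - Phi(|z|))` computed from the printed Z score; that every row
#' clears the published Bonferroni threshold; and that the
#' positive/negative direction split is 45/24.  Because Z scores are
#' printed to two decimals, the relative tolerance for the p check is the
#' larger of 5% and the worst-case effect of that rounding,
#' `exp(0.005 * |z|) - 1`; rows with censored p-values are checked as
#' bounds (computed p at or below the printed bound).  The threshold
#' check uses `<=` at printed precision.
#'
#' @param tab Association table (defaults to the packaged one).
#' @param p_threshold Published significance threshold.
#' @return List of checks, each with a `pass` flag: `pz_consistency`
#'   (with per-row failures), `bonferroni`, `direction_split`; plus
#'   `all_pass`.
#' @export
check_table1 <- function(tab = load_table1(), p_threshold = 3.01e-5) {
  need <- c("z", "p", "p_censored")
  if (!all(need %in% names(tab))) {
    stop("malformed table: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p_calc <- pvalue_from_z(tab$z)
  tol <- pmax(0.05, exp(0.005 * abs(tab$z)) - 1)
  ok <- ifelse(tab$p_censored,
               p_calc <= tab$p,
               abs(p_calc - tab$p) / tab$p <= tol)
  pz <- list(pass = all(ok), failures = tab$somamer_id[!ok])
  bonf <- list(pass = all(tab$p <= p_threshold))
  n_pos <- sum(tab$z > 0); n_neg <- sum(tab$z < 0)
  split <- list(pass = n_pos == 45L && n_neg == 24L,
                n_positive = n_pos, n_negative = n_neg)
  list(pz_consistency = pz, bonferroni = bonf, direction_split = split,
       all_pass = pz$pass && bonf$pass && split$pass)
}
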