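# Shared fixture builders; everything is generated in code under fixed
# seeds, nothing is stored on disk except the published association table.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_train = 200, n_valid = 100, n_ref = 100,
                   n_blocks = 2, n_snps = 10, ld_rho = 0.5, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A tiny trained world: genotypes, covariates, one protein with planted
# cis architecture, adjusted phenotype.
make_world <- function(h2_cis = 0.4, n_train = 600, n_snps = 20,
                       seed = 42, n_cis = 3) {
  cfg <- small_config(n_train = n_train, n_snps = n_snps, seed = seed)
  G <- simulate_genotypes(cfg, "train")
  truth <- make_truth(G, cfg, h2_cis = h2_cis, n_cis = n_cis, seed = seed)
  covs <- simulate_covariates(G$samples, seed = seed)
  prot <- simulate_proteome(G, covs, truth, seed = seed)
  y <- prepare_phenotypes(prot$proteins, covs)[, 1]
  list(cfg = cfg, G = G, truth = truth, covs = covs, prot = prot, y = y)
}

# Hand-built genotype matrix from an explicit dosage matrix.
manual_genotypes <- function(dosage, chrom = 1L, pos = NULL,
                             a1 = "A", a2 = "G") {
  m <- ncol(dosage)
  ids <- colnames(dosage) %||% sprintf("snp%d", seq_len(m))
  colnames(dosage) <- ids
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  }
  snps <- data.frame(snp_id = ids, chrom = rep_len(chrom, m),
                     pos = pos %||% seq(1e6, by = 2000, length.out = m),
                     a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                     maf = NA_real_, info = 0.99, missing_rate = 0,
                     hwe_p = NA_real_, in_reference_panel = TRUE,
                     block = 1L, stringsAsFactors = FALSE)
  protwas:::new_genotype_matrix(dosage, snps)
}

# Hand-built weight model.
manual_model <- function(snp_id, a1, a2, weight, aptamer_id = "APT",
                         method = "top1", cv_r2 = 0.5, chrom = 1L,
                         pos = NULL) {
  structure(list(
    aptamer_id = aptamer_id, method = method,
    weights = data.frame(snp_id = snp_id, chrom = rep_len(chrom,
                                                          length(snp_id)),
                         pos = pos %||% seq_along(snp_id) * 1000,
                         a1 = a1, a2 = a2, weight = weight,
                         stringsAsFactors = FALSE),
    cv_r2 = cv_r2, n_cis = NA_integer_, n_trans = NA_integer_,
    gene_chrom = chrom, tss = 1L), class = "weight_model")
}

# Independent brute-force oracle for the Hardy-Weinberg exact test:
# direct enumeration with log-factorials (no recurrence shared with the
# implementation).
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het          # allele-1 count
  prob <- function(h) {
    h1 <- (na - h) / 2
    h2 <- (2 * n - na - h) / 2
    exp(lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  ps <- vapply(hs, prob, numeric(1))
  ps <- ps / sum(ps)
  p_obs <- ps[match(n_het, hs)]
  min(1, sum(ps[ps <= p_obs * (1 + 1e-12)]))
}

# Brute-force Benjamini-Hochberg step-up: largest k with
# p_(k) <= k/m * q rejects p_(1..k).
bh_oracle_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) / m * q)))
  rej <- logical(m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

`%||%` <- function(a, b) if (is.null(a)) b else a
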