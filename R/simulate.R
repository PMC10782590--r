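# Synthetic-data generators: genotypes with block AR(1) LD, covariates,
# proteome with planted cis/trans architecture, GWAS summary statistics.

# Deterministic SNP map shared by all cohorts drawn from one config.
# Blocks are laid out on successive chromosomes, 2 kb between SNPs, and
# every SNP in a block shares the block MAF (keeps the haplotype Markov
# chain's AR(1) dosage correlation exact).
simulate_snp_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 11L), {
    b <- config$n_blocks
    m <- config$n_snps
    block <- rep(seq_len(b), each = m)
    chrom <- ((block - 1L) %% 22L) + 1L
    lap <- (block - 1L) %/% 22L          # blocks wrap onto reused chromosomes
    within <- rep(seq_len(m), times = b)
    pos <- 1000000L + lap * 10000000L + (within - 1L) * 2000L
    maf_block <- runif(b, config$maf_range[1], config$maf_range[2])
    # non-ambiguous allele pairs only; ambiguity is planted explicitly
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), b * m, replace = TRUE)
    data.frame(
      snp_id = sprintf("rs%d_%d", block, within),
      chrom = chrom, pos = pos,
      a1 = pairs[pick, 1], a2 = pairs[pick, 2],
      maf = maf_block[block],
      info = round(runif(b * m, 0.85, 1), 4),
      missing_rate = 0,
      hwe_p = NA_real_,
      in_reference_panel = TRUE,
      block = block,
      stringsAsFactors = FALSE
    )
  })
}

# One cohort's haplotypes for one block: binary AR(1) Markov chain with
# stationary frequency p and adjacent correlation rho, so that
# cor(h_i, h_j) = rho^|i-j| exactly and dosages (sum of two independent
# haplotypes) inherit the same correlation under Hardy-Weinberg.
sim_block_haplotypes <- function(n, m, p, rho) {
  H <- matrix(0L, n, m)
  H[, 1L] <- as.integer(runif(n) < p)
  if (m > 1L) {
    for (j in 2L:m) {
      pr <- p + rho * (H[, j - 1L] - p)
      H[, j] <- as.integer(runif(n) < pr)
    }
  }
  H
}

#' Simulate LD-structured genotype dosages
#'
#' Draws hard-call dosages (0/1/2 copies of allele `a1`) for one cohort from
#' the blockwise AR(1) haplotype model described in [sim_config()].  Within
#' a block the correlation between standardized dosages of SNPs `i` and `j`
#' is `ld_rho^|i-j|`; blocks are independent.  Each SNP is in
#' Hardy-Weinberg proportions.  The SNP map (positions, alleles, block MAF,
#' simulated imputation info) is identical across cohorts drawn from the
#' same config, so trained weights transfer.
#'
#' @param config A [sim_config()].
#' @param cohort One of `"train"`, `"valid"`, `"ref"`; selects the sample
#'   size and the RNG stream.
#' @param n Optional explicit sample size overriding the cohort's.
#' @return A `genotype_matrix`: list with `dosage` (samples x SNPs numeric
#'   matrix, dimnames set), `snps` (per-SNP metadata data frame) and
#'   `samples`.
#' @examples
#' G <- simulate_genotypes(sim_config(n_train = 50, n_blocks = 2,
#'                                    n_snps = 5, seed = 7))
#' dim(G$dosage)
#' @export
simulate_genotypes <- function(config, cohort = c("train", "valid", "ref"),
                               n = NULL) {
  cohort <- match.arg(cohort)
  snps <- simulate_snp_map(config)
  n <- n %||% switch(cohort, train = config$n_train,
                     valid = config$n_valid, ref = config$n_ref)
  if (!is.finite(n) || n < 1L) stop("non-positive sample size", call. = FALSE)
  offs <- switch(cohort, train = 20L, valid = 21L, ref = 22L)
  dosage <- with_seed(derive_seed(config$seed, offs), {
    blocks <- split(seq_len(nrow(snps)), snps$block)
    cols <- lapply(blocks, function(idx) {
      p <- snps$maf[idx[1L]]
      m <- length(idx)
      sim_block_haplotypes(n, m, p, config$ld_rho) +
        sim_block_haplotypes(n, m, p, config$ld_rho)
    })
    do.call(cbind, cols)
  })
  samples <- sprintf("%s%04d", toupper(substr(cohort, 1, 1)), seq_len(n))
  dimnames(dosage) <- list(samples, snps$snp_id)
  new_genotype_matrix(dosage, snps, samples)
}

new_genotype_matrix <- function(dosage, snps, samples = rownames(dosage)) {
  stopifnot(is.matrix(dosage), nrow(snps) == ncol(dosage))
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Plant quality-control violations in a clean genotype matrix
#'
#' Rewrites disjoint sets of SNPs so that each violates exactly one filter
#' criterion, and records the planted truth in metadata columns
#' `planted_low_maf`, `planted_low_info`, `planted_high_missing`,
#' `planted_hwe`, `planted_ambiguous`.  Used to verify that the QC module
#' recovers the planted counts exactly.
#'
#' Constructions are exact, not sampled: low-MAF SNPs get
#' `round(0.02 * n)` heterozygotes (MAF ~ 0.01); high-missing SNPs get 10%
#' of entries set missing; HWE violators get genotype counts from an
#' inbreeding model (F = 0.5, MAF 0.3), which at n in the hundreds or more
#' yields an exact-test p far below 5e-6 while keeping MAF and missingness
#' clean; low-info SNPs only have their info score set to 0.4; ambiguous
#' SNPs get A/T or C/G alleles.
#'
#' @param G A `genotype_matrix` with no pre-existing violations.
#' @param n_low_maf,n_low_info,n_high_missing,n_hwe,n_ambiguous Counts of
#'   SNPs to corrupt per class (disjoint sets).
#' @param seed Integer seed for choosing which SNPs are hit.
#' @return The modified `genotype_matrix`.
#' @export
plant_qc_violations <- function(G, n_low_maf = 0, n_low_info = 0,
                                n_high_missing = 0, n_hwe = 0,
                                n_ambiguous = 0, seed = 1) {
  counts <- c(low_maf = n_low_maf, low_info = n_low_info,
              high_missing = n_high_missing, hwe = n_hwe,
              ambiguous = n_ambiguous)
  m <- ncol(G$dosage)
  n <- nrow(G$dosage)
  if (sum(counts) > m) {
    stop("requested violation counts exceed the number of SNPs",
         call. = FALSE)
  }
  with_seed(seed, {
    idx <- sample.int(m, sum(counts))
  })
  grp <- rep(names(counts), counts)
  if (anyDuplicated(idx) > 0L) stop("overlapping violation assignment",
                                    call. = FALSE)
  for (nm in names(counts)) {
    G$snps[[paste0("planted_", nm)]] <- FALSE
  }
  assign_dosage <- function(j, d) {
    G$dosage[, j] <<- d
  }
  with_seed(derive_seed(seed, 31L), {
    for (k in seq_along(idx)) {
      j <- idx[k]
      G$snps[[paste0("planted_", grp[k])]][j] <- TRUE
      switch(grp[k],
        low_maf = {
          n_alt <- max(1L, round(0.02 * n))  # MAF ~ 0.01 < 0.05
          d <- numeric(n)
          d[sample.int(n, n_alt)] <- 1
          assign_dosage(j, d)
          G$snps$maf[j] <- n_alt / (2 * n)
        },
        low_info = {
          G$snps$info[j] <- 0.4
        },
        high_missing = {
          d <- G$dosage[, j]
          d[sample.int(n, ceiling(0.10 * n))] <- NA
          assign_dosage(j, d)
        },
        hwe = {
          # inbreeding-style homozygote excess: F = 0.5 at MAF q = 0.3
          q <- 0.3; f <- 0.5
          n_aa <- round(n * (q^2 + f * q * (1 - q)))
          n_het <- round(n * 2 * q * (1 - q) * (1 - f))
          d <- c(rep(2, n_aa), rep(1, n_het), rep(0, n - n_aa - n_het))
          assign_dosage(j, sample(d))
        },
        ambiguous = {
          al <- if (k %% 2L == 0L) c("A", "T") else c("C", "G")
          G$snps$a1[j] <- al[1]
          G$snps$a2[j] <- al[2]
        }
      )
    }
  })
  G
}

#' Simulate study covariates
#'
#' Age (years, uniform 18-80), sex (0/1), duration between blood draw and
#' processing (hours, gamma with mean ~24), and three ancestry principal
#' components (standard normal).  These are the covariates the adjustment
#' model removes.
#'
#' @param samples Character vector of sample ids.
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `age`, `sex`, `duration`,
#'   `pc1`, `pc2`, `pc3`.
#' @export
simulate_covariates <- function(samples, seed = 1) {
  n <- length(samples)
  with_seed(derive_seed(seed, 41L), {
    data.frame(
      sample_id = samples,
      age = round(runif(n, 18, 80), 1),
      sex = rbinom(n, 1L, 0.5),
      duration = round(rgamma(n, shape = 4, scale = 6), 2),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
      stringsAsFactors = FALSE
    )
  })
}

# Theoretical correlation matrix of standardized dosages for a SNP subset
# under the generative block AR(1) law.
theoretical_ld <- function(snps, ids, ld_rho) {
  sub <- snps[match(ids, snps$snp_id), , drop = FALSE]
  k <- nrow(sub)
  S <- diag(1, k)
  if (k > 1L) {
    within <- as.integer(sub(".*_", "", sub$snp_id))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (sub$block[i] == sub$block[j]) {
          S[i, j] <- S[j, i] <- ld_rho^abs(within[i] - within[j])
        }
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

# Scale raw effects so that beta' Sigma beta equals the target variance
# share under the generative LD (population, not sample, standardization).
scale_effects <- function(effects, Sigma, target) {
  if (length(effects) == 0L || target == 0) return(effects * 0)
  v <- as.numeric(t(effects) %*% Sigma %*% effects)
  if (v <= 0) stop("degenerate causal effect configuration", call. = FALSE)
  effects * sqrt(target / v)
}

#' Construct a planted truth record against a simulated SNP map
#'
#' Convenience builder: picks `n_cis` causal SNPs from one LD block (whose
#' mid position becomes the encoding gene's TSS) and `n_trans` causal SNPs
#' from other blocks, draws raw standard-normal effects, and rescales them
#' so the cis and trans genetic components have population variance exactly
#' `h2_cis` and `h2_trans` on the standardized latent scale.
#'
#' @param G A `genotype_matrix` from [simulate_genotypes()].
#' @param config The [sim_config()] that produced `G` (for `ld_rho`).
#' @param aptamer_id Identifier for the synthetic aptamer.
#' @param h2_cis,h2_trans Target variance shares.
#' @param n_cis,n_trans Causal SNP counts.
#' @param cis_block Index of the block hosting the gene (default 1).
#' @param gamma,gwas_n Passed through to [truth_record()].
#' @param seed Integer seed.
#' @return A [truth_record()] with attributes `gene_chrom` and `tss`.
#' @export
make_truth <- function(G, config, aptamer_id = "APT1", h2_cis = 0.2,
                       h2_trans = 0, n_cis = 3, n_trans = 0,
                       cis_block = 1L, gamma = 0, gwas_n = 4e5, seed = 1) {
  snps <- G$snps
  cis_pool <- which(snps$block == cis_block)
  trans_pool <- which(snps$block != cis_block)
  if (n_cis > length(cis_pool) || n_trans > length(trans_pool)) {
    stop("not enough SNPs in the requested blocks", call. = FALSE)
  }
  with_seed(derive_seed(seed, 51L), {
    ci <- sort(sample(cis_pool, n_cis))
    ti <- sort(sample(trans_pool, n_trans))
    mk <- function(i, h2) {
      if (length(i) == 0L || h2 == 0) {
        return(data.frame(snp_id = character(), effect = numeric()))
      }
      eff <- rnorm(length(i))
      S <- theoretical_ld(snps, snps$snp_id[i], config$ld_rho)
      data.frame(snp_id = snps$snp_id[i],
                 effect = scale_effects(eff, S, h2),
                 stringsAsFactors = FALSE)
    }
    tr <- truth_record(aptamer_id, mk(ci, h2_cis), mk(ti, h2_trans),
                       h2_cis, h2_trans, gamma, gwas_n)
    blk <- snps[cis_pool, ]
    attr(tr, "gene_chrom") <- blk$chrom[1]
    attr(tr, "tss") <- as.integer(round(mean(range(blk$pos))))
    tr
  })
}

#' Simulate raw protein abundances with planted architecture
#'
#' For each truth record, builds the latent standardized value
#' `cis genetic + trans genetic + covariate loadings + noise`, where the
#' genetic parts use population-standardized dosages (mean `2p`, variance
#' `2p(1-p)`) so the variance shares equal `h2_cis`/`h2_trans` exactly in
#' the generative law, and the noise variance is `1 - h2_cis - h2_trans`.
#' Covariate loadings (on standardized covariates) default to
#' `(age .3, sex .2, duration .2, pc1-3 .1)` and sit on top of the
#' unit-variance genetic+noise part; the downstream adjustment removes
#' them.  The emitted raw abundance is `exp(latent)`, strictly positive,
#' so the pipeline's log step is exercised.
#'
#' @param G A `genotype_matrix`.
#' @param covariates Output of [simulate_covariates()] for `G$samples`.
#' @param truth A [truth_record()] or list of them.
#' @param seed Integer seed.
#' @param covariate_loadings Named numeric loadings on standardized
#'   covariates.
#' @return List with `proteins` (samples x aptamers matrix of raw
#'   abundances), `latent` (same shape, pre-exponential), and `aptamers`
#'   (metadata: aptamer_id, gene chromosome, TSS).
#' @export
simulate_proteome <- function(G, covariates, truth, seed = 1,
                              covariate_loadings = c(age = 0.3, sex = 0.2,
                                                     duration = 0.2,
                                                     pc1 = 0.1, pc2 = 0.1,
                                                     pc3 = 0.1)) {
  if (inherits(truth, "truth_record")) truth <- list(truth)
  n <- nrow(G$dosage)
  stopifnot(identical(covariates$sample_id, G$samples))
  C <- scale(as.matrix(covariates[, names(covariate_loadings)]))
  C[is.nan(C)] <- 0
  cov_part <- as.numeric(C %*% covariate_loadings)
  std_dosage <- function(ids) {
    i <- match(ids, G$snps$snp_id)
    if (anyNA(i)) stop("causal SNP not present in G", call. = FALSE)
    p <- G$snps$maf[i]
    D <- G$dosage[, i, drop = FALSE]
    sweep(sweep(D, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  }
  lat <- matrix(NA_real_, n, length(truth))
  meta <- data.frame(aptamer_id = character(length(truth)),
                     gene_chrom = NA_integer_, tss = NA_integer_,
                     stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, 61L), {
    for (k in seq_along(truth)) {
      tr <- truth[[k]]
      g <- numeric(n)
      for (part in list(tr$causal_cis, tr$causal_trans)) {
        if (nrow(part) > 0L) {
          g <- g + as.numeric(std_dosage(part$snp_id) %*% part$effect)
        }
      }
      e_var <- 1 - tr$h2_cis - tr$h2_trans
      lat[, k] <- g + cov_part + rnorm(n, sd = sqrt(e_var))
      meta$aptamer_id[k] <- tr$aptamer_id
      meta$gene_chrom[k] <- attr(tr, "gene_chrom") %||% NA_integer_
      meta$tss[k] <- attr(tr, "tss") %||% NA_integer_
    }
  })
  dimnames(lat) <- list(G$samples, meta$aptamer_id)
  list(proteins = exp(lat), latent = lat, aptamers = meta)
}

#' Simulate GWAS summary-statistic z vectors
#'
#' Draws `z ~ MVN(mu, Sigma)` for the SNPs of one LD matrix.  Under the
#' null `mu = 0`; under a protein-to-disease effect `gamma` with effective
#' sample size `N`, `mu = gamma * sqrt(N) * Sigma %*% w_true`, the standard
#' summary-statistic generative model matched to the association statistic
#' this package computes.  `w_true` should be scaled so the predicted
#' protein has unit variance under `Sigma` (i.e. `w' Sigma w = 1`).
#'
#' @param Sigma SNP correlation matrix (positive semidefinite).
#' @param w_true Standardized weight vector (ignored when `null = TRUE`).
#' @param gamma,N Effect slope and GWAS effective sample size.
#' @param seed Integer seed.
#' @param null Logical; draw from the null (`mu = 0`)?
#' @param snps Optional data frame with `snp_id`, `a1`, `a2` used to label
#'   the output; defaults to the dimnames of `Sigma` with alleles A/G.
#' @param n_rep Number of independent z vectors to draw.
#' @return If `n_rep == 1` a `sumstats` data frame (`snp_id`, `a1`, `a2`,
#'   `z`); otherwise a matrix with `n_rep` columns of z draws.
#' @export
simulate_gwas_sumstats <- function(Sigma, w_true = NULL, gamma = 0, N = 4e5,
                                   seed = 1, null = FALSE, snps = NULL,
                                   n_rep = 1L) {
  Sigma <- as.matrix(Sigma)
  k <- nrow(Sigma)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("Sigma is not positive semidefinite", call. = FALSE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  mu <- if (null || is.null(w_true) || gamma == 0) {
    rep(0, k)
  } else {
    as.numeric(gamma * sqrt(N) * (Sigma %*% w_true))
  }
  Z <- with_seed(derive_seed(seed, 71L), {
    mu + L %*% matrix(rnorm(k * n_rep), k, n_rep)
  })
  if (n_rep > 1L) {
    rownames(Z) <- rownames(Sigma)
    return(Z)
  }
  ids <- rownames(Sigma) %||% sprintf("snp%d", seq_len(k))
  if (is.null(snps)) {
    snps <- data.frame(snp_id = ids, a1 = "A", a2 = "G",
                       stringsAsFactors = FALSE)
  }
  out <- data.frame(snp_id = snps$snp_id, a1 = snps$a1, a2 = snps$a2,
                    z = as.numeric(Z), stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}
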