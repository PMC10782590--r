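# Harmonization, LD estimation, the association statistic, and the batch
# runner's missingness and Bonferroni rules.

test_that("harmonization keeps, flips or drops per allele disposition", {
  ss <- data.frame(snp_id = c("s1", "s2", "s4", "s5"),
                   a1 = c("A", "G", "A", "A"),
                   a2 = c("G", "A", "C", "T"),
                   z = c(2.0, 2.0, 1.0, 1.5))
  model <- manual_model(c("s1", "s2", "s3", "s4", "s5"),
                        a1 = c("A", "A", "A", "A", "A"),
                        a2 = c("G", "G", "G", "G", "T"),
                        weight = c(0.3, 0.2, 0.1, 0.1, 0.1))
  h <- harmonize(model, ss)
  expect_equal(unname(h$z["s1"]), 2.0)     # exact match
  expect_equal(unname(h$z["s2"]), -2.0)    # swapped alleles negate z
  d <- setNames(h$disposition$disposition, h$disposition$snp_id)
  expect_identical(unname(d[c("s1", "s2", "s3", "s4", "s5")]),
                   c("match", "swap", "absent", "mismatch", "ambiguous"))
  expect_equal(h$missing_frac, 3 / 5)
})

test_that("LD estimation matches the generative law and repairs degeneracy", {
  cfg <- sim_config(n_ref = 5000, n_blocks = 1, n_snps = 6, ld_rho = 0.8,
                    seed = 12)
  panel <- simulate_genotypes(cfg, "ref")
  ld <- ld_from_panel(panel, panel$snps$snp_id)
  target <- outer(1:6, 1:6, function(i, j) 0.8^abs(i - j))
  expect_lt(max(abs(ld$Sigma - target)), 0.05)
  expect_equal(diag(ld$Sigma), rep(1, 6), ignore_attr = TRUE)
  # independent blocks -> near-zero off-diagonals
  cfg0 <- sim_config(n_ref = 5000, n_blocks = 6, n_snps = 1, seed = 12)
  p0 <- simulate_genotypes(cfg0, "ref")
  ld0 <- ld_from_panel(p0, p0$snps$snp_id)
  expect_lt(max(abs(ld0$Sigma - diag(6))), 0.05)
  # duplicated SNP column: correlation 1, repaired, computation proceeds
  dup <- panel
  dup$dosage <- cbind(dup$dosage, dup$dosage[, 1])
  dup$snps <- rbind(dup$snps, transform(dup$snps[1, ], snp_id = "dup1"))
  colnames(dup$dosage) <- dup$snps$snp_id
  ldd <- ld_from_panel(dup, dup$snps$snp_id)
  expect_gte(min(eigen(ldd$Sigma, symmetric = TRUE)$values), 1e-9)
  expect_equal(diag(ldd$Sigma), rep(1, 7), ignore_attr = TRUE)
  z <- pwas_z(rep(1, 7), rep(1, 7), ldd$Sigma)
  expect_true(is.finite(z))
  # absent SNPs dropped with a log entry
  expect_message(ld_from_panel(panel, c("rs1_1", "nope")), "dropped")
})

test_that("the association statistic matches hand-computed cases", {
  expect_equal(pwas_z(1, 3.2, matrix(1)), 3.2, tolerance = 1e-12)
  expect_equal(pwas_z(c(1, 1), c(2, 2), matrix(1, 2, 2)), 2,
               tolerance = 1e-12)
  expect_equal(pwas_z(c(0.5, -0.5), c(1.96, -1.96), diag(2)),
               1.96 / sqrt(0.5), tolerance = 1e-12)
  # scale invariance / sign flip
  w <- c(0.2, -0.4, 0.1)
  S <- outer(1:3, 1:3, function(i, j) 0.6^abs(i - j))
  z <- c(1.1, -0.3, 2.2)
  expect_equal(pwas_z(5 * w, z, S), pwas_z(w, z, S), tolerance = 1e-12)
  expect_equal(pwas_z(-w, z, S), -pwas_z(w, z, S), tolerance = 1e-12)
  expect_error(pwas_z(c(0, 0), c(1, 1), diag(2)), "degenerate")
  expect_error(pwas_z(1, c(1, 2), matrix(1)), "dimension")
})

test_that("p-values are two-sided normal with a floor", {
  expect_equal(pvalue_from_z(0), 1)
  expect_equal(pvalue_from_z(4.47), 7.78e-6, tolerance = 0.05)
  expect_equal(pvalue_from_z(-4.72), 2.41e-6, tolerance = 0.05)
  expect_identical(pvalue_from_z(40), 1e-300)
  expect_error(pvalue_from_z(NA), "finite")
})

test_that("allele-flip invariance of the full engine", {
  cfg <- sim_config(n_ref = 400, n_blocks = 1, n_snps = 5, ld_rho = 0.5,
                    seed = 9)
  panel <- simulate_genotypes(cfg, "ref")
  ids <- panel$snps$snp_id
  ss <- data.frame(snp_id = ids, a1 = panel$snps$a1, a2 = panel$snps$a2,
                   z = c(1.2, -0.4, 2.5, 0.3, -1.8))
  model <- manual_model(ids, panel$snps$a1, panel$snps$a2,
                        weight = c(0.2, 0.1, -0.3, 0.4, 0.05))
  r1 <- run_pwas(list(model), ss, panel)
  # flip SNP 3 everywhere: model alleles and weight orientation, sumstats
  # z, and the panel's dosage coding
  model2 <- model
  model2$weights$a1[3] <- model$weights$a2[3]
  model2$weights$a2[3] <- model$weights$a1[3]
  model2$weights$weight[3] <- -model$weights$weight[3]
  ss2 <- ss; ss2$z[3] <- -ss$z[3]
  ss2$a1[3] <- ss$a2[3]; ss2$a2[3] <- ss$a1[3]
  panel2 <- panel
  panel2$dosage[, 3] <- 2 - panel2$dosage[, 3]
  tmp <- panel2$snps$a1[3]
  panel2$snps$a1[3] <- panel2$snps$a2[3]; panel2$snps$a2[3] <- tmp
  r2 <- run_pwas(list(model2), ss2, panel2)
  expect_equal(r2$z_pwas, r1$z_pwas, tolerance = 1e-10)
})

test_that("batch runner applies the missingness and Bonferroni rules", {
  cfg <- sim_config(n_ref = 400, n_blocks = 2, n_snps = 10, ld_rho = 0.4,
                    seed = 21)
  panel <- simulate_genotypes(cfg, "ref")
  ids <- panel$snps$snp_id
  mk <- function(sel, apt) {
    manual_model(ids[sel], panel$snps$a1[sel], panel$snps$a2[sel],
                 weight = seq_along(sel) / 10, aptamer_id = apt)
  }
  # sumstats cover only the first block (10 SNPs)
  ss <- data.frame(snp_id = ids[1:10], a1 = panel$snps$a1[1:10],
                   a2 = panel$snps$a2[1:10], z = rnorm(10))
  m_ok <- mk(1:4, "covered")                   # fully present
  m_half <- mk(6:15, "half")                   # 5 of 10 absent -> tested
  m_skip <- mk(11:20, "gone")                  # 10 of 10 absent -> skipped
  m_six <- mk(c(1:4, 11:16), "sixmiss")        # 6 of 10 absent -> skipped
  res <- run_pwas(list(m_ok, m_half, m_skip, m_six), ss, panel)
  expect_identical(res$skip_reason[res$aptamer_id == "sixmiss"],
                   "missing_frac_gt_half")
  expect_equal(res$missing_frac[res$aptamer_id == "sixmiss"], 0.6)
  # exactly half is still tested (strictly-greater rule)
  expect_true(is.na(res$skip_reason[res$aptamer_id == "half"]))
  expect_identical(attr(res, "n_tested"), 2L)
  expect_equal(attr(res, "p_cutoff"), 0.05 / 2)
  # single-SNP model reduces to the harmonized SNP z times sign(w)
  m1 <- mk(3, "single")
  r1 <- run_pwas(list(m1), ss, panel)
  expect_equal(r1$z_pwas, ss$z[3], tolerance = 1e-12)
  m1n <- m1; m1n$weights$weight <- -1
  r1n <- run_pwas(list(m1n), ss, panel)
  expect_equal(r1n$z_pwas, -ss$z[3], tolerance = 1e-12)
  # absolute threshold mode
  ra <- run_pwas(list(m_ok, m_half), ss, panel, p_threshold = 3.01e-5)
  expect_equal(attr(ra, "p_cutoff"), 3.01e-5)
})

test_that("the statistic is null-calibrated against its own LD", {
  cfg <- sim_config(n_ref = 503, n_blocks = 1, n_snps = 8, ld_rho = 0.6,
                    seed = 33)
  panel <- simulate_genotypes(cfg, "ref")
  ld <- ld_from_panel(panel, panel$snps$snp_id)
  w <- protwas:::with_seed(1, rnorm(8))
  Z <- simulate_gwas_sumstats(ld$Sigma, null = TRUE, seed = 5,
                              n_rep = 5000)
  zp <- as.numeric(crossprod(w, Z)) /
    sqrt(as.numeric(t(w) %*% ld$Sigma %*% w))
  expect_lt(abs(mean(zp)), 0.05)
  expect_lt(abs(var(zp) - 1), 0.1)
  rej <- mean(abs(zp) > qnorm(0.975))
  expect_lt(abs(rej - 0.05), 2.58 * sqrt(0.05 * 0.95 / 5000))
})

test_that("power is monotone in gamma * sqrt(N)", {
  S <- outer(1:5, 1:5, function(i, j) 0.5^abs(i - j))
  w <- c(0.3, 0.1, 0.2, 0.05, 0.15)
  w <- w / sqrt(as.numeric(t(w) %*% S %*% w))   # unit predicted variance
  pow <- sapply(c(0, 2e-3, 5e-3, 1e-2), function(g) {
    Z <- simulate_gwas_sumstats(S, w_true = w, gamma = g, N = 1e5,
                                seed = 17, n_rep = 1500)
    zp <- as.numeric(crossprod(w, Z)) / sqrt(as.numeric(t(w) %*% S %*% w))
    mean(abs(zp) > qnorm(0.975))
  })
  expect_true(all(diff(pow) >= -0.02))   # non-decreasing up to MC noise
  expect_gt(pow[4], pow[1])
})
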