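test_that("standardized kinship has the contracted algebraic structure", {
  set.seed(1)
  dos <- matrix(rbinom(50 * 80, 2, 0.3), 50, 80)
  dos[2, ] <- dos[1, ]  # two identical accessions
  geno <- make_geno(dos)
  K <- compute_kinship(geno)
  expect_equal(K, t(K))
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # HWE simulated panel: diagonal mean near 1
  p <- sim_panel(n = 200, m = 4, seed = 3, n_snps = 300)
  K2 <- compute_kinship(p$geno)
  expect_lt(abs(mean(diag(K2)) - 1), 0.05)
})

test_that("monomorphic SNPs are excluded from kinship with a message", {
  set.seed(2)
  dos <- cbind(matrix(rbinom(30 * 10, 2, 0.4), 30, 10), 1L)
  geno <- make_geno(dos)
  expect_message(compute_kinship(geno), "monomorphic")
})

test_that("with identity kinship the LMM reduces exactly to ordinary regression", {
  set.seed(4)
  n <- 80
  geno <- make_geno(matrix(rbinom(n * 30, 2, 0.35), n, 30))
  dos <- geno$dosages
  y <- rnorm(n) + 0.3 * dos[, 5]
  K <- diag(n); dimnames(K) <- list(rownames(dos), rownames(dos))
  res <- lmm_scan(setNames(y, rownames(dos)), geno, K)
  ols <- t(sapply(seq_len(30), function(j) {
    s <- summary(lm(y ~ dos[, j]))$coefficients
    c(s[2, 1], s[2, 2], s[2, 4], s[2, 3])
  }))
  expect_lt(max(abs(res$beta / res$se - ols[, 4])), 1e-8)
  expect_equal(res$beta, ols[, 1], tolerance = 1e-10)
  expect_equal(res$p_value, ols[, 3], tolerance = 1e-10)
})

test_that("null scan is calibrated: type-I error and genomic control", {
  p <- sim_panel(n = 300, m = 4, seed = 5, n_snps = 5000, ld_rho = 0)
  K <- compute_kinship(p$geno)
  set.seed(6)
  y <- setNames(rnorm(300), p$geno$accession_ids)  # independent of genotypes
  res <- lmm_scan(y, p$geno, K)
  expect_gte(mean(res$p_value < 0.05), 0.04)
  expect_lte(mean(res$p_value < 0.05), 0.06)
  lambda_gc <- median(qchisq(res$p_value, 1, lower.tail = FALSE)) /
    qchisq(0.5, 1, lower.tail = FALSE)
  expect_gte(lambda_gc, 0.95)
  expect_lte(lambda_gc, 1.05)
  # no hidden randomness
  res2 <- lmm_scan(y, p$geno, K)
  expect_identical(res$p_value, res2$p_value)
})

test_that("a planted 10%-PVE SNP is detected at the genome-wide threshold", {
  # power oracle: NCP = n*pve/(1-pve) ~ 55.6 at n = 500 gives essentially
  # certain detection at alpha = 1.37e-6 (power > 0.999)
  thr <- bonferroni_threshold(0.05, 36508)
  hits <- sapply(1:20, function(s) {
    cfg <- sim_config(n_accessions = 500, n_snps = 60, ld_rho = 0, seed = 300 + s)
    geno <- simulate_genotypes(cfg)
    set.seed(1000 + s)
    x <- geno$dosages[, 30]
    pve <- 0.10
    beta <- sqrt(pve / (1 - pve) / var(x))
    y <- setNames(x * beta + rnorm(500), geno$accession_ids)
    res <- lmm_scan(y, geno, compute_kinship(geno))
    res$p_value[30] < thr
  })
  expect_gte(sum(hits), 19)
})

test_that("covariates absorbing the signal leave no marker effects", {
  p <- sim_panel(n = 100, m = 4, seed = 9, n_snps = 50)
  cov <- setNames(rnorm(100), p$geno$accession_ids)
  y <- cov  # phenotype equals the covariate exactly
  res <- lmm_scan(y, p$geno, compute_kinship(p$geno),
                  covariates = matrix(cov, dimnames = list(names(cov), "c1")))
  expect_lt(max(abs(res$beta)), 1e-8)
  expect_error(
    lmm_scan(y, p$geno, covariates = cbind(c1 = cov, c2 = 2 * cov)),
    "singular")
})

test_that("LD pruning retains independent SNPs and collapses duplicates", {
  set.seed(11)
  dos <- matrix(rbinom(200 * 20, 2, 0.4), 200, 20)
  geno <- make_geno(dos)
  expect_equal(as.integer(ld_prune_effective_tests(geno)), 20L)
  # duplicate each column: exactly one representative per duplicate pair
  dup <- make_geno(cbind(dos, dos), pos = seq_len(40) * 1000L)
  expect_equal(as.integer(ld_prune_effective_tests(dup)), 20L)
})

test_that("windowed pruning equals the un-windowed greedy oracle when the window spans all SNPs", {
  cfg <- sim_config(n_accessions = 150, n_snps = 100, ld_rho = 0.6,
                    ld_block_size = 5, n_chrom = 1, seed = 12)
  geno <- simulate_genotypes(cfg)
  kept <- ld_prune_effective_tests(geno, window_kb = 1e6, step = 1,
                                   r2_threshold = 0.3)
  # brute-force greedy oracle: repeatedly drop the lower-MAF member of the
  # first violating pair over all SNPs
  X <- geno$dosages
  alive <- rep(TRUE, 100)
  maf <- geno$snps$maf
  repeat {
    act <- which(alive)
    R2 <- suppressWarnings(cor(X[, act]))^2; diag(R2) <- 0
    bad <- which(R2 > 0.3, arr.ind = TRUE)
    if (nrow(bad) == 0) break
    pr <- act[bad[1, ]]
    drop <- if (maf[pr[1]] < maf[pr[2]]) pr[1]
            else if (maf[pr[2]] < maf[pr[1]]) pr[2] else max(pr)
    alive[drop] <- FALSE
  }
  expect_equal(sort(attr(kept, "keep")), sort(geno$snps$snp_id[alive]))
})

test_that("Bonferroni threshold reproduces the printed genome-wide level", {
  expect_equal(signif(bonferroni_threshold(0.05, 36508), 3), 1.37e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "alpha|n_independent")
})

test_that("per-SNP PVE follows the standardized formula in both algebraic forms", {
  expect_equal(snp_pve(0, 0.1, 0.2, 100), 0)
  expect_equal(snp_pve(0.5, 1e-12, 0.2, 100), 1, tolerance = 1e-6)
  expect_equal(snp_pve(0.5, 0.05, 0.3, 100), 0.5)
  # full form (with the 2*maf*(1-maf) factors) vs simplified form
  full <- function(b, se, f, N) {
    v <- 2 * f * (1 - f)
    (v * b^2) / (v * b^2 + v * N * se^2)
  }
  for (b in c(0.1, 0.5, 2)) for (se in c(0.01, 0.2)) for (f in c(0.05, 0.5)) {
    expect_equal(snp_pve(b, se, f, 250), full(b, se, f, 250),
                 tolerance = 1e-12)
    expect_equal(snp_pve(b, se, f, 250), b^2 / (b^2 + 250 * se^2),
                 tolerance = 1e-12)
  }
  # monotone decreasing in se and in N
  se_grid <- seq(0.01, 1, length.out = 20)
  expect_true(all(diff(snp_pve(0.4, se_grid, 0.2, 100)) < 0))
  n_grid <- seq(10, 1000, by = 50)
  expect_true(all(diff(sapply(n_grid, function(N) snp_pve(0.4, 0.1, 0.2, N))) < 0))
  expect_error(snp_pve(0, 0, 0.2, 100), "undefined")
})

test_that("Fst scan matches the Weir-Cockerham oracle and its fixed points", {
  # no differentiation: both groups drawn from one population
  cfg <- sim_config(n_accessions = 1000, n_snps = 100, ld_rho = 0,
                    maf_range = c(0.2, 0.5), seed = 14)
  geno <- simulate_genotypes(cfg)
  grp <- setNames(rep(c("A", "B"), each = 500), geno$accession_ids)
  fst <- fst_scan(geno, grp)
  expect_true(all(abs(fst$fst) < 0.02, na.rm = TRUE))
  # fixed difference
  dosF <- cbind(c(rep(2L, 50), rep(0L, 50)),
                rbinom(100, 2, 0.5))
  genoF <- make_geno(dosF)
  grpF <- setNames(rep(c("A", "B"), each = 50), rownames(dosF))
  expect_equal(fst_scan(genoF, grpF)$fst[1], 1)
  # random cases against the hand-coded oracle
  set.seed(15)
  for (rep in 1:5) {
    xa <- rbinom(50, 2, 0.2); xb <- rbinom(50, 2, 0.8)
    genoO <- make_geno(cbind(c(xa, xb)))
    grpO <- setNames(rep(c("A", "B"), each = 50), rownames(genoO$dosages))
    expect_equal(fst_scan(genoO, grpO)$fst[1], wc_fst_oracle(xa, xb),
                 tolerance = 1e-12)
  }
})
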