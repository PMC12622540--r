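test_that("noiseless 2x2 table is interpolated exactly by the LS decomposition", {
  fit <- fit_fw_ls(toy_2x2(), "TOY")
  expect_equal(fit$mu, 10)
  expect_equal(unname(fit$h), c(-2, 2))
  expect_equal(unname(fit$g), c(-1, 1))
  expect_equal(unname(fit$linear_plasticity), c(0.5, 1.5))
  fitted <- fit$mu + fit$g + outer(fit$linear_plasticity, fit$h)
  expect_equal(as.vector(fitted), c(8, 8, 10, 14))
  # 4 observations, 4 free parameters: residual variance is exactly zero
  expect_true(all(exp(fit$nonlinear_plasticity) == 0))
})

test_that("LS decomposition satisfies its identifiability invariants", {
  p <- sim_panel(n = 120, m = 5, seed = 31, n_snps = 40)
  fit <- fit_fw_ls(p$pheno, "GCR")
  expect_equal(sum(fit$h), 0, tolerance = 1e-10)
  expect_equal(mean(fit$linear_plasticity), 1, tolerance = 1e-8)
})

test_that("identical environment profiles give unit slopes for every accession", {
  base <- c(10, 20, 35, 50)
  pheno <- expand.grid(accession = sprintf("a%d", 1:6),
                       environment = sprintf("e%d", 1:4),
                       stringsAsFactors = FALSE)
  pheno$trait <- "T"
  pheno$value <- base[match(pheno$environment, sprintf("e%d", 1:4))] +
    as.numeric(sub("a", "", pheno$accession))
  fit <- fit_fw_ls(pheno, "T")
  expect_equal(unname(fit$linear_plasticity), rep(1, 6))
})

test_that("degenerate phenotype tables are rejected or flagged, not silently fit", {
  one_env <- data.frame(accession = c("a", "b"), environment = "e1",
                        trait = "T", value = c(1, 2))
  expect_error(fit_fw_ls(one_env, "T"), "2 environments")
  # an accession observed once is flagged with NA slope, not dropped
  pheno <- toy_2x2()
  pheno <- rbind(pheno, data.frame(accession = "a3", environment = "e1",
                                   trait = "TOY", value = 9))
  fit <- fit_fw_ls(pheno, "TOY")
  expect_true("a3" %in% fit$flagged)
  expect_true(is.na(fit$linear_plasticity["a3"]))
  expect_true("a3" %in% names(fit$g))
})

test_that("refitting the fitted values reproduces the decomposition (idempotence)", {
  p <- sim_panel(n = 60, m = 5, seed = 17, n_snps = 30)
  fit <- fit_fw_ls(p$pheno, "GCR")
  fitted <- fit$mu + fit$g + outer(fit$linear_plasticity, fit$h)
  pheno2 <- data.frame(
    accession = rep(rownames(fitted), ncol(fitted)),
    environment = rep(colnames(fitted), each = nrow(fitted)),
    trait = "GCR", value = as.vector(fitted), stringsAsFactors = FALSE)
  fit2 <- fit_fw_ls(pheno2, "GCR")
  expect_equal(fit2$g, fit$g, tolerance = 1e-10)
  expect_equal(fit2$linear_plasticity, fit$linear_plasticity, tolerance = 1e-10)
  expect_equal(fit2$h, fit$h, tolerance = 1e-10)
})

test_that("LS decomposition recovers the generating slopes and means", {
  p <- sim_panel(n = 300, m = 6, seed = 1)
  fit <- fit_fw_ls(p$pheno, "GCR")
  expect_gte(cor(fit$linear_plasticity - 1, p$truth$b_true), 0.9)
  expect_gte(cor(fit$g, p$truth$g_true), 0.95)
})

test_that("Gibbs sampler agrees with least squares where the model is identifiable", {
  # saturated noiseless toy: posterior-mean fitted cells match the LS fit
  gb <- fit_fw_gibbs(toy_2x2(), "TOY", n_iter = 2000, burnin = 500, seed = 3)
  fitted <- gb$mu + gb$g + outer(gb$linear_plasticity, gb$h)
  expect_lt(max(abs(as.vector(fitted) - c(8, 8, 10, 14))), 1e-2)
  # moderate noise, 200 x 6: cross-estimator agreement on the slopes
  p <- sim_panel(n = 200, m = 6, seed = 11, n_snps = 40)
  ls_fit <- fit_fw_ls(p$pheno, "GCR")
  gb2 <- fit_fw_gibbs(p$pheno, "GCR", n_iter = 2000, burnin = 500, seed = 5)
  expect_gt(cor(gb2$linear_plasticity, ls_fit$linear_plasticity), 0.98)
  expect_false(gb2$diagnostics$convergence_warning)
})

test_that("Gibbs and LS estimates converge as residual variance vanishes", {
  cfg <- sim_config(n_accessions = 60, n_snps = 30, n_envs = 5, seed = 2,
                    residual_var = 1e-6, residual_var_log_sd = 0)
  sim <- simulate_phenotypes(simulate_genotypes(cfg),
                             simulate_environments(cfg), cfg)
  ls_fit <- fit_fw_ls(sim$pheno, "GCR")
  gb <- fit_fw_gibbs(sim$pheno, "GCR", n_iter = 1500, burnin = 500, seed = 9)
  expect_lt(max(abs(gb$linear_plasticity - ls_fit$linear_plasticity)), 0.05)
})

test_that("Gibbs chains are reproducible under a fixed seed", {
  p <- sim_panel(n = 40, m = 4, seed = 23, n_snps = 20)
  a <- fit_fw_gibbs(p$pheno, "GCR", n_iter = 400, burnin = 100, seed = 7)
  b <- fit_fw_gibbs(p$pheno, "GCR", n_iter = 400, burnin = 100, seed = 7)
  expect_identical(a$g, b$g)
  expect_identical(a$linear_plasticity, b$linear_plasticity)
  expect_error(fit_fw_gibbs(p$pheno, "GCR", n_iter = 100, burnin = 100),
               "burnin")
})

test_that("coefficient of variation follows its definition and guards", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), ">= 2")
  # scale-free under positive rescaling, but not under translation
  v <- c(2, 4, 9, 11)
  expect_equal(coefficient_of_variation(v * 7), coefficient_of_variation(v))
  expect_false(isTRUE(all.equal(coefficient_of_variation(v + 5),
                                coefficient_of_variation(v))))
})

test_that("quartile coefficient of dispersion follows the interpolation rule", {
  expect_equal(quartile_coefficient_of_dispersion(rep(3, 6)), 0)
  # {1..5}: Q1 = 2, Q3 = 4 under linear interpolation => 2/6
  expect_equal(quartile_coefficient_of_dispersion(1:5), 1 / 3)
  expect_error(quartile_coefficient_of_dispersion(c(-2, -1, 1, 2)), "Q1 \\+ Q3")
  expect_error(quartile_coefficient_of_dispersion(1:3), ">= 4")
  v <- c(2, 4, 9, 11, 20)
  expect_equal(quartile_coefficient_of_dispersion(v * 3),
               quartile_coefficient_of_dispersion(v))
})

test_that("trait_summary reports per-environment dispersion consistently", {
  p <- sim_panel(n = 50, m = 4, seed = 19, n_snps = 20)
  ts <- trait_summary(p$pheno, "GCR")
  expect_equal(nrow(ts), 4)
  e1 <- p$pheno$value[p$pheno$environment == "E01"]
  expect_equal(ts$cv[ts$environment == "E01"],
               coefficient_of_variation(e1))
  expect_equal(ts$qcd[ts$environment == "E01"],
               quartile_coefficient_of_dispersion(e1))
  pooled <- trait_summary(p$pheno, "GCR", by_environment = FALSE)
  expect_equal(pooled$environment, "pooled")
})
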