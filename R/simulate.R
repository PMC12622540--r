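#' Simulation configuration for the synthetic mini-core panel
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()], [simulate_environments()] and
#' [simulate_phenotypes()]. The defaults emulate a rice mini-core diversity
#' panel scored for a percent-scale grain-chalkiness trait in five field
#' environments: roughly five hundred accessions, biallelic SNPs with
#' MAF >= 0.05 arranged in LD blocks, optional two-subpopulation structure,
#' planted mean-effect and plasticity-effect QTL, and heritability in the
#' 0.6-0.85 regime.
#'
#' @param n_accessions Number of accessions (>= 1).
#' @param n_snps Number of biallelic SNPs (>= 1).
#' @param maf_range Length-2 numeric, minor-allele-frequency range in
#'   (0, 0.5]; SNP allele frequencies are drawn uniformly on this range.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho Within-block latent (copula) correlation in `[0, 1)`.
#' @param n_subpops Number of subpopulations (1 = panmictic).
#' @param divergence Balding-Nichols differentiation parameter in `[0, 1)`;
#'   the expected per-SNP Fst between subpopulations.
#' @param n_envs Number of environments (>= 2 for phenotype simulation).
#' @param mu Grand mean of the trait, in trait units (percent for
#'   chalkiness-type traits).
#' @param env_effect_sd Standard deviation of the environment main effects
#'   `h_j` (trait units).
#' @param n_mean_qtl,n_plasticity_qtl Number of planted QTL feeding the
#'   genotype main effect and the reaction-norm slope (>= 0).
#' @param mean_qtl_pve,plasticity_qtl_pve Fraction of the variance of the
#'   genotype main effect (resp. slope deviation) attributable to the
#'   planted QTL, in `[0, 1)`.
#' @param polygenic_var Variance of the polygenic (non-QTL) part of the
#'   genotype main effect.
#' @param slope_sd Standard deviation of the non-QTL part of the slope
#'   deviations `b_i`.
#' @param residual_var Median of the genotype-specific residual variance
#'   `sigma^2_i`.
#' @param residual_var_log_sd Standard deviation of `log(sigma^2_i)` across
#'   accessions; positive values create genuine nonlinear plasticity.
#' @param missing_rate Fraction of dosages set missing (default 0).
#' @param n_chrom Number of chromosomes SNPs are laid out on.
#' @param bp_spacing Base-pair spacing between adjacent SNPs.
#' @param clip_percent Clip percent-scale phenotypes to `[0, 100]`?
#' @param seed Master seed; all stochastic draws derive named substreams
#'   from it, so a fixed seed gives bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_accessions = 50, n_snps = 100, seed = 1)
#' @export
sim_config <- function(n_accessions = 500,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.7,
                       n_subpops = 1,
                       divergence = 0,
                       n_envs = 5,
                       mu = 40,
                       env_effect_sd = 5,
                       n_mean_qtl = 3,
                       n_plasticity_qtl = 3,
                       mean_qtl_pve = 0.3,
                       plasticity_qtl_pve = 0.3,
                       polygenic_var = 45,
                       slope_sd = 0.25,
                       residual_var = 1.2,
                       residual_var_log_sd = 0.6,
                       missing_rate = 0,
                       n_chrom = 5,
                       bp_spacing = 5000,
                       clip_percent = TRUE,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_accessions", "n_snps", "ld_block_size", "n_subpops",
              "n_envs", "n_chrom")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1)
      stop_cfg("'%s' must be a count >= 1", nm)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (nm in c("n_mean_qtl", "n_plasticity_qtl")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop_cfg("'%s' must be a count >= 0", nm)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_cfg("'maf_range' must lie in (0, 0.5] with min <= max")
  if (ld_rho < 0 || ld_rho >= 1) stop_cfg("'ld_rho' must be in [0, 1)")
  if (divergence < 0 || divergence >= 1) stop_cfg("'divergence' must be in [0, 1)")
  for (nm in c("mean_qtl_pve", "plasticity_qtl_pve"))
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) stop_cfg("'%s' must be in [0, 1)", nm)
  for (nm in c("env_effect_sd", "polygenic_var", "slope_sd", "residual_var",
               "residual_var_log_sd", "missing_rate"))
    if (cfg[[nm]] < 0) stop_cfg("'%s' must be nonnegative", nm)
  if (missing_rate >= 1) stop_cfg("'missing_rate' must be < 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Simulate a genotype panel with LD blocks and population structure
#'
#' Draws biallelic SNP dosages for a diversity panel. SNP minor-allele
#' frequencies are uniform on `cfg$maf_range`; linkage disequilibrium is
#' induced by a block-equicorrelated latent Gaussian copula thresholded to
#' Hardy-Weinberg haplotypes (two latent draws per accession per SNP), and
#' population structure by Balding-Nichols subpopulation allele frequencies
#' `p_s ~ Beta(p (1-d)/d, (1-p)(1-d)/d)` at divergence `d`.
#'
#' @param cfg A [sim_config()] object.
#' @return A `genotype_matrix`: list with `dosages` (accessions x SNPs minor
#'   allele counts, `NA` = missing), `snps` (data.frame `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `maf` with empirical folded MAF), `accession_ids`,
#'   and `subpop` (accession subpopulation labels).
#' @examples
#' geno <- simulate_genotypes(sim_config(n_accessions = 20, n_snps = 50, seed = 1))
#' dim(geno$dosages)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_accessions; s <- cfg$n_snps
  with_seed(substream_seed(cfg$seed, "genotypes"), {
    p_anc <- stats::runif(s, cfg$maf_range[1], cfg$maf_range[2])
    subpop <- rep_len(seq_len(cfg$n_subpops), n)
    subpop <- subpop[order(subpop)]
    # subpopulation allele frequencies (Balding-Nichols)
    d <- cfg$divergence
    pmat <- matrix(p_anc, cfg$n_subpops, s, byrow = TRUE)
    if (cfg$n_subpops > 1L && d > 0) {
      a <- p_anc * (1 - d) / d
      b <- (1 - p_anc) * (1 - d) / d
      for (k in seq_len(cfg$n_subpops))
        pmat[k, ] <- stats::rbeta(s, a, b)
      pmat <- pmin(pmax(pmat, 1e-4), 1 - 1e-4)
    }
    blocks <- rep(seq_len(ceiling(s / cfg$ld_block_size)),
                  each = cfg$ld_block_size)[seq_len(s)]
    rho <- cfg$ld_rho
    thr <- stats::qnorm(t(pmat))           # s x n_subpops thresholds
    draw_hap <- function() {
      z <- matrix(stats::rnorm(n * s), n, s)
      if (rho > 0) {
        u <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
        z <- sqrt(rho) * u[, blocks, drop = FALSE] + sqrt(1 - rho) * z
      }
      # allele carried if latent value falls under the subpop quantile
      (z < t(thr[, subpop, drop = FALSE])) * 1L
    }
    dos <- draw_hap() + draw_hap()
    # re-draw (without LD) any column fixed by chance so every SNP segregates
    mono <- which(apply(dos, 2L, function(x) length(unique(x)) == 1L))
    for (j in mono) {
      for (tries in 1:25) {
        cand <- stats::rbinom(n, 2L, pmat[subpop, j])
        if (length(unique(cand)) > 1L) { dos[, j] <- cand; break }
      }
    }
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(n * s) < cfg$missing_rate
      dos[miss] <- NA_integer_
    }
    acc <- sprintf("ACC%04d", seq_len(n))
    rownames(dos) <- acc
    # lay SNPs in contiguous chunks over n_chrom chromosomes
    chrom_of <- rep(seq_len(cfg$n_chrom), each = ceiling(s / cfg$n_chrom))[seq_len(s)]
    pos <- integer(s)
    for (c in unique(chrom_of))
      pos[chrom_of == c] <- cfg$bp_spacing * seq_len(sum(chrom_of == c))
    snp_id <- sprintf("chr%d_%d", chrom_of, pos)
    colnames(dos) <- snp_id
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, s, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(alleles, r), 1L), ""))
    # fold to minor-allele dosage coding (swap ref/alt where alt is major)
    f <- colMeans(dos, na.rm = TRUE) / 2
    flip <- f > 0.5
    if (any(flip)) {
      dos[, flip] <- 2L - dos[, flip]
      tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
      f[flip] <- 1 - f[flip]
    }
    geno <- list(
      dosages = dos,
      snps = data.frame(snp_id = snp_id, chrom = paste0("chr", chrom_of),
                        pos = pos, ref = ref, alt = alt,
                        maf = f, stringsAsFactors = FALSE),
      accession_ids = acc,
      subpop = subpop
    )
    class(geno) <- "genotype_matrix"
    geno
  })
}

#' Simulate per-environment temperature covariates
#'
#' Generates an environment table (site/year labels plus minimum, mean and
#' maximum air temperature during the grain-filling window, degrees C). Mean
#' temperatures are drawn around 27 degrees C with ~2 degrees C spread; the
#' phenotype simulator ties the environment main effects `h_j` to these mean
#' temperatures, so warmer environments raise percent-chalkiness traits, as
#' observed in multi-year field trials.
#'
#' @param cfg A [sim_config()] object.
#' @return Data.frame `environment`, `site`, `year`, `tmin`, `tmean`, `tmax`.
#' @export
simulate_environments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(cfg$seed, "environments"), {
    m <- cfg$n_envs
    tmean <- stats::rnorm(m, 27, 2)
    data.frame(
      environment = sprintf("E%02d", seq_len(m)),
      site = rep_len(c("WH", "HN"), m),
      year = 2011L + seq_len(m),
      tmin = tmean - stats::runif(m, 3, 5),
      tmean = tmean,
      tmax = tmean + stats::runif(m, 3, 6),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate multi-environment phenotypes under the reaction-norm model
#'
#' Generates one trait under the genotype-specific Finlay-Wilkinson model
#' \deqn{y_{ij} = \mu + g_i + (1 + b_i) h_j + \varepsilon_{ij},}
#' with genotype main effects \eqn{g_i} built from planted mean-QTL plus a
#' polygenic term, slope deviations \eqn{b_i} from planted plasticity-QTL
#' plus noise, environment effects \eqn{h_j} proportional to the (centred)
#' mean filling-stage temperature, and heteroscedastic residuals
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2_i)} with log-normal
#' genotype-specific variances (the source of nonlinear plasticity).
#' Identifiability conventions \eqn{\sum_j h_j = 0} and
#' \eqn{\mathrm{mean}(b_i) = 0} are imposed at generation.
#'
#' @param geno A `genotype_matrix` from [simulate_genotypes()].
#' @param env An environment table from [simulate_environments()].
#' @param cfg The [sim_config()] used to create both.
#' @param trait Trait id for the generated records (default `"GCR"`).
#' @return List with `pheno` (long data.frame `accession`, `environment`,
#'   `trait`, `value`) and `truth` (a `sim_truth` list holding the planted
#'   QTL ids/effects `alpha_k`, `gamma_k`, the per-accession `g_true`,
#'   `b_true`, `sigma2_i`, per-environment `h_true`, generating variance
#'   components `vc_true`, and the fraction of values clipped).
#' @examples
#' cfg <- sim_config(n_accessions = 30, n_snps = 60, n_envs = 4, seed = 2)
#' geno <- simulate_genotypes(cfg)
#' env <- simulate_environments(cfg)
#' sim <- simulate_phenotypes(geno, env, cfg)
#' head(sim$pheno)
#' @export
simulate_phenotypes <- function(geno, env, cfg, trait = "GCR") {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_matrix"))
  if (cfg$n_envs < 2L) stop_cfg("n_envs must be >= 2: plasticity is undefined in one environment")
  if (nrow(env) != cfg$n_envs || nrow(geno$dosages) != cfg$n_accessions)
    stop_cfg("geno/env dimensions do not match cfg")
  n <- cfg$n_accessions; m <- cfg$n_envs
  X <- geno$dosages
  X[is.na(X)] <- matrix(colMeans(X, na.rm = TRUE), n, ncol(X), byrow = TRUE)[is.na(X)]
  with_seed(substream_seed(cfg$seed, paste0("phenotypes_", trait)), {
    scaled_qtl <- function(n_qtl, target_pve, background_var) {
      if (n_qtl == 0L || target_pve <= 0)
        return(list(idx = integer(0), eff = numeric(0), val = numeric(n)))
      idx <- sample(ncol(X), n_qtl)
      eff <- stats::rnorm(n_qtl)
      val <- drop(X[, idx, drop = FALSE] %*% eff)
      v <- stats::var(val)
      target <- target_pve / (1 - target_pve) * background_var
      sc <- if (v > 0) sqrt(target / v) else 0
      list(idx = idx, eff = eff * sc, val = val * sc)
    }
    mq <- scaled_qtl(cfg$n_mean_qtl, cfg$mean_qtl_pve, cfg$polygenic_var)
    g <- mq$val + stats::rnorm(n, 0, sqrt(cfg$polygenic_var))
    pq <- scaled_qtl(cfg$n_plasticity_qtl, cfg$plasticity_qtl_pve, cfg$slope_sd^2)
    b <- pq$val + stats::rnorm(n, 0, cfg$slope_sd)
    b <- b - mean(b)
    # environment effects follow mean filling-stage temperature exactly
    h <- env$tmean - mean(env$tmean)
    if (stats::sd(h) > 0 && cfg$env_effect_sd > 0) {
      h <- h / stats::sd(h) * cfg$env_effect_sd
    } else {
      h <- rep(0, m)
    }
    sigma2 <- if (cfg$residual_var > 0)
      exp(stats::rnorm(n, log(cfg$residual_var), cfg$residual_var_log_sd))
    else rep(0, n)
    eps <- matrix(stats::rnorm(n * m, 0, sqrt(sigma2)), n, m)
    y <- cfg$mu + g + outer(1 + b, h) + eps
    clipped <- 0
    if (cfg$clip_percent && is_percent_trait(trait)) {
      clipped <- mean(y < 0 | y > 100)
      y <- pmin(pmax(y, 0), 100)
    }
    pheno <- data.frame(
      accession = rep(geno$accession_ids, times = m),
      environment = rep(env$environment, each = n),
      trait = trait,
      value = as.vector(y),
      stringsAsFactors = FALSE
    )
    truth <- structure(list(
      trait = trait,
      mean_qtl = geno$snps$snp_id[mq$idx], alpha_k = mq$eff,
      plasticity_qtl = geno$snps$snp_id[pq$idx], gamma_k = pq$eff,
      g_true = stats::setNames(g, geno$accession_ids),
      b_true = stats::setNames(b, geno$accession_ids),
      h_true = stats::setNames(h, env$environment),
      sigma2_i = stats::setNames(sigma2, geno$accession_ids),
      vc_true = c(Vg = stats::var(g), VE = stats::var(h) * (m - 1) / m,
                  Vb = stats::var(b), Ve = mean(sigma2)),
      clipped_fraction = clipped
    ), class = "sim_truth")
    list(pheno = pheno, truth = truth)
  })
}
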