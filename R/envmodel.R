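#' DIFF scores against a high-temperature reference environment
#'
#' Per accession and per non-reference environment, the signed difference
#' between the phenotype in the reference environment and the phenotype in
#' the comparison environment — a sensitive indicator of
#' temperature-driven plasticity. For percent-scale traits the score lies
#' in `[-100, 100]`.
#'
#' @param pheno Long phenotype data.frame.
#' @param trait Trait id.
#' @param ref_env Reference (e.g. high-temperature) environment id.
#' @return Data.frame `accession`, `trait`, `ref_env`, `environment`,
#'   `value`; accessions lacking either member of a pair are omitted.
#' @export
diff_score <- function(pheno, trait, ref_env) {
  Y <- pheno_wide(pheno, trait)
  if (!ref_env %in% colnames(Y))
    stop_cfg("reference environment '%s' not present", ref_env)
  others <- setdiff(colnames(Y), ref_env)
  out <- do.call(rbind, lapply(others, function(e) {
    ok <- !is.na(Y[, ref_env]) & !is.na(Y[, e])
    data.frame(accession = rownames(Y)[ok], trait = trait, ref_env = ref_env,
               environment = e, value = Y[ok, ref_env] - Y[ok, e],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-genotype environment-response regression (PPRE)
#'
#' Regresses each accession's phenotype across environments on an
#' environmental index (e.g. filling-stage temperature, or grain width per
#' environment). The per-accession intercept and slope separate endogenous
#' from exogenous signal, and the mean of the per-accession R-squared
#' summarises how much of the plasticity the index explains.
#'
#' @param pheno Long phenotype data.frame.
#' @param trait Trait id.
#' @param env_index Named numeric vector, one value per environment.
#' @return List with `per_accession` (data.frame `accession`, `intercept`,
#'   `slope`, `r2`, `n_env`) and `mean_r2`. Accessions observed in fewer
#'   than 3 environments get `NA` rows (excluded from `mean_r2`); a
#'   zero-variance response has `slope = 0`, `r2 = 0` by convention.
#' @export
ppre_fit <- function(pheno, trait, env_index) {
  Y <- pheno_wide(pheno, trait)
  if (is.null(names(env_index)))
    stop_cfg("env_index must be named by environment id")
  envs <- intersect(colnames(Y), names(env_index))
  if (length(envs) < 3L) stop_cfg("PPRE needs >= 3 environments with an index")
  Y <- Y[, envs, drop = FALSE]
  x_all <- env_index[envs]
  if (stats::var(x_all) == 0) stop_cfg("constant environmental index: slope inestimable")
  per <- do.call(rbind, lapply(seq_len(nrow(Y)), function(i) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) < 3L || stats::var(x_all[ok]) == 0)
      return(data.frame(accession = rownames(Y)[i], intercept = NA_real_,
                        slope = NA_real_, r2 = NA_real_, n_env = sum(ok)))
    yi <- Y[i, ok]; xi <- x_all[ok]
    if (stats::var(yi) == 0)
      return(data.frame(accession = rownames(Y)[i], intercept = mean(yi),
                        slope = 0, r2 = 0, n_env = sum(ok)))
    sl <- stats::cov(yi, xi) / stats::var(xi)
    ic <- mean(yi) - sl * mean(xi)
    r2 <- stats::cor(yi, xi)^2
    data.frame(accession = rownames(Y)[i], intercept = ic, slope = sl,
               r2 = r2, n_env = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_accession = per, mean_r2 = mean(per$r2, na.rm = TRUE))
}

#' Correlation of a per-environment trait statistic with temperature
#'
#' Pearson correlation (with two-tailed p-value) between a per-environment
#' summary of the trait (mean or CV) and one of the temperature series of
#' the environment table — the mean-temperature and CV-temperature
#' correlations that reveal the external driver of the mean-plasticity
#' trade-off.
#'
#' @param pheno Long phenotype data.frame.
#' @param trait Trait id.
#' @param env Environment table with `environment` and temperature columns.
#' @param stat `"mean"` or `"cv"`.
#' @param temp `"tmin"`, `"tmean"` or `"tmax"`.
#' @return List with `estimate` (Pearson r), `p_value`, `n` (environments),
#'   `stat`, `temp`.
#' @export
env_correlation <- function(pheno, trait, env, stat = c("mean", "cv"),
                            temp = c("tmax", "tmean", "tmin")) {
  stat <- match.arg(stat); temp <- match.arg(temp)
  ts <- trait_summary(pheno, trait, by_environment = TRUE)
  m <- merge(ts, env, by = "environment")
  if (nrow(m) < 3L) stop_cfg("env_correlation needs >= 3 environments")
  x <- m[[temp]]
  y <- if (stat == "mean") m$mean else m$cv
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = nrow(m),
       stat = stat, temp = temp)
}

#' Bootstrap distribution of a statistic
#'
#' `n_boot` with-replacement resamples of the input (each of the original
#' size), returning the statistic on each resample; deterministic under the
#' seed. Defaults cover the summaries bootstrapped for per-environment
#' phenotype and CV displays.
#'
#' @param values Non-empty numeric vector.
#' @param statistic A function, or one of `"mean"`, `"cv"`.
#' @param n_boot Number of resamples (default 1000).
#' @param seed Seed.
#' @return Numeric vector of `n_boot` resampled statistics.
#' @export
bootstrap_resample <- function(values, statistic = "mean", n_boot = 1000,
                               seed = 1) {
  if (length(values) == 0L) stop_cfg("empty input")
  f <- if (is.function(statistic)) statistic
       else switch(statistic,
                   mean = mean,
                   cv = function(v) stats::sd(v) / mean(v) * 100,
                   stop_cfg("unknown statistic '%s'", statistic))
  with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) f(sample(values, length(values), replace = TRUE)), 0)
  })
}

#' Pleiotropy regression of one trait component on another
#'
#' Simple linear regression of a chalkiness component on a grain-width
#' component (mean on mean, plasticity on plasticity): the R-squared, as a
#' percentage, is the variance in chalkiness explained by width, and the
#' slope its direction.
#'
#' @param width Per-accession predictor values (e.g. grain-width means).
#' @param chalk Per-accession response values, same order/names.
#' @return List with `pve` (R-squared x 100), `slope`, `intercept`,
#'   `p_value`, `n`.
#' @export
width_effect_regression <- function(width, chalk) {
  if (!is.null(names(width)) && !is.null(names(chalk))) {
    common <- intersect(names(width), names(chalk))
    width <- width[common]; chalk <- chalk[common]
  }
  ok <- !is.na(width) & !is.na(chalk)
  width <- width[ok]; chalk <- chalk[ok]
  if (length(width) < 3L) stop_cfg("need >= 3 paired observations")
  if (stats::var(width) == 0) stop_cfg("zero-variance predictor")
  fit <- stats::lm(chalk ~ width)
  s <- summary(fit)
  list(pve = s$r.squared * 100, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = s$coefficients[2, 4], n = length(width))
}
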