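# ANOVA method-of-moments components for a balanced crossed layout
# (r = 1: additive model, interaction confounded with residual).
mom_gxe_balanced <- function(value, Line, Env, r) {
  n <- nlevels(Line); m <- nlevels(Env)
  cell <- tapply(value, list(Line, Env), mean)
  ybar <- mean(value)
  ms_a <- m * r * sum((rowMeans(cell) - ybar)^2) / (n - 1)
  ms_b <- n * r * sum((colMeans(cell) - ybar)^2) / (m - 1)
  ms_ab <- r * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") + ybar)^2) /
    ((n - 1) * (m - 1))
  if (r > 1) {
    ss_tot <- sum((value - ybar)^2)
    ms_e <- (ss_tot - r * sum((cell - ybar)^2)) / (n * m * (r - 1))
    c(Vg = (ms_a - ms_ab) / (m * r), VE = (ms_b - ms_ab) / (n * r),
      VGE = (ms_ab - ms_e) / r, Ve = ms_e)
  } else {
    c(Vg = (ms_a - ms_ab) / m, VE = (ms_b - ms_ab) / n, VGE = NA, Ve = ms_ab)
  }
}

# One EM-REML update of the variance components via the mixed-model
# equations. Z-blocks: Line always, Env always, Line:Env when withGE.
# Returns the updated component vector c(Vg, VE[, VGE], Ve).
em_update_gxe <- function(y, Li, Ei, n, m, vc, withGE) {
  N <- length(y)
  sigma_e <- vc[length(vc)]
  q <- if (withGE) c(n, m, n * m) else c(n, m)
  lambda <- sigma_e / vc[seq_along(q)]
  GEi <- if (withGE) (Li - 1L) * m + Ei else NULL
  # design cross-products (intercept + random blocks), all sparse patterns
  # expressible through tabulations
  off <- cumsum(c(1L, q))          # block offsets after the intercept
  dim_m <- 1L + sum(q)
  M <- matrix(0, dim_m, dim_m)
  rhs <- numeric(dim_m)
  M[1L, 1L] <- N
  rhs[1L] <- sum(y)
  idx <- list(Li, Ei, GEi)
  for (k in seq_along(q)) {
    rows <- off[k] + seq_len(q[k])
    cnt <- tabulate(idx[[k]], q[k])
    M[cbind(rows, rows)] <- cnt + lambda[k]
    M[rows, 1L] <- M[1L, rows] <- cnt
    rk <- numeric(q[k])
    rs <- rowsum(y, idx[[k]])
    rk[as.integer(rownames(rs))] <- rs[, 1L]
    rhs[rows] <- rk
    if (k > 1L) for (k2 in seq_len(k - 1L)) {
      rows2 <- off[k2] + seq_len(q[k2])
      ct <- table(factor(idx[[k]], levels = seq_len(q[k])),
                  factor(idx[[k2]], levels = seq_len(q[k2])))
      M[rows, rows2] <- as.numeric(ct)
      M[rows2, rows] <- t(ct)
    }
  }
  Cinv <- chol2inv(chol(M))
  sol <- Cinv %*% rhs
  vc_new <- numeric(length(vc))
  for (k in seq_along(q)) {
    rows <- off[k] + seq_len(q[k])
    u <- sol[rows]
    vc_new[k] <- (sum(u^2) + sigma_e * sum(diag(Cinv)[rows])) / q[k]
  }
  vc_new[length(vc)] <- (sum(y^2) - sum(sol * rhs)) / (N - 1L)
  vc_new
}

# EM-REML iteration with Aitken extrapolation; tol on relative change.
em_reml_gxe <- function(y, Li, Ei, n, m, init, withGE,
                        tol = 1e-8, max_iter = 5000) {
  vc <- pmax(init, 1e-8 * stats::var(y))
  prev <- NULL; prev2 <- NULL
  for (it in seq_len(max_iter)) {
    vc_new <- em_update_gxe(y, Li, Ei, n, m, vc, withGE)
    vc_new <- pmax(vc_new, 1e-10 * stats::var(y))
    # components driven to the boundary are treated as converged-to-zero;
    # EM approaches zero geometrically and never satisfies a relative test
    active <- vc_new > 1e-6 * stats::var(y)
    if (!any(active) ||
        max(abs(vc_new[active] - vc[active]) / pmax(vc[active], 1e-12)) < tol)
      return(list(vc = vc_new, iterations = it, converged = TRUE))
    # Aitken delta-squared extrapolation every third sweep
    if (!is.null(prev2) && it %% 3L == 0L) {
      d1 <- prev - prev2; d2 <- vc_new - prev
      denom <- d2 - d1
      acc <- ifelse(abs(denom) > 1e-12, prev2 - d1^2 / denom, vc_new)
      if (all(is.finite(acc)) && all(acc > 0)) vc_new <- acc
    }
    prev2 <- prev; prev <- vc_new; vc <- vc_new
  }
  list(vc = vc, iterations = max_iter, converged = FALSE)
}

#' Genotype / environment / GxE variance components by REML
#'
#' Fits the crossed random-effects model
#' `value ~ (1|Line) + (1|Env) + (1|Line:Env)` by REML and extracts the
#' genotype (`Vg`), environment (`VE`), interaction (`VGE`) and residual
#' (`Ve`) variance components. The reported components come from an
#' EM-REML solver on the mixed-model equations (Aitken-accelerated, max
#' 5000 sweeps, relative tolerance 1e-8), initialized at the ANOVA
#' method-of-moments estimates — on balanced data with interior moment
#' estimates these are the exact REML solution, which the first EM sweep
#' confirms. A parallel `lme4` fit is kept for downstream BLUPs and
#' likelihood-ratio tests. With a single observation per Line-by-Env
#' cell the interaction and residual variances are confounded: the
#' interaction term is then dropped and the residual variance reported as
#' the confounded sum `VGE + Ve` (with `VGE = NA`).
#'
#' @param pheno Long phenotype data.frame (`accession`, `environment`,
#'   `trait`, `value`).
#' @param trait Trait id.
#' @return An object of class `gxe_varcomp`: list with `Vg`, `VE`, `VGE`,
#'   `Ve`, `VGE_plus_Ve`, `m` (environments), `n` (accessions),
#'   `replicated` (any cell with > 1 observation), `H2`
#'   (via [broad_sense_heritability()]) and the underlying `lme4` fit in
#'   `$fit` (used by [blup_genotype_effects()] and [lrt_random_effect()]).
#' @examples
#' cfg <- sim_config(n_accessions = 40, n_snps = 30, n_envs = 4, seed = 4)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg),
#'                            simulate_environments(cfg), cfg)
#' vc <- fit_gxe_variance_components(sim$pheno, "GCR")
#' vc$H2
#' @export
fit_gxe_variance_components <- function(pheno, trait) {
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (nrow(d) == 0L) stop_cfg("trait '%s' not present", trait)
  d$Line <- factor(d$accession)
  d$Env <- factor(d$environment)
  n <- nlevels(d$Line); m <- nlevels(d$Env)
  if (n < 2L || m < 2L) stop_cfg("need >= 2 accessions and >= 2 environments")
  replicated <- anyDuplicated(paste(d$Line, d$Env)) > 0L
  form <- if (replicated)
    value ~ (1 | Line) + (1 | Env) + (1 | Line:Env)
  else
    value ~ (1 | Line) + (1 | Env)
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(term) {
    i <- match(term, vcdf$grp)
    if (is.na(i)) NA_real_ else vcdf$vcov[i]
  }
  lme4_est <- if (replicated)
    c(get_vc("Line"), get_vc("Env"), get_vc("Line:Env"),
      vcdf$vcov[vcdf$grp == "Residual"])
  else
    c(get_vc("Line"), get_vc("Env"), vcdf$vcov[vcdf$grp == "Residual"])

  Li <- as.integer(d$Line); Ei <- as.integer(d$Env)
  cell_counts <- table(d$Line, d$Env)
  r <- nrow(d) / (n * m)
  balanced <- all(cell_counts == r)
  init <- lme4_est
  if (balanced) {
    mom <- mom_gxe_balanced(d$value, d$Line, d$Env, r)
    mom_vec <- if (replicated) unname(mom) else unname(mom[c("Vg", "VE", "Ve")])
    if (all(mom_vec > 0)) init <- mom_vec
  }
  em <- em_reml_gxe(d$value, Li, Ei, n, m, init, withGE = replicated)
  if (!em$converged)
    stop_cfg("EM-REML did not converge in %d iterations; last iterate: %s",
             em$iterations, paste(signif(em$vc, 6), collapse = ", "))
  if (replicated) {
    Vg <- em$vc[1]; VE <- em$vc[2]; VGE <- em$vc[3]; Ve <- em$vc[4]
    conf <- VGE + Ve
  } else {
    Vg <- em$vc[1]; VE <- em$vc[2]; VGE <- NA_real_; Ve <- em$vc[3]
    conf <- Ve
  }
  out <- structure(list(Vg = Vg, VE = VE, VGE = VGE, Ve = Ve,
                        VGE_plus_Ve = conf, m = m, n = n,
                        replicated = replicated, trait = trait,
                        fit = fit, data = d),
                   class = "gxe_varcomp")
  out$H2 <- broad_sense_heritability(out)
  out
}

#' Broad-sense heritability of a multi-environment trait
#'
#' Computes
#' \deqn{H^2 = \frac{V_g}{V_g + V_E + V_{GE}/m + V_e/(n m)},}
#' where `m` is the number of environments and `n` the number of
#' individuals. The residual term is read as `Ve/(n*m)` (the only reading
#' that shrinks with more data); the literal alternative `(Ve/n)*m` is
#' available via `ve_reading = "ve_over_n_times_m"`. The environment
#' variance sits in the denominator by the formula's definition, which makes
#' this an entire-experiment heritability rather than a line-mean one. When
#' interaction and residual variances are confounded (single observation per
#' cell) their sum takes the interaction slot: denominator
#' `Vg + VE + (VGE+Ve)/m`.
#'
#' @param vc A `gxe_varcomp` object, or a list/vector with elements `Vg`,
#'   `VE`, `VGE`, `Ve`, `m`, `n`.
#' @param ve_reading `"ve_over_nm"` (default) or `"ve_over_n_times_m"`.
#' @return Heritability in `[0, 1]`.
#' @examples
#' broad_sense_heritability(list(Vg = 2, VE = 1, VGE = 1, Ve = 1, m = 5, n = 4))
#' @export
broad_sense_heritability <- function(vc,
                                     ve_reading = c("ve_over_nm",
                                                    "ve_over_n_times_m")) {
  ve_reading <- match.arg(ve_reading)
  v <- lapply(c("Vg", "VE", "VGE", "Ve", "m", "n"), function(k) vc[[k]])
  names(v) <- c("Vg", "VE", "VGE", "Ve", "m", "n")
  if (v$m < 1 || v$n < 1) stop_cfg("m and n must be >= 1")
  if (is.na(v$VGE)) {
    denom <- v$Vg + v$VE + v$Ve / v$m  # Ve holds the confounded VGE + Ve
  } else {
    ve_term <- if (ve_reading == "ve_over_nm") v$Ve / (v$n * v$m)
               else v$Ve / v$n * v$m
    denom <- v$Vg + v$VE + v$VGE / v$m + ve_term
  }
  if (denom == 0) stop_cfg("all variance components are zero: H2 undefined")
  v$Vg / denom
}

#' Likelihood-ratio test of a random term in the GxE model
#'
#' Compares the full crossed model with the model dropping one random term,
#' both fitted by REML; the statistic is twice the REML log-likelihood
#' difference (clamped at zero). Because the null value of a variance
#' component lies on the boundary of its parameter space, the default
#' reference distribution is the 50:50 mixture of a point mass at zero and
#' chi-squared with 1 df; a plain chi-squared(1) reference is available via
#' `mixture = FALSE`.
#'
#' @inheritParams fit_gxe_variance_components
#' @param term One of `"Line"`, `"Env"`, `"Line:Env"`.
#' @param mixture Use the boundary-corrected mixture null (default `TRUE`).
#' @return List with `statistic`, `p_value`, `term`.
#' @export
lrt_random_effect <- function(pheno, trait, term = c("Line", "Env", "Line:Env"),
                              mixture = TRUE) {
  term <- match.arg(term)
  vc <- fit_gxe_variance_components(pheno, trait)
  if (term == "Line:Env" && !vc$replicated)
    stop_cfg("Line:Env is not separable from the residual without replicates")
  d <- vc$data
  all_terms <- if (vc$replicated) c("Line", "Env", "Line:Env") else c("Line", "Env")
  keep <- setdiff(all_terms, term)
  rhs <- paste(sprintf("(1 | %s)", keep), collapse = " + ")
  red_form <- stats::as.formula(paste("value ~", if (nzchar(rhs)) rhs else "1"))
  red <- if (length(keep))
    lme4::lmer(red_form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  else stats::lm(value ~ 1, data = d)
  ll_full <- as.numeric(stats::logLik(vc$fit))
  ll_red <- as.numeric(stats::logLik(red, REML = TRUE))
  stat <- max(0, 2 * (ll_full - ll_red))
  p <- if (stat <= 0) 1
       else if (mixture) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
       else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, term = term, mixture = mixture)
}

#' BLUPs of genotype effects across environments
#'
#' Best linear unbiased predictions of the random Line effects from the
#' crossed GxE model — the multi-environment genotype values used downstream
#' as the response for marker selection. For balanced single-factor data the
#' predictions reduce to the textbook shrinkage
#' `Vg/(Vg + Ve/m) * (accession mean - grand mean)`.
#'
#' @param pheno Long phenotype data.frame; must cover the accessions of `vc`.
#' @param trait Trait id.
#' @param vc Optional pre-fitted `gxe_varcomp` on the same data (refitted
#'   when omitted).
#' @return A data.frame of class `blup_table` with columns `accession` and
#'   `blup`; attribute `shrinkage` gives the balanced-design shrinkage
#'   factor implied by the fitted components.
#' @export
blup_genotype_effects <- function(pheno, trait, vc = NULL) {
  if (is.null(vc)) vc <- fit_gxe_variance_components(pheno, trait)
  re <- lme4::ranef(vc$fit)$Line
  out <- data.frame(accession = rownames(re), blup = re[[1]],
                    stringsAsFactors = FALSE)
  resid_var <- if (vc$replicated) vc$VGE + vc$Ve else vc$Ve
  attr(out, "shrinkage") <- if (vc$Vg + resid_var / vc$m > 0)
    vc$Vg / (vc$Vg + resid_var / vc$m) else 0
  class(out) <- c("blup_table", "data.frame")
  out
}
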