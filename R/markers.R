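new_marker_model <- function(snps, coefficients, intercept, lambda, pve, aic) {
  structure(list(snps = snps, coefficients = coefficients,
                 intercept = intercept, lambda = lambda, pve = pve,
                 aic = aic),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("marker model: %d SNP(s), PVE %.1f%%, AIC %.2f\n",
              length(x$snps), x$pve, x$aic))
  invisible(x)
}

# AIC on the n*log(RSS/n) + 2k scale (k counts regression coefficients
# including the intercept), matching extractAIC() for lm fits.
rss_aic <- function(rss, n, k) n * log(rss / n) + 2 * k

refit_lm <- function(snps, geno_subset, y) {
  if (length(snps) == 0L)
    return(list(fit = NULL, r2 = 0,
                aic = rss_aic(sum((y - mean(y))^2), length(y), 1L)))
  missing <- setdiff(snps, colnames(geno_subset$dosages))
  if (length(missing))
    stop_cfg("selected SNP(s) absent from genotype subset: %s",
             paste(missing, collapse = ", "))
  X <- impute_dosages(geno_subset$dosages[, snps, drop = FALSE])
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  list(fit = fit, r2 = summary(fit)$r.squared,
       aic = stats::extractAIC(fit)[2])
}

impute_dosages <- function(X) {
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1L) %/% nrow(X) + 1L]
  X
}

#' LASSO selection of a minimal marker set
#'
#' Selects predictive SNPs for a per-accession phenotype (a raw trait value,
#' a reaction-norm component or a multi-environment BLUP) by
#' cross-validated LASSO on a candidate SNP panel. Near-duplicate SNPs are
#' pre-filtered (one of any pair with `r^2 > 0.95` dropped, keeping the
#' higher-MAF member), fold assignment is a seeded random permutation, the
#' penalty is chosen at the cross-validation minimum
#' (`lambda_rule = "1se"` for the sparser one-standard-error rule), and the
#' SNPs with nonzero coefficients form the marker set. The reported PVE and
#' AIC come from the unpenalized refit (see [model_pve()]).
#'
#' @param geno_subset A `genotype_matrix` restricted to candidate SNPs.
#' @param pheno Named per-accession numeric response.
#' @param k_folds Cross-validation folds (default 10; `n >= k_folds`).
#' @param seed Seed controlling fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param lambda Optional fixed penalty; when supplied, cross-validation is
#'   skipped and the LASSO is solved at this value (`0` gives the ordinary
#'   least-squares limit on a full-rank design).
#' @return A `marker_model`: selected `snps`, LASSO `coefficients`,
#'   `intercept`, chosen `lambda`, refit `pve` (percent) and `aic`.
#' @export
lasso_select <- function(geno_subset, pheno, k_folds = 10, seed = 1,
                         lambda_rule = c("min", "1se"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  X <- geno_subset$dosages
  if (!is.null(names(pheno))) {
    common <- intersect(rownames(X), names(pheno))
    X <- X[common, , drop = FALSE]
    pheno <- pheno[common]
  }
  ok <- !is.na(pheno)
  X <- impute_dosages(X[ok, , drop = FALSE])
  y <- as.numeric(pheno[ok])
  n <- length(y)
  if (n < k_folds) stop_cfg("need n >= k_folds")
  if (stats::var(y) == 0) stop_cfg("constant phenotype")
  # collinearity pre-filter: drop one of any r^2 > 0.95 pair (keep higher MAF)
  maf <- geno_subset$snps$maf[match(colnames(X), geno_subset$snps$snp_id)]
  v <- apply(X, 2L, stats::var)
  keep <- v > 0
  if (ncol(X) > 1L) {
    ord <- order(-maf)
    R <- suppressWarnings(stats::cor(X[, ord, drop = FALSE]))
    R[is.na(R)] <- 0
    for (j in seq_along(ord)[-1L]) {
      if (!keep[ord[j]]) next
      prev <- ord[seq_len(j - 1L)]
      prev <- prev[keep[prev]]
      if (length(prev) && any(R[j, match(prev, ord)]^2 > 0.95, na.rm = TRUE))
        keep[ord[j]] <- FALSE
    }
  }
  Xk <- X[, keep, drop = FALSE]
  if (is.null(lambda)) {
    foldid <- with_seed(substream_seed(seed, "lasso_folds"),
                        sample(rep_len(seq_len(k_folds), n)))
    cv <- glmnet::cv.glmnet(Xk, y, alpha = 1, foldid = foldid,
                            standardize = TRUE, thresh = 1e-10)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- stats::coef(cv, s = lam)
  } else {
    lam <- lambda
    fit <- glmnet::glmnet(Xk, y, alpha = 1, standardize = TRUE,
                          thresh = 1e-12)
    cf <- stats::coef(fit, s = lam, exact = TRUE, x = Xk, y = y,
                      thresh = 1e-12)
  }
  nz <- which(cf[-1L] != 0)
  snps <- colnames(Xk)[nz]
  rf <- refit_lm(snps, geno_subset, stats::setNames(y, rownames(Xk)))
  new_marker_model(snps = snps,
                   coefficients = stats::setNames(as.numeric(cf[-1L][nz]), snps),
                   intercept = as.numeric(cf[1L]),
                   lambda = lam, pve = rf$r2 * 100, aic = rf$aic)
}

#' Backward stepwise AIC pruning of a marker model
#'
#' Greedy backward elimination from the LASSO-selected SNPs on the
#' unpenalized linear model: a term is dropped only while doing so lowers
#' the AIC (`n log(RSS/n) + 2k` convention), so the final AIC never exceeds
#' the initial one.
#'
#' @param model A `marker_model` (e.g. from [lasso_select()]).
#' @param geno_subset The `genotype_matrix` the model was fitted on.
#' @param pheno Named per-accession response used for the fit.
#' @return A pruned `marker_model` (coefficients from the unpenalized
#'   refit); returned unchanged if the starting model is empty.
#' @export
stepwise_prune <- function(model, geno_subset, pheno) {
  if (length(model$snps) == 0L) return(model)
  X <- geno_subset$dosages
  if (!is.null(names(pheno))) {
    common <- intersect(rownames(X), names(pheno))
    X <- X[common, , drop = FALSE]
    pheno <- pheno[common]
  }
  ok <- !is.na(pheno)
  X <- impute_dosages(X[ok, model$snps, drop = FALSE])
  y <- as.numeric(pheno[ok])
  df <- data.frame(y = y, X, check.names = FALSE)
  full <- stats::lm(y ~ ., data = df)
  pruned <- MASS::stepAIC(full, direction = "backward", trace = 0)
  kept <- setdiff(names(stats::coef(pruned)), "(Intercept)")
  kept <- gsub("^`|`$", "", kept)
  new_marker_model(
    snps = kept,
    coefficients = stats::setNames(
      as.numeric(stats::coef(pruned)[-1L]), kept),
    intercept = unname(stats::coef(pruned)[1L]),
    lambda = model$lambda,
    pve = summary(pruned)$r.squared * 100,
    aic = stats::extractAIC(pruned)[2]
  )
}

#' Model PVE of a marker set
#'
#' Percent of phenotypic variance explained by the unpenalized linear model
#' refitted on the selected SNPs (in-sample R-squared x 100).
#'
#' @param model A `marker_model`.
#' @param geno_subset `genotype_matrix` holding the selected SNPs.
#' @param pheno Named per-accession response.
#' @return PVE in `[0, 100]` (0 for an empty model).
#' @export
model_pve <- function(model, geno_subset, pheno) {
  X <- geno_subset$dosages
  if (!is.null(names(pheno))) {
    common <- intersect(rownames(X), names(pheno))
    geno_subset$dosages <- X[common, , drop = FALSE]
    pheno <- pheno[common]
  }
  ok <- !is.na(pheno)
  geno_subset$dosages <- geno_subset$dosages[ok, , drop = FALSE]
  refit_lm(model$snps, geno_subset, as.numeric(pheno[ok]))$r2 * 100
}

#' Combined mean-plus-plasticity marker model
#'
#' Fits the unpenalized linear model on the union of a mean-component and a
#' plasticity-component marker set (duplicated ids deduplicated with a
#' warning). The response may be a raw phenotype, a reaction-norm component
#' or a multi-environment BLUP table. Because the models are nested, the
#' combined in-sample PVE is at least the larger single-set PVE on the same
#' data.
#'
#' @param mean_snps,plasticity_snps Character vectors of SNP ids.
#' @param geno A `genotype_matrix` holding all of them.
#' @param pheno Named per-accession response, or a `blup_table`.
#' @return A `marker_model` on the union set.
#' @export
combined_model <- function(mean_snps, plasticity_snps, geno, pheno) {
  if (inherits(pheno, "blup_table"))
    pheno <- stats::setNames(pheno$blup, pheno$accession)
  both <- c(mean_snps, plasticity_snps)
  if (anyDuplicated(both))
    warning("duplicated SNP ids in the union deduplicated")
  snps <- unique(both)
  if (length(snps) == 0L) stop_cfg("union of marker sets is empty")
  X <- geno$dosages
  common <- if (!is.null(names(pheno))) intersect(rownames(X), names(pheno))
            else rownames(X)
  sub <- geno
  sub$dosages <- X[common, , drop = FALSE]
  y <- pheno[common]
  ok <- !is.na(y)
  sub$dosages <- sub$dosages[ok, , drop = FALSE]
  rf <- refit_lm(snps, sub, as.numeric(y[ok]))
  cf <- stats::coef(rf$fit)
  kept <- gsub("^`|`$", "", setdiff(names(cf), "(Intercept)"))
  new_marker_model(snps = snps,
                   coefficients = stats::setNames(as.numeric(cf[-1L]), kept),
                   intercept = unname(cf[1L]),
                   lambda = NA_real_, pve = rf$r2 * 100, aic = rf$aic)
}
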