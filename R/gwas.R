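#' Standardized kinship (genomic relatedness) matrix
#'
#' Builds the accession-by-accession relatedness matrix used as the random
#' effect covariance in the mixed-model scan: each SNP column is mean
#' imputed, centred and scaled to unit variance, and `K = Z Z' / S` over the
#' `S` polymorphic SNPs (the standardized construction; the allele-frequency
#' centred alternative is available via `method = "centered"`). Monomorphic
#' SNPs are excluded with a message.
#'
#' @param geno A `genotype_matrix` (see [simulate_genotypes()] /
#'   [read_genotypes()]).
#' @param method `"standardized"` (default) or `"centered"`.
#' @return Symmetric positive semidefinite matrix with accession dimnames.
#' @export
compute_kinship <- function(geno, method = c("standardized", "centered")) {
  method <- match.arg(method)
  X <- geno$dosages
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1L) %/% nrow(X) + 1L]
  v <- apply(X, 2L, stats::var)
  mono <- v == 0 | is.na(v)
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) excluded from kinship")
    X <- X[, !mono, drop = FALSE]
  }
  if (ncol(X) == 0L) stop_cfg("no polymorphic SNPs left for kinship")
  Z <- if (method == "standardized") scale(X)
       else {
         p <- colMeans(X) / 2
         sweep(X, 2L, 2 * p)
       }
  K <- tcrossprod(Z) / ncol(Z)
  if (method == "centered") K <- K / mean(diag(K))
  dimnames(K) <- list(rownames(geno$dosages), rownames(geno$dosages))
  K
}

# REML profile log-likelihood for the variance ratio delta in the rotated
# model; d = eigenvalues of K, yr/Xr = rotated response and fixed effects.
reml_ll_delta <- function(log_delta, d, yr, Xr) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xr, Xr * w)
  XtWy <- crossprod(Xr, yr * w)
  beta <- solve(XtWX, XtWy)
  r <- yr - Xr %*% beta
  np <- length(yr) - ncol(Xr)
  rss <- sum(w * r^2)
  s2 <- rss / np
  -0.5 * (np * (log(2 * pi * s2) + 1) + sum(log(d + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

#' Single-marker linear mixed-model association scan
#'
#' Tests each SNP for association with a per-accession phenotype under the
#' mixed model `y = X b + x beta + u + e`, `u ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_g^2 delta I)`, using the spectral decomposition of the
#' kinship matrix. The variance ratio `delta` is estimated once by REML
#' under the null model and reused for every SNP (the standard
#' population-parameters-previously-determined approximation;
#' `method = "exact"` re-profiles `delta` per SNP). Each SNP then gets a
#' generalized-least-squares Wald t-test, its minor-allele frequency,
#' effective sample size (non-missing genotypes among phenotyped
#' accessions) and per-SNP variance explained via [snp_pve()].
#'
#' @param pheno_vector Named per-accession phenotype (names = accession
#'   ids); accessions with missing phenotype are dropped with a message.
#' @param geno A `genotype_matrix`.
#' @param K Kinship matrix from [compute_kinship()]; `NULL` computes it.
#' @param covariates Optional numeric matrix of fixed covariates (rows =
#'   accessions, aligned with `pheno_vector` names).
#' @param method `"emmax"` (null-model delta, default) or `"exact"`.
#' @param trait,category Metadata tags copied into the result (category is
#'   one of the scan families: mean, linear/nonlinear plasticity,
#'   environment-specific, condition-specific, grain width).
#' @return A data.frame of class `gwas_result`: `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `p_value`, `maf`, `n_effective`, `pve`, with attributes
#'   `trait`, `category`, `delta`, `n_dropped`.
#' @export
lmm_scan <- function(pheno_vector, geno, K = NULL, covariates = NULL,
                     method = c("emmax", "exact"),
                     trait = NA_character_, category = NA_character_) {
  method <- match.arg(method)
  if (is.null(names(pheno_vector)))
    names(pheno_vector) <- rownames(geno$dosages)
  acc <- intersect(rownames(geno$dosages), names(pheno_vector))
  y_all <- pheno_vector[acc]
  keep <- !is.na(y_all)
  if (any(!keep)) message(sum(!keep), " accession(s) with missing phenotype dropped")
  acc <- acc[keep]
  y <- as.numeric(y_all[keep])
  G <- geno$dosages[acc, , drop = FALSE]
  if (is.null(K)) K <- compute_kinship(geno)
  K <- K[acc, acc]
  n <- length(y)
  X0 <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (!is.null(rownames(C))) C <- C[acc, , drop = FALSE]
    X0 <- cbind(X0, C)
    if (qr(X0)$rank < ncol(X0)) stop_cfg("covariate matrix is singular")
  }
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  X0r <- crossprod(U, X0)
  opt <- stats::optimize(reml_ll_delta, c(-12, 12), d = d, yr = yr, Xr = X0r,
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)

  n_eff <- colSums(!is.na(G))
  cm <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G))
  if (length(idx)) G[idx] <- cm[(idx - 1L) %/% nrow(G) + 1L]
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  Gr <- crossprod(U, G)

  p_cov <- ncol(X0)
  test_one <- function(j, delta_j) {
    w <- 1 / (d + delta_j)
    Xr <- cbind(X0r, Gr[, j])
    XtWX <- crossprod(Xr, Xr * w)
    sol <- tryCatch(solve(XtWX, crossprod(Xr, yr * w)),
                    error = function(e) NULL)
    if (is.null(sol)) return(c(NA_real_, NA_real_, NA_real_))
    r <- yr - Xr %*% sol
    df <- n - p_cov - 1L
    s2 <- sum(w * r^2) / df
    vb <- s2 * solve(XtWX)[p_cov + 1L, p_cov + 1L]
    beta <- sol[p_cov + 1L]
    se <- sqrt(vb)
    t <- beta / se
    c(beta, se, 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  }
  res <- matrix(NA_real_, ncol(G), 3L)
  for (j in seq_len(ncol(G))) {
    dj <- delta
    if (method == "exact") {
      oj <- stats::optimize(reml_ll_delta, c(-12, 12), d = d, yr = yr,
                            Xr = cbind(X0r, Gr[, j]), maximum = TRUE, tol = 1e-8)
      dj <- exp(oj$maximum)
    }
    res[j, ] <- test_one(j, dj)
  }
  pve <- ifelse(is.na(res[, 1]) | (res[, 1] == 0 & res[, 2] == 0), NA_real_,
                res[, 1]^2 / (res[, 1]^2 + n_eff * res[, 2]^2))
  out <- data.frame(
    snp_id = geno$snps$snp_id, chrom = geno$snps$chrom, pos = geno$snps$pos,
    beta = res[, 1], se = res[, 2], p_value = res[, 3],
    maf = maf, n_effective = n_eff, pve = pve,
    stringsAsFactors = FALSE
  )
  attr(out, "trait") <- trait
  attr(out, "category") <- category
  attr(out, "delta") <- delta
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' LD pruning for the effective number of independent tests
#'
#' Greedy windowed pairwise-r^2 pruning of a SNP panel (the
#' `--indep-pairwise <window kb> <step> <r2>` procedure): within each
#' sliding window of `window_kb` kilobases, while any retained pair exceeds
#' `r2_threshold` the member with the lower MAF is removed (position order
#' breaks ties); the window then advances by `step` SNPs. The count of
#' retained SNPs is the effective number of independent tests used for
#' Bonferroni correction.
#'
#' @param geno A `genotype_matrix` with positions.
#' @param window_kb Window size in kb (default 1000).
#' @param step SNPs to advance per slide (default 10).
#' @param r2_threshold Pairwise r^2 above which one of a pair is removed
#'   (default 0.3).
#' @return Integer count of retained SNPs; retained ids in attribute
#'   `keep`.
#' @export
ld_prune_effective_tests <- function(geno, window_kb = 1000, step = 10,
                                     r2_threshold = 0.3) {
  X <- geno$dosages
  if (is.null(X) || ncol(X) == 0L) stop_cfg("empty genotype set")
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1L) %/% nrow(X) + 1L]
  snps <- geno$snps
  keep_global <- character(0)
  for (ch in unique(snps$chrom)) {
    sel <- which(snps$chrom == ch)
    sel <- sel[order(snps$pos[sel])]
    pos <- snps$pos[sel]
    maf <- snps$maf[sel]
    alive <- rep(TRUE, length(sel))
    for (start in seq(1L, length(sel), by = step)) {
      win <- which(pos >= pos[start] & pos < pos[start] + window_kb * 1000)
      win <- win[win >= start]
      act <- win[alive[win]]
      if (length(act) < 2L) next
      R2 <- suppressWarnings(stats::cor(X[, sel[act], drop = FALSE]))^2
      repeat {
        diag(R2) <- 0
        bad <- which(R2 > r2_threshold, arr.ind = TRUE)
        if (nrow(bad) == 0L) break
        pr <- bad[1L, ]
        a <- act[pr[1]]; b <- act[pr[2]]
        drop_local <- if (maf[a] < maf[b]) pr[1]
                      else if (maf[b] < maf[a]) pr[2]
                      else max(pr)  # tie: drop the later position
        alive[act[drop_local]] <- FALSE
        R2 <- R2[-drop_local, -drop_local, drop = FALSE]
        act <- act[-drop_local]
        if (length(act) < 2L) break
      }
    }
    keep_global <- c(keep_global, snps$snp_id[sel][alive])
  }
  structure(length(keep_global), keep = keep_global)
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / n_independent`, with `n_independent` the LD-pruned effective
#' number of independent SNPs (see [ld_prune_effective_tests()]).
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_independent Effective number of independent tests (>= 1).
#' @return The genome-wide per-test p-value threshold.
#' @examples
#' bonferroni_threshold(0.05, 36508) # ~1.37e-6
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_independent) {
  if (alpha <= 0 || n_independent < 1)
    stop_cfg("alpha must be > 0 and n_independent >= 1")
  alpha / n_independent
}

#' Per-SNP proportion of variance explained
#'
#' The standardized single-SNP PVE
#' \deqn{PVE = \frac{2 f (1-f) \beta^2}{2 f (1-f) \beta^2 + 2 f (1-f) N
#'   \,se^2} = \frac{\beta^2}{\beta^2 + N \, se^2},}
#' with `f` the minor-allele frequency and `N` the effective (non-missing)
#' sample size.
#'
#' @param beta Estimated allelic effect.
#' @param se Its standard error (>= 0).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param n_effective Effective sample size (>= 1).
#' @return PVE in `[0, 1]`.
#' @examples
#' snp_pve(0.5, 0.05, 0.2, 100) # 0.5
#' @export
snp_pve <- function(beta, se, maf, n_effective) {
  if (any(se < 0) || any(maf <= 0) || any(maf > 0.5) || any(n_effective < 1))
    stop_cfg("invalid se, maf or n_effective")
  if (any(se == 0 & beta == 0)) stop_cfg("PVE undefined for beta = 0, se = 0")
  v <- 2 * maf * (1 - maf)
  (v * beta^2) / (v * beta^2 + v * n_effective * se^2)
}

#' Two-population Fst scan (Weir-Cockerham)
#'
#' Per-SNP Weir-Cockerham (1984) theta between two accession groups,
#' computed from genotype counts (so observed heterozygosity enters the
#' correction terms). The estimator is slightly negative under no
#' differentiation; values are reported unfloored.
#'
#' @param geno A `genotype_matrix`.
#' @param group_labels Named factor/character vector mapping accessions to
#'   two group labels.
#' @return Data.frame `snp_id`, `fst`, `p_a`, `p_b` (group allele
#'   frequencies), `n_a`, `n_b`; `fst` is `NA` for SNPs monomorphic across
#'   both groups (count reported via message).
#' @export
fst_scan <- function(geno, group_labels) {
  acc <- rownames(geno$dosages)
  if (is.null(names(group_labels)))
    names(group_labels) <- acc
  gl <- factor(group_labels[acc])
  if (nlevels(gl) != 2L) stop_cfg("exactly two groups required")
  split_idx <- split(seq_along(acc), gl)
  n_mono <- 0L
  res <- t(vapply(seq_len(ncol(geno$dosages)), function(j) {
    x <- geno$dosages[, j]
    stats_grp <- lapply(split_idx, function(ii) {
      xi <- x[ii]; xi <- xi[!is.na(xi)]
      c(n = length(xi), p = if (length(xi)) sum(xi) / (2 * length(xi)) else NA,
        h = if (length(xi)) mean(xi == 1L) else NA)
    })
    n_i <- vapply(stats_grp, `[[`, 0, "n")
    p_i <- vapply(stats_grp, `[[`, 0, "p")
    h_i <- vapply(stats_grp, `[[`, 0, "h")
    r <- 2
    nbar <- mean(n_i)
    pbar <- sum(n_i * p_i) / (r * nbar)
    if (any(n_i == 0) || pbar %in% c(0, 1))
      return(c(NA_real_, p_i, n_i))
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    denom <- a + b + cc
    c(if (denom == 0) NA_real_ else a / denom, p_i, n_i)
  }, numeric(5)))
  out <- data.frame(snp_id = geno$snps$snp_id, fst = res[, 1],
                    p_a = res[, 2], p_b = res[, 3],
                    n_a = res[, 4], n_b = res[, 5],
                    stringsAsFactors = FALSE)
  if (anyNA(out$fst))
    message(sum(is.na(out$fst)), " SNP(s) monomorphic or undefined: Fst set NA")
  out
}
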