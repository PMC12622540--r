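#' Finlay-Wilkinson reaction-norm decomposition (least squares)
#'
#' Decomposes a multi-environment trait into genotype mean, linear
#' plasticity and nonlinear plasticity under the genotype-specific
#' Finlay-Wilkinson model
#' \deqn{y_{ij} = \mu + g_i + (1 + b_i) h_j + \varepsilon_{ij}.}
#' The two-step least-squares estimator first sets the environment effect
#' \eqn{h_j} to the environment mean minus the grand mean (centred to sum
#' zero), then regresses each accession's phenotype on \eqn{h_j}: the
#' intercept estimates \eqn{\mu + g_i}, the slope estimates \eqn{1 + b_i}
#' (linear plasticity), and the natural-log residual variance is the
#' nonlinear plasticity.
#'
#' @param pheno Long phenotype data.frame (`accession`, `environment`,
#'   `trait`, `value`).
#' @param trait Trait id to decompose.
#' @return An object of class `fw_fit`: list with `mu` (grand mean), `g`
#'   (named per-accession mean effect), `linear_plasticity` (named
#'   `1 + b_i`), `nonlinear_plasticity` (named log residual variance;
#'   `-Inf` for exact fits), `h` (named environment effects, sum 0),
#'   `flagged` (accessions with < 2 environments, slope set `NA`), and
#'   `method = "LS"`. Accessions whose available environments share a
#'   single `h` value also get `NA` slopes and are flagged.
#' @examples
#' cfg <- sim_config(n_accessions = 40, n_snps = 50, n_envs = 5, seed = 3)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg),
#'                            simulate_environments(cfg), cfg)
#' fit <- fit_fw_ls(sim$pheno, "GCR")
#' cor(fit$linear_plasticity - 1, sim$truth$b_true)
#' @export
fit_fw_ls <- function(pheno, trait) {
  Y <- pheno_wide(pheno, trait)
  if (ncol(Y) < 2L)
    stop_cfg("Finlay-Wilkinson regression needs >= 2 environments (got %d)", ncol(Y))
  mu <- mean(Y, na.rm = TRUE)
  h <- colMeans(Y, na.rm = TRUE) - mu
  h <- h - mean(h)
  n_obs <- rowSums(!is.na(Y))
  g <- slope <- nlp <- stats::setNames(rep(NA_real_, nrow(Y)), rownames(Y))
  flagged <- character(0)
  for (i in seq_len(nrow(Y))) {
    ok <- !is.na(Y[i, ])
    hi <- h[ok]; yi <- Y[i, ok]
    if (sum(ok) < 2L || stats::var(hi) == 0) {
      flagged <- c(flagged, rownames(Y)[i])
      if (sum(ok) >= 1L) g[i] <- mean(yi) - mu
      next
    }
    sl <- stats::cov(yi, hi) / stats::var(hi)
    ic <- mean(yi) - sl * mean(hi)
    rss <- sum((yi - ic - sl * hi)^2)
    slope[i] <- sl
    g[i] <- ic - mu
    nlp[i] <- log(rss / max(sum(ok) - 2L, 1L))
  }
  structure(list(mu = mu, g = g, linear_plasticity = slope,
                 nonlinear_plasticity = nlp, h = h,
                 flagged = flagged, method = "LS"),
            class = "fw_fit")
}

#' Bayesian Finlay-Wilkinson decomposition via Gibbs sampling
#'
#' Fits the same reaction-norm model as [fit_fw_ls()] with independent
#' normal priors on genotype effects, slope deviations and environment
#' effects (identity prior covariance, i.e. no pedigree/kinship structure)
#' and conjugate scaled-inverse-chi-squared priors on all variances, with
#' weakly informative hyperparameters (prior scale 1e3 times the data
#' variance). Posterior means are reported; the per-accession residual
#' variance of the posterior-mean fit, natural-log-transformed, is the
#' nonlinear plasticity. Identifiability is maintained by re-centring
#' environment effects (and genotype effects) each sweep, absorbing the
#' shifts into the grand mean.
#'
#' @inheritParams fit_fw_ls
#' @param n_iter Total Gibbs sweeps.
#' @param burnin Sweeps discarded before averaging (`n_iter > burnin`).
#' @param seed Seed making the chain reproducible.
#' @return An `fw_fit` (as in [fit_fw_ls()]) with `method = "Gibbs"` and an
#'   extra `diagnostics` element: split-chain potential-scale-reduction
#'   factors for the residual variance and grand mean, plus a
#'   `convergence_warning` flag set when any exceeds 1.1 (recorded, never
#'   silent).
#' @export
fit_fw_gibbs <- function(pheno, trait, n_iter = 2000, burnin = 500, seed = 1) {
  if (n_iter <= burnin) stop_cfg("n_iter must exceed burnin")
  Y <- pheno_wide(pheno, trait)
  if (ncol(Y) < 2L)
    stop_cfg("Finlay-Wilkinson regression needs >= 2 environments (got %d)", ncol(Y))
  n <- nrow(Y); m <- ncol(Y)
  obs <- !is.na(Y)
  vy <- stats::var(as.vector(Y), na.rm = TRUE)
  if (!is.finite(vy) || vy == 0) vy <- 1
  # scaled-inv-chi^2(nu0, s0) priors with nu0 = 0.01: diffuse scale
  # 1e3 * var(y) on the g and h effect variances, unit scale on the slope
  # variance; the residual variance gets a Jeffreys prior (see below)
  nu0 <- 0.01; s0 <- 1e3 * vy
  with_seed(seed, {
    ls <- fit_fw_ls(pheno, trait)
    mu <- ls$mu
    g <- ifelse(is.na(ls$g), 0, ls$g)
    b <- ifelse(is.na(ls$linear_plasticity), 0, ls$linear_plasticity - 1)
    h <- ls$h
    rv0 <- exp(ls$nonlinear_plasticity[is.finite(ls$nonlinear_plasticity)])
    s2e <- max(if (length(rv0)) mean(rv0) else 0, 1e-6 * vy, 1e-12)
    # residual-variance prior: anchored at the two-step LS residual variance
    # with 5 prior df — negligible against the RSS for ordinary panels, but
    # it pins the chain when the model saturates the data (no residual df)
    nu0_e <- 5; s0_e <- s2e
    s2g <- max(stats::var(g), 1e-6 * vy); s2b <- max(stats::var(b), 1e-4)
    s2h <- max(stats::var(h), 1e-6 * vy)
    keep <- n_iter - burnin
    sum_g <- numeric(n); sum_b <- numeric(n); sum_h <- numeric(m)
    sum_mu <- 0; tr_s2e <- numeric(keep); tr_mu <- numeric(keep)
    rinvchisq <- function(nu, scale) nu * scale / stats::rchisq(1L, nu)
    balanced <- all(obs)
    for (it in seq_len(n_iter)) {
      # (g_i, b_i) | rest: per-accession bivariate conjugate regression of
      # y_ij - mu - h_j on [1, h_j]
      if (balanced) {
        # all accessions share the design, so one Cholesky serves them all
        R0 <- Y - mu - matrix(h, n, m, byrow = TRUE)
        prec <- rbind(c(m, sum(h)), c(sum(h), sum(h^2))) / s2e +
          diag(c(1 / s2g, 1 / s2b))
        rhs <- rbind(rowSums(R0), drop(R0 %*% h)) / s2e
        ch <- chol(prec)
        mu_post <- backsolve(ch, forwardsolve(t(ch), rhs))
        draw <- mu_post + backsolve(ch, matrix(stats::rnorm(2L * n), 2L, n))
        g <- draw[1L, ]; b <- draw[2L, ]
      } else for (i in seq_len(n)) {
        ok <- obs[i, ]; hi <- h[ok]
        r <- Y[i, ok] - mu - hi
        XtX <- rbind(c(sum(ok), sum(hi)), c(sum(hi), sum(hi^2))) / s2e
        prec <- XtX + diag(c(1 / s2g, 1 / s2b))
        rhs <- c(sum(r), sum(hi * r)) / s2e
        ch <- chol(prec)
        mu_post <- backsolve(ch, forwardsolve(t(ch), rhs))
        draw <- mu_post + backsolve(ch, stats::rnorm(2L))
        g[i] <- draw[1]; b[i] <- draw[2]
      }
      # h_j | rest
      for (j in seq_len(m)) {
        ok <- obs[, j]; w <- 1 + b[ok]
        prec <- sum(w^2) / s2e + 1 / s2h
        mu_post <- sum(w * (Y[ok, j] - mu - g[ok])) / s2e / prec
        h[j] <- stats::rnorm(1L, mu_post, sqrt(1 / prec))
      }
      # identifiability: centre h and g (absorbed into mu and g), then pin
      # the h-vs-slope scale by the mean(b) = 0 convention — the likelihood
      # is invariant under (h, 1+b) -> (c h, (1+b)/c)
      hbar <- mean(h)
      mu <- mu + hbar; g <- g + b * hbar; h <- h - hbar
      gbar <- mean(g); mu <- mu + gbar; g <- g - gbar
      bbar <- mean(b)
      if (abs(1 + bbar) > 1e-8) {
        h <- (1 + bbar) * h
        b <- (b - bbar) / (1 + bbar)
      }
      # mu | rest (flat prior)
      R <- Y - g - outer(1 + b, h)
      N <- sum(obs)
      mu <- stats::rnorm(1L, mean(R[obs]), sqrt(s2e / N))
      # variances
      res <- R[obs] - mu
      s2e <- max(rinvchisq(nu0_e + N, (nu0_e * s0_e + sum(res^2)) / (nu0_e + N)),
                 1e-12 * vy)
      # floors guard against degenerate collapse of a hierarchy level when
      # it has very few units (heavy lower tail of inv-chi^2 at small df);
      # two orders of magnitude under the current mean square, so they
      # never bind for ordinary panel sizes
      s2g <- max(rinvchisq(nu0 + n, (nu0 * s0 + sum(g^2)) / (nu0 + n)),
                 1e-2 * mean(g^2))
      s2b <- max(rinvchisq(nu0 + n, (nu0 * 1 + sum(b^2)) / (nu0 + n)),
                 1e-2 * mean(b^2))
      s2h <- max(rinvchisq(nu0 + m, (nu0 * s0 + sum(h^2)) / (nu0 + m)),
                 1e-2 * mean(h^2))
      if (it > burnin) {
        k <- it - burnin
        sum_g <- sum_g + g; sum_b <- sum_b + b; sum_h <- sum_h + h
        sum_mu <- sum_mu + mu
        tr_s2e[k] <- s2e; tr_mu[k] <- mu
      }
    }
    g_hat <- sum_g / keep; b_hat <- sum_b / keep
    h_hat <- sum_h / keep; mu_hat <- sum_mu / keep
    fitted <- mu_hat + g_hat + outer(1 + b_hat, h_hat)
    nlp <- vapply(seq_len(n), function(i) {
      ok <- obs[i, ]
      log(sum((Y[i, ok] - fitted[i, ok])^2) / max(sum(ok) - 2L, 1L))
    }, 0)
    psrf <- function(x) {
      half <- length(x) %/% 2L
      ch <- list(x[seq_len(half)], x[half + seq_len(half)])
      W <- mean(vapply(ch, stats::var, 0))
      B <- half * stats::var(vapply(ch, mean, 0))
      if (W <= 0) return(1)
      sqrt(((half - 1) / half * W + B / half) / W)
    }
    diag <- c(sigma2 = psrf(tr_s2e), mu = psrf(tr_mu))
    structure(list(
      mu = mu_hat,
      g = stats::setNames(g_hat, rownames(Y)),
      linear_plasticity = stats::setNames(1 + b_hat, rownames(Y)),
      nonlinear_plasticity = stats::setNames(nlp, rownames(Y)),
      h = stats::setNames(h_hat, colnames(Y)),
      flagged = ls$flagged, method = "Gibbs",
      diagnostics = list(psrf = diag,
                         convergence_warning = any(diag > 1.1),
                         sigma2_posterior_mean = mean(tr_s2e))
    ), class = "fw_fit")
  })
}

#' Coefficient of variation (percent)
#'
#' `CV = sd / mean * 100`, with the sample (n-1) standard deviation. Used
#' throughout as a scale-free plasticity indicator.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_cfg("CV needs >= 2 values")
  m <- mean(values)
  if (m == 0) stop_cfg("CV is undefined for zero mean")
  stats::sd(values) / m * 100
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with linear-interpolation quantiles
#' (`stats::quantile` type 7). A robust, scale-free dispersion measure used
#' to compare the spread of mean, linear-plasticity and nonlinear-plasticity
#' components across traits.
#'
#' @param values Numeric vector, length >= 4, with `Q1 + Q3 != 0`.
#' @return QCD (a fraction; in `[0, 1]` for nonnegative data with `Q3 > 0`).
#' @examples
#' quartile_coefficient_of_dispersion(1:5) # 1/3
#' @export
quartile_coefficient_of_dispersion <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop_cfg("QCD needs >= 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  if (sum(q) == 0) stop_cfg("QCD is undefined when Q1 + Q3 = 0")
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Per-environment (or pooled) trait dispersion summary
#'
#' Mean, standard deviation, CV, quartiles and QCD for one trait, either per
#' environment or pooled across environments.
#'
#' @inheritParams fit_fw_ls
#' @param by_environment Summarise per environment (default) or pooled.
#' @return Data.frame with columns `trait`, `environment` (or `"pooled"`),
#'   `mean`, `sd`, `cv`, `q1`, `q3`, `qcd`.
#' @export
trait_summary <- function(pheno, trait, by_environment = TRUE) {
  sub <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop_cfg("trait '%s' not present", trait)
  groups <- if (by_environment) split(sub$value, sub$environment)
            else list(pooled = sub$value)
  out <- lapply(names(groups), function(e) {
    v <- groups[[e]][!is.na(groups[[e]])]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    data.frame(trait = trait, environment = e, mean = mean(v),
               sd = stats::sd(v),
               cv = if (mean(v) != 0) stats::sd(v) / mean(v) * 100 else NA_real_,
               q1 = q[1], q3 = q[2],
               qcd = if (sum(q) != 0) (q[2] - q[1]) / sum(q) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
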