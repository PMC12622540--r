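# Shared fixtures and independent oracles, built in code at test time.

# Noiseless 2x2 reaction-norm toy: mu = 10, g = (-1, 1), h = (-2, 2),
# slopes (0.5, 1.5)  =>  y = {8, 8; 10, 14}
toy_2x2 <- function() {
  data.frame(accession = rep(c("a1", "a2"), 2),
             environment = rep(c("e1", "e2"), each = 2),
             trait = "TOY", value = c(8, 8, 10, 14),
             stringsAsFactors = FALSE)
}

# Cached moderate-noise reaction-norm panel reused across test files.
sim_panel <- local({
  cache <- new.env()
  function(n = 300, m = 6, seed = 1, n_snps = 100, ...) {
    key <- paste(n, m, seed, n_snps, ...)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n_accessions = n, n_snps = n_snps, n_envs = m,
                        seed = seed, ...)
      geno <- simulate_genotypes(cfg)
      env <- simulate_environments(cfg)
      sim <- simulate_phenotypes(geno, env, cfg)
      cache[[key]] <- list(cfg = cfg, geno = geno, env = env,
                           pheno = sim$pheno, truth = sim$truth)
    }
    cache[[key]]
  }
})

# Balanced crossed-design simulation with explicit variance components and
# replicates (oracle generator for the variance-component model, distinct
# from the reaction-norm generator).
sim_crossed <- function(n = 200, m = 5, reps = 2,
                        Vg = 4, VE = 2, VGE = 1, Ve = 1, seed = 1) {
  set.seed(seed)
  # effects scaled to exact sample variance (the same convention the
  # package generator uses for h): recovery tests then measure estimator
  # error, not the chi-square spread of a handful of random draws
  rnorm_exact <- function(k, v) {
    if (v == 0) return(numeric(k))
    x <- rnorm(k); x <- x - mean(x)
    x / sd(x) * sqrt(v)
  }
  g <- rnorm_exact(n, Vg)
  h <- rnorm_exact(m, VE)
  ge <- matrix(rnorm_exact(n * m, VGE), n, m)
  acc <- sprintf("A%03d", seq_len(n))
  envs <- sprintf("E%02d", seq_len(m))
  rows <- expand.grid(accession = acc, environment = envs, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(rows$accession, acc); j <- match(rows$environment, envs)
  rows$trait <- "X"
  rows$value <- g[i] + h[j] + ge[cbind(i, j)] + rnorm(nrow(rows), 0, sqrt(Ve))
  # replicate index folded into the environment id would break the crossed
  # structure, so keep true replicates as duplicate (accession, env) rows
  rows[, c("accession", "environment", "trait", "value")]
}

# ANOVA method-of-moments estimator for the balanced crossed design with
# replicates (expected-mean-squares oracle).
mom_crossed <- function(pheno) {
  d <- pheno
  a <- factor(d$accession); b <- factor(d$environment)
  n <- nlevels(a); m <- nlevels(b)
  r <- nrow(d) / (n * m)
  cell <- tapply(d$value, list(a, b), mean)
  ybar <- mean(d$value)
  ms_a <- m * r * sum((rowMeans(cell) - ybar)^2) / (n - 1)
  ms_b <- n * r * sum((colMeans(cell) - ybar)^2) / (m - 1)
  ms_ab <- r * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") + ybar)^2) /
    ((n - 1) * (m - 1))
  ss_tot <- sum((d$value - ybar)^2)
  ss_within <- ss_tot - r * sum((cell - ybar)^2)
  ms_e <- ss_within / (n * m * (r - 1))
  c(Vg = (ms_a - ms_ab) / (m * r), VE = (ms_b - ms_ab) / (n * r),
    VGE = (ms_ab - ms_e) / r, Ve = ms_e)
}

# Brute-force connected components of the pairwise interval-overlap graph.
overlap_components_oracle <- function(qtl) {
  n <- nrow(qtl)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- qtl$chrom[i] == qtl$chrom[j] &&
      qtl$start[i] <= qtl$end[j] && qtl$start[j] <= qtl$end[i]
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Hand-coded two-population Weir-Cockerham theta from genotype data
# (independent of the package implementation).
wc_fst_oracle <- function(x_a, x_b) {
  n_i <- c(length(x_a), length(x_b))
  p_i <- c(sum(x_a) / (2 * n_i[1]), sum(x_b) / (2 * n_i[2]))
  h_i <- c(mean(x_a == 1), mean(x_b == 1))
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Minimal genotype_matrix construction from a dosage matrix.
make_geno <- function(dos, chrom = NULL, pos = NULL) {
  n <- nrow(dos); s <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("A%03d", seq_len(n))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("S%03d", seq_len(s))
  if (is.null(chrom)) chrom <- rep("chr1", s)
  if (is.null(pos)) pos <- seq_len(s) * 1000L
  f <- colMeans(dos, na.rm = TRUE) / 2
  structure(list(
    dosages = dos,
    snps = data.frame(snp_id = colnames(dos), chrom = chrom, pos = pos,
                      ref = "A", alt = "C", maf = pmin(f, 1 - f),
                      stringsAsFactors = FALSE),
    accession_ids = rownames(dos)
  ), class = "genotype_matrix")
}
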