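#' Call QTL regions from an association scan
#'
#' Clusters genome-wide-significant SNPs into QTL intervals: significant
#' SNPs on the same chromosome are merged when within `merge_kb` of each
#' other, the region spans the cluster padded by half the merge window on
#' each side, and the lead SNP is the member with the smallest p-value
#' (smallest position on ties).
#'
#' @param result A `gwas_result` data.frame (see [lmm_scan()]).
#' @param threshold Genome-wide p-value threshold
#'   (see [bonferroni_threshold()]).
#' @param merge_kb Clustering distance in kb (default 200); the interval
#'   pad is `merge_kb/2` on each side.
#' @param category,trait,scan Metadata copied onto the regions (defaults
#'   taken from the scan's attributes).
#' @return Data.frame of class `qtl_regions`: `qtl_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `lead_snp`, `lead_p`, `n_snps`, `category`,
#'   `trait`, `scan`. Empty (zero rows) when nothing is significant.
#' @export
call_qtl_regions <- function(result, threshold, merge_kb = 200,
                             category = attr(result, "category"),
                             trait = attr(result, "trait"),
                             scan = NA_character_) {
  sig <- result[!is.na(result$p_value) & result$p_value <= threshold, , drop = FALSE]
  pad <- as.integer(merge_kb * 1000 / 2)
  empty <- data.frame(qtl_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_snp = character(0), lead_p = numeric(0),
                      n_snps = integer(0), category = character(0),
                      trait = character(0), scan = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("qtl_regions", "data.frame")
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    cl <- cumsum(c(1L, diff(s$pos) > merge_kb * 1000))
    for (k in unique(cl)) {
      m <- s[cl == k, , drop = FALSE]
      lead <- m[order(m$p_value, m$pos), ][1L, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = max(1L, min(m$pos) - pad + 1L),
        end = max(m$pos) + pad,
        lead_snp = lead$snp_id, lead_p = lead$p_value,
        n_snps = nrow(m), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$qtl_id <- sprintf("Q%03d", seq_len(nrow(out)))
  out$category <- category %||% NA_character_
  out$trait <- trait %||% NA_character_
  out$scan <- scan
  out <- out[, c("qtl_id", "chrom", "start", "end", "lead_snp", "lead_p",
                 "n_snps", "category", "trait", "scan")]
  class(out) <- c("qtl_regions", "data.frame")
  out
}

#' Condense overlapping QTL into hotspot QTL
#'
#' Groups QTL intervals (possibly from many scans) into hotspots: on each
#' chromosome, QTL whose closed intervals share at least one base pair are
#' chained into connected components (`mode = "components"`, the default;
#' `mode = "pairwise"` instead requires every member of a group to overlap
#' every other). Components with at least `min_members` QTL become hotspot
#' H-QTL; a hotspot covering more than three member QTL is flagged as key.
#'
#' @param qtl A `qtl_regions` data.frame (rows may be pooled across scans;
#'   `qtl_id` values must be unique).
#' @param min_members Minimum member QTL per hotspot (default 2).
#' @param mode `"components"` (transitive chaining) or `"pairwise"`.
#' @return Data.frame of class `hotspots`: `hqtl_id`, `chrom`, `start`,
#'   `end`, `n_members`, `is_key`, `member_qtl` (comma-separated, sorted
#'   ids). Attribute `singletons` lists QTL in components below
#'   `min_members`.
#' @examples
#' q <- data.frame(qtl_id = c("A", "B", "C"), chrom = "chr1",
#'                 start = c(100, 150, 400), end = c(200, 250, 500))
#' condense_hotspots(q)
#' @export
condense_hotspots <- function(qtl, min_members = 2,
                              mode = c("components", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(all(c("qtl_id", "chrom", "start", "end") %in% names(qtl)))
  if (anyDuplicated(qtl$qtl_id)) stop_cfg("qtl_id values must be unique")
  empty <- data.frame(hqtl_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), is_key = logical(0),
                      member_qtl = character(0), stringsAsFactors = FALSE)
  if (nrow(qtl) == 0L) {
    class(empty) <- c("hotspots", "data.frame")
    attr(empty, "singletons") <- character(0)
    return(empty)
  }
  gr <- GenomicRanges::GRanges(qtl$chrom, IRanges::IRanges(qtl$start, qtl$end))
  comp <- if (mode == "components") {
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, red)
    S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  } else {
    # mutual overlap for intervals <=> max(start) <= min(end) in the group:
    # greedy left-to-right runs per chromosome
    comp <- integer(nrow(qtl)); next_id <- 1L
    for (ch in unique(qtl$chrom)) {
      ii <- which(qtl$chrom == ch)
      ii <- ii[order(qtl$start[ii], qtl$end[ii])]
      cur_min_end <- -Inf
      for (i in ii) {
        if (qtl$start[i] > cur_min_end) {
          next_id <- next_id + 1L
          cur_min_end <- qtl$end[i]
        } else cur_min_end <- min(cur_min_end, qtl$end[i])
        comp[i] <- next_id
      }
    }
    comp
  }
  groups <- split(seq_len(nrow(qtl)), comp)
  rows <- list(); singles <- character(0)
  for (g in groups) {
    ids <- sort(qtl$qtl_id[g])
    if (length(g) < min_members) {
      singles <- c(singles, ids)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = qtl$chrom[g[1L]],
      start = min(qtl$start[g]), end = max(qtl$end[g]),
      n_members = length(g), is_key = length(g) > 3L,
      member_qtl = paste(ids, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    class(empty) <- c("hotspots", "data.frame")
    attr(empty, "singletons") <- singles
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(hqtl_id = sprintf("HQTL%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "singletons") <- singles
  class(out) <- c("hotspots", "data.frame")
  out
}

#' Candidate genes within windows around significant SNPs
#'
#' Returns genes whose span intersects the closed window
#' `[pos - window_bp/2, pos + window_bp/2]` centred on any of the supplied
#' SNPs (default 20-kb windows).
#'
#' @param snps Data.frame with `snp_id`, `chrom`, `pos` (significant SNPs).
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_gff3_genes()].
#' @param window_bp Full window width in bp (default 20000).
#' @return Data.frame of class `candidate_genes`: `gene_id`, `chrom`,
#'   `start`, `end`, `n_snps`, `snp_ids` (comma separated); attribute
#'   `window_bp` records the window used.
#' @export
candidate_genes <- function(snps, genes, window_bp = 20000) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), snp_ids = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "window_bp") <- window_bp
  class(empty) <- c("candidate_genes", "data.frame")
  if (nrow(snps) == 0L || nrow(genes) == 0L) return(empty)
  half <- window_bp / 2
  win <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(pmax(1, snps$pos - half),
                                                 snps$pos + half))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(gg, win)
  if (length(hit) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  keep <- sort(unique(qh))
  snp_lists <- vapply(keep, function(i)
    paste(sort(snps$snp_id[sh[qh == i]]), collapse = ","), "")
  out <- data.frame(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
                    start = genes$start[keep], end = genes$end[keep],
                    n_snps = vapply(keep, function(i) sum(qh == i), 0L),
                    snp_ids = snp_lists, stringsAsFactors = FALSE)
  attr(out, "window_bp") <- window_bp
  class(out) <- c("candidate_genes", "data.frame")
  out
}

#' Venn-region counts of candidate genes across sub-phenotypes
#'
#' Compares the candidate-gene sets underlying the QTL of the three
#' sub-phenotypes (mean, linear plasticity, nonlinear plasticity) and
#' returns all seven Venn-region counts.
#'
#' @param mean_set,lp_set,nlp_set Character vectors of gene ids, or
#'   `candidate_genes` data.frames.
#' @return Named integer vector: `mean_only`, `lp_only`, `nlp_only`,
#'   `mean_lp`, `mean_nlp`, `lp_nlp`, `all_three`.
#' @export
subphenotype_overlap <- function(mean_set, lp_set, nlp_set) {
  as_ids <- function(x) unique(if (is.data.frame(x)) x$gene_id else as.character(x))
  a <- as_ids(mean_set); b <- as_ids(lp_set); c <- as_ids(nlp_set)
  abc <- intersect(intersect(a, b), c)
  c(mean_only = length(setdiff(a, union(b, c))),
    lp_only = length(setdiff(b, union(a, c))),
    nlp_only = length(setdiff(c, union(a, b))),
    mean_lp = length(setdiff(intersect(a, b), c)),
    mean_nlp = length(setdiff(intersect(a, c), b)),
    lp_nlp = length(setdiff(intersect(b, c), a)),
    all_three = length(abc))
}

#' Haplotype-group phenotype contrast
#'
#' Groups accessions by their exact dosage string at an ordered set of
#' defining SNPs and contrasts the phenotype across haplotype groups by
#' one-way ANOVA with Tukey-Kramer family-wise-adjusted pairwise
#' comparisons; unadjusted pairwise Welch t-tests are also emitted.
#' Accessions missing an allele at any defining SNP are excluded and
#' counted; groups below `min_group_size` are dropped.
#'
#' @param geno A `genotype_matrix`.
#' @param snp_ids Ordered SNP ids defining the haplotype.
#' @param pheno_values Named per-accession phenotype vector.
#' @param min_group_size Minimum accessions per haplotype group (default 10).
#' @return List with `groups` (haplotype, n, mean, sd), `anova_p`, `tukey`
#'   (data.frame of pairwise Tukey-Kramer contrasts), `t_tests` (matrix of
#'   unadjusted Welch p-values), `n_excluded_missing`,
#'   `n_excluded_small_group`.
#' @export
haplotype_contrast <- function(geno, snp_ids, pheno_values,
                               min_group_size = 10) {
  miss <- setdiff(snp_ids, colnames(geno$dosages))
  if (length(miss)) stop_cfg("SNP(s) not in genotype matrix: %s",
                             paste(miss, collapse = ", "))
  D <- geno$dosages[, snp_ids, drop = FALSE]
  acc <- rownames(D)
  if (is.null(names(pheno_values))) names(pheno_values) <- acc
  complete <- stats::complete.cases(D) & !is.na(pheno_values[acc])
  n_excl <- sum(!complete)
  D <- D[complete, , drop = FALSE]
  hap <- apply(D, 1L, paste, collapse = "")
  y <- as.numeric(pheno_values[rownames(D)])
  tab <- table(hap)
  keep_h <- names(tab)[tab >= min_group_size]
  small <- sum(tab[!names(tab) %in% keep_h])
  sel <- hap %in% keep_h
  hap <- factor(hap[sel]); y <- y[sel]
  if (nlevels(hap) < 2L)
    stop_cfg("fewer than two haplotype groups above the minimum size")
  groups <- do.call(rbind, lapply(levels(hap), function(h) {
    data.frame(haplotype = h, n = sum(hap == h), mean = mean(y[hap == h]),
               sd = stats::sd(y[hap == h]), stringsAsFactors = FALSE)
  }))
  fit <- stats::aov(y ~ hap)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$hap
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  tt <- stats::pairwise.t.test(y, hap, p.adjust.method = "none",
                               pool.sd = FALSE)$p.value
  list(groups = groups, anova_p = anova_p, tukey = tukey, t_tests = tt,
       n_excluded_missing = n_excl, n_excluded_small_group = small)
}

#' Per-SNP mean-vs-plasticity effect-sign profile
#'
#' Pairs each SNP's estimated effect on the phenotypic mean with its effect
#' on a plasticity component and flags the relationship: `antagonistic`
#' (opposite signs, both beyond `epsilon`) — the trade-off signature —
#' `concordant` (same sign, both beyond `epsilon`), `neutral` (either
#' effect within `epsilon`), or `missing` (SNP absent from a scan).
#'
#' @param mean_result,plasticity_result `gwas_result` data.frames.
#' @param snp_ids SNPs to profile (default: intersection of both scans).
#' @param epsilon Effect magnitude below which a SNP is neutral
#'   (default 1e-6).
#' @return Data.frame `snp_id`, `beta_mean`, `beta_plasticity`, `flag`.
#' @export
effect_sign_tradeoff <- function(mean_result, plasticity_result,
                                 snp_ids = NULL, epsilon = 1e-6) {
  if (is.null(snp_ids))
    snp_ids <- intersect(mean_result$snp_id, plasticity_result$snp_id)
  bm <- mean_result$beta[match(snp_ids, mean_result$snp_id)]
  bp <- plasticity_result$beta[match(snp_ids, plasticity_result$snp_id)]
  flag <- ifelse(is.na(bm) | is.na(bp), "missing",
          ifelse(abs(bm) <= epsilon | abs(bp) <= epsilon, "neutral",
          ifelse(sign(bm) == sign(bp), "concordant", "antagonistic")))
  data.frame(snp_id = snp_ids, beta_mean = bm, beta_plasticity = bp,
             flag = flag, stringsAsFactors = FALSE)
}

#' Per-category QTL accounting
#'
#' Counts QTL by scan category and returns the grand total, mirroring the
#' atlas bookkeeping of redundant QTL before hotspot condensation.
#'
#' @param qtl A `qtl_regions` data.frame (pooled across scans), each row
#'   carrying exactly one non-missing `category`.
#' @return List with `counts` (named integer vector by category) and
#'   `total`.
#' @export
category_accounting <- function(qtl) {
  if (nrow(qtl) == 0L) return(list(counts = integer(0), total = 0L))
  if (anyNA(qtl$category)) stop_cfg("every QTL must carry a category tag")
  counts <- table(qtl$category)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       total = nrow(qtl))
}
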