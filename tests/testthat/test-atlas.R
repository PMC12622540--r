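fake_scan <- function(p_values, pos = NULL, chrom = NULL,
                      category = "mean", trait = "GCR") {
  k <- length(p_values)
  if (is.null(pos)) pos <- seq_len(k) * 10000L
  if (is.null(chrom)) chrom <- rep("chr1", k)
  out <- data.frame(snp_id = sprintf("s%03d", seq_len(k)), chrom = chrom,
                    pos = pos, beta = 0.1, se = 0.05, p_value = p_values,
                    maf = 0.3, n_effective = 100L, pve = 0.01,
                    stringsAsFactors = FALSE)
  attr(out, "category") <- category
  attr(out, "trait") <- trait
  class(out) <- c("gwas_result", "data.frame")
  out
}

test_that("QTL regions are called by the merge-and-pad rule", {
  expect_equal(nrow(call_qtl_regions(fake_scan(rep(0.5, 10)), 1e-6)), 0)
  # single significant SNP at 1 Mb, 200-kb merge window: [900001, 1100000]
  res <- fake_scan(c(0.5, 1e-8, 0.5), pos = c(5e5, 1e6, 2e6))
  q <- call_qtl_regions(res, 1e-6, merge_kb = 200)
  expect_equal(q$start, 900001)
  expect_equal(q$end, 1100000)
  expect_equal(q$lead_snp, "s002")
  # two significant SNPs 50 kb apart merge into one region
  res2 <- fake_scan(c(1e-8, 1e-9), pos = c(1e6, 1e6 + 5e4))
  q2 <- call_qtl_regions(res2, 1e-6, merge_kb = 200)
  expect_equal(nrow(q2), 1)
  expect_equal(q2$lead_snp, "s002")
  expect_equal(q2$start, 1e6 - 1e5 + 1)
  expect_equal(q2$end, 1e6 + 5e4 + 1e5)
  # beyond the merge distance: two regions
  res3 <- fake_scan(c(1e-8, 1e-9), pos = c(1e6, 1.5e6))
  expect_equal(nrow(call_qtl_regions(res3, 1e-6, merge_kb = 200)), 2)
})

test_that("hotspot condensation matches the hand-worked overlap example", {
  q <- data.frame(qtl_id = c("A", "B", "C"), chrom = "chr1",
                  start = c(100, 150, 400), end = c(200, 250, 500),
                  stringsAsFactors = FALSE)
  h <- condense_hotspots(q)
  expect_equal(nrow(h), 1)
  expect_equal(h$member_qtl, "A,B")
  expect_equal(c(h$start, h$end), c(100, 250))
  expect_false(h$is_key)
  expect_equal(attr(h, "singletons"), "C")
  # pairwise-disjoint intervals produce no hotspots
  qd <- data.frame(qtl_id = c("A", "B"), chrom = "chr1",
                   start = c(1, 100), end = c(50, 150))
  expect_equal(nrow(condense_hotspots(qd)), 0)
  # adjacency without a shared base pair is not overlap
  qa <- data.frame(qtl_id = c("A", "B"), chrom = "chr1",
                   start = c(1, 101), end = c(100, 200))
  expect_equal(nrow(condense_hotspots(qa)), 0)
  # a hotspot covering more than three member QTL is key
  qk <- data.frame(qtl_id = letters[1:4], chrom = "chr1",
                   start = c(1, 10, 20, 30), end = c(15, 25, 35, 45))
  expect_true(condense_hotspots(qk)$is_key)
})

test_that("condensation equals the brute-force connected-components oracle", {
  set.seed(21)
  n <- 1000
  q <- data.frame(qtl_id = sprintf("Q%04d", 1:n),
                  chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
                  start = sample.int(2e6, n), stringsAsFactors = FALSE)
  q$end <- q$start + sample.int(5e4, n)
  h <- condense_hotspots(q)
  comp <- overlap_components_oracle(q)
  oracle_groups <- split(q$qtl_id, comp)
  oracle_hot <- sort(vapply(Filter(function(g) length(g) >= 2, oracle_groups),
                            function(g) paste(sort(g), collapse = ","), ""))
  expect_equal(sort(h$member_qtl), unname(oracle_hot))
  # order invariance
  perm <- sample.int(n)
  h2 <- condense_hotspots(q[perm, ])
  expect_equal(sort(h2$member_qtl), sort(h$member_qtl))
  # accounting: members + singletons = total
  expect_equal(sum(h$n_members) + length(attr(h, "singletons")), n)
})

test_that("candidate genes are collected from closed 20-kb windows", {
  genes <- data.frame(gene_id = c("inside", "other_chrom", "boundary", "far"),
                      chrom = c("chr1", "chr2", "chr1", "chr1"),
                      start = c(995000, 995000, 1010000, 2000000),
                      end = c(1000000, 1000000, 1015000, 2005000),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "lead", chrom = "chr1", pos = 1000000)
  cg <- candidate_genes(snps, genes, window_bp = 20000)
  expect_setequal(cg$gene_id, c("inside", "boundary"))
  # gene starting exactly at the window edge is included (closed intervals)
  expect_true("boundary" %in% cg$gene_id)
  # monotone nondecreasing in window size
  sizes <- c(1e3, 1e4, 1e5, 1e6)
  counts <- vapply(sizes, function(w) nrow(candidate_genes(snps, genes, w)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("sub-phenotype gene-set overlaps enumerate all Venn regions", {
  z <- subphenotype_overlap(letters[1:3], letters[4:6], letters[7:9])
  expect_true(all(z[c("mean_lp", "mean_nlp", "lp_nlp", "all_three")] == 0))
  ident <- subphenotype_overlap(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(unname(ident["all_three"]), 5L)
  expect_equal(sum(ident), 5L)
  hand <- subphenotype_overlap(c("a", "b", "c"), c("b", "c", "d"), "c")
  expect_equal(unname(hand["all_three"]), 1L)  # {c}
  expect_equal(unname(hand["mean_lp"]), 1L)    # {b}
  expect_equal(unname(hand["mean_only"]), 1L)  # {a}
  expect_equal(unname(hand["lp_only"]), 1L)    # {d}
})

test_that("haplotype contrast distinguishes planted group shifts from null data", {
  set.seed(23)
  n <- 200
  dos <- cbind(S001 = rep(c(0L, 2L), each = n / 2),
               S002 = rep(c(0L, 2L), each = n / 2))
  geno <- make_geno(dos)
  null_y <- setNames(rnorm(n), rownames(dos))
  hc0 <- haplotype_contrast(geno, colnames(dos), null_y)
  expect_equal(nrow(hc0$groups), 2)
  expect_lt(abs(diff(hc0$groups$mean)), 0.5)
  # planted 1-SD shift: detected in most seeds
  sig <- sapply(1:10, function(s) {
    set.seed(400 + s)
    y <- setNames(rnorm(n) + rep(c(0, 1), each = n / 2), rownames(dos))
    haplotype_contrast(geno, colnames(dos), y)$anova_p < 0.05
  })
  expect_gte(sum(sig), 9)
  # missing alleles excluded and counted
  dos_na <- dos; dos_na[1:7, 1] <- NA
  hc_na <- haplotype_contrast(make_geno(dos_na), colnames(dos), null_y)
  expect_equal(hc_na$n_excluded_missing, 7)
  # monomorphic haplotype: single group is an error
  mono <- make_geno(matrix(1L, n, 2))
  expect_error(haplotype_contrast(mono, c("S001", "S002"), null_y),
               "two haplotype groups")
})

test_that("effect-sign profiles flag antagonistic, concordant and neutral SNPs", {
  mk <- function(betas) {
    data.frame(snp_id = names(betas), beta = unname(betas),
               stringsAsFactors = FALSE)
  }
  mean_res <- mk(c(s1 = 0.4, s2 = 0.3, s3 = 0.2, s4 = 0.1))
  lp_res <- mk(c(s1 = -0.2, s2 = 0.3, s3 = 1e-12, s5 = 0.2))
  prof <- effect_sign_tradeoff(mean_res, lp_res, c("s1", "s2", "s3", "s4"))
  expect_equal(prof$flag, c("antagonistic", "concordant", "neutral", "missing"))
})

test_that("category accounting reproduces the printed per-category totals", {
  counts <- c(mean = 77, plasticity = 107, environment_specific = 333,
              condition_specific = 1070, grain_width = 115)
  qtl <- data.frame(
    qtl_id = sprintf("Q%04d", seq_len(sum(counts))),
    chrom = "chr1", start = 1, end = 2,
    category = rep(names(counts), counts), stringsAsFactors = FALSE)
  acc <- category_accounting(qtl)
  expect_equal(acc$total, 1702L)
  expect_equal(acc$counts[["mean"]] + acc$counts[["plasticity"]] +
                 acc$counts[["environment_specific"]] +
                 acc$counts[["condition_specific"]], 1587L)
  expect_equal(sum(acc$counts), acc$total)
  expect_equal(category_accounting(qtl[0, ])$total, 0L)
  qtl_bad <- qtl; qtl_bad$category[5] <- NA
  expect_error(category_accounting(qtl_bad), "category")
})
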