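#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF input (v4.x, GT field) keeps biallelic SNP records only
#' (multi-allelic records skipped with a message); dosages are counts of
#' the minor allele — columns whose ALT allele is the major allele are
#' flipped, with REF/ALT swapped accordingly. Missing genotypes (`./.`)
#' become `NA` (downstream kinship/association mean-impute them). Dosage
#' TSV input expects the header `snp_id, chrom, pos, ref, alt` followed by
#' one column per accession.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A `genotype_matrix` (see [simulate_genotypes()]).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_cfg("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi))
    message(sum(multi), " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1"), 0L)
    out
  }
  dos <- t(apply(gt, 1L, count_alt))
  if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L)
  dos <- t(dos)  # accessions x SNPs
  rownames(dos) <- colnames(gt)
  snp_id <- if (all(is.na(fix$ID)) || all(fix$ID == "."))
    paste0(fix$CHROM, "_", fix$POS) else fix$ID
  colnames(dos) <- snp_id
  ref <- fix$REF; alt <- fix$ALT
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    dos[, flip] <- 2L - dos[, flip]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
    f[flip] <- 1 - f[flip]
  }
  geno <- list(
    dosages = dos,
    snps = data.frame(snp_id = snp_id, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = ref, alt = alt,
                      maf = pmin(f, 1 - f), stringsAsFactors = FALSE),
    accession_ids = rownames(dos)
  )
  class(geno) <- "genotype_matrix"
  geno
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_cfg("dosage TSV lacks column(s): %s",
                             paste(miss, collapse = ", "))
  acc <- setdiff(names(d), need)
  dos <- t(as.matrix(d[, acc, drop = FALSE]))
  colnames(dos) <- d$snp_id
  storage.mode(dos) <- "integer"
  f <- colMeans(dos, na.rm = TRUE) / 2
  geno <- list(
    dosages = dos,
    snps = data.frame(snp_id = d$snp_id, chrom = d$chrom,
                      pos = as.integer(d$pos), ref = d$ref, alt = d$alt,
                      maf = pmin(f, 1 - f), stringsAsFactors = FALSE),
    accession_ids = acc
  )
  class(geno) <- "genotype_matrix"
  geno
}

#' Write a genotype matrix
#'
#' `write_genotypes_tsv()` emits the dosage TSV (`snp_id, chrom, pos, ref,
#' alt`, one column per accession); `write_genotypes_vcf()` emits a minimal
#' plain-text VCF v4.2 with GT-only unphased genotypes (`NA` dosage
#' becomes `./.`).
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  d <- cbind(geno$snps[, c("snp_id", "chrom", "pos", "ref", "alt")],
             as.data.frame(t(geno$dosages), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$accession_ids),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$dosages))) {
    dos <- geno$dosages[, j]
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1L])
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j],
                       geno$snps$snp_id[j], geno$snps$ref[j],
                       geno$snps$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Expects a TSV with header `accession, environment, trait, value`.
#' Duplicate (accession, environment, trait) records are an error;
#' percent-scale traits (the chalkiness family) with values outside
#' `[0, 100]` are kept but reported in the `validation` attribute.
#'
#' @param path File path.
#' @return Phenotype data.frame with attribute `validation` (data.frame of
#'   out-of-bounds records, zero rows when clean).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_cfg("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "environment", "trait", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_cfg("phenotype TSV lacks column(s): %s",
                             paste(miss, collapse = ", "))
  key <- paste(d$accession, d$environment, d$trait)
  if (anyDuplicated(key))
    stop_cfg("duplicate phenotype record(s): %s",
             paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  bad <- d$trait %in% percent_trait_ids() & !is.na(d$value) &
    (d$value < 0 | d$value > 100)
  attr(d, "validation") <- d[bad, , drop = FALSE]
  d
}

#' @rdname read_phenotypes
#' @param pheno Phenotype data.frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno[, c("accession", "environment", "trait", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the environment covariate table
#'
#' TSV with columns `environment, site, year, tmin, tmean, tmax`
#' (temperatures in degrees C over the grain-filling window). Reading
#' checks `tmin <= tmean <= tmax`.
#'
#' @param path File path.
#' @return Environment data.frame.
#' @export
read_environments <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("environment", "tmin", "tmean", "tmax")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_cfg("environment TSV lacks column(s): %s",
                             paste(miss, collapse = ", "))
  if (any(d$tmin > d$tmean | d$tmean > d$tmax))
    stop_cfg("temperature ordering tmin <= tmean <= tmax violated")
  d
}

#' @rdname read_environments
#' @param env Environment data.frame to write.
#' @export
write_environments <- function(env, path) {
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 annotation and returns its gene features as a plain
#' table for [candidate_genes()]. Lines with a wrong field count are
#' skipped with a warning giving the count.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return Data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop_cfg("file not found: %s", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- nf != 9L
  if (any(bad)) {
    warning(sum(bad), " malformed GFF3 record(s) skipped")
    keep <- rep(TRUE, length(lines))
    keep[which(body)[bad]] <- FALSE
    tmp <- tempfile(fileext = ".gff3")
    writeLines(lines[keep], tmp)
    path <- tmp
  }
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[g$type == feature_type]
  ids <- g$ID
  if (is.null(ids)) ids <- g$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(g))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Converts internal 1-based inclusive intervals (QTL regions or hotspots)
#' to 0-based half-open BED, sorted by chromosome then start; the name
#' field is `id|category|n_members` (missing parts rendered as `.`).
#'
#' @param intervals A `qtl_regions` or `hotspots` data.frame (or any frame
#'   with `chrom`, `start`, `end` and an id column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  d <- as.data.frame(intervals)
  if (nrow(d) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  id <- d$qtl_id %||% d$hqtl_id %||% rep(".", nrow(d))
  cat_f <- if ("category" %in% names(d)) as.character(d$category) else rep(".", nrow(d))
  nm <- if ("n_members" %in% names(d)) d$n_members else rep(".", nrow(d))
  cat_f[is.na(cat_f)] <- "."
  bed <- data.frame(chrom = d$chrom, start = d$start - 1L, end = d$end,
                    name = paste(id, cat_f, nm, sep = "|"),
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Serializes a simulated dataset — genotypes (plain-text VCF v4.2 and
#' dosage TSV), long phenotypes, environment covariates and the truth
#' tables — together with a JSON manifest recording the configuration,
#' seed, row counts and file checksums, so a run can be reproduced
#' bit-identically.
#'
#' @param geno A `genotype_matrix`.
#' @param pheno Long phenotype data.frame.
#' @param env Environment table.
#' @param truth A `sim_truth` (from [simulate_phenotypes()]).
#' @param out_dir Output directory (created if absent).
#' @param cfg The [sim_config()] used (stored in the manifest).
#' @return Named character vector of written paths (the manifest under
#'   `"manifest"`), invisibly.
#' @export
write_fixture <- function(geno, pheno, env, truth, out_dir, cfg = NULL) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    dosages = file.path(out_dir, "dosages.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    environments = file.path(out_dir, "environments.tsv"),
    truth_accessions = file.path(out_dir, "truth_accessions.tsv"),
    truth_environments = file.path(out_dir, "truth_environments.tsv"),
    truth_qtl = file.path(out_dir, "truth_qtl.tsv")
  )
  write_genotypes_vcf(geno, paths["vcf"])
  write_genotypes_tsv(geno, paths["dosages"])
  write_phenotypes(pheno, paths["phenotypes"])
  write_environments(env, paths["environments"])
  utils::write.table(
    data.frame(accession = names(truth$g_true), g_true = truth$g_true,
               b_true = truth$b_true, sigma2_i = truth$sigma2_i),
    paths["truth_accessions"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(environment = names(truth$h_true), h_true = truth$h_true),
    paths["truth_environments"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(snp_id = c(truth$mean_qtl, truth$plasticity_qtl),
               component = rep(c("mean", "plasticity"),
                               c(length(truth$mean_qtl),
                                 length(truth$plasticity_qtl))),
               effect = c(truth$alpha_k, truth$gamma_k)),
    paths["truth_qtl"], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, command = "write_fixture",
                 seed = if (!is.null(cfg)) cfg$seed else NA_integer_,
                 config = if (!is.null(cfg)) unclass(cfg) else NULL,
                 inputs = paths)
  invisible(c(paths, manifest = manifest_path))
}

#' Write a run manifest
#'
#' Records command, configuration snapshot, seed, input checksums, package
#' version and timestamp as JSON — one manifest per pipeline run, enough to
#' reproduce deterministic stages bit-identically.
#'
#' @param path Output JSON path.
#' @param command Character label of the stage run.
#' @param seed Seed used.
#' @param config Configuration list (serialized as-is).
#' @param inputs Named character vector of file paths to checksum (md5).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA_integer_, config = NULL,
                           inputs = character(0)) {
  manifest <- list(
    command = command,
    seed = seed,
    config = config,
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(unname(inputs))) else list(),
    tool_version = as.character(utils::packageVersion("plastmap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
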