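# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a stream name, so
# that independent stages (genotypes, phenotypes, folds, ...) draw from
# unrelated streams while staying fully determined by one master seed.
# Result stays inside 32-bit signed range.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((abs(as.integer(seed)) %% 21474000L) * 100L + h %% 100L + h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

# Trait ids measured as percentages in the chalkiness family.
percent_trait_ids <- function() {
  c("GCR", "GCA", "GCD", "WBR", "WBA", "WBD",
    "WCR", "WCA", "WCD", "FER", "FEA", "FED")
}

is_percent_trait <- function(trait) trait %in% percent_trait_ids()

# Wide accession x environment matrix for one trait from a long table.
pheno_wide <- function(pheno, trait) {
  stopifnot(is.data.frame(pheno))
  sub <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop_cfg("trait '%s' not present in phenotype table", trait)
  accs <- unique(sub$accession)
  envs <- sort(unique(sub$environment))
  m <- matrix(NA_real_, length(accs), length(envs),
              dimnames = list(accs, envs))
  m[cbind(match(sub$accession, accs), match(sub$environment, envs))] <- sub$value
  m
}
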