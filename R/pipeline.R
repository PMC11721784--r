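# End-to-end orchestration: configuration, stage execution, manifest.

#' Build a run configuration
#'
#' Collects input paths and every threshold the pipeline uses, with the
#' documented defaults. A configuration round-trips unchanged through
#' [write_config()]/[read_config()].
#'
#' @param fasta,vcf,gff,pops input paths (genome FASTA, variants VCF, gene
#'   models GFF3, accession-to-population TSV).
#' @param out_dir output directory.
#' @param policy presence-calling policy, see [call_presence()].
#' @param seed integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param nearly_fixed,low,tpm,identity,qcov,evalue,grid,minwin,maxwin,top,perm,collinearity
#'   stage thresholds (percent, percent, TPM, percent, percent, E-value, bp,
#'   bp, bp, fraction, count, correlation).
#' @param env optional list for the environmental stage: `path` (env TSV),
#'   `gene` (gene id whose presence defines the groups), `factor`.
#' @param features optional list for the feature contrast: `path` (feature
#'   TSV), `low`, `high` (gene id vectors).
#' @param sweep optional list for the sweep stage: `population` (restrict
#'   haplotypes to one population; default all).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(fasta, vcf, gff, pops, out_dir, policy = "strict",
                       seed = 1L, nearly_fixed = 90, low = 10, tpm = 1,
                       identity = 60, qcov = 70, evalue = 1e-5, grid = 10000,
                       minwin = 10000, maxwin = 100000, top = 0.05,
                       perm = 1000L, collinearity = 0.7, env = NULL,
                       features = NULL, sweep = NULL) {
  stopifnot(nearly_fixed >= 0, nearly_fixed <= 100, low >= 0, low <= 100,
            identity >= 0, identity <= 100, qcov >= 0, qcov <= 100,
            evalue >= 0, grid > 0, minwin > 0, maxwin >= minwin,
            top > 0, top < 1, perm >= 1, collinearity >= 0, collinearity <= 1)
  structure(list(fasta = fasta, vcf = vcf, gff = gff, pops = pops,
                 out_dir = out_dir, policy = policy, seed = as.integer(seed),
                 nearly_fixed = nearly_fixed, low = low, tpm = tpm,
                 identity = identity, qcov = qcov, evalue = evalue,
                 grid = grid, minwin = minwin, maxwin = maxwin, top = top,
                 perm = as.integer(perm), collinearity = collinearity,
                 env = env, features = features, sweep = sweep),
            class = "run_config")
}

#' Write a run configuration as JSON
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path path written by [write_config()].
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Convert a genotype matrix to haplotypes
#'
#' For a selfing species each accession contributes one haplotype:
#' homozygous alternate maps to 1, homozygous reference to 0, heterozygous
#' and missing calls to `NA`. Monomorphic columns are dropped by the
#' [haplotype_matrix()] constructor.
#'
#' @param gm a [genotype_matrix()].
#' @param accessions optional subset of accessions to keep.
#' @param population population label for the result.
#' @return a [haplotype_matrix()].
#' @export
haplotypes_from_genotypes <- function(gm, accessions = NULL,
                                      population = "pop1") {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- if (is.null(accessions)) gm$accessions else accessions
  calls <- gm$calls[match(keep, gm$accessions), , drop = FALSE]
  m <- matrix(NA_integer_, nrow = nrow(calls), ncol = ncol(calls))
  m[calls == "REF"] <- 0L
  m[calls == "ALT"] <- 1L
  chrom <- unique(gm$variants$chrom)
  if (length(chrom) != 1L)
    stop("haplotype conversion expects a single chromosome; got ",
         length(chrom))
  ord <- order(gm$variants$pos)
  dup <- duplicated(gm$variants$pos[ord])
  haplotype_matrix(m[, ord[!dup], drop = FALSE], gm$variants$pos[ord[!dup]],
                   chrom = chrom, population = population)
}

#' Run the presence-to-summary pipeline
#'
#' Executes presence calling, frequency computation, binning and the
#' population summary, plus the optional feature-contrast, environmental and
#' sweep stages when configured. Every stage writes its TSV into
#' `config$out_dir` and the run ends with a `manifest.json` recording the
#' package version, seed, every threshold used and per-stage row counts, so
#' that a run is reconstructible from the manifest alone. On a stage error a
#' `failed` marker naming the stage is left in the output directory and the
#' error is re-raised.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$fasta, config$vcf, config$gff, config$pops))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "failed")
  if (file.exists(marker)) unlink(marker)
  manifest <- list(package = "denovopop",
                   version = as.character(utils::packageVersion("denovopop")),
                   seed = config$seed,
                   thresholds = unclass(config)[c(
                     "policy", "nearly_fixed", "low", "tpm", "identity",
                     "qcov", "evalue", "grid", "minwin", "maxwin", "top",
                     "perm", "collinearity")],
                   inputs = unclass(config)[c("fasta", "vcf", "gff", "pops")],
                   stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 marker)
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     rows = if (is.data.frame(res)) nrow(res)
                                            else NA)
    res
  }

  genome <- stage("read_genome", function() {
    g <- read_sequences(config$fasta)
    invisible(g)
  })
  genotypes <- stage("read_variants", function() read_variants(config$vcf))
  models <- stage("read_models", function()
    gene_models_from_intervals(read_intervals(config$gff, "gff3")))
  pop_map <- stage("read_pops", function()
    read_table(config$pops, required = c("accession", "population")))

  calls <- stage("presence", function() {
    out <- do.call(rbind, lapply(models, function(m)
      call_presence(m, genome, genotypes, policy = config$policy)))
    rownames(out) <- NULL
    write_tsv(out, file.path(config$out_dir, "calls.tsv"))
    out
  })
  freqs <- stage("frequency", function() {
    fr <- compute_frequency(calls, pop_map)
    write_tsv(fr, file.path(config$out_dir, "frequencies.tsv"))
    fr
  })
  stage("bins", function() {
    b <- cbind(freqs, bin = bin_frequency(freqs$freq_pct))
    write_tsv(b, file.path(config$out_dir, "bins.tsv"))
    b
  })
  stage("summary", function() {
    s <- summarize_population(freqs, nearly_fixed_threshold = config$nearly_fixed,
                              low_threshold = config$low)
    write_tsv(s, file.path(config$out_dir, "summary.tsv"))
    s
  })

  if (!is.null(config$features)) {
    stage("features", function() {
      feats <- read_table(config$features$path, required = "gene_id")
      tests <- compare_features(feats, config$features$low,
                                config$features$high)
      write_tsv(tests, file.path(config$out_dir, "feature_tests.tsv"))
      tests
    })
  }
  if (!is.null(config$env)) {
    stage("envtest", function() {
      env <- read_table(config$env$path, required = "accession")
      gene_calls <- calls[calls$gene_id == config$env$gene, , drop = FALSE]
      pres <- gene_calls$accession[gene_calls$present]
      abs_ <- gene_calls$accession[!gene_calls$present &
                                     gene_calls$status != "UNRESOLVED"]
      tt <- ttest_env(env, pres, abs_)
      write_tsv(tt, file.path(config$out_dir, "env_ttests.tsv"))
      pt <- permutation_test(env[[config$env$factor]][env$accession %in% pres],
                             env[[config$env$factor]][env$accession %in% abs_],
                             n_perm = config$perm, seed = config$seed)
      write_tsv(data.frame(factor = config$env$factor,
                           observed_mean = pt$observed_mean,
                           ci_low = pt$ci_low, ci_high = pt$ci_high,
                           p_empirical = pt$p_empirical,
                           significant = pt$significant),
                file.path(config$out_dir, "env_permutation.tsv"))
      write_tsv(data.frame(null_mean = pt$null_means),
                file.path(config$out_dir, "env_null_means.tsv"))
      tt
    })
  }
  if (!is.null(config$sweep)) {
    stage("sweep", function() {
      popn <- config$sweep$population
      accs <- if (is.null(popn)) NULL else
        pop_map$accession[pop_map$population == popn]
      hap <- haplotypes_from_genotypes(genotypes, accessions = accs,
                                       population = popn %||% "all")
      res <- scan_omega(hap, grid_step = config$grid, minwin = config$minwin,
                        maxwin = config$maxwin)
      write_tsv(res, file.path(config$out_dir, "omega.tsv"))
      reg <- call_selected(res, top_frac = config$top, grid_step = config$grid)
      if (nrow(reg)) write_intervals(
        data.frame(reg[, c("chrom", "start", "end")], name = reg$population),
        file.path(config$out_dir, "regions.bed"))
      res
    })
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
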