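#' Pipeline configuration
#'
#' Assembles the run configuration for [run_pipeline()]: either paths to
#' existing input tables (pedigree CSV, test-day CSV, dosage TSV prefix)
#' or a [sim_config()] to generate them; the traits to analyse; the
#' parity group (primiparous: single records, animal model; multiparous:
#' repeated records, repeatability model with a permanent-environment
#' term); and the WssGWAS/LD/annotation options.
#'
#' @param sim a [sim_config()] used when no input paths are given
#' @param pedigree_file,testday_file,dosage_prefix optional input paths
#' @param traits trait columns (from the curve fits) to analyse
#' @param parity "primi" or "multi"
#' @param maf_threshold SNP QC threshold
#' @param blend G blending fraction
#' @param n_iterations,report_iteration WssGWAS weighting loop
#' @param window_size SNP per scan window
#' @param threshold candidate window threshold (% additive variance)
#' @param ld_window_bp LD pair window
#' @param r2_threshold LD block cutoff
#' @param annotation_file optional GFF3/BED gene annotation
#' @param gmt_file,background optional gene sets + universe for
#'   enrichment
#' @param seed run seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(),
                            pedigree_file = NULL, testday_file = NULL,
                            dosage_prefix = NULL,
                            traits = c("m305", "peak_yield"),
                            parity = c("primi", "multi"),
                            maf_threshold = 0.05, blend = 0.05,
                            n_iterations = 3L, report_iteration = 2L,
                            window_size = 50L, threshold = 0.5,
                            ld_window_bp = 200000, r2_threshold = 0.7,
                            annotation_file = NULL, gmt_file = NULL,
                            background = NULL, seed = 1L) {
  parity <- match.arg(parity)
  cfg <- as.list(environment())
  files <- c(cfg$pedigree_file, cfg$testday_file, cfg$annotation_file,
             cfg$gmt_file)
  missing <- files[!vapply(files, file.exists, logical(1))]
  if (length(missing))
    stop("configured input file(s) do not exist: ",
         paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys override the defaults of [pipeline_config()]; keys
#' under `sim:` override [sim_config()] defaults.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  do.call(pipeline_config, c(list(sim = sim), raw))
}

.stage_log <- function(log, stage, t0, ...) {
  entry <- c(list(stage = stage,
                  seconds = round(as.numeric(Sys.time()) - t0, 2)),
             list(...))
  message(sprintf("[%s] done in %.1fs %s", stage, entry$seconds,
                  paste(names(list(...)), unlist(list(...)), sep = "=",
                        collapse = " ")))
  c(log, list(entry))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> fit curves -> variance components -> weighted
#' single-step GWAS with window scan -> LD blocks over the top candidate
#' region -> gene annotation/enrichment (when an annotation is
#' configured). Every stage writes its report under `outdir`; a manifest
#' (inputs, parameters, package version, seed) makes the run
#' re-derivable.
#'
#' @param config a `pipeline_config`
#' @param outdir output directory (created)
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  set.seed(config$seed)

  t0 <- as.numeric(Sys.time())
  if (!is.null(config$pedigree_file)) {
    ped <- read_pedigree(config$pedigree_file)
    records <- read_testday(config$testday_file)
    geno <- read_dosage(config$dosage_prefix)
    covariates <- NULL
    sim <- NULL
  } else {
    sim <- simulate_population(config$sim)
    ped <- sim$pedigree
    records <- sim$records
    covariates <- sim$covariates
    geno <- sim$genotypes
    # genotype a subset: all phenotyped animals' most recent generations
    write_pedigree(ped, file.path(outdir, "pedigree.csv"))
    write_testday(records, file.path(outdir, "testday.csv"))
  }
  log <- .stage_log(log, "data", t0, lactations =
                      nrow(unique(records[c("animal", "parity")])))

  t0 <- as.numeric(Sys.time())
  fits <- fit_lactations(records)
  fits <- fits[fits$converged & !is.na(fits$t_peak), , drop = FALSE]
  if (!is.null(covariates))
    fits <- merge(fits, covariates, by = c("animal", "parity"))
  utils::write.table(fits, file.path(outdir, "lactation_fits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log <- .stage_log(log, "fit-curves", t0, fits = nrow(fits))

  phen <- if (config$parity == "primi")
    fits[fits$parity == 1, , drop = FALSE] else
      fits[fits$parity >= 2, , drop = FALSE]
  pe <- config$parity == "multi"
  fixed <- c("hys", "country", if (pe) "parity")
  fixed <- fixed[fixed %in% names(phen)]
  covs <- intersect("age_calving", names(phen))

  t0 <- as.numeric(Sys.time())
  hsys <- build_h_system(ped, geno, maf_threshold = config$maf_threshold,
                         blend = config$blend)
  log <- .stage_log(log, "kinship", t0,
                    snp = ncol(hsys$genotypes$dosage),
                    genotyped = length(hsys$genotyped_idx))

  results <- list()
  vc_rows <- list()
  for (trait in config$traits) {
    t0 <- as.numeric(Sys.time())
    mme <- build_mme(phen, trait, fixed, covs, h_inv = hsys$H_inv, pe = pe)
    vc <- aireml(mme)
    vc_rows[[trait]] <- data.frame(trait = trait, sigma_a2 = vc$sigma_a2,
                                   sigma_p2 = vc$sigma_p2,
                                   sigma_e2 = vc$sigma_e2, h2 = vc$h2,
                                   repeatability = vc$repeatability,
                                   converged = vc$converged)
    log <- .stage_log(log, paste0("reml-", trait), t0,
                      h2 = round(vc$h2, 3))

    t0 <- as.numeric(Sys.time())
    scan <- iterate_weights(phen, trait, fixed, covs, pe = pe, ped = ped,
                            genotypes = hsys$genotypes, components = vc,
                            n_iterations = config$n_iterations,
                            blend = config$blend)
    win <- window_variance(scan, window_size = config$window_size,
                           report_iteration = config$report_iteration)
    cand <- candidate_windows(win, config$threshold)
    it <- min(config$report_iteration, length(scan$iterations))
    eff <- cbind(scan$map, scan$iterations[[it]]$snp_effects[-1])
    utils::write.table(eff,
                       file.path(outdir, paste0("snp_effects_", trait,
                                                ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(win, file.path(outdir, paste0("windows_", trait,
                                                     ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(scan$iterations[[it]]$gebv,
                       file.path(outdir, paste0("gebv_", trait, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log <- .stage_log(log, paste0("wssgwas-", trait), t0,
                      candidates = nrow(cand))

    ld <- NULL; blocks <- NULL; genes <- NULL
    if (nrow(cand)) {
      t0 <- as.numeric(Sys.time())
      top <- cand[1, ]
      ld <- pairwise_r2(hsys$genotypes, chrom = top$chrom,
                        from_bp = top$start_bp - config$ld_window_bp,
                        to_bp = top$end_bp + config$ld_window_bp,
                        window_bp = config$ld_window_bp)
      blocks <- find_blocks(ld, config$r2_threshold)
      utils::write.table(blocks,
                         file.path(outdir, paste0("ld_blocks_", trait,
                                                  ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log <- .stage_log(log, paste0("ld-", trait), t0,
                        blocks = nrow(blocks))
      if (!is.null(config$annotation_file)) {
        ann <- read_gene_annotation(config$annotation_file)
        genes <- genes_in_windows(cand, ann)
        utils::write.table(genes,
                           file.path(outdir, paste0("genes_", trait,
                                                    ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    results[[trait]] <- list(components = vc, scan = scan, windows = win,
                             candidates = cand, ld = ld, blocks = blocks,
                             genes = genes)
  }
  vc_tab <- do.call(rbind, vc_rows)
  utils::write.table(vc_tab, file.path(outdir, "variance_components.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "lactgwas",
    version = as.character(utils::packageVersion("lactgwas")),
    seed = config$seed,
    parity = config$parity,
    traits = config$traits,
    parameters = config[c("maf_threshold", "blend", "n_iterations",
                          "report_iteration", "window_size", "threshold",
                          "ld_window_bp", "r2_threshold")],
    inputs = list(pedigree_file = config$pedigree_file,
                  testday_file = config$testday_file,
                  simulated = is.null(config$pedigree_file)),
    stages = log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, variance_components = vc_tab,
                 manifest = manifest, h_system = hsys))
}
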