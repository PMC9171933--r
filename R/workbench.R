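#' Run configuration
#'
#' Validated, fully serializable settings bundle for the pipeline entry
#' points; a run re-executed from its saved config and seeds reproduces
#' its outputs exactly.
#'
#' @param seed master integer seed.
#' @param design a [sim_design] (or list of its arguments).
#' @param traits traits to simulate (default: full catalogue).
#' @param genetic_model `"markers"` or `"pedigree"` (see
#'   [simulate_traits]).
#' @param objectives objective traits for estimation / cross-validation.
#' @param phenotyping phenotyping scenarios.
#' @param genotyping genotyping stages.
#' @param n_folds cross-validation folds.
#' @param chain Gibbs chain settings (`n_iter`, `burn_in`, `thin`).
#' @param call_rate_min,maf_min SNP QC thresholds.
#' @param alpha H-matrix blending weight.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, design = sim_design(), traits = NULL,
                       genetic_model = "markers",
                       objectives = "cIMF", phenotyping = "ST",
                       genotyping = "None", n_folds = 4L,
                       chain = list(n_iter = 100000L, burn_in = 20000L,
                                    thin = 20L),
                       call_rate_min = 0.90, maf_min = 0.05,
                       alpha = 0.05) {
  if (is.list(design) && !inherits(design, "sim_design"))
    design <- do.call(sim_design, design)
  if (!inherits(design, "sim_design"))
    stop("config field 'design' must be a sim_design")
  if (!genetic_model %in% c("markers", "pedigree"))
    stop("config field 'genetic_model' must be 'markers' or 'pedigree'")
  for (f in c("n_iter", "burn_in", "thin"))
    if (is.null(chain[[f]]) || chain[[f]] < 0)
      stop("config field 'chain$", f, "' missing or negative")
  if (chain$burn_in >= chain$n_iter)
    stop("config field 'chain': burn_in must be below n_iter")
  known <- c("ST", "PB-1", "PB-2", "PB-3", "CB-Live", "CB-FOM", "CB-Color")
  if (!all(phenotyping %in% known))
    stop("config field 'phenotyping': unknown scenario ",
         paste(setdiff(phenotyping, known), collapse = ", "))
  stages <- c("None", "Stage-1", "Stage-2", "Stage-3")
  if (!all(genotyping %in% stages))
    stop("config field 'genotyping': unknown stage ",
         paste(setdiff(genotyping, stages), collapse = ", "))
  structure(list(seed = as.integer(seed), design = design, traits = traits,
                 genetic_model = genetic_model, objectives = objectives,
                 phenotyping = phenotyping, genotyping = genotyping,
                 n_folds = as.integer(n_folds), chain = chain,
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 alpha = alpha),
            class = "run_config")
}

write_manifest <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write run manifests")
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory exists and is non-empty: ", out_dir,
         " (use force = TRUE to overwrite)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

#' Simulate a dataset to disk
#'
#' Generates the synthetic population and phenotypes of a [run_config],
#' applies the within-group phenotyping-subset rule to the expensive
#' crossbred traits, and writes pedigree, genotype, phenotype and truth
#' files plus a manifest with the seed and design.
#'
#' @param config a [run_config].
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @param verbose print stage progress.
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(config, out_dir, force = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  prepare_out_dir(out_dir, force)
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating population (seed %d)", config$seed)
  popn <- simulate_population(config$design, seed = config$seed)
  model <- default_trait_model(config$traits)
  say("simulating %d traits", length(model$traits))
  sim <- simulate_traits(popn, model, seed = config$seed + 1L,
                         genetic_model = config$genetic_model)
  phen <- sim$phenotypes
  cat_ <- pig_trait_catalogue()
  expensive <- intersect(cat_$trait[cat_$expensive], model$traits)
  anchor <- "cCDG"
  subset_ids <- character(0)
  if (length(expensive) && anchor %in% model$traits) {
    grp <- cb_groups(popn$animals)
    w <- !is.na(grp)
    # singleton groups are expected at small design scales
    subset_ids <- suppressWarnings(
      select_phenotyping_subset(phen[w, ], grp[w], anchor))
    phen <- apply_phenotyping_subset(phen, subset_ids, expensive)
  }
  paths <- list(
    pedigree = file.path(out_dir, "pedigree.txt"),
    genotypes = file.path(out_dir, "genotypes.txt"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    truth_bv = file.path(out_dir, "truth_bv.tsv"),
    truth_subset = file.path(out_dir, "truth_subset.txt"),
    manifest = file.path(out_dir, "manifest.json"))
  rec <- popn$ped$records
  utils::write.table(
    data.frame(id = rec$id,
               sire = ifelse(is.na(rec$sire), "0", rec$sire),
               dam = ifelse(is.na(rec$dam), "0", rec$dam),
               population = rec$population),
    paths$pedigree, quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_genotype_matrix(popn$geno, paths$genotypes)
  utils::write.table(phen, paths$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(id = rownames(sim$truth$bv),
                                sim$truth$bv),
                     paths$truth_bv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(subset_ids, paths$truth_subset)
  write_manifest(list(seed = config$seed,
                      design = unclass(config$design),
                      genetic_model = config$genetic_model,
                      traits = model$traits,
                      psd_adjustment = model$psd_adjustment),
                 paths$manifest)
  say("wrote %d files to %s", length(paths), out_dir)
  invisible(paths)
}

#' Estimate variance components per phenotyping scenario
#'
#' Runs the Gibbs sampler once per phenotyping scenario (single-trait
#' model for `ST`, multi-trait otherwise) and writes summary tables in the
#' customary `estimate (HPD low, HPD high)` layout, for heritabilities and
#' genetic correlations.  Traits without any record get an explicit
#' `no data` entry.
#'
#' @param config a [run_config].
#' @param phenotypes phenotype table.
#' @param ped the [pedigree].
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @param verbose print stage progress.
#' @return Invisibly, a list of chain summaries per scenario.
#' @export
cmd_estimate <- function(config, phenotypes, ped, out_dir, force = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (config$chain$burn_in >= config$chain$n_iter)
    stop("chain shorter than burn-in")
  prepare_out_dir(out_dir, force)
  say <- function(...) if (verbose) message(sprintf(...))
  A <- build_A(ped)
  out <- list()
  for (obj in config$objectives) for (phs in config$phenotyping) {
    traits <- unique(c(obj, setdiff(scenario_predictors(phs), obj)))
    nodata <- vapply(traits, function(tr)
      !tr %in% names(phenotypes) || all(is.na(phenotypes[[tr]])), TRUE)
    note <- NULL
    if (any(nodata)) {
      note <- data.frame(trait = traits[nodata], estimate = "no data")
      traits <- traits[!nodata]
    }
    key <- sprintf("%s_%s", obj, phs)
    if (!length(traits)) {
      out[[key]] <- list(note = note)
      next
    }
    say("estimating %s (%d traits)", key, length(traits))
    tp <- infer_trait_populations(phenotypes, traits)
    spec <- model_spec(traits, tp)
    ch <- gibbs_vc(spec, phenotypes, A, n_iter = config$chain$n_iter,
                   burn_in = config$chain$burn_in,
                   thin = config$chain$thin, seed = config$seed)
    sm <- summarize_chain(ch, c("heritability", "genetic_correlation"))
    f1 <- file.path(out_dir, paste0("h2_", key, ".tsv"))
    write_chain_summary(sm$heritability, f1)
    if (!is.null(sm$genetic_correlation))
      write_chain_summary(sm$genetic_correlation,
                          file.path(out_dir, paste0("rg_", key, ".tsv")))
    if (!is.null(note))
      utils::write.table(note, file.path(out_dir,
                                         paste0("nodata_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    out[[key]] <- list(summary = sm, n_saved = ch$n_saved, note = note)
  }
  write_manifest(list(seed = config$seed, chain = config$chain,
                      objectives = config$objectives,
                      phenotyping = config$phenotyping),
                 file.path(out_dir, "manifest.json"))
  invisible(out)
}

#' Cross-validate scenarios and write accuracy tables
#'
#' Builds sire folds by k-means on pedigree dissimilarities, runs
#' [run_grid] over the configured scenario grid, and writes long plus
#' aggregated accuracy tables and a reproducibility manifest.
#'
#' @param config a [run_config].
#' @param phenotypes phenotype table.
#' @param ped the [pedigree].
#' @param geno optional [genotype_set] (required for any stage other than
#'   `"None"`).
#' @param vc_fixed [variance_components] spanning all involved traits
#'   (when `NULL`, components are Gibbs-estimated per scenario with a
#'   scaled chain).
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @param verbose print stage progress.
#' @return Invisibly, the [run_grid] result.
#' @export
cmd_crossval <- function(config, phenotypes, ped, geno = NULL,
                         vc_fixed = NULL, out_dir, force = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (any(config$genotyping != "None") && is.null(geno))
    stop("genotype data required for genotyping stages other than 'None'; ",
         "supply `geno` (e.g. from read_genotype_matrix)")
  prepare_out_dir(out_dir, force)
  say <- function(...) if (verbose) message(sprintf(...))
  say("building A and sire folds")
  A <- build_A(ped)
  sires <- ped$records$id[ped$records$population == "PB_SIRE"]
  D <- sire_dissimilarity(A, sires)
  folds <- kmeans_folds(D, n_folds = config$n_folds, seed = config$seed,
                        ped = ped)
  say("running %dx%dx%d grid", length(config$objectives),
      length(config$phenotyping), length(config$genotyping))
  res <- run_grid(phenotypes, ped, geno, config$objectives,
                  config$phenotyping, config$genotyping, folds,
                  vc_source = if (is.null(vc_fixed))
                    "estimate_per_scenario" else "fixed",
                  vc_fixed = vc_fixed,
                  chain = c(config$chain, list(seed = config$seed)),
                  alpha = config$alpha, A = A)
  utils::write.table(res$long, file.path(out_dir, "accuracy_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$aggregate,
                     file.path(out_dir, "accuracy_aggregate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_folds(folds, file.path(out_dir, "folds.txt"))
  write_manifest(c(res$manifest, list(seed = config$seed,
                                      errors = res$errors)),
                 file.path(out_dir, "manifest.json"))
  invisible(res)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config].
#' @param path output path (`.yml`).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to serialize configurations")
  x <- unclass(config)
  x$design <- unclass(x$design)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Re-validates every field, so a malformed file raises an error naming
#' the offending entry.
#'
#' @param path path to a YAML file written by [write_run_config].
#' @return A validated [run_config].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configurations")
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}
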