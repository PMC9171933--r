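#' Predictor-trait sets of the phenotyping scenarios
#'
#' The selection criterion per scenario: `ST` uses the objective trait
#' alone; `PB-1` the purebred daily-gain traits; `PB-2` adds the purebred
#' ultrasound traits; `PB-3` further adds purebred intramuscular fat;
#' `CB-Live` the crossbred live growth traits; `CB-FOM` the carcass-probe
#' traits plus carcass daily gain; `CB-Color` the instrumental color and pH
#' traits.
#'
#' @param phenotyping scenario name.
#' @return Character vector of predictor traits (empty for `ST`).
#' @export
scenario_predictors <- function(phenotyping = c("ST", "PB-1", "PB-2",
                                                "PB-3", "CB-Live",
                                                "CB-FOM", "CB-Color")) {
  phenotyping <- match.arg(phenotyping)
  switch(phenotyping,
         "ST" = character(0),
         "PB-1" = c("pLDG1", "pLDG2"),
         "PB-2" = c("pLDG1", "pLDG2", "pLBF", "pLLD", "pLLA"),
         "PB-3" = c("pLDG1", "pLDG2", "pLBF", "pLLD", "pLLA", "pIMF"),
         "CB-Live" = c("cLLD", "cLBF", "cLDG"),
         "CB-FOM" = c("cCBF", "cCLD", "cCDG"),
         "CB-Color" = c("cM.L", "cM.a", "cM.b", "cPH"))
}

#' Scenario specification for one cross-validation cell
#'
#' @param phenotyping phenotyping scenario (see [scenario_predictors]).
#' @param objective_trait breeding-objective trait (predicted, crossbred).
#' @param genotyping genotyping stage: `"None"`, `"Stage-1"` (sires +
#'   dams), `"Stage-2"` (crossbreds + sires), `"Stage-3"` (sires, dams and
#'   crossbreds); purebred offspring genotypes are added whenever the
#'   phenotyping scenario includes purebred predictor traits.
#' @param fold validation fold index.
#' @param predictor_traits optional override of the scenario's predictor
#'   set.
#' @return A `scenario_spec` list; the objective is never in its own
#'   predictor set.
#' @export
scenario_spec <- function(phenotyping, objective_trait,
                          genotyping = c("None", "Stage-1", "Stage-2",
                                         "Stage-3"),
                          fold = 1L, predictor_traits = NULL) {
  genotyping <- match.arg(genotyping)
  if (is.null(predictor_traits))
    predictor_traits <- scenario_predictors(phenotyping)
  predictor_traits <- setdiff(predictor_traits, objective_trait)
  structure(list(phenotyping = phenotyping,
                 objective_trait = objective_trait,
                 predictor_traits = predictor_traits,
                 genotyping = genotyping, fold = as.integer(fold)),
            class = "scenario_spec")
}

#' Animals contributing genotypes under a genotyping stage
#'
#' @param animals animals data.frame with `id` and `population`
#'   (`PB_SIRE`, `DAM`, `CB`, `PB`, ...).
#' @param stage `"None"`, `"Stage-1"`, `"Stage-2"` or `"Stage-3"`.
#' @param include_pb add the purebred offspring genotypes (used whenever
#'   purebred phenotypes are in the model).
#' @return Character vector of genotyped animal ids (possibly empty).
#' @export
stage_genotyped_ids <- function(animals, stage = c("None", "Stage-1",
                                                   "Stage-2", "Stage-3"),
                                include_pb = FALSE) {
  stage <- match.arg(stage)
  pops <- switch(stage,
                 "None" = character(0),
                 "Stage-1" = c("PB_SIRE", "DAM"),
                 "Stage-2" = c("CB", "PB_SIRE"),
                 "Stage-3" = c("PB_SIRE", "DAM", "CB"))
  if (include_pb && stage != "None") pops <- c(pops, "PB")
  animals$id[animals$population %in% pops]
}

#' Mask the objective trait of a validation fold
#'
#' Sets the objective-trait records of crossbred animals in the validation
#' fold to missing, while predictor-trait records (purebred or crossbred)
#' remain available for all folds.  Idempotent.
#'
#' @param phenotypes phenotype data.frame (column `id` required).
#' @param objective_trait trait column to mask.
#' @param folds a `fold_assignment` with `animal_fold` populated.
#' @param fold validation fold index.
#' @return The phenotype table with masked objective records.
#' @export
mask_phenotypes <- function(phenotypes, objective_trait, folds, fold) {
  ids <- as.character(phenotypes$id)
  vfold <- folds$animal_fold[ids]
  mask <- !is.na(vfold) & vfold == fold & phenotypes$population == "CB"
  if (!any(mask & !is.na(phenotypes[[objective_trait]])) &&
      !any(mask))
    stop("empty validation set for fold ", fold)
  phenotypes[mask, objective_trait] <- NA
  phenotypes
}

#' Phenotypes adjusted for fixed effects
#'
#' `y* = y - X beta-hat` with the fixed-effect solutions taken from a fit
#' on the full (unmasked) data, as used for scoring prediction accuracy.
#'
#' @param spec the [model_spec] used for the full fit.
#' @param phenotypes full (unmasked) phenotype table.
#' @param K relationship matrix used in the full fit.
#' @param full_fit `mme_solution` from the full-data fit.
#' @param trait trait to adjust.
#' @return Named vector of adjusted phenotypes (names = animal ids) over
#'   animals with a record for `trait`; animals with unestimable
#'   fixed-effect values come back `NA`.
#' @export
adjusted_phenotype <- function(spec, phenotypes, K, full_fit, trait) {
  des <- build_design(spec, phenotypes, K)
  k <- match(trait, spec$traits)
  if (is.na(k)) stop("trait not in the model spec: ", trait)
  X <- des$Xs[[k]]
  beta <- full_fit$fixed[[trait]]
  stopifnot(identical(names(beta), colnames(X)))
  y <- as.numeric(phenotypes[[trait]])
  adj <- y - drop(X %*% beta)
  names(adj) <- as.character(phenotypes$id)
  adj[!is.na(y)]
}

#' Prediction accuracy of one validation fold
#'
#' Pearson correlation between estimated breeding values and
#' fixed-effect-adjusted phenotypes over the validation animals.
#'
#' @param ebv named numeric vector of estimated breeding values.
#' @param adjusted named numeric vector of adjusted phenotypes.
#' @param validation_ids animals to score.
#' @return List with `accuracy` (in `[-1, 1]`, `NA` when undefined) and
#'   `n` (animals scored).
#' @export
fold_accuracy <- function(ebv, adjusted, validation_ids) {
  ids <- intersect(as.character(validation_ids),
                   intersect(names(ebv), names(adjusted)))
  x <- ebv[ids]; y <- adjusted[ids]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("fewer than 2 validation animals with values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in EBV or adjusted phenotypes; ",
            "accuracy undefined")
    return(list(accuracy = NA_real_, n = length(x)))
  }
  list(accuracy = stats::cor(x, y), n = length(x))
}

# population of each trait inferred from where its records sit
infer_trait_populations <- function(phenotypes, traits) {
  out <- vapply(traits, function(tr) {
    if (!tr %in% names(phenotypes)) stop("trait column missing: ", tr)
    p <- unique(phenotypes$population[!is.na(phenotypes[[tr]])])
    p <- intersect(c("CB", "PB"), p)
    if (length(p) != 1L)
      stop("cannot infer a single measurement population for ", tr)
    p
  }, "")
  out
}

# subset a full-panel variance_components object to a trait set
subset_vc <- function(vc, traits) {
  stopifnot(all(traits %in% vc$traits))
  variance_components(vc$additive[traits, traits, drop = FALSE],
                      vc$litter[traits, traits, drop = FALSE],
                      vc$pen[traits, traits, drop = FALSE],
                      vc$residual[traits, traits, drop = FALSE],
                      traits = traits)
}

# restrict a genotype_set to a subset of animals
geno_subset <- function(geno, ids) {
  w <- match(ids, geno$ids)
  stopifnot(!anyNA(w))
  genotype_set(geno$dosages[w, , drop = FALSE], geno$marker_meta,
               geno$population[w])
}

#' Cross-validation grid over phenotyping and genotyping scenarios
#'
#' For every combination of breeding objective, phenotyping scenario,
#' genotyping stage and fold: builds the relationship matrix (A, or
#' single-step H from the stage's genotyped animals), masks the objective
#' for the validation fold, fits the multi-trait animal model, and scores
#' the Pearson correlation between EBV and the fixed-effect-adjusted
#' (masked) phenotypes of the validation crossbreds.  Duplicated cells are
#' computed once; failing cells are recorded and the grid continues.
#'
#' @param phenotypes full phenotype table (see [build_mme]).
#' @param ped the [pedigree].
#' @param geno a [genotype_set] over the genotypable animals (`NULL` for
#'   pedigree-only grids).
#' @param objectives character vector of objective traits.
#' @param phenotyping character vector of phenotyping scenarios.
#' @param genotyping character vector of genotyping stages.
#' @param folds `fold_assignment` from [kmeans_folds] (with offspring
#'   mapped).
#' @param vc_source `"fixed"` (use `vc_fixed`, estimated once up front) or
#'   `"estimate_per_scenario"` (Gibbs-estimate components on the full
#'   unmasked data once per phenotyping scenario, then fix across folds
#'   and stages).
#' @param vc_fixed a [variance_components] spanning all traits involved
#'   (required when `vc_source = "fixed"`).
#' @param chain list of Gibbs settings (`n_iter`, `burn_in`, `thin`,
#'   `seed`) for `vc_source = "estimate_per_scenario"`.
#' @param alpha blending weight passed to [blend_grm].
#' @param A optional precomputed full A matrix (built from `ped` when
#'   `NULL`).
#' @return List with `long` (per-fold accuracies), `aggregate` (mean and
#'   SD across folds), `errors` (failed cells) and `manifest` (settings).
#' @export
run_grid <- function(phenotypes, ped, geno = NULL, objectives,
                     phenotyping = "ST", genotyping = "None", folds,
                     vc_source = c("fixed", "estimate_per_scenario"),
                     vc_fixed = NULL,
                     chain = list(n_iter = 20000L, burn_in = 4000L,
                                  thin = 10L, seed = 1L),
                     alpha = 0.05, A = NULL) {
  vc_source <- match.arg(vc_source)
  if (vc_source == "fixed" && is.null(vc_fixed))
    stop("vc_fixed required when vc_source = 'fixed'")
  if (is.null(A)) A <- build_A(ped)
  animals <- data.frame(id = ped$records$id,
                        population = ped$records$population,
                        stringsAsFactors = FALSE)
  grid <- unique(expand.grid(objective = objectives,
                             phenotyping = phenotyping,
                             genotyping = genotyping,
                             stringsAsFactors = FALSE))
  long <- list(); errors <- list()
  for (r in seq_len(nrow(grid))) {
    obj <- grid$objective[r]; phs <- grid$phenotyping[r]
    stg <- grid$genotyping[r]
    cell_id <- sprintf("%s/%s/%s", obj, phs, stg)
    res <- tryCatch({
      sc <- scenario_spec(phs, obj, stg)
      traits <- c(obj, sc$predictor_traits)
      tp <- infer_trait_populations(phenotypes, traits)
      spec <- model_spec(traits, tp)
      vc <- if (vc_source == "fixed") subset_vc(vc_fixed, traits)
      else {
        ch <- gibbs_vc(spec, phenotypes, relmat(unclass(A), "A"),
                       n_iter = chain$n_iter, burn_in = chain$burn_in,
                       thin = chain$thin,
                       seed = if (is.null(chain$seed)) 1L else chain$seed)
        raw <- summarize_chain(ch, "raw")$raw
        variance_components(raw$additive, raw$litter, raw$pen,
                            raw$residual, traits = traits)
      }
      include_pb <- any(tp == "PB")
      gids <- if (is.null(geno)) character(0)
      else intersect(stage_genotyped_ids(animals, stg, include_pb),
                     geno$ids)
      K <- if (length(gids) == 0L) relmat(unclass(A), "A") else {
        gsub_ <- geno_subset(geno, gids)
        Graw <- build_grm(gsub_)
        A22 <- relmat(unclass(A)[gids, gids, drop = FALSE], "G")
        Gstar <- blend_grm(Graw, A22, alpha = alpha)
        build_H(A, Gstar, gids)
      }
      full_fit <- mme_fit(spec, phenotypes, K, vc)
      adj <- adjusted_phenotype(spec, phenotypes, K, full_fit, obj)
      rows <- lapply(seq_len(folds$n_folds), function(fd) {
        masked <- mask_phenotypes(phenotypes, obj, folds, fd)
        fit <- mme_fit(spec, masked, K, vc)
        vids <- names(folds$animal_fold)[folds$animal_fold == fd]
        vids <- intersect(vids, phenotypes$id[
          phenotypes$population == "CB" & !is.na(phenotypes[[obj]])])
        acc <- fold_accuracy(fit$ebv[, obj], adj, vids)
        data.frame(objective = obj, phenotyping = phs, genotyping = stg,
                   fold = fd, accuracy = acc$accuracy, n = acc$n)
      })
      do.call(rbind, rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[cell_id]] <- conditionMessage(res)
    } else {
      long[[cell_id]] <- res
    }
  }
  long <- if (length(long)) do.call(rbind, c(long, make.row.names = FALSE))
  else data.frame()
  aggregate <- if (nrow(long)) {
    sp <- split(long, long[c("objective", "phenotyping", "genotyping")],
                drop = TRUE)
    do.call(rbind, c(lapply(sp, function(d)
      data.frame(objective = d$objective[1L],
                 phenotyping = d$phenotyping[1L],
                 genotyping = d$genotyping[1L],
                 mean_accuracy = mean(d$accuracy, na.rm = TRUE),
                 sd_accuracy = stats::sd(d$accuracy),
                 n_folds = nrow(d))), make.row.names = FALSE))
  } else data.frame()
  list(long = long, aggregate = aggregate, errors = errors,
       manifest = list(objectives = objectives, phenotyping = phenotyping,
                       genotyping = genotyping, vc_source = vc_source,
                       alpha = alpha, chain = chain,
                       n_folds = folds$n_folds))
}

#' Panel plot of cross-validated accuracies
#'
#' Accuracy against phenotyping scenario, one panel per objective trait,
#' genotyping stages distinguished by color/shape.
#'
#' @param aggregate the `aggregate` table from [run_grid].
#' @return A ggplot object.
#' @export
plot_accuracy_grid <- function(aggregate) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(aggregate,
                  ggplot2::aes(x = phenotyping, y = mean_accuracy,
                               color = genotyping, shape = genotyping,
                               group = genotyping)) +
    ggplot2::geom_point(size = 2,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_accuracy - sd_accuracy,
                   ymax = mean_accuracy + sd_accuracy),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~objective) +
    ggplot2::labs(x = "phenotyping scenario", y = "prediction accuracy",
                  color = "genotyping", shape = "genotyping") +
    ggplot2::theme_bw()
}
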