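# shared small dataset with folds for the masking/accuracy tests; the
# trait panel covers the objective plus the PB-1 predictor set
eval_fixture <- function(seed = 71) {
  d <- sim_design(n_sires = 4L, n_dams = 16L, n_cb = 96L, n_pb = 48L,
                  n_pb_dams = 6L, n_markers = 150L, pen_size = 10L,
                  pens_per_cg = 2L)
  popn <- simulate_population(d, seed = seed)
  model <- default_trait_model(
    c("cIMF", "pIMF", "pLDG1", "pLDG2"),
    rg_overrides = data.frame(t1 = "pIMF", t2 = "cIMF", rg = 0.6))
  sim <- simulate_traits(popn, model, seed = seed + 1L,
                         genetic_model = "markers")
  A <- build_A(popn$ped)
  sires <- popn$ped$records$id[popn$ped$records$population == "PB_SIRE"]
  D <- sire_dissimilarity(A, sires)
  folds <- kmeans_folds(D, n_folds = 4L, seed = 1L, ped = popn$ped)
  list(popn = popn, sim = sim, phen = sim$phenotypes, A = A,
       folds = folds, sires = sires)
}

# the generating components spanning the fixture's traits
grid_vc <- function(fx) fx$sim$truth$vc

test_that("scenario predictor sets match the trait table", {
  expect_equal(scenario_predictors("ST"), character(0))
  expect_equal(scenario_predictors("PB-1"), c("pLDG1", "pLDG2"))
  expect_setequal(scenario_predictors("PB-2"),
                  c("pLDG1", "pLDG2", "pLBF", "pLLD", "pLLA"))
  expect_setequal(scenario_predictors("PB-3"),
                  c(scenario_predictors("PB-2"), "pIMF"))
  expect_setequal(scenario_predictors("CB-Live"), c("cLLD", "cLBF", "cLDG"))
  expect_setequal(scenario_predictors("CB-FOM"), c("cCBF", "cCLD", "cCDG"))
  expect_setequal(scenario_predictors("CB-Color"),
                  c("cM.L", "cM.a", "cM.b", "cPH"))
  # the objective never predicts itself
  sc <- scenario_spec("CB-Live", "cLLD")
  expect_false("cLLD" %in% sc$predictor_traits)
})

test_that("genotyping stages select the documented population sets", {
  an <- data.frame(id = as.character(1:5),
                   population = c("PB_SIRE", "DAM", "CB", "PB", "ANCESTOR"))
  expect_equal(stage_genotyped_ids(an, "None"), character(0))
  expect_setequal(stage_genotyped_ids(an, "Stage-1"), c("1", "2"))
  expect_setequal(stage_genotyped_ids(an, "Stage-2"), c("1", "3"))
  expect_setequal(stage_genotyped_ids(an, "Stage-3"), c("1", "2", "3"))
  # purebred offspring genotypes join when purebred phenotypes are modeled
  expect_setequal(stage_genotyped_ids(an, "Stage-1", include_pb = TRUE),
                  c("1", "2", "4"))
  expect_setequal(stage_genotyped_ids(an, "None", include_pb = TRUE),
                  character(0))
})

test_that("masking removes only the validation fold's objective records", {
  fx <- eval_fixture()
  ph <- fx$phen
  masked <- mask_phenotypes(ph, "cIMF", fx$folds, fold = 2L)
  vids <- names(fx$folds$animal_fold)[fx$folds$animal_fold == 2L]
  vcb <- intersect(vids, ph$id[ph$population == "CB"])
  expect_true(all(is.na(masked$cIMF[masked$id %in% vcb])))
  other <- ph$population == "CB" & !(ph$id %in% vcb)
  expect_equal(masked$cIMF[other], ph$cIMF[other])
  # predictor traits remain for everyone, including the validation fold
  expect_equal(masked$pIMF, ph$pIMF)
  # idempotence
  expect_identical(mask_phenotypes(masked, "cIMF", fx$folds, 2L), masked)
})

test_that("fixed-effect adjustment recovers the genetic-plus-residual signal", {
  fx <- eval_fixture()
  # strong two-level sex effect, null batch effects: adjustment must bring
  # the phenotype closer to the sex-free signal
  msex <- trait_model("cIMF", c(cIMF = "CB"), var_p = 0.93^2, h2 = 0.35,
                      fixed_sd = c(cg = 1e-8, sex = 1.5, dam_line = 1e-8,
                                   parity = 1e-8, age_slope = 1e-8))
  simx <- simulate_traits(fx$popn, msex, seed = 99,
                          genetic_model = "pedigree")
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  vc <- simx$truth$vc
  fit <- mme_fit(spec, simx$phenotypes, fx$A, vc)
  adj <- adjusted_phenotype(spec, simx$phenotypes, fx$A, fit, "cIMF")
  cb <- simx$phenotypes[simx$phenotypes$population == "CB", ]
  k <- 1L
  sexpart <- ifelse(cb$sex == "M", simx$truth$sex_effect[k] / 2,
                    -simx$truth$sex_effect[k] / 2)
  signal <- cb$cIMF - sexpart
  raw_cor <- cor(cb$cIMF, signal)
  adj_cor <- cor(adj[cb$id], signal)
  expect_gt(adj_cor, raw_cor)
  # intercept-only adjustment is y minus the mean
  sp0 <- model_spec("cIMF", c(cIMF = "CB"),
                    fixed = list(cIMF = character(0)),
                    random = list(cIMF = "additive"))
  vc0 <- variance_components(matrix(vc$additive[1, 1]),
                             residual = matrix(vc$residual[1, 1]),
                             traits = "cIMF")
  fit0 <- mme_fit(sp0, fx$phen, fx$A, vc0)
  adj0 <- adjusted_phenotype(sp0, fx$phen, fx$A, fit0, "cIMF")
  mu <- unname(fit0$fixed$cIMF["(Intercept)"])
  cb0 <- fx$phen[fx$phen$population == "CB", ]
  expect_equal(unname(adj0), cb0$cIMF - mu, tolerance = 1e-10)
})

test_that("fold accuracy is the Pearson correlation with guard rails", {
  x <- rnorm(50); names(x) <- sprintf("a%02d", 1:50)
  expect_equal(fold_accuracy(x, x, names(x))$accuracy, 1)
  expect_equal(fold_accuracy(x, -x, names(x))$accuracy, -1)
  y <- rnorm(50); names(y) <- names(x)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fold_accuracy(x, y, names(x))$accuracy, manual,
               tolerance = 1e-12)
  z <- rep(1, 50); names(z) <- names(x)
  expect_warning(res <- fold_accuracy(z, y, names(x)), "zero variance")
  expect_true(is.na(res$accuracy))
  expect_error(fold_accuracy(x[1], y[1], names(x)[1]), "fewer than 2")
})

test_that("run_grid wires folds, masking and aggregation together", {
  fx <- eval_fixture()
  res <- run_grid(fx$phen, fx$popn$ped, fx$popn$geno,
                  objectives = "cIMF",
                  phenotyping = c("ST", "PB-1"),
                  genotyping = c("None", "Stage-2"),
                  folds = fx$folds, vc_source = "fixed",
                  vc_fixed = grid_vc(fx))
  expect_equal(length(res$errors), 0L)
  # 2 phenotyping x 2 genotyping x 4 folds
  expect_equal(nrow(res$long), 16L)
  expect_true(all(res$long$accuracy >= -1 & res$long$accuracy <= 1,
                  na.rm = TRUE))
  expect_true(all(res$long$n > 1))
  # aggregation equals recomputation from the per-fold rows
  for (r in seq_len(nrow(res$aggregate))) {
    rows <- res$long$phenotyping == res$aggregate$phenotyping[r] &
      res$long$genotyping == res$aggregate$genotyping[r]
    expect_equal(res$aggregate$mean_accuracy[r],
                 mean(res$long$accuracy[rows], na.rm = TRUE))
    expect_equal(res$aggregate$sd_accuracy[r],
                 sd(res$long$accuracy[rows]))
  }
  # duplicated grid rows are computed once
  res2 <- run_grid(fx$phen, fx$popn$ped, fx$popn$geno, objectives = "cIMF",
                   phenotyping = c("ST", "ST"), genotyping = "None",
                   folds = fx$folds, vc_source = "fixed",
                   vc_fixed = grid_vc(fx))
  expect_equal(nrow(res2$long), 4L)
})

test_that("pedigree-only grids ignore the H machinery entirely", {
  fx <- eval_fixture()
  res_a <- run_grid(fx$phen, fx$popn$ped, geno = NULL, objectives = "cIMF",
                    phenotyping = "ST", genotyping = "None",
                    folds = fx$folds, vc_source = "fixed",
                    vc_fixed = grid_vc(fx))
  res_h <- run_grid(fx$phen, fx$popn$ped, fx$popn$geno, objectives = "cIMF",
                    phenotyping = "ST", genotyping = "None",
                    folds = fx$folds, vc_source = "fixed",
                    vc_fixed = grid_vc(fx))
  expect_equal(res_a$long$accuracy, res_h$long$accuracy, tolerance = 1e-12)
})

test_that("PB-1 predictors needs purebred traits present", {
  fx <- eval_fixture()
  res <- run_grid(fx$phen, fx$popn$ped, NULL, objectives = "cIMF",
                  phenotyping = "PB-2", genotyping = "None",
                  folds = fx$folds, vc_source = "fixed",
                  vc_fixed = grid_vc(fx))
  # pLBF etc. are absent from this fixture: the cell fails but is recorded
  expect_equal(nrow(res$long), 0L)
  expect_equal(length(res$errors), 1L)
})

test_that("stronger predictor-objective correlation does not hurt accuracy", {
  # matched populations and seeds; only the generating genetic correlation
  # between the purebred predictors and the crossbred objective changes.
  # The objective trait's data are bit-identical across rg settings (its
  # breeding values depend only on the first column of the Cholesky factor),
  # so differences isolate the predictor contribution.
  one <- function(rg, sd0) {
    d <- sim_design(n_sires = 16L, n_dams = 64L, n_cb = 320L, n_pb = 192L,
                    n_pb_dams = 24L, n_markers = 200L, pen_size = 12L,
                    pens_per_cg = 4L)
    popn <- simulate_population(d, seed = sd0)
    model <- default_trait_model(
      c("cIMF", "pLDG1", "pLDG2"),
      rg_overrides = data.frame(t1 = c("pLDG1", "pLDG2"),
                                t2 = c("cIMF", "cIMF"), rg = rg))
    sim <- simulate_traits(popn, model, seed = sd0 + 1L,
                           genetic_model = "pedigree")
    A <- build_A(popn$ped)
    sires <- popn$ped$records$id[popn$ped$records$population == "PB_SIRE"]
    folds <- kmeans_folds(sire_dissimilarity(A, sires), 4L, seed = 83L,
                          ped = popn$ped)
    res <- run_grid(sim$phenotypes, popn$ped, NULL, objectives = "cIMF",
                    phenotyping = c("ST", "PB-1"), genotyping = "None",
                    folds = folds, vc_source = "fixed",
                    vc_fixed = sim$truth$vc, A = A)
    with(res$aggregate, setNames(mean_accuracy, phenotyping))[c("ST", "PB-1")]
  }
  acc0 <- rowMeans(sapply(c(81L, 181L, 281L), function(s) one(0, s)))
  acc9 <- rowMeans(sapply(c(81L, 181L, 281L), function(s) one(0.9, s)))
  # at rg = 0 the decoupled multi-trait model reproduces single-trait
  expect_equal(unname(acc0["PB-1"]), unname(acc0["ST"]), tolerance = 1e-6)
  # raising rg from 0 to 0.9 does not decrease multi-trait accuracy
  expect_gte(acc9["PB-1"], acc0["PB-1"])
  # the objective's single-trait accuracy is untouched by the rg change
  expect_equal(unname(acc9["ST"]), unname(acc0["ST"]), tolerance = 1e-6)
})
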