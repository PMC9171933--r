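test_that("population structure of the three-way cross is correct", {
  d <- sim_design(n_sires = 1L, n_dams = 2L, n_cb = 2L, n_pb = 2L,
                  n_pb_dams = 1L, n_markers = 20L)
  popn <- simulate_population(d, seed = 1)
  rec <- popn$ped$records
  cb <- rec[rec$population == "CB", ]
  expect_equal(nrow(cb), 2L)
  # crossbred offspring have a Duroc sire and an F1 dam
  expect_true(all(grepl("^DS", cb$sire)))
  expect_true(all(grepl("^F1", cb$dam)))
  f1 <- rec[rec$population == "DAM", ]
  expect_equal(nrow(f1), 2L)
  # F1 dams have one Landrace and one Yorkshire parent
  expect_true(all((grepl("^LS", f1$sire) & grepl("^YD", f1$dam)) |
                    (grepl("^YS", f1$sire) & grepl("^LD", f1$dam))))
  pb <- rec[rec$population == "PB", ]
  expect_true(all(grepl("^DS", pb$sire)))
})

test_that("identical seeds give byte-identical simulations", {
  d <- sim_design(n_sires = 3L, n_dams = 9L, n_cb = 27L, n_pb = 9L,
                  n_pb_dams = 2L, n_markers = 50L)
  p1 <- simulate_population(d, seed = 5)
  p2 <- simulate_population(d, seed = 5)
  expect_identical(p1$geno$dosages, p2$geno$dosages)
  expect_identical(p1$animals, p2$animals)
  m <- default_trait_model(c("cIMF", "pLBF"))
  s1 <- simulate_traits(p1, m, seed = 6)
  s2 <- simulate_traits(p2, m, seed = 6)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("offspring allele frequencies obey Mendelian transmission", {
  d <- sim_design(n_sires = 10L, n_dams = 100L, n_cb = 1200L, n_pb = 10L,
                  n_pb_dams = 2L, n_markers = 150L)
  popn <- simulate_population(d, seed = 7)
  rec <- popn$ped$records
  cb <- rec$id[rec$population == "CB"]
  M <- popn$geno$dosages
  # parental mean frequency per marker (dosage mean over actual parents)
  par_f <- (colMeans(M[rec$sire[match(cb, rec$id)], , drop = FALSE]) +
              colMeans(M[rec$dam[match(cb, rec$id)], , drop = FALSE])) / 4
  obs_f <- colMeans(M[cb, , drop = FALSE]) / 2
  se <- sqrt(pmax(par_f * (1 - par_f), 1e-6) / (2 * length(cb)))
  z <- abs(obs_f - par_f) / se
  # ~binomial sampling of transmitted alleles: allow the usual exceedances
  expect_lt(mean(z > 3), 0.02)
})

test_that("founder lineage frequencies match the configured spectra", {
  d <- sim_design(n_sires = 30L, n_dams = 120L, n_cb = 240L, n_pb = 120L,
                  n_pb_dams = 30L, n_markers = 400L, fst = 0.15)
  popn <- simulate_population(d, seed = 8)
  rec <- popn$ped$records
  duroc <- c(rec$id[rec$population == "PB_SIRE"], grep("^DD", rec$id,
                                                       value = TRUE))
  M <- popn$geno$dosages
  f_obs <- colMeans(M[duroc, , drop = FALSE]) / 2
  f_true <- popn$founder_freqs["duroc", ]
  n2 <- 2 * length(duroc)
  # binomial goodness-of-fit per marker at the 1% level, ~1% exceedances
  pval <- vapply(seq_along(f_true), function(j)
    stats::binom.test(round(f_obs[j] * n2), n2, f_true[j])$p.value, 0)
  expect_lt(mean(pval < 0.01), 0.03)
})

test_that("breeding values reproduce the generating genetic parameters", {
  d <- sim_design(n_sires = 20L, n_dams = 200L, n_cb = 2000L, n_pb = 20L,
                  n_pb_dams = 4L, n_markers = 60L)
  popn <- simulate_population(d, seed = 9)
  m <- trait_model(c("tA", "tB"), c(tA = "CB", tB = "CB"), h2 = c(0.35, 0.3),
                   rg = matrix(c(1, 0.95, 0.95, 1), 2))
  sim <- simulate_traits(popn, m, seed = 10, genetic_model = "pedigree")
  bv <- sim$truth$bv
  # two traits simulated at rg = 0.95: sample correlation close
  r <- cor(bv[, 1], bv[, 2])
  expect_lt(abs(r - 0.95), 3 * (1 - 0.95^2) / sqrt(nrow(bv)) + 0.02)

  # parent-offspring regression of phenotype on mid-parent ~ h2 (here both
  # parents known) / on single parent ~ h2/2
  phen <- sim$phenotypes
  cb <- phen[phen$population == "CB", ]
  # regress offspring BV-free? use phenotype vs sire BV: slope ~ 0.5 var_a
  y <- cb$tA - ave(cb$tA, cb$cg)
  slope <- coef(lm(y ~ bv[cb$sire, 1]))[2]
  se3 <- 3 * sqrt(1 / (var(bv[cb$sire, 1]) * nrow(cb)))
  expect_lt(abs(slope - 0.5), se3 + 0.1)

  # null model: no genetic variance -> parent-offspring regression ~ 0
  m0 <- trait_model("tA", c(tA = "CB"), h2 = 1e-9)
  sim0 <- simulate_traits(popn, m0, seed = 11, genetic_model = "pedigree")
  cb0 <- sim0$phenotypes[sim0$phenotypes$population == "CB", ]
  spear <- cor(cb0$tA, sim0$truth$bv[cb0$sire, 1])
  expect_lt(abs(spear), 0.1)
})

test_that("marker-based breeding values carry marker-linked signal", {
  d <- sim_design(n_sires = 10L, n_dams = 50L, n_cb = 300L, n_pb = 50L,
                  n_pb_dams = 10L, n_markers = 300L)
  popn <- simulate_population(d, seed = 12)
  m <- trait_model("tA", c(tA = "CB"), h2 = 0.4)
  sim <- simulate_traits(popn, m, seed = 13, genetic_model = "markers")
  # BV equals centered dosages times marker effects by construction
  rec <- popn$ped$records
  M <- popn$geno$dosages[rec$id, ]
  Z <- sweep(M, 2, 2 * colMeans(M) / 2)
  pred <- Z %*% sim$truth$marker_effects
  expect_gt(cor(pred[, 1], sim$truth$bv[, 1]), 0.999)
  # realized additive variance near the target
  expect_lt(abs(var(sim$truth$bv[rec$population == "CB", 1]) /
                  m$additive[1, 1] - 1), 0.35)
})

test_that("trait catalogue covariances assemble into PSD matrices", {
  m <- default_trait_model()
  expect_equal(length(m$traits), 24L)
  ev <- eigen(m$additive, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # nearest-PSD adjustment applied and reported (the zero-filled 24-trait
  # matrix is structurally infeasible, so the adjustment is substantial)
  expect_true(is.numeric(m$psd_adjustment))
  expect_gt(m$psd_adjustment, 0)
  # feasible subsets keep the printed values exactly (no projection needed)
  m2 <- default_trait_model(c("pIMF", "cIMF"))
  expect_equal(m2$psd_adjustment, 0)
  expect_equal(unname(stats::cov2cor(m2$additive)["pIMF", "cIMF"]), 0.95,
               tolerance = 1e-8)
  m2b <- default_trait_model(c("pIMF", "pLBF"))
  expect_equal(unname(stats::cov2cor(m2b$additive)["pIMF", "pLBF"]), 0.83,
               tolerance = 1e-8)
})

test_that("phenotyping subset picks mean and +/-1, +/-2 SD individuals", {
  phen <- data.frame(id = c("a", "b", "c", "d", "e"),
                     growth = c(10, 12, 14, 16, 18))
  sel <- select_phenotyping_subset(phen, rep("g1", 5), "growth", k = 5)
  expect_setequal(sel, c("a", "b", "c", "d", "e"))

  # larger group: verify against the explicit greedy oracle
  set.seed(14)
  vals <- round(rnorm(12, 50, 8), 1)
  phen2 <- data.frame(id = sprintf("i%02d", 1:12), growth = vals)
  sel2 <- select_phenotyping_subset(phen2, rep("g", 12), "growth", k = 5)
  mu <- mean(vals); s <- sd(vals)
  targets <- mu + c(0, 1, 2, -1, -2) * s
  remaining <- order(phen2$id)
  oracle <- character(0)
  for (tg in targets) {
    j <- remaining[which.min(abs(vals[remaining] - tg))]
    oracle <- c(oracle, phen2$id[j])
    remaining <- setdiff(remaining, j)
  }
  expect_equal(sel2, oracle)

  # exhaustion rule: groups at or below k return everyone
  phen3 <- data.frame(id = c("x", "y", "z"), growth = c(1, 2, 3))
  expect_setequal(select_phenotyping_subset(phen3, rep("g", 3), "growth"),
                  c("x", "y", "z"))

  # ties: all values identical -> deterministic by lowest id
  phen4 <- data.frame(id = sprintf("t%02d", 7:1), growth = rep(5, 7))
  sel4 <- select_phenotyping_subset(phen4, rep("g", 7), "growth", k = 5)
  expect_equal(sort(sel4), sprintf("t%02d", 1:5))

  # group of one: selected with a warning
  expect_warning(
    s1 <- select_phenotyping_subset(data.frame(id = "solo", growth = 2),
                                    "g", "growth"), "size 1")
  expect_equal(s1, "solo")
})

test_that("subset design selects 4-5 per group under default structure", {
  d <- sim_design(n_sires = 6L, n_dams = 36L, n_cb = 360L, n_pb = 36L,
                  n_pb_dams = 6L, n_markers = 30L)
  popn <- simulate_population(d, seed = 15)
  m <- default_trait_model(c("cCDG", "cIMF"))
  sim <- simulate_traits(popn, m, seed = 16)
  grp <- cb_groups(popn$animals)
  w <- !is.na(grp)
  sel <- suppressWarnings(
    select_phenotyping_subset(sim$phenotypes[w, ], grp[w], "cCDG"))
  per_group <- table(grp[w][match(sel, sim$phenotypes$id[w])])
  big <- names(table(grp[w]))[table(grp[w]) >= 4]
  expect_true(all(per_group[big] >= 4 & per_group[big] <= 5))
  # applying the subset blanks expensive records of everyone else
  ph <- apply_phenotyping_subset(sim$phenotypes, sel, "cIMF")
  out <- ph$population == "CB" & !(ph$id %in% sel)
  expect_true(all(is.na(ph$cIMF[out])))
  expect_true(all(!is.na(ph$cIMF[ph$id %in% sel])))
})
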