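simple_phen <- function(y, id = sprintf("a%02d", seq_along(y))) {
  data.frame(id = id, population = "CB", litter = NA, pen = NA,
             cg = "g1", sex = "M", dam_line = "LY", tr = y)
}

test_that("intercept-only model with no random terms returns the mean", {
  set.seed(1)
  y <- rnorm(12, 5)
  phen <- simple_phen(y)
  ped <- pedigree(phen$id, rep(NA, 12), rep(NA, 12))
  A <- build_A(ped)
  spec <- model_spec("tr", c(tr = "CB"), random = list(tr = character(0)))
  vc <- variance_components(matrix(1), residual = matrix(1), traits = "tr")
  fit <- mme_fit(spec, phen, A, vc)
  expect_equal(unname(fit$fixed$tr["(Intercept)"]), mean(y))
})

test_that("EBV shrink to zero as the additive variance vanishes", {
  set.seed(2)
  ped <- random_pedigree(30L, seed = 3)
  ids <- ped$records$id
  phen <- simple_phen(rnorm(30, 2), id = ids)
  A <- build_A(ped)
  spec <- model_spec("tr", c(tr = "CB"), random = list(tr = "additive"))
  vc0 <- variance_components(matrix(1e-12), residual = matrix(1),
                             traits = "tr")
  fit <- mme_fit(spec, phen, A, vc0)
  expect_lt(max(abs(fit$ebv[, 1])), 1e-6)
})

test_that("MME solutions equal the dense GLS oracle on random instances", {
  for (rep in 1:6) {
    td <- toy_dataset(seed = 100 + rep, n_sires = 3L, n_dams = 8L,
                      n_cb = 24L, n_pb = 16L,
                      traits = c("cIMF", "pIMF"))
    spec <- model_spec(c("cIMF", "pIMF"), c(cIMF = "CB", pIMF = "PB"))
    vc <- td$sim$truth$vc
    fit <- mme_fit(spec, td$phen, td$A, vc)
    oracle <- gls_oracle(spec, td$phen, td$A, vc)
    expect_lt(max(abs(fit$ebv - oracle$ebv)), 1e-8)
  }
  # single-trait instances
  for (rep in 1:4) {
    td <- toy_dataset(seed = 200 + rep, n_sires = 3L, n_dams = 8L,
                      n_cb = 32L, n_pb = 8L, traits = "cIMF")
    spec <- model_spec("cIMF", c(cIMF = "CB"))
    vc <- td$sim$truth$vc
    fit <- mme_fit(spec, td$phen, td$A, vc)
    oracle <- gls_oracle(spec, td$phen, td$A, vc)
    expect_lt(max(abs(fit$ebv - oracle$ebv)), 1e-8)
  }
})

test_that("solutions are invariant to phenotype row order", {
  td <- toy_dataset(seed = 31, traits = "cIMF")
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  vc <- td$sim$truth$vc
  f1 <- mme_fit(spec, td$phen, td$A, vc)
  set.seed(4)
  f2 <- mme_fit(spec, td$phen[sample(nrow(td$phen)), ], td$A, vc)
  expect_equal(f2$ebv, f1$ebv, tolerance = 1e-10)
  expect_equal(f2$fixed$cIMF, f1$fixed$cIMF, tolerance = 1e-10)
})

test_that("two traits with zero covariances reproduce single-trait fits", {
  td <- toy_dataset(seed = 32, traits = c("cIMF", "pIMF"), rg = 0)
  spec2 <- model_spec(c("cIMF", "pIMF"), c(cIMF = "CB", pIMF = "PB"))
  vc2 <- td$sim$truth$vc
  # zero all cross-trait covariances
  for (term in c("additive", "litter", "pen", "residual")) {
    vc2[[term]][1, 2] <- vc2[[term]][2, 1] <- 0
  }
  fit2 <- mme_fit(spec2, td$phen, td$A, vc2)
  for (tr in c("cIMF", "pIMF")) {
    pop <- if (tr == "cIMF") "CB" else "PB"
    spec1 <- model_spec(tr, stats::setNames(pop, tr))
    vc1 <- variance_components(vc2$additive[tr, tr, drop = FALSE],
                               vc2$litter[tr, tr, drop = FALSE],
                               vc2$pen[tr, tr, drop = FALSE],
                               vc2$residual[tr, tr, drop = FALSE],
                               traits = tr)
    fit1 <- mme_fit(spec1, td$phen, td$A, vc1)
    expect_equal(unname(fit2$ebv[, tr]), unname(fit1$ebv[, tr]),
                 tolerance = 1e-8)
  }
})

test_that("K = A and K = H give identical fits when nobody is genotyped", {
  td <- toy_dataset(seed = 33, traits = "cIMF")
  H <- build_H(td$A, relmat(unclass(td$A)[1:2, 1:2], "G"), character(0))
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  vc <- td$sim$truth$vc
  fa <- mme_fit(spec, td$phen, td$A, vc)
  fh <- mme_fit(spec, td$phen, H, vc)
  expect_equal(fh$ebv, fa$ebv, tolerance = 1e-10)
})

test_that("chain bookkeeping yields the documented retained counts", {
  # (n_iter - burn_in) / thin retained samples
  expect_equal((100000 - 20000) / 20, 4000)
  expect_equal((600000 - 200000) / 20, 20000)
  td <- toy_dataset(seed = 34, n_sires = 3L, n_dams = 6L, n_cb = 18L,
                    n_pb = 6L, traits = "cIMF")
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  ch <- gibbs_vc(spec, td$phen, td$A, n_iter = 400L, burn_in = 100L,
                 thin = 3L, seed = 1L)
  expect_equal(ch$n_saved, (400L - 100L) %/% 3L)
  expect_equal(dim(ch$samples$additive)[3], ch$n_saved)
})

test_that("the sampler is deterministic given a seed", {
  td <- toy_dataset(seed = 35, n_sires = 3L, n_dams = 6L, n_cb = 18L,
                    n_pb = 6L, traits = "cIMF")
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  c1 <- gibbs_vc(spec, td$phen, td$A, n_iter = 300L, burn_in = 50L,
                 thin = 2L, seed = 7L)
  c2 <- gibbs_vc(spec, td$phen, td$A, n_iter = 300L, burn_in = 50L,
                 thin = 2L, seed = 7L)
  expect_identical(c1$samples, c2$samples)
})

test_that("null simulation keeps posterior heritability small", {
  # zero generating additive variance, decent data volume
  set.seed(40)
  n_s <- 50L; noff <- 1000L
  sires <- sprintf("S%02d", 1:n_s)
  off <- sprintf("O%04d", 1:noff)
  ped <- pedigree(c(sires, off), c(rep(NA, n_s), rep(sires, each = 20L)),
                  rep(NA, n_s + noff))
  A <- build_A(ped)
  phen <- simple_phen(rnorm(noff), id = off)
  spec <- model_spec("tr", c(tr = "CB"), random = list(tr = "additive"))
  ch <- gibbs_vc(spec, phen, A, n_iter = 6000L, burn_in = 2000L,
                 thin = 2L, seed = 8L)
  h2 <- summarize_chain(ch, "heritability")$heritability
  expect_lt(h2$estimate, 0.05)
})

test_that("chain summaries compute the documented functionals", {
  # degenerate chain: identical samples give exact arithmetic and zero-width
  # intervals
  ns <- 120L
  mk <- function(v) array(v, dim = c(1, 1, ns),
                          dimnames = list("t1", "t1", NULL))
  ch <- structure(list(samples = list(additive = mk(0.35), litter = mk(0.10),
                                      pen = mk(0.05), residual = mk(0.50)),
                       traits = "t1", n_iter = 100, burn_in = 0, thin = 1,
                       seed = 1, n_saved = ns, pd_resamples = 0),
                  class = "mcmc_chain")
  expect_warning(sm <- summarize_chain(ch, "heritability"), "degenerate")
  expect_equal(sm$heritability$estimate, 0.35)
  expect_equal(sm$heritability$hpd_low, sm$heritability$hpd_high)

  # perfectly correlated additive samples give genetic correlation 1
  set.seed(9)
  v <- runif(ns, 0.5, 2)
  arr <- array(0, dim = c(2, 2, ns), dimnames = list(c("a", "b"),
                                                     c("a", "b"), NULL))
  arr[1, 1, ] <- v; arr[2, 2, ] <- 4 * v
  arr[1, 2, ] <- arr[2, 1, ] <- 2 * v
  ch2 <- structure(list(samples = list(additive = arr,
                                       residual = array(1, dim = c(2, 2, ns))),
                        traits = c("a", "b"), n_iter = 100, burn_in = 0,
                        thin = 1, seed = 1, n_saved = ns, pd_resamples = 0),
                   class = "mcmc_chain")
  sm2 <- suppressWarnings(summarize_chain(ch2, "genetic_correlation"))
  expect_equal(sm2$genetic_correlation$estimate, 1)
})

test_that("HPD interval approaches normal quantiles on normal draws", {
  set.seed(1)
  h <- rowMeans(replicate(10, hpd_interval(rnorm(10000), 0.95)))
  expect_lt(abs(h[1] - (-1.96)), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
})

test_that("heritability is invariant to rescaling the phenotype", {
  td <- toy_dataset(seed = 36, n_sires = 4L, n_dams = 12L, n_cb = 60L,
                    n_pb = 12L, traits = "cIMF")
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  ch1 <- gibbs_vc(spec, td$phen, td$A, n_iter = 800L, burn_in = 200L,
                  thin = 2L, seed = 11L)
  ph2 <- td$phen
  ph2$cIMF <- ph2$cIMF * 10
  ch2 <- gibbs_vc(spec, ph2, td$A, n_iter = 800L, burn_in = 200L,
                  thin = 2L, seed = 11L)
  h1 <- summarize_chain(ch1, "heritability")$heritability$estimate
  h2 <- summarize_chain(ch2, "heritability")$heritability$estimate
  # same seed, scale-equivariant model: h2 paths agree closely
  expect_lt(abs(h1 - h2), 0.02)
})

test_that("table-style summary writes estimate (low, high) layout", {
  df <- data.frame(trait = "t1", estimate = 0.351, hpd_low = 0.14,
                   hpd_high = 0.58, ess = 100, split_rhat = 1.0)
  tf <- withr::local_tempfile()
  write_chain_summary(df, tf)
  txt <- readLines(tf)
  expect_match(txt[2], "0.35 \\(0.14, 0.58\\)")
})

test_that("posterior uncertainty shrinks as data volume grows", {
  widths <- sapply(c(400L, 1600L), function(noff) {
    n_s <- noff %/% 20L
    sires <- sprintf("S%03d", seq_len(n_s))
    off <- sprintf("O%04d", seq_len(noff))
    ped <- pedigree(c(sires, off), c(rep(NA, n_s), rep(sires, each = 20L)),
                    rep(NA, n_s + noff))
    A <- build_A(ped)
    set.seed(noff)
    a <- drop(t(chol(unclass(A))) %*% rnorm(nrow(A))) * sqrt(0.35)
    names(a) <- rownames(A)
    phen <- simple_phen(a[off] + rnorm(noff, 0, sqrt(0.65)), id = off)
    spec <- model_spec("tr", c(tr = "CB"), random = list(tr = "additive"))
    ch <- gibbs_vc(spec, phen, A, n_iter = 4000L, burn_in = 1000L,
                   thin = 3L, seed = noff + 1L)
    sm <- summarize_chain(ch, "heritability")$heritability
    sm$hpd_high - sm$hpd_low
  })
  expect_lt(widths[2], widths[1])
})

test_that("the optional trace file mirrors the retained samples", {
  td <- toy_dataset(seed = 37, n_sires = 3L, n_dams = 6L, n_cb = 18L,
                    n_pb = 6L, traits = "cIMF")
  spec <- model_spec("cIMF", c(cIMF = "CB"))
  tf <- withr::local_tempfile()
  ch <- gibbs_vc(spec, td$phen, td$A, n_iter = 300L, burn_in = 100L,
                 thin = 2L, seed = 5L, trace_file = tf)
  tr <- utils::read.delim(tf)
  expect_equal(nrow(tr), ch$n_saved)
  expect_equal(tr$additive_cIMF_cIMF, ch$samples$additive[1, 1, ])
})
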