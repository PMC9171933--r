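#' Multi-trait animal-model specification
#'
#' Describes, per trait, the fixed effects, covariates and random terms of
#' the animal model.  Crossbred-measured traits default to fixed dam line,
#' sex and contemporary group with random litter, pen and additive effects;
#' purebred-measured traits default to fixed contemporary group and parity
#' with age at recording as a (centered) covariate, and random litter and
#' additive effects.  Traits measured on different populations are never
#' jointly observed, so their residual covariance is constrained to zero
#' (block-diagonal residual over populations).
#'
#' @param traits character vector of trait (column) names.
#' @param population named character vector mapping each trait to the
#'   population it is measured on (`"CB"` or `"PB"`).
#' @param fixed named list of character vectors of fixed-factor column names
#'   per trait; defaults applied per population when missing.
#' @param covariates named list of numeric covariate column names per trait.
#' @param random named list of random terms per trait, subsets of
#'   `c("litter", "pen", "additive")`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(traits, population,
                       fixed = NULL, covariates = NULL, random = NULL) {
  traits <- as.character(traits)
  if (is.null(names(population))) names(population) <- traits
  population <- population[traits]
  if (anyNA(population)) stop("every trait needs a population tag")
  def_fixed <- list(CB = c("dam_line", "sex", "cg"),
                    PB = c("cg", "parity"))
  def_cov <- list(CB = character(0), PB = "age")
  def_ran <- list(CB = c("litter", "pen", "additive"),
                  PB = c("litter", "additive"))
  pick <- function(user, defs, tr) {
    if (!is.null(user) && tr %in% names(user)) user[[tr]]
    else defs[[population[[tr]]]]
  }
  spec <- list(traits = traits, population = population,
               fixed = lapply(stats::setNames(traits, traits), function(tr)
                 pick(fixed, def_fixed, tr)),
               covariates = lapply(stats::setNames(traits, traits), function(tr)
                 pick(covariates, def_cov, tr)),
               random = lapply(stats::setNames(traits, traits), function(tr)
                 pick(random, def_ran, tr)))
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %d trait(s)\n", length(x$traits)))
  for (tr in x$traits)
    cat(sprintf("  %s [%s]: fixed = %s; cov = %s; random = %s\n", tr,
                x$population[[tr]],
                paste(x$fixed[[tr]], collapse = "+"),
                if (length(x$covariates[[tr]]))
                  paste(x$covariates[[tr]], collapse = "+") else "-",
                paste(x$random[[tr]], collapse = "+")))
  invisible(x)
}

#' Variance-component container
#'
#' Trait-by-trait covariance matrices for each random term of the model.
#' Traits without a pen term carry zero rows/columns in the pen matrix.
#'
#' @param additive trait x trait additive genetic covariance matrix.
#' @param litter trait x trait litter covariance matrix.
#' @param pen trait x trait pen covariance matrix (zero rows/cols for traits
#'   without a pen term); may be `NULL` when no trait has a pen effect.
#' @param residual trait x trait residual covariance matrix (positive
#'   definite within each jointly-observed block).
#' @param traits trait names (taken from `additive` dimnames when omitted).
#' @return Object of class `var_comp`.
#' @export
variance_components <- function(additive, litter = NULL, pen = NULL,
                                residual, traits = NULL) {
  if (is.null(traits)) traits <- rownames(additive)
  if (is.null(traits)) traits <- paste0("t", seq_len(nrow(additive)))
  t <- length(traits)
  fix <- function(M, name) {
    if (is.null(M)) M <- matrix(0, t, t)
    M <- as.matrix(M)
    stopifnot(nrow(M) == t, ncol(M) == t)
    if (max(abs(M - t(M))) > 1e-8) stop(name, " matrix is not symmetric")
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop(name, " matrix is not positive semidefinite")
    dimnames(M) <- list(traits, traits)
    M
  }
  structure(list(additive = fix(additive, "additive"),
                 litter = fix(litter, "litter"),
                 pen = fix(pen, "pen"),
                 residual = fix(residual, "residual"),
                 traits = traits),
            class = "var_comp")
}

#' @export
print.var_comp <- function(x, ...) {
  cat(sprintf("variance components over %d trait(s): %s\n",
              length(x$traits), paste(x$traits, collapse = ", ")))
  cat("additive diag:", signif(diag(x$additive), 4), "\n")
  cat("residual diag:", signif(diag(x$residual), 4), "\n")
  invisible(x)
}

# --- internal design construction ------------------------------------------

# Per-trait design pieces over the rows of `phenotypes`:
#   X      dense fixed-effect matrix (zero rows outside the trait's population)
#   rows   row indices belonginging to the trait's population
# plus shared factor encodings for litter / pen / additive.
build_design <- function(spec, phenotypes, K) {
  n <- nrow(phenotypes)
  ids <- as.character(phenotypes$id)
  if (!all(ids %in% rownames(K)))
    stop("phenotyped animals missing from the relationship matrix: ",
         paste(utils::head(setdiff(ids, rownames(K))), collapse = ", "))
  pops <- sort(unique(spec$population))
  block_of <- match(spec$population, pops)            # per trait
  animal_block <- match(as.character(phenotypes$population), pops)

  Xs <- vector("list", length(spec$traits))
  names(Xs) <- spec$traits
  for (k in seq_along(spec$traits)) {
    tr <- spec$traits[k]
    rows <- which(animal_block == block_of[k])
    fx <- spec$fixed[[tr]]
    cv <- spec$covariates[[tr]]
    dat <- phenotypes[rows, , drop = FALSE]
    drop_fx <- character(0)
    for (f in fx) {
      if (!f %in% names(dat)) stop("fixed factor column missing: ", f)
      dat[[f]] <- factor(dat[[f]])
      if (nlevels(dat[[f]]) < 2L) drop_fx <- c(drop_fx, f)
    }
    fx <- setdiff(fx, drop_fx)  # single-level factors fold into the mean
    for (f in cv) {
      if (!f %in% names(dat)) stop("covariate column missing: ", f)
      dat[[f]] <- as.numeric(dat[[f]]) - mean(as.numeric(dat[[f]]))
    }
    form <- stats::as.formula(
      paste("~", paste(c("1", fx, cv), collapse = "+")))
    Xb <- stats::model.matrix(form, dat)
    X <- matrix(0, n, ncol(Xb), dimnames = list(NULL, colnames(Xb)))
    X[rows, ] <- Xb
    Xs[[k]] <- X
  }

  need_litter <- any(vapply(spec$random, function(r) "litter" %in% r, TRUE))
  need_pen    <- any(vapply(spec$random, function(r) "pen" %in% r, TRUE))
  litter_fac <- pen_fac <- NULL
  if (need_litter) {
    lv <- as.character(phenotypes$litter)
    litter_fac <- factor(lv, levels = sort(unique(stats::na.omit(lv))))
  }
  if (need_pen) {
    pv <- as.character(phenotypes$pen)
    pen_rows <- animal_block %in% block_of[vapply(
      spec$traits, function(tr) "pen" %in% spec$random[[tr]], TRUE)]
    pv[!pen_rows] <- NA
    pen_fac <- factor(pv, levels = sort(unique(stats::na.omit(pv))))
  }
  arow <- match(ids, rownames(K))

  list(n = n, Xs = Xs, block_of = block_of, animal_block = animal_block,
       blocks = pops, litter = litter_fac, pen = pen_fac, arow = arow,
       ids = ids)
}

# residual inverse per observation pattern; returns n x t x t weights as a
# list of t*t vectors indexed [s][t]
pattern_rinv <- function(Y, des, R) {
  n <- nrow(Y); t <- ncol(Y)
  pops <- des$blocks
  obs <- is.finite(as.matrix(Y))
  key <- apply(obs, 1L, function(o) paste(as.integer(o), collapse = ""))
  key <- paste(des$animal_block, key)
  D <- array(0, dim = c(n, t, t))
  for (kk in unique(key)) {
    rows <- which(key == kk)
    o <- which(obs[rows[1L], ])
    o <- o[des$block_of[o] == des$animal_block[rows[1L]]]
    if (!length(o)) next
    Rinv <- matrix(0, t, t)
    Rinv[o, o] <- solve(R[o, o, drop = FALSE])
    for (s in o) for (u in o) D[rows, s, u] <- Rinv[s, u]
  }
  D
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side of the (multi-trait)
#' mixed-model equations for the model of [model_spec], with record-level
#' missingness handled through pattern-specific residual inverse blocks (no
#' records are imputed).  The additive term uses `K^{-1}` combined with the
#' inverse of the additive trait covariance; litter and pen use identity
#' level structure with their trait covariances.
#'
#' @param spec a [model_spec].
#' @param phenotypes data.frame with columns `id`, `population`, the factor
#'   and covariate columns named in `spec`, and one column per trait
#'   (`NA` = missing record).
#' @param K relationship matrix (`relmat`, A or H) covering all phenotyped
#'   animals.
#' @param vc a [variance_components] over the spec's traits.
#' @return An `mme_system`: list with `C` (coefficient matrix), `rhs`,
#'   and a `layout` describing the equation blocks.
#' @export
build_mme <- function(spec, phenotypes, K, vc) {
  traits <- spec$traits
  t <- length(traits)
  stopifnot(identical(vc$traits, traits))
  des <- build_design(spec, phenotypes, K)
  n <- des$n
  q <- nrow(K)
  Y <- as.matrix(phenotypes[, traits, drop = FALSE])
  mode(Y) <- "numeric"
  # a record only counts for a trait measured on the animal's population
  for (k in seq_len(t))
    Y[which(is.na(des$animal_block) |
              des$animal_block != des$block_of[k]), k] <- NA
  D <- pattern_rinv(Y, des, vc$residual)

  # column layout per trait
  has_pen <- vapply(traits, function(tr) "pen" %in% spec$random[[tr]], TRUE)
  has_lit <- vapply(traits, function(tr) "litter" %in% spec$random[[tr]], TRUE)
  has_add <- vapply(traits, function(tr) "additive" %in% spec$random[[tr]],
                    TRUE)
  nlit <- if (!is.null(des$litter)) nlevels(des$litter) else 0L
  npen <- if (!is.null(des$pen)) nlevels(des$pen) else 0L
  p_t <- integer(t); layout <- vector("list", t)
  for (k in seq_len(t)) {
    f <- ncol(des$Xs[[k]])
    pieces <- c(fixed = f,
                litter = if (has_lit[k]) nlit else 0L,
                pen = if (has_pen[k]) npen else 0L,
                additive = if (has_add[k]) q else 0L)
    off <- cumsum(c(0L, pieces))[seq_along(pieces)]
    names(off) <- names(pieces)
    layout[[k]] <- list(sizes = pieces, offsets = off,
                        fixed_names = colnames(des$Xs[[k]]))
    p_t[k] <- sum(pieces)
  }
  toff <- cumsum(c(0L, p_t))[seq_len(t)]
  P <- sum(p_t)
  C <- matrix(0, P, P)
  rhs <- numeric(P)

  lit_idx <- if (nlit) as.integer(des$litter) else rep(NA_integer_, n)
  pen_idx <- if (npen) as.integer(des$pen) else rep(NA_integer_, n)
  fac_idx <- list(litter = lit_idx, pen = pen_idx, additive = des$arow)
  fac_n <- c(litter = nlit, pen = npen, additive = q)

  add_dd <- function(rs, cs, M) {
    C[rs, cs] <<- C[rs, cs] + M
    if (!identical(rs, cs)) C[cs, rs] <<- C[cs, rs] + t(M)
  }
  # scatter-accumulate for factor-factor cross products
  cross_ff <- function(ia, ib, na, nb, w) {
    ok <- !is.na(ia) & !is.na(ib) & w != 0
    if (!any(ok)) return(matrix(0, na, nb))
    M <- matrix(0, na, nb)
    idx <- (ib[ok] - 1L) * na + ia[ok]
    agg <- rowsum(w[ok], idx)
    M[as.integer(rownames(agg))] <- agg
    M
  }
  cross_df <- function(X, ib, nb, w) {
    ok <- !is.na(ib) & w != 0
    M <- matrix(0, ncol(X), nb)
    if (!any(ok)) return(M)
    agg <- rowsum(X[ok, , drop = FALSE] * w[ok], ib[ok])
    M[, as.integer(rownames(agg))] <- t(agg)
    M
  }

  term_names <- function(k) names(layout[[k]]$sizes)[layout[[k]]$sizes > 0L]
  for (s in seq_len(t)) for (u in s:t) {
    w <- D[, s, u]
    if (all(w == 0)) next
    for (ta in term_names(s)) for (tb in term_names(u)) {
      if (s == u && match(ta, term_names(s)) > match(tb, term_names(u))) next
      ra <- toff[s] + layout[[s]]$offsets[ta] + seq_len(layout[[s]]$sizes[ta])
      cb <- toff[u] + layout[[u]]$offsets[tb] + seq_len(layout[[u]]$sizes[tb])
      if (ta == "fixed" && tb == "fixed") {
        M <- crossprod(des$Xs[[s]] * w, des$Xs[[u]])
      } else if (ta == "fixed") {
        M <- cross_df(des$Xs[[s]], fac_idx[[tb]], fac_n[tb], w)
      } else if (tb == "fixed") {
        M <- t(cross_df(des$Xs[[u]], fac_idx[[ta]], fac_n[ta], w))
      } else {
        M <- cross_ff(fac_idx[[ta]], fac_idx[[tb]], fac_n[ta], fac_n[tb], w)
      }
      add_dd(ra, cb, M)
    }
  }
  # right-hand side
  Y0 <- Y; Y0[!is.finite(Y0)] <- 0
  for (s in seq_len(t)) {
    yt <- numeric(n)
    for (u in seq_len(t)) yt <- yt + D[, s, u] * Y0[, u]
    for (ta in term_names(s)) {
      rg <- toff[s] + layout[[s]]$offsets[ta] + seq_len(layout[[s]]$sizes[ta])
      if (ta == "fixed") {
        rhs[rg] <- rhs[rg] + drop(crossprod(des$Xs[[s]], yt))
      } else {
        idx <- fac_idx[[ta]]
        ok <- !is.na(idx) & yt != 0
        if (any(ok)) {
          agg <- rowsum(yt[ok], idx[ok])
          rhs[rg][as.integer(rownames(agg))] <-
            rhs[rg][as.integer(rownames(agg))] + agg
        }
      }
    }
  }

  # prior precisions
  Kinv <- if (any(has_add)) solve(unclass(K)) else NULL
  add_prior <- function(term, Ginv_term, unit) {
    for (s in seq_len(t)) for (u in seq_len(t)) {
      if (!(term %in% term_names(s)) || !(term %in% term_names(u))) next
      g <- Ginv_term[s, u]
      if (g == 0) next
      rg <- toff[s] + layout[[s]]$offsets[term] +
        seq_len(layout[[s]]$sizes[term])
      cg <- toff[u] + layout[[u]]$offsets[term] +
        seq_len(layout[[u]]$sizes[term])
      if (is.null(unit)) {
        C[cbind(rg, cg)] <<- C[cbind(rg, cg)] + g
      } else {
        C[rg, cg] <<- C[rg, cg] + g * unit
      }
    }
  }
  sub_inv <- function(M, active) {
    out <- matrix(0, t, t)
    if (any(active)) out[active, active] <-
        solve(M[active, active, drop = FALSE])
    out
  }
  if (any(has_lit) && nlit)
    add_prior("litter", sub_inv(vc$litter, has_lit), NULL)
  if (any(has_pen) && npen)
    add_prior("pen", sub_inv(vc$pen, has_pen), NULL)
  if (any(has_add))
    add_prior("additive", sub_inv(vc$additive, has_add), Kinv)

  # zero-pivot repair: fixed-effect levels untouched by any record (e.g. a
  # contemporary group fully masked in cross-validation) get an identity
  # equation and a zero solution, the customary normal-equation convention
  zero <- which(diag(C) <= 1e-12 * max(diag(C)))
  if (length(zero)) {
    C[zero, ] <- 0; C[, zero] <- 0
    C[cbind(zero, zero)] <- 1
    rhs[zero] <- 0
  }

  structure(list(C = C, rhs = rhs, layout = layout, toff = toff,
                 traits = traits, ids = rownames(K),
                 design = des, Y = Y),
            class = "mme_system")
}

#' Solve assembled mixed-model equations
#'
#' Dense symmetric solve via Cholesky; a singular coefficient matrix (e.g.
#' confounded fixed-effect levels) raises an informative error.
#'
#' @param system an `mme_system` from [build_mme].
#' @return An `mme_solution`: list with per-trait `fixed` (named vectors),
#'   `litter`, `pen` (level x trait matrices) and `ebv` (animal x trait
#'   matrix over the ids of `K`).
#' @export
solve_mme <- function(system) {
  force(system)
  sol <- tryCatch(
    drop(chol2inv_solve(system$C, system$rhs)),
    error = function(e)
      stop("mixed-model equations are singular; a fixed effect is likely ",
           "confounded with another effect - consider dropping a level (",
           conditionMessage(e), ")", call. = FALSE))
  if (any(!is.finite(sol))) stop("non-finite solutions from the MME solve")
  t <- length(system$traits)
  out <- list(fixed = list(), litter = NULL, pen = NULL, ebv = NULL,
              traits = system$traits)
  q <- length(system$ids)
  ebv <- matrix(NA_real_, q, t, dimnames = list(system$ids, system$traits))
  lit <- pen <- NULL
  for (k in seq_len(t)) {
    lay <- system$layout[[k]]
    base <- system$toff[k]
    fx <- sol[base + lay$offsets["fixed"] + seq_len(lay$sizes["fixed"])]
    names(fx) <- lay$fixed_names
    out$fixed[[system$traits[k]]] <- fx
    if (lay$sizes["litter"] > 0L) {
      v <- sol[base + lay$offsets["litter"] + seq_len(lay$sizes["litter"])]
      if (is.null(lit)) lit <- matrix(NA_real_, length(v), t,
                                      dimnames = list(NULL, system$traits))
      lit[, k] <- v
    }
    if (lay$sizes["pen"] > 0L) {
      v <- sol[base + lay$offsets["pen"] + seq_len(lay$sizes["pen"])]
      if (is.null(pen)) pen <- matrix(NA_real_, length(v), t,
                                      dimnames = list(NULL, system$traits))
      pen[, k] <- v
    }
    if (lay$sizes["additive"] > 0L)
      ebv[, k] <- sol[base + lay$offsets["additive"] + seq_len(q)]
  }
  out$litter <- lit; out$pen <- pen; out$ebv <- ebv
  class(out) <- "mme_solution"
  out
}

# Dense symmetric solve.  A rank-deficient system (e.g. a fixed-effect
# level left with collinear support after cross-validation masking) falls
# back to the customary generalized-inverse convention: pivoted Cholesky
# with the dependent equations zeroed, reported via a warning.
chol2inv_solve <- function(C, b) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(R)) return(backsolve(R, backsolve(R, b, transpose = TRUE)))
  Rp <- suppressWarnings(chol(C, pivot = TRUE))
  r <- attr(Rp, "rank")
  piv <- attr(Rp, "pivot")
  n <- length(b)
  if (r < 1L || r < n - max(20L, 0.05 * n))
    stop("coefficient matrix is rank ", r, " of ", n,
         "; the model is substantially confounded - drop a fixed effect")
  warning(sprintf(paste0("%d dependent equation(s) zeroed in the ",
                         "mixed-model solve (first indices: %s)"),
                  n - r,
                  paste(utils::head(sort(piv[(r + 1L):n]), 5L),
                        collapse = ", ")))
  lead <- piv[seq_len(r)]
  R11 <- Rp[seq_len(r), seq_len(r), drop = FALSE]
  x <- numeric(n)
  x[lead] <- backsolve(R11, backsolve(R11, b[lead], transpose = TRUE))
  x
}

#' Fit an animal model by BLUP (assemble + solve)
#'
#' @inheritParams build_mme
#' @return An `mme_solution` (see [solve_mme]).
#' @export
mme_fit <- function(spec, phenotypes, K, vc) {
  solve_mme(build_mme(spec, phenotypes, K, vc))
}

# Default priors are flat on each covariance matrix (p(Sigma) ~ 1), the
# convention of the reference Gibbs programs for animal models: the full
# conditional is then IW(m - d - 1, U'U).  An inverse-Wishart prior with
# small degrees of freedom may look vague but places a large density spike
# at zero variance, which collapses weakly identified components (e.g.
# litter variance vs. dam breeding values when each dam has one litter).
default_prior <- function(d) list(S0 = diag(0, d), nu0 = -(d + 1))

#' Gibbs sampling of (co)variance components
#'
#' Runs the compiled Gibbs sampler for the animal model defined by `spec`:
#' location effects from their (multivariate) normal full conditionals,
#' covariance matrices from inverted-Wishart full conditionals (scaled
#' inverted chi-square in the single-trait case), with flat default priors
#' on every covariance matrix and on the fixed effects (an apparently
#' vague inverse-Wishart prior with low degrees of freedom concentrates
#' mass at zero variance and can collapse weakly identified components, so
#' it is not the default).  The residual covariance is
#' block-diagonal over populations: traits measured on different
#' populations are never jointly observed, so their residual covariance is
#' fixed at zero.  Missing records within a population block are handled by
#' augmenting their residuals.  Deterministic given `seed`.
#'
#' @inheritParams build_mme
#' @param n_iter total chain length.
#' @param burn_in iterations discarded before saving.
#' @param thin save every `thin`-th post-burn-in sample; the retained count
#'   is `(n_iter - burn_in) / thin`.
#' @param seed integer seed for R's RNG.
#' @param start optional [variance_components] used as starting values;
#'   defaults to an even split of the phenotypic variance.
#' @param priors optional list with elements `nu0` and `scale` overriding
#'   the default inverse-Wishart prior (scale multiplies the identity).
#' @param trace_file optional path; when given, the retained samples of
#'   every (co)variance element are streamed to a tab-delimited trace file
#'   (one row per retained sample).
#' @return An `mcmc_chain`: list with `samples` (named list of
#'   trait x trait x n_saved arrays for `additive`, `litter`, `pen`,
#'   `residual`), posterior-mean EBV (`ebv_mean`), chain settings, `seed`
#'   and the count of jitter resamples needed to keep covariance draws
#'   positive definite.
#' @export
gibbs_vc <- function(spec, phenotypes, K, n_iter = 100000L,
                     burn_in = 20000L, thin = 20L, seed = 1L,
                     start = NULL, priors = NULL, trace_file = NULL) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter, thin >= 1)
  traits <- spec$traits
  t <- length(traits)
  des <- build_design(spec, phenotypes, K)
  Y <- as.matrix(phenotypes[, traits, drop = FALSE])
  mode(Y) <- "numeric"
  for (k in seq_len(t))
    Y[which(is.na(des$animal_block) |
              des$animal_block != des$block_of[k]), k] <- NA

  # keep rows contributing at least one record
  keep <- rowSums(is.finite(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  Xs <- lapply(des$Xs, function(X) X[keep, , drop = FALSE])
  animal_block <- des$animal_block[keep]
  arow <- des$arow[keep]
  lit <- if (!is.null(des$litter)) as.integer(des$litter)[keep] else NULL
  pen <- if (!is.null(des$pen)) as.integer(des$pen)[keep] else NULL

  vy <- apply(Y, 2L, stats::var, na.rm = TRUE)
  vy[!is.finite(vy) | vy <= 0] <- 1
  has_pen <- which(vapply(traits, function(tr) "pen" %in% spec$random[[tr]],
                          TRUE))
  has_lit <- which(vapply(traits, function(tr) "litter" %in% spec$random[[tr]],
                          TRUE))
  if (is.null(start)) {
    start <- list(additive = diag(0.3 * vy, t),
                  litter = diag(0.1 * vy, t),
                  pen = diag(0.1 * vy, t),
                  residual = diag(0.5 * vy, t))
  } else {
    start <- list(additive = start$additive, litter = start$litter,
                  pen = start$pen, residual = start$residual)
  }
  pscale <- if (!is.null(priors$scale)) priors$scale else 0

  flat_nu0 <- function(d, m) max(-(d + 1), (d + 1) - m)
  ran_terms <- list()
  if (length(has_lit) && !is.null(lit)) {
    d <- length(has_lit)
    nu0 <- if (!is.null(priors$nu0)) priors$nu0
    else flat_nu0(d, max(lit, na.rm = TRUE))
    ran_terms <- c(ran_terms, list(list(
      factor = as.integer(ifelse(is.na(lit), -1L, lit - 1L)),
      nlev = max(lit, na.rm = TRUE),
      traits = as.integer(has_lit - 1L),
      S0 = diag(pscale, d), nu0 = nu0,
      start = as.matrix(start$litter[has_lit, has_lit, drop = FALSE]),
      name = "litter")))
  }
  if (length(has_pen) && !is.null(pen) && any(!is.na(pen))) {
    d <- length(has_pen)
    nu0 <- if (!is.null(priors$nu0)) priors$nu0
    else flat_nu0(d, max(pen, na.rm = TRUE))
    ran_terms <- c(ran_terms, list(list(
      factor = as.integer(ifelse(is.na(pen), -1L, pen - 1L)),
      nlev = max(pen, na.rm = TRUE),
      traits = as.integer(has_pen - 1L),
      S0 = diag(pscale, d), nu0 = nu0,
      start = as.matrix(start$pen[has_pen, has_pen, drop = FALSE]),
      name = "pen")))
  }

  blocks <- sort(unique(animal_block))
  R_blocks <- lapply(blocks, function(b) {
    tb <- which(des$block_of == b)
    d <- length(tb)
    nu0 <- if (!is.null(priors$nu0)) priors$nu0
    else flat_nu0(d, sum(animal_block == b))
    list(traits = as.integer(tb - 1L),
         S0 = diag(pscale, d), nu0 = nu0,
         start = as.matrix(start$residual[tb, tb, drop = FALSE]))
  })
  # re-code blocks densely (some may have no data rows after filtering)
  bmap <- match(des$block_of, blocks)
  if (anyNA(bmap))
    stop("trait(s) with no phenotype records: ",
         paste(traits[is.na(bmap)], collapse = ", "))
  block_of_c <- as.integer(bmap - 1L)
  animal_block_c <- as.integer(match(animal_block, blocks) - 1L)

  Ainv <- solve(unclass(K))
  nu0a <- if (!is.null(priors$nu0)) priors$nu0 else flat_nu0(t, nrow(Ainv))

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  res <- gibbs_sampler_cpp(Y, Xs, block_of_c, animal_block_c, ran_terms,
                           Ainv, as.integer(arow - 1L),
                           diag(pscale, t), nu0a,
                           as.matrix(start$additive),
                           R_blocks, as.integer(n_iter),
                           as.integer(burn_in), as.integer(thin))
  samples <- list(additive = res$additive, residual = res$residual)
  term_names <- vapply(ran_terms, function(x) x$name, "")
  for (i in seq_along(term_names)) samples[[term_names[i]]] <- res$terms[[i]]
  for (nm in names(samples)) dimnames(samples[[nm]]) <- list(traits, traits, NULL)
  ebv_mean <- res$ebv_mean
  dimnames(ebv_mean) <- list(rownames(K), traits)
  if (!is.null(trace_file)) {
    cols <- list()
    for (nm in names(samples)) {
      for (i in seq_len(t)) for (j in i:t) {
        cols[[sprintf("%s_%s_%s", nm, traits[i], traits[j])]] <-
          samples[[nm]][i, j, ]
      }
    }
    utils::write.table(as.data.frame(cols), trace_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  structure(list(samples = samples, traits = traits, ebv_mean = ebv_mean,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, n_saved = res$n_saved,
                 pd_resamples = res$pd_resamples),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf(paste0("mcmc_chain: %d iterations (burn-in %d, thin %d) -> ",
                     "%d retained samples; traits: %s\n"),
              x$n_iter, x$burn_in, x$thin, x$n_saved,
              paste(x$traits, collapse = ", ")))
  if (x$pd_resamples > 0)
    cat(sprintf("  %d jitter resamples were needed for positive definiteness\n",
                x$pd_resamples))
  invisible(x)
}

#' Shortest (highest posterior density) interval
#'
#' @param x numeric sample vector.
#' @param prob probability mass of the interval (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Effective sample size by initial-positive-sequence autocorrelation
#' @param x numeric sample vector.
#' @return Estimated effective number of independent samples.
#' @export
effective_size <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE)$acf[-1L]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' Split-chain potential scale reduction factor
#' @param x numeric sample vector (one chain, split in two halves).
#' @return The split-Rhat statistic (values near 1 indicate mixing).
#' @export
split_rhat <- function(x) {
  x <- x[is.finite(x)]
  n2 <- floor(length(x) / 2)
  if (n2 < 5L) return(NA_real_)
  halves <- list(x[1:n2], x[(n2 + 1):(2 * n2)])
  m <- vapply(halves, mean, 0)
  v <- vapply(halves, stats::var, 0)
  W <- mean(v)
  B <- n2 * stats::var(m)
  if (W == 0) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Posterior summaries of a variance-component chain
#'
#' Evaluates functionals per retained sample and reports the posterior mean
#' and 95% highest-posterior-density interval.  Heritability for trait `i`
#' is `sigma2_a / (sigma2_a + sigma2_l + sigma2_p + sigma2_e)` (all
#' non-residual random terms count toward the phenotypic variance); genetic
#' correlations are additive covariances scaled by the additive standard
#' deviations.
#'
#' @param chain an `mcmc_chain` from [gibbs_vc].
#' @param functionals subset of `c("heritability", "genetic_correlation",
#'   "raw")`.
#' @param prob HPD mass (default 0.95).
#' @return List with one data.frame per requested functional
#'   (`estimate`, `hpd_low`, `hpd_high`, plus diagnostics `ess` and
#'   `split_rhat`); `raw` returns posterior-mean matrices.
#' @export
summarize_chain <- function(chain,
                            functionals = c("heritability",
                                            "genetic_correlation"),
                            prob = 0.95) {
  stopifnot(chain$n_saved >= 100L)
  functionals <- match.arg(functionals,
                           c("heritability", "genetic_correlation", "raw"),
                           several.ok = TRUE)
  t <- length(chain$traits)
  ns <- chain$n_saved
  S <- chain$samples
  zero <- array(0, dim = c(t, t, ns))
  litter <- if (!is.null(S$litter)) S$litter else zero
  pen <- if (!is.null(S$pen)) S$pen else zero
  out <- list()
  summarize_vec <- function(v) {
    if (length(unique(v)) == 1L)
      warning("degenerate samples: zero-width HPD interval")
    h <- hpd_interval(v, prob)
    c(estimate = mean(v), hpd_low = h[1L], hpd_high = h[2L],
      ess = effective_size(v), split_rhat = split_rhat(v))
  }
  if ("heritability" %in% functionals) {
    rows <- lapply(seq_len(t), function(i) {
      h2 <- S$additive[i, i, ] /
        (S$additive[i, i, ] + litter[i, i, ] + pen[i, i, ] +
           S$residual[i, i, ])
      summarize_vec(h2)
    })
    out$heritability <- data.frame(trait = chain$traits,
                                   do.call(rbind, rows))
  }
  if ("genetic_correlation" %in% functionals && t >= 2L) {
    pairs <- utils::combn(t, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      rg <- S$additive[i1, i2, ] /
        sqrt(S$additive[i1, i1, ] * S$additive[i2, i2, ])
      summarize_vec(rg)
    })
    out$genetic_correlation <- data.frame(
      trait1 = chain$traits[pairs[1L, ]],
      trait2 = chain$traits[pairs[2L, ]],
      do.call(rbind, rows))
  }
  if ("raw" %in% functionals) {
    out$raw <- lapply(S, function(arr) apply(arr, c(1L, 2L), mean))
  }
  out
}

#' Write a Table-style summary of posterior estimates
#'
#' Formats `estimate (hpd_low, hpd_high)` per row, mirroring the customary
#' presentation of heritability and correlation tables.
#'
#' @param summary a data.frame from [summarize_chain].
#' @param path output path (tab-delimited).
#' @export
write_chain_summary <- function(summary, path) {
  lab_cols <- setdiff(names(summary),
                      c("estimate", "hpd_low", "hpd_high", "ess",
                        "split_rhat"))
  txt <- data.frame(summary[, lab_cols, drop = FALSE],
                    estimate = sprintf("%.2f (%.2f, %.2f)",
                                       summary$estimate, summary$hpd_low,
                                       summary$hpd_high))
  utils::write.table(txt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
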