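# Independent oracles used across the suite.  Deliberately naive and
# separate from the package's own code paths.

# Random valid pedigree: `n_founders` unrelated animals, then `n` more each
# with parents drawn from earlier animals (or unknown).
random_pedigree <- function(n = 50L, n_founders = 10L, seed = 1L,
                            p_unknown = 0.15) {
  set.seed(seed)
  id <- as.character(seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    prev <- seq_len(i - 1L)
    if (stats::runif(1) > p_unknown) sire[i] <- as.character(sample(prev, 1L))
    if (stats::runif(1) > p_unknown) dam[i] <- as.character(sample(prev, 1L))
  }
  pedigree(id, sire, dam)
}

# Gene-dropping kinship oracle: drops one neutral locus `ndrops` times and
# estimates 2 * kinship for every pair, with Monte-Carlo standard errors.
gene_drop_A <- function(ped, ndrops = 1e5, seed = 1L) {
  set.seed(seed)
  rec <- ped$records
  n <- nrow(rec)
  pos <- seq_len(n); names(pos) <- rec$id
  h1 <- matrix(0L, n, ndrops)
  h2 <- matrix(0L, n, ndrops)
  lab <- 0L
  for (i in seq_len(n)) {
    s <- rec$sire[i]; d <- rec$dam[i]
    if (is.na(s)) {
      h1[i, ] <- (lab <- lab + 1L)
    } else {
      pick <- stats::runif(ndrops) < 0.5
      h1[i, ] <- ifelse(pick, h1[pos[s], ], h2[pos[s], ])
    }
    if (is.na(d)) {
      h2[i, ] <- (lab <- lab + 1L)
    } else {
      pick <- stats::runif(ndrops) < 0.5
      h2[i, ] <- ifelse(pick, h1[pos[d], ], h2[pos[d], ])
    }
  }
  A2 <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  SE <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  for (i in seq_len(n)) for (j in i:n) {
    m <- ((h1[i, ] == h1[j, ]) + (h1[i, ] == h2[j, ]) +
            (h2[i, ] == h1[j, ]) + (h2[i, ] == h2[j, ])) / 2
    A2[i, j] <- A2[j, i] <- mean(m)
    SE[i, j] <- SE[j, i] <- stats::sd(m) / sqrt(ndrops)
  }
  list(A = A2, se = SE)
}

# Dense multi-trait GLS oracle: builds the full phenotypic covariance of
# the stacked observed records and computes fixed effects and BLUP of the
# additive effects directly.
gls_oracle <- function(spec, phen, K, vc) {
  traits <- spec$traits
  ids_all <- rownames(K)
  recs <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    rows <- which(!is.na(phen[[tr]]) &
                    phen$population == spec$population[[tr]])
    if (length(rows))
      recs[[tr]] <- data.frame(row = rows, trait = k,
                               id = as.character(phen$id[rows]),
                               y = phen[[tr]][rows])
  }
  recs <- do.call(rbind, recs)
  N <- nrow(recs)
  V <- matrix(0, N, N)
  covadd <- matrix(0, length(ids_all) * length(traits), N)
  for (a_ in seq_len(N)) for (b_ in seq_len(N)) {
    s <- recs$trait[a_]; u <- recs$trait[b_]
    ia <- recs$id[a_]; ib <- recs$id[b_]
    ra <- recs$row[a_]; rb <- recs$row[b_]
    v <- 0
    if ("additive" %in% spec$random[[traits[s]]] &&
        "additive" %in% spec$random[[traits[u]]])
      v <- v + vc$additive[s, u] * K[ia, ib]
    if ("litter" %in% spec$random[[traits[s]]] &&
        "litter" %in% spec$random[[traits[u]]] &&
        !is.na(phen$litter[ra]) && !is.na(phen$litter[rb]) &&
        phen$litter[ra] == phen$litter[rb])
      v <- v + vc$litter[s, u]
    if ("pen" %in% spec$random[[traits[s]]] &&
        "pen" %in% spec$random[[traits[u]]] &&
        !is.na(phen$pen[ra]) && !is.na(phen$pen[rb]) &&
        phen$pen[ra] == phen$pen[rb])
      v <- v + vc$pen[s, u]
    if (ia == ib) v <- v + vc$residual[s, u]
    V[a_, b_] <- v
  }
  # X block-diagonal over traits, mirroring the package's design rules
  Xl <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    rows <- recs$row[recs$trait == k]
    dat <- phen[rows, , drop = FALSE]
    fx <- spec$fixed[[tr]]
    for (f in fx) dat[[f]] <- factor(dat[[f]])
    fx <- fx[vapply(fx, function(f) nlevels(dat[[f]]) > 1L, TRUE)]
    cv <- spec$covariates[[tr]]
    for (f in cv) dat[[f]] <- as.numeric(dat[[f]]) - mean(as.numeric(dat[[f]]))
    form <- stats::as.formula(paste("~", paste(c("1", fx, cv),
                                               collapse = "+")))
    Xl[[k]] <- stats::model.matrix(form, dat)
  }
  X <- matrix(0, N, sum(vapply(Xl, ncol, 1L)))
  off <- 0L
  for (k in seq_along(traits)) {
    X[recs$trait == k, off + seq_len(ncol(Xl[[k]]))] <- Xl[[k]]
    off <- off + ncol(Xl[[k]])
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% recs$y)
  resid <- recs$y - X %*% beta
  # cov(a_{i, trait u}, y_record) for every animal x trait
  ebv <- matrix(0, length(ids_all), length(traits),
                dimnames = list(ids_all, traits))
  for (u in seq_along(traits)) {
    if (!("additive" %in% spec$random[[traits[u]]])) { ebv[, u] <- NA; next }
    Cay <- matrix(0, length(ids_all), N)
    for (b_ in seq_len(N)) {
      s <- recs$trait[b_]
      if ("additive" %in% spec$random[[traits[s]]])
        Cay[, b_] <- vc$additive[u, s] * K[, recs$id[b_]]
    }
    ebv[, u] <- drop(Cay %*% Vi %*% resid)
  }
  list(beta = beta, ebv = ebv)
}

# Small simulated dataset shared by mixed-model and evaluation tests.
toy_dataset <- function(seed = 5L, n_sires = 4L, n_dams = 16L, n_cb = 64L,
                        n_pb = 32L, traits = c("cIMF", "pIMF"),
                        rg = NULL, genetic_model = "pedigree",
                        n_markers = 60L) {
  d <- sim_design(n_sires = n_sires, n_dams = n_dams, n_cb = n_cb,
                  n_pb = n_pb, n_pb_dams = max(2L, n_pb %/% 8L),
                  n_markers = n_markers, pen_size = 10L, pens_per_cg = 2L)
  popn <- simulate_population(d, seed = seed)
  model <- if (is.null(rg)) default_trait_model(traits)
  else {
    R <- diag(length(traits)); dimnames(R) <- list(traits, traits)
    R[1, 2] <- R[2, 1] <- rg
    cat_ <- pig_trait_catalogue()
    cat_ <- cat_[match(traits, cat_$trait), ]
    trait_model(traits, stats::setNames(cat_$population, traits),
                var_p = cat_$sd^2, h2 = cat_$h2, rg = R)
  }
  sim <- simulate_traits(popn, model, seed = seed + 1L,
                         genetic_model = genetic_model)
  list(popn = popn, model = model, sim = sim,
       phen = sim$phenotypes, A = build_A(popn$ped))
}
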