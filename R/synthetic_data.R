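#' Design of a synthetic three-way cross population
#'
#' Defaults emulate a commercial crossbreeding structure: 28 purebred Duroc
#' sires each producing paternal half-sib families of crossbred (CB)
#' offspring out of F1 Landrace x Yorkshire dams, and purebred Duroc (PB)
#' offspring out of Duroc sows.  Genotypes follow three divergent founder
#' lineages (Duroc, Landrace, Yorkshire) with Balding-Nichols
#' differentiation from a common ancestral frequency spectrum.
#'
#' @param n_sires number of Duroc sires (default 28).
#' @param n_dams number of F1 crossbred dams (default 914).
#' @param n_cb total crossbred offspring (default 5294).
#' @param n_pb total purebred Duroc offspring (default 3106).
#' @param n_pb_dams number of Duroc sows; default gives litters of ~10.
#' @param n_markers SNP count (default 2000; up to chip scale if desired).
#' @param n_chromosomes autosome count markers are spread over (default 18).
#' @param fst lineage differentiation from the ancestral spectrum
#'   (default 0.15, typical of divergent pig breeds).
#' @param freq_range range of ancestral allele frequencies (default
#'   `c(0.05, 0.95)`).
#' @param pen_size animals per pen (default 25).
#' @param pens_per_cg pens pooled into one contemporary group (default 8).
#' @param linkage `"independent"` (default, linkage equilibrium) or
#'   `"block"` (whole-chromosome cosegregation, a coarse LD model).
#' @param n_mat_sires,n_mat_dams founder males/females per maternal lineage;
#'   defaults scale with `n_dams`.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_sires = 28L, n_dams = 914L, n_cb = 5294L,
                       n_pb = 3106L, n_pb_dams = NULL, n_markers = 2000L,
                       n_chromosomes = 18L, fst = 0.15,
                       freq_range = c(0.05, 0.95), pen_size = 25L,
                       pens_per_cg = 8L,
                       linkage = c("independent", "block"),
                       n_mat_sires = NULL, n_mat_dams = NULL) {
  if (is.null(n_pb_dams)) n_pb_dams <- max(2L, ceiling(n_pb / 10))
  if (is.null(n_mat_sires)) n_mat_sires <- max(3L, round(n_dams / 30))
  if (is.null(n_mat_dams)) n_mat_dams <- max(5L, round(n_dams / 8))
  linkage <- match.arg(linkage)
  stopifnot(n_sires >= 1, n_dams >= n_sires, n_cb >= n_dams,
            n_pb_dams >= 1, fst > 0, fst < 1)
  structure(list(n_sires = n_sires, n_dams = n_dams, n_cb = n_cb,
                 n_pb = n_pb, n_pb_dams = n_pb_dams,
                 n_markers = n_markers, n_chromosomes = n_chromosomes,
                 fst = fst, freq_range = freq_range, pen_size = pen_size,
                 pens_per_cg = pens_per_cg, linkage = linkage,
                 n_mat_sires = n_mat_sires, n_mat_dams = n_mat_dams),
            class = "sim_design")
}

# split `total` into `k` parts differing by at most 1
even_split <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

#' Simulate a three-way cross population with genotypes
#'
#' Founder haplotypes are drawn per lineage from Balding-Nichols
#' differentiated allele frequencies; descendant haplotypes are produced by
#' gene dropping (independent loci by default, or whole-chromosome blocks).
#' F1 dams come in both cross directions (Landrace sire x Yorkshire dam and
#' the reverse), recorded as the `dam_line` of their crossbred offspring.
#' Byte-identical outputs are produced for identical seeds.
#'
#' @param design a [sim_design].
#' @param seed integer seed.
#' @return List with `ped` (a [pedigree]), `geno` (a [genotype_set] over
#'   all animals), `animals` (data.frame of id, population, sex, litter,
#'   pen, cg, dam_line, parity, age), and `founder_freqs` (per-lineage
#'   marker frequency matrix).
#' @export
simulate_population <- function(design = sim_design(), seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  d <- design
  m <- d$n_markers

  p0 <- stats::runif(m, d$freq_range[1L], d$freq_range[2L])
  bn <- function(p) {
    a <- p * (1 - d$fst) / d$fst
    b <- (1 - p) * (1 - d$fst) / d$fst
    pmin(pmax(stats::rbeta(length(p), a, b), 0.005), 0.995)
  }
  freqs <- rbind(duroc = bn(p0), landrace = bn(p0), yorkshire = bn(p0))

  chr <- rep(seq_len(d$n_chromosomes), length.out = m)
  meta <- data.frame(name = sprintf("snp%05d", seq_len(m)),
                     chromosome = as.character(chr),
                     position = stats::ave(seq_len(m), chr, FUN = seq_along))

  ids <- character(0); sire <- character(0); dam <- character(0)
  pop <- character(0)
  new_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

  dsires <- new_ids("DS", d$n_sires)
  dsows  <- new_ids("DD", d$n_pb_dams)
  lsires <- new_ids("LS", d$n_mat_sires); ldams <- new_ids("LD", d$n_mat_dams)
  ysires <- new_ids("YS", d$n_mat_sires); ydams <- new_ids("YD", d$n_mat_dams)
  f1     <- new_ids("F1", d$n_dams)

  add <- function(id, s, dm, p) {
    ids <<- c(ids, id); sire <<- c(sire, s); dam <<- c(dam, dm)
    pop <<- c(pop, p)
  }
  add(dsires, rep(NA, d$n_sires), rep(NA, d$n_sires), rep("PB_SIRE", d$n_sires))
  add(dsows, rep(NA, d$n_pb_dams), rep(NA, d$n_pb_dams),
      rep("ANCESTOR", d$n_pb_dams))
  for (v in list(lsires, ldams, ysires, ydams))
    add(v, rep(NA, length(v)), rep(NA, length(v)), rep("ANCESTOR", length(v)))

  # F1 dams, half per cross direction
  n_ly <- ceiling(d$n_dams / 2)
  f1_sire <- c(sample(lsires, n_ly, replace = TRUE),
               sample(ysires, d$n_dams - n_ly, replace = TRUE))
  f1_dam  <- c(sample(ydams, n_ly, replace = TRUE),
               sample(ldams, d$n_dams - n_ly, replace = TRUE))
  dam_line_of_f1 <- c(rep("LY", n_ly), rep("YL", d$n_dams - n_ly))
  add(f1, f1_sire, f1_dam, rep("DAM", d$n_dams))

  # crossbred litters: each F1 dam mated to one Duroc sire
  cb_sizes <- even_split(d$n_cb, d$n_dams)
  dam_sire <- sample(rep(dsires, length.out = d$n_dams))
  cb <- new_ids("CB", d$n_cb)
  cb_dam <- rep(f1, cb_sizes)
  cb_sire <- rep(dam_sire, cb_sizes)
  add(cb, cb_sire, cb_dam, rep("CB", d$n_cb))

  # purebred litters: Duroc sows mated to the same sires
  pb_sizes <- even_split(d$n_pb, d$n_pb_dams)
  sow_sire <- sample(rep(dsires, length.out = d$n_pb_dams))
  pb <- new_ids("PB", d$n_pb)
  pb_dam <- rep(dsows, pb_sizes)
  pb_sire <- rep(sow_sire, pb_sizes)
  add(pb, pb_sire, pb_dam, rep("PB", d$n_pb))

  ped <- pedigree(ids, sire, dam, population = pop)

  # ---- gene dropping ---------------------------------------------------
  rec <- ped$records
  n <- nrow(rec)
  pos <- seq_len(n); names(pos) <- rec$id
  lineage <- rep(NA_character_, n); names(lineage) <- rec$id
  lineage[c(dsires, dsows)] <- "duroc"
  lineage[c(lsires, ldams)] <- "landrace"
  lineage[c(ysires, ydams)] <- "yorkshire"
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  blocky <- d$linkage == "block"
  for (i in seq_len(n)) {
    if (is.na(rec$sire[i])) {
      f <- freqs[lineage[rec$id[i]], ]
      H1[i, ] <- stats::rbinom(m, 1L, f)
      H2[i, ] <- stats::rbinom(m, 1L, f)
    } else {
      si <- pos[rec$sire[i]]; di <- pos[rec$dam[i]]
      if (blocky) {
        pickS <- stats::rbinom(d$n_chromosomes, 1L, 0.5)[chr]
        pickD <- stats::rbinom(d$n_chromosomes, 1L, 0.5)[chr]
      } else {
        pickS <- stats::rbinom(m, 1L, 0.5)
        pickD <- stats::rbinom(m, 1L, 0.5)
      }
      H1[i, ] <- ifelse(pickS == 1L, H1[si, ], H2[si, ])
      H2[i, ] <- ifelse(pickD == 1L, H1[di, ], H2[di, ])
    }
  }
  M <- H1 + H2
  mode(M) <- "numeric"
  rownames(M) <- rec$id
  colnames(M) <- meta$name
  geno <- genotype_set(M, meta, grm_population(rec$population))

  # ---- husbandry structure --------------------------------------------
  sex_cb <- sample(c("M", "F"), d$n_cb, replace = TRUE)
  sex_pb <- sample(c("M", "F"), d$n_pb, replace = TRUE)
  # Pens are single-sex and filled family-wise (ordered by sire), so a pen
  # holds one or two paternal half-sib groups, as in commercial finishing
  # barns; litters are split across the two sexes, so litter and pen
  # effects remain separable.
  # pen sizes alternate by one so pen boundaries drift across family
  # boundaries instead of coinciding with them
  assign_pens <- function(ids, sex, sires, prefix) {
    pen <- character(length(ids))
    for (s in c("M", "F")) {
      w <- which(sex == s)
      w <- w[order(sires[w], ids[w])]
      k <- max(1L, ceiling(length(w) / design$pen_size) + 1L)
      sizes <- design$pen_size + rep_len(c(1L, -1L), k)
      pen[w] <- sprintf("%s_%s%03d", prefix, s,
                        rep(seq_len(k), times = pmax(sizes, 1L))[seq_along(w)])
    }
    pen
  }
  pen_cb <- assign_pens(cb, sex_cb, cb_sire, "CBP")
  pen_pb <- assign_pens(pb, sex_pb, pb_sire, "PBP")
  # contemporary groups pool pens across sexes (barn batches hold both
  # sexes), so cg is never confounded with the sex effect
  cg_of_pen <- function(pen, prefix) {
    uf <- sort(unique(pen[grepl("_F", pen)]))
    um <- sort(unique(pen[grepl("_M", pen)]))
    k <- max(length(uf), length(um))
    u <- as.vector(rbind(c(uf, rep(NA, k - length(uf))),
                         c(um, rep(NA, k - length(um)))))
    u <- u[!is.na(u)]
    grp <- sprintf("%s%02d", prefix,
                   rep(seq_len(ceiling(length(u) / design$pens_per_cg)),
                       each = design$pens_per_cg)[seq_along(u)])
    grp[match(pen, u)]
  }
  animals <- data.frame(
    id = rec$id, population = rec$population,
    sire = rec$sire, dam = rec$dam,
    sex = NA_character_, litter = NA_character_, pen = NA_character_,
    cg = NA_character_, dam_line = NA_character_,
    parity = NA_integer_, age = NA_real_,
    stringsAsFactors = FALSE)
  rownames(animals) <- animals$id
  animals[cb, "sex"] <- sex_cb
  animals[pb, "sex"] <- sex_pb
  animals[cb, "litter"] <- paste0("L_", cb_dam)
  animals[pb, "litter"] <- paste0("L_", pb_dam)
  animals[cb, "pen"] <- pen_cb
  animals[pb, "pen"] <- pen_pb
  animals[cb, "cg"] <- cg_of_pen(pen_cb, "CBG")
  animals[pb, "cg"] <- cg_of_pen(pen_pb, "PBG")
  animals[cb, "dam_line"] <- dam_line_of_f1[match(cb_dam, f1)]
  animals[pb, "parity"] <- sample(1:4, d$n_pb, replace = TRUE)
  animals[pb, "age"] <- round(stats::rnorm(d$n_pb, 180, 5), 1)

  list(ped = ped, geno = geno, animals = animals, founder_freqs = freqs,
       design = design, seed = seed)
}

#' Map pedigree population tags to GRM population labels
#'
#' The genomic relationship matrix distinguishes three populations:
#' crossbreds (`CB`), their F1 dams (`DAM`) and the purebred line including
#' the sires (`PBplusSIRES`); everything else is `OTHER`.
#'
#' @param tags character vector of pedigree population tags.
#' @return Character vector of GRM labels.
#' @export
grm_population <- function(tags) {
  out <- rep("OTHER", length(tags))
  out[tags == "CB"] <- "CB"
  out[tags == "DAM"] <- "DAM"
  out[tags %in% c("PB", "PB_SIRE")] <- "PBplusSIRES"
  out
}

#' Multi-trait generating model for the synthetic population
#'
#' Assembles the trait-level covariance structure used to simulate
#' phenotypes: additive, litter, pen and residual trait covariance matrices
#' derived from phenotypic variances, heritabilities, variance fractions
#' and a genetic correlation matrix.  The assembled genetic correlation
#' matrix is projected to the nearest positive semidefinite correlation
#' matrix when needed; the adjustment magnitude is stored in attribute
#' `"psd_adjustment"`.
#'
#' @param traits trait names.
#' @param population per-trait measurement population (`"CB"`/`"PB"`).
#' @param var_p phenotypic variances (default 1 per trait).
#' @param h2 narrow-sense heritabilities per trait.
#' @param c2_litter litter variance fractions (default 0.10).
#' @param c2_pen pen variance fractions (default 0.05 for CB traits, 0 for
#'   PB traits).
#' @param rg genetic correlation matrix (default identity).
#' @param re residual correlation matrix within jointly-observed blocks
#'   (default identity); cross-population entries are forced to 0.
#' @param mean_p trait means (default 0).
#' @param fixed_sd named vector with standard deviations of the generated
#'   fixed effects: `cg`, `sex`, `dam_line`, `parity`, `age_slope` (per
#'   trait-SD units).
#' @return A `trait_model` list with covariance matrices and generators.
#' @export
trait_model <- function(traits, population, var_p = NULL, h2,
                        c2_litter = NULL, c2_pen = NULL, rg = NULL,
                        re = NULL, mean_p = NULL,
                        fixed_sd = c(cg = 0.3, sex = 0.2, dam_line = 0.1,
                                     parity = 0.05, age_slope = 0.02)) {
  t <- length(traits)
  if (is.null(names(population))) names(population) <- traits
  if (is.null(var_p)) var_p <- rep(1, t)
  if (is.null(mean_p)) mean_p <- rep(0, t)
  if (is.null(c2_litter)) c2_litter <- rep(0.10, t)
  if (is.null(c2_pen)) c2_pen <- ifelse(population[traits] == "CB", 0.05, 0)
  if (is.null(rg)) rg <- diag(t)
  if (is.null(re)) re <- diag(t)
  stopifnot(length(h2) == t, all(h2 >= 0), all(h2 + c2_litter + c2_pen < 1))
  adj <- 0
  pr <- nearest_psd_corr(rg)
  adj <- attr(pr, "adjustment")
  rg <- pr
  sd_a <- sqrt(h2 * var_p)
  additive <- diag(sd_a, t) %*% rg %*% diag(sd_a, t)
  litter <- diag(c2_litter * var_p, t)
  pen <- diag(c2_pen * var_p, t)
  # cross-population residual correlations are meaningless: zero them
  blk <- outer(population[traits], population[traits], "==")
  re <- nearest_psd_corr(re * blk + diag(t) * 0)
  sd_e <- sqrt(pmax(var_p * (1 - h2 - c2_litter - c2_pen), 1e-8))
  residual <- diag(sd_e, t) %*% re %*% diag(sd_e, t)
  dimnames(additive) <- dimnames(litter) <- dimnames(pen) <-
    dimnames(residual) <- list(traits, traits)
  structure(list(traits = traits, population = population[traits],
                 var_p = stats::setNames(var_p, traits),
                 mean_p = stats::setNames(mean_p, traits),
                 additive = additive, litter = litter, pen = pen,
                 residual = residual, fixed_sd = fixed_sd,
                 psd_adjustment = adj),
            class = "trait_model")
}

#' Nearest positive semidefinite correlation matrix
#'
#' Higham's alternating-projection algorithm (via [Matrix::nearPD]) with an
#' eigenvalue-clipping fallback; attribute `"adjustment"` reports the
#' largest absolute change to any entry.  An assembled correlation matrix
#' with many strong reported entries and zero-filled unknown pairs can be
#' far from feasible, in which case the adjustment is substantial; models
#' built on small feasible trait subsets are returned unchanged.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps smallest retained eigenvalue (default 1e-6).
#' @return Adjusted correlation matrix.
#' @export
nearest_psd_corr <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  ee <- eigen(R, symmetric = TRUE, only.values = TRUE)
  if (min(ee$values) >= eps) {
    attr(R, "adjustment") <- 0
    return(R)
  }
  out <- tryCatch(
    as.matrix(Matrix::nearPD(R, corr = TRUE, eig.tol = eps,
                             maxit = 500)$mat),
    error = function(e) NULL)
  if (is.null(out)) {
    eef <- eigen(R, symmetric = TRUE)
    v <- pmax(eef$values, eps)
    M <- eef$vectors %*% diag(v, length(v)) %*% t(eef$vectors)
    D <- 1 / sqrt(diag(M))
    out <- diag(D, length(D)) %*% M %*% diag(D, length(D))
  }
  dimnames(out) <- dimnames(R)
  attr(out, "adjustment") <- max(abs(out - R))
  out
}

#' Catalogue of the pig meat-quality and growth traits
#'
#' Names, measurement population, descriptive statistics and single-trait
#' heritabilities of the 18 crossbred-measured and 6 purebred-measured
#' traits used throughout the package; the defaults of
#' [default_trait_model] are seeded from these values.
#'
#' @return data.frame with columns `trait`, `population`, `mean`, `sd`,
#'   `h2`, and `expensive` (recorded only on the phenotyping subset).
#' @export
pig_trait_catalogue <- function() {
  cb <- data.frame(
    trait = c("cIMF", "cSSF", "cM.L", "cM.a", "cM.b", "cPH", "cSCOL",
              "cSFIR", "cSMAR", "cCLD", "cCBF", "cCDG", "cLLD", "cLBF",
              "cLDG", "cLOI", "cBEL", "cHAM"),
    population = "CB",
    mean = c(2.71, 15.93, 45.3, 3.79, -0.15, 5.64, 2.72, 3.04, 3.10,
             66.78, 22.62, 0.52, 60.28, 23.51, 0.69, 23.09, 40.31, 55.53),
    sd = c(0.93, 3.65, 3.10, 1.10, 0.90, 0.18, 0.47, 0.99, 0.83,
           6.91, 4.88, 0.06, 5.14, 6.38, 0.08, 2.17, 6.12, 5.17),
    h2 = c(0.35, 0.19, 0.11, 0.14, 0.04, 0.06, 0.22, 0.04, 0.11,
           0.05, 0.28, 0.05, 0.13, 0.23, 0.05, 0.06, 0.04, 0.06),
    expensive = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                  TRUE))
  pb <- data.frame(
    trait = c("pIMF", "pLBF", "pLLD", "pLLA", "pLDG1", "pLDG2"),
    population = "PB",
    mean = c(2.49, 16.23, 6.00, 50.69, 0.45, 0.89),
    sd = c(0.83, 3.95, 0.55, 6.26, 0.09, 0.12),
    h2 = c(0.11, 0.32, 0.18, 0.15, 0.30, 0.23),
    expensive = FALSE)
  rbind(cb, pb)
}

# genetic correlations reported for this trait panel; unlisted pairs are 0
pig_rg_table <- function() {
  rbind(
    # among purebred traits
    data.frame(t1 = c("pIMF", "pIMF", "pIMF", "pIMF", "pIMF",
                      "pLBF", "pLBF", "pLBF", "pLBF",
                      "pLLD", "pLLD", "pLLD",
                      "pLLA", "pLLA", "pLDG1"),
               t2 = c("pLBF", "pLLD", "pLLA", "pLDG1", "pLDG2",
                      "pLLD", "pLLA", "pLDG1", "pLDG2",
                      "pLLA", "pLDG1", "pLDG2",
                      "pLDG1", "pLDG2", "pLDG2"),
               rg = c(0.83, 0.38, 0.29, 0.30, 0.51,
                      0.49, 0.39, 0.44, 0.79,
                      0.97, 0.55, 0.69,
                      0.63, 0.70, 0.72)),
    # purebred-crossbred
    data.frame(t1 = c("pIMF", "pIMF", "pIMF", "pIMF", "pIMF", "pIMF",
                      "pLBF", "pLBF", "pLBF", "pLDG1",
                      "pLLA", "pLLD", "pLLA", "pLLD"),
               t2 = c("cIMF", "cSFIR", "cSMAR", "cBEL", "cPH", "cSSF",
                      "cM.b", "cPH", "cIMF", "cPH",
                      "cCDG", "cCDG", "cCLD", "cCLD"),
               rg = c(0.95, 0.87, 0.79, 0.66, 0.58, 0.49,
                      0.60, 0.58, 0.55, 0.54,
                      0.78, 0.79, 0.67, 0.55)),
    # among crossbred traits
    data.frame(t1 = c("cLLD", "cLDG", "cLOI", "cLOI", "cCBF", "cCBF",
                      "cCLD", "cCDG", "cIMF", "cIMF", "cIMF", "cSSF",
                      "cSCOL"),
               t2 = c("cIMF", "cSFIR", "cLDG", "cLLD", "cSSF", "cIMF",
                      "cLOI", "cLOI", "cM.L", "cM.b", "cPH", "cM.a",
                      "cM.L"),
               rg = c(-0.51, 0.56, 0.90, 0.83, -0.41, 0.40,
                      0.84, 0.91, 0.96, 0.95, -0.72, 0.72,
                      -0.70)))
}

#' Default generating model over the full trait panel
#'
#' Builds a [trait_model] across all 24 catalogue traits (or a subset),
#' with phenotypic variances, means and heritabilities from
#' [pig_trait_catalogue] and the reported genetic correlations filled in
#' (unlisted pairs default to 0); the assembled correlation matrix is
#' projected to the nearest positive semidefinite correlation matrix.
#'
#' @param traits subset of catalogue traits (default: all).
#' @param rg_overrides optional data.frame (`t1`, `t2`, `rg`) replacing or
#'   adding correlation entries.
#' @param ... passed to [trait_model] (e.g. `c2_litter`, `c2_pen`).
#' @return A `trait_model`.
#' @export
default_trait_model <- function(traits = NULL, rg_overrides = NULL, ...) {
  cat_ <- pig_trait_catalogue()
  if (is.null(traits)) traits <- cat_$trait
  stopifnot(all(traits %in% cat_$trait))
  cat_ <- cat_[match(traits, cat_$trait), ]
  t <- length(traits)
  R <- diag(t); dimnames(R) <- list(traits, traits)
  tab <- pig_rg_table()
  if (!is.null(rg_overrides)) tab <- rbind(tab, rg_overrides)
  for (i in seq_len(nrow(tab))) {
    if (tab$t1[i] %in% traits && tab$t2[i] %in% traits) {
      R[tab$t1[i], tab$t2[i]] <- tab$rg[i]
      R[tab$t2[i], tab$t1[i]] <- tab$rg[i]
    }
  }
  trait_model(traits, stats::setNames(cat_$population, traits),
              var_p = cat_$sd^2, h2 = cat_$h2, rg = R,
              mean_p = cat_$mean, ...)
}

#' Simulate multi-trait phenotypes on a pedigree
#'
#' Breeding values follow the additive trait covariance combined with the
#' pedigree: either by Mendelian-sampling recursion (`"pedigree"` mode,
#' founders N(0, G_a), offspring mean-parent plus sampling variance
#' G_a / 2) or as sums of marker effects on centered dosages (`"markers"`
#' mode, so genomic prediction has marker-linked signal).  Litter, pen,
#' contemporary-group, sex/dam-line/parity effects, an age covariate (PB
#' traits) and residuals are added; each trait is reported only for
#' animals of its measurement population.
#'
#' @param popn output of [simulate_population] (uses `ped`, `animals` and,
#'   in markers mode, `geno`).
#' @param model a [trait_model].
#' @param seed integer seed.
#' @param genetic_model `"markers"` (default) or `"pedigree"`.
#' @return List with `phenotypes` (animals data.frame plus one column per
#'   trait), and `truth` (breeding-value matrix, generating
#'   [variance_components], fixed-effect values, marker effects when
#'   applicable).
#' @export
simulate_traits <- function(popn, model, seed = 1L,
                            genetic_model = c("markers", "pedigree")) {
  genetic_model <- match.arg(genetic_model)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ped <- popn$ped
  an <- popn$animals
  rec <- ped$records
  n <- nrow(rec); t <- length(model$traits)
  Ga <- model$additive
  cG <- chol_psd(Ga)

  alpha <- NULL
  if (genetic_model == "markers") {
    M <- popn$geno$dosages[rec$id, , drop = FALSE]
    p <- colMeans(M) / 2
    k <- sum(2 * p * (1 - p))
    Z <- sweep(M, 2L, 2 * p)
    alpha <- matrix(stats::rnorm(ncol(M) * t), ncol(M), t) %*% (cG / sqrt(k))
    a <- Z %*% alpha
  } else {
    a <- matrix(0, n, t)
    pos <- seq_len(n); names(pos) <- rec$id
    zz <- matrix(stats::rnorm(n * t), n, t)
    for (i in seq_len(n)) {
      if (is.na(rec$sire[i]) && is.na(rec$dam[i])) {
        a[i, ] <- zz[i, ] %*% cG
      } else {
        pa <- 0
        nk <- 0
        for (p_ in c(rec$sire[i], rec$dam[i])) if (!is.na(p_)) {
          pa <- pa + a[pos[p_], ]; nk <- nk + 1L
        }
        a[i, ] <- pa / 2 + sqrt(1 - nk / 4) * (zz[i, ] %*% cG)
      }
    }
  }
  rownames(a) <- rec$id
  colnames(a) <- model$traits

  draw_levels <- function(levels, cov) {
    u <- matrix(stats::rnorm(length(levels) * ncol(cov)), length(levels)) %*%
      chol_psd(cov)
    rownames(u) <- levels
    u
  }
  litter_lv <- sort(unique(stats::na.omit(an$litter)))
  pen_lv <- sort(unique(stats::na.omit(an$pen)))
  cg_lv <- sort(unique(stats::na.omit(an$cg)))
  u_lit <- draw_levels(litter_lv, model$litter)
  u_pen <- draw_levels(pen_lv, model$pen)
  sd_p <- sqrt(model$var_p)
  fx <- model$fixed_sd
  u_cg <- draw_levels(cg_lv, diag((fx["cg"] * sd_p)^2, t))
  eff_sex <- stats::rnorm(t, 0, fx["sex"] * sd_p)
  eff_line <- stats::rnorm(t, 0, fx["dam_line"] * sd_p)
  eff_parity <- matrix(stats::rnorm(4 * t, 0, rep(fx["parity"] * sd_p,
                                                  each = 4)), 4, t)
  slope_age <- stats::rnorm(t, 0, fx["age_slope"] * sd_p)
  e <- matrix(stats::rnorm(n * t), n, t) %*% chol_psd(model$residual)

  Y <- matrix(NA_real_, n, t, dimnames = list(rec$id, model$traits))
  an <- an[rec$id, ]
  for (k in seq_len(t)) {
    tr <- model$traits[k]
    rows <- which(an$population == model$population[tr])
    if (!length(rows)) next
    y <- model$mean_p[tr] + a[rows, k] + e[rows, k]
    y <- y + u_lit[an$litter[rows], k]
    if (model$population[tr] == "CB") {
      y <- y + u_pen[an$pen[rows], k] +
        ifelse(an$sex[rows] == "M", eff_sex[k] / 2, -eff_sex[k] / 2) +
        ifelse(an$dam_line[rows] == "LY", eff_line[k] / 2, -eff_line[k] / 2)
    } else {
      y <- y + eff_parity[an$parity[rows], k] +
        slope_age[k] * (an$age[rows] - 180)
      y <- y + ifelse(an$sex[rows] == "M", eff_sex[k] / 2, -eff_sex[k] / 2)
    }
    y <- y + u_cg[an$cg[rows], k]
    Y[rows, k] <- y
  }
  phenotypes <- cbind(an, as.data.frame(Y))
  vc_true <- variance_components(model$additive, model$litter, model$pen,
                                 model$residual, traits = model$traits)
  list(phenotypes = phenotypes,
       truth = list(bv = a, vc = vc_true, marker_effects = alpha,
                    cg_effects = u_cg, sex_effect = eff_sex,
                    dam_line_effect = eff_line, age_slope = slope_age))
}

# Cholesky factor tolerant of PSD (zero-variance) matrices
chol_psd <- function(M) {
  M <- as.matrix(M)
  ok <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(ee$values, 0)
  t(ee$vectors %*% diag(sqrt(v), length(v)) %*% t(ee$vectors))
}

#' Select the within-group phenotyping subset
#'
#' Implements the routine phenotyping design for expensive traits: within
#' each group (paternal half-sibs of the same sex housed in the same pen),
#' the individuals closest to the group mean of the anchor trait and to
#' +1, +2, -1 and -2 within-group standard deviations from it are chosen,
#' in that order, each target matched greedily to a distinct nearest
#' individual (ties broken by lowest id).  Groups smaller than `k` return
#' all their members.
#'
#' @param phenotypes data.frame with columns `id` and the anchor trait.
#' @param groups group label per row of `phenotypes`.
#' @param anchor_trait column name of the anchor trait (e.g. carcass
#'   growth); must be recorded for all group members.
#' @param k targets per group (default 5).
#' @return Character vector of selected ids.
#' @export
select_phenotyping_subset <- function(phenotypes, groups, anchor_trait,
                                      k = 5L) {
  stopifnot(anchor_trait %in% names(phenotypes))
  ids <- as.character(phenotypes$id)
  val <- as.numeric(phenotypes[[anchor_trait]])
  if (anyNA(val)) stop("anchor trait must be recorded for all group members")
  groups <- as.character(groups)
  sel <- character(0)
  for (g in sort(unique(groups))) {
    w <- which(groups == g)
    if (length(w) == 1L) {
      warning("group of size 1: ", g)
      sel <- c(sel, ids[w]); next
    }
    if (length(w) <= k) { sel <- c(sel, ids[w]); next }
    mu <- mean(val[w]); s <- stats::sd(val[w])
    targets <- mu + c(0, 1, 2, -1, -2) * s
    remaining <- order(ids[w])  # lowest-id-first among ties
    remaining <- w[remaining]
    for (tg in targets) {
      dd <- abs(val[remaining] - tg)
      pick <- remaining[which.min(dd)]  # first minimum = lowest id
      sel <- c(sel, ids[pick])
      remaining <- setdiff(remaining, pick)
    }
  }
  sel
}

#' Phenotyping groups of the crossbred offspring
#'
#' Group = paternal half-sibs of the same sex in the same pen.
#'
#' @param animals animals data.frame from [simulate_population].
#' @return Character vector of group labels (`NA` outside CB).
#' @export
cb_groups <- function(animals) {
  g <- rep(NA_character_, nrow(animals))
  w <- animals$population == "CB"
  g[w] <- paste(animals$sire[w], animals$sex[w], animals$pen[w], sep = "|")
  g
}

#' Apply the subset design to expensive crossbred traits
#'
#' Sets the expensive-trait records of non-selected crossbred animals to
#' `NA`, emulating a phenotyping scheme where only the within-group subset
#' is measured for costly traits.
#'
#' @param phenotypes phenotype data.frame (from [simulate_traits]).
#' @param subset_ids ids retaining expensive records (from
#'   [select_phenotyping_subset]).
#' @param expensive_traits trait columns to restrict.
#' @return The phenotype data.frame with restricted records.
#' @export
apply_phenotyping_subset <- function(phenotypes, subset_ids,
                                     expensive_traits) {
  drop <- phenotypes$population == "CB" &
    !(phenotypes$id %in% subset_ids)
  for (tr in expensive_traits)
    if (tr %in% names(phenotypes)) phenotypes[drop, tr] <- NA
  phenotypes
}
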