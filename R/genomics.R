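#' Genotype set container
#'
#' Holds SNP dosages with marker metadata and per-animal population labels.
#' Dosages count copies of the alternate allele (0/1/2, `NA` = missing call).
#'
#' @param dosages animal x marker numeric matrix with rownames = animal ids
#'   and colnames = marker names; entries in `{0, 1, 2, NA}`.
#' @param marker_meta data.frame with columns `name`, `chromosome` and
#'   optionally `position`; `chromosome` is character, with autosomes coded
#'   as numbers and sex chromosomes/unplaced as e.g. `"X"`, `"Y"`, `"0"`.
#' @param population character/factor per animal: `"CB"`, `"DAM"` or
#'   `"PBplusSIRES"` (any labels are accepted; these three are the
#'   conventional grouping of a three-way cross).
#' @return Object of class `genotype_set`.
#' @export
genotype_set <- function(dosages, marker_meta, population) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages))) stop("dosages need animal-id rownames")
  if (is.null(colnames(dosages))) colnames(dosages) <- marker_meta$name
  if (nrow(marker_meta) != ncol(dosages))
    stop("marker_meta rows must match dosage columns")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  population <- as.character(population)
  if (length(population) != nrow(dosages))
    stop("one population label per animal required")
  marker_meta$name <- as.character(marker_meta$name)
  marker_meta$chromosome <- as.character(marker_meta$chromosome)
  structure(list(ids = rownames(dosages), dosages = dosages,
                 marker_meta = marker_meta, population = population),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d animals x %d markers; populations: %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(sprintf("%s=%d", names(table(x$population)),
                            table(x$population)), collapse = ", ")))
  invisible(x)
}

is_autosome <- function(chr) {
  suppressWarnings(num <- as.numeric(chr))
  !is.na(num) & num >= 1 & num == floor(num)
}

#' SNP quality control
#'
#' Applies the standard marker filters in order: (1) drop non-autosomal
#' markers; (2) drop markers with call rate strictly below `call_rate_min`;
#' (3) drop markers with minor allele frequency strictly below `maf_min`,
#' computed on non-missing calls pooled over all animals.  Markers exactly at
#' a threshold are retained.  Each marker is counted once, against the first
#' rule that removes it.
#'
#' @param G a [genotype_set].
#' @param call_rate_min minimum call rate retained (default 0.90).
#' @param maf_min minimum minor allele frequency retained (default 0.05).
#' @return List with elements `genotypes` (filtered [genotype_set]) and
#'   `report` (a `qc_report`: counts per rule and the thresholds).
#' @export
qc_filter <- function(G, call_rate_min = 0.90, maf_min = 0.05) {
  M <- G$dosages
  m <- ncol(M)
  keep <- rep(TRUE, m)
  auto <- is_autosome(G$marker_meta$chromosome)
  n_nonauto <- sum(!auto)
  keep <- keep & auto

  cr <- colMeans(!is.na(M))
  fail_cr <- keep & (cr < call_rate_min)
  n_cr <- sum(fail_cr)
  keep <- keep & !fail_cr

  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail_maf <- keep & (maf < maf_min)
  n_maf <- sum(fail_maf)
  keep <- keep & !fail_maf

  if (!any(keep))
    stop("no markers retained after QC; review call-rate/MAF thresholds")
  out <- genotype_set(M[, keep, drop = FALSE],
                      G$marker_meta[keep, , drop = FALSE],
                      G$population)
  report <- structure(list(n_input = m,
                           n_removed_nonautosomal = n_nonauto,
                           n_removed_callrate = n_cr,
                           n_removed_maf = n_maf,
                           n_retained = sum(keep),
                           thresholds = c(call_rate_min = call_rate_min,
                                          maf_min = maf_min)),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("SNP QC: %d markers in; removed %d non-autosomal, ",
                     "%d call-rate < %.2f, %d MAF < %.2f; %d retained\n"),
              x$n_input, x$n_removed_nonautosomal, x$n_removed_callrate,
              x$thresholds["call_rate_min"], x$n_removed_maf,
              x$thresholds["maf_min"], x$n_retained))
  invisible(x)
}

#' Write a QC report as a key-value text file
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(sprintf("n_input %d", report$n_input),
             sprintf("n_removed_nonautosomal %d", report$n_removed_nonautosomal),
             sprintf("n_removed_callrate %d", report$n_removed_callrate),
             sprintf("n_removed_maf %d", report$n_removed_maf),
             sprintf("n_retained %d", report$n_retained),
             sprintf("call_rate_min %g", report$thresholds["call_rate_min"]),
             sprintf("maf_min %g", report$thresholds["maf_min"]))
  writeLines(lines, path)
  invisible(path)
}

#' Per-population allele frequencies
#'
#' Computes, for every population label, the alternate-allele frequency of
#' each marker (mean non-missing dosage over 2), plus an `average` set equal
#' to the unweighted mean of the per-population frequencies.  A population
#' with no non-missing call at a marker falls back to the pooled frequency
#' (with a warning).
#'
#' @param G a [genotype_set] (QC already applied).
#' @return Object of class `pop_freqs`: named list of frequency vectors, one
#'   per population plus `"average"` and `"pooled"`.
#' @export
population_frequencies <- function(G) {
  M <- G$dosages
  pooled <- colMeans(M, na.rm = TRUE) / 2
  pops <- sort(unique(G$population))
  out <- list()
  fell_back <- FALSE
  for (pp in pops) {
    sub <- M[G$population == pp, , drop = FALSE]
    f <- colMeans(sub, na.rm = TRUE) / 2
    if (anyNA(f) || any(is.nan(f))) {
      fell_back <- TRUE
      f[is.nan(f) | is.na(f)] <- pooled[is.nan(f) | is.na(f)]
    }
    out[[pp]] <- f
  }
  if (fell_back)
    warning("population with zero calls at some marker; pooled frequency used")
  out$average <- Reduce(`+`, out[pops]) / length(pops)
  out$pooled <- pooled
  structure(out, class = "pop_freqs")
}

#' Genomic relationship matrix with multi-population allele frequencies
#'
#' VanRaden-type GRM `G = Z Z' / k`.  In `multi_population` mode each
#' animal's dosages are centered by twice the allele frequency of its own
#' population, accommodating the different allele frequencies of the
#' crossbreds, their dams, and the purebred line; in `single` mode the pooled
#' frequencies are used for everyone.  The denominator
#' `k = sum_j 2 p_j (1 - p_j)` is computed from the `average` frequency set
#' so one common scale applies to all population blocks.  Missing dosages are
#' imputed to twice the centering frequency (i.e. they contribute 0 after
#' centering).
#'
#' Centering modes: `"multi_population"` (default) centers every animal by
#' its own population's frequencies, which scales relationships correctly
#' across heterogeneous populations but deliberately removes mean
#' between-population divergence; `"average"` centers everyone by the
#' across-population average frequencies and is the matrix to use for
#' population-structure eigen-analysis; `"single"` centers by the pooled
#' frequencies.
#'
#' @param G a [genotype_set] (QC applied).
#' @param freqs a `pop_freqs` from [population_frequencies]; computed from
#'   `G` when `NULL`.
#' @param mode `"multi_population"` (default), `"average"` or `"single"`.
#' @param k_source frequency set for the denominator: `"average"` (default)
#'   or `"pooled"`.
#' @return A `relmat` with `source = "G"`.
#' @export
build_grm <- function(G, freqs = NULL,
                      mode = c("multi_population", "average", "single"),
                      k_source = c("average", "pooled")) {
  mode <- match.arg(mode)
  k_source <- match.arg(k_source)
  if (is.null(freqs)) freqs <- population_frequencies(G)
  M <- G$dosages
  n <- nrow(M)
  Z <- matrix(0, n, ncol(M), dimnames = dimnames(M))
  if (mode == "single") {
    ctr <- matrix(2 * freqs$pooled, n, ncol(M), byrow = TRUE)
  } else if (mode == "average") {
    ctr <- matrix(2 * freqs$average, n, ncol(M), byrow = TRUE)
  } else {
    ctr <- matrix(0, n, ncol(M))
    for (pp in unique(G$population)) {
      rows <- which(G$population == pp)
      f <- if (pp %in% names(freqs)) freqs[[pp]] else freqs$pooled
      ctr[rows, ] <- matrix(2 * f, length(rows), ncol(M), byrow = TRUE)
    }
  }
  Z <- M - ctr
  Z[is.na(M)] <- 0  # missing imputed to the centering value
  pk <- freqs[[k_source]]
  k <- sum(2 * pk * (1 - pk))
  if (k <= 0) stop("all markers monomorphic: GRM denominator is zero")
  GG <- tcrossprod(Z) / k
  relmat(GG, source = "G")
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' `G* = (1 - alpha) G + alpha A22`, the conventional single-step blending
#' that guarantees invertibility of the genotyped block.
#'
#' @param G genomic `relmat` over the genotyped animals.
#' @param A22 pedigree `relmat` over the same animals in the same order.
#' @param alpha blending proportion in `[0, 1]` (default 0.05).
#' @return A `relmat` with `source = "G"`.
#' @export
blend_grm <- function(G, A22, alpha = 0.05) {
  if (!identical(dim(G), dim(A22)) ||
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 must cover the same animals in the same order")
  stopifnot(alpha >= 0, alpha <= 1)
  relmat((1 - alpha) * unclass(G) + alpha * unclass(A22), source = "G")
}

#' Single-step blended relationship matrix H
#'
#' Replaces the genotyped block of A with `G*` and propagates the genomic
#' information to non-genotyped relatives through the standard block
#' formula:
#' \deqn{H = A + \begin{bmatrix} A_{12}A_{22}^{-1}\Delta A_{22}^{-1}A_{21} &
#'   A_{12}A_{22}^{-1}\Delta \\ \Delta A_{22}^{-1}A_{21} & \Delta
#'   \end{bmatrix}, \quad \Delta = G^* - A_{22}.}
#'
#' @param A full pedigree `relmat`.
#' @param Gstar blended genomic `relmat` over `genotyped_ids` (see
#'   [blend_grm]).
#' @param genotyped_ids animals with genotypes; must be a subset of the ids
#'   of `A`.  When empty, `H = A`; when everyone is genotyped, `H = Gstar`.
#' @return A `relmat` with `source = "H"` and the id order of `A`.
#' @export
build_H <- function(A, Gstar, genotyped_ids) {
  ids <- rownames(A)
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% ids))
    stop("genotyped_ids must be a subset of the ids of A")
  if (length(genotyped_ids) == 0L)
    return(relmat(unclass(A), source = "H"))
  if (!all(genotyped_ids %in% rownames(Gstar)))
    stop("Gstar must cover all genotyped_ids")
  g <- genotyped_ids
  ng <- setdiff(ids, g)
  Gs <- unclass(Gstar)[g, g, drop = FALSE]
  A22 <- unclass(A)[g, g, drop = FALSE]
  ok <- tryCatch({chol(A22); TRUE}, error = function(e) FALSE)
  if (!ok) stop("A22 is singular; consider blending (blend_grm)")
  Delta <- Gs - A22
  H <- unclass(A)
  if (length(ng)) {
    A12 <- unclass(A)[ng, g, drop = FALSE]
    W <- t(solve(A22, t(A12)))      # A12 %*% A22^{-1}
    H[ng, ng] <- H[ng, ng] + W %*% Delta %*% t(W)
    cross <- W %*% Delta
    H[ng, g] <- H[ng, g] + cross
    H[g, ng] <- H[g, ng] + t(cross)
  }
  H[g, g] <- Gs
  relmat(H[ids, ids], source = "H")
}

#' Eigen-decomposition of a genomic relationship matrix
#'
#' Principal-component view of population structure: eigenvalues in
#' descending order, per-animal component scores (eigenvector times square
#' root of eigenvalue) and the fraction of variance (trace) each component
#' explains.
#'
#' @param G a symmetric `relmat` (or plain symmetric matrix with id
#'   dimnames).
#' @param n_components number of components to return scores for (default
#'   10, capped at the matrix order).
#' @return List with `values` (all eigenvalues), `scores` (animal x
#'   component matrix), `var_explained` (fractions summing to 1 over all
#'   components).
#' @export
grm_pca <- function(G, n_components = 10L) {
  ee <- eigen(unclass(G), symmetric = TRUE)
  k <- min(n_components, ncol(G))
  scores <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ee$values[seq_len(k)], 0)), k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(values = ee$values,
       scores = scores,
       var_explained = ee$values / sum(ee$values))
}

#' Read genotypes from a simple matrix text file
#'
#' Format: header line of marker names; each following row is an animal id
#' followed by 0/1/2/NA dosages.  Marker metadata (chromosome, position) and
#' population labels are supplied separately or default to autosome 1 and a
#' single population.
#'
#' @param path file path.
#' @param marker_meta optional data.frame (`name`, `chromosome`,
#'   `position`); defaults to chromosome `"1"` for every marker.
#' @param population optional per-animal labels (named by animal id or in
#'   file order).
#' @return A [genotype_set].
#' @export
read_genotype_matrix <- function(path, marker_meta = NULL, population = NULL) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = c("NA", "-9"))
  ids <- as.character(tab[[1L]])
  M <- as.matrix(tab[, -1L, drop = FALSE])
  mode(M) <- "numeric"
  rownames(M) <- ids
  if (is.null(marker_meta))
    marker_meta <- data.frame(name = colnames(M), chromosome = "1",
                              position = seq_len(ncol(M)))
  if (is.null(population)) population <- rep("POP", nrow(M))
  if (!is.null(names(population))) population <- population[ids]
  genotype_set(M, marker_meta, population)
}

#' Write genotypes as a simple matrix text file
#' @param G a [genotype_set].
#' @param path output path.
#' @export
write_genotype_matrix <- function(G, path) {
  df <- data.frame(id = G$ids, G$dosages, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PLINK-style text genotypes (.ped/.map pair)
#'
#' Minimal reader for the classic whitespace-delimited PLINK text format:
#' `.map` columns are chromosome, marker name, genetic distance, position;
#' `.ped` columns are family id, animal id, sire, dam, sex, phenotype, then
#' two allele columns per marker (alleles coded `1`/`2` or `A/C/G/T`; `0` =
#' missing).  Dosage counts the second (alternate) allele, defined per
#' marker as the lexicographically larger observed allele.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @param population optional per-animal population labels (named by id).
#' @return A [genotype_set].
#' @export
read_plink <- function(ped_path, map_path, population = NULL) {
  map <- utils::read.table(map_path, colClasses = "character")
  if (ncol(map) < 4L) stop(".map needs 4 columns (chr, name, cm, pos)")
  meta <- data.frame(name = map[[2L]], chromosome = map[[1L]],
                     position = as.numeric(map[[4L]]))
  ped <- utils::read.table(ped_path, colClasses = "character")
  m <- nrow(meta)
  if (ncol(ped) != 6L + 2L * m)
    stop(".ped column count does not match .map marker count")
  ids <- ped[[2L]]
  al1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  al2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  M <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, meta$name))
  for (j in seq_len(m)) {
    a <- c(al1[, j], al2[, j])
    obs <- sort(unique(a[a != "0"]))
    if (length(obs) > 2L)
      stop("marker ", meta$name[j], " has more than two alleles")
    alt <- obs[length(obs)]  # larger allele counted as dosage
    miss <- al1[, j] == "0" | al2[, j] == "0"
    M[, j] <- (al1[, j] == alt) + (al2[, j] == alt)
    M[miss, j] <- NA_real_
  }
  if (is.null(population)) population <- rep("POP", nrow(M))
  if (!is.null(names(population))) population <- population[ids]
  genotype_set(M, meta, population)
}
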