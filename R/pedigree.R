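#' Construct a validated pedigree
#'
#' Builds a topologically sorted pedigree from parallel vectors of animal,
#' sire and dam identifiers.  Unknown parents are encoded as `NA` (the string
#' `"0"` and empty strings are normalized to `NA` on input).  Parents that
#' appear only in the sire/dam columns are auto-added as founders.  Animals in
#' the base population are treated as unrelated; unknown-parent groups are not
#' used.
#'
#' @param id character or integer vector of animal identifiers (unique).
#' @param sire,dam parent identifiers, same length as `id`; `NA`/`"0"` =
#'   unknown.
#' @param population optional vector of population tags per animal (e.g.
#'   `"PB_SIRE"`, `"DAM"`, `"CB"`, `"PB"`, `"ANCESTOR"`); animals added as
#'   founders get `"ANCESTOR"`.
#' @return An object of class `pedigree`: a list with element `records`, a
#'   data.frame with columns `id`, `sire`, `dam`, `population`, `generation`
#'   (founders have generation 0), sorted so every parent precedes its
#'   offspring.
#' @export
pedigree <- function(id, sire, dam, population = NULL) {
  id   <- normalize_id(id)
  sire <- normalize_id(sire)
  dam  <- normalize_id(dam)
  if (anyNA(id)) stop("animal ids must be known (non-NA, non-zero)")
  if (anyDuplicated(id)) {
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  if (is.null(population)) population <- rep(NA_character_, length(id))
  population <- as.character(population)

  # auto-add parents never listed as animals, as founders
  parents <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(parents)) {
    id <- c(id, parents)
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam  <- c(dam,  rep(NA_character_, length(parents)))
    population <- c(population, rep("ANCESTOR", length(parents)))
  }

  ord <- ped_topo_sort(id, sire, dam)
  rec <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    population = population[ord],
                    stringsAsFactors = FALSE)
  gen <- integer(nrow(rec))
  pos <- seq_len(nrow(rec)); names(pos) <- rec$id
  for (i in seq_len(nrow(rec))) {
    gp <- c(rec$sire[i], rec$dam[i])
    gp <- gp[!is.na(gp)]
    gen[i] <- if (length(gp)) max(gen[pos[gp]]) + 1L else 0L
  }
  rec$generation <- gen
  structure(list(records = rec), class = "pedigree")
}

normalize_id <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "" | x == "." | x == "NA")] <- NA_character_
  x
}

# Kahn topological sort; stops with the offending cycle if one exists.
ped_topo_sort <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  parents <- lapply(seq_len(n), function(i) {
    p <- c(sire[i], dam[i]); pos[p[!is.na(p)]]
  })
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[[i]])
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- id[indeg > 0L]
    stop("pedigree contains a cycle (an animal is its own ancestor) ",
         "involving: ", paste(cyc, collapse = ", "))
  }
  out
}

#' Read a pedigree from a delimited text file
#'
#' Expects at least three whitespace- or comma-delimited columns: animal,
#' sire, dam; `"0"` encodes an unknown parent.  An optional fourth column
#' carries population tags.  Offspring may appear before their parents; the
#' result is topologically sorted.
#'
#' @param path path to the pedigree file.
#' @param header logical; does the file carry a header line?
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, header = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = header, sep = sep,
                           colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(tab) < 3L) stop("pedigree file needs >= 3 columns (animal sire dam)")
  pop <- if (ncol(tab) >= 4L) tab[[4L]] else NULL
  pedigree(tab[[1L]], tab[[2L]], tab[[3L]], population = pop)
}

#' @export
print.pedigree <- function(x, ...) {
  rec <- x$records
  cat(sprintf("pedigree: %d animals, %d founders, max generation %d\n",
              nrow(rec), sum(is.na(rec$sire) & is.na(rec$dam)),
              max(rec$generation)))
  invisible(x)
}

#' Restrict a pedigree to the ancestors of a set of animals
#'
#' Optionally prunes the trace to at most `generations` parent steps above
#' each seed animal (the default keeps every ancestor).
#'
#' @param ped a [pedigree].
#' @param ids animals whose ancestry to keep.
#' @param generations maximum number of generations to trace back
#'   (`Inf` = all).
#' @return A new [pedigree] containing `ids` and their (possibly truncated)
#'   ancestry; parents beyond the trace depth become unknown.
#' @export
trace_pedigree <- function(ped, ids, generations = Inf) {
  rec <- ped$records
  ids <- as.character(ids)
  stopifnot(all(ids %in% rec$id))
  pos <- seq_len(nrow(rec)); names(pos) <- rec$id
  depth <- rep(Inf, nrow(rec))
  depth[pos[ids]] <- 0
  # walk from youngest to oldest so child depths are final before parents
  for (i in rev(seq_len(nrow(rec)))) {
    if (!is.finite(depth[i]) || depth[i] >= generations) next
    for (p in c(rec$sire[i], rec$dam[i])) {
      if (!is.na(p)) depth[pos[p]] <- min(depth[pos[p]], depth[i] + 1)
    }
  }
  keep <- is.finite(depth)
  sub <- rec[keep, , drop = FALSE]
  kept <- sub$id
  sub$sire[!(sub$sire %in% kept)] <- NA_character_
  sub$dam [!(sub$dam  %in% kept)] <- NA_character_
  pedigree(sub$id, sub$sire, sub$dam, population = sub$population)
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes Wright's numerator relationship matrix A over the whole pedigree
#' using the tabular (recursive) method, with `a_ii = 1 + F_i` where `F_i` is
#' the inbreeding coefficient.  Base-population animals are unrelated and
#' non-inbred.
#'
#' @param ped a [pedigree].
#' @param subset optional vector of animal ids; the full-pedigree A is built
#'   and then restricted to these rows/columns (identical to slicing).
#' @return A `relmat` object: a symmetric numeric matrix with `ids` in
#'   dimnames and attribute `source = "A"`.
#' @export
build_A <- function(ped, subset = NULL) {
  rec <- ped$records
  n <- nrow(rec)
  pos <- seq_len(n); names(pos) <- rec$id
  si <- ifelse(is.na(rec$sire), 0L, pos[rec$sire])
  di <- ifelse(is.na(rec$dam),  0L, pos[rec$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[j, s]
      if (d > 0L) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(rec$id, rec$id)
  if (!is.null(subset)) {
    subset <- as.character(subset)
    if (!all(subset %in% rec$id))
      stop("subset contains ids absent from the pedigree")
    A <- A[subset, subset, drop = FALSE]
  }
  relmat(A, source = "A")
}

#' Relationship-matrix container
#'
#' Light wrapper asserting symmetry and carrying the matrix source tag
#' (`"A"`, `"G"` or `"H"`).
#'
#' @param values symmetric numeric matrix with ids as dimnames.
#' @param source one of `"A"`, `"G"`, `"H"`.
#' @return The matrix with class `relmat` and attribute `source`.
#' @export
relmat <- function(values, source = c("A", "G", "H")) {
  source <- match.arg(source)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    stop("relationship matrix needs animal ids as dimnames")
  if (max(abs(values - t(values))) > 1e-8)
    stop("relationship matrix is not symmetric")
  values <- (values + t(values)) / 2
  attr(values, "source") <- source
  class(values) <- c("relmat", "matrix")
  values
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix over %d animals\n",
              attr(x, "source"), nrow(x)))
  invisible(x)
}

#' Pedigree-based dissimilarities between sires
#'
#' Converts additive relationships into the metric
#' `d_ij = sqrt(a_ii + a_jj - 2 a_ij)`, i.e. the Euclidean distance induced
#' by the relationship inner product; `d` decreases as relatedness grows.
#' Small negative values under the root (numerical noise) are clamped at 0
#' with a warning.
#'
#' @param A a relationship matrix (from [build_A]) covering all `sire_ids`.
#' @param sire_ids identifiers of the sires to compare.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
sire_dissimilarity <- function(A, sire_ids) {
  sire_ids <- as.character(sire_ids)
  if (!all(sire_ids %in% rownames(A)))
    stop("sire_ids absent from the relationship matrix")
  a <- A[sire_ids, sire_ids, drop = FALSE]
  dg <- diag(a)
  d2 <- outer(dg, dg, "+") - 2 * a
  if (any(d2 < 0)) {
    if (any(d2 < -1e-8))
      warning("negative squared dissimilarities clamped to 0")
    d2[d2 < 0] <- 0
  }
  D <- sqrt(d2)
  diag(D) <- 0
  dimnames(D) <- list(sire_ids, sire_ids)
  D
}

#' K-means fold assignment of sires (and their offspring)
#'
#' Embeds the sire dissimilarity matrix by classical multidimensional
#' scaling (components kept until >= 99% of the positive-eigenvalue variance
#' is explained), then runs k-means with multiple restarts, keeping the best
#' solution by within-cluster sum of squares.  Paternal half-sib progeny
#' inherit their sire's fold, so validation folds split whole half-sib
#' families.
#'
#' @param D symmetric dissimilarity matrix over sires (see
#'   [sire_dissimilarity]).
#' @param n_folds number of folds/clusters (default 4).
#' @param seed integer seed making the assignment reproducible.
#' @param restarts number of random k-means initializations (default 50).
#' @param ped optional [pedigree]; when given, every animal whose sire is a
#'   clustered sire is assigned that sire's fold.
#' @return A `fold_assignment` object: list with `n_folds`, `sire_fold`
#'   (named integer vector) and `animal_fold` (named integer vector, possibly
#'   empty).
#' @export
kmeans_folds <- function(D, n_folds = 4L, seed = 1L, restarts = 50L,
                         ped = NULL) {
  sires <- rownames(D)
  if (is.null(sires)) stop("D needs sire ids as dimnames")
  if (n_folds > nrow(D)) stop("n_folds exceeds the number of sires")
  if (n_folds == nrow(D)) {
    cl <- seq_len(n_folds)
  } else {
    X <- cmdscale_99(D)
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    km <- suppressWarnings(
      stats::kmeans(X, centers = n_folds, nstart = as.integer(restarts),
                    iter.max = 100L))
    cl <- km$cluster
  }
  sire_fold <- as.integer(cl)
  names(sire_fold) <- sires
  if (length(unique(sire_fold)) < n_folds) stop("empty fold produced")
  animal_fold <- integer(0)
  if (!is.null(ped)) {
    rec <- ped$records
    hit <- !is.na(rec$sire) & rec$sire %in% sires
    animal_fold <- sire_fold[rec$sire[hit]]
    names(animal_fold) <- rec$id[hit]
  }
  structure(list(n_folds = as.integer(n_folds), sire_fold = sire_fold,
                 animal_fold = animal_fold),
            class = "fold_assignment")
}

# classical MDS keeping >=99% of positive-eigenvalue variance
cmdscale_99 <- function(D) {
  n <- nrow(D)
  full <- stats::cmdscale(stats::as.dist(D), k = n - 1L, eig = TRUE)
  ev <- full$eig[full$eig > 1e-10]
  if (!length(ev)) return(matrix(0, n, 1L))
  k <- which(cumsum(ev) / sum(ev) >= 0.99)[1L]
  full$points[, seq_len(max(k, 1L)), drop = FALSE]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold assignment: %d folds over %d sires (%d offspring mapped)\n",
              x$n_folds, length(x$sire_fold), length(x$animal_fold)))
  print(table(fold = x$sire_fold))
  invisible(x)
}

#' Write a fold assignment as two-column text
#'
#' @param folds a `fold_assignment`.
#' @param path output file path.
#' @export
write_folds <- function(folds, path) {
  all_ids <- c(names(folds$sire_fold), names(folds$animal_fold))
  all_fd  <- c(folds$sire_fold, folds$animal_fold)
  utils::write.table(data.frame(id = all_ids, fold = all_fd),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
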