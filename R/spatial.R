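## Radius-based neighborhood analysis.
##
## For chosen center and target phenotypes, count target cells whose
## centroid lies within a fixed radius (default 30 um) of every center
## cell. Conventions, all documented and deliberate:
##   * distance is Euclidean on centroids, boundary inclusive (d <= r);
##   * a center never counts itself, excluded by cell identity, so two
##     distinct cells at coincident coordinates are mutual neighbors;
##   * no edge correction by default -- centers near the core boundary
##     see truncated discs; an optional guard margin excludes centers
##     within r of a circular core boundary.

#' Build a grid spatial index over one core
#'
#' Uniform-grid bucketing of cell centroids; radius queries inspect only
#' the buckets overlapping the query disc, then filter by exact Euclidean
#' distance. Any query radius is supported regardless of `bin`.
#'
#' @param core a [core_table] (or a data.frame with `cell_id`, `x`, `y`).
#' @param bin bucket edge length in micrometres.
#' @return a `spatial_index` object.
#' @export
build_index <- function(core, bin = 30) {
  cells <- if (inherits(core, "core_table")) core$cells else core
  stopifnot(bin > 0)
  n <- nrow(cells)
  if (n) {
    ix <- floor(cells$x / bin); iy <- floor(cells$y / bin)
    key <- paste(ix, iy)
    buckets <- split(seq_len(n), key)
  } else buckets <- list()
  structure(list(x = cells$x, y = cells$y, cell_id = cells$cell_id,
                 bin = bin, buckets = buckets, n = n),
            class = "spatial_index")
}

#' Radius query against a spatial index
#'
#' @param index a [build_index()] result.
#' @param px,py query point (micrometres).
#' @param r radius; cells at distance exactly `r` are included.
#' @return integer row indices of in-range cells, ordered by cell id.
#' @export
query_index <- function(index, px, py, r) {
  if (!index$n) return(integer())
  b <- index$bin
  kx <- floor((px - r) / b):floor((px + r) / b)
  ky <- floor((py - r) / b):floor((py + r) / b)
  keys <- as.vector(outer(kx, ky, paste))
  cand <- unlist(index$buckets[keys], use.names = FALSE)
  if (!length(cand)) return(integer())
  d2 <- (index$x[cand] - px)^2 + (index$y[cand] - py)^2
  hit <- cand[d2 <= r * r]
  hit[order(index$cell_id[hit])]
}

## Per-cell neighbor flag counts: n x length(flags) integer matrix,
## M[i, f] = number of OTHER cells with flag f within radius of cell i.
## Same uniform-grid scheme as build_index, vectorised bucket-by-bucket:
## cells of one bucket are compared against the 3x3 surrounding buckets
## in one distance-matrix operation. Self-exclusion is by identity (the
## cell's own flag row is subtracted), so coincident distinct cells
## remain mutual neighbors.
neighbor_flag_matrix <- function(core, flags, radius) {
  cells <- core$cells
  n <- nrow(cells)
  M <- matrix(0, n, length(flags), dimnames = list(cells$cell_id, flags))
  if (!n) return(M)
  fm <- vapply(flags, function(f) {
    if (!f %in% names(cells)) stopf("unknown phenotype flag '%s'", f)
    as.numeric(!is.na(cells[[f]]) & cells[[f]])
  }, numeric(n))
  fm <- matrix(fm, nrow = n)
  x <- cells$x; y <- cells$y
  r2 <- radius^2
  ix <- floor(x / radius); iy <- floor(y / radius)
  key <- paste(ix, iy)
  buckets <- split(seq_len(n), key)
  for (b in names(buckets)) {
    me <- buckets[[b]]
    k <- as.integer(strsplit(b, " ", fixed = TRUE)[[1]])
    nbkeys <- as.vector(outer(k[1] + (-1:1), k[2] + (-1:1), paste))
    cand <- unlist(buckets[nbkeys], use.names = FALSE)
    d2 <- outer(x[me], x[cand], "-")^2 + outer(y[me], y[cand], "-")^2
    A <- (d2 <= r2) * 1
    M[me, ] <- A %*% fm[cand, , drop = FALSE] - fm[me, , drop = FALSE]
  }
  M
}

guard_keep <- function(core, radius) {
  g <- core$geometry
  if (is.null(g))
    stopf("guard margin requires circular core geometry on core '%s'",
          core$core_id)
  d <- sqrt((core$cells$x - g$center[1])^2 + (core$cells$y - g$center[2])^2)
  d <= g$radius - radius
}

#' In-range neighbor counts around center cells of one phenotype
#'
#' The central operation: for every cell carrying the center phenotype
#' flag, count the cells of each target phenotype within `radius`.
#'
#' @param core a [core_table].
#' @param center_phenotype flag column naming the index (center) cells.
#' @param target_phenotypes character vector of target flag columns.
#' @param radius micrometres (default 30).
#' @param guard_margin if `TRUE`, exclude centers closer than `radius` to
#'   the circular core boundary (requires core geometry); default `FALSE`,
#'   matching uncorrected whole-core analysis.
#' @return a `neighborhood_result`: list with `per_center` (data.frame
#'   `cell_id` + one count column per target), `summary` (per target:
#'   mean, min, max), `n_centers`, and the query parameters.
#' @export
neighbor_counts <- function(core, center_phenotype, target_phenotypes,
                            radius = 30, guard_margin = FALSE) {
  stopifnot(inherits(core, "core_table"), radius > 0)
  if (!center_phenotype %in% names(core$cells))
    stopf("unknown phenotype flag '%s'", center_phenotype)
  M <- neighbor_flag_matrix(core, target_phenotypes, radius)
  keep <- !is.na(core$cells[[center_phenotype]]) & core$cells[[center_phenotype]]
  if (guard_margin) keep <- keep & guard_keep(core, radius)
  Mc <- M[keep, , drop = FALSE]
  summ <- data.frame(
    target = target_phenotypes,
    mean = if (nrow(Mc)) colMeans(Mc) else rep(NA_real_, ncol(Mc)),
    min = if (nrow(Mc)) apply(Mc, 2, min) else rep(NA_real_, ncol(Mc)),
    max = if (nrow(Mc)) apply(Mc, 2, max) else rep(NA_real_, ncol(Mc)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_center = data.frame(cell_id = core$cells$cell_id[keep],
                                         Mc, check.names = FALSE,
                                         stringsAsFactors = FALSE),
                 summary = summ, n_centers = sum(keep),
                 center_phenotype = center_phenotype, radius = radius,
                 core_id = core$core_id),
            class = "neighborhood_result")
}

#' @export
print.neighborhood_result <- function(x, ...) {
  cat(sprintf("<neighborhood_result> core %s: %d %s centers, r = %g um\n",
              x$core_id, x$n_centers, x$center_phenotype, x$radius))
  print(x$summary, ...)
  invisible(x)
}

#' Center-by-target clustering matrices over a cohort
#'
#' Computes, for every (center phenotype, target phenotype) pair, the mean
#' in-range count at three aggregation levels: per core, per patient
#' (unweighted mean over that patient's replicate cores), and pooled (all
#' center cells pooled across cores, the level at which per-center
#' distributions are compared between groups). A phenotype with no center
#' cells anywhere yields `NA`, never 0 - absence of centers is not
#' evidence of zero clustering.
#'
#' @param tables list of [core_table] objects.
#' @param phenotypes flag columns used as both centers and targets.
#' @param radius micrometres.
#' @return a `clustering_result`: `pooled` and `patient_mean` matrices
#'   (centers as rows, targets as columns), `per_patient` (named list of
#'   matrices), `per_center` (long data.frame), and `report` on cores
#'   contributing no centers.
#' @export
clustering_matrix <- function(tables, phenotypes = c("CD3", "CD8", "NKp46"),
                              radius = 30) {
  if (inherits(tables, "core_table")) tables <- list(tables)
  if (!length(tables)) stopf("no cores supplied")
  k <- length(phenotypes)
  per_core <- list(); long <- list()
  sum_pool <- matrix(0, k, k, dimnames = list(phenotypes, phenotypes))
  n_pool <- matrix(0L, k, k, dimnames = list(phenotypes, phenotypes))
  empty_report <- list()
  for (tb in tables) {
    M <- neighbor_flag_matrix(tb, phenotypes, radius)
    cm <- matrix(NA_real_, k, k, dimnames = list(phenotypes, phenotypes))
    for (p in phenotypes) {
      keep <- !is.na(tb$cells[[p]]) & tb$cells[[p]]
      nc <- sum(keep)
      if (nc) {
        cm[p, ] <- colMeans(M[keep, , drop = FALSE])
        sum_pool[p, ] <- sum_pool[p, ] + colSums(M[keep, , drop = FALSE])
        n_pool[p, ] <- n_pool[p, ] + nc
        long[[length(long) + 1L]] <- data.frame(
          core_id = tb$core_id, patient_id = tb$patient_id,
          center_cell_id = rep(tb$cells$cell_id[keep], k),
          center_type = p,
          target_type = rep(phenotypes, each = nc),
          radius = radius, count = as.vector(M[keep, , drop = FALSE]),
          stringsAsFactors = FALSE)
      } else {
        empty_report[[length(empty_report) + 1L]] <-
          data.frame(core_id = tb$core_id, center_type = p,
                     stringsAsFactors = FALSE)
      }
    }
    per_core[[length(per_core) + 1L]] <-
      list(core_id = tb$core_id, patient_id = tb$patient_id, matrix = cm)
  }
  pats <- unique(vapply(per_core, function(z) z$patient_id, ""))
  per_patient <- lapply(pats, function(p) {
    ms <- lapply(Filter(function(z) z$patient_id == p, per_core),
                 function(z) z$matrix)
    apply(simplify2array(ms), c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  })
  names(per_patient) <- pats
  patient_mean <- apply(simplify2array(per_patient), c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  pooled <- sum_pool / n_pool
  pooled[n_pool == 0L] <- NA_real_
  structure(list(pooled = pooled, patient_mean = patient_mean,
                 per_patient = per_patient,
                 per_center = if (length(long)) do.call(rbind, long) else NULL,
                 n_centers_pooled = n_pool,
                 report = if (length(empty_report))
                   do.call(rbind, empty_report) else NULL,
                 phenotypes = phenotypes, radius = radius),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> r = %g um, %d patients; pooled mean in-range counts (center rows, target columns):\n",
              x$radius, length(x$per_patient)))
  print(round(x$pooled, 2))
  invisible(x)
}

#' Paired per-center counts of two target phenotypes
#'
#' For each center cell of one phenotype, records the in-range counts of
#' two target phenotypes as a pair, feeding a paired comparison (e.g. NK
#' versus CD3 counts around NK centers).
#'
#' @inheritParams clustering_matrix
#' @param center_phenotype center flag column.
#' @param target_a,target_b the two target flag columns.
#' @param radius micrometres.
#' @return data.frame: `core_id, patient_id, cell_id, count_a, count_b`.
#' @export
paired_in_range <- function(tables, center_phenotype, target_a, target_b,
                            radius = 30) {
  if (inherits(tables, "core_table")) tables <- list(tables)
  out <- lapply(tables, function(tb) {
    nc <- neighbor_counts(tb, center_phenotype,
                          unique(c(target_a, target_b)), radius)
    data.frame(core_id = tb$core_id, patient_id = tb$patient_id,
               cell_id = nc$per_center$cell_id,
               count_a = nc$per_center[[target_a]],
               count_b = nc$per_center[[target_b]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partition centers by a flag and count neighbors in each partition
#'
#' Splits all cells of a cohort into flag-positive and flag-negative
#' centers (e.g. MHC-I status) and computes in-range target counts for
#' each partition. Every cell with a defined flag is a center exactly
#' once; cells with an undefined flag are excluded and counted.
#'
#' @inheritParams clustering_matrix
#' @param flag flag column defining the partition (default `"MHC1"`).
#' @param target_phenotypes target flag columns.
#' @param radius micrometres.
#' @param restrict_to optional flag column: only cells also positive for
#'   this flag are eligible centers (e.g. restrict MHC-I centers to tumor
#'   cells). `NULL` (default) uses all cells.
#' @return list with `pos` and `neg` (each: pooled `summary` data.frame
#'   and `n_centers`), plus `n_excluded`.
#' @export
partition_centers_by_flag <- function(tables, flag = "MHC1",
                                      target_phenotypes = c("CD3", "CD8", "NKp46"),
                                      radius = 30, restrict_to = NULL) {
  if (inherits(tables, "core_table")) tables <- list(tables)
  acc <- list(pos = NULL, neg = NULL)
  n_centers <- c(pos = 0L, neg = 0L)
  n_excl <- 0L
  for (tb in tables) {
    if (!flag %in% names(tb$cells))
      stopf("flag '%s' absent from core '%s'", flag, tb$core_id)
    M <- neighbor_flag_matrix(tb, target_phenotypes, radius)
    fv <- tb$cells[[flag]]
    elig <- rep(TRUE, nrow(tb$cells))
    if (!is.null(restrict_to))
      elig <- !is.na(tb$cells[[restrict_to]]) & tb$cells[[restrict_to]]
    n_excl <- n_excl + sum(is.na(fv) & elig)
    for (side in c("pos", "neg")) {
      keep <- elig & !is.na(fv) & (if (side == "pos") fv else !fv)
      if (any(keep)) {
        acc[[side]] <- rbind(acc[[side]], M[keep, , drop = FALSE])
        n_centers[[side]] <- n_centers[[side]] + sum(keep)
      }
    }
  }
  mk <- function(side) {
    Mc <- acc[[side]]
    list(summary = data.frame(
           target = target_phenotypes,
           mean = if (!is.null(Mc)) colMeans(Mc) else rep(NA_real_, length(target_phenotypes)),
           min = if (!is.null(Mc)) apply(Mc, 2, min) else NA_real_,
           max = if (!is.null(Mc)) apply(Mc, 2, max) else NA_real_,
           row.names = NULL, stringsAsFactors = FALSE),
         n_centers = n_centers[[side]])
  }
  list(pos = mk("pos"), neg = mk("neg"), n_excluded = n_excl,
       flag = flag, radius = radius)
}

#' Correlation between a marker expression score and a cell density
#'
#' Pearson correlation between a per-patient expression score (e.g. the
#' MHC-I positive fraction or H-score) and a phenotype's cell density in
#' cells per square millimetre, averaged over each patient's cores.
#'
#' @inheritParams clustering_matrix
#' @param phenotype flag column whose density is correlated.
#' @param expression_scores data.frame with `patient_id` and `value`.
#' @return the [pearson_cor()] result (`r`, `p_value`, `n`, ...).
#' @export
density_expression_correlation <- function(tables, phenotype,
                                           expression_scores) {
  dens <- marker_scores(tables, phenotype, "density_per_mm2")
  m <- merge(dens[, c("patient_id", "value")], expression_scores,
             by = "patient_id", suffixes = c("_density", "_expr"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stopf("need >= 3 patients with defined values (have %d)",
                         nrow(m))
  pearson_cor(m$value_expr, m$value_density)
}
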