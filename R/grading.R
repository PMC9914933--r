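#' Min-max normalization of the indicator space
#'
#' Maps each indicator coordinate to \code{(x - min) / (max - min)}.  In
#' fit mode (\code{params = NULL}) the extrema are taken from the data
#' and the result lies in [0, 1]; in transform mode previously fitted
#' extrema are reused and out-of-range points may map outside [0, 1]
#' (they are deliberately not clipped, so distances stay faithful).
#'
#' @param x numeric matrix, points in rows.
#' @param params \code{NULL} (fit) or a list with numeric vectors
#'   \code{min} and \code{max} per column (transform).
#' @return list with \code{points} (normalized matrix) and \code{params}.
#' @export
minMaxNormalize <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (is.null(params)) {
    params <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  }
  rng <- params$max - params$min
  if (any(rng <= 0))
    stop("degenerate indicator: max equals min, cannot normalize")
  pts <- sweep(sweep(x, 2, params$min), 2, rng, "/")
  list(points = pts, params = params)
}

# Distance of every point to one point (Euclidean).
.dist_to <- function(x, y) sqrt(rowSums(sweep(x, 2, y)^2))

#' K-medoids clustering by randomized cost-decreasing swaps
#'
#' Partitions points around k medoids (cluster centers that are dataset
#' points) with the classical randomized swap scheme: k random initial
#' medoids; repeatedly propose replacing a random medoid with a random
#' non-medoid and accept the swap iff the total cost (sum of Euclidean
#' distances of every point to its nearest medoid) strictly decreases;
#' stop after \code{maxStall} consecutive rejected proposals.  The best
#' of \code{nRestarts} independently seeded restarts is returned.  Ties
#' in nearest-medoid assignment break toward the lowest medoid index, so
#' results are deterministic for a fixed seed.
#'
#' @param x numeric matrix of points (rows).
#' @param k number of clusters, \code{k <= nrow(x)}.
#' @param seed integer master seed.
#' @param nRestarts independent restarts (best cost kept).
#' @param maxStall consecutive rejected swap proposals that end a
#'   restart; default \code{200 * k}.
#' @param distMatrix optional precomputed n x n Euclidean distance
#'   matrix (avoids recomputation across repeated calls on one dataset).
#' @return list with \code{medoids} (row indices), \code{assignment}
#'   (integer cluster per point, clusters numbered by medoid slot),
#'   \code{cost} (total distance).
#' @export
kMedoids <- function(x, k, seed = 1L, nRestarts = 20L, maxStall = 200L * k,
                     distMatrix = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of points")
  if (k > nrow(unique(x))) stop("k must not exceed the number of distinct points")
  seeds <- .derive_seeds(seed, nRestarts)
  # pairwise distances once per call; every proposal then just reads a column
  DF <- if (is.null(distMatrix)) as.matrix(stats::dist(x)) else distMatrix
  best <- NULL
  for (r in seq_len(nRestarts)) {
    sol <- .with_seed(seeds[r], .kmedoids_once(DF, k, maxStall))
    if (is.null(best) || sol$cost < best$cost - 1e-12) best <- sol
  }
  D <- DF[, best$medoids, drop = FALSE]
  assignment <- max.col(-D, ties.method = "first")
  list(medoids = best$medoids, assignment = assignment, cost = best$cost)
}

.kmedoids_once <- function(DF, k, maxStall) {
  n <- nrow(DF)
  med <- sample.int(n, k)
  # minExcl[, j]: distance to the nearest medoid when slot j is removed,
  # so evaluating a proposed swap is a single pmin + sum
  minExcl <- function(med) {
    sapply(seq_len(k), function(j) {
      if (k == 1) return(rep(Inf, n))
      do.call(pmin, lapply(med[-j], function(m) DF[, m]))
    })
  }
  ME <- minExcl(med)
  cost <- sum(do.call(pmin, lapply(med, function(m) DF[, m])))
  stall <- 0L
  while (stall < maxStall) {
    y <- sample.int(n, 1)
    if (y %in% med) { stall <- stall + 1L; next }
    slot <- sample.int(k, 1)
    newCost <- sum(pmin(ME[, slot], DF[, y]))
    if (newCost < cost - 1e-12) {
      med[slot] <- y
      ME <- minExcl(med)
      cost <- newCost
      stall <- 0L
    } else stall <- stall + 1L
  }
  list(medoids = med, cost = cost)
}

#' Mean silhouette coefficient of a clustering
#'
#' For every point, \code{s = (b - a) / max(a, b)} with \code{a} the mean
#' distance to its own cluster (excluding itself) and \code{b} the
#' smallest mean distance to any other cluster; points in singleton
#' clusters score 0.  Returns the mean over all points, in [-1, 1].
#'
#' @param x numeric matrix of points (rows); Euclidean distances.
#' @param assignment integer or factor cluster labels, >= 2 clusters,
#'   each non-empty.
#' @param distMatrix optional precomputed n x n distance matrix.
#' @return mean silhouette width.
#' @export
silhouetteScore <- function(x, assignment, distMatrix = NULL) {
  x <- as.matrix(x)
  cl <- as.integer(factor(assignment))
  k <- max(cl)
  if (k < 2) stop("silhouette requires at least two clusters")
  n <- nrow(x)
  D <- if (is.null(distMatrix)) as.matrix(stats::dist(x)) else distMatrix
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), cl)] <- 1
  sums <- D %*% Z                       # n x k: summed distance to each cluster
  sizes <- colSums(Z)
  a <- sums[cbind(seq_len(n), cl)] / pmax(sizes[cl] - 1, 1)
  meanTo <- sweep(sums, 2, sizes, "/")
  meanTo[cbind(seq_len(n), cl)] <- Inf
  b <- apply(meanTo, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[cl] == 1] <- 0
  mean(s)
}

#' Grade the indicator space into risk levels
#'
#' Normalizes the (NIPI, THQ, TCR) points (fit mode), clusters them with
#' \code{\link{kMedoids}} for every candidate cluster count, selects the
#' count with the largest mean silhouette, and orders the chosen cluster
#' centers by their Euclidean distance from the origin of the normalized
#' space: the nearest center is the lowest risk level.  For k = 3 the
#' levels are named Low, Medium, High; otherwise L1..Lk.
#'
#' @param x an \code{\link{IndicatorExperiment}} or an n x 3 matrix of
#'   indicator points in original units.
#' @param kCandidates integer vector of candidate cluster counts.
#' @param seed integer master seed.
#' @param nRestarts K-medoids restarts per candidate.
#' @return a \code{\link{RiskLevelSpace}}.
#' @export
gradeRiskSpace <- function(x, kCandidates = 2:7, seed = 1L, nRestarts = 20L) {
  pts0 <- if (is(x, "IndicatorExperiment")) indicatorMatrix(x) else as.matrix(x)
  if (nrow(pts0) < max(kCandidates))
    stop("need at least max(kCandidates) points")
  norm <- minMaxNormalize(pts0)
  pts <- norm$points
  seeds <- .derive_seeds(seed, length(kCandidates))
  sil <- stats::setNames(numeric(length(kCandidates)), kCandidates)
  fits <- vector("list", length(kCandidates))
  DF <- as.matrix(stats::dist(pts))
  for (i in seq_along(kCandidates)) {
    fits[[i]] <- kMedoids(pts, kCandidates[i], seed = seeds[i],
                          nRestarts = nRestarts, distMatrix = DF)
    sil[i] <- silhouetteScore(pts, fits[[i]]$assignment, distMatrix = DF)
  }
  bestI <- which.max(sil)               # ties break toward the smaller k
  k <- as.integer(kCandidates[bestI])
  fit <- fits[[bestI]]
  ctr <- pts[fit$medoids, , drop = FALSE]
  ord <- order(sqrt(rowSums(ctr^2)))
  levels <- if (k == 3) c("Low", "Medium", "High") else paste0("L", seq_len(k))
  ctr <- ctr[ord, , drop = FALSE]
  rownames(ctr) <- levels
  ctrOrig <- sweep(sweep(ctr, 2, norm$params$max - norm$params$min, "*"),
                   2, norm$params$min, "+")
  relabel <- match(fit$assignment, ord)
  new("RiskLevelSpace", k = k, centers = ctr, centersOriginal = ctrOrig,
      levels = levels, silhouetteByK = sil, normalization = norm$params,
      assignment = factor(levels[relabel], levels = levels),
      medoids = as.integer(fit$medoids[ord]), cost = fit$cost)
}

#' Write/read a risk level space as a JSON artifact
#'
#' Serialises the centers (normalized and original units), level order,
#' silhouette table and normalization parameters so that downstream level
#' assignment can run without refitting.
#'
#' @param space a \code{\link{RiskLevelSpace}}.
#' @param path JSON file path.
#' @return \code{readRiskLevelSpace} returns a \code{RiskLevelSpace}
#'   (with an empty assignment: only what level assignment needs is kept).
#' @export
writeRiskLevelSpace <- function(space, path) {
  obj <- list(k = space@k, levels = space@levels,
              centers = space@centers, centersOriginal = space@centersOriginal,
              silhouetteByK = as.list(space@silhouetteByK),
              normalization = lapply(space@normalization, as.list),
              assignmentCounts = as.list(table(space@assignment)),
              cost = space@cost)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRiskLevelSpace
#' @export
readRiskLevelSpace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nrm <- lapply(obj$normalization, unlist)
  ctr <- as.matrix(obj$centers)
  ctrO <- as.matrix(obj$centersOriginal)
  dimnames(ctr) <- dimnames(ctrO) <- list(obj$levels, names(nrm$min))
  new("RiskLevelSpace", k = as.integer(obj$k), centers = ctr,
      centersOriginal = ctrO, levels = obj$levels,
      silhouetteByK = unlist(obj$silhouetteByK),
      normalization = nrm,
      assignment = factor(character(0), levels = obj$levels),
      medoids = integer(0), cost = as.numeric(obj$cost))
}
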