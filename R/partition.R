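#' Uniform interior point sampling
#'
#' Rejection sampling: proposals are drawn uniformly in the axis-aligned
#' bounding box and kept when the winding-number inside test accepts them.
#' The result is exactly `n` points uniformly distributed in the enclosed
#' volume.
#'
#' @param mesh a [volume_mesh()].
#' @param n number of points to return.
#' @param seed integer RNG seed; a fixed seed reproduces the cloud bit-exactly.
#' @return a tibble with columns `x`, `y`, `z` (mm); attributes `seed`,
#'   `n_proposed` and `n_accepted` (rejection-loop diagnostics; their ratio
#'   estimates the volume-to-bounding-box ratio).
#' @export
sample_interior <- function(mesh, n, seed = 1L) {
  stopifnot(n >= 0)
  if (mesh_volume(mesh) <= 0) stop("degenerate mesh: zero enclosed volume",
                                   call. = FALSE)
  bb <- mesh_bbox(mesh)
  lo <- bb[1, ]; span <- bb[2, ] - bb[1, ]
  if (any(span <= 0)) stop("degenerate mesh: flat bounding box", call. = FALSE)
  pts <- matrix(numeric(0), 0, 3)
  n_prop <- 0L
  n_acc <- 0L
  if (n > 0) {
    rng <- local_rng(seed)
    # expected acceptance = volume / bbox volume; batch with head-room
    p_acc <- max(mesh_volume(mesh) / prod(span), 1e-3)
    while (nrow(pts) < n) {
      m <- ceiling((n - nrow(pts)) / p_acc * 1.2) + 32L
      prop <- cbind(rng$runif(m) * span[1] + lo[1],
                    rng$runif(m) * span[2] + lo[2],
                    rng$runif(m) * span[3] + lo[3])
      n_prop <- n_prop + m
      keep <- points_inside(mesh, prop)
      n_acc <- n_acc + sum(keep)
      pts <- rbind(pts, prop[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
  }
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  attr(out, "seed") <- seed
  attr(out, "n_proposed") <- n_prop
  attr(out, "n_accepted") <- n_acc
  out
}

# private RNG stream that leaves the global .Random.seed untouched
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(runif = with_state(stats::runif),
       sample_int = with_state(function(n, size, prob = NULL) sample.int(n, size, prob = prob)),
       rnorm = with_state(stats::rnorm))
}

#' Partition an interior point cloud into super lobules
#'
#' k-means (k-means++ seeding, multiple restarts, Hartigan-Wong iteration via
#' [stats::kmeans()]) on the uniform cloud yields clusters of roughly equal
#' volume; the cluster centroids become the super-lobule centres and the
#' target attractors for vascular growth.
#'
#' @param cloud tibble with `x`, `y`, `z` from [sample_interior()].
#' @param k number of super lobules (1 <= k <= number of points).
#' @param seed integer RNG seed.
#' @param nstart number of k-means++ restarts (best total within-cluster
#'   sum of squares wins).
#' @return a list of class `sl_partition`: `k`, `centroids` (tibble
#'   `sl_id`, `x`, `y`, `z`), `assignment` (integer per point), `sizes`,
#'   `size_cv` (coefficient of variation of cluster sizes), `tot_withinss`.
#' @export
partition_super_lobules <- function(cloud, k, seed = 1L, nstart = 10L) {
  pts <- as.matrix(cloud[, c("x", "y", "z")])
  n <- nrow(pts)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")", call. = FALSE)
  rng <- local_rng(seed)
  if (k == n) {
    assignment <- seq_len(n)
    centroids <- pts
    tot_w <- 0
  } else {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- kmeanspp_centers(pts, k, rng)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(pts, centers = centers,
                                       iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(fit)) next
      fit <- fix_empty_clusters(fit, pts, k)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed to converge on any restart", call. = FALSE)
    assignment <- best$cluster
    centroids <- best$centers
    tot_w <- best$tot.withinss
  }
  sizes <- tabulate(assignment, nbins = k)
  structure(list(
    k = as.integer(k),
    centroids = tibble::tibble(sl_id = seq_len(k),
                               x = centroids[, 1], y = centroids[, 2],
                               z = centroids[, 3]),
    assignment = as.integer(assignment),
    sizes = sizes,
    size_cv = stats::sd(sizes) / mean(sizes),
    tot_withinss = tot_w,
    seed = as.integer(seed)),
    class = "sl_partition")
}

#' @export
print.sl_partition <- function(x, ...) {
  cat(sprintf("<sl_partition> k = %d, %d points, size CV = %.3f\n",
              x$k, length(x$assignment), x$size_cv))
  invisible(x)
}

# k-means++ seeding: centers drawn with probability proportional to squared
# distance from the nearest already-chosen center
kmeanspp_centers <- function(pts, k, rng) {
  n <- nrow(pts)
  idx <- integer(k)
  idx[1] <- rng$sample_int(n, 1L)
  d2 <- rowSums(sweep(pts, 2, pts[idx[1], ], "-")^2)
  for (j in seq_len(k - 1L)) {
    prob <- d2 / sum(d2)
    idx[j + 1L] <- rng$sample_int(n, 1L, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[idx[j + 1L], ], "-")^2))
  }
  pts[idx, , drop = FALSE]
}

# reseat any empty cluster at the point farthest from its assigned center
fix_empty_clusters <- function(fit, pts, k) {
  sizes <- tabulate(fit$cluster, nbins = k)
  while (any(sizes == 0L)) {
    empty <- which(sizes == 0L)[1]
    d2 <- rowSums((pts - fit$centers[fit$cluster, , drop = FALSE])^2)
    far <- which.max(d2)
    fit$centers[empty, ] <- pts[far, ]
    fit <- suppressWarnings(stats::kmeans(pts, centers = fit$centers,
                                          iter.max = 100L))
    sizes <- tabulate(fit$cluster, nbins = k)
  }
  fit
}

#' Super-lobule volume budget
#'
#' The super lobules jointly account for all blood-carrying volume that is
#' not explicitly modeled as vessels: `V_SL_total = V_blood - V_vessels`,
#' shared equally: `V_SL_individual = V_SL_total / n_SL`.
#'
#' @param V_blood total blood volume in the system (mm^3).
#' @param V_vessels total volume of the explicitly modeled vessels (mm^3).
#' @param n_SL number of super lobules.
#' @return a tibble with one row: `V_blood`, `V_vessels`, `V_SL_total`,
#'   `V_SL_individual`, `n_SL`.
#' @export
compute_volume_budget <- function(V_blood, V_vessels, n_SL) {
  stopifnot(n_SL >= 1, V_vessels >= 0)
  if (V_vessels >= V_blood) {
    stop("modeled vessels exceed blood volume (V_vessels = ", V_vessels,
         " >= V_blood = ", V_blood, ")", call. = FALSE)
  }
  V_SL_total <- V_blood - V_vessels
  tibble::tibble(V_blood = V_blood, V_vessels = V_vessels,
                 V_SL_total = V_SL_total,
                 V_SL_individual = V_SL_total / n_SL,
                 n_SL = as.integer(n_SL))
}
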