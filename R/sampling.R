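#' Farthest point sampling
#'
#' Greedy max-min selection: the first point is `start` (or chosen
#' uniformly at random under `seed`), and each subsequent point is the one
#' maximizing its minimum Euclidean distance to the already-selected set.
#' The nearest-selected distance of every point is updated incrementally,
#' giving O(Mn) distance evaluations for M source points.  Ties are broken
#' by the lowest index, so the result is deterministic given the start
#' point.
#'
#' @param coords numeric N x 3 matrix, or a [plant_cloud].
#' @param n number of points to select, `1 <= n <= N`.
#' @param seed integer seed used to pick the start point when `start` is
#'   not given.
#' @param start optional 1-based index of the first selected point.
#' @return integer vector of `n` unique 1-based indices, in selection
#'   order.
#' @examples
#' x <- cbind(c(0, 1, 4, 9, 10), 0, 0)
#' fps(x, 3, start = 1)  # 1, 5, 3
#' @export
fps <- function(coords, n, seed = NULL, start = NULL) {
  if (inherits(coords, "plant_cloud")) coords <- coords$coords
  coords <- as.matrix(coords)
  N <- nrow(coords)
  if (N < 1L) stop_data("empty point set")
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > N)
    stop_data("n must lie in [1, ", N, "], got ", n)
  if (is.null(start)) start <- with_seed(seed, sample.int(N, 1L))
  start <- as.integer(start)
  if (start < 1L || start > N) stop_data("start index out of range")
  .fps_cpp(coords, n, start - 1L) + 1L
}

#' Sequential random sampling without replacement
#'
#' One-pass uniform sampling of `n` of `N` sequence positions: at each
#' selection a skip count S is drawn from its exact distribution by drawing
#' one uniform variate V and finding the smallest s whose cumulative
#' permutation-ratio condition is met; the ratio is accumulated as an
#' incremental product of factors `(N'-m-j)/(N'-j)` so no factorials are
#' ever formed.  Every n-subset is equally likely, and the returned indices
#' are strictly increasing (the scan travels the sequence once, one way).
#'
#' @param N source sequence length.
#' @param n number of positions to sample, `1 <= n <= N`.
#' @param seed integer seed.
#' @return strictly increasing integer vector of `n` 1-based indices.
#' @export
rs <- function(N, n, seed = NULL) {
  N <- as.integer(N); n <- as.integer(n)
  if (is.na(n) || n < 1L || n > N)
    stop_data("n must lie in [1, ", N, "], got ", n)
  with_seed(seed, {
    out <- integer(n)
    pos <- 0L   # last visited position in the original sequence
    Np <- N     # points not yet visited
    m <- n      # points still to sample
    k <- 0L
    while (m > 0L) {
      V <- runif(1)
      s <- 0L
      p <- (Np - m) / Np
      while (p > V) {
        s <- s + 1L
        p <- p * (Np - m - s) / (Np - s)
      }
      pos <- pos + s + 1L
      k <- k + 1L
      out[k] <- pos
      Np <- Np - s - 1L
      m <- m - 1L
    }
    out
  })
}

#' Voxel grid specification
#'
#' @param l positive voxel edge length(s): one value for cubic voxels or
#'   three for `(l_x, l_y, l_z)`, in the units of the coordinates.
#' @param origin optional 3-vector anchoring the grid; default: the
#'   per-axis minimum of the cloud being voxelized.
#' @return an object of class `voxel_spec`.
#' @export
voxel_spec <- function(l, origin = NULL) {
  l <- as.numeric(l)
  if (length(l) == 1L) l <- rep(l, 3L)
  if (length(l) != 3L || anyNA(l) || any(l <= 0))
    stop_data("voxel edge lengths must be positive (one or three values)")
  if (!is.null(origin)) {
    origin <- as.numeric(origin)
    if (length(origin) != 3L || anyNA(origin))
      stop_data("origin must be a finite 3-vector")
  }
  structure(list(l = l, origin = origin), class = "voxel_spec")
}

#' Assign points to voxels
#'
#' Point p belongs to the half-open cell
#' `(floor((p_x - o_x)/l_x), floor((p_y - o_y)/l_y), floor((p_z - o_z)/l_z))`,
#' so every point falls in exactly one voxel.
#'
#' @param coords numeric N x 3 matrix or [plant_cloud].
#' @param spec a [voxel_spec].
#' @return a list with `groups` (named list mapping voxel key to member
#'   point indices), `key` (N x 3 integer matrix of cell coordinates),
#'   `gid` (integer group id per point, indexing `groups`), and `spec`
#'   (the spec with its origin resolved).
#' @export
voxelize <- function(coords, spec) {
  if (inherits(coords, "plant_cloud")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(inherits(spec, "voxel_spec"))
  origin <- if (is.null(spec$origin)) apply(coords, 2L, min) else spec$origin
  key <- floor(sweep(sweep(coords, 2L, origin), 2L, spec$l, "/"))
  storage.mode(key) <- "integer"
  id <- paste(key[, 1], key[, 2], key[, 3])
  fid <- factor(id, levels = unique(id))  # first-appearance order
  groups <- split(seq_len(nrow(coords)), fid)
  list(groups = groups, key = key, gid = as.integer(fid),
       spec = voxel_spec(spec$l, origin))
}

# shared voxel-stage plumbing: returns list(vx, counts, centers_per_point)
.voxel_stage <- function(cloud, spec, n) {
  if (is.null(spec)) spec <- auto_voxel_size(cloud$coords, n)
  vx <- voxelize(cloud$coords, spec)
  if (length(vx$groups) < n)
    stop_data("only ", length(vx$groups), " occupied voxels for n = ", n,
              "; use a smaller voxel size or auto_voxel_size()")
  vx
}

#' Uniform voxel sampling (UVS)
#'
#' Voxelizes the cloud, keeps in every occupied voxel the real member point
#' closest to the geometric center of the cube (ties: lowest index), then
#' reduces the survivors to exactly `n` points with seeded [fps].  Output
#' points are a subset of the input, so labels carry over directly.
#'
#' @param cloud a [plant_cloud].
#' @param n target point count.
#' @param spec a [voxel_spec]; default: tuned by [auto_voxel_size].
#' @param seed integer seed for the FPS stage.
#' @return a [sample_result] with `indices` into `cloud`.
#' @export
uvs <- function(cloud, n, spec = NULL, seed = NULL) {
  stopifnot(inherits(cloud, "plant_cloud"))
  n <- as.integer(n)
  vx <- .voxel_stage(cloud, spec, n)
  ctr <- sweep(sweep(vx$key + 0.5, 2L, vx$spec$l, "*"), 2L,
               vx$spec$origin, "+")
  d2 <- rowSums((cloud$coords - ctr)^2)
  N <- n_points(cloud)
  ord <- order(vx$gid, d2, seq_len(N))
  kept <- sort(ord[!duplicated(vx$gid[ord])])
  idx <- kept[fps(cloud$coords[kept, , drop = FALSE], n, seed = seed)]
  new_sample_result(cloud, indices = idx, strategy = "UVS",
                    params = list(n = n, voxel = vx$spec, seed = seed))
}

#' Voxelized farthest point sampling (VFPS)
#'
#' Voxelizes the cloud, replaces every occupied voxel by the gravity
#' centroid of its member points, then reduces the centroids to exactly
#' `n` with seeded [fps].  The output coordinates are synthetic (each lies
#' inside its generating voxel by convexity), so no source indices are
#' returned; labels are transferred by per-voxel majority vote, ties broken
#' by the smallest label id.
#'
#' @inheritParams uvs
#' @return a [sample_result] with synthetic `coords` (`indices = NULL`).
#' @export
vfps <- function(cloud, n, spec = NULL, seed = NULL) {
  stopifnot(inherits(cloud, "plant_cloud"))
  n <- as.integer(n)
  vx <- .voxel_stage(cloud, spec, n)
  counts <- as.vector(table(factor(vx$gid, levels = seq_along(vx$groups))))
  cent <- rowsum(cloud$coords, vx$gid, reorder = TRUE) / counts
  dimnames(cent) <- NULL
  maj <- function(lab) {
    tab <- table(factor(vx$gid, levels = seq_along(vx$groups)),
                 factor(lab, levels = sort(unique(lab))))
    as.integer(colnames(tab))[max.col(tab, ties.method = "first")]
  }
  sem <- if (!is.null(cloud$sem)) maj(cloud$sem)
  ins <- if (!is.null(cloud$ins)) maj(cloud$ins)
  pick <- fps(cent, n, seed = seed)
  new_sample_result(cloud, coords = cent[pick, , drop = FALSE],
                    sem = if (!is.null(sem)) sem[pick],
                    ins = if (!is.null(ins)) ins[pick],
                    strategy = "VFPS",
                    params = list(n = n, voxel = vx$spec, seed = seed))
}

#' Surface boundary filter
#'
#' Splits a cloud into edge and internal points from local neighborhood
#' geometry: for each point p, take its k nearest neighbors, compute the
#' displacement `d = ||mean(neighbors) - p||` and the mean neighbor
#' distance `rbar`, and flag p as an edge point iff `d / rbar > tau`.
#' Interior points of a locally symmetric surface have `d` near 0; points
#' on an organ boundary see all their neighbors on one side, pushing
#' `d / rbar` towards 1.
#'
#' @param coords numeric N x 3 matrix or [plant_cloud].
#' @param k neighborhood size, `k >= 3` and `k < N`; default 20.
#' @param tau edge threshold on the displacement ratio; default 0.5.
#' @return an object of class `edge_mask`: list with logical `flags`
#'   (TRUE = edge point) and the `k`, `tau` used.  The edge set and
#'   internal set partition the cloud.
#' @export
sbf <- function(coords, k = 20L, tau = 0.5) {
  if (inherits(coords, "plant_cloud")) coords <- coords$coords
  coords <- as.matrix(coords)
  N <- nrow(coords)
  k <- as.integer(k)
  if (k < 3L) stop_data("sbf needs k >= 3")
  if (N <= k) stop_data("sbf needs more points than neighbors (N > k)")
  nn <- RANN::nn2(coords, coords, k = k + 1L)
  idx <- nn$nn.idx[, -1L, drop = FALSE]     # drop self-match
  dst <- nn$nn.dists[, -1L, drop = FALSE]
  nb_mean <- sapply(1:3, function(d)
    rowMeans(matrix(coords[idx, d], nrow = N)))
  disp <- sqrt(rowSums((nb_mean - coords)^2))
  rbar <- rowMeans(dst)
  ratio <- ifelse(rbar > 0, disp / rbar, 0)
  structure(list(flags = ratio > tau, k = k, tau = tau),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("edge_mask: %d / %d edge points (k = %d, tau = %g)\n",
              sum(x$flags), length(x$flags), x$k, x$tau))
  invisible(x)
}

#' Edge-preserving sampling (3DEPS)
#'
#' Splits the cloud into edge and internal point sets with the surface
#' boundary filter ([sbf]), targets `round(ratio * n)` edge points and the
#' remainder internal (rounding half away from zero), runs seeded [fps]
#' independently on each part, and concatenates.  If a part is smaller than
#' its target, the whole part is taken and the deficit moves to the other
#' part, so the result always has exactly `n` unique source indices.
#' Recombining at a user-set edge fraction lets the sampled cloud retain
#' sharp organ outlines (leaf tips and edges, stem-leaf junctions) that
#' uniform samplers dilute; fractions above 0.5 hollow out organ interiors
#' and are not recommended.
#'
#' @param cloud a [plant_cloud].
#' @param n target point count.
#' @param ratio edge fraction in `[0, 1]`; default 0.2.
#' @param k,tau surface-boundary-filter parameters, see [sbf].
#' @param seed integer seed (drives both FPS stages).
#' @return a [sample_result] with `indices` into `cloud` (edge-part
#'   selections first).
#' @export
threedeps <- function(cloud, n, ratio = 0.2, k = 20L, tau = 0.5,
                      seed = NULL) {
  stopifnot(inherits(cloud, "plant_cloud"))
  n <- as.integer(n)
  N <- n_points(cloud)
  if (n < 1L || n > N) stop_data("n must lie in [1, ", N, "], got ", n)
  if (ratio < 0 || ratio > 1) stop_data("ratio must lie in [0, 1]")
  mask <- sbf(cloud$coords, k = k, tau = tau)
  edge <- which(mask$flags)
  internal <- which(!mask$flags)
  n_e <- as.integer(round_half_away(ratio * n))
  n_c <- n - n_e
  if (n_e > length(edge)) {        # deficit spills to the internal part
    n_c <- n_c + (n_e - length(edge))
    n_e <- length(edge)
  }
  if (n_c > length(internal)) {
    n_e <- n_e + (n_c - length(internal))
    n_c <- length(internal)
  }
  seeds <- derive_seeds(seed, 2L)
  sel_e <- if (n_e > 0L)
    edge[fps(cloud$coords[edge, , drop = FALSE], n_e,
             seed = if (!is.null(seed)) seeds[1])] else integer(0)
  sel_c <- if (n_c > 0L)
    internal[fps(cloud$coords[internal, , drop = FALSE], n_c,
                 seed = if (!is.null(seed)) seeds[2])] else integer(0)
  new_sample_result(cloud, indices = c(sel_e, sel_c), strategy = "3DEPS",
                    params = list(n = n, ratio = ratio, k = k, tau = tau,
                                  seed = seed, n_edge = n_e,
                                  n_internal = n_c))
}

#' Automatic voxel size selection
#'
#' Choosing voxel edge lengths by hand is tedious: too large and the voxel
#' stage cannot supply the `n_target` points the FPS stage needs, too small
#' and voxelization does nothing.  This helper bisects a single scale
#' factor applied to the bounding-box extents until the occupied-voxel
#' count lies in `[n_target, 2 * n_target]`.  Deterministic; at most 60
#' bisection steps.
#'
#' @param coords numeric N x 3 matrix or [plant_cloud].
#' @param n_target desired lower bound on occupied voxels (usually the
#'   down-sampling target `n`).
#' @param isotropy if TRUE (default) voxels are cubes scaled from the
#'   largest box extent; otherwise edges stay proportional to the box.
#' @return a [voxel_spec] whose occupied-voxel count on `coords` lies in
#'   `[n_target, 2 * n_target]`.
#' @export
auto_voxel_size <- function(coords, n_target, isotropy = TRUE) {
  if (inherits(coords, "plant_cloud")) coords <- coords$coords
  coords <- as.matrix(coords)
  N <- nrow(coords)
  n_target <- as.integer(n_target)
  if (n_target < 1L || n_target > N)
    stop_data("n_target must lie in [1, ", N, "]")
  ext <- apply(coords, 2L, function(v) diff(range(v)))
  if (all(ext == 0)) {
    if (n_target <= 1L) return(voxel_spec(rep(1, 3)))
    stop_data("degenerate cloud: all points coincide, cannot reach ",
              n_target, " occupied voxels")
  }
  ext[ext <= 0] <- max(ext)
  base <- if (isotropy) rep(max(ext), 3L) else ext
  occ <- function(s) length(voxelize(coords, voxel_spec(base * s))$groups)
  iter <- 0L
  hi <- 1 + 1e-9                   # one voxel covers the whole box
  if (occ(hi) >= n_target) return(voxel_spec(base * hi))
  lo <- hi
  repeat {                         # geometric search for the lower bracket
    lo <- lo / 2
    iter <- iter + 1L
    o <- occ(lo)
    if (o >= n_target) break
    if (iter >= 60L)
      stop_data("cannot reach ", n_target, " occupied voxels; the cloud ",
                "has too few distinct points")
  }
  if (o <= 2L * n_target) return(voxel_spec(base * lo))
  while (iter < 60L) {             # bisect: occ(lo) > 2*target, occ(hi) < target
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    o <- occ(mid)
    if (o < n_target) hi <- mid
    else if (o > 2L * n_target) lo <- mid
    else return(voxel_spec(base * mid))
  }
  stop_data("voxel-size bisection did not converge; the occupancy curve ",
            "of this cloud has no plateau in [n_target, 2 n_target]")
}

#' Hybrid RS-then-FPS sampling for very dense clouds
#'
#' FPS cost grows with the source size, so for very dense scans it pays to
#' first thin the cloud with cheap sequential random sampling to an
#' `intermediate` size (well under a million points) and only then run FPS
#' down to `n`.  Index bookkeeping is composed, so the returned indices are
#' valid into the original cloud.  When `intermediate >= N` the RS stage is
#' skipped and the call is plain seeded FPS.
#'
#' @param cloud a [plant_cloud].
#' @param n target point count.
#' @param intermediate RS-stage target size, `n <= intermediate`.
#' @param seed integer seed (drives both stages).
#' @return a [sample_result] with `indices` into `cloud`.
#' @export
rs_then_fps <- function(cloud, n, intermediate = 1e6, seed = NULL) {
  stopifnot(inherits(cloud, "plant_cloud"))
  n <- as.integer(n)
  N <- n_points(cloud)
  if (n > intermediate)
    stop_data("n (", n, ") exceeds the intermediate RS size (",
              intermediate, ")")
  if (intermediate >= N) {
    idx <- fps(cloud$coords, n, seed = seed)
  } else {
    seeds <- derive_seeds(seed, 2L)
    mid <- rs(N, as.integer(intermediate),
              seed = if (!is.null(seed)) seeds[1])
    sub <- fps(cloud$coords[mid, , drop = FALSE], n,
               seed = if (!is.null(seed)) seeds[2])
    idx <- mid[sub]
  }
  new_sample_result(cloud, indices = idx, strategy = "RS+FPS",
                    params = list(n = n, intermediate = intermediate,
                                  seed = seed))
}

#' Down-sample a labeled cloud with a named strategy
#'
#' Uniform front end over the five strategies.  Index-based strategies
#' (FPS, RS, UVS, 3DEPS) carry the source point's labels verbatim; VFPS
#' synthesizes voxel-centroid coordinates and transfers labels by per-voxel
#' majority.
#'
#' @param cloud a [plant_cloud].
#' @param strategy one of `"fps"`, `"rs"`, `"uvs"`, `"vfps"`, `"3deps"`.
#' @param n target point count.
#' @param seed integer seed.
#' @param ... strategy parameters: `start` (fps), `spec` (uvs/vfps),
#'   `ratio`, `k`, `tau` (3deps).
#' @return a [sample_result].
#' @examples
#' pl <- gen_plant(plant_spec(n_points = 2000, n_leaves = 3, seed = 1))
#' sample_cloud(pl, "fps", 256, seed = 7)
#' @export
sample_cloud <- function(cloud, strategy, n, seed = NULL, ...) {
  stopifnot(inherits(cloud, "plant_cloud"))
  strategy <- match.arg(tolower(strategy),
                        c("fps", "rs", "uvs", "vfps", "3deps"))
  n <- as.integer(n)
  switch(strategy,
    fps = {
      idx <- fps(cloud$coords, n, seed = seed, ...)
      new_sample_result(cloud, indices = idx, strategy = "FPS",
                        params = list(n = n, seed = seed))
    },
    rs = {
      idx <- rs(n_points(cloud), n, seed = seed)
      new_sample_result(cloud, indices = idx, strategy = "RS",
                        params = list(n = n, seed = seed))
    },
    uvs = uvs(cloud, n, seed = seed, ...),
    vfps = vfps(cloud, n, seed = seed, ...),
    `3deps` = threedeps(cloud, n, seed = seed, ...))
}

#' Down-sampling result
#'
#' Container returned by every strategy: the sampled coordinates (exactly
#' `n` rows), the source indices when the output is a subset of the input
#' (absent for VFPS, whose points are synthetic voxel centroids), carried
#' labels, and the strategy name and parameter set for provenance.
#'
#' @param cloud source [plant_cloud].
#' @param indices 1-based indices into the source, or NULL for synthetic
#'   output.
#' @param coords synthetic coordinates (used when `indices` is NULL).
#' @param sem,ins labels for synthetic output.
#' @param strategy strategy name.
#' @param params named list of the parameters used.
#' @return an object of class `sample_result` with fields `indices`,
#'   `coords`, `sem`, `ins`, `strategy`, `params`.
#' @name sample_result
#' @export
new_sample_result <- function(cloud, indices = NULL, coords = NULL,
                              sem = NULL, ins = NULL, strategy, params) {
  if (!is.null(indices)) {
    indices <- as.integer(indices)
    if (anyDuplicated(indices) || any(indices < 1L) ||
        any(indices > n_points(cloud)))
      stop("internal error: invalid sample indices")   # nocov
    coords <- cloud$coords[indices, , drop = FALSE]
    sem <- cloud$sem[indices]
    ins <- cloud$ins[indices]
  }
  structure(list(indices = indices, coords = coords, sem = sem, ins = ins,
                 strategy = strategy, params = params,
                 C = cloud$C, species = cloud$species),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("sample_result: %s, %d points%s\n", x$strategy,
              nrow(x$coords),
              if (is.null(x$indices)) " (synthetic coordinates)" else ""))
  invisible(x)
}

#' Convert a sample result back to a labeled cloud
#'
#' @param x a [sample_result].
#' @param ... unused.
#' @return a [plant_cloud].
#' @export
as_plant_cloud <- function(x, ...) {
  stopifnot(inherits(x, "sample_result"))
  plant_cloud(x$coords, sem = x$sem, ins = x$ins, C = x$C,
              species = x$species)
}
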