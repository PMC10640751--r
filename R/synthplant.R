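#' Specification of a synthetic plant
#'
#' Parameters of the synthetic single-plant generator.  Defaults emulate
#' the scan regime the samplers are designed for: one plant of a few tens
#' of thousands of points (raw terrestrial-scanner clouds run around
#' 10,000-100,000 points), a connected stem system, and a handful of leaf
#' instances.  Two morphologies are provided: `dicot` (broad deformed
#' elliptic leaves, tomato/tobacco-like) and `monocot` (long slender
#' arching leaves at least 5x longer than wide, sorghum-like).
#'
#' @param morphology `"dicot"` or `"monocot"`.
#' @param n_leaves number of leaf instances (>= 0); default 6.
#' @param n_points total points; must be at least `100 * (n_leaves + 1)`
#'   so every organ is non-degenerate.  Default 30000.
#' @param stem_height stem length in coordinate units (mm); default 300.
#' @param leaf_scale characteristic leaf length (mm); default 80.
#' @param noise_sigma std dev of additive Gaussian coordinate jitter (mm);
#'   default 1.
#' @param seed integer seed; the generator is bit-reproducible per seed.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(morphology = c("dicot", "monocot"), n_leaves = 6L,
                       n_points = 30000L, stem_height = 300,
                       leaf_scale = 80, noise_sigma = 1, seed = 1L) {
  morphology <- match.arg(morphology)
  n_leaves <- as.integer(n_leaves)
  n_points <- as.integer(n_points)
  if (n_leaves < 0L) stop_data("n_leaves must be >= 0")
  if (n_points < 100L * (n_leaves + 1L))
    stop_data("n_points must be at least 100 * (n_leaves + 1) = ",
              100L * (n_leaves + 1L), " so every organ is non-degenerate")
  if (stem_height <= 0 || leaf_scale <= 0)
    stop_data("stem_height and leaf_scale must be positive")
  if (noise_sigma < 0) stop_data("noise_sigma must be >= 0")
  structure(list(morphology = morphology, n_leaves = n_leaves,
                 n_points = n_points, stem_height = stem_height,
                 leaf_scale = leaf_scale, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

# points on a slightly curved vertical stem tube
.gen_stem <- function(n, height, radius, sway) {
  t <- runif(n)
  phi <- runif(n, 0, 2 * pi)
  cbind(sway * sin(2.2 * pi * t) + radius * cos(phi),
        sway * sin(1.7 * pi * t + 1) + radius * sin(phi),
        height * t)
}

# stem centerline position/azimuth at parameter t (for leaf attachment)
.stem_axis <- function(t, height, sway) {
  c(sway * sin(2.2 * pi * t), sway * sin(1.7 * pi * t + 1), height * t)
}

# points on one leaf surface attached at `base`, pointing along azimuth
# `az`.  Dicot: broad deformed ellipse (width 0.6 L, droop); monocot: long
# slender arc strip (width L/8, rises then falls).
.gen_leaf <- function(n, base, az, L, morphology) {
  u <- runif(n)                      # along the midrib, 0 = attachment
  v <- runif(n, -1, 1)               # across the blade
  dir <- c(cos(az), sin(az))
  side <- c(-sin(az), cos(az))
  if (morphology == "dicot") {
    half_w <- 0.3 * L * sin(pi * u)            # elliptic outline
    lift <- 0.25 * L * u - 0.45 * L * u^2      # tilt up then droop
    ripple <- 0.03 * L * sin(3 * pi * u) * v   # blade deformation
  } else {
    L <- 1.6 * L
    half_w <- (L / 16) * (1 - 0.6 * u^2) * (0.2 + 0.8 * sin(pi * pmin(u * 5, 1) / 2))
    lift <- 0.55 * L * u - 0.65 * L * u^2      # arching blade
    ripple <- 0
  }
  r <- u * L
  cbind(base[1] + dir[1] * r + side[1] * half_w * v,
        base[2] + dir[2] * r + side[2] * half_w * v,
        base[3] + lift + ripple)
}

#' Generate a labeled synthetic plant point cloud
#'
#' Builds a single-plant cloud with two semantic classes: the stem system
#' (class 0, instance id -1 -- stems are fully connected and carry no
#' instance concept) and leaves (class 1, instance ids `0..n_leaves-1`).
#' Leaves attach along the upper stem at golden-angle azimuths; points are
#' allocated to organs proportionally to surface area with a floor of 100
#' points per organ, and Gaussian jitter of sd `noise_sigma` is added to
#' every coordinate.  Output is bit-identical for a fixed spec.
#'
#' @param spec a [plant_spec].
#' @return a [plant_cloud] with `sem`, `ins`, `C = 2` and `species` set to
#'   the morphology.
#' @examples
#' pl <- gen_plant(plant_spec(n_points = 2000, n_leaves = 3, seed = 42))
#' table(pl$sem)
#' @export
gen_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    h <- spec$stem_height
    L <- spec$leaf_scale
    r_stem <- h / 60
    sway <- h / 20
    nl <- spec$n_leaves
    # area-proportional point allocation, floor 100 per organ
    stem_area <- 2 * pi * r_stem * h
    leaf_area <- if (spec$morphology == "dicot")
      pi * (L / 2) * (0.3 * L) else (1.6 * L) * (1.6 * L / 8)
    areas <- c(stem_area, rep(leaf_area, nl))
    alloc <- pmax(100L, as.integer(round(spec$n_points * areas / sum(areas))))
    alloc[1] <- alloc[1] + (spec$n_points - sum(alloc))  # stem absorbs slack
    if (alloc[1] < 100L) {  # many leaves squeezed the stem below the floor
      deficit <- 100L - alloc[1]
      alloc[1] <- 100L
      k <- which.max(alloc[-1]) + 1L
      alloc[k] <- alloc[k] - deficit
    }
    xyz <- .gen_stem(alloc[1], h, r_stem, sway)
    sem <- rep(0L, alloc[1])
    ins <- rep(-1L, alloc[1])
    if (nl > 0L) {
      attach_t <- seq(0.35, 0.95, length.out = nl)
      golden <- 137.5 / 180 * pi
      for (j in seq_len(nl)) {
        base <- .stem_axis(attach_t[j], h, sway)
        leaf <- .gen_leaf(alloc[j + 1L], base, (j - 1L) * golden, L,
                          spec$morphology)
        xyz <- rbind(xyz, leaf)
        sem <- c(sem, rep(1L, alloc[j + 1L]))
        ins <- c(ins, rep(j - 1L, alloc[j + 1L]))
      }
    }
    if (spec$noise_sigma > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, spec$noise_sigma),
                          ncol = 3L)
    plant_cloud(xyz, sem = sem, ins = ins, C = 2L,
                species = spec$morphology)
  })
}

#' Specification of prediction degradation
#'
#' Parameters of the synthetic "network prediction" model used to exercise
#' the metrics: segmentation errors concentrate where real networks fail
#' -- near semantic boundaries (leaf edges and tips, stem-leaf junctions)
#' -- and instance errors take the form of splitting one leaf in two or
#' merging adjacent leaves.
#'
#' @param boundary_flip_rate fraction of boundary points (points whose
#'   k-NN neighborhood holds >= 2 semantic classes) whose predicted
#'   semantic label is flipped; in `[0, 1]`.
#' @param split_prob per-instance probability of being split in two by a
#'   random plane through its centroid.
#' @param merge_prob per-instance probability of being merged with the
#'   instance whose centroid is nearest.
#' @param k neighborhood size for boundary detection; default 10.
#' @param seed integer seed.
#' @return an object of class `perturb_spec`.
#' @export
perturb_spec <- function(boundary_flip_rate = 0.1, split_prob = 0.1,
                         merge_prob = 0.1, k = 10L, seed = 1L) {
  rates <- c(boundary_flip_rate, split_prob, merge_prob)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop_data("all rates must lie in [0, 1]")
  structure(list(boundary_flip_rate = boundary_flip_rate,
                 split_prob = split_prob, merge_prob = merge_prob,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "perturb_spec")
}

#' Degrade ground-truth labels into a synthetic prediction
#'
#' Applies the error model of [perturb_spec] to a labeled cloud: semantic
#' flips hit only boundary points (interior points are never touched),
#' splits cut an instance by a random plane through its centroid, and
#' merges union an instance with its nearest-centroid neighbor.  With all
#' rates 0 the prediction equals the ground truth and every metric is 1.
#' Split/merge requests on clouds with too few instances are skipped with
#' a message.
#'
#' @param cloud a labeled [plant_cloud] (both `sem` and `ins` required).
#' @param pspec a [perturb_spec].
#' @return list with integer vectors `sem` and `ins`: the degraded
#'   prediction.
#' @export
perturb_prediction <- function(cloud, pspec) {
  stopifnot(inherits(cloud, "plant_cloud"), inherits(pspec, "perturb_spec"))
  if (is.null(cloud$sem) || is.null(cloud$ins))
    stop_data("perturb_prediction needs a fully labeled cloud")
  with_seed(pspec$seed, {
    sem <- cloud$sem
    ins <- cloud$ins
    N <- n_points(cloud)
    if (pspec$boundary_flip_rate > 0 && N > pspec$k) {
      nn <- RANN::nn2(cloud$coords, cloud$coords, k = pspec$k + 1L)
      nb <- nn$nn.idx[, -1L, drop = FALSE]
      nbsem <- matrix(sem[nb], nrow = N)
      boundary <- which(rowSums(nbsem != sem) > 0L)
      nflip <- as.integer(round(pspec$boundary_flip_rate * length(boundary)))
      if (nflip > 0L) {
        flip <- sample(boundary, nflip)
        # flip to the most common *other* class in the neighborhood
        sem[flip] <- vapply(flip, function(i) {
          others <- nbsem[i, nbsem[i, ] != sem[i]]
          if (length(others) == 0L) (sem[i] + 1L) %% cloud$C
          else as.integer(names(which.max(table(others))))
        }, 1L)
      }
    }
    ids <- sort(unique(ins[ins >= 0L]))
    next_id <- if (length(ids)) max(ids) + 1L else 0L
    # splits
    for (id in ids) {
      if (runif(1) >= pspec$split_prob) next
      pts <- which(ins == id)
      if (length(pts) < 2L) {
        message("skipping split of instance ", id, ": too few points")
        next
      }
      ctr <- colMeans(cloud$coords[pts, , drop = FALSE])
      nrm <- rnorm(3L)
      nrm <- nrm / sqrt(sum(nrm^2))
      side <- (cloud$coords[pts, , drop = FALSE] %*% nrm -
                 sum(ctr * nrm)) > 0
      if (any(side) && !all(side)) {
        ins[pts[side]] <- next_id
        next_id <- next_id + 1L
      }
    }
    # merges
    cur <- sort(unique(ins[ins >= 0L]))
    for (id in cur) {
      if (runif(1) >= pspec$merge_prob) next
      live <- sort(unique(ins[ins >= 0L]))
      if (length(live) < 2L) {
        message("skipping merge: fewer than two instances remain")
        next
      }
      if (!id %in% live) next   # already absorbed
      ctrs <- t(vapply(live, function(i)
        colMeans(cloud$coords[ins == i, , drop = FALSE]), numeric(3L)))
      me <- match(id, live)
      d2 <- rowSums(sweep(ctrs, 2L, ctrs[me, ])^2)
      d2[me] <- Inf
      ins[ins == live[which.min(d2)]] <- id
    }
    list(sem = sem, ins = ins)
  })
}

#' Randomized down-sampling augmentation
#'
#' Runs the chosen strategy `times` times with independently derived seeds
#' (e.g. the FPS start point is re-randomized each run), producing `times`
#' clouds of exactly `n` points from one source cloud -- the standard way
#' to augment a training set by 10x while keeping the fixed input size the
#' networks require.
#'
#' @param cloud a [plant_cloud].
#' @param strategy strategy name, see [sample_cloud].
#' @param n points per output cloud; default 4096.
#' @param times number of augmented copies; default 10.
#' @param seed base seed; run seeds are derived from it deterministically.
#' @param ... strategy parameters passed to [sample_cloud].
#' @return list of `times` [sample_result]s.
#' @export
augment <- function(cloud, strategy, n = 4096L, times = 10L, seed = 1L,
                    ...) {
  stopifnot(inherits(cloud, "plant_cloud"))
  times <- as.integer(times)
  if (times < 1L) stop_data("times must be >= 1")
  seeds <- derive_seeds(seed, times)
  lapply(seq_len(times), function(i)
    sample_cloud(cloud, strategy, n, seed = seeds[i], ...))
}

#' Shuffle-split clouds into training and testing sets
#'
#' Seeded shuffle followed by a deterministic cut:
#' `round(ratio[1] / sum(ratio) * K)` clouds go to training, the rest to
#' testing (default 2:1).  The two sets partition the input.
#'
#' @param clouds list of clouds (any objects).
#' @param ratio length-2 numeric train:test ratio; default `c(2, 1)`.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(clouds, ratio = c(2, 1), seed = 1L) {
  K <- length(clouds)
  if (K < length(ratio) + 1L)
    stop_data("need at least ", length(ratio) + 1L, " clouds to split")
  if (length(ratio) != 2L || any(ratio <= 0))
    stop_data("ratio must be two positive numbers")
  n_train <- as.integer(round(ratio[1] / sum(ratio) * K))
  perm <- with_seed(seed, sample.int(K))
  list(train = clouds[perm[seq_len(n_train)]],
       test = clouds[perm[seq.int(n_train + 1L, K)]])
}
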