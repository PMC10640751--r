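test_that("fps handles the exhaustive, single-point and collinear cases", {
  x <- matrix(runif(60), 20, 3)
  expect_setequal(fps(x, 20, start = 5), 1:20)       # n = N: a permutation
  expect_identical(fps(x, 1, start = 7L), 7L)
  line <- cbind(c(0, 1, 4, 9, 10), 0, 0)
  expect_identical(fps(line, 3, start = 1), c(1L, 5L, 3L))  # x = 0, 10, 4
  expect_error(fps(x, 21, start = 1), "\\[1, 20\\]")
  expect_error(fps(x, 0, start = 1), "\\[1, 20\\]")
})

test_that("fps matches the brute-force greedy max-min oracle for all starts", {
  for (seed in 1:3) {
    n_src <- c(12, 30, 50)[seed]
    x <- rand_cloud(n_src, labeled = FALSE, seed = seed)$coords
    n <- ceiling(n_src / 2)
    for (start in seq_len(n_src))
      expect_identical(fps(x, n, start = start),
                       as.integer(oracle_fps(x, n, start)))
  }
})

test_that("fps min pairwise distance among selections is non-increasing in n", {
  x <- rand_cloud(200, labeled = FALSE, seed = 4)$coords
  mindist <- vapply(c(2, 5, 10, 25, 50, 100, 200), function(n)
    min(dist(x[fps(x, n, start = 1), ])), 1)
  expect_true(all(diff(mindist) <= 1e-12))
})

test_that("rs returns strictly increasing index sets of the right size", {
  expect_identical(rs(7, 7, seed = 1), 1:7)          # n = N: no skips
  for (seed in 1:20) {
    idx <- rs(100, 13, seed = seed)
    expect_length(idx, 13L)
    expect_true(all(diff(idx) > 0))
    expect_true(all(idx >= 1L & idx <= 100L))
  }
  expect_error(rs(10, 11), "\\[1, 10\\]")
})

test_that("rs draws every subset uniformly (exhaustive enumeration, N=6 n=3)", {
  draws <- 20000L
  key <- vapply(seq_len(draws), function(i)
    paste(rs(6, 3, seed = i), collapse = "-"), "")
  counts <- table(key)
  expect_length(counts, choose(6, 3))                # all 20 subsets occur
  chi2 <- sum((counts - draws / 20)^2 / (draws / 20))
  expect_lt(chi2, qchisq(0.99, df = 19))
})

test_that("voxelize partitions points with the floor convention", {
  x <- rand_cloud(100, labeled = FALSE, seed = 2)$coords
  vx <- voxelize(x, voxel_spec(10))                  # one huge voxel
  expect_length(vx$groups, 1L)
  two <- voxelize(cbind(c(0.1, 1.1), 0, 0), voxel_spec(1, origin = c(0, 0, 0)))
  expect_length(two$groups, 2L)
  vx <- voxelize(x, voxel_spec(0.25))
  expect_setequal(unlist(vx$groups), seq_len(100))
  expect_identical(sum(lengths(vx$groups)), 100L)    # disjoint cover
  expect_error(voxel_spec(0), "positive")
})

test_that("uvs voxel stage keeps the member nearest each cube center", {
  pc <- rand_cloud(400, seed = 3)
  spec <- voxel_spec(0.3, origin = c(0, 0, 0))
  vx <- voxelize(pc$coords, spec)
  n_occ <- length(vx$groups)
  res <- uvs(pc, n_occ, spec = spec, seed = 1)       # fps stage keeps all
  picked <- sort(res$indices)
  oracle <- sort(vapply(seq_along(vx$groups), function(g) {
    mem <- vx$groups[[g]]
    ctr <- vx$spec$origin + (vx$key[mem[1], ] + 0.5) * vx$spec$l
    mem[which.min(colSums((t(pc$coords[mem, , drop = FALSE]) - ctr)^2))]
  }, 1L))
  expect_identical(picked, oracle)
  expect_identical(res$sem, pc$sem[res$indices])     # labels carried
  # two points in one voxel: the one nearer the cube center survives
  pair <- plant_cloud(rbind(c(0.6, 0.5, 0.5), c(0.9, 0.5, 0.5)))
  r <- uvs(pair, 1, spec = voxel_spec(1, origin = c(0, 0, 0)), seed = 1)
  expect_identical(r$indices, 1L)
  expect_error(uvs(pair, 2, spec = voxel_spec(1, origin = c(0, 0, 0))),
               "auto_voxel_size")
})

test_that("vfps emits per-voxel centroids that stay inside their cells", {
  pc <- rand_cloud(400, seed = 5)
  spec <- voxel_spec(0.3, origin = c(0, 0, 0))
  vx <- voxelize(pc$coords, spec)
  res <- vfps(pc, length(vx$groups), spec = spec, seed = 1)
  expect_null(res$indices)                           # synthetic coords
  oracle <- t(vapply(vx$groups, function(mem)
    colMeans(pc$coords[mem, , drop = FALSE]), numeric(3)))
  expect_equal(res$coords[order(res$coords[, 1]), ],
               unname(oracle[order(oracle[, 1]), ]))
  # convexity: every centroid falls back into its generating cell
  keys <- floor(sweep(sweep(res$coords, 2, spec$origin), 2, rep(0.3, 3), "/"))
  lookup <- paste(vx$key[, 1], vx$key[, 2], vx$key[, 3])
  expect_true(all(paste(keys[, 1], keys[, 2], keys[, 3]) %in% lookup))
  # simple mean example
  two <- plant_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  r <- vfps(two, 1, spec = voxel_spec(2, origin = c(-0.5, -0.5, -0.5)))
  expect_equal(r$coords, matrix(c(0.5, 0, 0), 1))
})

test_that("vfps transfers labels by per-voxel majority, ties to smallest id", {
  xyz <- rbind(c(0.1, 0.1, 0.1), c(0.2, 0.1, 0.1), c(0.15, 0.2, 0.1))
  pc <- plant_cloud(xyz, sem = c(1L, 1L, 0L), ins = c(2L, 2L, -1L))
  r <- vfps(pc, 1, spec = voxel_spec(1, origin = c(0, 0, 0)))
  expect_identical(r$sem, 1L)
  expect_identical(r$ins, 2L)
  pc2 <- plant_cloud(xyz[1:2, ], sem = c(0L, 1L), ins = c(-1L, 0L))
  r2 <- vfps(pc2, 1, spec = voxel_spec(1, origin = c(0, 0, 0)))
  expect_identical(r2$sem, 0L)   # tie -> smallest class id
  expect_identical(r2$ins, -1L)
})

test_that("sbf separates edge from interior geometry", {
  # interior of a dense planar grid is symmetric: not edge
  g <- as.matrix(expand.grid(x = 1:15, y = 1:15))
  grid <- cbind(g, 0)
  mask <- sbf(grid, k = 8, tau = 0.5)
  center <- which(g[, 1] == 8 & g[, 2] == 8)
  expect_false(mask$flags[center])
  expect_true(mask$flags[which(g[, 1] == 1 & g[, 2] == 1)])  # corner
  # endpoint of a regular 1-D segment sees all neighbors on one side
  seg <- cbind(seq_len(60), 0, 0)
  m2 <- sbf(seg, k = 20, tau = 0.5)
  expect_true(m2$flags[1])
  expect_false(m2$flags[30])
  # edge/internal sets partition the cloud
  expect_identical(sum(m2$flags) + sum(!m2$flags), 60L)
  expect_error(sbf(seg[1:10, ], k = 20), "N > k")
})

test_that("sbf flags concentrate on the rim of a sampled disk", {
  set.seed(11)
  r <- sqrt(runif(1500)); a <- runif(1500, 0, 2 * pi)
  disk <- cbind(r * cos(a), r * sin(a), 0)
  mask <- sbf(disk, k = 20, tau = 0.5)
  expect_gt(mean(r[mask$flags]), mean(r[!mask$flags]))
})

test_that("threedeps hits its edge-point budget, spilling deficits", {
  pl <- gen_plant(plant_spec(n_points = 6000, n_leaves = 4, seed = 8))
  mask <- sbf(pl$coords, k = 20, tau = 0.5)
  B <- which(mask$flags)
  res <- threedeps(pl, 2000, ratio = 0.2, seed = 1)
  expect_length(res$indices, 2000L)
  expect_false(anyDuplicated(res$indices) > 0)
  expect_identical(sum(res$indices %in% B), 400L)    # round(0.2 * 2000)
  # bookkeeping identity over a ratio sweep
  for (ratio in c(0, 0.35, 0.5)) {
    r <- threedeps(pl, 1000, ratio = ratio, seed = 2)
    expect_identical(sum(r$indices %in% B),
                     min(as.integer(round(ratio * 1000)), length(B)))
  }
  # deficit spill: demand more edge points than exist
  small <- threedeps(pl, n_points(pl) - 10L, ratio = 1, seed = 3)
  expect_identical(sum(small$indices %in% B), length(B))
  expect_length(small$indices, n_points(pl) - 10L)
})

test_that("auto_voxel_size lands occupancy in [n_target, 2 n_target]", {
  lat <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  spec <- auto_voxel_size(lat, 500)
  occ <- length(voxelize(lat, spec)$groups)
  expect_gte(occ, 500L); expect_lte(occ, 1000L)
  spec1 <- auto_voxel_size(lat, 1)
  expect_lte(length(voxelize(lat, spec1)$groups), 2L)
  for (seed in 1:4) {
    pc <- rand_cloud(800, labeled = FALSE, seed = seed)
    nt <- c(5, 50, 200, 400)[seed]
    o <- length(voxelize(pc$coords, auto_voxel_size(pc$coords, nt))$groups)
    expect_gte(o, nt); expect_lte(o, 2L * nt)
  }
  dup <- matrix(1, 50, 3)
  expect_error(auto_voxel_size(dup, 10), "distinct|coincide")
})

test_that("rs_then_fps composes index bookkeeping into the source cloud", {
  pl <- gen_plant(plant_spec(n_points = 10000, n_leaves = 4, seed = 5))
  res <- rs_then_fps(pl, 500, intermediate = 2000, seed = 9)
  expect_length(res$indices, 500L)
  expect_false(anyDuplicated(res$indices) > 0)
  expect_true(all(res$indices >= 1L & res$indices <= 10000L))
  expect_identical(res$sem, pl$sem[res$indices])
  # intermediate >= N skips the RS stage entirely
  direct <- rs_then_fps(pl, 100, intermediate = 1e6, seed = 4)
  expect_identical(direct$indices, fps(pl$coords, 100, seed = 4))
  expect_error(rs_then_fps(pl, 300, intermediate = 200), "exceeds")
})

test_that("every strategy returns exactly n points, deterministically per seed", {
  pl <- gen_plant(plant_spec(n_points = 3000, n_leaves = 3, seed = 2))
  for (strat in c("fps", "rs", "uvs", "vfps", "3deps")) {
    a <- sample_cloud(pl, strat, 512, seed = 31)
    b <- sample_cloud(pl, strat, 512, seed = 31)
    expect_identical(nrow(a$coords), 512L)
    expect_identical(a, b)                            # bit-identical
    if (!is.null(a$indices)) {
      expect_false(anyDuplicated(a$indices) > 0)
      expect_equal(a$coords, pl$coords[a$indices, ])
    }
    c2 <- sample_cloud(pl, strat, 512, seed = 99)
    expect_false(identical(a$coords, c2$coords))      # seed matters
  }
})
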