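make_volume <- function(dims, seed = 1) {
  set.seed(seed)
  array(sample(0:255, prod(dims), TRUE), dims)
}

test_that("cubing and reading back is lossless for arbitrary cube edges", {
  for (case in list(list(dims = c(64, 64, 64), edge = 64),
                    list(dims = c(70, 50, 40), edge = 32),
                    list(dims = c(33, 29, 17), edge = 13))) {
    vol <- make_volume(case$dims, seed = case$edge)
    st <- build_cubes(vol, tempfile("store_"), cube_edge = case$edge)
    back <- read_subvolume(st, c(0, 0, 0), case$dims)
    expect_identical(as.integer(back), as.integer(vol))
    n_files <- length(list.files(st$root, pattern = "cube.raw",
                                 recursive = TRUE))
    expect_equal(n_files, prod(ceiling(case$dims / case$edge)))
  }
})

test_that("cube files follow the documented on-disk layout", {
  vol <- make_volume(c(40, 40, 40), seed = 3)
  st <- build_cubes(vol, tempfile("store_"), cube_edge = 32,
                    name = "demo")
  expect_true(file.exists(file.path(st$root, "0", "x0001", "y0000",
                                    "z0000", "cube.raw")))
  expect_true(file.exists(file.path(st$root, "demo.conf")))
  # a cube file holds exactly edge^3 bytes, zero-padded at the boundary
  raw <- readBin(file.path(st$root, "0", "x0001", "y0000", "z0000",
                           "cube.raw"), "raw", 40000)
  expect_length(raw, 32^3)
  # reopen from the conf file
  st2 <- cube_store_open(st$root)
  expect_equal(st2$dimensions, c(40L, 40L, 40L))
  expect_equal(st2$voxel_size, c(9.25, 9.25, 25))
  expect_identical(read_subvolume(st2, c(0, 0, 0), c(40, 40, 40)),
                   read_subvolume(st, c(0, 0, 0), c(40, 40, 40)))
})

test_that("section lists are stacked with shape checks and z-gap metadata", {
  secs <- lapply(1:5, function(z) matrix((z * 7) %% 256, 20, 30))
  st <- build_cubes(secs, tempfile("store_"), cube_edge = 16,
                    z_gaps = 3L)
  expect_equal(st$dimensions, c(30L, 20L, 5L))     # x, y, z
  expect_equal(cube_store_open(st$root)$z_gaps, 3L)
  v <- read_subvolume(st, c(0, 0, 0), c(30, 20, 5))
  expect_true(all(v[, , 2] == 14))
  bad <- c(secs, list(matrix(0, 10, 10)))
  expect_error(build_cubes(bad, tempfile()), "section 6")
})

test_that("subvolume reads fill out-of-stack voxels with zero", {
  vol <- make_volume(c(40, 40, 40), seed = 4)
  st <- build_cubes(vol, tempfile("store_"), cube_edge = 32)
  r <- read_subvolume(st, c(30, 30, 30), c(20, 20, 20))
  expect_true(attr(r, "out_of_bounds"))
  expect_identical(r[1:10, 1:10, 1:10], vol[31:40, 31:40, 31:40])
  expect_true(all(r[11:20, , ] == 0))
  far <- read_subvolume(st, c(100, 100, 100), c(8, 8, 8))
  expect_true(all(far == 0))
  expect_true(attr(far, "out_of_bounds"))
  expect_error(read_subvolume(st, c(0, 0, 0), c(8, 8, 8), level = 1),
               "level")
})

test_that("pyramid levels mean-pool with half-up rounding and ceil dims", {
  # constant volume stays constant at every level
  stc <- build_cubes(array(200L, c(32, 32, 32)), tempfile("store_"),
                     cube_edge = 16)
  stc <- build_pyramid(stc, 3)
  expect_true(all(read_subvolume(stc, c(0, 0, 0), c(8, 8, 8),
                                 level = 2) == 200))

  # checkerboard averages to 128 (127.5 rounded half-up)
  idx <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  chk <- array(255L * ((idx$x + idx$y + idx$z) %% 2L), c(32, 32, 32))
  stk <- build_cubes(chk, tempfile("store_"), cube_edge = 16)
  stk <- build_pyramid(stk, 2)
  l1 <- read_subvolume(stk, c(0, 0, 0), c(16, 16, 16), level = 1)
  expect_true(all(l1 == 128))

  # ceil division of odd dimensions, validated voxel-by-voxel at level 1
  vol <- make_volume(c(21, 13, 9), seed = 9)
  st <- build_cubes(vol, tempfile("store_"), cube_edge = 8)
  st <- build_pyramid(st, 2)
  expect_equal(sbemtools:::level_dims(st, 1), c(11, 7, 5))
  l1 <- read_subvolume(st, c(0, 0, 0), c(11, 7, 5), level = 1)
  for (x in 1:11) for (y in 1:7) for (z in 1:5) {
    xs <- (2 * x - 1):min(2 * x, 21)
    ys <- (2 * y - 1):min(2 * y, 13)
    zs <- (2 * z - 1):min(2 * z, 9)
    expect_equal(l1[x, y, z],
                 as.integer(floor(mean(vol[xs, ys, zs]) + 0.5)))
  }

  expect_error(build_pyramid(st, 20), "log2")
})

test_that("neighborhood loading matches the box-intersection oracle", {
  vol <- make_volume(c(300, 300, 300), seed = 6)
  st <- build_cubes(vol, tempfile("store_"), cube_edge = 128)
  st <- build_pyramid(st, 2)

  # focal at a cube center with a sub-cube extent: one resident cube
  cache <- cube_cache()
  load_neighborhood(st, cache, focal_point = c(64, 64, 64), extent = 100,
                    levels = 0)
  expect_equal(nrow(cache_resident(cache)), 1)
  expect_equal(unname(unlist(cache_resident(cache)[1, ])), c(0, 0, 0, 0))

  # corner focal point, multi-level: equals the brute-force oracle
  cache <- cube_cache()
  load_neighborhood(st, cache, focal_point = c(128, 128, 128),
                    extent = 320, levels = c(0, 1))
  res <- cache_resident(cache)
  for (l in 0:1) {
    f <- floor(c(128, 128, 128) / 2^l)
    oracle <- brute_cube_intersection(floor(f - 160), ceiling(f + 160),
                                      128, ceiling(c(300, 300, 300) / 2^l))
    got <- as.matrix(res[res$level == l, c("cx", "cy", "cz")])
    got <- got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("the cache serves repeats from disk and evicts by LRU", {
  vol <- make_volume(c(256, 128, 128), seed = 7)
  st <- build_cubes(vol, tempfile("store_"), cube_edge = 64)
  cache <- cube_cache()
  load_neighborhood(st, cache, c(100, 64, 64), extent = 128, levels = 0)
  n1 <- cache$fetch_count
  expect_gt(n1, 0)
  load_neighborhood(st, cache, c(100, 64, 64), extent = 128, levels = 0)
  expect_equal(cache$fetch_count, n1)    # second call: zero backing reads

  # memory budget of two cubes: residency never exceeds it
  small <- cube_cache(memory_budget = 2 * 64^3)
  for (x in c(32, 96, 160, 224)) {
    load_neighborhood(st, small, c(x, 32, 32), extent = 60, levels = 0)
    expect_lte(nrow(cache_resident(small)), 2)
  }
  # evicted cubes are still on disk: re-loading fetches nothing new
  n2 <- small$fetch_count
  load_neighborhood(st, small, c(32, 32, 32), extent = 60, levels = 0)
  expect_equal(small$fetch_count, n2)

  expect_error(sbemtools:::cache_fetch(st, cache, 0, 50, 50, 50),
               "cannot fetch")
})

test_that("axis-aligned reslices equal the stored section exactly", {
  vol <- make_volume(c(41, 31, 21), seed = 8)
  st <- build_cubes(vol, tempfile("store_"), cube_edge = 32)
  z <- 10
  r <- reslice_plane(st, c(20, 15, z) * c(9.25, 9.25, 25),
                     u = c(1, 0, 0), v = c(0, 1, 0),
                     out_shape = c(41, 31), pixel_pitch = 9.25)
  expect_equal(r, vol[, , z + 1] * 1.0, ignore_attr = TRUE)
  expect_error(reslice_plane(st, c(0, 0, 0), c(1, 0, 0), c(1, 0, 0),
                             c(8, 8), 9.25), "orthonormal")
})

test_that("oblique reslices are exact on trilinear fields", {
  dims <- c(24, 24, 24)
  idx <- expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                     z = 0:(dims[3] - 1))
  lin <- array(idx$x + 2L * idx$y + 3L * idx$z, dims)
  st <- build_cubes(lin, tempfile("store_"), cube_edge = 24,
                    voxel_size = c(10, 10, 10))
  u <- c(1, 1, 0) / sqrt(2)
  v <- c(-1, 1, 2) / sqrt(6)
  center <- c(115, 115, 115)
  r <- reslice_plane(st, center, u, v, c(9, 9), pixel_pitch = 15)
  for (i in 1:9) for (j in 1:9) {
    p <- center + (i - 5) * 15 * u + (j - 5) * 15 * v
    pv <- p / 10
    expect_equal(r[i, j], pv[1] + 2 * pv[2] + 3 * pv[3],
                 tolerance = 1e-6)
  }

  # rotation consistency: sampling with a 90 degree rotated basis
  # transposes/flips the section
  vol <- make_volume(c(21, 21, 5), seed = 10)
  st2 <- build_cubes(vol, tempfile("store_"), cube_edge = 32,
                     voxel_size = c(10, 10, 10))
  a <- reslice_plane(st2, c(100, 100, 20), c(1, 0, 0), c(0, 1, 0),
                     c(21, 21), 10)
  b <- reslice_plane(st2, c(100, 100, 20), c(0, 1, 0), c(-1, 0, 0),
                     c(21, 21), 10)
  expect_equal(b, t(a)[, 21:1], ignore_attr = TRUE)

  # plane fully outside the stack is all zero
  far <- reslice_plane(st2, c(10000, 10000, 10000), c(1, 0, 0),
                       c(0, 1, 0), c(5, 5), 10)
  expect_true(all(far == 0))
})
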