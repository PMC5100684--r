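test_that("standardization zeroes row means and unitizes row sds", {
  set.seed(1)
  img <- matrix(runif(64 * 64, 0, 65535), 64)
  s <- standardize(img)
  expect_lt(max(abs(rowMeans(s))), 1e-6)
  expect_lt(max(abs(apply(s, 1, sd) - 1)), 1e-6)
  # standardizing again still leaves rows standardized
  s2 <- standardize(s)
  expect_lt(max(abs(rowMeans(s2))), 1e-6)
  expect_lt(max(abs(apply(s2, 1, sd) - 1)), 1e-6)

  w <- capture_warnings(out <- standardize(matrix(7, 8, 8)))
  expect_true(all(grepl("zero-variance", w)))   # column pass, then rows
  expect_true(all(out == 0))
  expect_error(standardize(matrix(1, 1, 5)), "at least 2")
})

test_that("offset estimation equals the exhaustive spatial oracle", {
  # small-scale exhaustive equivalence, several window sizes and offsets
  for (case in list(list(seed = 1, off = c(5, -3), w = 8),
                    list(seed = 2, off = c(-11, 7), w = 16),
                    list(seed = 3, off = c(0, 0), w = 8))) {
    tex <- gen_texture(160, 160, correlation_length = 3, seed = case$seed)
    tp <- gen_tile_pair(tex, case$off, 64, noise_sd = 0.05,
                        seed = case$seed)
    est <- estimate_offset(tp$tileA, tp$tileB, max_offset = case$w)
    oracle <- brute_xcorr_peak(standardize(tp$tileA),
                               standardize(tp$tileB), case$w)
    expect_equal(c(est$dx, est$dy), unname(oracle))
    expect_equal(c(est$dx, est$dy), case$off)
  }
})

test_that("seeded random offsets are recovered exactly under noise", {
  set.seed(42)
  for (k in 1:12) {
    off <- sample(-40:40, 2, replace = TRUE)
    tex <- gen_texture(220, 220, correlation_length = 3, seed = 500 + k)
    tp <- gen_tile_pair(tex, off, 128, noise_sd = 0.05, seed = k)
    est <- estimate_offset(tp$tileA, tp$tileB, max_offset = 48)
    expect_equal(c(est$dx, est$dy), off)
  }
})

test_that("offset estimation is translation-covariant and rejects junk", {
  tex <- gen_texture(300, 300, correlation_length = 3, seed = 11)
  base <- c(10, 6)
  tp1 <- gen_tile_pair(tex, base, 128)
  tp2 <- gen_tile_pair(tex, base + c(7, -4), 128)
  e1 <- estimate_offset(tp1$tileA, tp1$tileB, 40)
  e2 <- estimate_offset(tp2$tileA, tp2$tileB, 40)
  expect_equal(c(e2$dx - e1$dx, e2$dy - e1$dy), c(7, -4))

  expect_error(suppressWarnings(
    estimate_offset(matrix(5, 64, 64), matrix(5, 64, 64), 8)),
    "no signal")
  expect_error(estimate_offset(matrix(1:4, 2), matrix(1:6, 2), 8),
               "same shape")
})

test_that("global layout reproduces spanning-tree and dense oracles", {
  expect_equal(unname(solve_layout(data.frame(), 1, 1)$positions),
               matrix(0, 1, 2))

  # 3x3 grid with exact offsets: equals BFS accumulation oracle
  g <- gen_tile_grid(3, 3, 128, 0.06, jitter = 3, seed = 21)
  offs <- NULL
  for (i in 1:9) for (j in 1:9) {
    if (i >= j) next
    dr <- abs(g$grid_index[j, 1] - g$grid_index[i, 1])
    dc <- abs(g$grid_index[j, 2] - g$grid_index[i, 2])
    if (dr + dc != 1) next
    offs <- rbind(offs, data.frame(
      i = i, j = j,
      dx = g$true_positions[j, 1] - g$true_positions[i, 1],
      dy = g$true_positions[j, 2] - g$true_positions[i, 2]))
  }
  lay <- solve_layout(offs, 9, anchor = 1)
  expect_lt(max(lay$residuals), 1e-6)
  expect_equal(lay$positions, bfs_layout(offs, 9), tolerance = 1e-6,
               ignore_attr = TRUE)

  # perturbed 2x2 grid equals the dense normal-equations oracle
  offs2 <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                      dx = c(100, 0, 0, 104), dy = c(0, 100, 100, 0))
  lay2 <- solve_layout(offs2, 4)
  expect_equal(lay2$positions, dense_layout(offs2, 4), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(solve_layout(data.frame(i = 1, j = 2, dx = 1, dy = 1), 4),
               "disconnected")
})

test_that("noisy layouts average the error down (RMSE <= sigma)", {
  g <- gen_tile_grid(3, 3, 128, 0.06, seed = 31)
  base <- NULL
  for (i in 1:9) for (j in 1:9) {
    if (i >= j) next
    dr <- abs(g$grid_index[j, 1] - g$grid_index[i, 1])
    dc <- abs(g$grid_index[j, 2] - g$grid_index[i, 2])
    if (dr + dc != 1) next
    base <- rbind(base, data.frame(
      i = i, j = j,
      dx = g$true_positions[j, 1] - g$true_positions[i, 1],
      dy = g$true_positions[j, 2] - g$true_positions[i, 2]))
  }
  tpos <- sweep(g$true_positions, 2, g$true_positions[1, ])
  sigma <- 2
  sq <- c()
  set.seed(77)
  for (rep in 1:20) {
    noisy <- base
    noisy$dx <- noisy$dx + rnorm(nrow(base), 0, sigma)
    noisy$dy <- noisy$dy + rnorm(nrow(base), 0, sigma)
    lay <- solve_layout(noisy, 9)
    err <- lay$positions - tpos
    err <- sweep(err, 2, colMeans(err))   # positions are defined up to a
    sq <- c(sq, rowSums(err^2))           # common translation
  }
  expect_lte(sqrt(mean(sq) / 2), sigma)   # per-coordinate RMSE
})

test_that("contrast model recovers known histogram parameters", {
  set.seed(5)
  img <- matrix(rnorm(400 * 400, 30000, 1000), 400)
  cm <- fit_contrast(img)
  expect_lt(abs(cm$peak - 30000), 20)
  expect_lt(abs(cm$sigma - 1000), 20)
  expect_equal(cm$k, 2)

  # robustness: 10% uniform outliers barely move the fitted peak
  imgo <- img
  n_out <- round(0.1 * length(img))
  imgo[sample(length(img), n_out)] <- runif(n_out, 0, 65535)
  cmo <- fit_contrast(imgo)
  expect_lt(abs(cmo$peak - cm$peak), 100)   # sigma / 10

  expect_error(fit_contrast(matrix(4, 10, 10)), "constant")
})

test_that("8-bit conversion maps the model window linearly, half-up", {
  cm <- structure(list(peak = 30000, sigma = 1000, k = 2),
                  class = "contrast_model")
  expect_equal(as.integer(normalize_contrast(matrix(30000), cm)), 128L)
  expect_equal(as.integer(normalize_contrast(matrix(28000), cm)), 0L)
  expect_equal(as.integer(normalize_contrast(matrix(1000), cm)), 0L)
  expect_equal(as.integer(normalize_contrast(matrix(32000), cm)), 255L)
  expect_equal(as.integer(normalize_contrast(matrix(65000), cm)), 255L)
  x <- matrix(seq(27000, 33000, by = 40), 1)
  y <- as.integer(normalize_contrast(x, cm))
  expect_true(all(diff(y) >= 0))           # monotone

  # re-fit + re-normalize of an already normalized image is stable
  set.seed(8)
  img <- matrix(rnorm(300 * 300, 30000, 1000), 300)
  n1 <- normalize_contrast(img, fit_contrast(img))
  n2 <- normalize_contrast(n1, fit_contrast(n1 * 1.0))
  expect_lte(max(abs(n2 - n1)), 1)
})

test_that("stitching is exact on single coverage and tracks provenance", {
  tex <- gen_texture(96, 96, seed = 14)
  lay1 <- solve_layout(data.frame(), 1, 1)
  st1 <- stitch(list(tex), lay1)
  expect_identical(st1$mosaic, tex)
  expect_true(all(st1$mask == 1))

  g <- gen_tile_grid(1, 2, 64, 0.08, seed = 15)
  offs <- data.frame(i = 1, j = 2,
                     dx = g$true_positions[2, 1] - g$true_positions[1, 1],
                     dy = 0)
  lay <- solve_layout(offs, 2)
  st <- stitch(g$tiles, lay)
  w <- max(g$true_positions[, 1]) + 64
  expect_equal(dim(st$mosaic), c(64, w))
  # noiseless tiles from one texture: mosaic equals the texture everywhere
  expect_equal(st$mosaic, g$texture[1:64, 1:w])
  expect_true(all(st$mask %in% 1:2))
})

test_that("the full section pipeline recovers a jittered grid", {
  g <- gen_tile_grid(2, 2, 128, 0.15, jitter = 3, seed = 41,
                     correlation_length = 2)
  res <- register_section(g$tiles, g$grid_index, nominal_overlap = 0.15)
  tpos <- sweep(g$true_positions, 2, g$true_positions[1, ])
  expect_equal(res$layout$positions, tpos, tolerance = 1e-6,
               ignore_attr = TRUE)
  x0 <- min(g$true_positions[, 1]); y0 <- min(g$true_positions[, 2])
  expect_equal(res$mosaic,
               g$texture[y0 + seq_len(nrow(res$mosaic)),
                         x0 + seq_len(ncol(res$mosaic))])
})
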