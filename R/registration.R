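#' Standardize an image for cross-correlation
#'
#' Columns are standardized by subtracting the mean and dividing by the
#' standard deviation of the pixel intensities; the same standardization
#' is then applied to the rows. This whitening step removes the slow
#' intensity gradients of block-face images so that the cross-correlation
#' peak reflects texture, not illumination.
#'
#' Zero-variance columns or rows are set to all zeros (with a warning)
#' rather than raising an error.
#'
#' @param image numeric matrix (rows = y, columns = x), at least 2 x 2.
#' @return numeric matrix of the same size; every row has mean 0 and
#'   standard deviation 1 (unless it was degenerate).
#' @export
standardize <- function(image) {
  if (nrow(image) < 2 || ncol(image) < 2)
    stop("image must have at least 2 rows and 2 columns")
  std1 <- function(m, margin, what) {
    mu <- apply(m, margin, mean)
    sd_ <- apply(m, margin, stats::sd)
    bad <- sd_ == 0 | !is.finite(sd_)
    if (any(bad)) {
      warning(sum(bad), " zero-variance ", what, "(s) set to zero")
      sd_[bad] <- 1
    }
    out <- if (margin == 2) sweep(sweep(m, 2, mu), 2, sd_, `/`)
           else sweep(sweep(m, 1, mu), 1, sd_, `/`)
    if (any(bad)) {
      if (margin == 2) out[, bad] <- 0 else out[bad, ] <- 0
    }
    out
  }
  std1(std1(image, 2, "column"), 1, "row")
}

#' Estimate the translational offset between two tiles
#'
#' The maximum of the 2-D cross-correlation of the standardized images,
#' computed in the Fourier domain and restricted to the central window of
#' the correlogram corresponding to a maximal expected offset between
#' overlapping tiles (default 256 pixels). No sub-pixel refinement is
#' applied; ties are broken by the smallest offset norm, then
#' lexicographically, for deterministic output.
#'
#' The returned `(dx, dy)` satisfies `imageB(u) ~ imageA(u + (dx, dy))`
#' over the overlap, i.e. it is the displacement of B's origin relative to
#' A's in mosaic coordinates.
#'
#' @param imageA,imageB numeric matrices of identical size.
#' @param max_offset half-width of the correlogram search window, pixels.
#' @return list of class `"offset_estimate"` with integer `dx`, `dy` and
#'   `peak_score` (the correlation value at the peak).
#' @export
estimate_offset <- function(imageA, imageB, max_offset = 256) {
  if (!all(dim(imageA) == dim(imageB)))
    stop("images must have the same shape")
  if (max_offset >= min(dim(imageA)) / 2)
    stop("max_offset must be smaller than half the image size")
  a <- standardize(imageA)
  b <- standardize(imageB)
  if (all(a == 0) || all(b == 0))
    stop("no signal: image is degenerate after standardization")
  nr <- nrow(a); nc <- ncol(a)
  # zero-pad (the standardized mean is 0) so circular correlation within
  # the window equals linear correlation
  pr <- stats::nextn(nr + max_offset, c(2, 3, 5))
  pc <- stats::nextn(nc + max_offset, c(2, 3, 5))
  ap <- matrix(0, pr, pc); ap[1:nr, 1:nc] <- a
  bp <- matrix(0, pr, pc); bp[1:nr, 1:nc] <- b
  # C(d) = sum_u A(u + d) * B(u) = IFFT(FFT(A) * Conj(FFT(B)))
  cc <- Re(stats::fft(stats::fft(ap) * Conj(stats::fft(bp)),
                      inverse = TRUE)) / (pr * pc)
  lag <- -max_offset:max_offset
  rows <- ifelse(lag >= 0, lag + 1, pr + lag + 1)
  cols <- ifelse(lag >= 0, lag + 1, pc + lag + 1)
  win <- cc[rows, cols]          # win[iy, ix] = C(dy = lag[iy], dx = lag[ix])
  peak <- max(win)
  hits <- which(win >= peak, arr.ind = TRUE)
  dys <- lag[hits[, 1]]; dxs <- lag[hits[, 2]]
  ord <- order(dxs^2 + dys^2, dxs, dys)
  structure(list(dx = as.integer(dxs[ord[1]]), dy = as.integer(dys[ord[1]]),
                 peak_score = peak, pair = c(NA_integer_, NA_integer_)),
            class = "offset_estimate")
}

#' @exportS3Method base::print
print.offset_estimate <- function(x, ...) {
  cat(sprintf("offset dx=%d dy=%d (peak %.4g)\n", x$dx, x$dy, x$peak_score))
  invisible(x)
}

#' Globally optimize tile positions from pairwise offsets
#'
#' Places all tiles of a section so that the sum of squared displacement
#' residuals over all measured pairs, `sum || (p_j - p_i) - (dx, dy)_ij ||^2`,
#' is minimal -- the global least-squares placement of the mosaicking
#' pipeline. The anchor tile is fixed at the origin to remove the
#' translational gauge freedom. Solved per coordinate as a sparse normal
#' system. Optional weights (e.g. correlation peak scores) are off by
#' default.
#'
#' @param offsets data.frame (or list of rows) with columns `i`, `j`
#'   (tile ids in `1..n_tiles`), `dx`, `dy` and optionally `weight`.
#' @param n_tiles number of tiles.
#' @param anchor tile id fixed at (0, 0).
#' @param weighted if `TRUE`, residuals are weighted by `offsets$weight`.
#' @return list of class `"section_layout"`: `positions` (n x 2 matrix,
#'   mosaic pixels), `anchor_tile`, `residuals` (per-pair Euclidean
#'   displacement error, pixels).
#' @export
solve_layout <- function(offsets, n_tiles, anchor = 1L, weighted = FALSE) {
  offsets <- as.data.frame(offsets)
  if (!(anchor %in% seq_len(n_tiles))) stop("anchor tile does not exist")
  if (n_tiles == 1) {
    return(structure(list(positions = matrix(0, 1, 2,
                            dimnames = list(NULL, c("x", "y"))),
                          anchor_tile = anchor, residuals = numeric(0)),
                     class = "section_layout"))
  }
  # connectivity check on the pair graph
  comp <- integer(n_tiles)
  comp[anchor] <- 1L
  queue <- anchor
  nbr <- split(c(offsets$j, offsets$i), c(offsets$i, offsets$j))
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in nbr[[as.character(v)]]) {
      if (comp[w] == 0L) { comp[w] <- 1L; queue <- c(queue, w) }
    }
  }
  if (any(comp == 0L))
    stop("pair graph is disconnected; unreachable tiles: ",
         paste(which(comp == 0L), collapse = ", "))
  m <- nrow(offsets)
  w <- if (weighted && !is.null(offsets$weight)) offsets$weight else rep(1, m)
  # design matrix rows: p_j - p_i = d, anchor column dropped
  free <- setdiff(seq_len(n_tiles), anchor)
  colmap <- match(seq_len(n_tiles), free)   # NA for anchor
  ii <- c(seq_len(m), seq_len(m))
  jj <- c(colmap[offsets$i], colmap[offsets$j])
  xx <- c(rep(-1, m), rep(1, m)) * sqrt(rep(w, 2))
  keep <- !is.na(jj)
  A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(m, length(free)))
  AtA <- Matrix::crossprod(A)
  sol <- function(d) {
    b <- Matrix::crossprod(A, d * sqrt(w))
    as.numeric(Matrix::solve(AtA, b))
  }
  px <- sol(offsets$dx); py <- sol(offsets$dy)
  positions <- matrix(0, n_tiles, 2, dimnames = list(NULL, c("x", "y")))
  positions[free, 1] <- px
  positions[free, 2] <- py
  rx <- positions[offsets$j, 1] - positions[offsets$i, 1] - offsets$dx
  ry <- positions[offsets$j, 2] - positions[offsets$i, 2] - offsets$dy
  structure(list(positions = positions, anchor_tile = anchor,
                 residuals = sqrt(rx^2 + ry^2)),
            class = "section_layout")
}

#' Fit a Gaussian contrast model to an intensity histogram
#'
#' Fits a Gaussian to the dominant mode of the 16-bit pixel intensity
#' histogram; the fitted peak and width parameterize the linear 8-bit
#' conversion of [normalize_contrast()], thresholding at `k` standard
#' deviations around the peak (valid range 1.5--3). The fit is restricted
#' to +/- 3 MAD around the histogram mode, which keeps the dark-axon and
#' silver-particle tails of EM histograms from biasing the estimate.
#'
#' @param image numeric matrix of 16-bit intensities.
#' @param k threshold multiplier in standard deviations; default 2.
#' @return list of class `"contrast_model"` with `peak`, `sigma`, `k`.
#' @export
fit_contrast <- function(image, k = 2.0) {
  v <- as.numeric(image)
  if (stats::sd(v) == 0) stop("no signal: image is constant")
  if (k < 1.5 || k > 3)
    warning("k = ", k, " is outside the usual 1.5-3 range")
  med <- stats::median(v)
  mad_ <- stats::mad(v)
  if (mad_ == 0) mad_ <- stats::sd(v)
  # histogram at integer-friendly bin width
  bw <- max(1, round(2 * stats::IQR(v) * length(v)^(-1/3) / 4))
  breaks <- seq(floor(min(v)) - bw / 2, ceiling(max(v)) + bw, by = bw)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  # drop the extreme bins: saturated/clipped pixels pile up there and
  # would bias the Gaussian fit
  counts <- h$counts
  keep <- rep(TRUE, length(counts))
  if (length(counts) > 4) keep[c(1, length(counts))] <- FALSE
  mode_x <- h$mids[keep][which.max(counts[keep])]
  sel <- keep & abs(h$mids - mode_x) <= 3 * mad_
  x <- h$mids[sel]; y <- h$counts[sel]
  fit <- try(stats::nls(
    y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
    start = list(a = max(y), mu = mode_x, s = mad_),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    peak <- mode_x; sigma <- mad_
  } else {
    cf <- stats::coef(fit)
    peak <- as.numeric(cf["mu"]); sigma <- abs(as.numeric(cf["s"]))
  }
  structure(list(peak = peak, sigma = sigma, k = k),
            class = "contrast_model")
}

#' Convert a 16-bit image to 8 bit using a contrast model
#'
#' Linear map sending `peak - k*sigma` to 0 and `peak + k*sigma` to 255,
#' clipped to \[0, 255\] and rounded half-up.
#'
#' @param image numeric matrix of 16-bit intensities.
#' @param model a [fit_contrast()] model.
#' @return integer matrix in \[0, 255\].
#' @export
normalize_contrast <- function(image, model) {
  lo <- model$peak - model$k * model$sigma
  span <- 2 * model$k * model$sigma
  y <- (image - lo) / span * 255
  y <- pmin(pmax(y, 0), 255)
  out <- floor(y + 0.5)              # round half-up, not banker's
  storage.mode(out) <- "integer"
  dim(out) <- dim(image)
  out
}

#' Assemble a mosaic from placed tiles
#'
#' Pastes tiles at their (rounded) layout positions into a mosaic the
#' size of the bounding box. Single-coverage pixels equal the source tile
#' exactly. In overlaps, `blend = "last"` lets the later tile win
#' (bit-exact, the default) and `blend = "feather"` averages with linear
#' distance-to-edge weights.
#'
#' @param tiles list of numeric matrices.
#' @param layout a [solve_layout()] result (positions in pixels).
#' @param blend `"last"` or `"feather"`.
#' @return list: `mosaic` (matrix), `mask` (integer matrix, contributing
#'   tile index per pixel, 0 = uncovered), `origin` (x, y of the mosaic's
#'   top-left corner in layout coordinates).
#' @export
stitch <- function(tiles, layout, blend = c("last", "feather")) {
  blend <- match.arg(blend)
  pos <- round(layout$positions)
  if (nrow(pos) != length(tiles)) stop("layout does not cover all tiles")
  hs <- vapply(tiles, nrow, 0L); ws <- vapply(tiles, ncol, 0L)
  x0 <- min(pos[, 1]); y0 <- min(pos[, 2])
  W <- max(pos[, 1] + ws) - x0
  H <- max(pos[, 2] + hs) - y0
  mosaic <- matrix(0, H, W)
  mask <- matrix(0L, H, W)
  wsum <- if (blend == "feather") matrix(0, H, W)
  for (i in seq_along(tiles)) {
    rr <- (pos[i, 2] - y0 + 1):(pos[i, 2] - y0 + hs[i])
    cc <- (pos[i, 1] - x0 + 1):(pos[i, 1] - x0 + ws[i])
    if (blend == "last") {
      mosaic[rr, cc] <- tiles[[i]]
      mask[rr, cc] <- i
    } else {
      dr <- pmin(seq_len(hs[i]), rev(seq_len(hs[i])))
      dc <- pmin(seq_len(ws[i]), rev(seq_len(ws[i])))
      wt <- outer(dr, dc, pmin)
      mosaic[rr, cc] <- mosaic[rr, cc] + tiles[[i]] * wt
      wsum[rr, cc] <- wsum[rr, cc] + wt
      mask[rr, cc] <- i
    }
  }
  if (blend == "feather") {
    nz <- wsum > 0
    mosaic[nz] <- mosaic[nz] / wsum[nz]
  }
  list(mosaic = mosaic, mask = mask, origin = c(x = x0, y = y0))
}

#' Register and stitch one section's tile grid
#'
#' Convenience pipeline: for every adjacent tile pair the nominal
#' overlap strips are cut out (tiles overlap by only a few percent, so
#' correlating whole tiles would be dominated by non-shared content),
#' the residual displacement between the strips is estimated by
#' [estimate_offset()] -- the search window then bounds the deviation of
#' the true offset from the nominal one -- the global layout is solved,
#' and the mosaic is assembled.
#'
#' @param tiles list of tile matrices (row-major grid order).
#' @param grid_index n x 2 matrix of (row, col) per tile.
#' @param nominal_overlap nominal overlap fraction of the tile edge.
#' @param max_offset search window for [estimate_offset()]; clamped to
#'   fit the strip size.
#' @param blend blend policy for [stitch()].
#' @return list: `layout`, `offsets` (data.frame), `mosaic`, `mask`.
#' @export
register_section <- function(tiles, grid_index, nominal_overlap = 0.065,
                             max_offset = 256, blend = "last") {
  n <- length(tiles)
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      dr <- grid_index[j, 1] - grid_index[i, 1]
      dc <- grid_index[j, 2] - grid_index[i, 2]
      if (abs(dr) + abs(dc) != 1) next   # 4-neighborhood only
      a <- if (dr + dc > 0) i else j     # a is the up/left tile
      b <- if (dr + dc > 0) j else i
      if (abs(dc) == 1) {                # horizontal neighbors
        ov <- max(4L, round(nominal_overlap * tw))
        stripA <- tiles[[a]][, (tw - ov + 1):tw, drop = FALSE]
        stripB <- tiles[[b]][, 1:ov, drop = FALSE]
        nominal <- c(tw - ov, 0L)
      } else {                           # vertical neighbors
        ov <- max(4L, round(nominal_overlap * th))
        stripA <- tiles[[a]][(th - ov + 1):th, , drop = FALSE]
        stripB <- tiles[[b]][1:ov, , drop = FALSE]
        nominal <- c(0L, th - ov)
      }
      mo <- min(max_offset, ceiling(min(dim(stripA)) / 2) - 1L)
      est <- estimate_offset(stripA, stripB, mo)
      rows[[length(rows) + 1L]] <-
        data.frame(i = a, j = b, dx = nominal[1] + est$dx,
                   dy = nominal[2] + est$dy, weight = est$peak_score)
    }
  }
  offsets <- do.call(rbind, rows)
  layout <- solve_layout(offsets, n_tiles = n, anchor = 1L)
  st <- stitch(tiles, layout, blend = blend)
  list(layout = layout, offsets = offsets, mosaic = st$mosaic,
       mask = st$mask)
}
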