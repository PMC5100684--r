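#' Cubed multi-resolution volume store
#'
#' Volumes are stored as fixed-edge 8-bit cubes (default 128^3), one raw
#' file per cube under `level/x####/y####/z####/cube.raw` (x-fastest
#' voxel order), with a plain-text `.conf` file describing the geometry.
#' This mirrors the KNOSSOS-style cubed layout used for dynamic data
#' loading while browsing large SBEM stacks. Voxels are anisotropic; the
#' default pitch is 9.25 x 9.25 x 25 nm.
#'
#' @name cube_store
NULL

cube_path <- function(root, level, cx, cy, cz) {
  file.path(root, level, sprintf("x%04d", cx), sprintf("y%04d", cy),
            sprintf("z%04d", cz), "cube.raw")
}

level_dims <- function(store, level) ceiling(store$dimensions / 2^level)

write_conf <- function(store) {
  lines <- c(
    paste0("name=", store$name),
    paste0("cube_edge=", store$cube_edge),
    sprintf("scale_x=%g", store$voxel_size[1]),
    sprintf("scale_y=%g", store$voxel_size[2]),
    sprintf("scale_z=%g", store$voxel_size[3]),
    sprintf("dims_x=%d", store$dimensions[1]),
    sprintf("dims_y=%d", store$dimensions[2]),
    sprintf("dims_z=%d", store$dimensions[3]),
    paste0("levels=", store$n_levels))
  if (!is.null(store$z_gaps) && length(store$z_gaps))
    lines <- c(lines, paste0("z_gaps=", paste(store$z_gaps, collapse = ",")))
  if (!is.null(store$source_url_template))
    lines <- c(lines, paste0("source_url_template=",
                             store$source_url_template))
  writeLines(lines, file.path(store$root, paste0(store$name, ".conf")))
}

#' Open an existing cube store
#'
#' Reads the `.conf` geometry file in `root`.
#'
#' @param root store directory.
#' @return a `"cube_store"` object.
#' @export
cube_store_open <- function(root) {
  conf <- list.files(root, pattern = "\\.conf$", full.names = TRUE)
  if (!length(conf)) stop("no .conf file found in ", root)
  kv <- read_conf_kv(conf[1])
  store <- structure(list(
    root = root,
    name = kv[["name"]],
    cube_edge = as.integer(kv[["cube_edge"]]),
    voxel_size = as.numeric(c(kv[["scale_x"]], kv[["scale_y"]],
                              kv[["scale_z"]])),
    dimensions = as.integer(c(kv[["dims_x"]], kv[["dims_y"]],
                              kv[["dims_z"]])),
    n_levels = as.integer(kv[["levels"]]),
    z_gaps = if (!is.null(kv[["z_gaps"]]))
      as.integer(strsplit(kv[["z_gaps"]], ",")[[1]]) else integer(0)),
    class = "cube_store")
  store
}

read_conf_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
}

#' Build level-0 cubes from a volume
#'
#' Divides an 8-bit volume into cubes for dynamic data loading (default
#' edge 128, arbitrary edges supported) and writes the store to disk.
#' Boundary cubes are zero-padded to the full edge. Apply
#' [normalize_contrast()] first if the data are not 8-bit yet.
#'
#' @param volume 3-D integer array indexed `[x, y, z]` with values in
#'   0..255, or a list of section matrices (rows = y, columns = x)
#'   stacked along z.
#' @param root output directory (created).
#' @param voxel_size nm per voxel, length 3.
#' @param cube_edge cube edge length in voxels.
#' @param name dataset name (conf file stem).
#' @param z_gaps optional integer z indices after which a section is
#'   missing (recorded in the metadata; no interpolated data is
#'   fabricated).
#' @return a `"cube_store"` object.
#' @export
build_cubes <- function(volume, root, voxel_size = c(9.25, 9.25, 25),
                        cube_edge = 128, name = "dataset",
                        z_gaps = integer(0)) {
  if (is.list(volume)) {
    shapes <- vapply(volume, dim, integer(2))
    bad <- which(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])
    if (length(bad))
      stop("inconsistent section shape at section ", bad[1])
    volume <- aperm(array(unlist(volume),
                          c(shapes[1, 1], shapes[2, 1], length(volume))),
                    c(2, 1, 3))   # (y,x,z) -> (x,y,z)
  }
  if (length(dim(volume)) != 3) stop("volume must be 3-D")
  if (min(volume) < 0 || max(volume) > 255)
    stop("volume must be 8-bit (0..255); apply normalize_contrast first")
  dims <- dim(volume)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  store <- structure(list(root = root, name = name,
                          cube_edge = as.integer(cube_edge),
                          voxel_size = voxel_size,
                          dimensions = as.integer(dims), n_levels = 1L,
                          z_gaps = as.integer(z_gaps)),
                     class = "cube_store")
  write_level(store, volume, 0L)
  write_conf(store)
  store
}

write_level <- function(store, volume, level) {
  e <- store$cube_edge
  dims <- dim(volume)
  ncubes <- ceiling(dims / e)
  for (cz in 0:(ncubes[3] - 1)) for (cy in 0:(ncubes[2] - 1))
    for (cx in 0:(ncubes[1] - 1)) {
      cube <- array(0L, c(e, e, e))
      xs <- (cx * e + 1):min((cx + 1) * e, dims[1])
      ys <- (cy * e + 1):min((cy + 1) * e, dims[2])
      zs <- (cz * e + 1):min((cz + 1) * e, dims[3])
      cube[seq_along(xs), seq_along(ys), seq_along(zs)] <-
        volume[xs, ys, zs, drop = FALSE]
      p <- cube_path(store$root, level, cx, cy, cz)
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      writeBin(as.raw(cube), p)
    }
  invisible(store)
}

#' @exportS3Method base::print
print.cube_store <- function(x, ...) {
  cat(sprintf("cube store '%s': %d x %d x %d voxels, edge %d, %d level(s)\n",
              x$name, x$dimensions[1], x$dimensions[2], x$dimensions[3],
              x$cube_edge, x$n_levels))
  invisible(x)
}

#' Build a multi-scale pyramid
#'
#' Adds zoom levels 1..`n_levels - 1`, each 2 x 2 x 2 mean-pooled from
#' the level below (rounding half-up); level `l` has per-axis dimensions
#' `ceiling(dim / 2^l)`. Boundary blocks average only the voxels that
#' exist (padding never leaks into the mean).
#'
#' @param store a `"cube_store"`.
#' @param n_levels total number of levels including level 0.
#' @return the updated store.
#' @export
build_pyramid <- function(store, n_levels) {
  if (n_levels - 1 > floor(log2(min(store$dimensions))))
    stop("n_levels exceeds log2 of the smallest dimension")
  for (l in seq_len(n_levels - 1)) {
    below <- read_subvolume(store, c(0, 0, 0), level_dims(store, l - 1),
                            level = l - 1)
    pooled <- pool2(below)
    store$n_levels <- l + 1L
    write_level(store, pooled, l)
  }
  write_conf(store)
  store
}

# 2x2x2 mean pooling onto the ceil(d/2) grid; partial boundary blocks
# average over the voxels present; round half-up
pool2 <- function(v) {
  d <- dim(v)
  nd <- ceiling(d / 2)
  s <- array(0, nd); cnt <- array(0, nd)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    xs <- seq(1 + ox, d[1], by = 2)
    ys <- seq(1 + oy, d[2], by = 2)
    zs <- seq(1 + oz, d[3], by = 2)
    if (!length(xs) || !length(ys) || !length(zs)) next
    s[seq_along(xs), seq_along(ys), seq_along(zs)] <-
      s[seq_along(xs), seq_along(ys), seq_along(zs)] +
      v[xs, ys, zs, drop = FALSE]
    cnt[seq_along(xs), seq_along(ys), seq_along(zs)] <-
      cnt[seq_along(xs), seq_along(ys), seq_along(zs)] + 1
  }
  out <- floor(s / cnt + 0.5)
  storage.mode(out) <- "integer"
  out
}

read_cube_file <- function(path, edge) {
  if (!file.exists(path)) return(NULL)
  raw <- readBin(path, what = "raw", n = edge^3)
  a <- array(as.integer(raw), c(edge, edge, edge))
  a
}

#' Read a subvolume from the store
#'
#' Returns the stored voxels of an axis-aligned box at a given level;
#' voxels outside the stack are 0 and an `out_of_bounds` attribute flags
#' whether any part of the request fell outside.
#'
#' @param store a `"cube_store"`.
#' @param origin 0-based voxel coordinates of the box corner at `level`.
#' @param shape box size in voxels, length 3.
#' @param level zoom level (0 = native).
#' @return integer array `[x, y, z]` of size `shape`.
#' @export
read_subvolume <- function(store, origin, shape, level = 0) {
  if (level < 0 || level >= store$n_levels)
    stop("level ", level, " does not exist (store has ",
         store$n_levels, ")")
  origin <- as.integer(origin); shape <- as.integer(shape)
  dims <- level_dims(store, level)
  out <- array(0L, shape)
  lo <- pmax(origin, 0L)
  hi <- pmin(origin + shape, dims)
  oob <- any(origin < 0) || any(origin + shape > dims)
  if (any(lo >= hi)) {
    attr(out, "out_of_bounds") <- TRUE
    return(out)
  }
  e <- store$cube_edge
  crange <- function(a) (lo[a] %/% e):((hi[a] - 1L) %/% e)
  for (cz in crange(3)) for (cy in crange(2)) for (cx in crange(1)) {
    cube <- read_cube_file(cube_path(store$root, level, cx, cy, cz), e)
    if (is.null(cube))
      stop("missing cube file at level=", level, " cx=", cx,
           " cy=", cy, " cz=", cz)
    c0 <- c(cx, cy, cz) * e
    glo <- pmax(lo, c0); ghi <- pmin(hi, c0 + e)
    out[(glo[1] - origin[1] + 1):(ghi[1] - origin[1]),
        (glo[2] - origin[2] + 1):(ghi[2] - origin[2]),
        (glo[3] - origin[3] + 1):(ghi[3] - origin[3])] <-
      cube[(glo[1] - c0[1] + 1):(ghi[1] - c0[1]),
           (glo[2] - c0[2] + 1):(ghi[2] - c0[2]),
           (glo[3] - c0[3] + 1):(ghi[3] - c0[3]), drop = FALSE]
  }
  attr(out, "out_of_bounds") <- oob
  out
}

#' Create a cube cache
#'
#' Hybrid persistent cache: every cube fetched from the backing store is
#' written through to a local disk cache (so it is downloaded at most
#' once and remains available offline), and a least-recently-used subset
#' is kept resident in memory within a byte budget.
#'
#' @param disk_cache_root directory for the persistent disk cache.
#' @param memory_budget maximum resident bytes in memory.
#' @return an environment of class `"cube_cache"`.
#' @export
cube_cache <- function(disk_cache_root = tempfile("cube_cache_"),
                       memory_budget = 512 * 1024^2) {
  dir.create(disk_cache_root, recursive = TRUE, showWarnings = FALSE)
  e <- new.env(parent = emptyenv())
  e$disk_cache_root <- disk_cache_root
  e$memory_budget <- memory_budget
  e$resident <- list()      # key -> list(bytes, tick)
  e$tick <- 0L
  e$fetch_count <- 0L       # backing-source reads
  class(e) <- "cube_cache"
  e
}

#' Resident cube addresses of a cache
#' @param cache a [cube_cache()].
#' @return data.frame with columns `level`, `cx`, `cy`, `cz`.
#' @export
cache_resident <- function(cache) {
  keys <- names(cache$resident)
  if (!length(keys))
    return(data.frame(level = integer(0), cx = integer(0),
                      cy = integer(0), cz = integer(0)))
  m <- do.call(rbind, lapply(strsplit(keys, "/"), as.integer))
  data.frame(level = m[, 1], cx = m[, 2], cy = m[, 3], cz = m[, 4])
}

#' Load the cube neighborhood around a focal point
#'
#' Makes resident every cube intersecting the axis-aligned box of edge
#' `extent` around the focal point, at each requested zoom level (the
#' focal point is rescaled per level). While browsing, consecutive zoom
#' levels l-1, l, l+1 are typically requested with an extent of 320--576
#' voxels. Previously fetched cubes are served from the persistent disk
#' cache without touching the backing source; memory residency is
#' evicted least-recently-used beyond the budget.
#'
#' @param store a `"cube_store"` (the backing source).
#' @param cache a [cube_cache()]; updated in place.
#' @param focal_point 0-based level-0 voxel coordinates, length 3.
#' @param extent neighborhood box edge in voxels (applied at each level).
#' @param levels integer vector of levels to load.
#' @return the cache, invisibly.
#' @export
load_neighborhood <- function(store, cache, focal_point, extent = 512,
                              levels = 0L) {
  for (l in levels) {
    if (l < 0 || l >= store$n_levels)
      stop("level ", l, " does not exist")
    f <- floor(focal_point / 2^l)
    lo <- floor(f - extent / 2)
    hi <- ceiling(f + extent / 2)       # half-open box [lo, hi)
    dims <- level_dims(store, l)
    lo <- pmax(lo, 0); hi <- pmin(hi, dims)
    if (any(lo >= hi)) next
    e <- store$cube_edge
    for (cz in (lo[3] %/% e):((hi[3] - 1) %/% e))
      for (cy in (lo[2] %/% e):((hi[2] - 1) %/% e))
        for (cx in (lo[1] %/% e):((hi[1] - 1) %/% e))
          cache_fetch(store, cache, l, cx, cy, cz)
  }
  invisible(cache)
}

cache_fetch <- function(store, cache, level, cx, cy, cz) {
  key <- paste(level, cx, cy, cz, sep = "/")
  cache$tick <- cache$tick + 1L
  if (!is.null(cache$resident[[key]])) {
    cache$resident[[key]]$tick <- cache$tick
    return(invisible(TRUE))
  }
  local <- cube_path(cache$disk_cache_root, level, cx, cy, cz)
  if (!file.exists(local)) {
    src <- cube_path(store$root, level, cx, cy, cz)
    if (!file.exists(src))
      stop("cannot fetch cube level=", level, " cx=", cx, " cy=", cy,
           " cz=", cz, ": backing source has no such cube")
    dir.create(dirname(local), recursive = TRUE, showWarnings = FALSE)
    file.copy(src, local)
    cache$fetch_count <- cache$fetch_count + 1L
  }
  bytes <- store$cube_edge^3
  cache$resident[[key]] <- list(bytes = bytes, tick = cache$tick)
  # LRU eviction (disk copy is kept; only memory residency is dropped)
  repeat {
    total <- sum(vapply(cache$resident, `[[`, 0, "bytes"))
    if (total <= cache$memory_budget || length(cache$resident) <= 1) break
    ticks <- vapply(cache$resident, `[[`, 0L, "tick")
    cache$resident[[names(which.min(ticks))]] <- NULL
  }
  invisible(TRUE)
}

# trilinear interpolation of a [x,y,z] array at 0-based float voxel
# coordinates; samples outside the array are 0
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  n <- nrow(pts)
  out <- numeric(n)
  i0 <- floor(pts)
  fr <- pts - i0
  val <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    v <- numeric(n)
    idx <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
    v[ok] <- vol[idx]
    v
  }
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    w <- (if (ox) fr[, 1] else 1 - fr[, 1]) *
         (if (oy) fr[, 2] else 1 - fr[, 2]) *
         (if (oz) fr[, 3] else 1 - fr[, 3])
    if (!any(w > 0)) next
    out <- out + w * val(i0[, 1] + ox, i0[, 2] + oy, i0[, 3] + oz)
  }
  out
}

#' Extract an arbitrarily oriented reslice
#'
#' Samples a plane through the volume by trilinear interpolation, the
#' mechanism behind orthogonal tracing views at arbitrary orientations
#' and zoom levels. The plane is spanned by the orthonormal directions
#' `u` (output rows) and `v` (output columns) around `center`;
#' `output(i, j)` samples the volume at
#' `center + (i - ci) * pitch * u + (j - cj) * pitch * v`, where
#' `(ci, cj)` is the output center pixel. Positions are in nm and are
#' converted to voxel indices with the anisotropic voxel pitch (times
#' `2^level`). Samples outside the stack are 0.
#'
#' @param store a `"cube_store"`.
#' @param center nm position, length 3.
#' @param u,v orthonormal direction vectors (checked to 1e-9).
#' @param out_shape output size in pixels, length 2 (rows, cols).
#' @param pixel_pitch output pixel pitch in nm.
#' @param level zoom level.
#' @return numeric matrix of size `out_shape`.
#' @export
reslice_plane <- function(store, center, u, v, out_shape, pixel_pitch,
                          level = 0) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (abs(sum(u * v)) > 1e-9 || abs(sum(u^2) - 1) > 1e-9 ||
      abs(sum(v^2) - 1) > 1e-9)
    stop("u and v must be orthonormal")
  if (level < 0 || level >= store$n_levels) stop("level does not exist")
  ni <- out_shape[1]; nj <- out_shape[2]
  ci <- (ni + 1) / 2; cj <- (nj + 1) / 2
  ii <- rep(seq_len(ni), times = nj)
  jj <- rep(seq_len(nj), each = ni)
  pts_nm <- outer((ii - ci) * pixel_pitch, u) +
            outer((jj - cj) * pixel_pitch, v)
  pts_nm <- sweep(pts_nm, 2, center, `+`)
  vsize <- store$voxel_size * 2^level
  pts_vox <- sweep(pts_nm, 2, vsize, `/`)
  dims <- level_dims(store, level)
  lo <- pmax(floor(apply(pts_vox, 2, min)) - 1, 0)
  hi <- pmin(ceiling(apply(pts_vox, 2, max)) + 2, dims)
  if (any(lo >= hi)) return(matrix(0, ni, nj))
  sub <- read_subvolume(store, lo, hi - lo, level = level)
  vals <- trilinear_sample(sub, sweep(pts_vox, 2, lo, `-`))
  matrix(vals, ni, nj)
}
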