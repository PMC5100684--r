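# Run code under a private, seeded RNG stream without touching global
# RNG state. All fixture generators are pure functions of their seed.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a band-limited random texture
#'
#' Low-pass-filtered white noise (Gaussian kernel of width
#' `correlation_length`), rescaled to the 16-bit intensity range, with
#' optional additive white noise. The spatial autocorrelation has a unique
#' sharp peak at zero lag, emulating the membrane-rich texture of
#' block-face EM images that makes them registration-friendly.
#'
#' @param width,height raster size in pixels (>= 16).
#' @param correlation_length Gaussian smoothing width in pixels (>= 1).
#' @param noise_sd additive white-noise sd as a fraction of the intensity
#'   range.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return numeric matrix (`height` rows, `width` columns) in \[0, 65535\].
#' @export
gen_texture <- function(width, height, correlation_length = 4,
                        noise_sd = 0, seed = 1) {
  if (width < 16 || height < 16)
    stop("texture dimensions must be at least 16 pixels")
  if (correlation_length < 1) stop("correlation_length must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_local_seed(seed, {
    z <- matrix(stats::rnorm(height * width), height, width)
    # Gaussian low-pass in the Fourier domain (periodic boundary)
    fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
    fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
    h <- exp(-2 * pi^2 * correlation_length^2 *
               (outer(fy^2, rep(1, width)) + outer(rep(1, height), fx^2)))
    zs <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / (height * width)
    zs <- (zs - min(zs)) / (max(zs) - min(zs))
    if (noise_sd > 0) zs <- zs + stats::rnorm(length(zs), sd = noise_sd)
    round(pmin(pmax(zs, 0), 1) * 65535)
  })
}

#' Generate a pair of tiles with a known translational offset
#'
#' Cuts two equally sized tiles out of one texture, the second displaced by
#' an exact integer offset; the overlapping content of the second tile
#' equals the first tile's content shifted by exactly `(dx, dy)` before
#' noise. Serves as ground truth for offset estimation.
#'
#' @param texture matrix from [gen_texture()] (rows = y, columns = x).
#' @param offset integer `(dx, dy)` displacement of tile B relative to
#'   tile A, in pixels.
#' @param tile_size tile edge in pixels (scalar, or `(width, height)`).
#' @param noise_sd additive Gaussian noise sd as a fraction of the 16-bit
#'   range, applied independently to each tile.
#' @param seed integer seed for the noise.
#' @return list with `tileA`, `tileB` (matrices) and `offset`.
#' @export
gen_tile_pair <- function(texture, offset, tile_size, noise_sd = 0,
                          seed = 1) {
  offset <- as.integer(round(offset))
  if (length(tile_size) == 1) tile_size <- c(tile_size, tile_size)
  w <- tile_size[1]; h <- tile_size[2]
  # 0-based origins chosen so both tiles fit in the texture
  ax <- max(0L, -offset[1]); ay <- max(0L, -offset[2])
  bx <- ax + offset[1]; by <- ay + offset[2]
  if (max(ax, bx) + w > ncol(texture) || max(ay, by) + h > nrow(texture))
    stop("tiles do not fit inside the texture at the requested offset")
  cut <- function(x0, y0) texture[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
  tileA <- cut(ax, ay); tileB <- cut(bx, by)
  if (noise_sd > 0) {
    with_local_seed(seed, {
      tileA <- tileA + stats::rnorm(length(tileA), sd = noise_sd * 65535)
      tileB <- tileB + stats::rnorm(length(tileB), sd = noise_sd * 65535)
    })
  }
  list(tileA = tileA, tileB = tileB, offset = offset)
}

#' Generate a tile grid with known ground-truth positions
#'
#' Emulates a section acquired as a mosaic of overlapping camera tiles:
#' adjacent tiles overlap by `overlap_fraction` of the tile edge (the
#' acquisition used 5--8 %), plus integer position jitter.
#'
#' @param rows,cols grid size (>= 1).
#' @param tile_size tile edge in pixels.
#' @param overlap_fraction scalar in (0, 1), or a length-2 range from
#'   which one value is drawn; default range `c(0.05, 0.08)`.
#' @param jitter maximum absolute integer jitter (pixels) added to each
#'   tile position per axis.
#' @param seed integer seed.
#' @param correlation_length texture smoothing width (pixels).
#' @param noise_sd per-tile additive noise fraction.
#' @return list of class `"tile_grid"`: `tiles` (row-major list of
#'   matrices), `true_positions` (n x 2 integer, 0-based mosaic pixels),
#'   `grid_index` (n x 2, row/col), `overlap_fraction`, `tile_size`,
#'   `texture` (the source mosaic).
#' @export
gen_tile_grid <- function(rows, cols, tile_size = 256,
                          overlap_fraction = c(0.05, 0.08), jitter = 0,
                          seed = 1, correlation_length = 4, noise_sd = 0) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  with_local_seed(seed, {
    if (length(overlap_fraction) == 2)
      overlap_fraction <- stats::runif(1, overlap_fraction[1],
                                       overlap_fraction[2])
    f <- overlap_fraction * tile_size
    if (floor(f + jitter) < 1 && (rows > 1 || cols > 1))
      stop("overlap too small: adjacent tiles may not overlap")
    # integer per-transition overlaps drawn inside [f - jitter, f + jitter],
    # so every adjacent pair overlaps by overlap_fraction * tile_size
    # within the stated jitter by construction
    draw_ov <- function(n) {
      lo <- ceiling(f - jitter); hi <- floor(f + jitter)
      if (lo > hi) rep(round(f), n)
      else lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
    }
    xs <- c(0L, cumsum(tile_size - draw_ov(max(cols - 1, 0))))
    ys <- c(0L, cumsum(tile_size - draw_ov(max(rows - 1, 0))))
    pos <- cbind(x = rep(xs, each = rows), y = rep(ys, times = cols))
    storage.mode(pos) <- "integer"
    mosaic_w <- max(pos[, 1]) + tile_size
    mosaic_h <- max(pos[, 2]) + tile_size
    tex_seed <- sample.int(.Machine$integer.max, 1)
    texture <- gen_texture(mosaic_w, mosaic_h, correlation_length,
                           seed = tex_seed)
    grid_index <- cbind(row = rep(seq_len(rows), times = cols),
                        col = rep(seq_len(cols), each = rows))
    tiles <- vector("list", nrow(pos))
    for (i in seq_len(nrow(pos))) {
      t <- texture[(pos[i, 2] + 1):(pos[i, 2] + tile_size),
                   (pos[i, 1] + 1):(pos[i, 1] + tile_size)]
      if (noise_sd > 0)
        t <- t + stats::rnorm(length(t), sd = noise_sd * 65535)
      tiles[[i]] <- t
    }
    structure(list(tiles = tiles, true_positions = pos,
                   grid_index = grid_index,
                   overlap_fraction = overlap_fraction,
                   tile_size = tile_size, texture = texture),
              class = "tile_grid")
  })
}

#' Generate a random branching skeleton
#'
#' Correlated random walk inside a bounding box, with side branches
#' sprouting at randomly chosen nodes. Every edge has length exactly
#' `step`, so inter-node spacing is uniform.
#'
#' @param n_branch_points number of side branches (0 gives a simple path).
#' @param volume numeric length-3 box size in nm.
#' @param step inter-node spacing in nm.
#' @param seed integer seed.
#' @param total_length approximate total path length in nm; the main path
#'   receives 60 % when branches are requested, all of it otherwise.
#' @param min_separation minimum distance (nm) kept between
#'   non-consecutive parts of the arbor. Neurite branches at this scale
#'   run micrometres apart from each other; the walk retries steps that
#'   would bring the path back within this distance of its own earlier
#'   segments.
#' @return a [skeleton()] in nm with a `branch_id` node column.
#' @export
gen_skeleton <- function(n_branch_points = 3,
                         volume = c(20000, 20000, 20000),
                         step = 100, seed = 1,
                         total_length = 50 * step * (1 + n_branch_points / 2),
                         min_separation = 1500) {
  if (step <= 0) stop("step must be positive")
  if (any(volume <= 0)) stop("volume must be non-degenerate")
  with_local_seed(seed, {
    rand_dir <- function() {
      v <- stats::rnorm(3); v / sqrt(sum(v^2))
    }
    recent <- max(2L, ceiling(min_separation / step) + 2L)
    # self-avoiding persistent walk: `avoid` holds all previously placed
    # nodes; the walk's own last few positions and a grace ball around
    # its start (the branch anchor region) are exempt
    walk <- function(start, n_steps, dir, avoid) {
      out <- matrix(0, n_steps + 1, 3)
      out[1, ] <- start
      p <- start
      if (nrow(avoid)) {
        g <- sqrt(rowSums(sweep(avoid, 2, start)^2)) > min_separation
        avoid <- avoid[g, , drop = FALSE]
      }
      for (k in seq_len(n_steps)) {
        best_q <- NULL; best_dir <- dir; best_clear <- -Inf
        for (try_ in 1:30) {
          d2 <- if (try_ <= 10) dir + 0.4 * stats::rnorm(3) else rand_dir()
          d2 <- d2 / sqrt(sum(d2^2))
          q <- p + step * d2
          for (a in 1:3) {
            if (q[a] < 0 || q[a] > volume[a]) {
              d2[a] <- -d2[a]
              q <- p + step * d2
            }
          }
          q <- pmin(pmax(q, 0), volume)
          hist <- out[seq_len(max(1, k - recent)), , drop = FALSE]
          pool <- rbind(avoid, hist)
          clear <- if (nrow(pool))
            min(sqrt(rowSums(sweep(pool, 2, q)^2))) else Inf
          if (clear >= min_separation) {
            best_q <- q; best_dir <- d2; best_clear <- clear
            break
          }
          if (clear > best_clear) {
            best_q <- q; best_dir <- d2; best_clear <- clear
          }
        }
        out[k + 1, ] <- best_q
        dir <- best_dir
        p <- best_q
      }
      list(pos = out, dir = dir)
    }
    main_frac <- if (n_branch_points > 0) 0.6 else 1
    n_main <- max(2, round(total_length * main_frac / step))
    start <- volume * stats::runif(3, 0.3, 0.7)
    m <- walk(start, n_main, rand_dir(),
              avoid = matrix(numeric(0), 0, 3))
    pos <- m$pos
    branch_id <- rep(0L, nrow(pos))
    edges <- cbind(seq_len(nrow(pos) - 1), 2:nrow(pos))
    if (n_branch_points > 0) {
      per_branch <- max(2, round(total_length * (1 - main_frac) /
                                   (step * n_branch_points)))
      # sprout from interior main-path nodes, spread apart
      anchors <- unique(round(seq(2, n_main - 1,
                                  length.out = n_branch_points)))
      for (b in seq_len(n_branch_points)) {
        a <- anchors[((b - 1) %% length(anchors)) + 1]
        w <- walk(pos[a, ], per_branch, rand_dir(), avoid = pos)
        new_idx <- nrow(pos) + seq_len(per_branch)
        pos <- rbind(pos, w$pos[-1, , drop = FALSE])
        branch_id <- c(branch_id, rep(b, per_branch))
        edges <- rbind(edges, cbind(c(a, new_idx[-per_branch]), new_idx))
      }
    }
    nodes <- data.frame(id = seq_len(nrow(pos)), x = pos[, 1],
                        y = pos[, 2], z = pos[, 3], radius = 1,
                        branch_id = branch_id)
    skeleton(nodes, edges, id = 1L, name = "synthetic", units = "nm")
  })
}

# total length of the subtree hanging below each node when the tree is
# rooted at `root` (includes the edge from the node's parent)
subtree_lengths <- function(skel, root) {
  adj <- skeleton_adjacency(skel)
  p <- skeleton_xyz_nm(skel)
  rownames(p) <- as.character(skel$nodes$id)
  parent <- new.env(parent = emptyenv())
  order_ids <- character(0)
  queue <- as.character(root)
  assign(queue, NA_character_, envir = parent)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_ids <- c(order_ids, v)
    for (w in as.character(adj[[v]])) {
      if (!exists(w, envir = parent, inherits = FALSE)) {
        assign(w, v, envir = parent)
        queue <- c(queue, w)
      }
    }
  }
  sub <- stats::setNames(numeric(length(order_ids)), order_ids)
  for (v in rev(order_ids)) {
    pa <- get(v, envir = parent)
    if (!is.na(pa)) {
      elen <- sqrt(sum((p[v, ] - p[pa, ])^2))
      sub[pa] <- sub[pa] + sub[v] + elen
      sub[v] <- sub[v] + elen
    }
  }
  list(sub = sub, parent = parent, order = order_ids)
}

#' Perturb a skeleton with tracer-style errors
#'
#' Emulates the two error classes of manual neurite tracing -- missed
#' processes (a truncated terminal subtree) and wrongly traced processes
#' (grafted spurious branches) -- plus i.i.d. positional jitter.
#'
#' @param skel a [skeleton()] (nm units).
#' @param jitter_sd positional jitter sd per coordinate, nm.
#' @param truncate_fraction fraction of total path length to remove as a
#'   terminal subtree, in \[0, 1).
#' @param graft_length length of each spurious branch, nm.
#' @param graft_count number of spurious branches.
#' @param seed integer seed.
#' @return perturbed [skeleton()]; attributes `removed_nodes` and
#'   `graft_nodes` record the ground truth of the injected errors.
#' @export
perturb_skeleton <- function(skel, jitter_sd = 0, truncate_fraction = 0,
                             graft_length = 0, graft_count = 0, seed = 1) {
  if (jitter_sd < 0 || graft_length < 0 || graft_count < 0)
    stop("perturbation magnitudes must be non-negative")
  if (truncate_fraction < 0 || truncate_fraction >= 1)
    stop("truncate_fraction must be in [0, 1)")
  with_local_seed(seed, {
    nodes <- skel$nodes
    edges <- skel$edges
    removed <- integer(0)
    if (truncate_fraction > 0 && nrow(edges)) {
      target <- truncate_fraction * skeleton_length(skel)
      root <- nodes$id[1]
      st <- subtree_lengths(skel, root)
      cand <- st$sub[names(st$sub) != as.character(root)]
      cut <- names(cand)[which.min(abs(cand - target))]
      # drop the whole subtree below (and including) the cut node
      adj <- skeleton_adjacency(skel)
      drop_set <- cut
      queue <- cut
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        pa <- get(v, envir = st$parent)
        for (w in as.character(adj[[v]])) {
          if (!identical(w, pa) && !(w %in% drop_set)) {
            drop_set <- c(drop_set, w); queue <- c(queue, w)
          }
        }
      }
      removed <- as.integer(drop_set)
      keep <- !(nodes$id %in% removed)
      nodes <- nodes[keep, , drop = FALSE]
      edges <- edges[!(edges[, 1] %in% removed | edges[, 2] %in% removed),
                     , drop = FALSE]
    }
    if (jitter_sd > 0) {
      n <- nrow(nodes)
      nodes$x <- nodes$x + stats::rnorm(n, sd = jitter_sd)
      nodes$y <- nodes$y + stats::rnorm(n, sd = jitter_sd)
      nodes$z <- nodes$z + stats::rnorm(n, sd = jitter_sd)
    }
    graft_nodes <- integer(0)
    if (graft_count > 0 && graft_length > 0) {
      spacing <- if (nrow(edges)) skeleton_length(
        skeleton(nodes, edges, units = skel$units, scale = skel$scale)) /
        nrow(edges) else 100
      next_id <- max(nodes$id) + 1L
      for (g in seq_len(graft_count)) {
        anchor <- nodes$id[sample.int(nrow(nodes), 1)]
        a <- as.numeric(nodes[nodes$id == anchor, c("x", "y", "z")])
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        nseg <- max(1L, round(graft_length / spacing))
        tpos <- sweep(outer(seq_len(nseg) * (graft_length / nseg), d),
                      2, a, `+`)
        ids <- next_id + seq_len(nseg) - 1L
        add <- data.frame(id = ids, x = tpos[, 1], y = tpos[, 2],
                          z = tpos[, 3], radius = 1)
        for (cn in setdiff(names(nodes), names(add))) add[[cn]] <- NA
        nodes <- rbind(nodes, add[, names(nodes)])
        edges <- rbind(edges, cbind(c(anchor, ids[-nseg]), ids))
        graft_nodes <- c(graft_nodes, ids)
        next_id <- next_id + nseg
      }
    }
    out <- skeleton(nodes, edges, id = skel$id, name = skel$name,
                    units = skel$units, scale = skel$scale)
    attr(out, "removed_nodes") <- removed
    attr(out, "graft_nodes") <- graft_nodes
    out
  })
}

#' Generate a convex-region point set
#'
#' Points on and inside a sphere around a center, guaranteed non-coplanar
#' and guaranteed to enclose the center in their convex hull (the first
#' points form a scaled tetrahedron/octahedron around the center), as used
#' for manually outlined glomerular volumes.
#'
#' @param center numeric length-3 point, nm.
#' @param radius sphere radius, nm.
#' @param n_points number of points (>= 4).
#' @param seed integer seed.
#' @return `n_points` x 3 matrix of nm coordinates.
#' @export
gen_convex_region <- function(center, radius, n_points = 20, seed = 1) {
  if (n_points < 4) stop("n_points must be at least 4")
  if (radius <= 0) stop("radius must be positive")
  with_local_seed(seed, {
    base <- if (n_points >= 6) {
      rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    } else {
      rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    }
    pts <- base * 0.8 * radius
    n_extra <- n_points - nrow(pts)
    if (n_extra > 0) {
      d <- matrix(stats::rnorm(3 * n_extra), ncol = 3)
      d <- d / sqrt(rowSums(d^2))
      r <- radius * stats::runif(n_extra, 0.5, 1)^(1/3)
      pts <- rbind(pts, d * r)
    }
    pts <- pts[seq_len(n_points), , drop = FALSE]
    sweep(pts, 2, center, `+`)
  })
}
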