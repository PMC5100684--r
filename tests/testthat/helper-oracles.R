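# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: plain loops, dense linear algebra, enumeration.

# exhaustive spatial-domain cross-correlation of standardized images over
# the lag window [-w, w]^2; returns the argmax lag (dx, dy) using the same
# tie-break rule stated for the estimator (smallest norm, then lexicographic)
brute_xcorr_peak <- function(a, b, w) {
  nr <- nrow(a); nc <- ncol(a)
  best <- -Inf; best_dx <- integer(0); best_dy <- integer(0)
  for (dy in -w:w) {
    rb <- max(1, 1 - dy):min(nr, nr - dy)     # rows of b; a rows = rb + dy
    for (dx in -w:w) {
      cb <- max(1, 1 - dx):min(nc, nc - dx)
      v <- sum(a[rb + dy, cb + dx] * b[rb, cb])
      if (v > best + 1e-9) {
        best <- v; best_dx <- dx; best_dy <- dy
      } else if (abs(v - best) <= 1e-9) {
        best_dx <- c(best_dx, dx); best_dy <- c(best_dy, dy)
      }
    }
  }
  o <- order(best_dx^2 + best_dy^2, best_dx, best_dy)
  c(dx = best_dx[o[1]], dy = best_dy[o[1]])
}

# accumulate tile positions along a BFS spanning tree of exact offsets
bfs_layout <- function(offsets, n_tiles, anchor = 1L) {
  pos <- matrix(NA_real_, n_tiles, 2)
  pos[anchor, ] <- 0
  repeat {
    progressed <- FALSE
    for (k in seq_len(nrow(offsets))) {
      i <- offsets$i[k]; j <- offsets$j[k]
      if (!is.na(pos[i, 1]) && is.na(pos[j, 1])) {
        pos[j, ] <- pos[i, ] + c(offsets$dx[k], offsets$dy[k])
        progressed <- TRUE
      } else if (is.na(pos[i, 1]) && !is.na(pos[j, 1])) {
        pos[i, ] <- pos[j, ] - c(offsets$dx[k], offsets$dy[k])
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  pos
}

# dense normal-equations least squares for the layout (per coordinate)
dense_layout <- function(offsets, n_tiles, anchor = 1L) {
  free <- setdiff(seq_len(n_tiles), anchor)
  m <- nrow(offsets)
  A <- matrix(0, m, length(free))
  for (k in seq_len(m)) {
    ji <- match(offsets$j[k], free); ii <- match(offsets$i[k], free)
    if (!is.na(ji)) A[k, ji] <- 1
    if (!is.na(ii)) A[k, ii] <- -1
  }
  pos <- matrix(0, n_tiles, 2)
  pos[free, 1] <- solve(crossprod(A), crossprod(A, offsets$dx))
  pos[free, 2] <- solve(crossprod(A), crossprod(A, offsets$dy))
  pos
}

# all cube indices whose boxes intersect the half-open box [lo, hi)
brute_cube_intersection <- function(lo, hi, edge, dims) {
  out <- NULL
  nc <- ceiling(dims / edge)
  for (cz in 0:(nc[3] - 1)) for (cy in 0:(nc[2] - 1))
    for (cx in 0:(nc[1] - 1)) {
      c0 <- c(cx, cy, cz) * edge
      c1 <- c0 + edge
      if (all(pmax(lo, c0) < pmin(hi, c1)))
        out <- rbind(out, c(cx, cy, cz))
    }
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# a small random annotation with skeletons at integer voxel positions
random_annotation <- function(seed, n_things = 2, n_nodes = 15) {
  set.seed(seed)
  skels <- lapply(seq_len(n_things), function(t) {
    n <- sample(3:n_nodes, 1)
    nodes <- data.frame(id = sample(1000L, n), x = sample(0:500, n, TRUE),
                        y = sample(0:500, n, TRUE),
                        z = sample(0:500, n, TRUE),
                        radius = sample(1:5, n, TRUE))
    edges <- cbind(nodes$id[1:(n - 1)], nodes$id[2:n])
    skeleton(nodes, edges, id = t, name = paste0("neuron_", t),
             units = "voxel")
  })
  nml_annotation(skels)
}

# canonical form of an annotation for round-trip comparison
annotation_signature <- function(ann) {
  lapply(ann$skeletons, function(s) {
    nd <- s$nodes[order(s$nodes$id), c("id", "x", "y", "z", "radius")]
    rownames(nd) <- NULL
    nd[] <- lapply(nd, as.numeric)
    e <- s$edges
    storage.mode(e) <- "double"
    if (nrow(e)) {
      e <- t(apply(e, 1, sort))
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    }
    list(id = as.numeric(s$id), nodes = nd, edges = unname(e))
  })
}

# three redundant tracings of a common ground truth plus the truth
# itself; node spacing 160 nm emulates the sparser node placement of
# manual tracing (resampling brings it to the 100 nm working density)
make_tracing_set <- function(seed, total_length = 20000, n_branch = 3,
                             jitter = 20, truncate = 0.2,
                             graft = 5000, step = 160) {
  truth <- gen_skeleton(n_branch, volume = c(20000, 20000, 20000),
                        step = step, seed = seed,
                        total_length = total_length)
  mk <- function(id, ...) {
    s <- perturb_skeleton(truth, ...)
    s$id <- id
    s
  }
  list(truth = truth,
       tracings = list(
         mk(1L, jitter_sd = jitter, seed = seed * 100 + 1),
         mk(2L, jitter_sd = jitter, truncate_fraction = truncate,
            seed = seed * 100 + 2),
         mk(3L, jitter_sd = jitter, graft_length = graft, graft_count = 1,
            seed = seed * 100 + 3)))
}
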