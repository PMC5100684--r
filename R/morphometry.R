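#' Glomerular morphometry and reconstruction accuracy
#'
#' Glomeruli are outlined as convex hulls around manually placed 3-D
#' points; the innervation table lists the neurite path length (in
#' micrometres) each neuron contributes to each glomerulus, and the
#' glomerulus receiving the longest length is the neuron's parent
#' glomerulus. Reconstruction accuracy against a reference skeleton is
#' quantified by length-based recall, precision and relative length
#' error.
#'
#' @name morphometry
NULL

#' Build a convex region from 3-D points
#'
#' Computes the convex hull of at least 4 non-coplanar points by face
#' enumeration (every point triple whose plane has all points on one
#' side is a supporting plane), returning the half-space representation
#' used for exact segment clipping, the hull vertices and the enclosed
#' volume.
#'
#' @param points n x 3 matrix of nm coordinates, n >= 4.
#' @param region_id,group optional region name and group label.
#' @return object of class `"convex_region"`: `region_id`, `group`,
#'   `vertices` (input points), `normals` (outward unit normals, m x 3),
#'   `offsets` (m; hull = `{x : normals %*% x <= offsets}`),
#'   `hull_vertices`, `volume` (nm^3), `centroid`.
#' @export
build_hull <- function(points, region_id = "region", group = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  points <- unique(points)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 distinct points")
  scale <- max(apply(points, 2, function(c) diff(range(c))), 1)
  tol <- 1e-9 * scale
  planes <- list()
  combs <- utils::combn(n, 3)
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]; l <- combs[3, k]
    nv <- cross3(points[j, ] - points[i, ], points[l, ] - points[i, ])
    nn <- sqrt(sum(nv^2))
    if (nn < tol * scale) next
    nv <- nv / nn
    s <- as.numeric(points %*% nv) - sum(nv * points[i, ])
    if (all(s <= tol)) {
      planes[[length(planes) + 1L]] <- c(nv, sum(nv * points[i, ]))
    } else if (all(s >= -tol)) {
      planes[[length(planes) + 1L]] <- c(-nv, -sum(nv * points[i, ]))
    }
  }
  if (!length(planes))
    stop("degenerate input: points are coplanar or collinear")
  P <- unique(round(do.call(rbind, planes), 9))
  normals <- P[, 1:3, drop = FALSE]
  offsets <- P[, 4]
  # a proper 3-D hull needs >= 4 independent supporting planes
  if (nrow(normals) < 4 || qr(normals)$rank < 3)
    stop("degenerate input: points are coplanar or collinear")
  on_plane <- abs(points %*% t(normals) -
                    matrix(offsets, n, length(offsets), byrow = TRUE)) <= tol
  hull_idx <- which(rowSums(on_plane) >= 3)
  centroid <- colMeans(points[hull_idx, , drop = FALSE])
  # volume: fan-triangulate each face polygon, tetrahedra to the centroid
  vol <- 0
  for (f in seq_len(nrow(normals))) {
    face_pts <- points[on_plane[, f], , drop = FALSE]
    if (nrow(face_pts) < 3) next
    fc <- colMeans(face_pts)
    b1 <- face_pts[1, ] - fc
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- cross3(normals[f, ], b1)
    ang <- atan2((face_pts - matrix(fc, nrow(face_pts), 3,
                                    byrow = TRUE)) %*% b2,
                 (face_pts - matrix(fc, nrow(face_pts), 3,
                                    byrow = TRUE)) %*% b1)
    face_pts <- face_pts[order(ang), , drop = FALSE]
    m <- nrow(face_pts)
    for (i in seq_len(m)) {
      a <- face_pts[i, ] - centroid
      b <- face_pts[if (i == m) 1 else i + 1, ] - centroid
      vol <- vol + abs(det(rbind(a, b, fc - centroid))) / 6
    }
  }
  structure(list(region_id = region_id, group = group, vertices = points,
                 normals = normals, offsets = offsets,
                 hull_vertices = points[hull_idx, , drop = FALSE],
                 volume = vol, centroid = centroid, tol = tol),
            class = "convex_region")
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' @exportS3Method base::print
print.convex_region <- function(x, ...) {
  cat(sprintf("convex region '%s'%s: %d vertices, volume %.3g um^3\n",
              x$region_id,
              if (nzchar(x$group)) paste0(" (", x$group, ")") else "",
              nrow(x$hull_vertices), x$volume / 1e9))
  invisible(x)
}

#' Test points for hull membership
#'
#' @param region a [build_hull()] region.
#' @param points n x 3 matrix, nm.
#' @param tol slack in nm; defaults to the hull's own construction
#'   tolerance.
#' @return logical vector.
#' @export
in_hull <- function(region, points, tol = 2 * region$tol) {
  points <- rbind(points)
  s <- points %*% t(region$normals) -
    matrix(region$offsets, nrow(points), length(region$offsets),
           byrow = TRUE)
  apply(s <= tol, 1, all)
}

#' Exact length of a segment inside a convex region
#'
#' Clips the parametric segment against every half-space of the hull and
#' returns the length of the surviving interval; 0 when disjoint. Exact
#' and additive: splitting a segment anywhere leaves the summed clipped
#' length unchanged.
#'
#' @param region a [build_hull()] region.
#' @param p,q segment endpoints, nm.
#' @return length inside the hull, nm.
#' @export
clip_segment <- function(region, p, q) {
  d <- q - p
  len <- sqrt(sum(d^2))
  if (len == 0) return(0)
  t0 <- 0; t1 <- 1
  denom <- as.numeric(region$normals %*% d)
  num <- region$offsets - as.numeric(region$normals %*% p)
  for (i in seq_along(denom)) {
    if (abs(denom[i]) < 1e-12 * len) {
      if (num[i] < 0) return(0)
    } else if (denom[i] > 0) {
      t1 <- min(t1, num[i] / denom[i])
    } else {
      t0 <- max(t0, num[i] / denom[i])
    }
    if (t0 >= t1) return(0)
  }
  (t1 - t0) * len
}

#' Neurite path length of a skeleton inside a region
#'
#' Sum of the clipped sub-lengths of all skeleton edges inside the hull
#' (edges partially inside contribute their exact inside fraction),
#' converted to micrometres. Voxel-coordinate skeletons are scaled
#' anisotropically (default 9.25 x 9.25 x 25 nm) before clipping.
#'
#' @param skel a [skeleton()].
#' @param region a [build_hull()] region (nm).
#' @return length in micrometres.
#' @export
neurite_length_in_region <- function(skel, region) {
  if (skel$units == "voxel" &&
      (is.null(skel$scale) || length(skel$scale) != 3))
    stop("voxel skeleton without a scale; cannot convert to nm")
  if (!nrow(skel$edges)) return(0)
  p <- skeleton_xyz_nm(skel)
  rownames(p) <- as.character(skel$nodes$id)
  # cheap bounding-sphere rejection before exact clipping
  rmax <- max(sqrt(rowSums(sweep(region$vertices, 2,
                                 region$centroid)^2)))
  total <- 0
  for (k in seq_len(nrow(skel$edges))) {
    a <- p[as.character(skel$edges[k, 1]), ]
    b <- p[as.character(skel$edges[k, 2]), ]
    da <- sqrt(sum((a - region$centroid)^2))
    db <- sqrt(sum((b - region$centroid)^2))
    if (min(da, db) > rmax + sqrt(sum((a - b)^2))) next
    total <- total + clip_segment(region, a, b)
  }
  total / 1000
}

#' Build the innervation table
#'
#' One row per neuron, one column per region; each cell is the neurite
#' path length (micrometres) of that neuron inside that region.
#' Overlapping hulls are allowed (glomerular boundaries are not always
#' sharp), so a length segment may count toward several regions.
#'
#' @param skeletons named list of [skeleton()]s (names or skeleton ids
#'   are the neuron ids).
#' @param regions list of [build_hull()] regions.
#' @param cell_types named character vector mapping neuron id to cell
#'   type; unknown neurons get type `"other"` with a warning.
#' @return data.frame of class `"innervation_table"` with columns
#'   `neuron_id`, `cell_type`, then one numeric column per region.
#' @export
build_innervation_table <- function(skeletons, regions,
                                    cell_types = NULL) {
  ids <- if (!is.null(names(skeletons)) && all(nzchar(names(skeletons))))
    names(skeletons)
  else as.character(vapply(skeletons, function(s) s$id, 0L))
  if (anyDuplicated(ids)) stop("neuron ids must be unique")
  rids <- vapply(regions, function(r) r$region_id, "")
  ct <- rep("other", length(ids))
  if (!is.null(cell_types)) {
    hit <- match(ids, names(cell_types))
    miss <- is.na(hit)
    if (any(miss))
      warning("no cell type for neuron(s) ",
              paste(ids[miss], collapse = ", "), "; using 'other'")
    ct[!miss] <- cell_types[hit[!miss]]
    bad <- !(ct %in% CELL_TYPES)
    if (any(bad)) {
      warning("unknown cell type(s) mapped to 'other': ",
              paste(unique(ct[bad]), collapse = ", "))
      ct[bad] <- "other"
    }
  }
  tab <- data.frame(neuron_id = ids, cell_type = ct,
                    stringsAsFactors = FALSE)
  for (j in seq_along(regions))
    tab[[rids[j]]] <- vapply(skeletons, neurite_length_in_region, 0,
                             region = regions[[j]])
  class(tab) <- c("innervation_table", "data.frame")
  tab
}

#' Parent glomerulus of each neuron
#'
#' The region with the longest neurite length; ties are broken
#' lexicographically (flagged), all-zero rows are unassigned (`NA`).
#'
#' @param table an innervation table (or a single row of one).
#' @return data.frame with `neuron_id`, `parent`, `tie`.
#' @export
parent_glomerulus <- function(table) {
  regions <- setdiff(names(table), c("neuron_id", "cell_type"))
  regions_sorted <- sort(regions)
  out <- data.frame(neuron_id = table$neuron_id,
                    parent = NA_character_, tie = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table))) {
    v <- as.numeric(table[i, regions_sorted])
    if (all(v == 0)) next
    m <- max(v)
    hits <- regions_sorted[v == m]
    out$parent[i] <- hits[1]
    out$tie[i] <- length(hits) > 1
  }
  out
}

# min distance from each point (rows of pts) to a set of segments
min_dist_to_segments <- function(pts, seg_a, seg_b) {
  best <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(seg_a))) {
    a <- seg_a[k, ]; d <- seg_b[k, ] - a
    dd <- sum(d^2)
    rel <- sweep(pts, 2, a)
    t <- if (dd > 0) pmin(pmax(as.numeric(rel %*% d) / dd, 0), 1)
         else rep(0, nrow(pts))
    dx <- rel - outer(t, d)
    best <- pmin(best, rowSums(dx^2))
  }
  sqrt(best)
}

# arc-length sample points of a skeleton: positions plus the length
# weight each sample represents (half of its incident edges)
length_samples <- function(skel, spacing) {
  rs <- resample(skel, spacing)
  p <- skeleton_xyz_nm(rs)
  rownames(p) <- as.character(rs$nodes$id)
  w <- stats::setNames(rep(0, nrow(p)), rownames(p))
  if (nrow(rs$edges)) {
    el <- sqrt(rowSums((p[as.character(rs$edges[, 1]), , drop = FALSE] -
                        p[as.character(rs$edges[, 2]), , drop = FALSE])^2))
    for (k in seq_len(nrow(rs$edges))) {
      w[as.character(rs$edges[k, 1])] <-
        w[as.character(rs$edges[k, 1])] + el[k] / 2
      w[as.character(rs$edges[k, 2])] <-
        w[as.character(rs$edges[k, 2])] + el[k] / 2
    }
  }
  list(points = p, weights = as.numeric(w))
}

skeleton_segments <- function(skel) {
  p <- skeleton_xyz_nm(skel)
  rownames(p) <- as.character(skel$nodes$id)
  list(a = p[as.character(skel$edges[, 1]), , drop = FALSE],
       b = p[as.character(skel$edges[, 2]), , drop = FALSE])
}

#' Length-based reconstruction accuracy metrics
#'
#' Both skeletons are densely resampled (at `tolerance / 4`); recall is
#' the fraction of reference arc length whose sample points lie within
#' `tolerance` of the test skeleton (errors caused by missed processes),
#' precision the fraction of test arc length within `tolerance` of the
#' reference (errors caused by wrongly traced processes), and the
#' relative length error combines both:
#' `(missed reference length + excess test length) / reference length`.
#' Distances are measured from sample points to the other skeleton's
#' segments, in nm.
#'
#' @param test,truth non-empty [skeleton()]s in the same coordinate
#'   frame.
#' @param tolerance matching distance in nm (default 100, the CORE
#'   resampling density).
#' @return list of class `"error_metrics"`: `recall`, `precision`,
#'   `relative_length_error`, `tolerance`, `test_length`,
#'   `truth_length` (nm).
#' @export
reconstruction_metrics <- function(test, truth, tolerance = 100) {
  if (!nrow(test$edges) || !nrow(truth$edges))
    stop("both skeletons must have at least one edge")
  spacing <- tolerance / 4
  ts <- length_samples(truth, spacing)
  xs <- length_samples(test, spacing)
  tseg <- skeleton_segments(test)
  rseg <- skeleton_segments(truth)
  dtr <- min_dist_to_segments(ts$points, tseg$a, tseg$b)
  dte <- min_dist_to_segments(xs$points, rseg$a, rseg$b)
  Lt <- sum(ts$weights)
  Lx <- sum(xs$weights)
  recall <- sum(ts$weights[dtr <= tolerance]) / Lt
  precision <- sum(xs$weights[dte <= tolerance]) / Lx
  rle <- ((1 - recall) * Lt + (1 - precision) * Lx) / Lt
  structure(list(recall = recall, precision = precision,
                 relative_length_error = rle, tolerance = tolerance,
                 test_length = Lx, truth_length = Lt),
            class = "error_metrics")
}

#' @exportS3Method base::print
print.error_metrics <- function(x, ...) {
  cat(sprintf("recall %.4f, precision %.4f, relative length error %.4f (tolerance %g nm)\n",
              x$recall, x$precision, x$relative_length_error, x$tolerance))
  invisible(x)
}
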