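#' Skeleton objects
#'
#' A skeleton is the node-and-edge representation of a traced neuron: 3-D
#' nodes placed on neurite cross-sections, connected by edges, usually
#' forming a tree. Positions are carried either in nanometres (`units =
#' "nm"`) or in voxel indices (`units = "voxel"`); voxel skeletons carry the
#' anisotropic voxel pitch in `scale` so that physical lengths can be
#' computed.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (numeric) and optionally `radius`, `time`, `comment`; extra
#'   columns are preserved.
#' @param edges two-column matrix or data.frame of node ids (unordered
#'   pairs); may have zero rows.
#' @param id integer identifier of the skeleton ("thing" id).
#' @param name character name.
#' @param units `"nm"` or `"voxel"`.
#' @param scale numeric length-3 voxel pitch in nm (x, y, z); used only
#'   when `units == "voxel"`.
#' @return An object of class `"skeleton"`.
#' @export
skeleton <- function(nodes, edges = NULL, id = 1L, name = "",
                     units = c("nm", "voxel"),
                     scale = c(9.25, 9.25, 25)) {
  units <- match.arg(units)
  nodes <- as.data.frame(nodes)
  if (!all(c("id", "x", "y", "z") %in% names(nodes)))
    stop("nodes must have columns id, x, y, z")
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node positions must be finite")
  if (is.null(nodes$radius)) nodes$radius <- 1
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    edges <- as.matrix(as.data.frame(edges)[, 1:2])
    storage.mode(edges) <- "integer"
  }
  colnames(edges) <- c("source", "target")
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
    missing <- setdiff(as.vector(edges), nodes$id)
    if (length(missing))
      stop("edge references missing node id(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(id = as.integer(id), name = as.character(name),
                 nodes = nodes, edges = edges,
                 units = units, scale = as.numeric(scale)),
            class = "skeleton")
}

#' @exportS3Method base::print
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton %d '%s': %d nodes, %d edges (%s)\n",
              x$id, x$name, nrow(x$nodes), nrow(x$edges), x$units))
  invisible(x)
}

#' Node positions of a skeleton in nm
#'
#' Voxel coordinates are scaled anisotropically by the skeleton's voxel
#' pitch.
#'
#' @param skel a [skeleton()].
#' @return n x 3 numeric matrix.
#' @export
skeleton_positions_nm <- function(skel) skeleton_xyz_nm(skel)

# positions as an n x 3 matrix in nm
skeleton_xyz_nm <- function(skel) {
  p <- as.matrix(skel$nodes[, c("x", "y", "z")])
  if (skel$units == "voxel") p <- sweep(p, 2, skel$scale, `*`)
  p
}

#' Total path length of a skeleton
#'
#' Sum of Euclidean edge lengths, in nm (voxel coordinates are scaled
#' anisotropically first).
#'
#' @param skel a [skeleton()].
#' @return length in nm.
#' @export
skeleton_length <- function(skel) {
  if (!nrow(skel$edges)) return(0)
  p <- skeleton_xyz_nm(skel)
  idx <- match(skel$edges, skel$nodes$id)
  dim(idx) <- dim(skel$edges)
  d <- p[idx[, 1], , drop = FALSE] - p[idx[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# adjacency list keyed by node id (names are ids as character)
skeleton_adjacency <- function(skel) {
  ids <- skel$nodes$id
  adj <- vector("list", length(ids))
  names(adj) <- as.character(ids)
  if (nrow(skel$edges)) {
    for (k in seq_len(nrow(skel$edges))) {
      a <- as.character(skel$edges[k, 1]); b <- as.character(skel$edges[k, 2])
      adj[[a]] <- c(adj[[a]], skel$edges[k, 2])
      adj[[b]] <- c(adj[[b]], skel$edges[k, 1])
    }
  }
  adj
}

skeleton_degree <- function(skel) {
  deg <- integer(nrow(skel$nodes))
  names(deg) <- as.character(skel$nodes$id)
  if (nrow(skel$edges)) {
    t1 <- table(c(skel$edges))
    deg[names(t1)] <- as.integer(t1)
  }
  deg
}

# connected components; returns integer component label per node id
skeleton_components <- function(skel) {
  adj <- skeleton_adjacency(skel)
  comp <- integer(length(adj)); names(comp) <- names(adj)
  cur <- 0L
  for (s in names(adj)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in as.character(adj[[v]])) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# Decompose a tree skeleton into branch paths: maximal polylines whose
# interior nodes have degree 2. Returns a list of integer node-id vectors.
skeleton_branch_paths <- function(skel) {
  deg <- skeleton_degree(skel)
  adj <- skeleton_adjacency(skel)
  ids <- skel$nodes$id
  if (!nrow(skel$edges)) return(lapply(ids, function(i) i))
  breakpoints <- ids[deg[as.character(ids)] != 2L]
  if (!length(breakpoints)) {
    # a cycle: start anywhere (skeletons are trees in practice)
    breakpoints <- ids[1]
  }
  seen_edge <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  paths <- list()
  for (bp in breakpoints) {
    for (nb in adj[[as.character(bp)]]) {
      if (!is.null(seen_edge[[ekey(bp, nb)]])) next
      path <- c(bp, nb)
      assign(ekey(bp, nb), TRUE, envir = seen_edge)
      prev <- bp; cur <- nb
      while (deg[as.character(cur)] == 2L) {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        if (!length(nxt)) break
        nxt <- nxt[1]
        assign(ekey(cur, nxt), TRUE, envir = seen_edge)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  # isolated nodes become singleton paths
  iso <- ids[deg[as.character(ids)] == 0L]
  for (i in iso) paths[[length(paths) + 1L]] <- i
  paths
}
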