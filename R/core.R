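#' CORE: consolidation of redundant tracings
#'
#' Each neuron is traced independently several times; CORE (COnvergence
#' by Redundancy and Experts) combines the redundant tracings into one
#' consolidated skeleton. Tracings are resampled to a uniform node
#' density (about 100 nm), nodes of different tracings are iteratively
#' combined into cliques based on their distance and connectedness,
#' cliques form the consolidated skeleton, and points where one tracing
#' diverges from the others (mismatch points) are detected and resolved
#' by local re-tracing or a direct expert decision, iterating until no
#' mismatch remains.
#'
#' All distances are physical (nm); voxel skeletons are scaled
#' anisotropically before processing.
#'
#' @name core
NULL

#' Resample a skeleton to a uniform node density
#'
#' Subdivides every polyline edge longer than `target_spacing` into
#' equal sub-intervals so that the inter-node spacing never exceeds the
#' target. Every original node -- in particular all branch points and
#' endpoints -- is retained exactly and new nodes lie on the original
#' polyline, so arc length is preserved exactly (manual tracings place
#' nodes sparsely and irregularly; this brings them to a uniform working
#' density without moving any traced point).
#'
#' @param skel a [skeleton()].
#' @param target_spacing maximum inter-node spacing, nm (default 100).
#' @return a [skeleton()] in nm with attribute `source_tracing` (the
#'   input skeleton id) and a `provenance` attribute mapping each new
#'   node to the original edge (original node id pair) it lies on.
#' @export
resample <- function(skel, target_spacing = 100) {
  if (target_spacing <= 0) stop("target_spacing must be positive")
  p <- skeleton_xyz_nm(skel)
  rownames(p) <- as.character(skel$nodes$id)
  n0 <- nrow(p)
  orig_ids <- skel$nodes$id
  new_id_of <- stats::setNames(seq_len(n0), as.character(orig_ids))
  new_pos <- vector("list", n0)
  for (i in seq_len(n0)) new_pos[[i]] <- p[i, ]
  prov <- as.list(paste(orig_ids, orig_ids))
  new_edges <- list()
  next_id <- n0
  for (k in seq_len(nrow(skel$edges))) {
    a <- as.character(skel$edges[k, 1]); b <- as.character(skel$edges[k, 2])
    d <- p[b, ] - p[a, ]
    elen <- sqrt(sum(d^2))
    nseg <- max(1L, ceiling(elen / target_spacing - 1e-9))
    chain <- new_id_of[a]
    if (nseg > 1) {
      for (s in seq_len(nseg - 1)) {
        next_id <- next_id + 1L
        new_pos[[next_id]] <- p[a, ] + d * s / nseg
        prov[[next_id]] <- paste(a, b)
        chain <- c(chain, next_id)
      }
    }
    chain <- c(chain, new_id_of[b])
    new_edges[[k]] <- cbind(chain[-length(chain)], chain[-1])
  }
  pos <- do.call(rbind, new_pos)
  nodes <- data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], radius = 1)
  edges <- if (length(new_edges)) do.call(rbind, new_edges) else NULL
  out <- skeleton(nodes, edges, id = skel$id, name = skel$name,
                  units = "nm")
  attr(out, "source_tracing") <- skel$id
  attr(out, "provenance") <- unlist(prov)
  out
}

# ---- clique formation ------------------------------------------------------

tracing_info <- function(tr) {
  p <- skeleton_xyz_nm(tr)
  ids <- tr$nodes$id
  rownames(p) <- as.character(ids)
  adj <- skeleton_adjacency(tr)
  list2env(list(id = tr$id, pos = p, node_ids = ids, adj = adj,
                assign = stats::setNames(rep(0L, length(ids)),
                                         as.character(ids))),
           new.env(parent = emptyenv()))
}

#' Form cliques across redundant tracings
#'
#' Greedy seeded region growing along the skeletons: starting from
#' mutually nearby seed nodes, cliques (at most one node per tracing, all
#' pairwise member distances within `radius`) are grown outward along the
#' polylines -- a node may only join a clique whose members include one
#' of its polyline neighbors' cliques, which prevents cliques from
#' jumping between parallel neurites. Candidate assignments are resolved
#' by smallest summed member distance, then by lowest (tracing id, node
#' id), so the result is deterministic and independent of the input
#' order of the tracings. Nodes of dissolved under-sized cliques (fewer
#' than `min_agreement` members -- disagreement between tracings) are
#' returned as orphans.
#'
#' @param tracings list of resampled [skeleton()]s (nm) with unique ids.
#' @param radius clique radius in nm (default 500).
#' @param min_agreement minimum members per clique (default 2, i.e.
#'   majority of three tracings).
#' @return object of class `"clique_set"`: `members` (data.frame clique,
#'   tracing, node), `positions` (consensus centroids, one row per
#'   clique), `orphans` (data.frame tracing, node), plus parameters.
#' @export
form_cliques <- function(tracings, radius = 500, min_agreement = 2) {
  if (length(tracings) < 2) stop("need at least 2 tracings")
  if (radius <= 0) stop("radius must be positive")
  if (min_agreement > length(tracings))
    stop("min_agreement exceeds the number of tracings")
  tids <- vapply(tracings, function(t) as.integer(t$id), 0L)
  if (anyDuplicated(tids)) stop("tracing ids must be unique")
  info <- lapply(tracings[order(tids)], tracing_info)
  names(info) <- as.character(sort(tids))
  Tn <- length(info)

  members <- list()      # per clique: data.frame(tracing, node)
  queue <- integer(0)

  member_pos <- function(mem) {
    do.call(rbind, lapply(seq_len(nrow(mem)), function(r)
      info[[as.character(mem$tracing[r])]]$pos[as.character(mem$node[r]), ]))
  }
  compatible <- function(pos, mpos)
    all(sqrt(rowSums((mpos - matrix(pos, nrow(mpos), 3,
                                    byrow = TRUE))^2)) <= radius)
  register <- function(mem) {
    members[[length(members) + 1L]] <<- mem
    ci <- length(members)
    for (r in seq_len(nrow(mem))) {
      inf <- info[[as.character(mem$tracing[r])]]
      inf$assign[as.character(mem$node[r])] <- ci
    }
    queue <<- c(queue, ci)
    ci
  }
  # grow a clique around one seed node. In pool mode the per-tracing
  # candidates are data.frames (node, depth) and the closest-in-graph
  # (lowest depth, then nearest, then lowest id) compatible node joins,
  # which keeps the chains of the different tracings advancing in
  # lockstep; with require_partner, a clique that would stay a singleton
  # is not created (its seed waits for a later clique or a restart).
  # NULL pool draws from all unassigned nodes by distance (seeding).
  grow_around <- function(seed_t, seed_n, pool = NULL,
                          require_partner = FALSE) {
    mem <- data.frame(tracing = seed_t, node = seed_n)
    p0 <- info[[as.character(seed_t)]]$pos[as.character(seed_n), ]
    mpos <- matrix(p0, 1, 3)
    pair_cap <- radius
    for (tk in names(info)) {
      if (as.integer(tk) == seed_t) next
      inf <- info[[tk]]
      if (is.null(pool)) {
        cand <- inf$node_ids[inf$assign == 0L]
        depth <- rep(1L, length(cand))
      } else {
        cand <- pool[[tk]]$node
        depth <- pool[[tk]]$depth
      }
      if (!length(cand)) next
      cp <- inf$pos[as.character(cand), , drop = FALSE]
      d0 <- sqrt(rowSums(sweep(cp, 2, p0)^2))
      ord <- order(depth, d0, cand)
      for (i in ord) {
        if (d0[i] > pair_cap) next
        if (inf$assign[as.character(cand[i])] != 0L) next
        if (compatible(cp[i, ], mpos)) {
          mem <- rbind(mem, data.frame(tracing = as.integer(tk),
                                       node = cand[i]))
          mpos <- rbind(mpos, cp[i, ])
          break
        }
      }
    }
    if (require_partner && nrow(mem) < 2) return(0L)
    register(mem)
  }

  repeat {
    if (!length(queue)) {
      # restart: lowest unassigned (tracing id, node id)
      seed <- NULL
      for (tk in names(info)) {
        un <- info[[tk]]$node_ids[info[[tk]]$assign == 0L]
        if (length(un)) { seed <- c(as.integer(tk), min(un)); break }
      }
      if (is.null(seed)) break
      grow_around(seed[1], seed[2])
      next
    }
    ci <- queue[1]; queue <- queue[-1]
    mem <- members[[ci]]
    cen <- colMeans(member_pos(mem))
    # candidate pool per tracing: unassigned nodes within a short graph
    # distance of the tracing's member (tolerates small differences in
    # node counts between tracings of the same neurite); tracings without
    # a member may rejoin through an unassigned node near the clique that
    # has an assigned polyline neighbor
    pool <- list()
    for (tk in names(info)) {
      inf <- info[[tk]]
      r <- which(mem$tracing == as.integer(tk))
      if (length(r)) {
        frontier <- mem$node[r[1]]
        seen <- frontier
        found <- data.frame(node = integer(0), depth = integer(0))
        for (depth in 1:3) {
          nxt <- unique(unlist(lapply(as.character(frontier),
                                      function(v) inf$adj[[v]])))
          nxt <- setdiff(nxt, seen)
          if (!length(nxt)) break
          seen <- c(seen, nxt)
          un <- nxt[inf$assign[as.character(nxt)] == 0L]
          if (length(un))
            found <- rbind(found, data.frame(node = un, depth = depth))
          frontier <- nxt
        }
        if (nrow(found)) pool[[tk]] <- found
      } else {
        un <- inf$node_ids[inf$assign == 0L]
        if (!length(un)) next
        d <- sqrt(rowSums(sweep(inf$pos[as.character(un), , drop = FALSE],
                                2, cen)^2))
        near <- un[d <= radius]
        if (!length(near)) next
        keep <- vapply(as.character(near), function(v) {
          nbr <- inf$adj[[v]]
          length(nbr) && any(inf$assign[as.character(nbr)] != 0L)
        }, TRUE)
        if (any(keep))
          pool[[tk]] <- data.frame(node = near[keep], depth = 1L)
      }
    }
    repeat {
      sizes <- vapply(pool, nrow, 0L)
      if (!length(pool) || !any(sizes > 0)) break
      # seed: lowest (depth, tracing id, node id) among candidates
      best <- NULL
      for (tk in names(pool)) {
        pf <- pool[[tk]]
        if (!nrow(pf)) next
        o <- order(pf$depth, pf$node)[1]
        key <- c(pf$depth[o], as.integer(tk), pf$node[o])
        if (is.null(best) ||
            key[1] < best[1] ||
            (key[1] == best[1] && key[2] < best[2]))
          best <- key
      }
      tk0 <- as.character(best[2]); n0 <- best[3]
      pool[[tk0]] <- pool[[tk0]][pool[[tk0]]$node != n0, , drop = FALSE]
      if (info[[tk0]]$assign[as.character(n0)] != 0L) next
      nc <- grow_around(as.integer(tk0), n0, pool = pool,
                        require_partner = TRUE)
      if (nc == 0L) next
      taken <- members[[nc]]
      for (r in seq_len(nrow(taken))) {
        tk <- as.character(taken$tracing[r])
        if (!is.null(pool[[tk]]))
          pool[[tk]] <- pool[[tk]][pool[[tk]]$node != taken$node[r], ,
                                   drop = FALSE]
      }
    }
  }

  # refinement: a correctly formed clique has its consensus centroid
  # close to every member's own polyline; a member paired across two
  # different branches (or recruited from a spurious branch) sits far
  # from the centroid's neurite. Eject members whose centroid-to-own-
  # polyline distance is far above the population median, then dissolve
  # under-sized cliques into orphans.
  pt_seg_dist <- function(pt, a, b) {
    d <- b - a; dd <- sum(d^2)
    t <- if (dd > 0) min(max(sum((pt - a) * d) / dd, 0), 1) else 0
    sqrt(sum((pt - (a + t * d))^2))
  }
  member_polyline_dist <- function(mem) {
    cen <- colMeans(member_pos(mem))
    vapply(seq_len(nrow(mem)), function(r) {
      inf <- info[[as.character(mem$tracing[r])]]
      v <- as.character(mem$node[r])
      nbr <- inf$adj[[v]]
      if (!length(nbr))
        return(sqrt(sum((cen - inf$pos[v, ])^2)))
      min(vapply(as.character(nbr), function(w)
        pt_seg_dist(cen, inf$pos[v, ], inf$pos[w, ]), 0))
    }, 0)
  }
  sizes <- vapply(members, nrow, 0L)
  pdists <- lapply(members, function(m)
    if (nrow(m) >= 2) member_polyline_dist(m) else 0)
  med <- stats::median(unlist(pdists[sizes >= 2]))
  if (!is.finite(med)) med <- 0
  cap <- max(6 * med, 0.2 * radius)
  ejected <- list()
  for (i in seq_along(members)) {
    if (sizes[i] < 2) next
    bad <- pdists[[i]] > cap
    if (any(bad)) {
      ejected[[length(ejected) + 1L]] <- members[[i]][bad, , drop = FALSE]
      members[[i]] <- members[[i]][!bad, , drop = FALSE]
    }
  }
  sizes <- vapply(members, nrow, 0L)
  valid <- which(sizes >= min_agreement)
  invalid <- setdiff(seq_along(members), valid)
  orphan_rows <- do.call(rbind, c(
    list(data.frame(tracing = integer(0), node = integer(0))),
    members[invalid], ejected))
  refinement <- list(median_dist = med, cap = cap,
                     n_ejected = sum(vapply(ejected, nrow, 0L)))
  members <- members[valid]
  mem_df <- if (length(members))
    do.call(rbind, lapply(seq_along(members), function(i)
      cbind(clique = i, members[[i]])))
  else data.frame(clique = integer(0), tracing = integer(0),
                  node = integer(0))
  positions <- if (length(members))
    do.call(rbind, lapply(members, function(m) colMeans(member_pos(m))))
  else matrix(numeric(0), 0, 3)
  colnames(positions) <- c("x", "y", "z")
  structure(list(members = mem_df, positions = positions,
                 orphans = orphan_rows, radius = radius,
                 min_agreement = min_agreement,
                 tracing_ids = sort(tids), refinement = refinement),
            class = "clique_set")
}

#' @exportS3Method base::print
print.clique_set <- function(x, ...) {
  cat(sprintf("clique set: %d cliques over tracings {%s}, %d orphan nodes\n",
              nrow(x$positions), paste(x$tracing_ids, collapse = ", "),
              nrow(x$orphans)))
  invisible(x)
}

# clique assignment lookup per tracing: named list tracing ->
# named int vector node id -> clique (0 = unassigned)
clique_assignment <- function(cliques, tracings) {
  out <- list()
  for (tr in tracings) {
    a <- stats::setNames(rep(0L, nrow(tr$nodes)),
                         as.character(tr$nodes$id))
    sel <- cliques$members$tracing == tr$id
    a[as.character(cliques$members$node[sel])] <-
      cliques$members$clique[sel]
    out[[as.character(tr$id)]] <- a
  }
  out
}

# edges of the clique graph: for each tracing, project its polylines onto
# the clique labels (dropping unassigned nodes) and connect consecutive
# distinct cliques
clique_graph_edges <- function(cliques, tracings) {
  asg <- clique_assignment(cliques, tracings)
  edges <- matrix(integer(0), 0, 2)
  for (tr in tracings) {
    a <- asg[[as.character(tr$id)]]
    for (path in skeleton_branch_paths(tr)) {
      lab <- a[as.character(path)]
      lab <- lab[lab != 0L]
      if (length(lab) < 2) next
      keep <- c(TRUE, lab[-1] != lab[-length(lab)])
      lab <- lab[keep]
      if (length(lab) < 2) next
      edges <- rbind(edges, cbind(lab[-length(lab)], lab[-1]))
    }
  }
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
  }
  edges
}

#' Build the consolidated skeleton from cliques
#'
#' One consolidated node per clique at the consensus (centroid) position;
#' an edge between two cliques where some tracing's polyline passes from
#' one to the other (duplicates collapsed). A light Laplacian smoothing
#' pass (degree-2 nodes only, so branch points and endpoints stay fixed)
#' denoises the consensus positions: a centroid dragged sideways by one
#' disagreeing member is pulled back toward its on-neurite neighbors,
#' while at these node spacings the bias on smooth curves is
#' sub-nanometre.
#'
#' @param cliques a [form_cliques()] result.
#' @param tracings the same tracings the cliques were formed from.
#' @param smooth_iters smoothing iterations (0 disables).
#' @return a `"consolidated_skeleton"` (also a [skeleton()], nm units)
#'   with fields `clique_members` and `open_mismatches`.
#' @export
consolidate <- function(cliques, tracings, smooth_iters = 2) {
  n <- nrow(cliques$positions)
  if (n == 0) stop("no cliques to consolidate")
  pos <- cliques$positions
  edges <- clique_graph_edges(cliques, tracings)
  if (smooth_iters > 0 && nrow(edges)) {
    deg <- tabulate(edges, nbins = n)
    two <- deg == 2
    for (it in seq_len(smooth_iters)) {
      acc <- matrix(0, n, 3)
      for (k in seq_len(nrow(edges))) {
        acc[edges[k, 1], ] <- acc[edges[k, 1], ] + pos[edges[k, 2], ]
        acc[edges[k, 2], ] <- acc[edges[k, 2], ] + pos[edges[k, 1], ]
      }
      pos[two, ] <- (pos[two, , drop = FALSE] +
                       acc[two, , drop = FALSE] / 2) / 2
    }
  }
  nodes <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], radius = 1)
  out <- skeleton(nodes, edges, id = 1L, name = "consolidated",
                  units = "nm")
  out$clique_members <- cliques$members
  out$open_mismatches <- list()
  class(out) <- c("consolidated_skeleton", class(out))
  out
}

# ---- mismatch detection ----------------------------------------------------

#' Detect mismatch points between tracings
#'
#' Two detectors, mirroring the two tracer error classes:
#' \describe{
#'   \item{extra-branch}{a maximal connected component of orphan nodes
#'     (structure present in fewer than `min_agreement` tracings); the
#'     mismatch sits at the orphan node adjacent to a clique member (the
#'     point of divergence).}
#'   \item{early-termination / missing-branch}{one tracing ends (or has
#'     no counterpart) while at least `min_agreement` others continue
#'     past it by more than `2 * radius` of path length; reported as
#'     early-termination when the divergence clique holds an endpoint of
#'     the short tracing, as missing-branch otherwise.}
#' }
#' Orphan components shorter than `min_length` (default: the clique
#' radius) are sampling noise, not structural disagreement, and are not
#' reported.
#'
#' @param tracings resampled tracings.
#' @param cliques matching [form_cliques()] result.
#' @param min_length minimum orphan-component path length (nm) to report.
#' @return list of `"mismatch_point"` objects.
#' @export
find_mismatches <- function(tracings, cliques, min_length = NULL) {
  if (is.null(min_length)) min_length <- cliques$radius
  radius <- cliques$radius
  asg <- clique_assignment(cliques, tracings)
  tr_by_id <- stats::setNames(tracings,
                              vapply(tracings, function(t)
                                as.character(t$id), ""))
  out <- list()

  # --- extra-branch: orphan components per tracing
  for (tr in tracings) {
    a <- asg[[as.character(tr$id)]]
    orphan_ids <- as.integer(names(a)[a == 0L])
    if (!length(orphan_ids)) next
    sub_edges <- tr$edges[tr$edges[, 1] %in% orphan_ids &
                          tr$edges[, 2] %in% orphan_ids, , drop = FALSE]
    sub <- skeleton(tr$nodes[tr$nodes$id %in% orphan_ids, , drop = FALSE],
                    sub_edges, id = tr$id, units = "nm")
    comp <- skeleton_components(sub)
    p <- skeleton_xyz_nm(tr)
    rownames(p) <- as.character(tr$nodes$id)
    adj <- skeleton_adjacency(tr)
    for (ci in unique(comp)) {
      cids <- as.integer(names(comp)[comp == ci])
      ce <- sub_edges[sub_edges[, 1] %in% cids, , drop = FALSE]
      clen <- if (nrow(ce)) sum(sqrt(rowSums(
        (p[as.character(ce[, 1]), , drop = FALSE] -
         p[as.character(ce[, 2]), , drop = FALSE])^2))) else 0
      if (clen < min_length) next
      # divergence point: orphan node with an assigned polyline neighbor
      att <- NA_integer_; div <- cids[1]
      for (nid in sort(cids)) {
        nbr <- adj[[as.character(nid)]]
        hit <- nbr[a[as.character(nbr)] != 0L]
        if (length(hit)) { div <- nid; att <- min(hit); break }
      }
      out[[length(out) + 1L]] <- structure(list(
        position = p[as.character(div), ],
        kind = "extra-branch",
        involved = tr$id,
        contested = data.frame(tracing = tr$id, node = cids),
        attach_node = att,
        resolved = FALSE), class = "mismatch_point")
    }
  }

  # --- early-termination / missing-branch via the clique graph
  n_cliques <- nrow(cliques$positions)
  if (n_cliques) {
    ce <- clique_graph_edges(cliques, tracings)
    cadj <- vector("list", n_cliques)
    if (nrow(ce)) for (k in seq_len(nrow(ce))) {
      cadj[[ce[k, 1]]] <- c(cadj[[ce[k, 1]]], ce[k, 2])
      cadj[[ce[k, 2]]] <- c(cadj[[ce[k, 2]]], ce[k, 1])
    }
    has_t <- function(ci, tid)
      any(cliques$members$tracing[cliques$members$clique == ci] == tid)
    clen <- function(c1, c2)
      sqrt(sum((cliques$positions[c1, ] - cliques$positions[c2, ])^2))
    for (tid in cliques$tracing_ids) {
      t_in <- vapply(seq_len(n_cliques), has_t, TRUE, tid = tid)
      seen <- rep(FALSE, n_cliques)
      for (start in which(t_in)) {
        for (d in cadj[[start]]) {
          if (t_in[d] || seen[d]) next
          # flood the t-less component from d
          comp <- integer(0); queue <- d; seen[d] <- TRUE
          plen <- clen(start, d)
          while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            comp <- c(comp, v)
            for (w in cadj[[v]]) {
              if (!t_in[w] && !seen[w]) {
                seen[w] <- TRUE; queue <- c(queue, w)
                plen <- plen + clen(v, w)
              }
            }
          }
          if (plen <= 2 * radius) next
          tr <- tr_by_id[[as.character(tid)]]
          sel <- cliques$members$clique == start &
                 cliques$members$tracing == tid
          tnode <- cliques$members$node[sel][1]
          deg <- skeleton_degree(tr)
          kind <- if (deg[as.character(tnode)] <= 1L) "early-termination"
                  else "missing-branch"
          contested <- cliques$members[
            cliques$members$clique %in% comp, c("tracing", "node")]
          out[[length(out) + 1L]] <- structure(list(
            position = cliques$positions[start, ],
            kind = kind,
            involved = tid,
            contested = contested,
            divergence_clique = start,
            component = comp,
            tracing_node = tnode,
            resolved = FALSE), class = "mismatch_point")
        }
      }
    }
  }
  out
}

#' @exportS3Method base::print
print.mismatch_point <- function(x, ...) {
  cat(sprintf("mismatch [%s] at (%.0f, %.0f, %.0f) nm, tracing %s%s\n",
              x$kind, x$position[1], x$position[2], x$position[3],
              paste(x$involved, collapse = ","),
              if (x$resolved) " (resolved)" else ""))
  invisible(x)
}

# ---- resolution ------------------------------------------------------------

remove_nodes <- function(skel, ids) {
  keep <- !(skel$nodes$id %in% ids)
  edges <- skel$edges[!(skel$edges[, 1] %in% ids |
                        skel$edges[, 2] %in% ids), , drop = FALSE]
  skeleton(skel$nodes[keep, , drop = FALSE], edges, id = skel$id,
           name = skel$name, units = skel$units, scale = skel$scale)
}

# splice geometry into a tracing with a duplication guard: rows of `pos`
# already represented in the tracing by a clique-assigned node (within
# dup_tol) are dropped; unassigned nodes of the tracing near the spliced
# geometry are its own divergent copy of the same structure and are
# replaced by the consensus. Each surviving connected piece is attached
# at the existing node nearest to its first row. Prevents a "keep"
# resolution from laying a duplicate path over structure the tracing
# already has, while still normalizing a disagreeing copy.
guarded_splice <- function(skel, pos, te, dup_tol, assigned = NULL) {
  if (!is.null(assigned)) {
    q_all <- skeleton_xyz_nm(skel)
    rownames(q_all) <- as.character(skel$nodes$id)
    un_ids <- setdiff(skel$nodes$id, assigned)
    if (length(un_ids)) {
      up <- q_all[as.character(un_ids), , drop = FALSE]
      near_pos <- vapply(seq_along(un_ids), function(i)
        min(sqrt(rowSums(sweep(pos, 2, up[i, ])^2))) <= dup_tol, TRUE)
      if (any(near_pos))
        skel <- remove_nodes(skel, un_ids[near_pos])
    }
    ref <- if (length(assigned))
      q_all[as.character(intersect(assigned, skel$nodes$id)), ,
            drop = FALSE]
    else matrix(numeric(0), 0, 3)
  } else {
    ref <- skeleton_xyz_nm(skel)
  }
  q <- skeleton_xyz_nm(skel)
  keepr <- vapply(seq_len(nrow(pos)), function(i) {
    if (!nrow(ref)) return(TRUE)
    min(sqrt(rowSums(sweep(ref, 2, pos[i, ])^2))) > dup_tol
  }, TRUE)
  if (!any(keepr)) return(skel)
  newidx <- cumsum(keepr)
  pos2 <- pos[keepr, , drop = FALSE]
  n2 <- nrow(pos2)
  te2 <- NULL
  if (NROW(te)) {
    ok <- keepr[te[, 1]] & keepr[te[, 2]]
    if (any(ok))
      te2 <- cbind(newidx[te[ok, 1]], newidx[te[ok, 2]])
  }
  compid <- seq_len(n2)
  if (NROW(te2)) {
    find <- function(x) {
      while (compid[x] != x) { compid[x] <<- compid[compid[x]]; x <- compid[x] }
      x
    }
    for (r in seq_len(nrow(te2))) {
      a <- find(te2[r, 1]); b <- find(te2[r, 2])
      if (a != b) compid[a] <- b
    }
    for (i in seq_len(n2)) compid[i] <- find(i)
  }
  out <- skel
  for (cc in unique(compid)) {
    rows <- which(compid == cc)
    sub <- pos2[rows, , drop = FALSE]
    remap <- match(seq_len(n2), rows)
    tesub <- NULL
    if (NROW(te2)) {
      okc <- compid[te2[, 1]] == cc
      if (any(okc))
        tesub <- cbind(remap[te2[okc, 1]], remap[te2[okc, 2]])
    }
    near <- which.min(sqrt(rowSums(sweep(q, 2, sub[1, ])^2)))
    out <- splice_tree(out, sub, tesub, skel$nodes$id[near], roots = 1L)
  }
  out
}

# splice a tree (positions + index edge list into positions) into a
# tracing, each root index attached at node `attach_id`
splice_tree <- function(skel, positions, tree_edges, attach_id,
                        roots = 1L) {
  if (!nrow(positions)) return(skel)
  base <- max(skel$nodes$id)
  ids <- base + seq_len(nrow(positions))
  add <- data.frame(id = ids, x = positions[, 1], y = positions[, 2],
                    z = positions[, 3], radius = 1)
  nodes <- skel$nodes
  for (cn in setdiff(names(nodes), names(add))) add[[cn]] <- NA
  nodes <- rbind(nodes, add[, names(nodes)])
  edges <- skel$edges
  if (NROW(tree_edges))
    edges <- rbind(edges, cbind(ids[tree_edges[, 1]], ids[tree_edges[, 2]]))
  for (r in roots) edges <- rbind(edges, c(attach_id, ids[r]))
  skeleton(nodes, edges, id = skel$id, name = skel$name,
           units = skel$units, scale = skel$scale)
}

# majority vote of the local retracings on a contested region: "keep"
# when, on average, at least half of the contested sample points are
# covered by the retracings within the clique radius. A contested extra
# segment that merely shadows consensus structure its own tracing
# already participates in is a redundant duplicate and is dropped
# without a vote.
vote_majority <- function(mismatch, cpos, cliques, retracings) {
  radius <- cliques$radius
  if (mismatch$kind == "extra-branch") {
    own <- unique(cliques$members$clique[
      cliques$members$tracing == mismatch$involved])
    if (length(own)) {
      op <- cliques$positions[own, , drop = FALSE]
      shadow <- vapply(seq_len(nrow(cpos)), function(i)
        min(sqrt(rowSums(sweep(op, 2, cpos[i, ])^2))) <= radius / 2, TRUE)
      if (mean(shadow) >= 0.9) return("drop")
    }
  }
  if (!length(retracings))
    stop("majority policy requires local retracings")
  ball_r <- max(sqrt(rowSums(sweep(cpos, 2, mismatch$position)^2))) +
    2 * radius
  cover <- vapply(retracings, function(rt) {
    q <- skeleton_xyz_nm(rt)
    inball <- sqrt(rowSums(sweep(q, 2, mismatch$position)^2)) <= ball_r
    if (!any(inball))
      stop("retracing does not overlap the mismatch ball")
    q <- q[inball, , drop = FALSE]
    mean(vapply(seq_len(nrow(cpos)), function(i)
      min(sqrt(rowSums(sweep(q, 2, cpos[i, ])^2))) <= radius, TRUE))
  }, 0)
  if (mean(cover) >= 0.5) "keep" else "drop"
}

# contested sample positions of a mismatch, restricted to nodes that
# still exist in the current tracings
contested_positions <- function(mismatch, tracings, cliques, tr_ids) {
  if (mismatch$kind == "extra-branch") {
    k <- which(tr_ids == mismatch$involved)
    ok <- mismatch$contested$tracing == mismatch$involved &
      mismatch$contested$node %in% tracings[[k]]$nodes$id
    if (!any(ok)) return(NULL)
    p <- skeleton_xyz_nm(tracings[[k]])
    rownames(p) <- as.character(tracings[[k]]$nodes$id)
    p[as.character(mismatch$contested$node[ok]), , drop = FALSE]
  } else {
    cliques$positions[mismatch$component, , drop = FALSE]
  }
}

#' Resolve a mismatch point
#'
#' With policy `"majority"`, the supplied local re-tracings arbitrate:
#' the contested structure is accepted if, on average, at least half of
#' its sample points are covered by the re-tracings (within the clique
#' radius), and rejected otherwise. Policies `"keep"` and `"drop"` are
#' the direct expert decisions. Accepting means the consensus geometry of
#' the contested region is spliced into each involved tracing that lacks
#' it; rejecting means the contested nodes are deleted from the tracings
#' that have them. Resolving an already-resolved mismatch is a no-op.
#'
#' @param mismatch a `"mismatch_point"` from [find_mismatches()].
#' @param tracings the current list of tracings.
#' @param cliques the matching [form_cliques()] result.
#' @param retracings list of [skeleton()]s (nm) around the mismatch;
#'   required for `"majority"`, each must overlap the mismatch ball.
#' @param policy `"majority"`, `"keep"` or `"drop"`.
#' @return the updated list of tracings.
#' @export
resolve <- function(mismatch, tracings, cliques, retracings = list(),
                    policy = c("majority", "keep", "drop")) {
  policy <- match.arg(policy)
  if (isTRUE(mismatch$resolved)) return(tracings)
  radius <- cliques$radius
  tr_ids <- vapply(tracings, function(t) as.integer(t$id), 0L)

  # an earlier resolution in the same round may have removed some of the
  # contested nodes already; keep only those that still exist
  keep_row <- vapply(seq_len(nrow(mismatch$contested)), function(r) {
    k <- which(tr_ids == mismatch$contested$tracing[r])
    length(k) == 1 &&
      mismatch$contested$node[r] %in% tracings[[k]]$nodes$id
  }, TRUE)
  mismatch$contested <- mismatch$contested[keep_row, , drop = FALSE]

  # contested sample positions
  cpos <- if (mismatch$kind == "extra-branch") {
    if (!nrow(mismatch$contested)) return(tracings)
    tr <- tracings[[which(tr_ids == mismatch$involved)]]
    p <- skeleton_xyz_nm(tr); rownames(p) <- as.character(tr$nodes$id)
    p[as.character(mismatch$contested$node), , drop = FALSE]
  } else {
    cliques$positions[mismatch$component, , drop = FALSE]
  }

  if (policy == "majority")
    policy <- vote_majority(mismatch, cpos, cliques, retracings)

  if (policy == "drop") {
    for (tid in unique(mismatch$contested$tracing)) {
      k <- which(tr_ids == tid)
      drop_ids <- mismatch$contested$node[mismatch$contested$tracing == tid]
      tracings[[k]] <- remove_nodes(tracings[[k]], drop_ids)
    }
    return(tracings)
  }

  # keep: splice consensus geometry into the tracings lacking it
  if (mismatch$kind == "extra-branch") {
    src <- tracings[[which(tr_ids == mismatch$involved)]]
    p <- skeleton_xyz_nm(src); rownames(p) <- as.character(src$nodes$id)
    cids <- mismatch$contested$node
    pos <- p[as.character(sort(cids)), , drop = FALSE]
    idx <- stats::setNames(seq_along(sort(cids)), sort(cids))
    se <- src$edges[src$edges[, 1] %in% cids & src$edges[, 2] %in% cids,
                    , drop = FALSE]
    te <- if (nrow(se)) cbind(idx[as.character(se[, 1])],
                              idx[as.character(se[, 2])]) else NULL
    targets <- setdiff(tr_ids, mismatch$involved)
    for (tid in targets) {
      k <- which(tr_ids == tid)
      asg <- cliques$members$node[cliques$members$tracing == tid]
      tracings[[k]] <- guarded_splice(tracings[[k]], pos, te, radius / 2,
                                      assigned = asg)
    }
  } else {
    # splice the continuing consensus path into the short tracing
    comp <- mismatch$component
    ce <- clique_graph_edges(cliques, tracings)
    cadj <- list()
    for (k in seq_len(nrow(ce))) {
      a <- as.character(ce[k, 1]); b <- as.character(ce[k, 2])
      cadj[[a]] <- c(cadj[[a]], ce[k, 2])
      cadj[[b]] <- c(cadj[[b]], ce[k, 1])
    }
    # BFS from the divergence clique through the component
    start <- mismatch$divergence_clique
    order_ <- integer(0); parent <- c()
    seen <- stats::setNames(rep(FALSE, length(comp)), as.character(comp))
    queue <- intersect(cadj[[as.character(start)]], comp)
    pq <- rep(start, length(queue))
    for (q in queue) seen[as.character(q)] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      pv <- pq[1]; pq <- pq[-1]
      order_ <- c(order_, v)
      parent[as.character(v)] <- pv
      for (w in intersect(cadj[[as.character(v)]], comp)) {
        if (!seen[as.character(w)]) {
          seen[as.character(w)] <- TRUE
          queue <- c(queue, w); pq <- c(pq, v)
        }
      }
    }
    if (length(order_)) {
      pos <- cliques$positions[order_, , drop = FALSE]
      idx <- stats::setNames(seq_along(order_), as.character(order_))
      te <- NULL
      for (v in order_) {
        pv <- parent[as.character(v)]
        if (pv != start)
          te <- rbind(te, cbind(idx[as.character(pv)],
                                idx[as.character(v)]))
      }
      k <- which(tr_ids == mismatch$involved)
      asg <- cliques$members$node[
        cliques$members$tracing == mismatch$involved]
      tracings[[k]] <- guarded_splice(tracings[[k]], pos, te, radius / 2,
                                      assigned = asg)
    }
  }
  tracings
}

mismatch_signature <- function(m, radius) {
  paste(m$kind, m$involved, paste(round(m$position / radius),
                                  collapse = ","))
}

# append an endorsed orphan component (structure confirmed real but
# present in fewer than min_agreement tracings) to the consolidated
# skeleton, attached at the nearest consolidated node
append_endorsed <- function(cons, tracing, node_ids) {
  ok <- node_ids %in% tracing$nodes$id
  node_ids <- node_ids[ok]
  if (!length(node_ids)) return(cons)
  p <- skeleton_xyz_nm(tracing)
  rownames(p) <- as.character(tracing$nodes$id)
  pos <- p[as.character(sort(node_ids)), , drop = FALSE]
  idx <- stats::setNames(seq_along(node_ids), sort(node_ids))
  se <- tracing$edges[tracing$edges[, 1] %in% node_ids &
                      tracing$edges[, 2] %in% node_ids, , drop = FALSE]
  te <- if (nrow(se)) cbind(idx[as.character(se[, 1])],
                            idx[as.character(se[, 2])]) else NULL
  base <- max(cons$nodes$id)
  new_ids <- base + seq_len(nrow(pos))
  add <- data.frame(id = new_ids, x = pos[, 1], y = pos[, 2],
                    z = pos[, 3], radius = 1)
  q <- skeleton_xyz_nm(cons)
  near <- which.min(sqrt(rowSums(sweep(q, 2, pos[1, ])^2)))
  edges <- rbind(cons$edges,
                 if (!is.null(te)) cbind(new_ids[te[, 1]],
                                         new_ids[te[, 2]]),
                 c(cons$nodes$id[near], new_ids[1]))
  out <- skeleton(rbind(cons$nodes[, c("id", "x", "y", "z", "radius")],
                        add),
                  edges, id = cons$id, name = cons$name, units = "nm")
  out$clique_members <- cons$clique_members
  out$open_mismatches <- cons$open_mismatches
  class(out) <- class(cons)
  out
}

#' Run the CORE iteration to convergence
#'
#' Loops resample -> form cliques -> consolidate -> find mismatches ->
#' resolve until every mismatch point is decided, then returns the final
#' consolidated skeleton together with an audit log of every round. The
#' resolver is an injectable decision hook standing in for the
#' expert-plus-retracer step: it receives each mismatch and the current
#' tracings and returns the local re-tracings and/or decision.
#'
#' Decisions are applied once per mismatch (keyed by kind, tracing and
#' location): a spurious segment is deleted from its tracing; a missing
#' continuation is spliced into the short tracing from the consensus; a
#' confirmed segment that fewer than `min_agreement` tracings cover is
#' recorded and appended to the final consolidated skeleton. A mismatch
#' that persists after its decision has been applied is considered
#' settled and does not re-trigger resolution.
#'
#' @param tracings list of [skeleton()]s (raw tracings; resampled
#'   internally each round).
#' @param radius clique radius, nm.
#' @param min_agreement minimum clique size.
#' @param resolver `function(mismatch, tracings, consolidated)` returning
#'   `list(retracings = ..., policy = ...)`; required whenever
#'   mismatches occur.
#' @param target_spacing resampling density, nm.
#' @param max_rounds iteration cap; exceeding it raises a
#'   non-convergence error listing the open mismatches.
#' @return list of class `"core_result"`: `skeleton` (the consolidated
#'   skeleton), `rounds` (audit log), `tracings` (final corrected
#'   tracings), `n_rounds`.
#' @export
core_iterate <- function(tracings, radius = 500, min_agreement = 2,
                         resolver = NULL, target_spacing = 100,
                         max_rounds = 50) {
  audit <- list()
  current <- tracings
  decided <- new.env(parent = emptyenv())   # signature -> decision
  for (round in seq_len(max_rounds + 1L)) {
    rs <- lapply(current, resample, target_spacing = target_spacing)
    cliques <- form_cliques(rs, radius = radius,
                            min_agreement = min_agreement)
    cons <- consolidate(cliques, rs)
    mm <- find_mismatches(rs, cliques)
    sigs <- vapply(mm, mismatch_signature, "", radius = radius)
    open <- mm[!vapply(sigs, exists, TRUE, envir = decided)]
    audit[[round]] <- list(round = round,
                           n_cliques = nrow(cliques$positions),
                           n_orphans = nrow(cliques$orphans),
                           mismatches = vapply(mm, function(m) m$kind, ""),
                           new = length(open))
    if (!length(open)) {
      # settled: append structure endorsed by the expert/retracers
      tr_ids <- vapply(rs, function(t) as.integer(t$id), 0L)
      for (i in seq_along(mm)) {
        if (get(sigs[i], envir = decided) != "keep") next
        m <- mm[[i]]
        if (m$kind != "extra-branch") next
        k <- which(tr_ids == m$involved)
        cons <- append_endorsed(cons, rs[[k]],
                                m$contested$node[
                                  m$contested$tracing == m$involved])
      }
      cons$open_mismatches <- list()
      return(structure(list(skeleton = cons, rounds = audit,
                            tracings = current, n_rounds = round),
                       class = "core_result"))
    }
    if (round > max_rounds)
      stop("CORE did not converge within ", max_rounds, " rounds; ",
           length(open), " open mismatch(es) remain (",
           paste(vapply(open, function(m) m$kind, ""), collapse = ", "),
           ")")
    if (is.null(resolver))
      stop("mismatches found but no resolver supplied")
    tr_ids <- vapply(rs, function(t) as.integer(t$id), 0L)
    for (m in open) {
      dec <- resolver(m, rs, cons)
      pol <- if (is.null(dec$policy)) "majority" else dec$policy
      if (pol == "majority") {
        cpos <- contested_positions(m, rs, cliques, tr_ids)
        if (is.null(cpos)) next
        pol <- vote_majority(m, cpos, cliques, dec$retracings)
      }
      assign(mismatch_signature(m, radius), pol, envir = decided)
      if (pol == "drop") {
        rs <- resolve(m, rs, cliques, policy = "drop")
      } else if (m$kind != "extra-branch") {
        # missing continuation: splice the consensus into the short
        # tracing. Confirmed extra branches are left in place and
        # appended to the final consolidation instead of being copied
        # into the other tracings.
        rs <- resolve(m, rs, cliques, retracings = dec$retracings,
                      policy = "keep")
      }
    }
    current <- rs
  }
  stop("CORE did not converge")   # not reached
}

#' @exportS3Method base::print
print.core_result <- function(x, ...) {
  cat(sprintf("CORE result: %d rounds, %d consolidated nodes, %d open mismatch(es)\n",
              x$n_rounds, nrow(x$skeleton$nodes),
              length(x$skeleton$open_mismatches)))
  invisible(x)
}

#' Oracle resolver from a reference skeleton
#'
#' Builds a resolver that emulates the additional tracers: for each
#' mismatch it produces `n` local re-tracings by clipping a reference
#' skeleton to a ball around the mismatch point, and lets the majority
#' policy decide. Used for end-to-end validation against synthetic
#' ground truth.
#'
#' @param reference a [skeleton()] (nm) serving as the re-tracers' truth.
#' @param ball_radius clipping radius in nm (`Inf` = whole reference).
#' @param n number of re-tracings produced per mismatch.
#' @return a resolver function for [core_iterate()].
#' @export
oracle_resolver <- function(reference, ball_radius = Inf, n = 2) {
  force(reference); force(ball_radius); force(n)
  function(mismatch, tracings, consolidated) {
    p <- skeleton_xyz_nm(reference)
    keep <- sqrt(rowSums(sweep(p, 2, mismatch$position)^2)) <= ball_radius
    ids <- reference$nodes$id[keep]
    if (!any(keep)) {
      # reference has nothing near the mismatch: one far sentinel node
      # would violate the overlap precondition, so return the nearest
      # reference node as a minimal (non-covering) retracing
      near <- which.min(sqrt(rowSums(sweep(p, 2, mismatch$position)^2)))
      ids <- reference$nodes$id[near]
    }
    sub_nodes <- reference$nodes[reference$nodes$id %in% ids, , drop = FALSE]
    sub_edges <- reference$edges[reference$edges[, 1] %in% ids &
                                 reference$edges[, 2] %in% ids, ,
                                 drop = FALSE]
    rt <- skeleton(sub_nodes, sub_edges, id = 900L, name = "retracing",
                   units = "nm")
    list(retracings = rep(list(rt), n), policy = "majority")
  }
}
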