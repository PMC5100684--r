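straight_path <- function(n, spacing = 100, id = 1L, y = 0, z = 0) {
  nodes <- data.frame(id = seq_len(n), x = (seq_len(n) - 1) * spacing,
                      y = y, z = z, radius = 1)
  edges <- if (n > 1) cbind(1:(n - 1), 2:n) else NULL
  skeleton(nodes, edges, id = id, units = "nm")
}

test_that("resampling yields uniform spacing and preserves arc length", {
  # two nodes at the target spacing are unchanged
  sk <- straight_path(2, 100)
  rs <- resample(sk, 100)
  expect_equal(nrow(rs$nodes), 2)
  expect_equal(skeleton_length(rs), 100)

  # 1000 nm straight path at 100 nm: 11 nodes, uniform gaps
  sk <- straight_path(3, 500)
  rs <- resample(sk, 100)
  expect_equal(nrow(rs$nodes), 11)
  p <- skeleton_positions_nm(rs)
  idx <- match(rs$edges, rs$nodes$id); dim(idx) <- dim(rs$edges)
  gaps <- sqrt(rowSums((p[idx[, 1], ] - p[idx[, 2], ])^2))
  expect_equal(gaps, rep(100, 10))

  # random trees: total length preserved, spacing bound respected,
  # branch points and endpoints kept exactly
  for (seed in c(2, 5)) {
    tree <- gen_skeleton(3, step = 130, seed = seed, total_length = 12000)
    rs <- resample(tree, 100)
    expect_equal(skeleton_length(rs), skeleton_length(tree),
                 tolerance = 1e-6)
    p <- skeleton_positions_nm(rs)
    idx <- match(rs$edges, rs$nodes$id); dim(idx) <- dim(rs$edges)
    gaps <- sqrt(rowSums((p[idx[, 1], ] - p[idx[, 2], ])^2))
    expect_lte(max(gaps), 100 + 1e-9)
    deg <- sbemtools:::skeleton_degree(tree)
    keep <- tree$nodes$id[deg != 2]
    tp <- skeleton_positions_nm(tree)[match(keep, tree$nodes$id), ,
                                      drop = FALSE]
    for (r in seq_len(nrow(tp)))
      expect_lt(min(sqrt(rowSums(sweep(p, 2, tp[r, ])^2))), 1e-9)
  }
  expect_error(resample(straight_path(3), 0), "positive")
})

test_that("identical tracings form one clique per node with no orphans", {
  one <- skeleton(data.frame(id = 1, x = 0, y = 0, z = 0, radius = 1),
                  NULL, id = 1L, units = "nm")
  tr <- lapply(1:3, function(i) { s <- one; s$id <- i; s })
  cl <- form_cliques(tr, radius = 200, min_agreement = 2)
  expect_equal(nrow(cl$positions), 1)
  expect_equal(nrow(cl$members), 3)
  expect_equal(nrow(cl$orphans), 0)

  path <- straight_path(30)
  tr <- lapply(1:3, function(i) { s <- path; s$id <- i; s })
  cl <- form_cliques(tr, radius = 200, min_agreement = 2)
  expect_equal(nrow(cl$positions), 30)
  expect_equal(nrow(cl$orphans), 0)
  cons <- consolidate(cl, tr)
  expect_equal(nrow(cons$nodes), 30)
  expect_equal(nrow(cons$edges), 29)
  expect_equal(sort(cons$nodes$x), path$nodes$x)

  expect_error(form_cliques(tr, 200, min_agreement = 4), "min_agreement")
  expect_error(form_cliques(tr[1], 200), "at least 2")
})

test_that("jittered copies of a path form full cliques", {
  set.seed(3)
  base <- straight_path(50)
  tr <- lapply(1:3, function(i) {
    s <- base
    s$nodes[, c("x", "y", "z")] <- s$nodes[, c("x", "y", "z")] +
      rnorm(150, 0, 20)
    s$id <- i
    s
  })
  cl <- form_cliques(tr, radius = 200, min_agreement = 2)
  expect_equal(nrow(cl$positions), 50)
  expect_equal(nrow(cl$orphans), 0)
  # consolidated geometry matches the unjittered base path closely
  cons <- consolidate(cl, tr)
  m <- reconstruction_metrics(cons, base, tolerance = 100)
  expect_gt(m$recall, 0.99)
  expect_gt(m$precision, 0.99)
  # raising the agreement bar never adds consolidated nodes
  cl3 <- form_cliques(tr, radius = 200, min_agreement = 3)
  expect_lte(nrow(cl3$positions), nrow(cl$positions))
  # consensus positions are member centroids
  m1 <- cl$members[cl$members$clique == 1, ]
  cent <- colMeans(do.call(rbind, lapply(seq_len(nrow(m1)), function(r) {
    s <- tr[[m1$tracing[r]]]
    as.numeric(s$nodes[s$nodes$id == m1$node[r], c("x", "y", "z")])
  })))
  expect_equal(unname(cl$positions[1, ]), unname(cent))
})

test_that("clique formation is independent of tracing input order", {
  ts <- make_tracing_set(4, total_length = 8000, n_branch = 1,
                         graft = 2000)
  rs <- lapply(ts$tracings, resample)
  cl1 <- form_cliques(rs, 500, 2)
  cl2 <- form_cliques(rev(rs), 500, 2)
  key <- function(cl) {
    m <- cl$members[order(cl$members$clique, cl$members$tracing), ]
    split(paste(m$tracing, m$node), m$clique)
  }
  expect_identical(unname(key(cl1)), unname(key(cl2)))
  expect_identical(cl1$positions, cl2$positions)
})

test_that("grafted branches orphan and are localized as mismatches", {
  base <- straight_path(40)
  tr <- lapply(1:3, function(i) { s <- base; s$id <- i; s })
  # graft a 5-node side branch onto tracing 3 at node 20
  g <- tr[[3]]
  gn <- data.frame(id = 41:45, x = g$nodes$x[20],
                   y = seq(150, 750, by = 150), z = 0, radius = 1)
  nodes <- rbind(g$nodes, gn)
  edges <- rbind(g$edges, cbind(c(20L, 41:44), 41:45))
  tr[[3]] <- skeleton(nodes, edges, id = 3L, units = "nm")

  cl <- form_cliques(tr, radius = 100, min_agreement = 2)
  expect_setequal(cl$orphans$node[cl$orphans$tracing == 3], 41:45)
  expect_equal(nrow(cl$orphans), 5)

  mm <- find_mismatches(tr, cl)
  expect_length(mm, 1)
  expect_equal(mm[[1]]$kind, "extra-branch")
  expect_equal(mm[[1]]$involved, 3)
  # mismatch within one radius of the graft origin
  origin <- c(g$nodes$x[20], 0, 0)
  expect_lt(sqrt(sum((mm[[1]]$position - c(origin[1], 150, 0))^2)), 100)

  # identical tracings: no mismatches at all
  tr0 <- lapply(1:3, function(i) { s <- base; s$id <- i; s })
  expect_length(find_mismatches(tr0, form_cliques(tr0, 100, 2)), 0)
})

test_that("majority rule includes 2-of-3 branches and excludes 1-of-3", {
  base <- straight_path(20)
  branch <- data.frame(id = 21:30, x = 1000,
                       y = seq(100, 1000, by = 100), z = 0, radius = 1)
  with_branch <- skeleton(rbind(base$nodes, branch),
                          rbind(base$edges, cbind(c(11L, 21:29), 21:30)),
                          id = 1L, units = "nm")
  mk <- function(s, i) { s$id <- i; s }
  # branch in 2 of 3
  tr <- list(mk(with_branch, 1), mk(with_branch, 2), mk(base, 3))
  cl <- form_cliques(tr, 100, 2)
  cons <- consolidate(cl, tr)
  expect_gte(max(cons$nodes$y), 1000)      # branch included
  # branch in 1 of 3
  tr <- list(mk(with_branch, 1), mk(base, 2), mk(base, 3))
  cons1 <- consolidate(form_cliques(tr, 100, 2), tr)
  expect_lt(max(cons1$nodes$y), 100)       # branch excluded
})

test_that("early termination is detected at the truncation point", {
  base <- straight_path(60)
  short <- skeleton(base$nodes[1:48, ], base$edges[1:47, , drop = FALSE],
                    id = 2L, units = "nm")
  tr <- list(base, short, base)
  tr[[1]]$id <- 1L; tr[[3]]$id <- 3L
  cl <- form_cliques(tr, radius = 100, min_agreement = 2)
  mm <- find_mismatches(tr, cl)
  kinds <- vapply(mm, function(m) m$kind, "")
  expect_true("early-termination" %in% kinds)
  m <- mm[[which(kinds == "early-termination")[1]]]
  expect_equal(m$involved, 2)
  expect_lt(abs(m$position[1] - 4700), 200)   # 2 radii of the endpoint
})

test_that("resolution applies expert decisions and is idempotent", {
  ts <- make_tracing_set(6, total_length = 8000, n_branch = 1,
                         truncate = 0, graft = 3000)
  rs <- lapply(ts$tracings, resample)
  cl <- form_cliques(rs, 500, 2)
  mm <- find_mismatches(rs, cl)
  kinds <- vapply(mm, function(m) m$kind, "")
  expect_true("extra-branch" %in% kinds)
  m <- mm[[which(kinds == "extra-branch")[1]]]

  dropped <- resolve(m, rs, cl, policy = "drop")
  rs2 <- lapply(dropped, resample)
  cl2 <- form_cliques(rs2, 500, 2)
  expect_length(find_mismatches(rs2, cl2), 0)

  # already-resolved mismatch is a no-op
  m$resolved <- TRUE
  expect_identical(resolve(m, rs, cl, policy = "drop"), rs)

  # majority requires retracings that overlap the mismatch ball
  m$resolved <- FALSE
  expect_error(resolve(m, rs, cl, policy = "majority"), "retracings")
  far <- straight_path(5, id = 99L)
  far$nodes$x <- far$nodes$x + 1e7
  expect_error(resolve(m, rs, cl, retracings = list(far),
                       policy = "majority"), "overlap")
})

test_that("core iteration converges on identical tracings in one round", {
  base <- straight_path(40)
  tr <- lapply(1:3, function(i) { s <- base; s$id <- i; s })
  res <- core_iterate(tr, radius = 200, min_agreement = 2)
  expect_equal(res$n_rounds, 1)
  expect_length(res$skeleton$open_mismatches, 0)
  expect_equal(nrow(res$skeleton$nodes), 40)
})

test_that("unresolved mismatches trip the iteration cap", {
  ts <- make_tracing_set(7, total_length = 6000, n_branch = 0,
                         truncate = 0, graft = 2500)
  expect_error(
    core_iterate(ts$tracings, radius = 500, min_agreement = 2,
                 resolver = oracle_resolver(ts$truth), max_rounds = 0),
    "did not converge")
  # ... and with no resolver at all, mismatches are a hard error
  expect_error(
    core_iterate(ts$tracings, radius = 500, min_agreement = 2),
    "resolver")
})

test_that("CORE with an oracle resolver repairs one perturbed set", {
  ts <- make_tracing_set(2)
  res <- core_iterate(ts$tracings, radius = 500, min_agreement = 2,
                      resolver = oracle_resolver(ts$truth))
  m <- reconstruction_metrics(res$skeleton, ts$truth, tolerance = 100)
  expect_gte(m$recall, 0.99)
  expect_gte(m$precision, 0.99)
  expect_gt(length(res$rounds), 1)   # audit log covers every round
})
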