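test_that("growth parameter ordering D < d_k < d_i is advisory", {
  expect_silent(growth_params(5, 10, 15))
  expect_warning(growth_params(10, 5, 15), "ordering")
  expect_error(growth_params(-1, 10, 15))
})

test_that("a lone target within reach is snapped exactly", {
  att <- attractor_set(NULL, matrix(c(0, 0, 3), 1, 3))
  tr <- grow_tree(matrix(0, 1, 3), att,
                  growth_params(5, 10, 15), seed = 1)
  expect_equal(nrow(tr$nodes), 2L)
  expect_equal(as.numeric(tr$nodes[2, c("x", "y", "z")]), c(0, 0, 3))
  expect_equal(tr$terminal_map$node, 2L)
  expect_equal(tr$iterations, 1L)
})

test_that("a single ordinary attractor pulls growth straight toward it", {
  att <- attractor_set(matrix(c(0, 0, 10), 1, 3), matrix(numeric(0), 0, 3))
  tr <- grow_tree(matrix(0, 1, 3), att,
                  growth_params(5, 6, 15), seed = 1)
  expect_equal(as.numeric(tr$nodes[2, c("x", "y", "z")]), c(0, 0, 5))
})

test_that("every super-lobule centroid is reached and sits at a terminal", {
  fx <- cached_grown50()
  tr <- fx$tree
  part <- fx$partition
  expect_setequal(tr$terminal_map$sl_id, 1:50)
  # terminal positions coincide with the centroids exactly
  pos <- as.matrix(tr$nodes[tr$terminal_map$node, c("x", "y", "z")])
  ctr <- as.matrix(part$centroids[tr$terminal_map$sl_id, c("x", "y", "z")])
  expect_equal(unname(pos), unname(ctr), tolerance = 1e-12)
  # acyclic, rooted: every parent precedes its child
  nonroot <- !is.na(tr$nodes$parent)
  expect_true(all(tr$nodes$parent[nonroot] < tr$nodes$id[nonroot]))
})

test_that("growth is deterministic for a fixed seed", {
  set.seed(8)
  att <- attractor_set(matrix(runif(60, -20, 20), ncol = 3),
                       matrix(c(0, 0, 10), 1, 3))
  p <- growth_params(3, 6, 12)
  a <- grow_tree(matrix(0, 1, 3), att, p, seed = 99)
  b <- grow_tree(matrix(0, 1, 3), att, p, seed = 99)
  expect_identical(a$nodes, b$nodes)
})

test_that("pruning keeps exactly the union of terminal-to-root paths", {
  # pure path: unchanged
  path_nodes <- tibble::tibble(id = 1:4, x = 0, y = 0, z = c(0, 1, 2, 3),
                               parent = c(NA, 1L, 2L, 3L))
  path <- structure(list(nodes = path_nodes, roots = 1L,
                         terminal_map = tibble::tibble(sl_id = 1L, node = 4L),
                         label = "inlet", iterations = 0L),
                    class = "vascular_tree")
  expect_equal(nrow(prune_tree(path)$nodes), 4L)

  # dead-end side chain of 3 is removed
  side <- path
  side$nodes <- dplyr::bind_rows(path_nodes, tibble::tibble(
    id = 5:7, x = 1:3, y = 0, z = 1, parent = c(2L, 5L, 6L)))
  pruned <- prune_tree(side)
  expect_equal(nrow(pruned$nodes), 4L)
  expect_equal(pruned$terminal_map$node, 4L)

  # on a grown fixture: retained set == union of ancestor sets (oracle)
  tr <- cached_grown50()$tree
  keep <- rep(FALSE, nrow(tr$nodes))
  for (t in tr$terminal_map$node) {
    i <- t
    while (!is.na(i)) {
      keep[i] <- TRUE
      i <- tr$nodes$parent[i]
    }
  }
  pr <- prune_tree(tr)
  expect_equal(nrow(pr$nodes), sum(keep) + sum(!keep[tr$roots]))
  # every leaf of the pruned tree is a terminal
  leaves <- setdiff(pr$nodes$id, pr$nodes$parent)
  expect_true(all(leaves %in% pr$terminal_map$node))
})

test_that("pruning requires reached targets", {
  t0 <- structure(list(nodes = tibble::tibble(id = 1L, x = 0, y = 0, z = 0,
                                              parent = NA_integer_),
                       roots = 1L,
                       terminal_map = tibble::tibble(sl_id = integer(),
                                                     node = integer()),
                       label = "inlet", iterations = 0L),
                  class = "vascular_tree")
  expect_error(prune_tree(t0), "no reached targets")
})

test_that("primary branches reach the portal and hepatic landmarks", {
  m <- ellipsoid_mesh()
  inlet <- initialize_major_branches(m, "inlet", seed = 31)
  expect_equal(length(inlet$primary_terminals), 2L)
  outlet <- initialize_major_branches(m, "outlet", seed = 32)
  expect_equal(length(outlet$primary_terminals), 3L)
  expect_error(
    initialize_major_branches(m, "inlet",
                              targets = matrix(c(1e4, 0, 0), 1, 3)),
    "outside")
})

test_that("collinear primary targets still admit full growth", {
  m <- ellipsoid_mesh()
  bb <- mesh_bbox(m)
  ctr <- colMeans(bb)
  tgts <- rbind(ctr + c(-20, 0, 0), ctr + c(20, 0, 0))
  prim <- initialize_major_branches(m, "inlet", root = ctr + c(-60, 0, 0),
                                    targets = tgts, seed = 33)
  cloud <- sample_interior(m, 2500, seed = 34)
  part <- partition_super_lobules(cloud, 8, seed = 35)
  att <- attractor_set(cloud, part$centroids[, c("x", "y", "z")],
                       part$centroids$sl_id)
  tr <- grow_tree(prim, att, growth_params(), seed = 36)
  expect_setequal(tr$terminal_map$sl_id, 1:8)
})

test_that("stagnation fails loudly with the unreached target ids", {
  # a target far beyond the sphere of influence can never be engaged
  att <- attractor_set(NULL, matrix(c(0, 0, 1000), 1, 3))
  expect_error(grow_tree(matrix(0, 1, 3), att, growth_params(5, 10, 15),
                         seed = 1),
               "unreached target\\(s\\): 1")
})

test_that("connected topology links each super lobule exactly once", {
  mod <- cached_10sl_model()
  links <- mod$topology$links
  expect_setequal(links$sl_id, 1:10)
  el <- mod$network$elements
  sl <- dplyr::filter(el, type == "sl")
  expect_equal(nrow(sl), 10L)
  # every SL element bridges a degree-2 pair: its endpoints carry only the
  # SL and one vessel each
  deg <- table(c(el$from, el$to))
  expect_true(all(deg[as.character(sl$from)] == 2L))
  expect_true(all(deg[as.character(sl$to)] == 2L))
})

test_that("mismatched terminal sets are reported by super-lobule id", {
  mod <- cached_10sl_model()
  trimmed <- mod$topology$inlet
  trimmed$terminal_map <- trimmed$terminal_map[-3, ]
  expect_error(connect_trees(trimmed, mod$topology$outlet),
               "missing from inlet: \\{3\\}")
})

test_that("smaller colonization parameters give more tortuous trees", {
  m <- ellipsoid_mesh()
  # the fine-parameter run needs a cloud dense relative to d_i = 10 mm
  cloud <- sample_interior(m, 6000, seed = 41)
  part <- partition_super_lobules(cloud, 30, seed = 42)
  att <- attractor_set(cloud, part$centroids[, c("x", "y", "z")],
                       part$centroids$sl_id)
  prim <- initialize_major_branches(m, "inlet", params = growth_params(),
                                    seed = 43)
  fine <- grow_tree(prim, att,
                    growth_params(2.5, 5, 10, max_iterations = 20000L),
                    seed = 44)
  coarse <- suppressWarnings(
    grow_tree(prim, att, growth_params(10, 15, 25), seed = 44))
  # per-terminal tortuosity (path length over straight-line distance)
  # isolates wiggliness from coverage
  expect_gt(tree_tortuosity(prune_tree(fine)),
            tree_tortuosity(prune_tree(coarse)))
})
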