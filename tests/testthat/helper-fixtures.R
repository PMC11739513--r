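# shared fixtures, built in code and cached for the session

.fixture_env <- new.env()

# unit cube [0,1]^3 as a watertight 12-triangle surface
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces oriented outward
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  volume_mesh(v, f)
}

# cube with one face removed: 2 open edges x 3 -> not watertight
open_cube_mesh <- function() {
  m <- unit_cube_mesh()
  volume_mesh(m$vertices, m$faces[-1, ], validate = FALSE)
}

# small generated liver model shared across tests (expensive to rebuild)
cached_10sl_model <- function() {
  if (is.null(.fixture_env$m10)) {
    cfg <- run_config(geometry = list(n_super_lobules = 10L,
                                      min_points = 2000L))
    .fixture_env$m10 <- generate_model(cfg, seed = 1)
  }
  .fixture_env$m10
}

cached_10sl_solution <- function() {
  if (is.null(.fixture_env$s10)) {
    .fixture_env$s10 <- calibrate_flow(cached_10sl_model()$network,
                                       boundary_conditions())
  }
  .fixture_env$s10
}

# 100-super-lobule model for the time-step convergence protocol
cached_100sl_model <- function() {
  if (is.null(.fixture_env$m100)) {
    cfg <- run_config(geometry = list(n_super_lobules = 100L))
    .fixture_env$m100 <- generate_model(cfg, seed = 7)
  }
  .fixture_env$m100
}

cached_100sl_solution <- function() {
  if (is.null(.fixture_env$s100)) {
    .fixture_env$s100 <- calibrate_flow(cached_100sl_model()$network,
                                        boundary_conditions())
  }
  .fixture_env$s100
}

# grown (unpruned) 50-target tree on the ellipsoid, shared by growth tests
cached_grown50 <- function() {
  if (is.null(.fixture_env$grown50)) {
    m <- ellipsoid_mesh()
    cloud <- sample_interior(m, 3000, seed = 21)
    part <- partition_super_lobules(cloud, 50, seed = 22)
    att <- attractor_set(cloud, part$centroids[, c("x", "y", "z")],
                         part$centroids$sl_id)
    prim <- initialize_major_branches(m, "inlet", params = growth_params(),
                                      seed = 23)
    .fixture_env$grown50 <- list(
      tree = grow_tree(prim, att, growth_params(), seed = 24),
      partition = part)
  }
  .fixture_env$grown50
}

# random mirrored tree-SL-tree network with explicit resistances, plus an
# independent recursive series/parallel reduction oracle
random_mirror_network <- function(n_terminals, R_SL, seed) {
  set.seed(seed)
  # random full binary-ish tree over n_terminals leaves
  # node encoding: list of children per internal node id
  splits <- list()
  make_tree <- function(leaves) {
    id <- length(splits) + 1L
    splits[[id]] <<- list(pending = TRUE)
    if (length(leaves) == 1L) {
      splits[[id]] <<- list(leaf = leaves)
      return(id)
    }
    cut <- sample(seq_len(length(leaves) - 1L), 1L)
    l <- make_tree(leaves[seq_len(cut)])
    r <- make_tree(leaves[-seq_len(cut)])
    splits[[id]] <<- list(children = c(l, r))
    id
  }
  root <- make_tree(seq_len(n_terminals))

  # assemble elements: inlet edges mirror outlet edges with separate R
  elements <- list()
  nodes <- 0L
  new_node <- function() {
    nodes <<- nodes + 1L
    nodes
  }
  inlet_root_node <- new_node()
  outlet_root_node <- new_node()
  add_el <- function(type, from, to, R) {
    elements[[length(elements) + 1L]] <<- tibble::tibble(
      element = length(elements) + 1L, type = type, from = from, to = to,
      L = NA_real_, r = NA_real_, R = R, V = 1)
  }
  rnd_R <- function() exp(stats::rnorm(1, 0, 1))
  # returns equivalent resistance of the subnetwork between the node pair
  build <- function(id, in_node, out_node) {
    s <- splits[[id]]
    if (!is.null(s$leaf)) {
      add_el("sl", in_node, out_node, NA_real_)
      return(R_SL)
    }
    branch_Rs <- vapply(s$children, function(ch) {
      a <- rnd_R(); b <- rnd_R()
      cin <- new_node(); cout <- new_node()
      add_el("vessel", in_node, cin, a)
      sub <- build(ch, cin, cout)
      add_el("vessel", cout, out_node, b)
      a + sub + b
    }, numeric(1))
    1 / sum(1 / branch_Rs)
  }
  R_eq_oracle <- build(root, inlet_root_node, outlet_root_node)
  el <- dplyr::bind_rows(elements)
  el$sl_id <- cumsum(el$type == "sl") * (el$type == "sl")
  el$sl_id[el$sl_id == 0] <- NA_integer_
  net <- flow_network(el, tibble::tibble(node = seq_len(nodes)),
                      inlet_node = inlet_root_node,
                      outlet_node = outlet_root_node)
  list(network = net, R_eq_oracle = R_eq_oracle)
}

# binary STL writer (little-endian), to exercise the binary reader
write_stl_binary_fixture <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- mesh$vertices[f[i, ], , drop = FALSE]
    writeBin(numeric(3), con, size = 4, endian = "little")  # normal
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}
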