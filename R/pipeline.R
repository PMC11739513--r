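#' Run configuration
#'
#' Central, schema-checked configuration for the whole pipeline. Unknown
#' keys (at either level) are rejected before any computation. Values can
#' be loaded from a YAML file with [read_config()].
#'
#' @param geometry,growth,primary,flow,perfusion named lists overriding the
#'   section defaults (see Details in the package vignette).
#' @param seed master RNG seed; every stochastic stage derives its stream
#'   from it.
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(geometry = list(), growth = list(), primary = list(),
                       flow = list(), perfusion = list(), seed = 1L) {
  defaults <- list(
    geometry = list(
      mesh_path = NULL,            # NULL -> synthetic ellipsoid
      target_volume_ml = 1600,
      n_super_lobules = 10L,
      points_per_sl = 200L,
      min_points = 5000L,
      blood_volume_fraction = 0.25),
    growth = list(
      D = 5, d_k = 10, d_i = 15, max_iterations = 5000L,
      min_segment_length = 0.5),
    primary = list(
      inlet_root = NULL, inlet_targets = NULL,
      outlet_root = NULL, outlet_targets = NULL),
    flow = list(
      P_in_mmHg = 5.8, P_out_mmHg = 0, Q_target_ml_min = 767,
      mu_cP = 3.5, gamma = 3, root_diameter_mm = 15,
      bisect_tol = 1e-8, bisect_upper = 1),
    perfusion = list(
      dt_s = 0.01, thresholds = c(0.5, 0.9, 0.98), t_max_s = 2000,
      inlet_concentration = 1, record_every = 10L))
  sections <- list(geometry = geometry, growth = growth, primary = primary,
                   flow = flow, perfusion = perfusion)
  for (sec in names(sections)) {
    extra <- setdiff(names(sections[[sec]]), names(defaults[[sec]]))
    if (length(extra)) {
      stop("unknown config key(s) in '", sec, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    defaults[[sec]][names(sections[[sec]])] <- sections[[sec]]
  }
  defaults$seed <- as.integer(seed)
  structure(defaults, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] sections.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "growth", "primary", "flow", "perfusion", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Generate a complete connected liver model
#'
#' End-to-end geometry and growth pipeline: load (or synthesize) and scale
#' the organ surface, sample the interior attractor cloud, partition it
#' into super lobules, initialize the primary branches of both trees, grow
#' each tree until every super-lobule centroid is reached, prune
#' non-critical branches, and assemble the connected resistance network.
#' Any failure is re-raised with the failing stage named.
#'
#' @param config a [run_config()].
#' @param seed optional override of `config$seed`.
#' @return a list of class `liver_model`: `mesh`, `partition`, `topology`
#'   (pruned, connected trees), `network` (a `flow_network`), `cloud_size`,
#'   `config`, `seed`.
#' @export
generate_model <- function(config = run_config(), seed = NULL) {
  if (!inherits(config, "run_config")) {
    stop("config must be a run_config object", call. = FALSE)
  }
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  g <- config$geometry
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  mesh <- stage("geometry", {
    target <- g$target_volume_ml * 1000
    if (is.null(g$mesh_path)) {
      ellipsoid_mesh(target_volume = target)
    } else {
      scale_to_volume(read_stl(g$mesh_path), target)
    }
  })

  k <- as.integer(g$n_super_lobules)
  n_pts <- max(as.integer(g$points_per_sl) * k, as.integer(g$min_points))
  cloud <- stage("sampling", sample_interior(mesh, n_pts, seed = seed))
  partition <- stage("partition",
                     partition_super_lobules(cloud, k, seed = seed + 1L))

  gp <- config$growth
  params <- growth_params(D = gp$D, d_k = gp$d_k, d_i = gp$d_i,
                          max_iterations = gp$max_iterations)
  pr <- config$primary
  grow_one <- function(label, root, targets, seed_offset) {
    primary <- stage(paste0("primary_", label),
      initialize_major_branches(mesh, label, root = root, targets = targets,
                                params = params, seed = seed + seed_offset))
    att <- attractor_set(cloud, partition$centroids[, c("x", "y", "z")],
                         target_ids = partition$centroids$sl_id)
    tree <- stage(paste0("growth_", label),
      grow_tree(primary, att, params, seed = seed + seed_offset + 1L))
    tree <- stage(paste0("prune_", label), prune_tree(tree))
    stage(paste0("consolidate_", label),
          consolidate_short_edges(tree, gp$min_segment_length))
  }
  inlet <- grow_one("inlet", pr$inlet_root, pr$inlet_targets, 2L)
  outlet <- grow_one("outlet", pr$outlet_root, pr$outlet_targets, 10L)

  topology <- stage("connect", connect_trees(inlet, outlet, partition))
  fl <- config$flow
  network <- stage("network",
    build_flow_network(topology, mu_cP = fl$mu_cP, gamma = fl$gamma,
                       r_root = fl$root_diameter_mm / 2,
                       organ_volume = g$target_volume_ml * 1000,
                       blood_volume_fraction = g$blood_volume_fraction))
  structure(list(mesh = mesh, partition = partition, topology = topology,
                 network = network, cloud_size = n_pts,
                 config = config, seed = seed),
            class = "liver_model")
}

#' @export
print.liver_model <- function(x, ...) {
  cat(sprintf("<liver_model> %d super lobules, %d vessels, seed %d\n",
              x$network$n_SL, sum(x$network$elements$type == "vessel"),
              x$seed))
  invisible(x)
}

#' Merge sub-resolution stub segments into their chain
#'
#' Target snapping can leave vessel segments far shorter than the growth
#' step. Along an unbranched chain the Murray radius is constant, so
#' contracting such an edge leaves the chain's total resistance and volume
#' essentially unchanged while removing elements whose tiny volume would
#' otherwise dictate the loading time step. Edges shorter than `min_len`
#' are contracted where a legal contraction exists (terminal nodes and
#' roots are never removed, so terminals stay exactly at the super-lobule
#' centroids).
#'
#' @param tree a pruned `vascular_tree`.
#' @param min_len minimum edge length, mm (0 disables).
#' @return the consolidated `vascular_tree`.
#' @export
consolidate_short_edges <- function(tree, min_len = 0.5) {
  if (min_len <= 0) return(tree)
  repeat {
    n <- tree$nodes
    parent <- n$parent
    pos <- as.matrix(n[, c("x", "y", "z")])
    has_parent <- which(!is.na(parent))
    L <- sqrt(rowSums((pos[has_parent, , drop = FALSE] -
                       pos[parent[has_parent], , drop = FALSE])^2))
    short <- has_parent[L < min_len]
    if (!length(short)) return(tree)
    terminals <- tree$terminal_map$node
    removed <- FALSE
    for (child in short) {
      p <- parent[child]
      # prefer removing the child (reconnect its children upward)
      if (!(child %in% terminals) && !(child %in% tree$roots)) {
        drop <- child; attach_to <- p
      } else if (!(p %in% terminals) && !(p %in% tree$roots) &&
                 !is.na(parent[p])) {
        drop <- p; attach_to <- parent[p]
      } else next
      kids <- which(parent == drop)
      parent[kids] <- attach_to
      keep <- setdiff(seq_len(nrow(n)), drop)
      new_id <- integer(nrow(n))
      new_id[keep] <- seq_along(keep)
      n2 <- n[keep, , drop = FALSE]
      n2$id <- seq_len(nrow(n2))
      pv <- parent[keep]
      n2$parent <- ifelse(is.na(pv), NA_integer_, as.integer(new_id[pv]))
      tm <- tree$terminal_map
      tm$node <- as.integer(new_id[tm$node])
      tree <- structure(list(nodes = n2,
                             roots = as.integer(new_id[tree$roots]),
                             terminal_map = tm, label = tree$label,
                             iterations = tree$iterations),
                        class = "vascular_tree")
      removed <- TRUE
      break  # recompute geometry after each contraction
    }
    if (!removed) return(tree)
  }
}

#' Sweep pressure/flow boundary conditions
#'
#' For every (pressure drop, target flow) cell: calibrate the super-lobule
#' resistance, record the maximum wall shear stress, and (optionally)
#' simulate loading to report the time for the total concentration and the
#' slowest super lobule to reach 90%. Infeasible cells (no non-negative
#' R_SL admits the flow) are flagged, not fatal.
#'
#' @param network a `flow_network`.
#' @param pressures_mmHg inlet pressures, mmHg (outlet held at 0).
#' @param flows_ml_min target flows, mL/min.
#' @param perfuse also run the loading simulation per cell.
#' @param dt loading time step, s; `NULL` picks 90% of the stable limit
#'   capped at 0.01 s.
#' @param tol_ml_min bisection flow tolerance, mL/min.
#' @return tibble of class `bc_sweep`: one row per cell with `P_mmHg`,
#'   `Q_ml_min`, `feasible`, `R_SL`, `max_wss`, `t90_total`, `t90_last_sl`.
#' @export
sweep_boundary_conditions <- function(network, pressures_mmHg = 3:12,
                                      flows_ml_min = seq(100, 1000, 100),
                                      perfuse = TRUE, dt = NULL,
                                      tol_ml_min = 1e-8) {
  grid <- tidyr::expand_grid(P_mmHg = pressures_mmHg,
                             Q_ml_min = flows_ml_min)
  rows <- purrr::pmap(grid, function(P_mmHg, Q_ml_min) {
    bc <- boundary_conditions(P_in_mmHg = P_mmHg, P_out_mmHg = 0,
                              Q_target_ml_min = Q_ml_min)
    sol <- tryCatch(calibrate_flow(network, bc, tol_ml_min = tol_ml_min),
                    error = function(e) NULL)
    if (is.null(sol)) {
      return(tibble::tibble(P_mmHg = P_mmHg, Q_ml_min = Q_ml_min,
                            feasible = FALSE, R_SL = NA_real_,
                            max_wss = NA_real_, t90_total = NA_real_,
                            t90_last_sl = NA_real_))
    }
    t90_total <- t90_last <- NA_real_
    if (perfuse) {
      dt_use <- if (is.null(dt)) min(0.9 * max_stable_dt(network, sol), 0.01) else dt
      lr <- simulate_loading(network, sol, dt = dt_use, thresholds = 0.9,
                             record_every = 100L)
      t90_total <- unname(lr$total_times["t90"])
      t90_last <- max(lr$sl_times$t90)
    }
    tibble::tibble(P_mmHg = P_mmHg, Q_ml_min = Q_ml_min, feasible = TRUE,
                   R_SL = sol$R_SL, max_wss = sol$max_wss,
                   t90_total = t90_total, t90_last_sl = t90_last)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bc_sweep", class(out))
  out
}
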