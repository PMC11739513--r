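#' Space colonization growth parameters
#'
#' Three lengths control topology: the step distance `D` (how far each new
#' node is placed from its parent), the kill radius `d_k` (non-target
#' attractors this close to any node are consumed) and the sphere of
#' influence `d_i` (attractors farther than this from every node exert no
#' pull). Well-behaved growth has `D < d_k < d_i`; smaller values give more
#' tortuous trees, larger values more direct ones. Defaults are the values
#' used for the reference liver models (mm).
#'
#' @param D step distance, mm.
#' @param d_k kill radius, mm.
#' @param d_i sphere-of-influence radius, mm (may be `Inf`).
#' @param max_iterations hard iteration cap.
#' @return a list of class `growth_params`.
#' @export
growth_params <- function(D = 5, d_k = 10, d_i = 15, max_iterations = 5000L) {
  stopifnot(D > 0, d_k > 0, d_i > 0, max_iterations >= 1)
  if (!(D < d_k && d_k < d_i)) {
    warning("growth parameters violate the recommended ordering D < d_k < d_i; ",
            "growth may behave poorly", call. = FALSE)
  }
  structure(list(D = D, d_k = d_k, d_i = d_i,
                 max_iterations = as.integer(max_iterations)),
            class = "growth_params")
}

#' Attractor set for space colonization
#'
#' Target attractors (the super-lobule centroids, or the primary-branch
#' landmarks) cannot be consumed until a node is placed exactly at them,
#' which guarantees the tree reaches every prescribed terminal. Ordinary
#' attractors only steer growth and are consumed within the kill radius.
#'
#' @param positions matrix or tibble of ordinary attractor positions
#'   (may have zero rows).
#' @param targets matrix or tibble of target positions.
#' @param target_ids integer ids for the targets (default `1:n_targets`);
#'   these become the super-lobule ids in the terminal map.
#' @return a tibble with columns `x`, `y`, `z`, `is_target`, `target_id`.
#' @export
attractor_set <- function(positions, targets,
                          target_ids = seq_len(nrow(as.matrix(targets)))) {
  pos <- to_xyz(positions)
  tgt <- to_xyz(targets)
  stopifnot(nrow(tgt) == length(target_ids))
  tibble::tibble(
    x = c(pos[, 1], tgt[, 1]),
    y = c(pos[, 2], tgt[, 2]),
    z = c(pos[, 3], tgt[, 3]),
    is_target = rep(c(FALSE, TRUE), c(nrow(pos), nrow(tgt))),
    target_id = c(rep(NA_integer_, nrow(pos)), as.integer(target_ids)))
}

to_xyz <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0)) return(matrix(numeric(0), 0, 3))
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  matrix(as.numeric(x), ncol = 3)
}

#' Grow a vascular tree by space colonization
#'
#' Iterates the modified space colonization algorithm: each active attractor
#' is associated with its single nearest node when within `d_i`; each node
#' with associations adds a child at distance `D` along the normalized mean
#' of the unit vectors toward its associated attractors; ordinary attractors
#' within `d_k` of any node are then consumed. When all of a node's
#' associated attractors are targets and the nearest lies within `D`, a
#' child is placed exactly at that target and the target is marked reached.
#' Growth terminates when every target has been reached (or, in a
#' target-free run, when no further growth occurs).
#'
#' @param init either a matrix/tibble of root positions (one row per root)
#'   or an existing `vascular_tree` to extend (two-stage growth).
#' @param attractors an [attractor_set()].
#' @param params a [growth_params()].
#' @param seed integer seed (controls the node processing order only).
#' @param label `"inlet"` or `"outlet"`; kept as metadata.
#' @return a `vascular_tree`: tibble `nodes` (`id`, `x`, `y`, `z`,
#'   `parent`), `roots` (ids), `terminal_map` (tibble `sl_id`, `node`),
#'   `label`, and the iteration count.
#' @export
grow_tree <- function(init, attractors, params = growth_params(),
                      seed = 1L, label = c("inlet", "outlet")) {
  label <- if (inherits(init, "vascular_tree")) init$label else match.arg(label)

  if (inherits(init, "vascular_tree")) {
    pos <- as.matrix(init$nodes[, c("x", "y", "z")])
    parent <- init$nodes$parent
    roots <- init$roots
  } else {
    pos <- to_xyz(init)
    if (nrow(pos) < 1) stop("at least one root position required", call. = FALSE)
    parent <- rep(NA_integer_, nrow(pos))
    roots <- seq_len(nrow(pos))
  }

  A <- as.matrix(attractors[, c("x", "y", "z")])
  is_target <- attractors$is_target
  target_id <- attractors$target_id
  n_attr <- nrow(A)
  active <- rep(TRUE, n_attr)
  reached <- rep(FALSE, n_attr)
  terminal_node <- rep(NA_integer_, n_attr)

  # incremental nearest-node bookkeeping: nodes are only ever added, so the
  # nearest distance per attractor is a running minimum over new nodes
  nearest_d <- rep(Inf, n_attr)
  nearest_i <- rep(NA_integer_, n_attr)
  last_improved <- rep(0L, n_attr)
  cur_iter <- 0L
  update_nearest <- function(node_idx) {
    act <- which(active)
    if (!length(act) || !length(node_idx)) return()
    for (ni in node_idx) {
      dx <- A[act, 1] - pos[ni, 1]
      dy <- A[act, 2] - pos[ni, 2]
      dz <- A[act, 3] - pos[ni, 3]
      d <- sqrt(dx * dx + dy * dy + dz * dz)
      closer <- d < nearest_d[act] - 1e-9
      nearest_d[act[closer]] <<- d[closer]
      nearest_i[act[closer]] <<- ni
      last_improved[act[closer]] <<- cur_iter
    }
  }
  update_nearest(seq_len(nrow(pos)))
  # duplicate suppression: opposed pulls can otherwise re-create the same
  # child forever without approaching any attractor
  node_keys <- new.env(hash = TRUE)
  pos_key <- function(p) sprintf("%.6f|%.6f|%.6f", p[1], p[2], p[3])
  for (i in seq_len(nrow(pos))) node_keys[[pos_key(pos[i, ])]] <- TRUE
  stall_patience <- getOption("superlobule.stall_patience", 30L)
  # initial kill sweep: ordinary attractors already inside d_k are consumed
  active[!is_target & nearest_d <= params$d_k] <- FALSE

  rng <- local_rng(seed)
  debug_every <- getOption("superlobule.growth_debug", 0L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (debug_every > 0 && iter %% debug_every == 0) {
      message(sprintf("iter %d: %d nodes, %d active attractors, %d unreached targets",
                      iter, nrow(pos), sum(active), sum(is_target & !reached)))
    }
    if (iter > params$max_iterations) {
      unreached <- target_id[is_target & !reached]
      stop("max_iterations (", params$max_iterations,
           ") exceeded with unreached target(s): ",
           paste(sort(unreached), collapse = ", "), call. = FALSE)
    }
    cur_iter <- iter
    assoc <- which(active & nearest_d <= params$d_i)
    grew <- FALSE
    if (length(assoc)) {
      by_node <- split(assoc, nearest_i[assoc])
      node_order <- rng$sample_int(length(by_node), length(by_node))
      new_pos <- vector("list", length(by_node))
      new_parent <- integer(length(by_node))
      n_new <- 0L
      for (bi in node_order) {
        aset <- by_node[[bi]]
        ni <- nearest_i[aset[1]]
        p <- pos[ni, ]
        if (all(is_target[aset])) {
          # only targets pull this node: advance on (or snap to) the nearest
          # one; averaging opposed target directions would cancel and stall
          jt <- aset[which.min(nearest_d[aset])]
          if (nearest_d[jt] <= params$D) {
            reached[jt] <- TRUE
            active[jt] <- FALSE
            if (nearest_d[jt] < 1e-9) {
              # target coincides with an existing node: reuse it as terminal
              terminal_node[jt] <- ni
            } else {
              n_new <- n_new + 1L
              new_pos[[n_new]] <- A[jt, ]
              new_parent[n_new] <- ni
              terminal_node[jt] <- -n_new  # fixed up after ids are assigned
            }
            grew <- TRUE
            next
          }
          dir <- A[jt, ] - p
          dl <- sqrt(sum(dir^2))
          child <- p + params$D * dir / dl
          key <- pos_key(child)
          if (is.null(node_keys[[key]])) {
            node_keys[[key]] <- TRUE
            n_new <- n_new + 1L
            new_pos[[n_new]] <- child
            new_parent[n_new] <- ni
            grew <- TRUE
          }
          next
        }
        dirs <- cbind(A[aset, 1] - p[1], A[aset, 2] - p[2], A[aset, 3] - p[3])
        len <- sqrt(rowSums(dirs^2))
        ok <- len > 1e-12
        if (!any(ok)) next
        dirs <- dirs[ok, , drop = FALSE] / len[ok]
        mdir <- colMeans(dirs)
        mlen <- sqrt(sum(mdir^2))
        if (mlen < 1e-8) {
          # degenerate opposed pulls: deterministic tie-break toward the
          # lowest-index associated attractor
          j0 <- min(aset[ok])
          mdir <- c(A[j0, 1] - p[1], A[j0, 2] - p[2], A[j0, 3] - p[3])
          mlen <- sqrt(sum(mdir^2))
          if (mlen < 1e-12) next
        }
        child <- p + params$D * mdir / mlen
        key <- pos_key(child)
        if (!is.null(node_keys[[key]])) {
          # the averaged direction reproduces an existing node (opposed
          # pulls): fall back to stepping toward the nearest associated
          # attractor, which guarantees progress toward the kill radius
          jn <- aset[which.min(nearest_d[aset])]
          dirn <- c(A[jn, 1] - p[1], A[jn, 2] - p[2], A[jn, 3] - p[3])
          dln <- sqrt(sum(dirn^2))
          if (dln < 1e-12) next
          child <- p + params$D * dirn / dln
          key <- pos_key(child)
          if (!is.null(node_keys[[key]])) next
        }
        node_keys[[key]] <- TRUE
        n_new <- n_new + 1L
        new_pos[[n_new]] <- child
        new_parent[n_new] <- ni
        grew <- TRUE
      }
      if (n_new > 0L) {
        base <- nrow(pos)
        pos <- rbind(pos, do.call(rbind, new_pos[seq_len(n_new)]))
        parent <- c(parent, new_parent[seq_len(n_new)])
        terminal_node[which(terminal_node %in% -(seq_len(n_new)))] <-
          base - terminal_node[which(terminal_node %in% -(seq_len(n_new)))]
        update_nearest(base + seq_len(n_new))
        # consume ordinary attractors inside the kill radius
        active[!is_target & active & nearest_d <= params$d_k] <- FALSE
      }
    }
    # cull ordinary attractors that are engaged (inside d_i) but have made
    # no progress for many iterations: they sit in pockets the mean-direction
    # rule cannot colonize, and would otherwise stall growth indefinitely
    stalled <- active & !is_target & nearest_d <= params$d_i &
      (iter - last_improved) > stall_patience
    active[stalled] <- FALSE
    targets_pending <- any(is_target & !reached)
    if (!targets_pending && any(is_target)) break
    if (!grew) {
      if (targets_pending) {
        unreached <- target_id[is_target & !reached]
        stop("growth stagnated with unreached target(s): ",
             paste(sort(unreached), collapse = ", "), call. = FALSE)
      }
      break
    }
  }

  nodes <- tibble::tibble(id = seq_len(nrow(pos)),
                          x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          parent = as.integer(parent))
  tm_idx <- which(is_target & reached)
  terminal_map <- tibble::tibble(sl_id = as.integer(target_id[tm_idx]),
                                 node = as.integer(terminal_node[tm_idx]))
  terminal_map <- dplyr::arrange(terminal_map, .data$sl_id)
  structure(list(nodes = nodes, roots = as.integer(roots),
                 terminal_map = terminal_map, label = label,
                 iterations = iter),
            class = "vascular_tree")
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf("<vascular_tree:%s> %d nodes, %d root(s), %d terminal(s), %d iteration(s)\n",
              x$label, nrow(x$nodes), length(x$roots), nrow(x$terminal_map),
              x$iterations))
  invisible(x)
}

#' Prune non-critical branches
#'
#' Traverses the tree in reverse from every target terminal to the root and
#' retains exactly the visited nodes; dead-end branches that never reach a
#' super lobule are removed. Node ids are compacted; the terminal map is
#' re-indexed accordingly.
#'
#' @param tree a `vascular_tree` whose targets have all been reached.
#' @return the pruned `vascular_tree`.
#' @export
prune_tree <- function(tree) {
  if (nrow(tree$terminal_map) == 0) {
    stop("cannot prune: tree has no reached targets", call. = FALSE)
  }
  keep <- rep(FALSE, nrow(tree$nodes))
  parent <- tree$nodes$parent
  for (t in tree$terminal_map$node) {
    i <- t
    while (!is.na(i) && !keep[i]) {
      keep[i] <- TRUE
      i <- parent[i]
    }
  }
  keep[tree$roots] <- TRUE
  new_id <- cumsum(keep)
  nodes <- tree$nodes[keep, , drop = FALSE]
  nodes$id <- new_id[nodes$id]
  nodes$parent <- ifelse(is.na(nodes$parent), NA_integer_,
                         as.integer(new_id[nodes$parent]))
  tm <- tree$terminal_map
  tm$node <- as.integer(new_id[tm$node])
  structure(list(nodes = nodes, roots = as.integer(new_id[tree$roots]),
                 terminal_map = tm, label = tree$label,
                 iterations = tree$iterations),
            class = "vascular_tree")
}

#' Initialize the primary branches of a tree
#'
#' First-stage colonization from the root toward a small set of anatomical
#' landmarks: the left/right portal veins for the inlet tree, the left,
#' middle and right hepatic veins for the outlet tree. The resulting nodes
#' persist unchanged through the main growth stage (growth only ever adds
#' children). The primary stage uses an unbounded sphere of influence so the
#' landmarks steer growth from the first iteration.
#'
#' @param mesh a [volume_mesh()] bounding the domain.
#' @param label `"inlet"` or `"outlet"`.
#' @param root root position (length-3, mm); default chosen on the synthetic
#'   ellipsoid.
#' @param targets matrix of primary target positions; defaults for the
#'   synthetic ellipsoid (2 portal branches in, 3 hepatic branches out).
#' @param params main-stage [growth_params()]; the primary stage reuses its
#'   `D` and `d_k` with `d_i = Inf`.
#' @param seed integer seed.
#' @return a `vascular_tree` whose terminal map covers the primary targets.
#' @export
initialize_major_branches <- function(mesh, label = c("inlet", "outlet"),
                                      root = NULL, targets = NULL,
                                      params = growth_params(), seed = 1L) {
  label <- match.arg(label)
  defaults <- default_primary_layout(mesh)
  if (is.null(root)) root <- defaults[[label]]$root
  if (is.null(targets)) targets <- defaults[[label]]$targets
  targets <- to_xyz(targets)
  inside <- points_inside(mesh, targets)
  if (!all(inside)) {
    stop("primary target(s) ", paste(which(!inside), collapse = ", "),
         " lie outside the volume", call. = FALSE)
  }
  primary_params <- growth_params(D = params$D, d_k = params$d_k,
                                  d_i = Inf,
                                  max_iterations = params$max_iterations)
  att <- attractor_set(NULL, targets)
  tree <- suppressWarnings(
    grow_tree(matrix(root, 1, 3), att, primary_params, seed = seed,
              label = label))
  tree$primary_terminals <- tree$terminal_map$node
  tree$terminal_map <- tree$terminal_map[0, ]
  tree
}

# anatomy-inspired primary landmarks in fractional ellipsoid coordinates:
# inlet (portal) enters low, splitting left/right; outlet (hepatic) exits
# high toward the vena cava with left/middle/right branches
default_primary_layout <- function(mesh) {
  bb <- mesh_bbox(mesh)
  ctr <- colMeans(bb)
  half <- (bb[2, ] - bb[1, ]) / 2
  at <- function(fx, fy, fz) ctr + half * c(fx, fy, fz)
  list(
    inlet = list(root = at(0, 0, -0.85),
                 targets = rbind(at(-0.5, 0, -0.3), at(0.5, 0, -0.3))),
    outlet = list(root = at(0, 0, 0.85),
                  targets = rbind(at(-0.5, 0, 0.3), at(0, 0.15, 0.25),
                                  at(0.5, 0, 0.3))))
}

#' Connect inlet and outlet trees at the super lobules
#'
#' Each super lobule becomes a lumped element in series between the inlet
#' tree terminal and the outlet tree terminal that reached its centroid,
#' producing one fully connected network from inlet root to outlet root.
#'
#' @param inlet,outlet pruned `vascular_tree`s covering the same super-lobule
#'   ids.
#' @param partition the [partition_super_lobules()] result (for centroid
#'   metadata).
#' @return a list of class `network_topology`: `inlet`, `outlet`, `links`
#'   (tibble `sl_id`, `inlet_node`, `outlet_node`).
#' @export
connect_trees <- function(inlet, outlet, partition = NULL) {
  in_ids <- sort(inlet$terminal_map$sl_id)
  out_ids <- sort(outlet$terminal_map$sl_id)
  if (!identical(in_ids, out_ids)) {
    missing_in <- setdiff(out_ids, in_ids)
    missing_out <- setdiff(in_ids, out_ids)
    stop("terminal sets differ between trees; missing from inlet: {",
         paste(missing_in, collapse = ", "), "}, missing from outlet: {",
         paste(missing_out, collapse = ", "), "}", call. = FALSE)
  }
  links <- dplyr::inner_join(
    dplyr::rename(inlet$terminal_map, inlet_node = "node"),
    dplyr::rename(outlet$terminal_map, outlet_node = "node"),
    by = "sl_id")
  structure(list(inlet = inlet, outlet = outlet, links = links,
                 partition = partition),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d super lobules; inlet %d nodes, outlet %d nodes\n",
              nrow(x$links), nrow(x$inlet$nodes), nrow(x$outlet$nodes)))
  invisible(x)
}

#' Total centerline path length of a tree
#'
#' Sum of parent-child edge lengths; a simple tortuosity summary.
#'
#' @param tree a `vascular_tree`.
#' @return total length in mm.
#' @export
tree_path_length <- function(tree) {
  n <- tree$nodes
  has_parent <- !is.na(n$parent)
  p <- n[n$parent[has_parent], c("x", "y", "z")]
  c_ <- n[has_parent, c("x", "y", "z")]
  sum(sqrt(rowSums((as.matrix(c_) - as.matrix(p))^2)))
}

#' Mean terminal tortuosity of a tree
#'
#' For every terminal, the along-tree path length from the root divided by
#' the straight-line distance; averaged over terminals. 1 means perfectly
#' straight supply paths; smaller colonization parameters raise it.
#'
#' @param tree a `vascular_tree` with reached terminals.
#' @return mean tortuosity ratio (>= 1).
#' @export
tree_tortuosity <- function(tree) {
  n <- tree$nodes
  pos <- as.matrix(n[, c("x", "y", "z")])
  ratios <- vapply(tree$terminal_map$node, function(t) {
    i <- t
    plen <- 0
    while (!is.na(n$parent[i])) {
      p <- n$parent[i]
      plen <- plen + sqrt(sum((pos[i, ] - pos[p, ])^2))
      i <- p
    }
    plen / sqrt(sum((pos[t, ] - pos[i, ])^2))
  }, numeric(1))
  mean(ratios)
}
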