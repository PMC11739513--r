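#' Hagen-Poiseuille resistance of a cylindrical vessel
#'
#' `R = 8 mu L / (pi r^4)` for incompressible, Newtonian, laminar flow in a
#' long cylinder of constant cross section.
#'
#' @param L length, mm (>= 0).
#' @param r radius, mm (> 0).
#' @param mu dynamic viscosity in dyn.s/mm^2 (use [cP_to_dyn_s_mm2()]).
#' @return resistance in dyn.s/mm^5 (vectorized).
#' @export
hp_resistance <- function(L, r, mu) {
  if (any(r <= 0)) stop("vessel radius must be positive", call. = FALSE)
  if (any(L < 0)) stop("vessel length must be non-negative", call. = FALSE)
  8 * mu * L / (pi * r^4)
}

#' Wall shear stress in a cylindrical vessel
#'
#' `tau = 4 mu Q / (pi r^3)`; a vessel-damage proxy evaluated for vessel
#' segments only (super lobules are lumped elements without a wall).
#'
#' @param Q flow rate, mm^3/s.
#' @param r radius, mm (> 0).
#' @param mu dynamic viscosity, dyn.s/mm^2.
#' @return shear stress in dyn/mm^2 (vectorized).
#' @export
wall_shear_stress <- function(Q, r, mu) {
  if (any(r <= 0)) stop("vessel radius must be positive", call. = FALSE)
  4 * mu * Q / (pi * r^3)
}

#' Downstream-weighted Murray radius assignment
#'
#' Walks each tree from its root, assigning every child segment
#' `r_child = (omega)^(1/gamma) * r_parent`, where `omega` is the fraction
#' of the parent's super lobules served (inlet tree) or drained (outlet
#' tree) by that child. The omegas at any branch sum to 1, so
#' `sum(r_child^gamma) = r_parent^gamma` (Murray's law) holds exactly at
#' every branch; along unbranched chains the radius is constant.
#'
#' @param tree a pruned `vascular_tree`.
#' @param r_root root segment radius, mm (default 7.5, i.e. a 15 mm initial
#'   diameter for both portal and hepatic trunks).
#' @param gamma Murray exponent (default 3, the laminar-flow value).
#' @return tibble of segments: `node` (child/distal node id), `parent`
#'   (proximal node id), `L`, `r`, `n_down` (super lobules served), `omega`.
#' @export
tree_segments <- function(tree, r_root = 7.5, gamma = 3) {
  n <- nrow(tree$nodes)
  parent <- tree$nodes$parent
  pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  cnt <- numeric(n)
  for (t in tree$terminal_map$node) cnt[t] <- cnt[t] + 1
  for (i in n:1) if (!is.na(parent[i])) cnt[parent[i]] <- cnt[parent[i]] + cnt[i]
  if (any(cnt == 0 & seq_len(n) %in% setdiff(seq_len(n), tree$roots))) {
    bad <- which(cnt == 0)
    bad <- setdiff(bad, tree$roots)
    if (length(bad)) stop("segment(s) serving 0 super lobules after pruning: node ",
                          paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  children <- split(which(!is.na(parent)), parent[!is.na(parent)])
  r_edge <- rep(NA_real_, n)        # radius of the edge ending at node i
  omega <- rep(NA_real_, n)
  # parents always precede children in id order
  for (i in seq_len(n)) {
    kids <- children[[as.character(i)]]
    if (is.null(kids)) next
    if (i %in% tree$roots) {
      r_par <- r_root
      denom <- cnt[i]
    } else {
      r_par <- r_edge[i]
      denom <- cnt[i]
    }
    w <- cnt[kids] / denom
    if (length(kids) == 1L) w <- 1     # unbranched chain keeps the radius
    omega[kids] <- w
    r_edge[kids] <- (w)^(1 / gamma) * r_par
  }
  seg_nodes <- which(!is.na(parent))
  L <- sqrt(rowSums((pos[seg_nodes, , drop = FALSE] -
                     pos[parent[seg_nodes], , drop = FALSE])^2))
  tibble::tibble(node = as.integer(seg_nodes),
                 parent = as.integer(parent[seg_nodes]),
                 L = L, r = r_edge[seg_nodes],
                 n_down = as.integer(cnt[seg_nodes]),
                 omega = omega[seg_nodes])
}

#' Assemble a flow network from a connected topology
#'
#' Converts the connected inlet/outlet trees into a 0D resistance network:
#' one Hagen-Poiseuille element per space-colonization edge, plus one lumped
#' super-lobule element per super lobule bridging the matched inlet and
#' outlet terminals. Vessel volumes (`pi r^2 L`) feed the super-lobule
#' volume budget: the super lobules share equally whatever fraction of the
#' organ's blood volume the explicit vessels do not occupy.
#'
#' @param topology a [connect_trees()] result.
#' @param mu_cP fluid dynamic viscosity, cP (default 3.5, whole blood; the
#'   loaded CPA is modeled at the same viscosity).
#' @param gamma Murray exponent.
#' @param r_root root radius, mm, applied to both trees.
#' @param organ_volume organ volume, mm^3 (for the blood-volume budget).
#' @param blood_volume_fraction fraction of the organ volume occupied by
#'   blood (default 0.25); the budget input `V_blood` is
#'   `blood_volume_fraction * organ_volume`.
#' @return a `flow_network`: tibbles `elements` (`element`, `type`, `tree`,
#'   `from`, `to`, `L`, `r`, `R`, `V`, `n_down`, `sl_id`) and `nodes`
#'   (`node`, `x`, `y`, `z`); scalars `inlet_node`, `outlet_node`, `n_SL`,
#'   `mu`, and the volume `budget` row.
#' @export
build_flow_network <- function(topology, mu_cP = 3.5, gamma = 3,
                               r_root = 7.5, organ_volume = 1.6e6,
                               blood_volume_fraction = 0.25) {
  mu <- cP_to_dyn_s_mm2(mu_cP)
  seg_in <- tree_segments(topology$inlet, r_root = r_root, gamma = gamma)
  seg_out <- tree_segments(topology$outlet, r_root = r_root, gamma = gamma)
  n_in <- nrow(topology$inlet$nodes)
  offset <- n_in

  nodes <- tibble::tibble(
    node = seq_len(n_in + nrow(topology$outlet$nodes)),
    x = c(topology$inlet$nodes$x, topology$outlet$nodes$x),
    y = c(topology$inlet$nodes$y, topology$outlet$nodes$y),
    z = c(topology$inlet$nodes$z, topology$outlet$nodes$z))

  # inlet: flow runs proximal (parent) -> distal (child)
  el_in <- tibble::tibble(
    type = "vessel", tree = "inlet",
    from = seg_in$parent, to = seg_in$node,
    L = seg_in$L, r = seg_in$r,
    R = hp_resistance(seg_in$L, seg_in$r, mu),
    V = pi * seg_in$r^2 * seg_in$L,
    n_down = seg_in$n_down, sl_id = NA_integer_)
  # outlet: flow runs distal (child) -> proximal (parent), toward the root
  el_out <- tibble::tibble(
    type = "vessel", tree = "outlet",
    from = seg_out$node + offset, to = seg_out$parent + offset,
    L = seg_out$L, r = seg_out$r,
    R = hp_resistance(seg_out$L, seg_out$r, mu),
    V = pi * seg_out$r^2 * seg_out$L,
    n_down = seg_out$n_down, sl_id = NA_integer_)

  V_vessels <- sum(el_in$V) + sum(el_out$V)
  budget <- compute_volume_budget(blood_volume_fraction * organ_volume,
                                  V_vessels, nrow(topology$links))

  el_sl <- tibble::tibble(
    type = "sl", tree = NA_character_,
    from = topology$links$inlet_node,
    to = topology$links$outlet_node + offset,
    L = NA_real_, r = NA_real_, R = NA_real_,
    V = budget$V_SL_individual,
    n_down = 1L, sl_id = topology$links$sl_id)

  elements <- dplyr::bind_rows(el_in, el_out, el_sl)
  elements$element <- seq_len(nrow(elements))
  elements <- dplyr::relocate(elements, "element")
  flow_network(elements, nodes,
               inlet_node = topology$inlet$roots[1],
               outlet_node = topology$outlet$roots[1] + offset,
               mu = mu, budget = budget)
}

#' Low-level flow-network constructor
#'
#' Builds a `flow_network` from explicit element and node tables. Used by
#' [build_flow_network()] and directly for analytic fixtures (for example
#' the two-branch didactic circuit) where element resistances are prescribed
#' rather than derived from geometry.
#'
#' @param elements tibble with columns `element`, `type` ("vessel" or
#'   "sl"), `from`, `to`, `R` (NA for super lobules; filled at solve time),
#'   optionally `L`, `r`, `V`.
#' @param nodes tibble with column `node` (and optionally coordinates).
#' @param inlet_node,outlet_node boundary node ids.
#' @param mu dynamic viscosity, dyn.s/mm^2 (metadata for shear reporting).
#' @param budget optional volume-budget row.
#' @return a `flow_network`.
#' @export
flow_network <- function(elements, nodes, inlet_node, outlet_node,
                         mu = cP_to_dyn_s_mm2(3.5), budget = NULL) {
  stopifnot(all(c("element", "type", "from", "to", "R") %in% names(elements)))
  deg <- table(c(elements$from, elements$to))
  sl_el <- elements[elements$type == "sl", ]
  net <- structure(list(elements = elements, nodes = nodes,
                        inlet_node = as.integer(inlet_node),
                        outlet_node = as.integer(outlet_node),
                        n_SL = nrow(sl_el), mu = mu, budget = budget),
                   class = "flow_network")
  if (!network_connected(net)) {
    stop("flow network is not connected from inlet to outlet", call. = FALSE)
  }
  net
}

#' @export
print.flow_network <- function(x, ...) {
  j <- sum(x$elements$type == "vessel")
  k <- sum(x$elements$type == "sl")
  cat(sprintf("<flow_network> %d vessels, %d super lobules, %d nodes (n = %d)\n",
              j, k, nrow(x$nodes), j + k + nrow(x$nodes)))
  invisible(x)
}

network_connected <- function(network) {
  n <- nrow(network$nodes)
  adj <- split(c(network$elements$to, network$elements$from),
               c(network$elements$from, network$elements$to))
  seen <- rep(FALSE, n)
  stack <- network$inlet_node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    nb <- adj[[as.character(v)]]
    if (!is.null(nb)) stack <- c(stack, nb[!seen[nb]])
  }
  all(seen)
}

#' Assemble the linear pressure/flow system
#'
#' Unknowns are ordered as the `j + k` element flows (element table order)
#' followed by the `l` node pressures (node table order), giving a square
#' system of size `n = j + k + l`. Rows are: one Ohm row per element
#' (`P_from - P_to - R Q = 0`), one Kirchhoff current row per interior node,
#' and two boundary rows. Boundary rows are either two prescribed pressures
#' (`p_in`, `p_out`) or a prescribed total inlet flow plus the outlet
#' pressure (`q_in`, `p_out`).
#'
#' @param network a `flow_network`.
#' @param R_SL shared super-lobule resistance (same units as vessel `R`).
#' @param p_in,p_out,q_in boundary values in internal units (dyn/mm^2,
#'   mm^3/s); give either `p_in` and `p_out`, or `q_in` and `p_out`.
#' @return list with sparse matrix `A`, right-hand side `b`, and the
#'   unknown `layout`.
#' @export
assemble_system <- function(network, R_SL, p_in = NULL, p_out = NULL,
                            q_in = NULL) {
  el <- network$elements
  j_k <- nrow(el)
  l <- nrow(network$nodes)
  n <- j_k + l
  col_of_node <- function(v) j_k + match(v, network$nodes$node)

  R_vec <- ifelse(el$type == "sl", R_SL, el$R)
  if (any(is.na(R_vec))) stop("element resistance missing", call. = FALSE)

  # Ohm rows: P_from - P_to - R Q = 0
  i1 <- rep(seq_len(j_k), 3)
  j1 <- c(seq_len(j_k), col_of_node(el$from), col_of_node(el$to))
  x1 <- c(-R_vec, rep(1, j_k), rep(-1, j_k))

  interior <- setdiff(network$nodes$node,
                      c(network$inlet_node, network$outlet_node))
  # KCL rows: sum(Q in) - sum(Q out) = 0
  kcl_row <- match(c(el$to, el$from), interior)
  kcl_el <- rep(seq_len(j_k), 2)
  kcl_sign <- rep(c(1, -1), each = j_k)
  keep <- !is.na(kcl_row)
  i2 <- j_k + kcl_row[keep]
  j2 <- kcl_el[keep]
  x2 <- kcl_sign[keep]

  bc_base <- j_k + length(interior)
  b <- numeric(n)
  if (!is.null(p_in) && !is.null(q_in)) {
    stop("give either p_in or q_in, not both", call. = FALSE)
  }
  if (is.null(p_out)) stop("p_out is required", call. = FALSE)
  if (!is.null(p_in)) {
    i3 <- c(bc_base + 1L, bc_base + 2L)
    j3 <- c(col_of_node(network$inlet_node), col_of_node(network$outlet_node))
    x3 <- c(1, 1)
    b[bc_base + 1L] <- p_in
    b[bc_base + 2L] <- p_out
  } else if (!is.null(q_in)) {
    out_of_inlet <- which(el$from == network$inlet_node)
    into_inlet <- which(el$to == network$inlet_node)
    i3 <- c(rep(bc_base + 1L, length(out_of_inlet) + length(into_inlet)),
            bc_base + 2L)
    j3 <- c(out_of_inlet, into_inlet, col_of_node(network$outlet_node))
    x3 <- c(rep(1, length(out_of_inlet)), rep(-1, length(into_inlet)), 1)
    b[bc_base + 1L] <- q_in
    b[bc_base + 2L] <- p_out
  } else {
    stop("boundary conditions missing: give p_in or q_in", call. = FALSE)
  }

  A <- Matrix::sparseMatrix(i = c(i1, i2, i3), j = c(j1, j2, j3),
                            x = c(x1, x2, x3), dims = c(n, n))
  list(A = A, b = b,
       layout = list(n = n, j_k = j_k, l = l, interior = interior))
}

#' Solve the steady pressure/flow state of a network
#'
#' Sparse LU factorization of the assembled system; returns per-element
#' flows and per-node pressures together with Ohm/Kirchhoff residuals and
#' network summaries.
#'
#' @inheritParams assemble_system
#' @return a `flow_solution`: tibble `flows` (element table plus `Q` in
#'   mm^3/s, `tau` wall shear stress for vessels), tibble `pressures`
#'   (`node`, `P` in dyn/mm^2), scalars `Q_in`, `dP`, `R_eq`, `R_SL`,
#'   residual summaries, and per-super-lobule means.
#' @export
solve_flow <- function(network, R_SL, p_in = NULL, p_out = NULL,
                       q_in = NULL) {
  sys <- assemble_system(network, R_SL, p_in = p_in, p_out = p_out,
                         q_in = q_in)
  x <- tryCatch(
    as.numeric(Matrix::solve(sys$A, sys$b)),
    error = function(e) {
      stop("linear system is singular (disconnected components or ",
           "degenerate resistances): ", conditionMessage(e), call. = FALSE)
    })
  el <- network$elements
  j_k <- sys$layout$j_k
  Q <- x[seq_len(j_k)]
  P <- x[j_k + seq_len(sys$layout$l)]
  names(P) <- NULL

  node_P <- function(v) P[match(v, network$nodes$node)]
  R_vec <- ifelse(el$type == "sl", R_SL, el$R)
  ohm_res <- node_P(el$from) - node_P(el$to) - R_vec * Q
  net_flow <- vapply(sys$layout$interior, function(v) {
    sum(Q[el$to == v]) - sum(Q[el$from == v])
  }, numeric(1))
  Q_in <- sum(Q[el$from == network$inlet_node]) -
    sum(Q[el$to == network$inlet_node])
  dP <- node_P(network$inlet_node) - node_P(network$outlet_node)

  flows <- el
  flows$Q <- Q
  flows$tau <- NA_real_
  has_wall <- flows$type == "vessel" & !is.na(flows$r)
  flows$tau[has_wall] <- wall_shear_stress(abs(Q[has_wall]),
                                           flows$r[has_wall], network$mu)
  sl <- flows[flows$type == "sl", ]
  structure(list(
    flows = flows,
    pressures = tibble::tibble(node = network$nodes$node, P = P),
    Q_in = Q_in, dP = dP, R_eq = dP / Q_in, R_SL = R_SL,
    n_SL = network$n_SL,
    R_SL_eq = if (network$n_SL > 0) R_SL / network$n_SL else NA_real_,
    Q_SL_mean = if (nrow(sl)) mean(sl$Q) else NA_real_,
    dP_SL_mean = if (nrow(sl)) mean(node_P(sl$from) - node_P(sl$to)) else NA_real_,
    max_wss = if (any(!is.na(flows$tau))) max(flows$tau, na.rm = TRUE) else NA_real_,
    residual_ohm = max(abs(ohm_res)) / max(abs(Q_in), .Machine$double.eps),
    residual_kcl = if (length(net_flow)) max(abs(net_flow)) / max(abs(Q_in), .Machine$double.eps) else 0,
    mu = network$mu),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(paste0(
    "<flow_solution> Q_in = %.6g mm^3/s (%.4g mL/min), dP = %.6g dyn/mm^2 ",
    "(%.4g mmHg)\n  R_eq = %.6g, R_SL = %.6g dyn.s/mm^5; KCL residual %.2e\n"),
    x$Q_in, mm3_s_to_ml_min(x$Q_in), x$dP, dyn_mm2_to_mmHg(x$dP),
    x$R_eq, x$R_SL, x$residual_kcl))
  invisible(x)
}

#' Calibrate the super-lobule resistance by bisection
#'
#' With the inlet/outlet pressures fixed, the solved inlet flow is a
#' strictly decreasing function of the shared super-lobule resistance
#' `R_SL`. Bisection (with automatic doubling of the upper bound until the
#' target flow is bracketed) finds the `R_SL` at which the solved flow
#' matches the target within `tol`. Infeasible conditions -- where even
#' `R_SL = 0` cannot pass the requested flow at the requested pressure
#' drop -- raise an error reporting the maximum achievable flow.
#'
#' @param network a `flow_network`.
#' @param p_in,p_out boundary pressures (internal units, dyn/mm^2).
#' @param q_target target inlet flow (mm^3/s).
#' @param tol absolute flow tolerance, same units as `q_target`.
#' @param upper initial upper bound for `R_SL` (doubled as needed).
#' @param max_upper bound beyond which bracketing is abandoned.
#' @return list with `R_SL`, the final `solution` (a `flow_solution`), and
#'   the number of solver calls `n_eval`.
#' @export
find_sl_resistance <- function(network, p_in, p_out, q_target,
                               tol = ml_min_to_mm3_s(1e-8), upper = 1,
                               max_upper = 1e20) {
  stopifnot(p_in > p_out, q_target > 0, tol > 0)
  n_eval <- 0L
  qf <- function(R) {
    n_eval <<- n_eval + 1L
    solve_flow(network, R_SL = R, p_in = p_in, p_out = p_out)
  }
  # R_SL = 0 can make a vessel-free path between the boundary nodes exactly
  # singular; that means unbounded capacity, so the target is feasible
  s0 <- tryCatch(qf(0), error = function(e) NULL)
  if (!is.null(s0) && s0$Q_in < q_target - tol) {
    stop(sprintf(paste0(
      "infeasible boundary conditions: no non-negative R_SL admits the ",
      "target flow; at R_SL = 0 the maximum achievable flow is %.6g ",
      "(target %.6g) at dP = %.6g"), s0$Q_in, q_target, p_in - p_out),
      call. = FALSE)
  }
  if (!is.null(s0) && abs(s0$Q_in - q_target) <= tol) {
    return(list(R_SL = 0, solution = s0, n_eval = n_eval))
  }
  lo <- 0; hi <- upper
  s_hi <- qf(hi)
  while (s_hi$Q_in > q_target && hi < max_upper) {
    lo <- hi
    hi <- hi * 2
    s_hi <- qf(hi)
  }
  if (s_hi$Q_in > q_target) {
    stop("failed to bracket the target flow below R_SL = ", max_upper,
         call. = FALSE)
  }
  for (it in seq_len(400L)) {
    mid <- (lo + hi) / 2
    s_mid <- qf(mid)
    if (abs(s_mid$Q_in - q_target) <= tol) {
      return(list(R_SL = mid, solution = s_mid, n_eval = n_eval))
    }
    if (s_mid$Q_in > q_target) lo <- mid else hi <- mid
  }
  stop("bisection failed to converge to the flow tolerance", call. = FALSE)
}

#' Clinical boundary conditions
#'
#' @param P_in_mmHg inlet (portal vein) pressure, mmHg.
#' @param P_out_mmHg outlet (hepatic vein) pressure, mmHg.
#' @param Q_target_ml_min target steady inlet flow, mL/min.
#' @return a list of class `boundary_conditions` with clinical and internal
#'   unit fields.
#' @export
boundary_conditions <- function(P_in_mmHg = 5.8, P_out_mmHg = 0,
                                Q_target_ml_min = 767) {
  stopifnot(P_in_mmHg > P_out_mmHg, Q_target_ml_min > 0)
  structure(list(P_in_mmHg = P_in_mmHg, P_out_mmHg = P_out_mmHg,
                 Q_target_ml_min = Q_target_ml_min,
                 p_in = mmHg_to_dyn_mm2(P_in_mmHg),
                 p_out = mmHg_to_dyn_mm2(P_out_mmHg),
                 q_target = ml_min_to_mm3_s(Q_target_ml_min)),
            class = "boundary_conditions")
}

#' Calibrate and solve a network against clinical boundary conditions
#'
#' Convenience wrapper: converts the clinical boundary conditions to
#' internal units, calibrates `R_SL` by [find_sl_resistance()] with the
#' flow tolerance expressed in mL/min, and returns the calibrated solution.
#'
#' @param network a `flow_network`.
#' @param bc a [boundary_conditions()].
#' @param tol_ml_min absolute flow tolerance in mL/min (default 1e-8).
#' @return a `flow_solution` with the calibrated `R_SL`.
#' @export
calibrate_flow <- function(network, bc = boundary_conditions(),
                           tol_ml_min = 1e-8) {
  fit <- find_sl_resistance(network, p_in = bc$p_in, p_out = bc$p_out,
                            q_target = bc$q_target,
                            tol = ml_min_to_mm3_s(tol_ml_min))
  sol <- fit$solution
  sol$bc <- bc
  sol$n_eval <- fit$n_eval
  sol
}

#' Didactic two-branch super-lobule circuit
#'
#' Two parallel branches between the inlet and outlet node; each branch is a
#' vessel of resistance `R_i`, a super lobule, and a second vessel of
#' resistance `R_i`, so the branch resistance is `2 R_i + R_SL`. With
#' `R1 != R2` the circuit shows how a large shared super-lobule resistance
#' evens out the flow split.
#'
#' @param R1,R2 vessel resistance in branch 1 and 2 (consistent units).
#' @param L,r nominal vessel length and radius used only for element
#'   volumes in loading demos.
#' @param V_SL nominal super-lobule volume.
#' @return a `flow_network` with 4 vessels, 2 super lobules and 6 nodes.
#' @export
two_branch_network <- function(R1 = 1, R2 = 10, L = 10, r = 1, V_SL = 100) {
  v_vessel <- pi * r^2 * L
  elements <- tibble::tibble(
    element = 1:6,
    type = c("vessel", "sl", "vessel", "vessel", "sl", "vessel"),
    tree = c("inlet", NA, "outlet", "inlet", NA, "outlet"),
    from = c(1L, 2L, 3L, 1L, 5L, 6L),
    to = c(2L, 3L, 4L, 5L, 6L, 4L),
    L = c(L, NA, L, L, NA, L),
    r = c(r, NA, r, r, NA, r),
    R = c(R1, NA, R1, R2, NA, R2),
    V = c(v_vessel, V_SL, v_vessel, v_vessel, V_SL, v_vessel),
    n_down = 1L,
    sl_id = c(NA, 1L, NA, NA, 2L, NA))
  nodes <- tibble::tibble(node = 1:6, x = 0, y = 0, z = 0)
  flow_network(elements, nodes, inlet_node = 1L, outlet_node = 4L)
}
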