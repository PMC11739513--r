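mu35 <- cP_to_dyn_s_mm2(3.5)

test_that("Hagen-Poiseuille resistance scales as L / r^4", {
  expect_equal(hp_resistance(0, 1, mu35), 0)
  expect_equal(hp_resistance(10, 2, mu35), hp_resistance(10, 1, mu35) / 16)
  expect_equal(hp_resistance(10, 1, mu35), 8 * 3.5e-4 * 10 / pi)
  expect_equal(hp_resistance(10, 1, mu35), 8.913e-3, tolerance = 1e-4)
  expect_error(hp_resistance(10, 0, mu35), "radius")
})

test_that("wall shear stress scales as Q / r^3", {
  expect_equal(wall_shear_stress(0, 1, mu35), 0)
  expect_equal(wall_shear_stress(50, 0.5, mu35),
               8 * wall_shear_stress(50, 1, mu35))
  expect_equal(wall_shear_stress(100, 1, mu35), 4.456e-2, tolerance = 1e-4)
  expect_error(wall_shear_stress(1, -1, mu35), "radius")
})

test_that("Murray radii: chains keep the radius, branches partition r^gamma", {
  # hand-built tree: root 1 -> 2 (trunk), then 2 -> {3,4,5} serving 1,2,3
  # of 6 super lobules (extra targets hang off 4 and 5)
  nodes <- tibble::tibble(
    id = 1:11,
    x = c(0, 0, -5, 0, 5, -1, 1, 4, 6, 5, 7),
    y = 0,
    z = c(0, 5, 10, 10, 10, 15, 15, 15, 15, 20, 20),
    parent = c(NA, 1L, 2L, 2L, 2L, 4L, 4L, 5L, 5L, 8L, 8L))
  tm <- tibble::tibble(sl_id = 1:6, node = c(3L, 6L, 7L, 9L, 10L, 11L))
  tree <- structure(list(nodes = nodes, roots = 1L, terminal_map = tm,
                         label = "inlet", iterations = 0L),
                    class = "vascular_tree")
  seg <- tree_segments(tree, r_root = 1, gamma = 3)

  trunk <- seg[seg$node == 2, ]
  expect_equal(trunk$r, 1)           # single child of the root: omega = 1
  expect_equal(trunk$omega, 1)

  kids <- seg[seg$parent == 2, ]
  expect_equal(sort(kids$n_down), c(1L, 2L, 3L))
  expect_equal(sum(kids$omega), 1)
  expect_equal(sort(kids$r^3), c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-12)
  expect_equal(sum(kids$r^3), trunk$r^3)  # Murray conservation

  # symmetric bifurcation under node 4: ratio 2^(-1/3)
  under4 <- seg[seg$parent == 4, ]
  r4 <- seg$r[seg$node == 4]
  expect_equal(under4$r / r4, rep(2^(-1 / 3), 2), tolerance = 1e-12)
})

test_that("a single vessel between the boundary nodes obeys Ohm's law", {
  el <- tibble::tibble(element = 1L, type = "vessel", tree = NA_character_,
                       from = 1L, to = 2L, L = 10, r = 1,
                       R = 4, V = pi * 10, n_down = 1L, sl_id = NA_integer_)
  net <- flow_network(el, tibble::tibble(node = 1:2, x = 0, y = 0, z = 0),
                      inlet_node = 1L, outlet_node = 2L)
  sys <- assemble_system(net, R_SL = 0, p_in = 8, p_out = 0)
  expect_equal(dim(sys$A), c(3L, 3L))
  sol <- solve_flow(net, R_SL = 0, p_in = 8, p_out = 0)
  expect_equal(sol$Q_in, 2)
  expect_equal(sol$pressures$P, c(8, 0))
})

test_that("the two-branch circuit reproduces all four reference rows", {
  asym <- two_branch_network(R1 = 1, R2 = 10)
  sym <- two_branch_network(R1 = 1, R2 = 1)

  s <- solve_flow(sym, R_SL = 0, q_in = 1, p_out = 0)
  expect_equal(dplyr::filter(s$flows, type == "sl")$Q, c(0.5, 0.5))
  expect_equal(s$R_eq, 1)
  s <- solve_flow(sym, R_SL = 100, q_in = 1, p_out = 0)
  expect_equal(dplyr::filter(s$flows, type == "sl")$Q, c(0.5, 0.5))
  expect_equal(s$R_eq, 51)

  s <- solve_flow(asym, R_SL = 0, q_in = 1, p_out = 0)
  q <- dplyr::filter(s$flows, type == "sl")$Q
  expect_equal(round(q, 2), c(0.91, 0.09))
  expect_equal(round(s$R_eq, 2), 1.82)
  expect_equal(round(s$dP, 2), 1.82)

  s <- solve_flow(asym, R_SL = 100, q_in = 1, p_out = 0)
  q <- dplyr::filter(s$flows, type == "sl")$Q
  expect_equal(round(q, 2), c(0.54, 0.46))
  expect_equal(round(s$R_eq, 2), 55.14)
  # closed form: branches 2 R_i + R_SL in parallel
  expect_equal(s$R_eq, (102 * 120) / 222, tolerance = 1e-12)
})

test_that("system size is always j + k + l", {
  for (seed in 1:5) {
    fx <- random_mirror_network(2L + seed %% 5L, R_SL = 3, seed = seed)
    net <- fx$network
    sys <- assemble_system(net, R_SL = 3, p_in = 1, p_out = 0)
    n <- nrow(net$elements) + nrow(net$nodes)
    expect_equal(dim(sys$A), c(n, n))
  }
})

test_that("solved R_eq matches the recursive series/parallel oracle", {
  worst <- 0
  for (seed in 1:100) {
    k <- 2L + seed %% 5L
    set.seed(1000L + seed)
    R_SL <- exp(stats::rnorm(1, 1, 1.5))
    fx <- random_mirror_network(k, R_SL = R_SL, seed = seed)
    sol <- solve_flow(fx$network, R_SL = R_SL, p_in = 1, p_out = 0)
    worst <- max(worst, abs(sol$R_eq - fx$R_eq_oracle) / fx$R_eq_oracle)
  }
  expect_lt(worst, 1e-10)
})

test_that("Kirchhoff and Ohm residuals vanish on solved models", {
  sol <- cached_10sl_solution()
  expect_lt(sol$residual_kcl, 1e-10)
  expect_lt(sol$residual_ohm, 1e-10)
  # conservation: super-lobule flows sum to the inlet flow
  sl_q <- sum(dplyr::filter(sol$flows, type == "sl")$Q)
  expect_equal(sl_q, sol$Q_in, tolerance = 1e-10)
})

test_that("Murray partition of unity holds at every branch of a model", {
  mod <- cached_10sl_model()
  for (side in c("inlet", "outlet")) {
    seg <- tree_segments(mod$topology[[side]],
                         r_root = 7.5, gamma = 3)
    by_parent <- split(seg, seg$parent)
    for (grp in by_parent) {
      if (nrow(grp) < 2) next
      expect_equal(sum(grp$omega), 1, tolerance = 1e-12)
      parent_edge <- seg[seg$node == grp$parent[1], ]
      r_par <- if (nrow(parent_edge)) parent_edge$r else 7.5
      expect_equal(sum(grp$r^3), r_par^3, tolerance = 1e-9)
    }
  }
})

test_that("bisection inverts the flow-resistance relation", {
  # single super lobule directly between the boundary nodes: R = dP / Q
  el <- tibble::tibble(element = 1L, type = "sl", tree = NA_character_,
                       from = 1L, to = 2L, L = NA_real_, r = NA_real_,
                       R = NA_real_, V = 100, n_down = 1L, sl_id = 1L)
  net1 <- flow_network(el, tibble::tibble(node = 1:2, x = 0, y = 0, z = 0),
                       inlet_node = 1L, outlet_node = 2L)
  fit <- find_sl_resistance(net1, p_in = 10, p_out = 0, q_target = 2,
                            tol = 1e-10)
  expect_equal(fit$R_SL, 5, tolerance = 1e-9)

  # two-branch circuit: recover R_SL = 100 from the solved operating point
  fit2 <- find_sl_resistance(two_branch_network(1, 10),
                             p_in = 12240 / 222, p_out = 0, q_target = 1,
                             tol = 1e-8)
  expect_equal(fit2$R_SL, 100, tolerance = 1e-6)
})

test_that("infeasible boundary conditions are diagnosed before bisection", {
  # vessel-only resistance already exceeds what the target flow permits
  expect_error(
    find_sl_resistance(two_branch_network(10, 10), p_in = 1, p_out = 0,
                       q_target = 10),
    "infeasible.*maximum achievable flow")
})

test_that("calibration meets clinical targets and parallel-equivalence", {
  sol <- cached_10sl_solution()
  expect_lt(abs(mm3_s_to_ml_min(sol$Q_in) - 767), 1e-8 * 2)
  expect_equal(dyn_mm2_to_mmHg(sol$dP), 5.8, tolerance = 1e-12)
  expect_equal(sol$R_SL_eq, sol$R_SL / 10)
  expect_equal(mm3_s_to_ml_min(sol$Q_SL_mean), 76.7, tolerance = 1e-8)
  # Ohm across the lumped elements: mean drop = R_SL * mean flow
  expect_equal(sol$dP_SL_mean, sol$R_SL * sol$Q_SL_mean, tolerance = 1e-8)
})

test_that("R_SL moves monotonically with the boundary conditions", {
  net <- cached_10sl_model()$network
  cal <- function(P, Q) {
    calibrate_flow(net, boundary_conditions(P, 0, Q), tol_ml_min = 1e-6)$R_SL
  }
  # at fixed pressure, R_SL decreases with target flow
  r_q <- c(cal(5.8, 200), cal(5.8, 500), cal(5.8, 900))
  expect_true(all(diff(r_q) < 0))
  # at fixed flow, R_SL increases with pressure
  r_p <- c(cal(3, 500), cal(6, 500), cal(12, 500))
  expect_true(all(diff(r_p) > 0))
})

test_that("larger R_SL evens out the flow split on an asymmetric circuit", {
  net <- two_branch_network(1, 10)
  v <- vapply(c(0, 10, 100), function(R) {
    stats::var(dplyr::filter(solve_flow(net, R_SL = R, q_in = 1,
                                        p_out = 0)$flows,
                             type == "sl")$Q)
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("disconnected networks are rejected at construction", {
  el <- tibble::tibble(element = 1L, type = "vessel", tree = NA_character_,
                       from = 1L, to = 2L, L = 1, r = 1, R = 1, V = 1,
                       n_down = 1L, sl_id = NA_integer_)
  expect_error(
    flow_network(el, tibble::tibble(node = 1:3, x = 0, y = 0, z = 0),
                 inlet_node = 1L, outlet_node = 3L),
    "not connected")
})
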