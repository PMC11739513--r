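#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flow solution into one row per element
#'
#' @param x a `flow_solution`.
#' @param ... unused.
#' @return tibble with element geometry, resistance, flow in mm^3/s and
#'   mL/min, and wall shear stress (vessels only).
#' @export
tidy.flow_solution <- function(x, ...) {
  out <- x$flows
  out$Q_ml_min <- mm3_s_to_ml_min(out$Q)
  out
}

#' One-row summary of a flow solution
#'
#' @param x a `flow_solution`.
#' @param ... unused.
#' @return tibble with the bulk flow, pressure drop, equivalent and
#'   super-lobule resistances, mean super-lobule drop/flow, maximum wall
#'   shear stress and solver residuals.
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    Q_in_ml_min = mm3_s_to_ml_min(x$Q_in),
    dP_mmHg = dyn_mm2_to_mmHg(x$dP),
    R_eq = x$R_eq,
    R_SL = x$R_SL,
    R_SL_eq = x$R_SL_eq,
    n_SL = x$n_SL,
    Q_SL_mean_ml_min = mm3_s_to_ml_min(x$Q_SL_mean),
    dP_SL_mean_mmHg = dyn_mm2_to_mmHg(x$dP_SL_mean),
    max_wss = x$max_wss,
    residual_ohm = x$residual_ohm,
    residual_kcl = x$residual_kcl)
}

#' Tidy loading curves into long format
#'
#' @param x a `loading_result`.
#' @param ... unused.
#' @return tibble `t`, `element`, `C`.
#' @export
tidy.loading_result <- function(x, ...) {
  out <- tidyr::pivot_longer(x$curves, -"t", names_to = "element",
                             values_to = "C")
  out$element <- as.integer(out$element)
  out
}

#' One-row summary of a loading run
#'
#' @param x a `loading_result`.
#' @param ... unused.
#' @return tibble with the total times to each threshold, the slowest
#'   super-lobule times, step size and completion flag.
#' @export
glance.loading_result <- function(x, ...) {
  thr <- paste0("t", x$thresholds * 100)
  last_sl <- vapply(thr, function(cn) max(x$sl_times[[cn]]), numeric(1))
  tibble::tibble(!!!as.list(x$total_times),
                 !!!as.list(stats::setNames(last_sl, paste0("last_sl_", thr))),
                 dt = x$dt, steps = x$steps, completed = x$completed)
}

#' Plot loading curves per super lobule
#'
#' @param object a `loading_result`.
#' @param ... unused.
#' @return a ggplot: concentration versus time, one line per super lobule,
#'   with the total volume-weighted concentration overlaid.
#' @export
autoplot.loading_result <- function(object, ...) {
  sl_el <- object$sl_times$element
  curves <- tidy(object)
  sl_curves <- dplyr::filter(curves, .data$element %in% sl_el)
  sl_curves$sl_id <- object$sl_times$sl_id[match(sl_curves$element, sl_el)]
  ggplot2::ggplot(sl_curves,
                  ggplot2::aes(x = .data$t, y = .data$C,
                               group = .data$sl_id,
                               colour = factor(.data$sl_id))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_line(data = object$audit, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$t, y = .data$total_C),
                       linewidth = 1, colour = "black") +
    ggplot2::labs(x = "time (s)", y = "CPA concentration",
                  colour = "super lobule",
                  title = "CPA loading per super lobule (black: total)") +
    ggplot2::theme_minimal()
}

#' Plot the flow / shear structure of a solved network
#'
#' @param object a `flow_solution`.
#' @param ... unused.
#' @return a ggplot: per-vessel wall shear stress against radius, flow
#'   rate mapped to point size.
#' @export
autoplot.flow_solution <- function(object, ...) {
  v <- dplyr::filter(tidy(object), .data$type == "vessel")
  ggplot2::ggplot(v, ggplot2::aes(x = .data$r, y = .data$tau,
                                  size = abs(.data$Q_ml_min),
                                  colour = .data$tree)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "vessel radius (mm)",
                  y = "wall shear stress (dyn/mm^2)",
                  size = "|Q| (mL/min)", colour = "tree") +
    ggplot2::theme_minimal()
}

#' Heatmap of a boundary-condition sweep
#'
#' @param object a `bc_sweep`.
#' @param value column to map to fill (default `"R_SL"`; also `"max_wss"`,
#'   `"t90_total"`, `"t90_last_sl"`).
#' @param ... unused.
#' @return a ggplot tile map over pressure and flow; infeasible cells
#'   are blank.
#' @export
autoplot.bc_sweep <- function(object, value = "R_SL", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$Q_ml_min, y = .data$P_mmHg,
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "target flow (mL/min)", y = "inlet pressure (mmHg)",
                  fill = value) +
    ggplot2::theme_minimal()
}
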