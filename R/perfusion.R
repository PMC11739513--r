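#' Orient a solved network along the flow direction
#'
#' Flips any element whose solved flow is negative so that all flows are
#' positive from `from` to `to`, then derives the element-level directed
#' acyclic graph (element B is a parent of element A when B ends at the
#' node where A starts) and a topological order from the inlet to the
#' outlet. Loading updates walk this order so each element sees its
#' parents' already-updated concentrations.
#'
#' @param network a `flow_network`.
#' @param solution the matching `flow_solution`.
#' @return list of class `flow_dag`: oriented `elements` (with positive
#'   `Q`), integer `order` (topological, element ids), `parents` (list per
#'   element), `inlet_elements`, `outlet_elements`.
#' @export
orient_by_flow <- function(network, solution) {
  el <- solution$flows
  flip <- el$Q < 0
  tmp <- el$from[flip]
  el$from[flip] <- el$to[flip]
  el$to[flip] <- tmp
  el$Q <- abs(el$Q)

  m <- nrow(el)
  by_to <- split(seq_len(m), el$to)
  parents <- lapply(seq_len(m), function(e) {
    p <- by_to[[as.character(el$from[e])]]
    if (is.null(p)) integer(0) else p
  })
  # the inlet node has no upstream elements; anything "entering" it would be
  # a back-flow artifact
  indeg <- lengths(parents)
  order <- integer(m)
  queue <- which(indeg == 0L)
  children <- vector("list", m)
  for (e in seq_len(m)) for (p in parents[[e]]) {
    children[[p]] <- c(children[[p]], e)
  }
  k <- 0L
  while (length(queue)) {
    e <- queue[[1]]
    queue <- queue[-1]
    k <- k + 1L
    order[k] <- e
    for (c_ in children[[e]]) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) queue <- c(queue, c_)
    }
  }
  if (k < m) {
    stop("cannot topologically order the flow graph: directed cycle among ",
         "elements ", paste(setdiff(seq_len(m), order[seq_len(k)])[1:5],
                            collapse = ", "), call. = FALSE)
  }
  structure(list(
    elements = el, order = order, parents = parents,
    inlet_elements = which(lengths(parents) == 0L),
    outlet_elements = which(el$to == network$outlet_node)),
    class = "flow_dag")
}

#' Advance element concentrations by one explicit step
#'
#' Single exposed step of the loading scheme (the bulk simulation runs the
#' same update in compiled code): elements are updated in topological
#' order; each mixes the flow-weighted concentration of its updated parents
#' (`C_in`), receives `V_in = Q dt` of it, and displaces the same volume.
#'
#' @param C numeric concentrations per element (in element-table order).
#' @param dag a [orient_by_flow()] result.
#' @param dt time step, s.
#' @param c_inlet inlet boundary concentration (default 1, pure CPA).
#' @return updated concentration vector.
#' @export
step_concentrations <- function(C, dag, dt, c_inlet = 1) {
  el <- dag$elements
  V <- el$V
  Q <- el$Q
  v_in <- Q * dt
  bad <- which(v_in > V + 1e-12)
  if (length(bad)) {
    dt_max <- min(V / Q, na.rm = TRUE)
    stop(sprintf(paste0("time step too large: element %d receives V_in = %.4g ",
                        "> V = %.4g; maximum stable dt = %.4g s"),
                 el$element[bad[1]], v_in[bad[1]], V[bad[1]], dt_max),
         call. = FALSE)
  }
  for (e in dag$order) {
    p <- dag$parents[[e]]
    cin <- if (!length(p)) c_inlet else sum(C[p] * Q[p]) / sum(Q[p])
    C[e] <- (v_in[e] * cin + (V[e] - v_in[e]) * C[e]) / V[e]
  }
  C
}

#' Simulate constant-flow CPA loading
#'
#' Starting from all-blood (`C = 0`), loads pure CPA (`C = 1`) at the
#' solved steady flows and records per-element concentration curves, the
#' total volume-weighted concentration, a running CPA volume audit
#' (cumulative inflow vs stored + cumulative outflow) and
#' linearly-interpolated times to the requested thresholds, per element
#' and for the whole model. The run stops once the total concentration and
#' every super lobule have crossed the last threshold, or at `t_max`.
#'
#' @param network a `flow_network`.
#' @param solution the matching `flow_solution`.
#' @param dt time step, s (default 0.01, the converged value for the
#'   reference models). Must satisfy `Q dt <= V` for every element.
#' @param thresholds increasing concentration thresholds (default
#'   0.5, 0.9, 0.98).
#' @param t_max wall-clock cap of simulated time, s.
#' @param c_inlet inlet boundary concentration.
#' @param record_every record the state every this many steps (raised
#'   automatically so no more than ~4000 snapshots are kept).
#' @return a `loading_result`: tibbles `curves` (recorded `t` x element
#'   concentrations, long format via [generics::tidy()]), `audit`
#'   (`t`, `inflow_cum`, `stored`, `outflow_cum`, `total_C`),
#'   `element_times` and `sl_times` (times to thresholds), vector
#'   `total_times`, and metadata.
#' @export
simulate_loading <- function(network, solution, dt = 0.01,
                             thresholds = c(0.5, 0.9, 0.98),
                             t_max = 2000, c_inlet = 1,
                             record_every = 10L) {
  stopifnot(dt > 0, all(diff(thresholds) > 0), all(thresholds > 0),
            all(thresholds < 1))
  dag <- orient_by_flow(network, solution)
  el <- dag$elements
  pos_q <- el$Q > 0
  if (any(el$V[pos_q] < el$Q[pos_q] * dt - 1e-12)) {
    dt_max <- min(el$V[pos_q] / el$Q[pos_q])
    bad <- el$element[pos_q][which.min(el$V[pos_q] / el$Q[pos_q])]
    stop(sprintf(paste0("time step dt = %.4g s too large for element %d ",
                        "(V_in > V); maximum stable dt = %.4g s"),
                 dt, bad, dt_max), call. = FALSE)
  }

  max_steps <- ceiling(t_max / dt)
  record_every <- max(as.integer(record_every),
                      as.integer(ceiling(max_steps / 4000)))
  ord0 <- dag$order - 1L
  pl <- dag$parents
  parents_ptr <- c(0L, cumsum(lengths(pl)))
  parents_idx <- as.integer(unlist(pl, use.names = FALSE) - 1L)
  outlet_feeder <- as.integer(seq_len(nrow(el)) %in% dag$outlet_elements)
  watch <- as.integer(el$type == "sl")

  res <- run_loading_cpp(ord0, as.integer(parents_ptr), parents_idx,
                         el$Q, el$V, outlet_feeder, watch,
                         c_inlet, dt, t_max, thresholds,
                         as.integer(record_every))
  if (isTRUE(res$bound_violation)) {
    stop("concentration left [0, 1]; the time step is unstable", call. = FALSE)
  }
  if (!isTRUE(res$completed)) {
    warning("loading did not reach the final threshold before t_max = ",
            t_max, " s; returning the partial result", call. = FALSE)
  }

  thr_names <- paste0("t", thresholds * 100)
  etimes <- tibble::as_tibble(stats::setNames(
    as.data.frame(res$element_threshold_times), thr_names))
  etimes <- dplyr::bind_cols(el[, c("element", "type", "sl_id")], etimes)
  curves <- tibble::as_tibble(as.data.frame(res$C_rec))
  names(curves) <- as.character(el$element)
  curves <- dplyr::bind_cols(tibble::tibble(t = res$t), curves)

  structure(list(
    curves = curves,
    audit = tibble::tibble(t = res$t, total_C = res$total_C,
                           inflow_cum = res$inflow_cum,
                           stored = res$stored,
                           outflow_cum = res$outflow_cum),
    element_times = etimes,
    sl_times = dplyr::filter(etimes, .data$type == "sl"),
    total_times = stats::setNames(as.numeric(res$total_threshold_times),
                                  thr_names),
    final_C = as.numeric(res$final_C),
    thresholds = thresholds, dt = dt, steps = res$steps,
    completed = isTRUE(res$completed)),
    class = "loading_result")
}

#' @export
print.loading_result <- function(x, ...) {
  tt <- paste(sprintf("%s = %.3f s", names(x$total_times), x$total_times),
              collapse = ", ")
  cat(sprintf("<loading_result> dt = %g s, %d steps; total times: %s\n",
              x$dt, x$steps, tt))
  invisible(x)
}

#' Maximum stable loading time step
#'
#' The displacement update requires `Q dt <= V` for every element; the
#' maximum stable step is `min(V / Q)` over flowing elements.
#'
#' @param network a `flow_network`.
#' @param solution the matching `flow_solution`.
#' @return the largest stable `dt`, s.
#' @export
max_stable_dt <- function(network, solution) {
  dag <- orient_by_flow(network, solution)
  pos <- dag$elements$Q > 0
  min(dag$elements$V[pos] / dag$elements$Q[pos])
}

#' Time-step convergence study
#'
#' Re-runs the loading simulation over a descending ladder of time steps
#' and reports the times for the total concentration -- and for the slowest
#' super lobule -- to reach each threshold, flagging the steps at which
#' successive results agree within `tol` relative.
#'
#' @param network a `flow_network`.
#' @param solution the matching `flow_solution`.
#' @param dts descending vector of time steps, s; unstable entries are
#'   skipped with a message.
#' @param thresholds concentration thresholds.
#' @param tol relative successive-change tolerance declaring convergence.
#' @param t_max simulated-time cap passed through.
#' @return a tibble with one row per dt: total and last-SL times per
#'   threshold and `converged` (change from the previous dt below `tol`
#'   for every reported time).
#' @export
dt_convergence_study <- function(network, solution,
                                 dts = c(0.1, 0.05, 0.01, 0.005),
                                 thresholds = c(0.5, 0.9, 0.98),
                                 tol = 0.01, t_max = 2000) {
  stopifnot(all(diff(dts) < 0))
  dt_cap <- max_stable_dt(network, solution)
  rows <- list()
  prev <- NULL
  for (dt in dts) {
    if (dt > dt_cap) {
      message(sprintf("skipping dt = %g s (unstable; max stable dt = %.4g s)",
                      dt, dt_cap))
      next
    }
    lr <- simulate_loading(network, solution, dt = dt,
                           thresholds = thresholds, t_max = t_max)
    last_sl <- apply(as.matrix(lr$sl_times[, paste0("t", thresholds * 100)]),
                     2, max)
    vals <- c(lr$total_times, stats::setNames(last_sl,
              paste0("last_sl_t", thresholds * 100)))
    converged <- if (is.null(prev)) NA else
      all(abs(vals - prev) / prev < tol)
    rows[[length(rows) + 1]] <- tibble::tibble(
      dt = dt, !!!as.list(vals), converged = converged)
    prev <- vals
  }
  dplyr::bind_rows(rows)
}
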