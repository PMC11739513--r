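#' Write a generated model bundle to disk
#'
#' One directory per run: `manifest.json` (seed, parameters, package
#' version), `geometry/` (surface as ASCII STL, partition as JSON),
#' `trees/` (node tables as CSV and VTK legacy polylines), `network/`
#' (element and node tables as CSV).
#'
#' @param model a [generate_model()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(model, dir) {
  dir.create(file.path(dir, "geometry"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  dir.create(file.path(dir, "network"), showWarnings = FALSE)
  manifest <- list(
    package = "superlobule",
    version = as.character(utils::packageVersion("superlobule")),
    seed = model$seed,
    n_super_lobules = model$network$n_SL,
    cloud_size = model$cloud_size,
    config = unclass(model$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_stl(model$mesh, file.path(dir, "geometry", "surface.stl"))
  jsonlite::write_json(
    list(centroids = model$partition$centroids,
         assignment = model$partition$assignment),
    file.path(dir, "geometry", "partition.json"), auto_unbox = TRUE)
  for (side in c("inlet", "outlet")) {
    tree <- model$topology[[side]]
    utils::write.csv(tree$nodes,
                     file.path(dir, "trees", paste0(side, "_nodes.csv")),
                     row.names = FALSE)
    write_vtk_polylines(tree, file.path(dir, "trees", paste0(side, ".vtk")))
  }
  utils::write.csv(model$network$elements,
                   file.path(dir, "network", "elements.csv"),
                   row.names = FALSE)
  utils::write.csv(model$network$nodes,
                   file.path(dir, "network", "nodes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Export a vascular tree as VTK legacy polylines
#'
#' Each parent-child edge becomes a 2-point line cell; loadable in ParaView
#' for visual inspection of the generated vasculature.
#'
#' @param tree a `vascular_tree`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_polylines <- function(tree, path) {
  n <- tree$nodes
  edges <- which(!is.na(n$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("vascular tree:", tree$label),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(n))), con)
  writeLines(sprintf("%.6f %.6f %.6f", n$x, n$y, n$z), con)
  writeLines(sprintf("LINES %d %d", length(edges), 3L * length(edges)), con)
  writeLines(sprintf("2 %d %d", n$parent[edges] - 1L, n$id[edges] - 1L), con)
  invisible(path)
}

#' Export a flow solution as CSV + JSON summary
#'
#' `flow_elements.csv` holds per-element geometry, resistance, flow
#' (mm^3/s and mL/min) and wall shear stress; `node_pressures.csv` the
#' nodal pressures (dyn/mm^2 and mmHg); `flow_summary.json` the calibrated
#' R_SL, its parallel equivalent, mean super-lobule pressure drop and
#' flow, the maximum wall shear stress and the solver residuals.
#'
#' @param solution a `flow_solution`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_flow_solution <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fl <- solution$flows
  fl$Q_ml_min <- mm3_s_to_ml_min(fl$Q)
  utils::write.csv(fl, file.path(dir, "flow_elements.csv"), row.names = FALSE)
  pr <- solution$pressures
  pr$P_mmHg <- dyn_mm2_to_mmHg(pr$P)
  utils::write.csv(pr, file.path(dir, "node_pressures.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(glance(solution)),
                       file.path(dir, "flow_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export loading curves and threshold summaries
#'
#' @param result a `loading_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_loading_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$curves, file.path(dir, "loading_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(result$audit, file.path(dir, "loading_audit.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(total_times = as.list(result$total_times),
         sl_times = result$sl_times, dt = result$dt,
         completed = result$completed),
    file.path(dir, "loading_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
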