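#' Unit conversions for the mm-dyn-s internal system
#'
#' All internal computation uses millimetres, dynes and seconds: pressures in
#' dyn/mm^2, flows in mm^3/s, viscosity in dyn.s/mm^2, resistance in
#' dyn.s/mm^5. User-facing inputs and reports use the clinical units mmHg,
#' mL/min and cP.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

# 1 mmHg = 133.322 Pa = 13.3322 dyn/mm^2 (1 dyn/mm^2 = 10 Pa)
MMHG_PER_DYN_MM2 <- 1 / 13.3322387415

#' @rdname units
#' @export
mmHg_to_dyn_mm2 <- function(x) x / MMHG_PER_DYN_MM2

#' @rdname units
#' @export
dyn_mm2_to_mmHg <- function(x) x * MMHG_PER_DYN_MM2

#' @rdname units
#' @export
ml_min_to_mm3_s <- function(x) x * 1000 / 60

#' @rdname units
#' @export
mm3_s_to_ml_min <- function(x) x * 60 / 1000

#' @rdname units
#' @export
cP_to_dyn_s_mm2 <- function(x) x * 1e-4
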