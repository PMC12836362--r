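# Bactericidal and membrane-permeabilization assay statistics: plate-count
# arithmetic, LC99.9 calling from serial-dilution kill curves, and
# propidium-iodide (PI) uptake normalization.

#' Colony-forming units per mL from a plate count
#'
#' Standard plate-count back-calculation: `count x dilution_factor /
#' plated_volume`. A zero count is returned as 0 CFU/mL with a
#' `detection_limit` attribute (one colony at that dilution/volume).
#'
#' @param count Colony count on the plate (>= 0).
#' @param dilution Dilution factor of the plated sample (1 = undiluted,
#'   10 = 10-fold, ...; powers of ten in serial-dilution practice).
#' @param plated_volume Plated volume in mL (> 0), e.g. 0.1 for 100 uL.
#' @return Survivor density in CFU/mL.
#' @examples
#' survivors_per_ml(100, 10, 0.1)  # 1e4
#' @export
survivors_per_ml <- function(count, dilution = 1, plated_volume = 0.1) {
  if (any(plated_volume <= 0)) stop("plated_volume must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  out <- count * dilution / plated_volume
  if (length(count) == 1L && count == 0) {
    attr(out, "detection_limit") <- dilution / plated_volume
  }
  out
}

#' Construct a serial-dilution kill curve
#'
#' @param data Data frame with columns `concentration`, `dilution`,
#'   `count` (one row per plate; replicate plates allowed).
#' @param initial_density Inoculum density in CFU/mL (> 0).
#' @param plated_volume Plated volume in mL.
#' @param conc_unit Concentration unit label (e.g. `"uM"`, `"ug/mL"`).
#' @return A list of class `kill_curve`.
#' @export
kill_curve <- function(data, initial_density, plated_volume = 0.1,
                       conc_unit = "uM") {
  stopifnot(is.data.frame(data),
            all(c("concentration", "dilution", "count") %in% names(data)))
  if (initial_density <= 0) stop("initial_density must be > 0", call. = FALSE)
  if (any(data$count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(abs(log10(data$dilution) %% 1) > 1e-9)) {
    stop("dilutions must be powers of 10", call. = FALSE)
  }
  data <- data[order(data$concentration, data$dilution), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, initial_density = initial_density,
                 plated_volume = plated_volume, conc_unit = conc_unit),
            class = "kill_curve")
}

#' Call the LC99.9 bactericidal endpoint
#'
#' LC99.9 is the lowest tested concentration that killed >= 99.9% of the
#' initial population, with the additional colony-count gate that the
#' undiluted plate shows <= `max_colonies` (default 10) colonies. Kill
#' percentage is computed from the undiluted plate:
#' `100 x (1 - survivors/initial)`. Both sub-criteria can be switched off
#' individually; the conjunction is the default. If no concentration
#' qualifies the result is `"not reached"` with the maximum tested
#' concentration recorded.
#'
#' @param curve A [kill_curve()].
#' @param require_kill_fraction Apply the >= 99.9% kill gate.
#' @param require_colony_gate Apply the <= `max_colonies` undiluted-plate
#'   gate.
#' @param max_colonies Colony-count ceiling for the gate.
#' @return A list of class `lc999_result`: `lc999` (concentration, or `NA`
#'   when not reached), `reached`, `unit`, and the per-concentration
#'   summary table `summary`.
#' @export
lc999 <- function(curve, require_kill_fraction = TRUE,
                  require_colony_gate = TRUE, max_colonies = 10) {
  stopifnot(inherits(curve, "kill_curve"))
  concs <- sort(unique(curve$data$concentration))
  rows <- lapply(concs, function(conc) {
    sub <- curve$data[curve$data$concentration == conc, , drop = FALSE]
    und <- sub[sub$dilution == 1, , drop = FALSE]
    if (require_colony_gate && nrow(und) == 0L) {
      stop(sprintf(
        "no undiluted plate at %g %s but the colony-count gate is enabled",
        conc, curve$conc_unit), call. = FALSE)
    }
    est <- if (nrow(und) > 0L) und else sub[which.min(sub$dilution), ,
                                            drop = FALSE]
    survivors <- mean(survivors_per_ml(est$count, est$dilution,
                                       curve$plated_volume))
    kill_pct <- 100 * (1 - survivors / curve$initial_density)
    data.frame(concentration = conc, survivors_per_ml = survivors,
               kill_percent = kill_pct,
               undiluted_count = if (nrow(und) > 0L) mean(und$count) else NA,
               passes = (!require_kill_fraction || kill_pct >= 99.9) &&
                 (!require_colony_gate ||
                    (nrow(und) > 0L && mean(und$count) <= max_colonies)))
  })
  summary <- do.call(rbind, rows)
  hit <- which(summary$passes)
  structure(list(
    lc999 = if (length(hit) > 0L) summary$concentration[hit[1L]] else NA_real_,
    reached = length(hit) > 0L,
    max_tested = max(concs),
    unit = curve$conc_unit,
    summary = summary),
    class = "lc999_result")
}

#' @export
print.lc999_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("LC99.9 = %g %s\n", x$lc999, x$unit))
  } else {
    cat(sprintf("LC99.9 not reached (> %g %s tested)\n", x$max_tested, x$unit))
  }
  invisible(x)
}

#' Percent propidium-iodide uptake
#'
#' The membrane-permeabilization normalization
#' `%PI uptake = 100 x (Px - Po) / (P100 - Po)` applied elementwise over a
#' time grid, where `Px` is PI + cells + peptide, `Po` PI + cells alone
#' (intact-membrane baseline) and `P100` the Triton-X-100 full-lysis
#' control. Values outside \[0, 100\] arise with noisy controls and are
#' reported as-is unless `clip = TRUE`.
#'
#' @param Px,Po,P100 Numeric fluorescence vectors on a common time grid
#'   (scalars recycle).
#' @param clip Clip the result to \[0, 100\].
#' @return Numeric vector of percent PI uptake.
#' @examples
#' pi_uptake_percent(150, 100, 200)  # 50
#' @export
pi_uptake_percent <- function(Px, Po, P100, clip = FALSE) {
  if (any(P100 == Po)) {
    stop("P100 equals Po: %PI uptake is undefined", call. = FALSE)
  }
  out <- 100 * (Px - Po) / (P100 - Po)
  if (clip) out <- pmin(pmax(out, 0), 100)
  out
}

#' Mean and SD summary of replicate series
#'
#' Triplicate-style summaries (mean +/- SD) for assay time series or
#' per-concentration measurements.
#'
#' @param x Numeric matrix with replicates in columns.
#' @return Data frame with `mean` and `sd` per row.
#' @export
replicate_summary <- function(x) {
  x <- as.matrix(x)
  data.frame(mean = rowMeans(x), sd = apply(x, 1, stats::sd))
}
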