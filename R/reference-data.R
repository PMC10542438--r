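# Bundled reference tables from a validation campaign of a dual-head
# NaI(Tl) SPECT camera (Tc-99m with LEHR collimators, Lu-177 with MLEGP
# collimators): traceable calibration-source gamma lines, acquisition
# energy windows, activity uncertainty budgets and measured sensitivities.
# They serve as worked-example inputs and as fixtures for the metric
# functions.

refPath <- function(name) {
  p <- system.file("extdata", name, package = "spectval")
  stopIfNot(nzchar(p), paste("bundled table not found:", name))
  p
}

#' Bundled calibration-source gamma lines
#'
#' Energies, emission intensities and traceable activities (each with
#' standard uncertainty) of the calibration-ampoule gamma lines used to
#' measure the intrinsic camera efficiency, with their live times.
#'
#' @return data.frame with columns isotope, energy_keV, intensity_percent,
#'   intensity_sigma, activity_kBq, activity_sigma, live_time_s.
#' @export
refCalibrationLines <- function() {
  utils::read.csv(refPath("calibration_lines.csv"), stringsAsFactors = FALSE)
}

#' Bundled acquisition energy windows
#'
#' Emission (EM) and scatter (SC) window definitions for Tc-99m and Lu-177
#' phantom acquisitions.
#'
#' @param isotope optional filter, e.g. `"Tc-99m"`.
#' @return list of [EnergyWindow-class], named by label.
#' @export
refEnergyWindows <- function(isotope = NULL) {
  df <- utils::read.csv(refPath("energy_windows.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(isotope)) df <- df[df$isotope == isotope, ]
  out <- lapply(seq_len(nrow(df)), function(i)
    energyWindow(df$label[i], df$centre_keV[i], df$half_width_percent[i]))
  names(out) <- df$label
  out
}

#' Bundled activity uncertainty budgets
#'
#' The percentage uncertainty components for activity per unit mass of the
#' phantom solutions, combined in quadrature by [combineQuadrature()].
#'
#' @param isotope `"Tc-99m"` or `"Lu-177"`.
#' @return an [UncertaintyBudget-class].
#' @export
refActivityBudget <- function(isotope = c("Tc-99m", "Lu-177")) {
  isotope <- match.arg(isotope)
  f <- if (isotope == "Tc-99m") "budget_tc99m.csv" else "budget_lu177.csv"
  readBudget(refPath(f))
}

#' Bundled measured sensitivities
#'
#' Simulated and experimental sensitivities (counts/(s x MBq), standard
#' uncertainties) per phantom and energy window, with the published
#' simulation/experiment ratio cells.
#'
#' @param isotope `"Tc-99m"` or `"Lu-177"`.
#' @return data.frame with columns isotope, phantom, window, sim,
#'   sim_sigma, exp, exp_sigma, ratio, ratio_sigma.
#' @export
refSensitivityTable <- function(isotope = c("Tc-99m", "Lu-177")) {
  isotope <- match.arg(isotope)
  f <- if (isotope == "Tc-99m") "sensitivity_tc99m.csv" else
    "sensitivity_lu177.csv"
  utils::read.csv(refPath(f), stringsAsFactors = FALSE)
}

#' Reference efficiency-correction function
#'
#' The piecewise intrinsic-efficiency correction measured for the
#' reference camera: `-3.755 + 1.702 ln(E) - 0.168 ln^2(E)` at and above
#' 46 keV and `-0.0134 + 0.0067 E` below it (zero at 2 keV), with the
#' published (rounded) linear coefficients used verbatim.
#'
#' @return an [EfficiencyCorrection-class].
#' @examples
#' evaluateCorrection(referenceCorrection(), c(2, 46, 140.5))
#' @export
referenceCorrection <- function() {
  efficiencyCorrection(-3.755, 1.702, -0.168, breakpointKeV = 46,
                       anchorKeV = 2, slope = 0.0067, intercept = -0.0134)
}
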