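#' Built-in experimental scenarios
#'
#' Constructs the published protocol definitions as [protocol()] objects:
#' \describe{
#'   \item{oral_water_load}{drinking 1 l of water over 5 min: QIN = 0.2
#'     l/min on [5, 10] min, 3 h horizon.}
#'   \item{iv_saline}{intravenous 0.9\% w/v NaCl (154 mEq/l of Na+ and Cl-)
#'     at 0.2 l/min over 5 min: QVIN = 0.2 and YNIN = YCLI = 154 * 0.2 =
#'     30.8 mEq/min on [5, 10] min, 3 h horizon.}
#'   \item{co2_5pct}{5\% CO2 inhalation for 30 min: FCOI = 0.05 on
#'     [5, 35] min, 1 h horizon.}
#'   \item{glucose_tolerance}{glucose infusion of 1 g/min for 50 min:
#'     YGLI = 1000 mg/min on [5, 55] min, 3 h horizon.}
#'   \item{co2_10pct_48h}{chronic 10\% CO2 inhalation: FCOI = 0.1 for the
#'     whole 48 h run (respiratory acidosis with renal compensation).}
#'   \item{hyperventilation}{alveolar ventilation clamped to three times
#'     normal, VI = 15 l/min, FCOI = 0, for the whole 48 h run
#'     (respiratory alkalosis with renal compensation).}
#' }
#'
#' @param name scenario name, one of the six above.
#' @param duration optional horizon override, min.
#' @param sampling optional output sampling interval override, min.
#' @param saline_conc NaCl concentration of the infusate for
#'   \code{iv_saline}, mEq/l (default 154, i.e. 0.9\% w/v).
#' @param infusion_rate infusate rate for \code{iv_saline}, l/min
#'   (default 0.2).
#' @return an \code{ikeda_protocol}.
#' @export
#' @examples
#' build_scenario("co2_5pct")$events[[1]]$value   # 0.05
build_scenario <- function(name,
                           duration = NULL, sampling = NULL,
                           saline_conc = 154, infusion_rate = 0.2) {
  valid <- c("oral_water_load", "iv_saline", "co2_5pct",
             "glucose_tolerance", "co2_10pct_48h", "hyperventilation")
  if (!is.character(name) || length(name) != 1 || !name %in% valid)
    stop("unknown scenario; valid names are: ", paste(valid, collapse = ", "))
  dur <- function(d) if (is.null(duration)) d else duration
  pr <- switch(name,
    oral_water_load = protocol(
      override("QIN", 0.2, c(5, 10)),
      duration = dur(180), sampling = sampling),
    iv_saline = protocol(
      override("QVIN", infusion_rate, c(5, 10)),
      override("YNIN", saline_conc * infusion_rate, c(5, 10)),
      override("YCLI", saline_conc * infusion_rate, c(5, 10)),
      duration = dur(180), sampling = sampling),
    co2_5pct = protocol(
      override("FCOI", 0.05, c(5, 35)),
      duration = dur(60), sampling = sampling),
    glucose_tolerance = protocol(
      override("YGLI", 1000, c(5, 55)),
      duration = dur(180), sampling = sampling),
    co2_10pct_48h = protocol(
      override("FCOI", 0.1, c(0, Inf)),
      duration = dur(2880), sampling = sampling),
    hyperventilation = protocol(
      clamp("VI", 15, c(0, Inf)),
      duration = dur(2880), sampling = sampling))
  pr
}

#' List of built-in scenario names
#' @return character vector of the six scenario names.
#' @export
list_scenarios <- function() {
  c("oral_water_load", "iv_saline", "co2_5pct", "glucose_tolerance",
    "co2_10pct_48h", "hyperventilation")
}

#' Run a built-in scenario
#'
#' Equilibrates the model (or uses a supplied baseline state) and integrates
#' the named scenario.
#'
#' @inheritParams build_scenario
#' @param params parameter list.
#' @param state optional baseline state; when missing, [equilibrate()] is
#'   called.
#' @param ... further arguments to [simulate_model()] (e.g. \code{rtol}).
#' @return an \code{ikeda_result}.
#' @export
run_scenario <- function(name, params = default_parameters(), state = NULL,
                         duration = NULL, sampling = NULL, ...) {
  pr <- build_scenario(name, duration = duration, sampling = sampling)
  if (is.null(state)) state <- equilibrate(params)
  simulate_model(state, pr, params, ...)
}

#' Davenport-diagram trajectory
#'
#' Extracts (pH, bicarbonate) pairs at requested times from a simulation
#' result, by linear interpolation on the output grid. The points are
#' suitable for plotting on the pH-[HCO3-] plane against equi-PCO2
#' isopleths (e.g. at 13.3, 40.0 and 73.0 mmHg).
#'
#' @param result an \code{ikeda_result}.
#' @param sample_times times, min; defaults to log-spaced samples between
#'   12 min and 48 h capturing the fast respiratory and slow renal phases.
#' @return data.frame with columns \code{time}, \code{PHA}, \code{XCO3} and
#'   the implied \code{PCO2} recovered through the Henderson-Hasselbalch
#'   relation.
#' @export
davenport_trajectory <- function(result,
                                 sample_times = c(12, 30, 60, 120, 360,
                                                  720, 1440, 2880)) {
  stopifnot(inherits(result, "ikeda_result"))
  if (any(sample_times < min(result$time) |
          sample_times > max(result$time)))
    stop("sample time outside the result horizon [",
         min(result$time), ", ", max(result$time), "]")
  p <- attr(result, "params")
  ph  <- stats::approx(result$time, result$PHA, xout = sample_times)$y
  bic <- stats::approx(result$time, result$XCO3, xout = sample_times)$y
  data.frame(time = sample_times, PHA = ph, XCO3 = bic,
             PCO2 = bic / (p$SCO2 * 10^(ph - p$PKHH)))
}

#' Equi-PCO2 isopleth for the Davenport diagram
#'
#' Bicarbonate as a function of pH at constant PCO2 (a plotting helper).
#'
#' @param PCO2 CO2 tension, mmHg.
#' @param pH pH grid.
#' @param params parameter list.
#' @return data.frame with columns \code{PHA}, \code{XCO3}.
#' @export
davenport_isopleth <- function(PCO2, pH = seq(7.0, 7.8, by = 0.01),
                               params = default_parameters()) {
  p <- params
  data.frame(PHA = pH, XCO3 = p$SCO2 * PCO2 * 10^(pH - p$PKHH))
}
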