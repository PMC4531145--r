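#' Timed input override
#'
#' A stepwise override of one external input over a closed time window
#' \code{[t_start, t_end]} (both endpoints included, matching the
#' \code{IF (TIME >= a AND TIME <= b) THEN x ELSE y} idiom of stepwise
#' protocol definitions). Outside the window the input keeps its default.
#'
#' @param target external-input mnemonic (one of QIN, QVIN, YNIN, YCLI,
#'   YGLI, FCOI, YKIN, YMNIN).
#' @param value override value in the target's native unit.
#' @param window numeric length-2 vector \code{c(t_start, t_end)} in min;
#'   \code{t_end} may be \code{Inf}.
#' @return an object of class \code{"ikeda_override"}.
#' @export
#' @examples
#' override("QIN", 0.2, c(5, 10))  # drink 200 ml/min from t = 5 to 10 min
override <- function(target, value, window = c(0, Inf)) {
  if (!target %in% input_names())
    stop("override target must be an external input: ",
         paste(input_names(), collapse = ", "))
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value),
            length(window) == 2, window[1] < window[2], window[1] >= 0)
  if (value < 0) stop("external input rates must be non-negative")
  if (target == "FCOI" && value >= 1)
    stop("FCOI is a gas volume fraction and must lie in [0, 1)")
  structure(list(target = target, value = value,
                 window = as.numeric(window)),
            class = "ikeda_override")
}

#' Variable clamp
#'
#' Replaces the defining equation of an algebraic variable by a constant
#' while the clamp window is active; on expiry the equation is restored.
#'
#' @param target clampable variable mnemonic (one of VI, GFR, ADH, ALD).
#' @param value fixed value in the target's native unit.
#' @param window closed activity window in min (default: always).
#' @return an object of class \code{"ikeda_clamp"}.
#' @export
#' @examples
#' clamp("VI", 15)  # fixed hyperventilation at 15 l/min
clamp <- function(target, value, window = c(0, Inf)) {
  if (!target %in% clampable_names())
    stop("clamp target must be one of: ",
         paste(clampable_names(), collapse = ", "))
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value),
            length(window) == 2, window[1] < window[2], window[1] >= 0)
  structure(list(target = target, value = value,
                 window = as.numeric(window)),
            class = "ikeda_clamp")
}

#' Simulation protocol
#'
#' Bundles timed overrides and clamps with a horizon and an output sampling
#' interval. Windows on the same target may not partially overlap.
#'
#' @param ... [override()] and [clamp()] objects (or a single list of them).
#' @param duration total simulated time, min.
#' @param sampling output sampling interval, min; default 0.5 min for runs
#'   up to 3 h and 5 min for longer runs. Event boundaries are always added
#'   to the output grid.
#' @return an object of class \code{"ikeda_protocol"}.
#' @export
protocol <- function(..., duration = 180, sampling = NULL) {
  ev <- list(...)
  if (length(ev) == 1 && is.list(ev[[1]]) &&
      !inherits(ev[[1]], c("ikeda_override", "ikeda_clamp")))
    ev <- ev[[1]]
  ok <- vapply(ev, inherits, TRUE, what = c("ikeda_override", "ikeda_clamp"))
  if (length(ev) && !all(ok))
    stop("protocol(...) accepts only override() and clamp() objects")
  stopifnot(is.numeric(duration), duration > 0)
  if (is.null(sampling)) sampling <- if (duration <= 180) 0.5 else 5
  ## reject partially overlapping windows on one target
  tg <- vapply(ev, `[[`, "", "target")
  for (g in unique(tg)) {
    w <- lapply(ev[tg == g], `[[`, "window")
    if (length(w) > 1) {
      w <- w[order(vapply(w, `[`, 0, 1))]
      for (i in seq_len(length(w) - 1))
        if (w[[i + 1]][1] <= w[[i]][2])
          stop("overlapping windows on target ", g)
    }
  }
  structure(list(events = ev, duration = duration, sampling = sampling),
            class = "ikeda_protocol")
}

is_override <- function(x) inherits(x, "ikeda_override")

#' Effective external inputs at a time
#'
#' Resolves the protocol at time \code{t}: default input values outside all
#' windows, override values inside. Windows are closed on both ends, so the
#' instant exactly at a boundary uses the override.
#'
#' @param prot an [protocol()] object.
#' @param t time, min.
#' @param params parameter list supplying the default input values.
#' @return named numeric vector of external inputs (see [baseline_inputs()]).
#' @export
#' @examples
#' pr <- build_scenario("iv_saline")
#' effective_inputs(pr, 7)["QVIN"]   # 0.2 inside the infusion window
effective_inputs <- function(prot, t, params = default_parameters()) {
  stopifnot(inherits(prot, "ikeda_protocol"), t >= 0)
  inp <- baseline_inputs(params)
  seen <- character()
  for (ev in prot$events) {
    if (!is_override(ev)) next
    if (t >= ev$window[1] && t <= ev$window[2]) {
      if (ev$target %in% seen)
        stop("conflicting simultaneous overrides on ", ev$target,
             " at t = ", t)
      inp[ev$target] <- ev$value
      seen <- c(seen, ev$target)
    }
  }
  inp
}

#' Active clamps at a time
#'
#' @inheritParams effective_inputs
#' @return named list mapping clamped targets to their imposed values
#'   (empty when none are active).
#' @export
active_clamps <- function(prot, t) {
  stopifnot(inherits(prot, "ikeda_protocol"))
  cl <- list()
  for (ev in prot$events) {
    if (is_override(ev)) next
    if (t >= ev$window[1] && t <= ev$window[2]) {
      if (!is.null(cl[[ev$target]]))
        stop("conflicting simultaneous clamps on ", ev$target)
      cl[[ev$target]] <- ev$value
    }
  }
  cl
}

## all event boundary times falling inside [0, duration]
event_times <- function(prot) {
  tt <- unlist(lapply(prot$events, `[[`, "window"))
  tt <- tt[is.finite(tt) & tt >= 0 & tt <= prot$duration]
  sort(unique(tt))
}
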