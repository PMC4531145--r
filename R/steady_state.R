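#' Equilibrate the model to its unperturbed baseline
#'
#' Settles the model under baseline inputs by long forward integration
#' (default 14 simulated days) and verifies that all scaled derivatives are
#' below tolerance. Forward integration is used rather than algebraic
#' root-finding on the full system: the regulated physiology is built to
#' settle, and integration cannot land on an unphysiological root.
#'
#' @param params parameter list.
#' @param tolerance maximum allowed scaled derivative magnitude,
#'   \code{|dx/dt| / max(|x|, 1)} per min.
#' @param max_time integration horizon, min.
#' @param state optional starting state (defaults to [initial_state()]).
#' @return equilibrated state vector (cumulative bookkeeping integrals
#'   reset to zero).
#' @export
#' @examples
#' \donttest{
#' s <- equilibrate()
#' snapshot(s)[c("PHA", "OSMP", "PAS")]
#' }
equilibrate <- function(params = default_parameters(), tolerance = 1e-6,
                        max_time = 20160, state = NULL) {
  if (is.null(state)) state <- initial_state(params)
  pr  <- protocol(duration = max_time, sampling = max_time / 8)
  res <- simulate_model(state, pr, params)
  y <- unlist(res[nrow(res), names(state)])
  names(y) <- names(state)
  y[c("CWIN", "CWOUT", "CNAIN", "CNAOUT", "CKIN", "CKOUT", "CCLIN",
      "CCLOUT", "CGLIN", "CGLOUT")] <- 0
  d <- derivatives(0, y, baseline_inputs(params), params)
  scaled <- abs(d) / pmax(abs(y), 1)
  scaled <- scaled[!grepl("^C(W|NA|K|CL|GL)", names(scaled))]
  if (max(scaled) >= tolerance)
    stop("equilibrate: no fixed point within ", max_time,
         " min; largest scaled residual ", signif(max(scaled), 3),
         " on ", names(scaled)[which.max(scaled)])
  y
}

#' Mass-balance audit of a simulation result
#'
#' For each conserved species (water, sodium, chloride, potassium, glucose)
#' over a time window: cumulative intake minus cumulative output (urinary
#' excretion, insensible loss, metabolic conversion) minus the change in
#' total body store, with a relative-error column. Intake and output
#' integrals are carried as states by the integrator, so the audit measures
#' true conservation of the equations to solver tolerance, not quadrature
#' error.
#'
#' @param result an \code{ikeda_result}.
#' @param window length-2 numeric, audit window \code{[t0, t1]} in min
#'   (default: the whole run).
#' @return data.frame with one row per species: intake, output, store
#'   change, absolute residual and relative error (residual divided by the
#'   largest flux magnitude in the window, floored at 1).
#' @export
mass_balance_report <- function(result, window = NULL) {
  stopifnot(inherits(result, "ikeda_result"))
  if (is.null(window)) window <- range(result$time)
  if (window[1] < min(result$time) || window[2] > max(result$time))
    stop("window outside result horizon")
  at <- function(v, t) stats::approx(result$time, result[[v]], xout = t)$y
  span <- function(v) at(v, window[2]) - at(v, window[1])
  species <- list(
    water    = list(inn = "CWIN",  out = "CWOUT",
                    store = function() span("VEC") + span("VIC")),
    sodium   = list(inn = "CNAIN", out = "CNAOUT",
                    store = function() span("YNE")),
    chloride = list(inn = "CCLIN", out = "CCLOUT",
                    store = function() span("YCLE")),
    potassium = list(inn = "CKIN", out = "CKOUT",
                    store = function() span("YKE") + span("YKI")),
    glucose  = list(inn = "CGLIN", out = "CGLOUT",
                    store = function() span("YGLE")))
  rows <- lapply(names(species), function(nm) {
    sp <- species[[nm]]
    i <- span(sp$inn); o <- span(sp$out); ds <- sp$store()
    resid <- i - o - ds
    scale <- max(abs(i), abs(o), abs(ds), 1)
    data.frame(species = nm, intake = i, output = o, store_change = ds,
               residual = resid, rel_error = abs(resid) / scale)
  })
  do.call(rbind, rows)
}

#' Model variable census
#'
#' Counts and lists the named variables of the assembled model: integrated
#' state variables, distinct algebraic variables of the snapshot, and
#' parameters. The census is deterministic and stable across runs.
#'
#' @param params parameter list.
#' @return list with \code{n_state}, \code{n_algebraic}, \code{n_params}
#'   and \code{names} (list of the three name vectors).
#' @export
#' @examples
#' census <- variable_census()
#' census$n_state + census$n_algebraic   # the model's variable count
variable_census <- function(params = default_parameters()) {
  s  <- initial_state(params)
  sn <- snapshot(s, baseline_inputs(params), params)
  state_names <- names(s)
  alg_names <- setdiff(unique(names(sn)), state_names)
  list(n_state = length(state_names),
       n_algebraic = length(alg_names),
       n_params = length(params),
       names = list(state = state_names, algebraic = alg_names,
                    parameters = names(params)))
}
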