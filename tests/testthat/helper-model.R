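## shared fixtures: parameters, baseline state and memoized scenario runs
## (expensive 48-h integrations are computed once per test session)
.cache <- new.env(parent = emptyenv())

test_params <- function() {
  if (is.null(.cache$p)) .cache$p <- default_parameters()
  .cache$p
}

test_state <- function() {
  if (is.null(.cache$s)) .cache$s <- initial_state(test_params())
  .cache$s
}

baseline_eq <- function() {
  if (is.null(.cache$eq)) .cache$eq <- equilibrate(test_params())
  .cache$eq
}

cached_run <- function(name) {
  key <- paste0("run_", name)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- simulate_model(baseline_eq(), build_scenario(name),
                                    test_params())
  .cache[[key]]
}

interp <- function(res, var, t) stats::approx(res$time, res[[var]], xout = t)$y
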