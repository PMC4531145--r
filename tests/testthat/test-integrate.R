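test_that("an unperturbed run from the fixed point stays flat", {
  p <- test_params()
  r <- simulate_model(baseline_eq(), protocol(duration = 180), p)
  for (v in c("OSMP", "PHA", "PAS", "VI", "QWU", "VEC", "VIC"))
    expect_lt(diff(range(r[[v]])) / max(abs(r[[v]][1]), 1e-6), 1e-6)
})

test_that("the output grid contains every event boundary exactly", {
  p <- test_params()
  pr <- protocol(override("QIN", 0.2, c(5, 10)),
                 override("FCOI", 0.03, c(12.25, 40)), duration = 60)
  r <- simulate_model(test_state(), pr, p)
  expect_true(all(c(0, 5, 10, 12.25, 40, 60) %in% r$time))
  expect_true(all(diff(r$time) > 0))
})

test_that("splitting a run and restarting reproduces the trajectory", {
  p <- test_params()
  pr <- build_scenario("oral_water_load", duration = 60)
  full <- simulate_model(baseline_eq(), pr, p)
  ## split at t* = 22 (not an event time), restart from the saved state
  tstar <- 22
  first <- simulate_model(baseline_eq(), pr, p, duration = tstar)
  y <- unlist(first[nrow(first), names(test_state())])
  names(y) <- names(test_state())
  ## shift the protocol to the remaining horizon
  pr2 <- protocol(duration = 60 - tstar, sampling = pr$sampling)
  second <- simulate_model(y, pr2, p)
  for (v in c("VEC", "OSMP", "QWU", "PHA")) {
    end_full <- interp(full, v, 60)
    end_split <- second[[v]][nrow(second)]
    expect_equal(end_split, end_full, tolerance = 1e-5)
  }
})

test_that("refining the tolerance leaves the endpoint essentially unchanged", {
  p <- test_params()
  pr <- build_scenario("oral_water_load", duration = 60)
  a <- simulate_model(baseline_eq(), pr, p, rtol = 1e-6)
  b <- simulate_model(baseline_eq(), pr, p, rtol = 1e-7)
  for (v in c("VEC", "VIC", "YNE", "PCOA", "YBBE")) {
    ea <- a[[v]][nrow(a)]; eb <- b[[v]][nrow(b)]
    expect_lt(abs(ea - eb) / max(abs(eb), 1e-9), 1e-3)
  }
})

test_that("a clamp holds its variable exactly and releases continuously", {
  p <- test_params()
  ## clamp VI at its own baseline value: a no-op within tolerance
  pr <- protocol(clamp("VI", 5, c(0, Inf)), duration = 30)
  r <- simulate_model(baseline_eq(), pr, p)
  expect_true(all(abs(r$VI - 5) < 1e-12))
  free <- simulate_model(baseline_eq(), protocol(duration = 30), p)
  for (v in c("PCOA", "PHA", "VEC"))
    expect_equal(r[[v]][nrow(r)], free[[v]][nrow(free)], tolerance = 1e-4)

  ## clamp at 15 for one hour, then release: VI rejoins the controller
  pr2 <- protocol(clamp("VI", 15, c(0, 60)), duration = 120)
  r2 <- simulate_model(baseline_eq(), pr2, p)
  expect_true(all(abs(r2$VI[r2$time <= 60] - 15) < 1e-12))
  after <- r2[r2$time > 60, ]
  i <- nrow(after)
  st <- unlist(after[i, names(test_state())])
  names(st) <- names(test_state())
  sn <- snapshot(st, baseline_inputs(p), p)
  expect_equal(after$VI[i],
               ventilation_controller(sn[["PHA"]], sn[["PCOA"]],
                                      sn[["PO2A"]], p),
               tolerance = 1e-8)
  ## release is a continuous, rate-bounded rejoin, not a jump in the state
  expect_lt(abs(interp(r2, "PCOA", 60.5) - interp(r2, "PCOA", 60)), 10)
  expect_gt(interp(r2, "PCOA", 70), interp(r2, "PCOA", 60))
})

test_that("a near-zero-duration run returns the initial snapshot", {
  p <- test_params()
  r <- simulate_model(test_state(), protocol(duration = 1e-6), p)
  sn <- snapshot(test_state(), baseline_inputs(p), p)
  expect_equal(r$OSMP[1], sn[["OSMP"]], tolerance = 1e-12)
  expect_equal(r$time[1], 0)
})
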