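test_that("acute water load: diuresis surge, dilution, and cell swelling", {
  r <- cached_run("oral_water_load")
  base_qwu <- r$QWU[1]
  expect_gt(max(r$QWU), 10 * base_qwu)             # marked diuresis
  ## returns toward baseline by the end of the 3 h window
  expect_lt(r$QWU[nrow(r)], 3 * base_qwu)
  ## osmolality dips below baseline; intra- and interstitial volumes swell
  expect_lt(min(r$OSMP), r$OSMP[1] - 2)
  expect_gt(max(r$VIC), r$VIC[1] + 0.1)
  expect_gt(max(r$VIF), r$VIF[1] + 0.05)
  ## ADH effect is suppressed relative to baseline during the load
  expect_lt(min(r$ADH), 0.8)
  ## the bolus delivers exactly one liter above the baseline drink rate
  p <- test_params()
  pr <- attr(r, "protocol")
  ev <- pr$events[[1]]
  bolus <- (ev$value - p$QIN) * diff(ev$window)
  expect_equal(bolus + p$QIN * diff(ev$window), 1, tolerance = 1e-12)
})

test_that("saline vs water: larger sustained ECF expansion, smaller osmolality drop", {
  rw <- cached_run("oral_water_load")
  rs <- cached_run("iv_saline")
  t_late <- 60
  expect_gt(interp(rs, "VEC", t_late) - rs$VEC[1],
            2 * (interp(rw, "VEC", t_late) - rw$VEC[1]))
  expect_lt(rs$OSMP[1] - min(rs$OSMP), 2)
  expect_gt(rw$OSMP[1] - min(rw$OSMP), 5)
  ## saline triggers natriuresis; arterial pressure rises transiently
  expect_gt(max(rs$YNU), 2 * rs$YNU[1])
  expect_gt(max(rs$PAS), rs$PAS[1] + 2)
})

test_that("5% CO2 inhalation: PCO2 and ventilation rise, then recover", {
  r <- cached_run("co2_5pct")
  during <- r$time >= 15 & r$time <= 35
  expect_gt(max(r$PCOA[during]), r$PCOA[1] + 5)
  expect_gt(max(r$VI[during]), 2 * r$VI[1])
  expect_lt(min(r$PHA[during]), r$PHA[1] - 0.03)
  ## recovery after the inhalation window
  expect_lt(abs(r$PCOA[nrow(r)] - r$PCOA[1]), 1)
  expect_lt(abs(r$VI[nrow(r)] - r$VI[1]), 0.5)
})

test_that("glucose tolerance: rise-and-decay glucose, glycosuria only during load, hypokalemia", {
  r <- cached_run("glucose_tolerance")
  expect_gt(max(r$XGLE), 180)
  ## returns toward baseline within the 3 h window
  expect_lt(abs(r$XGLE[nrow(r)] - r$XGLE[1]), 10)
  ## urinary glucose appears only while plasma glucose is above threshold
  expect_equal(r$YGLU[1], 0)
  expect_gt(max(r$YGLU), 0)
  expect_equal(r$YGLU[nrow(r)], 0)
  spill <- r$time[r$YGLU > 0]
  expect_gt(min(spill), 5)      # no spill before the infusion starts
  expect_lt(max(spill), 120)    # none once glucose has fallen again
  ## insulin-driven potassium shift lowers ECF potassium during the test
  expect_lt(min(r$XKE), r$XKE[1] - 0.3)
  expect_gt(max(r$INS), 2)
  ## potassium excretion falls with the hypokalemia
  expect_lt(min(r$YKU), r$YKU[1])
})

test_that("with metabolism disabled, the glucose store is pure bookkeeping", {
  p0 <- default_parameters(CGL1 = 0, CGL2 = 0, CGL3 = 0)
  s0 <- initial_state(p0)
  pr <- protocol(override("YGLI", 500, c(0, 30)), duration = 60)
  r <- simulate_model(s0, pr, p0)
  n <- nrow(r)
  dstore <- r$YGLE[n] - r$YGLE[1]
  intake <- r$CGLIN[n] - r$CGLIN[1]
  renal  <- r$CGLOUT[n] - r$CGLOUT[1]
  expect_equal(intake, 500 * 30, tolerance = 1e-9)
  expect_equal(dstore, intake - renal, tolerance = 1e-6)
})

test_that("chronic respiratory acidosis: rising bicarbonate, partial pH compensation", {
  r <- cached_run("co2_10pct_48h")
  d <- davenport_trajectory(r)
  ## the trajectory stays on the hypercapnic side throughout
  expect_true(all(d$PCO2 > 40))
  ## bicarbonate rises monotonically between the sampled times
  expect_true(all(diff(d$XCO3) > 0))
  ## pH moves back toward 7.4 between 12 min and 48 h without reaching it
  expect_lt(d$PHA[1], 7.4)
  expect_gt(d$PHA[nrow(d)], d$PHA[1])
  expect_lt(d$PHA[nrow(d)], 7.4)
})

test_that("sustained hyperventilation: falling bicarbonate, pH drawn back toward 7.4", {
  r <- cached_run("hyperventilation")
  expect_true(all(abs(r$VI - 15) < 1e-10))
  d <- davenport_trajectory(r)
  expect_true(all(d$PCO2 < 40))
  expect_true(all(diff(d$XCO3) < 0))
  expect_gt(d$PHA[1], 7.4)
  expect_lt(abs(d$PHA[nrow(d)] - 7.4), abs(d$PHA[1] - 7.4))
})

test_that("Davenport extraction interpolates deterministically", {
  r <- cached_run("co2_5pct")
  d <- davenport_trajectory(r, sample_times = c(0, 10, 10, 30))
  expect_equal(d$PHA[2], d$PHA[3])     # duplicate times, identical points
  expect_equal(d$XCO3[2], d$XCO3[3])
  ## t = 0 on any run starting at baseline is the normal point
  expect_equal(d$PHA[1], 7.4, tolerance = 1e-6)
  expect_equal(d$XCO3[1], test_params()$XCO30, tolerance = 1e-4)
  expect_error(davenport_trajectory(r, sample_times = 100), "horizon")
})

test_that("every scenario closes its mass balances to solver precision", {
  for (nm in c("oral_water_load", "iv_saline", "glucose_tolerance")) {
    mb <- mass_balance_report(cached_run(nm))
    expect_lt(max(mb$rel_error), 1e-4)
  }
})
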