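test_that("Henderson-Hasselbalch identity: doubling PCO2 lowers pH by log10(2)", {
  p <- test_params()
  for (pco2 in c(20, 40, 60)) {
    ph1 <- blood_gas_chemistry(pco2, 95, 24, p)$PH
    ph2 <- blood_gas_chemistry(2 * pco2, 95, 24, p)$PH
    expect_equal(ph1 - ph2, log10(2), tolerance = 1e-12)
  }
})

test_that("bicarbonate round-trips through the pH relation", {
  p <- test_params()
  for (b in c(10, 24, 35)) {
    ph <- blood_gas_chemistry(40, 95, b, p)$PH
    expect_equal(p$SCO2 * 40 * 10^(ph - p$PKHH), b, tolerance = 1e-10)
  }
})

test_that("Bohr effect: lower pH lowers saturation at fixed PO2", {
  p <- test_params()
  ## lower bicarbonate at fixed PCO2 means lower pH
  s_acid   <- blood_gas_chemistry(40, 60, 15, p)
  s_normal <- blood_gas_chemistry(40, 60, 24, p)
  expect_lt(s_acid$PH, s_normal$PH)
  expect_lt(s_acid$SO2, s_normal$SO2)
  expect_gt(s_acid$P50, s_normal$P50)
})

test_that("Haldane effect: lower saturation raises CO2 content at fixed PCO2", {
  p <- test_params()
  high_po2 <- blood_gas_chemistry(40, 100, 24, p)
  low_po2  <- blood_gas_chemistry(40, 40, 24, p)
  expect_lt(low_po2$SO2, high_po2$SO2)
  expect_gt(low_po2$CCO2, high_po2$CCO2)
})

test_that("saturation stays in [0, 1] and outputs are finite across ranges", {
  p <- test_params()
  grid <- expand.grid(pco2 = c(10, 40, 90), po2 = c(25, 60, 150),
                      b = c(5, 24, 45))
  for (i in seq_len(nrow(grid))) {
    r <- blood_gas_chemistry(grid$pco2[i], grid$po2[i], grid$b[i], p)
    expect_true(is.finite(r$PH))
    expect_gte(r$SO2, 0); expect_lte(r$SO2, 1)
    expect_gt(r$CCO2, 0)
  }
})

test_that("non-positive gas pressure or bicarbonate is a domain error", {
  p <- test_params()
  expect_error(blood_gas_chemistry(0, 95, 24, p), "positive")
  expect_error(blood_gas_chemistry(40, -1, 24, p), "positive")
  expect_error(blood_gas_chemistry(40, 95, 0, p), "positive")
})

test_that("buffer-base pH solve agrees with an independent root finder", {
  p <- test_params()
  for (A in c(15, 23.94, 35)) for (pco2 in c(15, 40, 75)) {
    f <- function(x) p$SCO2 * pco2 * 10^(x - p$PKHH) +
      p$BUFB * (x - p$PHA0) - A
    ref <- uniroot(f, c(6, 8.5), tol = 1e-12)$root
    expect_equal(solve_ph(A, pco2, p), ref, tolerance = 1e-8)
  }
})

test_that("closed-form pH at baseline equals the assembled model's PHA", {
  p <- test_params()
  sn <- snapshot(test_state(), baseline_inputs(p), p)
  direct <- blood_gas_chemistry(sn[["PCOA"]], sn[["PO2A"]],
                                sn[["XCO3"]], p)$PH
  expect_equal(direct, sn[["PHA"]], tolerance = 1e-9)
  expect_equal(sn[["PHA"]], p$PHA0, tolerance = 1e-8)
})

test_that("standard bicarbonate equals bicarbonate re-equilibrated to PCO2 40", {
  p <- test_params()
  ## independent route: root-solve the buffer relation at PCO2 40, then
  ## apply Henderson-Hasselbalch at the found pH
  for (A in c(18, 23.94, 30)) {
    f <- function(x) p$SCO2 * p$PCOA0 * 10^(x - p$PKHH) +
      p$BUFB * (x - p$PHA0) - A
    ph40 <- uniroot(f, c(6, 8.5), tol = 1e-12)$root
    ref <- p$SCO2 * p$PCOA0 * 10^(ph40 - p$PKHH)
    expect_equal(standard_bicarbonate(A, p), ref, tolerance = 1e-7)
  }
  ## at baseline, STBC equals the actual bicarbonate (PCO2 is already 40)
  sn <- snapshot(test_state(), baseline_inputs(p), p)
  expect_equal(sn[["STBC"]], sn[["XCO3"]], tolerance = 1e-7)
})
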