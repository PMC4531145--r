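test_that("ventilation controller reproduces baseline and the clamp ratio", {
  p <- test_params()
  vi0 <- ventilation_controller(p$PHA0, p$PCOA0, p$PO2A0, p)
  expect_equal(vi0, 5, tolerance = 1e-12)
  ## the fixed hyperventilation level is three times normal
  expect_equal(15 / vi0, 3, tolerance = 1e-12)
  ## fixed-point consistency with the equilibrated model
  sn <- snapshot(baseline_eq(), baseline_inputs(p), p)
  expect_equal(ventilation_controller(sn[["PHA"]], sn[["PCOA"]],
                                      sn[["PO2A"]], p),
               sn[["VI"]], tolerance = 1e-6)
})

test_that("ventilation is monotone in PCO2 and in hypoxia", {
  p <- test_params()
  pco2 <- seq(30, 70, by = 2)
  vi <- vapply(pco2, function(x)
    ventilation_controller(p$PHA0, x, p$PO2A0, p), 0)
  expect_true(all(diff(vi) > 0))
  ## non-increasing in PO2 over the hypoxic range
  po2 <- seq(35, 100, by = 5)
  vi2 <- vapply(po2, function(x)
    ventilation_controller(p$PHA0, p$PCOA0, x, p), 0)
  expect_true(all(diff(vi2) < 0))
  ## never negative, even under strong alkalosis
  expect_gte(ventilation_controller(7.8, 15, 140, p), 0)
})

test_that("circulation is a pure monotone function of volume", {
  p <- test_params()
  s <- test_state()
  c1 <- circulation_steady_state(s, p)
  c2 <- circulation_steady_state(s, p)
  expect_identical(c1, c2)          # purity / determinism
  expect_equal(c1$PAS, p$PAS0, tolerance = 1e-12)
  sup <- s; sup["VEC"] <- s[["VEC"]] + 1
  expect_gt(circulation_steady_state(sup, p)$PAS, c1$PAS)
  expect_gt(circulation_steady_state(sup, p)$QCO, c1$QCO)
})

test_that("fluid compartments satisfy the volume identity and ratio scaling", {
  p <- test_params()
  s <- test_state()
  fc <- fluid_compartments(s, p)
  expect_equal(fc$VP + fc$VIF, fc$VEC, tolerance = 1e-12)
  expect_equal(fc$OSMP, p$OSMP0, tolerance = 1e-10)
  ## scaling a solute store scales its concentration
  s2 <- s; s2["YNE"] <- 1.25 * s[["YNE"]]
  expect_equal(fluid_compartments(s2, p)$XNE, 1.25 * fc$XNE,
               tolerance = 1e-12)
  ## degenerate volume errors out rather than being clamped
  s3 <- s; s3["VIC"] <- 0
  expect_error(fluid_compartments(s3, p), "degenerate")
})

test_that("mannitol raises osmolality additively and reversibly", {
  p <- test_params()
  s <- test_state()
  base <- fluid_compartments(s, p)$OSMP
  s2 <- s; s2["YMN"] <- 55        # 5 mOsm/l at 11 l ECF
  expect_equal(fluid_compartments(s2, p)$OSMP, base + 5, tolerance = 1e-10)
  s2["YMN"] <- 0
  expect_equal(fluid_compartments(s2, p)$OSMP, base, tolerance = 1e-12)
})

test_that("hormone targets respond with the physiological signs", {
  p <- test_params()
  sn <- as.list(snapshot(test_state(), baseline_inputs(p), p))
  h0 <- hormone_controllers(sn, params = p)
  expect_equal(h0$ADHT, 1, tolerance = 1e-10)
  expect_equal(h0$ALDT, 1, tolerance = 1e-10)
  expect_equal(h0$INST, 1, tolerance = 1e-10)
  ## ALD increases with ECF potassium
  snk <- sn; snk$XKE <- sn$XKE + 0.5
  expect_gt(hormone_controllers(snk, params = p)$ALDT, h0$ALDT)
  ## ADH increases with osmolality, decreases with volume expansion
  sno <- sn; sno$OSMP <- sn$OSMP + 5
  expect_gt(hormone_controllers(sno, params = p)$ADHT, h0$ADHT)
  snv <- sn; snv$VP <- sn$VP * 1.1
  expect_lt(hormone_controllers(snv, params = p)$ADHT, h0$ADHT)
  ## insulin increases with glucose
  sng <- sn; sng$XGLE <- 200
  expect_gt(hormone_controllers(sng, params = p)$INST, 1)
})

test_that("glucose production balances uptake at baseline and both stay non-negative", {
  p <- test_params()
  g0 <- glucose_metabolism(p$XGLE0, 1, p)
  expect_equal(g0$UGL, g0$HGL, tolerance = 1e-12)
  g1 <- glucose_metabolism(250, 4, p)
  expect_gt(g1$UGL, g0$UGL)
  expect_lt(g1$HGL, g0$HGL)
  expect_gte(glucose_metabolism(0, 0, p)$UGL, 0)
})

test_that("GFR is a saturating monotone function of arterial pressure", {
  p <- test_params()
  sn <- as.list(snapshot(test_state(), baseline_inputs(p), p))
  h <- list(ADH = 1, ALD = 1, ANH4 = p$ANH40)
  gfr <- vapply(seq(20, 220, by = 10), function(pas) {
    s <- sn; s$PAS <- pas
    kidney(s, h, p)$GFR
  }, 0)
  expect_true(all(diff(gfr) >= 0))
  expect_true(all(gfr >= 0))
  ## saturation: the gain at the extremes is a small fraction of the
  ## central gain
  gain <- diff(gfr)
  expect_lt(gain[1], 0.1 * max(gain))
  expect_lt(gain[length(gain)], 0.1 * max(gain))
})

test_that("renal glucose spills only above the tubular maximum", {
  p <- test_params()
  sn <- as.list(snapshot(test_state(), baseline_inputs(p), p))
  h <- list(ADH = 1, ALD = 1, ANH4 = p$ANH40)
  expect_identical(kidney(sn, h, p)$YGLU, 0)
  sn_hi <- sn; sn_hi$XGLE <- 400
  kd <- kidney(sn_hi, h, p)
  expect_gt(kd$YGLU, 0)
  expect_equal(kd$YGLU, kd$FILGL - p$TMG, tolerance = 1e-12)
})

test_that("aldosterone retains sodium and promotes potassium excretion", {
  p <- test_params()
  sn <- as.list(snapshot(test_state(), baseline_inputs(p), p))
  lo <- kidney(sn, list(ADH = 1, ALD = 0.5, ANH4 = p$ANH40), p)
  hi <- kidney(sn, list(ADH = 1, ALD = 2, ANH4 = p$ANH40), p)
  expect_lt(hi$YNU, lo$YNU)      # Na retention under high ALD
  expect_gt(hi$YKU, lo$YKU)      # K secretion stimulated by ALD
  ## all excretion rates stay non-negative
  ex <- unlist(hi[c("QWU", "YNU", "YKU", "YCLU", "YGLU", "YURU", "YHC3U",
                    "YNH4U", "YTAU", "YCAU", "YMGU", "YPO4U", "YOAU")])
  expect_true(all(ex >= 0))
})

test_that("ADH concentrates the urine; volume expansion raises THDF and flow", {
  p <- test_params()
  sn <- as.list(snapshot(test_state(), baseline_inputs(p), p))
  lo <- kidney(sn, list(ADH = 0.3, ALD = 1, ANH4 = p$ANH40), p)
  hi <- kidney(sn, list(ADH = 3, ALD = 1, ANH4 = p$ANH40), p)
  expect_gt(lo$QWU, hi$QWU)
  sx <- sn; sx$VEC <- sn$VEC * 1.1; sx$PAS <- sn$PAS * 1.05
  kd <- kidney(sx, list(ADH = 1, ALD = 1, ANH4 = p$ANH40), p)
  base <- kidney(sn, list(ADH = 1, ALD = 1, ANH4 = p$ANH40), p)
  expect_gt(kd$THDF, base$THDF)
  expect_gt(kd$QWU, base$QWU)
  expect_lt(kd$FPROX, base$FPROX)
})
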