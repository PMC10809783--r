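test_that("apportionComposition is exact largest-remainder rounding", {
  expect_identical(unname(apportionComposition(100, c(68, 20, 10, 2))),
                   c(68L, 20L, 10L, 2L))
  expect_identical(unname(apportionComposition(149, c(68, 20, 10, 2))),
                   c(101L, 30L, 15L, 3L))
  expect_identical(unname(apportionComposition(1, c(68, 20, 10, 2))),
                   c(1L, 0L, 0L, 0L))
  expect_error(apportionComposition(10, c(0, 0, 0, 0)), "zero")
  # conservation across totals and ratio tuples (sampled; the full
  # 1..10,000 sweep runs in the acceptance suite)
  for (ratios in list(c(68, 20, 10, 2), c(60, 20, 10, 10), c(1, 1, 1)))
    for (total in c(1:25, 149, 298, 997, 10000))
      expect_identical(sum(apportionComposition(total, ratios)),
                       as.integer(total))
})

test_that("watersPerLipid reproduces the stated hydration ratios", {
  w <- watersPerLipid(27040, 2 * 149)
  expect_equal(round(as.numeric(w), 2), 90.74)
  expect_identical(attr(w, "rounded"), 91)
  expect_equal(as.numeric(watersPerLipid(38400, 512)), 75)
  expect_equal(as.numeric(watersPerLipid(0, 10)), 0)
  expect_error(watersPerLipid(100, 0), "positive")
})

test_that("generateTrace follows the device schedules and protocol bounds", {
  lbt <- generateTrace(traceSpec("LBT"))
  expect_identical(device(lbt$trace), "LBT")
  expect_identical(measureKind(lbt$trace), "pressure")
  expect_equal(range(lbt$trace@area), c(56, 215))
  expect_identical(nCycles(segmentCycles(lbt$trace)), 10L)
  # 150 cm^2/min barrier rate: |dA/dt| = 2.5 cm^2/s away from vertices
  da <- abs(diff(lbt$trace@area[1:50]))
  expect_equal(max(da), 2.5, tolerance = 1e-9)

  csd <- generateTrace(traceSpec("CSD"))
  expect_identical(measureKind(csd$trace), "tension")
  expect_length(csd$trace@time, 600L)       # 120 s at 5 frames/s
  expect_equal(1 / diff(csd$trace@time)[1], 5)
  expect_lte(1 - min(csd$trace@area) / max(csd$trace@area), 0.2)

  expect_error(traceSpec("LBT", piMaxTarget = 80), "gamma0")
  expect_error(traceSpec("LBT", areaRange = c(10, 5)), "ordered")
})

test_that("noiseless traces round-trip through the analysis stages", {
  g <- generateTrace(traceSpec("LBT", nCycles = 2, samplingRate = 2.5))
  cyc <- segmentCycles(g$trace)
  tab <- cycleTable(cyc)
  ci <- seq(tab$comp_start[1], tab$comp_end[1])
  keep <- g$trace@surfaceValue[ci] < g$groundTruth$pi_cap - 1
  mc <- modulusCurve(g$trace@area[ci][keep],
                     g$trace@surfaceValue[ci][keep])
  interior <- 5:(length(mc@kappaRaw) - 4L)
  expect_lt(max(abs(mc@kappaRaw[interior] - 100)) / 100, 0.01)
  m <- cycleMetrics(g$trace, cyc)
  expect_equal(m$hysteresis_area[1], 0, tolerance = 1e-9)
  expect_equal(m$pi_max[1], g$groundTruth$pi_max)

  # constructed shift: exact on the grid-commensurate LBT schedule
  g3 <- generateTrace(traceSpec("LBT", nCycles = 2,
                                hysteresisShift = 3,
                                samplingRate = 2.5))
  m3 <- cycleMetrics(g3$trace, segmentCycles(g3$trace))
  expect_equal(m3$hysteresis_area, c(3, 3), tolerance = 1e-9)
})

test_that("kink plateaus stay monotone and the cap bounds the pressure", {
  g <- generateTrace(traceSpec("LBT", nCycles = 1,
                               kinkPositions = c(20, 40)))
  expect_lte(max(g$trace@surfaceValue), g$groundTruth$pi_cap)
  ci <- cycleTable(segmentCycles(g$trace))
  comp <- g$trace@surfaceValue[seq(ci$comp_start[1], ci$comp_end[1])]
  expect_true(all(diff(comp) >= -1e-9))
})

test_that("generateDecaySeries constructs the stated model with reproducible noise", {
  d <- generateDecaySeries(7, c(5, 5), c(44.52, 253.2), duration = 120,
                           rate = 5)
  expect_equal(d$values[1], 17)
  expect_equal(d$values[d$times == 40],
               7 + 5 * 2^(-40 / 44.52) + 5 * 2^(-40 / 253.2),
               tolerance = 1e-12)
  expect_identical(generateDecaySeries(7, 5, 40, noiseSd = 0.25,
                                       seed = 9)$values,
                   generateDecaySeries(7, 5, 40, noiseSd = 0.25,
                                       seed = 9)$values)
  expect_false(identical(generateDecaySeries(7, 5, 40, noiseSd = 0.25,
                                             seed = 9)$values,
                         generateDecaySeries(7, 5, 40, noiseSd = 0.25,
                                             seed = 10)$values))
  d0 <- generateDecaySeries(7, c(0, 0), c(10, 20), duration = 10,
                            rate = 1)
  expect_true(all(d0$values == 7))
})

test_that("generators are byte-identical under a fixed seed", {
  s <- traceSpec("CSD", noiseSd = 0.2, seed = 21)
  expect_identical(generateTrace(s), generateTrace(s))
  sp <- monolayerSpec(nLipidsPerLeaflet = 60, lcPatchFraction = 0.5,
                      nChemical = 30, seed = 13)
  expect_identical(buildMonolayerFrame(sp), buildMonolayerFrame(sp))
  sp2 <- sp; sp2$seed <- 14L
  expect_false(identical(buildMonolayerFrame(sp)$frame@coords,
                         buildMonolayerFrame(sp2)$frame@coords))
})

test_that("builder ground truth is recovered exactly by the analysis stages", {
  for (f in c(0, 0.5, 1)) {
    b <- buildMonolayerFrame(monolayerSpec(lcPatchFraction = f,
                                           tiltDeg = 25, seed = 5))
    expect_equal(lcFraction(packingFraction(b$frame)),
                 b$groundTruth$true_lc_fraction)
    expect_equal(chainTilt(b$frame)@meanTilt,
                 b$groundTruth$true_tilt_deg, tolerance = 1e-6)
    expect_equal(areaPerLipid(b$frame), b$groundTruth$apl,
                 tolerance = 1e-9)
  }
  expect_equal(buildMonolayerFrame(
    monolayerSpec(lcPatchFraction = 0.5))$groundTruth$true_lc_fraction,
    0.5016949, tolerance = 1e-6)
})

test_that("builder rejects geometrically infeasible specs", {
  expect_error(buildMonolayerFrame(monolayerSpec(lcPatchFraction = 0,
                                                 apl = 50)),
               "disordered region")
  expect_error(buildMonolayerFrame(monolayerSpec(lcPatchFraction = 0.05)),
               "3 wrapped rows")
  expect_error(buildMonolayerFrame(monolayerSpec(lcPatchFraction = 1,
                                                 apl = 40)),
               "overfull lattice")
  expect_error(monolayerSpec(apl = 30), "40, 120")
})

test_that("built frames survive a GRO write/read cycle as valid analysis input", {
  b <- buildMonolayerFrame(monolayerSpec(nLipidsPerLeaflet = 60,
                                         lcPatchFraction = 1,
                                         nChemical = 25,
                                         includeProtein = TRUE))
  f <- withr::local_tempfile(fileext = ".gro")
  writeGRO(b$frame, f)
  fr <- loadFrames(f)[[1]]
  expect_identical(lcFraction(packingFraction(fr)), 1)
  expect_equal(chainTilt(fr)@meanTilt, b$groundTruth$true_tilt_deg,
               tolerance = 0.1)
  expect_true("PROTEIN" %in% atomSpecies(fr))
})

test_that("compression series scales area linearly and preserves geometry ratios", {
  s <- simulateCompressionSeries(nFrames = 11)
  apl <- vapply(s$frames, areaPerLipid, numeric(1))
  expect_equal(apl, seq(110, 54.5, length.out = 11), tolerance = 1e-9)
  expect_equal(s$groundTruth$apl, apl, tolerance = 1e-9)
  # affine in-plane rescale: pairwise xy distance ratios are constant
  i <- c(10, 200, 400)
  d1 <- dist(s$frames[[1]]@coords[i, 1:2])
  d7 <- dist(s$frames[[7]]@coords[i, 1:2])
  expect_equal(as.numeric(d7 / d1), rep(sqrt(apl[7] / 110), 3),
               tolerance = 1e-9)
  expect_error(simulateCompressionSeries(nFrames = 1), "2 frames")
})

test_that("constructed contacts match their closed form exactly, rising at low area", {
  s <- simulateCompressionSeries(nFrames = 9, nChemical = 16,
                                 nProbe = 8)
  cc <- vapply(s$frames, function(f)
    as.numeric(contactCount(f, "PROTEIN", "CHEMICAL")), numeric(1))
  expect_identical(cc, s$groundTruth$contacts_true)
  expect_true(all(diff(cc) >= 0))
  expect_gt(cc[9], cc[1])
})
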