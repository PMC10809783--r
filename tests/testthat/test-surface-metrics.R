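# one triangular pressure cycle with controllable peak
make_cycle_trace <- function(peaks, kind = "pressure", floor_val = 7) {
  n_half <- 20L
  t <- seq_len((2 * n_half + 1) * length(peaks) +
                 (length(peaks) - 1) * 0) - 1L
  area <- c(); val <- c()
  for (p in peaks) {
    a <- c(seq(10, 5, length.out = n_half + 1),
           seq(5.25, 10, length.out = n_half))
    if (kind == "pressure")
      v <- c(seq(0, p, length.out = n_half + 1),
             seq(p * 0.95, 0, length.out = n_half))
    else
      v <- c(seq(70, floor_val, length.out = n_half + 1),
             seq(floor_val + 2, 70, length.out = n_half))
    area <- c(area, a); val <- c(val, v)
  }
  SurfactometryTrace(seq_along(area) - 1, area, val, measureKind = kind)
}

test_that("cycleExtrema extracts per-cycle peaks in order, from raw samples", {
  tr <- make_cycle_trace(70)
  ext <- cycleExtrema(tr, segmentCycles(tr))
  expect_equal(ext$pi_max, 70)
  expect_equal(ext$area_at_extremum, 5)

  tr2 <- make_cycle_trace(c(60, 65))
  ext2 <- cycleExtrema(tr2, segmentCycles(tr2))
  expect_equal(ext2$pi_max, c(60, 65))

  trc <- make_cycle_trace(0, kind = "tension", floor_val = 7)
  extc <- cycleExtrema(trc, segmentCycles(trc))
  expect_equal(extc$gamma_min, 7)

  const <- SurfactometryTrace(0:9, rep(10, 10), rep(1, 10))
  suppressWarnings(cyc0 <- segmentCycles(const))
  expect_warning(e0 <- cycleExtrema(const, cyc0), "no cycles")
  expect_identical(nrow(e0), 0L)
})

test_that("modulusCurve recovers the closed-form kappa of canonical isotherms", {
  for (k0 in c(50, 100, 150)) {
    Pi <- seq(0.25, 50, length.out = 200)
    A <- 200 * exp(-Pi / k0)
    mc <- modulusCurve(A, Pi)
    interior <- 5:(length(mc@kappaRaw) - 4L)
    expect_lt(max(abs(mc@kappaRaw[interior] - k0)) / k0, 0.01)
  }
  # linear isotherm Pi = a - b A: kappa = b * A elementwise (exact
  # because centered differences are exact for linear functions)
  A <- seq(20, 10, length.out = 50)
  Pi <- 60 - 2 * A
  mc <- modulusCurve(A, Pi)
  expect_equal(mc@kappaRaw, 2 * A, tolerance = 1e-9)
  # tension input converts through gamma0 first
  mct <- modulusCurve(A, 72.8 - Pi, measureKind = "tension")
  expect_equal(mct@kappaRaw, mc@kappaRaw, tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing reduces noise on the modulus curve", {
  # sigma = 0.2 mN/m on a 200-point kappa0 = 100 isotherm: raw
  # pointwise derivative noise exceeds the signal, smoothing shrinks
  # the worst-case deviation and centers the curve on kappa0
  set.seed(42)
  Pi <- seq(0.25, 50, by = 0.25)
  A <- 200 * exp(-Pi / 100)
  mc <- modulusCurve(A, Pi + rnorm(length(Pi), 0, 0.2), sgWindow = 9)
  interior <- 10:(length(Pi) - 9L)
  dev_raw <- max(abs(mc@kappaRaw[interior] - 100))
  dev_sm <- max(abs(mc@kappaSmoothed[interior] - 100))
  expect_lt(dev_sm, dev_raw)
  expect_lt(abs(median(mc@kappaSmoothed[interior]) - 100) / 100, 0.05)
})

test_that("modulusCurve validates monotonicity and window size", {
  A <- c(10, 9, 9.5, 8, 7, 6, 5, 4, 3, 2)
  expect_error(modulusCurve(A, seq(0, 45, by = 5)), "monotone")
  expect_error(modulusCurve(seq(10, 9, length.out = 5), 1:5),
               "window")
  # duplicate areas from plateau sampling are averaged, not fatal
  A2 <- c(10, 9, 9, 8, 7, 6, 5, 4, 3, 2)
  mc <- modulusCurve(A2, seq(0, 45, by = 5))
  expect_length(mc@pressure, 9L)
})

test_that("globalCompressibility is the endpoint slope magnitude", {
  A <- seq(30, 24, length.out = 25)
  gamma <- 72 - 2 * (30 - A)
  g <- globalCompressibility(A, gamma)
  expect_equal(as.numeric(g), 2)
  expect_equal(attr(g, "signed"), 2)
  expect_equal(as.numeric(globalCompressibility(A, rep(50, 25))), 0)
  expect_error(globalCompressibility(c(10, 10), c(1, 2)), "degenerate")
})

test_that("hysteresis interpolates the half-maximum crossing on both branches", {
  # reversible loop: expansion identical to compression
  A <- seq(10, 5, length.out = 21)
  v <- seq(0, 60, length.out = 21)
  expect_identical(hysteresis(A, v, rev(A), rev(v)), 0)
  # rigid -3 shift of the expansion branch at every level
  expect_equal(hysteresis(A, v, rev(A) - 3, rev(v)), 3)
  # piecewise-linear loop with hand-computed crossings: level = 25,
  # compression crosses between (8, 20) and (7, 30) -> A = 7.5;
  # expansion between (5.5, 30) and (6.5, 20) -> A = 6
  cA <- c(10, 9, 8, 7, 6);  cV <- c(0, 10, 20, 30, 50)
  eA <- c(4.5, 5.5, 6.5, 8, 10); eV <- c(50, 30, 20, 8, 0)
  expect_equal(hysteresis(cA, cV, eA, eV, level = 25), 7.5 - 6)
  # coverage errors name the branch that misses the level
  expect_error(hysteresis(cA, cV, eA, eV, level = 60), "compression")
  expect_error(hysteresis(cA, cV, eA, c(25, 20, 15, 8, 0), level = 28),
               "expansion")
})

test_that("hysteresis is additive under rigid shifts of the expansion branch", {
  g <- generateTrace(traceSpec("LBT", nCycles = 1, samplingRate = 2.5))
  cyc <- cycleTable(segmentCycles(g$trace))
  ci <- seq(cyc$comp_start[1], cyc$comp_end[1])
  ei <- seq(cyc$comp_end[1], cyc$exp_end[1])
  a <- g$trace@area; v <- g$trace@surfaceValue
  h0 <- hysteresis(a[ci], v[ci], a[ei], v[ei])
  for (s in c(1, 2.5, 7))
    expect_equal(hysteresis(a[ci], v[ci], a[ei] - s, v[ei]), h0 + s,
                 tolerance = 1e-9)
})

test_that("summarizeWindows averages the stated windows and skips incomplete cycles", {
  m <- data.frame(cycle = 1:10, gamma_min = 10:1,
                  complete = rep(TRUE, 10))
  s <- summarizeWindows(m, firstN = 5, lastN = 5)
  expect_equal(s$mean[s$window == "first_5" & s$metric == "gamma_min"], 8)
  expect_equal(s$mean[s$window == "last_5" & s$metric == "gamma_min"], 3)
  expect_equal(s$se[s$window == "first_5"][1],
               sd(10:6) / sqrt(5))
  # reordering within a window leaves the mean unchanged
  m2 <- m[c(3, 1, 5, 2, 4, 6:10), ]
  s2 <- summarizeWindows(m2, firstN = 5, lastN = 5)
  expect_equal(s2$mean, s$mean)
  # incomplete cycles are skipped
  m3 <- m; m3$complete[1] <- FALSE
  s3 <- summarizeWindows(m3, firstN = 5, lastN = 5)
  expect_equal(s3$mean[s3$window == "first_5" & s3$metric == "gamma_min"],
               mean(9:5))
  expect_error(summarizeWindows(m, firstN = 11), "window")
})

test_that("relativeToControl is a guarded ratio", {
  expect_equal(as.numeric(relativeToControl(6, 10)), 0.6)
  expect_equal(as.numeric(relativeToControl(4.2, 4.2)), 1)
  expect_equal(as.numeric(relativeToControl(0, 10)), 0)
  expect_identical(attr(relativeToControl(1, 2, "SLS first cycle"),
                        "reference_label"), "SLS first cycle")
  expect_error(relativeToControl(1, 0), "non-zero")
})
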