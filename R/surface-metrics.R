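#' Per-cycle surface-measure extrema
#'
#' Extracts, for every cycle, the maximum surface pressure (LBT traces)
#' or minimum surface tension (CSD traces) together with the area at
#' which it occurs. Values are taken from raw samples; no interpolation
#' is applied.
#'
#' @param trace a [SurfactometryTrace-class].
#' @param cycles the matching [CycleSet-class] from [segmentCycles()].
#' @return A data.frame with one row per cycle: `cycle`, `pi_max` or
#'   `gamma_min` (per the trace's measure kind), `area_at_extremum`,
#'   `complete`. Zero complete cycles yield an empty data.frame with a
#'   warning.
#' @export
cycleExtrema <- function(trace, cycles) {
  stopifnot(is(trace, "SurfactometryTrace"), is(cycles, "CycleSet"))
  cy <- cycles@cycles
  col <- if (trace@measureKind == "pressure") "pi_max" else "gamma_min"
  out <- data.frame(cycle = integer(), value = numeric(),
                    area_at_extremum = numeric(), complete = logical())
  names(out)[2] <- col
  if (!nrow(cy)) {
    warning("no cycles to extract extrema from")
    return(out)
  }
  for (k in seq_len(nrow(cy))) {
    idx <- c(.branch_indices(cy[k, ], "compression"),
             .branch_indices(cy[k, ], "expansion"))
    v <- trace@surfaceValue[idx]
    j <- if (trace@measureKind == "pressure") which.max(v) else
      which.min(v)
    row <- data.frame(cycle = cy$cycle[k], value = v[j],
                      area_at_extremum = trace@area[idx[j]],
                      complete = cy$complete[k])
    names(row)[2] <- col
    out <- rbind(out, row)
  }
  out
}

#' Pointwise compressibility modulus along an isotherm branch
#'
#' The compressibility modulus kappa = -A (dPi/dA) (mN/m), the
#' reciprocal of the compressibility C = -(1/A)(dA/dPi), measures a
#' film's resistance to lateral compression. The derivative is evaluated
#' by centered finite differences (one-sided at the ends) on the branch
#' after collapsing duplicate areas, and the curve is reported against
#' the surface pressure, raw and Savitzky-Golay smoothed (9-point
#' window, order 3 by default).
#'
#' Tension-valued input is converted to pressure with `gamma0` first.
#'
#' @param area,surfaceValue numeric arrays of one branch (typically the
#'   first-cycle compression branch, where the modulus is best defined).
#' @param measureKind `"pressure"` or `"tension"`.
#' @param sgWindow,sgOrder Savitzky-Golay parameters.
#' @param branch label stored in the result.
#' @param gamma0 water reference for tension input, mN/m.
#' @return A [ModulusCurve-class].
#' @examples
#' Pi <- seq(1, 50, length.out = 200)
#' A <- 200 * exp(-Pi / 100)      # kappa0 = 100 isotherm
#' mc <- modulusCurve(A, Pi)      # kappa constant at 100
#' @export
modulusCurve <- function(area, surfaceValue,
                         measureKind = c("pressure", "tension"),
                         sgWindow = 9L, sgOrder = 3L,
                         branch = c("compression", "expansion"),
                         gamma0 = 72.8) {
  measureKind <- match.arg(measureKind)
  branch <- match.arg(branch)
  if (length(area) != length(surfaceValue))
    stop("area and surfaceValue must align")
  pressure <- if (measureKind == "tension")
    convertMeasure(surfaceValue, "tension", gamma0) else surfaceValue
  ## collapse runs of duplicate areas (plateau sampling) by averaging
  ## the pressure over each run, keeping the branch's sample order
  grp <- cumsum(c(TRUE, diff(area) != 0))
  A <- as.numeric(tapply(area, grp, `[`, 1L))
  P <- as.numeric(tapply(pressure, grp, mean))
  dA <- diff(A)
  bad <- which(sign(dA) != sign(dA[1]))
  if (any(dA == 0) || length(bad)) {
    stop(sprintf("branch area not strictly monotone after cleaning (first violation at point %d)",
                 (if (length(bad)) bad[1] else which(dA == 0)[1]) + 1L))
  }
  n <- length(A)
  if (n < sgWindow)
    stop(sprintf("branch of %d points shorter than Savitzky-Golay window %d",
                 n, sgWindow))
  dPdA <- numeric(n)
  dPdA[1] <- (P[2] - P[1]) / (A[2] - A[1])
  dPdA[n] <- (P[n] - P[n - 1]) / (A[n] - A[n - 1])
  if (n > 2)
    dPdA[2:(n - 1)] <- (P[3:n] - P[1:(n - 2)]) / (A[3:n] - A[1:(n - 2)])
  kappa <- -A * dPdA
  new("ModulusCurve", pressure = P, kappaRaw = kappa,
      kappaSmoothed = savitzkyGolay(kappa, sgWindow, sgOrder),
      branch = branch)
}

#' Global compressibility of one iso-cycle
#'
#' For sparsely sampled CSD iso-cycles a pointwise modulus is not well
#' defined; instead a single global slope between the minimum- and
#' maximum-tension points of the compression branch, Delta gamma /
#' Delta A, is used. The value returned is the positive magnitude; the
#' signed slope is attached as attribute `"signed"`.
#'
#' @param area,surfaceValue numeric arrays of the compression branch
#'   (tension or pressure values both work; the slope magnitude is
#'   unit-faithful to the input).
#' @return Scalar |Delta gamma / Delta A| (mN/m per area unit) with
#'   attribute `signed`.
#' @export
globalCompressibility <- function(area, surfaceValue) {
  if (length(area) != length(surfaceValue) || length(area) < 2L)
    stop("need aligned arrays of at least 2 points")
  i_min <- which.min(surfaceValue)
  i_max <- which.max(surfaceValue)
  if (surfaceValue[i_min] == surfaceValue[i_max])
    return(structure(0, signed = 0))
  dA <- area[i_max] - area[i_min]
  if (dA == 0)
    stop("degenerate cycle: extrema of the surface measure occur at the same area")
  slope <- (surfaceValue[i_max] - surfaceValue[i_min]) / dA
  structure(abs(slope), signed = slope)
}

#' Loop hysteresis at the half-maximum level
#'
#' The area difference Delta A between the compression and expansion
#' branches of one iso-cycle, evaluated at half of the cycle's maximum
#' surface measure (pressure for LBT, tension for CSD). The area on each
#' branch is located by linear interpolation at that level; Delta A =
#' A_compression - A_expansion, positive when the expansion branch lies
#' inside the compression branch.
#'
#' @param compArea,compValue compression-branch arrays.
#' @param expArea,expValue expansion-branch arrays.
#' @param level optional explicit level (mN/m); default is half the
#'   maximum surface measure over both branches.
#' @return Scalar Delta A in the trace's area units.
#' @export
hysteresis <- function(compArea, compValue, expArea, expValue,
                       level = NULL) {
  if (is.null(level))
    level <- 0.5 * max(c(compValue, expValue))
  a_comp <- .area_at_level(compArea, compValue, level, "compression")
  a_exp <- .area_at_level(expArea, expValue, level, "expansion")
  a_comp - a_exp
}

## first crossing of `level` along the branch, linearly interpolated
.area_at_level <- function(area, value, level, label) {
  if (length(area) != length(value) || length(area) < 2L)
    stop(sprintf("%s branch needs at least 2 aligned points", label))
  hit <- which(value == level)
  if (length(hit))
    return(area[hit[1]])
  s <- sign(value - level)
  cross <- which(s[-1] * s[-length(s)] < 0)
  if (!length(cross))
    stop(sprintf("%s branch does not cross the level %.3f mN/m", label,
                 level))
  i <- cross[1]
  w <- (level - value[i]) / (value[i + 1] - value[i])
  area[i] + w * (area[i + 1] - area[i])
}

#' Per-cycle metrics table for a segmented trace
#'
#' Convenience wrapper computing, for every cycle of a segmented trace,
#' the surface-measure extremum, the global compressibility of the
#' compression branch, and (for complete cycles) the half-maximum
#' hysteresis.
#'
#' @param trace a [SurfactometryTrace-class].
#' @param cycles the matching [CycleSet-class].
#' @return data.frame: `cycle`, `pi_max`/`gamma_min`,
#'   `area_at_extremum`, `global_compressibility`, `hysteresis_area`
#'   (NA for incomplete cycles), `complete`.
#' @export
cycleMetrics <- function(trace, cycles) {
  ext <- cycleExtrema(trace, cycles)
  cy <- cycles@cycles
  gc <- rep(NA_real_, nrow(cy))
  hy <- rep(NA_real_, nrow(cy))
  for (k in seq_len(nrow(cy))) {
    ci <- .branch_indices(cy[k, ], "compression")
    gc[k] <- globalCompressibility(trace@area[ci], trace@surfaceValue[ci])
    ei <- .branch_indices(cy[k, ], "expansion", includeVertex = TRUE)
    if (cy$complete[k] && length(ei) >= 2L)
      hy[k] <- tryCatch(
        hysteresis(trace@area[ci], trace@surfaceValue[ci],
                   trace@area[ei], trace@surfaceValue[ei]),
        error = function(e) NA_real_)
  }
  ext$global_compressibility <- gc
  ext$hysteresis_area <- hy
  ext[c(1, 2, 3, 5, 6, 4)]
}

#' Window means of per-cycle metrics
#'
#' Mean and standard error of each metric over the first `firstN` and
#' last `lastN` complete cycles (incomplete cycles are skipped), the
#' summary used to compare early and late iso-cycles.
#'
#' @param metrics data.frame from [cycleMetrics()] (or any data.frame
#'   with a `cycle` column, a `complete` column and numeric metrics).
#' @param firstN,lastN window sizes in cycles.
#' @return data.frame with one row per (window, metric): columns
#'   `window`, `metric`, `mean`, `se`, `n`.
#' @export
summarizeWindows <- function(metrics, firstN = 5L, lastN = 5L) {
  stopifnot(is.data.frame(metrics))
  keep <- if ("complete" %in% names(metrics)) metrics$complete else
    rep(TRUE, nrow(metrics))
  m <- metrics[keep, , drop = FALSE]
  n_avail <- nrow(m)
  if (n_avail < max(firstN, lastN))
    stop(sprintf("window of %d cycles requested but only %d complete cycles available",
                 max(firstN, lastN), n_avail))
  num_cols <- setdiff(names(m)[vapply(m, is.numeric, logical(1))],
                      "cycle")
  one <- function(rows, label) {
    do.call(rbind, lapply(num_cols, function(cc) {
      v <- m[rows, cc]
      v <- v[is.finite(v)]
      data.frame(window = label, metric = cc, mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)), n = length(v))
    }))
  }
  rbind(one(seq_len(firstN), sprintf("first_%d", firstN)),
        one(seq.int(n_avail - lastN + 1L, n_avail),
            sprintf("last_%d", lastN)))
}

#' Metric relative to a control value
#'
#' Simple ratio used for reporting metrics relative to a reference
#' condition's first cycle (e.g. hysteresis relative to the untreated
#' surfactant's first cycle).
#'
#' @param value numeric metric value(s).
#' @param controlValue scalar reference value, non-zero.
#' @param referenceLabel label recorded with the result.
#' @return Numeric ratio(s) with attribute `reference_label`.
#' @export
relativeToControl <- function(value, controlValue,
                              referenceLabel = "control") {
  if (!is.finite(controlValue) || controlValue == 0)
    stop("control value must be finite and non-zero")
  structure(value / controlValue, reference_label = referenceLabel)
}
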