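## Trace CSV dialect: an optional block of '# key=value' header lines
## followed by a regular CSV with columns time_s, area, surface_mN_per_m.
## Recognized header keys: device, measure_kind, temperature_C,
## total_area_cm2 (LBT areas stored as fractions of the total trough
## area); any other key is kept verbatim in the metadata.

.DIALECTS <- list(
  lbt_csv     = list(device = "LBT", measure_kind = "pressure"),
  csd_csv     = list(device = "CSD", measure_kind = "tension"),
  generic_csv = list(device = "generic", measure_kind = "pressure"))

.TRACE_COLS <- c("time_s", "area", "surface_mN_per_m")

.parse_header_value <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num) && nzchar(x)) num else x
}

#' Read a surfactometry trace from CSV
#'
#' Reads a time / area / surface-measure series exported from a
#' Langmuir-Blodgett trough (LBT, surface pressure vs. cm^2) or a
#' constrained sessile drop surfactometer (CSD, surface tension vs.
#' mm^2). The dialect sets the device and measure-kind defaults; explicit
#' `device` / `measure_kind` header keys override them. Rows containing
#' non-finite values are dropped and counted in the metadata key
#' `dropped_rows`. If the header carries `total_area_cm2`, areas are
#' interpreted as fractions of the total trough area and converted to
#' absolute cm^2 (the consumed key is kept as `total_area_cm2_applied`).
#'
#' @param path path to a trace CSV file.
#' @param dialect `"generic_csv"` (default), `"lbt_csv"` or `"csd_csv"`.
#' @return A [SurfactometryTrace-class] object.
#' @seealso [writeTrace()], [segmentCycles()]
#' @export
readTrace <- function(path, dialect = c("generic_csv", "lbt_csv",
                                        "csd_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop(sprintf("empty trace file: %s", path))
  is_hdr <- startsWith(lines, "#")
  header <- list()
  for (ln in sub("^#\\s*", "", lines[is_hdr])) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0)
      header[[trimws(substr(ln, 1, eq - 1))]] <-
        .parse_header_value(trimws(substr(ln, eq + 1, nchar(ln))))
  }
  body <- lines[!is_hdr]
  if (length(body) < 2L)
    stop(sprintf("trace file %s has a header but no data rows", path))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  missing_cols <- setdiff(.TRACE_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("trace file %s lacks required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))

  defaults <- .DIALECTS[[dialect]]
  dev <- as.character(header$device %||% defaults$device)
  kind <- as.character(header$measure_kind %||% defaults$measure_kind)
  temp <- as.numeric(header$temperature_C %||% NA_real_)
  meta <- header[setdiff(names(header),
                         c("device", "measure_kind", "temperature_C"))]

  keep <- is.finite(df$time_s) & is.finite(df$area) &
    is.finite(df$surface_mN_per_m)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L)
    stop(sprintf("trace file %s has fewer than 2 usable rows", path))
  if (is.unsorted(df$time_s))
    stop(sprintf("time column of %s is not non-decreasing (first violation at row %d)",
                 path, which(diff(df$time_s) < 0)[1] + 1L))
  area <- df$area
  if (!is.null(meta$total_area_cm2)) {
    area <- area * as.numeric(meta$total_area_cm2)
    names(meta)[names(meta) == "total_area_cm2"] <- "total_area_cm2_applied"
  }
  if (dropped > 0L)
    meta$dropped_rows <- dropped
  SurfactometryTrace(time = df$time_s, area = area,
                     surfaceValue = df$surface_mN_per_m,
                     measureKind = kind, device = dev, temperature = temp,
                     metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a surfactometry trace to CSV
#'
#' Writes the package's trace dialect: a `# key=value` header block
#' (device, measure kind, temperature, all metadata) followed by the
#' `time_s,area,surface_mN_per_m` table at full double precision, so
#' that `readTrace(writeTrace(x))` reproduces the arrays to better than
#' 1e-9 relative error and all metadata.
#'
#' @param trace a [SurfactometryTrace-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "SurfactometryTrace"))
  validObject(trace)
  hdr <- c(sprintf("# device=%s", trace@device),
           sprintf("# measure_kind=%s", trace@measureKind))
  if (!is.na(trace@temperature))
    hdr <- c(hdr, sprintf("# temperature_C=%.10g", trace@temperature))
  for (k in names(trace@metadata)) {
    v <- trace@metadata[[k]]
    v <- if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
    hdr <- c(hdr, sprintf("# %s=%s", k, v))
  }
  body <- sprintf("%.15g,%.15g,%.15g", trace@time, trace@area,
                  trace@surfaceValue)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(.TRACE_COLS, collapse = ","), body), con,
             useBytes = TRUE)
  invisible(path)
}

#' Convert between surface tension and surface pressure
#'
#' Surface pressure is the depression of surface tension below that of a
#' clean water interface: Pi = gamma0 - gamma. The same relation maps
#' back, so the conversion is an exact involution. The water reference at
#' a 20 degree C air-water interface is gamma0 = 72.8 mN/m.
#'
#' @param values numeric vector, mN/m.
#' @param from `"tension"` (returns pressure) or `"pressure"` (returns
#'   tension).
#' @param gamma0 surface tension of the clean water reference, mN/m.
#' @return Numeric vector, mN/m.
#' @examples
#' convertMeasure(0, from = "tension")    # Pi = 72.8
#' convertMeasure(50, from = "tension")   # Pi = 22.8
#' @export
convertMeasure <- function(values, from = c("tension", "pressure"),
                           gamma0 = 72.8) {
  from <- match.arg(from)
  if (!is.numeric(gamma0) || length(gamma0) != 1L || !is.finite(gamma0) ||
      gamma0 <= 0)
    stop("gamma0 must be a single positive finite value (mN/m)")
  if (any(!is.finite(values)))
    stop("surface values must be finite")
  gamma0 - values
}

#' Segment a trace into compression-expansion cycles
#'
#' Finds area reversals on a median-smoothed copy of the area series and
#' groups them into cycles (a compression branch followed by an
#' expansion branch). Reversals whose amplitude is below
#' `minAmplitudeFraction` of the global area range are treated as jitter
#' and ignored. A trailing cycle with a missing or truncated expansion
#' branch (reaching less than half the compression amplitude back) is
#' retained but flagged incomplete; a leading expansion segment before
#' the first compression is skipped.
#'
#' @param trace a [SurfactometryTrace-class] object with >= 4 samples.
#' @param minAmplitudeFraction reversal threshold as a fraction of the
#'   global area range (default 0.02).
#' @param smoothWindow centered moving-median window, points (odd,
#'   default 5).
#' @return A [CycleSet-class]. A constant-area trace yields zero cycles
#'   with the `constantArea` flag set and a warning, not an error.
#' @export
segmentCycles <- function(trace, minAmplitudeFraction = 0.02,
                          smoothWindow = 5L) {
  stopifnot(is(trace, "SurfactometryTrace"))
  if (length(trace@time) < 4L)
    stop("need at least 4 samples to segment cycles")
  if (minAmplitudeFraction <= 0 || minAmplitudeFraction >= 1)
    stop("minAmplitudeFraction must lie in (0, 1)")
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow %% 2L == 0L) smoothWindow <- smoothWindow + 1L
  a <- if (smoothWindow >= 3L && length(trace@area) > smoothWindow)
    as.numeric(stats::runmed(trace@area, smoothWindow)) else trace@area
  rng <- max(a) - min(a)
  empty <- data.frame(cycle = integer(), comp_start = integer(),
                      comp_end = integer(), exp_start = integer(),
                      exp_end = integer(), complete = logical())
  if (rng <= 0) {
    warning("constant-area trace: no cycles found")
    return(new("CycleSet", cycles = empty, constantArea = TRUE))
  }
  thr <- minAmplitudeFraction * rng
  piv <- .zigzag_pivots(a, thr)
  ## the moving median flattens reversal tips: snap each pivot to the
  ## raw-area extremum within half a window of the smoothed pivot
  piv <- .refine_pivots(piv, a, trace@area, smoothWindow)
  if (length(piv) < 2L) {
    warning("no area excursion above the amplitude threshold")
    return(new("CycleSet", cycles = empty, constantArea = TRUE))
  }
  ## segment directions between consecutive pivots
  dirs <- sign(a[piv[-1]] - a[piv[-length(piv)]])
  seg_start <- piv[-length(piv)]
  seg_end <- piv[-1]
  i <- 1L
  if (dirs[1] > 0) i <- 2L          # skip a leading expansion
  rows <- list()
  cyc <- 0L
  prev_end <- 0L                    # keep consecutive cycles disjoint
  while (i <= length(dirs)) {
    if (dirs[i] >= 0) { i <- i + 1L; next }
    cyc <- cyc + 1L
    cs <- max(seg_start[i], prev_end + 1L); ce <- seg_end[i]
    if (i + 1L <= length(dirs) && dirs[i + 1L] > 0) {
      es <- min(seg_start[i + 1L] + 1L, seg_end[i + 1L])
      ee <- seg_end[i + 1L]
      comp_amp <- a[cs] - a[ce]
      exp_amp <- a[ee] - a[seg_start[i + 1L]]
      rows[[cyc]] <- data.frame(cycle = cyc, comp_start = cs,
                                comp_end = ce, exp_start = es,
                                exp_end = ee,
                                complete = exp_amp >= 0.5 * comp_amp)
      prev_end <- ee
      i <- i + 2L
    } else {
      prev_end <- ce
      rows[[cyc]] <- data.frame(cycle = cyc, comp_start = cs,
                                comp_end = ce, exp_start = NA_integer_,
                                exp_end = NA_integer_, complete = FALSE)
      i <- i + 1L
    }
  }
  cycles <- if (length(rows)) do.call(rbind, rows) else empty
  new("CycleSet", cycles = cycles, constantArea = FALSE)
}

## Reversal detection: commit the running extremum as a pivot once the
## series has moved away from it by at least `thr` in the opposite
## direction (standard zig-zag simplification; robust to jitter below
## the threshold). Returns pivot indices in order; the first pivot is
## the extremum of the opening segment.
.zigzag_pivots <- function(a, thr) {
  n <- length(a)
  piv <- integer(0)
  hi <- 1L; lo <- 1L
  dir <- 0L  # +1 rising since last pivot, -1 falling, 0 undecided
  for (i in 2:n) {
    if (a[i] > a[hi]) hi <- i
    if (a[i] < a[lo]) lo <- i
    if (dir <= 0L && a[i] - a[lo] >= thr) {
      piv <- c(piv, lo); dir <- 1L; hi <- i; lo <- i
    } else if (dir >= 0L && a[hi] - a[i] >= thr) {
      piv <- c(piv, hi); dir <- -1L; hi <- i; lo <- i
    }
  }
  last <- if (dir == 1L) hi else if (dir == -1L) lo else n
  if (length(piv) && last != piv[length(piv)] &&
      abs(a[last] - a[piv[length(piv)]]) >= thr)
    piv <- c(piv, last)
  piv
}

.refine_pivots <- function(piv, smoothed, raw, window) {
  if (length(piv) < 2L)
    return(piv)
  n <- length(raw)
  out <- piv
  for (k in seq_along(piv)) {
    ref <- if (k < length(piv)) piv[k + 1L] else piv[k - 1L]
    is_max <- if (k < length(piv)) smoothed[piv[k]] > smoothed[ref]
    else smoothed[piv[k]] > smoothed[ref]
    lo <- max(1L, piv[k] - window)
    hi <- min(n, piv[k] + window)
    idx <- lo:hi
    out[k] <- idx[if (is_max) which.max(raw[idx]) else
      which.min(raw[idx])]
  }
  ## keep pivots strictly increasing; fall back on collision
  bad <- c(FALSE, diff(out) <= 0)
  out[bad] <- piv[bad]
  out[!duplicated(out)]
}

## Branch extraction shared by the metric functions. Stored branch
## ranges are disjoint (expansion starts one sample after the shared
## turning point); includeVertex adds the turning-point sample back so
## both branches span the turning level for interpolation.
.branch_indices <- function(cycle_row, branch = c("compression",
                                                  "expansion"),
                            includeVertex = FALSE) {
  branch <- match.arg(branch)
  if (branch == "compression")
    return(seq.int(cycle_row$comp_start, cycle_row$comp_end))
  if (is.na(cycle_row$exp_start))
    return(integer(0))
  s <- if (includeVertex) cycle_row$comp_end else cycle_row$exp_start
  seq.int(s, cycle_row$exp_end)
}
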