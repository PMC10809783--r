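## Ground-truth-labeled synthetic inputs. Protocol defaults mirror the
## instruments' stated operating points: LBT, ten cycles at 150 cm^2/min
## between 215 and 56 cm^2 (triangular barrier schedule); CSD, <= 20%
## area reduction at up to 20 cycles/min, 120 s records at 5 frames/s
## (sinusoidal drop oscillation).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Largest-remainder apportionment of a lipid composition
#'
#' Splits a total molecule count across species according to molar
#' ratios so the counts sum exactly to the total (largest-remainder
#' rounding, ties broken by species order). E.g. 149 lipids at molar
#' ratios 68:20:10:2 of DPPC:POPC:POPG:cholesterol give 101/30/15/3.
#'
#' @param total total count, >= 1.
#' @param ratios nonnegative ratios, not all zero (named or not).
#' @return Integer counts summing to `total`, same names as `ratios`.
#' @examples
#' apportionComposition(149, c(DPPC = 68, POPC = 20, POPG = 10, CHOL = 2))
#' @export
apportionComposition <- function(total, ratios) {
  total <- as.integer(total)
  if (is.na(total) || total < 1L)
    stop("total must be a positive count")
  if (any(ratios < 0) || all(ratios == 0) || any(!is.finite(ratios)))
    stop("ratios must be nonnegative, finite, and not all zero")
  quota <- total * ratios / sum(ratios)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(ratios))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(ratios))
}

#' Waters per lipid of a simulation system
#'
#' @param nWaters water molecule count.
#' @param nLipidsTotal total lipid count (both leaflets), > 0.
#' @return Ratio with attribute `rounded` (nearest integer), e.g.
#'   27040 waters over 2 x 149 lipids ~ 91 per lipid.
#' @export
watersPerLipid <- function(nWaters, nLipidsTotal) {
  if (nLipidsTotal <= 0)
    stop("lipid count must be positive")
  r <- nWaters / nLipidsTotal
  structure(r, rounded = round(r))
}

#' Specification of a synthetic surfactometry trace
#'
#' Captures the generator's stated world. LBT defaults: 10 triangular
#' compression-expansion cycles at 150 cm^2/min between 215 and 56
#' cm^2, sampled at 1 Hz, surface pressure output. CSD defaults: 20
#' sinusoidal cycles/min with a 20% area reduction around a 30 mm^2
#' drop, 40 cycles (120 s) at 5 frames/s, surface tension output. The
#' surface measure follows the kappa0-exponential isotherm
#' `Pi = kappa0 log(A_max / A)` capped at `piMaxTarget`, with optional
#' kink plateaus and a rigid expansion-branch area shift that produces
#' exactly `hysteresisShift` of loop hysteresis.
#'
#' @param device `"LBT"` or `"CSD"`.
#' @param nCycles cycle count.
#' @param areaRange c(min, max) in the device's area unit.
#' @param rate cm^2/min (LBT) or cycles/min (CSD).
#' @param kappa0 isotherm stiffness, mN/m. Device defaults: 100 (LBT,
#'   where the barriers sweep a 3.8-fold area range) and 280 (CSD,
#'   where a functional film must reach low tension within the 20%
#'   area excursion).
#' @param piMaxTarget surface-pressure cap, mN/m, must be < gamma0.
#'   Device defaults 60 (LBT) and 65 (CSD; tension floor ~7.8 mN/m,
#'   the functional-surfactant regime).
#' @param hysteresisShift rigid expansion area shift, area units.
#' @param kinkPositions optional plateau onsets, mN/m (width
#'   `kinkWidth`, slope 0.1 inside the plateau).
#' @param kinkWidth plateau width, mN/m.
#' @param noiseSd Gaussian noise sd on the surface measure, mN/m.
#' @param seed RNG seed for the noise.
#' @param samplingRate Hz.
#' @param gamma0 water reference, mN/m.
#' @return A validated `traceSpec` list.
#' @export
traceSpec <- function(device = c("LBT", "CSD"), nCycles = NULL,
                      areaRange = NULL, rate = NULL, kappa0 = NULL,
                      piMaxTarget = NULL, hysteresisShift = 0,
                      kinkPositions = numeric(0), kinkWidth = 3,
                      noiseSd = 0, seed = 1L, samplingRate = NULL,
                      gamma0 = 72.8) {
  device <- match.arg(device)
  if (device == "LBT") {
    nCycles <- nCycles %||% 10L
    areaRange <- areaRange %||% c(56, 215)
    rate <- rate %||% 150
    samplingRate <- samplingRate %||% 1
    kappa0 <- kappa0 %||% 100
    piMaxTarget <- piMaxTarget %||% 60
  } else {
    nCycles <- nCycles %||% 40L
    areaRange <- areaRange %||% c(24, 30)
    rate <- rate %||% 20
    samplingRate <- samplingRate %||% 5
    kappa0 <- kappa0 %||% 280
    piMaxTarget <- piMaxTarget %||% 65
  }
  if (length(areaRange) != 2L || any(areaRange <= 0) ||
      areaRange[1] >= areaRange[2])
    stop("areaRange must be positive and ordered (min, max)")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (piMaxTarget >= gamma0)
    stop(sprintf("piMaxTarget %.1f mN/m infeasible: surface pressure cannot exceed gamma0 = %.1f",
                 piMaxTarget, gamma0))
  if (kappa0 <= 0) stop("kappa0 must be positive")
  if (device == "CSD" && (1 - areaRange[1] / areaRange[2]) > 0.2 + 1e-12)
    warning("CSD area reduction exceeds the 20% protocol bound")
  list(device = device, nCycles = as.integer(nCycles),
       areaRange = areaRange, rate = rate, kappa0 = kappa0,
       piMaxTarget = piMaxTarget, hysteresisShift = hysteresisShift,
       kinkPositions = sort(kinkPositions), kinkWidth = kinkWidth,
       noiseSd = noiseSd, seed = as.integer(seed),
       samplingRate = samplingRate, gamma0 = gamma0)
}

## monotone kink transform: slope 0.1 inside [p, p + w] per kink
.apply_kinks <- function(pi_raw, positions, width, slope = 0.1) {
  out <- pi_raw
  for (p in positions)
    out <- out - (1 - slope) * (pmin(pmax(out, p), p + width) - p)
  out
}

#' Generate a synthetic surfactometry trace with ground truth
#'
#' Area follows the device schedule (triangular ramps for LBT,
#' sinusoidal for CSD); the surface measure follows the
#' kappa0-exponential isotherm capped at the target maximum pressure,
#' the expansion branch is rigidly shifted in area by the requested
#' hysteresis, and seeded Gaussian noise is added last. The attached
#' ground truth carries every construction parameter, so analysis
#' round-trips can be scored without re-derivation.
#'
#' @param spec a [traceSpec()] list.
#' @return list with `trace` (a [SurfactometryTrace-class]) and
#'   `groundTruth` (named list).
#' @examples
#' g <- generateTrace(traceSpec("LBT", nCycles = 3))
#' segmentCycles(g$trace)
#' @export
generateTrace <- function(spec) {
  a_min <- spec$areaRange[1]; a_max <- spec$areaRange[2]
  if (spec$device == "LBT") {
    period <- 2 * (a_max - a_min) / (spec$rate / 60)
  } else {
    period <- 60 / spec$rate
  }
  duration <- spec$nCycles * period
  ## a recorder running T seconds at rate f captures T*f frames
  time <- seq_len(round(duration * spec$samplingRate)) /
    spec$samplingRate - 1 / spec$samplingRate
  phase <- (time %% period) / period
  if (spec$device == "LBT") {
    area <- ifelse(phase <= 0.5, a_max - (a_max - a_min) * 2 * phase,
                   a_min + (a_max - a_min) * 2 * (phase - 0.5))
    expanding <- phase > 0.5
  } else {
    area <- a_min + (a_max - a_min) * (1 + cos(2 * pi * phase)) / 2
    expanding <- phase > 0.5
  }
  a_eff <- area + ifelse(expanding, spec$hysteresisShift, 0)
  pi_raw <- spec$kappa0 * log(a_max / a_eff)
  pi_k <- .apply_kinks(pi_raw, spec$kinkPositions, spec$kinkWidth)
  pi_val <- pmin(pi_k, spec$piMaxTarget)
  pi_val <- pmax(pi_val, -4.9)
  noise <- if (spec$noiseSd > 0)
    .with_seed(spec$seed, stats::rnorm(length(time), 0, spec$noiseSd))
  else 0
  if (spec$device == "CSD") {
    value <- pmin(pmax(spec$gamma0 - pi_val + noise, 0), 100)
    kind <- "tension"
  } else {
    value <- pmin(pmax(pi_val + noise, -5), 100)
    kind <- "pressure"
  }
  trace <- SurfactometryTrace(
    time = time, area = area, surfaceValue = value, measureKind = kind,
    device = spec$device, temperature = if (spec$device == "CSD") 25
    else 20,
    metadata = list(generator = "monosurf", seed = spec$seed))
  pi_max_true <- min(spec$kappa0 * log(a_max / a_min), spec$piMaxTarget)
  gt <- list(kappa0 = spec$kappa0, hysteresis = spec$hysteresisShift,
             n_cycles = spec$nCycles, pi_max = pi_max_true,
             gamma_min = spec$gamma0 - pi_max_true,
             pi_cap = spec$piMaxTarget, device = spec$device,
             noise_sd = spec$noiseSd, seed = spec$seed,
             sampling_rate = spec$samplingRate, period_s = period)
  list(trace = trace, groundTruth = gt)
}

#' Generate a synthetic gamma_min decay series with ground truth
#'
#' `y(t) = plateau + sum_i a_i 2^(-t/thalf_i) + noise`, the model used
#' for the decay of the per-cycle minimum surface tension across
#' iso-cycles (half-life magnitudes in the tens to hundreds of seconds).
#'
#' @param plateau mN/m.
#' @param amplitudes nonnegative amplitudes, mN/m.
#' @param halfLives positive half-lives, s (same length).
#' @param duration record length, s (default 120, a CSD run).
#' @param rate sampling rate, Hz (default 5).
#' @param noiseSd Gaussian noise sd, mN/m.
#' @param seed RNG seed.
#' @return list with `times`, `values`, `groundTruth`.
#' @export
generateDecaySeries <- function(plateau, amplitudes, halfLives,
                                duration = 120, rate = 5, noiseSd = 0,
                                seed = 1L) {
  if (length(amplitudes) != length(halfLives))
    stop("amplitudes and halfLives must align")
  if (any(amplitudes < 0))
    stop("amplitudes must be nonnegative")
  if (any(halfLives <= 0) || duration <= 0)
    stop("halfLives and duration must be positive")
  times <- seq(0, duration, by = 1 / rate)
  y <- rep(plateau, length(times))
  for (i in seq_along(amplitudes))
    y <- y + amplitudes[i] * 2^(-times / halfLives[i])
  if (noiseSd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(times), 0, noiseSd))
  list(times = times, values = y,
       groundTruth = list(plateau = plateau, amplitudes = amplitudes,
                          half_lives = halfLives, noise_sd = noiseSd,
                          seed = seed))
}

#' Write a ground-truth sidecar JSON
#'
#' @param groundTruth named list as attached by the generators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
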