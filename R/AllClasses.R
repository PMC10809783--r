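## Central S4 containers. Units: traces carry seconds / instrument area
## units (cm^2 for the Langmuir-Blodgett trough, mm^2 for the constrained
## sessile drop) / mN/m; coordinate frames are in nm throughout, with area
## per lipid reported in Angstrom^2 at a single conversion point.

.MEASURE_KINDS <- c("pressure", "tension")
.DEVICES <- c("LBT", "CSD", "generic")
.SPECIES <- c("DPPC", "POPC", "POPG", "CHOL", "PROTEIN", "CHEMICAL",
              "WATER", "ION")

#' SurfactometryTrace: a timestamped area / surface-measure series
#'
#' One run of a surfactometer: time (s), interfacial area (cm^2 for LBT,
#' mm^2 for CSD) and a surface measure (mN/m) that is either surface
#' pressure (Pi, LBT convention) or surface tension (gamma, CSD
#' convention).
#'
#' @slot time numeric, seconds, non-decreasing.
#' @slot area numeric, positive, instrument units.
#' @slot surfaceValue numeric, mN/m.
#' @slot measureKind `"pressure"` or `"tension"`.
#' @slot device `"LBT"`, `"CSD"` or `"generic"`.
#' @slot temperature numeric scalar, degrees C (NA if unknown).
#' @slot metadata named list of free-form header values.
#'
#' @examples
#' tr <- SurfactometryTrace(time = 0:3, area = c(10, 9, 8, 7),
#'                          surfaceValue = c(0, 5, 10, 15))
#' measureKind(tr)
#' @export
setClass("SurfactometryTrace",
  representation(time = "numeric", area = "numeric",
                 surfaceValue = "numeric", measureKind = "character",
                 device = "character", temperature = "numeric",
                 metadata = "list"))

setValidity("SurfactometryTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 2L)
    msg <- c(msg, "trace must contain at least 2 samples")
  if (length(object@area) != n || length(object@surfaceValue) != n)
    msg <- c(msg, "time, area and surfaceValue must have equal length")
  if (any(!is.finite(object@time)) || is.unsorted(object@time))
    msg <- c(msg, "time must be finite and non-decreasing")
  if (any(!is.finite(object@area)) || any(object@area <= 0))
    msg <- c(msg, "area must be finite and positive everywhere")
  if (any(!is.finite(object@surfaceValue)))
    msg <- c(msg, "surfaceValue must be finite")
  if (!object@measureKind %in% .MEASURE_KINDS)
    msg <- c(msg, "measureKind must be 'pressure' or 'tension'")
  if (!object@device %in% .DEVICES)
    msg <- c(msg, "device must be one of 'LBT', 'CSD', 'generic'")
  ## soft physical plausibility bands for the surface measure
  if (object@measureKind == "tension" &&
      (any(object@surfaceValue < 0) || any(object@surfaceValue > 100)))
    msg <- c(msg, "surface tension outside [0, 100] mN/m")
  if (object@measureKind == "pressure" &&
      (any(object@surfaceValue < -5) || any(object@surfaceValue > 100)))
    msg <- c(msg, "surface pressure outside [-5, 100] mN/m")
  if (length(msg)) msg else TRUE
})

#' @param time,area,surfaceValue numeric vectors of equal length.
#' @param measureKind,device,temperature,metadata see slots.
#' @rdname SurfactometryTrace-class
#' @return A `SurfactometryTrace` object.
#' @export
SurfactometryTrace <- function(time, area, surfaceValue,
                               measureKind = "pressure",
                               device = "generic",
                               temperature = NA_real_,
                               metadata = list()) {
  new("SurfactometryTrace", time = as.numeric(time),
      area = as.numeric(area), surfaceValue = as.numeric(surfaceValue),
      measureKind = measureKind, device = device,
      temperature = as.numeric(temperature), metadata = metadata)
}

setMethod("length", "SurfactometryTrace", function(x) length(x@time))

#' @rdname accessors
#' @export
setMethod("measureKind", "SurfactometryTrace", function(x) x@measureKind)

#' @rdname accessors
#' @export
setMethod("device", "SurfactometryTrace", function(x) x@device)

#' @rdname accessors
#' @export
setMethod("traceMetadata", "SurfactometryTrace", function(x) x@metadata)

setMethod("show", "SurfactometryTrace", function(object) {
  cat(sprintf("SurfactometryTrace: %d samples over %.1f s (%s, %s)\n",
              length(object@time), diff(range(object@time)),
              object@device, object@measureKind))
  cat(sprintf("  area range [%.3g, %.3g], surface %s range [%.3g, %.3g] mN/m\n",
              min(object@area), max(object@area),
              object@measureKind, min(object@surfaceValue),
              max(object@surfaceValue)))
})

#' CycleSet: compression/expansion branch indices of a trace
#'
#' Result of [segmentCycles()]: one row per compression-expansion cycle
#' with index ranges into the parent trace. A trailing cycle whose
#' expansion is missing or truncated is retained but flagged incomplete;
#' downstream window summaries skip incomplete cycles.
#'
#' @slot cycles data.frame with columns `cycle`, `comp_start`, `comp_end`,
#'   `exp_start`, `exp_end` (NA when the expansion branch is absent) and
#'   `complete` (logical).
#' @slot constantArea logical; TRUE when the trace had no usable area
#'   excursion and no cycles were found.
#' @export
setClass("CycleSet",
  representation(cycles = "data.frame", constantArea = "logical"))

setValidity("CycleSet", function(object) {
  cy <- object@cycles
  need <- c("cycle", "comp_start", "comp_end", "exp_start", "exp_end",
            "complete")
  if (!all(need %in% names(cy)))
    return("cycles table missing required columns")
  if (nrow(cy) && any(cy$comp_end < cy$comp_start))
    return("compression ranges must be non-empty")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("nCycles", "CycleSet", function(x) nrow(x@cycles))

#' @rdname accessors
#' @export
setMethod("cycleTable", "CycleSet", function(x) x@cycles)

setMethod("show", "CycleSet", function(object) {
  n <- nrow(object@cycles)
  cat(sprintf("CycleSet: %d cycle(s), %d complete%s\n", n,
              sum(object@cycles$complete),
              if (object@constantArea) " [constant-area trace]" else ""))
})

#' ModulusCurve: pointwise compressibility modulus along a branch
#'
#' kappa = -A (dPi/dA) evaluated along one isotherm branch, reported
#' against the surface pressure, raw and Savitzky-Golay smoothed.
#'
#' @slot pressure numeric grid, mN/m.
#' @slot kappaRaw,kappaSmoothed numeric, mN/m.
#' @slot branch `"compression"` or `"expansion"`.
#' @export
setClass("ModulusCurve",
  representation(pressure = "numeric", kappaRaw = "numeric",
                 kappaSmoothed = "numeric", branch = "character"))

setValidity("ModulusCurve", function(object) {
  if (length(object@pressure) != length(object@kappaRaw) ||
      length(object@pressure) != length(object@kappaSmoothed))
    return("pressure, kappaRaw and kappaSmoothed must align")
  TRUE
})

setMethod("show", "ModulusCurve", function(object) {
  cat(sprintf("ModulusCurve (%s branch): %d points, Pi in [%.1f, %.1f] mN/m\n",
              object@branch, length(object@pressure),
              min(object@pressure), max(object@pressure)))
  cat(sprintf("  smoothed kappa range [%.1f, %.1f] mN/m\n",
              min(object@kappaSmoothed), max(object@kappaSmoothed)))
})

#' DecayFit: mono/biexponential decay of minimum surface tension
#'
#' Least-squares fit of y(t) = plateau + sum_i a_i 2^(-t / thalf_i) with
#' nonnegative amplitudes, as used for gamma_min kinetics across
#' iso-cycles.
#'
#' @slot model `"mono"` or `"bi"`.
#' @slot plateau numeric, mN/m.
#' @slot amplitudes numeric, mN/m, one per phase, >= 0.
#' @slot halfLives numeric, seconds, sorted ascending.
#' @slot rss residual sum of squares, (mN/m)^2.
#' @slot nPoints number of data points fitted.
#' @slot selection list: model-selection details when `model = "auto"`
#'   was requested (F statistic, p value, AICc values).
#' @export
setClass("DecayFit",
  representation(model = "character", plateau = "numeric",
                 amplitudes = "numeric", halfLives = "numeric",
                 rss = "numeric", nPoints = "integer",
                 selection = "list"))

setValidity("DecayFit", function(object) {
  msg <- character()
  if (!object@model %in% c("mono", "bi"))
    msg <- c(msg, "model must be 'mono' or 'bi'")
  if (length(object@amplitudes) != length(object@halfLives))
    msg <- c(msg, "one half-life per amplitude required")
  if (any(object@amplitudes < 0))
    msg <- c(msg, "amplitudes must be nonnegative")
  if (any(object@halfLives <= 0) || is.unsorted(object@halfLives))
    msg <- c(msg, "half-lives must be positive and sorted ascending")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("halfLives", "DecayFit", function(x) x@halfLives)

#' @rdname accessors
#' @export
setMethod("decayModel", "DecayFit", function(x) x@model)

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit (%sexponential): plateau %.3f mN/m, rss %.4g\n",
              object@model, object@plateau, object@rss))
  for (i in seq_along(object@halfLives))
    cat(sprintf("  phase %d: amplitude %.3f mN/m, half-life %.2f s\n",
                i, object@amplitudes[i], object@halfLives[i]))
})

#' Predicted decay curve
#'
#' @param object a [DecayFit-class] object.
#' @param times numeric vector of times (s).
#' @param ... unused.
#' @return Numeric vector of model predictions (mN/m).
#' @export
setMethod("predict", "DecayFit", function(object, times, ...) {
  y <- rep(object@plateau, length(times))
  for (i in seq_along(object@amplitudes))
    y <- y + object@amplitudes[i] * 2^(-times / object@halfLives[i])
  y
})

#' MonolayerFrame: labeled atom coordinates of a monolayer system
#'
#' One coordinate frame of a two-leaflet monolayer system: positions in
#' nm, per-atom names/elements, residue (molecule-species) labels from a
#' closed vocabulary, integer molecule grouping, and an orthorhombic box
#' periodic in x and y.
#'
#' @slot coords n x 3 numeric matrix, nm.
#' @slot atomName character, per atom (e.g. `"C210"`, `"P"`).
#' @slot element character, per atom (`"H"` atoms are excluded from
#'   contact analyses).
#' @slot resName character residue name per atom (force-field naming).
#' @slot species character per atom, one of DPPC, POPC, POPG, CHOL,
#'   PROTEIN, CHEMICAL, WATER, ION.
#' @slot moleculeId integer per atom; every atom belongs to exactly one
#'   molecule.
#' @slot box numeric length-3, nm.
#' @slot frameTime numeric, ns (NA if unknown).
#' @export
setClass("MonolayerFrame",
  representation(coords = "matrix", atomName = "character",
                 element = "character", resName = "character",
                 species = "character", moleculeId = "integer",
                 box = "numeric", frameTime = "numeric"))

setValidity("MonolayerFrame", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an n x 3 matrix")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@atomName) != n || length(object@element) != n ||
      length(object@resName) != n || length(object@species) != n ||
      length(object@moleculeId) != n)
    msg <- c(msg, "per-atom vectors must match coords rows")
  if (!all(object@species %in% .SPECIES))
    msg <- c(msg, sprintf("unknown species label(s): %s",
                          paste(setdiff(unique(object@species), .SPECIES),
                                collapse = ", ")))
  if (length(object@box) != 3L || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    msg <- c(msg, "box must be three positive finite lengths (nm)")
  if (length(msg)) msg else TRUE
})

#' @param coords,atomName,element,resName,species,moleculeId,box,frameTime
#'   see slots.
#' @rdname MonolayerFrame-class
#' @return A `MonolayerFrame` object.
#' @export
MonolayerFrame <- function(coords, atomName, element, resName, species,
                           moleculeId, box, frameTime = NA_real_) {
  new("MonolayerFrame", coords = coords, atomName = as.character(atomName),
      element = as.character(element), resName = as.character(resName),
      species = as.character(species),
      moleculeId = as.integer(moleculeId), box = as.numeric(box),
      frameTime = as.numeric(frameTime))
}

#' @rdname accessors
#' @export
setMethod("nAtoms", "MonolayerFrame", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setMethod("boxDims", "MonolayerFrame", function(x) x@box)

#' @rdname accessors
#' @export
setMethod("atomCoords", "MonolayerFrame", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("atomSpecies", "MonolayerFrame", function(x) x@species)

setMethod("show", "MonolayerFrame", function(object) {
  tab <- table(object@species[!duplicated(object@moleculeId)])
  cat(sprintf("MonolayerFrame: %d atoms, %d molecules, box %.2f x %.2f x %.2f nm\n",
              nrow(object@coords), length(unique(object@moleculeId)),
              object@box[1], object@box[2], object@box[3]))
  cat("  molecules:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = " "), "\n")
})

#' PackingResult: liquid-condensed packing by DBSCAN clustering
#'
#' Per-entity (acyl chain or cholesterol) cluster labels from periodic 2D
#' DBSCAN of packing marker atoms, and the resulting L_c fraction.
#'
#' @slot lcFraction fraction of entities with cluster label >= 0.
#' @slot nEntities number of clustering entities.
#' @slot clusterLabels integer per entity; -1 = unclustered (noise).
#' @slot entityTable data.frame describing each entity (molecule id,
#'   species, marker x/y).
#' @export
setClass("PackingResult",
  representation(lcFraction = "numeric", nEntities = "integer",
                 clusterLabels = "integer", entityTable = "data.frame"))

setValidity("PackingResult", function(object) {
  if (length(object@clusterLabels) != object@nEntities)
    return("one cluster label per entity required")
  frac <- if (object@nEntities == 0L) 0 else
    sum(object@clusterLabels >= 0L) / object@nEntities
  if (object@nEntities > 0L && abs(frac - object@lcFraction) > 1e-12)
    return("lcFraction must equal the labelled fraction exactly")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("lcFraction", "PackingResult", function(x) x@lcFraction)

setMethod("show", "PackingResult", function(object) {
  cat(sprintf("PackingResult: %d entities, L_c fraction %.3f (%d clusters)\n",
              object@nEntities, object@lcFraction,
              length(setdiff(unique(object@clusterLabels), -1L))))
})

#' TiltResult: acyl chain tilt relative to the monolayer normal
#'
#' @slot meanTilt mean tilt, degrees in [0, 90].
#' @slot perChainTilt per-chain tilt angles, degrees.
#' @slot nChains number of chains averaged.
#' @export
setClass("TiltResult",
  representation(meanTilt = "numeric", perChainTilt = "numeric",
                 nChains = "integer"))

setValidity("TiltResult", function(object) {
  if (length(object@perChainTilt) != object@nChains)
    return("one tilt per chain required")
  if (object@nChains > 0L &&
      abs(object@meanTilt - mean(object@perChainTilt)) > 1e-9)
    return("meanTilt must be the arithmetic mean of perChainTilt")
  TRUE
})

setMethod("show", "TiltResult", function(object) {
  cat(sprintf("TiltResult: mean tilt %.2f deg over %d chains\n",
              object@meanTilt, object@nChains))
})

#' DensityProfile: normalized number densities along the monolayer normal
#'
#' Per-species number-density histograms along z, centered per frame at
#' the leaflet's mean phosphate position and normalized so each non-empty
#' species curve has maximum 1.
#'
#' @slot zGrid bin centers, nm, relative to the phosphate plane.
#' @slot density bins x species matrix, max 1 per non-empty species.
#' @slot counts raw accumulated counts (same shape).
#' @slot binWidth nm.
#' @slot emptySpecies character: requested species with no atoms
#'   (all-zero profile, flagged rather than an error).
#' @export
setClass("DensityProfile",
  representation(zGrid = "numeric", density = "matrix",
                 counts = "matrix", binWidth = "numeric",
                 emptySpecies = "character"))

setValidity("DensityProfile", function(object) {
  if (nrow(object@density) != length(object@zGrid))
    return("density rows must match zGrid")
  occupied <- setdiff(colnames(object@density), object@emptySpecies)
  for (sp in occupied)
    if (abs(max(object@density[, sp]) - 1) > 1e-12)
      return(sprintf("profile of species %s not normalized to max 1", sp))
  TRUE
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf("DensityProfile: %d bins of %.2f nm, species: %s\n",
              length(object@zGrid), object@binWidth,
              paste(colnames(object@density), collapse = ", ")))
  if (length(object@emptySpecies))
    cat("  empty species:", paste(object@emptySpecies, collapse = ", "),
        "\n")
})

#' ContactSeries: partner-normalized contacts versus monolayer area
#'
#' Normalized heavy-atom contact counts for one group pair, binned by
#' area per lipid (APL, Angstrom^2). For replica-aggregated series the
#' error slot holds the half-difference between replicas.
#'
#' @slot aplGrid bin centers, Angstrom^2, strictly increasing.
#' @slot contacts normalized contact values, >= 0.
#' @slot error per-bin error estimate (0 for a single replica).
#' @slot groupPair character length-2: the two group labels.
#' @slot emptyBins integer indices of requested bins with no frames
#'   (dropped from the grid, flagged here).
#' @slot nOutOfRange number of frames falling outside the bin range.
#' @export
setClass("ContactSeries",
  representation(aplGrid = "numeric", contacts = "numeric",
                 error = "numeric", groupPair = "character",
                 emptyBins = "integer", nOutOfRange = "integer"))

setValidity("ContactSeries", function(object) {
  msg <- character()
  if (length(object@aplGrid) != length(object@contacts) ||
      length(object@aplGrid) != length(object@error))
    msg <- c(msg, "aplGrid, contacts and error must align")
  if (length(object@aplGrid) > 1L && any(diff(object@aplGrid) <= 0))
    msg <- c(msg, "aplGrid must be strictly increasing")
  if (any(object@contacts < 0) || any(object@error < 0))
    msg <- c(msg, "contacts and error must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContactSeries", function(object) {
  cat(sprintf("ContactSeries %s--%s: %d APL bins in [%.1f, %.1f] A^2\n",
              object@groupPair[1], object@groupPair[2],
              length(object@aplGrid),
              min(object@aplGrid), max(object@aplGrid)))
})
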