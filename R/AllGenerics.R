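#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @param object an object.
#' @param ... further arguments for methods.
#' @return The slot value the accessor names; see the class pages for
#'   details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("measureKind", function(x) standardGeneric("measureKind"))

#' @rdname accessors
#' @export
setGeneric("device", function(x) standardGeneric("device"))

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))

#' @rdname accessors
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))

#' @rdname accessors
#' @export
setGeneric("cycleTable", function(x) standardGeneric("cycleTable"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname accessors
#' @export
setGeneric("atomSpecies", function(x) standardGeneric("atomSpecies"))

#' @rdname accessors
#' @export
setGeneric("lcFraction", function(x) standardGeneric("lcFraction"))

#' @rdname accessors
#' @export
setGeneric("halfLives", function(x) standardGeneric("halfLives"))

#' @rdname accessors
#' @export
setGeneric("decayModel", function(x) standardGeneric("decayModel"))
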