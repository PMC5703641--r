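#' @rdname totalEnergy
#' @export
setGeneric("totalEnergy", function(object, ...) standardGeneric("totalEnergy"))

#' @rdname validateState
#' @export
setGeneric("validateState", function(object, ...) standardGeneric("validateState"))

#' @rdname largestClusterFraction
#' @export
setGeneric("largestClusterFraction",
           function(object, ...) standardGeneric("largestClusterFraction"))

#' @rdname densityParameter
#' @export
setGeneric("densityParameter",
           function(object, ...) standardGeneric("densityParameter"))

#' @rdname bindingNetwork
#' @export
setGeneric("bindingNetwork", function(object, ...) standardGeneric("bindingNetwork"))

#' Number of beads / molecules in a system
#' @param object a `SystemState`.
#' @return integer count.
#' @export
setGeneric("nBeads", function(object) standardGeneric("nBeads"))

#' @rdname nBeads
#' @export
setGeneric("nMolecules", function(object) standardGeneric("nMolecules"))
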