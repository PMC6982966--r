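#' @import methods
NULL

#' @rdname expandHydrogens
#' @export
setGeneric("expandHydrogens", function(x, ...) standardGeneric("expandHydrogens"))

#' @rdname distanceMatrix
#' @export
setGeneric("distanceMatrix", function(x, ...) standardGeneric("distanceMatrix"))

#' @rdname wienerPathNumber
#' @export
setGeneric("wienerPathNumber", function(x, ...) standardGeneric("wienerPathNumber"))

#' @rdname peoeCharges
#' @export
setGeneric("peoeCharges", function(x, ...) standardGeneric("peoeCharges"))

#' @rdname atomicVSA
#' @export
setGeneric("atomicVSA", function(x, ...) standardGeneric("atomicVSA"))

#' @rdname vdwVolume
#' @export
setGeneric("vdwVolume", function(x, ...) standardGeneric("vdwVolume"))

#' @rdname crippenContribs
#' @export
setGeneric("crippenContribs", function(x, ...) standardGeneric("crippenContribs"))

#' @rdname computeDescriptors
#' @export
setGeneric("computeDescriptors", function(x, ...) standardGeneric("computeDescriptors"))

#' @rdname predictActivity
#' @export
setGeneric("predictActivity", function(object, newdata, ...) standardGeneric("predictActivity"))

#' @rdname modelCoefficients
#' @export
setGeneric("modelCoefficients", function(object) standardGeneric("modelCoefficients"))

#' @rdname modelIntercept
#' @export
setGeneric("modelIntercept", function(object) standardGeneric("modelIntercept"))

#' Number of atoms or bonds in a molecular graph
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return integer count.
#' @rdname graph-accessors
#' @export
setGeneric("numAtoms", function(x) standardGeneric("numAtoms"))

#' @rdname graph-accessors
#' @export
setGeneric("numBonds", function(x) standardGeneric("numBonds"))

#' @rdname graph-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname graph-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname graph-accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))

#' @rdname QSARDataset
#' @export
setGeneric("descriptorMatrix", function(x, ...) standardGeneric("descriptorMatrix"))

#' @rdname QSARDataset
#' @export
setGeneric("activities", function(x, ...) standardGeneric("activities"))

#' @rdname QSARDataset
#' @export
setGeneric("setLabels", function(x, ...) standardGeneric("setLabels"))
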