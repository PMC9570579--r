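#' @import methods
NULL

#' @rdname QuantumCenter-class
#' @param x,object A \code{QuantumCenter}.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("atomPositions", function(x) standardGeneric("atomPositions"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("atomLabels", function(x) standardGeneric("atomLabels"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("stateEnergies", function(x) standardGeneric("stateEnergies"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("stateCharges", function(x) standardGeneric("stateCharges"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("dipoleArray", function(x) standardGeneric("dipoleArray"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("centerOfMass", function(x) standardGeneric("centerOfMass"))

#' @rdname QuantumCenter-class
#' @export
setGeneric("acidicProtonIndex", function(x) standardGeneric("acidicProtonIndex"))

#' @rdname SpeciesPair-class
#' @export
setGeneric("protonated", function(x) standardGeneric("protonated"))

#' @rdname SpeciesPair-class
#' @export
setGeneric("deprotonated", function(x) standardGeneric("deprotonated"))

#' @rdname SpeciesPair-class
#' @export
setGeneric("atomMap", function(x) standardGeneric("atomMap"))

#' @rdname PerturbationEnergySeries-class
#' @export
setGeneric("ensembleLabel", function(x) standardGeneric("ensembleLabel"))

#' @rdname PerturbationEnergySeries-class
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' @rdname FreeEnergyResult-class
#' @export
setGeneric("forwardEstimate", function(x) standardGeneric("forwardEstimate"))

#' @rdname FreeEnergyResult-class
#' @export
setGeneric("reverseEstimate", function(x) standardGeneric("reverseEstimate"))

#' @rdname FreeEnergyResult-class
#' @export
setGeneric("deltaA", function(x) standardGeneric("deltaA"))

#' @rdname FreeEnergyResult-class
#' @export
setGeneric("uncertainty", function(x) standardGeneric("uncertainty"))

#' @rdname EssentialSubspace-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname EssentialSubspace-class
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname EssentialSubspace-class
#' @export
setGeneric("meanStructure", function(x) standardGeneric("meanStructure"))

#' @rdname CoordinateTrajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname CoordinateTrajectory-class
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
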