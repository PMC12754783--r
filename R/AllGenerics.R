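## Accessor generics. Slots are never accessed with @ from user code.

#' @rdname accessors
#' @param object An object of the documented classes.
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname accessors
#' @export
setGeneric("intensityValues",
           function(object) standardGeneric("intensityValues"))

#' @rdname accessors
#' @export
setGeneric("speciesEntries", function(object) standardGeneric("speciesEntries"))

#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(object) standardGeneric("noiseSigma"))

#' @rdname accessors
#' @export
setGeneric("standardIntensity",
           function(object) standardGeneric("standardIntensity"))

#' @rdname accessors
#' @export
setGeneric("kd1", function(object) standardGeneric("kd1"))

#' @rdname accessors
#' @export
setGeneric("kd2", function(object) standardGeneric("kd2"))

#' @rdname accessors
#' @export
setGeneric("cooperativity", function(object) standardGeneric("cooperativity"))

#' @rdname accessors
#' @export
setGeneric("boundFraction", function(object) standardGeneric("boundFraction"))

#' @rdname accessors
#' @export
setGeneric("reducedMobility",
           function(object) standardGeneric("reducedMobility"))

#' @rdname accessors
#' @export
setGeneric("deadTime", function(object) standardGeneric("deadTime"))

#' @rdname accessors
#' @export
setGeneric("ccsValue", function(object) standardGeneric("ccsValue"))

#' @rdname accessors
#' @export
setGeneric("quartetCount", function(object) standardGeneric("quartetCount"))

#' @rdname accessors
#' @export
setGeneric("specificAdducts",
           function(object) standardGeneric("specificAdducts"))

#' @rdname accessors
#' @export
setGeneric("meltingTm", function(object) standardGeneric("meltingTm"))

#' Accessors for G4LigandMS result and container classes
#'
#' Small accessor functions exposing the slots of the package's S4 classes:
#' m/z and intensity axes of a \linkS4class{MassSpectrum}; the entries, noise
#' sigma and internal-standard intensity of a \linkS4class{SpeciesTable};
#' dissociation constants, cooperativity class and bound fraction of a
#' \linkS4class{BindingResult} or \linkS4class{TitrationFit}; reduced mobility
#' and dead time of a \linkS4class{SteppedFieldFit}; the CCS of a
#' \linkS4class{CCSResult}; the specific-adduct set and quartet count of a
#' \linkS4class{SpecificityCall}; and the Tm of a \linkS4class{MeltingResult}.
#'
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("mzValues", "MassSpectrum", function(object) object@mz)

#' @rdname accessors
setMethod("intensityValues", "MassSpectrum",
          function(object) object@intensity)

#' @rdname accessors
setMethod("intensityValues", "DriftRecord",
          function(object) object@intensity)

#' @rdname accessors
setMethod("speciesEntries", "SpeciesTable", function(object) object@entries)

#' @rdname accessors
setMethod("noiseSigma", "SpeciesTable", function(object) object@noiseSigma)

#' @rdname accessors
setMethod("standardIntensity", "SpeciesTable",
          function(object) object@standardIntensity)

#' @rdname accessors
setMethod("kd1", "BindingResult", function(object) object@KD1)

#' @rdname accessors
setMethod("kd2", "BindingResult", function(object) object@KD2)

#' @rdname accessors
setMethod("kd1", "TitrationFit", function(object) object@KD1)

#' @rdname accessors
setMethod("kd2", "TitrationFit", function(object) object@KD2)

#' @rdname accessors
setMethod("cooperativity", "BindingResult",
          function(object) object@cooperativity)

#' @rdname accessors
setMethod("boundFraction", "BindingResult",
          function(object) object@fractionBound)

#' @rdname accessors
setMethod("reducedMobility", "SteppedFieldFit", function(object) object@K0)

#' @rdname accessors
setMethod("deadTime", "SteppedFieldFit", function(object) object@t0)

#' @rdname accessors
setMethod("ccsValue", "CCSResult", function(object) object@ccs)

#' @rdname accessors
setMethod("quartetCount", "SpecificityCall",
          function(object) object@quartetCount)

#' @rdname accessors
setMethod("specificAdducts", "SpecificityCall",
          function(object) object@specificN)

#' @rdname accessors
setMethod("meltingTm", "MeltingResult", function(object) object@tm)
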