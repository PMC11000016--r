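#' Accessor generics for gatingnet containers
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param object a gatingnet S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setMethod("epochData", "EpochArray", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochArray", function(object) object@sfreq)

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochArray", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("epochTimes", "TFR", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(object) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setMethod("conditionLabels", "EpochArray", function(object) object@conditions)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "TFR", function(object) object@conditionNames)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochArray", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "Leadfield", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "TFR", function(object) object@channelNames)

#' @rdname accessors
#' @export
setGeneric("channelPositions",
           function(object) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setMethod("channelPositions", "EpochArray",
          function(object) object@channelPositions)
#' @rdname accessors
#' @export
setMethod("channelPositions", "Leadfield",
          function(object) object@channelPositions)

#' @rdname accessors
#' @export
setGeneric("gainMatrix", function(object) standardGeneric("gainMatrix"))
#' @rdname accessors
#' @export
setMethod("gainMatrix", "Leadfield", function(object) object@gain)

#' @rdname accessors
#' @export
setGeneric("voxelPositions", function(object) standardGeneric("voxelPositions"))
#' @rdname accessors
#' @export
setMethod("voxelPositions", "Leadfield", function(object) object@voxelPositions)

#' @rdname accessors
#' @export
setGeneric("filterWeights", function(object) standardGeneric("filterWeights"))
#' @rdname accessors
#' @export
setMethod("filterWeights", "SpatialFilter", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("tfrPower", function(object) standardGeneric("tfrPower"))
#' @rdname accessors
#' @export
setMethod("tfrPower", "TFR", function(object) object@power)

#' @rdname accessors
#' @export
setGeneric("tfrFreqs", function(object) standardGeneric("tfrFreqs"))
#' @rdname accessors
#' @export
setMethod("tfrFreqs", "TFR", function(object) object@freqs)

#' @rdname accessors
#' @export
setGeneric("linearWeights", function(object) standardGeneric("linearWeights"))
#' @rdname accessors
#' @export
setMethod("linearWeights", "NMVARModel", function(object) object@A)

#' @rdname accessors
#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))
#' @rdname accessors
#' @export
setMethod("modelOrder", "NMVARModel", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("linC", function(object) standardGeneric("linC"))
#' @rdname accessors
#' @export
setMethod("linC", "ConnectivityMatrix", function(object) object@lC)

#' @rdname accessors
#' @export
setGeneric("nonlinC", function(object) standardGeneric("nonlinC"))
#' @rdname accessors
#' @export
setMethod("nonlinC", "ConnectivityMatrix", function(object) object@NC)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "ConnectivityMatrix",
          function(object) object@normalized)
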