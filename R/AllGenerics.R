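# Accessor generics; slots are never reached into directly by user code.

#' @name accessors
#' @title Accessors for seedfuse S4 classes
#' @description Small accessor family: pixel arrays, spectral vectors,
#'   ground-truth tables, split members, profile numbers and metric values.
#' @param object An object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "SeedCrop", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "CurveImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "FusedImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralCurve", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setGeneric("reflectance", function(object) standardGeneric("reflectance"))
#' @rdname accessors
#' @export
setMethod("reflectance", "SpectralCurve", function(object) object@reflectance)

#' @rdname accessors
#' @export
setGeneric("seedCenters", function(object) standardGeneric("seedCenters"))
#' @rdname accessors
#' @export
setMethod("seedCenters", "GroundTruth", function(object) object@centers)

#' @rdname accessors
#' @export
setGeneric("seedLabels", function(object) standardGeneric("seedLabels"))
#' @rdname accessors
#' @export
setMethod("seedLabels", "GroundTruth", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("seedBboxes", function(object) standardGeneric("seedBboxes"))
#' @rdname accessors
#' @export
setMethod("seedBboxes", "GroundTruth", function(object) object@bboxes)

#' @rdname accessors
#' @export
setGeneric("sourceBbox", function(object) standardGeneric("sourceBbox"))
#' @rdname accessors
#' @export
setMethod("sourceBbox", "SeedCrop", function(object) object@sourceBbox)

#' @rdname accessors
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setMethod("trainIds", "DatasetSplit", function(object) object@trainIds)

#' @rdname accessors
#' @export
setGeneric("valIds", function(object) standardGeneric("valIds"))
#' @rdname accessors
#' @export
setMethod("valIds", "DatasetSplit", function(object) object@valIds)

#' @rdname accessors
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))
#' @rdname accessors
#' @export
setMethod("testIds", "DatasetSplit", function(object) object@testIds)

#' @rdname accessors
#' @export
setGeneric("paramsTotal", function(object) standardGeneric("paramsTotal"))
#' @rdname accessors
#' @export
setMethod("paramsTotal", "ModelProfile", function(object) object@paramsTotal)

#' @rdname accessors
#' @export
setGeneric("paramsMillions", function(object) standardGeneric("paramsMillions"))
#' @rdname accessors
#' @export
setMethod("paramsMillions", "ModelProfile", function(object) object@paramsMillions)

#' @rdname accessors
#' @export
setGeneric("macsTotal", function(object) standardGeneric("macsTotal"))
#' @rdname accessors
#' @export
setMethod("macsTotal", "ModelProfile", function(object) object@macsTotal)

#' @rdname accessors
#' @export
setGeneric("flopsG", function(object) standardGeneric("flopsG"))
#' @rdname accessors
#' @export
setMethod("flopsG", "ModelProfile", function(object) object@flopsG)

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setMethod("accuracy", "MetricsReport", function(object) object@accuracy)

#' @rdname accessors
#' @export
setGeneric("macroMetrics", function(object) standardGeneric("macroMetrics"))
#' @rdname accessors
#' @export
setMethod("macroMetrics", "MetricsReport", function(object)
  c(specificity = object@macroSpecificity, recall = object@macroRecall,
    precision = object@macroPrecision, f1 = object@macroF1))

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(object) standardGeneric("perClassMetrics"))
#' @rdname accessors
#' @export
setMethod("perClassMetrics", "MetricsReport", function(object) object@perClass)

#' @rdname accessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))
#' @rdname accessors
#' @export
setMethod("confusion", "MetricsReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("modelClasses", function(object) standardGeneric("modelClasses"))
#' @rdname accessors
#' @export
setMethod("modelClasses", "SeedNet", function(object) object@classes)
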