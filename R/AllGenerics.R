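# Accessor generics. Slots are never reached into directly by user code.

#' @name accessors
#' @title Accessors for ChangeScape containers
#' @param object a ChangeScape S4 object
#' @description Accessor functions returning the underlying tables, arrays
#'   and registries of the package's S4 containers.
NULL

#' @rdname accessors
#' @export
setGeneric("sceneObs", function(object) standardGeneric("sceneObs"))
#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))
#' @rdname accessors
#' @export
setGeneric("sceneDEM", function(object) standardGeneric("sceneDEM"))
#' @rdname accessors
#' @export
setGeneric("sceneStrata", function(object) standardGeneric("sceneStrata"))
#' @rdname accessors
#' @export
setGeneric("sceneMasks", function(object) standardGeneric("sceneMasks"))
#' @rdname accessors
#' @export
setGeneric("sceneConfig", function(object) standardGeneric("sceneConfig"))

#' @rdname accessors
#' @export
setGeneric("compositeBands", function(object) standardGeneric("compositeBands"))
#' @rdname accessors
#' @export
setGeneric("interpolatedFlags",
           function(object) standardGeneric("interpolatedFlags"))
#' @rdname accessors
#' @export
setGeneric("compositeDates", function(object) standardGeneric("compositeDates"))

#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("fittedSeries", function(object) standardGeneric("fittedSeries"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureRegistry",
           function(object) standardGeneric("featureRegistry"))

#' @rdname accessors
#' @export
setGeneric("confidenceValues",
           function(object) standardGeneric("confidenceValues"))
#' @rdname accessors
#' @export
setGeneric("classRegistry", function(object) standardGeneric("classRegistry"))
#' @rdname accessors
#' @export
setGeneric("classCodes", function(object) standardGeneric("classCodes"))
#' @rdname accessors
#' @export
setGeneric("mapYears", function(object) standardGeneric("mapYears"))

#' @rdname accessors
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setGeneric("reportOverall", function(object) standardGeneric("reportOverall"))
#' @rdname accessors
#' @export
setGeneric("reportByClass", function(object) standardGeneric("reportByClass"))
#' @rdname accessors
#' @export
setGeneric("reportConfusion",
           function(object) standardGeneric("reportConfusion"))

# ---- methods --------------------------------------------------------------

#' @rdname accessors
setMethod("sceneObs", "Scene", function(object) object@obs)
#' @rdname accessors
setMethod("sceneTruth", "Scene", function(object) object@truth)
#' @rdname accessors
setMethod("sceneDEM", "Scene", function(object) object@dem)
#' @rdname accessors
setMethod("sceneStrata", "Scene", function(object) object@strata)
#' @rdname accessors
setMethod("sceneMasks", "Scene", function(object) object@masks)
#' @rdname accessors
setMethod("sceneConfig", "Scene", function(object) object@config)

#' @rdname accessors
setMethod("compositeBands", "CompositeSeries", function(object) object@bands)
#' @rdname accessors
setMethod("interpolatedFlags", "CompositeSeries",
          function(object) object@interpolated)
#' @rdname accessors
setMethod("compositeDates", "CompositeSeries",
          function(object) object@composite_date)
#' @rdname accessors
setMethod("mapYears", "CompositeSeries", function(object) object@years)

#' @rdname accessors
setMethod("segments", "LTSegmentation", function(object) object@segments)
#' @rdname accessors
setMethod("vertices", "LTSegmentation", function(object) object@vertices)
#' @rdname accessors
setMethod("fittedSeries", "LTSegmentation", function(object) object@fitted)
#' @rdname accessors
setMethod("segments", "CCDCSegmentSet", function(object) object@segments)

#' @rdname accessors
setMethod("featureValues", "FeatureCube", function(object) object@values)
#' @rdname accessors
setMethod("featureRegistry", "FeatureCube", function(object) object@registry)
#' @rdname accessors
setMethod("mapYears", "FeatureCube", function(object) object@years)

#' @rdname accessors
setMethod("confidenceValues", "ConfidenceCube", function(object) object@values)
#' @rdname accessors
setMethod("classRegistry", "ConfidenceCube", function(object) object@classes)
#' @rdname accessors
setMethod("mapYears", "ConfidenceCube", function(object) object@years)

#' @rdname accessors
setMethod("classCodes", "ClassMapSeries", function(object) object@codes)
#' @rdname accessors
setMethod("classRegistry", "ClassMapSeries", function(object) object@classes)
#' @rdname accessors
setMethod("mapYears", "ClassMapSeries", function(object) object@years)

#' @rdname accessors
setMethod("designTable", "SampleDesign", function(object) object@design)

#' @rdname accessors
setMethod("reportOverall", "ValidationReport", function(object) object@overall)
#' @rdname accessors
setMethod("reportByClass", "ValidationReport", function(object) object@by_class)
#' @rdname accessors
setMethod("reportConfusion", "ValidationReport",
          function(object) object@confusion)
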