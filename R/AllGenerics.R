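#' @name msiScreen-accessors
#' @title Accessors for msiScreen classes
#' @description Accessor generics for [FeatureBag-class] and friends.
#' @param x an object
#' @param object an object
NULL

#' @rdname msiScreen-accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("scannerId", function(x) standardGeneric("scannerId"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("blockId", function(x) standardGeneric("blockId"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("bagFeatures", function(x) standardGeneric("bagFeatures"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("tileInfo", function(x) standardGeneric("tileInfo"))

#' @rdname msiScreen-accessors
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' Per-tile scores under a tile-scoring model
#'
#' @param bag a [FeatureBag-class]
#' @param model a [ChowderModel-class] or [TumorTileModel-class]
#' @return numeric vector, one score per tile, aligned to bag tile order.
#' @export
setGeneric("tileScores", function(bag, model) standardGeneric("tileScores"))

#' Slide-level score of a feature bag
#'
#' @param bag a [FeatureBag-class]
#' @param model a [ChowderModel-class]
#' @return probability in \[0, 1\] that the slide is MSI.
#' @export
setGeneric("slideScore", function(bag, model) standardGeneric("slideScore"))
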