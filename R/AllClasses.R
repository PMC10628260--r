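# S4 classes for the screening pipeline. FeatureBag is the MIL unit: one
# slide as an unordered set of tile feature vectors plus micron coordinates.

#' FeatureBag: one slide as a bag of tile feature vectors
#'
#' A `FeatureBag` extends [SummarizedExperiment::SummarizedExperiment] with
#' tiles as columns and feature dimensions as rows (assay `"features"`).
#' Column metadata carries the tile table (`x_um`, `y_um`, `size_um`, `px`,
#' `foreground_fraction`); slide-level metadata carries `slide_id`,
#' `scanner_id` and `block_id`. Coordinates are 0-based microns with the
#' origin at the slide top-left and y increasing downward; a tile occupies
#' the half-open square `[x, x + size) x [y, y + size)`.
#'
#' @slot .. see `SummarizedExperiment`; construct with [FeatureBag()].
#' @export
setClass("FeatureBag", contains = "SummarizedExperiment")

.validFeatureBag <- function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    else {
        f <- SummarizedExperiment::assay(object, "features")
        if (ncol(f) < 1L)
            msg <- c(msg, "a FeatureBag must contain at least one tile")
        if (!all(is.finite(f)))
            msg <- c(msg, "features contain non-finite values (NaN/Inf/NA)")
    }
    need <- c("x_um", "y_um", "size_um", "px", "foreground_fraction")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("tile table lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        ff <- SummarizedExperiment::colData(object)$foreground_fraction
        if (any(ff < 0 | ff > 1, na.rm = TRUE))
            msg <- c(msg, "foreground_fraction must lie in [0, 1]")
    }
    md <- S4Vectors::metadata(object)
    if (is.null(md$slide_id) || !nzchar(md$slide_id))
        msg <- c(msg, "metadata slide_id is required")
    if (length(msg)) msg else TRUE
}
setValidity("FeatureBag", .validFeatureBag)

#' Slide manifest
#'
#' A validated table of slide records: `slide_id`, `patient_id`, `label`
#' (`MSI`, `non-MSI` or `unknown`), `scanner_id`, `block_id`, `path`.
#' `slide_id` must be unique; `unknown` labels are permitted only for
#' prediction-only slides.
#'
#' @export
setClass("SlideManifest", contains = "DFrame")

MANIFEST_COLUMNS <- c("slide_id", "patient_id", "label", "scanner_id",
                      "block_id", "path")
LABEL_LEVELS <- c("MSI", "non-MSI", "unknown")

.validSlideManifest <- function(object) {
    msg <- character()
    miss <- setdiff(MANIFEST_COLUMNS, colnames(object))
    if (length(miss))
        return(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")))
    if (anyDuplicated(object$slide_id))
        msg <- c(msg, paste0("duplicated slide_id: ",
                 paste(unique(object$slide_id[duplicated(object$slide_id)]),
                       collapse = ", ")))
    bad <- setdiff(unique(as.character(object$label)), LABEL_LEVELS)
    if (length(bad))
        msg <- c(msg, paste0("unknown label token(s): ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
}
setValidity("SlideManifest", .validSlideManifest)

#' Binary tissue/matter mask at a stated working resolution
#'
#' @slot mask integer matrix in {0,1}; rows index y, columns x.
#' @slot mpp microns per pixel of the raster (default working resolution 4).
#' @slot provenance `"default-thresholder"` or `"external"`.
#' @export
setClass("MatterMask",
    representation(mask = "matrix", mpp = "numeric", provenance = "character"),
    validity = function(object) {
        if (!all(object@mask %in% c(0L, 1L)))
            return("mask values must be 0/1")
        if (object@mpp <= 0) return("mpp must be positive")
        TRUE
    })

#' Per-slide quality-check report
#'
#' Two-stage QC outcome: blur flagging (advisory, suggests a rescan) and
#' tumour-content gating (slides with too little detected tumour are
#' discarded). `tumor_area_mm2` is `n_tumor_tiles * (tile_size_um/1000)^2`.
#'
#' @export
setClass("QcReport",
    representation(slide_id = "character", n_tiles = "integer",
                   blur_fraction = "numeric", n_tumor_tiles = "integer",
                   tumor_area_mm2 = "numeric", status = "character"),
    validity = function(object) {
        msg <- character()
        if (!object@status %in% c("pass", "rescan_advised", "insufficient_tumor"))
            msg <- c(msg, "invalid status")
        if (object@n_tumor_tiles > object@n_tiles)
            msg <- c(msg, "n_tumor_tiles exceeds n_tiles")
        if (length(msg)) msg else TRUE
    })

#' Tumour-tile classifier (single hidden layer MLP)
#'
#' A per-tile binary classifier over feature vectors with exactly one hidden
#' layer of 256 ReLU units and a sigmoid output, used by the QC stage to
#' count tumour tiles.
#'
#' @export
setClass("TumorTileModel",
    representation(W1 = "matrix", b1 = "numeric", w2 = "numeric",
                   b2 = "numeric", featureDim = "integer", seed = "integer",
                   threshold = "numeric"))

#' Chowder-variant MIL classifier
#'
#' Parameters of the tile scorer (feature_dim -> 128 sigmoid -> 1 sigmoid
#' score), the extreme-pooling width R, and the aggregation head
#' (2R -> 128 -> 64 -> 1, all sigmoid). Training metadata (seed, class
#' weights, hyperparameters) is stored with the model for reproducibility.
#'
#' @export
setClass("ChowderModel",
    representation(scorerW1 = "matrix", scorerB1 = "numeric",
                   scorerW2 = "numeric", scorerB2 = "numeric",
                   headW1 = "matrix", headB1 = "numeric",
                   headW2 = "matrix", headB2 = "numeric",
                   headW3 = "numeric", headB3 = "numeric",
                   poolWidth = "integer", featureDim = "integer",
                   seed = "integer", classWeights = "numeric",
                   trainConfig = "list"),
    validity = function(object) {
        if (object@poolWidth < 1L) return("poolWidth must be >= 1")
        TRUE
    })

#' Result of the sensitivity-guaranteed calibration
#'
#' Operating threshold derived from a set of known-MSI slide scores such that
#' exactly one calibration slide falls below it (is called MSS-AI).
#'
#' @export
setClass("CalibrationResult",
    representation(threshold = "numeric", calibration_scores = "numeric",
                   misclassified_slide_id = "character",
                   target_band = "numeric"),
    validity = function(object) {
        below <- sum(object@calibration_scores < object@threshold)
        if (below != 1L)
            return(sprintf("%d calibration scores below threshold (must be 1)",
                           below))
        TRUE
    })

#' Cohort-level screening metrics
#'
#' Sensitivity, specificity, NPV and AUROC with optional bootstrap 95% CIs,
#' plus the rule-out enrichment (percent increase of MSI prevalence among
#' Undetermined calls relative to the whole cohort).
#'
#' @export
setClass("ScreenMetrics",
    representation(counts = "matrix", sensitivity = "numeric",
                   specificity = "numeric", npv = "numeric",
                   auroc = "numeric", ci95 = "list",
                   n = "integer", n_msi = "integer",
                   enrichment_pct = "numeric"))
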