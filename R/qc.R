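# Automated quality check, two stages:
#   1. blur flagging (advisory -> rescan): share of tiles whose sharpness
#      statistic falls below a threshold;
#   2. tumour-content gating (-> discard): a per-tile tumour classifier
#      counts tumour tiles; slides under the cut-off (default 500 tiles,
#      about 6 mm2) are set aside.

#' Sharpness statistic of a tile image
#'
#' Variance of the 3x3 Laplacian (high-pass) response of the grey image.
#' Focused histology texture yields a high value; Gaussian-smoothed
#' (out-of-focus) texture yields a value orders of magnitude lower.
#'
#' @param img grayscale matrix or RGB array in \[0, 1\].
#' @export
tileSharpness <- function(img) {
    g <- if (length(dim(img)) == 3L) apply(img, c(1, 2), mean) else img
    k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(g), k))
    stats::var(as.numeric(resp))
}

#' Flag blurry slides from tile images
#'
#' @param images list of tile images.
#' @param cfg a [pipelineConfig()]; `blur_sharpness_min` sets the per-tile
#'   blur threshold and `blur_rescan_limit` the slide-level advisory limit.
#' @return list: `sharpness` (per tile), `blur_fraction`, `rescan_advised`.
#' @export
flagBlur <- function(images, cfg = pipelineConfig()) {
    sharp <- vapply(images, tileSharpness, numeric(1))
    bf <- mean(sharp < cfg$blur_sharpness_min)
    list(sharpness = sharp, blur_fraction = bf,
         rescan_advised = bf > cfg$blur_rescan_limit)
}

#' Train the tumour-tile classifier
#'
#' Binary per-tile model over feature vectors: a multilayer perceptron with
#' exactly one hidden layer of 256 ReLU units and a sigmoid output, trained
#' with full-batch Adam on binary cross-entropy. Deterministic given the
#' seed.
#'
#' @param features numeric matrix `n_tiles x d` of training tiles.
#' @param is_tumor logical vector (TRUE = tumour tile).
#' @param epochs,learning_rate optimiser settings.
#' @param hidden hidden width (fixed architecture default 256).
#' @param seed initialisation seed.
#' @return a [TumorTileModel-class]
#' @export
trainTumorClassifier <- function(features, is_tumor, epochs = 80L,
                                 learning_rate = 5e-3, hidden = 256L,
                                 seed = 1L) {
    features <- as.matrix(features)
    y <- as.numeric(is_tumor)
    if (length(unique(y)) < 2L)
        stop("validation error: tumour classifier needs both classes",
             call. = FALSE)
    d <- ncol(features)
    set.seed(seed)
    params <- list(W1 = glorot(hidden, d), b1 = numeric(hidden),
                   w2 = stats::runif(hidden, -0.1, 0.1), b2 = 0)
    st <- adamInit(params)
    n <- nrow(features)
    for (ep in seq_len(epochs)) {
        Z1 <- features %*% t(params$W1) +
            rep(1, n) %o% params$b1
        H <- pmax(Z1, 0)
        p <- as.numeric(sigmoid(H %*% params$w2 + params$b2))
        dp <- (.clampP(p) - y) / n
        dH <- (dp %o% params$w2) * (Z1 > 0)
        grads <- list(W1 = t(dH) %*% features, b1 = colSums(dH),
                      w2 = as.numeric(t(H) %*% dp), b2 = sum(dp))
        upd <- adamStep(params, grads, st, learning_rate)
        params <- upd$params; st <- upd$state
    }
    new("TumorTileModel", W1 = params$W1, b1 = params$b1, w2 = params$w2,
        b2 = params$b2, featureDim = as.integer(d), seed = as.integer(seed),
        threshold = 0.5)
}

#' @describeIn trainTumorClassifier per-tile tumour probabilities for a bag.
#' @param bag a [FeatureBag-class]
#' @param model a [TumorTileModel-class]
#' @export
setMethod("tileScores", signature("FeatureBag", "TumorTileModel"),
    function(bag, model) {
        X <- bagFeatures(bag)
        if (ncol(X) != model@featureDim)
            stop("configuration error: bag has ", ncol(X),
                 " feature dims, model expects ", model@featureDim,
                 call. = FALSE)
        H <- pmax(X %*% t(model@W1) + rep(1, nrow(X)) %o% model@b1, 0)
        as.numeric(sigmoid(H %*% model@w2 + model@b2))
    })

#' Count tumour tiles in a bag
#'
#' Tiles with predicted tumour probability at or above the model threshold
#' (default 0.5) count as tumour.
#'
#' @param bag a [FeatureBag-class]
#' @param model a [TumorTileModel-class]
#' @export
countTumorTiles <- function(bag, model) {
    sum(tileScores(bag, model) >= model@threshold)
}

#' Tumour area represented by a tile count
#'
#' `n` tiles of side `tile_size_um` cover `n * (tile_size_um / 1000)^2` mm2;
#' at the default 112 um this is exactly `n * 0.012544` mm2, so the
#' 500-tile QC cut-off corresponds to about 6 mm2 of tumour.
#'
#' @param n tile count.
#' @param tile_size_um tile side in microns.
#' @export
tilesToAreaMm2 <- function(n, tile_size_um = 112) {
    n * (tile_size_um / 1000)^2
}

#' Assemble the QC decision for one slide
#'
#' `insufficient_tumor` iff the tumour-tile count is strictly below the
#' cut-off (the cut-off itself passes); otherwise `rescan_advised` if the
#' blurry-tile fraction exceeds the advisory limit; otherwise `pass`.
#' Rescanning is advisory: the pipeline flags and continues.
#'
#' @param slide_id slide identifier.
#' @param n_tiles number of tiles in the bag.
#' @param blur_fraction blurry-tile share, or `NA` when no images were
#'   available.
#' @param n_tumor_tiles tumour-tile count.
#' @param cfg a [pipelineConfig()].
#' @return a [QcReport-class]
#' @export
qcDecision <- function(slide_id, n_tiles, blur_fraction, n_tumor_tiles,
                       cfg = pipelineConfig()) {
    status <- if (n_tumor_tiles < cfg$tumor_tile_cutoff) "insufficient_tumor"
    else if (!is.na(blur_fraction) &&
             blur_fraction > cfg$blur_rescan_limit) "rescan_advised"
    else "pass"
    new("QcReport", slide_id = as.character(slide_id),
        n_tiles = as.integer(n_tiles), blur_fraction = blur_fraction,
        n_tumor_tiles = as.integer(n_tumor_tiles),
        tumor_area_mm2 = tilesToAreaMm2(n_tumor_tiles, cfg$tile_size_um),
        status = status)
}

#' Run the full QC on one slide bag
#'
#' @param bag a [FeatureBag-class]
#' @param model a [TumorTileModel-class]
#' @param cfg a [pipelineConfig()].
#' @param images optional list of tile images for the blur stage;
#'   feature-only bags skip blur flagging with a warning.
#' @return a [QcReport-class]
#' @export
qcSlide <- function(bag, model, cfg = pipelineConfig(), images = NULL) {
    bf <- if (is.null(images)) {
        warning("no images for slide '", slideId(bag),
                "': blur stage skipped", call. = FALSE)
        NA_real_
    } else flagBlur(images, cfg)$blur_fraction
    nt <- countTumorTiles(bag, model)
    rep <- qcDecision(slideId(bag), nTiles(bag), bf, nt, cfg)
    logStage(cfg, "qc", slideId(bag), status = rep@status, tumor_tiles = nt)
    rep
}

#' @rdname msiScreen-accessors
#' @export
setMethod("qcStatus", "QcReport", function(x) x@status)

setMethod("show", "QcReport", function(object) {
    cat(sprintf("QcReport %s: %d tiles, blur %.3f, tumour %d (%.2f mm2) -> %s\n",
                object@slide_id, object@n_tiles, object@blur_fraction,
                object@n_tumor_tiles, object@tumor_area_mm2, object@status))
})
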