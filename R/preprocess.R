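# Whole-slide preprocessing: matter detection at a low working resolution,
# micron-accurate tiling with the foreground rule, training-time tile
# subsampling, and the pluggable feature-extraction interface.

#' Detect tissue ("matter") on a low-resolution slide image
#'
#' Default provider: intensity/saturation thresholding followed by
#' small-object removal — background pixels on an H&E scan are bright and
#' unsaturated, tissue is darker and coloured. An externally produced mask
#' (e.g. from a learned segmenter) can be passed through unchanged with
#' `method = "external"`.
#'
#' @param image grayscale matrix (rows = y) or RGB array in \[0, 1\] at the
#'   working resolution.
#' @param mpp working resolution in microns per pixel (default 4).
#' @param method `"threshold"` (default provider) or `"external"`.
#' @param mask 0/1 matrix, required when `method = "external"`.
#' @param intensity_max pixels darker than this count as candidate tissue.
#' @param saturation_min for RGB input, minimum channel spread of tissue.
#' @param min_object_um2 connected components smaller than this area are
#'   removed as specks/artefacts.
#' @return a [MatterMask-class]
#' @export
detectMatter <- function(image, mpp = 4,
                         method = c("threshold", "external"), mask = NULL,
                         intensity_max = 0.85, saturation_min = 0.05,
                         min_object_um2 = 10000) {
    method <- match.arg(method)
    if (method == "external") {
        stopifnot(is.matrix(mask))
        return(new("MatterMask", mask = matrix(as.integer(mask != 0),
                                               nrow(mask), ncol(mask)),
                   mpp = mpp, provenance = "external"))
    }
    if (length(dim(image)) == 3L) {
        intensity <- apply(image, c(1, 2), mean)
        saturation <- apply(image, c(1, 2), max) -
            apply(image, c(1, 2), min)
        m <- intensity < intensity_max & saturation > saturation_min
    } else {
        m <- image < intensity_max
    }
    m <- matrix(as.integer(m), nrow(m), ncol(m))
    minPx <- max(1, round(min_object_um2 / mpp^2))
    if (any(m == 1L)) {
        lab <- EBImage::bwlabel(EBImage::Image(t(m)))
        sizes <- table(as.integer(lab)[as.integer(lab) > 0])
        drop <- as.integer(names(sizes)[sizes < minPx])
        if (length(drop)) {
            labm <- t(as.matrix(EBImage::imageData(lab)))
            m[labm %in% drop] <- 0L
        }
    }
    if (!any(m == 1L))
        warning("matter mask is empty: no tissue detected", call. = FALSE)
    new("MatterMask", mask = m, mpp = mpp, provenance = "default-thresholder")
}

#' Build the tile grid over a slide and apply the foreground rule
#'
#' A non-overlapping regular grid anchored at the slide origin (0, 0); a
#' tile is kept iff its foreground fraction is at least
#' `cfg$foreground_min` (the "at least 50% foreground" rule, inclusive).
#' Partial edge tiles are evaluated on their truncated area normalised by
#' the full tile area, so slivers at the slide border rarely pass.
#'
#' @param slide_dims_um slide `c(width, height)` in microns.
#' @param mask a [MatterMask-class]
#' @param cfg a [pipelineConfig()].
#' @param keep_all also return discarded tiles (with `kept = FALSE`).
#' @return `DataFrame` of tiles: `x_um`, `y_um`, `size_um`, `px`,
#'   `foreground_fraction`, `kept`.
#' @export
buildTileGrid <- function(slide_dims_um, mask, cfg = pipelineConfig(),
                          keep_all = FALSE) {
    stopifnot(is(mask, "MatterMask"), all(slide_dims_um > 0),
              cfg$tile_size_um > 0)
    m <- mask@mask
    mpp <- mask@mpp
    size <- cfg$tile_size_um
    fullPx <- (size / mpp)^2
    xs <- (seq_len(ceiling(slide_dims_um[1] / size)) - 1L) * size
    ys <- (seq_len(ceiling(slide_dims_um[2] / size)) - 1L) * size
    # integral image: S[i+1, j+1] = sum(m[1:i, 1:j])
    S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
    rectSum <- function(r0, r1, c0, c1) { # 1-based inclusive, clipped
        r0 <- max(r0, 1L); c0 <- max(c0, 1L)
        r1 <- min(r1, nrow(m)); c1 <- min(c1, ncol(m))
        if (r1 < r0 || c1 < c0) return(0)
        S[r1 + 1L, c1 + 1L] - S[r0, c1 + 1L] - S[r1 + 1L, c0] + S[r0, c0]
    }
    grid <- expand.grid(x_um = xs, y_um = ys)
    frac <- vapply(seq_len(nrow(grid)), function(i) {
        c0 <- floor(grid$x_um[i] / mpp) + 1L
        c1 <- ceiling((grid$x_um[i] + size) / mpp)
        r0 <- floor(grid$y_um[i] / mpp) + 1L
        r1 <- ceiling((grid$y_um[i] + size) / mpp)
        rectSum(r0, r1, c0, c1) / fullPx
    }, numeric(1))
    out <- S4Vectors::DataFrame(
        x_um = grid$x_um, y_um = grid$y_um, size_um = size,
        px = as.integer(round(size / cfg$mpp)),
        foreground_fraction = frac,
        kept = frac >= cfg$foreground_min)
    if (keep_all) out else out[out$kept, , drop = FALSE]
}

#' Subsample a bag's tiles for training
#'
#' Training uses at most `cfg$max_train_tiles` tiles per slide (default
#' 8,000), drawn uniformly without replacement; smaller bags pass through
#' unchanged. Inference never subsamples.
#'
#' @param bag a [FeatureBag-class]
#' @param cfg a [pipelineConfig()].
#' @param seed sampling seed.
#' @export
subsampleTrainingTiles <- function(bag, cfg = pipelineConfig(), seed = 1L) {
    stopifnot(is(bag, "FeatureBag"))
    n <- nTiles(bag)
    if (n <= cfg$max_train_tiles) return(bag)
    set.seed(seed)
    subsetBag(bag, sort(sample.int(n, cfg$max_train_tiles)))
}

#' Default deterministic tile feature extractor
#'
#' A fixed seeded random projection: the tile image is converted to grey,
#' mean-pooled to 16 x 16, and projected to `feature_dim` dimensions by a
#' frozen Gaussian matrix. This is a deterministic stand-in satisfying the
#' extractor interface (tile image in, d-vector out); any external
#' extractor (e.g. a pretrained network) can be plugged in instead.
#'
#' @param feature_dim output dimension.
#' @param seed projection seed (the projection is frozen at creation).
#' @return a function `image -> numeric(feature_dim)`.
#' @export
defaultExtractor <- function(feature_dim = 2048L, seed = 1L) {
    set.seed(seed)
    P <- matrix(stats::rnorm(feature_dim * 256, 0, 1 / 16), feature_dim, 256)
    function(img) {
        g <- if (length(dim(img)) == 3L) apply(img, c(1, 2), mean) else img
        small <- as.matrix(EBImage::imageData(
            EBImage::resize(EBImage::Image(g), 16L, 16L)))
        as.numeric(P %*% as.vector(small))
    }
}

#' Extract features for a set of tiles
#'
#' Applies an extractor to each tile image and assembles a [FeatureBag-class];
#' row order equals tile order. External feature matrices bypass this path
#' entirely (construct the bag with [FeatureBag()] directly).
#'
#' @param tiles tile table as returned by [buildTileGrid()].
#' @param images list of tile images aligned to `tiles` rows.
#' @param extractor function mapping an image to a `feature_dim` vector.
#' @param cfg a [pipelineConfig()]; `cfg$feature_dim` must match the
#'   extractor output (configuration error otherwise).
#' @param slide_id,scanner_id,block_id bag identity.
#' @export
extractFeatures <- function(tiles, images, extractor,
                            cfg = pipelineConfig(), slide_id,
                            scanner_id = "scanner01", block_id = "A") {
    stopifnot(length(images) == nrow(tiles))
    feats <- lapply(images, extractor)
    dims <- lengths(feats)
    if (any(dims != cfg$feature_dim))
        stop("configuration error: extractor returned ", dims[1],
             " dims but cfg$feature_dim is ", cfg$feature_dim, call. = FALSE)
    tiles <- tiles[, setdiff(colnames(tiles), "kept"), drop = FALSE]
    FeatureBag(do.call(rbind, feats), tiles = tiles, slide_id = slide_id,
               scanner_id = scanner_id, block_id = block_id)
}
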