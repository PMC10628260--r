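# FeatureBag construction, accessors and the on-disk feature store.
#
# Store format "msiscreen-bag/1": one slide = three files in a directory,
#   <slide_id>.meta.json      format tag, slide/scanner/block ids, dims
#   <slide_id>.tiles.csv      tile table (x_um, y_um, size_um, px,
#                             foreground_fraction, + any extra columns)
#   <slide_id>.features.csv   n_tiles x d numeric matrix, header f1..fd
# Features are written as shortest-round-trip decimal text, so the
# double-precision round trip is exact.

BAG_FORMAT <- "msiscreen-bag/1"

#' Construct a FeatureBag
#'
#' @param features numeric matrix, `n_tiles x d` (tiles in rows).
#' @param tiles tile table (`data.frame` or `DataFrame`) with one row per
#'   tile; if `NULL`, a placeholder grid with unit foreground is generated.
#'   Required columns `x_um`, `y_um`, `size_um`, `px`,
#'   `foreground_fraction`; extra columns (e.g. synthetic ground-truth
#'   `tissue`, `signal`) are preserved.
#' @param slide_id slide identifier (required, non-empty).
#' @param scanner_id,block_id slide provenance.
#' @return a [FeatureBag-class]
#' @examples
#' bag <- FeatureBag(matrix(rnorm(40), 10, 4), slide_id = "s1")
#' nTiles(bag)
#' @export
FeatureBag <- function(features, tiles = NULL, slide_id,
                       scanner_id = "scanner01", block_id = "A") {
    features <- as.matrix(features)
    n <- nrow(features)
    if (is.null(tiles)) {
        side <- ceiling(sqrt(n))
        idx <- seq_len(n) - 1L
        tiles <- S4Vectors::DataFrame(
            x_um = (idx %% side) * 112, y_um = (idx %/% side) * 112,
            size_um = 112, px = 224L, foreground_fraction = 1)
    } else tiles <- S4Vectors::DataFrame(tiles)
    if (nrow(tiles) != n)
        stop("tile table has ", nrow(tiles), " rows but features have ", n,
             call. = FALSE)
    rownames(tiles) <- NULL
    a <- t(features)
    dimnames(a) <- list(paste0("f", seq_len(nrow(a))),
                        sprintf("tile_%05d", seq_len(n)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = a), colData = tiles,
        metadata = list(slide_id = as.character(slide_id),
                        scanner_id = as.character(scanner_id),
                        block_id = as.character(block_id)))
    bag <- new("FeatureBag", se)
    validObject(bag)
    bag
}

#' @rdname msiScreen-accessors
#' @export
setMethod("slideId", "FeatureBag",
          function(x) S4Vectors::metadata(x)$slide_id)

#' @rdname msiScreen-accessors
#' @export
setMethod("scannerId", "FeatureBag",
          function(x) S4Vectors::metadata(x)$scanner_id)

#' @rdname msiScreen-accessors
#' @export
setMethod("blockId", "FeatureBag",
          function(x) S4Vectors::metadata(x)$block_id)

#' @rdname msiScreen-accessors
#' @export
setMethod("nTiles", "FeatureBag", function(x) ncol(x))

#' @rdname msiScreen-accessors
#' @export
setMethod("featureDim", "FeatureBag", function(x) nrow(x))

#' @rdname msiScreen-accessors
#' @export
setMethod("bagFeatures", "FeatureBag",
          function(x) t(SummarizedExperiment::assay(x, "features")))

#' @rdname msiScreen-accessors
#' @export
setMethod("tileInfo", "FeatureBag",
          function(x) SummarizedExperiment::colData(x))

setMethod("show", "FeatureBag", function(object) {
    cat(sprintf("FeatureBag '%s' (scanner %s, block %s): %d tiles x %d features\n",
                slideId(object), scannerId(object), blockId(object),
                nTiles(object), featureDim(object)))
})

# subset a bag to the tiles in `idx` (keeps order of idx)
subsetBag <- function(bag, idx) {
    FeatureBag(bagFeatures(bag)[idx, , drop = FALSE],
               tiles = tileInfo(bag)[idx, , drop = FALSE],
               slide_id = slideId(bag), scanner_id = scannerId(bag),
               block_id = blockId(bag))
}

#' Write a feature bag to the on-disk store
#'
#' Writes the `msiscreen-bag/1` container: a JSON meta file, a tile-table
#' CSV and a feature-matrix CSV, named after the slide id. Feature values
#' are written as shortest decimal representations that round-trip exactly
#' to the same doubles.
#'
#' @param bag a [FeatureBag-class]
#' @param dir store directory (created if needed).
#' @return the meta-file path, invisibly.
#' @export
writeBag <- function(bag, dir) {
    stopifnot(is(bag, "FeatureBag"))
    validObject(bag)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    id <- slideId(bag)
    meta <- list(format = BAG_FORMAT, slide_id = id,
                 scanner_id = scannerId(bag), block_id = blockId(bag),
                 n_tiles = nTiles(bag), feature_dim = featureDim(bag))
    metaPath <- file.path(dir, paste0(id, ".meta.json"))
    jsonlite::write_json(meta, metaPath, auto_unbox = TRUE)
    data.table::fwrite(as.data.frame(tileInfo(bag)),
                       file.path(dir, paste0(id, ".tiles.csv")))
    f <- bagFeatures(bag)
    # %.17g guarantees an exact decimal -> double round trip
    fc <- matrix(sprintf("%.17g", f), nrow(f), ncol(f))
    colnames(fc) <- paste0("f", seq_len(ncol(f)))
    data.table::fwrite(as.data.frame(fc, optional = TRUE),
                       file.path(dir, paste0(id, ".features.csv")),
                       quote = FALSE)
    invisible(metaPath)
}

#' Read a feature bag from the on-disk store
#'
#' @param dir store directory.
#' @param slide_id slide to load.
#' @return a [FeatureBag-class]
#' @export
readBag <- function(dir, slide_id) {
    metaPath <- file.path(dir, paste0(slide_id, ".meta.json"))
    if (!file.exists(metaPath))
        stop("no bag for slide '", slide_id, "' in ", dir, call. = FALSE)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!identical(meta$format, BAG_FORMAT))
        stop("unsupported bag format tag: ", meta$format, call. = FALSE)
    tiles <- data.table::fread(file.path(dir, paste0(slide_id, ".tiles.csv")),
                               data.table = FALSE)
    f <- as.matrix(data.table::fread(
        file.path(dir, paste0(slide_id, ".features.csv")),
        data.table = FALSE))
    if (nrow(f) != meta$n_tiles || ncol(f) != meta$feature_dim)
        stop("corrupt bag '", slide_id, "': feature matrix is ", nrow(f),
             "x", ncol(f), " but meta declares ", meta$n_tiles, "x",
             meta$feature_dim, call. = FALSE)
    if ("tissue" %in% colnames(tiles)) tiles$tissue <- factor(tiles$tissue,
                                                              TISSUE_LEVELS)
    FeatureBag(f, tiles = tiles, slide_id = meta$slide_id,
               scanner_id = meta$scanner_id, block_id = meta$block_id)
}
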