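# Pipeline and training configuration. Plain validated lists (mirroring a
# YAML/JSON file one-to-one) rather than S4: every field is a scalar knob.

#' Pipeline configuration
#'
#' Houses the fixed constants of the screening pipeline. Defaults follow the
#' deployed tool: 112 um tiles (224 px at 0.5 um/px), tiles kept when at
#' least half their area is foreground, an 8,000-tile per-slide cap during
#' training (inference always uses all tiles), 2048-dimensional tile
#' features, a 500-tumour-tile QC cut-off (about 6 mm2 of tumour),
#' extreme-pooling width R = 10, 30 calibration slides and 1000 bootstrap
#' repetitions.
#'
#' @param tile_size_um tile side in microns.
#' @param mpp microns per pixel at feature-extraction resolution.
#' @param foreground_min minimum foreground fraction for a tile to be kept
#'   (inclusive).
#' @param max_train_tiles per-slide tile cap applied during training only.
#' @param feature_dim dimension of tile feature vectors.
#' @param tumor_tile_cutoff minimum tumour-tile count to pass QC (inclusive).
#' @param pool_width number of top and of bottom tile scores pooled (R).
#' @param calibration_n number of known-MSI slides used for calibration.
#' @param bootstrap_reps bootstrap repetitions for confidence intervals.
#' @param mask_mpp working resolution of matter detection, microns per pixel.
#' @param blur_sharpness_min per-tile sharpness (variance of a 3x3 Laplacian
#'   response on the grey image) below which a tile counts as blurry.
#' @param blur_rescan_limit blurry-tile fraction above which a rescan is
#'   advised.
#' @param seed default seed for seeded operations.
#' @param verbose emit structured per-stage log messages.
#' @return a validated named list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(feature_dim = 64)
#' cfg$tumor_tile_cutoff
#' @export
pipelineConfig <- function(tile_size_um = 112, mpp = 0.5,
                           foreground_min = 0.5, max_train_tiles = 8000L,
                           feature_dim = 2048L, tumor_tile_cutoff = 500L,
                           pool_width = 10L, calibration_n = 30L,
                           bootstrap_reps = 1000L, mask_mpp = 4,
                           blur_sharpness_min = 1e-3,
                           blur_rescan_limit = 0.05,
                           seed = 1L, verbose = FALSE) {
    cfg <- list(tile_size_um = tile_size_um, mpp = mpp,
                foreground_min = foreground_min,
                max_train_tiles = as.integer(max_train_tiles),
                feature_dim = as.integer(feature_dim),
                tumor_tile_cutoff = as.integer(tumor_tile_cutoff),
                pool_width = as.integer(pool_width),
                calibration_n = as.integer(calibration_n),
                bootstrap_reps = as.integer(bootstrap_reps),
                mask_mpp = mask_mpp,
                blur_sharpness_min = blur_sharpness_min,
                blur_rescan_limit = blur_rescan_limit,
                seed = as.integer(seed), verbose = isTRUE(verbose))
    class(cfg) <- c("PipelineConfig", "list")
    validatePipelineConfig(cfg)
    cfg
}

validatePipelineConfig <- function(cfg) {
    num <- c("tile_size_um", "mpp", "max_train_tiles", "feature_dim",
             "tumor_tile_cutoff", "pool_width", "calibration_n",
             "bootstrap_reps", "mask_mpp")
    for (f in num)
        if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
            stop("config field '", f, "' must be a positive scalar",
                 call. = FALSE)
    if (cfg$foreground_min <= 0 || cfg$foreground_min > 1)
        stop("foreground_min must lie in (0, 1]", call. = FALSE)
    if (cfg$pool_width < 1L) stop("pool_width must be >= 1", call. = FALSE)
    invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override [pipelineConfig()] defaults;
#' unknown fields are rejected.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param ... overrides applied after the file (e.g. from CLI flags).
#' @export
readPipelineConfig <- function(path, ...) {
    stopifnot(file.exists(path))
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    over <- list(...)
    vals[names(over)] <- over
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    do.call(pipelineConfig, vals)
}

#' Training hyperparameters for the Chowder model
#'
#' The screening model's architecture is fixed; the optimisation
#' hyperparameters are free and are recorded in the trained model artifact.
#' Defaults: full-batch Adam, 200 epochs, learning rate 5e-3.
#'
#' @param epochs number of passes over the training slides.
#' @param learning_rate Adam step size.
#' @param batch_size slides per batch; `Inf` = full batch.
#' @param optimizer only `"adam"` is implemented.
#' @param seed seed for weight initialisation and batch shuffling.
#' @param patience early-stopping patience in epochs on training loss;
#'   `Inf` disables early stopping.
#' @param n_restarts independent seeded initialisations; the fit with the
#'   lowest final training loss is kept. Sigmoid MIL heads occasionally
#'   settle into spurious separators (low but not minimal loss); restarts
#'   make training robust to the initialisation draw.
#' @export
trainConfig <- function(epochs = 200L, learning_rate = 5e-3,
                        batch_size = Inf, optimizer = "adam", seed = 1L,
                        patience = Inf, n_restarts = 3L) {
    stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
              identical(optimizer, "adam"), n_restarts >= 1)
    structure(list(epochs = as.integer(epochs),
                   learning_rate = learning_rate, batch_size = batch_size,
                   optimizer = optimizer, seed = as.integer(seed),
                   patience = patience, n_restarts = as.integer(n_restarts)),
              class = c("TrainConfig", "list"))
}

# structured per-stage log line, gated by cfg$verbose
logStage <- function(cfg, stage, slide_id = NA_character_, ...) {
    if (!isTRUE(cfg$verbose)) return(invisible(NULL))
    kv <- list(...)
    extra <- if (length(kv))
        paste(paste0(names(kv), "=", unlist(kv)), collapse = " ")
    else ""
    message(sprintf("[%s] slide=%s %s", stage, slide_id, extra))
    invisible(NULL)
}
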