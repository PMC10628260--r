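# End-to-end orchestration on a synthetic cohort: generate -> QC -> train
# -> calibrate -> predict -> evaluate. Stage order is fixed; slides failing
# QC are excluded from calibration and evaluation, and calibration slides
# are excluded from the evaluated population, so for the scored cohort
#   n_input = n_failed_qc + n_calibration + n_evaluated.

.hashConfigs <- function(...) {
    f <- tempfile(fileext = ".json")
    on.exit(unlink(f))
    jsonlite::write_json(lapply(list(...), unclass), f, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    unname(tools::md5sum(f))
}

#' Run the full screening pipeline on a synthetic cohort
#'
#' Generates a seeded cohort, trains the tumour-tile classifier on tissue
#' ground truth from the discovery half, runs QC on all slides, trains the
#' Chowder model on QC-passing discovery slides, calibrates the operating
#' threshold on `cfg$calibration_n` QC-passing MSI validation slides, and
#' evaluates the remaining validation slides. Blur flagging is skipped
#' (feature-only bags); QC gating is by tumour content.
#'
#' @param scfg a [synthConfig()].
#' @param cfg a [pipelineConfig()]; its `feature_dim` is taken from `scfg`.
#' @param tcfg a [trainConfig()].
#' @param seed master seed: overrides `scfg$seed` and derives the split,
#'   training, calibration and bootstrap seeds.
#' @param train_fraction fraction of patients assigned to the discovery
#'   (training) split.
#' @param out_dir if non-NULL, write manifest, predictions, QC reports,
#'   calibration and metrics artifacts there.
#' @return list: `record` (run provenance + population accounting),
#'   `manifest`, `qc` (per-slide [QcReport-class]s), `tumor_model`,
#'   `model`, `calibration`, `records` (evaluated-slide data.frame) and
#'   `metrics` ([ScreenMetrics-class]).
#' @export
runPipeline <- function(scfg = synthConfig(), cfg = NULL,
                        tcfg = trainConfig(), seed = 1L,
                        train_fraction = 0.5, out_dir = NULL) {
    t0 <- proc.time()[["elapsed"]]
    timings <- c()
    tic <- function(stage) {
        t1 <- proc.time()[["elapsed"]]
        timings[[stage]] <<- t1 - t0
        t0 <<- t1
    }
    scfg$seed <- as.integer(seed)
    if (is.null(cfg))
        cfg <- pipelineConfig(feature_dim = scfg$feature_dim)
    tcfg$seed <- as.integer(seed)

    cohort <- generateCohort(scfg)
    man <- cohort$manifest
    tic("synth")

    set.seed(seed + 101L)
    pats <- unique(man$patient_id)
    trainPats <- sample(pats, max(2L, round(train_fraction * length(pats))))
    isTrain <- man$patient_id %in% trainPats
    if (length(unique(man$label[isTrain])) < 2L ||
        length(unique(man$label[!isTrain])) < 2L)
        stop("pipeline stage 'split': a split lacks one of the classes; ",
             "use a larger cohort", call. = FALSE)

    # tumour-tile classifier from discovery-tile ground truth
    trIds <- man$slide_id[isTrain]
    tileSrc <- head(trIds, 12L)
    feats <- do.call(rbind, lapply(cohort$bags[tileSrc], bagFeatures))
    isTum <- unlist(lapply(cohort$bags[tileSrc],
                           function(b) tileInfo(b)$tissue == "TUM"),
                    use.names = FALSE)
    cap <- 6000L
    if (length(isTum) > cap) {
        set.seed(seed + 202L)
        keep <- sample.int(length(isTum), cap)
        feats <- feats[keep, , drop = FALSE]; isTum <- isTum[keep]
    }
    tumorModel <- trainTumorClassifier(feats, isTum, seed = seed + 303L)
    tic("tumor_model")

    qc <- lapply(cohort$bags, function(b)
        suppressWarnings(qcSlide(b, tumorModel, cfg)))
    qcPass <- vapply(qc, function(r) r@status != "insufficient_tumor",
                     logical(1))
    tic("qc")

    trainIds <- man$slide_id[isTrain & qcPass[man$slide_id]]
    if (length(unique(man$label[man$slide_id %in% trainIds])) < 2L)
        stop("pipeline stage 'qc': no two-class discovery set left after ",
             "QC (tumour cut-off ", cfg$tumor_tile_cutoff, ")",
             call. = FALSE)
    labTrain <- man$label[match(trainIds, man$slide_id)]
    model <- trainChowder(cohort$bags[trainIds], labTrain, tcfg, cfg)
    tic("train")

    valIds <- man$slide_id[!isTrain]
    valPass <- valIds[qcPass[valIds]]
    valMsi <- valPass[man$label[match(valPass, man$slide_id)] == "MSI"]
    if (length(valMsi) <= cfg$calibration_n)
        stop("pipeline stage 'calibrate': ", length(valMsi),
             " QC-passing MSI slides but calibration needs more than ",
             cfg$calibration_n, call. = FALSE)
    set.seed(seed + 404L)
    calibIds <- sample(valMsi, cfg$calibration_n)
    calibScores <- scoreBags(cohort$bags[calibIds], model)
    calib <- calibrateThreshold(calibScores)
    tic("calibrate")

    evalIds <- setdiff(valPass, calibIds)
    scores <- scoreBags(cohort$bags[evalIds], model)
    records <- data.frame(
        slide_id = evalIds,
        patient_id = man$patient_id[match(evalIds, man$slide_id)],
        label = man$label[match(evalIds, man$slide_id)],
        score = unname(scores),
        class = as.character(classifyScore(scores, calib)))
    metrics <- evaluateScreen(records, B = cfg$bootstrap_reps,
                              seed = seed + 505L)
    tic("evaluate")

    record <- list(
        package_version = as.character(utils::packageVersion("msiScreen")),
        seed = as.integer(seed),
        config_hash = .hashConfigs(scfg, cfg, tcfg),
        timings_s = timings,
        n_slides = nrow(man),
        n_validation = length(valIds),
        n_failed_qc = sum(!qcPass[valIds]),
        n_calibration = length(calibIds),
        n_evaluated = length(evalIds))

    if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        writeManifest(man, file.path(out_dir, "manifest.csv"))
        utils::write.csv(
            data.frame(slide_id = records$slide_id, score = records$score,
                       threshold = calib@threshold, class = records$class),
            file.path(out_dir, "predictions.csv"), row.names = FALSE)
        jsonlite::write_json(
            lapply(qc, function(r) list(slide_id = r@slide_id,
                n_tiles = r@n_tiles, blur_fraction = r@blur_fraction,
                n_tumor_tiles = r@n_tumor_tiles,
                tumor_area_mm2 = r@tumor_area_mm2, status = r@status)),
            file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(
            list(threshold = calib@threshold,
                 scores = as.list(calib@calibration_scores),
                 misclassified = calib@misclassified_slide_id,
                 rule = "midpoint-two-lowest/v1"),
            file.path(out_dir, "calibration.json"), auto_unbox = TRUE,
            digits = NA)
        jsonlite::write_json(
            list(sensitivity = metrics@sensitivity,
                 specificity = metrics@specificity, npv = metrics@npv,
                 auroc = metrics@auroc,
                 enrichment_pct = metrics@enrichment_pct,
                 ci95 = metrics@ci95, record = record),
            file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
            digits = NA)
        writeChowderModel(model, file.path(out_dir, "model.json"))
    }
    list(record = record, manifest = man, qc = qc,
         tumor_model = tumorModel, model = model, calibration = calib,
         records = records, metrics = metrics)
}

#' Export a per-tile score heatmap
#'
#' Writes the canonical tile-score CSV (`x_um,y_um,score`), optionally a
#' PNG raster with one cell per tile at its micron grid position, and
#' returns the top/bottom tile lists for interpretability review.
#'
#' @param scores per-tile scores aligned to `tiles` rows.
#' @param tiles tile table with `x_um`, `y_um`, `size_um`.
#' @param csv_file,png_file output paths (`NULL` to skip).
#' @param k size of the exported top/bottom tile lists.
#' @return invisibly, a list: `raster` (matrix, NA = no tile), `top`,
#'   `bottom` (data.frames of the k highest/lowest scoring tiles).
#' @export
exportHeatmap <- function(scores, tiles, csv_file = NULL, png_file = NULL,
                          k = 10L) {
    stopifnot(length(scores) == nrow(tiles))
    size <- tiles$size_um[1]
    ci <- tiles$x_um / size + 1L
    ri <- tiles$y_um / size + 1L
    ras <- matrix(NA_real_, max(ri), max(ci))
    ras[cbind(ri, ci)] <- scores
    df <- data.frame(x_um = tiles$x_um, y_um = tiles$y_um, score = scores)
    if (!is.null(csv_file))
        utils::write.csv(df, csv_file, row.names = FALSE)
    if (!is.null(png_file)) {
        pal <- grDevices::hcl.colors(256, "viridis")
        filled <- ifelse(is.na(ras), 0, ras)
        idx <- pmin(255L, pmax(0L, as.integer(round(filled * 255)))) + 1L
        rgbv <- grDevices::col2rgb(pal[idx]) / 255
        a <- array(0, c(ncol(ras), nrow(ras), 3))
        for (ch in 1:3) {
            m <- matrix(rgbv[ch, ], nrow(ras), ncol(ras))
            m[is.na(ras)] <- 1
            a[, , ch] <- t(m)
        }
        EBImage::writeImage(EBImage::Image(a, colormode = "Color"),
                            png_file)
    }
    o <- order(scores, decreasing = TRUE)
    invisible(list(raster = ras, top = df[head(o, k), ],
                   bottom = df[tail(o, k)[seq_len(min(k, length(o)))], ]))
}
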