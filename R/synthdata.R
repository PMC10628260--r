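# Seeded synthetic cohorts with the statistical structure the pipeline
# assumes: bag-level MSI labels realised through a sparse set of signal
# tiles (the MIL premise), tissue-type structure in feature space (so the
# tumour-tile classifier is learnable), multi-block patients sharing a
# latent signal strength, scanner-dependent affine feature perturbations
# and a configurable rate of blurred slides.

TISSUE_LEVELS <- c("TUM", "NORM", "MUC", "LYM", "STR", "DEB", "ADI", "MUS")

#' Synthetic-cohort configuration
#'
#' Defaults mirror a consecutive colorectal-resection screening cohort:
#' 600 patients, 15% MSI prevalence (the approximate CRC population rate),
#' one block per patient, 3% of slides blurred. Feature structure: base
#' tile features are i.i.d. standard Gaussian plus a tissue-type mean
#' offset; in MSI slides a fraction of tumour tiles is additionally shifted
#' by `effect_size` along a fixed unit "MSI signal" direction, so the bag
#' label is 1 iff signal tiles are present.
#'
#' @param n_patients number of patients.
#' @param msi_prevalence probability a patient is MSI.
#' @param tiles_per_slide inclusive integer range, tiles drawn per slide.
#' @param tumor_fraction range of the per-slide tumour tile fraction.
#' @param msi_signal_fraction fraction of a slide's tiles carrying the MSI
#'   signal in MSI slides (capped at the tumour tile count, minimum 1).
#' @param effect_size mean feature-space shift of signal tiles along the
#'   signal direction; 0 gives a label-free null cohort.
#' @param scanner_shift default magnitude for [perturbScanner()].
#' @param blocks_per_patient inclusive range of tumour blocks per patient
#'   (one slide per block).
#' @param block_sigma relative SD of the per-block multiplicative jitter on
#'   the patient's latent signal strength.
#' @param blur_slide_rate probability a slide is recorded as blurred.
#' @param mucin_fraction range of the per-slide mucin tile fraction.
#' @param mucin_signal_leak fraction of the MSI signal direction added to
#'   mucin tiles of non-MSI slides (0 = off); reproduces the qualitative
#'   mucinous false-positive behaviour when enabled.
#' @param feature_dim synthetic feature dimension.
#' @param tissue_effect magnitude of per-tissue mean offsets.
#' @param seed RNG seed; identical config + seed gives an identical cohort.
#' @export
synthConfig <- function(n_patients = 600L, msi_prevalence = 0.15,
                        tiles_per_slide = c(800L, 1600L),
                        tumor_fraction = c(0.5, 0.9),
                        msi_signal_fraction = 0.3, effect_size = 1,
                        scanner_shift = 0.1, blocks_per_patient = c(1L, 1L),
                        block_sigma = 0.1, blur_slide_rate = 0.03,
                        mucin_fraction = c(0, 0.2), mucin_signal_leak = 0,
                        feature_dim = 64L, tissue_effect = 2,
                        seed = 1L) {
    if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
    if (msi_prevalence < 0 || msi_prevalence > 1)
        stop("msi_prevalence must lie in [0, 1]", call. = FALSE)
    if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
    if (tiles_per_slide[1] < 1L) stop("tiles_per_slide must be >= 1",
                                      call. = FALSE)
    structure(list(n_patients = as.integer(n_patients),
                   msi_prevalence = msi_prevalence,
                   tiles_per_slide = as.integer(tiles_per_slide),
                   tumor_fraction = tumor_fraction,
                   msi_signal_fraction = msi_signal_fraction,
                   effect_size = effect_size, scanner_shift = scanner_shift,
                   blocks_per_patient = as.integer(blocks_per_patient),
                   block_sigma = block_sigma,
                   blur_slide_rate = blur_slide_rate,
                   mucin_fraction = mucin_fraction,
                   mucin_signal_leak = mucin_signal_leak,
                   feature_dim = as.integer(feature_dim),
                   tissue_effect = tissue_effect, seed = as.integer(seed)),
              class = c("SynthConfig", "list"))
}

# random unit vector in d dimensions
.unitVec <- function(d) {
    v <- stats::rnorm(d)
    v / sqrt(sum(v^2))
}

#' Generate a seeded synthetic cohort of slide feature bags
#'
#' MSI slides contain `msi_signal_fraction` of tiles (drawn from the tumour
#' tiles) whose features are shifted by the patient/block signal strength
#' along a fixed unit direction; non-MSI slides contain none. Blocks of one
#' patient share the patient's latent strength with multiplicative
#' block-level jitter. Ground-truth tissue labels and signal flags travel in
#' each bag's tile table (columns `tissue`, `signal`).
#'
#' @param cfg a [synthConfig()].
#' @return list with elements `manifest` ([SlideManifest-class]), `bags`
#'   (named list of [FeatureBag-class]) and `truth` (signal direction,
#'   tissue mean matrix, blurred slide ids, per-block signal strengths).
#' @examples
#' co <- generateCohort(synthConfig(n_patients = 4,
#'                                  tiles_per_slide = c(30L, 40L),
#'                                  feature_dim = 8L, seed = 42L))
#' co$manifest
#' @export
generateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "SynthConfig"))
    d <- cfg$feature_dim
    set.seed(cfg$seed)
    u <- .unitVec(d)
    tissueMeans <- t(replicate(length(TISSUE_LEVELS),
                               .unitVec(d) * cfg$tissue_effect))
    rownames(tissueMeans) <- TISSUE_LEVELS

    rows <- list(); bags <- list(); blurSlides <- character()
    blockEffect <- numeric()
    for (p in seq_len(cfg$n_patients)) {
        pid <- sprintf("P%04d", p)
        msi <- stats::rbinom(1, 1, cfg$msi_prevalence) == 1
        aP <- cfg$effect_size
        nB <- if (cfg$blocks_per_patient[1] == cfg$blocks_per_patient[2])
            cfg$blocks_per_patient[1]
        else sample(cfg$blocks_per_patient[1]:cfg$blocks_per_patient[2], 1)
        for (b in seq_len(nB)) {
            sid <- sprintf("%s_B%s", pid, LETTERS[b])
            aPB <- aP * exp(stats::rnorm(1, 0, cfg$block_sigma))
            nT <- if (cfg$tiles_per_slide[1] == cfg$tiles_per_slide[2])
                cfg$tiles_per_slide[1]
            else sample(cfg$tiles_per_slide[1]:cfg$tiles_per_slide[2], 1)
            tumF <- stats::runif(1, cfg$tumor_fraction[1],
                                 cfg$tumor_fraction[2])
            mucF <- stats::runif(1, cfg$mucin_fraction[1],
                                 cfg$mucin_fraction[2])
            restW <- stats::runif(6)
            probs <- c(tumF, mucF, (1 - tumF - mucF) * restW / sum(restW))
            probs <- pmax(probs, 0)
            tissue <- sample(TISSUE_LEVELS[c(1, 3, 2, 4:8)], nT,
                             replace = TRUE, prob = probs)
            tissue <- factor(tissue, TISSUE_LEVELS)
            X <- matrix(stats::rnorm(nT * d), nT, d) +
                tissueMeans[as.character(tissue), , drop = FALSE]
            signal <- rep(FALSE, nT)
            if (msi) {
                tum <- which(tissue == "TUM")
                if (!length(tum)) { tissue[1] <- "TUM"; tum <- 1L }
                nSig <- max(1L, min(length(tum),
                                    round(cfg$msi_signal_fraction * nT)))
                sig <- if (length(tum) == 1L) tum else sample(tum, nSig)
                X[sig, ] <- X[sig, ] + rep(aPB, length(sig)) %o% u
                signal[sig] <- TRUE
            }
            if (!msi && cfg$mucin_signal_leak > 0) {
                muc <- which(tissue == "MUC")
                if (length(muc))
                    X[muc, ] <- X[muc, ] + rep(1, length(muc)) %o%
                        (cfg$mucin_signal_leak * cfg$effect_size * u)
            }
            side <- ceiling(sqrt(nT))
            idx <- seq_len(nT) - 1L
            tiles <- S4Vectors::DataFrame(
                x_um = (idx %% side) * 112, y_um = (idx %/% side) * 112,
                size_um = 112, px = 224L, foreground_fraction = 1,
                tissue = tissue, signal = signal)
            bags[[sid]] <- FeatureBag(X, tiles = tiles, slide_id = sid,
                                      block_id = LETTERS[b])
            if (stats::runif(1) < cfg$blur_slide_rate)
                blurSlides <- c(blurSlides, sid)
            blockEffect[sid] <- if (msi) aPB else 0
            rows[[sid]] <- data.frame(slide_id = sid, patient_id = pid,
                                      label = if (msi) "MSI" else "non-MSI",
                                      scanner_id = "scanner01",
                                      block_id = LETTERS[b], path = "")
        }
    }
    mdf <- do.call(rbind, rows)
    manifest <- new("SlideManifest", S4Vectors::DataFrame(mdf,
                                                          row.names = NULL))
    validObject(manifest)
    list(manifest = manifest, bags = bags,
         truth = list(signal_direction = u, tissue_means = tissueMeans,
                      blur_slides = blurSlides,
                      block_effect = blockEffect))
}

#' Write a synthetic cohort to disk
#'
#' Manifest CSV, one bag container per slide and a ground-truth JSON.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeManifest(cohort$manifest, file.path(dir, "manifest.csv"))
    bagDir <- file.path(dir, "bags")
    for (b in cohort$bags) writeBag(b, bagDir)
    jsonlite::write_json(
        list(blur_slides = cohort$truth$blur_slides,
             signal_direction = cohort$truth$signal_direction,
             block_effect = as.list(cohort$truth$block_effect)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

.scannerHash <- function(scanner_id) {
    sum(utf8ToInt(scanner_id) * seq_along(utf8ToInt(scanner_id))) %% 100003L
}

#' Apply a seeded scanner-dependent perturbation to a feature bag
#'
#' Emulates re-digitising the same glass slide on another scanner: tiles
#' (identity, coordinates, ground truth) are unchanged while features are
#' transformed by a scanner-specific affine map plus tile-level noise, all
#' scaled by `magnitude`. Magnitude 0 is the exact identity. The affine map
#' is a deterministic function of `scanner_id` and `seed`, so all slides
#' "digitised" on one scanner share one transform.
#'
#' @param bag a [FeatureBag-class]
#' @param scanner_id target scanner identifier.
#' @param magnitude perturbation magnitude, >= 0.
#' @param seed base seed.
#' @return a new [FeatureBag-class] tagged with `scanner_id`.
#' @export
perturbScanner <- function(bag, scanner_id, magnitude, seed = 1L) {
    stopifnot(is(bag, "FeatureBag"), magnitude >= 0)
    X <- bagFeatures(bag)
    if (magnitude > 0) {
        d <- ncol(X)
        set.seed(seed + .scannerHash(scanner_id))
        M <- matrix(stats::rnorm(d * d, 0, 1 / sqrt(d)), d, d)
        cc <- stats::rnorm(d)
        set.seed(seed + .scannerHash(scanner_id) +
                 .scannerHash(slideId(bag)))
        noise <- matrix(stats::rnorm(length(X), 0, 0.5), nrow(X), d)
        X <- X + magnitude * (X %*% M + rep(1, nrow(X)) %o% cc + noise)
    }
    FeatureBag(X, tiles = tileInfo(bag), slide_id = slideId(bag),
               scanner_id = scanner_id, block_id = blockId(bag))
}

#' Generate a synthetic low-resolution slide image with known tissue
#'
#' A grayscale slide-level image at the matter-detection working resolution:
#' bright background with one or more darker textured tissue rectangles.
#' The returned ground-truth mask lets matter-detection accuracy be scored
#' exactly (e.g. by intersection-over-union).
#'
#' @param dims_um slide `c(width, height)` in microns.
#' @param tissue_rects list of rectangles `c(x, y, w, h)` in microns.
#' @param mpp raster resolution, microns per pixel.
#' @param seed texture seed.
#' @return list with `image` (matrix in \[0,1\], rows = y) and `mask`
#'   (0/1 integer matrix of the true tissue pixels).
#' @export
generateSlideImage <- function(dims_um = c(2048, 2048),
                               tissue_rects = list(c(256, 256, 1024, 1024)),
                               mpp = 4, seed = 1L) {
    set.seed(seed)
    nx <- ceiling(dims_um[1] / mpp); ny <- ceiling(dims_um[2] / mpp)
    img <- matrix(stats::runif(ny * nx, 0.93, 1.0), ny, nx)
    mask <- matrix(0L, ny, nx)
    for (r in tissue_rects) {
        xs <- floor(r[1] / mpp) + seq_len(max(1, round(r[3] / mpp)))
        ys <- floor(r[2] / mpp) + seq_len(max(1, round(r[4] / mpp)))
        xs <- xs[xs <= nx]; ys <- ys[ys <= ny]
        img[ys, xs] <- stats::runif(length(ys) * length(xs), 0.30, 0.65)
        mask[ys, xs] <- 1L
    }
    list(image = img, mask = mask)
}

#' Generate a synthetic RGB tile image
#'
#' A deterministic textured 224 x 224 image for a tissue class; with
#' `blur = TRUE` the texture is Gaussian-smoothed so that its sharpness
#' statistic (variance of the Laplacian response, [tileSharpness()]) falls
#' below the default blur threshold.
#'
#' @param label one of the eight tissue classes (`"TUM"`, `"NORM"`, ...).
#' @param blur smooth the texture to emulate an out-of-focus scan region.
#' @param seed RNG seed; identical seed gives identical pixels.
#' @return numeric array `224 x 224 x 3` in \[0, 1\].
#' @export
generateTileImage <- function(label = "TUM", blur = FALSE, seed = 1L) {
    label <- match.arg(label, TISSUE_LEVELS)
    set.seed(seed + .scannerHash(label))
    px <- 224L
    base <- switch(label,
        TUM = c(0.72, 0.45, 0.62), NORM = c(0.85, 0.65, 0.75),
        MUC = c(0.80, 0.78, 0.88), LYM = c(0.45, 0.35, 0.60),
        STR = c(0.88, 0.70, 0.78), DEB = c(0.70, 0.60, 0.58),
        ADI = c(0.94, 0.90, 0.92), MUS = c(0.82, 0.55, 0.65))
    gx <- outer(seq_len(px), rep(1, px)) / px
    gy <- t(gx)
    freq <- 2 + 3 * match(label, TISSUE_LEVELS)
    pattern <- 0.08 * sin(2 * pi * freq * gx) * cos(2 * pi * freq * gy)
    img <- array(0, c(px, px, 3))
    for (ch in 1:3) {
        noise <- matrix(stats::runif(px * px, -0.12, 0.12), px, px)
        img[, , ch] <- pmin(pmax(base[ch] + pattern + noise, 0), 1)
    }
    if (blur) {
        e <- EBImage::Image(img, colormode = "Color")
        img <- as.array(EBImage::gblur(e, sigma = 6))
        img <- pmin(pmax(img, 0), 1)
    }
    img
}
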