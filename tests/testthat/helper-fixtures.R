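# Shared fixtures, built once per test run. The separable cohort and the
# model trained on it are reused across chowder, agreement and acceptance
# tests to keep the suite fast.

.fx <- new.env(parent = emptyenv())

# 200-slide cohort with a strong MSI signal (effect size 2), 32-dim features
fxSeparableCohort <- function() {
    if (is.null(.fx$sep))
        .fx$sep <- generateCohort(synthConfig(
            n_patients = 200L, tiles_per_slide = c(100L, 160L),
            feature_dim = 32L, effect_size = 2, seed = 11L))
    .fx$sep
}

# Chowder model trained on odd-indexed slides of the separable cohort;
# even-indexed slides are the held-out half
fxTrainedModel <- function() {
    if (is.null(.fx$model)) {
        co <- fxSeparableCohort()
        tr <- seq_len(nrow(co$manifest)) %% 2L == 1L
        .fx$trainIdx <- tr
        .fx$model <- trainChowder(
            co$bags[tr], co$manifest$label[tr],
            trainConfig(epochs = 120L, seed = 7L),
            pipelineConfig(feature_dim = 32L))
    }
    list(model = .fx$model, train = .fx$trainIdx)
}

# tumour-tile classifier trained on ground-truth tissue labels of a few
# separable-cohort slides
fxTumorModel <- function() {
    if (is.null(.fx$tumor)) {
        co <- fxSeparableCohort()
        ids <- head(co$manifest$slide_id, 8L)
        X <- do.call(rbind, lapply(co$bags[ids], bagFeatures))
        y <- unlist(lapply(co$bags[ids],
                           function(b) tileInfo(b)$tissue == "TUM"),
                    use.names = FALSE)
        .fx$tumor <- trainTumorClassifier(X, y, epochs = 60L, seed = 5L)
    }
    .fx$tumor
}

# tiny cohort for cheap structural tests
fxTinyCohort <- function() {
    if (is.null(.fx$tiny))
        .fx$tiny <- generateCohort(synthConfig(
            n_patients = 8L, tiles_per_slide = c(30L, 45L),
            feature_dim = 8L, seed = 42L))
    .fx$tiny
}

# paper confusion matrices (screening orientation)
cohortACounts <- function() msiScreen:::asCounts(208, 246, 2, 81)
cohortBCounts <- function() msiScreen:::asCounts(218, 250, 4, 82)

# reconstruct a per-slide cohort from a confusion matrix (one slide per
# patient)
countsToRecords <- function(counts) {
    lab <- rep(c("non-MSI", "non-MSI", "MSI", "MSI"), times = as.integer(
        c(counts["non-MSI", 1], counts["non-MSI", 2],
          counts["MSI", 1], counts["MSI", 2])))
    cls <- rep(c("MSS-AI", "Undetermined", "MSS-AI", "Undetermined"),
               times = as.integer(c(counts["non-MSI", 1],
                                    counts["non-MSI", 2],
                                    counts["MSI", 1], counts["MSI", 2])))
    # scores consistent with a 0.5 threshold and graded within each call,
    # so the reconstructed cohort has a high but imperfect AUROC
    data.frame(patient_id = sprintf("p%04d", seq_along(lab)),
               label = lab, class = cls,
               score = ifelse(cls == "Undetermined",
                              ifelse(lab == "MSI", 0.9, 0.6),
                              ifelse(lab == "MSI", 0.45, 0.2)))
}
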