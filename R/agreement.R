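# Reproducibility statistics: chance-corrected agreement between scanners
# (Cohen's kappa), across repeated digitisations (Fleiss' kappa), score
# correlation (Pearson, two-tailed), paired-classifier comparison (exact
# McNemar) and inter-block score consistency (RMSE against the patient
# mean). All tests are two-tailed; no multiplicity adjustment is applied in
# the slide-selection composition analysis.

#' Cohen's kappa for two raters
#'
#' `kappa = (po - pe) / (1 - pe)` with `pe` the product of marginal
#' proportions summed over categories. Undefined (error) when `pe = 1`
#' (both raters constant and identical).
#'
#' @param a,b aligned categorical vectors (two raters on the same items).
#' @export
cohensKappa <- function(a, b) {
    if (length(a) != length(b))
        stop("validation error: vectors differ in length", call. = FALSE)
    if (length(a) < 2L)
        stop("validation error: need at least 2 items", call. = FALSE)
    lev <- union(unique(as.character(a)), unique(as.character(b)))
    a <- factor(as.character(a), lev); b <- factor(as.character(b), lev)
    po <- mean(a == b)
    pe <- sum(prop.table(table(a)) * prop.table(table(b)))
    if (pe >= 1 - 1e-15)
        stop("kappa undefined: expected agreement is 1 (constant identical ",
             "marginals)", call. = FALSE)
    (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard Fleiss formulation over category proportions; every subject
#' must be rated by the same number of raters (default use: 30 slides, 8
#' digitisations each).
#'
#' @param ratings matrix or data.frame, `n_subjects x n_raters`,
#'   categorical entries.
#' @export
fleissKappa <- function(ratings) {
    ratings <- as.matrix(ratings)
    if (nrow(ratings) < 2L)
        stop("validation error: need at least 2 subjects", call. = FALSE)
    if (anyNA(ratings))
        stop("validation error: ragged ratings (missing entries)",
             call. = FALSE)
    m <- ncol(ratings)
    lev <- sort(unique(as.character(ratings)))
    counts <- t(apply(ratings, 1, function(r)
        table(factor(as.character(r), lev))))
    if (length(lev) == 1L) counts <- matrix(counts, ncol = 1L)
    Pi <- (rowSums(counts^2) - m) / (m * (m - 1))
    pj <- colSums(counts) / (nrow(ratings) * m)
    Pbar <- mean(Pi); Pe <- sum(pj^2)
    if (Pe >= 1 - 1e-15)
        stop("kappa undefined: all ratings identical in one category",
             call. = FALSE)
    (Pbar - Pe) / (1 - Pe)
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; p from the t transform with n - 2 degrees
#' of freedom, two-tailed.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return list with `r` and `p`.
#' @export
pearsonTest <- function(x, y) {
    if (length(x) < 3L)
        stop("validation error: need at least 3 pairs", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: constant vector", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Exact McNemar test on discordant counts
#'
#' Two-sided exact binomial test of `b` successes in `b + c` trials at
#' p = 0.5, where `b` and `c` are the discordant pair counts of two paired
#' classifiers. `p = 1` when `b = c`; when `b + c = 0` the test is vacuous
#' and `p = 1` is returned with a warning. An exact test is used (rather
#' than the chi-square approximation) because discordant counts are small
#' at screening-cohort sizes.
#'
#' @param b,c non-negative integer discordant counts.
#' @return two-sided p-value in (0, 1\].
#' @export
mcnemarExact <- function(b, c) {
    stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
    n <- b + c
    if (n == 0) {
        warning("no discordant pairs: McNemar p defined as 1", call. = FALSE)
        return(1)
    }
    if (b == c) return(1)
    min(2 * stats::pbinom(min(b, c), n, 0.5), 1)
}

#' Inter-block consistency of slide scores
#'
#' For patients with several slides (from different tumour blocks), each
#' slide's error is its score minus the mean score of that patient's
#' slides; the RMSE pools these errors over slides, separately per label
#' group. Patients with a single slide are excluded with a warning.
#'
#' @param scores named numeric vector of slide scores.
#' @param patient_id patient of each slide, aligned to `scores`.
#' @param label patient label (`"MSI"`/`"non-MSI"`), aligned to `scores`.
#' @return named numeric: RMSE for `non-MSI` and `MSI` groups (`NA` if a
#'   group has no multi-slide patient).
#' @export
interblockRmse <- function(scores, patient_id, label) {
    stopifnot(length(scores) == length(patient_id),
              length(scores) == length(label))
    nSlides <- table(patient_id)
    single <- names(nSlides)[nSlides < 2]
    if (length(single))
        warning(length(single), " patient(s) with a single slide excluded",
                call. = FALSE)
    keep <- !patient_id %in% single
    scores <- scores[keep]; patient_id <- patient_id[keep]
    label <- label[keep]
    err <- scores - stats::ave(scores, patient_id)
    vapply(c("non-MSI", "MSI"), function(g) {
        e <- err[label == g]
        if (!length(e)) NA_real_ else sqrt(mean(e^2))
    }, numeric(1))
}

#' Tissue-composition slide-selection analysis
#'
#' For each tissue category, classifies every multi-slide patient twice —
#' once using the slide with the *highest* tile count of that tissue, once
#' with the *lowest* — and compares the paired sensitivity/specificity.
#' Reported deltas are highest-minus-lowest (a negative specificity delta
#' for mucin means the lowest-mucin slide is the better choice);
#' significance per category and metric by exact McNemar on the discordant
#' patients. No multiple-comparison adjustment is applied.
#'
#' @param tissue_counts matrix `n_slides x n_categories` of per-slide tile
#'   counts (rownames = slide ids).
#' @param scores named numeric slide scores (names matching
#'   `tissue_counts` rows).
#' @param threshold operating threshold.
#' @param patient_id,label per-slide patient and patient label, aligned to
#'   `scores`.
#' @return data.frame: category, `delta_sensitivity`, `p_sensitivity`,
#'   `delta_specificity`, `p_specificity`, `n_patients`.
#' @export
compositionSlideSelection <- function(tissue_counts, scores, threshold,
                                      patient_id, label) {
    stopifnot(nrow(tissue_counts) == length(scores))
    if (is(threshold, "CalibrationResult")) threshold <- threshold@threshold
    pats <- split(seq_along(scores), patient_id)
    multi <- pats[lengths(pats) >= 2L]
    if (length(multi) < length(pats))
        warning(length(pats) - length(multi),
                " single-slide patient(s) excluded", call. = FALSE)
    patLabel <- vapply(multi, function(ix) as.character(label[ix[1]]),
                       character(1))
    res <- lapply(colnames(tissue_counts), function(cat) {
        hi <- vapply(multi, function(ix)
            ix[which.max(tissue_counts[ix, cat])], integer(1))
        lo <- vapply(multi, function(ix)
            ix[which.min(tissue_counts[ix, cat])], integer(1))
        clsHi <- classifyScore(scores[hi], threshold)
        clsLo <- classifyScore(scores[lo], threshold)
        one <- function(group, correct) {
            inG <- patLabel == group
            okHi <- clsHi[inG] == correct; okLo <- clsLo[inG] == correct
            d <- mean(okHi) - mean(okLo)
            p <- mcnemarExact(sum(okHi & !okLo), sum(!okHi & okLo))
            c(d, p)
        }
        s <- suppressWarnings(one("MSI", "Undetermined"))
        sp <- suppressWarnings(one("non-MSI", "MSS-AI"))
        data.frame(category = cat, delta_sensitivity = s[1],
                   p_sensitivity = s[2], delta_specificity = sp[1],
                   p_specificity = sp[2], n_patients = length(multi))
    })
    do.call(rbind, res)
}
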