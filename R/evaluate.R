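# Screening-performance evaluation. Confusion matrices use the screening
# orientation: rows {non-MSI, MSI} x columns {MSS-AI, Undetermined}, with
# "Undetermined" the positive (flagged) call. Sensitivity is the share of
# MSI slides flagged Undetermined; specificity the share of non-MSI slides
# ruled out; NPV the share of MSS-AI calls that are truly non-MSI.

# round-half-up for report display (base round() is round-half-even)
roundHalfUp <- function(x, digits = 2) {
    s <- 10^digits
    sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Confusion counts in the screening orientation
#'
#' @param labels vector of true labels, `"MSI"` / `"non-MSI"`.
#' @param classes vector of screening calls, `"MSS-AI"` / `"Undetermined"`,
#'   aligned to `labels`.
#' @return 2x2 integer matrix, rows `non-MSI`/`MSI`, columns
#'   `MSS-AI`/`Undetermined`.
#' @export
confusionCounts <- function(labels, classes) {
    if (length(labels) == 0L)
        stop("validation error: empty input", call. = FALSE)
    if (length(labels) != length(classes))
        stop("validation error: labels and classes differ in length",
             call. = FALSE)
    labels <- factor(as.character(labels), c("non-MSI", "MSI"))
    classes <- factor(as.character(classes), CLASS_LEVELS)
    if (anyNA(labels) || anyNA(classes))
        stop("validation error: labels must be MSI/non-MSI and classes ",
             "MSS-AI/Undetermined", call. = FALSE)
    unclass(table(labels, classes))
}

# build the 2x2 matrix from the four counts (paper table layout)
asCounts <- function(nonmsi_mssai, nonmsi_undet, msi_mssai, msi_undet) {
    matrix(as.integer(c(nonmsi_mssai, msi_mssai, nonmsi_undet, msi_undet)),
           2, 2, dimnames = list(labels = c("non-MSI", "MSI"),
                                 classes = CLASS_LEVELS))
}

#' Point screening metrics from confusion counts
#'
#' Sensitivity = MSI flagged Undetermined / all MSI; specificity = non-MSI
#' ruled out / all non-MSI; NPV = true non-MSI among MSS-AI calls. A metric
#' whose denominator is zero is reported as `NA` (undefined). Also computes
#' the rule-out enrichment (see [enrichment()]).
#'
#' @param counts 2x2 matrix from [confusionCounts()].
#' @return a [ScreenMetrics-class] (AUROC slot `NA`; see [aurocScore()]).
#' @export
screenMetrics <- function(counts) {
    stopifnot(is.matrix(counts), all(dim(counts) == 2L), all(counts >= 0))
    tn <- counts["non-MSI", "MSS-AI"]; fp <- counts["non-MSI", "Undetermined"]
    fn <- counts["MSI", "MSS-AI"];     tp <- counts["MSI", "Undetermined"]
    div <- function(a, b) if (b > 0) a / b else NA_real_
    new("ScreenMetrics", counts = counts,
        sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
        npv = div(tn, tn + fn), auroc = NA_real_, ci95 = list(),
        n = as.integer(sum(counts)), n_msi = as.integer(tp + fn),
        enrichment_pct = enrichment(counts))
}

#' Rule-out enrichment of MSI prevalence
#'
#' Percent increase of MSI prevalence among Undetermined calls relative to
#' the whole cohort: `100 * ((tp / undetermined) / (msi / n) - 1)`.
#' A screen that rules nobody out has enrichment 0.
#'
#' @param counts 2x2 matrix from [confusionCounts()].
#' @return raw percentage (round for display).
#' @export
enrichment <- function(counts) {
    undet <- sum(counts[, "Undetermined"])
    nMsi <- sum(counts["MSI", ])
    n <- sum(counts)
    if (undet == 0 || nMsi == 0) return(NA_real_)
    100 * ((counts["MSI", "Undetermined"] / undet) / (nMsi / n) - 1)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random MSI slide scores above a random non-MSI slide,
#' ties counting one half — computed from midranks, so it is exact under
#' ties and invariant to strictly monotone score transforms.
#'
#' @param scores numeric slide scores.
#' @param labels aligned labels, `"MSI"` (positive) / `"non-MSI"`, or 0/1.
#' @export
aurocScore <- function(scores, labels) {
    y <- if (is.numeric(labels)) labels == 1 else as.character(labels) == "MSI"
    n1 <- sum(y); n0 <- sum(!y)
    if (n1 == 0L || n0 == 0L)
        stop("validation error: AUROC needs both classes", call. = FALSE)
    r <- rank(scores, ties.method = "average")
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for a cohort metric
#'
#' Resamples *patients* with replacement (slides of a resampled patient are
#' carried along, so with one slide per patient this is a slide bootstrap)
#' and returns the 2.5/97.5 percentile interval of the metric over `B`
#' seeded resamples.
#'
#' @param records data.frame with one row per slide and at least a
#'   `patient_id` column plus whatever `metric_fn` needs (`label`, `class`,
#'   `score`, ...).
#' @param metric_fn function `records -> scalar`; may return `NA` when
#'   undefined on a resample.
#' @param B repetitions (default 1000).
#' @param seed RNG seed.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrapCi <- function(records, metric_fn, B = 1000L, seed = 1L) {
    stopifnot(B >= 1L, "patient_id" %in% colnames(records))
    pats <- unique(records$patient_id)
    byPat <- split(seq_len(nrow(records)), records$patient_id)
    set.seed(seed)
    vals <- vapply(seq_len(B), function(b) {
        take <- sample(pats, length(pats), replace = TRUE)
        metric_fn(records[unlist(byPat[take], use.names = FALSE), ,
                          drop = FALSE])
    }, numeric(1))
    nBad <- sum(is.na(vals))
    if (nBad > B / 2)
        stop("metric undefined in ", nBad, "/", B, " bootstrap resamples",
             call. = FALSE)
    stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE) |>
        stats::setNames(c("lo", "hi"))
}

#' Evaluate a scored cohort
#'
#' Convenience wrapper: confusion counts, point metrics, AUROC and
#' patient-level bootstrap CIs for sensitivity, specificity and NPV.
#'
#' @param records data.frame with columns `patient_id`, `label`, `score`,
#'   `class`.
#' @param B bootstrap repetitions; 0 skips CIs.
#' @param seed bootstrap seed.
#' @return a [ScreenMetrics-class] with `ci95` filled in.
#' @export
evaluateScreen <- function(records, B = 1000L, seed = 1L) {
    cm <- confusionCounts(records$label, records$class)
    m <- screenMetrics(cm)
    m@auroc <- aurocScore(records$score, records$label)
    if (B > 0) {
        mk <- function(f) function(r) {
            cc <- confusionCounts(r$label, r$class); f(cc)
        }
        sens <- function(cc) { x <- screenMetrics(cc); x@sensitivity }
        spec <- function(cc) { x <- screenMetrics(cc); x@specificity }
        npv <- function(cc) { x <- screenMetrics(cc); x@npv }
        m@ci95 <- list(
            sensitivity = bootstrapCi(records, mk(sens), B, seed),
            specificity = bootstrapCi(records, mk(spec), B, seed + 1L),
            npv = bootstrapCi(records, mk(npv), B, seed + 2L))
    }
    m
}

setMethod("show", "ScreenMetrics", function(object) {
    fmt <- function(v) ifelse(is.na(v), "NA",
                              sprintf("%.2f", roundHalfUp(v, 2)))
    ci <- function(nm) {
        if (is.null(object@ci95[[nm]])) return("")
        sprintf(" (95%% CI: %.2f-%.2f)", object@ci95[[nm]]["lo"],
                object@ci95[[nm]]["hi"])
    }
    cat(sprintf("ScreenMetrics on n = %d slides (MSI %d):\n", object@n,
                object@n_msi))
    print(object@counts)
    cat(sprintf("  sensitivity %s%s\n", fmt(object@sensitivity),
                ci("sensitivity")))
    cat(sprintf("  specificity %s%s\n", fmt(object@specificity),
                ci("specificity")))
    cat(sprintf("  NPV         %s%s\n", fmt(object@npv), ci("npv")))
    if (!is.na(object@auroc))
        cat(sprintf("  AUROC       %s\n", fmt(object@auroc)))
    if (!is.na(object@enrichment_pct))
        cat(sprintf("  rule-out enrichment: %d%%\n",
                    round(object@enrichment_pct)))
})
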