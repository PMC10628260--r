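test_that("confusion counts reproduce the screening-cohort tables", {
    cm <- cohortACounts()
    rec <- countsToRecords(cm)
    back <- confusionCounts(rec$label, rec$class)
    expect_identical(unname(back), unname(cm))
    expect_identical(sum(back), 537L)

    expect_error(confusionCounts(character(), character()), "empty")
    expect_error(confusionCounts(c("MSI", "non-MSI"), "MSS-AI"), "length")
    allU <- confusionCounts(c("MSI", "non-MSI"),
                            c("Undetermined", "Undetermined"))
    expect_identical(unname(allU[, "MSS-AI"]), c(0L, 0L))
})

test_that("screening metrics match the published two-decimal values", {
    m1 <- screenMetrics(cohortACounts())
    expect_identical(msiScreen:::roundHalfUp(m1@sensitivity, 2), 0.98)
    expect_identical(msiScreen:::roundHalfUp(m1@specificity, 2), 0.46)
    expect_identical(msiScreen:::roundHalfUp(m1@npv, 2), 0.99)
    expect_identical(m1@n, 537L)
    expect_identical(m1@n_msi, 83L)

    m2 <- screenMetrics(cohortBCounts())
    expect_identical(msiScreen:::roundHalfUp(m2@specificity, 2), 0.47)
    expect_identical(msiScreen:::roundHalfUp(m2@npv, 2), 0.98)

    perfect <- msiScreen:::asCounts(100, 0, 0, 20)
    mp <- screenMetrics(perfect)
    expect_identical(c(mp@sensitivity, mp@specificity, mp@npv), c(1, 1, 1))
})

test_that("metrics with empty denominators are reported as undefined", {
    noMsi <- msiScreen:::asCounts(50, 30, 0, 0)
    m <- screenMetrics(noMsi)
    expect_true(is.na(m@sensitivity))
    expect_false(is.na(m@specificity))
})

test_that("screen metrics agree with hand formulas on random matrices", {
    set.seed(41)
    for (i in 1:100) {
        cc <- msiScreen:::asCounts(sample(1:200, 1), sample(1:200, 1),
                                   sample(1:50, 1), sample(1:50, 1))
        m <- screenMetrics(cc)
        tn <- cc[1, 1]; fp <- cc[1, 2]; fn <- cc[2, 1]; tp <- cc[2, 2]
        expect_equal(m@sensitivity, tp / (tp + fn))
        expect_equal(m@specificity, tn / (tn + fp))
        expect_equal(m@npv, tn / (tn + fn))
        expect_equal(m@enrichment_pct,
                     100 * ((tp / (tp + fp)) / ((tp + fn) / sum(cc)) - 1))
    }
})

test_that("rule-out enrichment reproduces the 60% published value", {
    expect_identical(round(enrichment(cohortACounts())), 60)
    # a screen that rules out nobody does not enrich
    expect_equal(enrichment(msiScreen:::asCounts(0, 80, 0, 20)), 0)
    # ruling out only non-MSI slides enriches by the prevalence ratio
    cc <- msiScreen:::asCounts(40, 60, 0, 25)
    expect_equal(enrichment(cc),
                 100 * ((25 / 85) / (25 / 125) - 1))
})

test_that("AUROC equals exhaustive pair counting and handles ties", {
    set.seed(51)
    for (i in 1:30) {
        n <- sample(8:25, 1)
        scores <- round(runif(n), 1)
        labels <- c("MSI", "non-MSI", sample(c("MSI", "non-MSI"), n - 2,
                                             replace = TRUE))
        pos <- scores[labels == "MSI"]; neg <- scores[labels != "MSI"]
        pairs <- outer(pos, neg, function(a, b)
            (a > b) + 0.5 * (a == b))
        expect_equal(aurocScore(scores, labels), mean(pairs))
    }
    expect_identical(aurocScore(c(3, 4, 1, 2), c("MSI", "MSI", "non-MSI",
                                                 "non-MSI")), 1)
    expect_error(aurocScore(1:4, rep("MSI", 4)), "both classes")
})

test_that("AUROC is invariant to strictly monotone score transforms", {
    set.seed(52)
    scores <- rnorm(100)
    labels <- ifelse(runif(100) < plogis(scores), "MSI", "non-MSI")
    a <- aurocScore(scores, labels)
    expect_equal(aurocScore(exp(scores), labels), a)
    expect_equal(aurocScore(qlogis(plogis(scores)), labels), a)
})

test_that("AUROC agrees with an independent implementation", {
    skip_if_not_installed("pROC")
    set.seed(53)
    scores <- round(rnorm(300), 1)    # heavy ties
    labels <- sample(c("MSI", "non-MSI"), 300, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = scores, levels = c("non-MSI", "MSI"),
        direction = "<", quiet = TRUE)))
    expect_equal(aurocScore(scores, labels), ref, tolerance = 1e-12)
})

test_that("scores independent of labels give AUROC near one half", {
    set.seed(54)
    scores <- runif(4000)
    labels <- sample(c("MSI", "non-MSI"), 4000, replace = TRUE)
    expect_lt(abs(aurocScore(scores, labels) - 0.5), 0.03)
})

test_that("bootstrap CIs are seeded, centred and degenerate when constant", {
    rec <- countsToRecords(cohortACounts())
    sens <- function(r) {
        cc <- confusionCounts(r$label, r$class)
        cc["MSI", "Undetermined"] / sum(cc["MSI", ])
    }
    ci1 <- bootstrapCi(rec, sens, B = 200L, seed = 5L)
    ci2 <- bootstrapCi(rec, sens, B = 200L, seed = 5L)
    expect_identical(ci1, ci2)
    point <- sens(rec)
    expect_lte(ci1["lo"], point)
    expect_gte(ci1["hi"], point)

    # constant metric gives a zero-width interval
    const <- bootstrapCi(rec, function(r) 0.7, B = 50L, seed = 1L)
    expect_identical(unname(const), c(0.7, 0.7))
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
    set.seed(61)
    width <- vapply(c(100L, 400L, 1600L), function(n) {
        lab <- sample(c("MSI", "non-MSI"), n, replace = TRUE,
                      prob = c(0.3, 0.7))
        cls <- ifelse(lab == "MSI",
                      sample(c("Undetermined", "MSS-AI"), n, TRUE,
                             prob = c(0.9, 0.1)),
                      sample(c("Undetermined", "MSS-AI"), n, TRUE))
        rec <- data.frame(patient_id = sprintf("p%d", seq_len(n)),
                          label = lab, class = cls)
        sens <- function(r) {
            cc <- confusionCounts(r$label, r$class)
            cc["MSI", "Undetermined"] / sum(cc["MSI", ])
        }
        ci <- bootstrapCi(rec, sens, B = 300L, seed = 7L)
        ci["hi"] - ci["lo"]
    }, numeric(1))
    expect_true(all(diff(width) < 0))
})

test_that("evaluateScreen assembles counts, AUROC and CIs coherently", {
    rec <- countsToRecords(cohortBCounts())
    m <- evaluateScreen(rec, B = 100L, seed = 3L)
    expect_identical(m@n, 554L)
    expect_identical(unname(m@counts), unname(cohortBCounts()))
    expect_gt(m@auroc, 0.9)   # scores were constructed separable
    for (nm in c("sensitivity", "specificity", "npv")) {
        ci <- m@ci95[[nm]]
        expect_lte(ci["lo"], slot(m, nm))
        expect_gte(ci["hi"], slot(m, nm))
    }
})
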