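# independent brute-force oracles, written against the textbook formulas
# with naive loops (deliberately different code paths from the package)
oracleCohen <- function(a, b) {
    lev <- unique(c(a, b))
    n <- length(a)
    po <- sum(a == b) / n
    pe <- 0
    for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
    (po - pe) / (1 - pe)
}
oracleFleiss <- function(ratings) {
    lev <- unique(as.character(ratings))
    N <- nrow(ratings); m <- ncol(ratings)
    cnt <- matrix(0, N, length(lev))
    for (i in seq_len(N)) for (j in seq_len(m))
        cnt[i, match(as.character(ratings[i, j]), lev)] <-
            cnt[i, match(as.character(ratings[i, j]), lev)] + 1
    Pi <- numeric(N)
    for (i in seq_len(N)) Pi[i] <- (sum(cnt[i, ]^2) - m) / (m * (m - 1))
    pj <- colSums(cnt) / (N * m)
    (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}
oracleMcnemar <- function(b, c) {
    n <- b + c
    dev <- abs(b - n / 2)
    sum(dbinom(0:n, n, 0.5)[abs(0:n - n / 2) >= dev - 1e-9])
}

test_that("Cohen's kappa: perfect, chance and hand-computed cases", {
    a <- c("+", "+", "-", "-")
    expect_identical(cohensKappa(a, a), 1)
    expect_identical(cohensKappa(a, c("+", "-", "+", "-")), 0)
    expect_error(cohensKappa(a, a[1:3]), "length")
    expect_error(cohensKappa(rep("+", 5), rep("+", 5)), "undefined")
})

test_that("Cohen's kappa matches the textbook oracle and is symmetric", {
    set.seed(71)
    for (i in 1:50) {
        n <- sample(20:200, 1)
        a <- sample(c("MSS-AI", "Undetermined"), n, replace = TRUE)
        b <- ifelse(runif(n) < 0.7, a,
                    sample(c("MSS-AI", "Undetermined"), n, replace = TRUE))
        expect_equal(cohensKappa(a, b), oracleCohen(a, b),
                     tolerance = 1e-12)
        expect_equal(cohensKappa(a, b), cohensKappa(b, a),
                     tolerance = 1e-12)
    }
})

test_that("Fleiss' kappa: perfect agreement, the 4/4 split, and the oracle", {
    allAgree <- cbind(rep("A", 10), rep("A", 10), rep("A", 10))
    allAgree[1:5, ] <- "B"
    expect_identical(fleissKappa(allAgree), 1)
    # every subject split 4/4 over two categories: kappa = -1/7 exactly
    split44 <- matrix(rep(c("A", "B"), each = 4), 6, 8, byrow = TRUE)
    expect_equal(fleissKappa(split44), -1 / 7)
    set.seed(72)
    for (i in 1:20) {
        r <- matrix(sample(c("X", "Y", "Z"), 30 * 8, replace = TRUE), 30, 8)
        expect_equal(fleissKappa(r), oracleFleiss(r), tolerance = 1e-12)
    }
    expect_error(fleissKappa(matrix("A", 1, 8)), "2 subjects")
    expect_error(fleissKappa(cbind(c("A", "B"), c("A", NA))), "ragged")
})

test_that("two-rater Fleiss equals Cohen when rater marginals coincide", {
    a <- c("A", "A", "B", "B")
    b <- c("A", "B", "A", "B")
    expect_equal(fleissKappa(cbind(a, b)), cohensKappa(a, b),
                 tolerance = 1e-9)
    expect_equal(fleissKappa(cbind(a, a)), cohensKappa(a, a),
                 tolerance = 1e-9)
})

test_that("Pearson test reproduces hand computation and flags degeneracy", {
    x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
    y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12.3, 13.9, 16.2, 18.1, 19.7)
    res <- pearsonTest(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt(8 / (1 - r^2))
    expect_equal(res$r, r, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
    expect_equal(pearsonTest(x, x)$r, 1)
    expect_equal(pearsonTest(x, -x)$r, -1)
    expect_error(pearsonTest(x, rep(1, 10)), "constant")
    expect_error(pearsonTest(1:2, 2:1), "at least 3")
})

test_that("exact McNemar matches the binomial-sum oracle exhaustively", {
    expect_identical(mcnemarExact(5, 5), 1)
    expect_equal(mcnemarExact(10, 0), 2 * 0.5^10)
    expect_warning(p0 <- mcnemarExact(0, 0), "no discordant")
    expect_identical(p0, 1)
    for (n in 0:30) for (b in 0:n) {
        p <- if (n == 0) suppressWarnings(mcnemarExact(b, n - b))
        else mcnemarExact(b, n - b)
        expect_equal(p, min(1, oracleMcnemar(b, n - b)), tolerance = 1e-12)
    }
})

test_that("inter-block RMSE: hand cases and the variance decomposition", {
    # all slides of each patient identical -> zero error in both groups
    s <- c(0.2, 0.2, 0.8, 0.8)
    r <- suppressWarnings(interblockRmse(s, c("p1", "p1", "p2", "p2"),
                                         c("non-MSI", "non-MSI",
                                           "MSI", "MSI")))
    expect_equal(unname(r), c(0, 0))
    # two-slide patient scoring 0.4/0.6: errors are +-0.1, RMSE 0.1
    r2 <- interblockRmse(c(0.4, 0.6), c("p", "p"), c("MSI", "MSI"))
    expect_equal(unname(r2["MSI"]), 0.1)
    expect_true(is.na(r2["non-MSI"]))
    # singletons are excluded with a warning
    expect_warning(
        r3 <- interblockRmse(c(0.4, 0.6, 0.9), c("p", "p", "q"),
                             c("MSI", "MSI", "MSI")), "single slide")
    expect_equal(unname(r3["MSI"]), 0.1)
    # k slides per patient with iid noise sigma: RMSE -> sigma*sqrt((k-1)/k)
    set.seed(81)
    k <- 4L; nPat <- 400L; sigma <- 0.05
    pat <- rep(sprintf("p%03d", seq_len(nPat)), each = k)
    scores <- rep(runif(nPat, 0.3, 0.7), each = k) +
        rnorm(nPat * k, 0, sigma)
    r4 <- interblockRmse(scores, pat, rep("MSI", nPat * k))
    expect_equal(unname(r4["MSI"]), sigma * sqrt((k - 1) / k),
                 tolerance = 0.08)
})

test_that("slide-selection composition analysis detects a mucin artefact", {
    # identical slides per patient: all deltas 0, p = 1
    cnt <- matrix(5, 6, 2, dimnames = list(NULL, c("TUM", "MUC")))
    s <- rep(c(0.8, 0.1, 0.9), each = 2)
    res <- suppressWarnings(compositionSlideSelection(
        cnt, s, 0.5, rep(c("p1", "p2", "p3"), each = 2),
        rep(c("MSI", "non-MSI", "MSI"), each = 2)))
    expect_true(all(res$delta_sensitivity == 0))
    expect_true(all(res$delta_specificity == 0))
    expect_true(all(res$p_sensitivity == 1 & res$p_specificity == 1))

    # constructed effect: in non-MSI patients the high-mucin slide scores
    # above threshold (false positive), the low-mucin slide below
    nPat <- 40L
    pat <- rep(sprintf("p%02d", seq_len(nPat)), each = 2)
    muc <- rep(c(10, 100), nPat)             # slide 1 low, slide 2 high
    scores <- rep(c(0.2, 0.7), nPat)         # high mucin -> high score
    cnt2 <- cbind(TUM = rep(50, 2 * nPat), MUC = muc)
    res2 <- compositionSlideSelection(cnt2, scores, 0.5, pat,
                                      rep("non-MSI", 2 * nPat))
    mucRow <- res2[res2$category == "MUC", ]
    # highest-minus-lowest: choosing the high-mucin slide costs specificity
    expect_lt(mucRow$delta_specificity, 0)
    expect_lt(mucRow$p_specificity, 0.001)
})
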