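test_that("extreme pooling matches the full-sort oracle on random vectors", {
    set.seed(21)
    for (i in 1:200) {
        n <- sample(20:120, 1)
        R <- sample(1:10, 1)
        s <- round(rnorm(n), sample(0:2, 1))  # rounding provokes ties
        srt <- sort(s, decreasing = TRUE)
        expect_identical(extremePool(s, R),
                         c(srt[seq_len(R)], rev(srt)[seq_len(R)]))
    }
})

test_that("extreme pooling handles boundaries, ties and permutations", {
    expect_identical(extremePool(1:25, 10L), c(25:16, 1:10))
    expect_identical(extremePool(rep(3, 20), 10L), rep(3, 20))
    s <- rnorm(40)
    p <- extremePool(s, 10L)
    for (i in 1:5) expect_identical(extremePool(sample(s), 10L), p)
    expect_error(extremePool(rnorm(19), 10L), "insufficient tiles")
    # ties resolved by lowest tile index: duplicate max keeps the top block
    s2 <- c(5, 1, 2, 3, 4, 5)
    idx <- msiScreen:::.extremeIdx(s2, 2L)
    expect_identical(idx$top, c(1L, 6L))
    expect_identical(idx$bottom, c(2L, 3L))
})

test_that("adding a duplicate of the current maximum only re-ties the top", {
    set.seed(5)
    s <- rnorm(50)
    R <- 10L
    p <- extremePool(s, R)
    p2 <- extremePool(c(s, max(s)), R)
    expect_identical(p2[1:2], rep(max(s), 2))
    expect_identical(p2[3:R], p[2:(R - 1)])
    expect_identical(p2[(R + 1):(2 * R)], p[(R + 1):(2 * R)])
})

test_that("tile scores are deterministic, aligned and permutation-equivariant", {
    fx <- fxTrainedModel()
    co <- fxSeparableCohort()
    bag <- co$bags[[2]]
    s1 <- tileScores(bag, fx$model)
    expect_identical(tileScores(bag, fx$model), s1)
    expect_true(all(s1 >= 0 & s1 <= 1))
    set.seed(2)
    perm <- sample(nTiles(bag))
    expect_equal(tileScores(msiScreen:::subsetBag(bag, perm), fx$model),
                 s1[perm], tolerance = 1e-12)
    # identical tiles score identically (up to BLAS summation order)
    one <- msiScreen:::subsetBag(bag, rep(1L, 25L))
    sOne <- tileScores(one, fx$model)
    expect_lt(max(sOne) - min(sOne), 1e-12)
    bad <- FeatureBag(matrix(0, 25, 5), slide_id = "bad")
    expect_error(tileScores(bad, fx$model), "configuration error")
})

test_that("slide score is a tile-order-invariant probability", {
    fx <- fxTrainedModel()
    co <- fxSeparableCohort()
    for (sid in co$manifest$slide_id[3:6]) {
        bag <- co$bags[[sid]]
        s <- slideScore(bag, fx$model)
        expect_true(s >= 0 && s <= 1)
        set.seed(match(sid, co$manifest$slide_id))
        perm <- msiScreen:::subsetBag(bag, sample(nTiles(bag)))
        expect_lt(abs(slideScore(perm, fx$model) - s), 1e-6)
    }
})

test_that("the 2R extreme tiles are sufficient statistics for the score", {
    fx <- fxTrainedModel()
    co <- fxSeparableCohort()
    bag <- co$bags[[7]]
    s <- tileScores(bag, fx$model)
    idx <- msiScreen:::.extremeIdx(s, fx$model@poolWidth)
    sub <- msiScreen:::subsetBag(bag, c(idx$top, idx$bottom))
    expect_equal(slideScore(sub, fx$model), slideScore(bag, fx$model),
                 tolerance = 1e-12)
})

test_that("an untrained randomly initialised model emits finite scores", {
    p <- msiScreen:::chowderInit(8L, 10L, seed = 3L)
    m <- msiScreen:::.paramsToModel(p, 10L, 8L, 3L, c(`0` = 1, `1` = 1),
                                    trainConfig())
    bag <- FeatureBag(matrix(rnorm(200 * 8), 200, 8), slide_id = "r")
    s <- slideScore(bag, m)
    expect_true(is.finite(s) && s >= 0 && s <= 1)
})

test_that("class-weighted BCE reduces to unweighted at 50% prevalence", {
    y <- rep(c(0, 1), each = 8)
    w <- msiScreen:::balancedClassWeights(y)
    expect_identical(unname(w), c(1, 1))
    set.seed(6)
    p <- runif(16)
    expect_equal(msiScreen:::weightedBce(p, y, unname(w[as.character(y)])),
                 -mean(y * log(p) + (1 - y) * log(1 - p)))
    # imbalanced prevalence: weights are inverse-prevalence, mean 1
    y2 <- c(rep(0, 9), 1)
    w2 <- msiScreen:::balancedClassWeights(y2)
    expect_equal(unname(w2), c(1 / (2 * 0.9), 1 / (2 * 0.1)))
    expect_equal(mean(w2[as.character(y2)]), 1)
})

test_that("training is reproducible and validates its inputs", {
    co <- fxTinyCohort()
    bags <- co$bags
    lab <- co$manifest$label
    cfg <- pipelineConfig(feature_dim = 8L, pool_width = 3L)
    tc <- trainConfig(epochs = 8L, seed = 4L)
    m1 <- trainChowder(bags, lab, tc, cfg)
    m2 <- trainChowder(bags, lab, tc, cfg)
    expect_identical(m1@scorerW1, m2@scorerW1)
    expect_identical(m1@headW2, m2@headW2)
    expect_error(trainChowder(bags, rep("MSI", length(bags)), tc, cfg),
                 "both classes")
    tiny <- lapply(bags, function(b) msiScreen:::subsetBag(b, 1:4))
    expect_error(trainChowder(tiny, lab, tc, cfg), "tiles")
})

test_that("mini-batch training is seeded and produces a working model", {
    co <- fxTinyCohort()
    cfg <- pipelineConfig(feature_dim = 8L, pool_width = 3L)
    tc <- trainConfig(epochs = 6L, batch_size = 3L, seed = 9L)
    m1 <- trainChowder(co$bags, co$manifest$label, tc, cfg)
    m2 <- trainChowder(co$bags, co$manifest$label, tc, cfg)
    expect_identical(m1@scorerW1, m2@scorerW1)
    s <- scoreBags(co$bags, m1)
    expect_true(all(is.finite(s) & s >= 0 & s <= 1))
})

test_that("model artifacts round-trip through JSON serialisation", {
    fx <- fxTrainedModel()
    f <- tempfile(fileext = ".json")
    writeChowderModel(fx$model, f)
    back <- readChowderModel(f)
    co <- fxSeparableCohort()
    bag <- co$bags[[9]]
    expect_equal(slideScore(bag, back), slideScore(bag, fx$model),
                 tolerance = 1e-12)
    expect_identical(back@poolWidth, fx$model@poolWidth)
    expect_identical(back@seed, fx$model@seed)
})
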