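# Chowder-variant MIL classifier.
#
# Tile scorer: features -> 128 hidden (sigmoid) -> 1 sigmoid score, applied
# to every tile; the scorer output passes a sigmoid so per-tile heatmap
# scores live in [0, 1]. Extreme pooling keeps the R largest scores
# (descending) followed by the R smallest (ascending), ties broken by
# lowest tile index. Aggregation head: 2R -> 128 -> 64 -> 1, sigmoid
# activations and sigmoid output. Trained with class-weighted binary
# cross-entropy (weights inversely proportional to class prevalence) by
# Adam; tile features are frozen inputs, never updated.

# indices of the R largest (descending) and R smallest (ascending) scores,
# stable in tile index on ties
.extremeIdx <- function(scores, R) {
    n <- length(scores)
    if (n < 2L * R)
        stop("insufficient tiles: ", n, " scores but pooling needs ", 2L * R,
             call. = FALSE)
    list(top = order(scores, decreasing = TRUE, method = "radix")[seq_len(R)],
         bottom = order(scores, method = "radix")[seq_len(R)])
}

#' Extreme (top/bottom) score pooling
#'
#' Concatenates the R largest tile scores in descending order with the R
#' smallest in ascending order. Requires at least 2R scores (guaranteed
#' after QC, since the 500-tile cut-off far exceeds 2R = 20); ties are
#' broken by lowest tile index, making the pooling deterministic and
#' invariant to any permutation of the input.
#'
#' @param scores numeric vector of per-tile scores.
#' @param R pooling width (default 10).
#' @return numeric vector of length `2R`.
#' @examples
#' extremePool(c(5, 1, 4, 2, 3), R = 2)  # 5 4 1 2
#' @export
extremePool <- function(scores, R = 10L) {
    idx <- .extremeIdx(scores, R)
    c(scores[idx$top], scores[idx$bottom])
}

# seeded parameter initialisation for the fixed architecture
chowderInit <- function(featureDim, R = 10L, seed = 1L) {
    set.seed(seed)
    list(sW1 = glorot(128L, featureDim), sb1 = numeric(128L),
         sw2 = stats::runif(128L, -sqrt(6 / 129), sqrt(6 / 129)), sb2 = 0,
         hW1 = glorot(128L, 2L * R), hb1 = numeric(128L),
         hW2 = glorot(64L, 128L), hb2 = numeric(64L),
         hw3 = stats::runif(64L, -sqrt(6 / 65), sqrt(6 / 65)), hb3 = 0)
}

.paramsToModel <- function(params, R, d, seed, classWeights, tcfg) {
    new("ChowderModel", scorerW1 = params$sW1, scorerB1 = params$sb1,
        scorerW2 = params$sw2, scorerB2 = params$sb2,
        headW1 = params$hW1, headB1 = params$hb1,
        headW2 = params$hW2, headB2 = params$hb2,
        headW3 = params$hw3, headB3 = params$hb3,
        poolWidth = as.integer(R), featureDim = as.integer(d),
        seed = as.integer(seed), classWeights = classWeights,
        trainConfig = unclass(tcfg))
}

.modelToParams <- function(model) {
    list(sW1 = model@scorerW1, sb1 = model@scorerB1, sw2 = model@scorerW2,
         sb2 = model@scorerB2, hW1 = model@headW1, hb1 = model@headB1,
         hW2 = model@headW2, hb2 = model@headB2, hw3 = model@headW3,
         hb3 = model@headB3)
}

# scorer forward over a feature matrix; returns list(H = hidden, s = scores)
.scorerForward <- function(params, X) {
    H <- sigmoid(X %*% t(params$sW1) + rep(1, nrow(X)) %o% params$sb1)
    list(H = H, s = as.numeric(sigmoid(H %*% params$sw2 + params$sb2)))
}

# head forward over pooled matrix P (n_slides x 2R)
.headForward <- function(params, P) {
    H1 <- sigmoid(P %*% t(params$hW1) + rep(1, nrow(P)) %o% params$hb1)
    H2 <- sigmoid(H1 %*% t(params$hW2) + rep(1, nrow(P)) %o% params$hb2)
    y <- as.numeric(sigmoid(H2 %*% params$hw3 + params$hb3))
    list(H1 = H1, H2 = H2, y = y)
}

#' @describeIn slideScore per-tile MSI scores under a Chowder model.
#' @export
setMethod("tileScores", signature("FeatureBag", "ChowderModel"),
    function(bag, model) {
        X <- bagFeatures(bag)
        if (ncol(X) != model@featureDim)
            stop("configuration error: bag has ", ncol(X),
                 " feature dims, model expects ", model@featureDim,
                 call. = FALSE)
        .scorerForward(.modelToParams(model), X)$s
    })

#' @describeIn slideScore slide probability from a bag.
#' @export
setMethod("slideScore", signature("FeatureBag", "ChowderModel"),
    function(bag, model) {
        p <- extremePool(tileScores(bag, model), model@poolWidth)
        .headForward(.modelToParams(model), matrix(p, 1L))$y
    })

#' Train the Chowder-variant MIL classifier
#'
#' Minimises class-weighted binary cross-entropy over slides, with class
#' weights inversely proportional to class prevalence in the training set
#' (at 50% prevalence the loss is exactly unweighted). The per-slide
#' training tile cap (`cfg$max_train_tiles`, default 8,000) is applied
#' before training; features are frozen inputs. Fully deterministic given
#' the data and `tcfg$seed`.
#'
#' @param bags list of [FeatureBag-class] training slides.
#' @param labels vector aligned to `bags`: `"MSI"`/`"non-MSI"` (or 1/0).
#' @param tcfg a [trainConfig()].
#' @param cfg a [pipelineConfig()] (pool width, training tile cap).
#' @return a [ChowderModel-class]
#' @export
trainChowder <- function(bags, labels, tcfg = trainConfig(),
                         cfg = pipelineConfig(feature_dim =
                                              featureDim(bags[[1]]))) {
    y <- if (is.numeric(labels)) as.numeric(labels)
    else as.numeric(as.character(labels) == "MSI")
    if (length(unique(y)) < 2L)
        stop("validation error: training set must contain both classes",
             call. = FALSE)
    R <- cfg$pool_width
    bags <- lapply(seq_along(bags), function(i)
        subsampleTrainingTiles(bags[[i]], cfg, seed = tcfg$seed + i))
    sizes <- vapply(bags, nTiles, integer(1))
    if (any(sizes < 2L * R))
        stop("validation error: every training bag needs >= ", 2L * R,
             " tiles after subsampling", call. = FALSE)
    d <- featureDim(bags[[1]])
    Xall <- do.call(rbind, lapply(bags, bagFeatures))
    ends <- cumsum(sizes)
    rows <- lapply(seq_along(bags),
                   function(i) (c(0L, ends)[i] + 1L):ends[i])
    cw <- balancedClassWeights(y)
    w <- unname(cw[as.character(y)])
    nS <- length(bags)

    batch <- if (is.finite(tcfg$batch_size))
        min(as.integer(tcfg$batch_size), nS) else nS
    fits <- lapply(seq_len(tcfg$n_restarts), function(k)
        .chowderFit(Xall, rows, sizes, y, w, d, R, tcfg, batch,
                    initSeed = tcfg$seed + 1000L * (k - 1L)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "loss"))]]
    .paramsToModel(best$params, R, d, tcfg$seed, cw, tcfg)
}

# one seeded optimisation run; returns the parameters and the final
# (class-weighted) epoch loss used for restart selection
.chowderFit <- function(Xall, rows, sizes, y, w, d, R, tcfg, batch,
                        initSeed) {
    nS <- length(rows)
    params <- chowderInit(d, R, initSeed)
    st <- adamInit(params)
    set.seed(initSeed + 10007L)
    bestLoss <- Inf; wait <- 0; epLoss <- Inf
    for (ep in seq_len(tcfg$epochs)) {
        ord <- if (batch < nS) sample.int(nS) else seq_len(nS)
        epLoss <- 0
        for (start in seq(1L, nS, by = batch)) {
            sl <- ord[start:min(start + batch - 1L, nS)]
            tIdx <- unlist(rows[sl], use.names = FALSE)
            sf <- .scorerForward(params, Xall[tIdx, , drop = FALSE])
            # local tile positions of each batch slide within tIdx
            local <- split(seq_along(tIdx),
                           rep(seq_along(sl), sizes[sl]))
            P <- matrix(0, length(sl), 2L * R)
            selLocal <- integer(length(sl) * 2L * R)
            for (j in seq_along(sl)) {
                li <- local[[j]]
                ei <- .extremeIdx(sf$s[li], R)
                sel <- li[c(ei$top, ei$bottom)]
                P[j, ] <- sf$s[sel]
                selLocal[((j - 1L) * 2L * R + 1L):(j * 2L * R)] <- sel
            }
            hf <- .headForward(params, P)
            wB <- w[sl]; yB <- y[sl]; nB <- length(sl)
            epLoss <- epLoss + weightedBce(hf$y, yB, wB) * nB
            dy <- wB * (.clampP(hf$y) - yB) / nB
            dH2 <- (dy %o% params$hw3) * hf$H2 * (1 - hf$H2)
            dH1 <- (dH2 %*% params$hW2) * hf$H1 * (1 - hf$H1)
            dP <- dH1 %*% params$hW1
            ds <- numeric(length(tIdx))
            ds[selLocal] <- as.numeric(t(dP))
            I <- selLocal
            sI <- sf$s[I]
            dz2 <- ds[I] * sI * (1 - sI)
            HI <- sf$H[I, , drop = FALSE]
            dHI <- (dz2 %o% params$sw2) * HI * (1 - HI)
            grads <- list(
                sW1 = t(dHI) %*% Xall[tIdx[I], , drop = FALSE],
                sb1 = colSums(dHI),
                sw2 = as.numeric(t(HI) %*% dz2), sb2 = sum(dz2),
                hW1 = t(dH1) %*% P, hb1 = colSums(dH1),
                hW2 = t(dH2) %*% hf$H1, hb2 = colSums(dH2),
                hw3 = as.numeric(t(hf$H2) %*% dy), hb3 = sum(dy))
            upd <- adamStep(params, grads, st, tcfg$learning_rate)
            params <- upd$params; st <- upd$state
        }
        epLoss <- epLoss / nS
        if (is.finite(tcfg$patience)) {
            if (epLoss < bestLoss - 1e-6) { bestLoss <- epLoss; wait <- 0 }
            else if ((wait <- wait + 1) >= tcfg$patience) break
        }
    }
    list(params = params, loss = epLoss)
}

#' Score a list of bags
#'
#' @param bags list of [FeatureBag-class]
#' @param model a [ChowderModel-class]
#' @return named numeric vector of slide scores.
#' @export
scoreBags <- function(bags, model) {
    vapply(bags, slideScore, numeric(1), model = model)
}

setMethod("show", "ChowderModel", function(object) {
    cat(sprintf("ChowderModel: %d features -> 128 -> tile score; R = %d; head 2R -> 128 -> 64 -> 1\n",
                object@featureDim, object@poolWidth))
    cat(sprintf("  trained with seed %d, class weights %.3f / %.3f\n",
                object@seed, object@classWeights[1], object@classWeights[2]))
})

CHOWDER_FORMAT <- "msiscreen-chowder/1"

#' Serialise / restore a Chowder model
#'
#' Single JSON artifact carrying a format tag, the architecture constants,
#' all weights, the training seed and hyperparameters.
#'
#' @param model a [ChowderModel-class]
#' @param path output file.
#' @export
writeChowderModel <- function(model, path) {
    tc <- model@trainConfig
    # JSON has no Inf; absent fields mean "unbounded" and are restored as Inf
    if (!is.null(tc$batch_size) && !is.finite(tc$batch_size))
        tc$batch_size <- NULL
    if (!is.null(tc$patience) && !is.finite(tc$patience)) tc$patience <- NULL
    obj <- list(format = CHOWDER_FORMAT, feature_dim = model@featureDim,
                pool_width = model@poolWidth, seed = model@seed,
                class_weights = model@classWeights,
                train_config = tc,
                weights = .modelToParams(model))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    invisible(path)
}

#' @rdname writeChowderModel
#' @export
readChowderModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, CHOWDER_FORMAT))
        stop("unsupported model format tag: ", obj$format, call. = FALSE)
    p <- obj$weights
    for (k in c("sW1", "hW1", "hW2")) p[[k]] <- as.matrix(p[[k]])
    tc <- obj$train_config
    tc$batch_size <- if (is.null(tc$batch_size)) Inf else tc$batch_size
    tc$patience <- if (is.null(tc$patience)) Inf else tc$patience
    .paramsToModel(p, obj$pool_width, obj$feature_dim, obj$seed,
                   stats::setNames(obj$class_weights, c("0", "1")), tc)
}
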