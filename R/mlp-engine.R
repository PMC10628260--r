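# Minimal dense-network machinery shared by the tumour-tile MLP and the
# Chowder scorer/head: seeded Glorot initialisation, sigmoid/ReLU layers and
# an Adam optimizer. All gradients are analytic; everything is deterministic
# given the seed (full-batch) or seed + shuffling order (mini-batch).

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-uniform weight matrix (nOut x nIn); draws come from the current RNG
glorot <- function(nOut, nIn) {
    lim <- sqrt(6 / (nIn + nOut))
    matrix(stats::runif(nOut * nIn, -lim, lim), nOut, nIn)
}

adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    state$t <- state$t + 1L
    for (k in names(params)) {
        state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
        state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
        mhat <- state$m[[k]] / (1 - beta1^state$t)
        vhat <- state$v[[k]] / (1 - beta2^state$t)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(params = params, state = state)
}

# clamp probabilities away from 0/1 before taking logs
.clampP <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

weightedBce <- function(p, y, w) {
    p <- .clampP(p)
    -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# class weights proportional to 1/prevalence, normalised so that the mean
# per-observation weight is 1 (at 50% prevalence both weights are exactly 1)
balancedClassWeights <- function(y) {
    p1 <- mean(y == 1)
    if (p1 %in% c(0, 1))
        stop("both classes must be present to balance weights", call. = FALSE)
    c(`0` = 1 / (2 * (1 - p1)), `1` = 1 / (2 * p1))
}
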