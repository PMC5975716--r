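# shared input checks and seeded-RNG helper

.asBetaMatrix <- function(x, what = "beta matrix") {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (is.null(rownames(x)) || is.null(colnames(x))) {
        stop(what, " must have probe rownames and sample colnames")
    }
    if (anyDuplicated(rownames(x))) {
        stop("duplicate probe id(s): ",
             paste(unique(rownames(x)[duplicated(rownames(x))]),
                   collapse = ", "))
    }
    if (anyDuplicated(colnames(x))) {
        stop("duplicate sample id(s): ",
             paste(unique(colnames(x)[duplicated(colnames(x))]),
                   collapse = ", "))
    }
    bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "beta value out of [0, 1] at probe '%s', sample '%s' (%g)",
            rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
            x[bad[1, 1], bad[1, 2]]))
    }
    x
}

.asProportionMatrix <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (is.null(rownames(x)) || is.null(colnames(x))) {
        stop("proportion matrix must have sample rownames and cell-type ",
             "colnames")
    }
    if (any(x < -1e-12, na.rm = TRUE)) {
        stop("proportions must be non-negative")
    }
    x
}

# run expr under a temporary RNG seed; NULL seed leaves the stream alone
.withSeed <- function(seed, expr) {
    if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.alignToSamples <- function(est, truth) {
    est <- .asProportionMatrix(est)
    truth <- .asProportionMatrix(truth)
    if (!setequal(rownames(est), rownames(truth))) {
        stop("estimate and truth sample ids do not match")
    }
    if (!setequal(colnames(est), colnames(truth))) {
        stop("estimate and truth cell types do not match")
    }
    list(est = est[rownames(truth), colnames(truth), drop = FALSE],
         truth = truth)
}
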