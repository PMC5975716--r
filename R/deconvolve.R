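#' Estimate cell-type proportions from methylation beta values
#'
#' Reference-based deconvolution of target (mixture) samples against a
#' signature matrix of per-cell-type mean methylation, one sample at a
#' time. Three back-ends are provided:
#' \describe{
#'   \item{\code{cpqp}}{constrained projection / quadratic programming:
#'     per sample solves \eqn{\min_w \|y - S w\|^2} subject to
#'     \eqn{w \ge 0} and \eqn{\sum w \le 1}. The inequality sum constraint
#'     permits unmodelled cell mass; set \code{normalize = TRUE} to rescale
#'     rows to sum 1 for ratio work.}
#'   \item{\code{rpc}}{robust partial correlation: Huber M-estimation
#'     regression of the sample on the signature columns (tuning constant
#'     1.345), negative coefficients truncated to zero, row renormalized
#'     to sum 1.}
#'   \item{\code{svr}}{nu-support-vector regression with a linear kernel
#'     (CIBERSORT-style): signature and sample are z-scored over the
#'     library probes, the nu with the lowest reconstruction RMSE is kept,
#'     negative coefficients truncated, row renormalized to sum 1.}
#' }
#' Probes missing in a given sample are dropped for that sample only
#' (pairwise-complete).
#'
#' @param target Numeric probes-by-samples beta matrix (values in [0, 1]).
#' @param sig Signature matrix from \code{\link{buildSignature}} (library
#'   probes x K cell types); its probes must all be present in
#'   \code{target}.
#' @param method One of \code{"cpqp"}, \code{"rpc"}, \code{"svr"}.
#' @param normalize Rescale each estimate row to sum 1. Defaults to
#'   \code{FALSE} for \code{cpqp} (raw constrained projection) and
#'   \code{TRUE} for the unconstrained back-ends, which are only
#'   identified up to scale.
#' @param rpcMaxIterations IRLS iteration cap for \code{rpc} (default 100).
#' @param svrNuGrid nu values tried for \code{svr}
#'   (default \code{c(0.25, 0.5, 0.75)}).
#' @param qpTolerance Ridge added to the quadratic form when the signature
#'   is numerically rank-deficient (default 1e-9).
#' @return Numeric matrix, samples x K cell types, entries >= 0; row sums
#'   <= 1 + tolerance for raw \code{cpqp}, == 1 for normalized output.
#' @references Houseman et al. (2012) BMC Bioinformatics 13:86;
#'   Teschendorff et al. (2017) BMC Bioinformatics 18:105;
#'   Newman et al. (2015) Nat Methods 12:453.
#' @examples
#' sig <- cbind(A = c(0.9, 0.1, 0.5), B = c(0.1, 0.9, 0.5))
#' rownames(sig) <- paste0("cg", 1:3)
#' y <- 0.3 * sig[, 1] + 0.7 * sig[, 2]
#' target <- matrix(y, dimnames = list(rownames(sig), "mix1"))
#' deconvolve(target, sig, method = "cpqp")
#' @export
deconvolve <- function(target, sig, method = c("cpqp", "rpc", "svr"),
                       normalize = NULL, rpcMaxIterations = 100,
                       svrNuGrid = c(0.25, 0.5, 0.75),
                       qpTolerance = 1e-9) {
    method <- match.arg(method)
    if (is.null(normalize)) normalize <- method != "cpqp"
    switch(method,
           cpqp = deconvolveCPQP(target, sig, normalize = normalize,
                                 qpTolerance = qpTolerance),
           rpc = deconvolveRPC(target, sig, normalize = normalize,
                               maxIterations = rpcMaxIterations),
           svr = deconvolveSVR(target, sig, normalize = normalize,
                               nuGrid = svrNuGrid))
}

.checkDeconvInputs <- function(target, sig) {
    target <- .asBetaMatrix(target, "target matrix")
    if (is.null(rownames(sig)) || is.null(colnames(sig))) {
        stop("signature matrix needs probe rownames and cell-type colnames")
    }
    if (ncol(sig) < 2) stop("at least two cell types are required")
    missing <- setdiff(rownames(sig), rownames(target))
    if (length(missing)) {
        stop("signature probe(s) absent from target: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (and %d more)",
                                              length(missing) - 5))
    }
    list(target = target[rownames(sig), , drop = FALSE], sig = sig)
}

.emptyProps <- function(target, sig) {
    matrix(NA_real_, ncol(target), ncol(sig),
           dimnames = list(colnames(target), colnames(sig)))
}

.normalizeRows <- function(p) {
    s <- rowSums(p)
    ok <- s > 0
    p[ok, ] <- p[ok, , drop = FALSE] / s[ok]
    p
}

#' @rdname deconvolve
#' @export
deconvolveCPQP <- function(target, sig, normalize = FALSE,
                           qpTolerance = 1e-9) {
    inp <- .checkDeconvInputs(target, sig)
    target <- inp$target; sig <- inp$sig
    K <- ncol(sig)
    # an underdetermined system (fewer probes than cell types) is routine
    # in leave-one-out rescoring; warn only for genuinely collinear columns
    if (nrow(sig) >= K && qr(sig)$rank < K) {
        warning("signature matrix is rank-deficient (collinear cell ",
                "types); adding a ridge to the quadratic form")
    }
    Amat <- cbind(rep(-1, K), diag(K))
    bvec <- c(-1, rep(0, K))
    out <- .emptyProps(target, sig)
    for (s in seq_len(ncol(target))) {
        y <- target[, s]
        keep <- !is.na(y)
        if (sum(keep) < 2) {
            stop("too few non-missing probes for sample '",
                 colnames(target)[s], "'")
        }
        S <- sig[keep, , drop = FALSE]
        D <- crossprod(S)
        # guarantee positive definiteness for the QP solver
        if (nrow(S) < K || rcond(D) < 1e-8) {
            D <- D + diag(qpTolerance * max(diag(D), 1), K)
        }
        d <- crossprod(S, y[keep])
        fit <- tryCatch(
            quadprog::solve.QP(D, d, Amat, bvec, meq = 0),
            error = function(e) stop("QP failed for sample '",
                                     colnames(target)[s], "': ",
                                     conditionMessage(e)))
        w <- pmax(fit$solution, 0)
        out[s, ] <- w
    }
    if (normalize) out <- .normalizeRows(out)
    out
}

#' @rdname deconvolve
#' @export
deconvolveRPC <- function(target, sig, normalize = TRUE,
                          maxIterations = 100) {
    inp <- .checkDeconvInputs(target, sig)
    target <- inp$target; sig <- inp$sig
    out <- .emptyProps(target, sig)
    for (s in seq_len(ncol(target))) {
        y <- target[, s]
        keep <- !is.na(y)
        S <- sig[keep, , drop = FALSE]
        yk <- y[keep]
        # a (near-)perfect linear fit leaves no residual scale for the
        # M-estimator; ordinary least squares is then already robust
        ols <- stats::lm.fit(cbind(`(Intercept)` = 1, S), yk)
        if (sqrt(mean(ols$residuals^2)) < 1e-10) {
            w <- ols$coefficients[-1]
        } else {
            fit <- tryCatch(
                MASS::rlm(cbind(`(Intercept)` = 1, S), yk,
                          psi = MASS::psi.huber, k = 1.345,
                          maxit = maxIterations),
                error = function(e) NULL)
            if (is.null(fit)) {
                w <- ols$coefficients[-1]
            } else {
                if (!fit$converged) {
                    warning("robust regression did not converge within ",
                            maxIterations, " iterations for sample '",
                            colnames(target)[s],
                            "'; returning last iterate")
                }
                w <- fit$coefficients[-1]
            }
        }
        out[s, ] <- pmax(w, 0)
    }
    if (normalize) out <- .normalizeRows(out)
    out
}

#' @rdname deconvolve
#' @export
deconvolveSVR <- function(target, sig, normalize = TRUE,
                          nuGrid = c(0.25, 0.5, 0.75)) {
    if (any(nuGrid <= 0 | nuGrid >= 1)) stop("nu values must be in (0, 1)")
    inp <- .checkDeconvInputs(target, sig)
    target <- inp$target; sig <- inp$sig
    out <- .emptyProps(target, sig)
    for (s in seq_len(ncol(target))) {
        y <- target[, s]
        keep <- !is.na(y)
        S <- .zscore(sig[keep, , drop = FALSE])
        yk <- as.numeric(.zscore(matrix(y[keep])))
        best <- NULL
        for (nu in nuGrid) {
            fit <- e1071::svm(S, yk, type = "nu-regression",
                              kernel = "linear", nu = nu, scale = FALSE)
            rmse <- sqrt(mean((stats::predict(fit, S) - yk)^2))
            if (is.null(best) || rmse < best$rmse) {
                w <- drop(t(fit$coefs) %*% fit$SV)
                best <- list(rmse = rmse, w = w)
            }
        }
        w <- pmax(best$w, 0)
        if (all(w == 0)) {
            stop("degenerate estimate (all-zero coefficients) for ",
                 "sample '", colnames(target)[s], "'")
        }
        out[s, ] <- w
    }
    if (normalize) out <- .normalizeRows(out)
    out
}

.zscore <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sd, `/`)
}
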