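# Pairwise linear mixed model with a kinship random effect.
#
# Model: y = C gamma + beta * x + u + eps,  u ~ N(0, sg2 K), eps ~ N(0, se2 I).
# Rotating by the eigenvectors of K = U D U' diagonalizes the covariance:
# Var(U'y)_i = sg2 (d_i + delta) with delta = se2 / sg2, so for a fixed
# delta the fit is a weighted least squares and the ML profile likelihood
# over delta is one-dimensional (the EMMA device).

buildDesign <- function(n, covariates) {
    if (is.null(covariates)) return(matrix(1, n, 1,
                                           dimnames = list(NULL, "intercept")))
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    C <- cbind(intercept = 1, C)
    qrC <- qr(C)
    if (qrC$rank < ncol(C)) {
        drop <- colnames(C)[qrC$pivot[seq(qrC$rank + 1, ncol(C))]]
        stop("singular covariate matrix; collinear column(s): ",
             paste(drop, collapse = ", "))
    }
    C
}

# profile ML log-likelihood at log(delta) = l for rotated data
profileLogLik <- function(l, yt, Ct, d) {
    delta <- exp(l)
    w <- 1 / (d + delta)
    sw <- sqrt(w)
    fit <- lm.fit(Ct * sw, yt * sw)
    rss <- sum(fit$residuals^2)
    n <- length(yt)
    sg2 <- rss / n
    if (sg2 <= 0) return(-Inf)
    -0.5 * (n * log(2 * pi) + n * log(sg2) + sum(log(d + delta)) + n)
}

#' Estimate variance components by maximum likelihood
#'
#' Fits \eqn{y = C\gamma + u + \epsilon} with \eqn{u \sim N(0, \sigma_g^2
#' K)} by rotating with the eigenvectors of \eqn{K} and maximizing the
#' profile ML log-likelihood over \eqn{\delta = \sigma_e^2/\sigma_g^2} on
#' the log scale over \eqn{[e^{-10}, e^{10}]} (Brent, tolerance 1e-6).
#' With \eqn{K = I} the split between the two components is not
#' identifiable but their sum equals the ML residual variance.
#'
#' @param y numeric response vector.
#' @param covariates data.frame/matrix of fixed-effect covariates (an
#'   intercept is always added), or NULL.
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @return list with \code{sigma_g2}, \code{sigma_e2}, \code{delta},
#'   \code{loglik}.
#' @export
estimateVarianceComponents <- function(y, covariates = NULL, kinship) {
    stopifnot(is(kinship, "KinshipMatrix"))
    n <- length(y)
    C <- buildDesign(n, covariates)
    if (n <= ncol(C) + 2)
        stop("need n_samples > n_covariates + 2")
    if (sd(y) == 0) stop("response is constant; variance components degenerate")
    e <- kinshipEigen(kinship)
    yt <- crossprod(e$vectors, y)[, 1]
    Ct <- crossprod(e$vectors, C)
    opt <- optimize(profileLogLik, c(-10, 10), maximum = TRUE, tol = 1e-6,
                    yt = yt, Ct = Ct, d = e$values)
    # guard against boundary optima
    cand <- rbind(c(opt$maximum, opt$objective),
                  c(-10, profileLogLik(-10, yt, Ct, e$values)),
                  c(10, profileLogLik(10, yt, Ct, e$values)))
    best <- cand[which.max(cand[, 2]), ]
    delta <- exp(best[1])
    w <- 1 / (e$values + delta)
    sw <- sqrt(w)
    fit <- lm.fit(Ct * sw, yt * sw)
    sg2 <- sum(fit$residuals^2) / n
    list(sigma_g2 = sg2, sigma_e2 = delta * sg2, delta = delta,
         loglik = best[2])
}

#' Number of unordered feature pairs
#'
#' \eqn{n(n-1)/2}, the number of tests performed by
#' \code{\link{pairwiseAssociation}} on \eqn{n} features.
#'
#' @param n number of features.
#' @return the pair count as a double (exceeds integer range for large n).
#' @examples
#' countPairs(56978)  # 1,623,217,753 tests for the peak set
#' @export
countPairs <- function(n) n * (n - 1) / 2

#' Pairwise mixed-model association across all feature pairs
#'
#' For each unordered feature pair (k, j) with k < j (column order), fits
#' the response \eqn{Y_j} on the predictor \eqn{Y_k} plus covariates under
#' the kinship mixed model and reports the Wald test of \eqn{\beta_k}.
#' \code{mode = "per_response"} (default) estimates \eqn{\delta} once per
#' response from the covariates-only null model and plugs it into a
#' generalized-least-squares fit for every predictor (EMMAX-style);
#' \code{mode = "exact"} re-optimizes \eqn{\delta} per pair.
#'
#' @param mat samples x features matrix, inverse-normal transformed.
#' @param covariates data.frame/matrix of fixed covariates or NULL.
#' @param kinship a \linkS4class{KinshipMatrix}.
#' @param mode \code{"per_response"} or \code{"exact"}.
#' @param pairs optional 2-column matrix/data.frame of feature names to
#'   test; default all unordered pairs.
#' @param p_adjust_method multiplicity correction over the tested pairs
#'   (default \code{"bonferroni"}).
#' @param delta optional fixed \eqn{\delta} used for every response instead
#'   of estimating it (mainly for oracle comparisons at shared variance
#'   components).
#' @return data.frame with columns \code{feature_a} (predictor),
#'   \code{feature_b} (response), \code{beta}, \code{se}, \code{p_value}
#'   (two-sided Wald, floored at 1e-300), \code{p_adjusted}.
#' @export
pairwiseAssociation <- function(mat, covariates = NULL, kinship,
                                mode = c("per_response", "exact"),
                                pairs = NULL,
                                p_adjust_method = "bonferroni",
                                delta = NULL) {
    mode <- match.arg(mode)
    mat <- as.matrix(mat)
    n <- nrow(mat)
    p <- ncol(mat)
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("V", seq_len(p))
    fn <- colnames(mat)
    C <- buildDesign(n, covariates)
    e <- kinshipEigen(kinship)
    Yt <- crossprod(e$vectors, mat)
    Ct <- crossprod(e$vectors, C)
    d <- e$values
    dfree <- n - ncol(C) - 1

    if (is.null(pairs)) {
        pred_of <- lapply(seq_len(p), function(j) seq_len(max(j - 1, 0)))
        responses <- 2:p
    } else {
        pairs <- as.matrix(pairs)
        ia <- match(pairs[, 1], fn)
        ib <- match(pairs[, 2], fn)
        if (anyNA(ia) || anyNA(ib))
            stop("pair list references unknown features: ",
                 paste(unique(pairs[is.na(ia) | is.na(ib)]), collapse = ", "))
        lo <- pmin(ia, ib)
        hi <- pmax(ia, ib)
        pred_of <- split(lo, factor(hi, levels = seq_len(p)))
        responses <- sort(unique(hi))
    }

    out <- vector("list", length(responses))
    for (ri in seq_along(responses)) {
        j <- responses[ri]
        ks <- if (is.null(pairs)) pred_of[[j]] else pred_of[[j]]
        if (!length(ks)) next
        if (mode == "per_response") {
            dj <- if (is.null(delta))
                estimateVarianceComponentsRotated(Yt[, j], Ct, d)$delta
            else delta
            res <- waldGLS(Yt[, j], Yt[, ks, drop = FALSE], Ct, d,
                           dj, dfree)
        } else {
            res <- lapply(ks, function(k) {
                Caug <- cbind(Ct, Yt[, k])
                opt <- optimize(profileLogLik, c(-10, 10), maximum = TRUE,
                                tol = 1e-6, yt = Yt[, j], Ct = Caug, d = d)
                waldGLS(Yt[, j], Yt[, k, drop = FALSE], Ct, d,
                        exp(opt$maximum), dfree)
            })
            res <- do.call(rbind, res)
        }
        out[[ri]] <- data.frame(feature_a = fn[ks], feature_b = fn[j],
                                beta = res[, 1], se = res[, 2],
                                p_value = res[, 3],
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out$p_adjusted <- pmin(p.adjust(out$p_value, method = p_adjust_method), 1)
    out
}

# delta estimation on already-rotated data (covariates-only null model)
estimateVarianceComponentsRotated <- function(yt, Ct, d) {
    opt <- optimize(profileLogLik, c(-10, 10), maximum = TRUE, tol = 1e-6,
                    yt = yt, Ct = Ct, d = d)
    list(delta = exp(opt$maximum), loglik = opt$objective)
}

# Wald GLS of rotated response yt on each rotated predictor column plus
# rotated covariates Ct, at fixed delta. Returns matrix (beta, se, p).
waldGLS <- function(yt, Xt, Ct, d, delta, dfree) {
    sw <- sqrt(1 / (d + delta))
    A <- Ct * sw
    qa <- qr(A)
    rj <- qr.resid(qa, yt * sw)
    RZ <- qr.resid(qa, Xt * sw)
    den <- colSums(RZ^2)
    beta <- as.vector(crossprod(RZ, rj)) / den
    rss <- pmax(sum(rj^2) - beta^2 * den, 0)
    sigma2 <- rss / dfree
    se <- sqrt(sigma2 / den)
    z <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    pv <- pmax(2 * pnorm(-abs(z)), 1e-300)
    cbind(beta = beta, se = se, p = pv)
}

#' Generalized-least-squares oracle
#'
#' Direct GLS of \code{y} on \code{x} plus covariates with an explicit
#' covariance matrix, used as the exact reference for the spectral fast
#' path at fixed variance components. The covariance enters only up to
#' scale: the residual scale is estimated as \eqn{RSS_{GLS}/(n-p)}, so with
#' \eqn{\Sigma = \sigma^2 I} the result equals textbook OLS.
#'
#' @param y response vector.
#' @param x predictor vector.
#' @param covariates covariate matrix/data.frame or NULL.
#' @param Sigma positive-definite covariance matrix.
#' @return list with \code{beta}, \code{se}, \code{p} for the predictor.
#' @export
glsOracle <- function(y, x, covariates = NULL, Sigma) {
    n <- length(y)
    X <- cbind(buildDesign(n, covariates), x = x)
    ch <- tryCatch(chol(Sigma), error = function(e)
        stop("Sigma is not positive definite"))
    # whiten: L^-T applied to both sides
    W <- backsolve(ch, diag(n), transpose = TRUE)
    Xw <- W %*% X
    yw <- W %*% y
    XtX <- crossprod(Xw)
    b <- solve(XtX, crossprod(Xw, yw))
    rss <- sum((yw - Xw %*% b)^2)
    sigma2 <- rss / (n - ncol(X))
    covb <- sigma2 * solve(XtX)
    beta <- unname(b[ncol(X), 1])
    se <- unname(sqrt(covb[ncol(X), ncol(X)]))
    z <- beta / se
    list(beta = beta, se = se, p = max(2 * pnorm(-abs(z)), 1e-300))
}
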