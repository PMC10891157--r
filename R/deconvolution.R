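# Two-state cell-state deconvolution: signature construction from replicate
# reference profiles and constrained least-squares proportion estimation.

#' Build a two-state signature matrix
#'
#' Ranks features by a Welch t statistic on log2(x + 1)-transformed
#' replicate profiles and takes the top \code{n_features / 2} per direction
#' (up in A, up in B). Signature columns are the group means on the
#' original scale.
#'
#' @param group_a replicates x features matrix for state A.
#' @param group_b replicates x features matrix for state B.
#' @param n_features total signature size (default 300: 150 per direction;
#'   the peak-accessibility analogue uses 200).
#' @param labels length-2 character vector of state names.
#' @return a \linkS4class{SignatureMatrix}.
#' @export
buildSignature <- function(group_a, group_b, n_features = 300,
                           labels = c("A", "B")) {
    group_a <- as.matrix(group_a)
    group_b <- as.matrix(group_b)
    if (nrow(group_a) < 2 || nrow(group_b) < 2)
        stop("need >= 2 replicates per group")
    if (ncol(group_a) != ncol(group_b))
        stop("groups must share the feature set")
    half_a <- ceiling(n_features / 2)
    half_b <- n_features - half_a
    la <- log2(group_a + 1)
    lb <- log2(group_b + 1)
    t_stat <- welchT(la, lb)
    up_a <- which(t_stat > 0)
    up_b <- which(t_stat < 0)
    if (length(up_a) < half_a || length(up_b) < half_b)
        stop("n_features exceeds available differential features (",
             length(up_a), " up in A, ", length(up_b), " up in B)")
    sel_a <- up_a[order(-t_stat[up_a])][seq_len(half_a)]
    sel_b <- up_b[order(t_stat[up_b])][seq_len(half_b)]
    sel <- c(sel_a, sel_b)
    feats <- colnames(group_a)
    if (is.null(feats)) feats <- paste0("F", seq_len(ncol(group_a)))
    prof <- cbind(colMeans(group_a[, sel, drop = FALSE]),
                  colMeans(group_b[, sel, drop = FALSE]))
    dimnames(prof) <- list(feats[sel], labels)
    new("SignatureMatrix", profiles = prof,
        direction = rep(c("up_in_a", "up_in_b"), c(half_a, half_b)))
}

# per-feature Welch t statistic between two replicate matrices
welchT <- function(a, b) {
    na <- nrow(a); nb <- nrow(b)
    va <- apply(a, 2, var) / na
    vb <- apply(b, 2, var) / nb
    denom <- sqrt(va + vb)
    t_stat <- (colMeans(a) - colMeans(b)) / denom
    t_stat[denom == 0] <- 0
    t_stat
}

#' Estimate state proportions by constrained least squares
#'
#' Per sample, solves the nonnegative least-squares fit of the sample
#' vector on the two signature columns and renormalizes the coefficients
#' to sum to one. With two states the estimand is a one-dimensional mixing
#' fraction, so constrained least squares and support-vector variants agree
#' on clean data.
#'
#' @param samples samples x features matrix (original measurement scale).
#' @param signature a \linkS4class{SignatureMatrix}.
#' @param min_overlap minimum fraction of signature features that must be
#'   present in \code{samples} (default 0.5); missing features are dropped
#'   with a warning.
#' @return data.frame with \code{sample}, \code{p_a}, \code{p_b},
#'   \code{residual} (root-mean-square fit residual).
#' @export
deconvolve <- function(samples, signature, min_overlap = 0.5) {
    samples <- as.matrix(samples)
    prof <- signatureProfiles(signature)
    shared <- intersect(rownames(prof), colnames(samples))
    if (length(shared) < min_overlap * nrow(prof))
        stop("fewer than ", min_overlap * 100,
             "% of signature features present in samples")
    if (length(shared) < nrow(prof))
        warning(nrow(prof) - length(shared),
                " signature feature(s) missing from samples; dropped")
    S <- prof[shared, , drop = FALSE]
    Y <- samples[, shared, drop = FALSE]
    res <- t(apply(Y, 1, function(y) {
        if (all(y == 0)) stop("all-zero sample cannot be deconvolved")
        b <- nnls2(S, y)
        tot <- sum(b)
        p <- if (tot > 0) b / tot else c(0.5, 0.5)
        c(p[1], p[2], sqrt(mean((y - S %*% b)^2)))
    }))
    data.frame(sample = rownames(samples), p_a = res[, 1], p_b = res[, 2],
               residual = res[, 3], stringsAsFactors = FALSE)
}

# nonnegative least squares for a 2-column design: solve unconstrained,
# and if a coefficient is negative refit on the other column alone.
nnls2 <- function(S, y) {
    b <- tryCatch(solve(crossprod(S), crossprod(S, y))[, 1],
                  error = function(e) c(NA_real_, NA_real_))
    if (!anyNA(b) && all(b >= 0)) return(b)
    b1 <- max(0, sum(S[, 1] * y) / sum(S[, 1]^2))
    b2 <- max(0, sum(S[, 2] * y) / sum(S[, 2]^2))
    r1 <- sum((y - b1 * S[, 1])^2)
    r2 <- sum((y - b2 * S[, 2])^2)
    if (r1 <= r2) c(b1, 0) else c(0, b2)
}
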