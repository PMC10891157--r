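# Normalization of count/expression matrices ahead of the association stage.
# Matrices are samples x features throughout; the normalization applied is
# recorded in the "normalization" attribute.

#' TMM-normalized counts per million
#'
#' Trimmed-mean-of-M-values library-size normalization: the reference sample
#' is the one whose upper-quartile is closest to the mean upper-quartile;
#' per sample, gene-wise M (log2 ratio against the reference) and A (average
#' log2 abundance) are computed over features positive in both, doubly
#' trimmed (30\% by M, 5\% by A), and the scaling factor is the
#' inverse-variance-weighted mean of the remaining M values. Factors are
#' centred so they multiply to 1. The returned matrix is counts-per-million
#' divided by the factor. Computation is delegated to
#' \code{edgeR::calcNormFactors(method = "TMM")}.
#'
#' @param counts samples x features nonnegative integer matrix.
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return samples x features matrix of TMM-scaled CPM with attributes
#'   \code{"norm_factors"} (per-sample scaling factors) and
#'   \code{"normalization" = "TMM-CPM"}.
#' @examples
#' cts <- matrix(rpois(200, 50), 4, 50)
#' attr(tmmNormalize(cts), "norm_factors")
#' @export
tmmNormalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2) stop("TMM needs at least 2 samples")
    if (any(counts < 0)) stop("counts must be nonnegative")
    zero <- rowSums(counts) == 0
    if (any(zero))
        stop("sample(s) with all-zero counts: ",
             paste(rownames(counts)[zero], collapse = ", "))
    # edgeR convention: features x samples
    f <- edgeR::calcNormFactors(t(counts), method = "TMM",
                                logratioTrim = trim_m, sumTrim = trim_a)
    lib <- rowSums(counts)
    out <- counts / (lib * f) * 1e6
    attr(out, "norm_factors") <- setNames(f, rownames(counts))
    attr(out, "normalization") <- "TMM-CPM"
    out
}

#' Filter to expressed/accessible features
#'
#' Retains features whose value is at least \code{min_value} in at least
#' \code{ceiling(min_fraction * n_samples)} samples (the "TPM >= 1 in at
#' least 20\% of samples" rule). Feature order is preserved.
#'
#' @param mat samples x features nonnegative matrix.
#' @param min_value expression threshold (default 1).
#' @param min_fraction minimum fraction of samples at or above the
#'   threshold (default 0.2).
#' @return the filtered matrix; a warning is issued if nothing survives.
#' @export
filterExpressed <- function(mat, min_value = 1, min_fraction = 0.2) {
    mat <- as.matrix(mat)
    need <- ceiling(min_fraction * nrow(mat))
    keep <- colSums(mat >= min_value) >= need
    if (!any(keep)) warning("no features pass the expression filter")
    out <- mat[, keep, drop = FALSE]
    attr(out, "normalization") <- attr(mat, "normalization")
    out
}

#' Rank-based inverse-normal transform
#'
#' Per feature, maps values to normal quantiles
#' \eqn{\Phi^{-1}((r_i - 0.5)/n)} where \eqn{r} is the (average-tie) rank,
#' yielding mean 0 and standard deviation ~1 per feature. Constant features
#' are set to all zeros with a warning.
#'
#' @param mat samples x features matrix.
#' @return transformed matrix with \code{attr(,"normalization") =
#'   "inverse-normal"}.
#' @examples
#' inverseNormal(cbind(x = c(3, 1, 2)))  # qnorm(c(5, 1, 3)/6)
#' @export
inverseNormal <- function(mat) {
    mat <- as.matrix(mat)
    n <- nrow(mat)
    if (n < 3) stop("inverse-normal transform needs at least 3 samples")
    const <- apply(mat, 2, function(x) length(unique(x)) == 1)
    out <- apply(mat, 2, function(x) qnorm((rank(x, ties.method = "average")
                                            - 0.5) / n))
    if (any(const)) {
        warning(sum(const), " constant feature(s) set to 0")
        out[, const] <- 0
    }
    dimnames(out) <- dimnames(mat)
    attr(out, "normalization") <- "inverse-normal"
    out
}
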