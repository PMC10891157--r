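#' @import methods
#' @importFrom stats pnorm qnorm optimize rnorm rpois rbinom rbeta runif
#'   p.adjust fisher.test binom.test wilcox.test pbinom lm lm.fit coef cor
#'   sd var dist hclust cutree setNames
#' @importFrom utils read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# -- KinshipMatrix ------------------------------------------------------------

#' Kinship matrix with cached spectral decomposition
#'
#' Symmetric positive semi-definite relatedness matrix \eqn{K} that defines
#' the covariance of the random effect in the pairwise mixed model
#' (\eqn{u \sim N(0, \sigma_g^2 K)}). The eigendecomposition
#' \eqn{K = U D U^T} is computed once at construction and reused by every
#' model fit; eigenvalues in \eqn{[-10^{-8}, 0)} are clipped to zero.
#'
#' @slot K symmetric numeric matrix with sample IDs as dimnames.
#' @slot evectors orthonormal eigenvector matrix \eqn{U}.
#' @slot evalues eigenvalues \eqn{d}, clipped at zero.
#'
#' @export
setClass("KinshipMatrix",
    slots = c(K = "matrix", evectors = "matrix", evalues = "numeric"))

setValidity("KinshipMatrix", function(object) {
    K <- object@K
    if (nrow(K) != ncol(K)) return("K must be square")
    if (max(abs(K - t(K))) > 1e-8) return("K must be symmetric")
    if (min(object@evalues) < -1e-8)
        return("K must be positive semi-definite (min eigenvalue < -1e-8)")
    if (length(object@evalues) != nrow(K)) return("eigendecomposition stale")
    TRUE
})

#' Construct a KinshipMatrix
#'
#' @param K symmetric numeric matrix; dimnames, if present, are kept as
#'   sample IDs.
#' @return A \linkS4class{KinshipMatrix} with a cached eigendecomposition.
#' @examples
#' km <- KinshipMatrix(diag(4))
#' kinshipEigen(km)$values
#' @export
KinshipMatrix <- function(K) {
    K <- as.matrix(K)
    if (max(abs(K - t(K))) > 1e-8)
        stop("kinship matrix is not symmetric")
    K <- (K + t(K)) / 2
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        stop("kinship matrix is not positive semi-definite")
    e$values <- pmax(e$values, 0)
    new("KinshipMatrix", K = K, evectors = e$vectors, evalues = e$values)
}

#' @describeIn KinshipMatrix number of samples
#' @param x,object a \code{KinshipMatrix}
#' @export
setMethod("dim", "KinshipMatrix", function(x) dim(x@K))

setMethod("show", "KinshipMatrix", function(object) {
    cat("KinshipMatrix with", nrow(object@K), "samples\n")
    cat("  eigenvalue range: [",
        format(min(object@evalues), digits = 4), ", ",
        format(max(object@evalues), digits = 4), "]\n", sep = "")
})

#' Accessors for KinshipMatrix
#'
#' @param x a \linkS4class{KinshipMatrix}.
#' @return \code{kinshipMatrix} returns the raw matrix; \code{kinshipEigen}
#'   a list with elements \code{vectors} and \code{values}.
#' @export
kinshipMatrix <- function(x) x@K

#' @rdname kinshipMatrix
#' @export
kinshipEigen <- function(x) list(vectors = x@evectors, values = x@evalues)

# -- SyntheticCohort ----------------------------------------------------------

#' Synthetic cohort container
#'
#' A \linkS4class{SummarizedExperiment} (features in rows, samples in
#' columns) carrying a simulated count matrix together with the quantities
#' that downstream stages treat as ground truth: the per-sample latent
#' cell-state fraction, the family-block kinship matrix, the nuisance
#' covariates, and the planted feature-to-module assignment (module 0 is
#' background).
#'
#' @export
setClass("SyntheticCohort", contains = "SummarizedExperiment")

setValidity("SyntheticCohort", function(object) {
    if (!"latent_state" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must contain 'latent_state'")
    ls <- object$latent_state
    if (any(ls < 0 | ls > 1)) return("latent_state must lie in [0, 1]")
    if (!is(S4Vectors::metadata(object)$kinship, "KinshipMatrix"))
        return("metadata$kinship must be a KinshipMatrix")
    if (!"truth_module" %in%
            colnames(SummarizedExperiment::rowData(object)))
        return("rowData must contain 'truth_module'")
    TRUE
})

#' @rdname SyntheticCohort-accessors
#' @param x a \linkS4class{SyntheticCohort}.
#' @export
latentState <- function(x) x$latent_state

#' Accessors for SyntheticCohort
#'
#' @param x a \linkS4class{SyntheticCohort}.
#' @return \code{latentState}: true per-sample state fraction in [0, 1];
#'   \code{truthModules}: named integer vector of planted module labels
#'   (0 = background); \code{cohortKinship}: the \code{KinshipMatrix};
#'   \code{cohortCounts}: samples x features integer count matrix;
#'   \code{cohortCovariates}: standardized nuisance covariate data.frame.
#' @name SyntheticCohort-accessors
#' @export
truthModules <- function(x) {
    setNames(as.integer(SummarizedExperiment::rowData(x)$truth_module),
             rownames(x))
}

#' @rdname SyntheticCohort-accessors
#' @export
cohortKinship <- function(x) S4Vectors::metadata(x)$kinship

#' @rdname SyntheticCohort-accessors
#' @export
cohortCounts <- function(x) t(SummarizedExperiment::assay(x, "counts"))

#' @rdname SyntheticCohort-accessors
#' @export
cohortCovariates <- function(x) S4Vectors::metadata(x)$covariates

# -- ModulePartition ----------------------------------------------------------

#' Network module partition
#'
#' Result of Leiden community detection on a feature network, augmented with
#' the per-node intramodular degree and the per-module Pareto sets (top 20%
#' of members by intramodular degree) used for module scoring.
#'
#' @slot membership named integer vector, node -> module label.
#' @slot modularity modularity Q of the partition.
#' @slot params list of the Leiden parameters used (resolution, beta,
#'   n_iterations, seed) plus the major-module size rule.
#' @slot globalDegree named integer vector of node degrees in the full graph.
#' @slot intramodularDegree named integer vector counting only edges with
#'   both endpoints in the node's module (empty until
#'   \code{\link{intramodularPareto}} is called).
#' @slot pareto named list (one element per major module) of Pareto member
#'   IDs.
#' @slot majorModules character vector of module labels passing the size
#'   threshold.
#'
#' @export
setClass("ModulePartition",
    slots = c(membership = "integer", modularity = "numeric",
              params = "list", globalDegree = "integer",
              intramodularDegree = "integer", pareto = "list",
              majorModules = "character"))

setValidity("ModulePartition", function(object) {
    if (is.null(names(object@membership)))
        return("membership must be named by node ID")
    if (anyNA(object@membership))
        return("every node must be assigned a module")
    TRUE
})

setMethod("show", "ModulePartition", function(object) {
    sz <- moduleSizes(object)
    cat("ModulePartition:", length(object@membership), "nodes in",
        length(sz), paste0("modules (Q = ",
        format(object@modularity, digits = 3), ")\n"))
    cat("  major modules:", length(object@majorModules),
        if (length(object@pareto)) "| Pareto sets computed" else
            "| Pareto sets not yet computed", "\n")
})

#' Accessors for ModulePartition
#'
#' @param x a \linkS4class{ModulePartition}.
#' @return \code{moduleMembership}: named integer vector;
#'   \code{moduleSizes}: named integer vector of module sizes;
#'   \code{majorModules}: labels of major modules; \code{paretoMembers}:
#'   list of Pareto member IDs per major module;
#'   \code{intramodularDegree}: named integer vector;
#'   \code{modularityQ}: modularity of the partition.
#' @export
moduleMembership <- function(x) x@membership

#' @rdname moduleMembership
#' @export
moduleSizes <- function(x) {
    tab <- table(x@membership)
    setNames(as.integer(tab), names(tab))
}

#' @rdname moduleMembership
#' @export
majorModules <- function(x) x@majorModules

#' @rdname moduleMembership
#' @export
paretoMembers <- function(x) x@pareto

#' @rdname moduleMembership
#' @export
intramodularDegree <- function(x) x@intramodularDegree

#' @rdname moduleMembership
#' @export
modularityQ <- function(x) x@modularity

# -- SignatureMatrix ----------------------------------------------------------

#' Two-state signature matrix
#'
#' Reference mean profiles for two cell states over the features that best
#' discriminate them, with a per-feature direction label. Used as the design
#' of the constrained least-squares deconvolution.
#'
#' @slot profiles features x 2 numeric matrix of group means on the original
#'   measurement scale; column names are the state labels.
#' @slot direction character vector, \code{"up_in_a"} or \code{"up_in_b"}
#'   per feature.
#'
#' @export
setClass("SignatureMatrix",
    slots = c(profiles = "matrix", direction = "character"))

setValidity("SignatureMatrix", function(object) {
    if (ncol(object@profiles) != 2) return("profiles must have 2 columns")
    if (length(object@direction) != nrow(object@profiles))
        return("one direction label per feature required")
    if (anyDuplicated(rownames(object@profiles)))
        return("duplicate features in signature")
    if (!all(object@direction %in% c("up_in_a", "up_in_b")))
        return("direction must be 'up_in_a' or 'up_in_b'")
    TRUE
})

setMethod("show", "SignatureMatrix", function(object) {
    cat("SignatureMatrix:", nrow(object@profiles), "features (",
        sum(object@direction == "up_in_a"), "up in",
        colnames(object@profiles)[1], ",",
        sum(object@direction == "up_in_b"), "up in",
        colnames(object@profiles)[2], ")\n")
})

#' Accessors for SignatureMatrix
#'
#' @param x a \linkS4class{SignatureMatrix}.
#' @return \code{signatureProfiles}: the features x 2 matrix of state means;
#'   \code{signatureDirection}: named direction labels.
#' @export
signatureProfiles <- function(x) x@profiles

#' @rdname signatureProfiles
#' @export
signatureDirection <- function(x) setNames(x@direction, rownames(x@profiles))
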