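# Synthetic cohort generator. The generator emulates the data structure the
# downstream stages assume: families inducing a block kinship matrix, a
# latent per-sample cell-state fraction loading on planted feature modules,
# lognormal library-size variation, Poisson-lognormal counts, and binomially
# sampled allele read counts.

#' Configuration for the synthetic cohort generator
#'
#' @param n_families number of families.
#' @param family_sizes integer vector of family sizes; defaults to equal
#'   sizes \code{n_samples / n_families}.
#' @param n_samples number of samples; must equal \code{sum(family_sizes)}.
#' @param n_features number of molecular features.
#' @param n_modules number of planted co-varying modules.
#' @param module_sizes features per module; \code{sum(module_sizes)} must
#'   not exceed \code{n_features}; remaining features are background.
#' @param state_effect loading \eqn{\lambda} of the (standardized) latent
#'   state on module features. The first module loads \eqn{+\lambda}, the
#'   second \eqn{-\lambda}; further modules are driven by independent
#'   module factors with the same loading magnitude.
#' @param kinship_variance genetic variance \eqn{\sigma_g^2} of the
#'   per-feature random effect with covariance \eqn{\sigma_g^2 K}.
#' @param noise_variance residual log-scale variance \eqn{\sigma_e^2} (> 0).
#' @param depth_mean sequencing-depth scale multiplier (> 0); per-sample
#'   depths are \code{depth_mean * lognormal(0, 0.3)}.
#' @param seed integer seed; generation is bit-reproducible.
#' @return a validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(n_families = 30, family_sizes = NULL,
                         n_samples = 150, n_features = 600,
                         n_modules = 3, module_sizes = c(200, 200, 200),
                         state_effect = 1.5, kinship_variance = 0.2,
                         noise_variance = 0.25, depth_mean = 1,
                         seed = 1L) {
    if (is.null(family_sizes)) {
        base <- n_samples %/% n_families
        family_sizes <- rep(base, n_families)
        extra <- n_samples - sum(family_sizes)
        if (extra > 0)
            family_sizes[seq_len(extra)] <- family_sizes[seq_len(extra)] + 1
    }
    cfg <- list(n_families = as.integer(n_families),
                family_sizes = as.integer(family_sizes),
                n_samples = as.integer(n_samples),
                n_features = as.integer(n_features),
                n_modules = as.integer(n_modules),
                module_sizes = as.integer(module_sizes),
                state_effect = state_effect,
                kinship_variance = kinship_variance,
                noise_variance = noise_variance,
                depth_mean = depth_mean, seed = as.integer(seed))
    class(cfg) <- "CohortConfig"
    validateCohortConfig(cfg)
    cfg
}

validateCohortConfig <- function(cfg) {
    if (length(cfg$family_sizes) != cfg$n_families)
        stop("configuration error in 'family_sizes': need one size per family")
    if (sum(cfg$family_sizes) != cfg$n_samples)
        stop("configuration error in 'n_samples': must equal sum(family_sizes)")
    if (length(cfg$module_sizes) != cfg$n_modules)
        stop("configuration error in 'module_sizes': need one size per module")
    if (sum(cfg$module_sizes) > cfg$n_features)
        stop("configuration error in 'module_sizes': sum exceeds n_features")
    if (cfg$kinship_variance < 0)
        stop("configuration error in 'kinship_variance': must be >= 0")
    if (cfg$noise_variance <= 0)
        stop("configuration error in 'noise_variance': must be > 0")
    if (cfg$depth_mean < 0)
        stop("configuration error in 'depth_mean': must be >= 0")
    invisible(cfg)
}

#' Expected-relationship kinship matrix from family blocks
#'
#' Builds the block kinship matrix implied by a pedigree of nuclear
#' families: 1 on the diagonal, 0.5 between members of the same family,
#' 0 between families.
#'
#' @param family_sizes integer vector of family sizes.
#' @param ids optional sample IDs (default \code{S1, S2, ...}).
#' @return a \linkS4class{KinshipMatrix}.
#' @export
familyKinship <- function(family_sizes, ids = NULL) {
    n <- sum(family_sizes)
    if (is.null(ids)) ids <- paste0("S", seq_len(n))
    fam <- rep(seq_along(family_sizes), family_sizes)
    K <- 0.5 * outer(fam, fam, "==") + 0.5 * diag(n)
    dimnames(K) <- list(ids, ids)
    KinshipMatrix(K)
}

#' Simulate a cohort with planted co-varying modules
#'
#' Draws a per-sample latent state fraction \eqn{s_i \sim Beta(2, 5)}, and
#' for every feature a log-mean
#' \deqn{\log \mu_{if} = b_f + \lambda_m F_{im} + g_{if} + e_{if}}
#' where \eqn{F_{im}} is the module factor (the standardized latent state
#' for module 1, its negative for module 2, independent standard normal
#' factors for further modules; 0 for background), \eqn{g_{\cdot f} \sim
#' N(0, \sigma_g^2 K)} independently per feature and \eqn{e \sim N(0,
#' \sigma_e^2)}. Counts are Poisson with mean \code{depth_i * exp(logmu)},
#' depths lognormal around \code{depth_mean}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' sc <- simulateCohort(cohortConfig(n_samples = 40, n_families = 8,
#'     n_features = 60, module_sizes = c(20, 20, 20), seed = 7))
#' dim(cohortCounts(sc))
#' @export
simulateCohort <- function(config) {
    validateCohortConfig(config)
    set.seed(config$seed)
    n <- config$n_samples
    p <- config$n_features
    ids <- paste0("S", seq_len(n))
    feats <- paste0("F", formatC(seq_len(p), width = nchar(p), flag = "0"))

    kin <- familyKinship(config$family_sizes, ids)
    s <- rbeta(n, 2, 5)
    s_std <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, n)

    truth <- rep(0L, p)
    idx <- 0L
    for (m in seq_len(config$n_modules)) {
        truth[idx + seq_len(config$module_sizes[m])] <- m
        idx <- idx + config$module_sizes[m]
    }

    # module factors: state-loaded (+/-) for modules 1-2, independent for rest
    factors <- matrix(0, n, max(config$n_modules, 1))
    if (config$n_modules >= 1) factors[, 1] <- s_std
    if (config$n_modules >= 2) factors[, 2] <- -s_std
    if (config$n_modules >= 3)
        for (m in 3:config$n_modules) factors[, m] <- rnorm(n)

    baseline <- rnorm(p, mean = log(20), sd = 0.8)
    lam <- ifelse(truth > 0, config$state_effect, 0)

    logmu <- matrix(rep(baseline, each = n), n, p)
    loaded <- which(truth > 0)
    if (length(loaded))
        logmu[, loaded] <- logmu[, loaded] +
            factors[, truth[loaded], drop = FALSE] *
            rep(lam[loaded], each = n)

    if (config$kinship_variance > 0) {
        L <- t(chol(kinshipMatrix(kin) + 1e-10 * diag(n)))
        G <- sqrt(config$kinship_variance) * (L %*% matrix(rnorm(n * p), n, p))
        logmu <- logmu + G
    }
    logmu <- logmu + matrix(rnorm(n * p, sd = sqrt(config$noise_variance)),
                            n, p)

    depth <- config$depth_mean * exp(rnorm(n, 0, 0.3))
    counts <- matrix(rpois(n * p, lambda = depth * exp(logmu)), n, p,
                     dimnames = list(ids, feats))

    covar <- data.frame(
        sex = rbinom(n, 1, 0.5),
        age = scale01(rnorm(n, 45, 12)),
        passage = scale01(sample(12:40, n, replace = TRUE)),
        log_reads = scale01(log(pmax(rowSums(counts), 1))),
        row.names = ids)

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = t(counts)),
        rowData = S4Vectors::DataFrame(truth_module = truth,
                                       row.names = feats),
        colData = S4Vectors::DataFrame(latent_state = s, covar,
                                       row.names = ids),
        metadata = list(kinship = kin, covariates = covar,
                        config = config))
    new("SyntheticCohort", se)
}

scale01 <- function(x) as.numeric(scale(x))

#' Configuration for the allele-count simulator
#'
#' @param n_snps number of SNPs.
#' @param n_individuals cohort size.
#' @param frac_imbalanced fraction of SNPs with planted allelic imbalance.
#' @param pi_alt alt-allele read probability for imbalanced SNPs (balanced
#'   SNPs use 0.5).
#' @param depth_mean mean per-individual read depth (Poisson).
#' @param het_rate probability an individual is heterozygous at a SNP.
#' @param seed integer seed.
#' @return a validated list of class \code{"AlleleSimConfig"}.
#' @export
alleleSimConfig <- function(n_snps = 1000, n_individuals = 20,
                            frac_imbalanced = 0.1, pi_alt = 0.7,
                            depth_mean = 12, het_rate = 0.4, seed = 1L) {
    cfg <- list(n_snps = as.integer(n_snps),
                n_individuals = as.integer(n_individuals),
                frac_imbalanced = frac_imbalanced, pi_alt = pi_alt,
                depth_mean = depth_mean, het_rate = het_rate,
                seed = as.integer(seed))
    class(cfg) <- "AlleleSimConfig"
    if (frac_imbalanced < 0 || frac_imbalanced > 1)
        stop("configuration error in 'frac_imbalanced': must be in [0, 1]")
    if (pi_alt <= 0 || pi_alt >= 1)
        stop("configuration error in 'pi_alt': must be in (0, 1)")
    if (het_rate <= 0 || het_rate >= 1)
        stop("configuration error in 'het_rate': must be in (0, 1)")
    if (depth_mean < 0)
        stop("configuration error in 'depth_mean': must be >= 0")
    cfg
}

#' Simulate aggregated allele read counts
#'
#' Per SNP, each individual is heterozygous with probability
#' \code{het_rate}; each heterozygous individual contributes a
#' Poisson(\code{depth_mean}) read depth split binomially between alleles
#' with alt probability 0.5 (balanced) or \code{pi_alt} (the planted
#' imbalanced fraction, assigned at random).
#'
#' @param config an \code{\link{alleleSimConfig}}.
#' @param aggregate if \code{TRUE} (default) return per-SNP aggregated
#'   counts over heterozygous individuals; otherwise the per-individual
#'   records consumed by \code{\link{aggregateAlleleCounts}}.
#' @return a data.frame. Aggregated: \code{snp_id, chrom, pos, ref_count,
#'   alt_count, n_het, truth}. Per-individual: \code{snp_id, individual,
#'   ref_count, alt_count, het, truth}.
#' @export
simulateAlleleCounts <- function(config, aggregate = TRUE) {
    set.seed(config$seed)
    ns <- config$n_snps
    ni <- config$n_individuals
    snp_ids <- paste0("snp", seq_len(ns))
    n_imb <- floor(config$frac_imbalanced * ns)
    imb <- rep(FALSE, ns)
    if (n_imb > 0) imb[sample.int(ns, n_imb)] <- TRUE
    pi_snp <- ifelse(imb, config$pi_alt, 0.5)

    het <- matrix(runif(ns * ni) < config$het_rate, ns, ni)
    depth <- matrix(rpois(ns * ni, config$depth_mean), ns, ni) * het
    alt <- matrix(rbinom(ns * ni, as.vector(depth),
                         rep(pi_snp, ni)), ns, ni)
    ref <- depth - alt

    per_ind <- data.frame(
        snp_id = rep(snp_ids, ni),
        individual = rep(paste0("I", seq_len(ni)), each = ns),
        ref_count = as.vector(ref), alt_count = as.vector(alt),
        het = as.vector(het),
        truth = rep(ifelse(imb, "imbalanced", "balanced"), ni),
        stringsAsFactors = FALSE)

    if (!aggregate) return(per_ind)
    data.frame(snp_id = snp_ids,
               chrom = "chr1",
               pos = seq_len(ns) * 1000L,
               ref_count = rowSums(ref),
               alt_count = rowSums(alt),
               n_het = rowSums(het),
               truth = ifelse(imb, "imbalanced", "balanced"),
               stringsAsFactors = FALSE)
}

#' Simulate bulk mixtures of two reference profiles
#'
#' Each synthetic bulk sample is \eqn{p \cdot A + (1 - p) \cdot B +
#' N(0, \code{noise_sd})} for the given mixing proportions, emulating bulk
#' samples composed of two cell states.
#'
#' @param signature_profiles features x 2 matrix of reference state means
#'   (or a \linkS4class{SignatureMatrix}).
#' @param proportions numeric vector of state-A proportions in [0, 1], or a
#'   two-column matrix of (p_A, p_B) pairs summing to 1.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return samples x features matrix with attribute \code{"true_p"}.
#' @export
simulateMixtures <- function(signature_profiles, proportions,
                             noise_sd = 0, seed = 1L) {
    if (is(signature_profiles, "SignatureMatrix"))
        signature_profiles <- signatureProfiles(signature_profiles)
    if (is.matrix(proportions)) {
        if (any(abs(rowSums(proportions) - 1) > 1e-8) || any(proportions < 0))
            stop("each proportion pair must be nonnegative and sum to 1")
        p <- proportions[, 1]
    } else {
        if (any(proportions < 0 | proportions > 1))
            stop("each proportion pair must be nonnegative and sum to 1")
        p <- proportions
    }
    set.seed(seed)
    mix <- outer(p, signature_profiles[, 1]) +
        outer(1 - p, signature_profiles[, 2])
    if (noise_sd > 0)
        mix <- mix + matrix(rnorm(length(mix), sd = noise_sd),
                            nrow(mix), ncol(mix))
    rownames(mix) <- paste0("mix", seq_along(p))
    attr(mix, "true_p") <- p
    mix
}
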