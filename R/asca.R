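# Allele-specific chromatin accessibility: SNP filtering (MAF + exact
# Hardy-Weinberg), aggregation of per-individual allele counts, the exact
# binomial imbalance test with BH correction, group-level allelic-imbalance
# comparisons, and TFBS enrichment of imbalanced SNPs.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, enumerates all
#' heterozygote counts of matching parity and sums the probabilities of
#' configurations no more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return the exact p-value.
#' @examples
#' hweExactTest(25, 50, 25)
#' @export
hweExactTest <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    if (n == 0) stop("zero-total SNP")
    n_a <- 2 * n_aa + n_ab      # major allele count
    n_b <- 2 * n_bb + n_ab
    rare <- min(n_a, n_b)
    hets <- seq(rare %% 2, rare, by = 2)
    # P(h hets | allele counts) = C(n; nc_hom, h, nr_hom) 2^h / C(2n, n_a)
    logp <- vapply(hets, function(h) {
        nr_hom <- (rare - h) / 2                   # rare homozygotes
        nc_hom <- n - h - nr_hom                   # common homozygotes
        lgamma(n + 1) - lgamma(nc_hom + 1) - lgamma(h + 1) -
            lgamma(nr_hom + 1) + h * log(2) -
            (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(n_b + 1))
    }, numeric(1))
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    obs <- match(n_ab, hets)
    if (is.na(obs)) stop("inconsistent genotype counts")
    min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

#' Filter SNPs on minor allele frequency and Hardy-Weinberg equilibrium
#'
#' @param genotypes data.frame with columns \code{snp_id}, \code{n_aa},
#'   \code{n_ab}, \code{n_bb} (genotype counts across individuals).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param maf_inclusive if TRUE (default) retain MAF >= maf_min, else
#'   strictly greater.
#' @param hwe_p_min retain SNPs with exact HWE p strictly above this
#'   (default 1e-6).
#' @return the genotype table restricted to retained SNPs, with added
#'   columns \code{maf} and \code{hwe_p}; zero-total SNPs are dropped with
#'   a warning.
#' @export
snpFilter <- function(genotypes, maf_min = 0.05, maf_inclusive = TRUE,
                      hwe_p_min = 1e-6) {
    tot <- genotypes$n_aa + genotypes$n_ab + genotypes$n_bb
    if (any(tot == 0)) {
        warning(sum(tot == 0), " zero-total SNP(s) dropped")
        genotypes <- genotypes[tot > 0, , drop = FALSE]
    }
    p_b <- (2 * genotypes$n_bb + genotypes$n_ab) /
        (2 * (genotypes$n_aa + genotypes$n_ab + genotypes$n_bb))
    maf <- pmin(p_b, 1 - p_b)
    hwe <- mapply(hweExactTest, genotypes$n_aa, genotypes$n_ab,
                  genotypes$n_bb)
    genotypes$maf <- maf
    genotypes$hwe_p <- hwe
    keep <- if (maf_inclusive) maf >= maf_min else maf > maf_min
    keep <- keep & hwe > hwe_p_min
    genotypes[keep, , drop = FALSE]
}

#' Aggregate per-individual allele counts and apply coverage filters
#'
#' Sums reference/alternate read counts over heterozygous individuals per
#' SNP and retains SNPs with at least \code{min_het} heterozygous
#' individuals, at least \code{min_total} total reads, and at least
#' \code{min_per_allele} reads on each allele (all boundaries inclusive).
#'
#' @param records per-individual data.frame with \code{snp_id},
#'   \code{ref_count}, \code{alt_count}, \code{het} (logical).
#' @param min_het minimum heterozygous individuals (default 5).
#' @param min_total minimum total reads (default 50).
#' @param min_per_allele minimum reads per allele (default 10).
#' @return aggregated data.frame with \code{snp_id}, \code{ref_count},
#'   \code{alt_count}, \code{n_het} for retained SNPs.
#' @export
aggregateAlleleCounts <- function(records, min_het = 5, min_total = 50,
                                  min_per_allele = 10) {
    het <- records[records$het, , drop = FALSE]
    ref <- tapply(het$ref_count, het$snp_id, sum)
    alt <- tapply(het$alt_count, het$snp_id, sum)
    nh <- tapply(het$het, het$snp_id, length)
    agg <- data.frame(snp_id = names(ref),
                      ref_count = as.integer(ref),
                      alt_count = as.integer(alt),
                      n_het = as.integer(nh),
                      stringsAsFactors = FALSE, row.names = NULL)
    keep <- agg$n_het >= min_het &
        (agg$ref_count + agg$alt_count) >= min_total &
        pmin(agg$ref_count, agg$alt_count) >= min_per_allele
    agg[keep, , drop = FALSE]
}

#' Binomial test for allele-specific chromatin accessibility
#'
#' Per SNP, an exact two-sided binomial test of the aggregated alternate
#' read count against equal allele probability 0.5 (minlike convention:
#' the sum of outcome probabilities no larger than the observed outcome's,
#' as in the standard exact binomial test; a doubled one-sided p is
#' available via \code{convention = "doubling"}). P-values are
#' Benjamini-Hochberg adjusted across all tested SNPs; the allelic
#' imbalance fraction is AIF = max(ref, alt) / (ref + alt).
#'
#' @param records aggregated data.frame with \code{snp_id},
#'   \code{ref_count}, \code{alt_count} (pre-filtered by
#'   \code{\link{aggregateAlleleCounts}}).
#' @param alpha adjusted-p threshold calling imbalance (default 0.05).
#' @param convention two-sided p convention (\code{"minlike"} default).
#' @return data.frame with \code{snp_id}, \code{ref_count},
#'   \code{alt_count}, \code{aif}, \code{p_value}, \code{p_adjusted},
#'   \code{is_asca}; other input columns are carried through.
#' @export
binomialASCA <- function(records, alpha = 0.05,
                         convention = c("minlike", "doubling")) {
    convention <- match.arg(convention)
    tot <- records$ref_count + records$alt_count
    if (any(tot == 0)) stop("zero-total record; filter before testing")
    pv <- mapply(function(x, n) {
        if (convention == "minlike") {
            binom.test(x, n, 0.5)$p.value
        } else {
            min(1, 2 * min(pbinom(x, n, 0.5),
                           pbinom(x - 1, n, 0.5, lower.tail = FALSE)))
        }
    }, records$alt_count, tot)
    out <- records
    out$aif <- pmax(records$ref_count, records$alt_count) / tot
    out$p_value <- pmin(pv, 1)
    out$p_adjusted <- p.adjust(out$p_value, "BH")
    out$is_asca <- out$p_adjusted < alpha
    out
}

#' Group-level allelic-imbalance comparison
#'
#' For each group (regulatory module or TF group), a one-sided (greater)
#' Mann-Whitney U test of the allelic imbalance fractions of the group's
#' imbalanced SNPs against those of all remaining groups: exact when the
#' combined sample size is at most 30 and tie-free, otherwise the normal
#' approximation with tie correction. BH adjustment across groups.
#'
#' @param results output of \code{\link{binomialASCA}} with a grouping
#'   column.
#' @param group_col name of the grouping column (e.g. \code{"rnm"} or
#'   \code{"tf_group"}).
#' @param min_group groups with fewer imbalanced SNPs are skipped with a
#'   warning (default 3).
#' @return data.frame with \code{group}, \code{n}, \code{n_background},
#'   \code{u_statistic}, \code{p_value}, \code{p_adjusted}.
#' @export
groupAIFTest <- function(results, group_col, min_group = 3) {
    asca <- results[results$is_asca, , drop = FALSE]
    groups <- unique(asca[[group_col]])
    rows <- list()
    for (g in groups) {
        x <- asca$aif[asca[[group_col]] == g]
        y <- asca$aif[asca[[group_col]] != g]
        if (length(x) < min_group) {
            warning("group '", g, "' has fewer than ", min_group,
                    " imbalanced SNPs; skipped")
            next
        }
        exact <- (length(x) + length(y)) <= 30 &&
            !anyDuplicated(c(x, y))
        wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                           exact = exact, correct = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
            group = g, n = length(x), n_background = length(y),
            u_statistic = unname(wt$statistic), p_value = wt$p.value,
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(group = character(0), n = integer(0),
                          n_background = integer(0),
                          u_statistic = numeric(0), p_value = numeric(0),
                          p_adjusted = numeric(0)))
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, "BH")
    out
}

#' Enrichment of imbalanced SNPs in predicted TF binding sites
#'
#' Per TF group, a two-tailed Fisher test on the 2x2 table of imbalanced vs
#' balanced SNPs inside vs outside that group's predicted bound sites. A
#' group is called enriched when the BH-adjusted p is below \code{alpha}
#' and the odds ratio exceeds 1.
#'
#' @param results output of \code{\link{binomialASCA}}.
#' @param tfbs_tracks named list of \code{GRanges}, one per TF group.
#' @param snp_positions \code{GRanges} of width-1 SNP positions named by
#'   \code{snp_id}.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per TF group: counts, odds ratio, p,
#'   adjusted p, \code{enriched}.
#' @export
ascaTFBSEnrichment <- function(results, tfbs_tracks, snp_positions,
                               alpha = 0.05) {
    idx <- match(results$snp_id, names(snp_positions))
    if (anyNA(idx)) stop("SNP position(s) missing: ",
                         paste(results$snp_id[is.na(idx)][1:5],
                               collapse = ", "))
    pos <- snp_positions[idx]
    rows <- list()
    for (g in names(tfbs_tracks)) {
        inside <- GenomicRanges::countOverlaps(
            pos, tfbs_tracks[[g]], ignore.strand = TRUE) > 0
        a <- sum(results$is_asca & inside)
        b <- sum(results$is_asca & !inside)
        cc <- sum(!results$is_asca & inside)
        dd <- sum(!results$is_asca & !inside)
        ft <- fisher2x2(a, b, cc, dd)
        rows[[length(rows) + 1L]] <- cbind(data.frame(tf_group = g), ft)
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, "BH")
    out$enriched <- out$p_adjusted < alpha & out$odds_ratio > 1
    out
}
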