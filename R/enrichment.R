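# Exact 2x2 testing and the set-level enrichment analyses, plus the
# module-score vs state-proportion linear association.

#' Fisher's exact test on a 2x2 table
#'
#' Exact p by hypergeometric enumeration (two-sided: sum of table
#' probabilities at most that of the observed table). The reported effect
#' is the sample odds ratio \eqn{(ad)/(bc)}, with the Haldane 0.5
#' correction applied to every cell when any cell is zero (rather than the
#' conditional-MLE odds ratio).
#'
#' @param a,b,c,d nonnegative counts; \code{a} may alternatively be a 2x2
#'   matrix.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return one-row data.frame: \code{a,b,c,d,odds_ratio,log2_or,p_value}.
#' @examples
#' fisher2x2(10, 0, 0, 10)$p_value  # 2 / choose(20, 10)
#' @export
fisher2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                      alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    if (is.matrix(a)) {
        tab <- a
        a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    }
    cnt <- c(a, b, c, d)
    if (any(cnt < 0) || anyNA(cnt)) stop("counts must be nonnegative")
    if (sum(cnt) == 0) stop("empty table")
    p <- fisher.test(matrix(cnt, 2, 2, byrow = TRUE),
                     alternative = alternative)$p.value
    if (any(cnt == 0)) {
        or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    } else {
        or <- (a * d) / (b * c)
    }
    data.frame(a = a, b = b, c = c, d = d, odds_ratio = or,
               log2_or = log2(or), p_value = min(p, 1))
}

#' Gene-set enrichment across modules
#'
#' For every (major module, gene set) pair, tests membership of the set in
#' the module against the background of the remaining major modules with
#' Fisher's exact test. P-values are adjusted across all cells of the
#' analysis (one heatmap = one family).
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param gene_sets named list of feature-ID vectors; sets are intersected
#'   with the union of major-module members.
#' @param adjust_method multiplicity correction (default \code{"BH"};
#'   \code{"bonferroni"} for the epigenetic-feature analyses).
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per (module, set): counts, odds ratio,
#'   log2 OR, p, adjusted p and \code{direction}
#'   (\code{enriched}/\code{depleted}/\code{ns}).
#' @export
genesetModuleEnrichment <- function(partition, gene_sets,
                                    adjust_method = "BH", alpha = 0.05) {
    memb <- moduleMembership(partition)
    maj <- majorModules(partition)
    universe <- names(memb)[memb %in% as.integer(maj)]
    rows <- list()
    for (set_name in names(gene_sets)) {
        set <- intersect(gene_sets[[set_name]], universe)
        if (!length(set))
            warning("gene set '", set_name,
                    "' is empty after intersection with the universe")
        for (m in maj) {
            in_mod <- names(memb)[memb == as.integer(m)]
            bg <- setdiff(universe, in_mod)
            a <- length(intersect(in_mod, set))
            b <- length(in_mod) - a
            cc <- length(intersect(bg, set))
            dd <- length(bg) - cc
            ft <- fisher2x2(a, b, cc, dd)
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(module = m, gene_set = set_name),
                ft)
        }
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, adjust_method)
    out$direction <- ifelse(out$p_adjusted >= alpha, "ns",
                            ifelse(out$odds_ratio > 1, "enriched",
                                   "depleted"))
    out
}

#' Gene-module vs regulatory-module association
#'
#' Links the gene partition to the peak partition through the peak-to-gene
#' map: the shared gene universe is genes in a major gene module that are
#' also annotated targets of a peak in a major peak module. Each
#' (gene module, peak module) cell is a Fisher test of co-membership over
#' that universe.
#'
#' @param peak_to_gene data.frame with \code{peak_id}, \code{gene_id}
#'   (from \code{\link{assignTargetGene}}).
#' @param gene_partition,peak_partition \linkS4class{ModulePartition}s for
#'   genes and peaks.
#' @param adjust_method multiplicity correction (default \code{"BH"}).
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per (gene module, peak module) pair.
#' @export
gnmRnmAssociation <- function(peak_to_gene, gene_partition, peak_partition,
                              adjust_method = "BH", alpha = 0.05) {
    gm <- moduleMembership(gene_partition)
    pm <- moduleMembership(peak_partition)
    gmaj <- majorModules(gene_partition)
    pmaj <- majorModules(peak_partition)
    major_peaks <- names(pm)[pm %in% as.integer(pmaj)]
    p2g <- peak_to_gene[peak_to_gene$peak_id %in% major_peaks, ]
    target_genes <- unique(p2g$gene_id)
    universe <- intersect(names(gm)[gm %in% as.integer(gmaj)], target_genes)
    if (!length(universe)) stop("empty gene universe")
    rows <- list()
    for (g in gmaj) {
        G <- intersect(names(gm)[gm == as.integer(g)], universe)
        for (r in pmaj) {
            rp <- names(pm)[pm == as.integer(r)]
            Tr <- intersect(unique(p2g$gene_id[p2g$peak_id %in% rp]),
                            universe)
            a <- length(intersect(G, Tr))
            b <- length(G) - a
            cc <- length(Tr) - a
            dd <- length(universe) - a - b - cc
            ft <- fisher2x2(a, b, cc, dd)
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(gene_module = g, peak_module = r), ft)
        }
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, adjust_method)
    out$direction <- ifelse(out$p_adjusted >= alpha, "ns",
                            ifelse(out$odds_ratio > 1, "enriched",
                                   "depleted"))
    out
}

#' Module score vs state proportion association
#'
#' Ordinary least squares of each module's per-sample score on the
#' estimated state proportion, with the two-sided t-test on the slope.
#'
#' @param scores samples x modules score matrix (see
#'   \code{\link{moduleScore}}).
#' @param proportions numeric vector of per-sample estimated state
#'   fractions, aligned with the score rows.
#' @return data.frame with \code{module}, \code{slope}, \code{r}
#'   (Pearson correlation), \code{p_value}.
#' @export
scoreProportionAssociation <- function(scores, proportions) {
    scores <- as.matrix(scores)
    if (nrow(scores) != length(proportions))
        stop("scores and proportions must cover the same samples")
    if (nrow(scores) < 10) stop("need >= 10 samples")
    if (sd(proportions) == 0) stop("zero-variance proportion vector")
    out <- lapply(colnames(scores), function(m) {
        fit <- summary(lm(scores[, m] ~ proportions))
        data.frame(module = m,
                   slope = fit$coefficients[2, 1],
                   r = cor(scores[, m], proportions),
                   p_value = fit$coefficients[2, 4])
    })
    do.call(rbind, out)
}
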