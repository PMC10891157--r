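# Network construction, Leiden module detection with parameter sweep and
# permutation null, intramodular degrees / Pareto sets, and module scores.

#' Build the feature network from significant association edges
#'
#' Retains edges passing the chosen significance rule and (by default) with
#' positive effect size; nodes with no surviving edge are kept in the node
#' set as isolated vertices.
#'
#' @param edges data.frame from \code{\link{pairwiseAssociation}}.
#' @param p_mode \code{"bonferroni_0.05"} (adjusted p < alpha, for gene
#'   co-expression) or \code{"raw_5e-8"} (raw p < threshold, for peak
#'   co-accessibility).
#' @param require_positive keep only edges with beta > 0 (default TRUE).
#' @param nodes node IDs to include (default: all features appearing in
#'   \code{edges}).
#' @param alpha adjusted-p threshold for \code{"bonferroni_0.05"}.
#' @param raw_threshold raw-p threshold for \code{"raw_5e-8"}.
#' @return an \code{igraph} simple undirected graph.
#' @export
buildNetwork <- function(edges, p_mode = c("bonferroni_0.05", "raw_5e-8"),
                         require_positive = TRUE, nodes = NULL,
                         alpha = 0.05, raw_threshold = 5e-8) {
    p_mode <- match.arg(p_mode)
    keep <- if (p_mode == "bonferroni_0.05") edges$p_adjusted < alpha
            else edges$p_value < raw_threshold
    if (require_positive) keep <- keep & edges$beta > 0
    sig <- edges[keep, c("feature_a", "feature_b")]
    if (is.null(nodes))
        nodes <- unique(c(edges$feature_a, edges$feature_b))
    if (nrow(sig) == 0) warning("no edges pass the significance rule")
    g <- igraph::graph_from_data_frame(sig, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::simplify(g)
}

#' Leiden community detection at fixed parameters
#'
#' Runs the Leiden algorithm with the modularity objective at the given
#' resolution, refinement randomness \code{beta} and iteration count,
#' seeded for reproducibility, and reports the modularity Q of the final
#' partition. Major modules are flagged by a size rule (genes: size > 100;
#' peaks: size >= 500; configurable).
#'
#' @param graph an \code{igraph} graph.
#' @param resolution Leiden resolution parameter.
#' @param beta randomness of the refinement step.
#' @param n_iterations number of Leiden iterations.
#' @param seed integer seed.
#' @param major_min size threshold for major modules.
#' @param major_op \code{">"} (genes, default) or \code{">="} (peaks).
#' @return a \linkS4class{ModulePartition} (Pareto sets not yet computed;
#'   see \code{\link{intramodularPareto}}).
#' @export
detectModules <- function(graph, resolution = 1, beta = 0.01,
                          n_iterations = 10, seed = 1L,
                          major_min = 100, major_op = c(">", ">=")) {
    major_op <- match.arg(major_op)
    if (igraph::vcount(graph) == 0) stop("graph is empty")
    set.seed(seed)
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, beta = beta,
                                 n_iterations = n_iterations)
    memb <- igraph::membership(cl)
    memb <- setNames(as.integer(memb), names(memb))
    q <- igraph::modularity(graph, memb)
    sizes <- table(memb)
    major <- if (major_op == ">") names(sizes)[sizes > major_min]
             else names(sizes)[sizes >= major_min]
    new("ModulePartition", membership = memb, modularity = q,
        params = list(resolution = resolution, beta = beta,
                      n_iterations = n_iterations, seed = as.integer(seed),
                      major_min = major_min, major_op = major_op),
        globalDegree = setNames(as.integer(igraph::degree(graph)),
                                igraph::V(graph)$name),
        intramodularDegree = integer(0), pareto = list(),
        majorModules = major)
}

#' Permutation null for a module partition
#'
#' Statistic: number of intra-module edges under the partition. Null:
#' node-to-module labels permuted uniformly, preserving module sizes.
#' Empirical p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param graph an \code{igraph} graph.
#' @param partition a \linkS4class{ModulePartition}.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the empirical p-value.
#' @export
permutationNull <- function(graph, partition, n_perm = 999, seed = 1L) {
    if (n_perm < 100) stop("n_perm must be >= 100")
    memb <- moduleMembership(partition)
    el <- igraph::as_edgelist(graph, names = TRUE)
    if (nrow(el) == 0) return(1)
    obs <- sum(memb[el[, 1]] == memb[el[, 2]])
    i1 <- match(el[, 1], names(memb))
    i2 <- match(el[, 2], names(memb))
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(r) {
        pm <- sample(unname(memb))
        sum(pm[i1] == pm[i2])
    }, numeric(1))
    (1 + sum(null >= obs)) / (n_perm + 1)
}

#' Sweep Leiden parameters and select a partition
#'
#' Runs \code{\link{detectModules}} over the parameter grid, recording
#' modularity Q, the fraction of nodes in major modules, the module count
#' and the permutation-null p per combination. Selects the combination
#' maximizing the fraction of nodes in major modules among those with
#' permutation p < 0.05 and Q >= \code{q_min}; ties are broken by higher Q,
#' then smaller resolution. If no combination passes, the best-Q row is
#' returned flagged \code{"no_pass"}.
#'
#' @param graph an \code{igraph} graph.
#' @param resolution_grid resolutions in [0, 5].
#' @param beta_grid refinement randomness values in [0, 0.1].
#' @param iter_grid iteration counts in [5, 50].
#' @param n_perm permutations per combination.
#' @param seed integer seed.
#' @param q_min minimum modularity for selection (default 0.3).
#' @param major_min,major_op major-module size rule (see
#'   \code{\link{detectModules}}).
#' @return list with \code{sweep} (one row per combination, chosen row
#'   flagged), \code{partition} (the selected \linkS4class{ModulePartition},
#'   Pareto-augmented) and \code{status} (\code{"ok"} or \code{"no_pass"}).
#' @export
sweepAndSelect <- function(graph, resolution_grid = c(0.5, 1, 2),
                           beta_grid = c(0.01, 0.05),
                           iter_grid = c(10), n_perm = 199, seed = 1L,
                           q_min = 0.3, major_min = 100,
                           major_op = c(">", ">=")) {
    major_op <- match.arg(major_op)
    stopifnot(length(resolution_grid) > 0, length(beta_grid) > 0,
              length(iter_grid) > 0)
    grid <- expand.grid(resolution = resolution_grid, beta = beta_grid,
                        n_iterations = iter_grid)
    n <- igraph::vcount(graph)
    rows <- vector("list", nrow(grid))
    parts <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        part <- detectModules(graph, resolution = grid$resolution[i],
                              beta = grid$beta[i],
                              n_iterations = grid$n_iterations[i],
                              seed = seed + i, major_min = major_min,
                              major_op = major_op)
        pp <- permutationNull(graph, part, n_perm = n_perm, seed = seed + i)
        sz <- moduleSizes(part)
        frac <- sum(sz[majorModules(part)]) / n
        rows[[i]] <- data.frame(resolution = grid$resolution[i],
                                beta = grid$beta[i],
                                n_iterations = grid$n_iterations[i],
                                modularity_q = modularityQ(part),
                                frac_major = frac,
                                n_modules = length(sz),
                                perm_p = pp)
        parts[[i]] <- part
    }
    sweep <- do.call(rbind, rows)
    pass <- sweep$perm_p < 0.05 & sweep$modularity_q >= q_min
    if (any(pass)) {
        cand <- which(pass)
        ord <- order(-sweep$frac_major[cand], -sweep$modularity_q[cand],
                     sweep$resolution[cand])
        sel <- cand[ord[1]]
        status <- "ok"
    } else {
        sel <- which.max(sweep$modularity_q)
        status <- "no_pass"
    }
    sweep$chosen <- seq_len(nrow(sweep)) == sel
    list(sweep = sweep,
         partition = intramodularPareto(graph, parts[[sel]]),
         status = status)
}

#' Intramodular degrees and Pareto sets
#'
#' The intramodular degree of a node counts only edges whose other endpoint
#' lies in the node's module. For each major module the Pareto set is the
#' top \code{ceiling(0.2 * size)} members by intramodular degree, ties
#' broken by global degree, then lexicographic ID.
#'
#' @param graph an \code{igraph} graph.
#' @param partition a \linkS4class{ModulePartition} covering the graph.
#' @return the partition with \code{intramodularDegree} and \code{pareto}
#'   slots filled.
#' @export
intramodularPareto <- function(graph, partition) {
    memb <- moduleMembership(partition)
    el <- igraph::as_edgelist(graph, names = TRUE)
    intra <- el[memb[el[, 1]] == memb[el[, 2]], , drop = FALSE]
    deg <- setNames(integer(length(memb)), names(memb))
    if (nrow(intra)) {
        tab <- table(c(intra[, 1], intra[, 2]))
        deg[names(tab)] <- as.integer(tab)
    }
    pareto <- lapply(majorModules(partition), function(m) {
        members <- names(memb)[memb == as.integer(m)]
        k <- ceiling(0.2 * length(members))
        ord <- order(-deg[members], -partition@globalDegree[members],
                     members)
        members[ord[seq_len(k)]]
    })
    names(pareto) <- majorModules(partition)
    partition@intramodularDegree <- deg
    partition@pareto <- pareto
    partition
}

#' Per-sample module scores
#'
#' The score of module m in sample s is the sum over the module's Pareto
#' members of the inverse-normal-transformed value of that feature in that
#' sample (one score per major module per sample).
#'
#' @param mat samples x features matrix, inverse-normal transformed.
#' @param partition a Pareto-augmented \linkS4class{ModulePartition}.
#' @return samples x modules numeric matrix.
#' @export
moduleScore <- function(mat, partition) {
    pareto <- paretoMembers(partition)
    if (!length(pareto))
        stop("Pareto sets not computed; run intramodularPareto() first")
    missing <- setdiff(unlist(pareto), colnames(mat))
    if (length(missing))
        stop("Pareto member(s) missing from matrix: ",
             paste(missing, collapse = ", "))
    out <- vapply(pareto, function(ids)
        rowSums(mat[, ids, drop = FALSE]), numeric(nrow(mat)))
    rownames(out) <- rownames(mat)
    out
}

#' Module-pair co-membership enrichment
#'
#' For each pair of major modules (A, B), tests whether the edge density
#' of the corresponding node-pair block departs from the rest of the
#' graph: the 2x2 table contrasts observed vs possible edges in the block
#' (within-A pairs on the diagonal, A-B pairs off the diagonal) with
#' observed vs possible edges among all remaining node pairs. Correctly
#' partitioned cliques are enriched on the diagonal and depleted off it.
#' Odds ratios use the Haldane correction via \code{\link{fisher2x2}};
#' infinite ORs (two disjoint cliques) are thereby capped.
#'
#' @param graph an \code{igraph} graph.
#' @param partition a \linkS4class{ModulePartition} with >= 2 major modules.
#' @return long data.frame with columns \code{module_a}, \code{module_b},
#'   counts, \code{odds_ratio}, \code{log2_or}, \code{p_value},
#'   \code{p_adjusted}.
#' @export
coMembershipEnrichment <- function(graph, partition) {
    maj <- majorModules(partition)
    if (length(maj) < 2) stop("need >= 2 major modules")
    memb <- moduleMembership(partition)
    el <- igraph::as_edgelist(graph, names = TRUE)
    m1 <- memb[el[, 1]]
    m2 <- memb[el[, 2]]
    sizes <- moduleSizes(partition)
    ntot <- length(memb)
    n_edges <- nrow(el)
    n_pairs <- ntot * (ntot - 1) / 2
    rows <- list()
    for (a in maj) {
        ai <- as.integer(a)
        na <- sizes[[a]]
        for (b in maj) {
            bi <- as.integer(b)
            if (a == b) {
                in_block <- sum(m1 == ai & m2 == ai)
                poss <- na * (na - 1) / 2
            } else {
                in_block <- sum((m1 == ai & m2 == bi) |
                                (m1 == bi & m2 == ai))
                poss <- na * sizes[[b]]
            }
            rest <- n_edges - in_block
            rest_poss <- n_pairs - poss
            ft <- fisher2x2(in_block, poss - in_block, rest,
                            rest_poss - rest)
            rows[[length(rows) + 1L]] <-
                data.frame(module_a = a, module_b = b,
                           block_edges = in_block, block_possible = poss,
                           rest_edges = rest, rest_possible = rest_poss,
                           odds_ratio = ft$odds_ratio,
                           log2_or = ft$log2_or, p_value = ft$p_value)
        }
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_value, "BH")
    out
}
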