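fakeEdges <- function(beta, p, padj = p) {
  n <- length(beta)
  data.frame(feature_a = paste0("n", seq_len(n)),
             feature_b = paste0("n", seq_len(n) + n),
             beta = beta, se = 1, p_value = p, p_adjusted = padj)
}

test_that("edge filtering honours sign and strict thresholds", {
  ed <- fakeEdges(beta = c(-1, 1, 1, 1), p = c(1e-20, 1e-10, 1e-6, 0.2),
                  padj = c(1e-20, 0.049, 0.05, 0.9))
  g <- buildNetwork(ed, "bonferroni_0.05")
  # negative beta excluded despite tiny p; p_adj == 0.05 excluded (strict <)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 8)   # isolated nodes retained

  g2 <- buildNetwork(ed, "raw_5e-8", require_positive = FALSE)
  expect_equal(igraph::ecount(g2), 2)
  expect_warning(buildNetwork(fakeEdges(1, 0.9, 0.9), "bonferroni_0.05"),
                 "no edges")
})

test_that("counts of passing edges are exact", {
  ed <- fakeEdges(beta = rep(1, 8),
                  p = c(rep(1e-9, 3), rep(1e-3, 5)),
                  padj = c(rep(1e-3, 3), rep(0.6, 5)))
  expect_equal(igraph::ecount(buildNetwork(ed, "bonferroni_0.05")), 3)
})

test_that("two disjoint cliques are split into two intact modules", {
  g <- twoCliqueGraph(10)
  part <- detectModules(g, resolution = 1, seed = 3, major_min = 5,
                        major_op = ">=")
  memb <- moduleMembership(part)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("a", 1:10)])), 1)
  expect_gt(modularityQ(part), 0.3)
  # determinism under identical seed/parameters
  part2 <- detectModules(g, resolution = 1, seed = 3, major_min = 5,
                         major_op = ">=")
  expect_identical(moduleMembership(part), moduleMembership(part2))
})

test_that("random graphs carry no planted signal", {
  set.seed(4)
  g <- igraph::sample_gnp(60, 0.3)
  igraph::V(g)$name <- paste0("v", 1:60)
  part <- detectModules(g, resolution = 1, seed = 5)
  memb <- moduleMembership(part)
  planted <- setNames(rep(1:3, each = 20), paste0("v", 1:60))
  expect_lt(abs(ari(memb, planted[names(memb)])), 0.1)
})

test_that("permutation null is exact at both extremes", {
  g <- twoCliqueGraph(8)
  one_mod <- detectModules(g, resolution = 0.0001, seed = 1,
                           major_min = 2, major_op = ">=")
  if (length(unique(moduleMembership(one_mod))) == 1) {
    expect_equal(permutationNull(g, one_mod, n_perm = 199), 1)
  }
  # a manually-built one-module partition always gives p = 1
  all_one <- new("ModulePartition",
                 membership = setNames(rep(1L, igraph::vcount(g)),
                                       igraph::V(g)$name),
                 modularity = 0, params = list(), globalDegree = integer(0),
                 intramodularDegree = integer(0), pareto = list(),
                 majorModules = "1")
  expect_equal(permutationNull(g, all_one, n_perm = 199), 1)
  # correctly split cliques attain the maximal statistic
  split <- detectModules(g, resolution = 1, seed = 2, major_min = 2,
                         major_op = ">=")
  expect_equal(permutationNull(g, split, n_perm = 199, seed = 9),
               1 / 200)
})

test_that("sweep selects a passing combination and recovers cliques", {
  g <- twoCliqueGraph(10)
  sw <- sweepAndSelect(g, resolution_grid = c(0.5, 1, 2.25),
                       beta_grid = c(0.01, 0.05), iter_grid = c(10),
                       n_perm = 199, seed = 1, major_min = 5,
                       major_op = ">=")
  expect_equal(sw$status, "ok")
  expect_equal(sum(sw$sweep$chosen), 1)
  memb <- moduleMembership(sw$partition)
  truth <- ifelse(grepl("^a", names(memb)), 1, 2)
  expect_equal(ari(memb, truth), 1)
  # single clique: every combination captures everything
  g1 <- twoCliqueGraph(6)
  g1 <- igraph::induced_subgraph(g1, paste0("a", 1:6))
  sw1 <- sweepAndSelect(g1, resolution_grid = c(0.5, 1),
                        beta_grid = 0.01, iter_grid = 10, n_perm = 199,
                        seed = 2, major_min = 3, major_op = ">=")
  expect_true(all(sw1$sweep$frac_major == 1))
})

test_that("intramodular degree and Pareto sets follow the definitions", {
  # star module (hub + 9 leaves) plus a clique, connected by one bridge
  hub <- "h0"
  leaves <- paste0("l", 1:9)
  cl <- paste0("c", 1:10)
  edges <- rbind(cbind(hub, leaves), t(combn(cl, 2)), cbind("l1", "c1"))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  memb <- setNames(c(rep(1L, 10), rep(2L, 10)), c(hub, leaves, cl))
  part <- new("ModulePartition", membership = memb, modularity = 0.4,
              params = list(), globalDegree =
                setNames(as.integer(igraph::degree(g, c(hub, leaves, cl))),
                         c(hub, leaves, cl)),
              intramodularDegree = integer(0), pareto = list(),
              majorModules = c("1", "2"))
  part <- intramodularPareto(g, part)
  deg <- intramodularDegree(part)
  expect_equal(unname(deg[hub]), 9)
  expect_equal(unname(deg["l1"]), 1)   # bridge edge not counted
  # Pareto: ceil(0.2 * 10) = 2 per module; hub must be included
  expect_equal(lengths(paretoMembers(part)),
               c(`1` = 2, `2` = 2))
  expect_true(hub %in% paretoMembers(part)[["1"]])
  # conservation: intra + inter edge counts sum to |E|
  el <- igraph::as_edgelist(g)
  intra <- sum(memb[el[, 1]] == memb[el[, 2]])
  expect_equal(intra + sum(memb[el[, 1]] != memb[el[, 2]]),
               igraph::ecount(g))
})

test_that("nodes with only external neighbours have intramodular degree 0", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("x", "x"), b = c("y", "z")), directed = FALSE)
  memb <- setNames(c(1L, 2L, 2L), c("x", "y", "z"))
  part <- new("ModulePartition", membership = memb, modularity = 0,
              params = list(),
              globalDegree = setNames(c(2L, 1L, 1L), c("x", "y", "z")),
              intramodularDegree = integer(0), pareto = list(),
              majorModules = c("1", "2"))
  part <- intramodularPareto(g, part)
  expect_equal(unname(intramodularDegree(part)["x"]), 0)
})

test_that("module scores sum Pareto member values", {
  g <- twoCliqueGraph(5)
  part <- detectModules(g, resolution = 1, seed = 1, major_min = 2,
                        major_op = ">=")
  part <- intramodularPareto(g, part)
  mat <- matrix(0, nrow = 3, ncol = 10,
                dimnames = list(paste0("s", 1:3),
                                c(paste0("a", 1:5), paste0("b", 1:5))))
  expect_true(all(moduleScore(mat, part) == 0))
  mat[, ] <- rnorm(30)
  sc <- moduleScore(mat, part)
  m1 <- names(which(moduleMembership(part)[paste0("a", 1:5)][1] ==
                    moduleMembership(part)))
  p1 <- paretoMembers(part)[[as.character(moduleMembership(part)[["a1"]])]]
  expect_equal(sc[, as.character(moduleMembership(part)[["a1"]])],
               rowSums(mat[, p1, drop = FALSE]))
  expect_error(moduleScore(mat[, 1:3], part), "missing")
})

test_that("co-membership enrichment separates cliques from noise", {
  g <- twoCliqueGraph(8)
  part <- detectModules(g, resolution = 1, seed = 1, major_min = 4,
                        major_op = ">=")
  enr <- coMembershipEnrichment(g, part)
  diag_rows <- enr[enr$module_a == enr$module_b, ]
  off_rows <- enr[enr$module_a != enr$module_b, ]
  expect_true(all(diag_rows$odds_ratio > 100))  # capped-infinite
  expect_true(all(is.finite(diag_rows$log2_or)))
  expect_true(all(off_rows$odds_ratio < 1))
  # random partition on a random graph is unenriched on average
  set.seed(6)
  gr <- igraph::sample_gnp(40, 0.3)
  igraph::V(gr)$name <- paste0("v", 1:40)
  memb <- setNames(rep(1:2, each = 20L), igraph::V(gr)$name)
  rnd <- new("ModulePartition", membership = memb, modularity = 0,
             params = list(),
             globalDegree = setNames(as.integer(igraph::degree(gr)),
                                     igraph::V(gr)$name),
             intramodularDegree = integer(0), pareto = list(),
             majorModules = c("1", "2"))
  enr_r <- coMembershipEnrichment(gr, rnd)
  expect_lt(mean(abs(enr_r$log2_or)), 0.5)
})
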