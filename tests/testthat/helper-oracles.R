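# Independent brute-force oracles used to validate the package's fast
# paths. These deliberately re-derive each quantity from its definition and
# never call the implementation under test.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# TMM scaling factors computed feature-by-feature from the definition:
# reference = sample with upper-quartile closest to the mean upper-quartile;
# doubly trimmed (by M and A) inverse-variance-weighted mean of M; factors
# centred to multiply to 1.
bruteTMM <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- rowSums(counts)
  uq <- apply(counts, 1, function(x) quantile(x, 0.75)) / lib
  ref_i <- which.min(abs(uq - mean(uq)))
  ref <- counts[ref_i, ]
  nR <- lib[ref_i]
  f <- vapply(seq_len(nrow(counts)), function(i) {
    obs <- counts[i, ]
    nO <- lib[i]
    M <- log2((obs / nO) / (ref / nR))
    A <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
    ok <- is.finite(M) & is.finite(A)
    M <- M[ok]; A <- A[ok]; v <- v[ok]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# two-sided Fisher p by full enumeration of tables with the given margins
bruteFisher2sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# two-sided binomial p at 0.5 by enumeration (minlike convention)
bruteBinom2sided <- function(x, n) {
  pr <- dbinom(0:n, n, 0.5)
  sum(pr[pr <= dbinom(x, n, 0.5) * (1 + 1e-7)])
}

# exact HWE p by enumeration of all genotype configurations compatible
# with the observed allele counts
bruteHWE <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  cfg <- expand.grid(aa = 0:n, ab = 0:n)
  cfg$bb <- n - cfg$aa - cfg$ab
  cfg <- cfg[cfg$bb >= 0 & 2 * cfg$aa + cfg$ab == n_a, ]
  pr <- apply(cfg, 1, function(g)
    exp(lchoose(n, g["aa"]) + lchoose(n - g["aa"], g["ab"]) +
          g["ab"] * log(2)))
  pr <- pr / sum(pr)
  obs <- which(cfg$ab == n_ab)
  sum(pr[pr <= pr[obs] * (1 + 1e-7)])
}

# exact one-sided (greater) Mann-Whitney p by enumeration of all rank
# assignments (tie-free inputs only)
bruteMWUgreater <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(all_v)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(all_v), n1)
  u_null <- apply(combos, 2, function(idx)
    sum(rank(all_v)[idx]) - n1 * (n1 + 1) / 2)
  mean(u_null >= u_obs)
}

# small planted two-clique graph used across network tests
twoCliqueGraph <- function(k = 10) {
  m1 <- paste0("a", seq_len(k))
  m2 <- paste0("b", seq_len(k))
  edges <- rbind(t(combn(m1, 2)), t(combn(m2, 2)))
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
}

# quick null-cohort INT matrix for mixed-model tests
nullMatrix <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", 1:n), paste0("F", 1:p)))
  inverseNormal(m)
}
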