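# Independent oracles used across test files. Each reimplements the checked
# quantity by the most direct route available (dense linear algebra, explicit
# enumeration, brute-force scans), never by calling the package's own path.

# dense closed-form RWR: p = r (I - (1-r) M)^-1 e
oracle_rwr <- function(M, seedIdx, r) {
  n <- nrow(M)
  e <- numeric(n)
  e[seedIdx] <- 1 / length(seedIdx)
  drop(r * solve(diag(n) - (1 - r) * as.matrix(M), e))
}

# classic unweighted KS GSEA statistic: step 1/k at member ranks, 1/(N-k)
# elsewhere; the signed running-sum extremum
oracle_ks <- function(N, memberPos) {
  k <- length(memberPos)
  step <- rep(-1 / (N - k), N)
  step[memberPos] <- 1 / k
  rs <- cumsum(step)
  rs[[which(abs(rs) >= max(abs(rs)) - 1e-12)[[1]]]]
}

# brute-force age-specific selection by direct set comprehension
oracle_select <- function(rec, dir, fdr, tps, keepCt, dropCt, exclusion) {
  sig <- function(ct, tp) {
    r <- rec[rec$contrast == ct & rec$timepoint == tp, ]
    r$gene[r$fdr < fdr & ((dir == "up" & r$log2fc > 0) |
                            (dir == "down" & r$log2fc < 0))]
  }
  inAll <- Reduce(intersect, lapply(tps, function(tp) sig(keepCt, tp)))
  ex <- lapply(tps, function(tp) sig(dropCt, tp))
  ex <- if (exclusion == "any") Reduce(union, ex) else Reduce(intersect, ex)
  sort(setdiff(inAll, ex))
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# best Jaccard match of a truth module against detected modules
oracle_best_jaccard <- function(membership, truth, module) {
  tg <- names(truth)[truth == module]
  found <- unique(membership[membership > 0])
  if (!length(found)) return(0)
  max(vapply(found, function(k) {
    dg <- names(membership)[membership == k]
    length(intersect(dg, tg)) / length(union(dg, tg))
  }, numeric(1)))
}

# tiny deterministic test network: two triangles bridged by one weak edge
toy_two_cliques <- function() {
  WeightedNetwork(data.frame(
    from = c("A", "A", "B", "D", "D", "E", "C"),
    to   = c("B", "C", "C", "E", "F", "F", "D"),
    weight = c(1, 1, 1, 1, 1, 1, 0.1)))
}

random_network <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  genes <- sprintf("N%03d", seq_len(n))
  WeightedNetwork(data.frame(from = genes[pairs[keep, 1]],
                             to = genes[pairs[keep, 2]],
                             weight = runif(sum(keep), 0.1, 1)),
                  nodes = genes)
}
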