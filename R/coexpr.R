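## WGCNA-style co-expression modules: count filtering, soft-threshold
## selection, signed-magnitude adjacency, topological overlap, and
## size-constrained tree cutting.

#' Filter lowly expressed genes from a count matrix
#'
#' Implements the documented count-filter rule used for RNA-Seq
#' co-expression input: with min.count = 10, the CPM cutoff is
#' min.count / median(libSize) * 1e6; the required number of samples is
#' the smallest group size, shrunk to 10 + (size - 10) * 0.7 when above
#' 10; a gene is kept when its CPM reaches the cutoff in at least that
#' many samples and its total count is at least 15. (Small tolerances
#' mirror the reference implementation so boundary genes agree.)
#'
#' @param se SummarizedExperiment with assay "counts" and colData column
#'   "group" (see [makeExprSE()]), or a plain counts matrix.
#' @param groups group labels when `se` is a matrix.
#' @return object of the same kind as the input, rows filtered.
#' @export
filterLowExpression <- function(se, groups = NULL) {
  isSE <- is(se, "SummarizedExperiment")
  counts <- if (isSE) SummarizedExperiment::assay(se, "counts") else se
  if (isSE) groups <- SummarizedExperiment::colData(se)$group
  if (is.null(groups) || !length(groups)) stop("empty group labels")
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  lib <- colSums(counts)
  medianLib <- median(lib)
  cutoff <- 10 / medianLib * 1e6
  minSize <- min(table(groups))
  if (minSize > 10) minSize <- 10 + (minSize - 10) * 0.7
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  tol <- 1e-14
  keep <- rowSums(cpm >= cutoff) >= (minSize - tol) &
    rowSums(counts) >= (15 - tol)
  if (isSE) se[keep, ] else counts[keep, , drop = FALSE]
}

#' log2 counts-per-million
#'
#' @param counts genes x samples count matrix.
#' @param prior pseudo-count added before the log (default 1).
#' @return matrix of log2(CPM + prior) values.
#' @export
logCpm <- function(counts, prior = 1) {
  lib <- colSums(counts)
  log2(sweep(counts, 2L, lib, "/") * 1e6 + prior)
}

#' Pick a soft-threshold power for scale-free topology
#'
#' For each candidate power beta the unsigned adjacency |cor|^beta is
#' formed and the connectivity k_i = sum_j a_ij computed; the scale-free
#' fit R^2 is the squared correlation between log10 frequency and log10
#' bin center of the connectivity histogram. Returns the smallest beta
#' reaching `r2Target`; when none does, the argmax R^2 with a warning.
#' Constant expression rows are dropped with a warning before
#' correlation.
#'
#' @param expr genes x samples numeric matrix (e.g. [logCpm()] values).
#' @param powers candidate integer powers (default 1:20).
#' @param r2Target scale-free fit target (default 0.8).
#' @param nBins histogram bins for the fit (default 10).
#' @return list with `power`, `scaleFreeR2`, `meanConnectivity` and the
#'   per-power `fitTable`.
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, r2Target = 0.8,
                              nBins = 10L) {
  if (nrow(expr) < 10L) stop("need >= 10 genes")
  constant <- apply(expr, 1L, sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant expression row(s) dropped")
    expr <- expr[!constant, , drop = FALSE]
  }
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  fit <- do.call(rbind, lapply(powers, function(beta) {
    a <- ac^beta
    k <- rowSums(a)
    data.frame(power = beta, scaleFreeR2 = .scale_free_r2(k, nBins),
               meanConnectivity = mean(k))
  }))
  hit <- which(fit$scaleFreeR2 >= r2Target)
  if (length(hit)) {
    i <- hit[[1L]]
  } else {
    i <- which.max(fit$scaleFreeR2)
    warning("no power reached scale-free R2 >= ", r2Target,
            "; returning the best fit (R2 = ",
            signif(fit$scaleFreeR2[[i]], 3), ")")
  }
  list(power = fit$power[[i]], scaleFreeR2 = fit$scaleFreeR2[[i]],
       meanConnectivity = fit$meanConnectivity[[i]], fitTable = fit)
}

.scale_free_r2 <- function(k, nBins) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  ctr <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & ctr > 0
  if (sum(ok) < 3L) return(0)
  suppressWarnings(cor(log10(freq[ok]), log10(ctr[ok]))^2)
}

#' Unsigned soft-threshold adjacency
#'
#' @param expr genes x samples matrix.
#' @param power soft-threshold beta.
#' @return symmetric genes x genes adjacency |cor|^beta with zero diagonal.
#' @export
softAdjacency <- function(expr, power) {
  a <- abs(cor(t(expr), use = "pairwise.complete.obs"))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix from an adjacency
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' unit diagonal; 1 - TOM is the dissimilarity used for clustering.
#'
#' @param a symmetric adjacency, zero diagonal, entries in [0, 1].
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tomFromAdjacency <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(a)) > 1e-12)) stop("adjacency must have zero diagonal")
  k <- rowSums(a)
  shared <- a %*% a                         # sum_u a_iu a_uj
  minK <- outer(k, k, pmin)
  tom <- (shared + a) / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Cut a dissimilarity into modules with a minimum size
#'
#' Average-linkage hierarchical clustering of the dissimilarity, followed
#' by a size-constrained cut: the tree is cut into k clusters for every k,
#' and the partition kept is the one maximizing the number of clusters of
#' at least `minSize` genes. Among tied k the `deepSplit` knob (0-4)
#' selects the position in the tied range — 0 the coarsest cut, 4 the
#' finest, 2 (default) the middle — matching the usual semantics that a
#' deeper split gives smaller, tighter modules. Clusters below `minSize`
#' become module 0 (unassigned); a reattachment pass then returns
#' unassigned genes to a module when their mean similarity to it is
#' module-typical (at least the lower quartile of the module's own
#' pairwise similarities), so genes shed while peeling background away
#' rejoin their module while genuine background stays out. Modules are
#' relabelled 1, 2, ... by decreasing size (ties by lexicographically
#' smallest member). A degenerate all-equal dissimilarity yields a single
#' module.
#'
#' @param dissim symmetric dissimilarity matrix (e.g. 1 - TOM).
#' @param minSize minimum module size (default 30).
#' @param deepSplit split depth 0-4 (default 2).
#' @return A [ModulePartition-class] (modularity slot is NA: no network).
#' @export
cutModules <- function(dissim, minSize = 30L, deepSplit = 2L) {
  stopifnot(isSymmetric(unname(dissim), tol = 1e-8),
            deepSplit >= 0, deepSplit <= 4)
  genes <- rownames(dissim)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(dissim)))
  n <- nrow(dissim)
  if (n < minSize) {
    warning("fewer genes than minSize: all genes unassigned")
    return(new("ModulePartition", membership = setNames(integer(n), genes),
               modularity = NA_real_))
  }
  hc <- hclust(as.dist(dissim), method = "average")
  if (diff(range(hc$height)) < 1e-12)  # all-equal dissimilarity
    return(new("ModulePartition",
               membership = setNames(rep(1L, n), genes),
               modularity = NA_real_))
  cuts <- cutree(hc, k = seq_len(n - 1L))
  nBig <- vapply(seq_len(n - 1L), function(k)
    sum(table(cuts[, k]) >= minSize), integer(1))
  cand <- which(nBig == max(nBig))
  k <- cand[[round(quantile(seq_along(cand), min(1, deepSplit / 4)))]]
  cl <- cuts[, k]
  sizes <- table(cl)
  keep <- names(sizes)[as.integer(sizes) >= minSize]
  mem <- integer(n)
  names(mem) <- genes
  mem[as.character(cl) %in% keep] <-
    match(as.character(cl)[as.character(cl) %in% keep], keep)
  sim <- 1 - dissim
  for (m in seq_along(keep)) {
    inm <- which(mem == m)
    un <- which(mem == 0L)
    if (!length(un)) break
    within <- sim[inm, inm][upper.tri(sim[inm, inm])]
    thr <- quantile(within, 0.25)
    ms <- colMeans(sim[inm, un, drop = FALSE])
    mem[un[ms >= thr]] <- m
  }
  # deterministic relabelling by decreasing size
  sizes <- table(mem[mem > 0L])
  firstMember <- vapply(names(sizes), function(kk)
    min(genes[mem == as.integer(kk)]), character(1))
  ord <- names(sizes)[order(-as.integer(sizes), firstMember)]
  out <- integer(n)
  names(out) <- genes
  hit <- mem > 0L
  out[hit] <- match(as.character(mem)[hit], ord)
  new("ModulePartition", membership = out, modularity = NA_real_)
}

#' Full co-expression module pipeline
#'
#' Count filter -> log-CPM -> soft-threshold pick -> adjacency -> TOM ->
#' module cut, returning the partition plus the intermediate choices.
#'
#' @param se SummarizedExperiment with assay "counts" and colData "group".
#' @param minSize minimum module size (default 30).
#' @param deepSplit split depth (default 2).
#' @param powers candidate soft-threshold powers.
#' @param power fixed power overriding the automatic pick (optional).
#' @return list with `partition` ([ModulePartition-class]),
#'   `softThreshold`, and `nGenesKept`.
#' @export
coexprModules <- function(se, minSize = 30L, deepSplit = 2L, powers = 1:20,
                          power = NULL) {
  filtered <- filterLowExpression(se)
  expr <- logCpm(SummarizedExperiment::assay(filtered, "counts"))
  if (is.null(power)) {
    st <- suppressWarnings(pickSoftThreshold(expr, powers = powers))
  } else {
    st <- list(power = power, scaleFreeR2 = NA_real_,
               meanConnectivity = NA_real_)
  }
  tom <- tomFromAdjacency(softAdjacency(expr, st$power))
  part <- cutModules(1 - tom, minSize = minSize, deepSplit = deepSplit)
  list(partition = part, softThreshold = st, nGenesKept = nrow(expr))
}
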