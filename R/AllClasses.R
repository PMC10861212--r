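#' @import methods
#' @importFrom stats cor prcomp hclust cutree as.dist dhyper phyper pnorm
#'   p.adjust quantile rnorm runif rpois rbinom median sd setNames glm
#'   binomial coef vcov
#' @importFrom utils head read.delim write.table modifyList packageVersion
NULL

## ---------------------------------------------------------------------------
## Central value containers. All user-facing containers are S4 with validity;
## the expression-matrix container is a SummarizedExperiment (see coexpr.R).
## ---------------------------------------------------------------------------

#' GeneSet: a named, ordered collection of unique gene symbols
#'
#' Gene symbols are case-normalized to uppercase on construction so that
#' mouse symbols (e.g. "Bmp2") and their human orthologs ("BMP2") collapse
#' to a single identifier, the documented cross-species approximation.
#'
#' @slot name single nonempty string identifying the set.
#' @slot description free-text description (may be empty).
#' @slot genes character vector of unique uppercase gene symbols.
#' @export
setClass("GeneSet",
  slots = c(name = "character", description = "character", genes = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single nonempty string")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene symbols after normalization")
  if (length(object@genes) && any(object@genes != toupper(object@genes)))
    msg <- c(msg, "gene symbols must be uppercase (use GeneSet() constructor)")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param genes character vector of gene symbols; case-normalized to upper,
#'   deduplicated (first occurrence wins, with a warning).
#' @param name set identifier.
#' @param description optional free text.
#' @return A [GeneSet-class] object.
#' @examples
#' GeneSet(c("Bmp2", "Chad"), name = "demo")
#' @export
GeneSet <- function(genes, name = "set", description = "") {
  genes <- normalizeSymbols(genes)
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols in '", name, "' deduplicated")
    genes <- unique(genes)
  }
  new("GeneSet", name = name, description = description, genes = genes)
}

#' DETable: per-gene differential-expression records across contrasts and
#' timepoints
#'
#' Long-format table with one row per (gene, contrast, timepoint) holding
#' the log2 fold change, raw and BH-adjusted p-values, and mean expression.
#'
#' @slot records data.frame with columns gene, contrast, timepoint, log2fc,
#'   p, fdr, mean_expr.
#' @export
setClass("DETable", slots = c(records = "data.frame"))

.de_cols <- c("gene", "contrast", "timepoint", "log2fc", "p", "fdr", "mean_expr")

setValidity("DETable", function(object) {
  r <- object@records
  msg <- character()
  miss <- setdiff(.de_cols, names(r))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r[, c("gene", "contrast", "timepoint")]))
      msg <- c(msg, "(gene, contrast, timepoint) not unique")
    if (any(r$p < 0 | r$p > 1, na.rm = TRUE) || any(r$fdr < 0 | r$fdr > 1, na.rm = TRUE))
      msg <- c(msg, "p and fdr must lie in [0, 1]")
    if (any(r$mean_expr < 0, na.rm = TRUE))
      msg <- c(msg, "mean_expr must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DETable from a long data.frame
#'
#' @param records data.frame with columns gene, contrast, timepoint, log2fc,
#'   p, fdr, mean_expr. Gene symbols are uppercased.
#' @return A [DETable-class].
#' @export
DETable <- function(records) {
  records <- as.data.frame(records)
  records$gene <- normalizeSymbols(records$gene)
  records$contrast <- as.character(records$contrast)
  records$timepoint <- as.character(records$timepoint)
  rownames(records) <- NULL
  new("DETable", records = records)
}

#' WeightedNetwork: undirected weighted gene graph
#'
#' Simple graph (no self-loops, no multi-edges) whose edge weights are
#' interaction confidences in (0, 1]. This is the substrate for
#' random-walk-with-restart propagation and for module detection.
#'
#' @slot nodes character vector of node (gene) symbols.
#' @slot edges data.frame with columns from, to, weight; each unordered pair
#'   appears once with from < to lexicographically.
#' @export
setClass("WeightedNetwork",
  slots = c(nodes = "character", edges = "data.frame"))

setValidity("WeightedNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from, to, weight")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node names")
  if (nrow(e)) {
    if (any(e$weight <= 0 | e$weight > 1))
      msg <- c(msg, "edge weights must lie in (0, 1]")
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "multi-edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedNetwork from an edge table
#'
#' Repeated unordered pairs keep the maximum weight; self-loops are dropped
#' with a warning. Isolated nodes may be supplied through `nodes`.
#'
#' @param edges data.frame with columns from, to, weight.
#' @param nodes optional character vector of nodes (superset of endpoints).
#' @return A [WeightedNetwork-class].
#' @export
WeightedNetwork <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  names(edges)[1:3] <- c("from", "to", "weight")
  edges$from <- normalizeSymbols(edges$from)
  edges$to <- normalizeSymbols(edges$to)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges)) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a
    edges$to <- b
    o <- order(a, b, -edges$weight)
    edges <- edges[o, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  }
  nodes <- sort(unique(c(normalizeSymbols(nodes), edges$from, edges$to)))
  rownames(edges) <- NULL
  new("WeightedNetwork", nodes = nodes, edges = edges)
}

#' PropagationResult: steady-state affinities of a random walk with restart
#'
#' @slot seeds seed gene symbols the restart vector is uniform over.
#' @slot restart restart probability r in (0, 1).
#' @slot affinity named numeric; per-node visiting probability, sums to 1.
#' @slot iterations number of power iterations performed.
#' @slot converged whether the L1 change fell below tolerance.
#' @slot tolerance convergence tolerance used.
#' @export
setClass("PropagationResult",
  slots = c(seeds = "character", restart = "numeric", affinity = "numeric",
            iterations = "integer", converged = "logical", tolerance = "numeric"))

setValidity("PropagationResult", function(object) {
  msg <- character()
  if (is.null(names(object@affinity))) msg <- c(msg, "affinity must be named")
  if (any(object@affinity < 0)) msg <- c(msg, "affinities must be non-negative")
  if (abs(sum(object@affinity) - 1) > 1e-9)
    msg <- c(msg, "affinities must sum to 1")
  if (length(msg)) msg else TRUE
})

#' ModulePartition: assignment of network nodes or genes to modules
#'
#' Module id 0 means unassigned (below the minimum size). Proper modules are
#' labelled 1, 2, ... in decreasing size order.
#'
#' @slot membership named integer vector, one entry per node.
#' @slot modularity weighted Newman modularity of the partition (NA when not
#'   derived from a network).
#' @export
setClass("ModulePartition",
  slots = c(membership = "integer", modularity = "numeric"))

setValidity("ModulePartition", function(object) {
  if (is.null(names(object@membership))) return("membership must be named")
  if (any(object@membership < 0L)) return("module ids must be >= 0")
  TRUE
})

#' EffectSize: a standardized mean difference and its variance
#'
#' @slot d the SMD (Cohen's d, or Hedges' g when corrected).
#' @slot variance sampling variance of d.
#' @slot hedges whether the small-sample correction was applied.
#' @export
setClass("EffectSize",
  slots = c(d = "numeric", variance = "numeric", hedges = "logical"))

setValidity("EffectSize", function(object) {
  if (object@variance <= 0) return("variance must be > 0") else TRUE
})

#' PooledEffect: DerSimonian-Laird random-effects pooled SMD
#'
#' @slot smd pooled standardized mean difference.
#' @slot ciLow,ciHigh normal-approximation 95 percent confidence bounds.
#' @slot tau2 between-study variance estimate (>= 0).
#' @slot Q Cochran's heterogeneity statistic.
#' @slot I2 percent of total variance from heterogeneity, in [0, 100].
#' @slot weights per-study random-effects weights, normalized to sum to 1.
#' @export
setClass("PooledEffect",
  slots = c(smd = "numeric", ciLow = "numeric", ciHigh = "numeric",
            tau2 = "numeric", Q = "numeric", I2 = "numeric",
            weights = "numeric"))

setValidity("PooledEffect", function(object) {
  msg <- character()
  if (object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
  if (object@I2 < 0 || object@I2 > 100) msg <- c(msg, "I2 must be in [0, 100]")
  if (object@ciLow > object@smd || object@ciHigh < object@smd)
    msg <- c(msg, "CI must bracket the pooled estimate")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SignatureMatrix: genes x cytokines response-signature coefficients
#'
#' A plain numeric matrix whose rows are genes (uppercase symbols) and whose
#' columns are cytokines; entry (g, c) is the typical log2 fold change of
#' gene g when cells are exposed to cytokine c.
#'
#' @export
setClass("SignatureMatrix", contains = "matrix")

setValidity("SignatureMatrix", function(object) {
  m <- object@.Data
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("signature matrix needs gene rownames and cytokine colnames")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate gene symbols")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate cytokine names")
  if (any(colSums(abs(m)) == 0)) msg <- c(msg, "all-zero cytokine column")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureMatrix
#'
#' @param m numeric matrix, genes in rows (rownames), cytokines in columns
#'   (colnames). Gene symbols are uppercased.
#' @return A [SignatureMatrix-class].
#' @export
SignatureMatrix <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- normalizeSymbols(rownames(m))
  new("SignatureMatrix", m)
}

#' ActivityResult: inferred cytokine activities with permutation significance
#'
#' @slot table data.frame with columns cytokine, coefficient, perm_z, perm_p,
#'   in the signature matrix's cytokine order.
#' @slot lambda ridge penalty used.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used for the permutation null.
#' @slot label condition label of the response profile.
#' @export
setClass("ActivityResult",
  slots = c(table = "data.frame", lambda = "numeric", nPerm = "integer",
            seed = "integer", label = "character"))

setValidity("ActivityResult", function(object) {
  t <- object@table
  if (!all(c("cytokine", "coefficient", "perm_z", "perm_p") %in% names(t)))
    return("table must have cytokine, coefficient, perm_z, perm_p")
  if (nrow(t) && any(t$perm_p < 0 | t$perm_p > 1, na.rm = TRUE))
    return("perm_p must lie in [0, 1]")
  TRUE
})

#' SsgseaResult: single-sample enrichment of one gene set in one ranking
#'
#' @slot esIntegral integral (sum of running differences) enrichment score.
#' @slot esMaxDev maximum-deviation (KS-style) enrichment score.
#' @slot nes normalized enrichment score (NA before significance testing).
#' @slot permP two-sided empirical permutation p-value (NA before testing).
#' @slot leadingEdge set members at or before (after, for negative scores)
#'   the running-sum extremum.
#' @slot alpha rank-weight exponent.
#' @slot setName gene-set identifier.
#' @slot label ranking (sample/condition) identifier.
#' @export
setClass("SsgseaResult",
  slots = c(esIntegral = "numeric", esMaxDev = "numeric", nes = "numeric",
            permP = "numeric", leadingEdge = "character", alpha = "numeric",
            setName = "character", label = "character"))

#' Contingency: a 2x2 table of gene-set co-membership counts
#'
#' Cell a counts genes in both sets, b in A only, c in B only, d in neither.
#'
#' @slot a,b,c,d non-negative integer cell counts.
#' @export
setClass("Contingency",
  slots = c(a = "integer", b = "integer", c = "integer", d = "integer"))

setValidity("Contingency", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (any(cells < 0L)) return("cells must be non-negative")
  if (sum(cells) < 1L) return("empty table")
  TRUE
})

#' Construct a Contingency table
#' @param a,b,c,d cell counts (in both; A only; B only; neither).
#' @return A [Contingency-class].
#' @export
Contingency <- function(a, b, c, d)
  new("Contingency", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d))

#' EnrichmentResult: odds ratio with confidence interval and p-value
#'
#' @slot oddsRatio sample odds ratio (a*d)/(b*c); +Inf when b*c = 0, a*d > 0.
#' @slot ciLow,ciHigh 95 percent CI (Woolf for Fisher, Wald for logistic);
#'   NA when a cell is zero.
#' @slot p two-sided p-value.
#' @slot method "fisher" or "logistic".
#' @export
setClass("EnrichmentResult",
  slots = c(oddsRatio = "numeric", ciLow = "numeric", ciHigh = "numeric",
            p = "numeric", method = "character"))

#' SimTruth: planted ground truth of a synthetic dataset
#'
#' @slot plantedAgeGenes genes planted to respond in aged at W1 and W2 only.
#' @slot plantedModules named integer: gene -> planted module id.
#' @slot trueActivities named numeric: cytokine -> planted activity.
#' @slot trueSmd planted standardized mean difference.
#' @slot trueTau2 planted between-study variance.
#' @slot reverserId identifier of the planted signature-reversing perturbation.
#' @slot seed RNG seed the dataset was generated with.
#' @export
setClass("SimTruth",
  slots = c(plantedAgeGenes = "character", plantedModules = "integer",
            trueActivities = "numeric", trueSmd = "numeric",
            trueTau2 = "numeric", reverserId = "character", seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@trueTau2) && object@trueTau2 < 0)
    msg <- c(msg, "trueTau2 must be >= 0")
  if (length(object@plantedModules)) {
    tab <- table(object@plantedModules[object@plantedModules > 0L])
    if (length(tab) && any(tab < 2L))
      msg <- c(msg, "every planted module needs >= 2 members")
  }
  if (length(msg)) msg else TRUE
})
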