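## Single-sample GSEA: weighted running-sum enrichment, permutation
## significance, and leading-edge extraction.

#' Build a deterministic ranked list from named scores
#'
#' Orders by descending score with ties broken by ascending gene symbol,
#' so the ranking — and every statistic derived from it — is reproducible.
#'
#' @param scores named numeric vector (gene -> score, e.g. log2FC).
#' @return named numeric vector sorted for ranking.
#' @export
rankScores <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  names(scores) <- normalizeSymbols(names(scores))
  if (anyDuplicated(names(scores))) stop("duplicate gene symbols in ranking")
  scores[order(-scores, names(scores))]
}

# running-sum machinery shared by the integral and max-deviation forms
.running_diff <- function(ranked, members, alpha) {
  inSet <- names(ranked) %in% members
  if (!any(inSet)) stop("gene set absent from ranking")
  if (all(inSet)) stop("gene set covers the whole ranking")
  w <- abs(ranked)^alpha
  w[!inSet] <- 0
  pIn <- cumsum(w) / sum(w)
  pOut <- cumsum(!inSet) / sum(!inSet)
  pIn - pOut
}

#' Single-sample enrichment score of a gene set in a ranked list
#'
#' With P_in(i) the weighted (|score|^alpha) cumulative fraction of set
#' members up to rank i and P_out(i) the cumulative fraction of
#' non-members, reports both the integral score sum_i (P_in - P_out) and
#' the classic maximum-deviation (KS-style) score, the signed running
#' difference of largest magnitude. The leading edge contains the set
#' members at or before the extremum position when the max-deviation
#' score is positive, and strictly after it when negative.
#'
#' @param ranked named numeric scores; re-ranked deterministically via
#'   [rankScores()].
#' @param geneSet a [GeneSet-class]; at least one member (and at least one
#'   non-member) must be present in the ranking.
#' @param alpha rank-weight exponent (default 0.75, the single-sample GSEA
#'   default; alpha = 0 gives the unweighted KS statistic).
#' @param label ranking label stored in the result.
#' @return An [SsgseaResult-class] with NES/permP set to NA (see
#'   [ssgseaSignificance()] for the complete result).
#' @examples
#' r <- c(A = 3, B = 2, C = 1, D = 0.5)
#' enrichmentScore(r, GeneSet("A", name = "top"), alpha = 0)
#' @export
enrichmentScore <- function(ranked, geneSet, alpha = 0.75, label = "sample") {
  ranked <- rankScores(ranked)
  d <- .running_diff(ranked, geneIds(geneSet), alpha)
  esIntegral <- sum(d)
  # extremum position: earliest rank attaining the maximal |deviation|
  # (ties resolved to the earliest position, robust to rounding noise)
  peak <- which(abs(d) >= max(abs(d)) - 1e-12)[[1L]]
  esMaxDev <- d[[peak]]
  inSet <- names(ranked) %in% geneIds(geneSet)
  le <- if (esMaxDev >= 0) names(ranked)[inSet & seq_along(d) <= peak]
        else names(ranked)[inSet & seq_along(d) > peak]
  new("SsgseaResult", esIntegral = esIntegral, esMaxDev = esMaxDev,
      nes = NA_real_, permP = NA_real_, leadingEdge = le, alpha = alpha,
      setName = setName(geneSet), label = label)
}

#' Permutation significance for a single-sample enrichment score
#'
#' Gene-label permutation null: set membership is reassigned to |S| random
#' positions of the ranking `nPerm` times and the integral score
#' recomputed. NES is the observed score divided by the mean |null score|
#' of the same sign; permP is the two-sided empirical p-value with the +1
#' correction. Deterministic under a fixed seed.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return A complete [SsgseaResult-class].
#' @export
ssgseaSignificance <- function(ranked, geneSet, alpha = 0.75, nPerm = 1000L,
                               seed, label = "sample") {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  res <- enrichmentScore(ranked, geneSet, alpha = alpha, label = label)
  ranked <- rankScores(ranked)
  k <- sum(names(ranked) %in% geneIds(geneSet))
  n <- length(ranked)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(b) {
    members <- names(ranked)[sample.int(n, k)]
    sum(.running_diff(ranked, members, alpha))
  }, numeric(1))
  sameSign <- null[sign(null) == sign(res@esIntegral)]
  nes <- if (length(sameSign)) res@esIntegral / mean(abs(sameSign)) else NA_real_
  permP <- (1 + sum(abs(null) >= abs(res@esIntegral) - 1e-12)) / (nPerm + 1)
  res@nes <- nes
  res@permP <- permP
  res
}

#' Stiffness-set enrichment across conditions of a DE table
#'
#' Ranks every contrast x timepoint condition of the DE table by log2 fold
#' change and scores the supplied stiffness gene set (the shipped fixture
#' holds the 11 genes whose loss lowers cartilage stiffness) in each,
#' returning one result per condition with permutation significance.
#'
#' @param de a [DETable-class].
#' @param stiffnessSet a [GeneSet-class]; defaults to the shipped 11-gene
#'   cartilage-stiffness fixture.
#' @param alpha rank-weight exponent (default 0.75).
#' @param nPerm permutations per condition (default 1000).
#' @param seed integer RNG seed.
#' @return named list of [SsgseaResult-class], one per condition
#'   ("contrast_timepoint").
#' @export
runStiffnessSsgsea <- function(de, stiffnessSet = stiffnessGeneSet(),
                               alpha = 0.75, nPerm = 1000L, seed = 1L) {
  r <- deRecords(de)
  if (!any(r$gene %in% geneIds(stiffnessSet)))
    stop("stiffness genes absent from the DE table")
  cond <- unique(r[, c("contrast", "timepoint")])
  out <- list()
  for (i in seq_len(nrow(cond))) {
    lab <- paste(cond$contrast[[i]], cond$timepoint[[i]], sep = "_")
    ri <- r[r$contrast == cond$contrast[[i]] &
              r$timepoint == cond$timepoint[[i]], ]
    scores <- setNames(ri$log2fc, ri$gene)
    out[[lab]] <- ssgseaSignificance(scores, stiffnessSet, alpha = alpha,
                                     nPerm = nPerm, seed = seed, label = lab)
  }
  out
}

#' The shipped 11-gene cartilage-stiffness gene set
#'
#' Genes whose knockout/knockdown significantly decreases cartilage ECM
#' stiffness, curated from atomic-force-microscopy studies and shipped as
#' a GMT fixture.
#'
#' @return A [GeneSet-class] of 11 genes.
#' @export
stiffnessGeneSet <- function() {
  path <- system.file("extdata", "stiffness11.gmt", package = "cytoDriver",
                      mustWork = TRUE)
  readGmt(path)[[1L]]
}
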