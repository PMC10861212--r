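## Connectivity-map-style scoring: query connectivity to perturbation rank
## profiles, sign-stratified normalization, tau percentiles, shortlisting.

#' Connectivity enrichment score of a query set in one profile
#'
#' Weighted KS enrichment (the maximum-deviation score at alpha = 1) of
#' the upregulated query genes in the profile's descending ranking. A
#' positive score means the perturbation mimics the query; a negative
#' score means it opposes (reverses) it. With `queryDown` supplied, the
#' two-sided form (ES_up - ES_down) / 2 is returned (0 when both
#' enrichments share a sign, the usual null convention).
#'
#' @param queryUp [GeneSet-class] of upregulated query genes.
#' @param profile named numeric vector of signed per-gene scores for one
#'   perturbation.
#' @param queryDown optional [GeneSet-class] of downregulated query genes.
#' @return numeric enrichment score.
#' @export
connectivityEs <- function(queryUp, profile, queryDown = NULL) {
  esUp <- enrichmentScore(profile, queryUp, alpha = 1)@esMaxDev
  if (is.null(queryDown)) return(esUp)
  esDown <- enrichmentScore(profile, queryDown, alpha = 1)@esMaxDev
  if (sign(esUp) == sign(esDown)) 0 else (esUp - esDown) / 2
}

#' Sign-stratified normalization of connectivity scores
#'
#' ncs = es / mean(|es|) over scores of the same sign within the same
#' group (cell line). Groups with fewer than 2 same-sign scores pass
#' through unchanged with a warning.
#'
#' @param es numeric vector of enrichment scores.
#' @param groups grouping labels (cell lines), recycled when length 1.
#' @return numeric vector of normalized scores, same order as input.
#' @export
normalizeNcs <- function(es, groups = "all") {
  groups <- rep_len(as.character(groups), length(es))
  ncs <- es
  for (g in unique(groups)) {
    for (s in c(-1, 1)) {
      idx <- which(groups == g & sign(es) == s)
      if (length(idx) >= 2L) {
        ncs[idx] <- es[idx] / mean(abs(es[idx]))
      } else if (length(idx) == 1L) {
        warning("single ", if (s > 0) "positive" else "negative",
                " score in group '", g, "' passed through unnormalized")
      }
    }
  }
  ncs
}

#' Tau percentile of a normalized connectivity score
#'
#' Signed percentile of |ncs| against the same-sign reference scores:
#' tau = sign(ncs) * 100 * #(|ref| < |ncs|) / #(same-sign ref). Ranges
#' over [-100, 100]; an empty same-sign reference yields 0 with a
#' warning.
#'
#' @param ncsQuery a single normalized connectivity score.
#' @param referenceNcs nonempty numeric reference distribution.
#' @return tau in [-100, 100].
#' @export
tauScore <- function(ncsQuery, referenceNcs) {
  if (!length(referenceNcs)) stop("reference list must be nonempty")
  same <- referenceNcs[sign(referenceNcs) == sign(ncsQuery)]
  if (!length(same)) {
    warning("no same-sign reference scores; tau = 0")
    return(0)
  }
  sign(ncsQuery) * 100 * sum(abs(same) < abs(ncsQuery)) / length(same)
}

#' Score a query against a perturbation library
#'
#' Computes the connectivity enrichment score of the query in every
#' perturbation profile, normalizes within cell line and sign, and
#' assigns each perturbation a tau percentile against all other
#' perturbations of the library (self-excluded).
#'
#' @param library perturbations x genes score matrix (as from
#'   [simulatePerturbationLibrary()]).
#' @param queryUp [GeneSet-class] of upregulated query genes.
#' @param cellLines named character perturbation -> cell line (default:
#'   one line for all).
#' @return data.frame with columns perturbation, cell_line, es, ncs, tau,
#'   sorted ascending by tau (strongest reversers first).
#' @export
cmapScreen <- function(library, queryUp, cellLines = NULL) {
  if (is.null(cellLines))
    cellLines <- setNames(rep("all", nrow(library)), rownames(library))
  es <- vapply(rownames(library), function(id)
    connectivityEs(queryUp, library[id, ]), numeric(1))
  cl <- cellLines[rownames(library)]
  ncs <- suppressWarnings(normalizeNcs(es, cl))
  tau <- vapply(seq_along(ncs), function(i)
    suppressWarnings(tauScore(ncs[[i]], ncs[-i])), numeric(1))
  out <- data.frame(perturbation = rownames(library), cell_line = unname(cl),
                    es = unname(es), ncs = unname(ncs), tau = tau,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tau, out$perturbation), ]
  rownames(out) <- NULL
  out
}

#' Shortlist strong signature reversers
#'
#' Summarizes tau across cell lines by the arithmetic mean per
#' perturbation and returns the perturbations whose summary tau falls
#' below the threshold (default -90, the recommended cut for a
#' perturbation whose signature opposes the query), sorted ascending.
#'
#' @param results data.frame from [cmapScreen()] (columns perturbation,
#'   tau; optional cell_line).
#' @param threshold summary-tau cutoff (default -90).
#' @return character vector of perturbation ids, strongest reverser first.
#' @export
shortlistReversers <- function(results, threshold = -90) {
  if (!nrow(results)) return(character())
  summary <- tapply(results$tau, results$perturbation, mean)
  summary <- sort(summary)
  names(summary)[summary < threshold]
}
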