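## Age-specific trauma-response gene selection from time-course DE tables,
## plus PCA of fold-change trajectories.

.sig_genes <- function(records, contrast, timepoint, direction, fdrThreshold) {
  sgn <- if (direction == "up") 1 else -1
  r <- records[records$contrast == contrast & records$timepoint == timepoint, ]
  r$gene[r$fdr < fdrThreshold & sign(r$log2fc) == sgn]
}

.check_de_coverage <- function(records, contrasts, timepoints) {
  have <- unique(records[, c("contrast", "timepoint")])
  need <- expand.grid(contrast = contrasts, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$contrast, d$timepoint)
  miss <- need[!(key(need) %in% key(have)), ]
  if (nrow(miss))
    stop("DE table is missing contrast/timepoint combination(s): ",
         paste(paste0(miss$contrast, ":", miss$timepoint), collapse = ", "))
}

#' Select genes responding to trauma in one age group only
#'
#' A gene is selected when it is significantly regulated in the stated
#' direction (FDR < `fdrThreshold`, matching log2FC sign) at every required
#' timepoint in the `contrast` group, and not significantly regulated in
#' that direction in the `exclusionContrast` group. With
#' `exclusion = "any"` (default) a gene present in the exclusion group's
#' significant list at any required timepoint is removed; `"all"` removes
#' only genes significant at every required timepoint. Direction is taken
#' from the log2FC sign at each timepoint independently, so a gene up at
#' one required timepoint and down at another is never selected.
#'
#' @param de a [DETable-class].
#' @param fdrThreshold significance threshold on the FDR (default 0.05).
#' @param direction "up" or "down".
#' @param timepoints required timepoints (default c("W1", "W2")).
#' @param contrast the age group of interest (default "aged").
#' @param exclusionContrast the group whose responders are removed
#'   (default "young").
#' @param exclusion "any" (union over required timepoints, default) or
#'   "all" (intersection).
#' @param name name given to the returned set.
#' @return A [GeneSet-class] of selected genes, sorted.
#' @examples
#' sim <- simulateDETimecourse(300, 30, noiseSd = 0, seed = 1)
#' length(selectStressResponse(sim$de))
#' @export
selectStressResponse <- function(de, fdrThreshold = 0.05, direction = c("up", "down"),
                                 timepoints = c("W1", "W2"),
                                 contrast = "aged", exclusionContrast = "young",
                                 exclusion = c("any", "all"),
                                 name = "stress_response") {
  direction <- match.arg(direction)
  exclusion <- match.arg(exclusion)
  stopifnot(fdrThreshold > 0, fdrThreshold < 1, length(timepoints) >= 1L)
  r <- deRecords(de)
  .check_de_coverage(r, c(contrast, exclusionContrast), timepoints)
  inSets <- lapply(timepoints, function(tp)
    .sig_genes(r, contrast, tp, direction, fdrThreshold))
  exSets <- lapply(timepoints, function(tp)
    .sig_genes(r, exclusionContrast, tp, direction, fdrThreshold))
  selected <- Reduce(intersect, inSets)
  excluded <- if (exclusion == "any") Reduce(union, exSets)
              else Reduce(intersect, exSets)
  GeneSet(sort(setdiff(selected, excluded)), name = name,
          description = sprintf("%s at %s in %s not %s (FDR<%g, excl=%s)",
                                direction, paste(timepoints, collapse = "+"),
                                contrast, exclusionContrast, fdrThreshold,
                                exclusion))
}

#' Select genes responding to trauma in both age groups
#'
#' Intersection over both contrasts and all required timepoints of the
#' significant, direction-matched gene lists.
#'
#' @inheritParams selectStressResponse
#' @param contrasts the two (or more) groups that must all respond.
#' @return A [GeneSet-class], sorted.
#' @export
selectSharedResponse <- function(de, fdrThreshold = 0.05, direction = c("up", "down"),
                                 timepoints = c("W1", "W2"),
                                 contrasts = c("young", "aged"),
                                 name = "shared_response") {
  direction <- match.arg(direction)
  stopifnot(fdrThreshold > 0, fdrThreshold < 1, length(timepoints) >= 1L)
  r <- deRecords(de)
  .check_de_coverage(r, contrasts, timepoints)
  sets <- unlist(lapply(contrasts, function(ct)
    lapply(timepoints, function(tp)
      .sig_genes(r, ct, tp, direction, fdrThreshold))), recursive = FALSE)
  GeneSet(sort(Reduce(intersect, sets)), name = name,
          description = sprintf("%s at %s in all of %s (FDR<%g)", direction,
                                paste(timepoints, collapse = "+"),
                                paste(contrasts, collapse = "+"), fdrThreshold))
}

#' PCA of log2 fold-change trajectories
#'
#' Builds the conditions x genes matrix of log2 fold changes for the given
#' genes (conditions are contrast x timepoint combinations), centers each
#' gene (no scaling), and projects onto principal components. Component
#' signs follow the convention that each loading vector's
#' largest-magnitude entry is positive, making scores reproducible across
#' platforms.
#'
#' @param de a [DETable-class].
#' @param genes a [GeneSet-class] (>= 2 genes present in the table).
#' @return list with `scores` (conditions x PCs), `loadings` (genes x PCs),
#'   `varExplained` (percent per PC) and `conditions` (data.frame of
#'   contrast/timepoint per score row).
#' @export
fcTrajectoryPca <- function(de, genes) {
  r <- deRecords(de)
  ids <- intersect(geneIds(genes), unique(r$gene))
  if (length(ids) < 2L) stop("need >= 2 genes present in the DE table")
  r <- r[r$gene %in% ids, ]
  cond <- unique(r[, c("contrast", "timepoint")])
  if (nrow(cond) < 2L) stop("need >= 2 contrast x timepoint conditions")
  condKey <- paste(cond$contrast, cond$timepoint, sep = "_")
  m <- matrix(NA_real_, nrow(cond), length(ids),
              dimnames = list(condKey, ids))
  rKey <- paste(r$contrast, r$timepoint, sep = "_")
  m[cbind(match(rKey, condKey), match(r$gene, ids))] <- r$log2fc
  if (anyNA(m)) stop("incomplete log2fc matrix: every gene needs a value in every condition")
  if (all(abs(m - mean(m)) < 1e-12) || all(apply(m, 2L, sd) < 1e-12))
    stop("zero variance: constant fold-change matrix")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[[which.max(abs(v))]])
  }, numeric(1))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, "*")
  pc$x <- sweep(pc$x, 2L, flip, "*")
  varExplained <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       varExplained = varExplained, conditions = cond)
}

#' Filter strongly regulated, well-expressed genes
#'
#' Keeps genes whose mean expression and log2 fold change both exceed the
#' stated thresholds in one contrast (the defaults, mean expression > 10
#' and log fold change > 2.5, isolate drastically upregulated genes).
#'
#' @param de a [DETable-class].
#' @param contrast contrast to filter within.
#' @param timepoint optional timepoint restriction (default: all rows of
#'   the contrast; a gene qualifies if any of its rows qualifies).
#' @param meanExprMin mean-expression threshold (exclusive).
#' @param log2fcMin log2FC threshold (exclusive).
#' @param name name of the returned set.
#' @return A [GeneSet-class], sorted.
#' @export
filterTopRegulated <- function(de, contrast, timepoint = NULL,
                               meanExprMin = 10, log2fcMin = 2.5,
                               name = "top_regulated") {
  r <- deRecords(de)
  r <- r[r$contrast == contrast, ]
  if (!is.null(timepoint)) r <- r[r$timepoint %in% timepoint, ]
  if (!nrow(r)) stop("no rows for contrast '", contrast, "'")
  keep <- r$mean_expr > meanExprMin & r$log2fc > log2fcMin
  GeneSet(sort(unique(r$gene[keep])), name = name,
          description = sprintf("mean_expr>%g & log2fc>%g in %s",
                                meanExprMin, log2fcMin, contrast))
}
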