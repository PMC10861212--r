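## Cytokine activity inference: ridge regression of a response profile on a
## cytokine signature matrix, with gene-label permutation significance.

#' Infer cytokine activities from a response profile
#'
#' Restricts the signature matrix S and response y to their shared genes,
#' centers y and each column of S, and solves the ridge system
#' z = (S'S + lambda I)^-1 S' y. Significance comes from permuting y over
#' the shared-gene index `nPerm` times (preserving S's correlation
#' structure): perm_z = (z - mean_null) / sd_null and perm_p is the
#' two-sided empirical p-value with the +1 correction. When `lambda` is
#' NULL it is chosen by 5-fold cross-validation over {1e2, 1e3, 1e4}, the
#' penalty family used for published cytokine-signature regressions.
#'
#' @param S a [SignatureMatrix-class] (genes x cytokines).
#' @param y named numeric response profile (gene -> log2FC), e.g. from
#'   [readResponseProfile()].
#' @param lambda ridge penalty (>= 0) or NULL for cross-validation.
#' @param nPerm number of permutations (>= 100 for usable p-values).
#' @param seed integer RNG seed for the permutation null (mandatory).
#' @param label condition label stored in the result.
#' @return An [ActivityResult-class].
#' @examples
#' sim <- simulateSignatureResponse(300, paste0("CK", 1:5),
#'                                  active = c(CK2 = 2), noiseSd = 0, seed = 1)
#' fitActivity(sim$signatures, sim$response, lambda = 0, nPerm = 100, seed = 1)
#' @export
fitActivity <- function(S, y, lambda = NULL, nPerm = 1000L, seed,
                        label = "response") {
  stopifnot(is.numeric(y), !is.null(names(y)))
  if (any(!is.finite(y))) stop("response profile must be finite")
  m <- S@.Data
  shared <- intersect(rownames(m), normalizeSymbols(names(y)))
  if (length(shared) < 2L)
    stop("signature/response gene overlap too small (< 2 genes)")
  names(y) <- normalizeSymbols(names(y))
  X <- scale(m[shared, , drop = FALSE], center = TRUE, scale = FALSE)
  yv <- y[shared] - mean(y[shared])
  if (is.null(lambda)) lambda <- .cv_lambda(X, yv, seed = seed)
  if (lambda < 0) stop("lambda must be >= 0")
  G <- crossprod(X) + lambda * diag(ncol(X))
  ok <- tryCatch({ R <- chol(G); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular system at lambda = ", lambda, "; use lambda > 0")
  solveOp <- chol2inv(chol(G)) %*% t(X)  # k x n; z = solveOp %*% y
  z <- drop(solveOp %*% yv)
  set.seed(seed)
  null <- matrix(NA_real_, ncol(X), nPerm)
  for (b in seq_len(nPerm)) {
    null[, b] <- solveOp %*% yv[sample.int(length(yv))]
  }
  mu <- rowMeans(null)
  sdn <- apply(null, 1L, sd)
  permZ <- ifelse(sdn > 0, (z - mu) / sdn, 0)
  permP <- (1 + rowSums(abs(null) >= abs(z) - 1e-12)) / (nPerm + 1)
  tab <- data.frame(cytokine = colnames(m), coefficient = z,
                    perm_z = permZ, perm_p = permP,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("ActivityResult", table = tab, lambda = lambda,
      nPerm = as.integer(nPerm), seed = as.integer(seed), label = label)
}

# 5-fold CV over the published penalty family {1e2, 1e3, 1e4}
.cv_lambda <- function(X, y, grid = c(1e2, 1e3, 1e4), seed = 1L) {
  set.seed(seed)
  n <- length(y)
  fold <- sample(rep_len(1:5, n))
  err <- vapply(grid, function(lam) {
    se <- 0
    for (f in 1:5) {
      tr <- fold != f
      G <- crossprod(X[tr, , drop = FALSE]) + lam * diag(ncol(X))
      z <- solve(G, crossprod(X[tr, , drop = FALSE], y[tr]))
      se <- se + sum((y[!tr] - X[!tr, , drop = FALSE] %*% z)^2)
    }
    se
  }, numeric(1))
  grid[[which.min(err)]]
}

#' Differential cytokine activity between two conditions
#'
#' Compares matched activity fits (same cytokine panel) across timepoints
#' between an age group of interest and a reference group. A cytokine is
#' flagged `elevated` when its coefficient in the group of interest is
#' positive and exceeds the reference coefficient at every compared
#' timepoint.
#'
#' @param resultsA named list of [ActivityResult-class] (group of
#'   interest, e.g. aged), names are timepoints.
#' @param resultsB named list of [ActivityResult-class] (reference group,
#'   e.g. young) with the same names.
#' @return data.frame with one row per cytokine: per-timepoint coefficient
#'   and perm_z differences (A - B), and `elevated`.
#' @export
differentialActivity <- function(resultsA, resultsB) {
  if (length(resultsA) < 1L || !identical(sort(names(resultsA)),
                                          sort(names(resultsB))))
    stop("resultsA and resultsB need identical timepoint names")
  tps <- names(resultsA)
  panel <- activityTable(resultsA[[1L]])$cytokine
  for (r in c(resultsA, resultsB))
    if (!identical(activityTable(r)$cytokine, panel))
      stop("mismatched cytokine panels across conditions")
  out <- data.frame(cytokine = panel, stringsAsFactors = FALSE)
  above <- posA <- matrix(TRUE, length(panel), length(tps))
  for (i in seq_along(tps)) {
    ta <- activityTable(resultsA[[tps[[i]]]])
    tb <- activityTable(resultsB[[tps[[i]]]])
    out[[paste0("coef_diff_", tps[[i]])]] <- ta$coefficient - tb$coefficient
    out[[paste0("z_diff_", tps[[i]])]] <- ta$perm_z - tb$perm_z
    above[, i] <- ta$coefficient > tb$coefficient
    posA[, i] <- ta$coefficient > 0
  }
  out$elevated <- apply(above & posA, 1L, all)
  out
}

#' Filter candidate cytokines by tissue of origin
#'
#' Keeps candidates expressed in the designated source tissue (fraction of
#' expressing cells above `threshold`) and essentially absent from the
#' target tissue (fraction below `targetMax`, default 0.01 — the "< 1%"
#' rule used to call a cytokine synovium-derived rather than
#' chondrocyte-intrinsic).
#'
#' @param candidates character vector of cytokine names.
#' @param sourceExpression data.frame with a `cytokine` column and one
#'   fraction-expressing column per cell type / tissue.
#' @param sourceTissue column name of the releasing tissue.
#' @param targetTissue column name of the receiving tissue.
#' @param threshold minimum source fraction (exclusive).
#' @param targetMax maximum target fraction (exclusive; default 0.01).
#' @return character vector of retained cytokines.
#' @export
intersectSourceFilter <- function(candidates, sourceExpression, sourceTissue,
                                  targetTissue, threshold = 0.05,
                                  targetMax = 0.01) {
  stopifnot(all(c("cytokine", sourceTissue, targetTissue) %in%
                  names(sourceExpression)))
  miss <- setdiff(candidates, sourceExpression$cytokine)
  if (length(miss))
    stop("cytokine(s) missing from the expression table: ",
         paste(miss, collapse = ", "))
  rows <- sourceExpression[match(candidates, sourceExpression$cytokine), ]
  keep <- rows[[sourceTissue]] > threshold & rows[[targetTissue]] < targetMax
  candidates[keep]
}
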