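## Standardized mean differences and DerSimonian-Laird random-effects pooling
## for two-arm study summaries (histology scores rescaled to 0-100).

#' Standardized mean difference of a two-arm study
#'
#' d = (mean_trt - mean_ctrl) / s_p with the pooled standard deviation
#' s_p = sqrt(((n_t - 1) sd_t^2 + (n_c - 1) sd_c^2) / (n_t + n_c - 2)).
#' With `hedges = TRUE` (default, matching RevMan's SMD) the small-sample
#' correction J = 1 - 3 / (4 (n_t + n_c - 2) - 1) is applied. The sampling
#' variance is (n_t + n_c) / (n_t n_c) + d^2 / (2 (n_t + n_c)).
#'
#' @param meanCtrl,sdCtrl,nCtrl control-arm mean, SD and size (n >= 2).
#' @param meanTrt,sdTrt,nTrt treated-arm mean, SD and size (n >= 2).
#' @param hedges apply the Hedges small-sample correction (default TRUE).
#' @return An [EffectSize-class].
#' @examples
#' smd(8, 2, 10, 10, 2, 10, hedges = FALSE)  # Cohen d = 1
#' @export
smd <- function(meanCtrl, sdCtrl, nCtrl, meanTrt, sdTrt, nTrt, hedges = TRUE) {
  stopifnot(nCtrl >= 2L, nTrt >= 2L, sdCtrl >= 0, sdTrt >= 0)
  sp <- sqrt(((nTrt - 1) * sdTrt^2 + (nCtrl - 1) * sdCtrl^2) /
               (nTrt + nCtrl - 2))
  if (sp == 0) stop("degenerate pooled SD: both arm SDs are zero")
  d <- (meanTrt - meanCtrl) / sp
  if (hedges) d <- d * (1 - 3 / (4 * (nTrt + nCtrl - 2) - 1))
  v <- (nTrt + nCtrl) / (nTrt * nCtrl) + d^2 / (2 * (nTrt + nCtrl))
  new("EffectSize", d = d, variance = v, hedges = hedges)
}

#' Compute effect sizes for a table of studies
#'
#' @param studies data.frame with columns mean_ctrl, sd_ctrl, n_ctrl,
#'   mean_trt, sd_trt, n_trt (as produced by [simulateMetaStudies()]).
#' @param hedges apply the Hedges correction.
#' @return list of [EffectSize-class] objects, named by study_id when
#'   present.
#' @export
studyEffects <- function(studies, hedges = TRUE) {
  out <- lapply(seq_len(nrow(studies)), function(i)
    smd(studies$mean_ctrl[[i]], studies$sd_ctrl[[i]], studies$n_ctrl[[i]],
        studies$mean_trt[[i]], studies$sd_trt[[i]], studies$n_trt[[i]],
        hedges = hedges))
  if (!is.null(studies$study_id)) names(out) <- studies$study_id
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Fixed-effect weights w_i = 1/v_i give the fixed-effect mean and
#' Cochran's Q = sum w_i (d_i - d_FE)^2. The method-of-moments
#' between-study variance is tau2 = max(0, (Q - (k - 1)) /
#' (sum w - sum w^2 / sum w)); random-effects weights w*_i = 1/(v_i + tau2)
#' yield the pooled estimate, a normal-approximation 95 percent CI
#' pooled +/- 1.96 / sqrt(sum w*), and I2 = max(0, (Q - (k-1)) / Q) * 100
#' (0 when Q = 0).
#'
#' @param effects list of [EffectSize-class] objects (>= 2).
#' @return A [PooledEffect-class].
#' @examples
#' e <- list(new("EffectSize", d = 0.2, variance = 0.1, hedges = FALSE),
#'           new("EffectSize", d = 0.8, variance = 0.1, hedges = FALSE))
#' poolDL(e)
#' @export
poolDL <- function(effects) {
  if (length(effects) < 2L)
    stop("need >= 2 effects; for a single study report smd() alone")
  d <- vapply(effects, function(e) e@d, numeric(1))
  v <- vapply(effects, function(e) e@variance, numeric(1))
  w <- 1 / v
  dFE <- sum(w * d) / sum(w)
  Q <- sum(w * (d - dFE)^2)
  k <- length(d)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * d) / sum(ws)
  half <- 1.96 / sqrt(sum(ws))
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  new("PooledEffect", smd = pooled, ciLow = pooled - half,
      ciHigh = pooled + half, tau2 = tau2, Q = Q, I2 = I2,
      weights = ws / sum(ws))
}

#' Rescale a bounded score to 0-100
#'
#' Semiquantitative histology scales (e.g. OARSI 0-6) are converted to a
#' common 0-100 range before pooling: 100 (x - lo) / (hi - lo).
#'
#' @param x score value(s) within [lo, hi].
#' @param lo,hi scale bounds (hi > lo).
#' @return numeric in [0, 100].
#' @examples
#' rescaleScore(3, 0, 6)  # 50
#' @export
rescaleScore <- function(x, lo, hi) {
  if (hi <= lo) stop("need hi > lo")
  if (any(x < lo | x > hi)) stop("score outside [", lo, ", ", hi, "]")
  100 * (x - lo) / (hi - lo)
}

#' Average effect sizes across timepoints within one group
#'
#' Arithmetic mean of the d values; the variance is likewise the mean of
#' the per-timepoint variances (a documented simplification that ignores
#' the correlation between timepoints from shared animals).
#'
#' @param effects nonempty list of [EffectSize-class] objects.
#' @return An [EffectSize-class].
#' @export
averageEffects <- function(effects) {
  if (!length(effects)) stop("empty effect list")
  d <- vapply(effects, function(e) e@d, numeric(1))
  v <- vapply(effects, function(e) e@variance, numeric(1))
  new("EffectSize", d = mean(d), variance = mean(v),
      hedges = all(vapply(effects, function(e) e@hedges, logical(1))))
}
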