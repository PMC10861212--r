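## 2x2 enrichment statistics: Fisher's exact test (hypergeometric
## probability-mass enumeration), sample odds ratio with Woolf CI, and
## single-predictor binary logistic regression.

#' Build a 2x2 contingency table from gene sets
#'
#' a = |A intersect B|, b = |A \ B|, c = |B \ A|, d = |universe \ (A u B)|.
#' The universe is a mandatory explicit argument; both sets must lie
#' inside it.
#'
#' @param setA,setB [GeneSet-class] objects (or character vectors).
#' @param universe [GeneSet-class] or character vector of universe genes.
#' @return A [Contingency-class].
#' @export
contingencyFromSets <- function(setA, setB, universe) {
  g <- function(x) if (is(x, "GeneSet")) geneIds(x) else
    unique(normalizeSymbols(x))
  A <- g(setA); B <- g(setB); U <- g(universe)
  out <- setdiff(union(A, B), U)
  if (length(out))
    stop("set member(s) outside the universe: ",
         paste(head(out, 5L), collapse = ", "),
         if (length(out) > 5L) ", ..." else "")
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  c <- length(setdiff(B, A))
  d <- length(U) - a - b - c
  Contingency(a, b, c, d)
}

# two-sided Fisher p by the probability-mass rule: sum hypergeometric
# probabilities of all tables (at the observed margins) no more probable
# than the observed one.
.fisher_p <- function(a, b, c, d) {
  m <- a + b          # size of set A
  n <- c + d          # complement of A
  kk <- a + c         # size of set B
  lo <- max(0L, kk - n)
  hi <- min(kk, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, kk)
  pObs <- dhyper(a, m, n, kk)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by full hypergeometric enumeration with the
#' probability-mass rule (the R convention: all tables at the observed
#' margins whose probability does not exceed the observed table's). The
#' odds ratio is the sample OR (a d)/(b c), +Inf when b c = 0 with
#' a d > 0, with the Woolf log-normal CI exp(ln OR +/- 1.96 sqrt(1/a +
#' 1/b + 1/c + 1/d)) when all cells are positive. No multiple-testing
#' correction is applied here.
#'
#' @param ct a [Contingency-class].
#' @return An [EnrichmentResult-class] with method "fisher".
#' @examples
#' fisherEnrichment(Contingency(5, 5, 5, 85))
#' @export
fisherEnrichment <- function(ct) {
  a <- ct@a; b <- ct@b; c <- ct@c; d <- ct@d
  p <- min(1, .fisher_p(a, b, c, d))
  # sample OR with degenerate-cell conventions: a zero off-diagonal with
  # positive agreement cells is perfect positive association (+Inf); both
  # agreement cells zero with positive off-diagonals is perfect negative
  # association (0); tables carrying no association information give 1
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a > 0 && (b == 0 || c == 0)) Inf
        else if (a == 0 && d == 0 && b > 0 && c > 0) 0
        else 1
  if (all(c(a, b, c, d) > 0L)) {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  } else ci <- c(NA_real_, NA_real_)
  new("EnrichmentResult", oddsRatio = or, ciLow = ci[[1L]], ciHigh = ci[[2L]],
      p = p, method = "fisher")
}

#' Single-predictor binary logistic regression odds ratio
#'
#' Fits logit P(outcome = 1) = b0 + b1 predictor by iteratively
#' reweighted least squares and reports OR = exp(b1) with the Wald 95
#' percent CI. On a saturated binary-predictor design this equals the
#' sample odds ratio of the collapsed 2x2 table. Perfect separation is
#' rejected with a pointer to [fisherEnrichment()].
#'
#' @param outcome binary (0/1 or logical) response vector.
#' @param predictor binary (0/1 or logical) predictor of the same length.
#' @return An [EnrichmentResult-class] with method "logistic".
#' @export
logisticEnrichment <- function(outcome, predictor) {
  outcome <- as.integer(outcome); predictor <- as.integer(predictor)
  stopifnot(length(outcome) == length(predictor))
  if (length(unique(outcome)) < 2L || length(unique(predictor)) < 2L)
    stop("both vectors need both classes present")
  fit <- suppressWarnings(
    glm(outcome ~ predictor, family = binomial(),
        control = list(maxit = 25L, epsilon = 1e-10)))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
      abs(coef(fit)[["predictor"]]) > 15)
    stop("perfect (or quasi-perfect) separation: use fisherEnrichment()")
  b1 <- coef(fit)[["predictor"]]
  se <- sqrt(vcov(fit)["predictor", "predictor"])
  # Wald p; two-sided
  p <- 2 * pnorm(-abs(b1 / se))
  new("EnrichmentResult", oddsRatio = exp(b1),
      ciLow = exp(b1 - 1.96 * se), ciHigh = exp(b1 + 1.96 * se),
      p = p, method = "logistic")
}

#' Expand a 2x2 contingency table to per-gene binary vectors
#'
#' Convenience for running [logisticEnrichment()] on set co-membership:
#' outcome = membership in A, predictor = membership in B.
#'
#' @param ct a [Contingency-class].
#' @return list with `outcome` and `predictor` binary vectors of length n.
#' @export
contingencyToVectors <- function(ct) {
  outcome <- c(rep(1L, ct@a), rep(1L, ct@b), rep(0L, ct@c), rep(0L, ct@d))
  predictor <- c(rep(1L, ct@a), rep(0L, ct@b), rep(1L, ct@c), rep(0L, ct@d))
  list(outcome = outcome, predictor = predictor)
}
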