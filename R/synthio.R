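## Synthetic-data generators. Each plants a known signal that the matching
## pipeline stage must recover; identical seeds give identical outputs.

.gene_universe <- function(n) sprintf("G%06d", seq_len(n))

#' Simulate a two-group four-timepoint differential-expression time course
#'
#' Emulates a trauma time course in young and aged animals: contrasts
#' {young, aged} x timepoints {D1, W1, W2, W6}. A set of planted genes is
#' upregulated (log2FC ~ `effectLog2fc`) at W1 and W2 in the aged contrast
#' only; all other gene/condition combinations are null. Observed log2FC is
#' effect + Normal(0, noiseSd) noise; the p-value treats noiseSd as the
#' known standard error (so null p-values are exactly Uniform(0,1) in law),
#' and FDR is Benjamini-Hochberg within each contrast x timepoint. In the
#' zero-noise limit planted entries get p ~ 0 and null entries p = 1, so
#' downstream selection is exact.
#'
#' @param nGenes total number of genes.
#' @param nPlanted number of planted age-specific response genes.
#' @param effectLog2fc planted log2 fold change (default 2).
#' @param noiseSd standard deviation of the log2FC noise (>= 0).
#' @param seed integer RNG seed.
#' @return list with elements `de` ([DETable-class]) and `truth`
#'   ([SimTruth-class]).
#' @examples
#' sim <- simulateDETimecourse(200, 20, noiseSd = 0, seed = 1)
#' sim$de
#' @export
simulateDETimecourse <- function(nGenes, nPlanted, effectLog2fc = 2,
                                 noiseSd = 0.5, seed = 1L) {
  if (nPlanted <= 0L || nPlanted >= nGenes)
    stop("need 0 < nPlanted < nGenes")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  set.seed(seed)
  genes <- .gene_universe(nGenes)
  planted <- sort(sample(genes, nPlanted))
  meanExpr <- setNames(exp(rnorm(nGenes, mean = 3, sd = 1)), genes)
  grid <- expand.grid(contrast = c("young", "aged"),
                      timepoint = c("D1", "W1", "W2", "W6"),
                      stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ct <- grid$contrast[[i]]; tp <- grid$timepoint[[i]]
    mu <- rep(0, nGenes)
    if (ct == "aged" && tp %in% c("W1", "W2"))
      mu[genes %in% planted] <- effectLog2fc
    obs <- mu + if (noiseSd > 0) rnorm(nGenes, sd = noiseSd) else 0
    if (noiseSd > 0) {
      p <- 2 * pnorm(-abs(obs) / noiseSd)
    } else {
      p <- ifelse(mu != 0, 1e-12, 1)
    }
    data.frame(gene = genes, contrast = ct, timepoint = tp,
               log2fc = obs, p = p, fdr = p.adjust(p, "BH"),
               mean_expr = unname(meanExpr), stringsAsFactors = FALSE)
  }))
  truth <- new("SimTruth", plantedAgeGenes = planted,
               plantedModules = integer(), trueActivities = numeric(),
               trueSmd = numeric(), trueTau2 = numeric(),
               reverserId = character(), seed = as.integer(seed))
  list(de = DETable(recs), truth = truth)
}

#' Simulate a modular weighted gene network with a planted receptor
#'
#' Planted-partition graph: within-module edges appear with probability
#' `pIn`, all other pairs with `pOut`; edge weights are Uniform(0.1, 1) so
#' no zero-weight edges exist. A designated node "RECEPTOR" is wired into
#' `receptorModule` with at least 3 edges, standing in for a cytokine
#' receptor embedded in its downstream module. Nodes beyond the planted
#' modules are background (module 0). The graph is returned even if
#' disconnected.
#'
#' @param nNodes total nodes (excluding RECEPTOR); must be >=
#'   sum(moduleSizes).
#' @param moduleSizes integer vector of planted module sizes (nonempty).
#' @param pIn within-module edge probability.
#' @param pOut between-module / background edge probability (< pIn).
#' @param receptorModule index of the module RECEPTOR attaches to.
#' @param seed integer RNG seed.
#' @return list with `network` ([WeightedNetwork-class]) and `truth`
#'   ([SimTruth-class]; `plantedModules` maps gene -> module id).
#' @export
simulateNetwork <- function(nNodes, moduleSizes, pIn = 0.3, pOut = 0.02,
                            receptorModule = 1L, seed = 1L) {
  if (!length(moduleSizes)) stop("moduleSizes must be nonempty")
  if (sum(moduleSizes) > nNodes) stop("sum(moduleSizes) must be <= nNodes")
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  if (receptorModule < 1L || receptorModule > length(moduleSizes))
    stop("receptorModule out of range")
  set.seed(seed)
  genes <- .gene_universe(nNodes)
  mod <- integer(nNodes)
  idx <- 1L
  for (m in seq_along(moduleSizes)) {
    mod[idx:(idx + moduleSizes[[m]] - 1L)] <- m
    idx <- idx + moduleSizes[[m]]
  }
  pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
  same <- mod[pairs[, 1L]] == mod[pairs[, 2L]] & mod[pairs[, 1L]] > 0L
  prob <- ifelse(same, pIn, pOut)
  keep <- runif(nrow(pairs)) < prob
  edges <- data.frame(from = genes[pairs[keep, 1L]],
                      to = genes[pairs[keep, 2L]],
                      weight = runif(sum(keep), 0.1, 1),
                      stringsAsFactors = FALSE)
  rmem <- genes[mod == receptorModule]
  nAtt <- max(3L, rbinom(1L, length(rmem), pIn))
  att <- sample(rmem, min(nAtt, length(rmem)))
  edges <- rbind(edges,
                 data.frame(from = "RECEPTOR", to = att,
                            weight = runif(length(att), 0.1, 1),
                            stringsAsFactors = FALSE))
  net <- WeightedNetwork(edges, nodes = c(genes, "RECEPTOR"))
  membership <- setNames(c(mod, as.integer(receptorModule)),
                         c(genes, "RECEPTOR"))
  truth <- new("SimTruth", plantedAgeGenes = character(),
               plantedModules = membership, trueActivities = numeric(),
               trueSmd = numeric(), trueTau2 = numeric(),
               reverserId = character(), seed = as.integer(seed))
  list(network = net, truth = truth)
}

#' Simulate a cytokine signature matrix and response profile
#'
#' The signature matrix S has sparse signed entries (each gene responds to
#' ~10 percent of cytokines, effect magnitudes ~ |Normal(1, 0.25)| with
#' random sign) and unit-L2-normalized columns. The response is
#' y = S z_true + eps with eps ~ Normal(0, noiseSd^2) i.i.d. per gene,
#' where z_true holds the planted activities.
#'
#' @param nGenes number of genes.
#' @param cytokines character vector of cytokine names.
#' @param active named numeric of planted activities (names must be a
#'   subset of `cytokines`); may be empty for a pure-noise response.
#' @param noiseSd response noise standard deviation.
#' @param seed integer RNG seed.
#' @return list with `signatures` ([SignatureMatrix-class]), `response`
#'   (named numeric log2FC vector) and `truth` ([SimTruth-class]).
#' @export
simulateSignatureResponse <- function(nGenes, cytokines, active = numeric(),
                                      noiseSd = 1, seed = 1L) {
  if (length(active) && !all(names(active) %in% cytokines))
    stop("unknown cytokine in 'active': ",
         paste(setdiff(names(active), cytokines), collapse = ", "))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  set.seed(seed)
  genes <- .gene_universe(nGenes)
  k <- length(cytokines)
  S <- matrix(0, nGenes, k, dimnames = list(genes, cytokines))
  nz <- matrix(runif(nGenes * k) < 0.1, nGenes, k)
  S[nz] <- sample(c(-1, 1), sum(nz), replace = TRUE) *
    abs(rnorm(sum(nz), 1, 0.25))
  empty <- colSums(abs(S)) == 0
  if (any(empty))  # guarantee no all-zero column on tiny simulations
    S[cbind(sample(nGenes, sum(empty), replace = TRUE), which(empty))] <- 1
  S <- sweep(S, 2L, sqrt(colSums(S^2)), "/")
  z <- setNames(numeric(k), cytokines)
  z[names(active)] <- active
  y <- drop(S %*% z) + if (noiseSd > 0) rnorm(nGenes, sd = noiseSd) else 0
  names(y) <- genes
  truth <- new("SimTruth", plantedAgeGenes = character(),
               plantedModules = integer(), trueActivities = z,
               trueSmd = numeric(), trueTau2 = numeric(),
               reverserId = character(), seed = as.integer(seed))
  list(signatures = SignatureMatrix(S), response = y, truth = truth)
}

#' Simulate two-arm study summaries for random-effects meta-analysis
#'
#' Each study's true effect is delta_i ~ Normal(trueSmd, tau2); control-arm
#' observations are Normal(0, 1) and treated-arm observations
#' Normal(delta_i, 1), summarized to per-arm mean/SD/n.
#'
#' @param k number of studies (>= 2).
#' @param trueSmd planted standardized mean difference.
#' @param tau2 planted between-study variance (>= 0).
#' @param nPerArm observations per arm (>= 3).
#' @param seed integer RNG seed.
#' @return list with `studies` (data.frame: study_id, mean_ctrl, sd_ctrl,
#'   n_ctrl, mean_trt, sd_trt, n_trt) and `truth` ([SimTruth-class]).
#' @export
simulateMetaStudies <- function(k, trueSmd, tau2, nPerArm, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (tau2 < 0) stop("tau2 must be >= 0")
  if (nPerArm < 3L) stop("nPerArm must be >= 3")
  set.seed(seed)
  delta <- rnorm(k, trueSmd, sqrt(tau2))
  studies <- do.call(rbind, lapply(seq_len(k), function(i) {
    ctrl <- rnorm(nPerArm, 0, 1)
    trt <- rnorm(nPerArm, delta[[i]], 1)
    data.frame(study_id = sprintf("S%02d", i),
               mean_ctrl = mean(ctrl), sd_ctrl = sd(ctrl), n_ctrl = nPerArm,
               mean_trt = mean(trt), sd_trt = sd(trt), n_trt = nPerArm,
               stringsAsFactors = FALSE)
  }))
  truth <- new("SimTruth", plantedAgeGenes = character(),
               plantedModules = integer(), trueActivities = numeric(),
               trueSmd = trueSmd, trueTau2 = tau2,
               reverserId = character(), seed = as.integer(seed))
  list(studies = studies, truth = truth)
}

#' Simulate a blocked co-expression count matrix
#'
#' Genes in each planted module share a latent per-sample factor: on the
#' log scale, x = sqrt(withinCor) * factor + sqrt(1 - withinCor) * noise,
#' so the expected within-module log-scale correlation is `withinCor`.
#' Counts are Poisson with log-normal rates; library sizes vary by a
#' uniform factor in [0.5, 2]. Background genes are independent. Module
#' sizes below 30 are allowed but warned about, since the default module
#' cut leaves such modules unassigned.
#'
#' @param moduleSizes integer vector of planted module sizes.
#' @param nSamples number of samples (>= 4).
#' @param withinCor target within-module log-scale correlation in (0, 1);
#'   0 is accepted and yields pure noise (no-signal control).
#' @param nBackground independent background genes (default 100).
#' @param seed integer RNG seed.
#' @return list with `se` (SummarizedExperiment, assay "counts") and
#'   `truth` ([SimTruth-class]; `plantedModules` maps gene -> module,
#'   background = 0).
#' @export
simulateExprModules <- function(moduleSizes, nSamples, withinCor = 0.9,
                                nBackground = 100L, seed = 1L) {
  if (withinCor < 0 || withinCor >= 1) stop("withinCor must be in [0, 1)")
  if (nSamples < 4L) stop("nSamples must be >= 4")
  if (any(moduleSizes < 30L))
    warning("module size(s) below 30: default module cut will leave them unassigned")
  set.seed(seed)
  nMod <- sum(moduleSizes)
  nGenes <- nMod + nBackground
  genes <- .gene_universe(nGenes)
  mod <- c(rep(seq_along(moduleSizes), moduleSizes), rep(0L, nBackground))
  factors <- matrix(rnorm(length(moduleSizes) * nSamples),
                    length(moduleSizes), nSamples)
  sigma <- 1.2  # log-scale biological variation
  logx <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
  for (m in seq_along(moduleSizes)) {
    rows <- which(mod == m)
    logx[rows, ] <- sqrt(withinCor) *
      matrix(factors[m, ], length(rows), nSamples, byrow = TRUE) +
      sqrt(1 - withinCor) * logx[rows, ]
  }
  baseline <- rnorm(nGenes, mean = 4, sd = 1)
  rate <- exp(baseline + sigma * logx)
  libFactor <- runif(nSamples, 0.5, 2)
  counts <- matrix(rpois(nGenes * nSamples,
                         lambda = sweep(rate, 2L, libFactor, "*")),
                   nGenes, nSamples,
                   dimnames = list(genes, sprintf("SAMP%02d", seq_len(nSamples))))
  se <- makeExprSE(counts,
                   rep(c("A", "B"), length.out = nSamples))
  truth <- new("SimTruth", plantedAgeGenes = character(),
               plantedModules = setNames(as.integer(mod), genes),
               trueActivities = numeric(), trueSmd = numeric(),
               trueTau2 = numeric(), reverserId = character(),
               seed = as.integer(seed))
  list(se = se, truth = truth)
}

#' Simulate a perturbation signature library
#'
#' Each perturbation profile assigns every gene a signed score (higher =
#' more upregulated by the perturbation). Profiles are independent
#' Normal(0, 1) noise; if `plantReverser`, one profile ("PERT_REV") places
#' all query genes at the extreme bottom of its ranking, i.e. a compound
#' whose expression signature opposes the query.
#'
#' @param nPerts number of random perturbations (the reverser is added on
#'   top when planted).
#' @param nGenes gene universe size.
#' @param queryUp [GeneSet-class] of upregulated query genes (must be
#'   nonempty and inside the universe).
#' @param plantReverser logical; plant the signature-reversing profile.
#' @param cellLines character vector of cell-line labels cycled over
#'   perturbations (default one line).
#' @param seed integer RNG seed.
#' @return list with `library` (perturbations x genes score matrix),
#'   `cellLines` (named character: perturbation -> cell line) and `truth`
#'   ([SimTruth-class]).
#' @export
simulatePerturbationLibrary <- function(nPerts, nGenes, queryUp,
                                        plantReverser = TRUE,
                                        cellLines = "CL1", seed = 1L) {
  if (!length(geneIds(queryUp))) stop("queryUp must be nonempty")
  set.seed(seed)
  genes <- .gene_universe(nGenes)
  if (!all(geneIds(queryUp) %in% genes))
    stop("queryUp genes outside the simulated universe")
  ids <- sprintf("PERT%03d", seq_len(nPerts))
  lib <- matrix(rnorm(nPerts * nGenes), nPerts, nGenes,
                dimnames = list(ids, genes))
  reverser <- character()
  if (plantReverser) {
    prof <- rnorm(nGenes)
    qIdx <- match(geneIds(queryUp), genes)
    # push query genes strictly below every other score
    prof[qIdx] <- min(prof) - 1 - runif(length(qIdx))
    lib <- rbind(lib, PERT_REV = prof)
    reverser <- "PERT_REV"
  }
  cl <- setNames(rep(cellLines, length.out = nrow(lib)), rownames(lib))
  truth <- new("SimTruth", plantedAgeGenes = character(),
               plantedModules = integer(), trueActivities = numeric(),
               trueSmd = numeric(), trueTau2 = numeric(),
               reverserId = reverser, seed = as.integer(seed))
  list(library = lib, cellLines = cl, truth = truth)
}
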