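## End-to-end orchestration over synthetic fixtures or user files, with
## deterministic per-stage seeds and a provenance manifest.

#' Derive a per-stage seed from a global seed
#'
#' Stable string hash of the stage name folded into the global seed, so
#' adding a stage never perturbs the randomness of the others. Result is
#' a positive 32-bit integer.
#'
#' @param globalSeed integer global seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stageSeed <- function(globalSeed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(globalSeed)) * 1009 + h) %% 2147483629 + 1)
}

#' Rank candidate seed receptors by pseudo-activation enrichment
#'
#' For each candidate: propagate from it, call the pseudo-activated set
#' (with exclusions), and test its overlap with the target set over the
#' universe by Fisher's exact test. Candidates are ranked by descending
#' odds ratio, ties broken by ascending p. The planted receptor of a
#' synthetic network should come out first.
#'
#' @param network a [WeightedNetwork-class].
#' @param candidateSeeds character vector (or [GeneSet-class]) of
#'   candidate seed nodes, all present in the network.
#' @param targetSet [GeneSet-class] the pseudo-activated set is tested
#'   against.
#' @param exclude genes removed from the pseudo-activated sets.
#' @param universe universe for the contingency table (default: network
#'   nodes minus the candidate itself).
#' @param restart restart probability (default 0.7).
#' @return data.frame with columns seed, oddsRatio, p, nActivated, ranked.
#' @export
driverRank <- function(network, candidateSeeds, targetSet,
                       exclude = character(), universe = NULL,
                       restart = 0.7) {
  if (is(candidateSeeds, "GeneSet")) candidateSeeds <- geneIds(candidateSeeds)
  candidateSeeds <- normalizeSymbols(candidateSeeds)
  missing <- setdiff(candidateSeeds, networkNodes(network))
  if (length(missing))
    stop("candidate(s) not in network: ", paste(missing, collapse = ", "))
  rows <- lapply(candidateSeeds, function(s) {
    prop <- rwr(network, s, restart = restart)
    act <- pseudoActivated(prop, exclude = exclude)
    univ <- if (is.null(universe)) setdiff(networkNodes(network), s)
            else { u <- if (is(universe, "GeneSet")) geneIds(universe)
                        else normalizeSymbols(universe)
                   setdiff(u, s) }
    target <- intersect(if (is(targetSet, "GeneSet")) geneIds(targetSet)
                        else normalizeSymbols(targetSet), univ)
    ct <- contingencyFromSets(intersect(geneIds(act), univ), target, univ)
    fr <- fisherEnrichment(ct)
    data.frame(seed = s, oddsRatio = oddsRatio(fr), p = fr@p,
               nActivated = length(geneIds(act)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$oddsRatio, out$p, out$seed), ]
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on synthetic fixtures
#'
#' Generates every synthetic input (DE time course, modular network with a
#' planted receptor, signature/response pair, meta-analysis studies,
#' blocked count matrix, perturbation library), runs each stage —
#' stress-response selection, trajectory PCA, meta-analysis pooling,
#' propagation and pseudo-activation, module detection, cytokine activity
#' inference, stiffness ssGSEA, marker enrichment, co-expression modules,
#' connectivity screening — and writes the TSV/GMT/JSON artifacts plus a
#' manifest to `outDir`. All randomness fans out from `seed` through
#' [stageSeed()], so two runs with the same seed are identical.
#'
#' @param outDir output directory (created if needed).
#' @param seed global integer seed.
#' @param config named list overriding stage parameters; recognized keys
#'   (with defaults): nGenes (1000), nPlanted (80), noiseSd (0.4),
#'   fdrThreshold (0.05), restart (0.7), alpha (0.75), lambda (NULL: CV),
#'   nPerm (300), minModuleSize (30), deepSplit (2), tauThreshold (-90),
#'   stages (character vector of stages to run; default all).
#' @return invisibly, a named list of per-stage results (also serialized
#'   under `outDir`).
#' @export
runAll <- function(outDir, seed = 1L, config = list()) {
  cfg <- modifyList(list(
    nGenes = 1000L, nPlanted = 80L, noiseSd = 0.4, fdrThreshold = 0.05,
    restart = 0.7, alpha = 0.75, lambda = NULL, nPerm = 300L,
    minModuleSize = 30L, deepSplit = 2L, tauThreshold = -90,
    stages = c("stress", "meta", "propagate", "cytokines", "ssgsea",
               "enrich", "coexpr", "cmap")), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  onStage <- function(s) s %in% cfg$stages
  manifest <- list(seed = seed, parameters = cfg[setdiff(names(cfg), "stages")],
                   stages = list(), package_version =
                     as.character(utils::packageVersion("cytoDriver")))

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seed = stageSeed(seed, name))
    results[[name]] <<- res
    res
  }

  ## synthetic world shared across stages
  simDe <- simulateDETimecourse(cfg$nGenes, cfg$nPlanted,
                                noiseSd = cfg$noiseSd,
                                seed = stageSeed(seed, "simulate_de"))
  writeDeTable(simDe$de, file.path(outDir, "de_table.tsv"))

  if (onStage("stress")) run_stage("stress", function() {
    up <- selectStressResponse(simDe$de, fdrThreshold = cfg$fdrThreshold)
    down <- selectStressResponse(simDe$de, direction = "down",
                                 fdrThreshold = cfg$fdrThreshold,
                                 name = "stress_response_down")
    shared <- selectSharedResponse(simDe$de, fdrThreshold = cfg$fdrThreshold)
    writeGmt(list(up, down, shared), file.path(outDir, "stress_sets.gmt"))
    pca <- fcTrajectoryPca(simDe$de, up)
    write.table(data.frame(condition = rownames(pca$scores),
                           pca$scores[, 1:2, drop = FALSE]),
                file.path(outDir, "trajectory_pca.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(up = up, down = down, shared = shared, pca = pca)
  })

  if (onStage("meta")) run_stage("meta", function() {
    sim <- simulateMetaStudies(10L, trueSmd = 1, tau2 = 0.1, nPerArm = 12L,
                               seed = stageSeed(seed, "simulate_meta"))
    pooled <- poolDL(studyEffects(sim$studies))
    writeJsonSummary(list(smd = pooled@smd, ci_low = pooled@ciLow,
                          ci_high = pooled@ciHigh, tau2 = pooled@tau2,
                          Q = pooled@Q, I2 = pooled@I2),
                     file.path(outDir, "meta_pooled.json"))
    write.table(cbind(sim$studies, weight = pooled@weights),
                file.path(outDir, "meta_weights.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(studies = sim$studies, pooled = pooled, truth = sim$truth)
  })

  # modules as separate components (pOut = 0): pseudo-activation is
  # reachability, so the receptor's module is exactly its activated set
  simNet <- simulateNetwork(300L, moduleSizes = c(60L, 60L, 60L),
                            pIn = 0.3, pOut = 0,
                            seed = stageSeed(seed, "simulate_network"))
  writeEdgeList(simNet$network, file.path(outDir, "network.tsv"))

  if (onStage("propagate")) run_stage("propagate", function() {
    prop <- rwr(simNet$network, "RECEPTOR", restart = cfg$restart)
    act <- pseudoActivated(prop)
    write.table(data.frame(gene = names(affinity(prop)),
                           affinity = unname(affinity(prop))),
                file.path(outDir, "affinity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeGmt(act, file.path(outDir, "pseudo_activated.gmt"))
    modules <- detectModules(simNet$network)
    list(prop = prop, activated = act, modules = modules)
  })

  if (onStage("cytokines")) run_stage("cytokines", function() {
    cks <- sprintf("CK%02d", 1:20)
    sim <- simulateSignatureResponse(800L, cks,
                                     active = c(CK03 = 2, CK11 = -1.5),
                                     noiseSd = 1,
                                     seed = stageSeed(seed, "simulate_cyto"))
    fit <- fitActivity(sim$signatures, sim$response, lambda = cfg$lambda,
                       nPerm = cfg$nPerm,
                       seed = stageSeed(seed, "cytokines_perm"))
    tab <- activityTable(fit)
    write.table(tab[order(-abs(tab$perm_z)), ],
                file.path(outDir, "cytokine_activity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(fit = fit, truth = sim$truth)
  })

  if (onStage("ssgsea")) run_stage("ssgsea", function() {
    res <- runStiffnessSsgsea(.stiffness_demo_de(simDe$de),
                              nPerm = max(100L, cfg$nPerm),
                              alpha = cfg$alpha,
                              seed = stageSeed(seed, "ssgsea_perm"))
    out <- do.call(rbind, lapply(res, function(r)
      data.frame(condition = r@label, es_integral = r@esIntegral,
                 es_max_dev = r@esMaxDev, nes = r@nes, perm_p = r@permP,
                 leading_edge = paste(r@leadingEdge, collapse = ";"))))
    write.table(out, file.path(outDir, "ssgsea.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })

  if (onStage("enrich")) run_stage("enrich", function() {
    act <- if (!is.null(results$propagate)) results$propagate$activated
           else pseudoActivated(rwr(simNet$network, "RECEPTOR",
                                    restart = cfg$restart))
    truthMod <- names(simNet$truth@plantedModules)[
      simNet$truth@plantedModules == 1L]
    univ <- setdiff(networkNodes(simNet$network), "RECEPTOR")
    ct <- contingencyFromSets(intersect(geneIds(act), univ),
                              setdiff(truthMod, "RECEPTOR"), univ)
    fr <- fisherEnrichment(ct)
    writeJsonSummary(list(a = ct@a, b = ct@b, c = ct@c, d = ct@d,
                          odds_ratio = oddsRatio(fr), p = fr@p),
                     file.path(outDir, "enrichment.json"))
    list(contingency = ct, fisher = fr)
  })

  if (onStage("coexpr")) run_stage("coexpr", function() {
    sim <- simulateExprModules(c(60L, 60L), nSamples = 20L,
                               withinCor = 0.9, nBackground = 60L,
                               seed = stageSeed(seed, "simulate_expr"))
    res <- coexprModules(sim$se, minSize = cfg$minModuleSize,
                         deepSplit = cfg$deepSplit)
    mem <- moduleMembership(res$partition)
    write.table(data.frame(gene = names(mem), module = unname(mem)),
                file.path(outDir, "coexpr_modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeJsonSummary(list(power = res$softThreshold$power,
                          scale_free_r2 = res$softThreshold$scaleFreeR2,
                          n_genes_kept = res$nGenesKept),
                     file.path(outDir, "coexpr_beta.json"))
    c(res, list(truth = sim$truth))
  })

  if (onStage("cmap")) run_stage("cmap", function() {
    query <- GeneSet(.gene_universe(500L)[1:25], name = "query_up")
    sim <- simulatePerturbationLibrary(100L, 500L, query,
                                       plantReverser = TRUE,
                                       seed = stageSeed(seed, "simulate_pert"))
    screen <- cmapScreen(sim$library, query, sim$cellLines)
    write.table(screen, file.path(outDir, "cmap_screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    short <- shortlistReversers(screen, threshold = cfg$tauThreshold)
    writeJsonSummary(list(shortlist = as.list(short),
                          planted = sim$truth@reverserId),
                     file.path(outDir, "cmap_shortlist.json"))
    list(screen = screen, shortlist = short, truth = sim$truth)
  })

  writeJsonSummary(manifest, file.path(outDir, "manifest.json"))
  invisible(results)
}

# plant the stiffness genes into a copy of the DE table so the ssGSEA demo
# stage has its fixture genes present (aged conditions load them high)
.stiffness_demo_de <- function(de) {
  r <- deRecords(de)
  stiff <- geneIds(stiffnessGeneSet())
  extra <- do.call(rbind, lapply(unique(paste(r$contrast, r$timepoint)), function(k) {
    ct <- strsplit(k, " ")[[1L]]
    up <- ct[[1L]] == "aged" && ct[[2L]] %in% c("W1", "W2")
    data.frame(gene = stiff, contrast = ct[[1L]], timepoint = ct[[2L]],
               log2fc = if (up) seq(3, 2, length.out = length(stiff))
                        else seq(0.1, -0.1, length.out = length(stiff)),
               p = 0.5, fdr = 0.5, mean_expr = 50,
               stringsAsFactors = FALSE)
  }))
  r <- r[!r$gene %in% stiff, ]
  DETable(rbind(r, extra))
}
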