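## Accessor generics. Slot access from user code goes through these.

#' @rdname GeneSet-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneSet-class
#' @export
setGeneric("setName", function(object) standardGeneric("setName"))

#' @rdname DETable-class
#' @export
setGeneric("deRecords", function(object) standardGeneric("deRecords"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname PropagationResult-class
#' @export
setGeneric("affinity", function(object) standardGeneric("affinity"))

#' @rdname PropagationResult-class
#' @export
setGeneric("propagationSeeds", function(object) standardGeneric("propagationSeeds"))

#' @rdname PropagationResult-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname ModulePartition-class
#' @export
setGeneric("moduleMembership", function(object) standardGeneric("moduleMembership"))

#' @rdname ModulePartition-class
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname ActivityResult-class
#' @export
setGeneric("activityTable", function(object) standardGeneric("activityTable"))

#' @rdname SsgseaResult-class
#' @export
setGeneric("leadingEdge", function(object) standardGeneric("leadingEdge"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

## Methods -------------------------------------------------------------------

#' @rdname GeneSet-class
#' @export
setMethod("geneIds", "GeneSet", function(object) object@genes)

#' @rdname GeneSet-class
#' @export
setMethod("setName", "GeneSet", function(object) object@name)

#' @rdname GeneSet-class
#' @export
setMethod("length", "GeneSet", function(x) length(x@genes))

#' @rdname DETable-class
#' @export
setMethod("deRecords", "DETable", function(object) object@records)

#' @rdname WeightedNetwork-class
#' @export
setMethod("networkNodes", "WeightedNetwork", function(object) object@nodes)

#' @rdname WeightedNetwork-class
#' @export
setMethod("networkEdges", "WeightedNetwork", function(object) object@edges)

#' @rdname PropagationResult-class
#' @export
setMethod("affinity", "PropagationResult", function(object) object@affinity)

#' @rdname PropagationResult-class
#' @export
setMethod("propagationSeeds", "PropagationResult", function(object) object@seeds)

#' @rdname PropagationResult-class
#' @export
setMethod("isConverged", "PropagationResult", function(object) object@converged)

#' @rdname ModulePartition-class
#' @export
setMethod("moduleMembership", "ModulePartition", function(object) object@membership)

#' @rdname ModulePartition-class
#' @export
setMethod("moduleSizes", "ModulePartition", function(object) {
  m <- object@membership[object@membership > 0L]
  if (!length(m)) return(integer())
  tab <- table(m)
  setNames(as.integer(tab), names(tab))
})

#' @rdname ActivityResult-class
#' @export
setMethod("activityTable", "ActivityResult", function(object) object@table)

#' @rdname SsgseaResult-class
#' @export
setMethod("leadingEdge", "SsgseaResult", function(object) object@leadingEdge)

#' @rdname EnrichmentResult-class
#' @export
setMethod("oddsRatio", "EnrichmentResult", function(object) object@oddsRatio)

## show methods --------------------------------------------------------------

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet \"", object@name, "\" (", length(object@genes), " genes)\n",
      sep = "")
  if (length(object@genes))
    cat("  ", paste(head(object@genes, 8L), collapse = ", "),
        if (length(object@genes) > 8L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "DETable", function(object) {
  r <- object@records
  cat("DETable:", nrow(r), "records;",
      length(unique(r$gene)), "genes;",
      "contrasts:", paste(unique(r$contrast), collapse = "/"),
      "; timepoints:", paste(unique(r$timepoint), collapse = "/"), "\n")
})

setMethod("show", "WeightedNetwork", function(object) {
  cat("WeightedNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "PropagationResult", function(object) {
  cat("PropagationResult: seeds", paste(object@seeds, collapse = ","),
      "| restart", object@restart,
      "|", object@iterations, "iterations",
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  nonzero affinity on", sum(object@affinity > 0), "of",
      length(object@affinity), "nodes\n")
})

setMethod("show", "ModulePartition", function(object) {
  sz <- moduleSizes(object)
  cat("ModulePartition:", length(sz), "modules",
      sprintf("(sizes %s)", paste(sz, collapse = ",")),
      "|", sum(object@membership == 0L), "unassigned\n")
})

setMethod("show", "EffectSize", function(object) {
  cat(sprintf("EffectSize: %s = %.4f (var %.4f)\n",
              if (object@hedges) "Hedges g" else "Cohen d",
              object@d, object@variance))
})

setMethod("show", "PooledEffect", function(object) {
  cat(sprintf(
    "PooledEffect (DerSimonian-Laird): SMD %.4f [%.4f, %.4f]\n  tau2 %.4f, Q %.4f, I2 %.1f%%, k = %d\n",
    object@smd, object@ciLow, object@ciHigh, object@tau2, object@Q,
    object@I2, length(object@weights)))
})

setMethod("show", "ActivityResult", function(object) {
  t <- object@table[order(-abs(object@table$perm_z)), ]
  cat("ActivityResult \"", object@label, "\": ", nrow(object@table),
      " cytokines, lambda = ", format(object@lambda), ", ",
      object@nPerm, " permutations\n", sep = "")
  cat("  top |z|:", paste(head(t$cytokine, 5L), collapse = ", "), "\n")
})

setMethod("show", "SsgseaResult", function(object) {
  cat(sprintf(
    "SsgseaResult [%s in %s]: ES(integral) %.4f, ES(maxdev) %.4f, alpha %.2f\n",
    object@setName, object@label, object@esIntegral, object@esMaxDev,
    object@alpha))
  if (!is.na(object@permP))
    cat(sprintf("  NES %.4f, permutation p %.4g\n", object@nes, object@permP))
  cat("  leading edge:", paste(object@leadingEdge, collapse = ", "), "\n")
})

setMethod("show", "Contingency", function(object) {
  cat("Contingency 2x2 (a,b,c,d):", object@a, object@b, object@c, object@d,
      "| n =", object@a + object@b + object@c + object@d, "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult (%s): OR %.4g [%.4g, %.4g], p = %.4g\n",
              object@method, object@oddsRatio, object@ciLow, object@ciHigh,
              object@p))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: seed", object@seed, "\n")
  if (length(object@plantedAgeGenes))
    cat(" ", length(object@plantedAgeGenes), "planted age-response genes\n")
  if (length(object@plantedModules))
    cat(" ", length(unique(object@plantedModules[object@plantedModules > 0])),
        "planted modules\n")
  if (length(object@trueActivities))
    cat(" ", sum(object@trueActivities != 0), "active cytokines\n")
  if (length(object@reverserId) && nzchar(object@reverserId))
    cat("  planted reverser:", object@reverserId, "\n")
})
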