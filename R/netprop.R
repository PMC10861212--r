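## Random-walk-with-restart propagation on weighted gene networks,
## pseudo-activation calling, and community detection.

#' Convert a WeightedNetwork to an igraph object
#'
#' @param net a [WeightedNetwork-class].
#' @return an undirected weighted igraph graph over all network nodes
#'   (including isolated ones).
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                vertices = data.frame(name = networkNodes(net)))
}

#' Column-stochastic transition operator of a weighted network
#'
#' M[u, v] = w(u, v) / deg_w(v), the probability of stepping to u from v,
#' where deg_w(v) is v's weighted degree. Isolated nodes are made
#' self-absorbing (M[v, v] = 1) so every column sums to exactly 1.
#'
#' @param net a nonempty [WeightedNetwork-class].
#' @return a sparse column-stochastic [Matrix::Matrix] with node dimnames.
#' @export
buildTransition <- function(net) {
  nodes <- networkNodes(net)
  if (!length(nodes)) stop("empty network")
  e <- networkEdges(net)
  i <- c(match(e$from, nodes), match(e$to, nodes))
  j <- c(match(e$to, nodes), match(e$from, nodes))
  w <- c(e$weight, e$weight)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(A)
  iso <- which(deg == 0)
  if (length(iso)) {
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                  dims = dim(A), dimnames = dimnames(A))
    deg[iso] <- 1
  }
  M <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(M) <- list(nodes, nodes)
  M
}

#' Random walk with restart from seed genes
#'
#' Iterates p <- (1 - r) M p + r e until the L1 change falls below `tol`,
#' where M is the column-stochastic transition operator and e is uniform
#' over the seeds. The stationary vector is each node's affinity (visiting
#' probability) to the seeds; nodes with no path to any seed keep an exact
#' zero because the iteration never moves mass across components.
#'
#' @param net a [WeightedNetwork-class].
#' @param seeds a [GeneSet-class] or character vector of seed nodes.
#' @param restart restart probability r in (0, 1); default 0.7, the
#'   documented default of the multiplex-RWR package the field uses.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 10000).
#' @return A [PropagationResult-class].
#' @examples
#' net <- WeightedNetwork(data.frame(from = "A", to = "B", weight = 1))
#' affinity(rwr(net, "A"))
#' @export
rwr <- function(net, seeds, restart = 0.7, tol = 1e-10, maxIter = 10000L) {
  if (is(seeds, "GeneSet")) seeds <- geneIds(seeds)
  seeds <- normalizeSymbols(seeds)
  nodes <- networkNodes(net)
  missing <- setdiff(seeds, nodes)
  if (length(missing))
    stop("seed(s) not in network: ", paste(missing, collapse = ", "))
  if (restart <= 0 || restart >= 1) stop("restart must be in (0, 1)")
  M <- buildTransition(net)
  e <- setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  p <- e
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    pNew <- as.numeric((1 - restart) * (M %*% p)) + restart * e
    delta <- sum(abs(pNew - p))
    p <- pNew
    if (delta < tol) { converged <- TRUE; break }
  }
  names(p) <- nodes
  p <- p / sum(p)  # guard against accumulated rounding; analytic sum is 1
  new("PropagationResult", seeds = seeds, restart = restart, affinity = p,
      iterations = iter, converged = converged, tolerance = tol)
}

#' Pseudo-activated genes of a propagation
#'
#' Nodes with strictly positive affinity to the seed, minus an exclusion
#' set (e.g. genes already responding to injury in young animals, removed
#' to isolate the age-specific axis) and minus the seeds themselves by
#' default.
#'
#' @param prop a converged [PropagationResult-class].
#' @param exclude a [GeneSet-class] or character vector to remove.
#' @param dropSeeds drop the seed nodes from the result (default TRUE).
#' @param name name of the returned set.
#' @return A [GeneSet-class], sorted.
#' @export
pseudoActivated <- function(prop, exclude = character(), dropSeeds = TRUE,
                            name = "pseudo_activated") {
  if (!isConverged(prop))
    stop("propagation did not converge; increase maxIter or tol")
  if (is(exclude, "GeneSet")) exclude <- geneIds(exclude)
  a <- affinity(prop)
  hits <- names(a)[a > 0]
  hits <- setdiff(hits, normalizeSymbols(exclude))
  if (dropSeeds) hits <- setdiff(hits, propagationSeeds(prop))
  GeneSet(sort(hits), name = name,
          description = sprintf("affinity > 0 from %s (r=%g)",
                                paste(propagationSeeds(prop), collapse = "+"),
                                prop@restart))
}

#' Detect network modules by greedy modularity agglomeration
#'
#' Greedy weighted-modularity community detection (fast-greedy
#' agglomeration). Communities smaller than `minSize` are relabelled 0
#' (unassigned); the remaining modules are numbered 1, 2, ... by
#' decreasing size, ties broken by the lexicographically smallest member,
#' so the labelling is deterministic.
#'
#' @param net a nonempty [WeightedNetwork-class].
#' @param minSize minimum community size kept as a module (default 3).
#' @return A [ModulePartition-class] over all network nodes.
#' @export
detectModules <- function(net, minSize = 3L) {
  nodes <- networkNodes(net)
  if (!length(nodes)) stop("empty network")
  g <- asIgraph(net)
  fc <- igraph::cluster_fast_greedy(g,
                                    weights = igraph::E(g)$weight)
  mem <- igraph::membership(fc)
  mem <- setNames(as.integer(mem), names(mem))[nodes]
  mod <- igraph::modularity(g, membership = mem, weights = igraph::E(g)$weight)
  sizes <- table(mem)
  keep <- names(sizes)[as.integer(sizes) >= minSize]
  # deterministic relabelling: by decreasing size, tie-break lexicographic
  firstMember <- vapply(keep, function(k)
    min(names(mem)[mem == as.integer(k)]), character(1))
  ord <- keep[order(-as.integer(sizes[keep]), firstMember)]
  newLab <- setNames(seq_along(ord), ord)
  out <- integer(length(mem))
  names(out) <- names(mem)
  hit <- as.character(mem) %in% ord
  out[hit] <- newLab[as.character(mem)[hit]]
  new("ModulePartition", membership = out, modularity = mod)
}

#' Extract one module as a GeneSet
#'
#' @param partition a [ModulePartition-class].
#' @param moduleId module id (> 0).
#' @return A [GeneSet-class].
#' @export
moduleGeneSet <- function(partition, moduleId) {
  mem <- moduleMembership(partition)
  if (!moduleId %in% mem) stop("no module with id ", moduleId)
  GeneSet(sort(names(mem)[mem == moduleId]),
          name = sprintf("module_%d", moduleId))
}

#' Annotate a module against labelled gene sets
#'
#' Hypergeometric (one-sided Fisher) enrichment of the module's members in
#' each annotation set over the network's node universe; labels are ranked
#' by p-value (ties by descending overlap).
#'
#' @param partition a [ModulePartition-class].
#' @param moduleId module id to annotate.
#' @param annotationSets nonempty list of [GeneSet-class] objects.
#' @param universe character vector of universe genes (default: all
#'   partitioned nodes).
#' @return data.frame with columns label, overlap, setSize, p, ranked by p.
#' @export
annotateModule <- function(partition, moduleId, annotationSets,
                           universe = names(moduleMembership(partition))) {
  if (!length(annotationSets)) stop("annotationSets must be nonempty")
  mod <- geneIds(moduleGeneSet(partition, moduleId))
  universe <- normalizeSymbols(universe)
  mod <- intersect(mod, universe)
  rows <- lapply(annotationSets, function(s) {
    ann <- intersect(geneIds(s), universe)
    a <- length(intersect(mod, ann))
    # P(X >= a), X ~ Hypergeom(|ann|, |univ|-|ann|, |mod|)
    p <- phyper(a - 1L, length(ann), length(universe) - length(ann),
                length(mod), lower.tail = FALSE)
    data.frame(label = setName(s), overlap = a, setSize = length(ann),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$overlap, out$label), ]
  rownames(out) <- NULL
  out
}
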