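## Readers/writers for every on-disk artifact the pipeline touches.
## TSV everywhere; GMT (Broad dialect) is the only gene-set format.

#' Normalize gene symbols
#'
#' All symbols entering the package pass through this one function: trimmed
#' and uppercased, so mouse symbols and human orthologs collapse to one
#' identifier. An explicit orthology map (e.g. mouse -> human) may be
#' supplied; unmapped symbols fall back to the uppercase identity, an
#' approximation documented in the package vignette.
#'
#' @param x character vector of gene symbols.
#' @param orthology optional named character vector mapping input symbols to
#'   replacement symbols (case-insensitive on the input side).
#' @return character vector of normalized symbols.
#' @examples
#' normalizeSymbols(c("Bmp2", " chad "))
#' @export
normalizeSymbols <- function(x, orthology = NULL) {
  if (is.null(x)) return(character())
  x <- toupper(trimws(as.character(x)))
  if (!is.null(orthology)) {
    names(orthology) <- toupper(trimws(names(orthology)))
    hit <- x %in% names(orthology)
    x[hit] <- toupper(trimws(orthology[x[hit]]))
  }
  x
}

#' Read an orthology map (two-column TSV: from, to)
#'
#' @param path TSV file with a header and two columns.
#' @return named character vector usable as `orthology` in
#'   [normalizeSymbols()].
#' @export
readOrthology <- function(path) {
  t <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(t) < 2L) stop("orthology file needs two columns (from, to)")
  setNames(as.character(t[[2L]]), as.character(t[[1L]]))
}

#' Read gene sets from a GMT file
#'
#' One set per line: name TAB description TAB gene1 TAB gene2 ...
#' Symbols are case-normalized to uppercase; duplicates within one line are
#' removed with a warning.
#'
#' @param path GMT file path.
#' @return named list of [GeneSet-class] objects.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    GeneSet(f[-(1:2)], name = f[[1L]], description = f[[2L]])
  })
  names(sets) <- vapply(sets, setName, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [GeneSet-class] or list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(sets, path) {
  if (is(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s@name, s@description, s@genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted edge list (TSV: geneA, geneB, weight)
#'
#' Repeated unordered pairs keep the maximum weight; self-loops are dropped
#' with a warning; weights must lie in (0, 1].
#'
#' @param path TSV path with header columns geneA, geneB, weight (or
#'   from, to, weight).
#' @return A [WeightedNetwork-class].
#' @export
readEdgeList <- function(path) {
  t <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(t))
  cols <- c(match("genea", nm), match("geneb", nm), match("weight", nm))
  if (anyNA(cols)) {
    cols <- c(match("from", nm), match("to", nm), match("weight", nm))
    if (anyNA(cols))
      stop("edge list needs columns geneA, geneB, weight (or from, to, weight)")
  }
  w <- suppressWarnings(as.numeric(t[[cols[3L]]]))
  bad <- which(is.na(w) | w <= 0 | w > 1)
  if (length(bad))
    stop("edge weight outside (0, 1] at data row ", bad[[1L]])
  WeightedNetwork(data.frame(from = t[[cols[1L]]], to = t[[cols[2L]]],
                             weight = w, stringsAsFactors = FALSE))
}

#' Write a network as an edge-list TSV
#' @param net a [WeightedNetwork-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
  e <- networkEdges(net)
  out <- data.frame(geneA = e$from, geneB = e$to, weight = e$weight)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with header columns gene, contrast, timepoint, log2fc, p, fdr,
#' mean_expr.
#'
#' @param path TSV path.
#' @return A [DETable-class].
#' @export
readDeTable <- function(path) {
  t <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(.de_cols, names(t))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("log2fc", "p", "fdr", "mean_expr")) {
    v <- suppressWarnings(as.numeric(t[[col]]))
    bad <- which(is.na(v) & !is.na(t[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at data row ", bad[[1L]])
    t[[col]] <- v
  }
  DETable(t[, .de_cols])
}

#' Write a DETable (or any data.frame) as TSV
#' @param x a [DETable-class] or data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDeTable <- function(x, path) {
  if (is(x, "DETable")) x <- deRecords(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (first column gene, remaining columns samples)
#'
#' @param path TSV path.
#' @param groups named character vector sample -> group label; defaults to a
#'   single group "all".
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   "counts" and colData column "group".
#' @export
readExprMatrix <- function(path, groups = NULL) {
  t <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  genes <- normalizeSymbols(t[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene rows in ", path)
  m <- as.matrix(t[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  makeExprSE(m, groups)
}

#' Assemble the expression container used throughout the package
#'
#' @param counts numeric genes x samples matrix with rownames/colnames.
#' @param groups named character vector sample -> group, or a character
#'   vector in column order; defaults to one group.
#' @return a SummarizedExperiment with assay "counts" and colData "group".
#' @export
makeExprSE <- function(counts, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(counts), names(groups))
    if (length(miss))
      stop("samples without a group label: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(counts)]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(counts)))
}

#' Write an expression SummarizedExperiment as TSV
#' @param se SummarizedExperiment with assay "counts".
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExprMatrix <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "counts")
  out <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix (TSV; first column gene, remaining cytokines)
#' @param path TSV path.
#' @return A [SignatureMatrix-class].
#' @export
readSignatureMatrix <- function(path) {
  t <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  m <- as.matrix(t[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- t[[1L]]
  SignatureMatrix(m)
}

#' Write a signature matrix as TSV
#' @param sig a [SignatureMatrix-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSignatureMatrix <- function(sig, path) {
  out <- data.frame(gene = rownames(sig), sig@.Data, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a response profile (TSV: gene, log2fc)
#' @param path TSV path.
#' @param label condition label attached to the profile.
#' @return named numeric vector of log2 fold changes.
#' @export
readResponseProfile <- function(path, label = basename(path)) {
  t <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  v <- suppressWarnings(as.numeric(t[[2L]]))
  if (anyNA(v)) stop("non-numeric response value at data row ",
                     which(is.na(v))[[1L]])
  y <- setNames(v, normalizeSymbols(t[[1L]]))
  attr(y, "label") <- label
  y
}

#' Write a small named list or S4 summary as JSON
#' @param x list (or coercible) of scalar summaries.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeJsonSummary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
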