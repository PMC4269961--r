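#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

setOldClass("igraph")

#' Gene-by-tissue expression container
#'
#' `TissueExpression` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a single
#' non-negative assay named `"expr"`: rows are gene symbols, columns are
#' tissue names, values are expression on an arbitrary linear scale (raw
#' intensities or TPM-like). All scoring in this package applies
#' `log2(x + 1)` internally, so the unit convention never needs to be
#' declared. Specificity scoring requires at least two tissues; a
#' single-tissue matrix is loadable (with a warning at read time) so it can
#' still be inspected, but scoring functions reject it.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment-class].
#'
#' @seealso [readExpressionMatrix()], [tissueSpecificityZ()],
#'   [selectLocusOutliers()]
#' @export
setClass("TissueExpression",
         contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "expr"))
    msg <- c(msg, "assays must be exactly one assay named 'expr'")
  else {
    v <- SummarizedExperiment::assay(object, "expr")
    if (!is.numeric(v)) msg <- c(msg, "expression values must be numeric")
    else if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "expression values must be finite and non-missing")
    else if (any(v < 0)) msg <- c(msg, "expression values must be >= 0")
  }
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
    msg <- c(msg, "gene symbols must be nonempty and unique")
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msg <- c(msg, "tissue names must be nonempty and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueExpression object
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   tissues in columns (colnames = tissue names); all values `>= 0`.
#' @return A [TissueExpression-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("A", "B"), c("liver", "brain")))
#' TissueExpression(m)
#' @export
TissueExpression <- function(values) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values))
  new("TissueExpression", se)
}

#' @describeIn TissueExpression the expression matrix (linear scale).
#' @param x a `TissueExpression` object.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "TissueExpression"))
  SummarizedExperiment::assay(x, "expr")
}

#' Undirected protein-interaction network
#'
#' A simple undirected graph over gene symbols, wrapping an
#' [igraph::igraph] object. Self-loops and duplicate edges are rejected by
#' the validity method; the reader [readNetwork()] drops self-loops with a
#' logged count before construction.
#'
#' @slot graph an undirected simple `igraph` with named vertices.
#' @seealso [readNetwork()], [seedProximity()], [perturbationImpact()]
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "network must be undirected")
  if (igraph::any_loop(g)) msg <- c(msg, "self-loops are not allowed")
  if (igraph::any_multiple(g)) msg <- c(msg, "duplicate edges are not allowed")
  if (is.null(igraph::V(g)$name) ||
      anyDuplicated(igraph::V(g)$name))
    msg <- c(msg, "vertices must carry unique gene-symbol names")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param edges two-column character matrix or data frame of undirected
#'   edges (gene symbols). Self-loops are dropped with a message;
#'   duplicate edges (in either orientation) are collapsed.
#' @param nodes optional character vector of additional isolated nodes.
#' @return An [InteractionNetwork-class].
#' @examples
#' net <- InteractionNetwork(cbind(c("A", "B"), c("B", "C")))
#' networkGenes(net)
#' @export
InteractionNetwork <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edges must have exactly two columns")
    storage.mode(em) <- "character"
  }
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop edge(s)")
    em <- em[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(nodes)) {
    extra <- setdiff(as.character(nodes), igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra),
                                                 name = extra)
  }
  new("InteractionNetwork", graph = g)
}

#' @describeIn InteractionNetwork gene symbols of all nodes (sorted).
#' @param x an `InteractionNetwork`.
#' @export
networkGenes <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  sort(igraph::V(x@graph)$name)
}

#' @describeIn InteractionNetwork two-column character matrix of edges,
#'   each row sorted alphabetically, rows in lexicographic order.
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  em <- igraph::as_edgelist(x@graph, names = TRUE)
  if (nrow(em) == 0L)
    return(matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("geneA", "geneB"))))
  em <- t(apply(em, 1, sort))
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  dimnames(em) <- list(NULL, c("geneA", "geneB"))
  em
}

#' @describeIn InteractionNetwork the underlying `igraph` object.
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "InteractionNetwork"))
  x@graph
}

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat("InteractionNetwork with", igraph::vcount(g), "genes and",
      igraph::ecount(g), "interactions\n")
})

#' Named collection of pathway gene sets
#'
#' A pathway knowledgebase reduced to what the prioritization needs: a
#' mapping from unique pathway names to nonempty sets of gene symbols
#' (GMT semantics).
#'
#' @slot sets named list of character vectors.
#' @slot description named character vector, one free-text description per
#'   pathway (possibly empty strings).
#' @seealso [readGeneSetsGmt()], [pathwayOverlap()]
#' @export
setClass("PathwaySet",
         representation(sets = "list", description = "character"))

setValidity("PathwaySet", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "pathway names must be nonempty and unique")
    if (!all(vapply(object@sets, is.character, logical(1))) ||
        any(lengths(object@sets) == 0L))
      msg <- c(msg, "every pathway must be a nonempty character vector")
  }
  if (!identical(names(object@description), nm))
    msg <- c(msg, "descriptions must be named exactly like the sets")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwaySet
#'
#' @param sets named list of character vectors (gene symbols per pathway).
#' @param description optional character vector of per-pathway
#'   descriptions, recycled to `length(sets)`.
#' @return A [PathwaySet-class].
#' @examples
#' PathwaySet(list(P1 = c("A", "B"), P2 = c("B", "C")))
#' @export
PathwaySet <- function(sets = list(), description = NULL) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(description)) description <- rep("", length(sets))
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  new("PathwaySet", sets = sets, description = description)
}

#' @describeIn PathwaySet pathway names.
#' @param x a `PathwaySet`.
#' @export
pathwayNames <- function(x) {
  stopifnot(is(x, "PathwaySet"))
  names(x@sets)
}

#' @describeIn PathwaySet the gene sets as a named list.
#' @export
pathwayGenes <- function(x) {
  stopifnot(is(x, "PathwaySet"))
  x@sets
}

setMethod("show", "PathwaySet", function(object) {
  cat("PathwaySet with", length(object@sets), "pathways;",
      length(unique(unlist(object@sets))), "distinct genes\n")
})

setMethod("length", "PathwaySet", function(x) length(x@sets))
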