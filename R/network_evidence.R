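## Network and pathway evidence for candidate ranking: interactome
## proximity to phenotype seed genes, pathway co-membership, and pathway
## perturbation simulated as node removal with seed-connectivity impact.

#' Interactome proximity to phenotype seed genes
#'
#' Degree-normalized direct-neighbour seed count:
#' `|N(g) \\ intersect seeds\\{g}| / sqrt(deg(g))`. Zero for a gene with no
#' edges or absent from the network (absence is logged, not an error).
#' The square-root damping penalizes promiscuous hubs. A seed gene never
#' counts itself.
#'
#' @param network an [InteractionNetwork-class].
#' @param gene candidate gene symbol.
#' @param seeds nonempty character vector of phenotype seed symbols.
#' @return A single numeric `>= 0`.
#' @examples
#' net <- InteractionNetwork(cbind("HUB", c("S1", "S2", "S3")))
#' seedProximity(net, "HUB", c("S1", "S2", "S3"))  # 3 / sqrt(3)
#' @export
seedProximity <- function(network, gene, seeds) {
  stopifnot(is(network, "InteractionNetwork"))
  if (!length(seeds)) stop("seed set must be nonempty")
  g <- network@graph
  if (!gene %in% igraph::V(g)$name) {
    message("gene '", gene, "' not in network; proximity 0")
    return(0)
  }
  nb <- igraph::neighbors(g, gene)$name
  if (!length(nb)) return(0)
  hits <- length(intersect(nb, setdiff(seeds, gene)))
  hits / sqrt(length(nb))
}

#' Pathway co-membership with seed genes
#'
#' Fraction of the pathways containing the gene that also contain at
#' least one seed other than the gene itself; 0 when the gene belongs to
#' no pathway.
#'
#' @param pathways a [PathwaySet-class].
#' @param gene candidate gene symbol.
#' @param seeds character vector of seed symbols.
#' @return Numeric in `[0, 1]`.
#' @export
pathwayOverlap <- function(pathways, gene, seeds) {
  stopifnot(is(pathways, "PathwaySet"))
  sets <- pathwayGenes(pathways)
  mine <- vapply(sets, function(s) gene %in% s, TRUE)
  if (!any(mine)) return(0)
  s2 <- setdiff(seeds, gene)
  withSeed <- vapply(sets[mine], function(s) any(s2 %in% s), TRUE)
  mean(withSeed)
}

## seeds contained in the seed-dominant connected component
seedLcc <- function(graph, seeds) {
  seeds <- intersect(seeds, igraph::V(graph)$name)
  if (!length(seeds)) return(0L)
  comp <- igraph::components(graph)$membership
  max(table(comp[seeds]))
}

#' Simulated pathway perturbation by node removal
#'
#' Models the deletion/disruption of a set of genes as the removal of
#' their nodes (and incident edges) from the interactome, and measures the
#' impact on the phenotype subnetwork: `impact = 1 - L_after / L_before`,
#' where `L` is the number of seed genes held together in the
#' seed-dominant connected component (the component containing the most
#' seeds). Removed seeds leave the graph like any other node. Returns 0
#' when no seed is in the network to begin with.
#'
#' The seed-dominant count makes the impact lie in `[0, 1]` and increase
#' monotonically as the removed set grows, which a node-count-largest
#' definition would not guarantee.
#'
#' @param network an [InteractionNetwork-class].
#' @param seeds character vector of phenotype seed symbols.
#' @param removed character vector of genes to delete.
#' @return Numeric in `[0, 1]`.
#' @examples
#' path <- InteractionNetwork(cbind(c("s1", "g"), c("g", "s2")))
#' perturbationImpact(path, c("s1", "s2"), "g")  # 0.5
#' @export
perturbationImpact <- function(network, seeds, removed) {
  stopifnot(is(network, "InteractionNetwork"))
  g <- network@graph
  before <- seedLcc(g, seeds)
  if (before == 0L) return(0)
  keep <- setdiff(igraph::V(g)$name, removed)
  after <- seedLcc(igraph::induced_subgraph(g, keep), seeds)
  1 - after / before
}

#' Extend the candidate set beyond the imbalance
#'
#' Prioritized genes point outward: genes within network distance
#' `maxDistance` of any prioritized gene, or sharing at least one pathway
#' with one, are returned (excluding the prioritized set itself) for a
#' second evaluation pass by the same scoring operations. This is how
#' genes outside a chromosome imbalance enter the analysis.
#'
#' @param network an [InteractionNetwork-class].
#' @param pathways a [PathwaySet-class].
#' @param prioritized nonempty character vector of prioritized symbols.
#' @param maxDistance network radius (default 1 = direct neighbours).
#' @return Sorted character vector of new candidate symbols.
#' @export
extendedCandidates <- function(network, pathways, prioritized,
                               maxDistance = 1L) {
  stopifnot(is(network, "InteractionNetwork"),
            is(pathways, "PathwaySet"))
  if (!length(prioritized)) stop("prioritized set must be nonempty")
  g <- network@graph
  inNet <- intersect(prioritized, igraph::V(g)$name)
  nbrs <- character()
  if (length(inNet) && maxDistance >= 1L) {
    ego <- igraph::ego(g, order = maxDistance, nodes = inNet)
    nbrs <- unique(unlist(lapply(ego, function(v) v$name)))
  }
  sets <- pathwayGenes(pathways)
  shared <- unique(unlist(sets[vapply(sets, function(s)
    any(prioritized %in% s), TRUE)]))
  sort(setdiff(union(nbrs, shared), prioritized))
}

#' Score all network/pathway evidence for a candidate list
#'
#' Convenience wrapper computing [seedProximity()], [pathwayOverlap()]
#' and single-gene [perturbationImpact()] for each candidate. Candidates
#' absent from the network are flagged unscorable in the result
#' (`inNetwork = FALSE`); their numeric evidence is `NA` so that rank
#' fusion can assign them the worst rank rather than a spurious zero tie.
#'
#' @param network an [InteractionNetwork-class].
#' @param pathways a [PathwaySet-class].
#' @param candidates character vector of candidate symbols.
#' @param seeds nonempty character vector of seed symbols.
#' @return Data frame: `gene`, `proximity`, `pathwayOverlap`,
#'   `perturbationImpact`, `inNetwork`, `inPathways`.
#' @export
scoreNetworkEvidence <- function(network, pathways, candidates, seeds) {
  stopifnot(is(network, "InteractionNetwork"),
            is(pathways, "PathwaySet"))
  if (!length(seeds)) stop("seed set must be nonempty")
  candidates <- as.character(candidates)
  nodes <- igraph::V(network@graph)$name
  allPw <- unique(unlist(pathwayGenes(pathways)))
  inNetwork <- candidates %in% nodes
  inPathways <- candidates %in% allPw
  ## removing a node that is neither a seed nor an articulation point
  ## cannot change the seed component count, so its impact is 0
  arts <- igraph::articulation_points(network@graph)$name
  mayPerturb <- union(arts, seeds)
  prox <- imp <- pov <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    gene <- candidates[i]
    if (inNetwork[i]) {
      prox[i] <- seedProximity(network, gene, seeds)
      imp[i] <- if (gene %in% mayPerturb)
        perturbationImpact(network, seeds, gene) else 0
    } else {
      prox[i] <- NA_real_; imp[i] <- NA_real_
    }
    pov[i] <- if (inPathways[i]) pathwayOverlap(pathways, gene, seeds)
              else NA_real_
  }
  nOut <- sum(!inNetwork)
  if (nOut)
    message(nOut, " candidate(s) absent from network (unscorable there)")
  data.frame(gene = candidates, proximity = prox, pathwayOverlap = pov,
             perturbationImpact = imp, inNetwork = inNetwork,
             inPathways = inPathways, stringsAsFactors = FALSE)
}
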