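#' Fast-unfolding (Louvain) community detection on a PDN
#'
#' Partitions the OER-weighted network by multi-level greedy modularity
#' maximization (the fast-unfolding algorithm), returning the
#' highest-level (coarsest) partition, which carries the highest modularity
#' score among the algorithm's clustering layers. Tie-breaking inside the
#' algorithm is randomized, so a seed is required and recorded; results are
#' reproducible for a fixed seed.
#'
#' @param pdn a \linkS4class{PDN}; edge weights (OER) are used.
#' @param resolution resolution parameter (1 = classical modularity).
#' @param seed integer seed controlling tie-breaks.
#' @return a \linkS4class{CommunityPartition}.
#' @export
louvainCommunities <- function(pdn, resolution = 1.0, seed) {
  if (missing(seed) || is.null(seed))
    stop("louvainCommunities: a seed is required (tie-breaking is randomized)")
  g <- pdnGraph(pdn)
  if (igraph::vcount(g) == 0) stop("louvainCommunities: empty graph")
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution))
  memb <- setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
  q <- pdnModularity(pdn, memb)
  new("CommunityPartition", membership = memb, modularity = q,
      resolution = resolution, seed = as.integer(seed))
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ W_c/W - (S_c / 2W)^2 ]` with `W` the total edge weight,
#' `W_c` the weight inside community `c` and `S_c` the summed strength of
#' its nodes. Computed on the PDN's OER weights.
#'
#' @param pdn a \linkS4class{PDN}.
#' @param membership named (by node code) vector of community labels
#'   covering every node, or a \linkS4class{CommunityPartition}.
#' @return numeric Q in [-0.5, 1]; 0 for an edgeless graph.
#' @export
pdnModularity <- function(pdn, membership) {
  if (is(membership, "CommunityPartition"))
    membership <- communityMembership(membership)
  g <- pdnGraph(pdn)
  nm <- igraph::V(g)$name
  if (is.null(names(membership)))
    stop("pdnModularity: membership must be named by node code")
  if (!all(nm %in% names(membership)))
    stop("pdnModularity: membership does not cover all nodes")
  memb <- as.integer(factor(membership[nm]))
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, memb, weights = igraph::E(g)$weight)
}

#' Membership table of a partition
#'
#' @param pdn the \linkS4class{PDN} that was partitioned.
#' @param partition a \linkS4class{CommunityPartition}.
#' @return data.frame `code`, `chapter`, `community`.
#' @export
communityTable <- function(pdn, partition) {
  memb <- communityMembership(partition)
  nodes <- pdnNodes(pdn)
  data.frame(code = nodes$code, chapter = nodes$chapter,
             community = unname(memb[nodes$code]),
             stringsAsFactors = FALSE)
}
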