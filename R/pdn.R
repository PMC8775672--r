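#' Joint and marginal condition counts for an arm
#'
#' Exact counts from patient code sets: `C[i, j]` is the number of patients
#' carrying both codes (diagonal: marginal counts `C_i`), over `N` patients.
#'
#' @param profiles \linkS4class{PatientProfiles} restricted to the arm.
#' @param codes comorbidity list defining the node set.
#' @return list of class `pair_counts`: `C` (symmetric integer matrix with
#'   marginals on the diagonal), `N`, `codes`.
#' @export
pairCounts <- function(profiles, codes) {
  if (length(codes) == 0) stop("pairCounts: empty code list")
  inc <- incidenceMatrix(profiles)
  missing_codes <- setdiff(codes, colnames(inc))
  X <- inc[, intersect(codes, colnames(inc)), drop = FALSE] * 1
  C <- as.matrix(Matrix::crossprod(X))
  if (length(missing_codes)) {
    C <- rbind(cbind(C, matrix(0, nrow(C), length(missing_codes))),
               matrix(0, length(missing_codes), ncol(C) + length(missing_codes)))
    dimnames(C) <- list(c(colnames(X), missing_codes),
                        c(colnames(X), missing_codes))
  }
  C <- C[codes, codes, drop = FALSE]
  structure(list(C = C, N = nPatients(profiles), codes = codes),
            class = "pair_counts")
}

#' Observed-to-expected ratio of a disease pair
#'
#' `OER = C_ij * N / (C_i * C_j)`: the ratio of the observed co-occurrence
#' prevalence to that expected under independence of the two marginal
#' prevalences. Values above 1 indicate co-occurrence beyond chance;
#' below 1, mutual exclusivity.
#'
#' @param c_ij joint count. @param c_i,c_j marginal counts. @param n arm size.
#' @return numeric OER (vectorized).
#' @export
oer <- function(c_ij, c_i, c_j, n) {
  if (any(c_i <= 0) || any(c_j <= 0) || any(n <= 0))
    stop("oer: marginal counts and N must be positive")
  (c_ij * n) / (c_i * c_j)
}

#' Confidence interval for an OER
#'
#' Log-normal interval `exp(ln OER +/- z * sigma)`. The default sigma is the
#' Katz-style standard error for a ratio of an observed count to its
#' independence expectation, `sqrt(1/C_ij - 1/N + 1/E - 1/N)` with
#' `E = C_i*C_j/N`; `sigma = "poisson"` uses the simpler `1/sqrt(C_ij)`
#' approximation. With `C_ij = 0` no finite log interval exists and NA
#' bounds are returned (such a pair can never be a significant edge).
#'
#' @param c_ij,c_i,c_j,n counts as in [oer()] (vectorized).
#' @param level confidence level (default 0.99, the edge gate).
#' @param sigma "katz" (default) or "poisson".
#' @return data.frame `oer`, `ci_low`, `ci_high`.
#' @export
oerCI <- function(c_ij, c_i, c_j, n, level = 0.99,
                  sigma = c("katz", "poisson")) {
  sigma <- match.arg(sigma)
  est <- oer(c_ij, c_i, c_j, n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  e <- c_i * c_j / n
  s <- if (sigma == "katz") {
    sqrt(pmax(0, 1 / c_ij - 1 / n + 1 / e - 1 / n))
  } else 1 / sqrt(c_ij)
  lo <- exp(log(est) - z * s)
  hi <- exp(log(est) + z * s)
  zero <- c_ij == 0
  lo[zero] <- NA_real_; hi[zero] <- NA_real_
  data.frame(oer = est, ci_low = lo, ci_high = hi)
}

#' Build a phenotypic disease network
#'
#' Evaluates every unordered pair of listed comorbidities and keeps as edges
#' the pairs whose OER exceeds 1 with confidence-interval lower bound above
#' 1 at `level` (default 99%). Edge weight is the OER. Nodes are the full
#' comorbidity list - codes without any significant edge remain as isolates
#' - annotated with prevalence and ICD-10 chapter letter. Pairs with a zero
#' marginal are not evaluable and appear in `pairStats` with NA statistics.
#'
#' @param counts a `pair_counts` object from [pairCounts()].
#' @param level edge-gate confidence level (default 0.99).
#' @param sigma OER standard-error method, see [oerCI()].
#' @param arm label stored on the network ("case", "control", ...).
#' @return a \linkS4class{PDN}.
#' @export
buildPDN <- function(counts, level = 0.99, sigma = c("katz", "poisson"),
                     arm = "arm") {
  sigma <- match.arg(sigma)
  C <- counts$C; N <- counts$N; codes <- counts$codes
  marg <- diag(C)
  p <- length(codes)
  if (p >= 2) {
    ut <- which(upper.tri(C), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
    evaluable <- marg[i] > 0 & marg[j] > 0
    stats <- data.frame(oer = rep(NA_real_, nrow(ut)),
                        ci_low = NA_real_, ci_high = NA_real_)
    if (any(evaluable))
      stats[evaluable, ] <- oerCI(C[ut][evaluable], marg[i[evaluable]],
                                  marg[j[evaluable]], N, level, sigma)
    ps <- data.frame(
      code_i = codes[i], code_j = codes[j],
      c_ij = C[ut],
      oer = stats$oer, ci_low = stats$ci_low, ci_high = stats$ci_high,
      significant = !is.na(stats$ci_low) & stats$oer > 1 & stats$ci_low > 1,
      stringsAsFactors = FALSE
    )
  } else {
    ps <- data.frame(code_i = character(), code_j = character(),
                     c_ij = integer(), oer = numeric(), ci_low = numeric(),
                     ci_high = numeric(), significant = logical())
  }
  nodes <- data.frame(code = codes, chapter = substr(codes, 1, 1),
                      count = as.integer(marg), prevalence = marg / N,
                      stringsAsFactors = FALSE)
  ed <- ps[ps$significant, c("code_i", "code_j", "oer"), drop = FALSE]
  names(ed)[3] <- "weight"
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = nodes)
  new("PDN", graph = g, nodes = nodes, pairStats = ps,
      N = as.integer(N), arm = arm, ciLevel = level)
}

#' Network metrics of a PDN
#'
#' The five structural metrics used for comorbidity networks:
#' \describe{
#'   \item{degree}{per node, the number of direct disease connections;
#'     `avg_degree = 2|E|/|V|`.}
#'   \item{closeness}{per node, normalized closeness over unweighted hop
#'     distances, computed within the node's connected component and scaled
#'     by the component's share of the graph
#'     (`(n_c-1)/sum(d) * (n_c-1)/(|V|-1)`); isolates get 0.}
#'   \item{average neighbor degree}{mean degree of a node's neighbors;
#'     isolates get 0.}
#'   \item{diameter}{maximum weighted shortest-path distance over the
#'     largest connected component, with edge length `1/OER` (stronger
#'     comorbidity = shorter distance); 0 for a singleton component.}
#'   \item{density}{`2|E| / (|V|(|V|-1))`, isolates included in `|V|`.}
#' }
#'
#' @param pdn a \linkS4class{PDN}.
#' @return list `node_metrics` (data.frame code, degree, closeness,
#'   avg_neighbor_degree), `avg_degree`, `avg_closeness`,
#'   `avg_neighbor_degree`, `diameter`, `density`, `n_nodes`, `n_edges`.
#' @export
pdnMetrics <- function(pdn) {
  list(node_metrics = data.frame(code = pdnNodes(pdn)$code,
                                 degree = degreeCentrality(pdn),
                                 closeness = closenessCentrality(pdn),
                                 avg_neighbor_degree = avgNeighborDegree(pdn),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       avg_degree = avgDegree(pdn),
       avg_closeness = mean(closenessCentrality(pdn)),
       avg_neighbor_degree = mean(avgNeighborDegree(pdn)),
       diameter = weightedDiameter(pdn),
       density = networkDensity(pdn),
       n_nodes = igraph::vcount(pdnGraph(pdn)),
       n_edges = igraph::ecount(pdnGraph(pdn)))
}

#' @rdname pdnMetrics
#' @export
degreeCentrality <- function(pdn) {
  g <- pdnGraph(pdn)
  setNames(as.integer(igraph::degree(g)), igraph::V(g)$name)
}

#' Average degree from node and edge counts
#'
#' `2*E/V`; also the per-network summary of [degreeCentrality()].
#' @param n_nodes,n_edges graph size, or pass a PDN to [avgDegree()].
#' @export
averageDegree <- function(n_nodes, n_edges) {
  if (n_nodes == 0) return(0)
  2 * n_edges / n_nodes
}

#' @rdname pdnMetrics
#' @export
avgDegree <- function(pdn) {
  g <- pdnGraph(pdn)
  averageDegree(igraph::vcount(g), igraph::ecount(g))
}

#' @rdname pdnMetrics
#' @export
closenessCentrality <- function(pdn) {
  g <- pdnGraph(pdn)
  nv <- igraph::vcount(g)
  out <- setNames(numeric(nv), igraph::V(g)$name)
  if (nv <= 1) return(out)
  d <- igraph::distances(g, weights = NA)    # unweighted hops
  comp <- igraph::components(g)$membership
  for (v in seq_len(nv)) {
    same <- which(comp == comp[v])
    nc <- length(same)
    if (nc > 1) {
      tot <- sum(d[v, same])
      out[v] <- (nc - 1) / tot * (nc - 1) / (nv - 1)
    }
  }
  out
}

#' @rdname pdnMetrics
#' @export
avgNeighborDegree <- function(pdn) {
  g <- pdnGraph(pdn)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  s <- as.numeric(A %*% deg)
  out <- ifelse(deg > 0, s / deg, 0)
  setNames(out, igraph::V(g)$name)
}

#' @rdname pdnMetrics
#' @export
weightedDiameter <- function(pdn) {
  g <- pdnGraph(pdn)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) <= 1) return(0)
  d <- igraph::distances(sub, weights = 1 / igraph::E(sub)$weight)
  max(d)
}

#' @rdname pdnMetrics
#' @export
networkDensity <- function(pdn) {
  g <- pdnGraph(pdn)
  nv <- igraph::vcount(g)
  if (nv < 2) return(0)
  2 * igraph::ecount(g) / (nv * (nv - 1))
}

#' Retain only the strongest edges (P90 filter)
#'
#' Keeps edges whose OER strictly exceeds the 90th percentile (linear
#' interpolation) of this network's edge OERs - the filter used to focus a
#' dense comorbidity network on its strongest associations for display.
#' Nodes are all retained.
#'
#' @param pdn a \linkS4class{PDN}. @param probs percentile (default 0.9).
#' @return list `pdn` (filtered \linkS4class{PDN}) and `threshold`.
#' @export
p90EdgeFilter <- function(pdn, probs = 0.9) {
  g <- pdnGraph(pdn)
  w <- igraph::E(g)$weight
  if (length(w) == 0) return(list(pdn = pdn, threshold = NA_real_))
  thr <- unname(stats::quantile(w, probs, type = 7))
  keep <- w > thr
  g2 <- igraph::subgraph_from_edges(g, igraph::E(g)[keep],
                                    delete.vertices = FALSE)
  ps <- pairStats(pdn)
  ps$significant <- ps$significant & !is.na(ps$oer) & ps$oer > thr
  out <- new("PDN", graph = g2, nodes = pdnNodes(pdn), pairStats = ps,
             N = pdn@N, arm = pdn@arm, ciLevel = pdn@ciLevel)
  list(pdn = out, threshold = thr)
}

#' Write a PDN to GraphML and its edge table to TSV
#'
#' @param pdn a \linkS4class{PDN}.
#' @param graphml_path,edges_path output paths (NULL to skip either).
#' @export
writePdn <- function(pdn, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    g <- pdnGraph(pdn)
    igraph::V(g)$prevalence <- pdnNodes(pdn)$prevalence
    igraph::V(g)$chapter <- pdnNodes(pdn)$chapter
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path))
    data.table::fwrite(pairStats(pdn), edges_path, sep = "\t")
  invisible(pdn)
}
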