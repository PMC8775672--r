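# fixtures and independent oracles used across test files

# minimal canonical HDR file: rows = list of character vectors of dx codes,
# covariates recycled
write_hdr_fixture <- function(rows, path = tempfile(fileext = ".csv"),
                              sex = "male", birth_year = 1950,
                              discharge = "2017-06-01", level = "tertiary",
                              patient_id = NULL, died = 0L, n_dx = 16L) {
  n <- length(rows)
  if (is.null(patient_id)) patient_id <- sprintf("P%03d", seq_len(n))
  dx <- matrix("", n, n_dx, dimnames = list(NULL, paste0("dx", seq_len(n_dx))))
  for (i in seq_len(n)) dx[i, seq_along(rows[[i]])] <- rows[[i]]
  discharge <- rep_len(as.Date(discharge), n)
  df <- data.frame(patient_id = patient_id,
                   sex = rep_len(sex, n),
                   birth_year = rep_len(birth_year, n),
                   age = as.integer(format(discharge, "%Y")) -
                     rep_len(birth_year, n),
                   admission_date = as.character(discharge - 3),
                   discharge_date = as.character(discharge),
                   hospital_level = rep_len(level, n),
                   died = rep_len(died, n),
                   stringsAsFactors = FALSE)
  utils::write.csv(cbind(df, dx), path, row.names = FALSE, quote = FALSE)
  path
}

# PatientProfiles straight from a logical incidence matrix (bypassing files)
profiles_from_matrix <- function(inc, sex = "male", birth_year = 1950,
                                 age = 67, level = "tertiary",
                                 discharge = as.Date("2017-06-01"),
                                 died = FALSE) {
  n <- nrow(inc)
  ids <- rownames(inc)
  if (is.null(ids)) {
    ids <- sprintf("P%03d", seq_len(n))
    rownames(inc) <- ids
  }
  cov <- data.frame(patient_id = ids, sex = rep_len(sex, n),
                    birth_year = rep_len(birth_year, n),
                    age = rep_len(age, n),
                    age_group = comorbnet::ageGroup(rep_len(age, n)),
                    discharge_date = rep_len(discharge, n),
                    hospital_level = rep_len(level, n),
                    died = rep_len(died, n), stringsAsFactors = FALSE)
  new("PatientProfiles",
      incidence = methods::as(inc, "CsparseMatrix"),
      covariates = cov,
      chronicCodes = colnames(inc))
}

# PDN directly from an edge list (for metric/community tests); uniform or
# per-edge weights, all > 1 to satisfy the class invariant
pdn_from_edges <- function(edges, nodes = NULL, weight = 2, arm = "test",
                           N = 1000L) {
  ed <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(ed)[1:2] <- c("code_i", "code_j")
  if (!"weight" %in% names(ed)) ed$weight <- rep_len(weight, nrow(ed))
  if (is.null(nodes)) nodes <- sort(unique(c(ed$code_i, ed$code_j)))
  nd <- data.frame(code = nodes, chapter = substr(nodes, 1, 1),
                   count = 0L, prevalence = 0, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
  ps <- data.frame(code_i = ed$code_i, code_j = ed$code_j, c_ij = NA_integer_,
                   oer = ed$weight, ci_low = ed$weight, ci_high = ed$weight,
                   significant = TRUE, stringsAsFactors = FALSE)
  new("PDN", graph = g, nodes = nd, pairStats = ps, N = N, arm = arm,
      ciLevel = 0.99)
}

# --- independent oracles ------------------------------------------------

# joint/marginal counts by explicit double loop over patients and pairs
pair_counts_bruteforce <- function(inc, codes) {
  C <- matrix(0L, length(codes), length(codes), dimnames = list(codes, codes))
  for (p in seq_len(nrow(inc))) {
    for (a in seq_along(codes)) {
      if (!inc[p, codes[a]]) next
      C[a, a] <- C[a, a] + 1L
      for (b in seq_along(codes)) {
        if (b > a && inc[p, codes[b]]) {
          C[a, b] <- C[a, b] + 1L
          C[b, a] <- C[b, a] + 1L
        }
      }
    }
  }
  C
}

# hop distances by hand-rolled breadth-first search on an adjacency matrix
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(is.infinite(dist) & colSums(A[frontier, , drop = FALSE]) > 0)
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# all-pairs shortest weighted paths by exhaustive simple-path enumeration
# (viable only for tiny graphs)
exhaustive_shortest_paths <- function(edges) {
  nodes <- sort(unique(c(edges$code_i, edges$code_j)))
  len <- matrix(Inf, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  diag(len) <- 0
  wt <- function(a, b) {
    hit <- (edges$code_i == a & edges$code_j == b) |
           (edges$code_i == b & edges$code_j == a)
    if (any(hit)) edges$length[hit][1] else Inf
  }
  recurse <- function(path, total, target) {
    last <- path[length(path)]
    if (last == target) return(total)
    best <- Inf
    for (nb in nodes[!(nodes %in% path)]) {
      w <- wt(last, nb)
      if (is.finite(w)) best <- min(best, recurse(c(path, nb), total + w,
                                                  target))
    }
    best
  }
  for (a in nodes) for (b in nodes) if (a < b) {
    v <- recurse(a, 0, b)
    len[a, b] <- v; len[b, a] <- v
  }
  len
}

# weighted Newman-Girvan modularity straight from the formula
modularity_formula <- function(edges, membership) {
  W <- sum(edges$weight)
  nodes <- names(membership)
  strength <- sapply(nodes, function(v)
    sum(edges$weight[edges$code_i == v | edges$code_j == v]))
  q <- 0
  for (cm in unique(membership)) {
    inside <- names(membership)[membership == cm]
    Wc <- sum(edges$weight[edges$code_i %in% inside &
                           edges$code_j %in% inside])
    Sc <- sum(strength[inside])
    q <- q + Wc / W - (Sc / (2 * W))^2
  }
  q
}

# adjusted Rand index between a partition and planted block labels
planted_ari <- function(partition, truth) {
  planted <- truth$block_id[!is.na(truth$block_id)]
  memb <- communityMembership(partition)
  mclust::adjustedRandIndex(memb[names(planted)], planted)
}

# empirical OER of a code pair in an incidence matrix
empirical_oer <- function(inc, a, b) {
  ca <- sum(inc[, a]); cb <- sum(inc[, b]); cab <- sum(inc[, a] & inc[, b])
  cab * nrow(inc) / (ca * cb)
}
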