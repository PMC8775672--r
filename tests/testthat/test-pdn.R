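test_that("pair counts match a brute-force double loop", {
  # trivial cases
  inc <- matrix(FALSE, 2, 2, dimnames = list(NULL, c("A01", "B01")))
  inc[, ] <- TRUE
  pc <- pairCounts(profiles_from_matrix(inc), c("A01", "B01"))
  expect_equal(unname(pc$C["A01", "B01"]), 2)
  expect_equal(unname(diag(pc$C)), c(2, 2))

  inc2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                 dimnames = list(NULL, c("A01", "B01")))
  pc2 <- pairCounts(profiles_from_matrix(inc2), c("A01", "B01"))
  expect_equal(unname(pc2$C["A01", "B01"]), 0)

  # random 50-patient fixture vs oracle
  set.seed(8)
  codes <- sprintf("C%02d", 1:8)
  inc3 <- matrix(runif(50 * 8) < 0.3, 50, 8, dimnames = list(NULL, codes))
  pc3 <- pairCounts(profiles_from_matrix(inc3), codes)
  expect_equal(pc3$C, pair_counts_bruteforce(inc3, codes),
               ignore_attr = FALSE)
  expect_equal(pc3$N, 50)
  # joint counts never exceed marginals
  expect_true(all(pc3$C <= pmin(outer(diag(pc3$C), rep(1, 8)),
                                outer(rep(1, 8), diag(pc3$C)))))
})

test_that("OER is C_ij N / (C_i C_j)", {
  expect_equal(oer(5, 10, 20, 100), 2.5)
  expect_equal(oer(2, 10, 20, 100), 1)        # exact independence
  expect_error(oer(0, 0, 5, 100), "positive")
})

test_that("OER intervals collapse with N and widen at tiny counts", {
  # large counts: CI hugs the estimate
  big <- oerCI(2e5, 1e6, 1e6, 1e7)
  expect_equal(big$oer, 2)
  expect_lt(big$ci_high - big$ci_low, 0.05)
  # C_ij = 1: interval spans more than an order of magnitude
  small <- oerCI(1, 50, 50, 5000)
  expect_gt(small$ci_high / small$ci_low, 10)
  # C_ij = 0: no finite log interval
  zero <- oerCI(0, 50, 50, 5000)
  expect_true(is.na(zero$ci_low))
  # Poisson fallback is selectable and wider at equal inputs
  k <- oerCI(30, 300, 300, 10000, sigma = "katz")
  p <- oerCI(30, 300, 300, 10000, sigma = "poisson")
  expect_equal(k$oer, p$oer)
  expect_true(k$ci_low != p$ci_low)
})

test_that("false-edge rate under independence stays below the 99% gate", {
  set.seed(55)
  reps <- 60; sig <- 0; tot <- 0
  for (r in seq_len(reps)) {
    inc <- sapply(runif(30, 0.02, 0.3), function(q) runif(10000) < q)
    colnames(inc) <- syntheticCodePool(30)
    pdn <- buildPDN(pairCounts(profiles_from_matrix(inc), colnames(inc)))
    sig <- sig + sum(pairStats(pdn)$significant)
    tot <- tot + nrow(pairStats(pdn))
  }
  mc_se <- sqrt(0.01 * 0.99 / tot)
  expect_lte(sig / tot, 0.01 + 3 * mc_se)
})

test_that("planted associations become edges; weak-count pairs are gated", {
  cfg <- synthConfig(
    n_patients = 50000, case_fraction = 0,
    prevalence = setNames(rep(0.08, 10), syntheticCodePool(10)),
    blocks = list(list(codes = syntheticCodePool(10)[1:5], oer = 3)),
    seed = 13)
  sim <- simulateProfiles(cfg)
  pdn <- buildPDN(pairCounts(sim$profiles, names(cfg$prevalence)))
  e <- pdnEdges(pdn)
  key <- paste(e$code_i, e$code_j)
  blk <- cfg$blocks[[1]]$codes
  within <- combn(sort(blk), 2)
  expect_true(all(paste(within[1, ], within[2, ]) %in% key))  # all 10 edges
  # significance gate: C_ij = 1 with huge OER is still excluded
  ps <- oerCI(1, 10, 10, 500)
  expect_gt(ps$oer, 1)
  expect_false(!is.na(ps$ci_low) && ps$ci_low > 1)
})

test_that("node-level metrics match hand values and matrix/BFS oracles", {
  # degree on K5
  k5 <- t(combn(sprintf("N%02d", 1:5), 2))
  pdn5 <- pdn_from_edges(k5)
  expect_true(all(degreeCentrality(pdn5) == 4))
  expect_equal(avgDegree(pdn5), 4)
  expect_equal(networkDensity(pdn5), 1)

  # closeness on a path A-B-C
  path3 <- pdn_from_edges(rbind(c("A01", "B01"), c("B01", "C01")))
  cl <- closenessCentrality(path3)
  expect_equal(unname(cl["B01"]), 1)
  expect_equal(unname(cl["A01"]), 2 / 3)

  # star K1,3: neighbor-degree center 1, leaves 3
  star <- pdn_from_edges(rbind(c("H00", "L01"), c("H00", "L02"),
                               c("H00", "L03")))
  nd <- avgNeighborDegree(star)
  expect_equal(unname(nd["H00"]), 1)
  expect_equal(unname(nd[c("L01", "L02", "L03")]), c(3, 3, 3))

  # random graph vs oracles
  set.seed(4)
  nodes <- sprintf("R%02d", 1:30)
  all_pairs <- t(combn(nodes, 2))
  pick <- runif(nrow(all_pairs)) < 0.12
  pdnr <- pdn_from_edges(all_pairs[pick, , drop = FALSE], nodes = nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(pdnGraph(pdnr)))
  expect_equal(unname(degreeCentrality(pdnr)), unname(rowSums(A)))
  nd_oracle <- ifelse(rowSums(A) > 0, (A %*% rowSums(A)) / rowSums(A), 0)
  expect_equal(unname(avgNeighborDegree(pdnr)), as.vector(nd_oracle))
  # closeness vs hand-rolled BFS with component scaling
  D <- bfs_distances(A)
  nv <- nrow(A)
  cl_oracle <- sapply(seq_len(nv), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(nv) != v)
    if (!length(reach)) return(0)
    nc <- length(reach) + 1
    (nc - 1) / sum(D[v, reach]) * (nc - 1) / (nv - 1)
  })
  expect_equal(unname(closenessCentrality(pdnr)), cl_oracle)
})

test_that("weighted diameter uses 1/OER lengths (exhaustive oracle)", {
  # single edge, OER 2 -> diameter 0.5
  one <- pdn_from_edges(data.frame(code_i = "A01", code_j = "B01",
                                   weight = 2))
  expect_equal(weightedDiameter(one), 0.5)
  # triangle with OER just above 1: direct hop is always shortest
  eps <- 1e-6
  tri <- pdn_from_edges(data.frame(
    code_i = c("A01", "B01", "A01"), code_j = c("B01", "C01", "C01"),
    weight = 1 + eps))
  expect_equal(weightedDiameter(tri), 1 / (1 + eps), tolerance = 1e-9)
  # random weighted graph on 7 nodes vs exhaustive path enumeration
  set.seed(9)
  nodes <- sprintf("D%02d", 1:7)
  ap <- t(combn(nodes, 2))
  pick <- runif(nrow(ap)) < 0.45
  ed <- data.frame(code_i = ap[pick, 1], code_j = ap[pick, 2],
                   weight = runif(sum(pick), 1.1, 6))
  pdnw <- pdn_from_edges(ed, nodes = nodes)
  ed$length <- 1 / ed$weight
  L <- exhaustive_shortest_paths(ed)
  comp <- igraph::components(pdnGraph(pdnw))
  big <- names(which(comp$membership == which.max(comp$csize)))
  expect_equal(weightedDiameter(pdnw),
               max(L[big, big][is.finite(L[big, big])]))
})

test_that("avg degree and density identities hold on arbitrary graphs", {
  set.seed(2)
  nodes <- sprintf("E%02d", 1:20)
  ap <- t(combn(nodes, 2))
  pdnr <- pdn_from_edges(ap[runif(nrow(ap)) < 0.3, , drop = FALSE],
                         nodes = nodes)
  g <- pdnGraph(pdnr)
  expect_equal(avgDegree(pdnr),
               2 * igraph::ecount(g) / igraph::vcount(g))
  expect_equal(networkDensity(pdnr) * (igraph::vcount(g) - 1),
               avgDegree(pdnr))
  expect_equal(averageDegree(71, 1941), 2 * 1941 / 71)
})

test_that("edge sets are invariant to patient order and code relabeling", {
  set.seed(77)
  codes <- sprintf("F%02d", 1:12)
  inc <- matrix(runif(3000 * 12) < 0.2, 3000, 12,
                dimnames = list(sprintf("P%04d", 1:3000), codes))
  inc[, 1] <- inc[, 1] | inc[, 2]   # induce an association
  e1 <- pdnEdges(buildPDN(pairCounts(profiles_from_matrix(inc), codes)))
  perm <- sample(nrow(inc))
  e2 <- pdnEdges(buildPDN(pairCounts(profiles_from_matrix(inc[perm, ]),
                                     codes)))
  expect_equal(e1, e2)
  # relabel codes (reverse order)
  inc3 <- inc[, rev(codes)]
  e3 <- pdnEdges(buildPDN(pairCounts(profiles_from_matrix(inc3),
                                     rev(codes))))
  key <- function(e) sort(paste(pmin(e$code_i, e$code_j),
                                pmax(e$code_i, e$code_j)))
  expect_equal(key(e1), key(e3))
})

test_that("the P90 filter keeps strictly-above-percentile edges", {
  ed <- data.frame(code_i = sprintf("A%02d", 1:10),
                   code_j = sprintf("B%02d", 1:10),
                   weight = 1:10 + 0.5)   # OERs 1.5 .. 10.5
  pdn <- pdn_from_edges(ed)
  f <- p90EdgeFilter(pdn)
  expect_equal(f$threshold, unname(quantile(ed$weight, 0.9)))  # 9.6
  expect_equal(igraph::ecount(pdnGraph(f$pdn)), 1)
  expect_equal(igraph::vcount(pdnGraph(f$pdn)),
               igraph::vcount(pdnGraph(pdn)))   # nodes retained
  # degenerate ties: all equal OERs leave nothing above the percentile
  tied <- pdn_from_edges(within(ed, weight <- 3))
  expect_equal(igraph::ecount(pdnGraph(p90EdgeFilter(tied)$pdn)), 0)
})

test_that("planted OERs are recovered with small relative bias", {
  codes <- syntheticCodePool(8)
  targets <- c(1.5, 2, 3, 5)
  blocks <- lapply(seq_along(targets), function(k)
    list(codes = codes[c(2 * k - 1, 2 * k)], oer = targets[k]))
  est <- matrix(NA_real_, 8, length(targets))
  for (s in 1:8) {
    cfg <- synthConfig(n_patients = 50000, case_fraction = 0,
                       prevalence = setNames(rep(0.05, 8), codes),
                       blocks = blocks, seed = 1000 + s)
    sim <- simulateProfiles(cfg)
    inc <- as.matrix(incidenceMatrix(sim$profiles))[, codes]
    est[s, ] <- sapply(seq_along(targets), function(k)
      empirical_oer(inc, codes[2 * k - 1], codes[2 * k]))
  }
  bias <- abs(colMeans(est) - targets) / targets
  expect_true(all(bias < 0.05))
})
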