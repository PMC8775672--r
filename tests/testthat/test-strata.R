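strata_profiles <- function(n = 6000, seed = 3) {
  codes <- syntheticCodePool(12)
  set.seed(seed)
  inc <- sapply(rep(0.15, 12), function(q) runif(n) < q)
  colnames(inc) <- codes
  sex <- sample(c("male", "female"), n, TRUE)
  # plant a male-only association between codes 1-2 and 3-4
  male <- sex == "male"
  inc[male, 2] <- inc[male, 1] | inc[male, 2]
  inc[male, 4] <- inc[male, 3] | inc[male, 4]
  prof <- profiles_from_matrix(inc)
  cov <- covariates(prof)
  cov$sex <- sex
  cov$age <- sample(c(40, 65, 75, 85), n, TRUE)
  cov$age_group <- ageGroup(cov$age)
  new("PatientProfiles", incidence = incidenceMatrix(prof),
      covariates = cov, chronicCodes = codes)
}

test_that("stratification splits by sex/age and skips empty strata", {
  prof <- strata_profiles()
  nets <- stratifyAndBuild(prof, "sex")
  expect_setequal(names(nets), c("male", "female"))
  expect_s4_class(nets$male, "PDN")

  # all-male input: female stratum skipped with a warning
  cov <- covariates(prof)
  male_only <- prof[cov$sex == "male", ]
  expect_warning(nets_m <- stratifyAndBuild(male_only, "sex"), "female")
  expect_equal(names(nets_m), "male")

  nets_age <- stratifyAndBuild(prof, "age")
  expect_setequal(names(nets_age), c("35-59", "60-69", "70-79", "80+"))
})

test_that("age 59 and 60 land in adjacent strata", {
  prof <- strata_profiles(n = 400)
  cov <- covariates(prof)
  cov$age <- rep(c(59, 60), 200)
  cov$age_group <- ageGroup(cov$age)
  prof2 <- new("PatientProfiles", incidence = incidenceMatrix(prof),
               covariates = cov, chronicCodes = prof@chronicCodes)
  nets <- suppressWarnings(stratifyAndBuild(prof2, "age"))
  expect_setequal(names(nets), c("35-59", "60-69"))
  expect_equal(nets$`35-59`@N, 200L)
  expect_equal(nets$`60-69`@N, 200L)
})

test_that("planted density differences order the per-stratum edge counts", {
  prof <- strata_profiles(n = 20000)
  nets <- stratifyAndBuild(prof, "sex")
  # the male arm carries the planted associations
  expect_gt(igraph::ecount(pdnGraph(nets$male)),
            igraph::ecount(pdnGraph(nets$female)))
})

test_that("metric comparisons: identical, shifted, and multi-stratum inputs", {
  set.seed(14)
  nodes <- sprintf("K%02d", 1:15)
  ap <- t(combn(nodes, 2))
  base <- ap[runif(nrow(ap)) < 0.3, , drop = FALSE]
  pdn_a <- pdn_from_edges(base, nodes = nodes, arm = "a")

  # identical networks: t = 0, p = 1
  cmp0 <- compareMetrics(list(a = pdn_a, b = pdn_a))
  expect_true(all(cmp0$statistic == 0))
  expect_true(all(cmp0$p_value == 1))

  # uniformly denser second network: paired t detects the shift
  extra <- ap[!(paste(ap[, 1], ap[, 2]) %in% paste(base[, 1], base[, 2])), ]
  pdn_b <- pdn_from_edges(rbind(base, extra), nodes = nodes, arm = "b")
  cmp1 <- compareMetrics(list(a = pdn_a, b = pdn_b))
  deg <- cmp1[cmp1$metric == "degree", ]
  expect_lt(deg$p_value, 0.001)
  expect_lt(deg$mean_a, deg$mean_b)

  # four identical strata: ANOVA F ~ 0
  cmp4 <- compareMetrics(list(a = pdn_a, b = pdn_a, c = pdn_a, d = pdn_a))
  expect_true(all(abs(cmp4$statistic) < 1e-10))
  expect_equal(unique(cmp4$test), "one-way ANOVA")

  # too few common nodes: NA, not an error
  tiny <- pdn_from_edges(rbind(c("X01", "X02")), nodes = c("X01", "X02"))
  cmp_na <- compareMetrics(list(a = pdn_a, b = tiny))
  expect_true(all(is.na(cmp_na$p_value)))
})

test_that("dominance pairs: arithmetic, direction, disjointness, monotonicity", {
  ed_m <- data.frame(code_i = c("E11", "I10", "K29"),
                     code_j = c("I10", "K29", "N18"),
                     weight = c(3.0, 2.0, 2.0))
  ed_f <- data.frame(code_i = c("E11", "I10", "K29"),
                     code_j = c("I10", "K29", "N18"),
                     weight = c(2.0, 2.0, 3.0))
  pdn_m <- pdn_from_edges(ed_m, arm = "male")
  pdn_f <- pdn_from_edges(ed_f, arm = "female")
  dp <- dominancePairs(pdn_m, pdn_f)
  # E11-I10 male-dominated at 1.5; I10-K29 ratio 1 dropped; K29-N18 female
  expect_equal(nrow(dp), 2)
  male_row <- dp[dp$code_i == "E11", ]
  expect_equal(male_row$dominant, "male")
  expect_equal(male_row$ratio, 1.5)
  expect_setequal(dp$dominant, c("male", "female"))
  # directions are disjoint by construction
  expect_false(any(duplicated(paste(dp$code_i, dp$code_j))))
  # raising the threshold never yields more pairs
  n_by_thr <- sapply(c(1.2, 1.4, 1.6, 2), function(t)
    nrow(dominancePairs(pdn_m, pdn_f, t)))
  expect_true(all(diff(n_by_thr) <= 0))
  # same-chapter pairs can be excluded or kept
  ed_m2 <- rbind(ed_m, data.frame(code_i = "I50", code_j = "I48", weight = 4))
  ed_f2 <- rbind(ed_f, data.frame(code_i = "I50", code_j = "I48", weight = 2))
  dp2 <- dominancePairs(pdn_from_edges(ed_m2, arm = "male"),
                        pdn_from_edges(ed_f2, arm = "female"))
  expect_false(any(dp2$code_i == "I48" | dp2$code_i == "I50"))
  dp3 <- dominancePairs(pdn_from_edges(ed_m2, arm = "male"),
                        pdn_from_edges(ed_f2, arm = "female"),
                        cross_chapter_only = FALSE)
  expect_true(any(dp3$code_i == "I48"))
})

test_that("planted sex-boosted pairs are exactly the dominant ones", {
  # pair (1,2): association in both sexes, stronger in males (dominant);
  # pair (3,4): equally strong in both sexes (ratio 1, never emitted)
  set.seed(19)
  n <- 20000
  codes <- syntheticCodePool(12)
  inc <- sapply(rep(0.15, 12), function(q) runif(n) < q)
  colnames(inc) <- codes
  sex <- rep(c("male", "female"), n / 2)
  male <- sex == "male"
  inc[male, 2] <- inc[male, 2] | inc[male, 1]
  inc[!male, 2] <- inc[!male, 2] | (inc[!male, 1] & runif(sum(!male)) < 0.4)
  inc[, 4] <- inc[, 4] | inc[, 3]
  prof <- profiles_from_matrix(inc)
  cov <- covariates(prof)
  cov$sex <- sex
  prof <- new("PatientProfiles", incidence = incidenceMatrix(prof),
              covariates = cov, chronicCodes = codes)
  nets <- stratifyAndBuild(prof, "sex")
  dp <- dominancePairs(nets$male, nets$female, cross_chapter_only = FALSE)
  found <- paste(dp$code_i, dp$code_j)
  expect_equal(found[dp$dominant == "male"],
               paste(pmin(codes[1], codes[2]), pmax(codes[1], codes[2])))
  expect_false(paste(pmin(codes[3], codes[4]), pmax(codes[3], codes[4]))
               %in% found)
})

test_that("stratified prevalence aggregates to the pooled prevalence", {
  prof <- strata_profiles(n = 5000)
  cov <- covariates(prof)
  inc <- incidenceMatrix(prof)
  pooled <- Matrix::colSums(inc) / nrow(inc)
  agg <- rep(0, ncol(inc))
  for (s in c("male", "female")) {
    idx <- cov$sex == s
    agg <- agg + Matrix::colSums(inc[idx, , drop = FALSE]) / nrow(inc)
  }
  expect_equal(unname(agg), unname(pooled))
})
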