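make_cohort_profiles <- function(df, codes = c("I21", "E11")) {
  n <- nrow(df)
  inc <- matrix(FALSE, n, length(codes), dimnames = list(df$patient_id, codes))
  inc[df$is_case, "I21"] <- TRUE
  cov <- data.frame(patient_id = df$patient_id, sex = df$sex,
                    birth_year = df$birth_year, age = df$age,
                    age_group = ageGroup(df$age),
                    discharge_date = df$discharge_date,
                    hospital_level = df$hospital_level,
                    died = df$died, stringsAsFactors = FALSE)
  new("PatientProfiles", incidence = methods::as(inc, "CsparseMatrix"),
      covariates = cov, chronicCodes = codes)
}

base_row <- function(id, is_case = FALSE, sex = "male", birth_year = 1950,
                     age = 67, discharge = as.Date("2017-06-01"),
                     level = "tertiary", died = FALSE) {
  data.frame(patient_id = id, is_case = is_case, sex = sex,
             birth_year = birth_year, age = age, discharge_date = discharge,
             hospital_level = level, died = died, stringsAsFactors = FALSE)
}

test_that("case definition applies code range, age floor and survival", {
  df <- rbind(base_row("young", TRUE, age = 34),
              base_row("boundary", TRUE, age = 35),
              base_row("ok", TRUE, age = 40),
              base_row("dead", TRUE, died = TRUE),
              base_row("noihd", FALSE))
  prof <- make_cohort_profiles(df)
  expect_setequal(identifyCases(prof), c("boundary", "ok"))
  expect_setequal(identifyCases(prof, require_survival = FALSE),
                  c("boundary", "ok", "dead"))
  expect_error(identifyCases(prof[0, ]), "empty")
})

test_that("an identical pool member is always matched; sex mismatch never", {
  df <- rbind(base_row("case1", TRUE), base_row("ctrl1", FALSE))
  coh <- matchControls(make_cohort_profiles(df), "case1",
                       matchCriteria(seed = 1))
  expect_equal(nrow(matchedPairs(coh)), 1)
  expect_length(unmatchedCases(coh), 0)

  df2 <- rbind(base_row("case1", TRUE, sex = "male"),
               base_row("ctrl1", FALSE, sex = "female"))
  coh2 <- matchControls(make_cohort_profiles(df2), "case1",
                        matchCriteria(seed = 1))
  expect_equal(nrow(matchedPairs(coh2)), 0)
  expect_equal(unmatchedCases(coh2), "case1")
  expect_equal(unname(coh2@audit["sex"]), 1L)
})

test_that("two cases sharing one eligible control yield exactly one pair", {
  df <- rbind(base_row("caseA", TRUE), base_row("caseB", TRUE),
              base_row("ctrl", FALSE))
  prof <- make_cohort_profiles(df)
  for (s in 1:10) {   # both shuffle orders occur across seeds
    coh <- matchControls(prof, c("caseA", "caseB"), matchCriteria(seed = s))
    expect_equal(nrow(matchedPairs(coh)), 1)
    expect_length(unmatchedCases(coh), 1)
  }
})

test_that("every emitted pair satisfies all criteria; controls are unique", {
  set.seed(33)
  n <- 600
  df <- base_row(sprintf("P%03d", 1:n))
  df$is_case <- runif(n) < 0.4
  df$sex <- sample(c("male", "female"), n, TRUE)
  df$birth_year <- sample(1940:1960, n, TRUE)
  df$discharge_date <- as.Date("2017-01-01") + sample(0:365, n, TRUE)
  df$hospital_level <- sample(c("secondary", "tertiary"), n, TRUE)
  prof <- make_cohort_profiles(df)
  cases <- identifyCases(prof)
  crit <- matchCriteria(2, 30, seed = 5)
  coh <- matchControls(prof, cases, crit)
  p <- matchedPairs(coh)
  expect_gt(nrow(p), 0)
  expect_false(anyDuplicated(p$control_id) > 0)
  expect_true(all(abs(p$birth_year_case - p$birth_year_control) <= 2))
  expect_true(all(abs(as.numeric(p$discharge_date_case -
                                 p$discharge_date_control)) <= 30))
  rownames(df) <- df$patient_id
  expect_true(all(df[p$case_id, "sex"] == df[p$control_id, "sex"]))
  expect_true(all(df[p$case_id, "hospital_level"] ==
                  df[p$control_id, "hospital_level"]))
  # no matched control carries an index code
  expect_false(any(p$control_id %in% cases))

  # determinism under a fixed seed
  coh2 <- matchControls(prof, cases, crit)
  expect_identical(matchedPairs(coh2), p)

  # match rate never increases as tolerances tighten
  rates <- sapply(list(c(5, 60), c(2, 30), c(1, 7), c(0, 0)), function(tl) {
    nrow(matchedPairs(matchControls(prof, cases,
      matchCriteria(tl[1], tl[2], seed = 5))))
  })
  expect_true(all(diff(rates) <= 0))
})

test_that("planted case rate lands in the binomial 99% interval", {
  cfg <- synthConfig(n_patients = 5000, n_diseases = 10, case_fraction = 0.1,
                     underage_fraction = 0, death_rate = 0, seed = 77)
  sim <- simulateProfiles(cfg)
  cases <- identifyCases(sim$profiles)
  expect_gte(length(cases), qbinom(0.005, 5000, 0.1))
  expect_lte(length(cases), qbinom(0.995, 5000, 0.1))
  # and the labels agree with the generator's ground truth
  expect_setequal(cases, sim$case_ids)
})

test_that("cohort summaries recount arms and inherit the case sex ratio", {
  cfg <- synthConfig(n_patients = 4000, n_diseases = 10, case_fraction = 0.3,
                     underage_fraction = 0, death_rate = 0, seed = 21)
  sim <- simulateProfiles(cfg)
  cases <- identifyCases(sim$profiles)
  coh <- matchControls(sim$profiles, cases, matchCriteria(2, 30, seed = 4))
  s <- cohortSummary(coh, sim$profiles)
  expect_equal(s$n_case, nrow(matchedPairs(coh)))
  expect_equal(s$n_control, s$n_case)
  expect_equal(s$match_rate,
               s$n_case / (s$n_case + length(unmatchedCases(coh))))
  # exact sex matching forces identical arm sex ratios
  expect_equal(s$sex_ratio_case, s$sex_ratio_control)

  empty <- matchControls(sim$profiles, character(0),
                         matchCriteria(seed = 1))
  se <- suppressWarnings(cohortSummary(empty, sim$profiles))
  expect_equal(se$n_case, 0)
})
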