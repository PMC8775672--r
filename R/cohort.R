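#' Matching criteria for 1:1 control selection
#'
#' Controls are matched to index cases on year of birth (within a
#' tolerance), sex, discharge date (within a tolerance in days) and hospital
#' level. The canonical design matches birth year to +/- 2 years and sex and
#' hospital level exactly; the discharge-date window defaults to the same
#' calendar date and is widened (e.g. to +/- 30 days) for small cohorts
#' where exact-day matching is infeasible.
#'
#' @param birth_year_tolerance integer years (default 2).
#' @param discharge_date_tolerance integer days (default 0 = same date).
#' @param exact_on character, criteria matched exactly
#'   (subset of "sex", "hospital_level"; both by default).
#' @param seed integer seed controlling case order shuffling and control
#'   draws; required because matching is randomized.
#' @return list of class `match_criteria`.
#' @export
matchCriteria <- function(birth_year_tolerance = 2L,
                          discharge_date_tolerance = 0L,
                          exact_on = c("sex", "hospital_level"),
                          seed = NULL) {
  stopifnot(birth_year_tolerance >= 0, discharge_date_tolerance >= 0)
  exact_on <- match.arg(exact_on, c("sex", "hospital_level"),
                        several.ok = TRUE)
  structure(list(birth_year_tolerance = as.integer(birth_year_tolerance),
                 discharge_date_tolerance = as.integer(discharge_date_tolerance),
                 exact_on = exact_on, seed = seed),
            class = "match_criteria")
}

#' Identify index cases
#'
#' A case is a patient with at least one diagnosis in the index code range
#' (default I20-I25, ischemic heart disease), aged at or above `min_age`
#' (default 35) at their first record, and - when `require_survival` is TRUE
#' - with no death recorded on any hospitalization.
#'
#' @param profiles a \linkS4class{PatientProfiles} object.
#' @param code_range character of length 2, inclusive 3-character code
#'   interval defining the index condition.
#' @param min_age minimum age in years.
#' @param require_survival drop patients with a death record.
#' @return character vector of case patient ids.
#' @export
identifyCases <- function(profiles, code_range = c("I20", "I25"),
                          min_age = 35L, require_survival = TRUE) {
  if (nPatients(profiles) == 0) stop("identifyCases: empty profile set")
  codes <- conditionCodes(profiles)
  idx <- codes >= code_range[1] & codes <= code_range[2]
  has_index <- if (any(idx))
    Matrix::rowSums(incidenceMatrix(profiles)[, idx, drop = FALSE]) > 0
  else rep(FALSE, nPatients(profiles))
  cov <- covariates(profiles)
  keep <- has_index & !is.na(cov$age) & cov$age >= min_age
  if (require_survival) keep <- keep & !cov$died
  cov$patient_id[keep]
}

#' Index-condition codes carried by any patient
#'
#' Convenience: which patients carry any code in the index range (used to
#' exclude them from the control pool regardless of age/survival).
#' @param profiles PatientProfiles. @param code_range inclusive code interval.
#' @return logical vector along patients.
#' @keywords internal
.hasIndexCode <- function(profiles, code_range = c("I20", "I25")) {
  codes <- conditionCodes(profiles)
  idx <- codes >= code_range[1] & codes <= code_range[2]
  if (!any(idx)) return(rep(FALSE, nPatients(profiles)))
  Matrix::rowSums(incidenceMatrix(profiles)[, idx, drop = FALSE]) > 0
}

#' Select 1:1 matched controls
#'
#' Greedy randomized matching without replacement: cases are shuffled under
#' the criteria's seed and, for each case in turn, one control is drawn
#' uniformly at random from the pool members still available that satisfy
#' every criterion (birth year within tolerance, discharge date within
#' tolerance, exact sex and hospital level). Cases with no remaining
#' eligible control are reported as unmatched. The procedure is
#' deterministic for a fixed seed.
#'
#' @param profiles a \linkS4class{PatientProfiles} covering cases and pool.
#' @param case_ids character vector of case patient ids (see
#'   [identifyCases()]).
#' @param criteria a [matchCriteria()] object; its `seed` must be set.
#' @param index_code_range controls carrying any code in this range are
#'   excluded from the pool (index-condition-free controls).
#' @return a \linkS4class{MatchedCohort}.
#' @export
matchControls <- function(profiles, case_ids,
                          criteria = matchCriteria(),
                          index_code_range = c("I20", "I25")) {
  if (is.null(criteria$seed))
    stop("matchControls: criteria$seed must be set (matching is randomized)")
  cov <- covariates(profiles)
  is_case <- cov$patient_id %in% case_ids
  pool_ok <- !is_case & !.hasIndexCode(profiles, index_code_range)

  key <- rep("", nrow(cov))
  if ("sex" %in% criteria$exact_on)
    key <- paste(key, cov$sex, sep = "|")
  if ("hospital_level" %in% criteria$exact_on)
    key <- paste(key, cov$hospital_level, sep = "|")

  pool_idx <- which(pool_ok)
  pool_groups <- split(pool_idx, key[pool_idx])
  available <- rep(TRUE, nrow(cov))
  by <- cov$birth_year
  dd <- as.numeric(cov$discharge_date)
  tol_by <- criteria$birth_year_tolerance
  tol_dd <- criteria$discharge_date_tolerance

  case_idx <- which(is_case)
  pairs_case <- integer(0); pairs_ctrl <- integer(0); unmatched <- integer(0)

  withr::with_seed(criteria$seed, {
    case_idx <- sample(case_idx)
    for (ci in case_idx) {
      cand <- pool_groups[[key[ci]]]
      if (!is.null(cand)) {
        elig <- cand[available[cand] &
                     abs(by[cand] - by[ci]) <= tol_by &
                     abs(dd[cand] - dd[ci]) <= tol_dd]
      } else elig <- integer(0)
      if (length(elig) == 0) {
        unmatched <- c(unmatched, ci)
      } else {
        pick <- if (length(elig) == 1) elig else sample(elig, 1L)
        available[pick] <- FALSE
        pairs_case <- c(pairs_case, ci)
        pairs_ctrl <- c(pairs_ctrl, pick)
      }
    }
  })

  # audit: which single criterion, if dropped, would have rescued the case
  audit <- c(birth_year = 0L, discharge_date = 0L, sex = 0L,
             hospital_level = 0L)
  for (ci in unmatched) {
    free <- pool_idx[available[pool_idx]]
    m_by  <- abs(by[free] - by[ci]) <= tol_by
    m_dd  <- abs(dd[free] - dd[ci]) <= tol_dd
    m_sex <- !("sex" %in% criteria$exact_on) | cov$sex[free] == cov$sex[ci]
    m_lvl <- !("hospital_level" %in% criteria$exact_on) |
             cov$hospital_level[free] == cov$hospital_level[ci]
    if (any(m_dd & m_sex & m_lvl)) audit["birth_year"] <- audit["birth_year"] + 1L
    if (any(m_by & m_sex & m_lvl)) audit["discharge_date"] <- audit["discharge_date"] + 1L
    if (any(m_by & m_dd & m_lvl)) audit["sex"] <- audit["sex"] + 1L
    if (any(m_by & m_dd & m_sex)) audit["hospital_level"] <- audit["hospital_level"] + 1L
  }

  pairs <- data.frame(
    case_id    = cov$patient_id[pairs_case],
    control_id = cov$patient_id[pairs_ctrl],
    sex        = cov$sex[pairs_case],
    hospital_level = cov$hospital_level[pairs_case],
    birth_year_case    = cov$birth_year[pairs_case],
    birth_year_control = cov$birth_year[pairs_ctrl],
    discharge_date_case    = cov$discharge_date[pairs_case],
    discharge_date_control = cov$discharge_date[pairs_ctrl],
    stringsAsFactors = FALSE
  )
  new("MatchedCohort", pairs = pairs,
      unmatched = cov$patient_id[unmatched],
      criteria = unclass(criteria), audit = audit)
}

#' Summarize a matched cohort
#'
#' Per-arm n, sex composition, age-group distribution (in the fixed 35-59 /
#' 60-69 / 70-79 / 80+ bins) and the match rate.
#'
#' @param cohort a \linkS4class{MatchedCohort}.
#' @param profiles the \linkS4class{PatientProfiles} the cohort was built
#'   from (for age groups).
#' @return list with `n_case`, `n_control`, `match_rate`,
#'   `sex_ratio_case`, `sex_ratio_control` (proportion female), and
#'   `age_distribution` (table by arm and age group).
#' @export
cohortSummary <- function(cohort, profiles) {
  p <- matchedPairs(cohort)
  n <- nrow(p)
  n_cases_total <- n + length(unmatchedCases(cohort))
  if (n == 0) {
    return(list(n_case = 0L, n_control = 0L,
                match_rate = if (n_cases_total) 0 else NA_real_,
                sex_ratio_case = NA_real_, sex_ratio_control = NA_real_,
                age_distribution = table(arm = character(),
                                         age_group = character())))
  }
  cov <- covariates(profiles)
  rownames(cov) <- cov$patient_id
  ag_case <- cov[p$case_id, "age_group"]
  ag_ctrl <- cov[p$control_id, "age_group"]
  sex_ctrl <- cov[p$control_id, "sex"]
  list(
    n_case = n, n_control = n,
    match_rate = n / n_cases_total,
    sex_ratio_case = mean(p$sex == "female"),
    sex_ratio_control = mean(sex_ctrl == "female"),
    age_distribution = table(
      arm = rep(c("case", "control"), each = n),
      age_group = c(as.character(ag_case), as.character(ag_ctrl)))
  )
}
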