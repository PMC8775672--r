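#' Synthetic discharge-record generator configuration
#'
#' Defines a population of patients with known ground truth, generated from
#' a latent-block mixture: each patient independently joins each planted
#' disease block with the block's propensity; given memberships, diseases
#' fire independently, with within-block probabilities boosted for members
#' and lowered for non-members so that (a) every disease keeps its
#' configured marginal prevalence and (b) every within-block pair attains
#' exactly the block's target observed-to-expected ratio (OER) in the
#' population. With propensity `pi` and a shared boost `beta` (member
#' probability `beta*p`, non-member probability `p*(1-pi*beta)/(1-pi)`),
#' the population OER of a within-block pair is
#' `pi*beta^2 + (1-pi*beta)^2/(1-pi)`, and solving for the target `theta`
#' gives the closed form `beta = 1 + sqrt((1-pi)*(theta-1)/pi)`. The default
#' propensity is `0.5/theta`. Cross-block pairs are independent (OER = 1).
#'
#' Cases (an `is_case` draw at `case_fraction`) carry one index (I20-I25)
#' code and have the prevalence of each "enriched" disease multiplied by
#' its enrichment multiplier; blocks can be planted in either arm or both.
#'
#' A target OER is unattainable when `theta > 1/max(p_i, p_j)` for a pair
#' in the block (the attainability bound), or when the boosted member
#' probability `beta * p` would exceed 1 under this mechanism; both raise a
#' configuration error naming the offending disease.
#'
#' @param n_patients number of patients.
#' @param n_diseases number of chronic diseases (ignored when `prevalence`
#'   is a named vector).
#' @param prevalence named numeric vector of per-disease control-arm
#'   prevalences (names = 3-character codes), or NULL to draw a
#'   log-uniform spectrum over `prevalence_range` with synthetic codes.
#' @param prevalence_range range of the log-uniform spectrum
#'   (default c(0.01, 0.5)).
#' @param blocks list of planted blocks, each a list with `codes`
#'   (character, >= 2 member diseases), `oer` (target, > 1), optional
#'   `propensity` and `arm` ("both"/"case"/"control", default "both").
#' @param case_fraction fraction of patients that are index cases.
#' @param enriched character vector of disease codes whose case-arm
#'   prevalence is multiplied by `enrichment_multiplier`.
#' @param enrichment_multiplier scalar or named vector of case multipliers
#'   (clamped to 0.95 with a warning).
#' @param records_rate mean extra hospitalizations per patient (records per
#'   patient = 1 + Poisson(records_rate)).
#' @param noise_acute_rate per-record probability of an acute (non-chronic)
#'   noise diagnosis.
#' @param noise_excluded_rate per-record probability of an excluded-chapter
#'   (Z/S/T...) noise diagnosis.
#' @param female_fraction,birth_year_range,date_range,tertiary_fraction
#'   covariate distributions (sex mix, birth years, admission-date window,
#'   hospital-level mix).
#' @param underage_fraction fraction of patients younger than 35 (to
#'   exercise the age filter).
#' @param death_rate per-patient probability of a death record.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return a list of class `synth_config` with calibrated block parameters.
#' @export
synthConfig <- function(n_patients, n_diseases = 30L, prevalence = NULL,
                        prevalence_range = c(0.01, 0.5),
                        blocks = list(), case_fraction = 0.1,
                        enriched = character(),
                        enrichment_multiplier = 2,
                        records_rate = 1,
                        noise_acute_rate = 0.3, noise_excluded_rate = 0.2,
                        female_fraction = 0.516,
                        birth_year_range = c(1935L, 1980L),
                        date_range = as.Date(c("2015-01-01", "2019-12-31")),
                        tertiary_fraction = 0.4,
                        underage_fraction = 0.02,
                        death_rate = 0.02,
                        seed) {
  if (missing(seed) || is.null(seed)) stop("synthConfig: seed is mandatory")
  if (is.null(prevalence)) {
    codes <- syntheticCodePool(n_diseases)
    prevalence <- withr::with_seed(seed + 1L, setNames(
      exp(runif(n_diseases, log(prevalence_range[1]),
                log(prevalence_range[2]))), codes))
  }
  stopifnot(!is.null(names(prevalence)), all(prevalence > 0 & prevalence < 1))
  codes <- names(prevalence)

  if (length(enriched)) {
    stopifnot(all(enriched %in% codes))
    if (is.null(names(enrichment_multiplier)))
      enrichment_multiplier <- setNames(
        rep_len(enrichment_multiplier, length(enriched)), enriched)
  }
  prev_case <- prevalence
  if (length(enriched)) {
    boosted <- prevalence[enriched] * enrichment_multiplier[enriched]
    if (any(boosted > 0.95)) {
      warning("synthConfig: enriched prevalence clamped to 0.95 for: ",
              paste(enriched[boosted > 0.95], collapse = ", "))
      boosted <- pmin(boosted, 0.95)
    }
    prev_case[enriched] <- boosted
  }

  all_members <- unlist(lapply(blocks, `[[`, "codes"))
  if (anyDuplicated(all_members))
    stop("synthConfig: a disease may belong to at most one block")
  blocks <- lapply(blocks, function(b) {
    stopifnot(length(b$codes) >= 2, b$oer > 1, all(b$codes %in% codes))
    b$arm <- if (is.null(b$arm)) "both" else
      match.arg(b$arm, c("both", "case", "control"))
    if (is.null(b$propensity)) b$propensity <- 0.5 / b$oer
    for (armname in c("control", "case")) {
      if (b$arm != "both" && b$arm != armname) next
      p <- (if (armname == "case") prev_case else prevalence)[b$codes]
      bound <- 1 / max(p)
      if (b$oer > bound)
        stop("synthConfig: target OER ", b$oer, " unattainable for pair(s) ",
             "in block containing ", names(p)[which.max(p)],
             " (OER_max = 1/max prevalence = ", round(bound, 3), ")")
      beta <- .blockBoost(b$oer, b$propensity)
      if (beta * max(p) > 1)
        stop("synthConfig: boosted probability beta*p = ",
             round(beta * max(p), 3), " > 1 for ", names(p)[which.max(p)],
             "; lower the block propensity or the member prevalences")
      if (b$propensity * beta > 1)
        stop("synthConfig: pi*beta > 1; lower the block propensity")
    }
    b
  })

  structure(list(
    n_patients = as.integer(n_patients), codes = codes,
    prevalence = prevalence, prevalence_case = prev_case,
    blocks = blocks, case_fraction = case_fraction,
    enriched = enriched, enrichment_multiplier = enrichment_multiplier,
    records_rate = records_rate,
    noise_acute_rate = noise_acute_rate,
    noise_excluded_rate = noise_excluded_rate,
    female_fraction = female_fraction,
    birth_year_range = as.integer(birth_year_range),
    date_range = as.Date(date_range),
    tertiary_fraction = tertiary_fraction,
    underage_fraction = underage_fraction,
    death_rate = death_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# closed-form within-block boost for target OER theta at propensity pi
.blockBoost <- function(theta, pi) 1 + sqrt((1 - pi) * (theta - 1) / pi)

#' Synthetic 3-character code pool
#'
#' Deterministic sequence of plausible-looking 3-character codes spanning
#' the in-scope ICD-10 chapter letters (never S/T/V-Y/Z, never the index
#' range I20-I25).
#'
#' @param n number of codes.
#' @return character vector of length n.
#' @export
syntheticCodePool <- function(n) {
  letters_ok <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                  "L", "M", "N", "R")
  pool <- as.vector(outer(letters_ok, sprintf("%02d", 0:99),
                          function(l, d) paste0(l, d)))
  pool <- sort(pool)
  pool <- pool[!(pool >= "I20" & pool <= "I25")]
  if (n > length(pool)) stop("syntheticCodePool: pool exhausted")
  # spread over chapters rather than exhausting 'A' first
  idx <- round(seq(1, length(pool), length.out = n))
  pool[unique(idx)][seq_len(n)]
}

IHD_CODES <- paste0("I2", 0:5)

ACUTE_NOISE_CODES <- c("A09", "B99", "J06", "J03", "R10", "R50")
EXCLUDED_NOISE_CODES <- c("Z51", "Z00", "S06", "T81", "V43", "W19", "Y83")

# draw the patient x disease incidence for one arm
.drawIncidence <- function(n, prev, blocks, armname) {
  D <- length(prev)
  prob <- matrix(rep(prev, each = n), nrow = n,
                 dimnames = list(NULL, names(prev)))
  block_id <- setNames(rep(NA_integer_, D), names(prev))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (b$arm != "both" && b$arm != armname) next
    beta <- .blockBoost(b$oer, b$propensity)
    z <- stats::rbinom(n, 1, b$propensity) == 1
    p <- prev[b$codes]
    q1 <- beta * p
    q0 <- p * (1 - b$propensity * beta) / (1 - b$propensity)
    prob[z, b$codes] <- rep(q1, each = sum(z))
    prob[!z, b$codes] <- rep(q0, each = sum(!z))
    block_id[b$codes] <- k
  }
  x <- matrix(stats::runif(n * D), n, D) < prob
  colnames(x) <- names(prev)
  list(incidence = x, block_id = block_id)
}

#' Simulate patient-level profiles with ground truth
#'
#' Draws the population at the patient level (no discharge-record
#' scattering): case labels, covariates, and the chronic-disease incidence
#' from the calibrated latent-block model. Cases additionally carry one
#' index (I20-I25) code. This is the fast path used for statistical
#' validation; [generatePopulation()] layers the discharge-record
#' representation on top of the same draw.
#'
#' @param config a [synthConfig()].
#' @return list with `profiles` (\linkS4class{PatientProfiles} over all
#'   patients; covariates gain an `is_case` column), `case_ids`, and
#'   `truth` (list: per-arm prevalences, block membership/targets, enriched
#'   codes and multipliers, chronic code list).
#' @export
simulateProfiles <- function(config) {
  withr::with_seed(config$seed, .simulateProfilesImpl(config))
}

.simulateProfilesImpl <- function(config) {
  n <- config$n_patients
  is_case <- stats::runif(n) < config$case_fraction
  n1 <- sum(is_case); n0 <- n - n1

  inc <- matrix(FALSE, n, length(config$codes),
                dimnames = list(NULL, config$codes))
  if (n0 > 0)
    inc[!is_case, ] <- .drawIncidence(n0, config$prevalence,
                                      config$blocks, "control")$incidence
  if (n1 > 0)
    inc[is_case, ] <- .drawIncidence(n1, config$prevalence_case,
                                     config$blocks, "case")$incidence
  block_id <- setNames(rep(NA_integer_, length(config$codes)), config$codes)
  for (k in seq_along(config$blocks))
    block_id[config$blocks[[k]]$codes] <- k

  ihd <- sample(IHD_CODES, n, replace = TRUE,
                prob = c(.1, .3, .05, .05, .1, .4))
  inc_full <- cbind(inc,
                    matrix(FALSE, n, length(IHD_CODES),
                           dimnames = list(NULL, IHD_CODES)))
  inc_full[cbind(which(is_case), ncol(inc) + match(ihd[is_case], IHD_CODES))] <- TRUE
  inc_full <- inc_full[, sort(colnames(inc_full)), drop = FALSE]

  underage <- stats::runif(n) < config$underage_fraction
  by_range <- config$birth_year_range
  birth_year <- ifelse(underage,
    sample(seq(by_range[2] + 6L, by_range[2] + 15L), n, replace = TRUE),
    sample(seq(by_range[1], by_range[2]), n, replace = TRUE))
  dr <- as.integer(config$date_range)
  discharge <- as.Date(sample(seq(dr[1], dr[2]), n, replace = TRUE),
                       origin = "1970-01-01")
  age <- as.integer(format(discharge, "%Y")) - birth_year
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  level <- ifelse(stats::runif(n) < config$tertiary_fraction,
                  "tertiary", "secondary")
  died <- stats::runif(n) < config$death_rate

  ids <- sprintf("P%07d", seq_len(n))
  cov <- data.frame(patient_id = ids, sex = sex, birth_year = birth_year,
                    age = age, age_group = ageGroup(age),
                    discharge_date = discharge, hospital_level = level,
                    died = died, is_case = is_case,
                    stringsAsFactors = FALSE)
  rownames(inc_full) <- ids
  chronic <- sort(c(config$codes, IHD_CODES))
  profiles <- new("PatientProfiles",
                  incidence = methods::as(inc_full, "CsparseMatrix"),
                  covariates = cov, chronicCodes = chronic)
  truth <- list(
    prevalence_control = config$prevalence,
    prevalence_case = config$prevalence_case,
    blocks = lapply(config$blocks, function(b)
      b[c("codes", "oer", "propensity", "arm")]),
    block_id = block_id,
    enriched = config$enriched,
    enrichment_multiplier = config$enrichment_multiplier,
    chronic_codes = chronic
  )
  list(profiles = profiles, case_ids = ids[is_case], truth = truth)
}

#' Generate a synthetic hospital-discharge-record table
#'
#' Draws the population with [simulateProfiles()] under the config seed and
#' scatters each patient's diagnosis set across 1 + Poisson(records_rate)
#' hospitalization rows in the canonical dialect, injecting acute and
#' excluded-chapter noise diagnoses (to exercise the chronicity and chapter
#' filters), mixed sex encodings ("male"/"M", ...) and dotted code
#' extensions (to exercise parsing/normalization). Byte-identical output
#' for identical config and seed.
#'
#' @param config a [synthConfig()].
#' @param path optional path; when given the table is written as TSV.
#' @return list `table` (data.table, one row per hospitalization),
#'   `truth`, `case_ids`, `profiles` (the underlying patient-level draw).
#' @export
generatePopulation <- function(config, path = NULL) {
  sim <- simulateProfiles(config)
  tab <- withr::with_seed(config$seed + 2L, .scatterRecords(sim, config))
  if (!is.null(path)) data.table::fwrite(tab, path, sep = "\t")
  list(table = tab, truth = sim$truth, case_ids = sim$case_ids,
       profiles = sim$profiles)
}

.scatterRecords <- function(sim, config) {
  cov <- covariates(sim$profiles)
  inc <- methods::as(incidenceMatrix(sim$profiles), "TsparseMatrix")
  n <- nrow(cov)
  codes_all <- colnames(inc)
  long <- data.table::data.table(pid = inc@i + 1L,
                                 code = codes_all[inc@j + 1L])
  ncodes <- tabulate(long$pid, n)
  # enough records that balanced scattering never exceeds 12 chronic codes
  # per record (16-slot limit with room for noise)
  k <- pmax(1L + stats::rpois(n, config$records_rate),
            as.integer(ceiling(ncodes / 12)))
  m <- sum(k)
  rec_pid <- rep.int(seq_len(n), k)
  rec_seq <- sequence(k)
  start <- cumsum(k) - k   # records of patient i are start[i]+1 .. start[i]+k[i]

  data.table::setorder(long, pid)
  long[, rec := start[pid] + ((sample.int(.N) - 1L) %% k[pid[1L]]) + 1L,
       by = pid]
  long[, prio := ifelse(code >= "I20" & code <= "I25", 0L, 1L)]

  # noise injections, plus a fallback acute code for records with no
  # diagnosis at all
  add_acute <- which(stats::runif(m) < config$noise_acute_rate)
  add_excl <- which(stats::runif(m) < config$noise_excluded_rate)
  empty <- setdiff(seq_len(m), c(unique(long$rec), add_acute, add_excl))
  noise <- data.table::data.table(
    pid = rec_pid[c(add_acute, add_excl, empty)],
    code = c(sample(ACUTE_NOISE_CODES, length(add_acute), replace = TRUE),
             sample(EXCLUDED_NOISE_CODES, length(add_excl), replace = TRUE),
             sample(ACUTE_NOISE_CODES, length(empty), replace = TRUE)),
    rec = c(add_acute, add_excl, empty),
    prio = 2L)
  dt <- rbind(long, noise)
  data.table::setorder(dt, rec, prio)       # index code -> dx1 when present
  dt[, pos := seq_len(.N), by = rec]
  dt <- dt[pos <= 16L]
  # dotted extensions on about half of the written codes
  ext <- which(stats::runif(nrow(dt)) < 0.5)
  dt[ext, code := paste0(code, ".", sample(0:9, length(ext), replace = TRUE))]

  dx <- matrix(NA_character_, m, 16L, dimnames = list(NULL, DX_COLS))
  dx[cbind(dt$rec, dt$pos)] <- dt$code

  # record dates: the last record per patient carries the patient's (latest)
  # discharge date; earlier ones are scattered up to ~2 years back
  off <- sample.int(700L, m, replace = TRUE) - 1L
  off[cumsum(k)] <- 0L
  dis <- cov$discharge_date[rec_pid] - off
  los <- sample.int(14L, m, replace = TRUE)

  sex_enc <- ifelse(stats::runif(m) < 0.5,
                    ifelse(cov$sex[rec_pid] == "male", "M", "F"),
                    cov$sex[rec_pid])
  out <- data.table::data.table(
    patient_id = cov$patient_id[rec_pid],
    sex = sex_enc,
    birth_year = cov$birth_year[rec_pid],
    age = as.integer(format(dis, "%Y")) - cov$birth_year[rec_pid],
    admission_date = as.character(dis - los),
    discharge_date = as.character(dis),
    hospital_level = cov$hospital_level[rec_pid],
    died = as.integer(cov$died[rec_pid] & rec_seq == k[rec_pid])
  )
  cbind(out, data.table::as.data.table(dx))
}

#' A shipped scenario emulating the study's qualitative findings
#'
#' A desk-scale analogue of a large matched IHD comorbidity study: 70
#' chronic diseases on a log-spaced prevalence spectrum from 50% down to
#' 1%, two disease blocks planted in the case arm (target OERs 3 and 2.5,
#' 8 diseases each), and 20 enriched diseases whose case multiplier is set
#' analytically so the expected case/control comorbid-burden ratio is 1.5
#' (the "50% larger burden" regime). Cases are half the population so both
#' arms are equally sized.
#'
#' @param n_patients total patients (default 100000, i.e. about 50000 per
#'   arm).
#' @param seed integer seed.
#' @return a [synthConfig()].
#' @export
makePaperlikeScenario <- function(n_patients = 100000L, seed = 20150101L) {
  D <- 70L
  r <- (0.01 / 0.5)^(1 / (D - 1))
  prev <- setNames(0.5 * r^(0:(D - 1)), syntheticCodePool(D))
  codes <- names(prev)
  block_a <- codes[21:28]
  block_b <- codes[31:38]
  enriched <- codes[c(1:15, 41:45)]
  # multiplier m solves sum(case prevalence) = 1.5 * sum(control prevalence)
  m <- 1 + 0.5 * sum(prev) / sum(prev[enriched])
  synthConfig(
    n_patients = n_patients, prevalence = prev,
    blocks = list(list(codes = block_a, oer = 3.0, arm = "case"),
                  list(codes = block_b, oer = 2.5, arm = "case")),
    case_fraction = 0.5,
    enriched = enriched, enrichment_multiplier = m,
    seed = seed
  )
}
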