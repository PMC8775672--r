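#' Prevalence with confidence interval
#'
#' Point estimate `count/N` with a Wald interval
#' `p +/- z * sqrt(p(1-p)/N)` truncated to [0, 1]; a Wilson score interval
#' is available via `method = "wilson"`.
#'
#' @param count integer vector of patients carrying the condition.
#' @param N arm size(s).
#' @param level confidence level (default 0.95).
#' @param method "wald" (default) or "wilson".
#' @return data.frame `estimate`, `ci_low`, `ci_high` (proportions).
#' @export
prevalence <- function(count, N, level = 0.95,
                       method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (any(N <= 0)) stop("prevalence: N must be positive")
  if (any(count < 0 | count > N)) stop("prevalence: count outside [0, N]")
  p <- count / N
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / N)
    lo <- pmax(0, p - half); hi <- pmin(1, p + half)
  } else {
    den <- 1 + z^2 / N
    ctr <- (p + z^2 / (2 * N)) / den
    half <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / den
    lo <- pmax(0, ctr - half); hi <- pmin(1, ctr + half)
  }
  data.frame(estimate = p, ci_low = lo, ci_high = hi)
}

#' Comorbidity list of a cohort arm
#'
#' Codes whose prevalence in the arm is at or above `min_prevalence`
#' (default 1%, the usual reliability cut for rarely diagnosed diseases),
#' excluding the index-condition codes themselves. Chapter and chronicity
#' filtering has already happened at profile construction.
#'
#' @param profiles \linkS4class{PatientProfiles} restricted to the arm (use
#'   `profiles[ids, ]`).
#' @param min_prevalence inclusion threshold (>=, boundary included).
#' @param exclude_range inclusive 3-character code interval removed from the
#'   list (default the IHD index codes I20-I25); NULL to keep everything.
#' @return character vector of codes, sorted.
#' @export
comorbidityList <- function(profiles, min_prevalence = 0.01,
                            exclude_range = c("I20", "I25")) {
  n <- nPatients(profiles)
  if (n == 0) stop("comorbidityList: empty arm")
  prev <- Matrix::colSums(incidenceMatrix(profiles)) / n
  codes <- conditionCodes(profiles)
  keep <- prev >= min_prevalence
  if (!is.null(exclude_range))
    keep <- keep & !(codes >= exclude_range[1] & codes <= exclude_range[2])
  sort(codes[keep])
}

#' Odds ratio for a 2x2 case-control table
#'
#' `OR = (a*d)/(b*c)` with `a` exposed cases, `b` unexposed cases, `c`
#' exposed controls, `d` unexposed controls. The confidence interval is the
#' Woolf log-normal interval `exp(ln OR +/- z*sqrt(1/a+1/b+1/c+1/d))` and
#' the two-sided p-value comes from the normal score `ln OR / SE`. When any
#' cell is zero the Haldane-Anscombe 0.5 continuity correction is applied to
#' all four cells.
#'
#' @param a,b,c,d non-negative cell counts (vectorized).
#' @param level confidence level (default 0.95).
#' @return data.frame `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
oddsRatio <- function(a, b, c, d, level = 0.95) {
  if (any(c(a, b, c, d) < 0)) stop("oddsRatio: negative cell count")
  if (any(a + b == 0) || any(c + d == 0))
    stop("oddsRatio: empty arm margin (a+b or c+d is 0)")
  corr <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  a <- a + 0.5 * corr; b <- b + 0.5 * corr
  c <- c + 0.5 * corr; d <- d + 0.5 * corr
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  data.frame(or = or, ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se), p_value = p)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, with `m` the number of conditions tested (the length of the
#' case arm's comorbidity list, recomputed per dataset).
#'
#' @param alpha family-wise level (default 0.05). @param m number of tests.
#' @return the adjusted per-test threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("bonferroniThreshold: m must be >= 1")
  alpha / m
}

#' Per-condition case-control statistics and enrichment screen
#'
#' For every code in the case arm's comorbidity list: case and control
#' counts and prevalences with 95% CI, odds ratio with Woolf 95% CI and
#' p-value, Bonferroni significance at `alpha/m` (`m` = list length), and
#' the enrichment flag: OR > 1, p below the Bonferroni threshold, and case
#' prevalence at least 1.5x control prevalence ("increased over 0.5
#' times", boundary inclusive). A condition absent from controls gets an
#' infinite prevalence ratio and is enriched whenever the OR conditions
#' hold.
#'
#' @param case_profiles,control_profiles \linkS4class{PatientProfiles} for
#'   the two arms.
#' @param codes conditions to evaluate; default the case arm's
#'   [comorbidityList()].
#' @param alpha family-wise level for the Bonferroni rule.
#' @param level confidence level of the prevalence and OR intervals.
#' @param enrichment_ratio prevalence-ratio cut for enrichment (default 1.5).
#' @return data.frame with one row per code: counts, prevalences + CIs
#'   (proportions), `or`, `or_ci_low`, `or_ci_high`, `p_value`,
#'   `significant`, `prevalence_ratio`, `enriched`. The Bonferroni
#'   threshold and m are attached as attributes `bonferroni` and `m`.
#' @export
conditionStats <- function(case_profiles, control_profiles,
                           codes = comorbidityList(case_profiles),
                           alpha = 0.05, level = 0.95,
                           enrichment_ratio = 1.5) {
  n1 <- nPatients(case_profiles)
  n0 <- nPatients(control_profiles)
  armCounts <- function(p) {
    full <- Matrix::colSums(incidenceMatrix(p))
    out <- setNames(numeric(length(codes)), codes)
    hit <- intersect(codes, names(full))
    out[hit] <- full[hit]
    out
  }
  a <- armCounts(case_profiles)
  c_ <- armCounts(control_profiles)
  pc <- prevalence(a, n1, level)
  pk <- prevalence(c_, n0, level)
  orr <- oddsRatio(a, n1 - a, c_, n0 - c_, level)
  m <- length(codes)
  thr <- bonferroniThreshold(alpha, m)
  # (a/n1)/(c/n0) computed as (a/c)*(n0/n1) so equal-N boundary cases
  # (e.g. an exact 1.5x ratio) are not blurred by floating point
  ratio <- ifelse(c_ == 0, ifelse(a > 0, Inf, NaN), (a / c_) * (n0 / n1))
  sig <- orr$p_value < thr
  out <- data.frame(
    code = codes,
    case_count = a, control_count = c_,
    n_case = n1, n_control = n0,
    prevalence_case = pc$estimate,
    prevalence_case_low = pc$ci_low, prevalence_case_high = pc$ci_high,
    prevalence_control = pk$estimate,
    prevalence_control_low = pk$ci_low, prevalence_control_high = pk$ci_high,
    or = orr$or, or_ci_low = orr$ci_low, or_ci_high = orr$ci_high,
    p_value = orr$p_value,
    significant = sig,
    prevalence_ratio = ratio,
    enriched = orr$or > 1 & sig & !is.nan(ratio) & ratio >= enrichment_ratio,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "bonferroni") <- thr
  attr(out, "m") <- m
  out
}

#' Comorbid-burden distribution of an arm
#'
#' Per-patient count of listed comorbidities present, with mean, standard
#' deviation and the proportions of patients carrying at least 1 and at
#' least 2 comorbidities.
#'
#' @param profiles \linkS4class{PatientProfiles} restricted to the arm.
#' @param codes the arm's comorbidity list.
#' @return list `counts` (integer per patient), `mean`, `sd`, `p_ge1`,
#'   `p_ge2`.
#' @export
burdenDistribution <- function(profiles, codes) {
  present <- intersect(codes, conditionCodes(profiles))
  counts <- if (length(present))
    as.integer(Matrix::rowSums(
      incidenceMatrix(profiles)[, present, drop = FALSE]))
  else rep(0L, nPatients(profiles))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       p_ge1 = mean(counts >= 1), p_ge2 = mean(counts >= 2))
}
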