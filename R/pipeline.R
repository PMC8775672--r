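#' Run configuration for the end-to-end pipeline
#'
#' Bundles every threshold the pipeline uses: the 1% comorbidity prevalence
#' floor, the 0.05 family-wise level for the Bonferroni-corrected odds
#' ratios, the 99% confidence gate for OER edges, the 1.2 dominance ratio,
#' and the optional P90 display filter, together with matching criteria,
#' stratification axes and the top-level seed from which every stochastic
#' stage deterministically derives its own.
#'
#' @param input path to an HDR table (with `dialect`), or NULL to simulate
#'   from `scenario`.
#' @param dialect an [hdrDialect()] for `input`.
#' @param scenario a [synthConfig()] used when `input` is NULL (default
#'   [makePaperlikeScenario()] at a desk scale).
#' @param chronic chronic code list; default the scenario's ground-truth
#'   list when simulating, else [defaultChronicCodes()].
#' @param min_prevalence comorbidity inclusion threshold (default 0.01).
#' @param or_alpha family-wise level for the OR screen (default 0.05).
#' @param oer_ci_level OER edge gate (default 0.99).
#' @param dominance_ratio sex-dominance cut (default 1.2).
#' @param p90_filter apply the P90 edge filter for the exported display
#'   networks (default TRUE).
#' @param birth_year_tol,date_tol_days matching tolerances (defaults 2
#'   years; 30 days, the widened window used at synthetic scale).
#' @param strata_axes character subset of c("sex", "age").
#' @param out_dir output directory (created); NULL for no file output.
#' @param seed top-level integer seed.
#' @return list of class `run_config`.
#' @export
runConfig <- function(input = NULL, dialect = hdrDialect(),
                      scenario = NULL, chronic = NULL,
                      min_prevalence = 0.01, or_alpha = 0.05,
                      oer_ci_level = 0.99, dominance_ratio = 1.2,
                      p90_filter = TRUE,
                      birth_year_tol = 2L, date_tol_days = 30L,
                      strata_axes = c("sex", "age"),
                      out_dir = NULL, seed = 1L) {
  stopifnot(min_prevalence >= 0, min_prevalence < 1,
            or_alpha > 0, or_alpha < 1,
            oer_ci_level > 0, oer_ci_level < 1,
            dominance_ratio >= 1)
  if (is.null(input) && is.null(scenario))
    scenario <- makePaperlikeScenario(n_patients = 20000L,
                                      seed = seed + 101L)
  structure(list(input = input, dialect = dialect, scenario = scenario,
                 chronic = chronic, min_prevalence = min_prevalence,
                 or_alpha = or_alpha, oer_ci_level = oer_ci_level,
                 dominance_ratio = dominance_ratio, p90_filter = p90_filter,
                 birth_year_tol = as.integer(birth_year_tol),
                 date_tol_days = as.integer(date_tol_days),
                 strata_axes = match.arg(strata_axes, c("sex", "age"),
                                         several.ok = TRUE),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.stageSeed <- function(seed, stage) {
  # deterministic per-stage seeds derived from the single top-level seed
  (seed * 7919L + stage * 104729L) %% 2147483647L
}

#' Run the full comorbidity-network pipeline
#'
#' Executes records parsing -> patient profiles -> case identification and
#' 1:1 matching -> per-condition statistics and burden -> OER networks for
#' both arms -> community detection -> stratified networks and comparisons,
#' logging row/node/edge counts per stage. When `config$out_dir` is set,
#' all intermediate tables (TSV), networks (GraphML) and a single JSON
#' report are written.
#'
#' @param config a [runConfig()].
#' @param quiet suppress per-stage messages.
#' @return list of class `pdn_report`: cohort summary, condition statistics,
#'   burden summaries, per-arm networks + metrics + communities, stratified
#'   results, dominance pairs, thresholds and seeds used.
#' @export
runPipeline <- function(config = runConfig(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[comorbnet] ", ...)
  t0 <- Sys.time()

  # --- records ---------------------------------------------------------
  truth <- NULL
  if (is.null(config$input)) {
    say("simulating discharge records (seed ", config$scenario$seed, ")")
    gen <- generatePopulation(config$scenario)
    tmp <- tempfile(fileext = ".tsv")
    data.table::fwrite(gen$table, tmp, sep = "\t")
    parsed <- parseHdrTable(tmp, hdrDialect())
    unlink(tmp)
    truth <- gen$truth
    chronic <- if (is.null(config$chronic)) truth$chronic_codes
               else config$chronic
  } else {
    parsed <- parseHdrTable(config$input, config$dialect)
    chronic <- if (is.null(config$chronic)) defaultChronicCodes()
               else config$chronic
  }
  say(parsed$n_parsed, " records parsed, ", parsed$n_rejected, " rejected")

  # --- profiles --------------------------------------------------------
  profiles <- buildPatientProfiles(parsed$records, chronic)
  say(nPatients(profiles), " patient profiles")

  # --- cohort ----------------------------------------------------------
  cases <- identifyCases(profiles)
  crit <- matchCriteria(config$birth_year_tol, config$date_tol_days,
                        seed = .stageSeed(config$seed, 2L))
  cohort <- matchControls(profiles, cases, crit)
  say(length(cases), " cases; ", nrow(matchedPairs(cohort)),
      " matched pairs; ", length(unmatchedCases(cohort)), " unmatched")
  case_arm <- profiles[matchedPairs(cohort)$case_id, ]
  ctrl_arm <- profiles[matchedPairs(cohort)$control_id, ]

  # --- burden & condition statistics -----------------------------------
  case_list <- comorbidityList(case_arm, config$min_prevalence)
  ctrl_list <- comorbidityList(ctrl_arm, config$min_prevalence)
  stats_tab <- conditionStats(case_arm, ctrl_arm, codes = case_list,
                              alpha = config$or_alpha)
  burden <- list(case = burdenDistribution(case_arm, case_list),
                 control = burdenDistribution(ctrl_arm, ctrl_list))
  say(length(case_list), " case / ", length(ctrl_list),
      " control comorbidities; mean burden ",
      round(burden$case$mean, 2), " vs ", round(burden$control$mean, 2))

  # --- networks --------------------------------------------------------
  nets <- list(
    case = buildPDN(pairCounts(case_arm, case_list),
                    level = config$oer_ci_level, arm = "case"),
    control = buildPDN(pairCounts(ctrl_arm, ctrl_list),
                       level = config$oer_ci_level, arm = "control"))
  metrics <- lapply(nets, pdnMetrics)
  p90 <- lapply(nets, p90EdgeFilter)
  say("case PDN: ", metrics$case$n_edges, " edges; control PDN: ",
      metrics$control$n_edges, " edges")

  # --- communities -----------------------------------------------------
  comm <- lapply(nets, louvainCommunities,
                 seed = .stageSeed(config$seed, 5L))

  # --- strata ----------------------------------------------------------
  strata <- list(); strata_tests <- list(); dominance <- NULL
  for (ax in config$strata_axes) {
    sn <- suppressWarnings(
      stratifyAndBuild(case_arm, ax, config$min_prevalence,
                       config$oer_ci_level))
    if (length(sn) >= 2) {
      strata[[ax]] <- sn
      strata_tests[[ax]] <- compareMetrics(sn, paired = (length(sn) == 2))
      if (ax == "sex" && all(c("male", "female") %in% names(sn)))
        dominance <- dominancePairs(sn$male, sn$female,
                                    config$dominance_ratio)
    }
  }

  report <- structure(list(
    thresholds = config[c("min_prevalence", "or_alpha", "oer_ci_level",
                          "dominance_ratio", "p90_filter",
                          "birth_year_tol", "date_tol_days")],
    seed = config$seed,
    n_records = parsed$n_parsed, n_rejected = parsed$n_rejected,
    cohort = cohortSummary(cohort, profiles),
    condition_stats = stats_tab,
    bonferroni = attr(stats_tab, "bonferroni"),
    burden = lapply(burden, function(b) b[c("mean", "sd", "p_ge1", "p_ge2")]),
    networks = nets,
    metrics = metrics,
    p90_thresholds = lapply(p90, `[[`, "threshold"),
    communities = lapply(comm, function(cm)
      list(n = length(unique(communityMembership(cm))),
           modularity = cm@modularity, seed = cm@seed)),
    community_membership = lapply(names(nets), function(a)
      communityTable(nets[[a]], comm[[a]])),
    strata_tests = strata_tests,
    dominance = dominance,
    truth = truth,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "pdn_report")
  names(report$community_membership) <- names(nets)

  if (!is.null(config$out_dir))
    writeReport(report, cohort, profiles, p90, config)
  report
}

#' Write all pipeline artifacts to a directory
#'
#' Matched-pairs TSV, condition-stats TSV, per-arm edge tables and GraphML
#' (full and P90-filtered), community membership TSVs, and `report.json`
#' summarizing every stage with the thresholds and seeds used.
#'
#' @param report,cohort,profiles,p90,config pipeline internals (called by
#'   [runPipeline()]).
#' @return invisibly, the output directory.
#' @export
writeReport <- function(report, cohort, profiles, p90, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)
  data.table::fwrite(matchedPairs(cohort), od("matched_pairs.tsv"), sep = "\t")
  data.table::fwrite(report$condition_stats, od("condition_stats.tsv"),
                     sep = "\t")
  writeProfilesTsv(profiles, od("patient_profiles.tsv"))
  for (a in names(report$networks)) {
    writePdn(report$networks[[a]], od(paste0("pdn_", a, ".graphml")),
             od(paste0("pdn_", a, "_edges.tsv")))
    if (isTRUE(config$p90_filter) && !is.na(p90[[a]]$threshold))
      writePdn(p90[[a]]$pdn, od(paste0("pdn_", a, "_p90.graphml")))
    data.table::fwrite(report$community_membership[[a]],
                       od(paste0("communities_", a, ".tsv")), sep = "\t")
  }
  json <- list(
    thresholds = report$thresholds, seed = report$seed,
    n_records = report$n_records, n_rejected = report$n_rejected,
    cohort = report$cohort[c("n_case", "n_control", "match_rate",
                             "sex_ratio_case", "sex_ratio_control")],
    bonferroni = report$bonferroni,
    burden = report$burden,
    metrics = lapply(report$metrics, function(m)
      m[c("n_nodes", "n_edges", "avg_degree", "avg_closeness",
          "avg_neighbor_degree", "diameter", "density")]),
    p90_thresholds = report$p90_thresholds,
    communities = report$communities,
    strata_tests = lapply(report$strata_tests, function(x)
      as.list(as.data.frame(x))),
    n_dominance_pairs = if (is.null(report$dominance)) NULL
                        else nrow(report$dominance)
  )
  jsonlite::write_json(json, od("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  if (!is.null(report$dominance))
    data.table::fwrite(report$dominance, od("dominance_pairs.tsv"),
                       sep = "\t")
  invisible(config$out_dir)
}

#' @export
print.pdn_report <- function(x, ...) {
  cat("comorbnet pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  records: ", x$n_records, " (", x$n_rejected, " rejected)\n", sep = "")
  cat("  cohort: ", x$cohort$n_case, " matched pairs\n", sep = "")
  cat("  burden: ", round(x$burden$case$mean, 2), " (case) vs ",
      round(x$burden$control$mean, 2), " (control)\n", sep = "")
  for (a in names(x$metrics))
    cat("  ", a, " PDN: ", x$metrics[[a]]$n_nodes, " nodes / ",
        x$metrics[[a]]$n_edges, " edges, density ",
        round(x$metrics[[a]]$density, 3), ", Q = ",
        round(x$communities[[a]]$modularity, 3), " (",
        x$communities[[a]]$n, " communities)\n", sep = "")
  invisible(x)
}
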