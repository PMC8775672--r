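#' Stratified comorbidity networks
#'
#' Splits an arm's profiles by sex ("male" vs "female") or by the fixed age
#' bins (35-59, 60-69, 70-79, 80+) and runs the full network pipeline per
#' stratum: comorbidity list at the prevalence threshold within the
#' stratum, OER edge statistics with the confidence gate, and network
#' metrics. Strata smaller than `min_n` are skipped with a warning.
#'
#' @param profiles \linkS4class{PatientProfiles} restricted to the arm
#'   (e.g. the case arm).
#' @param axis "sex" or "age".
#' @param min_prevalence within-stratum comorbidity threshold (default 1%).
#' @param level edge-gate confidence level (default 0.99).
#' @param min_n minimum stratum size (default 50).
#' @param exclude_range index codes removed from comorbidity lists.
#' @return named list of \linkS4class{PDN} objects, one per non-empty
#'   stratum.
#' @export
stratifyAndBuild <- function(profiles, axis = c("sex", "age"),
                             min_prevalence = 0.01, level = 0.99,
                             min_n = 50L, exclude_range = c("I20", "I25")) {
  axis <- match.arg(axis)
  cov <- covariates(profiles)
  f <- if (axis == "sex") cov$sex else as.character(cov$age_group)
  out <- list()
  lev <- if (axis == "sex") c("male", "female")
         else c("35-59", "60-69", "70-79", "80+")
  for (s in lev) {
    idx <- which(!is.na(f) & f == s)
    if (length(idx) < min_n) {
      warning("stratum '", s, "' has ", length(idx),
              " patients (< ", min_n, "); skipped")
      next
    }
    arm <- profiles[idx, ]
    codes <- comorbidityList(arm, min_prevalence, exclude_range)
    if (length(codes) < 2) {
      warning("stratum '", s, "' has fewer than 2 comorbidities; skipped")
      next
    }
    out[[s]] <- buildPDN(pairCounts(arm, codes), level = level, arm = s)
  }
  out
}

#' Compare node-level network metrics between strata
#'
#' For two networks, a paired t test per metric (degree, closeness, average
#' neighbor degree) over the nodes common to both; for more than two, a
#' one-way ANOVA of per-node metric values grouped by stratum. Per-stratum
#' means are reported alongside the statistic and p-value. With fewer than
#' 3 common nodes (or < 3 values per group) the test is not run and NA is
#' reported.
#'
#' @param pdns named list of two or more \linkS4class{PDN} objects.
#' @param paired for exactly two networks, use a paired test over common
#'   nodes (default TRUE); FALSE gives Welch's two-sample test over each
#'   network's own nodes.
#' @return data.frame: `metric`, one `mean_<stratum>` column per stratum,
#'   `statistic`, `p_value`, `test`.
#' @export
compareMetrics <- function(pdns, paired = TRUE) {
  stopifnot(length(pdns) >= 2)
  nm <- names(pdns)
  if (is.null(nm)) nm <- paste0("stratum", seq_along(pdns))
  mets <- lapply(pdns, function(p) pdnMetrics(p)$node_metrics)
  metric_names <- c("degree", "closeness", "avg_neighbor_degree")
  rows <- lapply(metric_names, function(mtr) {
    vals <- lapply(mets, function(m) setNames(m[[mtr]], m$code))
    means <- vapply(vals, mean, numeric(1))
    stat <- NA_real_; pval <- NA_real_; test <- NA_character_
    if (length(pdns) == 2) {
      if (paired) {
        common <- intersect(names(vals[[1]]), names(vals[[2]]))
        test <- "paired t"
        if (length(common) >= 3) {
          d <- vals[[1]][common] - vals[[2]][common]
          if (stats::sd(d) > 0) {
            tt <- stats::t.test(vals[[1]][common], vals[[2]][common],
                                paired = TRUE)
            stat <- unname(tt$statistic); pval <- tt$p.value
          } else { stat <- 0; pval <- 1 }
        }
      } else {
        test <- "Welch t"
        if (min(lengths(vals)) >= 3) {
          tt <- stats::t.test(vals[[1]], vals[[2]])
          stat <- unname(tt$statistic); pval <- tt$p.value
        }
      }
    } else {
      test <- "one-way ANOVA"
      if (min(lengths(vals)) >= 3) {
        df <- data.frame(
          y = unlist(vals, use.names = FALSE),
          g = factor(rep(nm, lengths(vals))))
        if (stats::sd(df$y) > 0) {
          fit <- stats::aov(y ~ g, data = df)
          an <- summary(fit)[[1]]
          stat <- an[["F value"]][1]; pval <- an[["Pr(>F)"]][1]
        } else { stat <- 0; pval <- 1 }
      }
    }
    out <- data.frame(metric = mtr, stringsAsFactors = FALSE)
    for (k in seq_along(nm)) out[[paste0("mean_", nm[k])]] <- means[k]
    out$statistic <- stat; out$p_value <- pval; out$test <- test
    out
  })
  do.call(rbind, rows)
}

#' Sex/stratum-dominant disease pairs
#'
#' Among the comorbidities common to both strata, finds disease pairs that
#' are significant edges in both networks and whose OER in one stratum is
#' at least `ratio_threshold` (default 1.2) times the OER in the other;
#' each emitted pair is labeled with its dominant stratum. By default only
#' pairs "involving different disease systems" - the two codes in
#' different ICD-10 chapters - are considered.
#'
#' @param pdn_a,pdn_b \linkS4class{PDN} objects for the two strata.
#' @param ratio_threshold dominance cut (default 1.2).
#' @param cross_chapter_only restrict to pairs whose codes are in different
#'   ICD-10 chapters (default TRUE).
#' @return data.frame `code_i`, `code_j`, `oer_a`, `oer_b`, `ratio`
#'   (dominant over other), `dominant` (name of the dominant stratum, from
#'   the PDNs' arm labels).
#' @export
dominancePairs <- function(pdn_a, pdn_b, ratio_threshold = 1.2,
                           cross_chapter_only = TRUE) {
  stopifnot(ratio_threshold >= 1)
  common <- intersect(pdnNodes(pdn_a)$code, pdnNodes(pdn_b)$code)
  ea <- pdnEdges(pdn_a); eb <- pdnEdges(pdn_b)
  keyfun <- function(e) paste(pmin(e$code_i, e$code_j),
                              pmax(e$code_i, e$code_j), sep = "|")
  ea <- ea[ea$code_i %in% common & ea$code_j %in% common, , drop = FALSE]
  eb <- eb[eb$code_i %in% common & eb$code_j %in% common, , drop = FALSE]
  mm <- merge(
    data.frame(key = keyfun(ea), code_i = pmin(ea$code_i, ea$code_j),
               code_j = pmax(ea$code_i, ea$code_j), oer_a = ea$oer),
    data.frame(key = keyfun(eb), oer_b = eb$oer),
    by = "key")
  if (cross_chapter_only)
    mm <- mm[substr(mm$code_i, 1, 1) != substr(mm$code_j, 1, 1), ,
             drop = FALSE]
  ratio_ab <- mm$oer_a / mm$oer_b
  dom_a <- ratio_ab >= ratio_threshold
  dom_b <- (1 / ratio_ab) >= ratio_threshold
  keep <- dom_a | dom_b
  out <- data.frame(
    code_i = mm$code_i[keep], code_j = mm$code_j[keep],
    oer_a = mm$oer_a[keep], oer_b = mm$oer_b[keep],
    ratio = pmax(ratio_ab[keep], 1 / ratio_ab[keep]),
    dominant = ifelse(dom_a[keep], pdn_a@arm, pdn_b@arm),
    stringsAsFactors = FALSE
  )
  out[order(-out$ratio), , drop = FALSE]
}
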