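#' Accessors for comorbnet classes
#'
#' @param x a \linkS4class{PatientProfiles}, \linkS4class{MatchedCohort},
#'   \linkS4class{PDN} or \linkS4class{CommunityPartition} object.
#' @name accessors
NULL

#' @describeIn accessors number of patients in a profile set.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @describeIn accessors patient identifiers.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @describeIn accessors condition (node) codes.
#' @export
setGeneric("conditionCodes", function(x) standardGeneric("conditionCodes"))

#' @describeIn accessors sparse patient x condition incidence matrix.
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @describeIn accessors per-patient covariate table.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @describeIn accessors matched case/control pair table.
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @describeIn accessors ids of unmatched cases.
#' @export
setGeneric("unmatchedCases", function(x) standardGeneric("unmatchedCases"))

#' @describeIn accessors underlying igraph of a PDN.
#' @export
setGeneric("pdnGraph", function(x) standardGeneric("pdnGraph"))

#' @describeIn accessors node annotation table of a PDN.
#' @export
setGeneric("pdnNodes", function(x) standardGeneric("pdnNodes"))

#' @describeIn accessors significant edge table of a PDN.
#' @export
setGeneric("pdnEdges", function(x) standardGeneric("pdnEdges"))

#' @describeIn accessors full pair-statistics table of a PDN (all evaluable
#'   pairs, significant or not).
#' @export
setGeneric("pairStats", function(x) standardGeneric("pairStats"))

#' @describeIn accessors community membership vector.
#' @export
setGeneric("communityMembership", function(x) standardGeneric("communityMembership"))

setMethod("nPatients", "PatientProfiles", function(x) nrow(x@incidence))
setMethod("patientIds", "PatientProfiles", function(x) rownames(x@incidence))
setMethod("conditionCodes", "PatientProfiles", function(x) colnames(x@incidence))
setMethod("incidenceMatrix", "PatientProfiles", function(x) x@incidence)
setMethod("covariates", "PatientProfiles", function(x) x@covariates)

setMethod("matchedPairs", "MatchedCohort", function(x) x@pairs)
setMethod("unmatchedCases", "MatchedCohort", function(x) x@unmatched)

setMethod("pdnGraph", "PDN", function(x) x@graph)
setMethod("pdnNodes", "PDN", function(x) x@nodes)
setMethod("pdnEdges", "PDN", function(x)
  x@pairStats[x@pairStats$significant, , drop = FALSE])
setMethod("pairStats", "PDN", function(x) x@pairStats)

setMethod("communityMembership", "CommunityPartition", function(x) x@membership)

#' Subset patient profiles
#'
#' `x[i, j]` subsets patients (`i`: ids, indices or logical) and/or condition
#' codes (`j`).
#'
#' @param x a PatientProfiles object.
#' @param i patient selector. @param j code selector.
#' @param ... ignored. @param drop ignored (always FALSE).
#' @export
setMethod("[", "PatientProfiles", function(x, i, j, ..., drop = FALSE) {
  inc <- x@incidence
  cov <- x@covariates
  if (!missing(i)) {
    if (is.character(i)) i <- match(i, rownames(inc))
    inc <- inc[i, , drop = FALSE]
    cov <- cov[i, , drop = FALSE]
    rownames(cov) <- NULL
  }
  if (!missing(j)) inc <- inc[, j, drop = FALSE]
  new("PatientProfiles", incidence = inc, covariates = cov,
      chronicCodes = x@chronicCodes)
})

setMethod("show", "PatientProfiles", function(object) {
  cat("PatientProfiles:", nrow(object@incidence), "patients,",
      ncol(object@incidence), "chronic condition codes\n")
  cat("  mean codes/patient:",
      round(mean(Matrix::rowSums(object@incidence)), 2), "\n")
})

setMethod("show", "MatchedCohort", function(object) {
  cat("MatchedCohort:", nrow(object@pairs), "matched pairs,",
      length(object@unmatched), "unmatched cases\n")
})

setMethod("show", "PDN", function(object) {
  cat("PDN [", object@arm, "]: ", nrow(object@nodes), " nodes, ",
      igraph::ecount(object@graph), " significant edges (",
      object@ciLevel * 100, "% CI gate), N = ", object@N, "\n", sep = "")
})

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", length(unique(object@membership)),
      "communities over", length(object@membership),
      "nodes; Q =", round(object@modularity, 4), "\n")
})
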