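#' @import methods
#' @importFrom Matrix sparseMatrix colSums rowSums crossprod t
NULL

setOldClass("igraph")

EXCLUDED_CHAPTER_LETTERS <- c("S", "T", "V", "W", "X", "Y", "Z")

#' PatientProfiles: patient-level chronic condition profiles
#'
#' Collapses hospital discharge records into one row per patient: a sparse
#' logical incidence matrix (patients x 3-character ICD-10 codes, TRUE when
#' the patient received the code on any hospitalization in the study window)
#' together with per-patient covariates used for matching and stratification.
#' Only chronic, non-excluded-chapter codes are retained; see
#' [buildPatientProfiles()].
#'
#' @slot incidence sparse logical \linkS4class{Matrix}, patients x codes;
#'   rownames are patient ids, colnames are 3-character ICD-10 codes.
#' @slot covariates data.frame with one row per patient: `patient_id`, `sex`
#'   ("male"/"female"), `birth_year`, `age` (age at first record), `age_group`
#'   ("35-59", "60-69", "70-79", "80+", or NA below 35), `discharge_date`
#'   (latest discharge), `hospital_level` ("secondary"/"tertiary"), `died`.
#' @slot chronicCodes character vector of the chronic-condition code list the
#'   profiles were built against.
#'
#' @seealso [buildPatientProfiles()], [incidenceMatrix()], [covariates()]
#' @exportClass PatientProfiles
setClass("PatientProfiles",
  representation(
    incidence   = "Matrix",
    covariates  = "data.frame",
    chronicCodes = "character"
  )
)

setValidity("PatientProfiles", function(object) {
  msg <- character()
  inc <- object@incidence
  cov <- object@covariates
  if (nrow(inc) != nrow(cov))
    msg <- c(msg, "incidence and covariates disagree on patient count")
  if (nrow(inc) > 0 &&
      !identical(as.character(rownames(inc)), as.character(cov$patient_id)))
    msg <- c(msg, "incidence rownames must equal covariates$patient_id")
  cd <- colnames(inc)
  if (length(cd)) {
    if (any(nchar(cd) != 3L))
      msg <- c(msg, "condition codes must be 3 characters")
    if (any(substr(cd, 1, 1) %in% EXCLUDED_CHAPTER_LETTERS))
      msg <- c(msg, "condition codes include excluded ICD-10 chapters (S/T/V-Y/Z)")
    if (anyDuplicated(cd))
      msg <- c(msg, "duplicated condition codes")
  }
  need <- c("patient_id", "sex", "birth_year", "age", "age_group",
            "discharge_date", "hospital_level", "died")
  miss <- setdiff(need, names(cov))
  if (length(miss))
    msg <- c(msg, paste0("covariates missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' MatchedCohort: 1:1 matched case-control pairs
#'
#' Result of [matchControls()]: the matched pairs with their matching
#' covariates, the ids of cases for which no eligible control remained, the
#' criteria used, and an audit of which single criterion blocked each
#' unmatched case.
#'
#' @slot pairs data.frame, one row per matched pair (`case_id`, `control_id`
#'   plus matching covariates for both members).
#' @slot unmatched character vector of case ids without an eligible control.
#' @slot criteria list as returned by [matchCriteria()].
#' @slot audit named integer vector: for each criterion, the number of
#'   unmatched cases that would have had at least one eligible control had
#'   that single criterion been dropped.
#' @exportClass MatchedCohort
setClass("MatchedCohort",
  representation(
    pairs     = "data.frame",
    unmatched = "character",
    criteria  = "list",
    audit     = "integer"
  )
)

setValidity("MatchedCohort", function(object) {
  p <- object@pairs
  msg <- character()
  if (nrow(p)) {
    if (anyDuplicated(p$control_id))
      msg <- c(msg, "a control id is used more than once (1:1 violated)")
    if (anyDuplicated(p$case_id))
      msg <- c(msg, "a case id is matched more than once")
  }
  if (length(msg)) msg else TRUE
})

#' PDN: phenotypic disease network
#'
#' An undirected simple graph whose nodes are an arm's comorbidity codes
#' (annotated with prevalence and ICD-10 chapter) and whose edges are the
#' disease pairs with observed-to-expected ratio (OER) significantly above 1
#' at the configured confidence level; edge weight is the OER. Nodes without
#' any significant edge are retained as isolates. The full pair-level
#' statistics table (including non-significant pairs) is kept in `pairStats`.
#'
#' @slot graph igraph object (undirected, simple, edge attribute `weight` =
#'   OER).
#' @slot nodes data.frame: `code`, `chapter`, `count`, `prevalence`.
#' @slot pairStats data.frame of all evaluable pairs: `code_i`, `code_j`,
#'   `c_ij`, `oer`, `ci_low`, `ci_high`, `significant`.
#' @slot N integer, number of patients in the arm.
#' @slot arm character label ("case", "control", a stratum name, ...).
#' @slot ciLevel numeric confidence level of the edge gate (default 0.99).
#' @exportClass PDN
setClass("PDN",
  representation(
    graph     = "igraph",
    nodes     = "data.frame",
    pairStats = "data.frame",
    N         = "integer",
    arm       = "character",
    ciLevel   = "numeric"
  )
)

setValidity("PDN", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "PDN graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "PDN graph must have no self-loops")
  if (!setequal(igraph::V(g)$name, object@nodes$code))
    msg <- c(msg, "graph vertex set must equal the node table")
  if (igraph::ecount(g) > 0 && any(igraph::E(g)$weight <= 1))
    msg <- c(msg, "all PDN edge weights (OER) must exceed 1")
  if (length(msg)) msg else TRUE
})

#' CommunityPartition: modularity-based partition of a PDN
#'
#' @slot membership named integer vector, node code -> community label.
#' @slot modularity numeric, weighted Newman-Girvan modularity Q of the
#'   partition.
#' @slot resolution numeric resolution parameter (1 = classical modularity).
#' @slot seed integer seed that controlled tie-breaking.
#' @exportClass CommunityPartition
setClass("CommunityPartition",
  representation(
    membership = "integer",
    modularity = "numeric",
    resolution = "numeric",
    seed       = "integer"
  )
)

setValidity("CommunityPartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node code")
  if (length(object@modularity) == 1 && !is.na(object@modularity) &&
      (object@modularity < -0.5 || object@modularity > 1))
    msg <- c(msg, "modularity must lie in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})
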