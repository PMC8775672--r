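#' @importFrom data.table fread fwrite data.table as.data.table setnames
#'   setkey setorder melt rbindlist :=
#' @importFrom stats quantile rbinom rnorm runif rpois setNames
#' @importFrom utils head
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", "patient_id", "code", "value", "variable", "sex", "birth_year",
  "age", "age_group", "admission_date", "discharge_date", "hospital_level",
  "died", "record_id", "n_sex", "pid", "rec", "prio", "pos"
))

MAX_SECONDARY_DX <- 15L
DX_COLS <- paste0("dx", seq_len(MAX_SECONDARY_DX + 1L))

#' Normalize an ICD-10 code to its 3-character form
#'
#' Uppercases, strips dots and anything after them, drops extension
#' characters, and truncates to the first three characters (letter + two
#' digits), the granularity at which all downstream analyses operate.
#'
#' @param raw character vector of raw ICD-10 code strings (e.g. "I25.102").
#' @param strict if TRUE (default), codes that do not reduce to
#'   letter+digit+digit raise an error; if FALSE they return NA.
#' @return character vector of 3-character codes.
#' @examples
#' normalizeCode(c("I25.102", "i50", "K29.7"))  # "I25" "I50" "K29"
#' @export
normalizeCode <- function(raw, strict = TRUE) {
  if (any(!nzchar(raw) | is.na(raw)))
    stop("normalizeCode: empty or NA code")
  x <- toupper(trimws(raw))
  x <- sub("\\..*$", "", x)          # drop dot extension
  x <- gsub("[^A-Z0-9]", "", x)      # stray separators
  x <- substr(x, 1, 3)
  ok <- grepl("^[A-Z][0-9]{2}$", x)
  if (any(!ok)) {
    if (strict)
      stop("normalizeCode: invalid ICD-10 code(s) after cleanup: ",
           paste(unique(raw[!ok]), collapse = ", "))
    x[!ok] <- NA_character_
  }
  x
}

#' Is a 3-character code in an excluded ICD-10 chapter?
#'
#' Chapters XIX (injury/poisoning, S00-T88), XX (external causes, V00-Y99)
#' and XXI (factors influencing health status, Z00-Z99) are not diseases and
#' are excluded from comorbidity analysis. At 3-character granularity the
#' rule is: first letter in S, T, V, W, X, Y, Z. The sliver T89-T99 beyond
#' T88 cannot be separated from chapter XIX by the letter alone and is
#' excluded with it.
#'
#' @param code3 character vector of normalized 3-character codes.
#' @return logical vector.
#' @examples
#' isExcludedChapter(c("Z51", "I25", "T89"))  # TRUE FALSE TRUE
#' @export
isExcludedChapter <- function(code3) {
  substr(code3, 1, 1) %in% EXCLUDED_CHAPTER_LETTERS
}

#' Column-mapping dialect for discharge-record tables
#'
#' Describes how a delimited hospital-discharge-record (HDR) file maps onto
#' the canonical columns `patient_id`, `sex`, `birth_year`, `age`,
#' `admission_date`, `discharge_date`, `hospital_level`, `died`,
#' `dx1`..`dx16` (dx1 = primary diagnosis). The canonical dialect uses those
#' very names, ISO-8601 dates, and `male`/`female`, `secondary`/`tertiary`,
#' 0/1 encodings.
#'
#' @param columns named character vector mapping canonical names to the
#'   file's column names; omitted entries default to the canonical name.
#'   Diagnosis columns are configured through `dx_prefix`.
#' @param dx_prefix prefix of the diagnosis columns in the file (columns
#'   `<dx_prefix>1` .. `<dx_prefix>16`).
#' @param sex_codes named character vector mapping raw sex encodings to
#'   "male"/"female" (default understands male/female, M/F, 1/2).
#' @param level_codes named character vector mapping raw hospital-level
#'   encodings to "secondary"/"tertiary".
#' @param date_format passed to [as.Date()]; default ISO-8601.
#' @param sep field separator for reading (default: sniffed by fread).
#' @return a list of class `hdr_dialect`.
#' @export
hdrDialect <- function(columns = character(),
                       dx_prefix = "dx",
                       sex_codes = c(male = "male", female = "female",
                                     M = "male", F = "female",
                                     `1` = "male", `2` = "female"),
                       level_codes = c(secondary = "secondary",
                                       tertiary = "tertiary",
                                       `2` = "secondary", `3` = "tertiary"),
                       date_format = "%Y-%m-%d",
                       sep = "auto") {
  canon <- c("patient_id", "sex", "birth_year", "age", "admission_date",
             "discharge_date", "hospital_level", "died")
  map <- setNames(canon, canon)
  if (length(columns)) {
    bad <- setdiff(names(columns), canon)
    if (length(bad))
      stop("hdrDialect: unknown canonical column(s): ",
           paste(bad, collapse = ", "))
    map[names(columns)] <- columns
  }
  structure(list(columns = map, dx_prefix = dx_prefix,
                 sex_codes = sex_codes, level_codes = level_codes,
                 date_format = date_format, sep = sep),
            class = "hdr_dialect")
}

#' Parse a hospital-discharge-record table
#'
#' Reads a delimited HDR file (one row per hospitalization: demographics,
#' admission/discharge dates, hospital level, death flag, 1 primary + up to
#' 15 secondary ICD-10 diagnoses), normalizes encodings through the dialect,
#' and validates each row. Malformed rows are collected in a rejection
#' report, never silently dropped.
#'
#' Row-level validation: parseable dates with admission <= discharge, a
#' recognized sex and hospital-level encoding, at least one diagnosis code,
#' and every diagnosis reducible to a valid 3-character code. A file with
#' more than 16 populated diagnosis columns is a configuration error.
#'
#' @param path path to a delimited text file.
#' @param dialect an [hdrDialect()] describing the file's columns/encodings.
#' @return list with `records` (data.table in canonical form: canonical
#'   columns plus `dx1`..`dx16` and `record_id` = source row number),
#'   `rejects` (data.table `row`, `reason`), and counts `n_parsed`,
#'   `n_rejected`.
#' @export
parseHdrTable <- function(path, dialect = hdrDialect()) {
  if (!file.exists(path)) stop("parseHdrTable: file not found: ", path)
  raw <- data.table::fread(path, sep = dialect$sep, colClasses = "character",
                           na.strings = c("", "NA"))
  map <- dialect$columns
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols))
    stop("parseHdrTable: required column(s) missing from file: ",
         paste(missing_cols, collapse = ", "))
  dxcols_file <- paste0(dialect$dx_prefix, seq_len(40L))
  dxcols_file <- dxcols_file[dxcols_file %in% names(raw)]
  if (length(dxcols_file) == 0)
    stop("parseHdrTable: no diagnosis columns with prefix '",
         dialect$dx_prefix, "'")
  if (length(dxcols_file) > 16L)
    stop("parseHdrTable: more than 16 diagnosis columns (1 primary + 15 ",
         "secondary allowed)")

  n <- nrow(raw)
  out <- data.table::data.table(
    record_id      = seq_len(n),
    patient_id     = as.character(raw[[map["patient_id"]]]),
    sex            = unname(dialect$sex_codes[as.character(raw[[map["sex"]]])]),
    birth_year     = suppressWarnings(as.integer(raw[[map["birth_year"]]])),
    age            = suppressWarnings(as.integer(raw[[map["age"]]])),
    admission_date = as.Date(raw[[map["admission_date"]]],
                             format = dialect$date_format),
    discharge_date = as.Date(raw[[map["discharge_date"]]],
                             format = dialect$date_format),
    hospital_level = unname(dialect$level_codes[
                             as.character(raw[[map["hospital_level"]]])]),
    died           = as.character(raw[[map["died"]]]) %in% c("1", "TRUE", "true")
  )
  dx <- as.matrix(raw[, dxcols_file, with = FALSE])
  dxn <- matrix(NA_character_, nrow = n, ncol = 16L,
                dimnames = list(NULL, DX_COLS))
  has <- !is.na(dx) & nzchar(dx)
  dx_bad <- rep(FALSE, n)
  if (any(has)) {
    norm <- normalizeCode(dx[has], strict = FALSE)
    dx[has] <- norm
    dx_bad <- rowSums(has & is.na(replace(dx, !has, "x"))) > 0
    dxn[, seq_len(ncol(dx))] <- dx
  }

  reasons <- list(
    "missing patient id"       = is.na(out$patient_id) | !nzchar(out$patient_id),
    "unrecognized sex code"    = is.na(out$sex),
    "unparseable birth year"   = is.na(out$birth_year),
    "unparseable date"         = is.na(out$admission_date) |
                                 is.na(out$discharge_date),
    "admission after discharge" = !is.na(out$admission_date) &
                                  !is.na(out$discharge_date) &
                                  out$admission_date > out$discharge_date,
    "unrecognized hospital level" = is.na(out$hospital_level),
    "no diagnosis code"        = rowSums(has) == 0,
    "invalid diagnosis code"   = dx_bad
  )
  bad <- Reduce(`|`, reasons)
  rejects <- data.table::rbindlist(lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    if (length(idx)) data.table::data.table(row = idx, reason = r) else NULL
  }))
  if (is.null(rejects) || nrow(rejects) == 0)
    rejects <- data.table::data.table(row = integer(), reason = character())
  data.table::setorder(rejects, row)

  records <- cbind(out, as.data.table(dxn))[!bad]
  list(records = records, rejects = rejects,
       n_parsed = nrow(records), n_rejected = sum(bad))
}

#' Bundled chronic-condition code list (synthetic stand-in)
#'
#' A 3-character chronic-condition indicator list shipped with the package.
#' It is a synthetic stand-in assembled from well-known chronic 3-character
#' ICD-10 categories, not an official release of any published chronic
#' condition indicator; analyses on real data should supply the appropriate
#' licensed list via the `chronic` arguments throughout.
#'
#' @return character vector of uppercase 3-character codes, with a
#'   `provenance` attribute.
#' @export
defaultChronicCodes <- function() {
  path <- system.file("extdata", "chronic_codes_synthetic.tsv",
                      package = "comorbnet")
  tab <- data.table::fread(path, header = TRUE)
  structure(tab$code, provenance = "synthetic stand-in list shipped with comorbnet")
}

#' Age group bins used throughout
#'
#' Bins ages into the fixed strata 35-59, 60-69, 70-79, 80+; ages below 35
#' (outside the eligible population) map to NA.
#'
#' @param age integer vector of ages in years.
#' @return factor with levels "35-59", "60-69", "70-79", "80+".
#' @export
ageGroup <- function(age) {
  cut(age, breaks = c(35, 60, 70, 80, Inf), right = FALSE,
      labels = c("35-59", "60-69", "70-79", "80+"))
}

#' Collapse discharge records into patient-level chronic profiles
#'
#' For each distinct patient, takes the union over all of their
#' hospitalizations of normalized 3-character diagnosis codes, keeps only
#' codes on the chronic list that are not in an excluded chapter, and
#' attaches matching covariates: sex and birth year (constant per patient;
#' conflicting sex values are an error), latest discharge date and its
#' hospital level, age and age group at the first record, and whether death
#' was ever recorded.
#'
#' @param records canonical records data.table from [parseHdrTable()].
#' @param chronic character vector of chronic 3-character codes
#'   (default [defaultChronicCodes()]).
#' @return a \linkS4class{PatientProfiles} object. Codes never observed are
#'   not represented as columns.
#' @export
buildPatientProfiles <- function(records, chronic = defaultChronicCodes()) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("buildPatientProfiles: no records")
  if (length(chronic) == 0) stop("buildPatientProfiles: empty chronic list")
  chronic <- toupper(chronic)
  rec <- data.table::as.data.table(records)

  sexes <- rec[, .(n_sex = data.table::uniqueN(sex)), by = patient_id]
  if (any(sexes$n_sex > 1))
    stop("buildPatientProfiles: conflicting sex values for patient(s): ",
         paste(head(sexes$patient_id[sexes$n_sex > 1], 10), collapse = ", "))

  dxcols <- intersect(DX_COLS, names(rec))
  long <- data.table::melt(rec[, c("patient_id", dxcols), with = FALSE],
                           id.vars = "patient_id", na.rm = TRUE,
                           value.name = "code")
  long <- long[nzchar(code)]
  long[, code := normalizeCode(code)]
  long <- long[!isExcludedChapter(code) & code %in% chronic]
  long <- unique(long[, .(patient_id, code)])

  data.table::setorder(rec, patient_id, discharge_date, admission_date)
  cov <- rec[, .(
    sex            = sex[1],
    birth_year     = birth_year[1],
    age            = age[1],                      # at first record
    discharge_date = discharge_date[.N],          # latest
    hospital_level = hospital_level[.N],
    died           = any(died)
  ), by = patient_id]
  cov[, age_group := ageGroup(age)]
  data.table::setorder(cov, patient_id)

  ids <- cov$patient_id
  codes <- sort(unique(long$code))
  inc <- Matrix::sparseMatrix(
    i = match(long$patient_id, ids),
    j = match(long$code, codes),
    x = TRUE,
    dims = c(length(ids), length(codes)),
    dimnames = list(ids, codes)
  )
  covdf <- as.data.frame(cov[, .(patient_id, sex, birth_year, age, age_group,
                                 discharge_date, hospital_level, died)])
  new("PatientProfiles", incidence = inc, covariates = covdf,
      chronicCodes = chronic)
}

#' Write patient profiles to a TSV
#'
#' One row per patient with covariates and the chronic code set joined with
#' semicolons.
#'
#' @param profiles a PatientProfiles object. @param path output path.
#' @export
writeProfilesTsv <- function(profiles, path) {
  inc <- incidenceMatrix(profiles)
  codes <- colnames(inc)
  sets <- vapply(seq_len(nrow(inc)), function(i)
    paste(codes[inc[i, ] > 0], collapse = ";"), character(1))
  out <- cbind(data.table::as.data.table(covariates(profiles)),
               chronic_codes = sets)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
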