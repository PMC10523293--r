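## Structured-code channel: ICD-10-CM prefix matching for SUD cohort
## definition, poisoning episodes, and diagnosis-code housing evidence.

## Default code patterns. Shipped as data so sites can extend the lists
## without code changes (see load_code_patterns()).
default_code_patterns <- function() {
  data.table(
    prefix = c("F14.", "F15.", "T40.5", "T43.6",
               "F11.", "T40.0", "T40.1", "T40.2", "T40.3", "T40.4", "T40.6",
               "Z59",
               "T40.", "T43.6"),
    label = c(rep("stimulant", 4),
              rep("opioid", 7),
              "housing",
              rep("poisoning", 2))
  )
}

#' Load ICD-10-CM code patterns from a plain-text table
#'
#' The file is a two-column CSV (\code{prefix,label}) with labels in
#' \code{stimulant}, \code{opioid}, \code{housing}, \code{poisoning}.
#'
#' @param path CSV path; \code{NULL} returns the built-in defaults
#'   (stimulant: F14*, F15*, T40.5*, T43.6*; opioid: F11*, T40.0*-T40.4*,
#'   T40.6*; housing: Z59*; poisoning: T40*, T43.6*).
#' @return a \code{data.table} with columns \code{prefix}, \code{label}.
#' @export
load_code_patterns <- function(path = NULL) {
  pat <- if (is.null(path)) default_code_patterns() else fread(path, colClasses = "character")
  stopifnot(all(c("prefix", "label") %in% names(pat)))
  pat$prefix <- toupper(pat$prefix)
  bad <- !grepl("^[A-Z0-9.]+$", pat$prefix)
  if (any(bad)) stop_config("invalid code prefix: ", paste(pat$prefix[bad], collapse = ", "))
  pat
}

## Canonical form: uppercase, dots removed. Billing extracts vary in dot
## usage ("F14.10" vs "F1410"); one canonical form avoids dialect bugs.
strip_code <- function(code) gsub(".", "", toupper(code), fixed = TRUE)

#' Match an ICD-10-CM code against a prefix pattern
#'
#' Dot-stripped prefix semantics: \code{"T40.5"} matches the 7-character
#' billing code \code{"T40.5X1A"}; \code{"F14."} matches \code{"F140"}.
#' Matching is case-insensitive. A trailing \code{"*"} on the pattern is
#' accepted and ignored.
#'
#' @param code character vector of ICD codes.
#' @param prefix a single pattern stem, e.g. \code{"F14."} or \code{"T40.5*"}.
#' @return logical vector.
#' @export
match_code <- function(code, prefix) {
  stopifnot(length(prefix) == 1L, nzchar(prefix))
  p <- strip_code(sub("\\*$", "", prefix))
  startsWith(strip_code(code), p)
}

match_any <- function(codes, prefixes) {
  Reduce(`|`, lapply(prefixes, function(p) match_code(codes, p)),
         init = rep(FALSE, length(codes)))
}

#' Classify a patient's substance-use-disorder type from encounter codes
#'
#' Stimulant evidence is any code in F14*, F15*, T40.5*, T43.6*; opioid
#' evidence any code in F11*, T40.0*-T40.4*, T40.6*. The three-way cohort
#' split treats concurrent evidence as its own category rather than a tie.
#'
#' @param codes character vector of ICD-10-CM codes for one patient
#'   (encounter order and duplication are irrelevant).
#' @param patterns code-pattern table from \code{\link{load_code_patterns}}.
#' @return one of \code{"stimulant_only"}, \code{"opioid_only"},
#'   \code{"both"}, \code{"none"}.
#' @export
classify_sud <- function(codes, patterns = load_code_patterns()) {
  if (length(codes) == 0L) return("none")
  stim <- any(match_any(codes, patterns$prefix[patterns$label == "stimulant"]))
  opi  <- any(match_any(codes, patterns$prefix[patterns$label == "opioid"]))
  if (stim && opi) "both"
  else if (stim) "stimulant_only"
  else if (opi) "opioid_only"
  else "none"
}

#' Detect diagnosis-code housing evidence (Z59*) in a patient's encounters
#'
#' @param encounters a \code{data.frame}/\code{data.table} with columns
#'   \code{encounter_id}, \code{code} (and optionally \code{date}) for one
#'   patient.
#' @param patterns code-pattern table.
#' @return an evidence-flag row (\code{data.table}: source, method,
#'   provenance) for the earliest matching encounter, or \code{NULL}.
#' @export
detect_housing_code <- function(encounters, patterns = load_code_patterns()) {
  enc <- as.data.table(encounters)
  if (nrow(enc) == 0L) return(NULL)
  hit <- match_any(enc$code, patterns$prefix[patterns$label == "housing"])
  if (!any(hit)) return(NULL)
  enc <- enc[hit]
  if ("date" %in% names(enc)) enc <- enc[order(date, encounter_id)]
  data.table(source = "diagnosis", method = "icd_z59",
             provenance = paste0(enc$encounter_id[1], ":", enc$code[1]))
}

#' Detect a stimulant/opioid poisoning episode (T40*, T43.6*)
#'
#' @inheritParams detect_housing_code
#' @return logical scalar.
#' @export
detect_poisoning <- function(encounters, patterns = load_code_patterns()) {
  enc <- as.data.table(encounters)
  if (nrow(enc) == 0L) return(FALSE)
  any(match_any(enc$code, patterns$prefix[patterns$label == "poisoning"]))
}

## Vectorized per-patient channel used by the pipeline: returns one row per
## patient with a Z59 flag, with earliest-encounter provenance.
detect_housing_codes_all <- function(encounters, patterns = load_code_patterns()) {
  enc <- as.data.table(encounters)
  if (nrow(enc) == 0L) {
    return(data.table(patient_id = character(), source = character(),
                      method = character(), provenance = character()))
  }
  hit <- enc[match_any(code, patterns$prefix[patterns$label == "housing"])]
  if (nrow(hit) == 0L) {
    return(data.table(patient_id = character(), source = character(),
                      method = character(), provenance = character()))
  }
  if ("date" %in% names(hit)) setorder(hit, patient_id, date, encounter_id)
  first <- hit[, .SD[1], by = patient_id]
  data.table(patient_id = first$patient_id, source = "diagnosis",
             method = "icd_z59",
             provenance = paste0(first$encounter_id, ":", first$code))
}

classify_sud_all <- function(encounters, patterns = load_code_patterns()) {
  enc <- as.data.table(encounters)
  stim_pref <- patterns$prefix[patterns$label == "stimulant"]
  opi_pref  <- patterns$prefix[patterns$label == "opioid"]
  enc[, `:=`(is_stim = match_any(code, stim_pref),
             is_opi  = match_any(code, opi_pref))]
  agg <- enc[, .(stim = any(is_stim), opi = any(is_opi)), by = patient_id]
  enc[, c("is_stim", "is_opi") := NULL]
  agg[, sud_type := fifelse(stim & opi, "both",
                     fifelse(stim, "stimulant_only",
                       fifelse(opi, "opioid_only", "none")))]
  agg[, .(patient_id, sud_type)]
}
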