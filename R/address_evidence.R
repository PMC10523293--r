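## Address channel: normalization of semi-structured EHR address fields,
## matching against the curated community-resource directory, and flags for
## literal-"homeless" and generic placeholder addresses.

## USPS-style street-suffix abbreviations applied during normalization.
usps_suffix_map <- c(
  STREET = "ST", AVENUE = "AVE", BOULEVARD = "BLVD", DRIVE = "DR",
  ROAD = "RD", LANE = "LN", COURT = "CT", CIRCLE = "CIR", PLACE = "PL",
  TERRACE = "TER", HIGHWAY = "HWY", PARKWAY = "PKWY", SQUARE = "SQ",
  TRAIL = "TRL", WAY = "WAY", NORTH = "N", SOUTH = "S", EAST = "E",
  WEST = "W", APARTMENT = "APT", SUITE = "STE", UNIT = "UNIT"
)

## Tokens that, with everything after them, are dropped as unit designators.
unit_designators <- c("APT", "STE", "UNIT", "#")

default_placeholders <- c("", "UNKNOWN", "NONE", "N/A", "NA", "XXX", "X",
                          "UNK", "NOT GIVEN", "SAME")

normalize_line <- function(line) {
  x <- toupper(line)
  x <- gsub("#", " # ", x, fixed = TRUE)
  x <- gsub("[^A-Z0-9# ]+", " ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  if (length(toks) == 0L) return("")
  mapped <- ifelse(toks %in% names(usps_suffix_map), usps_suffix_map[toks], toks)
  ## drop unit designator and its argument ("APT 4", "# 12B", "STE 300")
  drop <- rep(FALSE, length(mapped))
  i <- match(TRUE, mapped %in% unit_designators)
  if (!is.na(i)) {
    drop[i] <- TRUE
    if (i < length(mapped) && grepl("^[0-9A-Z]+$", mapped[i + 1L])) drop[i + 1L] <- TRUE
  }
  paste(mapped[!drop], collapse = " ")
}

#' Normalize an address record to a canonical matching key
#'
#' Uppercases, strips punctuation, collapses whitespace, abbreviates street
#' suffixes USPS-style (STREET to ST, AVENUE to AVE, ...), removes unit
#' designators (APT/STE/#n), and concatenates
#' \code{line1|city|state|zip5}. Normalization is idempotent.
#'
#' @param line1,city,state,zip character vectors (recycled to a common
#'   length). \code{line2} is intentionally excluded from the key; it mostly
#'   carries unit information.
#' @return character vector of canonical keys.
#' @export
normalize_address <- function(line1, city = "", state = "", zip = "") {
  n <- max(length(line1), length(city), length(state), length(zip))
  line1 <- rep_len(as.character(line1), n)
  city <- rep_len(as.character(city), n)
  state <- rep_len(as.character(state), n)
  zip <- rep_len(as.character(zip), n)
  zip5 <- substr(gsub("[^0-9]", "", zip), 1, 5)
  paste(vapply(line1, normalize_line, character(1), USE.NAMES = FALSE),
        vapply(city, normalize_line, character(1), USE.NAMES = FALSE),
        toupper(trimws(state)), zip5, sep = "|")
}

#' Load the community-resource directory
#'
#' CSV schema: \code{resource_id, name, aliases} (pipe-delimited),
#' \code{line1, city, state, zip, roles} (pipe-delimited subset of
#' emergency_shelter / transitional_housing / residential_sud_treatment).
#' Address keys are normalized at load and must be unique.
#'
#' @param path CSV path; \code{NULL} loads the synthetic directory shipped
#'   with the package.
#' @return \code{data.table} with an added \code{address_key} column.
#' @export
load_resource_directory <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "resources_synthetic.csv", package = "hinstab")
  }
  dir <- fread(path, colClasses = "character")
  need <- c("resource_id", "name", "aliases", "line1", "city", "state", "zip", "roles")
  stopifnot(all(need %in% names(dir)))
  if (any(!nzchar(dir$name))) stop_config("resource with empty canonical name")
  dir[, address_key := normalize_address(line1, city, state, zip)]
  if (anyDuplicated(dir$address_key)) {
    stop_config("duplicate normalized resource addresses in directory")
  }
  dir
}

## All matchable surface names for a directory row: canonical name + aliases.
resource_surfaces <- function(directory) {
  out <- directory[, .(surface = c(name, strsplit(aliases, "|", fixed = TRUE)[[1]])),
                   by = resource_id]
  out[nzchar(trimws(surface))]
}

#' Match a normalized address key against the resource directory
#'
#' Exact key match first; optionally a fuzzy pass using normalized edit
#' similarity (1 - Levenshtein distance / max length) with the decision
#' logged via a \code{message}. Multiple fuzzy candidates above threshold are
#' ambiguous: a warning is raised and no match returned.
#'
#' @param key canonical key from \code{\link{normalize_address}}.
#' @param directory resource directory from
#'   \code{\link{load_resource_directory}}.
#' @param fuzzy enable the fuzzy pass (default TRUE).
#' @param threshold minimum normalized edit similarity (default 0.92).
#' @return the matching directory row (\code{data.table}) or \code{NULL}.
#' @export
match_resource <- function(key, directory, fuzzy = TRUE, threshold = 0.92) {
  hit <- directory[address_key == key]
  if (nrow(hit)) return(hit[1])
  if (!fuzzy) return(NULL)
  d <- adist(key, directory$address_key)[1, ]
  sim <- 1 - d / pmax(nchar(key), nchar(directory$address_key))
  above <- which(sim >= threshold)
  if (length(above) == 0L) return(NULL)
  if (length(above) > 1L) {
    warning("ambiguous fuzzy address match for key '", key, "' (",
            length(above), " candidates); no evidence emitted")
    return(NULL)
  }
  message(sprintf("fuzzy address match: '%s' ~ '%s' (similarity %.3f)",
                  key, directory$address_key[above], sim[above]))
  directory[above]
}

#' Flag a literal "homeless" first address line
#'
#' True iff line1 contains, case-insensitively, the token "homeless" or a
#' configured synonym. Token containment means "123 Homeless Shelter Rd"
#' also flags (surfaced for review, method recorded as literal_homeless).
#'
#' @param line1 character vector of first address lines.
#' @param synonyms additional trigger phrases.
#' @return logical vector.
#' @export
flag_literal_homeless <- function(line1, synonyms = c("unhoused", "no address")) {
  pats <- c("homeless", tolower(synonyms))
  x <- tolower(trimws(line1))
  Reduce(`|`, lapply(pats, function(p) {
    stringi::stri_detect_regex(x, paste0("\\b", stringi::stri_replace_all_fixed(p, " ", "\\s+"), "\\b"))
  }), init = rep(FALSE, length(x)))
}

#' Flag a generic placeholder address
#'
#' True iff both address lines are empty or placeholders while city or state
#' is present — e.g. a bare "Lexington, KY". Generic addresses are reported
#' as a descriptive count but never emitted as housing evidence: an
#' unspecified address does not itself imply a housing issue.
#'
#' @param line1,line2,city,state character vectors.
#' @param placeholders line values treated as empty.
#' @return logical vector.
#' @export
flag_generic <- function(line1, line2 = "", city = "", state = "",
                         placeholders = default_placeholders) {
  n <- max(length(line1), length(line2), length(city), length(state))
  l1 <- toupper(trimws(rep_len(as.character(line1), n)))
  l2 <- toupper(trimws(rep_len(as.character(line2), n)))
  ct <- trimws(rep_len(as.character(city), n))
  st <- trimws(rep_len(as.character(state), n))
  (l1 %in% toupper(placeholders)) & (l2 %in% toupper(placeholders)) &
    (nzchar(ct) | nzchar(st))
}

#' Detect address-channel housing evidence for an address table
#'
#' Evaluates one (most recent) address per patient: resource-directory match
#' (exact, then optional fuzzy) and literal-"homeless" lines produce
#' evidence flags; generic placeholder addresses are counted but never
#' flagged. If several rows share a patient_id the last one is used,
#' mirroring an EHR limited to the most recent address on file.
#'
#' @param addresses \code{data.table} with patient_id, line1, line2, city,
#'   state, zip.
#' @param directory resource directory.
#' @param fuzzy,threshold fuzzy-match controls (see
#'   \code{\link{match_resource}}).
#' @param include_treatment count resources whose only role is
#'   residential_sud_treatment as housing evidence (default TRUE; such
#'   matches may overestimate housing instability, hence the switch).
#' @return list with \code{flags} (patient_id, source, method, provenance)
#'   and \code{generic} (patient_id vector of generic-address patients).
#' @export
detect_address_evidence <- function(addresses, directory, fuzzy = TRUE,
                                    threshold = 0.92,
                                    include_treatment = TRUE) {
  adr <- as.data.table(addresses)[, .SD[.N], by = patient_id]
  adr[, key := normalize_address(line1, city, state, zip)]

  eligible <- directory
  if (!include_treatment) {
    only_tx <- vapply(strsplit(directory$roles, "|", fixed = TRUE),
                      function(r) all(r == "residential_sud_treatment"), logical(1))
    eligible <- directory[!only_tx]
  }

  ## exact pass (vectorized), fuzzy pass only on the misses (one adist
  ## call over the distinct miss keys x directory keys)
  adr[, resource_id := eligible$resource_id[match(key, eligible$address_key)]]
  if (fuzzy && nrow(eligible)) {
    miss_keys <- unique(adr[is.na(resource_id) & nzchar(gsub("[| ]", "", key)), key])
    if (length(miss_keys)) {
      d <- adist(miss_keys, eligible$address_key)
      sim <- 1 - d / outer(nchar(miss_keys), nchar(eligible$address_key), pmax)
      for (i in seq_along(miss_keys)) {
        above <- which(sim[i, ] >= threshold)
        if (length(above) == 1L) {
          message(sprintf("fuzzy address match: '%s' ~ '%s' (similarity %.3f)",
                          miss_keys[i], eligible$address_key[above], sim[i, above]))
          adr[key == miss_keys[i], resource_id := eligible$resource_id[above]]
        } else if (length(above) > 1L) {
          warning("ambiguous fuzzy address match for key '", miss_keys[i],
                  "' (", length(above), " candidates); no evidence emitted")
        }
      }
    }
  }
  adr[, literal := flag_literal_homeless(line1)]
  adr[, generic := flag_generic(line1, line2, city, state)]

  res_flags <- adr[!is.na(resource_id),
                   .(patient_id, source = "address", method = "resource_address",
                     provenance = paste0(resource_id, ":", key))]
  lit_flags <- adr[literal & is.na(resource_id),
                   .(patient_id, source = "address", method = "literal_homeless",
                     provenance = key)]
  list(flags = rbindlist(list(res_flags, lit_flags)),
       generic = adr[generic & is.na(resource_id) & !literal, patient_id])
}
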