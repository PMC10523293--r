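## Evidence fusion: merge per-patient evidence flags from the three channels
## (D = diagnosis codes, A = addresses, N = notes) into identification sets,
## decompose the union into the 7 Venn regions, report coverage percentages,
## and compare census-tract aggregation under codes-only vs all-sources.

method_source_map <- c(icd_z59 = "diagnosis",
                       resource_address = "address", literal_homeless = "address",
                       keyword = "note", shelter_name = "note", ner = "note")

#' Fuse evidence flags into per-patient source sets
#'
#' @param flags \code{data.table} of evidence flags: patient_id, source
#'   (diagnosis/address/note), method, provenance. Duplicate flags are
#'   idempotent. A flag whose method is inconsistent with its source, or
#'   whose patient is not in \code{patients}, is a referential-integrity
#'   error.
#' @param patients character vector of all patient ids (the population).
#' @return \code{data.table} one row per patient: patient_id, D, A, N
#'   (logicals), n_sources.
#' @export
fuse <- function(flags, patients) {
  flags <- as.data.table(flags)
  if (nrow(flags)) {
    bad_src <- method_source_map[flags$method] != flags$source
    if (any(is.na(bad_src) | bad_src)) {
      stop("flag method inconsistent with source: ",
           paste(unique(paste0(flags$method, "/", flags$source)[is.na(bad_src) | bad_src]),
                 collapse = ", "))
    }
    orphan <- setdiff(flags$patient_id, patients)
    if (length(orphan)) {
      stop("evidence flag for unknown patient: ", paste(head(orphan, 5), collapse = ", "))
    }
  }
  out <- data.table(patient_id = patients, D = FALSE, A = FALSE, N = FALSE)
  if (nrow(flags)) {
    out[patient_id %in% flags[source == "diagnosis", patient_id], D := TRUE]
    out[patient_id %in% flags[source == "address", patient_id], A := TRUE]
    out[patient_id %in% flags[source == "note", patient_id], N := TRUE]
  }
  out[, n_sources := D + A + N]
  out
}

#' Venn partition of the identification sets
#'
#' @param sets output of \code{\link{fuse}} (or any table with logical
#'   D/A/N columns).
#' @return named list: the 7 region counts (\code{D_only}, \code{A_only},
#'   \code{N_only}, \code{DA}, \code{DN}, \code{AN}, \code{DAN}), the
#'   \code{union} size and per-source \code{totals}. Regions always sum to
#'   the union; each source total is the sum of its 4 regions.
#' @export
venn <- function(sets) {
  s <- as.data.table(sets)
  cnt <- function(d, a, n) s[D == d & A == a & N == n, .N]
  p <- list(
    D_only = cnt(TRUE, FALSE, FALSE),
    A_only = cnt(FALSE, TRUE, FALSE),
    N_only = cnt(FALSE, FALSE, TRUE),
    DA = cnt(TRUE, TRUE, FALSE),
    DN = cnt(TRUE, FALSE, TRUE),
    AN = cnt(FALSE, TRUE, TRUE),
    DAN = cnt(TRUE, TRUE, TRUE))
  p$union <- sum(unlist(p))
  p$totals <- c(D = p$D_only + p$DA + p$DN + p$DAN,
                A = p$A_only + p$DA + p$AN + p$DAN,
                N = p$N_only + p$DN + p$AN + p$DAN)
  p
}

#' Build a Venn partition directly from region counts
#'
#' For published-count fixtures where only the partition, not patient-level
#' rows, is available.
#'
#' @param D_only,A_only,N_only,DA,DN,AN,DAN nonnegative region counts.
#' @return partition list as from \code{\link{venn}}.
#' @export
venn_from_regions <- function(D_only, A_only, N_only, DA, DN, AN, DAN) {
  p <- list(D_only = D_only, A_only = A_only, N_only = N_only,
            DA = DA, DN = DN, AN = AN, DAN = DAN)
  stopifnot(all(unlist(p) >= 0))
  p$union <- sum(unlist(p))
  p$totals <- c(D = D_only + DA + DN + DAN,
                A = A_only + DA + AN + DAN,
                N = N_only + DN + AN + DAN)
  p
}

#' Coverage summary of a Venn partition
#'
#' All percentages at 1 decimal place, round-half-up. Reports the union
#' prevalence in the population, per-source coverage of the union, the
#' codes-only view (what fraction diagnosis codes alone identify) and its
#' complement split into address-only / notes-only / address-and-notes
#' without codes, and the single-source fraction.
#'
#' @param partition from \code{\link{venn}} or
#'   \code{\link{venn_from_regions}}.
#' @param population_size total population (>= union).
#' @return named list of counts and percentages.
#' @export
coverage_summary <- function(partition, population_size) {
  p <- partition
  stopifnot(p$union <= population_size)
  u <- p$union
  list(
    population = population_size,
    union = u,
    union_prevalence_pct = pct(u, population_size),
    no_evidence_pct = pct(population_size - u, population_size),
    coverage_pct = c(D = pct(p$totals[["D"]], u),
                     A = pct(p$totals[["A"]], u),
                     N = pct(p$totals[["N"]], u)),
    codes_coverage_pct = pct(p$totals[["D"]], u),
    complement_pct = pct(u - p$totals[["D"]], u),
    complement_split_pct = c(
      address_only = pct(p$A_only, u),
      notes_only = pct(p$N_only, u),
      address_and_notes = pct(p$AN, u)),
    single_source_pct = pct(p$D_only + p$A_only + p$N_only, u),
    all_three = p$DAN,
    all_three_pct = pct(p$DAN, u)
  )
}

#' Census-tract comparison: codes-only versus all-sources identification
#'
#' Patients lacking a tract id aggregate into a sentinel "unknown" tract
#' rather than being dropped.
#'
#' @param sets output of \code{\link{fuse}} with a \code{tract} column
#'   merged in (or pass \code{tracts} separately).
#' @param tracts optional \code{data.table(patient_id, tract)}.
#' @return list: per-tract table (tract, n_codes_only, n_all_sources,
#'   increase), \code{n_missed} (tracts invisible under codes-only),
#'   \code{n_increased}, \code{mean_increase}, \code{max_increase}. Per-tract
#'   increases sum to |union| - |D|.
#' @export
tract_compare <- function(sets, tracts = NULL) {
  s <- as.data.table(sets)
  if (!is.null(tracts)) {
    s <- merge(s, as.data.table(tracts), by = "patient_id", all.x = TRUE)
  }
  if (!"tract" %in% names(s)) stop("no tract column or tracts table supplied")
  s[, tract := fifelse(is.na(as.character(tract)), "unknown", as.character(tract))]
  per <- s[, .(n_codes_only = sum(D), n_all_sources = sum(D | A | N)), by = tract]
  per[, increase := n_all_sources - n_codes_only]
  pos <- per[n_all_sources > 0]
  list(per_tract = per[],
       n_tracts = nrow(pos),
       n_missed = pos[n_codes_only == 0, .N],
       n_increased = per[increase > 0, .N],
       mean_increase = if (per[increase > 0, .N]) mean(per[increase > 0, increase]) else 0,
       max_increase = if (nrow(per)) max(per$increase) else 0,
       total_increase = sum(per$increase))
}
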