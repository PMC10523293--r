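## Orchestration: generate-or-load data, run the three evidence channels,
## fuse, compute statistics, and emit a report bundle mirroring the standard
## result surfaces (cohort demographics, housing-by-source, notes-by-method,
## demographics-by-source, Venn counts, tract deltas, concordance, and — in
## synthetic mode — truth-based precision/recall).

#' Build a run configuration
#'
#' @param mode "synthetic" (generate data from \code{gen}) or "files" (read
#'   a dataset directory written by \code{\link{write_dataset}}).
#' @param gen generator config for synthetic mode.
#' @param data_dir dataset directory for files mode.
#' @param out optional output directory; when given, the bundle is written
#'   as CSV/JSON.
#' @param directory_path,lexicon_path,vocabulary_path optional overrides for
#'   the resource directory, lexicon, and concept vocabulary files.
#' @param fuzzy_addresses,historical_counts,third_party_counts,
#'   include_treatment,run_ner feature toggles.
#' @param adjudication_n notes per method stratum for the review sample.
#' @param seed seed for sampling stages (adjudication, simulated raters).
#' @return validated config list.
#' @export
run_config <- function(mode = c("synthetic", "files"), gen = gen_config(),
                       data_dir = NULL, out = NULL,
                       directory_path = NULL, lexicon_path = NULL,
                       vocabulary_path = NULL,
                       fuzzy_addresses = TRUE, historical_counts = TRUE,
                       third_party_counts = FALSE, include_treatment = TRUE,
                       run_ner = TRUE, adjudication_n = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files" && (is.null(data_dir) || !dir.exists(data_dir))) {
    stop_config("files mode requires an existing data_dir")
  }
  for (p in c(directory_path, lexicon_path, vocabulary_path)) {
    if (!is.null(p) && !file.exists(p)) stop_config("missing path: ", p)
  }
  as.list(environment())
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

#' Run the full multi-source housing-instability pipeline
#'
#' @param config from \code{\link{run_config}}.
#' @return report bundle (list of tables and statistics); if
#'   \code{config$out} is set, also written to disk.
#' @export
run_pipeline <- function(config = run_config()) {
  directory <- load_resource_directory(config$directory_path)
  lexicon <- load_lexicon(config$lexicon_path)
  vocab <- load_vocabulary(config$vocabulary_path)

  ds <- if (config$mode == "synthetic") {
    generate_dataset(config$gen, directory)
  } else read_dataset(config$data_dir)
  stage_log("load", 0L, nrow(ds$patients))

  ## channel 1: diagnosis codes
  dx_flags <- detect_housing_codes_all(ds$encounters)
  stage_log("diagnosis", nrow(ds$encounters), nrow(dx_flags))

  ## channel 2: addresses
  adr <- detect_address_evidence(ds$addresses, directory,
                                 fuzzy = config$fuzzy_addresses,
                                 include_treatment = config$include_treatment)
  stage_log("address", nrow(ds$addresses), nrow(adr$flags))

  ## channel 3: notes (keyword + shelter, then NER + linker)
  nt <- detect_note_evidence(ds$notes, directory, lexicon,
                             historical_counts = config$historical_counts,
                             third_party_counts = config$third_party_counts)
  ner <- if (config$run_ner) {
    detect_ner_evidence(ds$notes, vocab, lexicon)
  } else list(flags = data.table(patient_id = character(), source = character(),
                                 method = character(), provenance = character()),
              n_recognized_unlinked = 0L, n_linked = 0L)
  stage_log("notes", nrow(ds$notes), nrow(nt$flags) + nrow(ner$flags))

  flags <- rbindlist(list(
    dx_flags,
    adr$flags[, .(patient_id, source, method, provenance)],
    nt$flags, ner$flags[, .(patient_id, source, method, provenance)]),
    use.names = TRUE)

  ## fusion
  sets <- fuse(flags, ds$patients$patient_id)
  part <- venn(sets)
  cov <- coverage_summary(part, nrow(ds$patients))
  tracts <- tract_compare(sets, ds$patients[, .(patient_id, tract)])
  stage_log("fusion", nrow(flags), part$union)

  ## cohort classification from codes
  sud <- classify_sud_all(ds$encounters)
  pats <- merge(ds$patients, sud, by = "patient_id", all.x = TRUE)
  pats[is.na(sud_type), sud_type := "none"]
  pats <- merge(pats, sets, by = "patient_id")
  pats[, any_evidence := D | A | N]
  pats[, poisoning := patient_id %in%
         ds$encounters[match_any(code, c("T40.", "T43.6")), patient_id]]

  tables <- list(
    demographics = demographics_table(pats),
    housing_by_source = housing_by_source_table(pats),
    notes_by_method = notes_method_table(rbindlist(list(nt$flags, ner$flags)), pats),
    demographics_by_source = demographics_by_source_table(pats),
    venn = part, coverage = cov, tract_deltas = tracts,
    ner_linking = list(n_linked = ner$n_linked,
                       n_recognized_unlinked = ner$n_recognized_unlinked)
  )

  ## association tests on the report tables
  tables$tests <- association_tests(pats)

  ## adjudication sample + (synthetic mode) simulated three-rater review
  mentions <- nt$mentions
  concord <- NULL
  if (nrow(mentions)) {
    sheet <- sample_adjudication(mentions, ds$notes, config$adjudication_n,
                                 seed = config$seed)
    concord <- list(sheet_n = nrow(sheet),
                    by_method = as.list(table(sheet$method)))
    if (config$mode == "synthetic" && nrow(sheet)) {
      rated <- simulate_ratings(sheet, ds$truth, seed = config$seed)
      concord$fleiss_kappa <- fleiss_kappa(rated)
      concord$unanimity_pct <- round_half_up(100 * unanimity_rate(rated))
    }
  }
  tables$concordance <- concord

  if (config$mode == "synthetic") {
    tables$truth_eval <- evaluate_against_truth(flags, ds$truth)
  }
  tables$meta <- list(seed = config$seed,
                      mode = config$mode,
                      n_patients = nrow(ds$patients),
                      config_hash = config_hash(config))

  ## reconciliation: every table's totals trace back to the patient count
  stopifnot(cov$union + (cov$population - cov$union) == nrow(ds$patients))

  if (!is.null(config$out)) write_bundle(tables, config$out)
  tables
}

config_hash <- function(config) {
  ## the output location is not part of the scientific configuration
  config <- config[setdiff(names(config), "out")]
  s <- jsonlite::toJSON(config[!vapply(config, is.function, logical(1))],
                        auto_unbox = TRUE, force = TRUE)
  ## tiny stable polynomial string hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

demographics_table <- function(pats) {
  long <- rbindlist(lapply(c("sex", "race", "age_band"), function(v) {
    x <- pats[, .N, by = .(level = get(v), sud_type)]
    x[, variable := v]
    x
  }))
  wide <- data.table::dcast(long, variable + level ~ sud_type, value.var = "N", fill = 0L)
  wide[, total := as.integer(rowSums(.SD)), .SDcols = setdiff(names(wide), c("variable", "level"))]
  wide[]
}

housing_by_source_table <- function(pats) {
  src_order <- c("any", "diagnosis", "address", "notes", "none")
  rows <- list(any = pats[any_evidence == TRUE], diagnosis = pats[D == TRUE],
               address = pats[A == TRUE], notes = pats[N == TRUE],
               none = pats[any_evidence == FALSE])
  out <- rbindlist(lapply(src_order, function(nm) {
    r <- rows[[nm]][, .N, by = sud_type]
    r[, source := nm]
    r
  }))
  wide <- data.table::dcast(out, source ~ sud_type, value.var = "N", fill = 0L)
  ## a source with zero patients still gets a (zero) row
  wide <- merge(data.table(source = src_order), wide, by = "source",
                all.x = TRUE, sort = FALSE)
  for (j in setdiff(names(wide), "source")) {
    data.table::set(wide, which(is.na(wide[[j]])), j, 0L)
  }
  wide[, total := as.integer(rowSums(.SD)), .SDcols = setdiff(names(wide), "source")]
  wide[match(src_order, source)]
}

notes_method_table <- function(note_flags, pats) {
  if (nrow(note_flags) == 0L) {
    return(data.table(method = character(), n_patients = integer()))
  }
  nf <- merge(unique(note_flags[, .(patient_id, method)]),
              pats[, .(patient_id, sud_type)], by = "patient_id")
  wide <- data.table::dcast(nf[, .N, by = .(method, sud_type)],
                            method ~ sud_type, value.var = "N", fill = 0L)
  wide[, n_patients := as.integer(rowSums(.SD)), .SDcols = setdiff(names(wide), "method")]
  wide[]
}

demographics_by_source_table <- function(pats) {
  srcs <- list(diagnosis = quote(D), address = quote(A), notes = quote(N))
  rbindlist(lapply(names(srcs), function(s) {
    sub <- pats[eval(srcs[[s]]) == TRUE]
    long <- rbindlist(lapply(c("sex", "race", "age_band", "poisoning"), function(v) {
      x <- sub[, .N, by = .(level = as.character(get(v)))]
      x[, variable := v]
      x
    }))
    long[, source := s]
    long
  }))
}

## chi-squared (sex, race, age by SUD type) and Fisher (source by SUD type)
association_tests <- function(pats) {
  pats3 <- pats[sud_type %in% c("stimulant_only", "opioid_only", "both")]
  out <- list()
  for (v in c("sex", "race", "age_band")) {
    tab <- as.matrix(table(pats3[[v]], pats3$sud_type))
    out[[paste0("chisq_", v)]] <- tryCatch({
      r <- chi_squared(tab)
      list(test = "chi_squared", variable = v, statistic = r$statistic,
           df = r$df, p = r$p)
    }, error = function(e) list(test = "chi_squared", variable = v,
                                error = conditionMessage(e)))
  }
  src_long <- rbindlist(list(
    pats3[D == TRUE, .(src = "diagnosis", sud_type)],
    pats3[A == TRUE, .(src = "address", sud_type)],
    pats3[N == TRUE, .(src = "note", sud_type)]))
  if (nrow(src_long)) {
    tab <- as.matrix(table(src_long$src, src_long$sud_type))
    out$fisher_source <- tryCatch({
      f <- fisher_exact(tab, monte_carlo = TRUE, B = 2e4, seed = 7L)
      c(list(test = "fisher_exact", variable = "source_by_sud"), f)
    }, error = function(e) list(test = "fisher_exact", error = conditionMessage(e)))
  }
  out
}

#' Simulate a three-rater adjudication of a review sheet
#'
#' Ground-truth correctness of an extraction is whether the mention's
#' patient is truly housing-unstable; each rater independently rates
#' "correct" with the given accuracy when the extraction is correct, and
#' "incorrect" with that accuracy otherwise. Returns the items x 2 rating
#' count matrix for \code{\link{fleiss_kappa}}.
#'
#' @param sheet review sheet from \code{\link{sample_adjudication}}.
#' @param truth truth table from the generator.
#' @param accuracy per-rater agreement with ground truth (default 0.85,
#'   chosen as a realistic expert-reviewer accuracy on ambiguous
#'   housing-status notes).
#' @param raters number of raters (default 3).
#' @param seed RNG seed.
#' @return n x 2 integer matrix, columns (correct, incorrect).
#' @export
simulate_ratings <- function(sheet, truth, accuracy = 0.85, raters = 3L, seed = 1L) {
  set.seed(seed + 1L)
  is_correct <- truth$housing_unstable[match(sheet$patient_id, truth$patient_id)]
  votes_correct <- rbinom(nrow(sheet), raters, ifelse(is_correct, accuracy, 1 - accuracy))
  m <- cbind(correct = votes_correct, incorrect = raters - votes_correct)
  rownames(m) <- sheet$note_id
  m
}

#' Evaluate pipeline flags against planted ground truth
#'
#' @param flags evidence-flag table.
#' @param truth generator truth table.
#' @return \code{data.table} of precision/recall/F1 per source, per method,
#'   and for the union; \code{recall} is against truly unstable patients,
#'   \code{recall_documented} against patients the generator actually
#'   documented via that source (should be 1 when detection is lossless).
#' @export
evaluate_against_truth <- function(flags, truth) {
  flags <- as.data.table(flags)
  truth <- as.data.table(truth)
  pos <- truth[housing_unstable == TRUE, patient_id]
  doc_col <- c(diagnosis = "doc_diagnosis", address = "doc_address", note = "doc_note")
  score <- function(found, positives, documented = NULL) {
    tp <- length(intersect(found, positives))
    prec <- if (length(found)) tp / length(found) else NA_real_
    rec <- if (length(positives)) tp / length(positives) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) 2 * prec * rec / (prec + rec) else NA_real_
    rd <- if (!is.null(documented) && length(documented)) {
      length(intersect(found, documented)) / length(documented)
    } else NA_real_
    list(n_flagged = length(found), precision = prec, recall = rec, f1 = f1,
         recall_documented = rd)
  }
  rows <- list()
  for (s in c("diagnosis", "address", "note")) {
    found <- unique(flags[source == s, patient_id])
    documented <- truth[get(doc_col[[s]]) == TRUE & housing_unstable == TRUE, patient_id]
    rows[[paste0("source_", s)]] <- c(list(unit = paste0("source:", s)),
                                      score(found, pos, documented))
  }
  for (m in unique(flags$method)) {
    found <- unique(flags[method == m, patient_id])
    rows[[paste0("method_", m)]] <- c(list(unit = paste0("method:", m)),
                                      score(found, pos))
  }
  rows$union <- c(list(unit = "union"), score(unique(flags$patient_id), pos))
  rbindlist(rows, fill = TRUE)
}

write_bundle <- function(tables, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("demographics", "housing_by_source", "notes_by_method",
               "demographics_by_source")) {
    if (!is.null(tables[[nm]])) fwrite(tables[[nm]], file.path(out, paste0(nm, ".csv")))
  }
  if (!is.null(tables$truth_eval)) fwrite(tables$truth_eval, file.path(out, "truth_eval.csv"))
  fwrite(tables$tract_deltas$per_tract, file.path(out, "tract_counts.csv"))
  json <- tables
  json$demographics <- json$housing_by_source <- json$notes_by_method <- NULL
  json$demographics_by_source <- json$truth_eval <- NULL
  json$tract_deltas$per_tract <- NULL
  jsonlite::write_json(json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(out)
}
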