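## Synthetic EHR generator with planted housing-instability ground truth.
## Emulates the statistical structure the analysis assumes — SUD cohort mix
## and demographics, per-source documentation of housing instability,
## negated/historical/third-party note phrasings, shelter-by-name and
## literal-"homeless" and generic addresses, and tract assignment — at desk
## scale. Same config + seed => identical dataset.

#' Build a generator configuration
#'
#' Defaults state the world the generator emulates: 29.2% housing-instability
#' prevalence in an SUD population, per-source documentation sensitivities
#' ordered notes > diagnosis codes > addresses (0.7 / 0.6 / 0.17, chosen so
#' the synthetic Venn structure qualitatively reproduces the published
#' pattern: notes the largest identification set, addresses the smallest),
#' small false-documentation noise among stably housed patients, and a
#' heavy-tailed notes-per-patient count (negative binomial, mode 1,
#' truncated to [1, cap]) standing in for the real distribution whose full
#' scale (average 945 notes/patient) is infeasible at desk scale.
#'
#' @param n_patients number of patients.
#' @param cohort_mix probabilities over stimulant / opioid / both (sum 1).
#' @param housing_prevalence fraction truly housing-unstable.
#' @param sensitivity named vector: probability a truly unstable patient is
#'   documentable via diagnosis / address / note.
#' @param specificity_noise named vector: false-documentation rate per
#'   source among stable patients.
#' @param negation_rate,history_rate,third_party_rate fractions of
#'   additional generated housing mentions rendered in negated / historical
#'   / third-party templates.
#' @param distractor_rate probability a patient without note documentation
#'   still carries a non-evidential (negated or third-party) housing
#'   mention.
#' @param oov_rate probability a note-documented patient also has an
#'   out-of-vocabulary housing phrasing (e.g. "couch surfing") that
#'   dictionary NER recognizes but cannot link.
#' @param n_tracts number of synthetic census tracts (integer ids).
#' @param notes_nb list(size, mu) negative-binomial parameters for notes per
#'   patient; \code{notes_cap} truncates the tail.
#' @param p_generic_address fraction of the population with a generic
#'   placeholder address (city/state only).
#' @param p_literal_homeless among address-documented patients, fraction
#'   realized as a literal "HOMELESS" first address line (the rest get a
#'   resource address).
#' @param p_shelter_mention among evidential note mentions, fraction
#'   realized as shelter-by-name rather than keyword phrasing.
#' @param p_poisoning probability a patient has a poisoning episode code.
#' @param correlated_sources optional shared-latent-severity correlation in
#'   [0, 1); 0 (default) makes per-source documentation independent given
#'   truth.
#' @param seed RNG seed.
#' @return validated config list (class \code{hinstab_gen_config}).
#' @export
gen_config <- function(n_patients = 5000,
                       cohort_mix = c(stimulant = 0.40, opioid = 0.45, both = 0.15),
                       housing_prevalence = 0.292,
                       sensitivity = c(diagnosis = 0.6, address = 0.17, note = 0.7),
                       specificity_noise = c(diagnosis = 0.002, address = 0.002, note = 0.004),
                       negation_rate = 0.10, history_rate = 0.08,
                       third_party_rate = 0.03, distractor_rate = 0.05,
                       oov_rate = 0.05,
                       n_tracts = 100,
                       notes_nb = list(size = 0.4, mu = 5), notes_cap = 50,
                       p_generic_address = 0.082,
                       p_literal_homeless = 0.066,
                       p_shelter_mention = 0.35,
                       p_poisoning = 0.2,
                       correlated_sources = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  rate_ok <- function(x) num_ok(x) && all(x >= 0 & x <= 1)
  if (!num_ok(cfg$n_patients) || cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients))
    stop_config("n_patients must be a nonnegative integer")
  if (!rate_ok(cohort_mix) || abs(sum(cohort_mix) - 1) > 1e-9)
    stop_config("cohort_mix must be probabilities summing to 1")
  if (!setequal(names(cohort_mix), c("stimulant", "opioid", "both")))
    stop_config("cohort_mix needs names stimulant/opioid/both")
  for (nm in c("housing_prevalence", "negation_rate", "history_rate",
               "third_party_rate", "distractor_rate", "oov_rate",
               "p_generic_address", "p_literal_homeless", "p_shelter_mention",
               "p_poisoning")) {
    if (!rate_ok(cfg[[nm]])) stop_config(nm, " must be in [0,1]")
  }
  if (cfg$negation_rate + cfg$history_rate + cfg$third_party_rate > 1)
    stop_config("mention label rates exceed 1")
  for (nm in c("sensitivity", "specificity_noise")) {
    if (!rate_ok(cfg[[nm]]) || !setequal(names(cfg[[nm]]), c("diagnosis", "address", "note")))
      stop_config(nm, " must be rates named diagnosis/address/note")
  }
  if (!num_ok(cfg$n_tracts) || cfg$n_tracts < 1) stop_config("n_tracts must be positive")
  if (!rate_ok(cfg$correlated_sources) || cfg$correlated_sources >= 1)
    stop_config("correlated_sources must be in [0,1)")
  if (!num_ok(cfg$seed)) stop_config("seed must be finite numeric")
  structure(cfg, class = "hinstab_gen_config")
}

## --- template bank ---------------------------------------------------------

#' Note sentence templates by mention label
#'
#' \code{{NAME}} in shelter templates is substituted with a directory
#' resource name. Filler ("none") sentences contain no lexicon term and no
#' resource alias.
#'
#' @return named list of template character vectors.
#' @export
template_bank <- function() {
  list(
    affirmed = c(
      "Patient is homeless.",
      "Patient reports unstable housing at this time.",
      "Pt has been living on the streets for the past month.",
      "She is currently homeless and staying with acquaintances.",
      "Patient endorses housing insecurity."),
    negated = c(
      "Asked if she was homeless and she denied.",
      "Patient denies being homeless.",
      "No evidence of unstable housing.",
      "Patient is not homeless and lives with family."),
    historical = c(
      "History of homelessness documented in prior records.",
      "Patient was previously homeless but is now housed.",
      "Hx of unstable housing in the past."),
    third_party = c(
      "Found a homeless person sleeping in her bathroom.",
      "Her boyfriend is homeless and stays elsewhere.",
      "Family member reports being homeless herself."),
    shelter_name = c(
      "Discharged to {NAME}.",
      "Lives at {NAME}.",
      "Transported from {NAME} this morning.",
      "Currently staying at {NAME}."),
    oov = c(
      "Patient has been couch surfing for several weeks.",
      "Reports sleeping rough since losing his apartment lease."),
    none = c(
      "Vital signs stable.",
      "Medication reconciliation completed.",
      "Patient seen for routine follow up.",
      "Tolerating diet without issue.",
      "Plan discussed with patient.",
      "Follow up in two weeks.",
      "Labs reviewed and within normal limits.",
      "Patient resting comfortably."))
}

#' Render a clinical note from mention labels
#'
#' One realized sentence per label, shuffled among filler sentences. For
#' \code{shelter_name} labels a resource name from the directory is
#' substituted. Templates within one note are sampled without replacement
#' per label so each persisted label back-matches exactly one sentence.
#'
#' @param labels character vector of labels (subset of affirmed, negated,
#'   historical, third_party, shelter_name, oov; empty vector or "none"
#'   gives a filler-only note).
#' @param resources resource directory rows used for \code{shelter_name}
#'   substitution; a \code{resource_id} is drawn per shelter label.
#' @param templates template bank.
#' @param n_filler number of filler sentences.
#' @return list: \code{text}, and \code{realized} (data.table label,
#'   sentence, resource_id).
#' @export
render_note <- function(labels, resources = NULL, templates = template_bank(),
                        n_filler = 2L) {
  labels <- labels[labels != "none"]
  bad <- setdiff(labels, names(templates))
  if (length(bad)) stop("no template for label: ", paste(bad, collapse = ", "))
  realized <- list()
  for (lb in unique(labels)) {
    k <- sum(labels == lb)
    bank <- templates[[lb]]
    if (k > length(bank)) k <- length(bank)   # cap repeats at bank size
    picks <- sample(bank, k)
    for (p in picks) {
      rid <- NA_character_
      if (lb == "shelter_name") {
        if (is.null(resources) || nrow(resources) == 0L)
          stop("shelter_name label requires a resource directory")
        ri <- sample(nrow(resources), 1)
        rid <- resources$resource_id[ri]
        p <- gsub("{NAME}", resources$name[ri], p, fixed = TRUE)
      }
      realized[[length(realized) + 1L]] <- data.table(label = lb, sentence = p,
                                                      resource_id = rid)
    }
  }
  realized <- if (length(realized)) rbindlist(realized) else
    data.table(label = character(), sentence = character(), resource_id = character())
  filler <- sample(templates$none, min(n_filler, length(templates$none)))
  all_s <- c(realized$sentence, filler)
  ord <- sample(length(all_s))
  list(text = paste(all_s[ord], collapse = " "), realized = realized)
}

## --- code pools ------------------------------------------------------------

sud_code_pool <- list(
  stimulant = c("F14.10", "F14.20", "F14.23", "F15.10", "F15.20", "F15.929"),
  opioid = c("F11.10", "F11.20", "F11.23", "F11.90"))
poisoning_pool <- list(
  stimulant = c("T40.5X1A", "T43.621A", "T43.631A"),
  opioid = c("T40.0X1A", "T40.1X1A", "T40.2X1A", "T40.2X2A", "T40.3X1A",
             "T40.4X1A", "T40.601A"))
z59_pool <- c("Z59.0", "Z59.00", "Z59.01", "Z59.1", "Z59.811", "Z59.89")
filler_code_pool <- c("I10", "E11.9", "J45.909", "K21.9", "N39.0", "M54.5",
                      "R07.9", "J06.9", "E78.5", "F32.9", "F41.9", "G47.00",
                      "B18.2", "L03.115", "R51.9")

street_names <- c("Maplewood", "Oakridge", "Birchfield", "Cedarbrook",
                  "Willowmere", "Elmhurst", "Ashgrove", "Pinecrest",
                  "Sycamore Glen", "Juniper Hollow", "Larkspur", "Foxglove",
                  "Meadowlark", "Thornberry", "Clearwater")
street_suffixes <- c("St", "Ave", "Rd", "Dr", "Ln", "Ct", "Blvd")

## --- demographics ----------------------------------------------------------

## Cohort-conditional demographic distributions, anchored to the published
## contrasts (stimulant group more male, 59.7% vs 47.2%, and more Black
## patients, 19% vs 5%, than the opioid group); remaining cells are
## realistic desk-scale choices, not reproductions.
demo_params <- list(
  stimulant = list(p_male = 0.597,
                   race = c(White = 0.77, Black = 0.19, Other = 0.04),
                   age = c(`18-24` = 0.12, `25-34` = 0.30, `35-44` = 0.26,
                           `45-54` = 0.16, `55-64` = 0.11, `65+` = 0.05)),
  opioid = list(p_male = 0.472,
                race = c(White = 0.91, Black = 0.05, Other = 0.04),
                age = c(`18-24` = 0.06, `25-34` = 0.26, `35-44` = 0.26,
                        `45-54` = 0.18, `55-64` = 0.14, `65+` = 0.10)),
  both = list(p_male = 0.55,
              race = c(White = 0.84, Black = 0.12, Other = 0.04),
              age = c(`18-24` = 0.09, `25-34` = 0.31, `35-44` = 0.28,
                      `45-54` = 0.17, `55-64` = 0.11, `65+` = 0.04)))

sample_cat <- function(n, probs) {
  if (n == 0L) return(character())
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

## --- generator -------------------------------------------------------------

#' Generate a synthetic EHR dataset with planted ground truth
#'
#' Each truly unstable patient is documented, per source independently (or
#' with shared-latent correlation if configured), with the configured
#' sensitivity; documentation is realized as Z59* codes, a resource or
#' literal-"HOMELESS" address, or housing-mention sentences woven into
#' notes. Every patient carries at least one SUD-defining code matching
#' their cohort. Stable patients can be falsely documented at the
#' specificity-noise rate (address noise is realized only as a resource
#' address, never literal "HOMELESS"). Ground-truth labels — including the
#' per-note mention labels and their realized sentences — are persisted
#' alongside the dataset.
#'
#' @param config from \code{\link{gen_config}}.
#' @param directory resource directory
#'   (default: \code{\link{load_resource_directory}()}).
#' @return list of \code{data.table}s: patients, encounters, addresses,
#'   notes, truth, truth_mentions; plus the config.
#' @export
generate_dataset <- function(config = gen_config(),
                             directory = load_resource_directory()) {
  stopifnot(inherits(config, "hinstab_gen_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  empty <- function(...) data.table(...)
  if (n == 0L) {
    return(list(
      patients = empty(patient_id = character(), sex = character(),
                       race = character(), age_band = character(),
                       cohort = character(), tract = integer()),
      encounters = empty(patient_id = character(), encounter_id = character(),
                         date = character(), code = character()),
      addresses = empty(patient_id = character(), line1 = character(),
                        line2 = character(), city = character(),
                        state = character(), zip = character()),
      notes = empty(note_id = character(), patient_id = character(),
                    date = character(), text = character()),
      truth = empty(patient_id = character(), housing_unstable = logical(),
                    doc_diagnosis = logical(), doc_address = logical(),
                    doc_note = logical(), noise_diagnosis = logical(),
                    noise_address = logical(), noise_note = logical()),
      truth_mentions = empty(note_id = character(), patient_id = character(),
                             label = character(), sentence = character(),
                             resource_id = character()),
      config = config))
  }
  pid <- sprintf("P%05d", seq_len(n))

  ## cohort, demographics, tract
  cohort <- sample_cat(n, config$cohort_mix)
  sex <- character(n); race <- character(n); age <- character(n)
  for (co in names(demo_params)) {
    idx <- which(cohort == co)
    dp <- demo_params[[co]]
    sex[idx] <- ifelse(runif(length(idx)) < dp$p_male, "M", "F")
    race[idx] <- sample_cat(length(idx), dp$race)
    age[idx] <- sample_cat(length(idx), dp$age)
  }
  tract <- sample.int(config$n_tracts, n, replace = TRUE)
  patients <- data.table(patient_id = pid, sex = sex, race = race,
                         age_band = age, cohort = cohort, tract = tract)

  ## ground truth + per-source documentation
  unstable <- runif(n) < config$housing_prevalence
  rho <- config$correlated_sources
  if (rho > 0) {
    ## shared latent severity: mix each source's uniform with a common one
    z <- runif(n)
    u_src <- function() rho * z + (1 - rho) * runif(n)
  } else u_src <- function() runif(n)
  doc <- sapply(c("diagnosis", "address", "note"), function(s) {
    unstable & (u_src() < config$sensitivity[[s]])
  })
  noise <- sapply(c("diagnosis", "address", "note"), function(s) {
    !unstable & (runif(n) < config$specificity_noise[[s]])
  })
  eff <- doc | noise   # realized documentation per source
  truth <- data.table(patient_id = pid, housing_unstable = unstable,
                      doc_diagnosis = eff[, "diagnosis"],
                      doc_address = eff[, "address"],
                      doc_note = eff[, "note"],
                      noise_diagnosis = noise[, "diagnosis"],
                      noise_address = noise[, "address"],
                      noise_note = noise[, "note"])

  ## encounters with ICD codes: one code per encounter; every patient gets
  ## their cohort-defining code(s), optional poisoning and Z59 codes, and
  ## filler codes up to a Poisson-sized encounter count
  n_enc <- 1L + rpois(n, 1.5)
  pois <- runif(n) < config$p_poisoning
  codes <- vector("list", n)
  for (i in seq_len(n)) {
    co <- cohort[i]
    cc <- switch(co,
      stimulant = sample(sud_code_pool$stimulant, 1),
      opioid = sample(sud_code_pool$opioid, 1),
      both = c(sample(sud_code_pool$stimulant, 1), sample(sud_code_pool$opioid, 1)))
    if (pois[i]) {
      pp <- switch(co,
        stimulant = poisoning_pool$stimulant,
        opioid = poisoning_pool$opioid,
        both = c(poisoning_pool$stimulant, poisoning_pool$opioid))
      cc <- c(cc, sample(pp, 1))
    }
    if (eff[i, "diagnosis"]) cc <- c(cc, sample(z59_pool, 1))
    n_fill <- max(0L, n_enc[i] - length(cc))
    if (n_fill > 0) cc <- c(cc, sample(filler_code_pool, n_fill, replace = TRUE))
    codes[[i]] <- sample(cc)   # shuffle order across the patient's encounters
  }
  enc_pid <- rep(pid, lengths(codes))
  encounters <- data.table(
    patient_id = enc_pid,
    encounter_id = sprintf("E%07d", seq_along(enc_pid)),
    date = format(as.Date("2019-01-01") + sample.int(1200, length(enc_pid), replace = TRUE),
                  "%Y-%m-%d"),
    code = unlist(codes))

  ## addresses (one per patient: the most recent address on file)
  line1 <- character(n); line2 <- rep("", n)
  city <- rep("Lexington", n); state <- rep("KY", n); zip <- character(n)
  res_row <- sample.int(nrow(directory), n, replace = TRUE)
  lit <- runif(n) < config$p_literal_homeless
  generic <- runif(n) < config$p_generic_address
  for (i in seq_len(n)) {
    if (eff[i, "address"]) {
      if (doc[i, "address"] && lit[i]) {     # noise is never literal "HOMELESS"
        line1[i] <- "HOMELESS"; zip[i] <- "40508"
      } else {
        r <- directory[res_row[i]]
        line1[i] <- r$line1; city[i] <- r$city; state[i] <- r$state; zip[i] <- r$zip
      }
    } else if (generic[i]) {
      line1[i] <- ""; zip[i] <- ""
    } else {
      line1[i] <- paste(sample(100:2999, 1), sample(street_names, 1),
                        sample(street_suffixes, 1))
      zip[i] <- sample(c("40502", "40503", "40504", "40505", "40508",
                         "40509", "40511", "40514", "40515", "40517"), 1)
    }
  }
  addresses <- data.table(patient_id = pid, line1 = line1, line2 = line2,
                          city = city, state = state, zip = zip)

  ## notes with planted mention labels
  n_notes <- pmin(pmax(rnbinom(n, size = config$notes_nb$size,
                               mu = config$notes_nb$mu), 1L), config$notes_cap)
  note_pid <- rep(pid, n_notes)
  note_id <- sprintf("N%07d", seq_along(note_pid))
  note_date <- format(as.Date("2019-01-01") + sample.int(1200, length(note_pid), replace = TRUE),
                      "%Y-%m-%d")
  ## mention plan per patient
  plan <- vector("list", n)
  extra_rates <- c(negated = config$negation_rate, historical = config$history_rate,
                   third_party = config$third_party_rate)
  p_extra_other <- max(0, 1 - sum(extra_rates))
  for (i in seq_len(n)) {
    lbl <- character()
    if (eff[i, "note"]) {
      ## guaranteed evidential mention
      lbl <- if (runif(1) < config$p_shelter_mention) "shelter_name" else "affirmed"
      ## additional mentions drawn from the full label distribution
      n_extra <- rpois(1, 0.6)
      if (n_extra > 0) {
        lbl <- c(lbl, sample_cat(n_extra, c(extra_rates, affirmed = p_extra_other)))
      }
      if (runif(1) < config$oov_rate) lbl <- c(lbl, "oov")
    } else if (runif(1) < config$distractor_rate) {
      ## non-evidential mention on an undocumented patient
      lbl <- sample(c("negated", "third_party"), 1,
                    prob = c(config$negation_rate + 1e-9, config$third_party_rate + 1e-9))
    }
    plan[[i]] <- lbl
  }
  ## assemble notes: mentions distributed over the patient's notes; notes
  ## without mentions are filler-only and built vectorized for speed
  note_start <- c(0L, cumsum(n_notes))
  n_all <- length(note_pid)
  tmpl <- template_bank()
  assign_i <- vector("list", n)
  for (i in seq_len(n)) {
    lbl <- plan[[i]]
    if (!length(lbl)) next
    idx <- (note_start[i] + 1L):(note_start[i] + n_notes[i])
    assign_i[[i]] <- idx[sample.int(length(idx), length(lbl),
                                    replace = length(lbl) > length(idx))]
  }
  ## filler-only notes, vectorized (1-3 filler sentences each)
  bank0 <- tmpl$none
  k_filler <- sample.int(3L, n_all, replace = TRUE)
  s1 <- bank0[sample.int(length(bank0), n_all, replace = TRUE)]
  s2 <- bank0[sample.int(length(bank0), n_all, replace = TRUE)]
  s3 <- bank0[sample.int(length(bank0), n_all, replace = TRUE)]
  texts <- paste0(s1, fifelse(k_filler >= 2L, paste0(" ", s2), ""),
                  fifelse(k_filler >= 3L, paste0(" ", s3), ""))
  ## mention-bearing notes rendered individually
  mention_rows <- list()
  for (i in seq_len(n)) {
    an <- assign_i[[i]]
    if (is.null(an)) next
    lbl <- plan[[i]]
    for (j in unique(an)) {
      rn <- render_note(lbl[an == j], directory, tmpl, n_filler = sample(1:3, 1))
      texts[j] <- rn$text
      if (nrow(rn$realized)) {
        mention_rows[[length(mention_rows) + 1L]] <-
          cbind(data.table(note_id = note_id[j], patient_id = pid[i]), rn$realized)
      }
    }
  }
  notes <- data.table(note_id = note_id, patient_id = note_pid,
                      date = note_date, text = texts)
  truth_mentions <- if (length(mention_rows)) rbindlist(mention_rows) else
    data.table(note_id = character(), patient_id = character(),
               label = character(), sentence = character(),
               resource_id = character())

  list(patients = patients, encounters = encounters, addresses = addresses,
       notes = notes, truth = truth, truth_mentions = truth_mentions,
       config = config)
}

#' Write a synthetic dataset to a directory
#'
#' Patients/encounters/addresses/truth/truth_mentions as CSV, notes as JSONL
#' (one object per line: note_id, patient_id, date, text), and the config
#' echoed as YAML (including the RNG seed).
#'
#' @param ds dataset from \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("patients", "encounters", "addresses", "truth", "truth_mentions")) {
    fwrite(ds[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  con <- file(file.path(dir, "notes.jsonl"), "w")
  on.exit(close(con))
  if (nrow(ds$notes)) {
    lines <- vapply(seq_len(nrow(ds$notes)), function(i) {
      jsonlite::toJSON(as.list(ds$notes[i]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  yaml::write_yaml(unclass(ds$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir dataset directory.
#' @return list of tables (same shape as \code{\link{generate_dataset}}).
#' @export
read_dataset <- function(dir) {
  out <- lapply(setNames(nm = c("patients", "encounters", "addresses",
                                "truth", "truth_mentions")), function(nm) {
    fread(file.path(dir, paste0(nm, ".csv")), colClasses = NULL)
  })
  lines <- readLines(file.path(dir, "notes.jsonl"))
  out$notes <- if (length(lines)) {
    rbindlist(lapply(lines, function(l) as.data.table(jsonlite::fromJSON(l))))
  } else data.table(note_id = character(), patient_id = character(),
                    date = character(), text = character())
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) out$config <- yaml::read_yaml(cfg_path)
  out
}
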