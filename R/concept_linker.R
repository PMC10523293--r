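## Concept channel: deterministic dictionary named-entity recognition over a
## concept vocabulary plus a knowledgebase linker that emits coded housing
## concepts. An adapter seam lets a trained external recognizer replace the
## dictionary scanner without changing downstream code. Entities recognized
## but absent from the vocabulary are counted as recognized_unlinked — the
## characteristic precision/recall trade of dictionary linking: matches are
## limited to the target vocabulary, which may lack housing phrasings.

norm_surface <- function(x) {
  trimws(gsub("\\s+", " ", gsub("[^a-z0-9 ]+", " ", tolower(x))))
}

#' Load a concept vocabulary
#'
#' Tab-separated schema: \code{concept_id}, \code{preferred_term},
#' \code{synonyms} (pipe-delimited), \code{housing_related} (0/1). The
#' package ships a synthetic mini-vocabulary with this schema in place of a
#' licensed terminology; a full user-supplied vocabulary uses the same
#' format. Surface forms are normalized (lowercase, punctuation-stripped,
#' whitespace-collapsed) identically at index build and query time; a
#' surface mapping to two concepts is a load error.
#'
#' @param path TSV path, or \code{NULL} for the shipped fixture.
#' @return list with \code{concepts} (data.table) and \code{index}
#'   (data.table surface -> concept_id).
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary_synthetic.tsv", package = "hinstab")
  }
  vc <- fread(path, sep = "\t", colClasses = list(character = 1:3))
  stopifnot(all(c("concept_id", "preferred_term", "synonyms", "housing_related") %in% names(vc)))
  vc[, housing_related := as.logical(as.integer(housing_related))]
  idx <- vc[, .(surface = norm_surface(c(preferred_term,
                                         strsplit(synonyms, "|", fixed = TRUE)[[1]]))),
            by = .(concept_id, housing_related)]
  idx <- idx[nzchar(surface)]
  idx <- unique(idx, by = c("surface", "concept_id"))
  dup <- idx$surface[duplicated(idx$surface)]
  if (length(dup)) {
    stop_config("vocabulary surface form maps to multiple concepts: ",
                paste(unique(dup), collapse = ", "))
  }
  list(concepts = vc, index = idx)
}

## hashed surface lookup; callers scanning many notes build it once
vocab_hash <- function(vocab, entity_patterns) {
  ht <- new.env(hash = TRUE, parent = emptyenv(),
                size = length(vocab$index$surface) + length(entity_patterns))
  for (s in vocab$index$surface) ht[[s]] <- TRUE
  for (s in norm_surface(entity_patterns)) if (nzchar(s)) ht[[s]] <- TRUE
  ht
}

default_entity_patterns <- function() {
  ## out-of-vocabulary housing phrasings the recognizer should still surface
  c("couch surfing", "couch surfer", "doubled up", "sleeping rough",
    "sleeping in his car", "sleeping in her car")
}

#' Extract candidate entity spans from a note
#'
#' Reference implementation: deterministic longest-match dictionary scanning
#' over 1-5 token windows against the vocabulary surface index, plus a list
#' of extra surface patterns for entities worth recognizing even when no
#' concept exists for them. A custom \code{recognizer(text)} returning a
#' \code{data.table(surface, start, end)} (0-based half-open spans) can be
#' supplied instead, so a trained model slots in without touching the
#' linker.
#'
#' @param text note text.
#' @param vocab vocabulary from \code{\link{load_vocabulary}}.
#' @param entity_patterns additional surface phrases to recognize.
#' @param recognizer optional external recognizer function (adapter seam).
#' @param max_window maximum token window (default 5).
#' @param .ht internal: prebuilt surface hash (see callers scanning corpora).
#' @return \code{data.table} with \code{surface}, \code{start}, \code{end}.
#' @export
extract_entities <- function(text, vocab, entity_patterns = default_entity_patterns(),
                             recognizer = NULL, max_window = 5L, .ht = NULL) {
  if (!is.null(recognizer)) {
    out <- as.data.table(recognizer(text))
    stopifnot(all(c("surface", "start", "end") %in% names(out)))
    return(out[, .(surface, start, end)])
  }
  ht <- .ht %||% vocab_hash(vocab, entity_patterns)
  raw <- extract_entities_raw(text, ht, max_window)
  data.table(surface = raw$surface, start = raw$start, end = raw$end)
}

## allocation-light scanner core shared by the table API and the corpus path
extract_entities_raw <- function(text, ht, max_window = 5L) {
  sents <- segment_raw(text)
  surfaces <- character(); starts <- integer(); ends <- integer()
  for (si in seq_along(sents$sentence)) {
    tok <- tokenize_raw(sents$sentence[si])
    n <- tok$n
    if (n == 0L) next
    tl <- tolower(tok$token)
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      for (k in seq(min(max_window, n - i + 1L), 1L)) {   # longest match first
        cand <- paste(tl[i:(i + k - 1L)], collapse = " ")
        if (!is.null(ht[[cand]])) { hit_len <- k; break }
      }
      if (hit_len > 0L) {
        st <- tok$start[i] + sents$start[si]
        en <- tok$end[i + hit_len - 1L] + sents$start[si]
        surfaces <- c(surfaces, stringi::stri_sub(text, st + 1L, en))
        starts <- c(starts, st); ends <- c(ends, en)
        i <- i + hit_len
      } else i <- i + 1L
    }
  }
  list(surface = surfaces, start = starts, end = ends)
}

#' Link an entity surface to a concept
#'
#' Normalized-exact lookup against the vocabulary surface index; no fuzzy
#' linking. A miss is a \code{recognized_unlinked} outcome, counted and
#' reported rather than silently dropped.
#'
#' @param surface entity surface text (nonempty).
#' @param vocab vocabulary.
#' @return one-row \code{data.table}: surface, concept_id, housing_related,
#'   link_outcome.
#' @export
link_entity <- function(surface, vocab) {
  stopifnot(length(surface) == 1L, nzchar(surface))
  s <- norm_surface(surface)
  hit <- vocab$index[surface == s]
  if (nrow(hit)) {
    data.table(surface = surface, concept_id = hit$concept_id[1],
               housing_related = hit$housing_related[1], link_outcome = "linked")
  } else {
    data.table(surface = surface, concept_id = NA_character_,
               housing_related = FALSE, link_outcome = "recognized_unlinked")
  }
}

#' Detect housing concepts in a note via NER + linking
#'
#' Emits a note-source evidence flag (method \code{"ner"}) iff some linked
#' concept is housing-related and its span is not negation-qualified
#' (qualification reuses the keyword channel's window rule).
#'
#' @param text note text.
#' @param vocab vocabulary.
#' @param note_id identifier for provenance.
#' @param lexicon cue lexicon for qualification.
#' @param window qualification window.
#' @param entity_patterns,recognizer see \code{\link{extract_entities}}.
#' @param .ht internal: prebuilt surface hash.
#' @return list with \code{matches} (all ConceptMatch rows incl. status) and
#'   \code{flag} (evidence row or \code{NULL}).
#' @export
detect_housing_concepts <- function(text, vocab, note_id = NA_character_,
                                    lexicon = default_lexicon(), window = 6L,
                                    entity_patterns = default_entity_patterns(),
                                    recognizer = NULL, .ht = NULL) {
  ents <- extract_entities(text, vocab, entity_patterns, recognizer, .ht = .ht)
  if (nrow(ents) == 0L) {
    return(list(matches = data.table(note_id = character(), surface = character(),
                                     start = integer(), end = integer(),
                                     concept_id = character(),
                                     housing_related = logical(),
                                     link_outcome = character(),
                                     status = character()),
                flag = NULL))
  }
  ## vectorized normalized-exact linking
  mi <- match(norm_surface(ents$surface), vocab$index$surface)
  matches <- data.table(note_id = note_id, start = ents$start, end = ents$end,
                        surface = ents$surface,
                        concept_id = vocab$index$concept_id[mi],
                        housing_related = !is.na(mi) & vocab$index$housing_related[mi],
                        link_outcome = fifelse(is.na(mi), "recognized_unlinked", "linked"))
  sents <- segment(text)
  matches[, status := NA_character_]
  hr <- which(matches$housing_related & matches$link_outcome == "linked")
  for (j in hr) {
    si <- which(sents$start <= matches$start[j] & sents$end >= matches$end[j])[1]
    matches[j, status := qualify(sents$sentence[si],
                                 matches$start[j] - sents$start[si],
                                 matches$end[j] - sents$start[si],
                                 lexicon, window)]
  }
  ok <- matches[housing_related & link_outcome == "linked" &
                  status %in% c("affirmed", "historical")]
  flag <- if (nrow(ok)) {
    data.table(source = "note", method = "ner",
               provenance = paste0(note_id, ":", ok$start[1], "-", ok$end[1]))
  } else NULL
  list(matches = matches, flag = flag)
}

## Vectorized wrapper over a notes table; returns flags + unlinked count.
detect_ner_evidence <- function(notes, vocab, lexicon = default_lexicon(),
                                window = 6L,
                                entity_patterns = default_entity_patterns(),
                                recognizer = NULL) {
  notes <- as.data.table(notes)
  flags <- list(); n_unlinked <- 0L; n_linked <- 0L
  if (nrow(notes)) {
    ## prefilter: housing-related surfaces + OOV patterns only (the linker
    ## decides evidence; non-housing concepts can't produce flags)
    trig <- c(vocab$index$surface[vocab$index$housing_related],
              norm_surface(entity_patterns))
    note_norm <- norm_surface(notes$text)
    has_trigger <- Reduce(`|`, lapply(trig, function(tr) {
      stringi::stri_detect_fixed(note_norm, tr)
    }), init = rep(FALSE, nrow(notes)))
    ht <- if (is.null(recognizer)) vocab_hash(vocab, entity_patterns) else NULL
    cue_toks <- cue_token_lists(lexicon)
    idx_surface <- vocab$index$surface
    idx_housing <- vocab$index$housing_related
    fpid <- character(); fprov <- character()
    for (i in which(has_trigger)) {
      txt <- notes$text[i]
      ents <- if (is.null(recognizer)) extract_entities_raw(txt, ht) else {
        as.list(extract_entities(txt, vocab, entity_patterns, recognizer))
      }
      if (!length(ents$surface)) next
      mi <- match(norm_surface(ents$surface), idx_surface)
      n_unlinked <- n_unlinked + sum(is.na(mi))
      n_linked <- n_linked + sum(!is.na(mi))
      housing_hit <- !is.na(mi)
      housing_hit[housing_hit] <- idx_housing[mi[housing_hit]]
      for (j in which(housing_hit)) {
        sents <- segment_raw(txt)
        si <- which(sents$start <= ents$start[j] & sents$end >= ents$end[j])[1]
        st <- qualify(sents$sentence[si], ents$start[j] - sents$start[si],
                      ents$end[j] - sents$start[si], lexicon, window)
        if (st %in% c("affirmed", "historical")) {
          fpid <- c(fpid, notes$patient_id[i])
          fprov <- c(fprov, paste0(notes$note_id[i], ":", ents$start[j], "-", ents$end[j]))
          break
        }
      }
    }
    if (length(fpid)) {
      flags[[1L]] <- data.table(patient_id = fpid, source = "note",
                                method = "ner", provenance = fprov)
    }
  }
  flags <- if (length(flags)) {
    unique(rbindlist(flags), by = "patient_id")
  } else {
    data.table(patient_id = character(), source = character(),
               method = character(), provenance = character())
  }
  list(flags = flags, n_recognized_unlinked = n_unlinked, n_linked = n_linked)
}
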