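## Unstructured-notes channel: rule-based sentence segmentation, lexicon
## keyword matching with NegEx-style window qualification
## (negated / historical / third-party / affirmed), and shelter-by-name
## matching against the community-resource directory.
##
## Inner loops deliberately use base vectors, not data.table rows: at tens
## of thousands of notes per run, per-sentence allocation dominates.

#' Default housing lexicon and qualification cues
#'
#' The seed term list is a starting point, not a reconstruction of any
#' site-specific list; extend it via a YAML file (see
#' \code{\link{load_lexicon}}). All entries are stored lowercase; matching
#' is token-sequence based and case-insensitive.
#'
#' @return list with \code{terms}, \code{negation}, \code{history},
#'   \code{third_party} character vectors.
#' @export
default_lexicon <- function() {
  list(
    terms = c("homeless", "unhoused", "unstable housing", "homelessness",
              "housing insecure", "housing insecurity", "living on the streets",
              "homeless shelter", "no stable housing"),
    negation = c("denies", "denied", "deny", "no evidence of", "not", "no",
                 "negative for", "without"),
    history = c("history of", "previously", "years ago", "hx of", "prior",
                "in the past", "formerly"),
    third_party = c("found a", "her boyfriend", "his girlfriend",
                    "family member", "her husband", "his wife", "friend is",
                    "mother is", "father is", "son is", "daughter is")
  )
}

#' Load a lexicon from YAML
#'
#' Expected top-level keys: \code{terms}, \code{negation}, \code{history},
#' \code{third_party}; missing keys fall back to the defaults.
#'
#' @param path YAML file path, or \code{NULL} for the built-in lexicon.
#' @return lexicon list (entries lowercased).
#' @export
load_lexicon <- function(path = NULL) {
  base <- default_lexicon()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  for (k in names(base)) if (!is.null(user[[k]])) base[[k]] <- tolower(unlist(user[[k]]))
  base
}

#' Segment note text into sentences with exact character offsets
#'
#' Rule-based splitting on sentence punctuation (. ! ?) and newlines.
#' Offsets are 0-based half-open; the substring of the original text at each
#' sentence's span reproduces the sentence exactly, so downstream mention
#' spans can always be traced back to the note.
#'
#' @param text a single character string (possibly empty).
#' @return \code{data.table} with \code{sentence}, \code{start}, \code{end}.
#' @export
segment <- function(text) {
  s <- segment_raw(text)
  data.table(sentence = s$sentence, start = s$start, end = s$end)
}

## list-based segmentation used internally (no data.table allocation)
segment_raw <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(list(sentence = character(), start = integer(), end = integer()))
  }
  loc <- stringi::stri_locate_all_regex(text, "[.!?]+[ \t]*|\n+")[[1]]
  n <- nchar(text)
  cuts <- if (is.na(loc[1, 1])) n else unique(c(loc[, 2], n))
  starts <- c(0L, head(cuts, -1L))
  sent <- stringi::stri_sub(text, starts + 1L, cuts)
  keep <- stringi::stri_detect_regex(sent, "[A-Za-z0-9]")
  list(sentence = sent[keep], start = as.integer(starts[keep]),
       end = as.integer(cuts[keep]))
}

## list-based tokenizer (see tokenize_offsets in utils.R for the table form)
tokenize_raw <- function(text) {
  loc <- stringi::stri_locate_all_regex(text, "[A-Za-z0-9']+")[[1]]
  if (is.na(loc[1, 1])) {
    return(list(token = character(), start = integer(), end = integer(), n = 0L))
  }
  list(token = stringi::stri_sub(text, loc[, 1], loc[, 2]),
       start = as.integer(loc[, 1] - 1L), end = as.integer(loc[, 2]),
       n = nrow(loc))
}

## Longest-match phrase scan over one tokenized sentence. phrases_tokens is
## a list of lowercase token vectors. Returns parallel vectors: phrase
## index, token start, token length. Overlapping shorter matches suppressed
## greedily left-to-right with longest-first priority at each start.
scan_phrases <- function(tl, phrases_tokens) {
  ps <- integer(); pl <- integer(); pi_out <- integer()
  for (pi in seq_along(phrases_tokens)) {
    pt <- phrases_tokens[[pi]]
    for (s in find_token_seq(tl, pt)) {
      ps <- c(ps, s); pl <- c(pl, length(pt)); pi_out <- c(pi_out, pi)
    }
  }
  if (!length(ps)) return(list(tok_start = integer(), tok_len = integer(),
                               phrase = integer()))
  o <- order(ps, -pl)
  ps <- ps[o]; pl <- pl[o]; pi_out <- pi_out[o]
  keep <- logical(length(ps)); covered <- 0L
  for (i in seq_along(ps)) {
    if (ps[i] > covered) { keep[i] <- TRUE; covered <- ps[i] + pl[i] - 1L }
  }
  list(tok_start = ps[keep], tok_len = pl[keep], phrase = pi_out[keep])
}

## cue-window qualification on a tokenized sentence
qualify_tokens <- function(tl, first_tok, last_tok, cue_toks, window) {
  positions <- function(plist) {
    out <- integer()
    for (pt in plist) {
      s <- find_token_seq(tl, pt)
      s <- s[!(s >= first_tok & s <= last_tok)]  # cue inside the mention doesn't qualify it
      out <- c(out, s)
    }
    out
  }
  before <- function(pos) any(pos < first_tok & pos >= first_tok - window)
  either <- function(pos) {
    any((pos < first_tok & pos >= first_tok - window) |
        (pos > last_tok & pos <= last_tok + window))
  }
  neg <- positions(cue_toks$negation)
  if (length(neg) && either(neg)) return("negated")
  tp <- positions(cue_toks$third_party)
  if (length(tp) && before(tp)) return("third_party")
  hist <- positions(cue_toks$history)
  if (length(hist) && before(hist)) return("historical")
  "affirmed"
}

cue_token_lists <- function(lexicon) {
  list(negation = lapply(lexicon$negation, phrase_tokens),
       history = lapply(lexicon$history, phrase_tokens),
       third_party = lapply(lexicon$third_party, phrase_tokens))
}

#' Match housing-lexicon keywords in a note
#'
#' One mention per non-overlapping longest match; an overlapping shorter
#' match is suppressed (so "unstable housing situation" yields the phrase
#' match, not two unigrams). Paradoxical phrasings ("has stable housing
#' including homeless shelter") are surfaced as mentions, not resolved.
#'
#' @param text note text.
#' @param note_id identifier carried into the mention rows.
#' @param lexicon lexicon list (see \code{\link{default_lexicon}}).
#' @return mention \code{data.table}: note_id, method, surface, start, end,
#'   sentence_index, status (unqualified: \code{NA}), resource_id.
#' @export
match_keywords <- function(text, note_id = NA_character_, lexicon = default_lexicon()) {
  m <- scan_note(text, term_toks = lapply(lexicon$terms, phrase_tokens),
                 shelter = NULL, cue_toks = NULL, window = 6L)
  data.table(note_id = note_id, method = m$method, surface = m$surface,
             start = m$start, end = m$end, sentence_index = m$sentence_index,
             status = NA_character_, resource_id = m$resource_id)
}

#' Qualify a mention as affirmed, negated, historical, or third-party
#'
#' NegEx-style window rule: the sentence containing the mention is scanned
#' for cue phrases within \code{window} tokens of the match. Negation cues
#' count before or after the match ("denied" follows "homeless" in real
#' notes); history and experiencer cues count only before. Precedence:
#' negated > third_party > historical > affirmed. Cues never cross sentence
#' boundaries.
#'
#' @param sentence the sentence text containing the mention.
#' @param m_start,m_end mention character span relative to the sentence
#'   (0-based half-open).
#' @param lexicon lexicon list with cue vectors.
#' @param window token window (default 6).
#' @return one of \code{"affirmed"}, \code{"negated"}, \code{"historical"},
#'   \code{"third_party"}.
#' @export
qualify <- function(sentence, m_start, m_end, lexicon = default_lexicon(),
                    window = 6L) {
  tok <- tokenize_raw(sentence)
  if (tok$n == 0L) return("affirmed")
  in_mention <- tok$start >= m_start & tok$end <= m_end
  if (!any(in_mention)) return("affirmed")
  qualify_tokens(tolower(tok$token), which(in_mention)[1],
                 tail(which(in_mention), 1), cue_token_lists(lexicon), window)
}

## Unified single-pass scanner: segments once, tokenizes each sentence once,
## finds keyword and shelter mentions, qualifies keyword mentions in place.
## Returns parallel vectors.
scan_note <- function(text, term_toks, shelter, cue_toks, window) {
  out <- list(method = character(), surface = character(), start = integer(),
              end = integer(), sentence_index = integer(),
              status = character(), resource_id = character())
  sents <- segment_raw(text)
  if (!length(sents$sentence)) return(out)
  for (si in seq_along(sents$sentence)) {
    tok <- tokenize_raw(sents$sentence[si])
    if (tok$n == 0L) next
    tl <- tolower(tok$token)
    off <- sents$start[si]
    if (!is.null(term_toks)) {
      m <- scan_phrases(tl, term_toks)
      for (k in seq_along(m$tok_start)) {
        s <- m$tok_start[k]; l <- m$tok_len[k]
        st <- tok$start[s] + off; en <- tok$end[s + l - 1L] + off
        status <- if (is.null(cue_toks)) NA_character_ else
          qualify_tokens(tl, s, s + l - 1L, cue_toks, window)
        out$method <- c(out$method, "keyword")
        out$surface <- c(out$surface, stringi::stri_sub(text, st + 1L, en))
        out$start <- c(out$start, st); out$end <- c(out$end, en)
        out$sentence_index <- c(out$sentence_index, si)
        out$status <- c(out$status, status)
        out$resource_id <- c(out$resource_id, NA_character_)
      }
    }
    if (!is.null(shelter)) {
      for (pi in seq_along(shelter$toks)) {
        for (s in find_token_seq(tl, shelter$toks[[pi]])) {
          l <- length(shelter$toks[[pi]])
          st <- tok$start[s] + off; en <- tok$end[s + l - 1L] + off
          out$method <- c(out$method, "shelter_name")
          out$surface <- c(out$surface, stringi::stri_sub(text, st + 1L, en))
          out$start <- c(out$start, st); out$end <- c(out$end, en)
          out$sentence_index <- c(out$sentence_index, si)
          out$status <- c(out$status, "affirmed")
          out$resource_id <- c(out$resource_id, shelter$resource_id[pi])
        }
      }
    }
  }
  out
}

shelter_surfaces <- function(directory, lexicon) {
  surf <- resource_surfaces(directory)
  collide <- tolower(surf$surface) %in% tolower(lexicon$terms)
  if (any(collide)) {
    stop_config("directory alias collides with lexicon keyword: ",
                paste(unique(surf$surface[collide]), collapse = ", "))
  }
  list(toks = lapply(surf$surface, phrase_tokens),
       resource_id = surf$resource_id)
}

#' Match community shelters by name in a note
#'
#' Token-sequence, case-insensitive matching of directory canonical names
#' and aliases. Indirect mentions (information-giving, discharge planning)
#' still match: a provider naming a shelter implies a perceived housing
#' need, so shelter mentions are never negation-qualified. An alias that
#' collides with a lexicon keyword is rejected at load time.
#'
#' @param text note text.
#' @param directory resource directory
#'   (\code{\link{load_resource_directory}}).
#' @param note_id identifier carried into the mention rows.
#' @param lexicon lexicon used only for the collision check.
#' @return mention \code{data.table} (method \code{"shelter_name"}, status
#'   \code{"affirmed"}, resource_id filled); duplicate same-span matches
#'   (canonical name vs alias) collapse to one row.
#' @export
match_shelters <- function(text, directory, note_id = NA_character_,
                           lexicon = default_lexicon()) {
  m <- scan_note(text, term_toks = NULL,
                 shelter = shelter_surfaces(directory, lexicon),
                 cue_toks = NULL, window = 6L)
  res <- data.table(note_id = note_id, method = m$method, surface = m$surface,
                    start = m$start, end = m$end,
                    sentence_index = m$sentence_index, status = m$status,
                    resource_id = m$resource_id)
  unique(res, by = c("start", "end", "resource_id"))
}

#' Run the full note channel over a notes table
#'
#' Keyword mentions are qualified in their sentence; shelter mentions are
#' always affirmed. Which statuses yield evidence is configurable:
#' historical counts by default (no temporal filter is imposed), third-party
#' is excluded by default.
#'
#' @param notes \code{data.table} with note_id, patient_id, text.
#' @param directory resource directory (or \code{NULL} to skip shelter
#'   matching).
#' @param lexicon lexicon list.
#' @param window qualification window in tokens.
#' @param historical_counts,third_party_counts status-to-evidence toggles.
#' @return list with \code{mentions} (all mentions with status) and
#'   \code{flags} (patient-level evidence rows, methods keyword /
#'   shelter_name).
#' @export
detect_note_evidence <- function(notes, directory = NULL,
                                 lexicon = default_lexicon(), window = 6L,
                                 historical_counts = TRUE,
                                 third_party_counts = FALSE) {
  notes <- as.data.table(notes)
  empty_m <- data.table(note_id = character(), patient_id = character(),
                        method = character(), surface = character(),
                        start = integer(), end = integer(),
                        sentence_index = integer(), status = character(),
                        resource_id = character())
  empty_f <- data.table(patient_id = character(), source = character(),
                        method = character(), provenance = character())
  if (nrow(notes) == 0L) return(list(mentions = empty_m, flags = empty_f))

  term_toks <- lapply(lexicon$terms, phrase_tokens)
  shelter <- if (is.null(directory)) NULL else shelter_surfaces(directory, lexicon)
  cue_toks <- cue_token_lists(lexicon)

  ## cheap prefilter: only notes containing some trigger string get the
  ## full tokenizing pass (matters at tens of thousands of notes)
  triggers <- tolower(lexicon$terms)
  if (!is.null(shelter)) {
    triggers <- c(triggers, tolower(vapply(shelter$toks, paste, "", collapse = " ")))
  }
  low_norm <- stringi::stri_replace_all_regex(tolower(notes$text), "[^a-z0-9]+", " ")
  trig_norm <- unique(trimws(stringi::stri_replace_all_regex(triggers, "[^a-z0-9]+", " ")))
  has_trigger <- Reduce(`|`, lapply(trig_norm, function(tr) {
    stringi::stri_detect_fixed(low_norm, tr)
  }), init = rep(FALSE, nrow(notes)))

  rows <- vector("list", sum(has_trigger)); ri <- 0L
  for (i in which(has_trigger)) {
    m <- scan_note(notes$text[i], term_toks, shelter, cue_toks, window)
    if (!length(m$method)) next
    ri <- ri + 1L
    rows[[ri]] <- data.table(note_id = notes$note_id[i],
                             patient_id = notes$patient_id[i],
                             method = m$method, surface = m$surface,
                             start = m$start, end = m$end,
                             sentence_index = m$sentence_index,
                             status = m$status, resource_id = m$resource_id)
  }
  mentions <- if (ri) rbindlist(rows[seq_len(ri)]) else empty_m
  if (nrow(mentions)) {
    mentions <- unique(mentions, by = c("note_id", "method", "start", "end", "resource_id"))
  }

  ok_status <- c("affirmed",
                 if (historical_counts) "historical",
                 if (third_party_counts) "third_party")
  ev <- mentions[status %in% ok_status]
  flags <- unique(ev[, .(patient_id, source = "note", method,
                         provenance = paste0(note_id, ":", start, "-", end))],
                  by = c("patient_id", "method"))
  list(mentions = mentions, flags = flags)
}
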