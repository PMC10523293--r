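## Sentence segmentation, keyword matching, cue-window qualification, and
## shelter-by-name matching.

test_that("segment returns exact offsets", {
  expect_identical(nrow(segment("")), 0L)
  s <- segment("A. B.")
  expect_identical(nrow(s), 2L)
  txt <- "A. B."
  for (i in seq_len(nrow(s))) {
    expect_identical(substr(txt, s$start[i] + 1, s$end[i]), s$sentence[i])
  }
  ## newline splitting
  s2 <- segment("first line\nsecond line")
  expect_identical(nrow(s2), 2L)
})

test_that("segment round-trips template notes and recovers mention sentences", {
  ds <- fixture_dataset()
  tm <- ds$truth_mentions
  set.seed(61)
  for (nid in sample(unique(tm$note_id), 100)) {
    txt <- ds$notes[note_id == nid, text]
    sents <- segment(txt)
    for (i in seq_len(nrow(sents))) {
      expect_identical(substr(txt, sents$start[i] + 1, sents$end[i]), sents$sentence[i])
    }
    for (sn in tm[note_id == nid, sentence]) {
      expect_true(any(trimws(sents$sentence) == sn), info = paste(nid, sn))
    }
  }
})

test_that("keyword matching is longest-match, non-overlapping", {
  m <- match_keywords("patient is homeless")
  expect_identical(nrow(m), 1L)
  expect_identical(tolower(m$surface), "homeless")
  ## phrase beats its unigram parts
  m2 <- match_keywords("unstable housing situation noted")
  expect_identical(nrow(m2), 1L)
  expect_identical(tolower(m2$surface), "unstable housing")
  ## paradoxical phrasing is surfaced, not resolved
  m3 <- match_keywords("has stable housing including homeless shelter")
  expect_gte(nrow(m3), 1L)
  expect_true("homeless shelter" %in% tolower(m3$surface))
})

test_that("mention spans slice back to their surface text", {
  notes <- fixture_dataset()$notes
  res <- detect_note_evidence(notes[1:400], fixture_directory())
  m <- res$mentions
  expect_gt(nrow(m), 0)
  for (i in seq_len(nrow(m))) {
    txt <- notes[note_id == m$note_id[i], text]
    expect_identical(tolower(substr(txt, m$start[i] + 1, m$end[i])),
                     tolower(m$surface[i]))
  }
})

test_that("qualify handles the documented failure vignettes", {
  q <- function(s) {
    m <- match_keywords(s)
    qualify(s, m$start[1], m$end[1])
  }
  expect_identical(q("asked if she was homeless and she denied"), "negated")
  expect_identical(q("found a homeless person sleeping in her bathroom"), "third_party")
  expect_identical(q("patient is homeless"), "affirmed")
  expect_identical(q("history of homelessness documented"), "historical")
  expect_identical(q("patient denies being homeless"), "negated")
})

test_that("qualify agrees with a brute-force cue scanner on random placements", {
  lex <- default_lexicon()
  fillers <- c("alpha", "bravo", "charlie", "delta", "echo", "golf", "hotel",
               "india", "juliet", "kilo", "lima", "mike")
  cues <- list(negated = "denied", third_party = "family member",
               historical = "previously")
  W <- 6L
  ## independent oracle over token positions
  oracle <- function(toks, kw_pos) {
    hit <- function(cue_toks, side) {
      k <- length(cue_toks)
      for (s in seq_len(length(toks) - k + 1)) {
        if (!all(toks[s:(s + k - 1)] == cue_toks)) next
        if (s == kw_pos) next
        if (side == "before" && s < kw_pos && s >= kw_pos - W) return(TRUE)
        if (side == "either" &&
            ((s < kw_pos && s >= kw_pos - W) || (s > kw_pos && s <= kw_pos + W))) return(TRUE)
      }
      FALSE
    }
    for (cue in lex$negation) if (hit(strsplit(cue, " ")[[1]], "either")) return("negated")
    for (cue in lex$third_party) if (hit(strsplit(cue, " ")[[1]], "before")) return("third_party")
    for (cue in lex$history) if (hit(strsplit(cue, " ")[[1]], "before")) return("historical")
    "affirmed"
  }
  set.seed(71)
  for (i in 1:250) {
    n_tok <- sample(6:14, 1)
    toks <- sample(fillers, n_tok, replace = TRUE)
    kw_pos <- sample(n_tok, 1)
    toks[kw_pos] <- "homeless"
    if (runif(1) < 0.8) {
      cue <- sample(unlist(cues), 1)
      ct <- strsplit(cue, " ")[[1]]
      cands <- setdiff(seq_len(n_tok - length(ct) + 1), kw_pos)
      cp <- cands[sample.int(length(cands), 1)]
      toks[cp:(cp + length(ct) - 1)] <- ct
      if (cp <= kw_pos && kw_pos <= cp + length(ct) - 1) next  # cue overlapped keyword
    }
    sent <- paste(toks, collapse = " ")
    m <- match_keywords(sent)
    m <- m[tolower(surface) == "homeless"]
    if (nrow(m) != 1L) next
    kw_tok <- length(strsplit(substr(sent, 1, m$start[1]), " ")[[1]]) + 1L
    got <- qualify(sent, m$start[1], m$end[1])
    expect_identical(got, oracle(toks, kw_tok), info = sent)
  }
})

test_that("shelter mentions match by name and alias, carrying resource ids", {
  dir <- fixture_directory()
  m <- match_shelters("Discharged to Hope House.", dir)
  expect_identical(nrow(m), 1L)
  expect_identical(m$resource_id, "R001")
  expect_identical(m$status, "affirmed")
  ## indirect information-giving mention still matches, twice
  m2 <- match_shelters(paste("Social worker printed out information about two",
                             "facilities, Hope House and New Start, and gave to patient"), dir)
  expect_identical(nrow(m2), 2L)
  expect_setequal(m2$resource_id, c("R001", "R002"))
  expect_identical(nrow(match_shelters("No facilities were discussed today.", dir)), 0L)
})

test_that("shelter mentions are not negation-qualified", {
  dir <- fixture_directory()
  res <- detect_note_evidence(
    data.table::data.table(note_id = "n1", patient_id = "P1",
                           text = "Patient did not go to Hope House."), dir)
  expect_identical(nrow(res$flags), 1L)
  expect_identical(res$flags$method, "shelter_name")
})

test_that("an alias colliding with a lexicon keyword is rejected at load", {
  dir <- tiny_directory()
  dir$aliases[1] <- "homeless shelter"
  expect_error(match_shelters("whatever", dir), "collides")
})

test_that("status toggles control which mentions become evidence", {
  notes <- data.table::data.table(
    note_id = c("n1", "n2", "n3"),
    patient_id = c("P1", "P2", "P3"),
    text = c("Patient denies being homeless.",
             "Her boyfriend is homeless and stays elsewhere.",
             "History of homelessness documented in prior records."))
  res <- detect_note_evidence(notes)
  expect_identical(res$flags$patient_id, "P3")   # historical counts by default
  res2 <- detect_note_evidence(notes, historical_counts = FALSE)
  expect_identical(nrow(res2$flags), 0L)
  res3 <- detect_note_evidence(notes, third_party_counts = TRUE)
  expect_setequal(res3$flags$patient_id, c("P2", "P3"))
  expect_setequal(res$mentions$status, c("negated", "third_party", "historical"))
})
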