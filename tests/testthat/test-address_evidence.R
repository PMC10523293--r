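## Address normalization, resource matching, literal-"homeless" and generic
## flags.

test_that("normalization collapses case/punctuation/suffix variants", {
  k1 <- normalize_address("123 Main St., Apt 4", "Lexington", "KY", "40508")
  k2 <- normalize_address("123 MAIN STREET", "Lexington", "ky", "40508")
  expect_identical(k1, k2)
})

test_that("normalization is idempotent", {
  keys <- normalize_address(c("123 Main Street Apt 4", "77 Pine Rd.", "HOMELESS"),
                            "Lexington", "KY", "40508")
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    parts <- c(parts, rep("", 4 - length(parts)))
    expect_identical(normalize_address(parts[1], parts[2], parts[3], parts[4]), k)
  }
})

test_that("randomized perturbations collapse to the canonical keys", {
  set.seed(52)
  base <- data.frame(
    line1 = paste(100:119, c("Maple", "Oak", "Pine", "Cedar"),
                  c("Street", "Avenue", "Road", "Drive")),
    city = "Lexington", state = "KY", zip = "40508")
  canon <- normalize_address(base$line1, base$city, base$state, base$zip)
  expect_identical(length(unique(canon)), 20L)
  abbrev <- c(Street = "St", Avenue = "Ave", Road = "Rd", Drive = "Dr")
  perturb <- function(line) {
    for (w in names(abbrev)) {
      if (grepl(w, line) && runif(1) < 0.5) line <- sub(w, paste0(abbrev[[w]], "."), line)
    }
    if (runif(1) < 0.5) line <- toupper(line) else if (runif(1) < 0.5) line <- tolower(line)
    if (runif(1) < 0.3) line <- paste0(line, ",")
    if (runif(1) < 0.3) line <- paste0(line, " Apt ", sample(1:20, 1))
    line
  }
  for (rep in 1:25) {
    i <- sample(20, 1)
    k <- normalize_address(perturb(base$line1[i]), "LEXINGTON", "ky", "40508")
    expect_identical(k, canon[i])
  }
})

test_that("match_resource: exact hit, miss, typo threshold behavior", {
  dir <- tiny_directory()
  key <- normalize_address("100 Main Street", "Lexington", "KY", "40507")
  expect_identical(match_resource(key, dir)$resource_id, "T1")
  expect_null(match_resource(normalize_address("999 Nowhere Blvd", "Lexington", "KY", "40502"),
                             dir, fuzzy = FALSE))
  typo <- normalize_address("100 Mair Street", "Lexington", "KY", "40507")
  sim <- 1 - utils::adist(typo, dir$address_key[1])[1, 1] /
    max(nchar(typo), nchar(dir$address_key[1]))
  expect_gte(sim, 0.92)   # fixture sanity: one substitution stays above threshold
  expect_message(hit <- match_resource(typo, dir, threshold = 0.92), "fuzzy address match")
  expect_identical(hit$resource_id, "T1")
  expect_null(suppressMessages(match_resource(typo, dir, threshold = 0.99)))
})

test_that("ambiguous fuzzy candidates produce a warning and no match", {
  dir <- data.table::data.table(
    resource_id = c("A", "B"), name = c("House A", "House B"),
    aliases = "", line1 = c("100 Main Street", "101 Main Street"),
    city = "Lexington", state = "KY", zip = "40507",
    roles = "emergency_shelter")
  dir[, address_key := normalize_address(line1, city, state, zip)]
  typo <- normalize_address("10X Main Street", "Lexington", "KY", "40507")
  expect_warning(res <- match_resource(typo, dir, threshold = 0.9), "ambiguous")
  expect_null(res)
})

test_that("literal-homeless flag is token containment on line1", {
  expect_true(flag_literal_homeless("HOMELESS"))
  expect_true(flag_literal_homeless("123 Homeless Shelter Rd"))
  expect_true(flag_literal_homeless("unhoused"))
  expect_false(flag_literal_homeless(""))
  expect_false(flag_literal_homeless("123 Homelessness Way"))  # token, not substring
})

test_that("generic placeholder addresses are flagged but never evidence", {
  expect_true(flag_generic("", "", "Lexington", "KY"))
  expect_true(flag_generic("UNKNOWN", "", "Lexington", "KY"))
  expect_false(flag_generic("123 Main St", "", "Lexington", "KY"))
  expect_false(flag_generic("", "", "", ""))   # nothing at all present
  adr <- data.table::data.table(patient_id = "P1", line1 = "", line2 = "",
                                city = "Lexington", state = "KY", zip = "")
  res <- detect_address_evidence(adr, tiny_directory())
  expect_identical(nrow(res$flags), 0L)
  expect_identical(res$generic, "P1")
})

test_that("generic and resource-match are mutually exclusive per record", {
  dir <- tiny_directory()
  adr <- data.table::data.table(
    patient_id = c("P1", "P2", "P3"),
    line1 = c("100 Main Street", "", "HOMELESS"), line2 = "",
    city = "Lexington", state = "KY",
    zip = c("40507", "", "40508"))
  res <- suppressMessages(detect_address_evidence(adr, dir))
  expect_setequal(res$flags$patient_id, c("P1", "P3"))
  expect_identical(res$flags[patient_id == "P1", method], "resource_address")
  expect_identical(res$flags[patient_id == "P3", method], "literal_homeless")
  expect_identical(res$generic, "P2")
  expect_length(intersect(res$generic, res$flags$patient_id), 0)
})

test_that("adding directory entries never removes an evidence flag", {
  dir <- tiny_directory()
  adr <- data.table::data.table(
    patient_id = sprintf("P%02d", 1:6),
    line1 = c("100 Main Street", "250 Oak Avenue", "1 Elm Court",
              "HOMELESS", "", "9 Birch Way"),
    line2 = "", city = "Lexington", state = "KY",
    zip = c("40507", "40508", "40502", "40502", "", "40503"))
  before <- suppressMessages(detect_address_evidence(adr, dir, fuzzy = FALSE))
  grown <- data.table::rbindlist(list(dir, data.table::data.table(
    resource_id = "T9", name = "Elm Court Refuge", aliases = "",
    line1 = "1 Elm Court", city = "Lexington", state = "KY", zip = "40502",
    roles = "emergency_shelter",
    address_key = normalize_address("1 Elm Court", "Lexington", "KY", "40502"))))
  after <- suppressMessages(detect_address_evidence(adr, grown, fuzzy = FALSE))
  expect_true(all(before$flags$patient_id %in% after$flags$patient_id))
  expect_true("P03" %in% after$flags$patient_id)  # new entry adds evidence
})

test_that("treatment-only resources can be excluded by config", {
  dir <- tiny_directory()   # T3 is residential_sud_treatment only
  adr <- data.table::data.table(patient_id = "P1", line1 = "77 Pine Road",
                                line2 = "", city = "Georgetown", state = "KY",
                                zip = "40324")
  with_tx <- detect_address_evidence(adr, dir, fuzzy = FALSE)
  without <- detect_address_evidence(adr, dir, fuzzy = FALSE, include_treatment = FALSE)
  expect_identical(nrow(with_tx$flags), 1L)
  expect_identical(nrow(without$flags), 0L)
})

test_that("only the most recent address per patient is evaluated", {
  dir <- tiny_directory()
  adr <- data.table::data.table(
    patient_id = c("P1", "P1"),
    line1 = c("100 Main Street", "500 Stable Home Dr"), line2 = "",
    city = "Lexington", state = "KY", zip = c("40507", "40502"))
  res <- suppressMessages(detect_address_evidence(adr, dir, fuzzy = FALSE))
  expect_identical(nrow(res$flags), 0L)   # latest row is not a resource
})
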