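## Shared fixtures, built in code. Heavyweight objects are memoized per
## test run so multiple files can reuse them.

the <- new.env(parent = emptyenv())

fixture_directory <- function() {
  if (is.null(the$directory)) the$directory <- load_resource_directory()
  the$directory
}

fixture_vocab <- function() {
  if (is.null(the$vocab)) the$vocab <- load_vocabulary()
  the$vocab
}

## one moderately sized dataset reused across files
fixture_dataset <- function() {
  if (is.null(the$dataset)) {
    the$dataset <- generate_dataset(gen_config(n_patients = 800, seed = 101L))
  }
  the$dataset
}

## small in-code directory for address unit tests
tiny_directory <- function() {
  d <- data.table::data.table(
    resource_id = c("T1", "T2", "T3"),
    name = c("Main Street Shelter", "Second Chance Home", "Quiet Pines Lodge"),
    aliases = c("MSS", "", ""),
    line1 = c("100 Main Street", "250 Oak Avenue", "77 Pine Road"),
    city = c("Lexington", "Lexington", "Georgetown"),
    state = c("KY", "KY", "KY"),
    zip = c("40507", "40508", "40324"),
    roles = c("emergency_shelter", "transitional_housing", "residential_sud_treatment"))
  d[, address_key := normalize_address(line1, city, state, zip)]
  d
}

## random ICD-ish code pool for prefix-matching oracles
random_codes <- function(n, seed) {
  set.seed(seed)
  stems <- c("F14", "F15", "F11", "F10", "T40", "T43", "Z59", "Z58", "I10",
             "E11", "J45", "K21", "T436", "T405")
  suff <- c("", ".0", ".10", ".20", ".5X1A", ".61XA", ".9", "0", "5X2A")
  paste0(sample(stems, n, TRUE), sample(suff, n, TRUE))
}
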