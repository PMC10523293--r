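## Evidence fusion, Venn partitioning, coverage reporting, tract comparison.

rand_sets <- function(n, seed) {
  set.seed(seed)
  data.table::data.table(patient_id = sprintf("P%04d", seq_len(n)),
                         D = runif(n) < 0.4, A = runif(n) < 0.15,
                         N = runif(n) < 0.5)
}

test_that("fuse groups flags into source sets and validates integrity", {
  patients <- c("P1", "P2", "P3")
  flags <- data.table::data.table(
    patient_id = c("P1", "P1"), source = c("diagnosis", "note"),
    method = c("icd_z59", "shelter_name"), provenance = c("e", "n"))
  s <- fuse(flags, patients)
  expect_identical(s[patient_id == "P1", .(D, A, N)],
                   data.table::data.table(D = TRUE, A = FALSE, N = TRUE))
  expect_identical(s[patient_id == "P2", n_sources], 0L)
  expect_error(fuse(data.table::data.table(patient_id = "PX", source = "note",
                                           method = "keyword", provenance = ""),
                    patients), "unknown patient")
  expect_error(fuse(data.table::data.table(patient_id = "P1", source = "address",
                                           method = "keyword", provenance = ""),
                    patients), "inconsistent")
})

test_that("fuse equals a brute-force grouping oracle on random flags", {
  set.seed(92)
  patients <- sprintf("P%03d", 1:120)
  method_of <- c(diagnosis = "icd_z59", address = "resource_address", note = "keyword")
  flags <- data.table::data.table(
    patient_id = sample(patients, 1000, TRUE),
    source = sample(names(method_of), 1000, TRUE))
  flags[, method := method_of[source]]
  flags[, provenance := ""]
  s <- fuse(flags, patients)
  for (p in patients) {
    expect_identical(s[patient_id == p, D], "diagnosis" %in% flags[patient_id == p, source])
    expect_identical(s[patient_id == p, A], "address" %in% flags[patient_id == p, source])
    expect_identical(s[patient_id == p, N], "note" %in% flags[patient_id == p, source])
  }
})

test_that("venn regions equal an inclusion-exclusion oracle on random sets", {
  for (seed in c(1, 2, 3)) {
    s <- rand_sets(500, seed)
    p <- venn(s)
    ## oracle: direct membership counting
    expect_identical(p$D_only, sum(s$D & !s$A & !s$N))
    expect_identical(p$AN, sum(!s$D & s$A & s$N))
    expect_identical(p$DAN, sum(s$D & s$A & s$N))
    expect_identical(p$union, sum(s$D | s$A | s$N))
    expect_identical(p$totals[["D"]], sum(s$D))
    expect_identical(p$totals[["A"]], sum(s$A))
    expect_identical(p$totals[["N"]], sum(s$N))
  }
})

test_that("disjoint singleton sets give three regions and empty intersections", {
  s <- data.table::data.table(patient_id = c("a", "b", "c"),
                              D = c(TRUE, FALSE, FALSE),
                              A = c(FALSE, TRUE, FALSE),
                              N = c(FALSE, FALSE, TRUE))
  p <- venn(s)
  expect_identical(c(p$D_only, p$A_only, p$N_only), c(1L, 1L, 1L))
  expect_identical(c(p$DA, p$DN, p$AN, p$DAN), c(0L, 0L, 0L, 0L))
})

test_that("published-count fixture reproduces the printed coverage percentages", {
  ## region solution consistent with the printed per-source totals
  ## D=3515, A=981, N=4213, triple overlap 286
  p <- venn_from_regions(D_only = 1341, A_only = 427, N_only = 1827,
                         DA = 28, DN = 1860, AN = 240, DAN = 286)
  expect_identical(p$totals, c(D = 3515, A = 981, N = 4213))
  cov <- coverage_summary(p, 20556)
  expect_identical(unname(cov$coverage_pct), c(58.5, 16.3, 70.1))
  expect_identical(cov$union_prevalence_pct, 29.2)
  expect_identical(cov$no_evidence_pct, 70.8)
  expect_identical(cov$complement_pct, 41.5)
  expect_identical(unname(cov$complement_split_pct), c(7.1, 30.4, 4.0))
})

test_that("degenerate coverage: diagnosis set equals the union", {
  p <- venn_from_regions(D_only = 50, A_only = 0, N_only = 0,
                         DA = 10, DN = 15, AN = 0, DAN = 25)
  cov <- coverage_summary(p, 200)
  expect_identical(cov$codes_coverage_pct, 100.0)
  expect_identical(cov$complement_pct, 0.0)
})

test_that("complement sub-splits sum to the complement up to rounding", {
  for (seed in 4:8) {
    s <- rand_sets(300, seed)
    cov <- coverage_summary(venn(s), 400)
    expect_lte(abs(sum(cov$complement_split_pct) - cov$complement_pct), 0.2)
  }
})

test_that("duplicate flags are idempotent and extra flags monotone", {
  patients <- sprintf("P%02d", 1:30)
  flags <- data.table::data.table(
    patient_id = c("P01", "P02", "P03"), source = c("diagnosis", "note", "address"),
    method = c("icd_z59", "keyword", "literal_homeless"), provenance = "x")
  p1 <- venn(fuse(flags, patients))
  p2 <- venn(fuse(rbind(flags, flags), patients))
  expect_identical(p1, p2)
  grown <- rbind(flags, data.table::data.table(
    patient_id = "P04", source = "note", method = "ner", provenance = "y"))
  p3 <- venn(fuse(grown, patients))
  expect_gte(p3$union, p1$union)
  expect_true(all(p3$totals >= p1$totals))
})

test_that("tract comparison counts missed and increased tracts", {
  s <- rand_sets(200, 9)
  tr <- data.table::data.table(patient_id = s$patient_id,
                               tract = sample(1:12, 200, TRUE))
  ## identical modes: force A and N empty
  s0 <- data.table::data.table(s)
  s0[, `:=`(A = FALSE, N = FALSE)]
  t0 <- tract_compare(s0, tr)
  expect_identical(t0$n_missed, 0L)
  expect_identical(t0$n_increased, 0L)
  ## conservation: increases sum to |union| - |D|
  t1 <- tract_compare(s, tr)
  expect_identical(t1$total_increase, sum(s$D | s$A | s$N) - sum(s$D))
})

test_that("notes-only patients concentrated in specific tracts are missed under codes-only", {
  s <- data.table::data.table(
    patient_id = sprintf("P%02d", 1:40),
    D = c(rep(TRUE, 20), rep(FALSE, 20)),
    A = FALSE,
    N = c(rep(FALSE, 20), rep(TRUE, 20)))
  tr <- data.table::data.table(patient_id = s$patient_id,
                               tract = c(rep(1:5, 4), rep(6:8, length.out = 20)))
  t1 <- tract_compare(s, tr)
  expect_identical(t1$n_missed, 3L)          # tracts 6-8 invisible to codes
  expect_identical(t1$n_increased, 3L)
  ## patients without a tract fall into the sentinel bucket
  tr2 <- data.table::data.table(patient_id = s$patient_id, tract = NA_integer_)
  t2 <- tract_compare(s, tr2)
  expect_identical(t2$per_tract$tract, "unknown")
})
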