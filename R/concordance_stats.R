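## Concordance and association statistics: Fleiss' kappa for the
## multi-adjudicator review, chi-squared tests with adjusted standardized
## residuals, Fisher's exact test (full enumeration with a Monte-Carlo
## fallback), and the seeded stratified adjudication sampler.

#' Fleiss' kappa for a rating matrix
#'
#' Chance-corrected agreement for a fixed number of raters r over n items:
#' kappa = (Pbar - Pe) / (1 - Pe), with per-item agreement
#' P_i = sum_j n_ij (n_ij - 1) / (r (r - 1)), Pbar the item mean, and
#' Pe = sum_j p_j^2 for marginal category proportions p_j.
#'
#' @param m n x k integer matrix of category counts; every row must sum to
#'   the same r >= 2, k >= 2.
#' @return kappa in [-1, 1].
#' @export
fleiss_kappa <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 1, ncol(m) >= 2, all(m >= 0), all(m == round(m)))
  r <- sum(m[1, ])
  if (r < 2 || any(rowSums(m) != r)) {
    stop("every item must have the same number of raters r >= 2")
  }
  n <- nrow(m)
  p_j <- colSums(m) / (n * r)
  pe <- sum(p_j^2)
  if (1 - pe < .Machine$double.eps) {
    stop("kappa undefined: all ratings in a single category (Pe = 1)")
  }
  p_i <- (rowSums(m^2) - r) / (r * (r - 1))
  (mean(p_i) - pe) / (1 - pe)
}

#' Unanimity rate of a rating matrix
#'
#' Fraction of items on which one category holds all r ratings.
#'
#' @inheritParams fleiss_kappa
#' @return fraction in [0, 1].
#' @export
unanimity_rate <- function(m) {
  m <- as.matrix(m)
  r <- sum(m[1, ])
  mean(apply(m, 1, max) == r)
}

#' Pearson chi-squared test with adjusted standardized residuals
#'
#' Residuals r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N) (1 - col_j/N)),
#' used to localize which cells drive a significant overall test
#' (approximately standard normal under independence).
#'
#' @param t R x C nonnegative integer table (matrix; dimnames preserved).
#' @return list: statistic, df, p, expected, residuals (adjusted
#'   standardized).
#' @export
chi_squared <- function(t) {
  t <- as.matrix(t)
  stopifnot(all(t >= 0), sum(t) > 0)
  N <- sum(t)
  rs <- rowSums(t); cs <- colSums(t)
  E <- outer(rs, cs) / N
  if (any(E <= 0)) stop("degenerate table: zero expected count")
  stat <- sum((t - E)^2 / E)
  df <- (nrow(t) - 1L) * (ncol(t) - 1L)
  adj <- (t - E) / sqrt(E * outer(1 - rs / N, 1 - cs / N))
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE),
       expected = E, residuals = adj)
}

## log multivariate hypergeometric probability of an RxC table with fixed
## margins (product of multinomial coefficients over the total one).
log_table_prob <- function(t, rs, cs, N) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1) - sum(lgamma(t + 1))
}

## enumerate all RxC tables with the given margins, applying FUN to each;
## recursion fills row by row. Count guard handled by the caller.
enumerate_tables <- function(rs, cs, FUN) {
  R <- length(rs); C <- length(cs)
  tab <- matrix(0L, R, C)
  rec_row <- function(ri, cs_left) {
    if (ri == R) {
      tab[R, ] <<- cs_left
      FUN(tab)
      return(invisible())
    }
    fill_cell <- function(ci, remaining, cs_left) {
      if (ci == C) {
        if (remaining <= cs_left[C]) {
          tab[ri, C] <<- remaining
          cs2 <- cs_left; cs2[C] <- cs2[C] - remaining
          rec_row(ri + 1L, cs2)
        }
        return(invisible())
      }
      for (v in 0:min(remaining, cs_left[ci])) {
        tab[ri, ci] <<- v
        cs2 <- cs_left; cs2[ci] <- cs2[ci] - v
        fill_cell(ci + 1L, remaining - v, cs2)
      }
    }
    fill_cell(1L, rs[ri], cs_left)
  }
  rec_row(1L, cs)
}

## upper bound on the number of tables with the given margins
table_count_bound <- function(rs, cs) {
  prod(vapply(rs[-length(rs)], function(r) choose(r + length(cs) - 1, length(cs) - 1),
              numeric(1)))
}

#' Fisher's exact test for an R x C contingency table
#'
#' Two-sided p by the point-probability rule: sum of multivariate
#' hypergeometric probabilities, over all tables with the observed margins,
#' of tables whose probability does not exceed the observed table's (with a
#' small relative tolerance for floating-point ties). Full enumeration is
#' guarded at 1e7 tables; beyond that a seeded Monte-Carlo estimate over
#' margin-preserving simulated tables is used if enabled.
#'
#' @param t R x C nonnegative integer matrix.
#' @param monte_carlo allow the Monte-Carlo fallback (default FALSE).
#' @param B Monte-Carlo replicates (default 1e5).
#' @param seed Monte-Carlo seed.
#' @param force_monte_carlo skip enumeration even for small tables (used for
#'   self-consistency checks of the Monte-Carlo path).
#' @return list: p, method ("exact" or "monte_carlo"), and for Monte-Carlo
#'   the replicate count and seed.
#' @export
fisher_exact <- function(t, monte_carlo = FALSE, B = 1e5, seed = 1L,
                         force_monte_carlo = FALSE) {
  t <- as.matrix(t)
  stopifnot(all(t >= 0), all(t == round(t)), sum(t) > 0)
  rs <- rowSums(t); cs <- colSums(t); N <- sum(t)
  lp_obs <- log_table_prob(t, rs, cs, N)
  if (force_monte_carlo) monte_carlo <- TRUE
  if (!force_monte_carlo && table_count_bound(rs, cs) <= 1e7) {
    tol <- 1e-7
    psum <- 0
    enumerate_tables(rs, cs, function(tab) {
      lp <- log_table_prob(tab, rs, cs, N)
      if (lp <= lp_obs + tol) psum <<- psum + exp(lp)
    })
    return(list(p = min(psum, 1), method = "exact"))
  }
  if (!monte_carlo) {
    stop("table too large for exact enumeration; set monte_carlo = TRUE")
  }
  ## simulate margin-fixed tables via r2dtable (Patefield's algorithm)
  set.seed(seed)
  sims <- stats::r2dtable(B, rs, cs)
  lps <- vapply(sims, log_table_prob, numeric(1), rs = rs, cs = cs, N = N)
  p <- (sum(lps <= lp_obs + 1e-7) + 1) / (B + 1)
  list(p = p, method = "monte_carlo", B = B, seed = seed)
}

#' Stratified adjudication sampler
#'
#' Seeded, without-replacement, note-level sample stratified by detection
#' method, producing a review sheet with the note text, the highlighted
#' span, and blank rating columns for r raters. A stratum smaller than the
#' request is sampled in full with a warning; an empty stratum is skipped
#' with a warning.
#'
#' @param mentions mention table (note_id, patient_id, method, surface,
#'   start, end, ...); one note is sampled at most once per stratum.
#' @param notes notes table (note_id, text) to pull display text from.
#' @param per_method_n notes per method stratum (e.g. 100).
#' @param seed RNG seed.
#' @param raters number of blank rating columns (default 3).
#' @return review-sheet \code{data.table}.
#' @export
sample_adjudication <- function(mentions, notes, per_method_n, seed = 1L,
                                raters = 3L) {
  mentions <- as.data.table(mentions)
  notes <- as.data.table(notes)
  sheet <- list()
  set.seed(seed)
  for (m in sort(unique(mentions$method))) {
    pool <- unique(mentions[method == m], by = "note_id")
    if (nrow(pool) == 0L) {
      warning("empty stratum for method '", m, "'; skipped")
      next
    }
    n_take <- min(per_method_n, nrow(pool))
    if (n_take < per_method_n) {
      warning("stratum '", m, "' has only ", nrow(pool), " notes; sampling all")
    }
    if (n_take == 0L) next
    take <- pool[sample(.N, n_take)]
    take <- merge(take, notes[, .(note_id, text)], by = "note_id", sort = FALSE)
    take[, highlight := paste0(substr(text, 1, start), "[[",
                               substr(text, start + 1, end), "]]",
                               substr(text, end + 1, nchar(text)))]
    sheet[[length(sheet) + 1L]] <-
      take[, .(note_id, patient_id, method, surface, start, end, highlight)]
  }
  if (!length(sheet)) {
    out <- data.table(note_id = character(), patient_id = character(),
                      method = character(), surface = character(),
                      start = integer(), end = integer(), highlight = character())
  } else out <- rbindlist(sheet)
  for (r in seq_len(raters)) out[, paste0("rater_", r) := NA_character_]
  out[]
}
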