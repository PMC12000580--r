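# Centriole inheritance through spermatogonial cyst divisions.
#
# A goniablast carries an engaged centriole pair (2 centrioles). Four
# synchronous symmetric mitoses produce a 16-cell cyst; at each division the
# centrioles duplicate (count doubles) unless duplication has failed, and the
# pool is segregated as evenly as possible between the daughters. After the
# mitoses, spermatocytes normally duplicate once more before meiosis, ending
# with 4 centrioles per cell.

#' One cell division under the inheritance model
#'
#' Doubles the centriole count when duplication is active, then splits the
#' pool as evenly as possible (`ceiling(n/2)`, `floor(n/2)`) between the two
#' daughters. Total centrioles are conserved across the split.
#'
#' @param count non-negative integer centriole count of the mother cell.
#' @param duplication_active logical; has duplication occurred this cycle?
#' @return integer pair of daughter counts.
#' @export
divide_cell <- function(count, duplication_active) {
  if (count < 0 || count != round(count))
    stop_uexm("count must be a non-negative integer", "uexm_validation_error")
  n <- if (duplication_active) 2L * as.integer(count) else as.integer(count)
  c(as.integer(ceiling(n / 2)), as.integer(floor(n / 2)))
}

#' Centriole-count distribution of a 16-cell cyst
#'
#' Runs the four cyst mitoses from a single cell with one engaged centriole
#' pair, with duplication active up to (and inactive from) the chosen failure
#' stage. With no failure, each spermatocyte then duplicates once more
#' (pre-meiotic S phase), giving 4 centrioles per cell. Failure from the
#' 8-cell stage leaves every final cell with a single centriole; failure from
#' the 4-cell stage additionally halves the pool once more, leaving half the
#' descendants with one centriole and half with none.
#'
#' @param failure_onset `"none"`, `"stage4"` (duplication fails from the
#'   4-cell stage onward) or `"stage8"` (fails from the 8-cell stage).
#' @param premeiotic_duplication should unaffected spermatocytes duplicate
#'   once more after the mitoses? Default `TRUE`.
#' @return object of class `lineage_outcome`: `cells` (16 final counts),
#'   `counts` (named tally over classes `0C`..`4C`), `scenario`,
#'   `premeiotic_duplication`.
#' @export
simulate_cyst <- function(failure_onset = c("none", "stage4", "stage8"),
                          premeiotic_duplication = TRUE) {
  failure_onset <- match.arg(failure_onset)
  # duplication is active for divisions of cells at stages (cell counts)
  # 1, 2, 4, 8 strictly before the failure-onset stage
  fail_from <- switch(failure_onset, none = Inf, stage4 = 4, stage8 = 8)
  cells <- 2L  # goniablast: one engaged pair
  for (stage in c(1L, 2L, 4L, 8L)) {
    active <- stage < fail_from
    cells <- unlist(lapply(cells, divide_cell,
                           duplication_active = active))
  }
  if (premeiotic_duplication && failure_onset == "none")
    cells <- 2L * cells
  classes <- paste0(0:4, "C")
  counts <- table(factor(paste0(pmin(cells, 4L), "C"), levels = classes))
  out <- as.integer(counts)
  names(out) <- classes
  structure(list(cells = cells, counts = out, scenario = failure_onset,
                 premeiotic_duplication = premeiotic_duplication),
            class = "lineage_outcome")
}

#' Predicted centriole-count distribution under a failure mixture
#'
#' Mixture of the two duplication-failure scenarios consistent with a
#' knockdown acting between the 4- and 16-cell stages: a fraction `f` of
#' final cells descend from lineages failing at the 4-cell stage (half of
#' which end with 0 centrioles, half with 1), and the remaining `1 - f` from
#' 8-cell-stage failures (all ending with 1). Hence `P(0C) = f/2` and
#' `P(1C) = 1 - f/2`; both components are taken from [simulate_cyst()], not
#' hard-coded.
#'
#' @param f mixture fraction in `[0, 1]`.
#' @return named probability vector over classes `0C`..`4C`.
#' @export
predict_distribution <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop_uexm("f must lie in [0, 1]", "uexm_validation_error")
  p8 <- simulate_cyst("stage8")$counts
  p4 <- simulate_cyst("stage4")$counts
  p8 <- p8 / sum(p8)
  p4 <- p4 / sum(p4)
  f * p4 + (1 - f) * p8
}

# multinomial log-likelihood of the observed 0C/1C counts at mixture f,
# with the 0*log(0) = 0 convention at the boundaries
mixture_loglik <- function(f, n0, n1) {
  p0 <- f / 2
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(p0)
  if (n1 > 0) ll <- ll + n1 * log(1 - p0)
  ll
}

#' Fit the duplication-failure mixture to an observed count table
#'
#' Maximum multinomial likelihood for the fraction `f` of final cells
#' descending from 4-cell-stage failures, given observed numbers of cells
#' with 0 and 1 centrioles. The likelihood is maximized on a grid over
#' `[0, 1]` refined by golden-section search; the closed form
#' `f_hat = 2 * n0 / (n0 + n1)` (clipped to `[0, 1]`) is reported alongside
#' as a check. Classes other than `0C`/`1C` (e.g. escaper `2C` pairs) are
#' excluded with a warning and reported as `n_residual`.
#'
#' @param observed named integer vector of counts, e.g.
#'   `c("1C" = 82, "0C" = 6)`.
#' @return object of class `mixture_fit`: `f_hat`, `f_closed_form`,
#'   `loglik`, `predicted` (full class distribution at `f_hat`), `observed`,
#'   `n_residual`.
#' @export
fit_failure_mixture <- function(observed) {
  if (length(observed) == 0L || is.null(names(observed)))
    stop_uexm("observed must be a named count vector", "uexm_validation_error")
  if (any(observed < 0))
    stop_uexm("counts must be non-negative", "uexm_validation_error")
  n0 <- sum(observed[names(observed) == "0C"])
  n1 <- sum(observed[names(observed) == "1C"])
  n_res <- sum(observed) - n0 - n1
  if (n_res > 0)
    warning(sprintf(
      "%d cells outside the 0C/1C classes excluded from the mixture fit",
      n_res))
  if (n0 + n1 == 0L)
    stop_uexm("no 0C or 1C cells to fit", "uexm_validation_error")

  grid <- seq(0, 1, by = 1e-3)
  ll <- vapply(grid, mixture_loglik, 1.0, n0 = n0, n1 = n1)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  f_hat <- if (lo == hi) lo else
    stats::optimize(mixture_loglik, c(lo, hi), n0 = n0, n1 = n1,
                    maximum = TRUE, tol = 1e-9)$maximum
  # snap to the boundary when the grid maximum sits there
  if (i == 1L && mixture_loglik(0, n0, n1) >= mixture_loglik(f_hat, n0, n1))
    f_hat <- 0
  if (i == length(grid) &&
      mixture_loglik(1, n0, n1) >= mixture_loglik(f_hat, n0, n1))
    f_hat <- 1
  f_cf <- min(1, max(0, 2 * n0 / (n0 + n1)))
  structure(list(f_hat = f_hat, f_closed_form = f_cf,
                 loglik = mixture_loglik(f_hat, n0, n1),
                 predicted = predict_distribution(f_hat),
                 observed = observed, n_residual = n_res),
            class = "mixture_fit")
}
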