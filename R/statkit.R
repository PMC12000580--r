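# Exact statistics implemented from first principles: two-sided Fisher
# tests on contingency tables (2x2 hypergeometric; r x c by enumeration or
# seeded Monte Carlo) and the two-sided unpaired Wilcoxon rank-sum test
# (exact permutation distribution for small tie-free samples, otherwise a
# tie-corrected normal approximation with continuity correction).

new_test_result <- function(statistic, p_value, method, exact_flag,
                            mc_reps = NA_integer_, seed = NA_integer_) {
  structure(list(statistic = statistic, p_value = min(1, max(0, p_value)),
                 method = method, exact_flag = exact_flag,
                 mc_reps = mc_reps, seed = seed),
            class = "uexm_test_result")
}

validate_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_uexm("table entries must be non-negative integers",
              "uexm_validation_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_uexm("every row and column margin must be positive",
              "uexm_validation_error")
  storage.mode(tab) <- "integer"
  tab
}

# log multivariate hypergeometric probability of a table with fixed margins
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# recursively enumerate log-probabilities of all r x c tables with the
# observed margins (feasible for small totals)
enumerate_table_logprobs <- function(rs, cs) {
  r <- length(rs)
  out <- numeric(0)
  cells <- matrix(0L, r, length(cs))
  rec <- function(j, rs_left) {
    if (j == length(cs)) {
      cells[, j] <<- rs_left
      out[length(out) + 1L] <<- log_table_prob(cells)
      return(invisible())
    }
    # distribute column j among rows subject to remaining row margins
    fill_col <- function(i, col_left, col) {
      if (i == r) {
        if (col_left > rs_left[r]) return(invisible())
        col[r] <- col_left
        cells[, j] <<- col
        rec(j + 1L, rs_left - col)
        return(invisible())
      }
      for (v in 0:min(rs_left[i], col_left))
        fill_col(i + 1L, col_left - v, `[<-`(col, i, v))
    }
    fill_col(1L, cs[j], integer(r))
  }
  rec(1L, rs)
  out
}

#' Fisher exact test on a contingency table
#'
#' Two-sided exact test of independence. For 2x2 tables the p-value is the
#' sum of hypergeometric probabilities of all tables (with the observed
#' margins) at most as probable as the observed one — the convention used by
#' R's own implementation; `convention = "double_tail"` instead doubles the
#' smaller one-sided tail (capped at 1), as some commercial software does.
#' Larger tables are handled by full enumeration when the total is at most
#' `enumerate_limit`, otherwise by seeded Monte Carlo over random tables with
#' the observed margins.
#'
#' @param tab integer matrix (counts) with positive row/column margins.
#' @param mc_reps Monte Carlo replicates for large tables (default 1e4).
#' @param seed integer seed used only on the Monte Carlo path.
#' @param convention `"sum_smaller"` (default) or `"double_tail"` (2x2 only).
#' @param enumerate_limit largest table total enumerated exactly.
#' @return a `uexm_test_result`; `statistic` is the sample odds ratio for
#'   2x2 tables, `NA` otherwise.
#' @export
fisher_exact <- function(tab, mc_reps = 10000L, seed = 1L,
                         convention = c("sum_smaller", "double_tail"),
                         enumerate_limit = 200L) {
  convention <- match.arg(convention)
  tab <- validate_table(tab)
  tol <- 1 + 1e-7

  if (all(dim(tab) == c(2L, 2L))) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    a <- tab[1, 1]
    support <- max(0L, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    p <- switch(convention,
      sum_smaller = sum(probs[probs <= p_obs * tol]),
      double_tail = min(1, 2 * min(sum(probs[support <= a]),
                                   sum(probs[support >= a]))))
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    return(new_test_result(or, p, sprintf("Fisher exact (2x2, %s)",
                                          convention), TRUE))
  }

  if (convention == "double_tail")
    stop_uexm("double_tail convention is defined for 2x2 tables only",
              "uexm_validation_error")
  lp_obs <- log_table_prob(tab)
  if (sum(tab) <= enumerate_limit) {
    lps <- enumerate_table_logprobs(rowSums(tab), colSums(tab))
    p <- sum(exp(lps)[exp(lps) <= exp(lp_obs) * tol])
    return(new_test_result(NA_real_, p, "Fisher exact (r x c, enumeration)",
                           TRUE))
  }
  lps <- withr::with_seed(seed, {
    tabs <- stats::r2dtable(mc_reps, rowSums(tab), colSums(tab))
    vapply(tabs, log_table_prob, 1.0)
  })
  p <- (1 + sum(lps <= lp_obs + log(tol))) / (mc_reps + 1)
  new_test_result(NA_real_, p, "Fisher exact (r x c, Monte Carlo)", FALSE,
                  mc_reps = as.integer(mc_reps), seed = as.integer(seed))
}

#' Two-sided unpaired Wilcoxon rank-sum test
#'
#' Mid-ranks are used for ties. In exact mode (automatic when the combined
#' sample size is at most 12 and there are no ties) the full permutation
#' distribution of the rank sum is enumerated and the two-sided p-value is
#' the probability of a rank sum at least as far from its null mean as
#' observed. Otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used.
#'
#' @param x,y numeric samples (nonempty).
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @return a `uexm_test_result`; `statistic` is the Mann-Whitney U of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop_uexm("both samples must be nonempty", "uexm_validation_error")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (mode == "auto") mode <- if (N <= 12L && !ties) "exact" else
    "normal_approx"

  if (mode == "exact") {
    if (ties)
      stop_uexm("exact mode requires tie-free samples", "uexm_validation_error")
    # permutation distribution of the rank sum by dynamic programming:
    # counts[k + 1, s + 1] = number of size-k subsets of ranks 1..N summing
    # to s (tie-free ranks are exactly the integers 1..N)
    smax <- sum(seq.int(N - m + 1L, N))
    counts <- matrix(0, m + 1L, smax + 1L)
    counts[1L, 1L] <- 1
    for (rk in seq_len(N)) {
      kmax <- min(rk, m)
      for (k in kmax:1) {
        s <- seq.int(rk, smax)
        counts[k + 1L, s + 1L] <- counts[k + 1L, s + 1L] +
          counts[k, s - rk + 1L]
      }
    }
    dist <- counts[m + 1L, ]
    sums <- seq.int(0L, smax)
    mu <- m * (N + 1) / 2
    p <- sum(dist[abs(sums - mu) >= abs(W - mu) - 1e-9]) / choose(N, m)
    return(new_test_result(U, p, "Wilcoxon rank-sum (exact enumeration)",
                           TRUE))
  }
  mu_U <- m * n / 2
  tie_tab <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0)  # all observations identical
    return(new_test_result(U, 1, "Wilcoxon rank-sum (normal approximation)",
                           FALSE))
  z <- (abs(U - mu_U) - 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-max(0, z))
  new_test_result(U, p, "Wilcoxon rank-sum (normal approximation)", FALSE)
}

#' Five-number box-plot summary with 10/90 percentile whiskers
#'
#' Median, quartiles, and 10th/90th percentiles (linear-interpolation type-7
#' convention), matching box plots whose whiskers extend to the 10th and
#' 90th percentiles.
#'
#' @param values numeric vector (n >= 1).
#' @return object of class `box_summary`: `p10`, `q1`, `median`, `q3`,
#'   `p90`, `n`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop_uexm("values must contain at least one observation",
              "uexm_validation_error")
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                       names = FALSE)
  structure(list(p10 = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 p90 = q[5], n = length(values)),
            class = "box_summary")
}
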