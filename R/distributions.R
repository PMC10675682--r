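# Association-number distributions: F_n / F_w histograms, averages,
# unimer fractions, and the main-peak / tail decomposition.

#' Association-number distributions of an aggregate table
#'
#' Pools aggregates over all frames and forms unit-bin histograms over
#' the association number `A_S`:
#'
#' * `F_n(A) = count(A) / total aggregates` (number fraction),
#' * `F_w(A) = A count(A) / sum A count(A)` (weight fraction),
#'
#' together with the number-average `An = sum A F_n(A)` and
#' weight-average `Aw = sum A^2 count(A) / sum A count(A)` association
#' numbers, the unimer fractions of [unimer_fractions()] and the
#' main-peak/tail boundary of [split_main_tail()].
#'
#' @param aggregates A tibble with an `a_s` column (e.g. from
#'   [aggregate_trajectory()]), an `aggregate_set`, or a bare integer
#'   vector of association numbers.
#' @param smooth_window Odd moving-average window used by the minimum
#'   and second-derivative detectors (default 3 bins).
#' @return Object of class `dpd_distributions`; see [tidy.dpd_distributions()]
#'   and [glance.dpd_distributions()].
#' @examples
#' d <- aggregate_distributions(c(rep(1, 9), 10))
#' glance(d)$Aw_avg  # (9 + 100) / 19
#' @export
aggregate_distributions <- function(aggregates, smooth_window = 3) {
  a_s <- if (is.numeric(aggregates)) as.integer(aggregates)
         else as.integer(aggregates$a_s)
  if (!length(a_s)) rlang::abort("no aggregates to histogram")
  stopifnot(all(a_s >= 1))
  amax <- max(a_s)
  count <- tabulate(a_s, nbins = amax)
  grid <- seq_len(amax)
  total <- sum(count)
  wsum <- sum(grid * count)
  F_n <- count / total
  F_w <- grid * count / wsum
  tbl <- tibble::tibble(a_s = grid, count = count, F_n = F_n, F_w = F_w)
  obj <- structure(
    list(table = tbl,
         An_avg = sum(grid * F_n),
         Aw_avg = sum(grid^2 * count) / wsum,
         n_aggregates = total,
         smooth_window = smooth_window),
    class = "dpd_distributions"
  )
  # detector fallbacks are encoded in the fields (f_low == f_1 with
  # low_minimum NA; split_As == max a_s); the warnings are for direct calls
  uf <- suppressWarnings(unimer_fractions(obj))
  obj$f_1 <- uf$f_1
  obj$f_low <- uf$f_low
  obj$low_minimum <- uf$minimum
  sp <- suppressWarnings(split_main_tail(obj))
  obj$split_As <- sp$split_As
  obj$tail_weight <- sp$tail_weight
  obj
}

#' @export
print.dpd_distributions <- function(x, ...) {
  cat(sprintf(
    "<dpd_distributions> %d aggregates, A_S in [1, %d]\n  An = %.3f, Aw = %.3f, f_1 = %.3f, f_low = %.3f, main-peak/tail split at A_S = %s\n",
    x$n_aggregates, max(x$table$a_s), x$An_avg, x$Aw_avg, x$f_1, x$f_low,
    format(x$split_As)))
  invisible(x)
}

#' Unimer and low-associate number fractions
#'
#' `f_1` is the number fraction of free chains, `F_n(1)`.  `f_low` sums
#' `F_n` up to the interior minimum of the smoothed number distribution
#' between the unimer peak and the main associate peak (ties broken
#' toward the smallest `A_S`), capturing unimers together with the low
#' associates that coexist with them.  When no interior minimum exists
#' (monotone distribution, or no associate peak) `f_low` falls back to
#' `f_1` with a warning.
#'
#' @param dist A `dpd_distributions` object, or a numeric vector of
#'   `F_n` values on the unit grid `A_S = 1, 2, ...`.
#' @param smooth_window Odd moving-average window (default: the one
#'   stored in `dist`, else 3).
#' @return List with `f_1`, `f_low` and `minimum` (the `A_S` of the
#'   detected minimum, `NA` on the fallback path).
#' @export
unimer_fractions <- function(dist, smooth_window = NULL) {
  if (inherits(dist, "dpd_distributions")) {
    F_n <- dist$table$F_n
    smooth_window <- smooth_window %||% dist$smooth_window
  } else {
    F_n <- dist
    smooth_window <- smooth_window %||% 3
  }
  f_1 <- if (length(F_n) >= 1) F_n[1] else 0
  s <- moving_average(F_n, smooth_window)
  n <- length(s)
  # main associate peak: the highest smoothed value beyond A_S = 1
  fallback <- function(msg) {
    rlang::warn(msg)
    list(f_1 = f_1, f_low = f_1, minimum = NA_integer_)
  }
  if (n < 3) return(fallback("distribution too narrow for an interior minimum; f_low = f_1"))
  # main associate peak: the highest genuine local maximum of the smoothed
  # curve beyond A_S = 1 (a decaying unimer shoulder is not a peak)
  left <- c(Inf, s[-n])
  right <- c(s[-1], -Inf)
  cand <- which(s > left & s >= right & seq_len(n) >= 3L)
  if (!length(cand)) {
    return(fallback("no associate peak beyond the unimers; f_low = f_1"))
  }
  peak <- cand[which.max(s[cand])]
  interior <- 2:(peak - 1L)
  m <- interior[which.min(s[interior])]
  # a genuine minimum must lie below both flanks
  if (!(s[m] <= s[1] && s[m] <= s[peak])) {
    return(fallback("no interior minimum between unimer and associate peaks; f_low = f_1"))
  }
  list(f_1 = f_1, f_low = sum(F_n[1:m]), minimum = m)
}

#' Main-peak / tail boundary of the weight distribution
#'
#' The weight distribution of associates is split into the main peak
#' (spherical-micelle region) and the high-`A_S` tail at the maximum of
#' the discrete second derivative of the smoothed `F_w` beyond the main
#' mode -- the point of sharpest upward curvature where the shoulder
#' hands over to the tail.  Ties go to the smallest `A_S`.  A monotone
#' distribution has no split; the largest `A_S` is returned with a
#' warning.
#'
#' @inheritParams unimer_fractions
#' @param dist A `dpd_distributions` object or a numeric `F_w` vector on
#'   the unit grid.
#' @return List with `split_As` and `tail_weight` (total `F_w` beyond
#'   the split).
#' @export
split_main_tail <- function(dist, smooth_window = NULL) {
  if (inherits(dist, "dpd_distributions")) {
    F_w <- dist$table$F_w
    smooth_window <- smooth_window %||% dist$smooth_window
  } else {
    F_w <- dist
    smooth_window <- smooth_window %||% 3
  }
  n <- length(F_w)
  s <- moving_average(F_w, smooth_window)
  mode_i <- which.max(s)
  if (n < 3 || mode_i >= n - 1) {
    rlang::warn("no main peak with a descending flank; no main-peak/tail split")
    return(list(split_As = n, tail_weight = 0))
  }
  # discrete second derivative on the descending side, beyond the mode
  idx <- (mode_i + 1L):(n - 1L)
  d2 <- s[idx - 1L] - 2 * s[idx] + s[idx + 1L]
  split <- idx[which.max(d2)]
  list(split_As = split, tail_weight = sum(F_w[seq_len(n) > split]))
}

#' Tidy an association-number distribution
#'
#' @param x A `dpd_distributions`.
#' @param ... Unused.
#' @return Tibble with `a_s`, `count`, `F_n`, `F_w`.
#' @export
tidy.dpd_distributions <- function(x, ...) x$table

#' One-row summary of an association-number distribution
#'
#' @param x A `dpd_distributions`.
#' @param ... Unused.
#' @return Tibble with `n_aggregates`, `An_avg`, `Aw_avg`, `f_1`,
#'   `f_low`, `split_As`, `tail_weight`.
#' @export
glance.dpd_distributions <- function(x, ...) {
  tibble::tibble(n_aggregates = x$n_aggregates, An_avg = x$An_avg,
                 Aw_avg = x$Aw_avg, f_1 = x$f_1, f_low = x$f_low,
                 split_As = x$split_As, tail_weight = x$tail_weight)
}
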