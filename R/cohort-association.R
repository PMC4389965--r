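#' Kernel density estimate of log2 expression values
#'
#' Gaussian-kernel density on an evenly spaced grid of at least `n_grid`
#' points spanning `[min - 3h, max + 3h]` where `h` is the bandwidth.
#' Silverman's rule of thumb is the default bandwidth; a numeric bandwidth
#' may be supplied instead. The estimate integrates to 1 (trapezoid rule)
#' to within 1e-3.
#'
#' @param values Numeric vector, length >= 10, non-constant.
#' @param bandwidth `"silverman"` or a positive number (log2 units).
#' @param n_grid Number of grid points (default 512).
#' @return A tibble with columns `x` and `density`, carrying the bandwidth
#'   in attribute `"bw"`.
#' @export
estimate_density <- function(values, bandwidth = "silverman", n_grid = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) stop_bad_arg("need at least 10 finite values")
  if (stats::var(values) == 0) stop_bad_arg("values are constant; no density structure")
  bw <- if (identical(bandwidth, "silverman")) {
    stats::bw.nrd0(values)
  } else {
    check_number(bandwidth, "bandwidth", min = 0, strict = TRUE)
  }
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      n = n_grid, cut = 3)
  out <- tibble::tibble(x = d$x, density = d$y)
  attr(out, "bw") <- bw
  out
}

#' Locate the expression cutoff at a density minimum
#'
#' Finds the interior local minima of a density grid. With exactly one
#' minimum, that point is the cutoff. With several, the five-percent rule
#' applies: among minima whose density is below `five_pct` of the maximal
#' density, the one closest to the dominant low-expression mode — the
#' qualifying minimum with the smallest `x` above the global density mode —
#' defines the cutoff. A unimodal density yields `rule_applied =
#' "none_found"` (a signal, not an error).
#'
#' @param density_grid Tibble with columns `x`, `density` (e.g. from
#'   [estimate_density()]).
#' @param five_pct Fraction of the maximal density below which a minimum
#'   qualifies when several exist (default 0.05).
#' @param min_prominence Minimum relative depth of a valley: a local
#'   minimum counts only if the density rises above it by this fraction of
#'   the lower flanking peak on both sides (default 0.1). Filters the
#'   shallow wiggles a kernel estimate produces near a mode, which are
#'   estimation noise rather than evidence of a second component.
#' @return An object of class `evi1_cutoff`: a list with `cutoff` (or `NA`),
#'   `minima`, `max_density`, `rule_applied` (`"single_minimum"`,
#'   `"five_percent_rule"` or `"none_found"`) and the grid.
#' @export
find_cutoff <- function(density_grid, five_pct = 0.05, min_prominence = 0.1) {
  x <- density_grid$x
  y <- density_grid$density
  if (length(x) < 3L) stop_bad_arg("density grid too short")
  i <- 2:(length(y) - 1L)
  is_min <- y[i] < y[i - 1L] & y[i] <= y[i + 1L]
  cand <- i[is_min]
  # keep genuine valleys: density must exceed the minimum by min_prominence
  # of the flanking maximum on both sides
  genuine <- vapply(cand, function(j) {
    left <- max(y[1:j]); right <- max(y[j:length(y)])
    y[j] <= (1 - min_prominence) * min(left, right)
  }, logical(1))
  minima <- x[cand][genuine]
  minima_y <- y[cand][genuine]
  max_density <- max(y)
  mode_x <- x[which.max(y)]

  if (length(minima) == 0L) {
    cutoff <- NA_real_; rule <- "none_found"
  } else if (length(minima) == 1L) {
    cutoff <- minima; rule <- "single_minimum"
  } else {
    qual <- minima_y < five_pct * max_density & minima > mode_x
    if (any(qual)) {
      cutoff <- min(minima[qual]); rule <- "five_percent_rule"
    } else {
      cutoff <- NA_real_; rule <- "none_found"
    }
  }
  structure(
    list(cutoff = cutoff, minima = minima, minima_density = minima_y,
         max_density = max_density, mode_x = mode_x,
         rule_applied = rule, five_pct = five_pct, grid = density_grid),
    class = "evi1_cutoff"
  )
}

#' @export
print.evi1_cutoff <- function(x, ...) {
  cat(sprintf("<evi1_cutoff> rule: %s; cutoff: %s (%d local minima)\n",
              x$rule_applied,
              if (is.na(x$cutoff)) "none" else sprintf("%.3f", x$cutoff),
              length(x$minima)))
  invisible(x)
}

#' Split a cohort into high and low expressors at a cutoff
#'
#' Labels each patient `"high"` when the splitter gene exceeds the cutoff
#' and `"low"` otherwise; values exactly equal to the cutoff are assigned
#' to the low group (deterministic, conservative high-group membership).
#'
#' @param cohort Tibble with the splitter column (default `evi1_log2`).
#' @param cutoff Numeric cutoff (log2 units).
#' @param splitter Name of the splitter column.
#' @return `cohort` with an added `group` column.
#' @seealso [pct_high()]
#' @export
dichotomize <- function(cohort, cutoff, splitter = "evi1_log2") {
  cutoff <- check_number(cutoff, "cutoff")
  dplyr::mutate(
    tibble::as_tibble(cohort),
    group = dplyr::if_else(.data[[splitter]] > cutoff, "high", "low")
  )
}

#' Percentage of high-expressing patients
#'
#' `100 * n_high / (n_high + n_low)`, rounded to one decimal for reporting
#' (the precision used in cohort summary tables).
#'
#' @param n_high,n_low Group sizes.
#' @return A single number (percent).
#' @examples
#' pct_high(18, 229)  # 7.3
#' @export
pct_high <- function(n_high, n_low) {
  round(100 * n_high / (n_high + n_low), 1)
}

#' Two-sided normal p-value from a Z-score
#'
#' `p = 2 * (1 - pnorm(|z|))`: the two-sided tail probability of the
#' standard normal distribution.
#'
#' @param z Z-score(s).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' signif(z_to_p(2.56), 2)  # 0.010
#' @export
z_to_p <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Resampling test for response-gene difference between expression groups
#'
#' Compares the high-expressor group to `n_iter` randomly sampled,
#' equally sized groups of low expressors. In each iteration the difference
#' `d_i` between the mean response of the high group and that of the sampled
#' low group is recorded; the test reports `M = mean(d_i)`,
#' `SD = sd(d_i)` (sample SD, n-1 denominator), the Z-score of the sampling
#' distribution `Z = -M/SD`, and the two-sided normal p-value. Repression of
#' the response gene in the high group gives `M < 0` and hence `Z > 0`.
#'
#' Sampling is without replacement within each iteration (distinct
#' patients); set `replace = TRUE` for classical bootstrap draws.
#'
#' @param cohort Tibble with a `group` column (from [dichotomize()]) and the
#'   response column.
#' @param n_iter Number of resampling iterations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @param response Name of the response column.
#' @param replace Sample low-group patients with replacement?
#' @return An object of class `evi1_bootstrap`; see [tidy.evi1_bootstrap()].
#' @export
bootstrap_association <- function(cohort, n_iter = 10000L, seed = 1L,
                                  response = "ms4a3_log2", replace = FALSE) {
  n_iter <- check_count(n_iter, "n_iter", min = 1L)
  if (!"group" %in% names(cohort)) {
    stop_bad_arg("`cohort` must carry a 'group' column; see dichotomize()")
  }
  resp_high <- cohort[[response]][cohort$group == "high"]
  resp_low <- cohort[[response]][cohort$group == "low"]
  n_high <- length(resp_high)
  n_low <- length(resp_low)
  if (n_high < 2L) stop_bad_arg("need at least 2 high-group patients, got %d", n_high)
  if (!replace && n_low < n_high) {
    stop_bad_arg("low group (%d) smaller than high group (%d)", n_low, n_high)
  }
  local_seed(check_count(seed, "seed"))
  mean_high <- mean(resp_high)
  d <- vapply(seq_len(n_iter), function(i) {
    mean_high - mean(resp_low[sample.int(n_low, n_high, replace = replace)])
  }, numeric(1))
  M <- mean(d)
  SD <- stats::sd(d)
  degenerate <- n_iter < 2L || !is.finite(SD) || SD == 0
  Z <- if (degenerate) 0 else -M / SD
  p <- if (degenerate) 1 else z_to_p(Z)
  structure(
    list(n_high = n_high, n_low = n_low,
         pct_high = pct_high(n_high, n_low),
         M = M, SD = SD, Z = Z, p_two_sided = p,
         n_iter = n_iter, seed = seed, replace = replace,
         degenerate = degenerate, d = d),
    class = "evi1_bootstrap"
  )
}

#' @export
print.evi1_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<evi1_bootstrap> n_high=%d n_low=%d (%.1f%% high)\n  M=%.3f SD=%.3f Z=%.2f p=%.2g (%d iterations)%s\n",
    x$n_high, x$n_low, x$pct_high, x$M, x$SD, x$Z, x$p_two_sided, x$n_iter,
    if (x$degenerate) " [degenerate: zero-variance sampling distribution]" else ""
  ))
  invisible(x)
}

#' Cohort dichotomization and association test in one step
#'
#' Estimates the splitter-gene density, locates the cutoff at a density
#' minimum, dichotomizes the cohort and runs the resampling association
#' test of the response gene — the full procedure behind cohort summary
#' tables (Cutoff, #high, #low, %high, M, SD, Z, P).
#'
#' @param cohort Tibble with splitter and response columns.
#' @param n_iter,seed,replace Passed to [bootstrap_association()].
#' @param bandwidth,five_pct Passed to [estimate_density()] /
#'   [find_cutoff()].
#' @param splitter,response Column names.
#' @return An object of class `evi1_cohort_assoc` bundling the
#'   `evi1_cutoff` and `evi1_bootstrap` results; `tidy()` returns the
#'   one-row summary table.
#' @examples
#' cohort <- simulate_cohort(cohort_design(seed = 11))
#' fit <- cohort_association(cohort, n_iter = 1000, seed = 11)
#' tidy(fit)
#' @export
cohort_association <- function(cohort, n_iter = 10000L, seed = 1L,
                               bandwidth = "silverman", five_pct = 0.05,
                               splitter = "evi1_log2",
                               response = "ms4a3_log2", replace = FALSE) {
  grid <- estimate_density(cohort[[splitter]], bandwidth = bandwidth)
  cut <- find_cutoff(grid, five_pct = five_pct)
  if (is.na(cut$cutoff)) {
    stop_bad_arg("no qualifying density minimum found (rule: %s); cohort not dichotomizable",
                 cut$rule_applied)
  }
  labelled <- dichotomize(cohort, cut$cutoff, splitter = splitter)
  boot <- bootstrap_association(labelled, n_iter = n_iter, seed = seed,
                                response = response, replace = replace)
  structure(
    list(cutoff_result = cut, bootstrap = boot, data = labelled,
         splitter = splitter, response = response),
    class = "evi1_cohort_assoc"
  )
}

#' @export
print.evi1_cohort_assoc <- function(x, ...) {
  cat(sprintf("<evi1_cohort_assoc> cutoff %.3f (%s)\n",
              x$cutoff_result$cutoff, x$cutoff_result$rule_applied))
  print(x$bootstrap)
  invisible(x)
}
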