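#' Tidy a resampling association result
#'
#' One row in the layout of cohort summary tables: group sizes, percent
#' high, mean resampled difference M, its SD, the Z-score `Z = -M/SD` and
#' the two-sided normal p-value (also given rounded to two significant
#' figures as `p_2sf`, the precision used in printed tables).
#'
#' @param x An `evi1_bootstrap` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.evi1_bootstrap <- function(x, ...) {
  tibble::tibble(
    n_high = x$n_high, n_low = x$n_low, pct_high = x$pct_high,
    M = x$M, SD = x$SD, Z = x$Z,
    p_two_sided = x$p_two_sided, p_2sf = signif(x$p_two_sided, 2)
  )
}

#' @rdname tidy.evi1_bootstrap
#' @export
glance.evi1_bootstrap <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter, seed = x$seed, replace = x$replace,
    degenerate = x$degenerate
  )
}

#' Tidy a cutoff-finding result
#'
#' @param x An `evi1_cutoff` object.
#' @param ... Unused.
#' @return `tidy()`: one row per local minimum with its density and
#'   whether it was chosen; `glance()`: one row with the cutoff and rule.
#' @export
tidy.evi1_cutoff <- function(x, ...) {
  tibble::tibble(
    minimum_x = x$minima,
    density = x$minima_density,
    chosen = !is.na(x$cutoff) & x$minima == x$cutoff
  )
}

#' @rdname tidy.evi1_cutoff
#' @export
glance.evi1_cutoff <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, rule_applied = x$rule_applied,
    n_minima = length(x$minima), max_density = x$max_density
  )
}

#' Tidy a full cohort-association fit
#'
#' The one-row summary mirroring published cohort tables: Cutoff, #high,
#' #low, %high, M, SD, Z, P.
#'
#' @param x An `evi1_cohort_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.evi1_cohort_assoc <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cutoff = x$cutoff_result$cutoff),
    tidy(x$bootstrap)
  )
}

#' @rdname tidy.evi1_cohort_assoc
#' @export
glance.evi1_cohort_assoc <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$cutoff_result),
    glance(x$bootstrap)
  )
}
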