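#' Delta-delta-Ct relative quantification of qPCR data
#'
#' Implements the standard ddCt calculation with an assumed amplification
#' efficiency of 2. Technical replicates are averaged on the Ct scale
#' before differencing; then per biological replicate
#' `dCt = mean(Ct_target) - mean(Ct_housekeeping)` within each condition,
#' `ddCt = dCt(condition) - dCt(reference)` (paired within the replicate),
#' and `fold = 2^(-ddCt)`. Mean fold change and the standard error of the
#' mean (SEM) are reported across biological replicates; with fewer than
#' two replicates the SEM is undefined and flagged `NA`.
#'
#' @param ct Tibble with columns `biological_replicate`, `condition`,
#'   `gene`, `technical_replicate`, `ct` (cycles, in (0, 45)).
#' @param reference_condition The condition whose fold change is defined
#'   as 1.
#' @param target,housekeeping Gene labels in the `gene` column.
#' @return A tibble with one row per condition: `condition`,
#'   `n_replicates`, `fold_change` (mean over biological replicates) and
#'   `sem`. Per-replicate fold changes are attached as attribute
#'   `"replicates"`.
#' @examples
#' ct <- simulate_qpcr(true_fold_change = 4, ct_sd = 0, n_replicates = 3)
#' delta_delta_ct(ct, reference_condition = "reference")
#' @export
delta_delta_ct <- function(ct, reference_condition,
                           target = "target", housekeeping = "housekeeping") {
  ct <- tibble::as_tibble(ct)
  needed <- c("biological_replicate", "condition", "gene",
              "technical_replicate", "ct")
  if (!all(needed %in% names(ct))) {
    stop_bad_arg("`ct` must have columns %s", paste(needed, collapse = ", "))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45)) {
    stop_bad_arg("Ct values must be finite and in (0, 45)")
  }
  if (!reference_condition %in% ct$condition) {
    stop_bad_arg("reference condition '%s' absent from table", reference_condition)
  }

  dct <- ct |>
    dplyr::filter(.data$gene %in% c(target, housekeeping)) |>
    dplyr::group_by(.data$biological_replicate, .data$condition, .data$gene) |>
    dplyr::summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mean_ct")
  if (!all(c(target, housekeeping) %in% names(dct)) ||
      anyNA(dct[[housekeeping]]) || anyNA(dct[[target]])) {
    stop_bad_arg("target and housekeeping Cts must be present for every (replicate, condition)")
  }
  dct <- dplyr::mutate(dct, dct = .data[[target]] - .data[[housekeeping]])

  ref <- dct |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::select("biological_replicate", ref_dct = "dct")
  folds <- dct |>
    dplyr::inner_join(ref, by = "biological_replicate") |>
    dplyr::mutate(
      ddct = .data$dct - .data$ref_dct,
      fold = 2^(-.data$ddct)
    ) |>
    dplyr::select("biological_replicate", "condition", "ddct", "fold")

  out <- folds |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      fold_change = mean(.data$fold),
      sem = dplyr::if_else(
        .data$n_replicates >= 2L,
        stats::sd(.data$fold) / sqrt(.data$n_replicates),
        NA_real_
      )
    )
  if (any(out$n_replicates < 2L)) {
    rlang::warn("fewer than 2 biological replicates: SEM undefined (NA)")
  }
  attr(out, "replicates") <- folds
  out
}
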