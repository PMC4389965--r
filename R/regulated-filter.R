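#' @keywords internal
#' Long-format join of expression values with sample metadata.
#' @noRd
.expr_long <- function(expr, meta) {
  missing_cols <- setdiff(meta$sample_id, names(expr))
  if (length(missing_cols) > 0) {
    stop_bad_arg("expression matrix lacks sample column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  expr |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "log2_intensity") |>
    dplyr::inner_join(meta, by = "sample_id")
}

#' Intensity filter for time-course probe sets
#'
#' Retains a probe set only if its average log2 intensity — the mean of the
#' plus-tet and minus-tet measurements within a condition — is at least
#' `min_intensity` in every named (cell line, time) condition: both
#' inducible clones at 24 h and 48 h and both control lines at 48 h, by
#' default. Probe sets without a gene annotation in `probe_map` are dropped,
#' mirroring the removal of probe sets lacking a current gene annotation.
#'
#' @param expr Expression tibble (`probe_id` + one column per sample,
#'   log2 intensities).
#' @param meta Sample metadata tibble (`sample_id`, `cell_line`, `tet`,
#'   `hours`).
#' @param probe_map Tibble mapping `probe_id` to `gene` (possibly
#'   many-to-one); probes absent from it are treated as unannotated.
#' @param min_intensity Log2 intensity threshold (default 3).
#' @param conditions Tibble of required (`cell_line`, `hours`) conditions;
#'   defaults to E10/E14 at 24 and 48 h plus P2/U937T at 48 h.
#'
#' @return A tibble with one row per probe set: `probe_id`, `has_gene`,
#'   `min_condition_mean` (smallest per-condition average) and `retained`.
#' @export
filter_probesets <- function(expr, meta, probe_map, min_intensity = 3,
                             conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- tibble::tibble(
      cell_line = c("E10", "E10", "E14", "E14", "P2", "U937T"),
      hours = c(24, 48, 24, 48, 48, 48)
    )
  }
  for (i in seq_len(nrow(conditions))) {
    sel <- meta$cell_line == conditions$cell_line[i] &
      meta$hours == conditions$hours[i]
    for (tt in c("plus", "minus")) {
      n_found <- sum(sel & meta$tet == tt)
      if (n_found != 1L) {
        stop_bad_arg(
          "condition (%s, %g h, %s tet) must be present exactly once, found %d",
          conditions$cell_line[i], conditions$hours[i], tt, n_found
        )
      }
    }
  }
  cond_means <- .expr_long(expr, meta) |>
    dplyr::inner_join(conditions, by = c("cell_line", "hours")) |>
    dplyr::group_by(.data$probe_id, .data$cell_line, .data$hours) |>
    dplyr::summarise(cond_mean = mean(.data$log2_intensity), .groups = "drop") |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(min_condition_mean = min(.data$cond_mean))

  tibble::tibble(probe_id = expr$probe_id) |>
    dplyr::left_join(cond_means, by = "probe_id") |>
    dplyr::mutate(
      has_gene = .data$probe_id %in%
        probe_map$probe_id[!is.na(probe_map$gene)],
      retained = .data$has_gene & .data$min_condition_mean >= min_intensity
    )
}

#' Per-probe log2 fold changes of tetracycline withdrawal
#'
#' For every (cell line, time point) with a paired plus/minus tetracycline
#' measurement, computes the induction fold change on the log2 scale:
#' `log2fc = log2(minus tet) - log2(plus tet)`, i.e. the expression change
#' relative to cultures maintained in tetracycline.
#'
#' @inheritParams filter_probesets
#' @return A tibble with `probe_id`, `cell_line`, `hours`, `log2fc`.
#' @export
compute_fold_changes <- function(expr, meta) {
  wide <- .expr_long(expr, meta) |>
    tidyr::pivot_wider(
      id_cols = c("probe_id", "cell_line", "hours"),
      names_from = "tet", values_from = "log2_intensity"
    )
  if (!all(c("plus", "minus") %in% names(wide)) ||
      anyNA(wide$plus) || anyNA(wide$minus)) {
    stop_bad_arg("every (cell_line, hours) must have paired plus/minus tet columns")
  }
  wide |>
    dplyr::mutate(log2fc = .data$minus - .data$plus) |>
    dplyr::select("probe_id", "cell_line", "hours", "log2fc")
}

#' Call regulated probe sets from induction fold changes
#'
#' A probe set is called regulated when both rules hold:
#' \describe{
#'   \item{fold-change rule}{its |log2 FC| is at least `log2(min_fold)` at
#'     24 h and 48 h in both inducible clones, with one consistent sign
#'     across all four measurements (a single direction of regulation);}
#'   \item{background-exceedance rule}{for each clone, the 48 h effect
#'     satisfies `|log2FC48| >= base^(|log2FC48| / divisor) * E`, where `E`
#'     is the larger |log2 FC at 48 h| of the two control lines — i.e. the
#'     induced effect must be at least `10^(FC/3)` times the background
#'     effect of tetracycline withdrawal alone.}
#' }
#' Control effects enter as absolute values regardless of sign
#' (conservative background handling). Fold changes at 6 h and 12 h are
#' carried through for reporting but take part in no criterion.
#'
#' @param fcs Fold-change tibble from [compute_fold_changes()].
#' @param probe_map Tibble mapping `probe_id` to `gene`.
#' @param min_fold Minimum linear fold change (default 2).
#' @param exceedance_base,exceedance_divisor Parameters of the
#'   background-exceedance threshold `base^(|log2FC48|/divisor)`.
#' @param clones,controls Cell-line labels of inducible clones and controls.
#'
#' @return A tibble with one row per probe set: `gene`, `probe_id`, wide
#'   fold-change columns `fc_<line>_<hours>h`, `control_effect` (max
#'   absolute control 48 h FC), `passes_fc`, `passes_background`, `called`,
#'   `direction` (`"up"`/`"down"`, `NA` when not called) and `mean_fc_48h`
#'   (clone average at 48 h).
#' @export
call_regulated <- function(fcs, probe_map, min_fold = 2,
                           exceedance_base = 10, exceedance_divisor = 3,
                           clones = c("E10", "E14"),
                           controls = c("P2", "U937T")) {
  min_fold <- check_number(min_fold, "min_fold", min = 1)
  needed <- tidyr::expand_grid(cell_line = clones, hours = c(24, 48))
  have <- dplyr::distinct(fcs, .data$cell_line, .data$hours)
  miss <- dplyr::anti_join(needed, have, by = c("cell_line", "hours"))
  if (nrow(miss) > 0 || !all(controls %in% have$cell_line[have$hours == 48])) {
    stop_bad_arg("fold changes must cover both clones at 24/48 h and both controls at 48 h")
  }

  wide <- fcs |>
    dplyr::arrange(match(.data$cell_line, c(clones, controls)), .data$hours) |>
    dplyr::mutate(key = sprintf("fc_%s_%gh", .data$cell_line, .data$hours)) |>
    tidyr::pivot_wider(id_cols = "probe_id", names_from = "key",
                       values_from = "log2fc") |>
    dplyr::arrange(.data$probe_id)

  clone_cols <- sprintf("fc_%s_%sh", rep(clones, each = 2), c(24, 48))
  clone48_cols <- sprintf("fc_%s_48h", clones)
  control_cols <- sprintf("fc_%s_48h", controls)
  cl <- as.matrix(wide[clone_cols])
  cl48 <- as.matrix(wide[clone48_cols])
  ctrl <- as.matrix(wide[control_cols])

  min_log2 <- log2(min_fold)
  passes_fc <- rowSums(abs(cl) >= min_log2) == ncol(cl) &
    (rowSums(cl > 0) == ncol(cl) | rowSums(cl < 0) == ncol(cl))
  control_effect <- apply(abs(ctrl), 1, max)
  thresholds <- exceedance_base^(abs(cl48) / exceedance_divisor) * control_effect
  passes_background <- rowSums(abs(cl48) >= thresholds) == ncol(cl48)

  wide |>
    dplyr::mutate(
      control_effect = control_effect,
      passes_fc = passes_fc,
      passes_background = passes_background,
      called = passes_fc & passes_background,
      mean_fc_48h = rowMeans(cl48),
      direction = dplyr::if_else(
        .data$called, dplyr::if_else(.data$mean_fc_48h > 0, "up", "down"),
        NA_character_
      )
    ) |>
    dplyr::left_join(probe_map, by = "probe_id") |>
    dplyr::relocate("gene")
}

#' Collapse probe-set calls to one call per gene
#'
#' When several probe sets of the same gene are called regulated, keeps the
#' probe set with the most pronounced regulation: the largest |log2 FC at
#' 48 h| averaged over the two clones. Ties are broken by lexicographic
#' probe-set identifier for determinism.
#'
#' @param calls Output of [call_regulated()] (only rows with
#'   `called == TRUE` are considered).
#' @return The called subset of `calls`, one row per gene.
#' @export
collapse_probesets <- function(calls) {
  calls |>
    dplyr::filter(.data$called) |>
    dplyr::mutate(.abs48 = abs(.data$mean_fc_48h)) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$.abs48), .data$probe_id) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::select(-".abs48")
}

#' Order regulated genes for heatmap display
#'
#' Sorts gene-level calls by decreasing mean 48 h log2 fold change (clone
#' average), the display order used for induction heatmaps, and returns the
#' per-time-point fold-change table ready for export.
#'
#' @param calls Gene-level calls from [collapse_probesets()].
#' @return `calls` re-ordered, with `gene` first.
#' @export
order_for_heatmap <- function(calls) {
  calls |>
    dplyr::arrange(dplyr::desc(.data$mean_fc_48h), .data$gene) |>
    dplyr::relocate("gene", "probe_id")
}

#' Full regulated-gene calling chain
#'
#' Runs the intensity filter, fold-change computation, regulation calling,
#' per-gene collapse and heatmap ordering in sequence, returning gene-level
#' calls for the probe sets that survive every rule.
#'
#' @inheritParams filter_probesets
#' @inheritParams call_regulated
#' @return A tibble of gene-level regulation calls in heatmap order (see
#'   [call_regulated()] for columns), with the intensity-filter verdict in
#'   `passes_intensity`.
#' @examples
#' tc <- simulate_timecourse(timecourse_design(n_probes = 200, seed = 5))
#' calls <- regulated_genes(tc$expr, tc$meta, tc$probe_map)
#' head(calls[, c("gene", "direction", "mean_fc_48h")])
#' @export
regulated_genes <- function(expr, meta, probe_map, min_intensity = 3,
                            min_fold = 2, exceedance_base = 10,
                            exceedance_divisor = 3,
                            clones = c("E10", "E14"),
                            controls = c("P2", "U937T")) {
  kept <- filter_probesets(expr, meta, probe_map, min_intensity = min_intensity)
  retained_ids <- kept$probe_id[kept$retained]
  fcs <- compute_fold_changes(expr, meta) |>
    dplyr::filter(.data$probe_id %in% retained_ids)
  if (nrow(fcs) == 0L) {
    return(tibble::tibble(gene = character(), probe_id = character()))
  }
  call_regulated(fcs, probe_map, min_fold = min_fold,
                 exceedance_base = exceedance_base,
                 exceedance_divisor = exceedance_divisor,
                 clones = clones, controls = controls) |>
    dplyr::mutate(passes_intensity = TRUE) |>
    collapse_probesets() |>
    order_for_heatmap()
}
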