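#' Design of a tet-off induction time course
#'
#' Describes a synthetic gene-expression experiment modelled on a
#' tetracycline-regulable (tet-off) induction system: two independent
#' inducible clones are sampled at several time points after tetracycline
#' withdrawal (`minus` = induced) together with matched cultures kept in
#' tetracycline (`plus` = reference), and two control lines carrying no
#' inducible construct are profiled at the final time point to capture
#' background effects of tetracycline removal itself.
#'
#' A planted subset of probe sets responds to the induced factor: their
#' log2 fold change in the induced (`minus` tet) clone columns reaches a
#' magnitude drawn from `induced_log2fc_range` at 24 h and 48 h (with a
#' 25% / 50% ramp at 6 h and 12 h, emulating gradual onset). Background
#' tetracycline-withdrawal effects of SD `background_log2fc_sd` are applied
#' to the `minus` columns of every line — clones and controls alike — so
#' the background-exceedance rule of [call_regulated()] is genuinely
#' exercised. All values live on the log2-intensity scale of RMA-style
#' normalized arrays; measurement noise is Gaussian on that scale.
#'
#' @param n_probes Number of probe sets.
#' @param n_regulated_up,n_regulated_down Numbers of planted induced /
#'   repressed probe sets; their sum must not exceed `n_probes`.
#' @param induced_log2fc_range Interval (log2 units) from which planted
#'   effect magnitudes are drawn uniformly.
#' @param background_log2fc_sd SD (log2 units) of the per-(probe, line)
#'   background effect of tetracycline withdrawal.
#' @param noise_sd SD (log2 units) of i.i.d. measurement noise per value.
#' @param baseline_log2_range Interval of per-probe baseline log2 intensities.
#' @param clones,controls Labels of the inducible clones and control lines.
#' @param timepoints_h Time points (hours) profiled for the clones; the
#'   controls are profiled at the last time point only.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#'
#' @return An object of class `timecourse_design` (a validated list).
#' @seealso [simulate_timecourse()]
#' @export
timecourse_design <- function(n_probes = 500L,
                              n_regulated_up = 20L,
                              n_regulated_down = 20L,
                              induced_log2fc_range = c(1, 4),
                              background_log2fc_sd = 0.1,
                              noise_sd = 0.05,
                              baseline_log2_range = c(4, 12),
                              clones = c("E10", "E14"),
                              controls = c("P2", "U937T"),
                              timepoints_h = c(6, 12, 24, 48),
                              seed = 1L) {
  design <- list(
    n_probes = check_count(n_probes, "n_probes", min = 1L),
    n_regulated_up = check_count(n_regulated_up, "n_regulated_up"),
    n_regulated_down = check_count(n_regulated_down, "n_regulated_down"),
    induced_log2fc_range = check_interval(induced_log2fc_range, "induced_log2fc_range"),
    background_log2fc_sd = check_number(background_log2fc_sd, "background_log2fc_sd", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    baseline_log2_range = check_interval(baseline_log2_range, "baseline_log2_range"),
    clones = as.character(clones),
    controls = as.character(controls),
    timepoints_h = sort(as.numeric(timepoints_h)),
    seed = check_count(seed, "seed")
  )
  if (design$n_regulated_up + design$n_regulated_down > design$n_probes) {
    stop_bad_arg("n_regulated_up + n_regulated_down must not exceed n_probes")
  }
  if (length(design$clones) < 1L || length(design$controls) < 1L ||
      length(design$timepoints_h) < 1L) {
    stop_bad_arg("clones, controls and timepoints_h must be non-empty")
  }
  structure(design, class = "timecourse_design")
}

# fraction of the full planted effect present at each time point
.effect_ramp <- function(hours, timepoints_h) {
  full <- timepoints_h[timepoints_h >= 24]
  ramp <- setNames(rep(1, length(timepoints_h)), timepoints_h)
  if (length(full) < length(timepoints_h)) {
    early <- setdiff(timepoints_h, full)
    ramp[as.character(early)] <- c(0.25, 0.5)[seq_along(early)]
  }
  unname(ramp[as.character(hours)])
}

#' Simulate a tet-off induction time course with planted regulated genes
#'
#' Generates a probe-set-by-sample log2 expression matrix following the
#' layout assumed by the regulated-gene filter: each inducible clone at
#' every time point with and without tetracycline, and each control line at
#' the final time point with and without tetracycline. A truth table records
#' which probe sets carry a planted effect, in which direction, and at what
#' magnitude, so downstream calls can be scored against ground truth.
#'
#' @param design A [timecourse_design()].
#'
#' @return A list with components
#' \describe{
#'   \item{expr}{tibble, one row per probe set: `probe_id` plus one numeric
#'     column per sample (log2 intensities).}
#'   \item{meta}{tibble with `sample_id`, `cell_line`, `tet`
#'     (`"plus"`/`"minus"`) and `hours`.}
#'   \item{probe_map}{tibble with `probe_id`, `gene`.}
#'   \item{truth}{tibble with `probe_id`, `gene`, `status`
#'     (`"up"`/`"down"`/`"null"`) and `planted_log2fc` (signed, 0 for null).}
#' }
#' @examples
#' tc <- simulate_timecourse(timecourse_design(n_probes = 50, seed = 42))
#' dim(tc$expr)
#' table(tc$truth$status)
#' @export
simulate_timecourse <- function(design) {
  if (!inherits(design, "timecourse_design")) {
    stop_bad_arg("`design` must be created with timecourse_design()")
  }
  local_seed(design$seed)

  last_h <- max(design$timepoints_h)
  meta <- dplyr::bind_rows(
    tidyr::expand_grid(
      cell_line = design$clones, hours = design$timepoints_h,
      tet = c("plus", "minus")
    ),
    tidyr::expand_grid(
      cell_line = design$controls, hours = last_h, tet = c("plus", "minus")
    )
  ) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_%gh", .data$cell_line, .data$tet, .data$hours)
    ) |>
    dplyr::select("sample_id", "cell_line", "tet", "hours")

  n <- design$n_probes
  width <- max(4L, nchar(as.character(n)))
  probe_id <- sprintf(paste0("PS%0", width, "d_at"), seq_len(n))
  gene <- sprintf(paste0("G%0", width, "d"), seq_len(n))

  n_reg <- design$n_regulated_up + design$n_regulated_down
  reg_idx <- if (n_reg > 0) sample.int(n, n_reg) else integer(0)
  status <- rep("null", n)
  status[reg_idx[seq_len(design$n_regulated_up)]] <- "up"
  if (design$n_regulated_down > 0) {
    status[reg_idx[design$n_regulated_up + seq_len(design$n_regulated_down)]] <- "down"
  }
  magnitude <- rep(0, n)
  magnitude[reg_idx] <- runif(
    n_reg, design$induced_log2fc_range[1], design$induced_log2fc_range[2]
  )
  planted <- magnitude * (status == "up") - magnitude * (status == "down")

  lines <- c(design$clones, design$controls)
  background <- matrix(
    rnorm(n * length(lines), 0, design$background_log2fc_sd),
    nrow = n, dimnames = list(NULL, lines)
  )
  baseline <- runif(n, design$baseline_log2_range[1], design$baseline_log2_range[2])

  values <- matrix(0, nrow = n, ncol = nrow(meta),
                   dimnames = list(probe_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    line <- meta$cell_line[j]
    col <- baseline
    if (meta$tet[j] == "minus") {
      col <- col + background[, line]
      if (line %in% design$clones) {
        col <- col + planted * .effect_ramp(meta$hours[j], design$timepoints_h)
      }
    }
    values[, j] <- col + rnorm(n, 0, design$noise_sd)
  }

  list(
    expr = dplyr::bind_cols(
      tibble::tibble(probe_id = probe_id),
      tibble::as_tibble(values)
    ),
    meta = meta,
    probe_map = tibble::tibble(probe_id = probe_id, gene = gene),
    truth = tibble::tibble(
      probe_id = probe_id, gene = gene,
      status = status, planted_log2fc = planted
    )
  )
}
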