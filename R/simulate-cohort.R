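#' Design of a synthetic patient cohort with a bimodal splitter gene
#'
#' Describes a cohort in which the expression of a "splitter" gene (e.g. the
#' transcription factor EVI1) follows a two-component Gaussian mixture on the
#' log2 scale — a large low-expressing mode and a smaller high-expressing
#' mode, as seen in AML patient data sets — and a "response" gene (e.g.
#' MS4A3) is shifted downwards by `effect_delta` log2 units in the
#' high-expressing group. `effect_delta > 0` therefore encodes repression of
#' the response gene by the splitter.
#'
#' @param n_high,n_low Numbers of patients in the high / low splitter mode
#'   (`n_high` may be 0 to emulate a cohort without a high-expressing group).
#' @param mu_low,mu_high Mode centres (log2 units); `mu_high > mu_low`.
#' @param sigma_low,sigma_high Mode SDs (log2 units), strictly positive.
#' @param ms4a3_baseline Response-gene mean (log2) in the low group.
#' @param effect_delta Downward log2 shift of the response gene in the high
#'   group (positive = repression).
#' @param ms4a3_sd Response-gene SD (log2 units), strictly positive.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `cohort_design`.
#' @seealso [simulate_cohort()], [cohort_association()]
#' @export
cohort_design <- function(n_high = 20L, n_low = 200L,
                          mu_low = 4, mu_high = 9,
                          sigma_low = 0.5, sigma_high = 0.5,
                          ms4a3_baseline = 8, effect_delta = 1,
                          ms4a3_sd = 0.5, seed = 1L) {
  design <- list(
    n_high = check_count(n_high, "n_high"),
    n_low = check_count(n_low, "n_low", min = 1L),
    mu_low = check_number(mu_low, "mu_low"),
    mu_high = check_number(mu_high, "mu_high"),
    sigma_low = check_number(sigma_low, "sigma_low", min = 0, strict = TRUE),
    sigma_high = check_number(sigma_high, "sigma_high", min = 0, strict = TRUE),
    ms4a3_baseline = check_number(ms4a3_baseline, "ms4a3_baseline"),
    effect_delta = check_number(effect_delta, "effect_delta"),
    ms4a3_sd = check_number(ms4a3_sd, "ms4a3_sd", min = 0, strict = TRUE),
    seed = check_count(seed, "seed")
  )
  if (design$mu_high <= design$mu_low) {
    stop_bad_arg("mu_high must be greater than mu_low")
  }
  structure(design, class = "cohort_design")
}

#' Simulate a patient cohort with planted splitter/response coupling
#'
#' Draws splitter-gene values from the two-component mixture of the design
#' and response-gene values from a Gaussian whose mean is lowered by
#' `effect_delta` for patients in the high-splitter component. The true
#' component membership is returned so downstream dichotomization and
#' association statistics can be scored against ground truth.
#'
#' @param design A [cohort_design()].
#'
#' @return A tibble with columns `sample_id`, `evi1_log2` (splitter),
#'   `ms4a3_log2` (response) and `true_group` (`"high"`/`"low"`).
#' @examples
#' cohort <- simulate_cohort(cohort_design(seed = 11))
#' dplyr::count(cohort, true_group)
#' @export
simulate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) {
    stop_bad_arg("`design` must be created with cohort_design()")
  }
  local_seed(design$seed)
  group <- c(rep("low", design$n_low), rep("high", design$n_high))
  n <- length(group)
  evi1 <- c(
    rnorm(design$n_low, design$mu_low, design$sigma_low),
    rnorm(design$n_high, design$mu_high, design$sigma_high)
  )
  ms4a3 <- design$ms4a3_baseline - design$effect_delta * (group == "high") +
    rnorm(n, 0, design$ms4a3_sd)
  tibble::tibble(
    sample_id = sprintf("PT%04d", seq_len(n)),
    evi1_log2 = evi1,
    ms4a3_log2 = ms4a3,
    true_group = group
  )
}
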