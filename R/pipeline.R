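#' Default end-to-end pipeline configuration
#'
#' Builds the nested configuration list consumed by [run_pipeline()]:
#' stage toggles, per-stage parameter blocks mirroring the module
#' parameters, and a global seed from which per-stage seeds are derived
#' (seed + a fixed per-stage offset, so stages have independent RNG
#' streams). Unknown keys are rejected to catch typos in YAML configs.
#'
#' @param seed Global integer seed.
#' @param ... Named overrides merged into the defaults, e.g.
#'   `cohort = list(n_iter = 1000)` or `stages = list(qpcr = FALSE)`.
#' @return A named list of class `evi1_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = check_count(seed, "seed"),
    stages = list(timecourse = TRUE, cohort = TRUE, motifs = TRUE,
                  go = TRUE, qpcr = TRUE),
    timecourse = list(
      n_probes = 500L, n_regulated_up = 20L, n_regulated_down = 20L,
      induced_log2fc_range = c(1, 4), background_log2fc_sd = 0.1,
      noise_sd = 0.05, min_intensity = 3, min_fold = 2,
      exceedance_base = 10, exceedance_divisor = 3
    ),
    cohort = list(
      n_high = 20L, n_low = 200L, mu_low = 4, mu_high = 9,
      sigma_low = 0.5, sigma_high = 0.5, ms4a3_baseline = 8,
      effect_delta = 1, ms4a3_sd = 0.5, n_iter = 10000L,
      bandwidth = "silverman", five_pct = 0.05, replace = FALSE
    ),
    motifs = list(
      promoter_length = 268L, gc_fraction = 0.5, planted_position = 100L,
      planted_strand = "+", target_rate = 1e-4, bg_length = 200000L
    ),
    go = list(
      n_genes = 1000L, n_terms = 50L, density = 0.05,
      study_size = 40L, enrichment_fold = 5, alpha = 0.1
    ),
    qpcr = list(
      true_fold_change = 16, ct_sd = 0.1, n_replicates = 4L
    )
  )
  structure(.merge_config(defaults, list(...), path = ""), class = "evi1_config")
}

.merge_config <- function(defaults, overrides, path) {
  extra <- setdiff(names(overrides), names(defaults))
  if (length(extra) > 0) {
    stop_bad_arg("unknown configuration key(s): %s",
                 paste0(path, extra, collapse = ", "))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], overrides[[nm]],
                                      path = paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it into [pipeline_config()] defaults;
#' unknown keys raise an error naming the offending key.
#'
#' @param path YAML file path.
#' @return An `evi1_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(list(seed = seed), raw))
}

.stage_seed <- function(config, stage) {
  offsets <- c(timecourse = 101L, cohort = 211L, motifs = 307L,
               go = 401L, qpcr = 503L)
  config$seed + offsets[[stage]]
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in order — simulate + call regulated genes,
#' simulate + associate a cohort, simulate + calibrate + scan a promoter,
#' simulate + enrich GO annotations, simulate + quantify qPCR — writing
#' plain-text outputs (TSV/BED/FASTA) per stage into `out_dir` and a JSON
#' manifest recording every parameter, per-stage seed and output-file MD5
#' hash. Rerunning with the same configuration reproduces the manifest
#' hashes bit-identically.
#'
#' @param config An `evi1_config` list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "evi1_config")) {
    stop_bad_arg("`config` must come from pipeline_config() or read_pipeline_config()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      params = params,
      seed = .stage_seed(config, stage),
      outputs = as.list(setNames(tools::md5sum(files), basename(files)))
    )
  }

  if (isTRUE(config$stages$timecourse)) {
    p <- config$timecourse
    tc <- simulate_timecourse(timecourse_design(
      n_probes = p$n_probes, n_regulated_up = p$n_regulated_up,
      n_regulated_down = p$n_regulated_down,
      induced_log2fc_range = p$induced_log2fc_range,
      background_log2fc_sd = p$background_log2fc_sd, noise_sd = p$noise_sd,
      seed = .stage_seed(config, "timecourse")
    ))
    calls <- regulated_genes(
      tc$expr, tc$meta, tc$probe_map,
      min_intensity = p$min_intensity, min_fold = p$min_fold,
      exceedance_base = p$exceedance_base,
      exceedance_divisor = p$exceedance_divisor
    )
    files <- file.path(out_dir, c("timecourse_expr.tsv", "timecourse_meta.tsv",
                                  "timecourse_truth.tsv", "regulated_calls.tsv"))
    write_expression_tsv(tc$expr, files[1])
    readr::write_tsv(tc$meta, files[2])
    readr::write_tsv(tc$truth, files[3])
    readr::write_tsv(calls, files[4])
    record("timecourse", p, files)
  }

  if (isTRUE(config$stages$cohort)) {
    p <- config$cohort
    seed <- .stage_seed(config, "cohort")
    cohort <- simulate_cohort(cohort_design(
      n_high = p$n_high, n_low = p$n_low, mu_low = p$mu_low,
      mu_high = p$mu_high, sigma_low = p$sigma_low,
      sigma_high = p$sigma_high, ms4a3_baseline = p$ms4a3_baseline,
      effect_delta = p$effect_delta, ms4a3_sd = p$ms4a3_sd, seed = seed
    ))
    fit <- cohort_association(cohort, n_iter = p$n_iter, seed = seed,
                              bandwidth = p$bandwidth, five_pct = p$five_pct,
                              replace = p$replace)
    files <- file.path(out_dir, c("cohort.tsv", "cohort_association.tsv"))
    readr::write_tsv(cohort, files[1])
    readr::write_tsv(tidy(fit), files[2])
    record("cohort", p, files)
  }

  if (isTRUE(config$stages$motifs)) {
    p <- config$motifs
    seed <- .stage_seed(config, "motifs")
    pwm_file <- system.file("extdata", "synthetic_evi1_like.jaspar",
                            package = "evi1kit", mustWork = TRUE)
    mat <- read_jaspar(pwm_file)[[1]]
    sim <- simulate_promoters(
      promoter_spec(
        length = p$promoter_length, gc_fraction = p$gc_fraction,
        planted_motifs = tibble::tibble(
          pwm_id = mat$id, position = p$planted_position,
          strand = p$planted_strand
        ),
        seed = seed
      ),
      pwms = setNames(list(mat), mat$id)
    )
    thr <- calibrate_threshold(mat, target_rate = p$target_rate,
                               bg_length = p$bg_length,
                               gc = p$gc_fraction, seed = seed + 1L)
    hits <- scan_pwm(sim$sequences, mat, threshold = thr$threshold,
                     tss_relative = TRUE)
    files <- file.path(out_dir, c("promoter.fa", "motif_hits.tsv",
                                  "motif_hits.bed"))
    write_fasta(sim$sequences, files[1])
    readr::write_tsv(hits, files[2])
    write_hits_bed(hits, files[3])
    record("motifs", c(p, list(threshold = thr$threshold)), files)
  }

  if (isTRUE(config$stages$go)) {
    p <- config$go
    seed <- .stage_seed(config, "go")
    study <- sprintf("G%04d", seq_len(p$study_size))
    ann <- simulate_go_annotations(
      n_genes = p$n_genes, n_terms = p$n_terms, density = p$density,
      seed = seed, enriched_term = sprintf("GO:%07d", 1L),
      study_genes = study, enrichment_fold = p$enrichment_fold
    )
    res <- enrich(study, ann$annotations, population = ann$genes,
                  alpha = p$alpha)
    files <- file.path(out_dir, c("go_annotations.tsv", "go_enrichment.tsv"))
    readr::write_tsv(ann$annotations, files[1])
    readr::write_tsv(res, files[2])
    record("go", p, files)
  }

  if (isTRUE(config$stages$qpcr)) {
    p <- config$qpcr
    ct <- simulate_qpcr(true_fold_change = p$true_fold_change,
                        ct_sd = p$ct_sd, n_replicates = p$n_replicates,
                        seed = .stage_seed(config, "qpcr"))
    res <- delta_delta_ct(ct, reference_condition = "reference")
    files <- file.path(out_dir, c("qpcr_ct.tsv", "qpcr_fold_changes.tsv"))
    readr::write_tsv(ct, files[1])
    readr::write_tsv(res, files[2])
    record("qpcr", p, files)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
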