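#' Specification of a synthetic promoter sequence
#'
#' Describes a promoter-proximal region (by convention the window just
#' upstream of a transcription start site, e.g. -268..-1) into which exact
#' PWM consensus sites are planted at known positions and strands. Serves as
#' ground truth for the motif scanner.
#'
#' @param length Sequence length in bp.
#' @param gc_fraction Background GC content in `[0, 1]`.
#' @param planted_motifs A tibble/data frame with columns `pwm_id`,
#'   `position` (0-based offset on the forward strand) and `strand`
#'   (`"+"`/`"-"`), or `NULL` for no planted sites.
#' @param seed Integer seed.
#'
#' @return An object of class `promoter_spec`.
#' @export
promoter_spec <- function(length = 268L, gc_fraction = 0.5,
                          planted_motifs = NULL, seed = 1L) {
  if (is.null(planted_motifs)) {
    planted_motifs <- tibble::tibble(
      pwm_id = character(), position = integer(), strand = character()
    )
  }
  planted_motifs <- tibble::as_tibble(planted_motifs)
  stopifnot(all(c("pwm_id", "position", "strand") %in% names(planted_motifs)))
  if (!all(planted_motifs$strand %in% c("+", "-"))) {
    stop_bad_arg("planted strand must be '+' or '-'")
  }
  structure(
    list(
      length = check_count(length, "length", min = 1L),
      gc_fraction = check_number(gc_fraction, "gc_fraction", min = 0),
      planted_motifs = planted_motifs,
      seed = check_count(seed, "seed")
    ),
    class = "promoter_spec"
  )
}

#' Simulate a promoter sequence with planted consensus motifs
#'
#' Generates a random background sequence at the requested GC content and
#' overwrites it with the consensus of each planted PWM (reverse-complemented
#' for minus-strand sites) at the stated 0-based forward-strand positions.
#' The emitted truth table lists each planted site so scanner hits can be
#' checked against it.
#'
#' @param spec A [promoter_spec()].
#' @param pwms A named list of [pwm()] objects covering every `pwm_id` in
#'   `spec$planted_motifs`.
#' @param sequence_id Name of the emitted sequence.
#'
#' @return A list with `sequences` (named character vector) and `truth`
#'   (tibble: `sequence_id`, `pwm_id`, `start` 0-based, `strand`).
#' @examples
#' p <- pwm(rbind(A = c(9, 0, 0, 9), C = c(0, 9, 0, 0),
#'                G = c(0, 0, 9, 0), T = c(0, 0, 0, 0)), id = "toy")
#' sim <- simulate_promoters(
#'   promoter_spec(length = 100, planted_motifs =
#'     data.frame(pwm_id = "toy", position = 50, strand = "+"), seed = 3),
#'   pwms = list(toy = p)
#' )
#' substr(sim$sequences, 51, 54)  # "ACGA"
#' @export
simulate_promoters <- function(spec, pwms, sequence_id = "promoter_1") {
  if (!inherits(spec, "promoter_spec")) {
    stop_bad_arg("`spec` must be created with promoter_spec()")
  }
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$id)
  seq <- random_dna(spec$length, gc = spec$gc_fraction, seed = spec$seed)
  pm <- spec$planted_motifs
  for (i in seq_len(nrow(pm))) {
    p <- pwms[[pm$pwm_id[i]]]
    if (is.null(p)) stop_bad_arg("no PWM named '%s' supplied", pm$pwm_id[i])
    if (pm$position[i] + p$length > spec$length) {
      stop_bad_arg("planted motif '%s' at %d overruns the sequence",
                   pm$pwm_id[i], pm$position[i])
    }
    site <- pwm_consensus(p)
    if (pm$strand[i] == "-") site <- .revcomp(site)
    substr(seq, pm$position[i] + 1L, pm$position[i] + p$length) <- site
  }
  list(
    sequences = setNames(seq, sequence_id),
    truth = tibble::tibble(
      sequence_id = sequence_id,
      pwm_id = pm$pwm_id,
      start = as.integer(pm$position),
      strand = pm$strand
    )
  )
}

#' Simulate a gene-to-GO-term annotation table
#'
#' Annotates each (gene, term) pair independently with probability
#' `density`. Optionally plants an enriched term: genes in `study_genes`
#' are annotated with `enriched_term` at `enrichment_fold * density`
#' (capped at 1), giving a known positive for enrichment ranking tests.
#'
#' @param n_genes,n_terms Population size and number of terms.
#' @param density Baseline annotation probability per (gene, term) pair.
#' @param seed Integer seed.
#' @param enriched_term,study_genes,enrichment_fold Optional planted
#'   enrichment (see Details); `study_genes` are gene names from the
#'   emitted population.
#'
#' @return A list with `annotations` (tibble `gene`, `term`), `genes`
#'   (population character vector) and `planted` (list or `NULL`).
#' @export
simulate_go_annotations <- function(n_genes = 1000L, n_terms = 50L,
                                    density = 0.05, seed = 1L,
                                    enriched_term = NULL,
                                    study_genes = NULL,
                                    enrichment_fold = 5) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_terms <- check_count(n_terms, "n_terms", min = 1L)
  density <- check_number(density, "density", min = 0)
  if (density > 1) stop_bad_arg("`density` must be in [0, 1]")
  local_seed(check_count(seed, "seed"))
  genes <- sprintf("G%04d", seq_len(n_genes))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  prob <- matrix(density, nrow = n_genes, ncol = n_terms,
                 dimnames = list(genes, terms))
  planted <- NULL
  if (!is.null(enriched_term)) {
    stopifnot(enriched_term %in% terms, all(study_genes %in% genes))
    prob[study_genes, enriched_term] <- min(1, enrichment_fold * density)
    planted <- list(term = enriched_term, study_genes = study_genes,
                    fold = enrichment_fold)
  }
  hit <- matrix(runif(length(prob)) < prob, nrow = n_genes)
  idx <- which(hit, arr.ind = TRUE)
  list(
    annotations = tibble::tibble(
      gene = genes[idx[, 1]], term = terms[idx[, 2]]
    ) |> dplyr::arrange(.data$gene, .data$term),
    genes = genes,
    planted = planted
  )
}

#' Simulate a qPCR Ct table with a planted fold change
#'
#' Emulates a relative-quantification experiment: a target and a
#' housekeeping gene measured in technical triplicate for a treated and a
#' reference condition across several biological replicates. The treated
#' condition's target Ct is shifted by `-log2(true_fold_change)` cycles so
#' the delta-delta-Ct estimate recovers `true_fold_change` exactly when
#' `ct_sd = 0`.
#'
#' @param true_fold_change Planted fold change of the target gene in the
#'   treated condition (on the linear scale; must be > 0).
#' @param ct_sd SD (cycles) of i.i.d. Gaussian noise added to every Ct.
#' @param n_replicates Number of biological replicates.
#' @param seed Integer seed.
#' @param n_technical Technical replicates per (condition, gene).
#'
#' @return A tibble with `biological_replicate`, `condition`
#'   (`"treated"`/`"reference"`), `gene` (`"target"`/`"housekeeping"`),
#'   `technical_replicate`, `ct`.
#' @seealso [delta_delta_ct()]
#' @export
simulate_qpcr <- function(true_fold_change, ct_sd = 0.1, n_replicates = 3L,
                          seed = 1L, n_technical = 3L) {
  true_fold_change <- check_number(true_fold_change, "true_fold_change",
                                   min = 0, strict = TRUE)
  ct_sd <- check_number(ct_sd, "ct_sd", min = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  n_technical <- check_count(n_technical, "n_technical", min = 1L)
  local_seed(check_count(seed, "seed"))
  base_ct <- c(target = 25, housekeeping = 20)
  grid <- tidyr::expand_grid(
    biological_replicate = seq_len(n_replicates),
    condition = c("reference", "treated"),
    gene = c("target", "housekeeping"),
    technical_replicate = seq_len(n_technical)
  )
  shift <- ifelse(
    grid$condition == "treated" & grid$gene == "target",
    -log2(true_fold_change), 0
  )
  grid$ct <- base_ct[grid$gene] + shift + rnorm(nrow(grid), 0, ct_sd)
  grid
}
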