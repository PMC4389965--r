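#' Read and write the plain-text interchange formats
#'
#' All stages exchange data as TSV: a wide expression matrix (`probe_id`
#' plus one column per sample) with a sidecar metadata table, a cohort
#' table (`sample_id`, `evi1_log2`, `ms4a3_log2`), a two-column annotation
#' table (`gene`, `term`) and a Ct table. These helpers are thin readr
#' wrappers fixing column types.
#'
#' @param path File path.
#' @return A tibble.
#' @name evi1kit_io
NULL

#' @rdname evi1kit_io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(probe_id = "c", .default = "d"))
}

#' @rdname evi1kit_io
#' @param expr Wide expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname evi1kit_io
#' @export
read_sample_meta_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", cell_line = "c", tet = "c", hours = "d"
                  ))
}

#' @rdname evi1kit_io
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", evi1_log2 = "d", ms4a3_log2 = "d",
                    .default = "c"
                  ))
}

#' @rdname evi1kit_io
#' @export
read_annotations_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene = "c", term = "c"))
}

#' @rdname evi1kit_io
#' @export
read_ct_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    biological_replicate = "i", condition = "c", gene = "c",
                    technical_replicate = "i", ct = "d"
                  ))
}
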