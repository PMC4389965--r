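DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' A PWM is stored as a 4 x L matrix of per-position base frequencies (rows
#' A, C, G, T; columns sum to 1). Counts are accepted and normalized per
#' column after adding `pseudocount` to every cell. Frequencies are used as
#' given by default (`pseudocount = 0`): a zero-frequency base contributes a
#' score of 0 at that position, it does not veto the window.
#'
#' @param mat Numeric matrix of counts or frequencies, either 4 x L with
#'   rows in A, C, G, T order (row names honoured when present) or L x 4.
#' @param id Matrix identifier used in hit reports.
#' @param pseudocount Non-negative value added to every cell before column
#'   normalization.
#'
#' @return An object of class `pwm`: a list with `id`, `mat` (4 x L
#'   frequency matrix) and `length`.
#' @examples
#' m <- pwm(rbind(A = c(1, 0.5, 0), C = c(0, 0.5, 0),
#'                G = c(0, 0, 1), T = c(0, 0, 0)), id = "toy")
#' pwm_consensus(m)
#' @export
pwm <- function(mat, id = "pwm", pseudocount = 0) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop_bad_arg("`mat` must be a numeric matrix")
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  if (nrow(mat) != 4L) stop_bad_arg("`mat` must have 4 rows (A, C, G, T) or 4 columns")
  if (!is.null(rownames(mat))) {
    if (!setequal(rownames(mat), DNA_BASES)) {
      stop_bad_arg("PWM row names must be A, C, G, T")
    }
    mat <- mat[DNA_BASES, , drop = FALSE]
  } else {
    rownames(mat) <- DNA_BASES
  }
  if (ncol(mat) < 3L) stop_bad_arg("PWM must have length >= 3")
  if (any(mat < 0) || anyNA(mat)) stop_bad_arg("PWM entries must be non-negative")
  pseudocount <- check_number(pseudocount, "pseudocount", min = 0)
  mat <- mat + pseudocount
  csum <- colSums(mat)
  if (any(csum <= 0)) stop_bad_arg("every PWM column must have positive mass")
  mat <- sweep(mat, 2, csum, "/")
  structure(
    list(id = as.character(id), mat = mat, length = ncol(mat)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (length %d)\n", x$id, x$length))
  print(round(x$mat, 3))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The highest-frequency base at each position; ties broken in A, C, G, T
#' order for determinism.
#'
#' @param x A [pwm()].
#' @return A character scalar of length `x$length`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$mat, 2, which.max)], collapse = "")
}

#' Read position weight matrices from a JASPAR-style text file
#'
#' Parses the plain-text JASPAR matrix format: a `>identifier [name]` header
#' line followed by four rows `A [ 1 2 3 ]` ... `T [ ... ]` (brackets
#' optional). Counts are normalized per column. No installed package reads
#' this format, so the parser is provided here.
#'
#' @param path Path to the matrix file (may contain several matrices).
#' @param pseudocount Passed to [pwm()].
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop_bad_arg("no '>' header found in %s", path)
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- strsplit(sub("^>\\s*", "", lines[headers[i]]), "\\s+")[[1]][1]
    rows <- lapply(block, function(l) {
      l <- trimws(l)
      base <- toupper(substr(l, 1, 1))
      nums <- gsub("[^0-9eE+. -]", " ", substr(l, 2, nchar(l)))
      vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES)) {
      stop_bad_arg("matrix '%s' must have one row per base A, C, G, T", id)
    }
    lens <- vapply(rows, function(r) length(r$vals), 1L)
    if (length(unique(lens)) != 1L) {
      stop_bad_arg("matrix '%s' has rows of unequal length", id)
    }
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- bases
    out[[id]] <- pwm(mat[DNA_BASES, , drop = FALSE], id = id,
                     pseudocount = pseudocount)
  }
  out
}

#' Generate a random DNA sequence with a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc / 2`. Used as the default
#' background for threshold calibration and as promoter scaffold sequence.
#'
#' @param length Sequence length (bp).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return A character scalar over the alphabet A, C, G, T.
#' @export
random_dna <- function(length, gc = 0.5, seed = NULL) {
  length <- check_count(length, "length", min = 1L)
  gc <- check_number(gc, "gc", min = 0)
  if (gc > 1) stop_bad_arg("`gc` must be in [0, 1]")
  if (!is.null(seed)) local_seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
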