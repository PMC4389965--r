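#' Per-position information weights of a PWM
#'
#' The information weight of column `l` with base frequencies `f(b, l)` is
#' `ci(l) = (100 / ln 4) * sum_b f(b,l) * ln f(b,l) + 100`, with
#' `0 * ln 0 := 0`. It ranges from 0 for a uniform column (no preference)
#' to 100 for a column fixed on one base, and weights each position's
#' contribution to the matrix-similarity score.
#'
#' @param x A [pwm()].
#' @return Numeric vector of length `x$length`, values in `[0, 100]`.
#' @examples
#' p <- pwm(rbind(A = c(1, 0.5, 0), C = c(0, 0.5, 0),
#'                G = c(0, 0, 1), T = c(0, 0, 0)), id = "toy")
#' information_weights(p)  # 100, 50, 100
#' @export
information_weights <- function(x) {
  stopifnot(inherits(x, "pwm"))
  f <- x$mat
  plogp <- ifelse(f > 0, f * log(f), 0)
  (100 / log(4)) * colSums(plogp) + 100
}

# integer row indices of a sequence's bases in the PWM matrix (NA for N etc.)
.base_index <- function(seq_string) {
  match(strsplit(toupper(seq_string), "")[[1]], DNA_BASES)
}

# scores of every length-L window of an index vector; NA bases contribute 0
.window_scores <- function(idx, x, ci) {
  L <- x$length
  n_win <- length(idx) - L + 1L
  if (n_win < 1L) return(numeric(0))
  fmax <- apply(x$mat, 2, max)
  denom <- sum(ci * fmax)
  num <- numeric(n_win)
  offsets <- seq_len(n_win)
  for (l in seq_len(L)) {
    b <- idx[offsets + l - 1L]
    contrib <- ci[l] * x$mat[cbind(b, l)]
    contrib[is.na(contrib)] <- 0
    num <- num + contrib
  }
  if (denom == 0) rep(1, n_win) else num / denom
}

#' Information-weighted matrix similarity of a sequence window
#'
#' Scores a window of length `L` against a PWM as
#' `sum_l ci(l) * f(b_l, l) / sum_l ci(l) * f_max(l)`, where `b_l` is the
#' window base at position `l`, `f_max(l)` the column maximum and `ci` the
#' [information_weights()]. The score lies in `[0, 1]` and equals 1 exactly
#' when every base attains its column maximum. Non-ACGT characters (e.g.
#' `N`) contribute 0 at their position.
#'
#' @param x A [pwm()].
#' @param window Character scalar of length `x$length`.
#' @param weights Optional precomputed [information_weights()].
#' @return A similarity score in `[0, 1]`.
#' @examples
#' p <- pwm(rbind(A = c(1, 0.5, 0), C = c(0, 0.5, 0),
#'                G = c(0, 0, 1), T = c(0, 0, 0)), id = "toy")
#' matrix_similarity(p, "ACG")  # 1
#' matrix_similarity(p, "ATG")  # 200/225
#' @export
matrix_similarity <- function(x, window, weights = NULL) {
  stopifnot(inherits(x, "pwm"))
  if (!is.character(window) || length(window) != 1L ||
      nchar(window) != x$length) {
    stop_bad_arg("`window` must be a single string of length %d", x$length)
  }
  ci <- weights %||% information_weights(x)
  .window_scores(.base_index(window), x, ci)
}

#' Scan sequences for PWM matches on both strands
#'
#' Slides the PWM across every window of each sequence and of its reverse
#' complement, reporting windows whose matrix-similarity score is at or
#' above `threshold`. Reverse-strand hits are scored on the reverse
#' complement but reported in forward-strand coordinates (0-based,
#' half-open).
#'
#' @param sequences Named character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param x A [pwm()].
#' @param threshold Minimum similarity score in `[0, 1]`.
#' @param tss_relative If `TRUE`, adds a `tss_position` column giving the
#'   hit start relative to a transcription start site placed at the
#'   sequence end (start - sequence length; e.g. -268..-1 labels for a
#'   268 bp promoter window).
#' @return A tibble of hits: `sequence_id`, `start` (0-based), `end`,
#'   `strand`, `score`, `pwm_id` (and optionally `tss_position`), ordered
#'   by sequence, position and strand.
#' @export
scan_pwm <- function(sequences, x, threshold, tss_relative = FALSE) {
  stopifnot(inherits(x, "pwm"))
  threshold <- check_number(threshold, "threshold")
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  }
  ci <- information_weights(x)
  L <- x$length
  hits <- purrr::imap(sequences, function(s, sid) {
    len <- nchar(s)
    fwd <- .window_scores(.base_index(s), x, ci)
    rev <- .window_scores(.base_index(.revcomp(s)), x, ci)
    keep_f <- which(fwd >= threshold)
    keep_r <- which(rev >= threshold)
    tibble::tibble(
      sequence_id = sid,
      start = c(keep_f - 1L, len - L - (keep_r - 1L)),
      strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
      score = c(fwd[keep_f], rev[keep_r]),
      seq_length = len
    )
  }) |>
    purrr::list_rbind()
  hits <- hits |>
    dplyr::mutate(end = .data$start + L, pwm_id = x$id) |>
    dplyr::arrange(.data$sequence_id, .data$start, .data$strand)
  if (tss_relative) {
    hits <- dplyr::mutate(hits, tss_position = .data$start - .data$seq_length)
  }
  dplyr::select(hits, "sequence_id", "start", "end", "strand", "score",
                "pwm_id", dplyr::any_of("tss_position"))
}

#' Calibrate a PWM score threshold to a target background hit rate
#'
#' Scores every window of a background sequence set on both strands and
#' returns the smallest score threshold at which the background yields at
#' most `target_rate` hits per base pair — by default one binding site per
#' 10 kb, the conventional false-positive allowance for promoter scans of
#' coding-sequence background. The threshold is the appropriate upper
#' quantile of the pooled window scores. When even the maximal score is
#' attained too often (a degenerate, uninformative matrix), the threshold
#' is reported as 1 with `rate_achieved = FALSE`.
#'
#' @param x A [pwm()].
#' @param background Named character vector of background sequences, or
#'   `NULL` to generate `bg_length` bp of i.i.d. sequence at GC fraction
#'   `gc` with seed `seed`. Total length must be at least 100 kb.
#' @param target_rate Allowed hits per base pair (default `1e-4` = 1 per
#'   10 kb).
#' @param bg_length,gc,seed Synthetic-background parameters used when
#'   `background` is `NULL`.
#' @return An object of class `evi1_threshold`: list with `threshold`,
#'   `target_rate`, `achieved_rate` (hits/bp on the calibration background
#'   at the threshold), `rate_achieved`, `n_windows`, `background_bp`,
#'   `pwm_id`.
#' @export
calibrate_threshold <- function(x, background = NULL, target_rate = 1e-4,
                                bg_length = 200000L, gc = 0.5, seed = 1L) {
  stopifnot(inherits(x, "pwm"))
  target_rate <- check_number(target_rate, "target_rate", min = 0, strict = TRUE)
  if (is.null(background)) {
    background <- random_dna(bg_length, gc = gc, seed = seed)
  }
  if (methods::is(background, "DNAStringSet")) {
    background <- as.character(background)
  }
  total_bp <- sum(nchar(background))
  if (total_bp < 100000L) {
    stop_bad_arg("background must total at least 100 kb, got %d bp", total_bp)
  }
  ci <- information_weights(x)
  scores <- unlist(lapply(background, function(s) {
    c(.window_scores(.base_index(s), x, ci),
      .window_scores(.base_index(.revcomp(s)), x, ci))
  }), use.names = FALSE)
  allowed <- floor(target_rate * total_bp)
  s <- sort(scores, decreasing = TRUE)
  # smallest t with #(scores >= t) <= allowed; ties may force a higher t
  threshold <- NA_real_
  if (allowed >= 1L) {
    m <- min(allowed, length(s))
    while (m >= 1L && (m < length(s) && s[m + 1L] == s[m])) m <- m - 1L
    if (m >= 1L) threshold <- s[m]
  }
  rate_achieved <- TRUE
  if (is.na(threshold)) {
    threshold <- 1
    rate_achieved <- sum(s >= 1) <= allowed
  }
  structure(
    list(threshold = threshold, target_rate = target_rate,
         achieved_rate = sum(s >= threshold) / total_bp,
         rate_achieved = rate_achieved,
         n_windows = length(s), background_bp = total_bp, pwm_id = x$id),
    class = "evi1_threshold"
  )
}

#' @export
print.evi1_threshold <- function(x, ...) {
  cat(sprintf(
    "<evi1_threshold> %s: %.4f (%.2f hits/10kb on calibration background%s)\n",
    x$pwm_id, x$threshold, x$achieved_rate * 1e4,
    if (x$rate_achieved) "" else "; target rate NOT reachable"
  ))
  invisible(x)
}

#' Write motif hits as BED6
#'
#' `chrom` = sequence id, 0-based half-open `start`/`end`, `name` = PWM id,
#' `score` = similarity times 1000 rounded, `strand`. Exact float scores
#' belong in the TSV written by [readr::write_tsv()] on the hit tibble.
#'
#' @param hits Hit tibble from [scan_pwm()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- tibble::tibble(
    chrom = hits$sequence_id,
    start = hits$start,
    end = hits$end,
    name = hits$pwm_id,
    score = as.integer(round(hits$score * 1000)),
    strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings FASTA I/O returning/accepting named
#' character vectors, the sequence representation used throughout the
#' package.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path
  )
  invisible(path)
}
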