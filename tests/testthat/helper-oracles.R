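# Independent reference implementations used to cross-check the package.
# These are deliberately naive (plain loops, direct formulas) and share no
# code with the implementation under test.

# regulated-gene calling by plain loops over probes, conditions and rules
oracle_regulated_probes <- function(expr, meta, probe_map, min_intensity = 3,
                                    min_fold = 2, base = 10, div = 3) {
  val <- function(pid, line, tet, h) {
    sid <- meta$sample_id[meta$cell_line == line & meta$tet == tet &
                            meta$hours == h]
    as.numeric(expr[expr$probe_id == pid, sid][[1]])
  }
  conds <- list(c("E10", 24), c("E10", 48), c("E14", 24), c("E14", 48),
                c("P2", 48), c("U937T", 48))
  called <- character()
  for (pid in expr$probe_id) {
    gene <- probe_map$gene[probe_map$probe_id == pid]
    if (length(gene) == 0 || is.na(gene[1])) next
    ok <- TRUE
    for (cond in conds) {
      h <- as.numeric(cond[2])
      m <- mean(c(val(pid, cond[1], "plus", h), val(pid, cond[1], "minus", h)))
      if (m < min_intensity) ok <- FALSE
    }
    if (!ok) next
    fc <- function(line, h) val(pid, line, "minus", h) - val(pid, line, "plus", h)
    cl <- c(fc("E10", 24), fc("E10", 48), fc("E14", 24), fc("E14", 48))
    if (!all(abs(cl) >= log2(min_fold))) next
    if (!(all(cl > 0) || all(cl < 0))) next
    ctrl <- max(abs(fc("P2", 48)), abs(fc("U937T", 48)))
    for (f48 in c(fc("E10", 48), fc("E14", 48))) {
      if (abs(f48) < base^(abs(f48) / div) * ctrl) ok <- FALSE
    }
    if (ok) called <- c(called, pid)
  }
  called
}

# exact hypergeometric upper tail by direct combinatorial summation
oracle_hyper_tail <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# per-window PWM scan by explicit substring scoring on both strands
oracle_scan <- function(seq, p, threshold) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  L <- p$length
  len <- nchar(seq)
  rows <- list()
  for (start0 in 0:(len - L)) {
    w <- substr(seq, start0 + 1, start0 + L)
    s_f <- matrix_similarity(p, w)
    if (s_f >= threshold) {
      rows[[length(rows) + 1]] <- data.frame(start = start0, strand = "+",
                                             score = s_f)
    }
    s_r <- matrix_similarity(p, revcomp(w))
    if (s_r >= threshold) {
      rows[[length(rows) + 1]] <- data.frame(start = start0, strand = "-",
                                             score = s_r)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(start = integer(), strand = character(),
                                      score = numeric())
  out[order(out$start, out$strand), , drop = FALSE]
}

# small PWM fixtures shared across motif tests
toy_pwm3 <- function() {
  pwm(rbind(A = c(1, 0.5, 0), C = c(0, 0.5, 0),
            G = c(0, 0, 1), T = c(0, 0, 0)), id = "toy3")
}

info_pwm8 <- function() {
  pwm(rbind(A = c(.85, .05, .70, .10, .80, .05, .75, .10),
            C = c(.05, .80, .10, .05, .08, .85, .10, .05),
            G = c(.06, .10, .15, .80, .07, .06, .10, .80),
            T = c(.04, .05, .05, .05, .05, .04, .05, .05)), id = "info8")
}
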