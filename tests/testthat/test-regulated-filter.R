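# compact constructor for hand-built time-course fixtures
make_tc <- function(values, probe_ids = sprintf("P%03d_at", seq_len(nrow(values))),
                    genes = sub("_at$", "", probe_ids)) {
  meta <- dplyr::bind_rows(
    tidyr::expand_grid(cell_line = c("E10", "E14"), hours = c(6, 12, 24, 48),
                       tet = c("plus", "minus")),
    tidyr::expand_grid(cell_line = c("P2", "U937T"), hours = 48,
                       tet = c("plus", "minus"))
  )
  meta$sample_id <- sprintf("%s_%s_%gh", meta$cell_line, meta$tet, meta$hours)
  colnames(values) <- meta$sample_id
  list(
    expr = dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                            tibble::as_tibble(values)),
    meta = tibble::as_tibble(meta[, c("sample_id", "cell_line", "tet", "hours")]),
    probe_map = tibble::tibble(probe_id = probe_ids, gene = genes)
  )
}

flat_tc <- function(n, level = 10) {
  make_tc(matrix(level, nrow = n, ncol = 20))
}

test_that("intensity filter applies the per-condition average rule", {
  tc <- flat_tc(3)
  kept <- filter_probesets(tc$expr, tc$meta, tc$probe_map)
  expect_true(all(kept$retained))

  # drop a probe whose E10/24h average is 2.9 but >= 3 everywhere else
  tc2 <- flat_tc(2)
  for (s in c("E10_plus_24h", "E10_minus_24h")) tc2$expr[1, s] <- 2.9
  kept2 <- filter_probesets(tc2$expr, tc2$meta, tc2$probe_map)
  expect_false(kept2$retained[1])
  expect_true(kept2$retained[2])

  # an unannotated probe is removed even at high intensity
  tc3 <- flat_tc(2)
  tc3$probe_map$gene[2] <- NA
  kept3 <- filter_probesets(tc3$expr, tc3$meta, tc3$probe_map)
  expect_false(kept3$retained[2])

  # boundary: a mean of exactly 3 is retained
  tc4 <- flat_tc(1)
  tc4$expr[1, "E14_plus_48h"] <- 2
  tc4$expr[1, "E14_minus_48h"] <- 4
  expect_true(filter_probesets(tc4$expr, tc4$meta, tc4$probe_map)$retained[1])
})

test_that("intensity filter uses only the named conditions and 100-probe fixture counts agree", {
  set.seed(71)
  n <- 100
  vals <- matrix(10, nrow = n, ncol = 20)
  tc <- make_tc(vals)
  conds <- list(c("E10", 24), c("E10", 48), c("E14", 24), c("E14", 48),
                c("P2", 48), c("U937T", 48))
  low <- sample(n, 30)
  for (i in low) {
    cond <- conds[[sample(length(conds), 1)]]
    cols <- sprintf("%s_%s_%sh", cond[1], c("plus", "minus"), cond[2])
    tc$expr[i, cols] <- 1
  }
  kept <- filter_probesets(tc$expr, tc$meta, tc$probe_map)
  expect_equal(sum(kept$retained), 70)
  expect_identical(which(!kept$retained), sort(low))

  # low intensity at 6 h does not matter: rule names 24/48 h only
  tc5 <- flat_tc(1)
  tc5$expr[1, c("E10_plus_6h", "E10_minus_6h")] <- 0
  expect_true(filter_probesets(tc5$expr, tc5$meta, tc5$probe_map)$retained[1])
})

test_that("fold changes are minus-tet minus plus-tet and antisymmetric", {
  tc <- flat_tc(2)
  fcs <- compute_fold_changes(tc$expr, tc$meta)
  expect_true(all(fcs$log2fc == 0))

  set.seed(8)
  vals <- matrix(rnorm(5 * 20, 8), nrow = 5)
  tc2 <- make_tc(vals)
  fcs2 <- compute_fold_changes(tc2$expr, tc2$meta)
  # element-wise oracle
  for (r in sample(nrow(fcs2), 10)) {
    row <- fcs2[r, ]
    minus <- tc2$expr[tc2$expr$probe_id == row$probe_id,
                      sprintf("%s_minus_%gh", row$cell_line, row$hours)][[1]]
    plus <- tc2$expr[tc2$expr$probe_id == row$probe_id,
                     sprintf("%s_plus_%gh", row$cell_line, row$hours)][[1]]
    expect_equal(row$log2fc, minus - plus)
  }
  # swapping tet labels flips every fold change
  meta_sw <- tc2$meta
  meta_sw$tet <- ifelse(meta_sw$tet == "plus", "minus", "plus")
  fcs_sw <- compute_fold_changes(tc2$expr, meta_sw)
  joined <- dplyr::inner_join(fcs2, fcs_sw,
                              by = c("probe_id", "cell_line", "hours"))
  expect_equal(joined$log2fc.x, -joined$log2fc.y)

  # a uniform +2 shift of all minus-tet columns gives FC = 2 everywhere
  tc3 <- flat_tc(3)
  minus_cols <- tc3$meta$sample_id[tc3$meta$tet == "minus"]
  tc3$expr[minus_cols] <- tc3$expr[minus_cols] + 2
  expect_true(all(compute_fold_changes(tc3$expr, tc3$meta)$log2fc == 2))
})

test_that("missing or unpaired columns give informative errors", {
  tc <- flat_tc(2)
  meta_missing <- tc$meta[tc$meta$sample_id != "P2_minus_48h", ]
  expect_error(filter_probesets(tc$expr, meta_missing, tc$probe_map),
               "P2.*48.*minus")
  expect_error(compute_fold_changes(tc$expr, meta_missing), "paired")
})

# fixture with chosen fold changes: clone FCs at 24/48 h and control FCs at 48 h
fc_fixture <- function(cl24, cl48, p2, u937t) {
  tibble::tibble(
    probe_id = "P001_at",
    cell_line = c("E10", "E10", "E14", "E14", "P2", "U937T"),
    hours = c(24, 48, 24, 48, 48, 48),
    log2fc = c(cl24, cl48, cl24, cl48, p2, u937t)
  )
}
one_map <- tibble::tibble(probe_id = "P001_at", gene = "P001")

test_that("regulation calling applies the two-fold and background-exceedance rules", {
  # 24h = +1.2, 48h = +2.0 in both clones; controls +0.3/+0.1:
  # threshold 10^(2/3)*0.3 = 1.392 <= 2.0 -> called up
  calls <- call_regulated(fc_fixture(1.2, 2.0, 0.3, 0.1), one_map)
  expect_true(calls$called)
  expect_identical(calls$direction, "up")
  expect_equal(calls$control_effect, 0.3)

  # control effect 0.5: threshold 10^(2/3)*0.5 = 2.321 > 2.0 -> not called
  calls2 <- call_regulated(fc_fixture(1.2, 2.0, 0.5, 0.1), one_map)
  expect_false(calls2$called)
  expect_true(calls2$passes_fc)
  expect_false(calls2$passes_background)

  # all-zero fold changes produce no call
  calls0 <- call_regulated(fc_fixture(0, 0, 0, 0), one_map)
  expect_false(calls0$called)

  # inconsistent sign across time points is not a single direction
  mixed <- fc_fixture(1.5, 2.0, 0, 0)
  mixed$log2fc[mixed$cell_line == "E10" & mixed$hours == 24] <- -1.5
  expect_false(call_regulated(mixed, one_map)$passes_fc)

  # repression: negative fold changes give direction "down"
  calls_dn <- call_regulated(fc_fixture(-1.2, -2.0, 0.3, 0.1), one_map)
  expect_true(calls_dn$called)
  expect_identical(calls_dn$direction, "down")

  # control sign is irrelevant: |-0.3| behaves like +0.3
  calls_neg <- call_regulated(fc_fixture(1.2, 2.0, -0.3, 0.1), one_map)
  expect_true(calls_neg$called)
})

test_that("probe-set collapse keeps the most pronounced regulation per gene", {
  fcs <- dplyr::bind_rows(
    fc_fixture(1.5, 2.0, 0, 0),
    dplyr::mutate(fc_fixture(1.5, 3.5, 0, 0), probe_id = "P002_at")
  )
  map2 <- tibble::tibble(probe_id = c("P001_at", "P002_at"), gene = "GENE1")
  collapsed <- collapse_probesets(call_regulated(fcs, map2))
  expect_equal(nrow(collapsed), 1)
  expect_identical(collapsed$probe_id, "P002_at")

  # single probe per gene passes through unchanged
  single <- collapse_probesets(call_regulated(fc_fixture(1.5, 2, 0, 0), one_map))
  expect_equal(nrow(single), 1)

  # ties break by lexicographic probe id
  tie <- dplyr::bind_rows(
    fc_fixture(1.5, 2.0, 0, 0),
    dplyr::mutate(fc_fixture(1.5, 2.0, 0, 0), probe_id = "P000_at")
  )
  map_tie <- tibble::tibble(probe_id = c("P001_at", "P000_at"), gene = "GENE1")
  expect_identical(collapse_probesets(call_regulated(tie, map_tie))$probe_id,
                   "P000_at")

  # random fixture equals a brute-force per-gene argmax
  set.seed(12)
  n <- 30
  fcs_r <- tidyr::expand_grid(
    probe_id = sprintf("P%03d_at", 1:n),
    tibble::tibble(cell_line = c("E10", "E10", "E14", "E14", "P2", "U937T"),
                   hours = c(24, 48, 24, 48, 48, 48))
  )
  fcs_r$log2fc <- ifelse(fcs_r$cell_line %in% c("P2", "U937T"), 0,
                         runif(nrow(fcs_r), 1.1, 4))
  map_r <- tibble::tibble(probe_id = sprintf("P%03d_at", 1:n),
                          gene = sprintf("GENE%d", rep(1:10, each = 3)))
  calls_r <- call_regulated(fcs_r, map_r)
  collapsed_r <- collapse_probesets(calls_r)
  brute <- vapply(split(calls_r, calls_r$gene), function(df) {
    score <- abs((df$fc_E10_48h + df$fc_E14_48h) / 2)
    df$probe_id[order(-score, df$probe_id)][1]
  }, character(1))
  expect_setequal(collapsed_r$probe_id, unname(brute))
})

test_that("heatmap ordering sorts by descending mean 48h fold change", {
  fcs <- dplyr::bind_rows(
    dplyr::mutate(fc_fixture(1.2, 2, 0, 0), probe_id = "P001_at"),
    dplyr::mutate(fc_fixture(-2, -4, 0, 0), probe_id = "P002_at"),
    dplyr::mutate(fc_fixture(1.01, 1.2, 0, 0), probe_id = "P003_at")
  )
  map3 <- tibble::tibble(probe_id = sprintf("P%03d_at", 1:3),
                         gene = sprintf("P%03d", 1:3))
  calls <- collapse_probesets(call_regulated(fcs, map3, min_fold = 2))
  # only the +-2-fold genes are called with min_fold 2; relax to keep all three
  calls_all <- collapse_probesets(call_regulated(fcs, map3, min_fold = 1.6))
  ordered <- order_for_heatmap(calls_all)
  expect_identical(ordered$probe_id, c("P001_at", "P003_at", "P002_at"))
  # reversing input row order leaves the output unchanged
  expect_identical(order_for_heatmap(calls_all[rev(seq_len(nrow(calls_all))), ]),
                   ordered)
})

test_that("full filter chain equals the brute-force loop oracle", {
  tc <- simulate_timecourse(timecourse_design(
    n_probes = 120, n_regulated_up = 8, n_regulated_down = 8,
    induced_log2fc_range = c(0.8, 3.5), background_log2fc_sd = 0.15,
    noise_sd = 0.15, seed = 33
  ))
  calls <- regulated_genes(tc$expr, tc$meta, tc$probe_map)
  oracle <- oracle_regulated_probes(tc$expr, tc$meta, tc$probe_map)
  expect_setequal(calls$probe_id, oracle)
})

test_that("calls are invariant to row and column permutation of the input", {
  tc <- simulate_timecourse(timecourse_design(n_probes = 80, seed = 14))
  calls <- regulated_genes(tc$expr, tc$meta, tc$probe_map)
  set.seed(1)
  expr_p <- tc$expr[sample(nrow(tc$expr)), ]
  expr_p <- expr_p[, c("probe_id", sample(setdiff(names(expr_p), "probe_id")))]
  meta_p <- tc$meta[sample(nrow(tc$meta)), ]
  calls_p <- regulated_genes(expr_p, meta_p, tc$probe_map)
  expect_equal(calls, calls_p)
})
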