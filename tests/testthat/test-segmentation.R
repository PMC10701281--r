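test_that("epitope meta p-value equals the order-statistic Beta closed form", {
  expect_equal(epitope_pvalue(c(0.001, 0.01, 0.02)),
               3 * 0.01^2 - 2 * 0.01^3, tolerance = 1e-12)
  p <- 0.37
  expect_equal(epitope_pvalue(c(p, p)), 1 - (1 - p)^2, tolerance = 1e-12)
  expect_equal(epitope_pvalue(0.123), 0.123)
  expect_error(epitope_pvalue(numeric()), "empty")
})

test_that("protein meta p-value equals the Tippett closed form", {
  expect_equal(protein_pvalue(c(0.01, 0.5, 0.9, 0.2, 0.8)),
               1 - 0.99^5, tolerance = 1e-12)
  expect_equal(protein_pvalue(0.42), 0.42)
  expect_error(protein_pvalue(numeric()), "empty")
})

test_that("meta p-values are Uniform(0,1) under the null", {
  set.seed(2024)
  n_draw <- 1e5
  # Wilkinson max, k = 2
  u <- matrix(runif(2 * n_draw), ncol = 2)
  p_max <- pmax(u[, 1], u[, 2])^2
  expect_gt(suppressWarnings(stats::ks.test(p_max, "punif"))$p.value, 0.01)
  # order-statistic Beta on the 2nd highest of n = 5
  x <- matrix(runif(5 * n_draw), ncol = 5)
  second <- apply(x, 1, function(r) sort(r)[4])
  p_ep <- stats::pbeta(second, 4, 2)
  expect_gt(suppressWarnings(stats::ks.test(p_ep, "punif"))$p.value, 0.01)
  # Tippett over m = 4
  y <- matrix(runif(4 * n_draw), ncol = 4)
  p_pr <- 1 - (1 - pmin(y[, 1], y[, 2], y[, 3], y[, 4]))^4
  expect_gt(suppressWarnings(stats::ks.test(p_pr, "punif"))$p.value, 0.01)
})

test_that("consensus sequence is the overlap core of the member probes", {
  prot_seq <- rand_protein(60, seed = 30)
  cons <- consensus_sequence(seq(11, 19, by = 2), prot_seq)  # 5 members
  expect_equal(cons$length, 16 - 2 * 4)
  expect_equal(cons$seq, substr(prot_seq, 19, 26))
  expect_false(cons$no_common_core)

  one <- consensus_sequence(7, prot_seq)
  expect_equal(one$length, 16L)
  expect_equal(one$seq, substr(prot_seq, 7, 22))

  nine <- consensus_sequence(seq(1, 17, by = 2), prot_seq)  # 16 - 16 = 0
  expect_true(nine$no_common_core)
  expect_equal(c(nine$start, nine$end), c(1, 32))           # full span
})

# Helper to drive segmentation directly: a single protein, a handmade
# called pattern and feature matrix.
segment_toy <- function(called_starts, feature_rows, L = 80,
                        features_by_sample = NULL, ...) {
  prot <- data.frame(accession = "P", sequence = rand_protein(L, seed = 8))
  lib <- build_probe_library(prot)
  occ <- lib$occurrences
  ids <- paste0("P:", called_starts)
  ns <- if (is.null(features_by_sample)) 2L else ncol(features_by_sample)
  called <- matrix(FALSE, nrow(occ), ns,
                   dimnames = list(occ$occ_id, paste0("s", seq_len(ns))))
  called[ids, ] <- TRUE
  feats <- matrix(0, nrow(occ), ns, dimnames = dimnames(called))
  if (is.null(features_by_sample)) feats[ids, ] <- feature_rows
  else feats[ids, ] <- features_by_sample
  segment_epitopes(called, feats, lib, ...)
}

test_that("homogeneous called runs form a single region", {
  reg <- segment_toy(seq(21, 29, by = 2), feature_rows = 5)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$aa_start, reg$aa_end), c(21, 44))
  expect_equal(reg$n_members, 5L)
})

test_that("uncalled gaps split chains into separate regions", {
  reg <- segment_toy(c(5, 7, 9, 51, 53, 55), feature_rows = 5, L = 90)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$aa_start, c(5, 51))
})

test_that("orthogonal per-sample features are cut where the SSD oracle cuts", {
  # 10-probe chain: first 5 probes strong only in sample A, last 5 only
  # in sample B
  fb <- rbind(matrix(rep(c(8, 0), each = 5), 5),
              matrix(rep(c(0, 8), each = 5), 5))
  reg <- segment_toy(seq(11, 29, by = 2), features_by_sample = fb)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_members, c(5L, 5L))
  expect_equal(reg$aa_start, c(11, 21))
  # exhaustive single-cut SSD oracle agrees on the split point
  ssd <- function(m) sum(sweep(m, 2, colMeans(m))^2)
  cuts <- vapply(1:9, function(j) ssd(fb[1:j, , drop = FALSE]) +
                   ssd(fb[(j + 1):10, , drop = FALSE]), numeric(1))
  expect_equal(which.min(cuts), 5L)
})

test_that("full hierarchy is consistent on simulated data", {
  run <- small_run(seed = 5)
  res <- run$result
  # every epitope contains >= 1 probe called in some sample
  for (i in seq_len(nrow(res$epitopes))) {
    mem <- res$epitopes$members[[i]]
    expect_true(any(res$probe$called[mem, ]))
  }
  # every called protein has >= 1 epitope; q in [0,1]; K <= N
  expect_true(all(res$proteins$n_epitopes >= 1))
  expect_true(all(res$epitope_q >= 0 & res$epitope_q <= 1))
  expect_true(all(res$epitopes$K <= res$epitopes$N))
  # tier counts monotone at every level
  for (mat in list(res$epitope_tier, res$protein_tier)) {
    rk <- match(mat, c("none", "inclusive", "moderate", "restrictive"))
    expect_true(sum(rk >= 4) <= sum(rk >= 3) &&
                  sum(rk >= 3) <= sum(rk >= 2))
  }
  # per-tier K never exceeds the FDR-called K
  expect_true(all(res$epitopes$K_moderate <= res$epitopes$K))
  expect_true(all(res$epitopes$K_restrictive <= res$epitopes$K_moderate))
})

test_that("epitope length histogram bins by 2-aa bins per mouse and tier", {
  run <- small_run(seed = 6)
  hist <- summarize_epitopes(run$result)
  expect_true(all(hist$count > 0))
  expect_true(all(grepl("^[0-9]+-[0-9]+$", hist$bin)))
  lo <- as.integer(sub("-.*", "", hist$bin))
  hi <- as.integer(sub(".*-", "", hist$bin))
  expect_true(all(hi - lo == 1L) && all(lo %% 2 == 1L))
  # spiked 8-12 aa epitopes yield mostly 7-16 aa consensus cores
  reg <- run$result$epitopes
  core <- reg$consensus_len[reg$tier %in% c("moderate", "restrictive") &
                              !reg$no_common_core]
  expect_gte(mean(core >= 7 & core <= 16), 0.5)
})
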