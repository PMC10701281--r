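test_that("global z-test p-values follow the upper-tail normal", {
  expect_equal(global_pvalue(5, 5, 1), 0.5)
  expect_equal(global_pvalue(5 + 1.96, 5, 1), 0.025, tolerance = 1e-3)
  p <- global_pvalue(seq(0, 20, by = 0.5), 5, 2)
  expect_true(all(diff(p) < 0))
  expect_error(global_pvalue(1, 0, 0), "sd")
})

test_that("differential t-test matches the t-distribution tail", {
  expect_equal(differential_pvalue(2, c(1, 2, 3)), 0.5)
  # degenerate naive vector handled by the variance floor
  expect_equal(differential_pvalue(1, c(1, 1, 1)), 0.5)
  # tail oracle: naive (0,0,0,0), floor 0.1, immune 10
  t_exp <- 10 / (0.1 * sqrt(1 + 1 / 4))
  expect_equal(differential_pvalue(10, c(0, 0, 0, 0), var_floor = 0.1),
               stats::pt(t_exp, df = 3, lower.tail = FALSE))
  expect_lt(differential_pvalue(10, c(0, 0, 0, 0), var_floor = 0.1), 1e-5)
  expect_error(differential_pvalue(1, c(1)), ">= 2 naive")
})

test_that("Wilkinson's max combination: closed form and boundary", {
  expect_equal(combine_wilkinson_max(c(0.1, 0.2)), 0.04)
  expect_equal(combine_wilkinson_max(c(1, 0.3)), 1)
  expect_equal(combine_wilkinson_max(0.7), 0.7)
  expect_error(combine_wilkinson_max(numeric()), "empty")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(123)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))   # order-preserving
  }
})

test_that("SD tiers use strict inequalities at their boundaries", {
  th <- heron_thresholds()
  expect_equal(as.character(assign_sd_tier(10.1, 0, 1, th)), "restrictive")
  expect_equal(as.character(assign_sd_tier(7, 0, 1, th)), "moderate")
  expect_equal(as.character(assign_sd_tier(3, 0, 1, th)), "none")
  expect_equal(as.character(assign_sd_tier(6, 0, 1, th)), "inclusive")
  expect_equal(as.character(assign_sd_tier(10, 0, 1, th)), "moderate")
  expect_error(heron_thresholds(moderate_sd = 2))
})

test_that("singleton calls are removed unless neighbored or replicate-rescued", {
  prot <- data.frame(accession = "P", sequence = rand_protein(40, seed = 6))
  lib <- build_probe_library(prot)     # starts 1,3,...,25 (step 2)
  samples <- data.frame(sample_id = c("i1", "i2"), mouse_id = c("m1", "m1"),
                        condition = "immune",
                        replicate_group = c("g", "g"))
  called <- matrix(FALSE, nrow(lib$occurrences), 2,
                   dimnames = list(lib$occurrences$occ_id, c("i1", "i2")))
  called[c("P:5", "P:7", "P:9"), "i1"] <- TRUE   # consecutive run
  called["P:17", "i1"] <- TRUE                   # isolated, no rescue
  called["P:25", "i1"] <- TRUE                   # isolated, rescued by i2
  called["P:25", "i2"] <- TRUE
  out <- remove_singletons(called, lib, samples)
  expect_true(all(out[c("P:5", "P:7", "P:9"), "i1"]))
  expect_false(out["P:17", "i1"])
  expect_true(out["P:25", "i1"])
  # without the replicate the same call disappears
  solo <- data.frame(sample_id = "i1", mouse_id = "m1",
                     condition = "immune", replicate_group = NA)
  out1 <- remove_singletons(called[, "i1", drop = FALSE], lib, solo)
  expect_false(out1["P:25", "i1"])
  bad <- data.frame(sample_id = "i1", mouse_id = "m1", condition = "immune",
                    replicate_group = "g")
  expect_error(remove_singletons(called, lib,
                                 rbind(bad, list("ghost", "m2", "immune",
                                                 "g"))),
               "unknown sample")
})

test_that("K-of-N collapses replicate chips to one mouse", {
  called <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                     TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("a", "b"),
                                   c("m1r1", "m1r2", "m2", "m3", "m4", "m5")))
  kn <- tabulate_k_of_n(called, c("M1", "M1", "M2", "M3", "M4", "M5"))
  expect_equal(kn$K, c(2L, 1L))   # replicate pair counts once
  expect_equal(kn$N, c(5L, 5L))
  all_false <- matrix(FALSE, 1, 6, dimnames = list("z", colnames(called)))
  expect_equal(tabulate_k_of_n(all_false, c("M1", "M1", "M2", "M3", "M4",
                                            "M5"))$K, 0L)
})

test_that("probe calls respect the FDR cutoff and tier invariants", {
  run <- small_run(seed = 4)
  pct <- run$result$probe
  expect_true(all(pct$q >= pct$p_combined - 1e-15))
  expect_true(all(pct$q[pct$called] <= 0.05))
  # tiers nested: restrictive subset of moderate subset of inclusive
  rk <- matrix(match(pct$tier, c("none", "inclusive", "moderate",
                                 "restrictive")), nrow(pct$tier))
  n_inc <- sum(rk >= 2); n_mod <- sum(rk >= 3); n_res <- sum(rk >= 4)
  expect_true(n_res <= n_mod && n_mod <= n_inc)
})
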