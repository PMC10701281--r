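test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(prob_at_least_hypergeom(2, 3, 5, 10), 0.5)   # 60/120
  expect_equal(prob_at_least_hypergeom(0, 3, 5, 10), 1)
  for (N in 4:9) for (K in 0:N) for (n in 1:N) for (x in 0:n)
    expect_equal(prob_at_least_hypergeom(x, n, K, N),
                 brute_hyper_tail(x, n, K, N), tolerance = 1e-12)
  expect_error(prob_at_least_hypergeom(5, 3, 5, 10), "draws")
  expect_error(prob_at_least_hypergeom(1, 3, 12, 10), "pool")
})

test_that("binomial tail and hypergeometric converge for large pools", {
  expect_equal(prob_at_least_binomial(0, 14, 0.3), 1)
  expect_equal(prob_at_least_binomial(1, 1, 0.3), 0.3)
  frac <- 0.01
  pb <- prob_at_least_binomial(8, 14, frac)
  rel <- vapply(c(1e5, 1e6, 1e7), function(N)
    abs(prob_at_least_hypergeom(8, 14, round(frac * N), N) / pb - 1),
    numeric(1))
  expect_true(all(diff(rel) < 0))          # error shrinks with the pool
  expect_lt(rel[3], 1e-3)
  # at the assay's pool size the two models agree to a few percent
  expect_lt(abs(prob_at_least_hypergeom(8, 14, 60906, 6090593) / pb - 1),
            0.05)
})

test_that("fraction sweep tabulates both models over assumed fractions", {
  sw <- fraction_sweep(c(0.001, 0.005, 0.01, 0.05), x = 8, n = 14,
                       N = 6090593)
  expect_equal(sw$K[3], 60906)
  expect_true(all(diff(sw$p_hypergeom) > 0))   # monotone in the fraction
  expect_true(all(diff(sw$p_binomial) > 0))
  expect_true(all(abs(sw$p_hypergeom / sw$p_binomial - 1) < 0.05))
  expect_error(fraction_sweep(1.2, 8, 14, 100), "fractions")
})

test_that("two-proportion z-test matches the pooled-variance formula", {
  r <- two_proportion_test(5, 10, 5, 10)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  # symmetry under group swap
  a <- two_proportion_test(3, 20, 9, 30)
  b <- two_proportion_test(9, 30, 3, 20)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$z, -b$z)
  # cross-check against the chi-square score test (z^2 = X^2)
  pt <- suppressWarnings(stats::prop.test(c(9, 3), c(30, 20),
                                          correct = FALSE))
  expect_equal(a$z^2, unname(pt$statistic), tolerance = 1e-12)
  expect_equal(a$p_value, pt$p.value, tolerance = 1e-12)
  expect_error(two_proportion_test(0, 0, 1, 2), ">= 1")
})

test_that("ICC recovers simulated variance shares and maps to bands", {
  expect_equal(icc_band(0.87), "good")
  expect_equal(icc_band(0.3), "poor")
  expect_equal(icc_band(0.95), "excellent")
  expect_equal(icc_band(0.6), "moderate")

  mk_oneway <- function(share, n_groups = 50, per = 20, seed = 1) {
    set.seed(seed)
    s_inst <- sqrt(share); s_res <- sqrt(1 - share)
    inst <- rep(seq_len(n_groups), each = per)
    data.frame(reading = stats::rnorm(n_groups)[inst] * s_inst +
                 stats::rnorm(n_groups * per) * s_res,
               instrument = factor(inst),
               sample = factor(rep(seq_len(per), n_groups)))
  }
  for (share in c(0.1, 0.5, 0.9)) {
    d <- mk_oneway(share, n_groups = 100, seed = round(100 * share))
    fit <- icc_from_variance_components(d, "reading", "instrument",
                                        random = "instrument")
    expect_lt(abs(fit$icc - share), 0.05)
  }
  # no instrument effect at all: ICC ~ 0, poor band
  d0 <- mk_oneway(0.001, seed = 7)
  fit0 <- icc_from_variance_components(d0, "reading", "instrument",
                                       random = "instrument")
  expect_lt(fit0$icc, 0.05)
  expect_equal(fit0$band, "poor")
  # two random components plus a fixed effect are accepted
  d2 <- mk_oneway(0.5, seed = 9)
  d2$stage <- factor(rep(c("pre", "post"), length.out = nrow(d2)))
  fit2 <- icc_from_variance_components(d2, "reading", "instrument",
                                       random = c("instrument", "sample"),
                                       fixed = "stage")
  expect_true(all(c("instrument", "sample", "residual") %in%
                    names(fit2$components)))
  expect_error(icc_from_variance_components(
    data.frame(reading = 1:4, instrument = factor(1)), "reading",
    "instrument", random = "instrument"), ">= 2 levels")
})

test_that("r-squared equals squared correlation and its null expectation", {
  x <- 1:10
  expect_equal(simple_r2(x, 2 * x + 1), 1)
  expect_equal(simple_r2(x, -x), 1)
  expect_error(simple_r2(rep(1, 5), 1:5), "variance")
  set.seed(31)
  n <- 8
  r2 <- replicate(4000, simple_r2(stats::rnorm(n), stats::rnorm(n)))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.02)
})

test_that("ELISA positivity averages replicates then applies OD >= 2", {
  od <- matrix(c(1.9, 2.1,   # replicate pair averaging to exactly 2.0
                 2.0, 2.0,   # exactly at threshold
                 0.4, 0.3),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("pepA", "pepB", "pepC"),
                               c("s1_r1", "s1_r2")))
  out <- elisa_call_positives(od, serum_of_well = c("s1", "s1"))
  expect_true(out$positive["pepA", "s1"])   # mean 2.0 counts as positive
  expect_true(out$positive["pepB", "s1"])
  expect_false(out$positive["pepC", "s1"])

  # 5 of 20 sera positive -> fraction 0.25 -> validated (boundary)
  od2 <- matrix(c(rep(2.5, 5), rep(0.2, 15)), 1,
                dimnames = list("pep", paste0("s", 1:20)))
  v <- elisa_call_positives(od2)$validation
  expect_equal(v$fraction, 0.25)
  expect_true(v$validated)
  # per-group accounting
  grp <- stats::setNames(rep(c("immune", "naive"), each = 10),
                         paste0("s", 1:20))
  v2 <- elisa_call_positives(od2, group_of_serum = grp)$validation
  expect_equal(v2$fraction[v2$group == "immune"], 0.5)
  expect_equal(v2$fraction[v2$group == "naive"], 0)
  expect_error(elisa_call_positives(od2, threshold = 0), "> 0")
})
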