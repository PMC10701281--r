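# Probe-level antibody-binding inference. Each immune sample gets, per
# probe occurrence: a global z-test p-value against the pooled mean/sd of
# the whole processed matrix, a differential one-observation t-test
# against the naive samples, a Wilkinson's-max combination of the two,
# BH-adjusted q-values, an FDR call with singleton removal, and a
# signal-strength tier. All tests are one-sided (upper tail): antibody
# binding only elevates signal.

#' Calling thresholds
#'
#' Signal tiers are defined in pooled standard deviations above the
#' pooled mean of the processed matrix: inclusive > 3 SD, moderate > 6 SD,
#' restrictive > 10 SD (strict inequalities); calls require a BH
#' q-value <= \code{fdr_cutoff}.
#'
#' @param inclusive_sd,moderate_sd,restrictive_sd Tier cutoffs (SD units).
#' @param fdr_cutoff FDR threshold for calls.
#' @return A \code{CategoryThresholds} list.
#' @export
heron_thresholds <- function(inclusive_sd = 3, moderate_sd = 6,
                             restrictive_sd = 10, fdr_cutoff = 0.05) {
  stopifnot(0 < inclusive_sd, inclusive_sd < moderate_sd,
            moderate_sd < restrictive_sd,
            0 < fdr_cutoff, fdr_cutoff < 1)
  structure(list(inclusive_sd = inclusive_sd, moderate_sd = moderate_sd,
                 restrictive_sd = restrictive_sd, fdr_cutoff = fdr_cutoff),
            class = "CategoryThresholds")
}

#' Global z-test p-value for a probe signal
#'
#' Upper-tail normal p-value of a processed signal against the mean and
#' standard deviation pooled over the entire matrix (all samples x all
#' occurrences).
#'
#' @param signal Processed (smoothed log2) value(s); vectorised.
#' @param pool_mean,pool_sd Pooled statistics of the whole matrix.
#' @return p-value(s) in [0, 1].
#' @export
global_pvalue <- function(signal, pool_mean, pool_sd) {
  if (!isTRUE(pool_sd > 0)) stop("pooled sd must be > 0 (degenerate matrix)")
  stats::pnorm(signal, mean = pool_mean, sd = pool_sd, lower.tail = FALSE)
}

#' Differential t-test p-value: one immune observation vs the naive group
#'
#' One-observation prediction-style t-test of an immune sample's probe
#' signal against the naive samples of the same probe:
#' t = (x - mean_naive) / (sd_naive * sqrt(1 + 1/n_naive)), df = n_naive - 1,
#' upper tail. A variance floor guards probes with (near-)constant naive
#' signal.
#'
#' @param immune_signal Immune value(s) (vectorised).
#' @param naive_signals Numeric vector (length >= 2) of naive values for
#'   the probe; or, when \code{immune_signal} is a vector over probes, a
#'   matrix with one row per probe.
#' @param var_floor Minimum naive standard deviation (log2 units).
#' @return p-value(s) in [0, 1].
#' @export
differential_pvalue <- function(immune_signal, naive_signals,
                                var_floor = 0.01) {
  if (is.matrix(naive_signals)) {
    n <- ncol(naive_signals)
    if (n < 2L) stop("need >= 2 naive samples")
    mu <- rowMeans(naive_signals)
    sd0 <- pmax(apply(naive_signals, 1L, stats::sd), var_floor)
  } else {
    n <- length(naive_signals)
    if (n < 2L) stop("need >= 2 naive samples")
    mu <- mean(naive_signals)
    sd0 <- max(stats::sd(naive_signals), var_floor)
  }
  tval <- (immune_signal - mu) / (sd0 * sqrt(1 + 1 / n))
  stats::pt(tval, df = n - 1L, lower.tail = FALSE)
}

#' Wilkinson's max meta p-value
#'
#' Combines k p-values through the null distribution of their maximum:
#' p_combined = max(p)^k. With the global and differential probe tests,
#' k = 2.
#'
#' @param p Vector of p-values (the set to combine), all in [0, 1].
#' @return Combined p-value.
#' @export
combine_wilkinson_max <- function(p) {
  if (length(p) == 0L) stop("empty p-value set")
  stopifnot(all(p >= 0 & p <= 1))
  max(p)^length(p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wrapper around \code{p.adjust}).
#' @param p Vector of p-values.
#' @return q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Signal-strength tier of a processed value
#'
#' @inheritParams global_pvalue
#' @param thresholds A [heron_thresholds()] object.
#' @return Factor with levels none < inclusive < moderate < restrictive.
#' @export
assign_sd_tier <- function(signal, pool_mean, pool_sd,
                           thresholds = heron_thresholds()) {
  z <- (signal - pool_mean) / pool_sd
  tier <- ifelse(z > thresholds$restrictive_sd, "restrictive",
          ifelse(z > thresholds$moderate_sd, "moderate",
          ifelse(z > thresholds$inclusive_sd, "inclusive", "none")))
  factor(tier, levels = c("none", "inclusive", "moderate", "restrictive"),
         ordered = TRUE)
}

# Replicate chips of each immune serum, from the sample sheet.
# Returns a list mapping sample_id -> character vector of sibling chips.
.replicate_siblings <- function(sheet) {
  sib <- list()
  grp <- sheet$replicate_group
  for (g in unique(grp[!is.na(grp)])) {
    ids <- sheet$sample_id[!is.na(grp) & grp == g]
    for (id in ids) sib[[id]] <- setdiff(ids, id)
  }
  sib
}

#' Compute the per-probe call table for all immune samples
#'
#' Runs the global z-test, the differential t-test, Wilkinson's max
#' combination and per-sample BH adjustment over an occurrence-level
#' processed matrix, then applies the FDR cutoff and singleton removal
#' (see [remove_singletons()]). Signal tiers are attached per
#' (occurrence, sample).
#'
#' @param m Smoothed occurrence-level log2 matrix.
#' @param library \code{ProbeLibrary}.
#' @param sheet Sample sheet covering all columns of \code{m}.
#' @param thresholds [heron_thresholds()].
#' @param var_floor Naive-sd floor for the differential test.
#' @return A \code{ProbeCallTable}: list of occurrence x immune-sample
#'   matrices (\code{signal, p_global, p_diff, p_combined, q, called,
#'   tier}) plus \code{pool} (mean/sd) and the immune sample sheet rows.
#' @export
probe_call_table <- function(m, library, sheet,
                             thresholds = heron_thresholds(),
                             var_floor = 0.01) {
  stopifnot(is.matrix(m))
  missing_cols <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing_cols))
    stop("sample sheet does not cover matrix column(s): ",
         paste(missing_cols, collapse = ", "))
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  naive_cols <- sheet$sample_id[sheet$condition == "naive"]
  immune_cols <- sheet$sample_id[sheet$condition == "immune"]
  if (length(naive_cols) < 2L) stop("need >= 2 naive samples")
  if (length(immune_cols) < 1L) stop("need >= 1 immune sample")

  pool_mean <- mean(m)
  pool_sd <- stats::sd(as.vector(m))
  if (pool_sd == 0) stop("pooled sd is zero (degenerate matrix)")

  naive_m <- m[, naive_cols, drop = FALSE]
  n0 <- ncol(naive_m)
  mu0 <- rowMeans(naive_m)
  sd0 <- pmax(sqrt(rowSums((naive_m - mu0)^2) / (n0 - 1L)), var_floor)

  sig <- m[, immune_cols, drop = FALSE]
  p_g <- stats::pnorm(sig, pool_mean, pool_sd, lower.tail = FALSE)
  tmat <- (sig - mu0) / (sd0 * sqrt(1 + 1 / n0))
  p_d <- stats::pt(tmat, df = n0 - 1L, lower.tail = FALSE)
  p_c <- pmax(p_g, p_d)^2
  q <- apply(p_c, 2L, bh_adjust)
  dimnames(q) <- dimnames(p_c)
  called <- q <= thresholds$fdr_cutoff
  tier <- matrix(as.character(
    assign_sd_tier(sig, pool_mean, pool_sd, thresholds)),
    nrow = nrow(sig), dimnames = dimnames(sig))

  res <- structure(list(signal = sig, p_global = p_g, p_diff = p_d,
                        p_combined = p_c, q = q, called = called,
                        tier = tier,
                        pool = list(mean = pool_mean, sd = pool_sd),
                        thresholds = thresholds,
                        samples = sheet[sheet$condition == "immune", ,
                                        drop = FALSE]),
                   class = "ProbeCallTable")
  res$called <- remove_singletons(res$called, library, res$samples)
  res
}

#' Remove spatially isolated probe calls
#'
#' A called occurrence with no called occurrence within one tiling step on
#' either side (same protein, same sample) is suppressed, unless the same
#' occurrence is also called in a replicate chip of the same serum
#' (replicate rescue). Guards against prioritising spurious single-probe
#' noise.
#'
#' @param called Logical occurrence x immune-sample matrix.
#' @param library \code{ProbeLibrary}.
#' @param samples Immune rows of the sample sheet (for replicate groups).
#' @return Logical matrix of the same shape.
#' @export
remove_singletons <- function(called, library, samples) {
  sib <- .replicate_siblings(samples)
  unknown <- setdiff(unlist(sib), colnames(called))
  if (length(unknown))
    stop("replicate group references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  occ <- library$occurrences
  idx <- match(rownames(called), occ$occ_id)
  acc <- occ$accession[idx]
  start <- occ$start[idx]
  step <- library$tiling_steps[acc]
  out <- called
  for (rows in split(seq_len(nrow(called)), acc)) {
    o <- order(start[rows]); rows <- rows[o]
    s <- start[rows]; st <- step[rows]
    n <- length(rows)
    sub <- called[rows, , drop = FALSE]
    if (n == 1L) {
      has_neighbor <- matrix(FALSE, 1L, ncol(sub))
    } else {
      adj <- diff(s) <= st[-n]
      prev_ok <- rbind(FALSE, sub[-n, , drop = FALSE] & adj)
      next_ok <- rbind(sub[-1L, , drop = FALSE] & adj, FALSE)
      has_neighbor <- prev_ok | next_ok
    }
    rescued <- matrix(FALSE, n, ncol(sub), dimnames = dimnames(sub))
    for (j in colnames(sub)) {
      sb <- sib[[j]]
      if (length(sb))
        rescued[, j] <- apply(sub[, sb, drop = FALSE], 1L, any)
    }
    out[rows, ] <- sub & (has_neighbor | rescued)
  }
  out
}

#' K-of-N co-recognition counts
#'
#' Tabulates, per item, the number of immune mice (K) out of all immune
#' mice tested (N) whose samples call the item. Replicate chips of one
#' serum collapse to a single mouse (a mouse counts if any of its chips
#' calls the item).
#'
#' @param called Logical item x immune-sample matrix.
#' @param mouse_of_sample Character vector mapping each column to its
#'   mouse ID.
#' @return data.frame(item, K, N).
#' @export
tabulate_k_of_n <- function(called, mouse_of_sample) {
  stopifnot(ncol(called) == length(mouse_of_sample))
  mice <- unique(mouse_of_sample)
  per_mouse <- vapply(mice, function(mus)
    apply(called[, mouse_of_sample == mus, drop = FALSE], 1L, any),
    logical(nrow(called)))
  if (nrow(called) == 1L) per_mouse <- matrix(per_mouse, nrow = 1L)
  data.frame(item = rownames(called) %||% seq_len(nrow(called)),
             K = as.integer(rowSums(per_mouse)),
             N = length(mice), row.names = NULL)
}
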