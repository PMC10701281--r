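# Replicate-concordance analysis: how often an item (probe occurrence,
# epitope region, protein) placed in a signal tier by one chip of a serum
# is co-recognised by the other chip of the same serum. Tier membership
# is cumulative (restrictive items are also moderate and inclusive).
# Co-recognition has two modes: "called" (the item is an antibody-binding
# call in the other chip, at any tier - the default) and "same_tier"
# (the other chip must also place it in the tier under consideration).

.tier_rank <- function(tier) match(tier, .tier_levels)

# Count items of `a` having a Jaccard >= min_jaccard interval match in
# `b` (greedy best-match, same accession).
.match_intervals <- function(a, b, min_jaccard = 0.5) {
  if (!nrow(a) || !nrow(b)) return(0L)
  matched <- 0L
  used <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) {
    cand <- which(!used & b$accession == a$accession[i])
    if (!length(cand)) next
    inter <- pmin(a$aa_end[i], b$aa_end[cand]) -
      pmax(a$aa_start[i], b$aa_start[cand]) + 1L
    uni <- pmax(a$aa_end[i], b$aa_end[cand]) -
      pmin(a$aa_start[i], b$aa_start[cand]) + 1L
    jac <- ifelse(inter > 0, inter / uni, 0)
    j <- which.max(jac)
    if (jac[j] >= min_jaccard) {
      matched <- matched + 1L
      used[cand[j]] <- TRUE
    }
  }
  matched
}

#' Directional replicate concordance at one level and tier
#'
#' \code{calls_A}/\code{calls_B} are the items each chip places in the
#' tier under consideration; \code{recognized_A}/\code{recognized_B} are
#' the item sets that count as co-recognition in the other chip (by
#' default the same sets, i.e. same-tier matching; the chip's full FDR
#' call set gives tier-conditional co-recognition). Probe and protein
#' items match by identity; epitopes match by interval overlap
#' (Jaccard >= 0.5 on protein coordinates).
#'
#' @param calls_A,calls_B For level "probe"/"protein": character vectors
#'   of called item IDs drawn from a shared universe. For level
#'   "epitope": data.frames with accession, aa_start, aa_end.
#' @param level One of "probe", "epitope", "protein".
#' @param tier Tier label attached to the report.
#' @param recognized_A,recognized_B Recognition sets (same type as the
#'   call sets); default the call sets themselves.
#' @param universe Optional full item universe; IDs outside it error.
#' @return One-row data.frame: level, tier, n_A, n_B, n_A_in_B, n_B_in_A,
#'   pct_A_in_B (fraction of A's tier items co-recognised in B, percent)
#'   and pct_B_in_A (NA when a denominator is 0).
#' @export
replicate_concordance <- function(calls_A, calls_B,
                                  level = c("probe", "epitope", "protein"),
                                  tier = "inclusive",
                                  recognized_A = calls_A,
                                  recognized_B = calls_B,
                                  universe = NULL) {
  level <- match.arg(level)
  if (level == "epitope") {
    stopifnot(is.data.frame(calls_A), is.data.frame(calls_B))
    nA <- nrow(calls_A); nB <- nrow(calls_B)
    a_in_b <- .match_intervals(calls_A, recognized_B)
    b_in_a <- .match_intervals(calls_B, recognized_A)
  } else {
    if (!is.null(universe)) {
      bad <- setdiff(c(calls_A, calls_B), universe)
      if (length(bad))
        stop("call set contains items outside the shared universe: ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
    nA <- length(calls_A); nB <- length(calls_B)
    a_in_b <- length(intersect(calls_A, recognized_B))
    b_in_a <- length(intersect(calls_B, recognized_A))
  }
  data.frame(level = level, tier = tier, n_A = nA, n_B = nB,
             n_A_in_B = a_in_b, n_B_in_A = b_in_a,
             pct_A_in_B = if (nA) 100 * a_in_b / nA else NA_real_,
             pct_B_in_A = if (nB) 100 * b_in_a / nB else NA_real_)
}

# Items called by chip `chip` at cumulative tier >= `tier`.
.called_at_tier <- function(called, tier_mat, chip, tier) {
  rank_needed <- .tier_rank(tier)
  rownames(called)[called[, chip] &
                     .tier_rank(tier_mat[, chip]) >= rank_needed]
}

#' Full concordance report for a replicate chip pair
#'
#' Runs [replicate_concordance()] for every level (probe, epitope,
#' protein) and tier (inclusive, moderate, restrictive) of a
#' [heron_call()] result, comparing two chips of the same serum.
#'
#' @param result A \code{heron_result}.
#' @param chip_A,chip_B Immune chip sample IDs.
#' @param match One of \code{"called"} (default: an item counts as
#'   co-recognised when the other chip calls it at any tier) or
#'   \code{"same_tier"} (the other chip must place it in the same tier).
#' @return data.frame, one row per level x tier.
#' @export
concordance_report <- function(result, chip_A, chip_B,
                               match = c("called", "same_tier")) {
  stopifnot(inherits(result, "heron_result"))
  match <- match.arg(match)
  chips <- colnames(result$probe$called)
  if (!all(c(chip_A, chip_B) %in% chips))
    stop("chips not found among immune samples")
  ep_iv <- function(ids)
    result$epitopes[result$epitopes$region_id %in% ids,
                    c("accession", "aa_start", "aa_end")]
  tier_sets <- function(called, tier_mat, chip, tier) {
    ids <- .called_at_tier(called, tier_mat, chip, tier)
    rec <- if (match == "called") rownames(called)[called[, chip]] else ids
    list(ids = ids, rec = rec)
  }
  out <- list()
  for (tier in c("inclusive", "moderate", "restrictive")) {
    A <- tier_sets(result$probe$called, result$probe$tier, chip_A, tier)
    B <- tier_sets(result$probe$called, result$probe$tier, chip_B, tier)
    out[[length(out) + 1L]] <- replicate_concordance(
      A$ids, B$ids, "probe", tier, A$rec, B$rec)
    A <- tier_sets(result$epitope_called, result$epitope_tier, chip_A, tier)
    B <- tier_sets(result$epitope_called, result$epitope_tier, chip_B, tier)
    out[[length(out) + 1L]] <- replicate_concordance(
      ep_iv(A$ids), ep_iv(B$ids), "epitope", tier,
      ep_iv(A$rec), ep_iv(B$rec))
    A <- tier_sets(result$protein_called, result$protein_tier, chip_A, tier)
    B <- tier_sets(result$protein_called, result$protein_tier, chip_B, tier)
    out[[length(out) + 1L]] <- replicate_concordance(
      A$ids, B$ids, "protein", tier, A$rec, B$rec)
  }
  do.call(rbind, out)
}

#' Scatter-plot export for replicate comparisons
#'
#' Per-item signals on two chips with a co-recognition status, the data
#' behind replicate scatter plots.
#'
#' @param result A \code{heron_result}.
#' @param chip_A,chip_B Immune chip sample IDs.
#' @param tier Tier at which calls are taken.
#' @return data.frame(item, signal_A, signal_B, status) with status in
#'   both/onlyA/onlyB/neither.
#' @export
concordance_scatter <- function(result, chip_A, chip_B,
                                tier = "inclusive") {
  sA <- result$probe$signal[, chip_A]
  sB <- result$probe$signal[, chip_B]
  inA <- rownames(result$probe$called) %in%
    .called_at_tier(result$probe$called, result$probe$tier, chip_A, tier)
  inB <- rownames(result$probe$called) %in%
    .called_at_tier(result$probe$called, result$probe$tier, chip_B, tier)
  status <- ifelse(inA & inB, "both",
            ifelse(inA, "onlyA", ifelse(inB, "onlyB", "neither")))
  data.frame(item = rownames(result$probe$called),
             signal_A = sA, signal_B = sB, status = status,
             row.names = NULL)
}
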