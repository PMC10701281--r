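# Epitope segmentation and hierarchical rollup. Called probes adjacent on
# the tiling grid are chained; each chain is a path in the probe
# contiguity graph, whose minimum spanning tree is the path itself, so
# SKATER-style partitioning reduces to recursively cutting the path edge
# that most decreases the within-cluster sum of squared deviations of the
# per-sample -log10 combined p features. Regions then receive order-
# statistic meta p-values, FDR calls, tiers, consensus sequences and
# K-of-N counts; proteins aggregate their epitopes via Tippett's method.

# Recursive SSD-cut partition of a 1-D ordered feature block.
# F: members x features matrix. Returns integer segment labels.
.skater_split <- function(F, min_gain_frac = 0.1, min_size = 1L) {
  k <- nrow(F)
  labels <- integer(k)
  if (k <= 1L) return(rep(1L, k))
  cs <- rbind(0, apply(F, 2L, cumsum))
  cs2 <- rbind(0, apply(F^2, 2L, cumsum))
  ssd <- function(a, b) {
    n <- b - a + 1L
    s <- cs[b + 1L, ] - cs[a, ]
    s2 <- cs2[b + 1L, ] - cs2[a, ]
    sum(s2 - s^2 / n)
  }
  min_gain <- min_gain_frac * ssd(1L, k)
  cuts <- integer(0)
  recurse <- function(a, b) {
    len <- b - a + 1L
    if (len < 2L * min_size || len < 2L) return()
    total <- ssd(a, b)
    js <- seq.int(a + min_size - 1L, b - min_size)
    within <- vapply(js, function(j) ssd(a, j) + ssd(j + 1L, b), numeric(1))
    j <- js[which.min(within)]
    if (total - min(within) >= min_gain && min_gain > 0) {
      cuts <<- c(cuts, j)
      recurse(a, j)
      recurse(j + 1L, b)
    }
  }
  recurse(1L, k)
  bounds <- sort(unique(c(0L, cuts, k)))
  rep(seq_len(length(bounds) - 1L), diff(bounds))
}

#' Segment called probes into epitope regions
#'
#' Chains probe occurrences called in any immune sample when their starts
#' are within \code{max_gap_aa} on the same protein (default: the
#' protein's tiling step, i.e. grid-adjacent only), then splits each chain
#' by recursive minimum-spanning-tree edge cuts minimising within-region
#' sum of squared deviations of the feature matrix (per-sample -log10
#' combined p). Regions never span protein boundaries or gaps wider than
#' \code{max_gap_aa}.
#'
#' @param called Logical occurrence x immune-sample matrix (post
#'   singleton removal).
#' @param features Numeric matrix of the same shape.
#' @param library \code{ProbeLibrary}.
#' @param max_gap_aa Maximum start-to-start gap chained (default: tiling
#'   step per protein).
#' @param min_gain_frac Minimum SSD decrease to accept a cut, as a
#'   fraction of the chain's total SSD (default 0.1).
#' @param min_size Minimum probes per region (default 1).
#' @return data.frame, one row per region: \code{region_id, accession,
#'   aa_start, aa_end, n_members} and a \code{members} list-column of
#'   occurrence IDs.
#' @export
segment_epitopes <- function(called, features, library, max_gap_aa = NULL,
                             min_gain_frac = 0.1, min_size = 1L) {
  stopifnot(identical(dim(called), dim(features)))
  occ <- library$occurrences
  idx <- match(rownames(called), occ$occ_id)
  if (anyNA(idx)) stop("rows of `called` are not occurrence IDs")
  any_call <- rowSums(called) > 0L
  out <- list()
  plen <- library$probe_length
  for (a in unique(occ$accession[idx][any_call])) {
    rows <- which(any_call & occ$accession[idx] == a)
    s <- occ$start[idx][rows]
    o <- order(s)
    if (is.unsorted(s[o])) stop("internal: unordered starts")
    rows <- rows[o]; s <- s[o]
    gap <- if (is.null(max_gap_aa)) unname(library$tiling_steps[a]) else max_gap_aa
    chain_id <- cumsum(c(1L, as.integer(diff(s) > gap)))
    for (ch in split(seq_along(rows), chain_id)) {
      lab <- .skater_split(features[rows[ch], , drop = FALSE],
                           min_gain_frac, min_size)
      for (seg in split(ch, lab)) {
        st <- s[seg]
        out[[length(out) + 1L]] <- data.frame(
          accession = a, aa_start = min(st), aa_end = max(st) + plen - 1L,
          n_members = length(seg),
          members = I(list(rownames(called)[rows[seg]])))
      }
    }
  }
  if (!length(out))
    return(data.frame(region_id = character(), accession = character(),
                      aa_start = integer(), aa_end = integer(),
                      n_members = integer(),
                      members = I(list())))
  df <- do.call(rbind, out)
  df <- df[order(df$accession, df$aa_start), , drop = FALSE]
  data.frame(region_id = paste0(df$accession, ":", df$aa_start, "-",
                                df$aa_end),
             df, row.names = NULL)
}

#' Epitope meta p-value from member probe p-values
#'
#' Wilkinson's method on the second-highest member p-value: for n >= 2
#' members the combined p is the Beta(n-1, 2) CDF evaluated at the
#' 2nd-largest member p (the (n-1)-th ascending order statistic); a
#' single-member region keeps its probe p.
#'
#' @param p Member combined p-values for one sample (length >= 1).
#' @return Epitope p-value.
#' @export
epitope_pvalue <- function(p) {
  n <- length(p)
  if (n == 0L) stop("empty member p-value set")
  if (n == 1L) return(p)
  stats::pbeta(sort(p)[n - 1L], n - 1L, 2)
}

#' Protein meta p-value from member epitope p-values
#'
#' Tippett's (Wilkinson's min) method: p = 1 - (1 - min p)^m.
#'
#' @param p Epitope p-values within one protein for one sample.
#' @return Protein p-value.
#' @export
protein_pvalue <- function(p) {
  m <- length(p)
  if (m == 0L) stop("empty epitope p-value set")
  -expm1(m * log1p(-min(p)))
}

#' Consensus sequence shared by a region's member probes
#'
#' The stretch common to all member 16-mers is the protein slice from the
#' last member start to 15 past the first member start; for k members on a
#' step-s grid its length is 16 - s(k-1). When the region spans more than
#' one probe length of contiguous sequence the members share no common
#' core; the full spanned interval is returned with
#' \code{no_common_core = TRUE}.
#'
#' @param member_starts 1-based start positions of the member probes
#'   (one protein).
#' @param protein_seq The protein's amino-acid sequence (NA allowed; then
#'   only coordinates/length are returned).
#' @param probe_length Probe length (default 16).
#' @return list(seq, start, end, length, no_common_core).
#' @export
consensus_sequence <- function(member_starts, protein_seq = NA,
                               probe_length = 16L) {
  stopifnot(length(member_starts) >= 1L)
  cstart <- max(member_starts)
  cend <- min(member_starts) + probe_length - 1L
  if (cstart <= cend) {
    core <- TRUE
  } else {
    cstart <- min(member_starts)
    cend <- max(member_starts) + probe_length - 1L
    core <- FALSE
  }
  list(seq = if (is.na(protein_seq)) NA_character_ else
         substr(protein_seq, cstart, cend),
       start = cstart, end = cend, length = cend - cstart + 1L,
       no_common_core = !core)
}

.tier_levels <- c("none", "inclusive", "moderate", "restrictive")

# Highest tier whose SD cutoff the signal exceeds, given the item is
# called; vectorised over a signal vector.
.conjunction_tier <- function(max_signal, called, pool, thresholds) {
  z <- (max_signal - pool$mean) / pool$sd
  tier <- ifelse(!called, "none",
          ifelse(z > thresholds$restrictive_sd, "restrictive",
          ifelse(z > thresholds$moderate_sd, "moderate",
          ifelse(z > thresholds$inclusive_sd, "inclusive", "none"))))
  tier
}

#' Hierarchical antibody-binding calls: probes, epitopes, proteins
#'
#' End-to-end inference on a processed (smoothed, occurrence-level)
#' intensity matrix: probe-level tests/calls ([probe_call_table()]),
#' epitope segmentation ([segment_epitopes()]), order-statistic epitope
#' p-values, Tippett protein p-values, per-sample BH adjustment and FDR
#' calls at each level, signal tiers (an item is in tier T when its
#' q-value passes the FDR cutoff AND its maximum member signal exceeds
#' the tier-T SD cutoff), consensus sequences and K-of-N counts with
#' replicate chips collapsed per mouse.
#'
#' @param m Smoothed occurrence-level log2 matrix.
#' @param library \code{ProbeLibrary}.
#' @param sheet Sample sheet.
#' @param proteome Optional data.frame(accession, sequence) for consensus
#'   sequence extraction.
#' @param thresholds [heron_thresholds()].
#' @param var_floor Naive-sd floor of the differential test.
#' @param max_gap_aa,min_gain_frac,min_size Segmentation parameters, see
#'   [segment_epitopes()].
#' @return A \code{heron_result} list: \code{probe} (ProbeCallTable),
#'   \code{epitopes}/\code{proteins} (annotated data.frames with K-of-N
#'   and overall tier) and per-sample matrices \code{epitope_p, epitope_q,
#'   epitope_called, epitope_tier, protein_p, protein_q, protein_called,
#'   protein_tier}.
#' @export
heron_call <- function(m, library, sheet, proteome = NULL,
                       thresholds = heron_thresholds(), var_floor = 0.01,
                       max_gap_aa = NULL, min_gain_frac = 0.1,
                       min_size = 1L) {
  pct <- probe_call_table(m, library, sheet, thresholds, var_floor)
  feats <- -log10(pmax(pct$p_combined, .Machine$double.xmin))
  regions <- segment_epitopes(pct$called, feats, library, max_gap_aa,
                              min_gain_frac, min_size)
  chips <- colnames(pct$called)
  mouse <- pct$samples$mouse_id[match(chips, pct$samples$sample_id)]
  nr <- nrow(regions)

  ep_p <- matrix(NA_real_, nr, length(chips),
                 dimnames = list(regions$region_id, chips))
  ep_sig <- ep_p
  for (i in seq_len(nr)) {
    mem <- regions$members[[i]]
    for (j in seq_along(chips))
      ep_p[i, j] <- epitope_pvalue(pct$p_combined[mem, chips[j]])
    ep_sig[i, ] <- apply(pct$signal[mem, chips, drop = FALSE], 2L, max)
  }
  ep_q <- if (nr == 0L) ep_p else apply(ep_p, 2L, bh_adjust)
  if (nr == 1L) ep_q <- matrix(ep_q, 1L, dimnames = dimnames(ep_p))
  ep_called <- ep_q <= thresholds$fdr_cutoff
  ep_tier <- matrix(.conjunction_tier(ep_sig, ep_called, pct$pool,
                                      thresholds),
                    nr, length(chips), dimnames = dimnames(ep_p))

  # consensus
  if (nr) {
    occ <- library$occurrences
    cons <- vector("list", nr)
    for (i in seq_len(nr)) {
      st <- occ$start[match(regions$members[[i]], occ$occ_id)]
      pseq <- if (is.null(proteome)) NA else
        proteome$sequence[match(regions$accession[i], proteome$accession)]
      cons[[i]] <- consensus_sequence(st, pseq, library$probe_length)
    }
    regions$consensus_seq <- vapply(cons, `[[`, character(1), "seq")
    regions$consensus_start <- vapply(cons, `[[`, numeric(1), "start")
    regions$consensus_end <- vapply(cons, `[[`, numeric(1), "end")
    regions$consensus_len <- vapply(cons, `[[`, numeric(1), "length")
    regions$no_common_core <- vapply(cons, `[[`, logical(1),
                                     "no_common_core")
    kn <- tabulate_k_of_n(ep_called, mouse)
    regions$K <- kn$K
    regions$N <- kn$N
    rk <- matrix(match(ep_tier, .tier_levels), nr)
    for (ti in 2:4)
      regions[[paste0("K_", .tier_levels[ti])]] <-
        tabulate_k_of_n(rk >= ti, mouse)$K
    regions$tier <- apply(ep_tier, 1L, function(x)
      .tier_levels[max(match(x, .tier_levels))])
  }

  # protein rollup
  prot_acc <- unique(regions$accession)
  np <- length(prot_acc)
  pr_p <- matrix(NA_real_, np, length(chips),
                 dimnames = list(prot_acc, chips))
  pr_sig <- pr_p
  n_eps <- integer(np)
  for (i in seq_len(np)) {
    rr <- which(regions$accession == prot_acc[i])
    n_eps[i] <- length(rr)
    for (j in seq_along(chips))
      pr_p[i, j] <- protein_pvalue(ep_p[rr, chips[j]])
    pr_sig[i, ] <- apply(ep_sig[rr, , drop = FALSE], 2L, max)
  }
  pr_q <- if (np == 0L) pr_p else apply(pr_p, 2L, bh_adjust)
  if (np == 1L) pr_q <- matrix(pr_q, 1L, dimnames = dimnames(pr_p))
  pr_called <- pr_q <= thresholds$fdr_cutoff
  pr_tier <- matrix(.conjunction_tier(pr_sig, pr_called, pct$pool,
                                      thresholds),
                    np, length(chips), dimnames = dimnames(pr_p))
  proteins <- data.frame(accession = prot_acc, n_epitopes = n_eps,
                         row.names = NULL)
  if (np) {
    kn <- tabulate_k_of_n(pr_called, mouse)
    proteins$K <- kn$K
    proteins$N <- kn$N
    rk <- matrix(match(pr_tier, .tier_levels), np)
    for (ti in 2:4)
      proteins[[paste0("K_", .tier_levels[ti])]] <-
        tabulate_k_of_n(rk >= ti, mouse)$K
    proteins$tier <- apply(pr_tier, 1L, function(x)
      .tier_levels[max(match(x, .tier_levels))])
  }

  structure(list(probe = pct, epitopes = regions, proteins = proteins,
                 epitope_p = ep_p, epitope_q = ep_q,
                 epitope_called = ep_called, epitope_tier = ep_tier,
                 epitope_max_signal = ep_sig,
                 protein_p = pr_p, protein_q = pr_q,
                 protein_called = pr_called, protein_tier = pr_tier,
                 mouse_of_chip = stats::setNames(mouse, chips)),
            class = "heron_result")
}

#' @export
print.heron_result <- function(x, ...) {
  cat("heron_result:", nrow(x$probe$called), "probe occurrences,",
      nrow(x$epitopes), "epitope regions,", nrow(x$proteins),
      "proteins;", ncol(x$probe$called), "immune chips\n")
  invisible(x)
}

#' Epitope length histogram by mouse and tier
#'
#' Bins consensus lengths of the epitopes called by each mouse at each
#' tier (tier membership is cumulative: an epitope above the restrictive
#' cutoff is also in the moderate and inclusive categories) into 2-aa
#' bins (1-2, 3-4, ...).
#'
#' @param result A [heron_call()] result.
#' @return data.frame(mouse, tier, bin, count) with zero-count bins
#'   omitted; zero rows for an empty epitope set.
#' @export
summarize_epitopes <- function(result) {
  stopifnot(inherits(result, "heron_result"))
  regions <- result$epitopes
  out <- list()
  if (nrow(regions)) {
    tier_rank <- matrix(match(result$epitope_tier, .tier_levels),
                        nrow(regions))
    for (mus in unique(result$mouse_of_chip)) {
      cols <- which(result$mouse_of_chip == mus)
      rank_m <- apply(tier_rank[, cols, drop = FALSE], 1L, max)
      for (ti in 2:4) {
        lens <- regions$consensus_len[rank_m >= ti]
        if (!length(lens)) next
        bin_lo <- 2L * ((as.integer(lens) + 1L) %/% 2L) - 1L
        tb <- table(paste0(bin_lo, "-", bin_lo + 1L))
        out[[length(out) + 1L]] <- data.frame(
          mouse = mus, tier = .tier_levels[ti], bin = names(tb),
          count = as.integer(tb))
      }
    }
  }
  if (!length(out))
    return(data.frame(mouse = character(), tier = character(),
                      bin = character(), count = integer()))
  do.call(rbind, out)
}
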