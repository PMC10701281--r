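# Synthetic-data generator. Emulates the structure the analysis assumes:
# lognormal probe background with a shared per-probe affinity component,
# sparse naive autoantibody binding present in both conditions of a
# mouse, a global multiplicative signal elevation in hyper-immune sera,
# per-mouse private epitope spikes plus a minority of epitopes shared by
# several mice (elevating runs of consecutive probes consistent with
# 16-mer / 2-aa tiling), per-chip replicate noise and an additive batch
# shift. Every stage draws from its own seed substream so enlarging one
# stage does not perturb the draws of another.

# Amino-acid frequencies (approximate natural proteome composition).
.aa_freq <- c(A = .083, R = .055, N = .041, D = .055, C = .014, Q = .039,
              E = .067, G = .071, H = .023, I = .059, L = .097, K = .058,
              M = .024, F = .039, P = .047, S = .066, T = .054, W = .011,
              Y = .029, V = .069)

.substream <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  set.seed((as.integer(seed) %% 1000003L) * 1009L + offs %% 99991L)
}

#' Simulation configuration
#'
#' Defaults are sized to mirror the study design the analysis targets:
#' 5 naive + 6 immune mice with one replicated immune serum, ~10-12k
#' probes from 200 proteins of mean length 120 aa, epitopes of 8-12 aa
#' spiked at 8 pooled-background SD on the log2 scale.
#'
#' @param n_proteins,protein_length_mean,protein_length_min Proteome size
#'   and length distribution (normal, truncated at the minimum).
#' @param n_naive,n_immune Mouse counts per condition (naive mice are the
#'   first \code{n_naive} immune mice, i.e. matched sera).
#' @param n_replicate_pairs Number of immune sera assayed on two chips.
#' @param background_log2_mean,background_log2_sd Lognormal background of
#'   raw fluorescence, parameterised on the log2 scale.
#' @param probe_effect_frac Fraction of background variance attributable
#'   to a per-probe affinity shared across all chips.
#' @param immune_global_shift Multiplicative raw-scale elevation of all
#'   immune chips (hyper-immune sera).
#' @param naive_hit_rate Fraction of probes with naive autoantibody
#'   binding per mouse (elevated in both conditions of that mouse).
#' @param naive_hit_amplitude_sd Amplitude of naive hits, in background
#'   SD units on the log2 scale.
#' @param n_private_epitopes,n_shared_epitopes Per-mouse private spike
#'   count and the number of regions shared by several mice.
#' @param shared_k_range Range the number of spiked mice per shared
#'   region is drawn from.
#' @param epitope_length_range Epitope length range in aa.
#' @param spike_amplitude_sd Spike amplitude in background SD units
#'   (additive on log2, multiplicative on the raw scale).
#' @param replicate_noise_sd Per-cell chip noise (log2 units).
#' @param batch_shift Additive log2 shift applied to the second batch.
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return A \code{SimulationConfig} list.
#' @export
sim_config <- function(n_proteins = 200L, protein_length_mean = 120,
                       protein_length_min = 16L,
                       n_naive = 5L, n_immune = 6L, n_replicate_pairs = 1L,
                       background_log2_mean = 7, background_log2_sd = 1,
                       probe_effect_frac = 0.5,
                       immune_global_shift = 1.5,
                       naive_hit_rate = 0.001, naive_hit_amplitude_sd = 4,
                       n_private_epitopes = 6L, n_shared_epitopes = 4L,
                       shared_k_range = c(2L, 6L),
                       epitope_length_range = c(8L, 12L),
                       spike_amplitude_sd = 8,
                       replicate_noise_sd = 0.25, batch_shift = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_proteins >= 1, cfg$n_naive >= 0, cfg$n_immune >= 0,
            cfg$n_replicate_pairs >= 0, cfg$spike_amplitude_sd > 0,
            cfg$background_log2_sd > 0, cfg$naive_hit_rate >= 0,
            cfg$n_replicate_pairs <= cfg$n_immune,
            cfg$shared_k_range[2] <= max(cfg$n_immune, 1L))
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a proteome
#'
#' i.i.d. residues from a fixed amino-acid frequency table; lengths drawn
#' from a normal distribution truncated at \code{protein_length_min}.
#'
#' @param config A [sim_config()].
#' @return data.frame(accession, sequence, reviewed); deterministic under
#'   the config seed.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$protein_length_mean < config$protein_length_min)
    stop("degenerate length distribution: mean below the minimum length")
  .substream(config$seed, "proteome")
  n <- config$n_proteins
  lens <- pmax(config$protein_length_min,
               round(stats::rnorm(n, config$protein_length_mean,
                                  config$protein_length_mean / 4)))
  seqs <- vapply(lens, function(L)
    paste(sample(names(.aa_freq), L, replace = TRUE, prob = .aa_freq),
          collapse = ""), character(1))
  data.frame(accession = sprintf("SYN%04d", seq_len(n)),
             sequence = seqs, reviewed = TRUE)
}

# Probes of `acc` whose window overlaps the epitope [a, b] by at least
# half the epitope length: the consecutive-probe structure of a spiked
# region. (A containment rule - only probes holding the complete epitope
# - reproduces the shared-core geometry of real binding more closely but
# leaves long epitopes on too few probes to survive +/-8 aa smoothing;
# the half-overlap rule is the declared simulation contract.)
.footprint_occurrences <- function(library, acc, a, b) {
  occ <- library$occurrences
  sel <- occ$accession == acc
  s <- occ$start[sel]
  ov <- pmin(s + library$probe_length - 1L, b) - pmax(s, a) + 1L
  occ$occ_id[sel][ov >= (b - a + 1L) / 2]
}

#' Simulate probe intensities with a known ground truth
#'
#' Builds a sample sheet (naive chips, immune chips, replicate chips),
#' spikes private and shared epitope regions into the immune mice, adds
#' naive autoantibody probes to both conditions of their mouse, and
#' returns the raw (relative fluorescence) matrix at unique-peptide level
#' together with the truth manifest.
#'
#' @param library A \code{ProbeLibrary} built from the simulated proteome.
#' @param config A [sim_config()].
#' @return list(intensities, sheet, truth): \code{intensities} is a raw
#'   peptide x chip matrix (stage "raw"), \code{truth} a
#'   \code{GroundTruthManifest} with per-region accession, core interval
#'   (\code{aa_start, aa_end}), spiked-probe footprint interval
#'   (\code{probe_start, probe_end}), amplitude, type, spiked mice and
#'   intended K, plus the naive background probe sets.
#' @export
simulate_intensities <- function(library, config) {
  stopifnot(inherits(library, "ProbeLibrary"),
            inherits(config, "SimulationConfig"))
  if (nrow(library$probes) == 0L) stop("empty probe library")
  occ <- library$occurrences
  prot_len <- tapply(occ$start, occ$accession, max) + library$probe_length - 1L

  mice <- sprintf("M%d", seq_len(config$n_immune))
  naive_mice <- utils::head(mice, config$n_naive)
  sheet <- data.frame(sample_id = character(), mouse_id = character(),
                      condition = character(),
                      replicate_group = character(), batch = character())
  for (mus in naive_mice)
    sheet[nrow(sheet) + 1L, ] <- list(paste0(mus, "_naive"), mus, "naive",
                                      NA_character_, NA_character_)
  for (i in seq_along(mice)) {
    mus <- mice[i]
    if (i <= config$n_replicate_pairs) {
      grp <- paste0(mus, "_immune")
      for (r in 1:2)
        sheet[nrow(sheet) + 1L, ] <- list(paste0(grp, "_r", r), mus,
                                          "immune", grp, NA_character_)
    } else {
      sheet[nrow(sheet) + 1L, ] <- list(paste0(mus, "_immune"), mus,
                                        "immune", NA_character_,
                                        NA_character_)
    }
  }
  sheet$batch <- rep(c("b1", "b2"), length.out = nrow(sheet))

  # --- truth: epitope regions -------------------------------------------
  .substream(config$seed, "truth")
  elig <- names(prot_len)[prot_len >= max(config$epitope_length_range) + 4L]
  if (!length(elig)) stop("no protein long enough for the requested epitopes")
  draw_region <- function() {
    acc <- sample(elig, 1L)
    L <- sample(seq(config$epitope_length_range[1],
                    config$epitope_length_range[2]), 1L)
    if (prot_len[acc] < L) stop("spike region exceeds protein length")
    a <- sample(seq_len(prot_len[acc] - L + 1L), 1L)
    c(acc = acc, a = a, b = a + L - 1L)
  }
  regions <- list()
  add_region <- function(type, reg_mice) {
    r <- draw_region()
    fp <- .footprint_occurrences(library, r[["acc"]],
                                 as.integer(r[["a"]]), as.integer(r[["b"]]))
    fps <- occ$start[match(fp, occ$occ_id)]
    regions[[length(regions) + 1L]] <<- data.frame(
      region_id = sprintf("T%03d", length(regions) + 1L),
      accession = r[["acc"]], aa_start = as.integer(r[["a"]]),
      aa_end = as.integer(r[["b"]]),
      probe_start = min(fps), probe_end = max(fps) + library$probe_length - 1L,
      amplitude_sd = config$spike_amplitude_sd, type = type,
      mice = paste(reg_mice, collapse = ";"),
      intended_k = length(reg_mice))
  }
  if (config$n_immune > 0) {
    for (mus in mice)
      for (e in seq_len(config$n_private_epitopes)) add_region("private", mus)
    for (e in seq_len(config$n_shared_epitopes)) {
      k <- sample(seq(config$shared_k_range[1],
                      min(config$shared_k_range[2], length(mice))), 1L)
      add_region("shared", sort(sample(mice, k)))
    }
  }
  truth_regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(region_id = character(), accession = character(),
               aa_start = integer(), aa_end = integer(),
               probe_start = integer(), probe_end = integer(),
               amplitude_sd = numeric(), type = character(),
               mice = character(), intended_k = integer())

  .substream(config$seed, "naive_hits")
  n_hits <- round(config$naive_hit_rate * nrow(library$probes))
  naive_hits <- lapply(stats::setNames(mice, mice), function(mus)
    sort(sample(library$probes$probe_seq, n_hits)))

  # --- intensity matrix (log2 scale), unique-peptide rows ---------------
  .substream(config$seed, "intensity")
  peptides <- library$probes$probe_seq
  npep <- length(peptides)
  chips <- sheet$sample_id
  sd_probe <- config$background_log2_sd * sqrt(config$probe_effect_frac)
  sd_cell <- config$background_log2_sd * sqrt(1 - config$probe_effect_frac)
  probe_eff <- stats::rnorm(npep, 0, sd_probe)
  lm2 <- matrix(stats::rnorm(npep * length(chips), 0, sd_cell),
                npep, length(chips), dimnames = list(peptides, chips))
  lm2 <- lm2 + probe_eff + config$background_log2_mean
  imm <- sheet$condition == "immune"
  lm2[, imm] <- lm2[, imm] + log2(config$immune_global_shift)
  lm2[, sheet$batch == "b2"] <- lm2[, sheet$batch == "b2"] +
    config$batch_shift
  if (config$replicate_noise_sd > 0)
    lm2 <- lm2 + matrix(stats::rnorm(length(lm2), 0,
                                     config$replicate_noise_sd),
                        npep, length(chips))

  amp <- function(sd_units) sd_units * config$background_log2_sd
  if (nrow(truth_regions)) {
    for (i in seq_len(nrow(truth_regions))) {
      fp <- .footprint_occurrences(library, truth_regions$accession[i],
                                   truth_regions$aa_start[i],
                                   truth_regions$aa_end[i])
      pep <- unique(occ$probe_seq[match(fp, occ$occ_id)])
      reg_mice <- strsplit(truth_regions$mice[i], ";")[[1]]
      cols <- sheet$sample_id[imm & sheet$mouse_id %in% reg_mice]
      lm2[pep, cols] <- lm2[pep, cols] + amp(truth_regions$amplitude_sd[i])
    }
  }
  for (mus in names(naive_hits)) {
    cols <- sheet$sample_id[sheet$mouse_id == mus]
    if (length(naive_hits[[mus]]) && length(cols))
      lm2[naive_hits[[mus]], cols] <- lm2[naive_hits[[mus]], cols] +
        amp(config$naive_hit_amplitude_sd)
  }

  raw <- 2^lm2
  attr(raw, "stage") <- "raw"
  truth <- structure(list(regions = truth_regions,
                          naive_hits = naive_hits,
                          n_immune = config$n_immune),
                     class = "GroundTruthManifest")
  list(intensities = raw, sheet = sheet, truth = truth)
}

#' Simulate an ELISA OD panel
#'
#' OD is a saturating (Hill-type) function of the underlying log titer
#' implied by the truth manifest plus noise, clipped to the plate range
#' [0, 3.5]. Peptides spiked at high amplitude in a mouse read >= 2 OD in
#' that mouse's immune serum; unspiked peptide/serum pairs stay near the
#' blank.
#'
#' @param peptides Probe sequences to assay (must exist in the library).
#' @param library \code{ProbeLibrary}.
#' @param sheet Sample sheet naming the sera (mouse + condition).
#' @param truth \code{GroundTruthManifest} from [simulate_intensities()].
#' @param config [sim_config()].
#' @return OD matrix, peptides x sera.
#' @export
simulate_elisa <- function(peptides, library, sheet, truth, config) {
  unknown <- setdiff(peptides, library$probes$probe_seq)
  if (length(unknown))
    stop("unknown peptide(s): ", paste(utils::head(unknown, 5),
                                       collapse = ", "))
  .substream(config$seed, "elisa")
  occ <- library$occurrences
  od <- matrix(0, length(peptides), nrow(sheet),
               dimnames = list(peptides, sheet$sample_id))
  titer <- od
  if (nrow(truth$regions)) {
    for (i in seq_len(nrow(truth$regions))) {
      fp <- .footprint_occurrences(library, truth$regions$accession[i],
                                   truth$regions$aa_start[i],
                                   truth$regions$aa_end[i])
      pep <- intersect(unique(occ$probe_seq[match(fp, occ$occ_id)]),
                       peptides)
      if (!length(pep)) next
      reg_mice <- strsplit(truth$regions$mice[i], ";")[[1]]
      cols <- sheet$sample_id[sheet$condition == "immune" &
                                sheet$mouse_id %in% reg_mice]
      titer[pep, cols] <- pmax(titer[pep, cols],
                               truth$regions$amplitude_sd[i])
    }
  }
  for (mus in names(truth$naive_hits)) {
    pep <- intersect(truth$naive_hits[[mus]], peptides)
    cols <- sheet$sample_id[sheet$mouse_id == mus]
    if (length(pep) && length(cols))
      titer[pep, cols] <- pmax(titer[pep, cols],
                               config$naive_hit_amplitude_sd)
  }
  od <- 3.4 * titer^2 / (titer^2 + 25) +
    matrix(stats::rnorm(length(od), 0.15, 0.12), nrow(od))
  od <- pmin(pmax(od, 0), 3.5)
  od
}

#' Match called epitope regions against the simulation ground truth
#'
#' For every spiked truth region, finds the best-overlapping recovered
#' epitope region (Jaccard on protein coordinates between the spiked
#' probe footprint and the region span) and reports whether it is
#' recovered at the requested tier by at least one spiked mouse, plus
#' the K-of-N agreement for shared regions.
#'
#' @param result A [heron_call()] result.
#' @param truth \code{GroundTruthManifest} from [simulate_intensities()].
#' @param min_jaccard Overlap required to count a region as recovered.
#' @param tier Minimum tier the matched region must reach in a spiked
#'   mouse's chip.
#' @return data.frame, one row per truth region: region_id, type,
#'   intended_k, best_jaccard, recovered, K_called, k_match.
#' @export
evaluate_recovery <- function(result, truth, min_jaccard = 0.5,
                              tier = "moderate") {
  stopifnot(inherits(result, "heron_result"),
            inherits(truth, "GroundTruthManifest"))
  tr <- truth$regions
  eps <- result$epitopes
  rank_needed <- match(tier, .tier_levels)
  out <- data.frame(region_id = tr$region_id, type = tr$type,
                    intended_k = tr$intended_k,
                    best_jaccard = 0, recovered = FALSE,
                    K_called = NA_integer_, k_match = NA)
  for (i in seq_len(nrow(tr))) {
    cand <- which(eps$accession == tr$accession[i])
    if (!length(cand)) next
    inter <- pmin(eps$aa_end[cand], tr$probe_end[i]) -
      pmax(eps$aa_start[cand], tr$probe_start[i]) + 1L
    uni <- pmax(eps$aa_end[cand], tr$probe_end[i]) -
      pmin(eps$aa_start[cand], tr$probe_start[i]) + 1L
    jac <- ifelse(inter > 0, inter / uni, 0)
    mice <- strsplit(tr$mice[i], ";")[[1]]
    chips <- names(result$mouse_of_chip)[result$mouse_of_chip %in% mice]
    at_tier <- vapply(cand, function(r) any(
      match(result$epitope_tier[r, chips], .tier_levels) >= rank_needed),
      logical(1))
    ok <- jac >= min_jaccard & at_tier
    out$best_jaccard[i] <- max(jac)
    if (any(ok)) {
      out$recovered[i] <- TRUE
      best <- cand[ok][which.max(jac[ok])]
      k_col <- paste0("K_", tier)
      out$K_called[i] <- eps[[k_col]][best]
      out$k_match[i] <- out$K_called[i] == tr$intended_k[i]
    }
  }
  out
}
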