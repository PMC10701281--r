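# Shared fixtures, built in code at test time.

# Deterministic random protein sequence.
rand_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Two-protein toy proteome: P1 reviewed (step 2), P2 unreviewed (step 4).
toy_proteome <- function() {
  set.seed(42)
  data.frame(accession = c("P1", "P2"),
             sequence = c(rand_protein(40), rand_protein(33)),
             reviewed = c(TRUE, FALSE))
}

toy_library <- function() build_probe_library(toy_proteome())

# Small end-to-end simulation (reduced size, fast) through calling.
small_run <- function(seed = 1, ...) {
  cfg <- sim_config(n_proteins = 60L, protein_length_mean = 90,
                    seed = seed, ...)
  proteome <- simulate_proteome(cfg)
  lib <- build_probe_library(proteome)
  sim <- simulate_intensities(lib, cfg)
  smoothed <- preprocess_intensities(sim$intensities, lib)
  list(cfg = cfg, proteome = proteome, lib = lib, sim = sim,
       smoothed = smoothed,
       result = heron_call(smoothed, lib, sim$sheet, proteome))
}

# Brute-force window enumerator: all probe starts for a protein of
# length L, step s, optionally with the C-terminal anchor.
brute_starts <- function(L, step, probe_length = 16L, cterm = TRUE) {
  if (L < probe_length) return(integer())
  starts <- integer()
  s <- 1L
  while (s <= L - probe_length + 1L) {
    starts <- c(starts, s)
    s <- s + step
  }
  if (cterm && max(starts) != L - probe_length + 1L)
    starts <- c(starts, L - probe_length + 1L)
  starts
}

# Brute-force BH step-up: q_i = min over j with p_(j) >= p_(i) of
# min(1, m p_(j) / j).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(o == i)  # rank of p_i
    cand <- vapply(ri:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    q[i] <- min(cand)
  }
  q
}

# Exhaustive hypergeometric tail by enumerating draw compositions.
brute_hyper_tail <- function(x, n, K, N) {
  sum(vapply(x:n, function(i)
    if (i <= K && n - i <= N - K)
      choose(K, i) * choose(N - K, n - i) / choose(N, n) else 0,
    numeric(1)))
}
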