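test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 20L, protein_length_mean = 60, seed = 5L)
  p1 <- simulate_proteome(cfg)
  p2 <- simulate_proteome(cfg)
  expect_identical(p1, p2)
  lib <- build_probe_library(p1)
  s1 <- simulate_intensities(lib, cfg)
  s2 <- simulate_intensities(lib, cfg)
  expect_identical(s1$intensities, s2$intensities)
  expect_identical(s1$truth$regions, s2$truth$regions)

  cfg2 <- sim_config(n_proteins = 20L, protein_length_mean = 60, seed = 6L)
  expect_false(identical(simulate_proteome(cfg2)$sequence, p1$sequence))
})

test_that("simulated proteome honours counts and the length floor", {
  cfg <- sim_config(n_proteins = 5L, protein_length_mean = 60, seed = 1L)
  prot <- simulate_proteome(cfg)
  expect_equal(nrow(prot), 5L)
  expect_true(all(nchar(prot$sequence) >= 16L))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", prot$sequence)))
  expect_error(simulate_proteome(
    sim_config(protein_length_mean = 10, protein_length_min = 16L)),
    "degenerate")
})

test_that("spiked regions elevate runs of consecutive probes (overlap rule)", {
  run <- small_run(seed = 2)
  tr <- run$sim$truth$regions
  occ <- run$lib$occurrences
  raw_l2 <- log2(run$sim$intensities)
  for (i in seq_len(min(5L, nrow(tr)))) {
    # independent overlap enumeration: probes overlapping the core
    # interval by at least half the epitope length
    sel <- occ$accession == tr$accession[i]
    s <- occ$start[sel]
    len <- tr$aa_end[i] - tr$aa_start[i] + 1L
    ov <- pmin(s + 15L, tr$aa_end[i]) - pmax(s, tr$aa_start[i]) + 1L
    hits <- s[ov >= len / 2]
    expect_gte(length(hits), 4L)                 # 8 aa on a 2-aa grid
    # consecutive on the grid (the C-terminal anchor probe may sit 1 aa
    # from its neighbour)
    expect_true(all(diff(sort(hits)) <= 2L))
    expect_equal(range(hits) + c(0L, 15L),
                 c(tr$probe_start[i], tr$probe_end[i]))
    # those peptides are elevated in a spiked mouse vs a non-spiked one
    mice <- strsplit(tr$mice[i], ";")[[1]]
    chip_in <- run$sim$sheet$sample_id[run$sim$sheet$condition == "immune" &
                                run$sim$sheet$mouse_id == mice[1]][1]
    pep <- occ$probe_seq[sel][ov >= len / 2]
    expect_gt(min(raw_l2[pep, chip_in]) - mean(raw_l2[, chip_in]),
              0.5 * run$cfg$spike_amplitude_sd)
  }
})

test_that("replicate chips correlate above any cross-mouse immune pair", {
  for (s in 1:3) {
    cfg <- sim_config(n_proteins = 40L, protein_length_mean = 80,
                      seed = s)
    lib <- build_probe_library(simulate_proteome(cfg))
    sim <- simulate_intensities(lib, cfg)
    l2 <- log2(sim$intensities)
    imm <- sim$sheet$sample_id[sim$sheet$condition == "immune"]
    mouse <- sim$sheet$mouse_id[match(imm, sim$sheet$sample_id)]
    cm <- stats::cor(l2[, imm])
    rep_cor <- cm["M1_immune_r1", "M1_immune_r2"]
    cross <- cm[outer(mouse, mouse, "!=")]
    expect_gt(rep_cor, max(cross))
  }
})

test_that("ELISA panel saturates for spiked peptide-mouse pairs only", {
  run <- small_run(seed = 3)
  tr <- run$sim$truth$regions
  occ <- run$lib$occurrences
  spiked_pep <- unique(occ$probe_seq[occ$accession == tr$accession[1] &
    occ$start >= tr$probe_start[1] & occ$start + 15L <= tr$probe_end[1]])
  all_spiked <- unique(unlist(c(
    lapply(seq_len(nrow(tr)), function(i)
      occ$probe_seq[occ$accession == tr$accession[i] &
                      occ$start >= tr$probe_start[i] &
                      occ$start + 15L <= tr$probe_end[i]]),
    run$sim$truth$naive_hits)))
  null_pep <- setdiff(run$lib$probes$probe_seq, all_spiked)[1:20]
  od <- simulate_elisa(c(spiked_pep[1], null_pep), run$lib, run$sim$sheet,
                       run$sim$truth, run$cfg)
  mouse1 <- strsplit(tr$mice[1], ";")[[1]][1]
  chip <- run$sim$sheet$sample_id[run$sim$sheet$mouse_id == mouse1 &
                                    run$sim$sheet$condition == "immune"][1]
  expect_gte(od[spiked_pep[1], chip], 2)
  expect_lt(mean(od[null_pep, ]), 1)
  expect_true(all(od >= 0 & od <= 3.5))
  od2 <- simulate_elisa(c(spiked_pep[1], null_pep), run$lib, run$sim$sheet,
                        run$sim$truth, run$cfg)
  expect_identical(od, od2)
  expect_error(simulate_elisa(strrep("A", 16), run$lib, run$sim$sheet,
                              run$sim$truth, run$cfg), "unknown peptide")
})
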