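# End-to-end orchestration: validate inputs, preprocess, call, write all
# result tables plus a run manifest under one output directory.

#' Pipeline configuration
#'
#' Bundles the input paths, thresholds and stage parameters of one
#' reproducible run. All paths are checked at run start; the effective
#' configuration is serialised verbatim into the run directory.
#'
#' @param proteome_fasta Proteome FASTA path.
#' @param intensity_tsv Raw intensity matrix TSV (probes or occurrences x
#'   samples).
#' @param sample_sheet_csv Sample sheet CSV.
#' @param output_dir Run directory (created if absent).
#' @param review_tsv Optional accession/reviewed TSV controlling tiling.
#' @param thresholds [heron_thresholds()].
#' @param half_window_aa,pseudocount,anchor,norm_groups Preprocessing
#'   options, see [preprocess_intensities()].
#' @param max_gap_aa,min_gain_frac,min_size Segmentation parameters.
#' @param var_floor Differential-test naive-sd floor.
#' @param cterm_anchor Tiling C-terminal anchor, see [tile_protein()].
#' @param seed Seed recorded in the manifest (the calling pipeline itself
#'   is deterministic).
#' @return A \code{PipelineConfig} list.
#' @export
pipeline_config <- function(proteome_fasta, intensity_tsv,
                            sample_sheet_csv, output_dir,
                            review_tsv = NULL,
                            thresholds = heron_thresholds(),
                            half_window_aa = 8L, pseudocount = 0,
                            anchor = "start", norm_groups = NULL,
                            max_gap_aa = NULL, min_gain_frac = 0.1,
                            min_size = 1L, var_floor = 0.01,
                            cterm_anchor = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Reads the proteome and raw intensities, validates them against each
#' other, preprocesses (log2, quantile normalisation, restore to
#' occurrences, positional smoothing), runs the hierarchical calling, and
#' writes probe/epitope/protein tables, a GFF3 of epitope regions on
#' protein coordinates, a concordance report when replicate chips are
#' present, and a JSON run manifest. A \code{FAILED} marker file is left
#' in the run directory if any stage errors out.
#'
#' @param config A [pipeline_config()].
#' @return The [heron_call()] result, invisibly; side effect: files under
#'   \code{config$output_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$proteome_fasta, config$intensity_tsv,
              config$sample_sheet_csv, config$review_tsv))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$output_dir, "FAILED")
  file.create(marker)

  proteome <- read_proteome(config$proteome_fasta, config$review_tsv)
  library <- build_probe_library(proteome, cterm_anchor = config$cterm_anchor)
  raw <- read_intensity_matrix(config$intensity_tsv)
  sheet <- read_sample_sheet(config$sample_sheet_csv)

  missing_cols <- setdiff(colnames(raw), sheet$sample_id)
  if (length(missing_cols))
    stop("sample sheet missing matrix column(s): ",
         paste(missing_cols, collapse = ", "))
  by_occ <- all(rownames(raw) %in% library$occurrences$occ_id)
  by_pep <- all(rownames(raw) %in% library$probes$probe_seq)
  if (!by_occ && !by_pep)
    stop("matrix rows are neither library occurrences nor unique peptides")

  smoothed <- preprocess_intensities(raw, library,
                                     half_window_aa = config$half_window_aa,
                                     pseudocount = config$pseudocount,
                                     norm_groups = config$norm_groups,
                                     anchor = config$anchor)
  res <- heron_call(smoothed, library, sheet, proteome,
                    thresholds = config$thresholds,
                    var_floor = config$var_floor,
                    max_gap_aa = config$max_gap_aa,
                    min_gain_frac = config$min_gain_frac,
                    min_size = config$min_size)
  write_heron_result(res, config$output_dir)

  rep_groups <- unique(stats::na.omit(sheet$replicate_group))
  if (length(rep_groups)) {
    conc <- list()
    for (g in rep_groups) {
      chips <- sheet$sample_id[!is.na(sheet$replicate_group) &
                                 sheet$replicate_group == g]
      if (length(chips) >= 2L)
        conc[[g]] <- data.frame(replicate_group = g,
                                concordance_report(res, chips[1], chips[2]))
    }
    if (length(conc))
      utils::write.table(do.call(rbind, conc),
                         file.path(config$output_dir, "concordance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("episcope")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[!vapply(config, is.function, logical(1))],
    inputs = list(
      proteome_fasta = unname(tools::md5sum(config$proteome_fasta)),
      intensity_tsv = unname(tools::md5sum(config$intensity_tsv)),
      sample_sheet_csv = unname(tools::md5sum(config$sample_sheet_csv))),
    n_probes = nrow(library$probes),
    n_occurrences = nrow(library$occurrences),
    n_epitopes = nrow(res$epitopes),
    n_proteins_called = sum(res$proteins$K > 0))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
  file.remove(marker)
  invisible(res)
}

#' Write the tables of a calling result
#'
#' Emits probe_calls.tsv (per-occurrence q/call/tier per immune chip),
#' epitopes.tsv, proteins.tsv and epitopes.gff3 under \code{dir}.
#'
#' @param result A \code{heron_result}.
#' @param dir Output directory.
#' @export
write_heron_result <- function(result, dir) {
  stopifnot(inherits(result, "heron_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chips <- colnames(result$probe$called)

  wide <- function(mats, ids) {
    df <- data.frame(id = ids, row.names = NULL)
    for (nm in names(mats))
      for (ch in chips)
        df[[paste0(nm, ".", ch)]] <- mats[[nm]][, ch]
    df
  }
  pc <- wide(list(q = result$probe$q, called = result$probe$called,
                  tier = result$probe$tier),
             rownames(result$probe$q))
  names(pc)[1] <- "occ_id"
  utils::write.table(pc, file.path(dir, "probe_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ep <- result$epitopes
  ep$members <- vapply(ep$members, paste, character(1), collapse = ";")
  if (nrow(ep)) {
    epw <- wide(list(p = result$epitope_p, q = result$epitope_q,
                     called = result$epitope_called,
                     tier = result$epitope_tier), ep$region_id)
    ep <- cbind(ep, epw[, -1, drop = FALSE])
  }
  utils::write.table(ep, file.path(dir, "epitopes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pr <- result$proteins
  if (nrow(pr)) {
    prw <- wide(list(p = result$protein_p, q = result$protein_q,
                     called = result$protein_called,
                     tier = result$protein_tier), pr$accession)
    pr <- cbind(pr, prw[, -1, drop = FALSE])
  }
  utils::write.table(pr, file.path(dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_epitope_gff3(result$epitopes, file.path(dir, "epitopes.gff3"))
  invisible(dir)
}

#' Write all simulator outputs to disk
#'
#' FASTA, probe-library TSV, raw intensity TSV, sample-sheet CSV and the
#' truth manifest JSON for one simulated dataset.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return list of written paths plus the in-memory objects, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proteome <- simulate_proteome(config)
  library <- build_probe_library(proteome)
  sim <- simulate_intensities(library, config)
  paths <- list(
    proteome = file.path(dir, "proteome.fasta"),
    library = file.path(dir, "probe_library.tsv"),
    intensities = file.path(dir, "intensities.tsv"),
    sheet = file.path(dir, "sample_sheet.csv"),
    truth = file.path(dir, "truth_manifest.json"))
  write_proteome_fasta(proteome, paths$proteome)
  write_probe_library(library, paths$library)
  write_intensity_matrix(sim$intensities, paths$intensities)
  write_sample_sheet(sim$sheet, paths$sheet)
  jsonlite::write_json(
    list(regions = sim$truth$regions,
         naive_hits = sim$truth$naive_hits,
         n_immune = sim$truth$n_immune),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(paths = paths, proteome = proteome, library = library,
                 sim = sim))
}
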