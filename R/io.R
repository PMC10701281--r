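# Table and sequence I/O. All text formats: TSV/CSV with a header row,
# '#'-prefixed comment lines, UTF-8; FASTA wrapped at 60; GFF3 1-based
# inclusive. Paths ending in .gz are read/written through a gzip
# connection transparently.

.open_out <- function(path) if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")

#' Read a proteome FASTA (plus optional review-status table)
#'
#' @param fasta Path to an amino-acid FASTA file; the first whitespace
#'   token of each header is taken as the accession.
#' @param review_tsv Optional TSV with columns \code{accession} and
#'   \code{reviewed} (true/false). Accessions absent from the table
#'   default to reviewed (denser step-2 tiling).
#' @return data.frame(accession, sequence, reviewed).
#' @export
read_proteome <- function(fasta, review_tsv = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  prot <- data.frame(accession = acc,
                     sequence = as.character(aa),
                     reviewed = TRUE, row.names = NULL)
  if (!is.null(review_tsv)) {
    rv <- utils::read.delim(review_tsv, comment.char = "#",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("accession", "reviewed") %in% names(rv)))
    idx <- match(prot$accession, rv$accession)
    hit <- !is.na(idx)
    prot$reviewed[hit] <- as.logical(rv$reviewed[idx[hit]])
    prot$reviewed[is.na(prot$reviewed)] <- TRUE
  }
  prot
}

#' Write a proteome to FASTA (60-column wrap)
#' @param proteome data.frame(accession, sequence).
#' @param path Output path (.gz allowed).
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- proteome$accession
  Biostrings::writeXStringSet(aa, path, width = 60L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a probe library to TSV
#'
#' One row per unique peptide: sequence, occurrence count, semicolon-joined
#' \code{accession:start} placements, and a flag column for nonstandard
#' residues.
#' @param library A \code{ProbeLibrary}.
#' @param path Output path (.gz allowed).
#' @export
write_probe_library <- function(library, path) {
  stopifnot(inherits(library, "ProbeLibrary"))
  occ_join <- vapply(
    split(library$occurrences$occ_id, library$occurrences$probe_seq),
    paste, character(1), collapse = ";")
  df <- library$probes
  df$occurrences <- unname(occ_join[df$probe_seq])
  df$flags <- ifelse(df$nonstandard, "nonstandard", "")
  df$nonstandard <- NULL
  con <- .open_out(path)
  on.exit(close(con))
  writeLines(paste0("#probe_length=", library$probe_length, "\t#steps=",
                    paste(names(library$tiling_steps), library$tiling_steps,
                          sep = ":", collapse = ";")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe library TSV written by [write_probe_library()]
#' @param path Input path.
#' @return A \code{ProbeLibrary}.
#' @export
read_probe_library <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#probe_length="))
    stop("not a probe-library file (missing #probe_length= header): ", path)
  meta <- strsplit(hdr, "\t")[[1]]
  plen <- as.integer(sub("#probe_length=", "", meta[1]))
  step_str <- strsplit(sub("#steps=", "", meta[2]), ";")[[1]]
  kv <- strsplit(step_str, ":")
  steps <- stats::setNames(as.integer(vapply(kv, `[`, character(1), 2L)),
                           vapply(kv, `[`, character(1), 1L))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  occ_lists <- strsplit(df$occurrences, ";", fixed = TRUE)
  occ <- data.frame(
    occ_id = unlist(occ_lists),
    probe_seq = rep(df$probe_seq, lengths(occ_lists)))
  pos <- regexpr(":[0-9]+$", occ$occ_id)
  occ$accession <- substr(occ$occ_id, 1L, pos - 1L)
  occ$start <- as.integer(substring(occ$occ_id, pos + 1L))
  occ <- occ[order(occ$accession, occ$start),
             c("occ_id", "accession", "start", "probe_seq")]
  row.names(occ) <- NULL
  probes <- data.frame(probe_seq = df$probe_seq,
                       n_occurrences = df$n_occurrences,
                       nonstandard = !is.na(df$flags) &
                         df$flags == "nonstandard")
  probes <- probes[order(probes$probe_seq), ]
  row.names(probes) <- NULL
  structure(list(probes = probes, occurrences = occ, tiling_steps = steps,
                 probe_length = plen), class = "ProbeLibrary")
}

#' Write an intensity matrix to TSV with a stage header
#'
#' The first line records the processing stage
#' (\code{#stage=raw|log2|quantile|smoothed}); rows are probes or
#' occurrences, columns samples.
#' @param m Numeric matrix with row and column names.
#' @param path Output path (.gz allowed).
#' @export
write_intensity_matrix <- function(m, path) {
  con <- .open_out(path)
  on.exit(close(con))
  writeLines(paste0("#stage=", attr(m, "stage") %||% "raw"), con)
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity matrix TSV
#' @param path Input path.
#' @return Matrix with a \code{stage} attribute (defaults to "raw" when the
#'   header line is absent).
#' @export
read_intensity_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- if (startsWith(first, "#stage=")) sub("#stage=", "", first) else "raw"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "stage") <- stage
  m
}

#' Read / write a sample sheet
#'
#' CSV with columns sample_id, mouse_id, condition (naive/immune),
#' replicate_group (empty when the chip is unreplicated), batch.
#' @param path File path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  req <- c("sample_id", "mouse_id", "condition")
  if (!all(req %in% names(ss)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(ss$sample_id))
    stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(ss$condition), c("naive", "immune"))
  if (length(bad)) stop("unknown condition value(s): ",
                        paste(bad, collapse = ", "))
  if (!"replicate_group" %in% names(ss)) ss$replicate_group <- NA_character_
  if (!"batch" %in% names(ss)) ss$batch <- NA_character_
  ss
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Export epitope regions as GFF3 on protein coordinates
#'
#' Coordinates are 1-based inclusive; seqid is the protein accession.
#' @param epitopes Epitope table as returned in a [heron_call()] result.
#' @param path Output path.
#' @export
write_epitope_gff3 <- function(epitopes, path) {
  con <- .open_out(path)
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(epitopes)) {
    attrs <- paste0("ID=", epitopes$region_id,
                    ";consensus=", epitopes$consensus_seq,
                    ";K=", epitopes$K, ";N=", epitopes$N,
                    ";tier=", epitopes$tier)
    writeLines(paste(epitopes$accession, "episcope", "epitope",
                     epitopes$aa_start, epitopes$aa_end, ".", ".", ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
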