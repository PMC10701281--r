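#' Tile a protein into overlapping peptide probes
#'
#' Generates the ordered set of fixed-length windows used to represent a
#' protein on a high-density peptide array: probe starts at positions
#' 1, 1+step, 1+2*step, ... while a full window fits. If the last regular
#' window does not end exactly at the C-terminus, one extra probe anchored
#' at \code{len - length + 1} is appended so the terminal residues are
#' covered (disable with \code{cterm_anchor = FALSE} for strict arithmetic
#' tiling).
#'
#' @param sequence Amino-acid string.
#' @param step Tiling offset in residues; 2 for reviewed proteins, 4 for
#'   unreviewed ones.
#' @param probe_length Window length in residues (default 16).
#' @param cterm_anchor Append a C-terminus-anchored probe when the regular
#'   grid stops short (default TRUE).
#' @return data.frame with columns \code{start} (1-based) and
#'   \code{probe_seq}; zero rows (with a warning) when the protein is
#'   shorter than \code{probe_length}.
#' @examples
#' tile_protein(paste(rep("ACDEFGHIKL", 2), collapse = ""), step = 2)
#' @export
tile_protein <- function(sequence, step, probe_length = 16L,
                         cterm_anchor = TRUE) {
  if (!step %in% c(2L, 4L))
    stop("`step` must be 2 or 4, got ", step)
  if (probe_length < 1L) stop("`probe_length` must be >= 1")
  len <- nchar(sequence)
  if (len < probe_length) {
    warning("protein of length ", len, " is shorter than the probe length (",
            probe_length, "); skipped", call. = FALSE)
    return(data.frame(start = integer(), probe_seq = character()))
  }
  last <- len - probe_length + 1L
  starts <- seq.int(1L, last, by = step)
  if (cterm_anchor && starts[length(starts)] != last)
    starts <- c(starts, last)
  data.frame(start = as.integer(starts),
             probe_seq = substring(sequence, starts,
                                   starts + probe_length - 1L))
}

#' Build a deduplicated probe library from a proteome
#'
#' Tiles every protein (step 2 for reviewed, 4 for unreviewed entries),
#' deduplicates identical peptides so each unique sequence is represented
#' once, and keeps the full map from each unique peptide back to every
#' (protein, start) placement. Probes containing residues outside the 20
#' canonical amino acids (X, U, B, Z, ...) are retained but flagged.
#'
#' @param proteome data.frame with columns \code{accession},
#'   \code{sequence} and optionally \code{reviewed} (logical; missing or NA
#'   entries default to reviewed, i.e. dense step-2 tiling).
#' @param probe_length Probe length (default 16).
#' @param cterm_anchor See [tile_protein()].
#' @return A \code{ProbeLibrary}: list with \code{probes} (one row per
#'   unique peptide: \code{probe_seq}, \code{n_occurrences},
#'   \code{nonstandard}), \code{occurrences} (one row per placement:
#'   \code{occ_id} = "accession:start", \code{accession}, \code{start},
#'   \code{probe_seq}, ordered by accession then start),
#'   \code{tiling_steps} (named integer vector) and \code{probe_length}.
#' @export
build_probe_library <- function(proteome, probe_length = 16L,
                                cterm_anchor = TRUE) {
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  if (nrow(proteome) == 0L) stop("empty proteome")
  if (anyDuplicated(proteome$accession))
    stop("duplicate accession(s): ",
         paste(unique(proteome$accession[duplicated(proteome$accession)]),
               collapse = ", "))
  reviewed <- if ("reviewed" %in% names(proteome)) proteome$reviewed
              else rep(TRUE, nrow(proteome))
  reviewed[is.na(reviewed)] <- TRUE
  steps <- ifelse(reviewed, 2L, 4L)
  names(steps) <- proteome$accession

  tiles <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    tl <- suppressWarnings(
      tile_protein(proteome$sequence[i], steps[i], probe_length, cterm_anchor))
    if (nrow(tl))
      tiles[[i]] <- data.frame(accession = proteome$accession[i], tl)
  }
  occ <- do.call(rbind, tiles)
  if (is.null(occ) || nrow(occ) == 0L)
    stop("no protein of length >= ", probe_length, " in the proteome")
  occ <- occ[order(occ$accession, occ$start), , drop = FALSE]
  occ <- data.frame(occ_id = paste0(occ$accession, ":", occ$start), occ,
                    row.names = NULL)

  tab <- table(occ$probe_seq)
  seqs <- names(tab)
  probes <- data.frame(
    probe_seq = seqs,
    n_occurrences = as.integer(tab),
    nonstandard = grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs),
    row.names = NULL)

  structure(list(probes = probes, occurrences = occ,
                 tiling_steps = steps, probe_length = as.integer(probe_length)),
            class = "ProbeLibrary")
}

#' @export
print.ProbeLibrary <- function(x, ...) {
  cat("ProbeLibrary:", nrow(x$probes), "unique peptides,",
      nrow(x$occurrences), "occurrences across",
      length(x$tiling_steps), "proteins\n")
  invisible(x)
}

#' Restore per-peptide values to every protein placement
#'
#' Identical peptides shared by several proteins are assayed once; this
#' broadcasts each unique peptide's value verbatim onto every
#' (protein, start) occurrence so positional (protein-coordinate)
#' operations can follow.
#'
#' @param values Named numeric vector keyed by \code{probe_seq}.
#' @param library A [build_probe_library()] result.
#' @return Named numeric vector keyed by \code{occ_id}, ordered as
#'   \code{library$occurrences}; length equals the total occurrences of the
#'   input probes.
#' @export
restore_redundant <- function(values, library) {
  stopifnot(inherits(library, "ProbeLibrary"))
  if (length(values) == 0L) return(stats::setNames(numeric(), character()))
  if (is.null(names(values))) stop("`values` must be named by probe_seq")
  unknown <- setdiff(names(values), library$probes$probe_seq)
  if (length(unknown))
    stop("unknown probe sequence(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  occ <- library$occurrences
  occ <- occ[occ$probe_seq %in% names(values), , drop = FALSE]
  stats::setNames(unname(values[occ$probe_seq]), occ$occ_id)
}

#' Restore a peptide-level matrix to occurrence level
#'
#' Matrix counterpart of [restore_redundant()]: rows keyed by unique
#' peptide become rows keyed by \code{occ_id}, duplicating shared peptides
#' into each protein context.
#'
#' @param m Numeric matrix with rownames in \code{library$probes$probe_seq}.
#' @param library A \code{ProbeLibrary}.
#' @return Matrix with one row per occurrence of the input probes; the
#'   \code{stage} attribute of \code{m} is carried over.
#' @export
restore_matrix <- function(m, library) {
  stopifnot(inherits(library, "ProbeLibrary"), is.matrix(m))
  unknown <- setdiff(rownames(m), library$probes$probe_seq)
  if (length(unknown))
    stop("unknown probe sequence(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  occ <- library$occurrences
  occ <- occ[occ$probe_seq %in% rownames(m), , drop = FALSE]
  out <- m[occ$probe_seq, , drop = FALSE]
  rownames(out) <- occ$occ_id
  attr(out, "stage") <- attr(m, "stage")
  out
}
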