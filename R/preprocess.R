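# Preprocessing: raw relative-fluorescence values are log2 transformed,
# quantile normalised across samples, then smoothed along each protein
# with a +/-8 aa sliding mean. Order is fixed; each step records its
# stage in the matrix's "stage" attribute.

.set_stage <- function(m, stage) { attr(m, "stage") <- stage; m }

#' Log2-transform an intensity matrix
#'
#' @param m Raw intensity matrix (values > 0 unless a pseudocount is
#'   given).
#' @param pseudocount Added to every value before the log when > 0;
#'   with the default 0, any nonpositive value is an error (the offending
#'   cells are listed).
#' @return Matrix on the log2 scale, stage \code{"log2"}.
#' @export
log2_transform <- function(m, pseudocount = 0) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (pseudocount > 0) m <- m + pseudocount
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive values (pseudocount disabled) at e.g. ",
         paste(utils::head(paste0(rownames(m)[bad[, 1]], " x ",
                                  colnames(m)[bad[, 2]]), 5),
               collapse = "; "))
  .set_stage(log2(m), "log2")
}

#' Quantile-normalise samples to a common distribution
#'
#' Every column is mapped onto the vector of cross-column rank means so
#' all samples share one empirical distribution; within-column rank order
#' is preserved and ties receive the mean of the rank means they span.
#'
#' @param m Log2 intensity matrix with >= 2 sample columns (a single
#'   column is returned unchanged with a warning).
#' @return Matrix, stage \code{"quantile"}.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(.set_stage(m, "quantile"))
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  .set_stage(out, "quantile")
}

#' Sliding-mean smoothing along protein coordinates
#'
#' For each probe occurrence at start position s in a protein, replaces
#' the value by the mean over all of that protein's occurrences whose
#' anchor lies within \code{half_window_aa} residues of s (window
#' truncated at the protein ends; never crosses protein boundaries).
#' Rows must be occurrence-level (\code{accession:start}); run
#' [restore_matrix()] first on peptide-level data.
#'
#' @param m Occurrence-level matrix.
#' @param library The \code{ProbeLibrary} providing the positional index.
#' @param half_window_aa Half window in residues (default 8).
#' @param anchor Window anchor: probe \code{"start"} (default) or
#'   \code{"mid"}point.
#' @return Smoothed matrix, stage \code{"smoothed"}.
#' @export
sliding_mean_smooth <- function(m, library, half_window_aa = 8L,
                                anchor = c("start", "mid")) {
  stopifnot(is.matrix(m), inherits(library, "ProbeLibrary"))
  anchor <- match.arg(anchor)
  occ <- library$occurrences
  if (!all(rownames(m) %in% occ$occ_id))
    stop("matrix rows are not occurrence IDs (accession:start); ",
         "restore peptide-level values to occurrences first ",
         "(see restore_matrix)")
  idx <- match(rownames(m), occ$occ_id)
  pos <- occ$start[idx]
  if (anchor == "mid") pos <- pos + (library$probe_length - 1) / 2
  acc <- occ$accession[idx]
  out <- m
  for (rows in split(seq_len(nrow(m)), acc)) {
    p <- pos[rows]
    o <- order(p)
    rows <- rows[o]; p <- p[o]
    n <- length(rows)
    if (n == 1L) next
    cs <- rbind(0, apply(m[rows, , drop = FALSE], 2L, cumsum))
    lo <- findInterval(p - half_window_aa - 0.5, p) + 1L
    hi <- findInterval(p + half_window_aa + 0.5, p)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  .set_stage(out, "smoothed")
}

#' Run the full preprocessing chain
#'
#' log2 -> quantile normalisation -> positional smoothing, with
#' peptide-level rows restored to protein occurrences before smoothing.
#'
#' @inheritParams sliding_mean_smooth
#' @inheritParams log2_transform
#' @param norm_groups Optional factor over columns: quantile-normalise
#'   within each group separately (default: all samples jointly).
#' @return Smoothed occurrence-level matrix.
#' @export
preprocess_intensities <- function(m, library, half_window_aa = 8L,
                                   pseudocount = 0, norm_groups = NULL,
                                   anchor = "start") {
  m <- log2_transform(m, pseudocount)
  if (is.null(norm_groups)) {
    m <- quantile_normalize(m)
  } else {
    stopifnot(length(norm_groups) == ncol(m))
    for (g in split(seq_len(ncol(m)), norm_groups))
      m[, g] <- quantile_normalize(m[, g, drop = FALSE])
    m <- .set_stage(m, "quantile")
  }
  if (!all(rownames(m) %in% library$occurrences$occ_id))
    m <- restore_matrix(m, library)
  sliding_mean_smooth(m, library, half_window_aa, anchor)
}
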