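# Orthogonal-validation statistics: enrichment probabilities for
# re-testing array-selected peptides in an independent cohort, the
# two-proportion comparison of ELISA positivity rates, variance-component
# ICC across assay platforms, simple r-squared, and the ELISA positivity
# and validation calling rules.

#' Upper-tail hypergeometric probability
#'
#' Probability of at least \code{x} positives among \code{n} draws
#' without replacement from a pool of \code{N} peptides of which \code{K}
#' are positive.
#'
#' @param x Minimum number of successes.
#' @param n Number of draws.
#' @param K Positives in the pool.
#' @param N Pool size.
#' @return P(X >= x).
#' @export
prob_at_least_hypergeom <- function(x, n, K, N) {
  if (x > n) stop("x exceeds the number of draws")
  if (K > N) stop("K exceeds the pool size")
  if (n > N) stop("more draws than pool members")
  if (x <= 0) return(1)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Upper-tail binomial probability
#'
#' Sampling-with-replacement counterpart of
#' [prob_at_least_hypergeom()]: P(X >= x) for X ~ Binomial(n, p).
#'
#' @param x Minimum number of successes.
#' @param n Number of draws.
#' @param p Per-draw success probability.
#' @return P(X >= x).
#' @export
prob_at_least_binomial <- function(x, n, p) {
  stopifnot(p >= 0, p <= 1)
  if (x <= 0) return(1)
  stats::pbinom(x - 1, n, p, lower.tail = FALSE)
}

#' Enrichment probability sweep over assumed positive fractions
#'
#' The true fraction of antibody-reactive peptides in the pool is
#' unknown; this sweeps assumed fractions, setting K = round(fraction*N),
#' and reports both the hypergeometric and the binomial tail probability
#' of observing at least \code{x} validated peptides in \code{n} draws.
#'
#' @param fractions Assumed positive fractions, each in (0, 1).
#' @param x Minimum successes.
#' @param n Draws.
#' @param N Pool size.
#' @return data.frame(fraction, K, p_hypergeom, p_binomial).
#' @export
fraction_sweep <- function(fractions, x, n, N) {
  stopifnot(all(fractions > 0 & fractions < 1))
  K <- round(fractions * N)
  data.frame(
    fraction = fractions, K = K,
    p_hypergeom = vapply(K, function(k)
      prob_at_least_hypergeom(x, n, k, N), numeric(1)),
    p_binomial = vapply(K, function(k)
      prob_at_least_binomial(x, n, k / N), numeric(1)))
}

#' Two-proportion z-test
#'
#' Pooled-variance score test comparing k1/n1 with k2/n2:
#' z = (p2 - p1) / sqrt(phat (1 - phat) (1/n1 + 1/n2)), two-sided normal
#' p-value; optional Yates-style continuity correction.
#'
#' @param k1,n1 Successes and size of group 1.
#' @param k2,n2 Successes and size of group 2.
#' @param correct Apply a continuity correction (default FALSE).
#' @return list(z, p_value, estimate = c(p1, p2)).
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  phat <- (k1 + k2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  d <- p2 - p1
  if (correct) d <- sign(d) * max(0, abs(d) - (1 / n1 + 1 / n2) / 2)
  z <- if (se == 0) 0 else d / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), estimate = c(p1, p2))
}

.icc_bands <- c(poor = 0, moderate = 0.5, good = 0.75, excellent = 0.9)

#' Reliability band of an ICC value
#'
#' poor [0, 0.5), moderate [0.5, 0.75), good [0.75, 0.9),
#' excellent [0.9, 1].
#' @param icc ICC in [0, 1].
#' @return Band label.
#' @export
icc_band <- function(icc) {
  stopifnot(icc >= 0, icc <= 1)
  names(.icc_bands)[findInterval(icc, .icc_bands)]
}

#' ICC from a variance-components mixed model
#'
#' Fits a linear mixed model with random intercepts for the listed
#' grouping factors (and any fixed covariates) to log-transformed
#' readings, and reports the share of total variance attributable to the
#' target component: ICC = sigma2_target / (sum of all random-intercept
#' variances + residual). Negative variance estimates are truncated at 0
#' by the fitter.
#'
#' @param data Long-format data.frame.
#' @param value Column of (log-transformed) readings.
#' @param target Random-effect column whose variance share is reported
#'   (e.g. the instrument).
#' @param random Character vector of random-intercept grouping columns
#'   (must include \code{target}).
#' @param fixed Character vector of fixed-effect columns (optional).
#' @return list(icc, band, components) where components is a named vector
#'   of variance estimates including "residual".
#' @export
icc_from_variance_components <- function(data, value, target,
                                         random = c(target, "sample"),
                                         fixed = character()) {
  stopifnot(target %in% random, value %in% names(data),
            all(c(random, fixed) %in% names(data)))
  for (g in random)
    if (length(unique(data[[g]])) < 2L)
      stop("random-effect grouping `", g, "` needs >= 2 levels")
  rhs <- c(if (length(fixed)) fixed else "1",
           paste0("(1|", random, ")"))
  fml <- stats::as.formula(paste(value, "~", paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(fml, data = data,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                          vc$grp))
  icc <- unname(comp[target] / sum(comp))
  list(icc = icc, band = icc_band(icc), components = comp)
}

#' Squared Pearson correlation of a simple linear regression
#'
#' @param x,y Numeric vectors (>= 3 points; x must vary).
#' @return r-squared.
#' @export
simple_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("zero variance in x")
  stats::cor(x, y)^2
}

#' Call ELISA positives and validated peptides
#'
#' Replicate wells are averaged per serum first; a serum is positive for
#' a peptide when its averaged OD is at or above the threshold (default
#' 2.0, inclusive); a peptide is validated within a sample group when the
#' positive fraction reaches \code{validation_fraction} (default 25%).
#'
#' @param od OD matrix, peptides x wells.
#' @param serum_of_well Character vector mapping each column to its serum
#'   (replicate wells share a serum ID); defaults to one well per serum.
#' @param group_of_serum Named character vector mapping serum to sample
#'   group (e.g. immune/naive); defaults to one group.
#' @param threshold Positivity threshold in OD units (> 0).
#' @param validation_fraction Fraction of group sera that must be
#'   positive.
#' @return list(positive = peptide x serum logical matrix,
#'   validation = data.frame(peptide, group, n_positive, n_sera, fraction,
#'   validated)).
#' @export
elisa_call_positives <- function(od, serum_of_well = colnames(od),
                                 group_of_serum = NULL, threshold = 2,
                                 validation_fraction = 0.25) {
  if (threshold <= 0) stop("positivity threshold must be > 0")
  stopifnot(is.matrix(od), all(od >= 0), ncol(od) == length(serum_of_well))
  sera <- unique(serum_of_well)
  avg <- vapply(sera, function(s)
    rowMeans(od[, serum_of_well == s, drop = FALSE]), numeric(nrow(od)))
  if (nrow(od) == 1L) avg <- matrix(avg, 1L, dimnames = list(rownames(od),
                                                             sera))
  positive <- avg >= threshold
  if (is.null(group_of_serum))
    group_of_serum <- stats::setNames(rep("all", length(sera)), sera)
  out <- list()
  for (g in unique(group_of_serum)) {
    cols <- sera[group_of_serum[sera] == g]
    np <- rowSums(positive[, cols, drop = FALSE])
    frac <- np / length(cols)
    out[[length(out) + 1L]] <- data.frame(
      peptide = rownames(od) %||% seq_len(nrow(od)), group = g,
      n_positive = as.integer(np), n_sera = length(cols),
      fraction = frac, validated = frac >= validation_fraction,
      row.names = NULL)
  }
  list(positive = positive, validation = do.call(rbind, out))
}
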