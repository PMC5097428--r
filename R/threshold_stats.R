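# Threshold-comparability statistics: how many standard deviations the 2-D
# and 3-D neighboring thresholds sit above random-pair similarity scores,
# the one-sided normal tail probabilities this implies, and their ratio.
#
# The random-pair similarity moments (0.42 +/- 0.13 for the 2-D fingerprint
# Tanimoto, 0.77 +/- 0.13 for the best ST-optimized ComboT over diverse
# conformer pairs) are taken as inputs; the 3-D "threshold" in this
# calculation is the implied ComboT floor 1.3. Probabilities are computed
# from the unrounded z-scores.

#' Random-pair similarity statistics
#'
#' @param mean_2d,sd_2d mean and standard deviation of the 2-D Tanimoto
#'   score for random compound pairs.
#' @param mean_3d,sd_3d mean and standard deviation of the best ComboT score
#'   for random compound pairs.
#' @return list of class `random_similarity_stats`.
#' @export
random_similarity_stats <- function(mean_2d = 0.42, sd_2d = 0.13,
                                    mean_3d = 0.77, sd_3d = 0.13) {
  if (sd_2d <= 0 || sd_3d <= 0) stop("standard deviations must be > 0")
  structure(list(mean_2d = mean_2d, sd_2d = sd_2d,
                 mean_3d = mean_3d, sd_3d = sd_3d),
            class = "random_similarity_stats")
}

#' Standardized distance of a threshold from a random-score mean
#'
#' @param threshold similarity threshold.
#' @param mean,sd random-pair score moments; `sd` must be positive.
#' @return (threshold - mean) / sd, unrounded.
#' @export
z_score <- function(threshold, mean, sd) {
  if (sd <= 0) stop("sd must be > 0")
  (threshold - mean) / sd
}

#' One-sided upper-tail standard-normal probability
#'
#' @param z finite z-score.
#' @return P(Z >= z) for standard normal Z.
#' @export
tail_probability <- function(z) {
  stopifnot(is.finite(z))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Ratio of two tail probabilities
#'
#' @param p_2d,p_3d tail probabilities; `p_3d` must be positive.
#' @return p_2d / p_3d.
#' @export
comparability_ratio <- function(p_2d, p_3d) {
  if (p_3d <= 0) stop("p_3d must be > 0")
  p_2d / p_3d
}

#' Full threshold-comparability calculation
#'
#' Computes the z-scores of the 2-D Tanimoto threshold and the 3-D ComboT
#' floor against random-pair score statistics, the implied one-sided normal
#' tail probabilities (from the unrounded z-scores), and their ratio.
#'
#' @param stats a `random_similarity_stats` object.
#' @param threshold_2d 2-D Tanimoto neighboring threshold (default 0.9).
#' @param threshold_3d ComboT floor implied by the 3-D thresholds
#'   (default 1.3).
#' @return list of class `threshold_comparison` with fields z_2d, z_3d,
#'   p_2d, p_3d (probabilities, not percentages) and ratio.
#' @export
threshold_comparison <- function(stats = random_similarity_stats(),
                                 threshold_2d = 0.9, threshold_3d = 1.3) {
  z2 <- z_score(threshold_2d, stats$mean_2d, stats$sd_2d)
  z3 <- z_score(threshold_3d, stats$mean_3d, stats$sd_3d)
  p2 <- tail_probability(z2)
  p3 <- tail_probability(z3)
  structure(list(z_2d = z2, z_3d = z3, p_2d = p2, p_3d = p3,
                 ratio = comparability_ratio(p2, p3)),
            class = "threshold_comparison")
}

#' @export
print.threshold_comparison <- function(x, ...) {
  cat("Threshold comparability\n")
  cat(sprintf("  2-D: z = %.1f, tail = %.3g%% (1 in %.0f)\n",
              x$z_2d, 100 * x$p_2d, 1 / x$p_2d))
  cat(sprintf("  3-D: z = %.1f, tail = %.3g%% (1 in %.0f)\n",
              x$z_3d, 100 * x$p_3d, 1 / x$p_3d))
  cat(sprintf("  ratio (2-D/3-D): %.2f\n", x$ratio))
  invisible(x)
}

#' Reference dataset sizes for the raw and parent-collapsed series
#'
#' The published population sizes of the five annotation-defined compound
#' sets in their raw (series A) and parent-collapsed, conformer-eligible
#' (series B) forms, with the B/A percentage recomputed from the counts.
#'
#' @return data frame with columns dataset, series_a, series_b, ratio_pct.
#' @export
reference_dataset_sizes <- function() {
  d <- data.frame(
    dataset = c("PubChem", "MeSH", "Protein3D", "PharmAct", "Drug"),
    series_a = c(36017715L, 82446L, 22753L, 11415L, 1773L),
    series_b = c(31776025L, 62217L, 17387L, 6977L, 950L),
    stringsAsFactors = FALSE)
  d$ratio_pct <- 100 * d$series_b / d$series_a
  d
}
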