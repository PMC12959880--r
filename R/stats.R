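#' Differential gain/loss classification of per-region counts
#'
#' Classifies each region (e.g. TSS +/- 500 bp windows) as `gain`, `loss`
#' or `nc` between two conditions. The normalised fold change is
#' `(counts_dayN * norm_factors[2]) / (counts_day0 * norm_factors[1])`;
#' significance is a two-sided exact binomial test of the day-N share of
#' the region's total against the null proportion implied by the
#' normalisation factors, BH-adjusted across regions. `gain` requires fold
#' change >= `fc_threshold` and adjusted p <= `alpha`; `loss` is the
#' symmetric condition (fold change <= 1/threshold). Regions with zero
#' counts in both conditions are `nc`.
#'
#' @param counts_day0,counts_dayN non-negative integer counts per region.
#' @param norm_factors length-2 multipliers taking raw counts to the
#'   common scale (e.g. inverse relative sequencing depths).
#' @param fc_threshold minimum normalised fold change.
#' @param alpha BH-adjusted significance level.
#' @return data frame with `fold_change`, `p_value`, `p_adj`, `class`.
#' @export
differential_class <- function(counts_day0, counts_dayN,
                               norm_factors = c(1, 1), fc_threshold = 2,
                               alpha = 0.01) {
  stopifnot(length(counts_day0) == length(counts_dayN),
            length(norm_factors) == 2, all(norm_factors > 0))
  n0 <- counts_day0 * norm_factors[1]
  nN <- counts_dayN * norm_factors[2]
  fc <- nN / n0
  # null day-N share of the raw total under equal normalised signal
  p0 <- (1 / norm_factors[2]) / (1 / norm_factors[1] + 1 / norm_factors[2])
  total <- counts_day0 + counts_dayN
  p <- vapply(seq_along(total), function(i) {
    if (total[i] == 0) return(1)
    stats::binom.test(counts_dayN[i], total[i], p = p0,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  cls <- rep("nc", length(total))
  cls[!is.nan(fc) & fc >= fc_threshold & p_adj <= alpha] <- "gain"
  cls[!is.nan(fc) & fc <= 1 / fc_threshold & p_adj <= alpha] <- "loss"
  cls[total == 0] <- "nc"
  data.frame(fold_change = fc, p_value = p, p_adj = p_adj, class = cls,
             stringsAsFactors = FALSE)
}

#' Congruence enrichment of a 2x2 classification table
#'
#' For a 2x2 table (e.g. H3K115ac gain/loss x expression up/down), the
#' focal-cell enrichment is `log2(observed / expected)` with
#' `expected = row_total * col_total / N`, and significance is the
#' two-sided Fisher exact test of the table.
#'
#' @param a,b,c,d the table cells, row-wise: `a` is the focal cell
#'   (row 1 = e.g. gain, column 1 = e.g. up). A 2x2 matrix may be passed
#'   as `a`.
#' @return object of class `enrichment_result`: list with `log2_obs_exp`,
#'   `p_value`, `observed`, `expected`.
#' @examples
#' congruence_enrichment(30, 20, 30, 120)  # expected 15, log2 = 1
#' @export
congruence_enrichment <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(tab < 0) || sum(tab) == 0)
    stop("table cells must be non-negative with a positive total")
  N <- sum(tab)
  expected <- sum(tab[1, ]) * sum(tab[, 1]) / N
  if (expected == 0)
    stop("expected count is zero: enrichment undefined")
  p <- stats::fisher.test(tab)$p.value
  structure(list(log2_obs_exp = log2(tab[1, 1] / expected), p_value = p,
                 observed = tab[1, 1], expected = expected),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment: observed", x$observed, "expected",
      format(x$expected, digits = 4), "log2(obs/exp)",
      format(x$log2_obs_exp, digits = 4), "p",
      format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Per-fragment A/T fraction
#'
#' Counts A and T bases (either case) in the reference sequence under each
#' fragment, divided by the number of unambiguous (non-N) bases.
#' Fragments covering only ambiguous bases return `NaN`.
#'
#' @param fragments a [fragment_set()] on the reference chromosomes.
#' @param reference a named `Biostrings::DNAStringSet`.
#' @return numeric vector of A/T fractions per fragment.
#' @export
at_content <- function(fragments, reference) {
  out <- numeric(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    if (!ch %in% names(reference))
      stop("fragment chromosome not in reference: ", ch)
    sel <- which(fragments$chrom == ch)
    L <- length(reference[[ch]])
    if (any(fragments$start[sel] < 0 | fragments$end[sel] > L))
      stop("fragment extends beyond reference sequence on ", ch)
    v <- Biostrings::Views(reference[[ch]], start = fragments$start[sel] + 1,
                           end = fragments$end[sel])
    freq <- Biostrings::letterFrequency(v, c("A", "T", "C", "G"))
    informative <- rowSums(freq)
    out[sel] <- rowSums(freq[, c("A", "T"), drop = FALSE]) / informative
  }
  out
}

#' Compare two A/T-content distributions
#'
#' Two-sided Wilcoxon rank-sum test: exact enumeration when the combined
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param dist_a,dist_b numeric samples (each non-empty).
#' @return list with `statistic` (the rank-sum W for sample a) and
#'   `p_value`.
#' @export
compare_at <- function(dist_a, dist_b) {
  if (length(dist_a) == 0 || length(dist_b) == 0)
    stop("both samples must be non-empty")
  exact <- (length(dist_a) + length(dist_b)) <= 20 &&
    !any(duplicated(c(dist_a, dist_b)))
  wt <- suppressWarnings(stats::wilcox.test(dist_a, dist_b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Spike-in barcode recovery
#'
#' Percent of total input chromatin recovered per barcode:
#' `100 * chip / (input / input_fraction)`, where `input_fraction` is the
#' share of chromatin saved as input (default 10%).
#'
#' @param chip_counts named ChIP counts per barcode.
#' @param input_counts matching positive input counts.
#' @param input_fraction fraction of chromatin saved as input.
#' @return percent recovery per barcode.
#' @examples
#' barcode_recovery(5, 50, 0.10)  # 1 percent
#' @export
barcode_recovery <- function(chip_counts, input_counts,
                             input_fraction = 0.10) {
  stopifnot(length(chip_counts) == length(input_counts),
            input_fraction > 0, input_fraction <= 1)
  if (any(input_counts <= 0))
    stop("input counts must be positive")
  100 * chip_counts / (input_counts / input_fraction)
}
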