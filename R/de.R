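# Differential expression: TPM normalization, the Audic-Claverie exact test
# for a pair of count libraries, Bonferroni correction and regulation calls.

#' Normalize raw counts to transcripts per million
#'
#' `tpm = count / library clean-read total x 10^6`; any exact zero is then
#' replaced by 0.01 so fold-change ratios stay finite.
#'
#' @param counts miRNA x library matrix (or data.frame) of raw counts.
#' @param clean_totals named vector of per-library clean-read totals.
#' @param zero_sub substitution for zero TPM (0.01).
#' @return TPM matrix.
#' @export
normalize_tpm <- function(counts, clean_totals, zero_sub = 0.01) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("negative counts")
  if (any(clean_totals <= 0)) stopf("clean_totals must be positive")
  totals <- clean_totals[colnames(counts)]
  if (any(is.na(totals))) stopf("clean_totals missing for some libraries")
  tpm <- sweep(counts, 2L, totals, "/") * 1e6
  tpm[tpm == 0] <- zero_sub
  tpm
}

#' Low-expression filter
#'
#' A miRNA whose normalized expression is below `tpm_min` in all libraries
#' is ignored; retained iff max TPM across libraries >= `tpm_min`.
#'
#' @param tpm TPM matrix from [normalize_tpm()].
#' @param tpm_min retention threshold (1 TPM).
#' @return the retained rows.
#' @export
filter_low_expression <- function(tpm, tpm_min = 1) {
  tpm[apply(tpm, 1L, max) >= tpm_min, , drop = FALSE]
}

#' Audic-Claverie point probability
#'
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y!) (1 + N2/N1)^-(x+y+1)`:
#' the probability of observing `y` reads in a library of total size `N2`
#' given `x` reads in a library of size `N1`, computed in log space via
#' log-gamma so counts up to 10^7 are safe. For fixed `x`, `p(.|x)` is a
#' proper distribution over y (sums to 1).
#'
#' @param y treatment count(s) (vectorized).
#' @param x control count.
#' @param n1,n2 control and treatment library totals.
#' @return `p(y|x)`.
#' @export
ac_point_probability <- function(y, x, n1, n2) {
  if (any(c(x, y) < 0) || any(c(x, y) != round(c(x, y))))
    stopf("counts must be non-negative integers")
  if (n1 <= 0 || n2 <= 0) stopf("library totals must be positive")
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

#' Audic-Claverie exact test for one miRNA between two libraries
#'
#' Lower tail `C = sum_{y' <= y} p(y'|x)`, upper tail
#' `D = sum_{y' >= y} p(y'|x) = 1 - C + p(y|x)` (the observed point mass
#' belongs to both tails, so `C + D = 1 + p(y|x)`), and the two-sided
#' `p = min(1, 2 min(C, D))` -- doubling the smaller tail, the conventional
#' two-sided rule. Swapping `(x, N1)` with `(y, N2)` leaves p unchanged.
#'
#' @inheritParams ac_point_probability
#' @return list with `C`, `D`, `p_value` and the point probability `p_obs`.
#' @export
ac_test <- function(x, y, n1, n2) {
  p_obs <- ac_point_probability(y, x, n1, n2)
  # log-space cumulative sum in chunks (y can be large)
  r <- n2 / n1
  lsum <- -Inf
  step <- 1e6
  lo <- 0
  while (lo <= y) {
    hi <- min(y, lo + step - 1)
    yy <- lo:hi
    lp <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
      lgamma(yy + 1) - (x + yy + 1) * log1p(r)
    m <- max(lp, lsum)
    lsum <- m + log(sum(exp(lp - m)) + exp(lsum - m))
    lo <- hi + 1
  }
  C <- min(1, exp(lsum))
  D <- min(1, 1 - C + p_obs)
  list(C = C, D = D, p_value = min(1, 2 * min(C, D)), p_obs = p_obs)
}

#' Run the exact test across miRNAs for one treatment-vs-control comparison
#'
#' @param counts miRNA x library raw-count matrix (already filtered).
#' @param clean_totals named per-library clean totals (the test's N1/N2).
#' @param control,treatment library names.
#' @param zero_sub TPM zero substitution.
#' @return data.frame of per-miRNA test results: x, y, N1, N2, TPMs,
#'   log2 fold-change, C, D, p_value.
#' @export
ac_test_table <- function(counts, clean_totals, control, treatment,
                          zero_sub = 0.01) {
  counts <- as.matrix(counts)
  tpm <- normalize_tpm(counts[, c(control, treatment), drop = FALSE],
                       clean_totals[c(control, treatment)],
                       zero_sub = zero_sub)
  n1 <- clean_totals[[control]]; n2 <- clean_totals[[treatment]]
  res <- lapply(seq_len(nrow(counts)), function(i) {
    tst <- ac_test(counts[i, control], counts[i, treatment], n1, n2)
    data.frame(mirna = rownames(counts)[i],
               x = counts[i, control], y = counts[i, treatment],
               N1 = n1, N2 = n2,
               tpm_control = tpm[i, control], tpm_treatment = tpm[i, treatment],
               log2fc = log2(tpm[i, treatment] / tpm[i, control]),
               C = tst$C, D = tst$D, p_value = tst$p_value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify differential expression with Bonferroni control
#'
#' `p_corrected = min(1, m p)`; a miRNA is called up if
#' `p_corrected < alpha` and `log2fc >= fc_threshold`, down if
#' `p_corrected < alpha` and `log2fc <= -fc_threshold`, otherwise ns.
#' Also returns the volcano columns (`log2fc`, `-log10 p_corrected`).
#'
#' @param results output of [ac_test_table()].
#' @param m number of tests in the comparison (defaults to `nrow(results)`).
#' @param alpha significance threshold on the corrected p.
#' @param fc_threshold minimum |log2 fold-change|.
#' @return `results` with `p_corrected`, `neg_log10_p`, `regulation`.
#' @export
classify_de <- function(results, m = nrow(results), alpha = 0.05,
                        fc_threshold = 1) {
  if (m <= 0) stopf("m must be a positive number of tests")
  results$p_corrected <- pmin(1, m * results$p_value)
  results$neg_log10_p <- -log10(results$p_corrected)
  results$regulation <- ifelse(
    results$p_corrected < alpha & results$log2fc >= fc_threshold, "up",
    ifelse(results$p_corrected < alpha & results$log2fc <= -fc_threshold,
           "down", "ns"))
  results
}
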