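#' Bland-Altman agreement between paired HRV and PRV index values
#'
#' Differences are taken as `x = HRV - PRV` per segment; the bias is
#' `mean(x)` and the limits of agreement `mean(x) +/- 1.96 * SD(x)`.
#'
#' @param hrv_values per-segment index values from the ECG.
#' @param prv_values paired values from the PPG.
#' @param index_name,bp_state optional labels carried into the result.
#' @return an `agreement_result`: `index_name`, `bp_state`, `bias`,
#'   `loa_lower`, `loa_upper`, `bar`, `category`.
#' @export
bland_altman <- function(hrv_values, prv_values, index_name = NA_character_,
                         bp_state = NA_character_) {
  if (length(hrv_values) != length(prv_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(hrv_values) < 2) stop("need at least 2 pairs", call. = FALSE)
  x <- hrv_values - prv_values
  bias <- mean(x)
  s <- stats::sd(x)
  bar <- bar_ratio(hrv_values, prv_values)
  structure(list(index_name = index_name, bp_state = bp_state,
                 bias = bias,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 bar = bar,
                 category = classify_agreement(bar, bias = bias, sd_x = s)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement (%s, %s): bias %.4g, LoA [%.4g, %.4g], BAR %.3g%% (%s)\n",
              x$index_name, x$bp_state, x$bias, x$loa_lower, x$loa_upper,
              x$bar, x$category))
  invisible(x)
}

#' Ratio of agreement (BAR)
#'
#' `BAR = 100 * |1.96 * SD(HRV - PRV)| / |mean(HRV + PRV)|` in percent,
#' where the denominator is the grand mean of the per-segment sums.
#'
#' @inheritParams bland_altman
#' @return percentage, or `NA` when the denominator is zero.
#' @export
bar_ratio <- function(hrv_values, prv_values) {
  if (length(hrv_values) != length(prv_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  denom <- mean(hrv_values + prv_values)
  if (denom == 0) return(NA_real_)
  100 * abs(1.96 * stats::sd(hrv_values - prv_values)) / abs(denom)
}

#' Categorize a ratio of agreement
#'
#' Good when BAR <= 10 percent, moderate when 10 < BAR <= 20, insufficient
#' when BAR > 20. When the paired differences are identically zero in both
#' spread and bias the agreement is reported as `"total"` (the NN50/pNN50
#' situation, where both sources return exactly the same counts).
#'
#' @param bar ratio of agreement in percent.
#' @param bias,sd_x optional bias and SD of the differences, used only to
#'   recognize total agreement.
#' @return one of `"good"`, `"moderate"`, `"insufficient"`, `"total"`, or
#'   `NA` for a missing BAR.
#' @export
classify_agreement <- function(bar, bias = NA_real_, sd_x = NA_real_) {
  # zero bias with zero spread is total agreement even when BAR itself is
  # undefined (both sources identically zero, e.g. NN50 on a quiet series)
  if (!is.na(bias) && !is.na(sd_x) && bias == 0 && sd_x == 0) return("total")
  if (is.na(bar)) return(NA_character_)
  if (bar <= 10) "good" else if (bar <= 20) "moderate" else "insufficient"
}

#' Spearman correlation between HRV and PRV values
#'
#' Rank correlation with average ranks for ties and a two-sided p-value.
#'
#' @inheritParams bland_altman
#' @return list `rho`, `p`; both `NA` when either vector has zero variance.
#' @export
correlate_sources <- function(hrv_values, prv_values) {
  stopifnot(length(hrv_values) == length(prv_values), length(hrv_values) >= 3)
  if (stats::sd(hrv_values) == 0 || stats::sd(prv_values) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(hrv_values, prv_values,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Friedman test between the two measurement sources
#'
#' Two-treatment (HRV vs PRV) randomized-block layout with segments as
#' blocks, using the tie-corrected Friedman chi-square. When every block is
#' an exact tie the test carries no information and p = 1 is returned.
#'
#' @inheritParams bland_altman
#' @return list `statistic`, `p`.
#' @export
compare_sources <- function(hrv_values, prv_values) {
  stopifnot(length(hrv_values) == length(prv_values))
  if (length(hrv_values) < 6) stop("need at least 6 blocks", call. = FALSE)
  if (all(hrv_values == prv_values)) {
    return(list(statistic = 0, p = 1))
  }
  ft <- stats::friedman.test(cbind(HRV = hrv_values, PRV = prv_values))
  list(statistic = unname(ft$statistic), p = ft$p.value)
}

#' Kruskal-Wallis comparison of an index across blood pressure states
#'
#' Kruskal-Wallis over the (up to three) state groups; when significant at
#' `alpha`, unpaired pairwise Wilcoxon rank-sum tests with Bonferroni
#' correction (p multiplied by 3, clipped at 1). A pairwise comparison is
#' `NA` when either group has fewer than 2 values.
#'
#' @param values_by_state named list of numeric vectors, names from
#'   `c("hypotension", "normotension", "hypertension")`.
#' @param alpha significance level gating the post hoc tests (default 0.05).
#' @return a `state_comparison`: `kw_p` and `pairwise_p` (named vector:
#'   hypo-normo, hypo-hyper, normo-hyper; `NA` when not computed).
#' @export
compare_states <- function(values_by_state, alpha = 0.05) {
  groups <- values_by_state[lengths(values_by_state) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  kw <- stats::kruskal.test(groups)
  pairs <- list(c("hypotension", "normotension"),
                c("hypotension", "hypertension"),
                c("normotension", "hypertension"))
  pw <- stats::setNames(rep(NA_real_, 3),
                        c("hypo-normo", "hypo-hyper", "normo-hyper"))
  if (!is.na(kw$p.value) && kw$p.value < alpha) {
    for (k in seq_along(pairs)) {
      a <- values_by_state[[pairs[[k]][1]]]
      b <- values_by_state[[pairs[[k]][2]]]
      if (length(a) >= 2 && length(b) >= 2) {
        raw <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
        pw[k] <- min(1, 3 * raw)
      }
    }
  }
  structure(list(kw_p = kw$p.value, pairwise_p = pw),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("state_comparison: KW p = %.3g\n", x$kw_p))
  print(x$pairwise_p)
  invisible(x)
}

#' Lilliefors normality screen
#'
#' Kolmogorov-Smirnov test with estimated mean and SD, used to justify the
#' nonparametric test battery. A constant vector is reported as non-normal
#' with p = 0.
#'
#' @param values numeric vector, n >= 5.
#' @return list `p`, `normal` (logical at the 0.05 level).
#' @export
normality_screen <- function(values) {
  stopifnot(length(values) >= 5)
  if (stats::sd(values) == 0) return(list(p = 0, normal = FALSE))
  p <- nortest::lillie.test(values)$p.value
  list(p = p, normal = p >= 0.05)
}
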