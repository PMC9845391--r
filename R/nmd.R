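#' Allelic-imbalance deviation from altered-allele frequency
#'
#' In RNA-seq from a heterozygous truncating-variant carrier, efficient
#' nonsense-mediated decay depletes the altered allele below the balanced
#' 0.5. AI deviation is `0.5 - altered_af`, clamped at zero when sampling
#' noise pushes the altered allele above 0.5: 0 means no detectable decay,
#' 0.5 complete decay of the altered allele.
#'
#' @param altered_af altered-allele frequency in \[0, 1\] (vectorized).
#' @return AI deviation in \[0, 0.5\].
#' @examples
#' ai_deviation(c(0.5, 0.62, 0.25))
#' @export
ai_deviation <- function(altered_af) {
  if (anyNA(altered_af) || any(altered_af < 0 | altered_af > 1)) {
    stop("altered allele frequency must lie in [0, 1]")
  }
  pmax(0, 0.5 - altered_af)
}

#' Compare AI deviation between two variant groups
#'
#' Group medians plus a two-sided Mann-Whitney U p-value (exact at small
#' samples, tie-corrected normal approximation otherwise; see
#' [mann_whitney()]). AI deviations are bounded and typically skewed toward
#' zero, so the comparison is rank-based by design rather than
#' normality-gated.
#'
#' @param group_a,group_b numeric vectors of AI deviations (nonempty).
#' @return list `median_a`, `median_b`, `n`, `p_value`, `method`.
#' @export
compare_ai_groups <- function(group_a, group_b) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("both groups must be nonempty")
  }
  if (any(c(group_a, group_b) < 0 | c(group_a, group_b) > 0.5)) {
    stop("AI deviations must lie in [0, 0.5]")
  }
  mw <- mann_whitney(group_a, group_b)
  list(median_a = stats::median(group_a),
       median_b = stats::median(group_b),
       n = c(length(group_a), length(group_b)),
       p_value = mw$p_value,
       method = mw$method)
}

#' Read per-variant expression measurements
#'
#' Accepts either layout studies publish: `variant_id  altered_af` (AI
#' deviation derived via [ai_deviation()]) or `variant_id  ai_deviation`
#' (deviation given directly, already clamped by the source).
#'
#' @param path TSV path with a header naming one of the two value columns.
#' @return data.frame `variant_id`, `altered_af` (NA when deviation was
#'   supplied directly), `ai_deviation`.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"variant_id" %in% names(tab)) {
    stop("expression table must have a 'variant_id' column")
  }
  if ("altered_af" %in% names(tab)) {
    tab$ai_deviation <- ai_deviation(tab$altered_af)
  } else if ("ai_deviation" %in% names(tab)) {
    if (any(tab$ai_deviation < 0 | tab$ai_deviation > 0.5, na.rm = TRUE)) {
      stop("ai_deviation values must lie in [0, 0.5]")
    }
    tab$altered_af <- NA_real_
  } else {
    stop("expression table needs an 'altered_af' or 'ai_deviation' column")
  }
  tab[c("variant_id", "altered_af", "ai_deviation")]
}

#' NMD-efficiency analysis of an annotated cohort with expression data
#'
#' Joins AI deviations onto annotated variants, then runs the standard
#' battery: exon-327 versus other-variant group comparison of AI deviation
#' ([compare_ai_groups()]) and the normality-gated correlation of
#' PTC-to-intron distance with AI deviation ([gated_correlation()]).
#' Variants without a defined distance (splice-class, final-exon PTCs) stay
#' in the group comparison but drop out of the distance correlation.
#'
#' @param annotated annotated variant table (NMD-stage filtered) with a
#'   `variant_id` column.
#' @param expression data.frame from [read_expression_table()] (or with the
#'   same columns).
#' @param alpha_gate Shapiro-Wilk gate level for the correlation; default
#'   0.05.
#' @return list `measurements` (joined per-variant table), `group_comparison`
#'   (exon 327 vs other), `distance_correlation`.
#' @export
nmd_analysis <- function(annotated, expression, alpha_gate = 0.05) {
  stopifnot("variant_id" %in% names(annotated),
            "variant_id" %in% names(expression))
  m <- match(annotated$variant_id, expression$variant_id)
  meas <- annotated
  meas$ai_deviation <- expression$ai_deviation[m]
  meas <- meas[!is.na(meas$ai_deviation), , drop = FALSE]
  in327 <- !is.na(meas$region) & meas$region == "Exon 327"
  grp <- if (any(in327) && any(!in327)) {
    compare_ai_groups(meas$ai_deviation[in327], meas$ai_deviation[!in327])
  } else {
    NULL
  }
  has_d <- !is.na(meas$ptc_to_intron_distance)
  corr <- if (sum(has_d) >= 3L) {
    gated_correlation(meas$ptc_to_intron_distance[has_d],
                      meas$ai_deviation[has_d], alpha_gate)
  } else {
    NULL
  }
  list(measurements = meas, group_comparison = grp,
       distance_correlation = corr)
}
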