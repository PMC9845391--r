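#' Clinical indicators compared between variant groups
#'
#' @return Character vector of the continuous phenotype columns understood
#'   by [phenotype_summary()]: diagnosis age (years), LVEF (%), fractional
#'   shortening (%), LVEDD (mm), NYHA class (ordinal, handled numerically),
#'   and age at the composite endpoint (heart transplantation, death, or
#'   ventricular assist device; years).
#' @export
phenotype_indicators <- function() {
  c("diagnosis_age", "lvef", "fractional_shortening", "lvedd",
    "nyha_class", "endpoint_age")
}

#' Read a phenotype table
#'
#' @param path TSV keyed by `variant_id` with a `group` column
#'   (`"Exon 327"` / `"Other"`), any of the [phenotype_indicators()]
#'   columns, and an optional logical/0-1 `family_history`. Missing values
#'   are empty cells.
#' @return data.frame with numeric indicator columns.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("variant_id", "group") %in% names(tab))) {
    stop("phenotype table needs 'variant_id' and 'group' columns")
  }
  for (col in intersect(phenotype_indicators(), names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  if ("family_history" %in% names(tab)) {
    tab$family_history <- as.logical(tab$family_history)
  }
  tab
}

#' Phenotype comparison battery between exon-327 and other carriers
#'
#' For each continuous indicator present: available-case count, per-group
#' median (Q1-Q3) summaries, and the normality-gated test
#' ([compare_continuous()]: t-test when both groups pass the Shapiro-Wilk
#' gate, Mann-Whitney otherwise). NYHA class is compared numerically.
#' `family_history` is summarized as yes/no counts per group and tested with
#' Fisher's exact test ([compare_categorical()]).
#'
#' @param records phenotype data.frame with a `group` column whose first
#'   level (alphabetically, or factor levels if a factor) is reported first;
#'   for the packaged workflow the groups are `"Exon 327"` and `"Other"`.
#' @param alpha_gate Shapiro-Wilk gate level; default 0.05.
#' @param welch passed to [compare_continuous()].
#' @return data.frame with one row per indicator: `indicator`, `n_available`,
#'   `summary_a`, `summary_b` (median (Q1-Q3), or yes-count for family
#'   history), `method`, `p_value`. Attribute `groups` names the two groups.
#' @export
phenotype_summary <- function(records, alpha_gate = 0.05, welch = FALSE) {
  stopifnot(is.data.frame(records), "group" %in% names(records))
  groups <- if (is.factor(records$group)) levels(records$group) else
    sort(unique(as.character(records$group)))
  if (length(groups) != 2L) stop("phenotype comparison needs exactly 2 groups")
  a <- records[records$group == groups[1L], , drop = FALSE]
  b <- records[records$group == groups[2L], , drop = FALSE]
  fmt <- function(med, q1, q3) {
    if (is.na(med)) return(NA_character_)
    sprintf("%s (%s-%s)", format(med, trim = TRUE), format(q1, trim = TRUE),
            format(q3, trim = TRUE))
  }
  rows <- list()
  for (ind in intersect(phenotype_indicators(), names(records))) {
    cc <- compare_continuous(a[[ind]], b[[ind]], alpha_gate, welch)
    rows[[ind]] <- data.frame(
      indicator = ind,
      n_available = sum(!is.na(records[[ind]])),
      summary_a = fmt(cc$median[1L], cc$q1[1L], cc$q3[1L]),
      summary_b = fmt(cc$median[2L], cc$q1[2L], cc$q3[2L]),
      method = cc$method,
      p_value = cc$p_value,
      stringsAsFactors = FALSE)
  }
  if ("family_history" %in% names(records)) {
    fh <- table(factor(records$group, levels = groups),
                factor(records$family_history, levels = c(TRUE, FALSE)))
    p <- if (any(rowSums(fh) == 0) || any(colSums(fh) == 0)) NA_real_ else
      compare_categorical(fh)$p_value
    rows[["family_history"]] <- data.frame(
      indicator = "family_history",
      n_available = sum(!is.na(records$family_history)),
      summary_a = sprintf("%d yes / %d no", fh[1L, 1L], fh[1L, 2L]),
      summary_b = sprintf("%d yes / %d no", fh[2L, 1L], fh[2L, 2L]),
      method = "Fisher's exact test",
      p_value = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}
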