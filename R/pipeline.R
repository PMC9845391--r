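#' Format a p-value in report style
#'
#' Three decimals without a leading zero; values below .001 print as
#' `"<.001"` (the convention of the published tables).
#'
#' @param p numeric vector of p-values.
#' @return character vector, e.g. `".533"`, `"<.001"`, `"1.000"`.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 0.001, "<.001",
                       sub("^0\\.", ".", sprintf("%.3f", p))))
  out
}

#' Format an estimate (degree, ratio) in report style
#'
#' Two decimals, leading zero dropped for values below 1 (`".38"`, `"1.37"`).
#'
#' @param x numeric vector.
#' @param digits decimal places; default 2.
#' @return character vector.
#' @export
format_estimate <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_,
         sub("^0\\.", ".", sprintf(paste0("%.", digits, "f"), x)))
}

#' Render the regional enrichment table for display
#'
#' @param tab output of [reproduce_enrichment_table()] (or a same-shaped
#'   table from simulated cohorts).
#' @return data.frame of formatted strings: lengths with percent share,
#'   expected counts to two decimals, degrees/ratios to two decimals,
#'   p-values per [format_pvalue()].
#' @export
render_enrichment_table <- function(tab) {
  data.frame(region = tab$region,
             coding_length = format(tab$coding_length, big.mark = ","),
             pct_length = sprintf("%.2f", tab$pct_length),
             observed_dcm = tab$observed_dcm,
             expected_dcm = sprintf("%.2f", tab$expected_dcm),
             degree_dcm = format_estimate(tab$degree_dcm),
             p_dcm = format_pvalue(tab$p_dcm),
             observed_gnomad = tab$observed_gnomad,
             expected_gnomad = sprintf("%.2f", tab$expected_gnomad),
             degree_gnomad = format_estimate(tab$degree_gnomad),
             p_gnomad = format_pvalue(tab$p_gnomad),
             ratio = format_estimate(tab$ratio),
             p_ratio = format_pvalue(tab$p_ratio),
             stringsAsFactors = FALSE)
}

#' Read a cohort variant table
#'
#' @param path TSV with header `study_id  cdna_hgvs  protein_hgvs` plus any
#'   further columns (`altered_af`, phenotype fields), empty cells as NA.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!"protein_hgvs" %in% names(tab)) {
    stop("variant table must have a 'protein_hgvs' column")
  }
  if (!"variant_id" %in% names(tab)) {
    tab$variant_id <- sprintf("v%04d", seq_len(nrow(tab)))
  }
  tab
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the analysis pipeline end to end
#'
#' Annotate, filter, tally, enrich — plus the NMD and phenotype batteries
#' when their inputs are given — writing TSV and JSON reports and a run
#' manifest (input digests, configuration, per-stage record counts) to
#' `out_dir`. With `fixture = "table2"` the packaged reference inputs are
#' used and the published regional enrichment table is reproduced without
#' any variant-level input. Every excluded variant is logged to stderr with
#' its reason.
#'
#' @param variants variant table (data.frame or TSV path); ignored when
#'   `fixture = "table2"`.
#' @param exons exon table path or [transcript_model()]; defaults to the
#'   packaged synthetic TTN table.
#' @param partition partition path or [region_partition()]; defaults to
#'   [ttn_partition()].
#' @param fixture `"none"` (default) or `"table2"`.
#' @param psi_threshold PSI cut-off; default 0.9.
#' @param expression optional expression table (data.frame or TSV path) for
#'   the NMD stage.
#' @param phenotypes optional phenotype table (data.frame or TSV path).
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param distance_anchor passed to [annotate_variants()].
#' @return (invisibly) list with `annotated`, `excluded`, `enrichment`,
#'   `per_study`, `nmd`, `phenotype`, `manifest` (elements `NULL` for stages
#'   not run).
#' @export
run_pipeline <- function(variants = NULL, exons = NULL, partition = NULL,
                         fixture = c("none", "table2"),
                         psi_threshold = 0.9, expression = NULL,
                         phenotypes = NULL, out_dir = NULL,
                         distance_anchor = "first") {
  fixture <- match.arg(fixture)
  inputs <- character(0)
  model <- if (is.null(exons)) {
    inputs <- c(inputs, ttn_exon_fixture_path())
    ttn_model()
  } else if (inherits(exons, "transcript_model")) {
    exons
  } else {
    inputs <- c(inputs, exons)
    read_exon_table(exons)
  }
  part <- if (is.null(partition)) {
    ttn_partition()
  } else if (inherits(partition, "region_partition")) {
    partition
  } else {
    inputs <- c(inputs, partition)
    read_partition(partition)
  }
  rollups <- ttn_rollups()
  all_rollups <- all(unlist(rollups) %in% names(part))
  counts <- list()
  result <- list(annotated = NULL, excluded = NULL, enrichment = NULL,
                 per_study = NULL, nmd = NULL, phenotype = NULL)

  if (fixture == "table2") {
    result$enrichment <- reproduce_enrichment_table(psi_threshold)
    counts$regions <- nrow(result$enrichment)
  } else {
    if (!is.null(variants)) {
      if (is.character(variants)) {
        inputs <- c(inputs, variants)
        variants <- read_variant_table(variants)
      }
      ann <- annotate_variants(variants, model, part, psi_threshold,
                               distance_anchor)
      split <- apply_cohort_filters(ann, stage = "enrichment")
      if (nrow(split$excluded) > 0L) {
        for (i in seq_len(nrow(split$excluded))) {
          message("excluded ", split$excluded$variant_id[i], " [",
                  split$excluded$protein_hgvs[i], "]: ",
                  split$excluded$exclusion_reason[i])
        }
      }
      result$annotated <- split$retained
      result$excluded <- split$excluded
      counts$input <- nrow(variants)
      counts$retained <- nrow(split$retained)
      counts$excluded <- nrow(split$excluded)
      if (nrow(split$retained) > 0L) {
        high <- filter_high_psi(model, psi_threshold)
        lengths <- region_lengths(high, part,
                                  rollups = if (all_rollups) rollups else NULL)
        tal <- tally_by_region(split$retained, part,
                               rollups = if (all_rollups) rollups else NULL)
        result$enrichment <- enrichment_table(tal, lengths)
        if (length(unique(split$retained$study_id)) > 1L) {
          result$per_study <- per_study_enrichment(split$retained, lengths)
        }
      }
      nmd_split <- apply_cohort_filters(ann, stage = "nmd")
      if (!is.null(expression)) {
        if (is.character(expression)) {
          inputs <- c(inputs, expression)
          expression <- read_expression_table(expression)
        } else if (!"ai_deviation" %in% names(expression)) {
          expression$ai_deviation <- ai_deviation(expression$altered_af)
        }
        result$nmd <- nmd_analysis(nmd_split$retained, expression)
      }
      if (!is.null(phenotypes)) {
        if (is.character(phenotypes)) {
          inputs <- c(inputs, phenotypes)
          phenotypes <- read_phenotype_table(phenotypes)
        }
        result$phenotype <- phenotype_summary(phenotypes)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ttnenrich")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    fixture = fixture,
    psi_threshold = psi_threshold,
    distance_anchor = distance_anchor,
    inputs = lapply(unique(inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    record_counts = counts,
    outputs = character(0))
  result$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outs <- character(0)
    if (!is.null(result$annotated)) {
      outs <- c(outs, write_tsv(result$annotated,
                                file.path(out_dir, "annotated.tsv")))
      outs <- c(outs, write_tsv(result$excluded,
                                file.path(out_dir, "excluded.tsv")))
    }
    if (!is.null(result$enrichment)) {
      outs <- c(outs, write_tsv(result$enrichment,
                                file.path(out_dir, "enrichment.tsv")))
      if (fixture == "table2") {
        outs <- c(outs, write_tsv(render_enrichment_table(result$enrichment),
                                  file.path(out_dir, "enrichment_rendered.tsv")))
      }
      jsonlite::write_json(result$enrichment,
                           file.path(out_dir, "enrichment.json"),
                           dataframe = "rows", digits = NA)
      outs <- c(outs, file.path(out_dir, "enrichment.json"))
    }
    if (!is.null(result$per_study)) {
      outs <- c(outs, write_tsv(result$per_study,
                                file.path(out_dir, "per_study.tsv")))
    }
    if (!is.null(result$nmd)) {
      jsonlite::write_json(
        list(group_comparison = result$nmd$group_comparison,
             distance_correlation = result$nmd$distance_correlation),
        file.path(out_dir, "nmd.json"), auto_unbox = TRUE, digits = NA)
      outs <- c(outs, file.path(out_dir, "nmd.json"),
                write_tsv(result$nmd$measurements[
                  c("variant_id", "region", "ptc_to_intron_distance",
                    "ai_deviation")],
                  file.path(out_dir, "ai_deviation.tsv")))
    }
    if (!is.null(result$phenotype)) {
      outs <- c(outs, write_tsv(result$phenotype,
                                file.path(out_dir, "phenotype.tsv")))
    }
    manifest$outputs <- outs
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
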