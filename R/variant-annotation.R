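#' Parse an HGVS protein change into class, anchor residue and Ter extension
#'
#' Handles the truncating-variant grammar needed for PTC resolution:
#' nonsense substitutions (`p.Arg5Ter`, `p.Arg5*`) and frameshifts with a
#' stated stop extension (`p.Ser4228LeufsTer23`, `p.Ser4228Leufs*23`).
#' Frameshifts without the `TerK` extension (`p.Ser4228Leufs`) do not pin
#' down the premature termination codon and are classed `incomplete`;
#' splice-style descriptions (`p.?`) are classed `splice` and carry no
#' residue. Leading `p.` and enclosing parentheses are tolerated.
#'
#' @param protein_hgvs character vector of protein-level HGVS descriptions.
#' @param strict if `TRUE` (default), incomplete or unparseable descriptions
#'   raise classed errors (`ttnenrich_incomplete_description`,
#'   `ttnenrich_parse_error`); if `FALSE` they are returned as rows with
#'   `variant_class` `"incomplete"` / `"unparseable"` for bulk filtering.
#' @return data.frame with columns `protein_hgvs`, `variant_class`
#'   (`nonsense`, `frameshift`, `splice`, `incomplete`, `unparseable`),
#'   `anchor_residue`, `ter_extension` (NA where not applicable).
#' @examples
#' parse_protein_change("p.Ser4228LeufsTer23")
#' parse_protein_change("p.Arg5Ter")
#' @export
parse_protein_change <- function(protein_hgvs, strict = TRUE) {
  aa <- "[A-Z][a-z]{2}"
  re_nonsense <- sprintf("^(%s)(\\d+)(?:Ter|\\*)$", aa)
  re_fs_full <- sprintf("^(%s)(\\d+)(?:%s)?fs(?:Ter|\\*)(\\d+)$", aa, aa)
  re_fs_incomplete <- sprintf("^(%s)(\\d+)(?:%s)?fs(?:(?:Ter|\\*)\\??)?$", aa, aa)
  one <- function(x) {
    s <- sub("^p\\.", "", trimws(x))
    s <- sub("^\\((.*)\\)$", "\\1", s)
    if (is.na(x) || !nzchar(s)) {
      return(list(class = "unparseable", anchor = NA_integer_, ter = NA_integer_))
    }
    if (s == "?" || grepl("^spl", s, ignore.case = TRUE)) {
      return(list(class = "splice", anchor = NA_integer_, ter = NA_integer_))
    }
    if (grepl(re_nonsense, s)) {
      return(list(class = "nonsense",
                  anchor = as.integer(sub(re_nonsense, "\\2", s)),
                  ter = NA_integer_))
    }
    if (grepl(re_fs_full, s)) {
      return(list(class = "frameshift",
                  anchor = as.integer(sub(re_fs_full, "\\2", s)),
                  ter = as.integer(sub(re_fs_full, "\\3", s))))
    }
    if (grepl(re_fs_incomplete, s)) {
      if (strict) {
        stop(structure(class = c("ttnenrich_incomplete_description",
                                 "error", "condition"),
                       list(message = paste0("frameshift without Ter extension, PTC ",
                                             "cannot be located: '", x, "'"),
                            call = NULL)))
      }
      return(list(class = "incomplete",
                  anchor = as.integer(sub(re_fs_incomplete, "\\2", s)),
                  ter = NA_integer_))
    }
    if (strict) {
      stop(structure(class = c("ttnenrich_parse_error", "error", "condition"),
                     list(message = paste0("unparseable protein change: '", x, "'"),
                          call = NULL)))
    }
    list(class = "unparseable", anchor = NA_integer_, ter = NA_integer_)
  }
  parsed <- lapply(protein_hgvs, one)
  data.frame(protein_hgvs = as.character(protein_hgvs),
             variant_class = vapply(parsed, `[[`, character(1L), "class"),
             anchor_residue = vapply(parsed, `[[`, integer(1L), "anchor"),
             ter_extension = vapply(parsed, `[[`, integer(1L), "ter"),
             stringsAsFactors = FALSE)
}

#' Resolve the premature termination codon residue
#'
#' For a nonsense variant the PTC is the anchor residue itself. For a
#' frameshift `fsTerK` the shifted reading frame starts at the anchor
#' residue, which counts as residue 1 of the new frame, so the stop sits at
#' protein position `anchor + K - 1`. This counting convention is validated
#' against a translate-and-scan oracle in the package tests rather than
#' assumed.
#'
#' @param variant_class `"nonsense"` or `"frameshift"` (vectorized).
#' @param anchor_residue first affected residue.
#' @param ter_extension stop position `K` within the shifted frame
#'   (frameshifts only; `K >= 1`).
#' @return Integer vector of PTC residue positions.
#' @export
resolve_ptc <- function(variant_class, anchor_residue, ter_extension = NA_integer_) {
  if (!all(variant_class %in% c("nonsense", "frameshift"))) {
    stop("PTC is only defined for nonsense and frameshift variants")
  }
  fs <- variant_class == "frameshift"
  if (any(fs & (is.na(ter_extension) | ter_extension < 1L))) {
    stop("frameshift Ter extension must be a positive integer")
  }
  out <- as.integer(anchor_residue)
  out[fs] <- as.integer(anchor_residue[fs] + ter_extension[fs] - 1L)
  out
}

#' First coding nucleotide of a protein residue
#'
#' @param residue protein position (1-based).
#' @return 1-based coding position of the codon's first nucleotide,
#'   `3 * (residue - 1) + 1`.
#' @export
ptc_cds_start <- function(residue) {
  if (any(residue < 1L)) stop("residue must be >= 1")
  as.integer(3L * (as.numeric(residue) - 1L) + 1L)
}

#' Annotate truncating variants on a transcript model
#'
#' For each variant the protein change is parsed, the PTC residue resolved,
#' and the containing exon looked up on the full (unfiltered) model so that
#' exon PSI, region membership, and PTC-to-intron distance can be attached.
#' A stop codon straddling an exon junction is assigned to the exon holding
#' its first nucleotide. Rows whose description cannot be parsed (splice,
#' incomplete frameshift, free text) or whose PTC falls outside the coding
#' sequence are retained with an `exclusion_reason` instead of aborting the
#' batch; [apply_cohort_filters()] consumes those reasons.
#'
#' PTC-to-intron distance is `cds_end(exon) - ptc_cds_start` under the
#' default first-nucleotide anchor (the ribosome stalls at the start of the
#' stop codon); `distance_anchor = "last"` measures from the codon's final
#' nucleotide instead, 2 nt less. A PTC in the final coding exon has no
#' downstream junction: the distance is `NA` and `last_exon` is set (an
#' NMD-escape flag).
#'
#' @param variants data.frame with at least `protein_hgvs`; `study_id`,
#'   `cdna_hgvs`, `altered_af` and any phenotype columns are carried through.
#'   An optional logical `convertible` column marks variants that could not
#'   be lifted onto the meta-transcript (`FALSE` rows are flagged).
#' @param model full [transcript_model()] (not PSI-filtered).
#' @param partition a [region_partition()].
#' @param psi_threshold PSI cut-off defining `high_psi`; default 0.9.
#' @param distance_anchor `"first"` (default) or `"last"` stop-codon
#'   nucleotide as the distance origin; recorded in the result's
#'   `distance_anchor` attribute.
#' @return data.frame of the input plus `variant_class`, `anchor_residue`,
#'   `ter_extension`, `ptc_residue`, `ptc_cds_start`, `exon_number`,
#'   `exon_psi`, `high_psi`, `region`, `ptc_to_intron_distance`, `last_exon`,
#'   `exclusion_reason` (NA when fully annotated).
#' @export
annotate_variants <- function(variants, model, partition,
                              psi_threshold = 0.9,
                              distance_anchor = c("first", "last")) {
  stopifnot(is.data.frame(variants), inherits(model, "transcript_model"),
            inherits(partition, "region_partition"))
  distance_anchor <- match.arg(distance_anchor)
  if (!"protein_hgvs" %in% names(variants)) {
    stop("variant table must have a 'protein_hgvs' column")
  }
  n <- nrow(variants)
  out <- variants
  parsed <- parse_protein_change(variants$protein_hgvs, strict = FALSE)
  # cDNA intron-offset notation marks splice variants even when the protein
  # field is blank or a guess
  if ("cdna_hgvs" %in% names(variants)) {
    splice_cdna <- !is.na(variants$cdna_hgvs) &
      grepl("[0-9]+[+-][0-9]+", variants$cdna_hgvs)
    parsed$variant_class[splice_cdna] <- "splice"
  }
  out$variant_class <- parsed$variant_class
  out$anchor_residue <- parsed$anchor_residue
  out$ter_extension <- parsed$ter_extension
  out$ptc_residue <- rep(NA_integer_, n)
  out$ptc_cds_start <- rep(NA_integer_, n)
  out$exon_number <- rep(NA_integer_, n)
  out$exon_psi <- rep(NA_real_, n)
  out$high_psi <- rep(NA, n)
  out$region <- rep(NA_character_, n)
  out$ptc_to_intron_distance <- rep(NA_integer_, n)
  out$last_exon <- rep(NA, n)
  out$exclusion_reason <- rep(NA_character_, n)

  out$exclusion_reason[parsed$variant_class == "splice"] <- "splice"
  out$exclusion_reason[parsed$variant_class == "incomplete"] <- "incomplete_description"
  out$exclusion_reason[parsed$variant_class == "unparseable"] <- "unparseable"
  if ("convertible" %in% names(variants)) {
    unconv <- !is.na(variants$convertible) & !variants$convertible
    out$exclusion_reason[unconv] <- "unconvertible_to_meta_transcript"
  }

  resolvable <- parsed$variant_class %in% c("nonsense", "frameshift") &
    is.na(out$exclusion_reason)
  if (any(resolvable)) {
    res <- resolve_ptc(parsed$variant_class[resolvable],
                       parsed$anchor_residue[resolvable],
                       parsed$ter_extension[resolvable])
    starts <- ptc_cds_start(res)
    total <- max(model$cds_end)
    in_range <- starts >= 1L & starts <= total
    idx <- which(resolvable)
    out$exclusion_reason[idx[!in_range]] <- "ptc_outside_coding_sequence"
    ok <- idx[in_range]
    out$ptc_residue[ok] <- res[in_range]
    out$ptc_cds_start[ok] <- starts[in_range]
    ex <- exon_of_position(model, starts[in_range])
    row_of <- match(ex, model$exon_number)
    out$exon_number[ok] <- ex
    out$exon_psi[ok] <- model$psi[row_of]
    out$high_psi[ok] <- model$psi[row_of] > psi_threshold
    out$region[ok] <- region_of_exon(partition, ex)
    last_ex <- max(model$exon_number)
    is_last <- ex == last_ex
    out$last_exon[ok] <- is_last
    origin <- starts[in_range] + if (distance_anchor == "last") 2L else 0L
    dist <- pmax(model$cds_end[row_of] - origin, 0L)
    dist[is_last] <- NA_integer_
    out$ptc_to_intron_distance[ok] <- as.integer(dist)
  }
  attr(out, "distance_anchor") <- distance_anchor
  attr(out, "psi_threshold") <- psi_threshold
  out
}

#' Apply the cohort inclusion/exclusion rules
#'
#' Splits an annotated variant table into retained and excluded sets with
#' machine-readable reasons. The enrichment stage excludes splice-class
#' variants, descriptions too incomplete to place the PTC, variants that
#' could not be converted to the meta-transcript, and variants in low-PSI
#' exons. The NMD stage keeps splice variants (published allelic-imbalance
#' values cannot always be tied to a parseable description) and only drops
#' rows that carry no usable measurement context.
#'
#' @param annotated output of [annotate_variants()].
#' @param stage `"enrichment"` (default) or `"nmd"`.
#' @return list with data.frames `retained` and `excluded`; `excluded` keeps
#'   the `exclusion_reason` column filled.
#' @export
apply_cohort_filters <- function(annotated, stage = c("enrichment", "nmd")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(annotated), "exclusion_reason" %in% names(annotated))
  reason <- annotated$exclusion_reason
  if (stage == "nmd") {
    reason[!is.na(reason) & reason == "splice"] <- NA_character_
  } else {
    low <- is.na(reason) & !is.na(annotated$high_psi) & !annotated$high_psi
    reason[low] <- "low_psi_exon"
  }
  keep <- is.na(reason)
  excluded <- annotated[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  retained <- annotated[keep, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}
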