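#' Construct a transcript model from an exon table
#'
#' A transcript model is an ordered table of coding exons in 1-based inclusive
#' cDNA coordinates, each carrying a percent-spliced-in (PSI) value for the
#' tissue of interest (left ventricle for TTN). Exons must tile the coding
#' sequence contiguously: each exon starts one nucleotide after the previous
#' one ends.
#'
#' @param exons data.frame with columns `exon_number`, `cds_start`, `cds_end`,
#'   `psi`.
#' @return An object of class `transcript_model`: the exon data.frame with an
#'   added `length` column and attributes `total_coding_length` and
#'   `psi_threshold` (NA until [filter_high_psi()] is applied).
#' @export
transcript_model <- function(exons) {
  required <- c("exon_number", "cds_start", "cds_end", "psi")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L) {
    stop("exon table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons)[required]
  for (col in required) {
    if (!is.numeric(exons[[col]])) {
      stop("exon table column '", col, "' must be numeric")
    }
  }
  if (anyNA(exons)) stop("exon table contains missing values")
  if (any(exons$psi < 0 | exons$psi > 1)) stop("psi values must lie in [0, 1]")
  if (any(exons$cds_end < exons$cds_start)) {
    bad <- which(exons$cds_end < exons$cds_start)[1L]
    stop("exon ", exons$exon_number[bad], ": cds_end < cds_start")
  }
  ord <- order(exons$cds_start)
  if (is.unsorted(exons$exon_number[ord], strictly = TRUE)) {
    stop("exon numbers must be strictly increasing with cds_start")
  }
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L) {
    gap <- exons$cds_start[-1L] - exons$cds_end[-nrow(exons)]
    if (any(gap != 1L)) {
      bad <- which(gap != 1L)[1L]
      what <- if (gap[bad] < 1L) "overlaps" else "leaves a gap after"
      stop("exon ", exons$exon_number[bad + 1L], " ", what,
           " exon ", exons$exon_number[bad],
           ": coding coordinates must be contiguous")
    }
  }
  exons$length <- exons$cds_end - exons$cds_start + 1L
  rownames(exons) <- NULL
  structure(exons,
            total_coding_length = sum(exons$length),
            psi_threshold = NA_real_,
            class = c("transcript_model", "data.frame"))
}

#' Read an exon table into a transcript model
#'
#' Two on-disk layouts are supported: a header TSV with columns
#' `exon_number  cds_start  cds_end  psi` in 1-based inclusive coding
#' coordinates, or a 4-column BED-like file (0-based half-open `start end`,
#' exon number in the name field, PSI in the score field) which is converted
#' to 1-based inclusive coordinates on load.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A [transcript_model()].
#' @examples
#' ttn <- read_exon_table(ttn_exon_fixture_path())
#' total_coding_length(ttn)
#' @export
read_exon_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("exon table not found: ", path)
  if (format == "tsv") {
    tab <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "numeric"),
      warning = function(w) stop("malformed exon table '", path, "': ",
                                 conditionMessage(w), call. = FALSE),
      error = function(e) stop("malformed exon table '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 5L) stop("BED exon table needs chrom/start/end/name/score columns")
    tab <- data.frame(exon_number = as.numeric(raw[[4L]]),
                      cds_start = as.numeric(raw[[2L]]) + 1L,
                      cds_end = as.numeric(raw[[3L]]),
                      psi = as.numeric(raw[[5L]]))
  }
  bad <- which(!stats::complete.cases(tab))
  if (length(bad) > 0L) {
    stop("malformed exon table '", path, "': unparseable value on data line ",
         bad[1L])
  }
  transcript_model(tab)
}

#' @export
print.transcript_model <- function(x, ...) {
  thr <- attr(x, "psi_threshold")
  cat(sprintf("Transcript model: %d coding exon(s), %s nt coding sequence\n",
              nrow(x), format(attr(x, "total_coding_length"), big.mark = ",")))
  if (!is.na(thr)) cat(sprintf("  filtered to PSI > %g\n", thr))
  NextMethod()
  invisible(x)
}

#' Total coding length of a transcript model
#'
#' @param model a [transcript_model()].
#' @return Total coding length in nucleotides (after PSI filtering if the
#'   model was filtered).
#' @export
total_coding_length <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  attr(model, "total_coding_length")
}

#' Drop exons that are not constitutively expressed
#'
#' Exons with PSI less than or equal to `threshold` are removed; exons with
#' PSI strictly greater are retained. Coding coordinates are deliberately not
#' renumbered, so positions computed on the full meta-transcript remain valid
#' on the filtered model. The operation is idempotent.
#'
#' @param model a [transcript_model()].
#' @param threshold PSI cut-off in (0, 1); default 0.9 (left-ventricle
#'   constitutive exons).
#' @return A filtered `transcript_model` whose `total_coding_length` counts
#'   retained exons only.
#' @export
filter_high_psi <- function(model, threshold = 0.9) {
  stopifnot(inherits(model, "transcript_model"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  keep <- model$psi > threshold
  if (!any(keep)) warning("no exons exceed PSI threshold ", threshold)
  out <- as.data.frame(model)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            total_coding_length = sum(out$length),
            psi_threshold = threshold,
            class = c("transcript_model", "data.frame"))
}

#' Define a partition of exons into named regions
#'
#' @param regions named list; each element is a length-2 integer vector
#'   `c(first_exon, last_exon)`, inclusive. Regions must be disjoint.
#' @return A validated named list of integer ranges, class `region_partition`.
#' @export
region_partition <- function(regions) {
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop("every region must be named")
  }
  regions <- lapply(regions, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || anyNA(r) || r[2L] < r[1L]) {
      stop("each region must be c(first_exon, last_exon) with last >= first")
    }
    r
  })
  covered <- unlist(lapply(regions, function(r) seq.int(r[1L], r[2L])))
  if (anyDuplicated(covered)) stop("regions overlap: partition must be disjoint")
  structure(regions, class = "region_partition")
}

#' Read a region partition from YAML or JSON
#'
#' @param path file mapping region label to `[first_exon, last_exon]`.
#' @return A [region_partition()].
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  parsed <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  region_partition(parsed)
}

#' The titin meta-transcript region partition
#'
#' The seven disjoint regions used throughout: Z-disk, proximal and distal
#' I-band (the differentially spliced middle I-band is low-PSI and falls
#' outside the partition), the A-band split into pre-exon-327, exon 327 and
#' post-exon-327, and the M-band.
#'
#' @return A [region_partition()] of the seven disjoint regions.
#' @export
ttn_partition <- function() {
  read_partition(system.file("extdata", "ttn_partition.json",
                             package = "ttnenrich", mustWork = TRUE))
}

#' Roll-up region groupings for the titin partition
#'
#' I-band = proximal + distal; A-band = pre-exon-327 + exon 327 +
#' post-exon-327; "Other A-band exons" = A-band without exon 327.
#'
#' @return Named list mapping roll-up label to its member region labels.
#' @export
ttn_rollups <- function() {
  list("I-band" = c("Proximal I-band", "Distal I-band"),
       "A-band" = c("Pre-exon 327 A-band", "Exon 327", "Post-exon 327 A-band"),
       "Other A-band exons" = c("Pre-exon 327 A-band", "Post-exon 327 A-band"))
}

#' Path to the packaged synthetic TTN exon table
#'
#' The meta-transcript's exact per-exon boundaries are not published in full;
#' the packaged table is a synthetic 363-exon stand-in whose regional
#' aggregates are exact: total coding length 107,976 nt, exon 327 = 17,106 nt,
#' and high-PSI (> 0.9) regional coding lengths of 6,232 / 6,912 / 6,171 /
#' 22,749 / 17,106 / 13,944 / 7,211 nt (80,325 nt in total), with the
#' 27,651 nt of differentially spliced sequence placed in the middle I-band
#' (exons 51-219, PSI 0.2).
#'
#' @return File path of the packaged TSV.
#' @export
ttn_exon_fixture_path <- function() {
  system.file("extdata", "ttn_exons_synthetic.tsv",
              package = "ttnenrich", mustWork = TRUE)
}

#' Load the packaged synthetic TTN meta-transcript model
#'
#' @return A [transcript_model()]; see [ttn_exon_fixture_path()] for what the
#'   fixture does and does not reproduce.
#' @export
ttn_model <- function() {
  read_exon_table(ttn_exon_fixture_path())
}

#' Regional coding lengths and length fractions
#'
#' Sums exon lengths per region of a (typically PSI-filtered) model and
#' expresses each region as a fraction of the model's total coding length.
#' Roll-up groupings are sums over their member regions.
#'
#' @param model a [transcript_model()], usually after [filter_high_psi()].
#' @param partition a [region_partition()].
#' @param rollups optional named list mapping roll-up label to member region
#'   labels (e.g. [ttn_rollups()]).
#' @return data.frame with columns `region`, `coding_length`, `fraction`,
#'   `rollup` (logical). Fractions of the disjoint regions sum to 1.
#' @export
region_lengths <- function(model, partition, rollups = NULL) {
  stopifnot(inherits(model, "transcript_model"),
            inherits(partition, "region_partition"))
  total <- attr(model, "total_coding_length")
  if (total == 0L) stop("model has zero coding length")
  len <- vapply(names(partition), function(lab) {
    r <- partition[[lab]]
    in_region <- model$exon_number >= r[1L] & model$exon_number <= r[2L]
    if (!any(in_region)) {
      stop("partition region '", lab, "' (exons ", r[1L], "-", r[2L],
           ") matches no exon in the model")
    }
    sum(model$length[in_region])
  }, numeric(1L))
  out <- data.frame(region = names(partition),
                    coding_length = unname(len),
                    fraction = unname(len) / total,
                    rollup = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(rollups)) {
    for (lab in names(rollups)) {
      members <- match(rollups[[lab]], out$region[!out$rollup])
      if (anyNA(members)) stop("roll-up '", lab, "' references unknown region")
      out <- rbind(out, data.frame(region = lab,
                                   coding_length = sum(out$coding_length[members]),
                                   fraction = sum(out$fraction[members]),
                                   rollup = TRUE,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Locate the exon containing a coding position
#'
#' @param model a [transcript_model()] (full, unfiltered, so every coding
#'   position is covered).
#' @param cds_pos vector of 1-based coding positions.
#' @return Integer vector of exon numbers; errors if a position falls outside
#'   the coding sequence.
#' @export
exon_of_position <- function(model, cds_pos) {
  stopifnot(inherits(model, "transcript_model"))
  if (any(cds_pos < 1L)) stop("coding position must be >= 1")
  idx <- findInterval(cds_pos, model$cds_start)
  beyond <- idx == 0L | cds_pos > model$cds_end[pmax(idx, 1L)]
  if (any(beyond)) {
    stop("coding position ", cds_pos[which(beyond)[1L]],
         " falls outside the model's coding sequence")
  }
  model$exon_number[idx]
}

#' Region label of an exon under a partition
#'
#' @param partition a [region_partition()].
#' @param exon_number integer vector.
#' @return Character vector of region labels; `NA` for exons no region covers
#'   (for the TTN partition these are the low-PSI middle I-band exons).
#' @export
region_of_exon <- function(partition, exon_number) {
  stopifnot(inherits(partition, "region_partition"))
  labs <- rep(NA_character_, length(exon_number))
  for (lab in names(partition)) {
    r <- partition[[lab]]
    labs[exon_number >= r[1L] & exon_number <= r[2L]] <- lab
  }
  labs
}
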