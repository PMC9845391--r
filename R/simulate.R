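#' Simulation settings for a synthetic TTNtv study
#'
#' Defaults describe the study conditions the package analyzes: 570 probands
#' (the regional-enrichment cohort size), neutral region multipliers (null
#' length-proportional placement), and a logistic PTC-to-intron-distance to
#' NMD-efficiency link with midpoint `nmd_d0 = 500` nt and scale
#' `nmd_slope = 300` nt — the simplest monotone bounded model that separates
#' exon-327-scale distances (~10^4 nt, essentially no decay) from typical
#' short-exon distances (~10^2 nt, substantial decay). Measurement noise on
#' the altered-allele frequency defaults to sd 0.05, a realistic
#' read-sampling scale for moderate-coverage RNA-seq.
#'
#' @param n_probands cohort size.
#' @param region_multipliers named vector of target enrichment degrees
#'   (1 = neutral): a named region receives probability mass `degree x its
#'   length share`, and the unnamed regions share the complement in
#'   proportion to length, so the generator's true enrichment degree in a
#'   named region is the configured value exactly. The named degrees must
#'   leave positive mass for the rest (`sum(degree * share) < 1`).
#' @param nmd_d0 logistic midpoint of the distance-NMD link (nt).
#' @param nmd_slope logistic scale (nt).
#' @param ai_noise_sd Gaussian noise sd on altered-allele frequency.
#' @param frameshift_prop fraction of simulated variants emitted as
#'   frameshift (`fsTerK`) rather than nonsense descriptions.
#' @param phenotype_effects list; `endpoint_age_per_deviation` is the linear
#'   shift in endpoint age per unit of true AI deviation (default 0, the
#'   null).
#' @param missingness named list/vector of per-field missingness rates.
#' @return list of settings, class `sim_config`.
#' @export
sim_config <- function(n_probands = 570L,
                       region_multipliers = NULL,
                       nmd_d0 = 500,
                       nmd_slope = 300,
                       ai_noise_sd = 0.05,
                       frameshift_prop = 0,
                       phenotype_effects = list(endpoint_age_per_deviation = 0),
                       missingness = NULL) {
  stopifnot(n_probands >= 0, nmd_slope > 0, ai_noise_sd >= 0,
            frameshift_prop >= 0, frameshift_prop <= 1)
  if (!is.null(region_multipliers) && any(region_multipliers <= 0)) {
    stop("region multipliers must be positive")
  }
  structure(list(n_probands = as.integer(n_probands),
                 region_multipliers = region_multipliers,
                 nmd_d0 = nmd_d0, nmd_slope = nmd_slope,
                 ai_noise_sd = ai_noise_sd,
                 frameshift_prop = frameshift_prop,
                 phenotype_effects = phenotype_effects,
                 missingness = missingness),
            class = "sim_config")
}

aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

# codon-start positions (p == 1 mod 3) within [start, end]
codon_starts_in <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  first <- start + ((3L - ((start - 1L) %% 3L)) %% 3L)
  if (first > end) return(integer(0))
  seq.int(first, end, by = 3L)
}

#' Simulate a truncating-variant cohort over a transcript model
#'
#' Each proband receives one PTC: a region is drawn with probability
#' proportional to its high-PSI coding length times its multiplier, an exon
#' within the region proportional to its codon count, and a codon uniformly
#' within the exon. Variants are emitted as HGVS protein changes (nonsense
#' by default, a configurable fraction as `fsTerK` frameshifts) that
#' round-trip through [annotate_variants()] back to the generator's true
#' exon and distance.
#'
#' @param config a [sim_config()].
#' @param model [transcript_model()] filtered to high-PSI exons.
#' @param partition a [region_partition()].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the cohort is reproducible.
#' @param study_id label for the `study_id` column; default `"sim"`.
#' @return data.frame `variant_id`, `study_id`, `protein_hgvs`,
#'   `true_residue`, `true_exon`, `true_region`.
#' @export
simulate_cohort <- function(config, model, partition, seed = NULL,
                            study_id = "sim") {
  stopifnot(inherits(config, "sim_config"),
            inherits(model, "transcript_model"),
            inherits(partition, "region_partition"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_probands
  if (n == 0L) {
    return(data.frame(variant_id = character(0), study_id = character(0),
                      protein_hgvs = character(0), true_residue = integer(0),
                      true_exon = integer(0), true_region = character(0),
                      stringsAsFactors = FALSE))
  }
  model$region <- region_of_exon(partition, model$exon_number)
  model <- as.data.frame(model)[!is.na(model$region), , drop = FALSE]
  starts_by_exon <- Map(codon_starts_in, model$cds_start, model$cds_end)
  n_codons <- lengths(starts_by_exon)
  mult <- rep(1, nrow(model))
  if (!is.null(config$region_multipliers)) {
    mm <- config$region_multipliers
    named <- model$region %in% names(mm)
    share_named <- sum(n_codons[named]) / sum(n_codons)
    mass_named <- sum((mm[model$region[named]] * n_codons[named])) / sum(n_codons)
    if (mass_named >= 1 && share_named < 1) {
      stop("region multipliers assign probability mass >= 1; ",
           "no mass left for the remaining regions")
    }
    mult[named] <- mm[model$region[named]]
    if (share_named < 1) {
      mult[!named] <- (1 - mass_named) / (1 - share_named)
    }
  }
  w <- n_codons * mult
  exon_idx <- sample.int(nrow(model), n, replace = TRUE, prob = w)
  pos <- vapply(exon_idx, function(i) {
    s <- starts_by_exon[[i]]
    s[sample.int(length(s), 1L)]
  }, integer(1L))
  residue <- (pos - 1L) %/% 3L + 1L
  is_fs <- stats::runif(n) < config$frameshift_prop
  hgvs <- character(n)
  ref_aa <- aa3[(residue %% 20L) + 1L]
  hgvs[!is_fs] <- sprintf("p.%s%dTer", ref_aa[!is_fs], residue[!is_fs])
  if (any(is_fs)) {
    k <- pmin(residue[is_fs],
              sample(1:30, sum(is_fs), replace = TRUE))
    anchor <- residue[is_fs] - k + 1L
    hgvs[is_fs] <- sprintf("p.%s%dLeufsTer%d", aa3[(anchor %% 20L) + 1L],
                           anchor, k)
  }
  data.frame(variant_id = sprintf("%s_v%04d", study_id, seq_len(n)),
             study_id = study_id,
             protein_hgvs = hgvs,
             true_residue = residue,
             true_exon = model$exon_number[exon_idx],
             true_region = model$region[exon_idx],
             stringsAsFactors = FALSE)
}

#' Simulate RNA-seq expression measurements for annotated variants
#'
#' The true NMD-driven AI deviation follows a logistic decay in
#' PTC-to-intron distance, `0.5 * plogis((nmd_d0 - d) / nmd_slope)`: full
#' decay (deviation 0.5) at distance 0 in the limit of a steep link, the
#' midpoint deviation 0.25 at `d = nmd_d0`, and no decay as distance grows.
#' The observed altered-allele frequency is `0.5 - true deviation` plus
#' Gaussian noise, clamped to \[0, 1\]. Variants without a defined distance
#' (final-exon PTCs) escape NMD entirely (true deviation 0).
#'
#' @param config a [sim_config()].
#' @param annotated annotated variant table with `variant_id` and
#'   `ptc_to_intron_distance`.
#' @param seed optional integer seed.
#' @return data.frame `variant_id`, `altered_af`, `true_deviation`.
#' @export
simulate_expression <- function(config, annotated, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            all(c("variant_id", "ptc_to_intron_distance") %in% names(annotated)))
  if (!is.null(seed)) set.seed(seed)
  d <- annotated$ptc_to_intron_distance
  truth <- ifelse(is.na(d), 0,
                  0.5 * stats::plogis((config$nmd_d0 - d) / config$nmd_slope))
  af <- 0.5 - truth + stats::rnorm(length(truth), 0, config$ai_noise_sd)
  data.frame(variant_id = annotated$variant_id,
             altered_af = pmin(pmax(af, 0), 1),
             true_deviation = truth,
             stringsAsFactors = FALSE)
}

#' Simulate a phenotype table for annotated variants
#'
#' Draws the clinical indicator battery from fixed distributions typical of
#' a TTNtv-DCM cohort (diagnosis around age 40, severely reduced LVEF around
#' 20%, dilated LVEDD around 65 mm, NYHA skewed to III-IV), groups variants
#' by exon-327 membership, optionally shifts endpoint age linearly in the
#' true AI deviation (to emulate a decay-efficiency effect on outcome), and
#' applies per-field missingness. With all effects zero the two groups are
#' exchangeable — the null used for type-I-error calibration.
#'
#' @param config a [sim_config()].
#' @param annotated annotated variant table with `variant_id` and `region`.
#' @param true_deviation optional vector aligned with `annotated` (from
#'   [simulate_expression()]); required when the endpoint-age effect is
#'   nonzero.
#' @param seed optional integer seed.
#' @return data.frame `variant_id`, `group` (`"Exon 327"` / `"Other"`), the
#'   [phenotype_indicators()] columns and `family_history`.
#' @export
simulate_phenotypes <- function(config, annotated, true_deviation = NULL,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"), "variant_id" %in% names(annotated))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(annotated)
  eff <- config$phenotype_effects$endpoint_age_per_deviation
  if (is.null(eff)) eff <- 0
  if (eff != 0 && is.null(true_deviation)) {
    stop("true_deviation is required when the endpoint-age effect is nonzero")
  }
  dev <- if (is.null(true_deviation)) rep(0, n) else true_deviation
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- data.frame(
    variant_id = annotated$variant_id,
    group = ifelse(!is.na(annotated$region) & annotated$region == "Exon 327",
                   "Exon 327", "Other"),
    diagnosis_age = round(clamp(stats::rnorm(n, 40, 10), 18, 80)),
    lvef = round(clamp(stats::rnorm(n, 22, 8), 5, 45)),
    fractional_shortening = round(clamp(stats::rnorm(n, 16, 4), 5, 35), 1),
    lvedd = round(clamp(stats::rnorm(n, 65, 8), 40, 90)),
    nyha_class = sample(1:4, n, replace = TRUE, prob = c(0.1, 0.2, 0.4, 0.3)),
    endpoint_age = round(clamp(stats::rnorm(n, 50, 10) + eff * dev, 18, 80)),
    family_history = stats::runif(n) < 0.35,
    stringsAsFactors = FALSE)
  if (!is.null(config$missingness)) {
    for (field in names(config$missingness)) {
      if (!field %in% names(out)) next
      gone <- stats::runif(n) < config$missingness[[field]]
      out[[field]][gone] <- NA
    }
  }
  out
}

#' Run the full synthetic study: cohort, expression, phenotypes
#'
#' Convenience wrapper chaining [simulate_cohort()], [annotate_variants()],
#' [simulate_expression()] and [simulate_phenotypes()] under one seed, and
#' returning the generator's ground truth alongside the tables.
#'
#' @param config a [sim_config()].
#' @param model full [transcript_model()]; filtered internally for cohort
#'   placement, kept whole for annotation.
#' @param partition a [region_partition()].
#' @param seed integer seed for the whole study.
#' @param psi_threshold PSI cut-off; default 0.9.
#' @return list `variants` (with truth columns), `annotated`, `expression`,
#'   `phenotypes`, `truth` (list of generator settings actually used).
#' @export
simulate_study <- function(config, model, partition, seed = 1L,
                           psi_threshold = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  high <- filter_high_psi(model, psi_threshold)
  variants <- simulate_cohort(config, high, partition)
  annotated <- annotate_variants(variants, model, partition, psi_threshold)
  expression <- simulate_expression(config, annotated)
  phenotypes <- simulate_phenotypes(config, annotated,
                                    true_deviation = expression$true_deviation)
  list(variants = variants, annotated = annotated, expression = expression,
       phenotypes = phenotypes,
       truth = list(config = unclass(config), seed = seed,
                    psi_threshold = psi_threshold))
}
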