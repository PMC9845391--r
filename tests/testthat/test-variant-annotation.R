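test_that("protein-change parsing covers the truncating grammar", {
  fs <- parse_protein_change("p.Ser4228LeufsTer23")
  expect_equal(fs$variant_class, "frameshift")
  expect_equal(fs$anchor_residue, 4228L)
  expect_equal(fs$ter_extension, 23L)

  ns <- parse_protein_change("p.Arg5Ter")
  expect_equal(ns$variant_class, "nonsense")
  expect_equal(ns$anchor_residue, 5L)
  expect_true(is.na(ns$ter_extension))

  # star notation and parentheses are equivalent spellings
  expect_equal(parse_protein_change("p.(Arg5*)")$anchor_residue, 5L)
  expect_equal(parse_protein_change("p.Gln10Profs*7")$ter_extension, 7L)

  expect_error(parse_protein_change("p.Ser4228Leufs"),
               class = "ttnenrich_incomplete_description")
  expect_error(parse_protein_change("p.Met1Val"),
               class = "ttnenrich_parse_error")
  expect_equal(parse_protein_change("p.?")$variant_class, "splice")

  bulk <- parse_protein_change(c("p.Arg5Ter", "p.Ser4228Leufs", "garbage"),
                               strict = FALSE)
  expect_equal(bulk$variant_class, c("nonsense", "incomplete", "unparseable"))
})

test_that("PTC resolution follows the frameshift stop-counting convention", {
  expect_equal(resolve_ptc("nonsense", 976L), 976L)
  expect_equal(resolve_ptc("frameshift", 4228L, 23L), 4250L)
  expect_equal(resolve_ptc("frameshift", 10L, 1L), 10L)
  expect_error(resolve_ptc("frameshift", 10L, 0L), "positive")
  expect_error(resolve_ptc("splice", 10L), "nonsense and frameshift")
  expect_equal(ptc_cds_start(c(1L, 4250L)), c(1L, 12748L))
})

test_that("frameshift convention matches the translate-and-scan oracle", {
  # random coding sequences carrying random 1/2-nt deletions and duplications;
  # the HGVS-style description is reconstructed from the mutant translation
  # and must resolve to the stop the full translation actually reaches
  set.seed(7)
  types <- c("del1", "del2", "dup1", "dup2")
  checked <- 0L
  while (checked < 25L) {
    cds <- random_cds(60L)
    ref_aa <- translate_cds(cds)
    pos <- sample(4:120, 1L)            # spare the initiator codon
    mut <- mutate_cds(cds, pos, sample(types, 1L))
    stop_res <- first_stop_residue(mut)
    if (is.na(stop_res)) next           # ran off the end without a stop
    mut_aa <- translate_cds(mut)
    anchor <- which(mut_aa[seq_len(min(length(mut_aa), length(ref_aa)))] !=
                    ref_aa[seq_len(min(length(mut_aa), length(ref_aa)))])[1L]
    if (is.na(anchor) || anchor > stop_res) next
    # Ter extension as a reporter states it: stop position in the shifted
    # frame counting the first changed residue as 1
    k <- stop_res - anchor + 1L
    expect_equal(resolve_ptc("frameshift", anchor, k), stop_res)
    checked <- checked + 1L
  }
  expect_gte(checked, 25L)
})

test_that("annotation fills exon, region, PSI and PTC-to-intron distance", {
  one <- toy_model(300)
  part1 <- toy_partition("only", list(c(1, 1)))
  # single-exon model: that exon is terminal, so no downstream junction
  ann <- annotate_variants(data.frame(protein_hgvs = "p.Gln1Ter"), one, part1)
  expect_equal(ann$exon_number, 1L)
  expect_true(ann$last_exon)
  expect_true(is.na(ann$ptc_to_intron_distance))

  two <- toy_model(c(150, 150))
  part2 <- toy_partition(c("first", "second"), list(c(1, 1), c(2, 2)))
  # residue 50 starts at cds 148: stop codon straddles the junction but is
  # assigned to the exon holding its first nucleotide, distance 150 - 148
  ann2 <- annotate_variants(data.frame(protein_hgvs = "p.Gln50Ter"), two, part2)
  expect_equal(ann2$exon_number, 1L)
  expect_equal(ann2$ptc_to_intron_distance, 2L)
  expect_equal(ann2$region, "first")
  expect_false(ann2$last_exon)

  # non-terminal exon: distance = cds_end - ptc_cds_start
  ann3 <- annotate_variants(data.frame(protein_hgvs = "p.Gln1Ter"), two, part2)
  expect_equal(ann3$ptc_to_intron_distance, 149L)

  # last-nucleotide anchor sits 2 nt closer to the junction
  ann4 <- annotate_variants(data.frame(protein_hgvs = "p.Gln1Ter"), two, part2,
                            distance_anchor = "last")
  expect_equal(ann4$ptc_to_intron_distance, 147L)
  expect_equal(attr(ann4, "distance_anchor"), "last")
})

test_that("a PTC inside exon 327 is labelled with the exon-327 region", {
  ttn <- ttn_model()
  e327 <- as.data.frame(ttn)[ttn$exon_number == 327, ]
  mid_residue <- (e327$cds_start + 3000 - 1) %/% 3 + 1
  ann <- annotate_variants(data.frame(protein_hgvs = sprintf("p.Trp%dTer", mid_residue)),
                           ttn, ttn_partition())
  expect_equal(ann$exon_number, 327L)
  expect_equal(ann$region, "Exon 327")
  expect_true(ann$high_psi)
})

test_that("PTCs beyond the coding sequence are flagged, not annotated", {
  ann <- annotate_variants(data.frame(protein_hgvs = "p.Gln200Ter"),
                           toy_model(300), toy_partition("only", list(c(1, 1))))
  expect_equal(ann$exclusion_reason, "ptc_outside_coding_sequence")
  expect_true(is.na(ann$exon_number))
})

test_that("PTC-to-intron distance is bounded by the exon length", {
  set.seed(11)
  ttn <- ttn_model()
  part <- ttn_partition()
  cohort <- simulate_cohort(sim_config(n_probands = 200L),
                            filter_high_psi(ttn, 0.9), part)
  ann <- annotate_variants(cohort, ttn, part)
  ok <- !is.na(ann$ptc_to_intron_distance)
  exon_len <- ttn$length[match(ann$exon_number[ok], ttn$exon_number)]
  expect_true(all(ann$ptc_to_intron_distance[ok] >= 0))
  expect_true(all(ann$ptc_to_intron_distance[ok] <= exon_len - 1))
  # deterministic: annotating the same rows twice is identical
  expect_identical(ann, annotate_variants(cohort, ttn, part))
})

test_that("cohort filters exclude with machine-readable reasons per stage", {
  ttn <- ttn_model()
  part <- ttn_partition()
  low_exon <- as.data.frame(ttn)[ttn$exon_number == 100, ]  # PSI 0.2
  low_res <- (low_exon$cds_start - 1) %/% 3 + 2
  variants <- data.frame(
    variant_id = sprintf("v%d", 1:5),
    cdna_hgvs = c(NA, NA, "c.100+1G>A", NA, NA),
    protein_hgvs = c("p.Arg5Ter", "p.Ser10LeufsTer4", NA,
                     sprintf("p.Gln%dTer", low_res), "p.Lys7Glufs"),
    stringsAsFactors = FALSE)
  ann <- annotate_variants(variants, ttn, part)
  split <- apply_cohort_filters(ann, stage = "enrichment")
  expect_equal(nrow(split$retained), 2L)
  expect_setequal(split$excluded$exclusion_reason,
                  c("splice", "low_psi_exon", "incomplete_description"))
  # NMD stage keeps splice variants for published AI values
  nmd <- apply_cohort_filters(ann, stage = "nmd")
  expect_true("c.100+1G>A" %in% nmd$retained$cdna_hgvs)
  # empty input passes through
  empty <- apply_cohort_filters(ann[0, ], stage = "enrichment")
  expect_equal(nrow(empty$retained), 0L)
  # unconvertible transcript flag is honoured
  variants$convertible <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  ann2 <- annotate_variants(variants, ttn, part)
  expect_equal(ann2$exclusion_reason[2], "unconvertible_to_meta_transcript")
})

test_that("low-PSI exclusions reproduce the cohort accounting pattern", {
  # 612 parseable variants of which 6 sit in low-PSI exons -> 606 retained
  set.seed(3)
  ttn <- ttn_model()
  part <- ttn_partition()
  high <- simulate_cohort(sim_config(n_probands = 606L),
                          filter_high_psi(ttn, 0.9), part)
  low_exons <- as.data.frame(ttn)[ttn$psi <= 0.9, ]
  low_rows <- low_exons[sample.int(nrow(low_exons), 6L), ]
  low_res <- (low_rows$cds_start - 1) %/% 3 + 2
  low <- data.frame(variant_id = sprintf("low%d", 1:6), study_id = "sim",
                    protein_hgvs = sprintf("p.Gln%dTer", low_res),
                    true_residue = NA, true_exon = NA, true_region = NA)
  ann <- annotate_variants(rbind(high, low), ttn, part)
  split <- apply_cohort_filters(ann, stage = "enrichment")
  expect_equal(nrow(ann), 612L)
  expect_equal(nrow(split$retained), 606L)
  expect_true(all(split$excluded$exclusion_reason == "low_psi_exon"))
})
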