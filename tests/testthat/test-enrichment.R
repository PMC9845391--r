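test_that("tallying counts variants per region with roll-ups", {
  part <- toy_partition(c("A", "B"), list(c(1, 1), c(2, 2)))
  empty <- tally_by_region(data.frame(region = character(0)), part)
  expect_equal(empty$observed, c(0, 0))
  expect_equal(attr(empty, "N"), 0L)

  ten <- tally_by_region(data.frame(region = rep("A", 10)), part,
                         rollups = list(AB = c("A", "B")))
  expect_equal(ten$observed, c(10, 0, 10))
  expect_equal(attr(ten, "N"), 10L)

  expect_error(tally_by_region(data.frame(region = c("A", NA)), part),
               "no region")
})

test_that("expected counts are the cohort size spread by length share", {
  lens <- region_lengths(filter_high_psi(ttn_model(), 0.9), ttn_partition(),
                         ttn_rollups())
  e <- expected_counts(570, lens)
  expect_equal(round(e$expected[e$region == "Exon 327"], 2), 121.39)
  expect_equal(round(e$expected[e$region == "Z-disk"], 2), 44.22)
  expect_equal(expected_counts(0, lens)$expected, rep(0, nrow(lens)))
  disjoint <- !e$rollup
  expect_equal(sum(e$expected[disjoint]), 570, tolerance = 1e-9)
})

test_that("enrichment degree is observed over expected, guarded", {
  expect_equal(round(enrichment_degree(166, 570 * 17106 / 80325), 2), 1.37)
  expect_equal(round(enrichment_degree(17, 570 * 6232 / 80325), 2), 0.38)
  expect_equal(enrichment_degree(5, 5), 1)
  expect_error(enrichment_degree(1, 0), "> 0")
})

test_that("two-sided binomial test matches the enumeration oracle everywhere small", {
  for (n in 1:12) {
    for (p0 in c(0.1, 0.25, 0.5, 0.9)) {
      for (k in 0:n) {
        expect_equal(binom_two_sided(k, n, p0), binom_oracle(k, n, p0),
                     tolerance = 1e-10,
                     label = sprintf("k=%d n=%d p0=%.2f", k, n, p0))
      }
    }
  }
  expect_equal(binom_two_sided(2, 3, 0.5), 1)
  expect_equal(round(binom_two_sided(87, 570, 13083 / 80325), 3), 0.533)
  expect_equal(round(binom_two_sided(34, 570, 7211 / 80325), 3), 0.010)
  expect_error(binom_two_sided(5, 3, 0.5), "k <= n")
  expect_error(binom_two_sided(1, 3, 0), "strictly")
})

test_that("the per-cohort enrichment table conserves totals and recomputes roll-ups", {
  set.seed(5)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    m <- toy_model(sample(60:600, k, replace = TRUE))
    part <- toy_partition(paste0("R", seq_len(k)),
                          lapply(seq_len(k), function(i) c(i, i)))
    lens <- region_lengths(m, part)
    n <- sample(50:400, 1)
    obs <- as.vector(stats::rmultinom(1, n, lens$fraction))
    tal <- data.frame(region = lens$region, observed = obs, rollup = FALSE)
    attr(tal, "N") <- n
    tab <- enrichment_table(tal, lens)
    expect_equal(sum(tab$expected), n, tolerance = 1e-9)
    expect_equal(sum(tab$observed), n)
    # length-weighted mean degree is exactly 1
    expect_equal(sum(tab$fraction * tab$degree), 1, tolerance = 1e-12)
  }
  # monotonicity in the observed count, all else fixed
  lens1 <- region_lengths(toy_model(c(100, 300)),
                          toy_partition(c("a", "b"), list(c(1, 1), c(2, 2))))
  degs <- vapply(1:40, function(k) {
    tal <- data.frame(region = c("a", "b"), observed = c(k, 40 - k),
                      rollup = FALSE)
    attr(tal, "N") <- 40L
    enrichment_table(tal, lens1)$degree[1]
  }, numeric(1))
  expect_true(all(diff(degs) > 0))
})

test_that("roll-up rows aggregate counts, not degrees", {
  tab <- reproduce_enrichment_table()
  pick <- function(r, col) tab[tab$region == r, col]
  expect_equal(pick("A-band", "observed_dcm"),
               pick("Pre-exon 327 A-band", "observed_dcm") +
                 pick("Exon 327", "observed_dcm") +
                 pick("Post-exon 327 A-band", "observed_dcm"))
  expect_equal(pick("I-band", "coding_length"),
               pick("Proximal I-band", "coding_length") +
                 pick("Distal I-band", "coding_length"))
  expect_equal(pick("A-band", "degree_dcm"),
               pick("A-band", "observed_dcm") / pick("A-band", "expected_dcm"))
})

test_that("cohort comparison uses unrounded degrees and flags zero controls", {
  tab <- reproduce_enrichment_table()
  e327 <- tab[tab$region == "Exon 327", ]
  expect_equal(e327$ratio, e327$degree_dcm / e327$degree_gnomad)
  expect_equal(round(e327$ratio, 2), 2.76)

  lens <- region_lengths(toy_model(c(100, 100)),
                         toy_partition(c("a", "b"), list(c(1, 1), c(2, 2))))
  tal <- function(obs) {
    t <- data.frame(region = c("a", "b"), observed = obs, rollup = FALSE)
    attr(t, "N") <- sum(obs)
    t
  }
  same <- enrichment_table(tal(c(30, 30)), lens)
  cc <- compare_cohorts(same, same)
  expect_equal(cc$ratio, c(1, 1))
  zero <- enrichment_table(tal(c(60, 0)), lens)
  expect_warning(cc0 <- compare_cohorts(same, zero), "ratio undefined")
  expect_true(is.na(cc0$ratio[2]))
})

test_that("per-study enrichment transforms exact binomial intervals to the degree scale", {
  lens <- region_lengths(filter_high_psi(ttn_model(), 0.9), ttn_partition(),
                         ttn_rollups())
  counts <- table2_counts()
  # one study holding the whole cohort reproduces the headline degree
  whole <- data.frame(
    study_id = "pooled",
    region = rep(counts$region, counts$observed_dcm))
  ps <- per_study_enrichment(whole, lens)
  expect_equal(round(ps$degree, 2), 1.37)
  expect_lt(ps$p_value, 0.001)
  expect_true(ps$lower < ps$degree && ps$degree < ps$upper)

  none <- data.frame(study_id = "s0", region = rep("Z-disk", 8))
  ps0 <- per_study_enrichment(none, lens)
  expect_equal(ps0$degree, 0)
  expect_equal(ps0$lower, 0)
})

test_that("simulated cohorts with a configured exon-327 degree are recovered within the interval", {
  set.seed(101)
  ttn <- ttn_model()
  part <- ttn_partition()
  high <- filter_high_psi(ttn, 0.9)
  lens <- region_lengths(high, part, ttn_rollups())
  cfg <- sim_config(n_probands = 500L,
                    region_multipliers = c("Exon 327" = 2.0))
  cohort <- simulate_cohort(cfg, high, part)
  ann <- annotate_variants(cohort, ttn, part)
  ps <- per_study_enrichment(ann, lens)
  expect_true(ps$lower <= 2.0 && 2.0 <= ps$upper)
})
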