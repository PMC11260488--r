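gated_sample <- function(n = 10000, seed = 1, ...) {
  gate_pipeline(gen_events(reporter_model(...), n, seed = seed))
}

test_that("outermost selection takes exactly floor(fraction * n) events", {
  ev <- gated_sample(20000, seed = 1)
  mask <- outermost_selection(ev, fraction = 0.10)
  expect_equal(sum(mask), floor(0.10 * nrow(ev)))
  # selected distances dominate unselected distances
  X <- cbind(ev$GFP, ev$mCherry)
  d <- mahalanobis(X, colMeans(X), cov(X))
  expect_gte(min(d[mask]), max(d[!mask]))
})

test_that("outermost selection falls back to Euclidean ranking on singular covariance", {
  ev <- gated_sample(1000, seed = 2)
  ev$mCherry <- rep(1, nrow(ev))  # constant channel
  expect_warning(mask <- outermost_selection(ev, 0.10), "singular")
  expect_equal(sum(mask), floor(0.10 * nrow(ev)))
  # all-identical events: ties broken by event index
  ev$GFP <- rep(1, nrow(ev))
  expect_warning(mask2 <- outermost_selection(ev, 0.10), "singular")
  expect_equal(which(mask2), seq_len(floor(0.10 * nrow(ev))))
})

test_that("quadrant masks are disjoint median splits with ~25% occupancy", {
  # independent channels (no shared extrinsic factor), so the two median
  # splits are independent and each quadrant holds about a quarter
  ev <- gated_sample(40000, seed = 3, sigma_ext = 0)
  qi <- quadrant_mask(ev, "QI")
  qii <- quadrant_mask(ev, "QII")
  qiv <- quadrant_mask(ev, "QIV")
  expect_false(any(qi & qii))
  expect_false(any(qi & qiv))
  expect_false(any(qii & qiv))
  for (frac in c(mean(qi), mean(qii), mean(qiv)))
    expect_lt(abs(frac - 0.25), 0.03)
  # boundary events fall on the at/below side
  ev$GFP <- rep(median(ev$GFP), nrow(ev))
  expect_false(any(quadrant_mask(ev, "QI")))
})

test_that("EMS mutagenesis founds mutant lineages at the configured rates", {
  pop <- founding_population(1e6)
  out <- ems_mutagenize(pop, mutant_fraction = 1,
                        class_probs = c(noise_up = 1e-3, neutral = 0.999),
                        seed = 1)
  ab <- out$lineages$abundance
  n_up <- sum(ab[out$lineages$class == "noise_up"])
  ci <- qbinom(c(0.0005, 0.9995), 1e6, 1e-3)
  expect_gte(n_up, ci[1])
  expect_lte(n_up, ci[2])
  expect_equal(sum(ab), 1e6)
  # zero mutagenesis leaves the population unchanged
  same <- ems_mutagenize(pop, mutant_fraction = 0, seed = 1)
  expect_equal(same$lineages$abundance, pop$lineages$abundance)
  # determinism
  expect_identical(ems_mutagenize(pop, 0.5, seed = 9),
                   ems_mutagenize(pop, 0.5, seed = 9))
  expect_error(ems_mutagenize(pop, 1, class_probs = c(noise_up = 0.8,
                                                      neutral = 0.5)),
               "at most 1")
})

test_that("a pure wild-type population stays pure through a sort", {
  pop <- founding_population(1e5)
  out <- sort_step(pop, "QII_QIV", n_sample = 5000, seed = 1)
  fr <- lineage_frequencies(out)
  expect_equal(unname(fr["wild_type"]), 1)
})

test_that("the outermost QII/QIV sort enriches high-noise lineages", {
  for (s in 1:10) {
    pop <- founding_population(1e6)
    pop <- add_lineage(pop, "noise_up", 1e4, sigma_multiplier = 2)
    f0 <- lineage_frequencies(pop)["noise_up"]
    out <- sort_step(pop, "QII_QIV", n_sample = 1e4, seed = s)
    expect_gt(lineage_frequencies(out)["noise_up"], f0)
  }
})

test_that("enrichment grows with the noise multiplier", {
  mean_freq <- sapply(c(1, 1.5, 2), function(m) {
    mean(sapply(1:8, function(s) {
      pop <- founding_population(1e6)
      pop <- add_lineage(pop, "noise_up", 1e4, sigma_multiplier = m)
      out <- sort_step(pop, "QII_QIV", n_sample = 1e4, seed = s)
      lineage_frequencies(out)["noise_up"]
    }))
  })
  expect_true(all(diff(mean_freq) > 0))
})

test_that("the QI sort counter-selects reporter-defective lineages", {
  for (s in 1:10) {
    pop <- founding_population(1e6)
    pop <- add_lineage(pop, "gfp_defect", 1e5, gfp_defect = TRUE)
    f0 <- lineage_frequencies(pop)["gfp_defect"]
    out <- sort_step(pop, "QI", n_sample = 1e4, seed = s)
    expect_lt(lineage_frequencies(out)["gfp_defect"], f0)
  }
})

test_that("glycerol recovery depletes mito-defective lineages and hits the target size exactly", {
  pop <- founding_population(1e5)
  pop <- add_lineage(pop, "mito_defect", 1e5, mito_defect = TRUE)
  out <- recover_population(pop, 1e5, generations = 10, seed = 1)
  expect_equal(sum(out$lineages$abundance), 1e5)
  expect_lt(lineage_frequencies(out)["mito_defect"], 0.01)
  # neutral resampling: equal growth keeps composition within multinomial CI
  pop2 <- founding_population(5e4)
  pop2 <- add_lineage(pop2, "neutral", 5e4)
  out2 <- recover_population(pop2, 1e5, generations = 10, seed = 2)
  fr <- lineage_frequencies(out2)["neutral"]
  ci <- qbinom(c(0.0005, 0.9995), 1e5, 0.5) / 1e5
  expect_gte(fr, ci[1])
  expect_lte(fr, ci[2])
  # single-lineage identity
  one <- founding_population(1234)
  expect_equal(recover_population(one, 1234, seed = 3)$lineages$abundance,
               1234)
})

test_that("a full protocol run is reproducible and enriches noise-up mutants", {
  # 2e4 events per sort sample: at 1e-3 starting frequency the noise-up
  # lineage enters each sort with ~20 cells, enough that selection rather
  # than drift dominates (the bench sorter streams millions of cells)
  cfg <- evolution_config(n_founding = 1e5, n_sample = 2e4,
                          target_size = 1e5,
                          class_probs = c(noise_up = 1e-3, neutral = 0.99))
  r1 <- run_protocol(cfg, n_rounds = 1, seed = 5)
  r2 <- run_protocol(cfg, n_rounds = 1, seed = 5)
  expect_identical(r1$trajectory, r2$trajectory)
  wins <- sapply(1:10, function(s) {
    r <- run_protocol(cfg, n_rounds = 2, seed = s)
    tr <- r$trajectory
    f_init <- tr$frequency[tr$step == "initial" &
                             tr$lineage_class == "noise_up"]
    f_final <- tail(tr$frequency[tr$lineage_class == "noise_up"], 1)
    length(f_init) == 1 && f_final > f_init
  })
  expect_gte(sum(wins), 9)
})

test_that("alternating quadrants favors noise over general activation", {
  # a general activator (3x both means, wild-type noise) starts at the same
  # frequency as a noise-up lineage; after QII/QIV + QI sorting the
  # noise-up lineage ends higher on average
  final <- sapply(1:6, function(s) {
    pop <- founding_population(1e6)
    pop <- add_lineage(pop, "noise_up", 1e4, sigma_multiplier = 2)
    pop <- add_lineage(pop, "general_regulator", 1e4, mean_multiplier = 3)
    pop <- sort_step(pop, "QII_QIV", n_sample = 1e4, seed = s)
    pop <- recover_population(pop, 1e5, seed = s)
    pop <- sort_step(pop, "QI", n_sample = 1e4, seed = s + 100)
    fr <- lineage_frequencies(pop)
    c(noise = unname(fr["noise_up"]), act = unname(fr["general_regulator"]))
  })
  expect_gt(mean(final["noise", ]), mean(final["act", ]))
})

test_that("no mutagenesis leaves population Fano unchanged within sampling error", {
  cfg <- evolution_config(n_founding = 1e5, mutant_fraction = 0,
                          n_sample = 5000, target_size = 1e5)
  r <- run_protocol(cfg, n_rounds = 1, seed = 2)
  tr <- r$trajectory
  f0 <- tr$fano_gfp[tr$step == "initial"][1]
  f_sorts <- tr$fano_gfp[tr$step_type == "sort"]
  expect_true(all(abs(f_sorts - f0) / f0 < 0.25))
})
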