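test_that("generator parameter invariants are enforced", {
  expect_error(lick_gen_params(within_ili_mean = 0.4, within_ili_sd = 0.05),
               class = "bingetools_infeasible_params")
  expect_error(lick_gen_params(pause_min = 0.4),
               class = "bingetools_infeasible_params")
  expect_error(lick_gen_params(mean_cluster_licks = 2),
               class = "bingetools_bad_argument")
})

test_that("lick generation is seed-deterministic", {
  p <- lick_gen_params()
  a <- gen_lick_train(p, seed = 12)
  b <- gen_lick_train(p, seed = 12)
  expect_identical(a$licks, b$licks)
  expect_identical(a$truth, b$truth)
  c <- gen_lick_train(p, seed = 13)
  expect_false(identical(a$licks, c$licks))
})

test_that("segmentation recovers the generator's ground-truth clusters exactly", {
  # the generator's truncations make truth and segmentation coincide
  for (s in 1:20) {
    g <- gen_lick_train(lick_gen_params(), seed = s)
    cl <- segment_clusters(g$licks)
    expect_equal(nrow(cl), nrow(g$truth))
    expect_equal(cl$start, g$truth$start)
    expect_equal(cl$end, g$truth$end)
    expect_equal(cl$n_licks, g$truth$n_licks)
  }
})

test_that("complete tone suppression silences cluster onsets inside tones", {
  des <- fc_design()
  p <- lick_gen_params(tone_suppression = 0, pause_mean_excess = 2,
                       latency_mean = 5)
  part <- epoch_partition(des)
  tones <- part[part$phase == "tone", ]
  for (s in 1:10) {
    g <- gen_lick_train(p, design = des, seed = s)
    onsets <- g$truth$start
    in_tone <- vapply(onsets, function(t) {
      any(t >= tones$start & t < tones$end)
    }, logical(1))
    expect_false(any(in_tone))
  }
})

test_that("estimated cluster size converges to the generator expectation", {
  # 500 sessions at mean cluster size 6: within 5% of truth
  p <- lick_gen_params(mean_cluster_licks = 6, pause_mean_excess = 2,
                       latency_mean = 5, session_duration = 300)
  set.seed(71)
  sizes <- numeric(0)
  durations <- numeric(0)
  for (s in 1:500) {
    g <- gen_lick_train(p, seed = sample.int(1e7, 1))
    cl <- segment_clusters(g$licks)
    sizes <- c(sizes, cl$n_licks)
    durations <- c(durations, cl$duration)
  }
  expect_lt(abs(mean(sizes) - 6) / 6, 0.05)
  # expected duration = (mean size - 1) * mean within-cluster interval
  expected_dur <- 5 * p$within_ili_mean
  expect_lt(abs(mean(durations) - expected_dur) / expected_dur, 0.05)
})

test_that("cohort generation is deterministic and honors p_bep", {
  a <- gen_cohort(n_rats = 20, seed = 5)
  b <- gen_cohort(n_rats = 20, seed = 5)
  expect_identical(a$intakes, b$intakes)
  all_ber <- gen_cohort(n_rats = 20, p_bep = 0, seed = 6)
  expect_true(all(all_ber$truth$phenotype == "BER"))
  all_bep <- gen_cohort(n_rats = 20, p_bep = 1, seed = 6)
  expect_true(all(all_bep$truth$phenotype == "BEP"))
  # six sessions per rat, labeled and kinded
  expect_equal(nrow(a$intakes), 20 * 6)
  expect_setequal(unique(a$intakes$session_kind), c("no_stress", "stress"))
  expect_true(all(a$intakes$grams >= 0))
})

test_that("planted phenotypes are recovered when separation is wide", {
  # >= 2 sigma between phenotype means; >= 95% correct over 200 cohorts
  set.seed(72)
  correct <- 0; total <- 0
  for (i in 1:200) {
    sim <- gen_cohort(
      n_rats = 30, p_bep = 1 / 3, p_intermediate = 1 / 3,
      bep_intake_mean = 16, bep_intake_sd = 2,
      ber_intake_mean = 8, ber_intake_sd = 2,
      seed = sample.int(1e7, 1)
    )
    ph <- suppressWarnings(phenotype_cohort(sim$intakes, c("S1", "S2", "S3")))
    joined <- dplyr::inner_join(tidy(ph), sim$truth, by = "rat_id")
    planted <- joined[joined$phenotype %in% c("BEP", "BER"), ]
    correct <- correct + sum(as.character(planted$label) == planted$phenotype)
    total <- total + nrow(planted)
  }
  expect_gte(correct / total, 0.95)
})

test_that("stress-by-phenotype interaction is detectable at planted power", {
  # 1 sigma stress escalation in prone rats only, n = 40 rats/phenotype:
  # the two-way interaction should be significant in > 80% of replicates
  set.seed(73)
  hits <- 0
  n_reps <- 60
  for (i in 1:n_reps) {
    sim <- gen_cohort(
      n_rats = 80, p_bep = 0.5,
      bep_intake_mean = 12, bep_intake_sd = 2,
      ber_intake_mean = 12, ber_intake_sd = 2,
      stress_effect_bep = 2, stress_effect_ber = 0,
      seed = sample.int(1e7, 1)
    )
    df <- dplyr::inner_join(sim$intakes, sim$truth, by = "rat_id")
    fit <- two_way_anova(df, "grams", "phenotype", "session_kind")
    p_int <- fit$effects$p.value[3]
    if (p_int < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_reps, 0.8)
})

test_that("freezing generation plants the sucrose effect and clips bounds", {
  curve <- c(F1 = 4, F2 = 10, F3 = 12, F4 = 12, Test = 12)
  noiseless <- gen_freezing(4, curve, sucrose_effect = 0.5,
                            sucrose_group = c(TRUE, TRUE, FALSE, FALSE),
                            noise_sd = 0, seed = 74)
  out <- normalized_freezing(noiseless$freezing)
  # training mean (F2-F4) = 34/3; test = 12 (or 6 with sucrose)
  expect_equal(sort(unique(round(out$baseline_ratio, 10))),
               sort(round(c(6 / (34 / 3), 12 / (34 / 3)), 10)))

  # positive noise on a ceiling-level curve stays clipped at the tone length
  hi <- gen_freezing(50, c(Test = 20), noise_sd = 3, seed = 75)
  expect_true(all(hi$freezing$freezing_s <= 20))
  expect_true(all(hi$freezing$freezing_s >= 0))

  expect_error(gen_freezing(2, c(Test = 25)),
               class = "bingetools_out_of_bounds")
})

test_that("a planted sucrose ratio reduction is recovered within its CI", {
  curve <- c(F2 = 12, F3 = 12, F4 = 12, Test = 12)
  sim <- gen_freezing(100, curve, sucrose_effect = 0.5,
                      sucrose_group = rep(TRUE, 100),
                      noise_sd = 1.5, seed = 76)
  out <- normalized_freezing(sim$freezing)
  m <- mean(out$baseline_ratio)
  se <- sd(out$baseline_ratio) / sqrt(nrow(out))
  expect_lt(abs(m - 0.5), 3 * se + 0.02)
})

test_that("grain images are seed-deterministic with correct truth", {
  roi <- square_poly(20, 20, 30)
  a <- gen_grain_image(80, 80, background_density = 0.5, signal_density = 2,
                       roi_polygon = roi, grain_intensity = 20, seed = 77)
  b <- gen_grain_image(80, 80, background_density = 0.5, signal_density = 2,
                       roi_polygon = roi, grain_intensity = 20, seed = 77)
  expect_identical(a$image, b$image)
  expect_equal(a$truth$expected_corrected_od, 30)
  expect_error(
    gen_grain_image(50, 50, roi_polygon = square_poly(40, 40, 20)),
    class = "bingetools_outside_image"
  )
})

test_that("null grain images give corrected OD near zero", {
  roi <- square_poly(20, 20, 30)
  bgs <- list(square_poly(5, 5, 10), square_poly(60, 5, 10),
              square_poly(60, 60, 10))
  set.seed(78)
  ods <- vapply(1:20, function(i) {
    sim <- gen_grain_image(80, 80, background_density = 1, signal_density = 1,
                           roi_polygon = roi, grain_intensity = 10,
                           seed = sample.int(1e7, 1))
    suppressWarnings(measure_roi(sim$image, roi, bgs))$corrected_od
  }, numeric(1))
  # Poisson mean 1 at grain gain 10: the SE of each OD is ~ 0.4
  expect_lt(abs(mean(ods)), 1)
})
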