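#' Simulate and analyze one full conflict-test experiment
#'
#' Generates a complete synthetic conflict experiment — appetitive and test
#' intakes for tone-only and tone-shock (paired) groups of both phenotypes,
#' and freezing trajectories for the paired groups with and without sucrose
#' access — runs it through the package's analysis pipeline, and reports the
#' three headline group contrasts of such an experiment:
#'
#' 1. `appetitive_intake`: mean appetitive kcal/kg, prone minus resistant
#'    (planted positive — prone rats overconsume at baseline);
#' 2. `cs_suppression_ber`: mean test/appetitive intake ratio, resistant
#'    paired minus resistant tone-only (planted negative — the conditioned
#'    stimulus suppresses intake in resistant rats only);
#' 3. `sucrose_anxiolysis_bep`: mean test/training freezing ratio, prone
#'    paired sucrose minus prone paired no-sucrose (planted negative —
#'    sucrose blunts the fear response of prone rats).
#'
#' Effects are planted at `effect_size` standard deviations of the relevant
#' noise term with `n_per_group` rats per group.
#'
#' @param n_per_group Rats per phenotype-by-condition group (default 12).
#' @param effect_size Planted effect size in noise-SD units (default 1.5).
#' @param intake_sd Per-session intake SD, grams (default 2).
#' @param ber_intake_mean Resistant-rat appetitive mean, grams (default 10).
#' @param freezing_noise_sd Per-tone freezing noise SD, seconds
#'   (default 1.5).
#' @param seed Integer seed.
#' @return A tibble with one row per contrast: `contrast, mean_a, mean_b,
#'   difference, expected_sign, sign_correct`.
#' @export
simulate_conflict_experiment <- function(n_per_group = 12, effect_size = 1.5,
                                         intake_sd = 2, ber_intake_mean = 10,
                                         freezing_noise_sd = 1.5,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bep_mean <- ber_intake_mean + effect_size * intake_sd
  conds <- tidyr::crossing(
    phenotype = c("BEP", "BER"), condition = c("tone", "paired")
  )
  rats <- conds[rep(seq_len(nrow(conds)), each = n_per_group), ]
  rats$rat_id <- sprintf("r%03d", seq_len(nrow(rats)))
  rats$body_weight_g <- rtruncnorm(nrow(rats), 300, 15, lower = 0)

  sessions <- c("A1", "A2", "A3", "Test")
  intake_rows <- purrr::pmap(rats, function(phenotype, condition, rat_id,
                                            body_weight_g) {
    mu <- if (phenotype == "BEP") bep_mean else ber_intake_mean
    grams <- vapply(sessions, function(s) {
      m <- mu
      # the conditioned stimulus suppresses test intake in resistant rats only
      if (s == "Test" && phenotype == "BER" && condition == "paired") {
        m <- m - effect_size * intake_sd
      }
      rtruncnorm(1, m, intake_sd, lower = 0)
    }, numeric(1))
    tibble::tibble(
      rat_id = rat_id, session_id = sessions,
      session_kind = c(rep("appetitive", 3), "test"),
      condition = condition, grams = grams,
      body_weight_g = body_weight_g, sucrose_access = TRUE,
      phenotype = phenotype
    )
  })
  intakes <- dplyr::bind_rows(intake_rows)

  norm <- normalized_intake(intakes, c("A1", "A2", "A3"), "Test")
  norm <- dplyr::left_join(
    norm, dplyr::distinct(intakes, .data$rat_id, .data$phenotype, .data$condition),
    by = "rat_id"
  )
  app <- intakes[intakes$session_kind == "appetitive", ]
  app$energy_per_kg <- intake_energy(app$grams, app$body_weight_g)
  c1_a <- mean(app$energy_per_kg[app$phenotype == "BEP"])
  c1_b <- mean(app$energy_per_kg[app$phenotype == "BER"])
  c2_a <- mean(norm$baseline_ratio[norm$phenotype == "BER" &
                                     norm$condition == "paired"])
  c2_b <- mean(norm$baseline_ratio[norm$phenotype == "BER" &
                                     norm$condition == "tone"])

  # freezing: paired groups only, sucrose vs no sucrose, both phenotypes
  curve <- c(F1 = 4, F2 = 10, F3 = 12, F4 = 12, Test = 12)
  freeze_drop <- effect_size * freezing_noise_sd # seconds off the test mean
  mult_bep <- max(0, 1 - freeze_drop / curve[["Test"]])
  n_fr <- 2 * n_per_group
  sucrose <- rep(c(TRUE, FALSE), each = n_per_group)
  fr_bep <- gen_freezing(n_fr, curve, sucrose_effect = mult_bep,
                         sucrose_group = sucrose,
                         noise_sd = freezing_noise_sd)
  fr_bep$freezing$rat_id <- paste0("bep_", fr_bep$freezing$rat_id)
  nf <- normalized_freezing(fr_bep$freezing)
  sucrose_ids <- paste0("bep_", names(fr_bep$truth$sucrose_group))[sucrose]
  c3_a <- mean(nf$baseline_ratio[nf$rat_id %in% sucrose_ids])
  c3_b <- mean(nf$baseline_ratio[!nf$rat_id %in% sucrose_ids])

  out <- tibble::tibble(
    contrast = c("appetitive_intake", "cs_suppression_ber",
                 "sucrose_anxiolysis_bep"),
    mean_a = c(c1_a, c2_a, c3_a),
    mean_b = c(c1_b, c2_b, c3_b),
    difference = .data$mean_a - .data$mean_b,
    expected_sign = c(1, -1, -1)
  )
  out$sign_correct <- sign(out$difference) == out$expected_sign
  out
}

#' Directional reproduction rate over replicate experiments
#'
#' Replicates [simulate_conflict_experiment()] and reports how often all
#' three planted contrasts come out with their expected signs.
#'
#' @param n_reps Number of replicate experiments (default 100).
#' @param seed Integer seed (replicate seeds are derived from it).
#' @inheritParams simulate_conflict_experiment
#' @return A list with `rate` (fraction of replicates with all signs
#'   correct), `per_contrast` (per-contrast sign-correct rates) and
#'   `n_reps`.
#' @export
directional_reproduction <- function(n_reps = 100, n_per_group = 12,
                                     effect_size = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  res <- purrr::map(seeds, function(s) {
    simulate_conflict_experiment(
      n_per_group = n_per_group, effect_size = effect_size, seed = s
    )
  })
  all_ok <- vapply(res, function(r) all(r$sign_correct), logical(1))
  per <- dplyr::bind_rows(res) |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(rate = mean(.data$sign_correct), .groups = "drop")
  list(rate = mean(all_ok), per_contrast = per, n_reps = n_reps)
}
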