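# truncated-normal draws by rejection; bounds are strict
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    x <- rep(mean, n)
    if (any(x <= lower | x >= upper)) {
      bt_abort("Degenerate truncated normal outside its bounds.", "bad_argument")
    }
    return(x)
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lower & draw < upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Parameters for the synthetic lick-train generator
#'
#' Describes a two-timescale renewal process for licking: clusters of
#' rapid licks (within-cluster inter-lick intervals well below the 0.5 s
#' segmentation threshold) separated by pauses of at least `pause_min`
#' seconds. The constraints `within_ili_mean + 3 * within_ili_sd < 0.5` and
#' `pause_min >= 0.5` guarantee that the generated ground-truth clusters are
#' exactly what the segmenter should recover, making recovery tests exact.
#'
#' @param mean_cluster_licks Expected licks per cluster (>= 3; the count is
#'   `3 + Poisson(mean_cluster_licks - 3)`).
#' @param within_ili_mean,within_ili_sd Within-cluster inter-lick interval
#'   distribution (truncated normal on `(0, 0.5)` seconds).
#' @param pause_min Minimum inter-cluster pause, seconds (>= 0.5).
#' @param pause_mean_excess Mean of the exponential pause excess above
#'   `pause_min`; `1 / (pause_min + pause_mean_excess)` is the cluster rate
#'   during active drinking, per second of non-licking time.
#' @param latency_mean Mean first-cluster latency, seconds (exponential).
#' @param tone_suppression Multiplier in `[0, 1]` applied to the cluster
#'   initiation rate inside tone epochs (0 = complete suppression by the
#'   conditioned stimulus, 1 = no effect).
#' @param session_duration Session length, seconds.
#' @return A validated list of class `lick_gen_params`.
#' @export
lick_gen_params <- function(mean_cluster_licks = 6,
                            within_ili_mean = 0.15,
                            within_ili_sd = 0.04,
                            pause_min = 0.5,
                            pause_mean_excess = 5,
                            latency_mean = 30,
                            tone_suppression = 1,
                            session_duration = 900) {
  check_number(mean_cluster_licks, "mean_cluster_licks", 3)
  check_number(within_ili_mean, "within_ili_mean", 0, strict_min = TRUE)
  check_number(within_ili_sd, "within_ili_sd", 0)
  check_number(pause_mean_excess, "pause_mean_excess", 0, strict_min = TRUE)
  check_number(latency_mean, "latency_mean", 0, strict_min = TRUE)
  check_number(session_duration, "session_duration", 0, strict_min = TRUE)
  if (!is.numeric(tone_suppression) || tone_suppression < 0 || tone_suppression > 1) {
    bt_abort("`tone_suppression` must lie in [0, 1].", "bad_argument")
  }
  if (within_ili_mean + 3 * within_ili_sd >= 0.5) {
    bt_abort(
      "Infeasible: within_ili_mean + 3 * within_ili_sd must stay below 0.5 s, or clusters would self-split.",
      "infeasible_params"
    )
  }
  if (pause_min < 0.5) {
    bt_abort("Infeasible: pause_min must be >= 0.5 s so pauses split clusters.",
             "infeasible_params")
  }
  structure(
    list(
      mean_cluster_licks = mean_cluster_licks,
      within_ili_mean = within_ili_mean,
      within_ili_sd = within_ili_sd,
      pause_min = pause_min,
      pause_mean_excess = pause_mean_excess,
      latency_mean = latency_mean,
      tone_suppression = tone_suppression,
      session_duration = session_duration
    ),
    class = "lick_gen_params"
  )
}

#' Generate a synthetic lick train with ground truth
#'
#' Simulates one session of licking as a renewal process: cluster onsets
#' separated by exponential-excess pauses (rate thinned by
#' `tone_suppression` inside the design's tone epochs), within-cluster lick
#' counts `3 + Poisson`, within-cluster inter-lick intervals truncated-normal
#' below 0.5 s. The generated clusters are returned as ground truth; under
#' the parameter invariants they coincide exactly with what
#' [segment_clusters()] finds.
#'
#' @param params A [lick_gen_params()] object.
#' @param design A [fc_design()] (its `session_duration` must match
#'   `params$session_duration`). Defaults to a tone-free session.
#' @param rat_id,session_id Labels for the output.
#' @param seed Integer seed; the same seed reproduces the train exactly.
#' @return A list with `licks` (tibble `rat_id, session_id, timestamp_s`)
#'   and `truth` (tibble of generated clusters: `start, end, n_licks,
#'   duration`).
#' @export
gen_lick_train <- function(params, design = NULL, rat_id = "r1",
                           session_id = "s1", seed = NULL) {
  stopifnot(inherits(params, "lick_gen_params"))
  if (is.null(design)) {
    design <- fc_design(n_tones = 0, session_duration = params$session_duration)
  }
  if (!isTRUE(all.equal(design$session_duration, params$session_duration))) {
    bt_abort("Design and params disagree on session_duration.", "duration_mismatch")
  }
  if (!is.null(seed)) set.seed(seed)
  part <- epoch_partition(design)
  in_tone <- function(t) {
    i <- findInterval(t, part$start)
    i >= 1 && i <= nrow(part) && part$phase[i] == "tone" && t < part$end[i]
  }
  dur <- params$session_duration
  ts <- numeric(0)
  truth <- list()
  t_now <- rexp(1, rate = 1 / params$latency_mean)
  repeat {
    if (t_now >= dur) break
    # thin candidate onsets inside tones to rate * tone_suppression
    if (in_tone(t_now) && runif(1) > params$tone_suppression) {
      t_now <- t_now + params$pause_min +
        rexp(1, rate = 1 / params$pause_mean_excess)
      next
    }
    n_licks <- 3L + rpois(1, params$mean_cluster_licks - 3)
    ilis <- rtruncnorm(n_licks - 1L, params$within_ili_mean,
                       params$within_ili_sd, lower = 0, upper = 0.5)
    lick_times <- t_now + c(0, cumsum(ilis))
    if (lick_times[n_licks] > dur) break # drop a cluster that would overrun
    ts <- c(ts, lick_times)
    truth[[length(truth) + 1L]] <- tibble::tibble(
      start = lick_times[1], end = lick_times[n_licks],
      n_licks = n_licks, duration = lick_times[n_licks] - lick_times[1]
    )
    t_now <- lick_times[n_licks] + params$pause_min +
      rexp(1, rate = 1 / params$pause_mean_excess)
  }
  list(
    licks = tibble::tibble(
      rat_id = rat_id, session_id = session_id, timestamp_s = ts
    ),
    truth = if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
      start = numeric(0), end = numeric(0), n_licks = integer(0),
      duration = numeric(0)
    )
  )
}

#' Generate a synthetic binge-eating cohort
#'
#' Draws per-rat, per-session sucrose intakes from phenotype-specific
#' truncated normals (at 0 g). The cohort is composed of a fraction `p_bep`
#' of binge-eating-prone rats, a fraction `p_intermediate` of
#' intermediate-intake rats, and resistant rats for the remainder (fractions
#' are deterministic counts, rounded; phenotype order is shuffled). Stress
#' sessions add a phenotype-specific additive effect (conventionally
#' positive for prone rats and zero for resistant rats, mirroring the
#' stress-escalation structure such cohorts are built to detect).
#'
#' Because the tertile rule is rank-based, the high and low tertiles can
#' each hold only a third of the cohort: recovery of planted extremes is
#' only achievable when the planted prone/resistant fractions do not exceed
#' a third each, which is what an intermediate population provides.
#'
#' @param n_rats Cohort size.
#' @param p_bep Fraction of binge-eating-prone rats.
#' @param p_intermediate Fraction of intermediate-intake rats (default 0).
#' @param bep_intake_mean,bep_intake_sd,ber_intake_mean,ber_intake_sd
#'   Baseline intake distributions, grams.
#' @param int_intake_mean,int_intake_sd Intermediate-population intake
#'   distribution; defaults to the midpoint of the prone/resistant means and
#'   the mean of their SDs.
#' @param stress_effect_bep,stress_effect_ber Additive grams in stress
#'   sessions (the intermediate population gets their average).
#' @param n_no_stress,n_stress Number of no-stress / stress sessions
#'   (default 3 and 3, labeled `N1..` and `S1..`).
#' @param body_weight_mean,body_weight_sd Body weight distribution, grams.
#' @param seed Integer seed.
#' @return A list with `intakes` (tibble `rat_id, session_id, session_kind,
#'   condition, grams, body_weight_g, sucrose_access`) and `truth` (tibble
#'   `rat_id, phenotype` with phenotype `BEP`/`INT`/`BER`).
#' @export
gen_cohort <- function(n_rats = 30, p_bep = 0.5, p_intermediate = 0,
                       bep_intake_mean = 18, bep_intake_sd = 2,
                       ber_intake_mean = 8, ber_intake_sd = 2,
                       int_intake_mean = NULL, int_intake_sd = NULL,
                       stress_effect_bep = 4, stress_effect_ber = 0,
                       n_no_stress = 3, n_stress = 3,
                       body_weight_mean = 300, body_weight_sd = 15,
                       seed = NULL) {
  if (!is.numeric(p_bep) || p_bep < 0 || p_bep > 1 ||
      !is.numeric(p_intermediate) || p_intermediate < 0 ||
      p_bep + p_intermediate > 1) {
    bt_abort("`p_bep` and `p_intermediate` must be fractions summing to <= 1.",
             "bad_argument")
  }
  check_number(n_rats, "n_rats", 3)
  check_number(bep_intake_mean, "bep_intake_mean", 0, strict_min = TRUE)
  check_number(ber_intake_mean, "ber_intake_mean", 0, strict_min = TRUE)
  check_number(bep_intake_sd, "bep_intake_sd", 0)
  check_number(ber_intake_sd, "ber_intake_sd", 0)
  int_intake_mean <- int_intake_mean %||% (bep_intake_mean + ber_intake_mean) / 2
  int_intake_sd <- int_intake_sd %||% (bep_intake_sd + ber_intake_sd) / 2
  if (!is.null(seed)) set.seed(seed)
  rat_ids <- sprintf("rat%03d", seq_len(n_rats))
  n_bep <- round(n_rats * p_bep)
  n_int <- round(n_rats * p_intermediate)
  pheno <- sample(c(rep("BEP", n_bep), rep("INT", n_int),
                    rep("BER", n_rats - n_bep - n_int)))
  weights <- rtruncnorm(n_rats, body_weight_mean, body_weight_sd, lower = 0)
  sessions <- c(
    if (n_no_stress > 0) sprintf("N%d", seq_len(n_no_stress)),
    if (n_stress > 0) sprintf("S%d", seq_len(n_stress))
  )
  kinds <- c(rep("no_stress", n_no_stress), rep("stress", n_stress))
  rows <- purrr::map(seq_len(n_rats), function(i) {
    mu <- switch(pheno[i], BEP = bep_intake_mean, INT = int_intake_mean,
                 BER = ber_intake_mean)
    sdv <- switch(pheno[i], BEP = bep_intake_sd, INT = int_intake_sd,
                  BER = ber_intake_sd)
    eff <- switch(pheno[i], BEP = stress_effect_bep,
                  INT = (stress_effect_bep + stress_effect_ber) / 2,
                  BER = stress_effect_ber)
    grams <- vapply(seq_along(sessions), function(s) {
      m <- mu + if (kinds[s] == "stress") eff else 0
      rtruncnorm(1, m, sdv, lower = 0)
    }, numeric(1))
    tibble::tibble(
      rat_id = rat_ids[i], session_id = sessions,
      session_kind = kinds, condition = NA_character_,
      grams = grams, body_weight_g = weights[i], sucrose_access = TRUE
    )
  })
  list(
    intakes = dplyr::bind_rows(rows),
    truth = tibble::tibble(rat_id = rat_ids, phenotype = pheno)
  )
}

#' Generate synthetic freezing annotations
#'
#' Simulates per-tone freezing seconds across conditioning sessions and the
#' test session: per-tone freezing is the session's acquisition-curve mean,
#' multiplied by `sucrose_effect` for sucrose-access rats in the test
#' session, plus truncated Gaussian noise, clipped to `[0, tone_duration]`.
#'
#' @param n_rats Number of rats.
#' @param acquisition_curve Named numeric vector of per-session mean
#'   freezing seconds (names are session ids, e.g. `F1..F4, Test`); all
#'   values in `[0, tone_duration]`.
#' @param sucrose_effect Multiplier applied in the test session for rats in
#'   the sucrose group (< 1 = sucrose reduces freezing).
#' @param sucrose_group Logical vector (length `n_rats`) marking
#'   sucrose-access rats; default none.
#' @param noise_sd Per-tone Gaussian noise SD, seconds.
#' @param n_tones Tones per session (default 6).
#' @param tone_duration Tone length, seconds (default 20).
#' @param test_session Name of the test session in the curve (default
#'   `"Test"`).
#' @param seed Integer seed.
#' @return A list with `freezing` (tibble `rat_id, session_id, tone_index,
#'   freezing_s`) and `truth` (list of the planted curve and effect).
#' @export
gen_freezing <- function(n_rats, acquisition_curve, sucrose_effect = 1,
                         sucrose_group = rep(FALSE, n_rats), noise_sd = 1.5,
                         n_tones = 6, tone_duration = 20,
                         test_session = "Test", seed = NULL) {
  if (is.null(names(acquisition_curve))) {
    bt_abort("`acquisition_curve` must be a named vector of sessions.",
             "bad_argument")
  }
  if (any(acquisition_curve < 0 | acquisition_curve > tone_duration)) {
    bt_abort(sprintf(
      "Acquisition curve values must lie in [0, %g].", tone_duration
    ), "out_of_bounds")
  }
  if (length(sucrose_group) != n_rats) {
    bt_abort("`sucrose_group` must have one entry per rat.", "bad_argument")
  }
  check_number(noise_sd, "noise_sd", 0)
  if (!is.null(seed)) set.seed(seed)
  rat_ids <- sprintf("rat%03d", seq_len(n_rats))
  rows <- purrr::map(seq_len(n_rats), function(i) {
    purrr::map(names(acquisition_curve), function(sess) {
      m <- acquisition_curve[[sess]]
      if (sess == test_session && sucrose_group[i]) m <- m * sucrose_effect
      v <- m + if (noise_sd > 0) rnorm(n_tones, 0, noise_sd) else 0
      v <- pmin(pmax(v, 0), tone_duration)
      tibble::tibble(
        rat_id = rat_ids[i], session_id = sess,
        tone_index = seq_len(n_tones), freezing_s = v
      )
    }) |> dplyr::bind_rows()
  })
  list(
    freezing = dplyr::bind_rows(rows),
    truth = list(
      acquisition_curve = acquisition_curve,
      sucrose_effect = sucrose_effect,
      sucrose_group = setNames(sucrose_group, rat_ids)
    )
  )
}

#' Generate a synthetic grain-noise dark-field image
#'
#' Emulates the pixel statistics of a dark-field emulsion autoradiograph:
#' independent per-pixel grain counts, Poisson with density
#' `background_density` outside the ROI polygon and `signal_density` inside,
#' scaled by `grain_intensity` and clipped to the bit depth. The expected
#' background-corrected optical density of the ROI is
#' `(signal_density - background_density) * grain_intensity`.
#'
#' @param width,height Image size in pixels.
#' @param background_density,signal_density Mean grains per pixel (>= 0).
#' @param roi_polygon Two-column vertex matrix (x, y in pixel units), inside
#'   the image.
#' @param grain_intensity Gray-value increment per grain.
#' @param bit_depth Bits per pixel (default 8; intensities clip at
#'   `2^bit_depth - 1`).
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix), and `truth` (list of the
#'   planted densities and the expected corrected OD).
#' @export
gen_grain_image <- function(width = 120, height = 120,
                            background_density = 0.5, signal_density = 2,
                            roi_polygon, grain_intensity = 20,
                            bit_depth = 8, seed = NULL) {
  check_number(background_density, "background_density", 0)
  check_number(signal_density, "signal_density", 0)
  check_number(grain_intensity, "grain_intensity", 0, strict_min = TRUE)
  if (!is.matrix(roi_polygon) || ncol(roi_polygon) != 2 || nrow(roi_polygon) < 3) {
    bt_abort("`roi_polygon` must be a >= 3-vertex two-column matrix.", "bad_polygon")
  }
  if (any(roi_polygon[, 1] < 0 | roi_polygon[, 1] > width |
          roi_polygon[, 2] < 0 | roi_polygon[, 2] > height)) {
    bt_abort("ROI polygon extends outside the image.", "outside_image")
  }
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(rpois(width * height, background_density), height, width)
  mask <- polygon_pixel_mask(matrix(0, height, width), roi_polygon)
  img[mask] <- rpois(sum(mask), signal_density)
  img <- pmin(img * grain_intensity, 2^bit_depth - 1)
  list(
    image = img,
    truth = list(
      background_density = background_density,
      signal_density = signal_density,
      grain_intensity = grain_intensity,
      expected_corrected_od =
        (signal_density - background_density) * grain_intensity
    )
  )
}

#' Write a grain image to a grayscale TIFF
#'
#' @param image Numeric matrix of intensities.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_grayscale_image <- function(image, path, bit_depth = 8) {
  if (!bit_depth %in% c(8, 16)) {
    bt_abort("`bit_depth` must be 8 or 16.", "bad_argument")
  }
  tiff::writeTIFF(image / (2^bit_depth - 1), path, bits.per.sample = bit_depth)
  invisible(path)
}
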