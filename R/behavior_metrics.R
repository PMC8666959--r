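#' Body-weight-normalized intake energy
#'
#' Converts grams of consumed sucrose solution to kcal per kg body weight.
#' The defaults assume a 10% sucrose solution (0.4 kcal/ml) and a solution
#' density of 1.0 g/ml, i.e. grams are read as ml; a 10% solution is really
#' about 1.04 g/ml, so the density is configurable.
#'
#' @param grams Grams consumed (vectorized, `>= 0`).
#' @param body_weight_g Body weight in grams (`> 0`).
#' @param energy_density Energy density of the solution, kcal/ml
#'   (default 0.4).
#' @param solution_density Solution density, g/ml (default 1.0).
#' @return kcal per kg body weight.
#' @examples
#' intake_energy(15, 300) # 20 kcal/kg
#' @export
intake_energy <- function(grams, body_weight_g, energy_density = 0.4,
                          solution_density = 1.0) {
  if (any(!is.finite(grams) | grams < 0)) {
    bt_abort("`grams` must be finite and >= 0.", "bad_argument")
  }
  if (any(!is.finite(body_weight_g) | body_weight_g <= 0)) {
    bt_abort("`body_weight_g` must be finite and > 0.", "bad_argument")
  }
  check_number(energy_density, "energy_density", 0, strict_min = TRUE)
  check_number(solution_density, "solution_density", 0, strict_min = TRUE)
  grams / solution_density * energy_density / (body_weight_g / 1000)
}

#' Normalize a test value to a baseline mean
#'
#' Divides a test-session value by the arithmetic mean of its baseline
#' values (e.g. test-session intake over the mean appetitive-session intake,
#' or test-session freezing over the mean of the last training sessions).
#' The baseline mean itself maps onto exactly 1.0. A zero baseline mean
#' gives `NA` with a warning rather than an infinity.
#'
#' @param test_value Test-session value (vectorized).
#' @param baseline_values Numeric vector of baseline values (non-empty).
#' @return `test_value / mean(baseline_values)`, or `NA` when the baseline
#'   mean is zero.
#' @examples
#' normalize_to_baseline(12, c(10, 10, 10)) # 1.2
#' @export
normalize_to_baseline <- function(test_value, baseline_values) {
  if (length(baseline_values) == 0) {
    bt_abort("`baseline_values` must be non-empty.", "bad_argument")
  }
  if (any(!is.finite(baseline_values))) {
    bt_abort("`baseline_values` must be finite.", "bad_argument")
  }
  m <- mean(baseline_values)
  if (m == 0) {
    bt_warn("Baseline mean is zero; ratio is undefined (NA).", "zero_baseline")
    return(rep(NA_real_, length(test_value)))
  }
  test_value / m
}

#' Per-session freezing score
#'
#' The fear readout of a session is the mean freezing time over its tones.
#'
#' @param freezing A data frame with `rat_id`, `session_id`, `freezing_s`
#'   (one row per tone), or a bare numeric vector of per-tone seconds.
#' @param n_tones Expected tones per session (default 6).
#' @param tone_duration Upper bound for per-tone freezing, seconds
#'   (default 20).
#' @return For a data frame: a tibble `rat_id, session_id, freezing_score`.
#'   For a vector: the mean as a number.
#' @examples
#' freezing_score(c(2, 4, 6, 8, 10, 12)) # 7
#' @export
freezing_score <- function(freezing, n_tones = 6, tone_duration = 20) {
  score_one <- function(v) {
    if (length(v) != n_tones) {
      bt_abort(sprintf(
        "Expected exactly %d per-tone values, got %d.", n_tones, length(v)
      ), "bad_value")
    }
    if (any(!is.finite(v) | v < 0 | v > tone_duration)) {
      bt_abort(sprintf(
        "Per-tone freezing must lie in [0, %g].", tone_duration
      ), "out_of_bounds")
    }
    mean(v)
  }
  if (is.numeric(freezing)) return(score_one(freezing))
  if (!is.data.frame(freezing) ||
      !all(c("rat_id", "session_id", "freezing_s") %in% names(freezing))) {
    bt_abort(
      "`freezing` must be numeric or contain rat_id, session_id, freezing_s.",
      "bad_argument"
    )
  }
  freezing |>
    dplyr::group_by(.data$rat_id, .data$session_id) |>
    dplyr::summarise(
      freezing_score = score_one(.data$freezing_s), .groups = "drop"
    )
}

#' Baseline-normalized intake for a test session
#'
#' Computes kcal/kg intake for every session and, per rat, the ratio of the
#' test-session intake to the mean over the appetitive (baseline) sessions.
#'
#' @param intakes Intake table with `rat_id`, `session_id`, `grams`,
#'   `body_weight_g` (see [read_intake_log()]).
#' @param appetitive_sessions Session ids forming the baseline.
#' @param test_session Session id of the test session.
#' @inheritParams intake_energy
#' @return A tibble `rat_id, energy_per_kg (test), baseline_mean,
#'   baseline_ratio`; rats missing the test session or every baseline
#'   session are dropped with a warning.
#' @export
normalized_intake <- function(intakes, appetitive_sessions, test_session,
                              energy_density = 0.4, solution_density = 1.0) {
  need <- c("rat_id", "session_id", "grams", "body_weight_g")
  if (!is.data.frame(intakes) || !all(need %in% names(intakes))) {
    bt_abort("`intakes` must contain rat_id, session_id, grams, body_weight_g.",
             "bad_argument")
  }
  df <- tibble::as_tibble(intakes)
  df$energy_per_kg <- intake_energy(df$grams, df$body_weight_g,
                                    energy_density, solution_density)
  base <- df[df$session_id %in% appetitive_sessions, ] |>
    dplyr::group_by(.data$rat_id) |>
    dplyr::summarise(baseline_mean = mean(.data$energy_per_kg), .groups = "drop")
  test <- df[df$session_id == test_session,
             c("rat_id", "energy_per_kg")]
  out <- dplyr::inner_join(test, base, by = "rat_id")
  dropped <- setdiff(unique(df$rat_id), out$rat_id)
  if (length(dropped)) {
    bt_warn(sprintf(
      "Dropping %d rat(s) without both test and baseline sessions: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ), "missing_sessions")
  }
  zero <- out$baseline_mean == 0
  if (any(zero)) {
    bt_warn("Zero appetitive baseline for some rats; their ratio is NA.",
            "zero_baseline")
  }
  out$baseline_ratio <- ifelse(zero, NA_real_, out$energy_per_kg / out$baseline_mean)
  out
}

#' Baseline-normalized freezing for a test session
#'
#' Scores every session by mean freezing over tones and, per rat, divides
#' the test-session score by the mean score over the reference training
#' sessions (conventionally the last three conditioning sessions, F2-F4).
#'
#' @param freezing Per-tone freezing table (see [read_freezing_log()]).
#' @param training_sessions Session ids of the reference conditioning
#'   sessions (default `c("F2", "F3", "F4")`).
#' @param test_session Session id of the test session (default `"Test"`).
#' @inheritParams freezing_score
#' @return A tibble `rat_id, freezing_score (test), baseline_mean,
#'   baseline_ratio`.
#' @export
normalized_freezing <- function(freezing, training_sessions = c("F2", "F3", "F4"),
                                test_session = "Test", n_tones = 6,
                                tone_duration = 20) {
  scores <- freezing_score(freezing, n_tones, tone_duration)
  base <- scores[scores$session_id %in% training_sessions, ] |>
    dplyr::group_by(.data$rat_id) |>
    dplyr::summarise(baseline_mean = mean(.data$freezing_score), .groups = "drop")
  test <- scores[scores$session_id == test_session,
                 c("rat_id", "freezing_score")]
  out <- dplyr::inner_join(test, base, by = "rat_id")
  zero <- out$baseline_mean == 0
  if (any(zero)) {
    bt_warn("Zero training baseline for some rats; their ratio is NA.",
            "zero_baseline")
  }
  out$baseline_ratio <- ifelse(zero, NA_real_,
                               out$freezing_score / out$baseline_mean)
  out
}
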