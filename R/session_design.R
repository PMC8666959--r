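#' Build a fear-conditioning session design
#'
#' Constructs the tone/shock timeline of a fear-conditioning session. The
#' defaults reproduce the standard schedule used with this paradigm: a 15-min
#' (900 s) session in which the first 20-s tone starts 20 s after session
#' onset and six tones are separated by 125-s no-stimulus periods. In
#' conditioning sessions a foot shock occupies the last second of each tone.
#'
#' Tone onsets are `first_tone_delay + k * (tone_duration +
#' inter_tone_interval)` for `k = 0, ..., n_tones - 1`. All intervals are
#' half-open `[start, end)` in 0-based session time, so an event at a tone's
#' exact onset belongs to the tone.
#'
#' @param n_tones Number of tones (default 6). `0` gives a tone-free session.
#' @param first_tone_delay Seconds from session start to the first tone onset.
#' @param tone_duration Tone length in seconds.
#' @param inter_tone_interval No-stimulus gap between consecutive tones,
#'   seconds.
#' @param session_duration Total session length in seconds.
#' @param with_shock If `TRUE`, place a shock interval inside each tone
#'   (conditioning sessions).
#' @param shock_duration Shock length in seconds (default 1).
#' @param shock_offset_within_tone Seconds from tone onset to shock onset
#'   (default 19, i.e. the last second of a 20-s tone).
#'
#' @return An object of class `session_design`: a list with fields
#'   `session_duration`, `tone_onsets`, `tone_duration`,
#'   `inter_tone_interval`, `first_tone_delay`, `with_shock`,
#'   `shock_duration`, `shock_offset_within_tone`.
#' @examples
#' des <- fc_design()
#' des$tone_onsets # 20 165 310 455 600 745
#' epoch_partition(des)
#' @export
fc_design <- function(n_tones = 6,
                      first_tone_delay = 20,
                      tone_duration = 20,
                      inter_tone_interval = 125,
                      session_duration = 900,
                      with_shock = FALSE,
                      shock_duration = 1,
                      shock_offset_within_tone = 19) {
  if (!is.numeric(n_tones) || length(n_tones) != 1L || n_tones < 0 ||
      n_tones != round(n_tones)) {
    bt_abort("`n_tones` must be a single non-negative integer.", "bad_argument")
  }
  check_number(session_duration, "session_duration", 0, strict_min = TRUE)
  check_number(first_tone_delay, "first_tone_delay", 0)
  if (n_tones > 0) {
    check_number(tone_duration, "tone_duration", 0, strict_min = TRUE)
    check_number(inter_tone_interval, "inter_tone_interval", 0, strict_min = TRUE)
  }
  onsets <- if (n_tones > 0) {
    first_tone_delay + (seq_len(n_tones) - 1) * (tone_duration + inter_tone_interval)
  } else {
    numeric(0)
  }
  if (n_tones > 0) {
    last_off <- onsets[n_tones] + tone_duration
    if (last_off > session_duration) {
      bt_abort(sprintf(
        "Tone schedule overruns the session by %g s (last tone ends at %g s, session is %g s).",
        last_off - session_duration, last_off, session_duration
      ), "schedule_overrun")
    }
  }
  if (isTRUE(with_shock) && n_tones > 0) {
    check_number(shock_duration, "shock_duration", 0, strict_min = TRUE)
    check_number(shock_offset_within_tone, "shock_offset_within_tone", 0)
    if (shock_offset_within_tone + shock_duration > tone_duration) {
      bt_abort("Shock interval must lie within its tone.", "bad_argument")
    }
  }
  structure(
    list(
      session_duration = session_duration,
      tone_onsets = onsets,
      tone_duration = tone_duration,
      inter_tone_interval = inter_tone_interval,
      first_tone_delay = first_tone_delay,
      with_shock = isTRUE(with_shock),
      shock_duration = shock_duration,
      shock_offset_within_tone = shock_offset_within_tone
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf(
    "<session_design> %g s, %d tone(s) of %g s%s\n",
    x$session_duration, length(x$tone_onsets), x$tone_duration,
    if (x$with_shock) sprintf(", shock in last %g s of each tone", x$shock_duration) else ""
  ))
  if (length(x$tone_onsets)) {
    cat("tone onsets:", paste(x$tone_onsets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partition a session into labeled epochs
#'
#' Splits `[0, session_duration)` into alternating half-open intervals:
#' `pre_tone` before the first tone, `tone_k` / `between_k` alternating, and
#' `post_tone` after the last tone offset. The intervals are pairwise disjoint
#' and cover the session exactly once.
#'
#' @param design A [fc_design()] object.
#' @return A tibble with columns `epoch` (label), `phase` (`tone`, `between`,
#'   or `tail` for pre/post), `start`, `end` (seconds, half-open).
#' @examples
#' epoch_partition(fc_design())
#' @export
epoch_partition <- function(design) {
  stopifnot(inherits(design, "session_design"))
  dur <- design$session_duration
  on <- design$tone_onsets
  n <- length(on)
  if (n == 0) {
    return(tibble::tibble(
      epoch = "pre_tone", phase = "tail", start = 0, end = dur
    ))
  }
  td <- design$tone_duration
  rows <- list(tibble::tibble(epoch = "pre_tone", phase = "tail", start = 0, end = on[1]))
  for (k in seq_len(n)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      epoch = sprintf("tone_%d", k), phase = "tone",
      start = on[k], end = on[k] + td
    )
    if (k < n) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        epoch = sprintf("between_%d", k), phase = "between",
        start = on[k] + td, end = on[k + 1]
      )
    }
  }
  if (on[n] + td < dur) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      epoch = "post_tone", phase = "tail", start = on[n] + td, end = dur
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::filter(out, .data$end > .data$start)
}

#' Assign lick events to session epochs
#'
#' Labels every lick with the epoch whose half-open interval contains it. An
#' event at exactly `session_duration` (a closed upper session bound) is
#' assigned to the final epoch.
#'
#' @param licks A data frame with a `timestamp_s` column (plus any id
#'   columns, which are preserved).
#' @param design A [fc_design()] object.
#' @param session_duration Session length of the lick train; must equal
#'   `design$session_duration`.
#' @return The input as a tibble with `epoch` and `phase` columns appended.
#' @examples
#' licks <- tibble::tibble(timestamp_s = c(25, 40, 800))
#' assign_epochs(licks, fc_design())
#' @export
assign_epochs <- function(licks, design, session_duration = design$session_duration) {
  stopifnot(inherits(design, "session_design"))
  if (!is.data.frame(licks) || !"timestamp_s" %in% names(licks)) {
    bt_abort("`licks` must be a data frame with a `timestamp_s` column.", "bad_argument")
  }
  if (!isTRUE(all.equal(session_duration, design$session_duration))) {
    bt_abort(sprintf(
      "Session duration mismatch: lick train is %g s, design is %g s.",
      session_duration, design$session_duration
    ), "duration_mismatch")
  }
  part <- epoch_partition(design)
  licks <- tibble::as_tibble(licks)
  if (nrow(licks) == 0) {
    licks$epoch <- character(0)
    licks$phase <- character(0)
    return(licks)
  }
  ts <- licks$timestamp_s
  if (any(ts < 0 | ts > design$session_duration)) {
    bt_abort("Lick timestamps fall outside [0, session_duration].", "out_of_bounds")
  }
  idx <- findInterval(ts, part$start)
  idx[ts >= design$session_duration] <- nrow(part)
  licks$epoch <- part$epoch[idx]
  licks$phase <- part$phase[idx]
  licks
}

#' Serialize / deserialize a session design as JSON
#'
#' @param design A [fc_design()] object.
#' @param path File path to write to / read from.
#' @return `design_to_json()` returns `path` invisibly; `design_from_json()`
#'   returns a `session_design`.
#' @export
design_to_json <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fc_design(
    n_tones = length(x$tone_onsets),
    first_tone_delay = x$first_tone_delay,
    tone_duration = x$tone_duration,
    inter_tone_interval = x$inter_tone_interval,
    session_duration = x$session_duration,
    with_shock = isTRUE(x$with_shock),
    shock_duration = x$shock_duration,
    shock_offset_within_tone = x$shock_offset_within_tone
  )
}
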