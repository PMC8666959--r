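#' Read a lickometer event log
#'
#' Reads a CSV of lick timestamps (`rat_id,session_id,timestamp_s[,spout]`),
#' validates it against the session length, sorts within each rat-session and
#' collapses duplicate timestamps (a physical lick cannot occur twice at one
#' instant) with a warning. Timestamps are seconds from session start,
#' 0-based.
#'
#' @param path Path to the CSV file.
#' @param session_duration Session length in seconds; every timestamp must lie
#'   in `[0, session_duration]`.
#' @param spout Optional spout label (e.g. `"sucrose"`). When given and the
#'   file has a `spout` column, only that spout's licks are kept. Lickometer
#'   rigs often record a second (water) spout; filtering makes its exclusion
#'   explicit.
#' @return A tibble with columns `rat_id`, `session_id`, `timestamp_s`,
#'   sorted by rat, session and time. Empty (header-only) files give an empty
#'   tibble.
#' @export
read_lick_log <- function(path, session_duration, spout = NULL) {
  check_number(session_duration, "session_duration", 0, strict_min = TRUE)
  if (!file.exists(path)) {
    bt_abort(sprintf("Lick log not found: %s", path), "missing_file")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("rat_id", "session_id", "timestamp_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    bt_abort(sprintf(
      "Lick log is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ), "bad_columns")
  }
  if (!is.null(spout)) {
    if ("spout" %in% names(df)) {
      df <- dplyr::filter(df, .data$spout == .env$spout)
    }
  }
  df <- dplyr::select(df, "rat_id", "session_id", "timestamp_s")
  df <- dplyr::mutate(df,
    rat_id = as.character(.data$rat_id),
    session_id = as.character(.data$session_id),
    timestamp_s = as.numeric(.data$timestamp_s)
  )
  bad <- which(!is.finite(df$timestamp_s) | df$timestamp_s < 0 |
                 df$timestamp_s > session_duration)
  if (length(bad)) {
    bt_abort(sprintf(
      "Timestamp outside [0, %g] at data row %d (value %g).",
      session_duration, bad[1], df$timestamp_s[bad[1]]
    ), "out_of_bounds")
  }
  df <- dplyr::arrange(df, .data$rat_id, .data$session_id, .data$timestamp_s)
  n0 <- nrow(df)
  df <- dplyr::distinct(df, .data$rat_id, .data$session_id, .data$timestamp_s)
  if (nrow(df) < n0) {
    bt_warn(sprintf(
      "Collapsed %d duplicate timestamp(s) to single licks.", n0 - nrow(df)
    ), "duplicate_timestamps")
  }
  df
}

# allowed intake session kinds; condition labels only make sense once the
# fear-conditioning group structure exists (test sessions)
.session_kinds <- c("no_stress", "stress", "appetitive", "test")
.conditions <- c("control", "tone", "paired")

#' Read a session intake table
#'
#' Reads a CSV of bottle-weight-derived sucrose consumption
#' (`rat_id,session_id,session_kind,condition,grams,body_weight_g,
#' sucrose_access`). `session_kind` must be one of `no_stress`, `stress`,
#' `appetitive`, `test`; `condition` (`control`/`tone`/`paired`) may only be
#' set for sessions at or after the fear-conditioning stage (`appetitive`,
#' `test`) — phenotyping-stage sessions carry no group assignment.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_intake_log <- function(path) {
  if (!file.exists(path)) {
    bt_abort(sprintf("Intake table not found: %s", path), "missing_file")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("rat_id", "session_id", "session_kind", "grams", "body_weight_g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    bt_abort(sprintf(
      "Intake table is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ), "bad_columns")
  }
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  if (!"sucrose_access" %in% names(df)) df$sucrose_access <- TRUE
  df <- dplyr::mutate(df,
    rat_id = as.character(.data$rat_id),
    session_id = as.character(.data$session_id),
    session_kind = as.character(.data$session_kind),
    condition = as.character(.data$condition),
    grams = as.numeric(.data$grams),
    body_weight_g = as.numeric(.data$body_weight_g),
    sucrose_access = as.logical(.data$sucrose_access)
  )
  bad_kind <- which(!df$session_kind %in% .session_kinds)
  if (length(bad_kind)) {
    bt_abort(sprintf(
      "Unknown session_kind '%s' at data row %d.",
      df$session_kind[bad_kind[1]], bad_kind[1]
    ), "bad_value")
  }
  bad_cond <- which(!is.na(df$condition) & !df$condition %in% .conditions)
  if (length(bad_cond)) {
    bt_abort(sprintf(
      "Unknown condition '%s' at data row %d.",
      df$condition[bad_cond[1]], bad_cond[1]
    ), "bad_value")
  }
  clash <- which(!is.na(df$condition) & df$session_kind %in% c("no_stress", "stress"))
  if (length(clash)) {
    bt_abort(sprintf(
      "Row %d: a '%s' session cannot carry a fear-conditioning condition.",
      clash[1], df$session_kind[clash[1]]
    ), "bad_value")
  }
  bad_g <- which(!is.finite(df$grams) | df$grams < 0)
  if (length(bad_g)) {
    bt_abort(sprintf("grams must be >= 0 (data row %d).", bad_g[1]), "bad_value")
  }
  bad_w <- which(!is.finite(df$body_weight_g) | df$body_weight_g <= 0)
  if (length(bad_w)) {
    bt_abort(sprintf("body_weight_g must be > 0 (data row %d).", bad_w[1]), "bad_value")
  }
  tibble::as_tibble(df)
}

#' Read per-tone freezing annotations
#'
#' Reads a CSV of experimenter-scored freezing seconds per tone
#' (`rat_id,session_id,tone_index,freezing_s`). Each rat-session must carry
#' exactly one value per tone and every value must lie in
#' `[0, tone_duration]`.
#'
#' @param path Path to the CSV file.
#' @param n_tones Expected number of tones per session (default 6).
#' @param tone_duration Tone length in seconds (default 20); upper bound for
#'   freezing values.
#' @return A validated tibble sorted by rat, session, tone.
#' @export
read_freezing_log <- function(path, n_tones = 6, tone_duration = 20) {
  if (!file.exists(path)) {
    bt_abort(sprintf("Freezing table not found: %s", path), "missing_file")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("rat_id", "session_id", "tone_index", "freezing_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    bt_abort(sprintf(
      "Freezing table is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ), "bad_columns")
  }
  df <- dplyr::mutate(df,
    rat_id = as.character(.data$rat_id),
    session_id = as.character(.data$session_id),
    tone_index = as.integer(.data$tone_index),
    freezing_s = as.numeric(.data$freezing_s)
  )
  bad <- which(!is.finite(df$freezing_s) | df$freezing_s < 0 |
                 df$freezing_s > tone_duration)
  if (length(bad)) {
    bt_abort(sprintf(
      "freezing_s outside [0, %g] at data row %d.", tone_duration, bad[1]
    ), "out_of_bounds")
  }
  counts <- dplyr::count(df, .data$rat_id, .data$session_id)
  off <- counts[counts$n != n_tones, ]
  if (nrow(off)) {
    bt_abort(sprintf(
      "Rat %s session %s has %d tone value(s); expected exactly %d.",
      off$rat_id[1], off$session_id[1], off$n[1], n_tones
    ), "bad_value")
  }
  dplyr::arrange(df, .data$rat_id, .data$session_id, .data$tone_index)
}

# signed polygon area by the shoelace formula
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# proper-crossing test for two segments (shared endpoints excluded upstream)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, jmax)) {
      i2 <- i + 1L
      j2 <- if (j == n) 1L else j + 1L
      if (segments_cross(v[i, ], v[i2, ], v[j, ], v[j2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Read a region-of-interest contour file
#'
#' Reads a JSON list of named polygons, each `{name, role, image,
#' vertices: [[x, y], ...]}` with `role` either `"roi"` or `"background"`.
#' Every polygon must have at least 3 vertices, nonzero area and no
#' self-intersection. Each ROI must be accompanied by at least one background
#' contour on the same image; the established densitometry practice is three
#' small background contours per region, so fewer than three draws a warning.
#'
#' @param path Path to the JSON file.
#' @return A tibble with columns `name`, `role`, `image`, and a `vertices`
#'   list-column of two-column matrices.
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) {
    bt_abort(sprintf("ROI file not found: %s", path), "missing_file")
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(raw)) bt_abort("ROI file contains no polygons.", "bad_value")
  rows <- purrr::map(raw, function(p) {
    v <- do.call(rbind, purrr::map(p$vertices, ~ as.numeric(unlist(.x))))
    if (is.null(v) || nrow(v) < 3) {
      bt_abort(sprintf(
        "Polygon '%s' has %d vertices; at least 3 are required.",
        p$name %||% "?", if (is.null(v)) 0L else nrow(v)
      ), "bad_polygon")
    }
    if (ncol(v) != 2 || any(!is.finite(v))) {
      bt_abort(sprintf("Polygon '%s' has malformed vertices.", p$name %||% "?"),
               "bad_polygon")
    }
    if (abs(polygon_area(v)) < .Machine$double.eps * 100) {
      bt_abort(sprintf("Polygon '%s' has zero area.", p$name %||% "?"),
               "bad_polygon")
    }
    if (polygon_self_intersects(v)) {
      bt_abort(sprintf("Polygon '%s' is self-intersecting.", p$name %||% "?"),
               "bad_polygon")
    }
    role <- p$role %||% "roi"
    if (!role %in% c("roi", "background")) {
      bt_abort(sprintf("Polygon '%s' has unknown role '%s'.", p$name %||% "?", role),
               "bad_value")
    }
    tibble::tibble(
      name = as.character(p$name %||% NA_character_),
      role = role,
      image = as.character(p$image %||% NA_character_),
      vertices = list(v)
    )
  })
  out <- dplyr::bind_rows(rows)
  by_img <- split(out, out$image)
  for (img in names(by_img)) {
    sub <- by_img[[img]]
    n_roi <- sum(sub$role == "roi")
    n_bg <- sum(sub$role == "background")
    if (n_roi > 0 && n_bg < 1) {
      bt_abort(sprintf(
        "Image '%s' has ROI contour(s) but no background contour.", img
      ), "missing_background")
    }
    if (n_roi > 0 && n_bg < 3) {
      bt_warn(sprintf(
        "Image '%s' has %d background contour(s); three are customary.", img, n_bg
      ), "few_backgrounds")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table to CSV
#'
#' Writes any result tibble to CSV at full floating-point precision so a
#' read-back reproduces every value to within 1e-9. Refuses to write empty
#' tables (an empty output is more often a pipeline bug than a result).
#'
#' @param records A non-empty data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(records, path) {
  if (!is.data.frame(records)) {
    bt_abort("`records` must be a data frame.", "bad_argument")
  }
  if (nrow(records) == 0) {
    bt_abort("Refusing to write an empty table.", "empty_output")
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
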