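# core one-pass segmenter on a sorted timestamp vector; returns a data frame
# of bursts (>= 1 lick) with keep = burst reaches the cluster minimum
segment_train <- function(ts, threshold, min_licks) {
  n <- length(ts)
  if (n == 0) {
    return(tibble::tibble(
      cluster = integer(0), start = numeric(0), end = numeric(0),
      n_licks = integer(0), duration = numeric(0)
    ))
  }
  # an inter-lick interval of `threshold` or longer separates clusters
  breaks <- if (n > 1) which(diff(ts) >= threshold) else integer(0)
  burst_id <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% breaks)))
  starts <- ts[!duplicated(burst_id)]
  ends <- ts[!duplicated(burst_id, fromLast = TRUE)]
  sizes <- tabulate(burst_id)
  keep <- sizes >= min_licks
  tibble::tibble(
    cluster = seq_len(sum(keep)),
    start = starts[keep],
    end = ends[keep],
    n_licks = sizes[keep],
    duration = ends[keep] - starts[keep]
  )
}

check_cluster_params <- function(threshold, min_licks) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    bt_abort("`threshold` must be a single positive number of seconds.", "bad_argument")
  }
  if (!is.numeric(min_licks) || length(min_licks) != 1L || min_licks < 1 ||
      min_licks != round(min_licks)) {
    bt_abort("`min_licks` must be a positive integer.", "bad_argument")
  }
}

#' Segment lick trains into licking clusters
#'
#' A licking cluster is a burst of `min_licks` (default 3) or more licks whose
#' internal inter-lick intervals are all shorter than `threshold` (default
#' 0.5 s): an interval of 500 ms *or longer* closes the current burst. Bursts
#' below the lick minimum are not clusters, but their licks still count in
#' `total_licks` (see [lick_summary()]).
#'
#' @param licks A data frame with a numeric `timestamp_s` column. If `rat_id`
#'   / `session_id` (or any columns named in `by`) are present, segmentation
#'   runs independently per group.
#' @param threshold Inter-cluster interval in seconds (default 0.5). An
#'   inter-lick interval `>= threshold` splits the burst.
#' @param min_licks Minimum licks per cluster (default 3).
#' @param by Character vector of grouping columns; defaults to whichever of
#'   `rat_id`, `session_id`, `epoch` are present.
#' @return A tibble of clusters with the grouping columns plus `cluster`
#'   (index within group), `start`, `end`, `n_licks`, `duration` (seconds,
#'   last lick minus first lick).
#' @examples
#' licks <- tibble::tibble(timestamp_s = c(1.0, 1.2, 1.4, 2.0, 2.1, 5.0, 5.1, 5.2, 5.3))
#' segment_clusters(licks) # two clusters; the 2-lick burst at 2.0 s is dropped
#' @export
segment_clusters <- function(licks, threshold = 0.5, min_licks = 3, by = NULL) {
  check_cluster_params(threshold, min_licks)
  if (!is.data.frame(licks) || !"timestamp_s" %in% names(licks)) {
    bt_abort("`licks` must be a data frame with a `timestamp_s` column.", "bad_argument")
  }
  by <- by %||% intersect(c("rat_id", "session_id", "epoch"), names(licks))
  licks <- tibble::as_tibble(licks)
  if (length(by) == 0) {
    ts <- sort(licks$timestamp_s)
    return(segment_train(ts, threshold, min_licks))
  }
  licks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::arrange(.data$timestamp_s, .by_group = TRUE) |>
    dplyr::group_modify(~ segment_train(.x$timestamp_s, threshold, min_licks)) |>
    dplyr::ungroup()
}

# six-metric summary for one train given its cluster table
summarize_train <- function(ts, clusters, session_duration = NA_real_) {
  total <- length(ts)
  ncl <- nrow(clusters)
  tibble::tibble(
    total_licks = total,
    n_clusters = ncl,
    cluster_size = if (ncl > 0) mean(clusters$n_licks) else NA_real_,
    cluster_duration = if (ncl > 0) mean(clusters$duration) else NA_real_,
    meal_duration = if (ncl > 0) sum(clusters$duration) else 0,
    first_lick_latency = if (total > 0) min(ts) else NA_real_
  )
}

#' Licking-microstructure summary
#'
#' Computes the six standard licking-microstructure metrics per rat-session:
#' total number of licks, number of clusters, cluster size (mean licks per
#' cluster), cluster duration (mean seconds per cluster), meal duration
#' (summed duration of all clusters), and first lick latency (seconds from
#' session start to the first lick). Metrics that are means over clusters are
#' `NA` — not zero — when there are no clusters, and the latency is `NA` when
#' there are no licks, so downstream group means are not biased by empty
#' sessions.
#'
#' Licks in sub-threshold bursts (1–2 licks) count toward `total_licks` but
#' toward no cluster metric; set `count_stray_licks = FALSE` to restrict
#' `total_licks` to in-cluster licks instead.
#'
#' @inheritParams segment_clusters
#' @param count_stray_licks Count licks from sub-minimum bursts in
#'   `total_licks` (default `TRUE`).
#' @return A tibble with one row per group and the six metric columns.
#' @examples
#' licks <- tibble::tibble(timestamp_s = c(1.0, 1.2, 1.4, 2.0, 2.1, 5.0, 5.1, 5.2, 5.3))
#' lick_summary(licks)
#' @export
lick_summary <- function(licks, threshold = 0.5, min_licks = 3, by = NULL,
                         count_stray_licks = TRUE) {
  check_cluster_params(threshold, min_licks)
  if (!is.data.frame(licks) || !"timestamp_s" %in% names(licks)) {
    bt_abort("`licks` must be a data frame with a `timestamp_s` column.", "bad_argument")
  }
  by <- by %||% intersect(c("rat_id", "session_id", "epoch"), names(licks))
  one <- function(ts) {
    ts <- sort(ts)
    cl <- segment_train(ts, threshold, min_licks)
    out <- summarize_train(ts, cl)
    if (!count_stray_licks) out$total_licks <- sum(cl$n_licks)
    out
  }
  licks <- tibble::as_tibble(licks)
  if (length(by) == 0) {
    return(one(licks$timestamp_s))
  }
  licks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ one(.x$timestamp_s)) |>
    dplyr::ungroup()
}

#' Per-epoch licking-microstructure summaries
#'
#' Assigns licks to session epochs (see [epoch_partition()]) and computes the
#' microstructure summary independently within each epoch: segmentation is
#' epoch-local, so a burst straddling a tone boundary is split into two
#' epoch-local bursts and never bridges epochs. During-tone and between-tone
#' metrics are therefore independently computable.
#'
#' @inheritParams segment_clusters
#' @param design A [fc_design()] object.
#' @param session_duration Session length of the lick trains.
#' @return A tibble with the grouping columns plus `epoch`, `phase`, and the
#'   six metric columns; epochs with no licks appear with `total_licks = 0`.
#' @export
epoch_summaries <- function(licks, design, threshold = 0.5, min_licks = 3,
                            by = NULL, session_duration = design$session_duration) {
  by <- by %||% intersect(c("rat_id", "session_id"), names(licks))
  lab <- assign_epochs(licks, design, session_duration)
  part <- epoch_partition(design)
  summ <- lick_summary(lab, threshold, min_licks, by = c(by, "epoch"))
  # reinstate empty epochs so conservation sums are explicit
  grid <- if (length(by)) {
    dplyr::distinct(lab, dplyr::across(dplyr::all_of(by))) |>
      tidyr::crossing(part[, c("epoch", "phase")])
  } else {
    part[, c("epoch", "phase")]
  }
  out <- dplyr::left_join(grid, summ, by = c(by, "epoch"))
  out$phase <- part$phase[match(out$epoch, part$epoch)]
  out$total_licks[is.na(out$total_licks)] <- 0L
  out$n_clusters[is.na(out$n_clusters)] <- 0L
  out$meal_duration[is.na(out$meal_duration)] <- 0
  out
}

#' Pooled during-tone / between-tone summaries
#'
#' Pools epoch-local clusters into the two aggregates used for tone-aligned
#' analyses: `during_tone` (all tone epochs) and `between_tone` (all
#' inter-tone gaps). The pre-tone and post-tone tails are reported as a
#' separate `tail` phase unless `include_tail = TRUE`, which folds them into
#' `between_tone`.
#'
#' @inheritParams epoch_summaries
#' @param include_tail Fold the pre-tone/post-tone tails into the
#'   between-tone aggregate (default `FALSE`).
#' @return A tibble with one row per group and phase
#'   (`during_tone`, `between_tone`, and `tail` unless folded), with the six
#'   metric columns. Cluster-size and -duration means pool the epoch-local
#'   clusters of the phase; `first_lick_latency` is the earliest lick of the
#'   phase in session time.
#' @export
tone_split_summary <- function(licks, design, threshold = 0.5, min_licks = 3,
                               by = NULL, include_tail = FALSE,
                               session_duration = design$session_duration) {
  by <- by %||% intersect(c("rat_id", "session_id"), names(licks))
  lab <- assign_epochs(licks, design, session_duration)
  phase_of <- function(ph) {
    if (include_tail && ph == "tail") "between_tone"
    else switch(ph, tone = "during_tone", between = "between_tone", tail = "tail")
  }
  lab$pool <- vapply(lab$phase, phase_of, character(1))
  cl <- segment_clusters(lab, threshold, min_licks, by = c(by, "epoch"))
  if (nrow(cl)) {
    part <- epoch_partition(design)
    cl$pool <- vapply(part$phase[match(cl$epoch, part$epoch)], phase_of, character(1))
  } else {
    cl$pool <- character(0)
  }
  pools <- c("during_tone", "between_tone", if (!include_tail) "tail")
  grid <- if (length(by)) {
    dplyr::distinct(tibble::as_tibble(licks), dplyr::across(dplyr::all_of(by))) |>
      tidyr::crossing(phase = pools)
  } else {
    tibble::tibble(phase = pools)
  }
  one <- function(keys, pool) {
    sub <- lab
    clsub <- cl
    if (length(by)) {
      for (b in by) {
        sub <- sub[sub[[b]] == keys[[b]], ]
        clsub <- clsub[clsub[[b]] == keys[[b]], ]
      }
    }
    sub <- sub[sub$pool == pool, ]
    clsub <- clsub[clsub$pool == pool, , drop = FALSE]
    summarize_train(sub$timestamp_s, clsub)
  }
  res <- purrr::pmap(grid, function(...) {
    row <- list(...)
    one(row, row$phase)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
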