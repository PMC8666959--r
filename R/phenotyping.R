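#' Assign per-session intake tertiles
#'
#' Ranks the cohort's intakes within each session and splits it into high,
#' intermediate and low tertiles. The split is rank-based: with `n` rats,
#' `floor(n / 3)` go to the high and low extremes and the remainder to the
#' intermediate tertile (so 7 rats split 2/3/2), keeping the extreme groups
#' strict. Ties at a tertile boundary are broken deterministically by
#' `rat_id` and draw a warning. A value-based alternative (`method =
#' "range"`) splits the intake *range* into equal thirds instead.
#'
#' @param intakes A data frame with columns `rat_id`, `session_id` and the
#'   intake column. Raw grams — not body-weight-normalized intake — are the
#'   conventional classification variable.
#' @param intake_col Name of the intake column (default `"grams"`).
#' @param method `"rank"` (default) or `"range"`.
#' @return A tibble `rat_id, session_id, intake, tertile` with `tertile` a
#'   factor `high`/`intermediate`/`low`; one row per rat per session.
#' @examples
#' x <- tibble::tibble(
#'   rat_id = LETTERS[1:6], session_id = "S1",
#'   grams = c(10, 9, 6, 5, 2, 1)
#' )
#' assign_tertiles(x)
#' @export
assign_tertiles <- function(intakes, intake_col = "grams", method = c("rank", "range")) {
  method <- match.arg(method)
  if (!is.data.frame(intakes) ||
      !all(c("rat_id", "session_id", intake_col) %in% names(intakes))) {
    bt_abort(sprintf(
      "`intakes` must contain rat_id, session_id and '%s' columns.", intake_col
    ), "bad_argument")
  }
  df <- tibble::as_tibble(intakes)
  df$intake <- as.numeric(df[[intake_col]])
  miss <- which(!is.finite(df$intake))
  if (length(miss)) {
    bt_abort(sprintf(
      "Missing intake for rat %s in session %s.",
      df$rat_id[miss[1]], df$session_id[miss[1]]
    ), "missing_value")
  }
  one_session <- function(sub, sess) {
    n <- nrow(sub)
    if (n < 3) {
      bt_abort(sprintf(
        "Session %s has %d rat(s); at least 3 are required for tertiles.",
        sess, n
      ), "too_few_rats")
    }
    if (anyDuplicated(sub$rat_id)) {
      bt_abort(sprintf("Session %s has duplicated rat_id rows.", sess),
               "bad_value")
    }
    if (method == "rank") {
      k <- n %/% 3
      ord <- order(-sub$intake, sub$rat_id)
      tert <- rep("intermediate", n)
      tert[ord[seq_len(k)]] <- "high"
      tert[ord[seq.int(n - k + 1, n)]] <- "low"
      # a tie spanning a cut point means ranking was decided by rat_id
      cuts <- sort(sub$intake, decreasing = TRUE)
      tied <- (k >= 1 && k < n && cuts[k] == cuts[k + 1]) ||
        (k >= 1 && cuts[n - k] == cuts[n - k + 1])
      if (tied) {
        bt_warn(sprintf(
          "Session %s: intake tie at a tertile boundary broken by rat_id.",
          sess
        ), "tertile_tie")
      }
    } else {
      rng <- range(sub$intake)
      if (diff(rng) == 0) {
        bt_warn(sprintf(
          "Session %s: constant intake; all rats assigned intermediate.",
          sess
        ), "tertile_tie")
        tert <- rep("intermediate", n)
      } else {
        br <- rng[1] + diff(rng) * c(1, 2) / 3
        tert <- ifelse(sub$intake > br[2], "high",
                       ifelse(sub$intake <= br[1], "low", "intermediate"))
      }
    }
    sub$tertile <- factor(tert, levels = c("high", "intermediate", "low"))
    sub
  }
  out <- df |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(~ one_session(.x, .y$session_id)) |>
    dplyr::ungroup()
  dplyr::select(out, "rat_id", "session_id", "intake", "tertile")
}

#' Classify binge-eating-prone and -resistant phenotypes
#'
#' Applies the tertile rule over repeated stress-session intakes: a rat in
#' the high tertile at least twice and never in the low tertile is
#' binge-eating prone (`BEP`); a rat in the low tertile at least twice and
#' never in the high tertile is binge-eating resistant (`BER`); every other
#' rat is `unclassified` (labeled, not dropped). Rats missing any included
#' session are excluded with a warning.
#'
#' @param tertiles A tertile table from [assign_tertiles()], covering at
#'   least two sessions.
#' @param min_count Minimum number of extreme-tertile sessions required for a
#'   label (default 2).
#' @return A tibble of class `phenotype_tbl`: `rat_id, label, n_high, n_low,
#'   n_sessions`, with `label` a factor `BEP`/`BER`/`unclassified`. The
#'   per-session tertile table is attached as attribute `"tertiles"`.
#' @examples
#' x <- tidyr::crossing(rat_id = LETTERS[1:6], session_id = c("S1", "S2", "S3"))
#' x$grams <- c(10, 11, 12, 9, 5, 8, 6, 9, 9, 5, 6, 5, 2, 2, 3, 1, 1, 1)
#' classify_phenotype(assign_tertiles(x))
#' @export
classify_phenotype <- function(tertiles, min_count = 2) {
  if (!is.data.frame(tertiles) ||
      !all(c("rat_id", "session_id", "tertile") %in% names(tertiles))) {
    bt_abort("`tertiles` must come from assign_tertiles().", "bad_argument")
  }
  sessions <- unique(tertiles$session_id)
  if (length(sessions) < 2) {
    bt_abort("At least two sessions are required for phenotyping.", "bad_argument")
  }
  counts <- tertiles |>
    dplyr::group_by(.data$rat_id) |>
    dplyr::summarise(
      n_high = sum(.data$tertile == "high"),
      n_low = sum(.data$tertile == "low"),
      n_sessions = dplyr::n(),
      .groups = "drop"
    )
  incomplete <- counts$rat_id[counts$n_sessions < length(sessions)]
  if (length(incomplete)) {
    bt_warn(sprintf(
      "Excluding %d rat(s) with missing sessions: %s",
      length(incomplete), paste(incomplete, collapse = ", ")
    ), "missing_sessions")
    counts <- counts[!counts$rat_id %in% incomplete, ]
  }
  counts$label <- factor(
    ifelse(counts$n_high >= min_count & counts$n_low == 0, "BEP",
           ifelse(counts$n_low >= min_count & counts$n_high == 0, "BER",
                  "unclassified")),
    levels = c("BEP", "BER", "unclassified")
  )
  out <- dplyr::select(counts, "rat_id", "label", "n_high", "n_low", "n_sessions")
  attr(out, "tertiles") <- tertiles
  class(out) <- c("phenotype_tbl", class(out))
  out
}

#' Phenotype a cohort from an intake table
#'
#' Convenience wrapper: filters the stress sessions out of a raw intake
#' table, assigns per-session tertiles and applies the BEP/BER rule.
#'
#' @param intakes An intake table (see [read_intake_log()]).
#' @param stress_sessions Character vector of session ids to classify on
#'   (conventionally three stress sessions).
#' @inheritParams assign_tertiles
#' @inheritParams classify_phenotype
#' @return A `phenotype_tbl` (see [classify_phenotype()]).
#' @export
phenotype_cohort <- function(intakes, stress_sessions, intake_col = "grams",
                             method = c("rank", "range"), min_count = 2) {
  sub <- intakes[intakes$session_id %in% stress_sessions, , drop = FALSE]
  if (nrow(sub) == 0) {
    bt_abort("No rows match `stress_sessions`.", "bad_argument")
  }
  classify_phenotype(assign_tertiles(sub, intake_col, method), min_count = min_count)
}

#' @export
tidy.phenotype_tbl <- function(x, ...) {
  out <- x
  attr(out, "tertiles") <- NULL
  class(out) <- setdiff(class(out), "phenotype_tbl")
  out
}

#' @export
glance.phenotype_tbl <- function(x, ...) {
  tibble::tibble(
    n_rats = nrow(x),
    n_bep = sum(x$label == "BEP"),
    n_ber = sum(x$label == "BER"),
    n_unclassified = sum(x$label == "unclassified")
  )
}

#' Detect a stable intake baseline
#'
#' Finds the earliest run of `window` consecutive sessions over which group
#' intake shows no significant change — the conventional criterion for
#' declaring the last sessions of habituation the appetitive baseline. The
#' default criterion is a repeated-measures one-way ANOVA across sessions
#' (rats as the blocking factor) with `p > alpha`; the alternative
#' (`method = "cv"`) requires the coefficient of variation of the session
#' means to stay below `cv_limit`.
#'
#' @param intakes A data frame with `rat_id`, `session_id` and an intake
#'   column; sessions are taken in the order given by `sessions` (default:
#'   order of first appearance).
#' @param window Number of consecutive sessions that must be stable
#'   (default 3).
#' @param alpha Significance criterion for the ANOVA method (default 0.05).
#' @param intake_col Name of the intake column (default `"grams"`).
#' @param method `"rm_anova"` (default) or `"cv"`.
#' @param cv_limit CV threshold for `method = "cv"` (default 0.15).
#' @param sessions Optional character vector fixing the session order.
#' @return A one-row tibble `start_index, sessions, p_value` (or `cv`) for
#'   the earliest stable window, or a zero-row tibble if none qualifies.
#' @export
detect_stable_baseline <- function(intakes, window = 3, alpha = 0.05,
                                   intake_col = "grams",
                                   method = c("rm_anova", "cv"),
                                   cv_limit = 0.15, sessions = NULL) {
  method <- match.arg(method)
  if (!is.numeric(window) || length(window) != 1L || window < 2 ||
      window != round(window)) {
    bt_abort("`window` must be an integer >= 2.", "bad_argument")
  }
  if (!is.data.frame(intakes) ||
      !all(c("rat_id", "session_id", intake_col) %in% names(intakes))) {
    bt_abort(sprintf(
      "`intakes` must contain rat_id, session_id and '%s' columns.", intake_col
    ), "bad_argument")
  }
  sessions <- sessions %||% unique(intakes$session_id)
  if (length(sessions) < window) {
    bt_abort("Fewer sessions than the stability window.", "bad_argument")
  }
  for (i in seq_len(length(sessions) - window + 1)) {
    win <- sessions[seq.int(i, i + window - 1)]
    sub <- intakes[intakes$session_id %in% win, , drop = FALSE]
    sub$intake <- as.numeric(sub[[intake_col]])
    if (method == "rm_anova") {
      # rats complete in the window; session effect blocked on rat
      keep <- names(which(table(sub$rat_id) == window))
      sub <- sub[sub$rat_id %in% keep, , drop = FALSE]
      if (length(keep) < 2) next
      fit <- aov(intake ~ factor(session_id) + factor(rat_id), data = sub)
      tab <- summary(fit)[[1]]
      ss_session <- tab[grep("session_id", rownames(tab)), "Sum Sq"]
      p <- tab[grep("session_id", rownames(tab)), "Pr(>F)"]
      # a session effect of exactly zero is stable even when the residual is
      # also zero (F = 0/0): no change at all
      if (is.na(p) && isTRUE(ss_session < 1e-12)) p <- 1
      if (is.na(p)) next
      if (p > alpha) {
        return(tibble::tibble(
          start_index = i, sessions = list(win), p_value = p
        ))
      }
    } else {
      m <- tapply(sub$intake, sub$session_id, mean)[win]
      cv <- sd(m) / mean(m)
      if (is.finite(cv) && cv < cv_limit) {
        return(tibble::tibble(start_index = i, sessions = list(win), cv = cv))
      }
    }
  }
  tibble::tibble(
    start_index = integer(0), sessions = list(),
    p_value = numeric(0)
  )[0, ]
}
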