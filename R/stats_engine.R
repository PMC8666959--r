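#' Two-way factorial ANOVA
#'
#' Fits a two-factor ANOVA with interaction and reports main effects,
#' interaction and residual as sums of squares, degrees of freedom, F and p.
#' Unbalanced designs (unequal cell sizes are the rule in phenotype-by-
#' condition cohorts) use Type-III sums of squares with sum-to-zero
#' contrasts, the convention of the mainstream GUI statistics packages this
#' layer mirrors; on balanced designs Type III coincides with the sequential
#' decomposition and the effect sums of squares add up to the total exactly.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns.
#' @param type `"III"` (default) or `"I"` (sequential).
#' @return An object of class `anova_fit`: a list with `effects` (tibble:
#'   `term, sumsq, df, statistic, p.value`), `residual` (list `sumsq, df`),
#'   `cells` (cell means and counts), `fit` (the underlying `lm`), and
#'   `constant_response` flag. `tidy()` and `glance()` methods are provided.
#' @examples
#' d <- tidyr::crossing(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:2)
#' d$y <- c(1, 3, 2, 4, 5, 7, 9, 11)
#' tidy(two_way_anova(d, "y", "a", "b"))
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          type = c("III", "I")) {
  type <- match.arg(type)
  check_anova_input(data, response, c(factor_a, factor_b))
  df <- data.frame(
    y = as.numeric(data[[response]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  for (f in c("A", "B")) {
    if (nlevels(df[[f]]) < 2) {
      bt_abort(sprintf("Factor '%s' needs at least 2 levels.",
                       if (f == "A") factor_a else factor_b), "bad_design")
    }
  }
  cells <- dplyr::count(df, .data$A, .data$B)
  full <- tidyr::crossing(A = levels(df$A), B = levels(df$B))
  empty <- dplyr::anti_join(full, cells, by = c("A", "B"))
  if (nrow(empty)) {
    bt_abort(sprintf(
      "Empty design cell: %s = %s, %s = %s.",
      factor_a, empty$A[1], factor_b, empty$B[1]
    ), "empty_cell")
  }
  fit <- lm(y ~ A * B, data = df,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  # base R warns about F-tests on perfect fits; the zero-residual case is
  # flagged explicitly below instead
  quiet_perfect_fit <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  if (type == "III") {
    # drop1 on a sum-to-zero parameterization yields Type-III SS
    d1 <- quiet_perfect_fit(drop1(fit, scope = ~ A + B + A:B, test = "F"))
    terms_tab <- d1[c("A", "B", "A:B"), ]
    ss <- terms_tab[, "Sum of Sq"]
    dfs <- terms_tab[, "Df"]
  } else {
    a1 <- stats::anova(fit)
    ss <- a1[c("A", "B", "A:B"), "Sum Sq"]
    dfs <- a1[c("A", "B", "A:B"), "Df"]
  }
  rss <- sum(stats::residuals(fit)^2)
  rdf <- stats::df.residual(fit)
  ms_res <- rss / rdf
  f_stat <- (ss / dfs) / ms_res
  p <- pf(f_stat, dfs, rdf, lower.tail = FALSE)
  if (rss < 1e-12 * max(1, sum(df$y^2))) {
    # zero residual variance: F is undefined, flag instead of fabricating
    f_stat <- rep(NA_real_, 3)
    p <- rep(NA_real_, 3)
  }
  cell_means <- df |>
    dplyr::group_by(.data$A, .data$B) |>
    dplyr::summarise(mean = mean(.data$y), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cell = paste(.data$A, .data$B, sep = ":"))
  structure(
    list(
      effects = tibble::tibble(
        term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
        sumsq = as.numeric(ss), df = as.numeric(dfs),
        statistic = as.numeric(f_stat), p.value = as.numeric(p)
      ),
      residual = list(sumsq = rss, df = rdf),
      cells = cell_means,
      factors = c(factor_a, factor_b),
      response = response,
      fit = fit,
      zero_residual = rss < 1e-12 * max(1, sum(df$y^2)),
      type = type
    ),
    class = "anova_fit"
  )
}

check_anova_input <- function(data, response, factors) {
  if (!is.data.frame(data) ||
      !all(c(response, factors) %in% names(data))) {
    bt_abort("`data` must contain the response and factor columns.",
             "bad_argument")
  }
  if (any(!is.finite(as.numeric(data[[response]])))) {
    bt_abort("Response contains missing or non-finite values.", "bad_value")
  }
}

#' One-way ANOVA
#'
#' Between/within decomposition for a single factor; equivalent to
#' [two_way_anova()] with one factor. With two equal-size groups the F
#' statistic equals the squared pooled two-sample t statistic.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param factor Name of the grouping column (>= 2 groups, each >= 2
#'   values).
#' @return An `anova_fit` (see [two_way_anova()]) with a single effect row.
#' @export
one_way_anova <- function(data, response, factor) {
  check_anova_input(data, response, factor)
  df <- data.frame(
    y = as.numeric(data[[response]]),
    A = base::factor(data[[factor]])
  )
  if (nlevels(df$A) < 2) {
    bt_abort("One-way ANOVA needs at least 2 groups.", "bad_design")
  }
  sizes <- table(df$A)
  if (any(sizes < 2)) {
    bt_abort(sprintf("Group '%s' has fewer than 2 values.",
                     names(sizes)[sizes < 2][1]), "bad_design")
  }
  fit <- lm(y ~ A, data = df, contrasts = list(A = "contr.sum"))
  a1 <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ss <- a1["A", "Sum Sq"]; dfs <- a1["A", "Df"]
  rss <- a1["Residuals", "Sum Sq"]; rdf <- a1["Residuals", "Df"]
  zero_res <- rss < 1e-12 * max(1, sum(df$y^2))
  f_stat <- if (zero_res) NA_real_ else (ss / dfs) / (rss / rdf)
  p <- if (zero_res) NA_real_ else pf(f_stat, dfs, rdf, lower.tail = FALSE)
  if (zero_res && ss < 1e-12) { f_stat <- 0; p <- 1 } # flat everywhere
  cell_means <- df |>
    dplyr::group_by(.data$A) |>
    dplyr::summarise(mean = mean(.data$y), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cell = as.character(.data$A))
  structure(
    list(
      effects = tibble::tibble(
        term = factor, sumsq = ss, df = as.numeric(dfs),
        statistic = f_stat, p.value = p
      ),
      residual = list(sumsq = rss, df = rdf),
      cells = cell_means,
      factors = factor,
      response = response,
      fit = fit,
      zero_residual = zero_res,
      type = "I"
    ),
    class = "anova_fit"
  )
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("<anova_fit> %s ~ %s\n", x$response,
              paste(x$factors, collapse = " * ")))
  print(as.data.frame(x$effects), row.names = FALSE)
  cat(sprintf("residual: SS = %g, df = %d\n", x$residual$sumsq, x$residual$df))
  invisible(x)
}

#' @export
tidy.anova_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$effects,
    tibble::tibble(
      term = "Residuals", sumsq = x$residual$sumsq,
      df = as.numeric(x$residual$df),
      statistic = NA_real_, p.value = NA_real_
    )
  )
}

#' @export
glance.anova_fit <- function(x, ...) {
  tibble::tibble(
    n = sum(x$cells$n),
    df.residual = as.numeric(x$residual$df),
    ss.residual = x$residual$sumsq,
    type = x$type,
    zero_residual = x$zero_residual
  )
}

#' Bonferroni post hoc pairwise comparisons
#'
#' Pairwise comparisons between design cells following an ANOVA, using the
#' pooled residual mean square and residual degrees of freedom of the fit
#' for every pairwise t statistic. P-values are Bonferroni-adjusted by the
#' number of comparisons actually requested — not all possible pairs —
#' matching the starred subsets of a typical figure: `adjusted_p =
#' min(1, raw_p * m)`.
#'
#' @param fit An `anova_fit` from [one_way_anova()] or [two_way_anova()].
#' @param comparisons A list of 2-element character vectors naming cells;
#'   for a two-way fit, cells are `"levelA:levelB"`. Default: all pairs.
#' @param alpha Significance level (default 0.05).
#' @return A tibble `group_a, group_b, mean_diff, statistic, df, raw_p,
#'   adjusted_p, significant`.
#' @export
bonferroni_posthoc <- function(fit, comparisons = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "anova_fit"))
  cells <- fit$cells
  if (is.null(comparisons)) {
    comparisons <- utils::combn(cells$cell, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  if (m == 0) bt_abort("No comparisons requested.", "bad_argument")
  ms <- fit$residual$sumsq / fit$residual$df
  rows <- purrr::map(comparisons, function(pr) {
    if (length(pr) != 2) {
      bt_abort("Each comparison must name exactly two cells.", "bad_argument")
    }
    ia <- match(pr[1], cells$cell)
    ib <- match(pr[2], cells$cell)
    if (is.na(ia) || is.na(ib)) {
      bad <- pr[is.na(c(ia, ib))][1]
      bt_abort(sprintf(
        "Unknown group '%s'; cells are: %s.",
        bad, paste(cells$cell, collapse = ", ")
      ), "unknown_group")
    }
    diff <- cells$mean[ia] - cells$mean[ib]
    se <- sqrt(ms * (1 / cells$n[ia] + 1 / cells$n[ib]))
    t_stat <- if (se == 0) {
      if (diff == 0) 0 else sign(diff) * Inf
    } else {
      diff / se
    }
    raw_p <- if (is.infinite(t_stat)) 0 else
      2 * pt(abs(t_stat), fit$residual$df, lower.tail = FALSE)
    tibble::tibble(
      group_a = pr[1], group_b = pr[2], mean_diff = diff,
      statistic = t_stat, df = as.numeric(fit$residual$df), raw_p = raw_p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- pmin(1, out$raw_p * m)
  out$significant <- out$adjusted_p < alpha
  out
}

#' Two-tailed unpaired t-test
#'
#' Pooled-variance two-sample t-test (Student), the default companion of the
#' ANOVA layer. Zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means is reported as an infinite t with
#' `p = 0` and a flag rather than an error.
#'
#' @param values_a,values_b Numeric vectors (each >= 2 values).
#' @param two_tailed Two-tailed p (default `TRUE`).
#' @return A one-row tibble `statistic, df, p.value, mean_a, mean_b,
#'   mean_diff, degenerate`.
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6)) # |t| = 3.674, df = 4
#' @export
unpaired_t <- function(values_a, values_b, two_tailed = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    bt_abort("Each group needs at least 2 values.", "bad_design")
  }
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    bt_abort("Inputs must be finite.", "bad_value")
  }
  na <- length(values_a); nb <- length(values_b)
  df <- na + nb - 2
  if (var(values_a) == 0 && var(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    return(tibble::tibble(
      statistic = if (d == 0) 0 else sign(d) * Inf,
      df = as.numeric(df),
      p.value = if (d == 0) 1 else 0,
      mean_a = mean(values_a), mean_b = mean(values_b), mean_diff = d,
      degenerate = TRUE
    ))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE,
                      alternative = "two.sided")
  p <- if (two_tailed) ht$p.value else ht$p.value / 2
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = p,
    mean_a = mean(values_a), mean_b = mean(values_b),
    mean_diff = mean(values_a) - mean(values_b),
    degenerate = FALSE
  )
}
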