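balanced_2x2 <- function() {
  d <- tidyr::crossing(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:2)
  d <- dplyr::arrange(d, a, b)
  d$y <- c(1, 3, 2, 4, 5, 7, 9, 11)
  d
}

test_that("the balanced 2x2 reproduces the closed-form decomposition", {
  d <- balanced_2x2()
  fit <- two_way_anova(d, "y", "a", "b")
  eff <- fit$effects
  expect_equal(eff$sumsq, c(60.5, 12.5, 4.5), tolerance = 1e-12)
  expect_equal(eff$statistic, c(30.25, 6.25, 2.25), tolerance = 1e-12)
  expect_equal(eff$df, c(1, 1, 1))
  expect_equal(fit$residual$sumsq, 8, tolerance = 1e-12)
  expect_equal(fit$residual$df, 4)

  # and matches the independent textbook oracle
  o <- oracle_balanced_ss(d$y, d$a, d$b)
  expect_equal(eff$sumsq, c(o$ss_a, o$ss_b, o$ss_ab), tolerance = 1e-12)
  expect_equal(fit$residual$sumsq, o$ss_res, tolerance = 1e-12)
})

test_that("balanced designs decompose the total SS exactly", {
  set.seed(31)
  for (i in 1:20) {
    d <- tidyr::crossing(a = c("x", "y", "z"), b = c("p", "q"), rep = 1:4)
    d$y <- rnorm(nrow(d), 5, 2)
    fit <- two_way_anova(d, "y", "a", "b")
    total <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(fit$effects$sumsq) + fit$residual$sumsq, total,
                 tolerance = 1e-9)
    expect_equal(sum(fit$effects$df) + fit$residual$df, nrow(d) - 1)
    expect_true(all(fit$effects$statistic >= 0))
  }
})

test_that("swapping the factors swaps the main effects only", {
  d <- balanced_2x2()
  f1 <- two_way_anova(d, "y", "a", "b")$effects
  f2 <- two_way_anova(d, "y", "b", "a")$effects
  expect_equal(f1$sumsq[1], f2$sumsq[2])
  expect_equal(f1$sumsq[2], f2$sumsq[1])
  expect_equal(f1$sumsq[3], f2$sumsq[3])
})

test_that("degenerate two-way inputs are flagged, not fabricated", {
  d <- balanced_2x2()
  d$y <- 7 # constant everywhere
  fit <- two_way_anova(d, "y", "a", "b")
  expect_equal(fit$effects$sumsq, c(0, 0, 0), tolerance = 1e-12)
  expect_true(fit$zero_residual)
  expect_true(all(is.na(fit$effects$statistic)))

  d2 <- balanced_2x2()
  d2 <- d2[!(d2$a == "a1" & d2$b == "b1"), ]
  expect_error(two_way_anova(d2, "y", "a", "b"),
               class = "bingetools_empty_cell")
})

test_that("Type-III sums of squares match car::Anova on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(32)
  d <- tidyr::crossing(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:6)
  d <- d[-c(1, 2, 13), ] # unbalance the cells
  d$y <- rnorm(nrow(d), 3, 1.5) + as.numeric(d$a == "a2") * 2
  fit <- two_way_anova(d, "y", "a", "b")
  m <- lm(y ~ A * B, data = data.frame(y = d$y, A = factor(d$a), B = factor(d$b)),
          contrasts = list(A = "contr.sum", B = "contr.sum"))
  ref <- car::Anova(m, type = 3)
  expect_equal(fit$effects$sumsq, ref[c("A", "B", "A:B"), "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(fit$effects$p.value, ref[c("A", "B", "A:B"), "Pr(>F)"],
               tolerance = 1e-9)
})

test_that("one-way F equals the squared pooled t for two groups", {
  set.seed(33)
  for (i in 1:10) {
    d <- tibble::tibble(
      g = rep(c("u", "v"), each = 8),
      y = rnorm(16, rep(c(0, 1), each = 8))
    )
    f <- one_way_anova(d, "y", "g")
    t <- unpaired_t(d$y[d$g == "u"], d$y[d$g == "v"])
    expect_equal(f$effects$statistic, t$statistic^2, tolerance = 1e-9)
    expect_equal(f$effects$p.value, t$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA rejects degenerate designs and flat data", {
  d <- tibble::tibble(g = rep("u", 4), y = rnorm(4))
  expect_error(one_way_anova(d, "y", "g"), class = "bingetools_bad_design")
  d2 <- tibble::tibble(g = c("u", "u", "v"), y = 1:3)
  expect_error(one_way_anova(d2, "y", "g"), class = "bingetools_bad_design")
  d3 <- tibble::tibble(g = rep(c("u", "v"), each = 3), y = rep(5, 6))
  f <- one_way_anova(d3, "y", "g")
  expect_equal(f$effects$statistic, 0)
  expect_equal(f$effects$p.value, 1)
})

test_that("Bonferroni adjustment is the capped raw-p multiple", {
  d <- tidyr::crossing(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:5)
  set.seed(34)
  d$y <- rnorm(nrow(d), as.numeric(d$a == "a2") * 3)
  fit <- two_way_anova(d, "y", "a", "b")
  all_pairs <- bonferroni_posthoc(fit)
  expect_equal(nrow(all_pairs), 6)
  expect_equal(all_pairs$adjusted_p, pmin(1, all_pairs$raw_p * 6))
  # adjusted never below raw, and monotone in raw
  expect_true(all(all_pairs$adjusted_p >= all_pairs$raw_p))
  ord <- order(all_pairs$raw_p)
  expect_true(all(diff(all_pairs$adjusted_p[ord]) >= 0))

  one <- bonferroni_posthoc(fit, list(c("a1:b1", "a2:b1")))
  expect_equal(one$adjusted_p, one$raw_p) # m = 1 is the identity

  expect_error(bonferroni_posthoc(fit, list(c("a1:b1", "nope"))),
               class = "bingetools_unknown_group")
})

test_that("post hoc t statistics use the pooled residual mean square", {
  d <- tidyr::crossing(g = c("u", "v", "w"), rep = 1:4)
  set.seed(35)
  d$y <- rnorm(nrow(d), c(u = 0, v = 1, w = 4)[d$g])
  fit <- one_way_anova(d, "y", "g")
  ph <- bonferroni_posthoc(fit, list(c("u", "v")))
  ms <- fit$residual$sumsq / fit$residual$df
  want_t <- (mean(d$y[d$g == "u"]) - mean(d$y[d$g == "v"])) /
    sqrt(ms * (1 / 4 + 1 / 4))
  expect_equal(ph$statistic, want_t, tolerance = 1e-12)
  expect_equal(ph$df, fit$residual$df)
})

test_that("unpaired t handles identity, antisymmetry and degeneracy", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  out <- unpaired_t(x, y)
  # closed form: diff = -3, pooled var = 1, se = sqrt(2/3)
  expect_equal(out$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(out$df, 4)

  same <- unpaired_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_true(same$degenerate)

  inf <- unpaired_t(c(2, 2, 2), c(5, 5, 5))
  expect_true(is.infinite(inf$statistic))
  expect_equal(inf$p.value, 0)

  ab <- unpaired_t(x, y); ba <- unpaired_t(y, x)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- balanced_2x2()
  fit <- two_way_anova(d, "y", "a", "b")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "a:b", "Residuals"))
  expect_equal(sum(td$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n, 8)
  expect_equal(gl$df.residual, 4)
})
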