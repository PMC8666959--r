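# Independent oracles and fixture builders shared across test files.
# These deliberately use naive algorithms (quadratic scans, per-pixel loops,
# closed-form textbook sums) so they share no code with the implementation.

# brute-force cluster segmentation: split at every inter-lick interval
# >= threshold, then filter bursts by size
oracle_segment <- function(ts, threshold = 0.5, min_licks = 3) {
  ts <- sort(ts)
  n <- length(ts)
  if (n == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_licks = integer(0)))
  }
  groups <- list()
  current <- ts[1]
  for (i in seq_len(n - 1)) {
    if (ts[i + 1] - ts[i] >= threshold) {
      groups[[length(groups) + 1]] <- current
      current <- ts[i + 1]
    } else {
      current <- c(current, ts[i + 1])
    }
  }
  groups[[length(groups) + 1]] <- current
  keep <- Filter(function(g) length(g) >= min_licks, groups)
  data.frame(
    start = vapply(keep, min, numeric(1)),
    end = vapply(keep, max, numeric(1)),
    n_licks = vapply(keep, length, integer(1))
  )
}

# random lick train with a mix of short and long inter-lick intervals so
# both burst continuations and splits occur, including intervals at the
# exact 0.5 s boundary
random_train <- function(n = NULL) {
  if (is.null(n)) n <- sample(0:60, 1)
  if (n == 0) return(numeric(0))
  ilis <- sample(
    c(runif(n, 0.05, 0.45), runif(n, 0.5, 3), rep(0.5, n)),
    n - 1, replace = TRUE
  )
  cumsum(c(runif(1, 0, 5), ilis))
}

# textbook cell-mean sums of squares for a balanced a x b design
oracle_balanced_ss <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  cells <- tapply(y, list(A, B), mean)
  ns <- tapply(y, list(A, B), length)
  stopifnot(length(unique(as.vector(ns))) == 1)
  n <- ns[1, 1]
  ma <- rowMeans(cells); mb <- colMeans(cells); g <- mean(cells)
  ss_a <- n * ncol(cells) * sum((ma - g)^2)
  ss_b <- n * nrow(cells) * sum((mb - g)^2)
  dev <- sweep(sweep(cells, 1, ma), 2, mb) + g
  ss_ab <- n * sum(dev^2)
  ss_res <- sum((y - cells[cbind(A, B)])^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_res = ss_res)
}

# scalar ray-casting point-in-polygon used as the rasterization oracle
oracle_point_in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > y) != (v[j, 2] > y)) {
      xint <- (v[j, 1] - v[i, 1]) * (y - v[i, 2]) / (v[j, 2] - v[i, 2]) + v[i, 1]
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# random convex polygon: points on a jittered circle, ordered by angle
random_convex_polygon <- function(cx, cy, r_min, r_max, n_vertices = 8) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# square polygon helper (vertices counterclockwise)
square_poly <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# the six-rat, three-session worked intake table for phenotyping
worked_cohort <- function() {
  tibble::tibble(
    rat_id = rep(LETTERS[1:6], times = 3),
    session_id = rep(c("S1", "S2", "S3"), each = 6),
    grams = c(10, 9, 6, 5, 2, 1,
              11, 5, 9, 6, 2, 1,
              12, 8, 9, 5, 3, 1)
  )
}
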