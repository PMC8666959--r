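test_that("uniform-intensity fixtures reproduce hand-computed OD", {
  img <- matrix(40, 60, 60)
  img[10:20, 10:20] <- 180
  roi <- square_poly(9, 9, 11)        # covers the bright block exactly
  bgs <- list(square_poly(30, 5, 6), square_poly(40, 5, 6),
              square_poly(50, 5, 6))
  m <- measure_roi(img, roi, bgs)
  expect_equal(m$roi_mean, 180)
  expect_equal(m$background_mean, 40)
  expect_equal(m$corrected_od, 140)
  expect_false(m$negative_od)

  # three backgrounds at different levels average to their mean of means
  img2 <- matrix(40, 60, 60)
  img2[1:10, 1:10] <- 180
  img2[30:35, 1:6] <- 40; img2[30:35, 10:15] <- 50; img2[30:35, 20:25] <- 60
  m2 <- measure_roi(
    img2, square_poly(0, 0, 10),
    list(square_poly(0, 29, 6), square_poly(9, 29, 6), square_poly(19, 29, 6))
  )
  expect_equal(m2$background_mean, 50)
  expect_equal(m2$corrected_od, 130)

  # constant image: signal equals background exactly
  flat <- matrix(77, 40, 40)
  m3 <- measure_roi(flat, square_poly(5, 5, 10),
                    list(square_poly(25, 25, 5)))
  expect_equal(m3$corrected_od, 0)
})

test_that("a half-bright ROI averages its two halves", {
  img <- matrix(50, 40, 40)
  img[11:20, 1:10] <- 100 # rows 11-20 of the ROI columns
  img[1:10, 1:10] <- 200
  m <- measure_roi(img, cbind(c(0, 10, 10, 0), c(0, 0, 20, 20)),
                   list(square_poly(25, 25, 10)))
  expect_equal(m$roi_mean, 150)
  expect_equal(m$corrected_od, 100)
})

test_that("corrected OD is offset-invariant and gain-equivariant", {
  set.seed(61)
  img <- matrix(runif(80 * 80, 20, 120), 80, 80)
  roi <- square_poly(10, 10, 25)
  bgs <- list(square_poly(50, 10, 8), square_poly(50, 30, 8),
              square_poly(50, 50, 8))
  base <- suppressWarnings(measure_roi(img, roi, bgs))$corrected_od
  plus <- suppressWarnings(measure_roi(img + 31.7, roi, bgs)$corrected_od)
  times <- suppressWarnings(measure_roi(img * 2.5, roi, bgs)$corrected_od)
  expect_equal(plus, base, tolerance = 1e-9)
  expect_equal(times, 2.5 * base, tolerance = 1e-9)
})

test_that("negative corrected OD is flagged and retained, not clipped", {
  img <- matrix(100, 30, 30)
  img[1:10, 1:10] <- 20 # ROI darker than background
  expect_warning(
    m <- measure_roi(img, square_poly(0, 0, 10),
                     list(square_poly(15, 15, 8))),
    class = "bingetools_negative_od"
  )
  expect_lt(m$corrected_od, 0)
  expect_true(m$negative_od)
})

test_that("polygons outside the image or enclosing no pixels error", {
  img <- matrix(10, 20, 20)
  expect_error(
    measure_roi(img, square_poly(15, 15, 10), list(square_poly(1, 1, 5))),
    class = "bingetools_outside_image"
  )
  tiny <- cbind(c(5.1, 5.3, 5.2), c(5.1, 5.1, 5.3)) # no pixel center inside
  expect_error(
    measure_roi(img, tiny, list(square_poly(1, 1, 5))),
    class = "bingetools_empty_polygon"
  )
})

test_that("rasterization agrees with a per-pixel point-in-polygon oracle", {
  set.seed(62)
  img <- matrix(seq_len(40 * 40), 40, 40) # distinct values index pixels
  for (i in 1:100) {
    poly <- random_convex_polygon(runif(1, 12, 28), runif(1, 12, 28),
                                  4, 9, sample(5:10, 1))
    got <- measure_roi(img, poly, list(square_poly(0.2, 0.2, 3)))
    centers <- expand.grid(r = 1:40, c = 1:40)
    inside <- mapply(function(r, c) {
      oracle_point_in_polygon(c - 0.5, r - 0.5, poly)
    }, centers$r, centers$c)
    expect_equal(got$n_pixels, sum(inside))
    expect_equal(got$roi_mean, mean(img[cbind(centers$r, centers$c)][inside]))
  }
})

test_that("the batch guard blocks cross-region and cross-batch pooling", {
  meas <- tibble::tibble(
    region = c("AcbC", "AcbC", "PVNp", "PVNp"),
    batch_id = c("b1", "b1", "b2", "b2"),
    rat_id = c("r1", "r2", "r1", "r2"),
    corrected_od = c(10, 12, 30, 33)
  )
  ok <- batch_compare_guard(meas, regions = "AcbC")
  expect_named(ok, "AcbC")
  expect_equal(nrow(ok$AcbC), 2)

  expect_error(batch_compare_guard(meas, regions = c("AcbC", "PVNp")),
               class = "bingetools_cross_region")

  mixed <- meas
  mixed$batch_id <- c("b1", "b9", "b2", "b2")
  expect_error(batch_compare_guard(mixed, regions = "AcbC"),
               class = "bingetools_mixed_batches")
  ok2 <- batch_compare_guard(mixed, regions = "AcbC", pool_batches = TRUE)
  expect_equal(nrow(ok2$AcbC), 2)
})

test_that("group summaries match hand means and SDs", {
  meas <- tibble::tibble(
    region = "AcbC",
    phenotype = rep(c("BEP", "BER"), each = 3),
    corrected_od = c(10, 12, 14, 30, 30, 30)
  )
  out <- region_group_summary(meas, "phenotype")
  expect_equal(out$mean_od, c(12, 30))
  expect_equal(out$sd_od, c(2, 0))

  small <- dplyr::bind_rows(
    meas, tibble::tibble(region = "AcbC", phenotype = "lone",
                         corrected_od = 5)
  )
  expect_warning(out2 <- region_group_summary(small, "phenotype"),
                 class = "bingetools_small_group")
  expect_false("lone" %in% out2$phenotype)

  expect_error(region_group_summary(meas[0, ], "phenotype"),
               class = "bingetools_bad_argument")
})

test_that("per-animal averaging collapses sections to one row per rat", {
  meas <- tibble::tibble(
    region = "PVNp", batch_id = "b1",
    rat_id = rep(c("r1", "r2"), c(3, 2)),
    corrected_od = c(10, 12, 14, 20, 22)
  )
  out <- per_animal_od(meas)
  expect_equal(nrow(out), 2)
  expect_equal(out$corrected_od, c(12, 21))
  expect_equal(out$n_sections, c(3L, 2L))
})

test_that("grain images round-trip through grayscale TIFF", {
  roi <- square_poly(30, 30, 40)
  sim <- gen_grain_image(100, 100, background_density = 0.4,
                         signal_density = 2, roi_polygon = roi,
                         grain_intensity = 10, seed = 63)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_grayscale_image(sim$image, path)
  back <- read_grayscale_image(path)
  expect_equal(dim(back), dim(sim$image))
  expect_equal(back, sim$image)
})
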