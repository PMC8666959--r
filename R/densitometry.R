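# Vectorized even-odd (crossing-number) point-in-polygon test.
# Points exactly on an edge follow the half-open crossing convention; the
# random ROI placements used here never put pixel centers on edges.
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# logical mask of pixels whose centers fall inside the polygon; pixel (r, c)
# covers [c-1, c] x [r-1, r] with center (c - 0.5, r - 0.5)
polygon_pixel_mask <- function(image, v) {
  nr <- nrow(image); nc <- ncol(image)
  if (any(v[, 1] < 0 | v[, 1] > nc | v[, 2] < 0 | v[, 2] > nr)) {
    bt_abort("Polygon extends outside the image bounds.", "outside_image")
  }
  cmin <- max(1L, floor(min(v[, 1]) + 0.5))
  cmax <- min(nc, ceiling(max(v[, 1]) + 0.5))
  rmin <- max(1L, floor(min(v[, 2]) + 0.5))
  rmax <- min(nr, ceiling(max(v[, 2]) + 0.5))
  mask <- matrix(FALSE, nr, nc)
  if (cmin > cmax || rmin > rmax) return(mask)
  cols <- seq.int(cmin, cmax)
  rows <- seq.int(rmin, rmax)
  grid <- expand.grid(r = rows, c = cols)
  inside <- point_in_polygon(grid$c - 0.5, grid$r - 0.5, v)
  mask[cbind(grid$r, grid$c)] <- inside
  mask
}

#' Load a grayscale image for densitometry
#'
#' Reads an 8- or 16-bit grayscale TIFF into a numeric matrix of native
#' intensity values (rows = y, columns = x).
#'
#' @param path Path to the TIFF file.
#' @return A numeric matrix of pixel intensities.
#' @export
read_grayscale_image <- function(path) {
  if (!file.exists(path)) {
    bt_abort(sprintf("Image not found: %s", path), "missing_file")
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) {
      img <- img[, , 1]
    } else {
      bt_abort("Only single-channel grayscale images are supported.", "bad_value")
    }
  }
  img
}

#' Background-corrected ROI optical density
#'
#' Measures the relative hybridization signal of a dark-field image region:
#' the mean gray value over the pixels whose centers fall inside the ROI
#' polygon, corrected by subtracting the background estimate — the mean over
#' the background polygons of their own per-polygon mean intensities
#' (customarily three small contours on unlabeled tissue near the region).
#' Dark-field signal is bright-on-dark, so no logarithmic transform is
#' applied; the quantity is a *relative* optical density. A negative
#' corrected value is retained and flagged, never clipped, so group means
#' stay unbiased.
#'
#' @param image A numeric matrix (see [read_grayscale_image()]) or a path to
#'   a grayscale TIFF.
#' @param roi A two-column vertex matrix (x, y in pixel units), or a one-row
#'   subset of a [read_roi_set()] tibble.
#' @param backgrounds A list of vertex matrices (or a `read_roi_set()` tibble
#'   subset) for the background contours; at least one, customarily three.
#' @param region,image_id,batch_id,rat_id Optional labels carried through to
#'   the output (batch = hybridization/exposure batch).
#' @param statistic `"mean"` (default) or `"integrated"` (sum of ROI pixel
#'   intensities minus background mean per pixel times ROI area).
#' @return A one-row tibble `region, image_id, batch_id, rat_id, roi_mean,
#'   background_mean, corrected_od, n_pixels, negative_od`.
#' @examples
#' img <- matrix(40, 30, 30)
#' img[5:15, 5:15] <- 180
#' roi <- cbind(c(5, 15, 15, 5), c(5, 5, 15, 15))
#' bg <- list(cbind(c(20, 28, 28, 20), c(20, 20, 28, 28)))
#' measure_roi(img, roi, bg)
#' @export
measure_roi <- function(image, roi, backgrounds,
                        region = NA_character_, image_id = NA_character_,
                        batch_id = NA_character_, rat_id = NA_character_,
                        statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  if (is.character(image)) image <- read_grayscale_image(image)
  if (!is.matrix(image) || !is.numeric(image)) {
    bt_abort("`image` must be a numeric matrix or a TIFF path.", "bad_argument")
  }
  as_vertices <- function(x, what) {
    if (is.data.frame(x) && "vertices" %in% names(x)) x <- x$vertices[[1]]
    if (!is.matrix(x) || ncol(x) != 2 || nrow(x) < 3) {
      bt_abort(sprintf("`%s` must be a >= 3-vertex two-column matrix.", what),
               "bad_polygon")
    }
    x
  }
  roi_v <- as_vertices(roi, "roi")
  if (is.data.frame(backgrounds)) {
    backgrounds <- backgrounds$vertices
  }
  if (!is.list(backgrounds) || length(backgrounds) < 1) {
    bt_abort("`backgrounds` must be a non-empty list of polygons.", "bad_argument")
  }
  bg_v <- purrr::map(backgrounds, as_vertices, what = "backgrounds")

  roi_mask <- polygon_pixel_mask(image, roi_v)
  n_roi <- sum(roi_mask)
  if (n_roi == 0) {
    bt_abort("ROI polygon encloses no pixel centers.", "empty_polygon")
  }
  bg_means <- purrr::map_dbl(bg_v, function(v) {
    m <- polygon_pixel_mask(image, v)
    if (!any(m)) {
      bt_abort("A background polygon encloses no pixel centers.", "empty_polygon")
    }
    mean(image[m])
  })
  roi_mean <- mean(image[roi_mask])
  bg_mean <- mean(bg_means)
  corrected <- if (statistic == "mean") {
    roi_mean - bg_mean
  } else {
    sum(image[roi_mask]) - bg_mean * n_roi
  }
  if (corrected < 0) {
    bt_warn("Corrected optical density is negative (retained, flagged).",
            "negative_od")
  }
  tibble::tibble(
    region = region, image_id = image_id, batch_id = batch_id, rat_id = rat_id,
    roi_mean = roi_mean, background_mean = bg_mean,
    corrected_od = corrected, n_pixels = n_roi,
    negative_od = corrected < 0
  )
}

#' Guard densitometry comparisons against incomparable batches
#'
#' Relative optical densities are comparable only between images of the same
#' brain region hybridized and exposed together: exposure settings differ
#' from region to region. This guard partitions a measurement table by
#' region and refuses any requested contrast that pools different regions,
#' or different batches within a region unless batch pooling is explicitly
#' allowed.
#'
#' @param measurements A tibble of [measure_roi()] rows (must carry `region`
#'   and `batch_id`).
#' @param regions Optional character vector restricting the output regions.
#' @param pool_batches Allow multiple `batch_id`s within one region
#'   (default `FALSE`).
#' @return A named list of per-region tibbles, each internally comparable.
#' @export
batch_compare_guard <- function(measurements, regions = NULL,
                                pool_batches = FALSE) {
  need <- c("region", "batch_id")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    bt_abort("`measurements` must carry region and batch_id columns.",
             "bad_argument")
  }
  if (!is.null(regions)) {
    found <- unique(measurements$region)
    if (length(regions) > 1) {
      bt_abort(sprintf(
        "Refusing a contrast pooling different brain regions: %s.",
        paste(regions, collapse = ", ")
      ), "cross_region")
    }
    missing_r <- setdiff(regions, found)
    if (length(missing_r)) {
      bt_abort(sprintf("Region(s) not present: %s.",
                       paste(missing_r, collapse = ", ")), "bad_argument")
    }
    measurements <- measurements[measurements$region %in% regions, ]
  }
  out <- split(tibble::as_tibble(measurements), measurements$region)
  for (rg in names(out)) {
    nb <- length(unique(out[[rg]]$batch_id))
    if (nb > 1 && !pool_batches) {
      bt_abort(sprintf(
        "Region %s mixes %d exposure batches; set pool_batches = TRUE only if exposures matched.",
        rg, nb
      ), "mixed_batches")
    }
  }
  out
}

#' Average ROI measurements per animal
#'
#' Collapses per-section measurements to one value per animal and region,
#' since the animal — not the section — is the experimental unit for group
#' statistics.
#'
#' @param measurements A tibble of [measure_roi()] rows with `rat_id`.
#' @return A tibble `region, batch_id, rat_id, corrected_od, n_sections`.
#' @export
per_animal_od <- function(measurements) {
  measurements |>
    dplyr::group_by(.data$region, .data$batch_id, .data$rat_id) |>
    dplyr::summarise(
      corrected_od = mean(.data$corrected_od),
      n_sections = dplyr::n(), .groups = "drop"
    )
}

#' Per-group optical-density summary
#'
#' Summarizes corrected optical densities as mean and standard deviation per
#' region and experimental group, the form group contrasts and ANOVA
#' consume. Groups with fewer than two measurements are excluded with a
#' warning.
#'
#' @param measurements A tibble with `region`, `corrected_od` and the
#'   grouping columns.
#' @param groups Character vector of grouping columns (e.g.
#'   `c("phenotype", "condition", "sucrose")`).
#' @return A tibble `region, <groups>, n, mean_od, sd_od`.
#' @export
region_group_summary <- function(measurements, groups) {
  need <- c("region", "corrected_od", groups)
  if (!is.data.frame(measurements) || nrow(measurements) == 0) {
    bt_abort("`measurements` must be a non-empty data frame.", "bad_argument")
  }
  if (!all(need %in% names(measurements))) {
    bt_abort(sprintf("Missing column(s): %s.",
                     paste(setdiff(need, names(measurements)), collapse = ", ")),
             "bad_argument")
  }
  out <- measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("region", groups)))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_od = mean(.data$corrected_od),
      sd_od = sd(.data$corrected_od),
      .groups = "drop"
    )
  small <- out$n < 2
  if (any(small)) {
    bt_warn(sprintf(
      "Excluding %d group(s) with fewer than 2 measurements.", sum(small)
    ), "small_group")
    out <- out[!small, ]
  }
  out
}
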