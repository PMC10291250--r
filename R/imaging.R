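#' Render a synthetic cross-section sector image
#'
#' Draws the conduits of a [conduit_set()] as dark, non-overlapping
#' ellipses on a light background inside a wedge-shaped sector, emulating a
#' digitalized cross-section micrograph. The wedge has the set's opening
#' angle and an outer radius chosen so the wedge area equals the sector
#' area; each conduit keeps its measured lumen area, with an aspect ratio
#' drawn uniformly from `aspect_range` and random orientation. Placement is
#' by dart throwing with rejection (bounding-circle separation, so
#' segmented components never touch); edges are anti-aliased with a
#' one-pixel linear ramp.
#'
#' @param conduits a [conduit_set()]. The total lumen area must not exceed
#'   60\% of the sector area (placement feasibility).
#' @param pixel_size image resolution, um per pixel (default 0.5, a typical
#'   light-microscopy scale).
#' @param seed optional integer seed.
#' @param aspect_range range of ellipse major/minor aspect ratios.
#' @param noise_sd SD of additive Gaussian pixel noise (0 disables).
#' @param max_attempts dart-throwing attempts per conduit before giving up.
#' @return An object of class `sector_image`: list with `pixels` (matrix in
#'   \[0, 1\], rows = y), `pixel_size`, `origin_um` (um coordinates of the
#'   center of pixel \[1, 1\]; the wedge apex is at (0, 0) and the wedge
#'   opens symmetrically about the +x axis), `theta_deg`, `radius_um` and
#'   `placements` (data frame of true centroids and ellipse parameters).
#' @export
render_sector <- function(conduits, pixel_size = 0.5, seed = NULL,
                          aspect_range = c(1, 1.3), noise_sd = 0.01,
                          max_attempts = 5000L) {
  stopifnot(inherits(conduits, "conduit_set"), pixel_size > 0)
  if (!is.null(seed)) set.seed(seed)
  areas <- conduits$lumen_areas
  sector_area <- conduits$sector_area
  if (sum(areas) > 0.6 * sector_area)
    stop("total lumen area exceeds 60% of the sector area; ",
         "placement is not feasible")
  theta <- conduits$sector_angle * pi / 180
  radius <- sqrt(2 * sector_area / theta)

  n <- length(areas)
  ord <- order(areas, decreasing = TRUE)  # place large conduits first
  q <- stats::runif(n, aspect_range[1L], aspect_range[2L])
  a <- sqrt(areas * q / pi)               # semi-major, um
  b <- a / q
  phi <- stats::runif(n, 0, pi)
  cx <- cy <- numeric(n)
  guard <- 2 * pixel_size
  margin <- 1.5 * pixel_size              # keep centroids clear of the border
  half <- theta / 2
  for (idx in ord) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- radius * sqrt(stats::runif(1L))
      ang <- stats::runif(1L, -half, half)
      x <- r * cos(ang); y <- r * sin(ang)
      if (r > radius - margin) next
      if (abs(ang) > half - margin / max(r, margin)) next
      prev <- which(cx != 0 | cy != 0)
      prev <- setdiff(prev, idx)
      if (length(prev)) {
        dd <- sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2)
        if (any(dd <= a[prev] + a[idx] + guard)) next
      }
      cx[idx] <- x; cy[idx] <- y
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place conduit of area ", format(areas[idx]),
           " um^2 after ", max_attempts, " attempts")
  }

  pad <- max(a) + 4 * pixel_size
  x_min <- -pad; x_max <- radius + pad
  y_half <- radius * sin(min(half, pi / 2)) + pad
  ncol_px <- ceiling((x_max - x_min) / pixel_size)
  nrow_px <- ceiling(2 * y_half / pixel_size)
  origin <- c(x_min + pixel_size / 2, -y_half + pixel_size / 2)

  bg <- 0.85; fg <- 0.10
  px <- matrix(bg, nrow = nrow_px, ncol = ncol_px)
  for (i in seq_len(n)) {
    half_ext <- a[i] + 2 * pixel_size
    c0 <- max(1L, floor((cx[i] - half_ext - origin[1L]) / pixel_size) + 1L)
    c1 <- min(ncol_px, ceiling((cx[i] + half_ext - origin[1L]) / pixel_size) + 1L)
    r0 <- max(1L, floor((cy[i] - half_ext - origin[2L]) / pixel_size) + 1L)
    r1 <- min(nrow_px, ceiling((cy[i] + half_ext - origin[2L]) / pixel_size) + 1L)
    xs <- origin[1L] + (seq(c0, c1) - 1) * pixel_size - cx[i]
    ys <- origin[2L] + (seq(r0, r1) - 1) * pixel_size - cy[i]
    gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
    xr <- gx * cos(phi[i]) + gy * sin(phi[i])
    yr <- -gx * sin(phi[i]) + gy * cos(phi[i])
    rho <- sqrt((xr / a[i])^2 + (yr / b[i])^2)
    cov <- pmin(1, pmax(0, (1 - rho) * b[i] / pixel_size + 0.5))
    block <- px[r0:r1, c0:c1]
    px[r0:r1, c0:c1] <- pmin(block, bg - (bg - fg) * cov)
  }
  if (noise_sd > 0) {
    px <- px + stats::rnorm(length(px), 0, noise_sd)
    px <- pmin(pmax(px, 0), 1)  # argument order preserves the matrix dims
  }

  structure(list(
    pixels = px, pixel_size = pixel_size, origin_um = origin,
    theta_deg = conduits$sector_angle, radius_um = radius,
    sample_id = conduits$sample_id, organ = conduits$organ,
    placements = data.frame(x_um = cx, y_um = cy, semi_major_um = a,
                            semi_minor_um = b, angle_rad = phi,
                            area_um2 = areas)),
    class = "sector_image")
}

#' @export
print.sector_image <- function(x, ...) {
  cat("Sector image:", nrow(x$pixels), "x", ncol(x$pixels), "px at",
      x$pixel_size, "um/px;", nrow(x$placements), "conduits;",
      format(x$theta_deg), "deg wedge, R =", format(round(x$radius_um, 1)),
      "um\n")
  invisible(x)
}

# Otsu threshold of a [0,1] grayscale matrix (256-bin histogram)
.otsu_threshold <- function(px, n_bins = 256L) {
  h <- tabulate(pmin(n_bins, floor(px * n_bins) + 1L), nbins = n_bins)
  w <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w1 <- cumsum(w)
  mu1 <- cumsum(w * mids)
  mu_total <- mu1[n_bins]
  between <- (mu_total * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Re-measure conduits from a sector image by segmentation
#'
#' Recovers a [conduit_set()] from a rendered (or otherwise supplied)
#' sector image: global thresholding (Otsu's bimodal-histogram method by
#' default, or a fixed value), connected-component labeling, an area
#' filter, and the centroid rule - a component counts as a conduit of the
#' sector exactly when its centroid lies inside the wedge. Lumen areas are
#' pixel counts times the pixel area.
#'
#' @param image a `sector_image`.
#' @param threshold `"otsu"` or a numeric gray value in (0, 1); pixels
#'   darker than the threshold are foreground.
#' @param min_area smallest component area kept, um^2.
#' @return A [conduit_set()] with the recovered lumen areas (empty
#'   components produce a warning and an error from the constructor is
#'   avoided by returning `NULL`).
#' @export
segment_conduits <- function(image, threshold = "otsu", min_area = 20) {
  stopifnot(inherits(image, "sector_image"))
  px <- image$pixels
  th <- if (identical(threshold, "otsu")) .otsu_threshold(px)
        else as.numeric(threshold)
  if (!is.finite(th) || th <= 0 || th >= 1)
    stop("threshold must be inside (0, 1)")
  binary <- px < th
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary * 1)))
  n_comp <- max(labels)
  if (n_comp == 0L) {
    warning("no components found; returning NULL")
    return(NULL)
  }
  ps <- image$pixel_size
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  x_um <- image$origin_um[1L] + (cols - 1L) * ps
  y_um <- image$origin_um[2L] + (rows - 1L) * ps
  count <- tabulate(lab, nbins = n_comp)
  cx <- rowsum(x_um, lab)[, 1L] / count
  cy <- rowsum(y_um, lab)[, 1L] / count
  area <- count * ps^2

  half <- image$theta_deg * pi / 180 / 2
  r <- sqrt(cx^2 + cy^2)
  ang <- atan2(cy, cx)
  keep <- area >= min_area & r <= image$radius_um & abs(ang) <= half
  if (!any(keep)) {
    warning("no conduits pass the area filter and centroid rule")
    return(NULL)
  }
  conduit_set(image$sample_id, image$organ,
              sector_angle = image$theta_deg,
              sector_area = image$theta_deg * pi / 180 / 2 *
                image$radius_um^2,
              lumen_areas = area[keep])
}

#' Write a sector image as PNG
#'
#' @param image a `sector_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sector_png <- function(image, path) {
  stopifnot(inherits(image, "sector_image"))
  png::writePNG(image$pixels, target = path)
  invisible(path)
}
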