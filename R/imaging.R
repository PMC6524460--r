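#' Percentile contrast stretch of a grayscale image
#'
#' Linearly rescales intensities so the `p_low` and `p_high` quantiles map
#' to 0 and 1 (full scale). The default stretches the observed min/max.
#' Pixel rank order is preserved. A constant image is returned unchanged
#' with a warning.
#'
#' @param image Numeric matrix of intensities (any scale; 8/16-bit values
#'   are accepted as-is).
#' @param p_low,p_high Quantiles mapped to the output endpoints.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
enhance_contrast <- function(image, p_low = 0, p_high = 1) {
  image <- as.matrix(image)
  stopifnot(is.numeric(image), p_low < p_high)
  q <- quantile(image, c(p_low, p_high), names = FALSE)
  if (q[1] == q[2]) {
    warning("constant image: contrast stretch is a no-op")
    return(image)
  }
  out <- (image - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Merge EBImage's 4-connected labels across diagonal adjacencies to obtain
# 8-connected components (union-find over the label set).
merge_diagonal_labels <- function(lab) {
  mx <- max(lab)
  if (mx < 2) return(lab)
  parent <- seq_len(mx)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
  }
  roots <- vapply(seq_len(mx), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment dark regions of an enhanced image
#'
#' Thresholds the image (global Otsu by default) and labels the connected
#' components of the dark foreground with 8-connectivity. Cryoconite holes
#' and sediment patches are darker than the surrounding ice, so foreground
#' means intensity below the threshold.
#'
#' @param image Numeric matrix in \[0, 1\] (see [enhance_contrast()]).
#' @param threshold `"otsu"` or a fixed numeric cutoff in (0, 1).
#' @param min_size Components smaller than this many pixels are dropped as
#'   noise (default 5).
#' @return Integer label matrix; 0 is background. Attribute `threshold`
#'   records the cutoff used.
#' @export
segment_dark_regions <- function(image, threshold = "otsu", min_size = 5L) {
  image <- as.matrix(image)
  stopifnot(is.numeric(image))
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    threshold
  }
  mask <- image < thr
  if (!any(mask)) {
    lab <- matrix(0L, nrow(image), ncol(image))
    attr(lab, "threshold") <- thr
    return(lab)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- merge_diagonal_labels(lab)
  if (min_size > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_size)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  attr(lab, "threshold") <- thr
  lab
}

#' Shape descriptors of segmented regions
#'
#' For each labeled component, computes area, centroid, the major-axis
#' length of the intensity-equivalent ellipse (from second central moments
#' of the pixel coordinates), and roundness `4 * area / (pi * major^2)`,
#' clipped at 1. A circle scores 1; a 2:1 ellipse scores 0.5; thin
#' elongated shapes score near 0. `literal_plus = TRUE` switches to the
#' variant `4 * area / (pi + major^2)` for auditing; it is not
#' scale-invariant and is not used by default.
#'
#' @param labels Integer label matrix from [segment_dark_regions()].
#' @param literal_plus Use the additive-denominator roundness variant.
#' @return data.frame with one row per region: `label`, `area_px`,
#'   `major_axis_px`, `roundness`, `centroid_x`, `centroid_y`.
#' @export
roi_shapes <- function(labels, literal_plus = FALSE) {
  labels <- as.matrix(labels)
  n <- max(labels, 0)
  out <- data.frame(label = integer(0), area_px = numeric(0),
                    major_axis_px = numeric(0), roundness = numeric(0),
                    centroid_x = numeric(0), centroid_y = numeric(0))
  if (n == 0) return(out)
  idx <- which(labels > 0)
  lb <- labels[idx]
  # pixel-center coordinates: x along columns, y along rows (image convention)
  y <- (idx - 1) %% nrow(labels)
  x <- (idx - 1) %/% nrow(labels)
  area <- tabulate(lb, nbins = n)
  cx <- tapply(x, lb, mean)
  cy <- tapply(y, lb, mean)
  mxx <- tapply(x, lb, var) * (area - 1) / area
  myy <- tapply(y, lb, var) * (area - 1) / area
  mxy <- vapply(seq_len(n), function(k) {
    s <- lb == k
    mean((x[s] - cx[k]) * (y[s] - cy[k]))
  }, numeric(1))
  mxx[is.na(mxx)] <- 0; myy[is.na(myy)] <- 0
  tr <- mxx + myy
  det <- mxx * myy - mxy^2
  lam1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
  major <- 4 * sqrt(pmax(lam1, 1 / 48))  # single pixel floor
  roundness <- if (literal_plus) 4 * area / (pi + major^2)
               else pmin(4 * area / (pi * major^2), 1)
  data.frame(label = seq_len(n), area_px = as.numeric(area),
             major_axis_px = as.numeric(major),
             roundness = as.numeric(roundness),
             centroid_x = as.numeric(cx), centroid_y = as.numeric(cy))
}

#' Fractional cryoconite coverage of an image
#'
#' Sums the area of regions whose roundness exceeds `roundness_min`
#' (strictly) and divides by the image area. The roundness filter excludes
#' elongated dark features such as moraine sediment bands, which would
#' otherwise inflate the coverage estimate.
#'
#' @param rois data.frame from [roi_shapes()].
#' @param image_area_px Total image area in pixels, > 0.
#' @param roundness_min Regions must exceed this roundness (default 0.6).
#' @return Fraction in \[0, 1\].
#' @export
coverage <- function(rois, image_area_px, roundness_min = 0.6) {
  stopifnot(image_area_px > 0, roundness_min >= 0, roundness_min <= 1)
  if (nrow(rois) == 0) return(0)
  sum(rois$area_px[rois$roundness > roundness_min]) / image_area_px
}

#' Per-region coverage summaries
#'
#' Aggregates per-image coverage fractions into per-region mean and sample
#' standard deviation, reported as percentages.
#'
#' @param per_image data.frame with columns `region` and `fraction`.
#' @return data.frame with `region`, `n_images`, `mean_pct`, `sd_pct`.
#' @export
aggregate_coverage <- function(per_image) {
  stopifnot(all(c("region", "fraction") %in% names(per_image)),
            all(per_image$fraction >= 0 & per_image$fraction <= 1))
  regions <- split(per_image$fraction, per_image$region)
  out <- data.frame(
    region = names(regions),
    n_images = vapply(regions, length, integer(1)),
    mean_pct = vapply(regions, function(f) 100 * mean(f), numeric(1)),
    sd_pct = vapply(regions, function(f) {
      if (length(f) < 2) return(0)
      100 * sd(f)
    }, numeric(1)),
    row.names = NULL)
  if (any(out$n_images < 2))
    warning("regions with a single image report SD = 0: ",
            paste(out$region[out$n_images < 2], collapse = ", "))
  out
}
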