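#' @name synthetic-data
#' @title Synthetic inputs with known ground truth
#' @description Generators for every input class the pipeline consumes:
#'   digitized boundaries with known retreat rates, bathymetry grids with
#'   closed-form volumes, glacier-surface scenes with known hole and patch
#'   areas, and Dirichlet-multinomial community tables with known source
#'   mixtures, planted contaminants and effect RSVs. Every generator is a
#'   pure function of its seed and parameters: repeated calls are
#'   identical. Each generator's truth payload is sufficient to compute
#'   the expected output of every downstream operation consuming its data.
NULL

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate digitized boundaries with known retreat rates
#'
#' Produces one boundary per year; between consecutive years the mean y
#' offset equals exactly `rate * duration` (in meters). Sinuosity is a
#' zero-mean wiggle shared by all epochs, so it cancels from mean offsets
#' but makes the polyline longer than its chord.
#'
#' @param seed RNG seed.
#' @param years Increasing calendar years (length >= 2).
#' @param rates_m_per_a Retreat rate of each interval (length
#'   `length(years) - 1`, >= 0).
#' @param sinuosity Amplitude of the shared wiggle, in pixels.
#' @param n_points Points per boundary (>= 2).
#' @param pixel_scale Meters per pixel.
#' @param width_px Boundary extent along x, in pixels.
#' @return List: `boundaries` (list of [glacier_boundary()]) and `truth`
#'   (`rates_m_per_a`, `offsets_m` cumulative from the first year,
#'   `weighted_mean_rate`).
#' @export
gen_boundaries <- function(seed, years = c(1939, 1995, 2015),
                           rates_m_per_a = c(1.16, 5.76), sinuosity = 8,
                           n_points = 200, pixel_scale = 1.2,
                           width_px = 1000) {
  stopifnot(length(years) >= 2, all(diff(years) > 0),
            length(rates_m_per_a) == length(years) - 1,
            all(rates_m_per_a >= 0))
  if (n_points < 2) stop("n_points must be >= 2")
  with_seed(substream_seed(seed, "boundaries"), {
    x <- seq(0, width_px, length.out = n_points)
    wiggle <- sinuosity * sin(2 * pi * x / (width_px / 3)) +
      rnorm(n_points, 0, sinuosity / 4)
    wiggle <- wiggle - mean(wiggle)  # exactly zero-mean
    cum_off_m <- c(0, cumsum(rates_m_per_a * diff(years)))
    boundaries <- lapply(seq_along(years), function(k) {
      y <- 100 + cum_off_m[k] / pixel_scale + wiggle
      glacier_boundary(years[k], cbind(x = x, y = y), pixel_scale)
    })
    list(boundaries = boundaries,
         truth = list(years = years, rates_m_per_a = rates_m_per_a,
                      offsets_m = cum_off_m,
                      weighted_mean_rate = sum(rates_m_per_a * diff(years)) /
                        sum(diff(years))))
  })
}

#' Generate a bathymetry grid with closed-form volume
#'
#' `shape = "uniform"` fills the whole extent at constant depth (volume
#' `depth * W * H`); `shape = "paraboloid"` builds a basin
#' `d(r) = d_max (1 - r^2 / R^2)` over a disk of radius `R` centered in a
#' `2R x 2R` extent (volume `d_max * pi * R^2 / 2`), with nodata outside
#' the rim.
#'
#' @param shape `"uniform"` or `"paraboloid"`.
#' @param depth_m Uniform depth, or maximum depth `d_max` for the
#'   paraboloid.
#' @param extent_m For `"uniform"`: c(width, height); for `"paraboloid"`:
#'   the basin radius R.
#' @param cell_size Grid cell size in meters.
#' @param origin Lower-left corner.
#' @return List: `grid` (a [bathymetry_grid()]) and `truth`
#'   (`volume_m3`).
#' @export
gen_bathymetry <- function(shape = c("uniform", "paraboloid"), depth_m = 10,
                           extent_m = c(1000, 1000), cell_size = 10,
                           origin = c(0, 0)) {
  shape <- match.arg(shape)
  if (shape == "uniform") {
    if (cell_size > min(extent_m)) stop("cell_size exceeds extent")
    nc <- round(extent_m[1] / cell_size)
    nr <- round(extent_m[2] / cell_size)
    grid <- bathymetry_grid(matrix(depth_m, nr, nc), origin, cell_size)
    vol <- depth_m * (nc * cell_size) * (nr * cell_size)
  } else {
    R <- extent_m[1]
    if (cell_size > 2 * R) stop("cell_size exceeds extent")
    n <- round(2 * R / cell_size)
    cx <- origin[1] + (seq_len(n) - 0.5) * cell_size
    cy <- origin[2] + (n - seq_len(n) + 0.5) * cell_size
    X <- matrix(cx, n, n, byrow = TRUE)
    Y <- matrix(cy, n, n)
    r2 <- (X - origin[1] - R)^2 + (Y - origin[2] - R)^2
    d <- depth_m * pmax(1 - r2 / R^2, 0)
    d[r2 > R^2] <- -9999
    grid <- bathymetry_grid(d, origin, cell_size)
    vol <- depth_m * pi * R^2 / 2
  }
  list(grid = grid, truth = list(volume_m3 = vol, shape = shape,
                                 depth_m = depth_m))
}

paint_disk <- function(img, cx, cy, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  i0 <- max(1, floor(cy - r)); i1 <- min(nr, ceiling(cy + r))
  j0 <- max(1, floor(cx - r)); j1 <- min(nc, ceiling(cx + r))
  ii <- i0:i1; jj <- j0:j1
  sub <- outer(ii - cy, jj - cx, function(a, b) a^2 + b^2) <= r^2
  img[ii, jj][sub] <- value
  img
}

paint_bar <- function(img, cx, cy, len, wid, theta, value) {
  nr <- nrow(img); nc <- ncol(img)
  half <- len / 2 + wid
  i0 <- max(1, floor(cy - half)); i1 <- min(nr, ceiling(cy + half))
  j0 <- max(1, floor(cx - half)); j1 <- min(nc, ceiling(cx + half))
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sub <- abs(u) <= len / 2 & abs(v) <= wid / 2
  img[ii, jj][sub] <- value
  img
}

#' Generate a glacier-surface scene with known hole coverage
#'
#' Bright noisy ice background with dark near-circular cryoconite holes
#' totaling `hole_coverage` of the image (within 0.1 percentage points, by
#' adjusting the final hole radius), plus dark elongated sediment patches
#' (aspect ratio >= 4, roundness below the 0.6 filter) totaling about
#' `patch_coverage`. No two features touch.
#'
#' @param seed RNG seed.
#' @param image_size Image edge length in pixels (square image).
#' @param hole_coverage Target hole area fraction.
#' @param n_holes Number of holes.
#' @param patch_coverage Target patch area fraction.
#' @param n_patches Number of elongated patches.
#' @param patch_aspect Patch length-to-width ratio (>= 4 recommended).
#' @return List: `image` (matrix in \[0, 1\]) and `truth` (`hole_px`,
#'   `patch_px`, `hole_fraction`, `patch_fraction`, `n_holes`,
#'   `n_patches`).
#' @export
gen_cryoconite_scene <- function(seed, image_size = 512,
                                 hole_coverage = 0.0346, n_holes = 25,
                                 patch_coverage = 0.02, n_patches = 4,
                                 patch_aspect = 6) {
  if (hole_coverage + patch_coverage >= 0.5)
    stop("combined coverage must stay below 0.5 for feasible packing")
  with_seed(substream_seed(seed, "scene"), {
    A <- image_size^2
    img <- matrix(pmin(pmax(rnorm(A, 0.85, 0.02), 0.6), 1),
                  image_size, image_size)
    occupied <- matrix(FALSE, image_size, image_size)
    features <- list()
    place <- function(rad_eff) {
      for (try in 1:500) {
        cx <- runif(1, rad_eff + 2, image_size - rad_eff - 2)
        cy <- runif(1, rad_eff + 2, image_size - rad_eff - 2)
        i0 <- max(1, floor(cy - rad_eff - 3)); i1 <- min(image_size, ceiling(cy + rad_eff + 3))
        j0 <- max(1, floor(cx - rad_eff - 3)); j1 <- min(image_size, ceiling(cx + rad_eff + 3))
        if (!any(occupied[i0:i1, j0:j1])) return(c(cx, cy))
      }
      stop("infeasible packing: could not place feature after 500 tries")
    }
    # patches first (they are big)
    patch_mask <- matrix(FALSE, image_size, image_size)
    if (n_patches > 0 && patch_coverage > 0) {
      per <- patch_coverage * A / n_patches
      wid <- sqrt(per / patch_aspect)
      len <- patch_aspect * wid
      for (k in seq_len(n_patches)) {
        theta <- runif(1, 0, pi)
        ctr <- place(len / 2 + wid)
        patch_mask <- paint_bar(patch_mask, ctr[1], ctr[2], len, wid, theta,
                                TRUE)
        occupied <- occupied | patch_mask
      }
    }
    # holes: split target area over holes, correct with the last radius
    hole_mask <- matrix(FALSE, image_size, image_size)
    target_px <- round(hole_coverage * A)
    areas <- target_px * rdirichlet1(rep(8, n_holes))
    for (k in seq_len(n_holes)) {
      if (k == n_holes) {
        deficit <- target_px - sum(hole_mask)
        if (deficit < 4) break
        # search the radius whose rasterized disk best matches the deficit
        r_cand <- seq(max(1, sqrt(deficit / pi) - 1.5),
                      sqrt(deficit / pi) + 1.5, by = 0.02)
        px <- vapply(r_cand, function(r) {
          d <- ceiling(r)
          g <- expand.grid(a = -d:d, b = -d:d)
          sum(g$a^2 + g$b^2 <= r^2)
        }, numeric(1))
        r <- r_cand[which.min(abs(px - deficit))]
      } else {
        r <- sqrt(areas[k] / pi)
      }
      ctr <- place(r)
      hole_mask <- paint_disk(hole_mask, ctr[1], ctr[2], r, TRUE)
      occupied <- occupied | hole_mask
    }
    img[patch_mask] <- pmin(pmax(rnorm(sum(patch_mask), 0.18, 0.02), 0), 0.35)
    img[hole_mask] <- pmin(pmax(rnorm(sum(hole_mask), 0.15, 0.02), 0), 0.35)
    list(image = img,
         truth = list(hole_px = sum(hole_mask), patch_px = sum(patch_mask),
                      hole_fraction = sum(hole_mask) / A,
                      patch_fraction = sum(patch_mask) / A,
                      n_holes = n_holes, n_patches = n_patches))
  })
}

#' Generate Dirichlet-multinomial community tables with known truth
#'
#' Each habitat gets a sparse base composition; samples are drawn
#' Dirichlet-multinomial around it (overdispersion set by `theta`).
#' Optional sink samples are multinomial draws from stated mixtures of
#' the habitat base profiles plus a novel "unknown" profile making up the
#' residual. Negative controls carry planted contaminant RSVs that are
#' also spiked into real samples at low abundance, and a set of effect
#' RSVs is fold-shifted in one habitat to give differential-abundance
#' tests a known answer.
#'
#' @param seed RNG seed.
#' @param habitats Habitat group names.
#' @param n_samples_per Samples per habitat.
#' @param depth_range Library-size range; depths are drawn uniformly in
#'   it (default matches amplicon depths of a few thousand to tens of
#'   thousands of reads).
#' @param n_rsvs Number of community RSVs (before contaminants).
#' @param base_alpha Dirichlet concentration of each habitat's base
#'   composition (small = sparse, distinct habitats).
#' @param theta Dirichlet-multinomial precision around the base profile.
#' @param sink_mixtures Named list: each element a named proportion
#'   vector over habitats with sum <= 1; the residual comes from the
#'   unknown profile. Each sink name yields `n_sinks_per` samples.
#' @param n_sinks_per Sink samples per mixture.
#' @param sink_depth Reads per sink sample.
#' @param n_contaminants Planted contaminant RSVs (present in controls
#'   and spiked everywhere).
#' @param n_controls Negative-control samples.
#' @param effect List `habitat_a`, `habitat_b`, `n`, `fold`: `n` RSVs are
#'   fold-multiplied in `habitat_b` samples.
#' @param share_profiles If `TRUE`, all habitats share one base
#'   composition (habitats differ only through sampling noise and any
#'   planted effect); default `FALSE` draws an independent composition
#'   per habitat.
#' @param genus_multiplicity Mean RSVs per genus in the generated
#'   taxonomy tree.
#' @return List: `table` (an [rsv_table()]; sinks carry habitat
#'   `"sink:<name>"`) and `truth` (base profiles, unknown profile,
#'   mixtures, contaminant and effect RSV ids, depths).
#' @export
gen_community_tables <- function(seed,
                                 habitats = c("glacier_ice", "cryoconite",
                                              "terrestrial", "air"),
                                 n_samples_per = 6,
                                 depth_range = c(3545, 50838),
                                 n_rsvs = 300, base_alpha = 0.3,
                                 theta = 200, sink_mixtures = NULL,
                                 n_sinks_per = 1, sink_depth = 2000,
                                 n_contaminants = 7, n_controls = 2,
                                 effect = NULL, genus_multiplicity = 2,
                                 share_profiles = FALSE) {
  with_seed(substream_seed(seed, "community"), {
    if (min(depth_range) < 100)
      warning("library sizes below 100 reads give unstable indices")
    rsv_ids <- sprintf("rsv_%03d", seq_len(n_rsvs))
    base <- if (share_profiles) {
      one <- rdirichlet1(rep(base_alpha, n_rsvs))
      vapply(habitats, function(h) one, numeric(n_rsvs))
    } else {
      vapply(habitats, function(h) rdirichlet1(rep(base_alpha, n_rsvs)),
             numeric(n_rsvs))
    }
    rownames(base) <- rsv_ids
    unknown_profile <- rdirichlet1(rep(base_alpha, n_rsvs))
    names(unknown_profile) <- rsv_ids

    samp_names <- character(0); samp_hab <- character(0)
    counts <- NULL
    for (h in habitats) {
      for (i in seq_len(n_samples_per)) {
        depth <- round(runif(1, depth_range[1], depth_range[2]))
        p <- rdirichlet1(theta * base[, h] + 1e-8)
        counts <- rbind(counts, as.integer(rmultinom(1, depth, p)))
        samp_names <- c(samp_names, sprintf("%s_%02d", h, i))
        samp_hab <- c(samp_hab, h)
      }
    }
    truth_mix <- NULL
    if (!is.null(sink_mixtures)) {
      truth_mix <- list()
      for (nm in names(sink_mixtures)) {
        mix <- sink_mixtures[[nm]]
        stopifnot(all(names(mix) %in% habitats), sum(mix) <= 1 + 1e-9)
        p_mix <- as.vector(base[, names(mix), drop = FALSE] %*% mix) +
          (1 - sum(mix)) * unknown_profile
        full <- setNames(c(mix[habitats], 1 - sum(mix)),
                         c(habitats, "Unknown"))
        full[is.na(full)] <- 0
        truth_mix[[nm]] <- full
        for (i in seq_len(n_sinks_per)) {
          counts <- rbind(counts,
                          as.integer(rmultinom(1, sink_depth, p_mix)))
          samp_names <- c(samp_names, sprintf("sink_%s_%02d", nm, i))
          samp_hab <- c(samp_hab, paste0("sink:", nm))
        }
      }
    }
    rownames(counts) <- samp_names
    colnames(counts) <- rsv_ids

    # effect RSVs: fold-shift in habitat_b; drawn from a configurable
    # abundance band of habitat_b's base composition (effect$band,
    # default 0.002-0.01) so the shift is detectable at typical read
    # depths while the planted mass stays a small fraction of the library
    effect_ids <- character(0)
    if (!is.null(effect)) {
      pb <- base[, effect$habitat_b]
      eb <- effect$band %||% c(0.002, 0.01)
      band <- rsv_ids[pb >= eb[1] & pb <= eb[2]]
      if (length(band) < effect$n)
        band <- rsv_ids[order(abs(pb - mean(eb)))][seq_len(effect$n * 2)]
      effect_ids <- sample(band, effect$n)
      sel <- samp_hab == effect$habitat_b
      counts[sel, effect_ids] <- as.integer(
        round(counts[sel, effect_ids] * effect$fold))
    }

    # contaminants: extra RSVs in controls, spiked into every real sample
    contam_ids <- character(0)
    if (n_contaminants > 0 && n_controls > 0) {
      contam_ids <- sprintf("contam_%02d", seq_len(n_contaminants))
      spike <- matrix(rbinom(nrow(counts) * n_contaminants, 20, 0.5),
                      nrow(counts), n_contaminants,
                      dimnames = list(rownames(counts), contam_ids))
      counts <- cbind(counts, spike)
      ctrl <- matrix(0L, n_controls, ncol(counts),
                     dimnames = list(sprintf("neg_ctrl_%02d",
                                             seq_len(n_controls)),
                                     colnames(counts)))
      ctrl[, contam_ids] <- rbinom(n_controls * n_contaminants, 200, 0.5)
      counts <- rbind(counts, ctrl)
    }

    all_ids <- colnames(counts)
    n_genera <- max(2, ceiling(length(all_ids) / genus_multiplicity))
    genus_of <- sprintf("genus_%03d", sample.int(n_genera, length(all_ids),
                                                 replace = TRUE))
    fam_of <- sprintf("family_%02d",
                      (match(genus_of, sort(unique(genus_of))) - 1) %/% 5 + 1)
    taxonomy <- data.frame(
      phylum = sprintf("phylum_%02d",
                       (match(fam_of, sort(unique(fam_of))) - 1) %/% 4 + 1),
      class = "class_1", order = fam_of, family = fam_of, genus = genus_of,
      row.names = all_ids)

    is_control <- grepl("^neg_ctrl", rownames(counts))
    habitat <- setNames(samp_hab, samp_names)
    tab <- rsv_table(counts, taxonomy, habitat,
                     is_control = setNames(is_control, rownames(counts)))
    list(table = tab,
         truth = list(base_profiles = base,
                      unknown_profile = unknown_profile,
                      sink_mixtures = truth_mix,
                      contaminant_rsvs = contam_ids,
                      effect_rsvs = effect_ids,
                      depth_range = depth_range))
  })
}
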