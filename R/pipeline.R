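default_config <- function() {
  list(
    seed = 1L,
    outdir = "cryoflux_out",
    stages = c("retreat", "meltvol", "coverage", "flux", "diversity",
               "compare", "sourcetrack"),
    scenario_dir = NULL,
    # imaging
    threshold = "otsu",
    roundness_min = 0.6,
    min_size = 5L,
    # flux constants
    cryoconite_thickness_m = 0.01,
    lake_volume_km3 = 0.872,
    swept_area_m2_per_a = NULL,
    annual_melt_m3_per_a = NULL,
    # statistics
    permutations = 999L,
    alpha = 0.05,
    fdr = 0.05,
    # source tracking
    sampler = unclass(sampler_config())
  )
}

validate_config <- function(cfg) {
  if (!is.null(cfg$roundness_min) &&
      (cfg$roundness_min < 0 || cfg$roundness_min > 1))
    stop("config key `roundness_min` must lie in [0, 1], got ",
         cfg$roundness_min)
  if (!is.null(cfg$lake_volume_km3) && cfg$lake_volume_km3 <= 0)
    stop("config key `lake_volume_km3` must be positive")
  if (!is.null(cfg$permutations) && cfg$permutations < 1)
    stop("config key `permutations` must be >= 1")
  if (!is.null(cfg$cryoconite_thickness_m) && cfg$cryoconite_thickness_m < 0)
    stop("config key `cryoconite_thickness_m` must be >= 0")
  bad <- setdiff(cfg$stages, default_config()$stages)
  if (length(bad)) stop("config key `stages` has unknown stage(s): ",
                        paste(bad, collapse = ", "))
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration, applies defaults for absent keys, rejects
#' unknown keys (naming them), and validates value ranges. An empty file
#' yields the all-defaults configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), c(names(cfg), names(cfg$sampler)))
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
      for (k in names(user)) {
        if (k %in% names(cfg$sampler)) cfg$sampler[[k]] <- user[[k]]
        else cfg[[k]] <- user[[k]]
      }
    }
  }
  structure(validate_config(cfg), class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg A config list from [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a grayscale image
#'
#' Accepts an 8/16-bit grayscale PNG (first channel of multichannel
#' input, via the png package) or a plain-text TSV matrix of intensities
#' in \[0, 1\].
#'
#' @param path Image path (`.png` or `.tsv`).
#' @return Numeric matrix in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the png package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    a
  } else {
    as.matrix(read.delim(path, header = FALSE))
  }
}

#' Write boundary digitizations to CSV
#'
#' Long format `epoch_year,x_px,y_px` plus a YAML sidecar holding
#' `pixel_scale_m`.
#'
#' @param boundaries List of [glacier_boundary()] objects sharing a scale.
#' @param path Output CSV path; the sidecar is `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  df <- do.call(rbind, lapply(boundaries, function(b)
    data.frame(epoch_year = b$year, x_px = b$points[, "x"],
               y_px = b$points[, "y"])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(pixel_scale_m = boundaries[[1]]$pixel_scale),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read boundary digitizations from CSV
#'
#' @param path CSV with columns `epoch_year,x_px,y_px`; pixel scale comes
#'   from the sidecar `<path>.yml` or the `pixel_scale` argument.
#' @param pixel_scale Meters per pixel; overrides the sidecar.
#' @return List of [glacier_boundary()], ordered by year.
#' @export
read_boundaries <- function(path, pixel_scale = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("epoch_year", "x_px", "y_px") %in% names(df)))
  if (is.null(pixel_scale)) {
    side <- paste0(path, ".yml")
    if (!file.exists(side))
      stop("missing required pixel scale: no sidecar ", side,
           " and no `pixel_scale` argument")
    pixel_scale <- yaml::read_yaml(side)$pixel_scale_m
  }
  years <- sort(unique(df$epoch_year))
  lapply(years, function(y) {
    sub <- df[df$epoch_year == y, ]
    glacier_boundary(y, cbind(x = sub$x_px, y = sub$y_px), pixel_scale)
  })
}

#' Write a self-contained synthetic scenario directory
#'
#' Generates every pipeline input with one master seed: boundary CSV,
#' ESRI ASCII bathymetry, glacier-surface scenes (TSV matrices with a
#' manifest assigning each to a region), and the community tables, plus
#' `truth.json` (all generator ground truths) and `manifest.json`
#' (parameters and seed). Regeneration with the same seed and parameters
#' is byte-identical.
#'
#' @param dir Output directory (created).
#' @param seed Master seed; each generator uses its own substream.
#' @param n_scenes Glacier-surface scenes per region.
#' @param scene_regions Named list of per-region hole/patch coverages,
#'   e.g. `list(interface = c(0.0636, 0.01), moraine = c(0.0173, 0.02))`.
#' @param sink_mixtures Passed to [gen_community_tables()].
#' @param ... Further arguments to [gen_community_tables()].
#' @return `dir`, invisibly; side effect: files written.
#' @export
simulate_scenario <- function(dir, seed = 1, n_scenes = 3,
                              scene_regions = list(
                                interface = c(0.0636, 0.01),
                                moraine = c(0.0173, 0.02)),
                              sink_mixtures = list(
                                mat = c(cryoconite = 0.5,
                                        glacier_ice = 0.3,
                                        terrestrial = 0.2)),
                              ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list(seed = seed)

  gb <- gen_boundaries(seed)
  write_boundaries(gb$boundaries, file.path(dir, "boundaries.csv"))
  truth$boundaries <- gb$truth

  bat <- gen_bathymetry("uniform", depth_m = 60,
                        extent_m = c(1200, 400), cell_size = 5)
  write_esri_ascii(bat$grid, file.path(dir, "bathymetry.asc"))
  truth$bathymetry <- bat$truth

  manifest_rows <- NULL
  truth$scenes <- list()
  k <- 0
  for (rg in names(scene_regions)) {
    for (i in seq_len(n_scenes)) {
      k <- k + 1
      sc <- gen_cryoconite_scene(substream_seed(seed, paste0(rg, i)),
                                 hole_coverage = scene_regions[[rg]][1],
                                 patch_coverage = scene_regions[[rg]][2])
      f <- sprintf("scene_%s_%02d.tsv", rg, i)
      write.table(round(sc$image, 4), file.path(dir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      manifest_rows <- rbind(manifest_rows,
                             data.frame(image_path = f, region = rg))
      truth$scenes[[f]] <- sc$truth
    }
  }
  write.table(manifest_rows, file.path(dir, "scenes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  com <- suppressWarnings(
    gen_community_tables(seed, sink_mixtures = sink_mixtures, ...))
  write_count_table(com$table, dir)
  truth$community <- com$truth[c("sink_mixtures", "contaminant_rsvs",
                                 "effect_rsvs")]

  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(seed = seed, n_scenes = n_scenes,
                            scene_regions = scene_regions,
                            package_version =
                              as.character(utils::packageVersion("cryoflux"))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline on a scenario directory
#'
#' Executes the selected stages in dependency order (retreat and coverage
#' feed flux; the community table feeds diversity, comparison and source
#' tracking), writes per-stage TSV/JSON outputs under `cfg$outdir`, and
#' returns (and writes) a single summary of the headline quantities. A
#' failing stage aborts its dependents but not independent branches.
#'
#' @param cfg A `run_config` from [load_config()]; `cfg$scenario_dir`
#'   must point to a directory laid out like [simulate_scenario()]'s
#'   output.
#' @return The summary list, invisibly; side effect: files under
#'   `cfg$outdir` including `summary.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(!is.null(cfg$scenario_dir))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sdir <- cfg$scenario_dir
  summary <- list(seed = cfg$seed)
  failed <- character(0)
  run_stage <- function(name, deps, expr) {
    if (!name %in% cfg$stages) return(NULL)
    if (any(deps %in% failed)) {
      message("stage ", name, " skipped: failed dependency")
      failed <<- c(failed, name)
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      message("stage ", name, " failed: ", conditionMessage(e))
      failed <<- c(failed, name)
      NULL
    })
    message(sprintf("stage %s: %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  boundaries <- NULL
  res_retreat <- run_stage("retreat", character(0), {
    boundaries <- read_boundaries(file.path(sdir, "boundaries.csv"))
    n <- length(boundaries)
    rates <- lapply(seq_len(n - 1), function(i)
      retreat_rate(boundaries[[i]], boundaries[[i + 1]]))
    ep <- epoch_rates(vapply(rates, `[[`, 0, "year_from"),
                      vapply(rates, `[[`, 0, "year_to"),
                      vapply(rates, `[[`, 0, "rate_m_per_a"))
    df <- cbind(ep, boundary_length_m =
                  vapply(seq_len(n - 1), function(i)
                    polyline_length(boundaries[[i]]), numeric(1)))
    write.table(df, file.path(cfg$outdir, "retreat.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(epochs = ep, weighted = weighted_mean_rate(ep),
         ref_length_m = polyline_length(boundaries[[1]]))
  })
  if (!is.null(res_retreat)) {
    summary$retreat_rates_m_per_a <- res_retreat$epochs$rate_m_per_a
    summary$weighted_mean_rate_m_per_a <- res_retreat$weighted
    summary$epoch_share_pct <- vapply(
      seq_len(nrow(res_retreat$epochs)),
      function(i) epoch_share(res_retreat$epochs, i), numeric(1))
  }

  res_melt <- run_stage("meltvol", "retreat", {
    grid <- read_esri_ascii(file.path(sdir, "bathymetry.asc"))
    est <- melt_volume_scenarios(boundaries[[1]],
                                 boundaries[[length(boundaries)]], grid)
    est
  })
  if (!is.null(res_melt)) {
    span <- res_retreat$epochs$year_to[nrow(res_retreat$epochs)] -
      res_retreat$epochs$year_from[1]
    summary$melt_volume_mean_m3 <- res_melt$mean_m3
    summary$melt_volume_half_range_m3 <- res_melt$half_range_m3
    summary$annual_melt_m3_per_a <- res_melt$mean_m3 / span
  }

  res_cov <- run_stage("coverage", character(0), {
    man <- read.delim(file.path(sdir, "scenes.tsv"))
    per <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
      img <- read_gray_image(file.path(sdir, man$image_path[i]))
      lab <- segment_dark_regions(enhance_contrast(img),
                                  threshold = cfg$threshold,
                                  min_size = cfg$min_size)
      data.frame(image = man$image_path[i], region = man$region[i],
                 fraction = coverage(roi_shapes(lab), length(img),
                                     cfg$roundness_min))
    }))
    write.table(per, file.path(cfg$outdir, "coverage_per_image.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    agg <- suppressWarnings(aggregate_coverage(per))
    write.table(agg, file.path(cfg$outdir, "coverage_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    agg
  })
  if (!is.null(res_cov)) summary$coverage_regions <- res_cov

  res_flux <- run_stage("flux", "coverage", {
    if (!is.null(res_retreat) && !is.null(res_melt)) {
      swept <- cfg$swept_area_m2_per_a %||%
        (res_retreat$weighted * res_retreat$ref_length_m)
      fb <- flux_budget(res_retreat$epochs,
                        coverage_low = min(res_cov$mean_pct) / 100,
                        coverage_high = max(res_cov$mean_pct) / 100,
                        swept_area_m2_per_a = swept,
                        annual_melt_m3_per_a = summary$annual_melt_m3_per_a,
                        thickness_m = cfg$cryoconite_thickness_m,
                        lake_volume_m3 = cfg$lake_volume_km3 * 1e9)
    } else {
      # declared fallback: no geometry results; both constants must be
      # supplied in the config
      if (is.null(cfg$swept_area_m2_per_a) ||
          is.null(cfg$annual_melt_m3_per_a))
        stop("flux without retreat/meltvol stages needs config keys ",
             "`swept_area_m2_per_a` and `annual_melt_m3_per_a`")
      warning("flux computed from supplied swept_area_m2_per_a and ",
              "annual_melt_m3_per_a (geometry stages not run)")
      f_low <- cryoconite_flux(min(res_cov$mean_pct) / 100,
                               cfg$cryoconite_thickness_m,
                               cfg$swept_area_m2_per_a)
      f_high <- cryoconite_flux(max(res_cov$mean_pct) / 100,
                                cfg$cryoconite_thickness_m,
                                cfg$swept_area_m2_per_a)
      fr <- flux_fractions(f_high, cfg$annual_melt_m3_per_a,
                           cfg$lake_volume_km3 * 1e9)
      fb <- list(flux_low_m3_per_a = f_low, flux_high_m3_per_a = f_high,
                 pct_of_annual_melt = fr$pct_of_melt,
                 pct_of_lake_volume = fr$pct_of_lake,
                 melt_pct_of_lake = melt_fraction_of_lake(
                   cfg$annual_melt_m3_per_a, cfg$lake_volume_km3 * 1e9))
    }
    jsonlite::write_json(unclass(fb), file.path(cfg$outdir, "flux.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fb
  })
  if (!is.null(res_flux)) {
    summary$flux_low_m3_per_a <- res_flux$flux_low_m3_per_a
    summary$flux_high_m3_per_a <- res_flux$flux_high_m3_per_a
    summary$flux_pct_of_annual_melt <- res_flux$pct_of_annual_melt
    summary$flux_pct_of_lake_volume <- res_flux$pct_of_lake_volume
    summary$melt_pct_of_lake <- res_flux$melt_pct_of_lake
  }

  tab <- NULL
  res_div <- run_stage("diversity", character(0), {
    tab <- suppressWarnings(
      read_count_table(file.path(sdir, "rsv_counts.tsv"),
                       file.path(sdir, "rsv_taxonomy.tsv"),
                       file.path(sdir, "rsv_metadata.tsv")))
    tab <- remove_control_rsvs(tab)
    alpha <- alpha_diversity(tab)
    write.table(alpha, file.path(cfg$outdir, "alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- bray_curtis(tab)
    write.table(as.matrix(dm), file.path(cfg$outdir, "bray_curtis.tsv"),
                sep = "\t", quote = FALSE)
    ord <- pcoa(dm)
    write.table(ord$coordinates, file.path(cfg$outdir, "pcoa.tsv"),
                sep = "\t", quote = FALSE)
    list(alpha = alpha, dm = dm, ord = ord)
  })
  if (!is.null(res_div)) {
    summary$n_rsvs_after_control_filter <- ncol(tab$counts)
    summary$n_removed_control_rsvs <- length(attr(tab, "removed_rsvs"))
    summary$mean_shannon <- mean(res_div$alpha$shannon, na.rm = TRUE)
    summary$pcoa_pct_axis1 <- 100 * res_div$ord$proportion_explained[1]
  }

  res_cmp <- run_stage("compare", "diversity", {
    hab <- tab$habitat[res_div$alpha$sample]
    src <- !grepl("^sink:", hab)
    cmp <- suppressWarnings(
      compare_alpha_groups(res_div$alpha$shannon[src], hab[src],
                           alpha = cfg$alpha))
    pm <- permanova(stats::as.dist(as.matrix(res_div$dm)[src, src]),
                    hab[src], n_perm = cfg$permutations, seed = cfg$seed)
    an <- anosim(stats::as.dist(as.matrix(res_div$dm)[src, src]),
                 hab[src], n_perm = cfg$permutations, seed = cfg$seed)
    sh <- genus_sharing(tab)
    jsonlite::write_json(
      list(cells = sh$cells, pairwise = sh$pairwise,
           total_genera = sh$total_genera),
      file.path(cfg$outdir, "sharing.json"), pretty = TRUE)
    list(alpha_test = cmp, permanova = pm, anosim = an, sharing = sh)
  })
  if (!is.null(res_cmp)) {
    summary$alpha_test_method <- res_cmp$alpha_test$method
    summary$alpha_test_p <- res_cmp$alpha_test$p_value
    summary$permanova_p <- res_cmp$permanova$p_value
    summary$anosim_r <- res_cmp$anosim$statistic
    summary$core_genus_pct <- core_genera(res_cmp$sharing)$pct
  }

  res_st <- run_stage("sourcetrack", "diversity", {
    hab <- tab$habitat
    sink_sel <- grepl("^sink:", hab)
    if (!any(sink_sel)) return(NULL)
    sink_names <- names(hab)[sink_sel]
    srcs <- pool_sources(tab, habitats = sort(unique(hab[!sink_sel])))
    cfg_s <- do.call(sampler_config,
                     utils::modifyList(cfg$sampler, list(seed = cfg$seed)))
    res <- fit_all(srcs, tab$counts[sink_names, , drop = FALSE], cfg_s)
    write.table(res, file.path(cfg$outdir, "source_proportions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  if (!is.null(res_st)) summary$source_proportions <- res_st

  summary$failed_stages <- failed
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_config(cfg, file.path(cfg$outdir, "config_used.yml"))
  if (length(failed)) warning("failed stages: ",
                              paste(unique(failed), collapse = ", "))
  invisible(summary)
}
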