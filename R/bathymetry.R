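#' Lake bathymetry as a regular depth grid
#'
#' @param depths Matrix of water depths in meters, positive down. Row 1 is
#'   the northernmost (top) row, matching the ESRI ASCII layout.
#' @param origin Numeric length-2: x, y of the lower-left corner (meters).
#' @param cell_size Cell edge length in meters, > 0.
#' @param nodata Value marking cells outside the basin (default -9999).
#' @return Object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(depths, origin = c(0, 0), cell_size = 1,
                            nodata = -9999) {
  depths <- as.matrix(depths)
  stopifnot(is.numeric(depths), length(origin) == 2,
            is.numeric(cell_size), cell_size > 0)
  valid <- depths != nodata & !is.na(depths)
  if (any(depths[valid] < 0))
    stop("depths must be >= 0 (positive down) or the nodata marker")
  structure(list(depths = depths, origin = as.numeric(origin),
                 cell_size = cell_size, nodata = nodata),
            class = "bathymetry_grid")
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  cat(sprintf("<bathymetry_grid %d x %d cells @ %.3g m, origin (%g, %g)>\n",
              nrow(x$depths), ncol(x$depths), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Read an ESRI ASCII raster as a bathymetry grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' whitespace-separated depths, top row first.
#'
#' @param path Path to the `.asc` file.
#' @return A [bathymetry_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ESRI ASCII header missing: ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  depths <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  bathymetry_grid(depths, origin = c(hdr$xllcorner, hdr$yllcorner),
                  cell_size = hdr$cellsize,
                  nodata = hdr[["nodata_value"]] %||% -9999)
}

#' Write a bathymetry grid to an ESRI ASCII raster
#'
#' @param grid A [bathymetry_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "bathymetry_grid"))
  hdr <- c(sprintf("ncols %d", ncol(grid$depths)),
           sprintf("nrows %d", nrow(grid$depths)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(grid$depths, 1, function(r) paste(format(r, trim = TRUE,
                                                         scientific = FALSE),
                                                  collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Cell-center coordinates of a grid; row 1 = top (max y).
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$depths); nc <- ncol(grid$depths); cs <- grid$cell_size
  cx <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  cy <- grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs
  list(x = matrix(cx, nr, nc, byrow = TRUE),
       y = matrix(cy, nr, nc, byrow = FALSE))
}

#' Water volume beneath a planar region
#'
#' Integrates grid depth over a polygon: by default every cell whose center
#' lies inside the polygon contributes its full cell area times its depth
#' (cell-center inclusion). Grid resolution controls the discretization
#' error. `exact = TRUE` refines boundary cells by subsampling each on a
#' `subdiv` x `subdiv` lattice for a closer area fraction.
#'
#' @param region A [swept_region()] or an n x 2 vertex matrix in meters.
#' @param grid A [bathymetry_grid()].
#' @param exact Refine partially covered cells by subsampling.
#' @param subdiv Subsamples per cell edge when `exact = TRUE`.
#' @return Volume in cubic meters (scalar, >= 0).
#' @export
melt_volume <- function(region, grid, exact = FALSE, subdiv = 4L) {
  stopifnot(inherits(grid, "bathymetry_grid"))
  poly <- if (inherits(region, "swept_region")) region$vertices else as.matrix(region)
  if (is.null(poly) || nrow(poly) < 3 ||
      abs(pracma::polyarea(poly[, 1], poly[, 2])) == 0) return(0)
  nr <- nrow(grid$depths); nc <- ncol(grid$depths); cs <- grid$cell_size
  xr <- grid$origin[1] + c(0, nc * cs)
  yr <- grid$origin[2] + c(0, nr * cs)
  if (max(poly[, 1]) < xr[1] || min(poly[, 1]) > xr[2] ||
      max(poly[, 2]) < yr[1] || min(poly[, 2]) > yr[2])
    stop("region lies entirely outside the bathymetry grid extent")
  ctr <- grid_cell_centers(grid)
  inside <- matrix(pracma::inpolygon(as.vector(ctr$x), as.vector(ctr$y),
                                     poly[, 1], poly[, 2], boundary = TRUE),
                   nr, nc)
  depth <- grid$depths
  is_nodata <- depth == grid$nodata | is.na(depth)
  if (any(inside & is_nodata))
    warning(sum(inside & is_nodata),
            " nodata cells inside the region contribute zero volume")
  depth[is_nodata] <- 0
  frac <- matrix(0, nr, nc)
  frac[inside] <- 1
  if (exact) {
    # refine cells whose 3x3 center neighborhood is mixed (cheap boundary test)
    nb <- inside
    grow <- function(m) {
      p <- matrix(FALSE, nr + 2, nc + 2); p[2:(nr + 1), 2:(nc + 1)] <- m
      out <- matrix(FALSE, nr, nc)
      for (di in -1:1) for (dj in -1:1)
        out <- out | p[2:(nr + 1) + di, 2:(nc + 1) + dj]
      out
    }
    mixed <- which(grow(nb) & grow(!nb))
    if (length(mixed)) {
      off <- (seq_len(subdiv) - 0.5) / subdiv - 0.5
      sub <- expand.grid(dx = off * cs, dy = off * cs)
      for (k in mixed) {
        i <- (k - 1) %% nr + 1; j <- (k - 1) %/% nr + 1
        cxk <- ctr$x[i, j] + sub$dx; cyk <- ctr$y[i, j] + sub$dy
        frac[i, j] <- mean(pracma::inpolygon(cxk, cyk, poly[, 1], poly[, 2],
                                             boundary = TRUE))
      }
    }
  }
  sum(frac * depth) * cs^2
}

#' Melt volume under both ice-front scenarios
#'
#' Computes the swept volume with the boundary treated as its endpoint
#' chord ("straight wall" scenario) and as the digitized surface polyline,
#' and reports the mean plus half the range, since the true subaqueous ice
#' front is neither exactly straight nor exactly the surface shape.
#'
#' @inheritParams mean_boundary_offset
#' @param grid A [bathymetry_grid()].
#' @param ... Passed to [melt_volume()].
#' @return List of class `melt_volume_estimate` with `v_chord_m3`,
#'   `v_polyline_m3`, `mean_m3`, `half_range_m3`.
#' @export
melt_volume_scenarios <- function(b_ref, b_new, grid, ...) {
  v_chord <- melt_volume(swept_region(b_ref, b_new, "chord"), grid, ...)
  v_poly <- melt_volume(swept_region(b_ref, b_new, "polyline"), grid, ...)
  structure(list(v_chord_m3 = v_chord, v_polyline_m3 = v_poly,
                 mean_m3 = (v_chord + v_poly) / 2,
                 half_range_m3 = abs(v_chord - v_poly) / 2),
            class = "melt_volume_estimate")
}

#' @export
print.melt_volume_estimate <- function(x, ...) {
  cat(sprintf("Melt volume: %.3g +/- %.3g m3 (chord %.3g, polyline %.3g)\n",
              x$mean_m3, x$half_range_m3, x$v_chord_m3, x$v_polyline_m3))
  invisible(x)
}
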