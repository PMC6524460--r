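# Shared fixtures, all built in code.

# straight horizontal boundary at a given y (pixels)
flat_boundary <- function(year, y, scale = 1, n = 11, width = 100) {
  glacier_boundary(year, cbind(x = seq(0, width, length.out = n), y = y),
                   scale)
}

# tiny rsv_table: counts given as samples x RSVs matrix
toy_table <- function(counts, habitat, genus = NULL, is_control = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("r", seq_len(ncol(counts)))
  genus <- genus %||% paste0("g_", colnames(counts))
  tax <- data.frame(phylum = "p1", class = "c1", order = "o1", family = "f1",
                    genus = genus, row.names = colnames(counts))
  if (is.null(is_control))
    is_control <- setNames(rep(FALSE, nrow(counts)), rownames(counts))
  suppressWarnings(
    rsv_table(counts, tax, setNames(habitat, rownames(counts)), is_control))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rasterize a filled shape given an inside() predicate on pixel centers
raster_mask <- function(n, inside) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  matrix(inside(g$x, g$y), n, n, byrow = TRUE) * 1L
}

# presence/absence table whose habitat genus sets are exactly as given
sets_table <- function(sets) {
  genera <- sort(unique(unlist(sets)))
  counts <- t(vapply(sets, function(s) as.integer(genera %in% s),
                     integer(length(genera))))
  rownames(counts) <- names(sets)
  colnames(counts) <- genera
  toy_table(counts, habitat = names(sets), genus = genera)
}
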