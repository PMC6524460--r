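#' Per-sample alpha diversity
#'
#' Observed richness, Shannon entropy (natural log) and inverse Simpson
#' index on the raw, unrarefied counts. For an empty sample the entropy
#' indices are `NA` and `degenerate` is flagged.
#'
#' @param table An [rsv_table()] or counts matrix (samples x RSVs).
#' @param base Logarithm base for Shannon (default `exp(1)`, i.e. nats).
#' @return data.frame: `sample`, `observed`, `shannon`, `inv_simpson`,
#'   `degenerate`.
#' @examples
#' alpha_diversity(matrix(c(25, 25, 25, 25), 1,
#'                        dimnames = list("s1", paste0("r", 1:4))))
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- if (inherits(table, "rsv_table")) {
    table$counts[!table$is_control, , drop = FALSE]
  } else as.matrix(table)
  tot <- rowSums(m)
  observed <- rowSums(m > 0)
  shannon <- rep(NA_real_, nrow(m))
  invsimp <- rep(NA_real_, nrow(m))
  ok <- tot > 0
  if (any(ok)) {
    shannon[ok] <- vegan::diversity(m[ok, , drop = FALSE], index = "shannon",
                                    base = base)
    invsimp[ok] <- vegan::diversity(m[ok, , drop = FALSE],
                                    index = "invsimpson")
  }
  data.frame(sample = rownames(m) %||% as.character(seq_len(nrow(m))),
             observed = as.integer(observed), shannon = shannon,
             inv_simpson = invsimp, degenerate = !ok, row.names = NULL)
}

#' Bray-Curtis dissimilarity on relative abundances
#'
#' Transforms each sample to relative abundance, then computes pairwise
#' Bray-Curtis dissimilarities. Values lie in \[0, 1\]; identical profiles
#' give 0 and disjoint supports give 1.
#'
#' @param table An [rsv_table()] or counts matrix (samples x RSVs);
#'   control samples are excluded.
#' @return A `dist` object.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "rsv_table")) {
    table$counts[!table$is_control, , drop = FALSE]
  } else as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  vegan::vegdist(relative_abundance(m), method = "bray")
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical (metric) scaling of the Gower-centered dissimilarity matrix.
#' Negative eigenvalues, which Bray-Curtis matrices commonly produce, are
#' reported but excluded from the explained-variance proportions.
#'
#' @param dm A `dist` or symmetric dissimilarity matrix.
#' @param n_axes Number of coordinate axes to return (default 2). If it
#'   exceeds the number of positive eigenvalues, zero axes pad the result
#'   with a warning.
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (over
#'   positive eigenvalues only).
#' @export
pcoa <- function(dm, n_axes = 2L) {
  dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  sc <- suppressWarnings(cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)]
  n_pos <- ncol(sc$points)
  coords <- sc$points
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive axes; padding with zeros")
    coords <- cbind(coords, matrix(0, n, n_axes - n_pos))
  }
  coords <- coords[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  prop <- c(pos / sum(pos), rep(0, n_axes))[seq_len(n_axes)]
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result: %d samples, %d axes (%s%% explained)>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(round(100 * x$proportion_explained, 1), collapse = ", ")))
  invisible(x)
}
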