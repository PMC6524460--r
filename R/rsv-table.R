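#' Amplicon RSV count table with taxonomy and metadata
#'
#' Container for a denoised amplicon dataset: a samples x RSVs count
#' matrix, a taxonomy table, a habitat-group label per sample, and flags
#' marking negative-control samples. RSV (ribosomal sequence variant) is
#' used synonymously with ASV.
#'
#' @param counts Non-negative integer matrix, samples in rows, RSVs in
#'   columns, both dimnamed.
#' @param taxonomy data.frame with rownames = RSV ids and columns
#'   `phylum`, `class`, `order`, `family`, `genus` (any entry may be
#'   `"unassigned"`).
#' @param habitat Named character vector: habitat group per sample.
#' @param is_control Named logical vector: negative-control flag per
#'   sample. Defaults to all FALSE.
#' @return Object of class `rsv_table`.
#' @export
rsv_table <- function(counts, taxonomy, habitat,
                      is_control = setNames(rep(FALSE, nrow(counts)),
                                            rownames(counts))) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample rownames and RSV colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate RSV ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  miss_tax <- setdiff(colnames(counts), rownames(taxonomy))
  if (length(miss_tax))
    stop("RSVs missing from taxonomy: ", paste(utils::head(miss_tax, 5),
                                               collapse = ", "))
  taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  is_control <- is_control[rownames(counts)]
  is_control[is.na(is_control)] <- FALSE
  names(is_control) <- rownames(counts)
  real <- rownames(counts)[!is_control]
  miss_hab <- setdiff(real, names(habitat))
  if (length(miss_hab))
    stop("samples missing habitat metadata: ", paste(miss_hab, collapse = ", "))
  habitat <- habitat[intersect(rownames(counts), names(habitat))]
  lib <- rowSums(counts[!is_control, , drop = FALSE])
  if (length(lib) > 1 && min(lib) > 0 && max(lib) / min(lib) > 10)
    warning("library sizes differ by more than 10x (", min(lib), "-",
            max(lib), "); indices are computed on raw counts (no rarefaction)")
  structure(list(counts = counts, taxonomy = taxonomy, habitat = habitat,
                 is_control = is_control),
            class = "rsv_table")
}

#' @export
print.rsv_table <- function(x, ...) {
  cat(sprintf("<rsv_table: %d samples (%d controls) x %d RSVs, %d habitats>\n",
              nrow(x$counts), sum(x$is_control), ncol(x$counts),
              length(unique(x$habitat))))
  invisible(x)
}

#' Read an RSV table from its three TSV files
#'
#' @param counts_path TSV, RSV rows x sample columns (first column RSV id).
#' @param taxonomy_path TSV with columns `rsv`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @param metadata_path TSV with columns `sample`, `habitat`, `is_control`.
#' @return An [rsv_table()].
#' @export
read_count_table <- function(counts_path, taxonomy_path, metadata_path) {
  cdf <- read.delim(counts_path, check.names = FALSE)
  rsv_ids <- as.character(cdf[[1]])
  m <- as.matrix(cdf[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m)))
    stop("non-integer counts in ", counts_path)
  rownames(m) <- rsv_ids
  tax <- read.delim(taxonomy_path)
  rownames(tax) <- tax$rsv
  tax$rsv <- NULL
  meta <- read.delim(metadata_path)
  need <- c("sample", "habitat", "is_control")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(colnames(m), meta$sample)
  if (length(miss))
    stop("samples in counts absent from metadata: ",
         paste(miss, collapse = ", "))
  rsv_table(t(m), tax,
            habitat = setNames(as.character(meta$habitat), meta$sample),
            is_control = setNames(as.logical(meta$is_control), meta$sample))
}

#' Write an RSV table to its three TSV files
#'
#' Inverse of [read_count_table()]; writes deterministic column order.
#'
#' @param table An [rsv_table()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_count_table <- function(table, dir, prefix = "rsv") {
  stopifnot(inherits(table, "rsv_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_counts.tsv", "_taxonomy.tsv",
                                           "_metadata.tsv")))
  cdf <- data.frame(rsv = colnames(table$counts), t(table$counts),
                    check.names = FALSE)
  write.table(cdf, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  tdf <- data.frame(rsv = rownames(table$taxonomy), table$taxonomy)
  write.table(tdf, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  mdf <- data.frame(sample = rownames(table$counts),
                    habitat = ifelse(table$is_control, "control",
                                     table$habitat[rownames(table$counts)]),
                    is_control = table$is_control)
  write.table(mdf, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(setNames(paths, c("counts", "taxonomy", "metadata")))
}

#' Remove RSVs detected in negative controls
#'
#' Any RSV with a nonzero count in any negative-control sample is removed
#' from every sample; the control samples themselves are dropped from the
#' output. The removed RSV ids are attached as attribute `removed_rsvs`.
#'
#' @param table An [rsv_table()] with at least one control sample.
#' @return A filtered [rsv_table()] without control samples.
#' @export
remove_control_rsvs <- function(table) {
  stopifnot(inherits(table, "rsv_table"))
  ctrl <- table$is_control
  if (!any(ctrl)) {
    warning("no negative-control samples; table returned unchanged")
    return(table)
  }
  in_ctrl <- colSums(table$counts[ctrl, , drop = FALSE] > 0) > 0
  dropped <- colnames(table$counts)[in_ctrl]
  counts <- table$counts[!ctrl, !in_ctrl, drop = FALSE]
  # library-size diagnostics were already issued when the input was built
  out <- suppressWarnings(
    rsv_table(counts,
              table$taxonomy[colnames(counts), , drop = FALSE],
              table$habitat,
              is_control = setNames(rep(FALSE, nrow(counts)),
                                    rownames(counts))))
  attr(out, "removed_rsvs") <- dropped
  out
}

#' Relative abundances of an RSV table
#'
#' @param table An [rsv_table()] or a counts matrix (samples x RSVs).
#' @return Matrix of row-normalized proportions.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "rsv_table")) table$counts else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero-total sample(s): ",
                          paste(rownames(m)[tot == 0], collapse = ", "))
  sweep(m, 1, tot, "/")
}
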