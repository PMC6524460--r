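#' Dunn's rank-based post hoc test
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis omnibus, with the
#' standard tie correction; p-values are two-sided and Bonferroni-adjusted
#' over the number of pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length.
#' @return data.frame: `group_a`, `group_b`, `z`, `p_value`, `adjusted_p`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  n <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ni <- table(groups)
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / ni[[p[1]]] + 1 / ni[[p[2]]]))
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  m <- ncol(pairs)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             z = res["z", ], p_value = res["p", ],
             adjusted_p = pmin(1, res["p", ] * m), row.names = NULL)
}

#' Compare an alpha-diversity index across habitat groups
#'
#' A Shapiro-Wilk test on the pooled within-group residuals (alpha 0.05)
#' gates the omnibus: ANOVA if the residuals look normal, Kruskal-Wallis
#' otherwise. If the omnibus rejects at `alpha`, post hoc pairwise tests
#' follow: Tukey HSD after ANOVA, Dunn's test with Bonferroni adjustment
#' after Kruskal-Wallis. Groups with fewer than 2 members are excluded
#' with a warning.
#'
#' @param values Numeric vector (e.g. a column of [alpha_diversity()]).
#' @param groups Group label per value.
#' @param alpha Significance level for the gate and omnibus (default 0.05).
#' @return List of class `group_comparison`: `normality_p`, `method`,
#'   `statistic`, `p_value`, and `posthoc` (data.frame or NULL).
#' @export
compare_alpha_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  keep_lv <- names(which(table(groups) >= 2))
  if (length(keep_lv) < nlevels(groups))
    warning("excluding single-member group(s): ",
            paste(setdiff(levels(groups), keep_lv), collapse = ", "))
  keep <- groups %in% keep_lv
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 members")
  if (length(unique(values)) == 1)
    return(structure(list(normality_p = NA_real_, method = "degenerate",
                          statistic = NA_real_, p_value = NA_real_,
                          posthoc = NULL),
                     class = "group_comparison"))
  resid <- values - ave(values, groups)
  sw <- tryCatch(shapiro.test(resid)$p.value, error = function(e) 0)
  if (sw >= alpha) {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    method <- "anova"
    stat <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    posthoc <- if (p < alpha) {
      tk <- TukeyHSD(fit)$groups
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      data.frame(group_a = vapply(nm, `[`, "", 2),
                 group_b = vapply(nm, `[`, "", 1),
                 diff = tk[, "diff"], p_value = tk[, "p adj"],
                 adjusted_p = tk[, "p adj"], row.names = NULL)
    }
  } else {
    kw <- kruskal.test(values, groups)
    method <- "kruskal-wallis"
    stat <- unname(kw$statistic)
    p <- kw$p.value
    posthoc <- if (p < alpha) dunn_test(values, groups)
  }
  structure(list(normality_p = sw, method = method, statistic = stat,
                 p_value = p, posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (Shapiro-Wilk gate p = %.3g)\n",
              x$method, x$statistic, x$p_value, x$normality_p))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n"); print(x$posthoc)
  }
  invisible(x)
}

#' Differential RSV abundance between two habitat groups
#'
#' Per-RSV two-sided Mann-Whitney (Wilcoxon rank-sum) tests on relative
#' abundances, with Benjamini-Hochberg FDR adjustment. RSVs constant
#' across all tested samples are skipped and reported with `NA` p-values.
#'
#' @param table An [rsv_table()].
#' @param group_a,group_b Habitat labels to contrast (>= 2 samples each).
#' @param fdr Significance threshold on the adjusted p (default 0.05).
#' @return data.frame: `rsv`, `statistic`, `p_value`, `adjusted_p`,
#'   `significant`.
#' @export
differential_abundance <- function(table, group_a, group_b, fdr = 0.05) {
  stopifnot(inherits(table, "rsv_table"))
  hab <- table$habitat[rownames(table$counts)]
  sel_a <- which(!table$is_control & hab == group_a)
  sel_b <- which(!table$is_control & hab == group_b)
  if (length(sel_a) < 2 || length(sel_b) < 2)
    stop("both groups need at least 2 samples")
  ra <- relative_abundance(table$counts[c(sel_a, sel_b), , drop = FALSE])
  ia <- seq_along(sel_a)
  ib <- length(sel_a) + seq_along(sel_b)
  res <- apply(ra, 2, function(v) {
    if (length(unique(v)) == 1) return(c(NA_real_, NA_real_))
    w <- suppressWarnings(wilcox.test(v[ia], v[ib], exact = FALSE))
    c(unname(w$statistic), w$p.value)
  })
  p <- res[2, ]
  adj <- p.adjust(p, method = "BH")
  data.frame(rsv = colnames(ra), statistic = res[1, ], p_value = p,
             adjusted_p = adj,
             significant = !is.na(adj) & adj < fdr, row.names = NULL)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance (the `adonis`
#' partition): a pseudo-F from the Gower-centered dissimilarity matrix,
#' with a permutation p-value `(1 + #better) / (1 + n_perm)`. Reruns with
#' the same seed are bit-identical.
#'
#' @param dm A `dist` object.
#' @param grouping Group label per sample (>= 2 groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed (default 1).
#' @return data.frame: `method`, `statistic` (pseudo-F), `r2`, `p_value`.
#' @export
permanova <- function(dm, grouping, n_perm = 999, seed = 1) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  df <- data.frame(grp = grouping)
  fit <- with_seed(seed,
    vegan::adonis2(dm ~ grp, data = df, permutations = n_perm))
  data.frame(method = "permanova", statistic = fit$F[1], r2 = fit$R2[1],
             p_value = fit$`Pr(>F)`[1])
}

#' ANOSIM on a dissimilarity matrix
#'
#' Analysis of similarities: the R statistic contrasts mean between-group
#' and within-group dissimilarity ranks, scaled to \[-1, 1\]; significance
#' by permutation. Reruns with the same seed are bit-identical.
#'
#' @inheritParams permanova
#' @return data.frame: `method`, `statistic` (R), `p_value`.
#' @export
anosim <- function(dm, grouping, n_perm = 999, seed = 1) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  fit <- with_seed(seed, vegan::anosim(dm, grouping, permutations = n_perm))
  data.frame(method = "anosim", statistic = fit$statistic,
             p_value = fit$signif)
}

#' Genus presence sharing across habitats
#'
#' Collapses the RSV table to genus presence per habitat and reports the
#' full intersection lattice: for every non-empty habitat combination, the
#' number of genera found in exactly those habitats (disjoint cells that
#' sum to the total), plus pairwise shared counts with percentages
#' relative to each member of the pair. RSVs unassigned at the requested
#' rank are excluded (their count is reported).
#'
#' @param table An [rsv_table()].
#' @param rank Taxonomy column to collapse on (default `"genus"`).
#' @param keep_unassigned Retain unassigned taxa as rank-qualified
#'   placeholders instead of dropping them.
#' @return List of class `sharing_summary`: `habitats`, `sets` (genus
#'   character vectors per habitat), `total_genera`, `cells` (data.frame
#'   `combo`, `n`), `pairwise` (data.frame `habitat_a`, `habitat_b`,
#'   `shared`, `pct_of_a`, `pct_of_b`), `n_unassigned_excluded`.
#' @export
genus_sharing <- function(table, rank = "genus", keep_unassigned = FALSE) {
  stopifnot(inherits(table, "rsv_table"))
  if (!rank %in% colnames(table$taxonomy))
    stop("taxonomy has no rank: ", rank)
  tax <- as.character(table$taxonomy[[rank]])
  names(tax) <- rownames(table$taxonomy)
  unassigned <- is.na(tax) | tax %in% c("", "unassigned", "Unassigned", "NA")
  if (keep_unassigned) {
    tax[unassigned] <- paste0(rank, "_unassigned_", names(tax)[unassigned])
    unassigned[] <- FALSE
  }
  counts <- table$counts[!table$is_control, , drop = FALSE]
  hab <- table$habitat[rownames(counts)]
  habs <- sort(unique(hab))
  empty <- setdiff(unique(table$habitat), habs)
  if (length(empty)) warning("habitats with no samples excluded: ",
                             paste(empty, collapse = ", "))
  sets <- lapply(habs, function(h) {
    present_rsv <- colnames(counts)[colSums(counts[hab == h, , drop = FALSE]) > 0]
    sort(unique(tax[setdiff(present_rsv, names(tax)[unassigned])]))
  })
  names(sets) <- habs
  all_genera <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_genera %in% s,
                       logical(length(all_genera)))
  if (length(all_genera) == 1) membership <- matrix(membership, nrow = 1,
                                                    dimnames = list(NULL, habs))
  combo <- apply(membership, 1, function(m) paste(habs[m], collapse = "&"))
  cells <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(cells) <- c("combo", "n")
  pw <- utils::combn(habs, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pw)), function(k) {
    a <- pw[1, k]; b <- pw[2, k]
    sh <- length(intersect(sets[[a]], sets[[b]]))
    data.frame(habitat_a = a, habitat_b = b, shared = sh,
               n_a = length(sets[[a]]), n_b = length(sets[[b]]),
               pct_of_a = 100 * sh / max(length(sets[[a]]), 1),
               pct_of_b = 100 * sh / max(length(sets[[b]]), 1))
  }))
  structure(list(habitats = habs, sets = sets,
                 total_genera = length(all_genera), cells = cells,
                 pairwise = pairwise,
                 n_unassigned_excluded = sum(unassigned)),
            class = "sharing_summary")
}

#' Number of genera present in every habitat
#'
#' @param sharing A `sharing_summary` from [genus_sharing()].
#' @return List `n_core`, `total`, `pct`.
#' @export
core_genera <- function(sharing) {
  core <- Reduce(intersect, sharing$sets)
  list(n_core = length(core), total = sharing$total_genera,
       pct = 100 * length(core) / sharing$total_genera)
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary: %d genera over %d habitats (%d unassigned excluded)>\n",
              x$total_genera, length(x$habitats), x$n_unassigned_excluded))
  invisible(x)
}
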