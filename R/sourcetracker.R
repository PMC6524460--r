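#' Sampler configuration for source tracking
#'
#' Defaults follow the canonical settings of the collapsed-Gibbs
#' Dirichlet-multinomial source-tracking algorithm: a small Dirichlet
#' smoothing `alpha_known = 0.001` on the known source profiles, a larger
#' `alpha_unknown = 0.1` letting the Unknown source absorb unexplained
#' taxa, and `beta = 10` pseudocounts on the mixing proportions.
#'
#' @param alpha_known Dirichlet smoothing for known source profiles (> 0).
#' @param alpha_unknown Smoothing for the Unknown source (> 0).
#' @param beta Pseudocounts on mixing proportions (> 0).
#' @param n_restarts Independent restarts averaged in the estimate (>= 1).
#' @param burn_in Discarded initial sweeps per restart.
#' @param n_draws Retained draws per restart.
#' @param thin Sweeps between retained draws.
#' @param seed Master RNG seed; each sink and restart gets its own
#'   deterministic substream.
#' @param track_training Whether sink assignments also accumulate onto the
#'   assigned known source's taxon counts during sampling.
#' @param init `"known"` starts every sink sequence on a known source
#'   (drawn proportional to the sources' smoothed taxon likelihoods), so
#'   the Unknown source only accumulates sequences the known sources
#'   cannot explain; `"uniform"` starts uniformly over all sources
#'   including Unknown. The known-source start avoids a label-switching
#'   race in which Unknown, having learned the sink's own composition
#'   from a random start, ties with a source that explains the sink
#'   equally well.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(alpha_known = 0.001, alpha_unknown = 0.1,
                           beta = 10, n_restarts = 10, burn_in = 100,
                           n_draws = 25, thin = 10, seed = 1,
                           track_training = TRUE,
                           init = c("known", "uniform")) {
  stopifnot(alpha_known > 0, alpha_unknown > 0, beta > 0,
            n_restarts >= 1, burn_in >= 0, n_draws >= 1, thin >= 1)
  structure(list(alpha_known = alpha_known, alpha_unknown = alpha_unknown,
                 beta = beta, n_restarts = as.integer(n_restarts),
                 burn_in = as.integer(burn_in),
                 n_draws = as.integer(n_draws), thin = as.integer(thin),
                 seed = as.integer(seed),
                 track_training = isTRUE(track_training),
                 init = match.arg(init)),
            class = "sampler_config")
}

#' Known source profiles for source tracking
#'
#' @param counts Sources x taxa count matrix with source rownames and
#'   taxon colnames; every source must have a positive total.
#' @return Object of class `source_profiles`.
#' @export
source_profiles <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs source rownames and taxon colnames")
  if (any(counts < 0)) stop("source counts must be non-negative")
  if (any(rowSums(counts) == 0))
    stop("all-zero source profile(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  structure(list(counts = counts, sources = rownames(counts),
                 taxa = colnames(counts)),
            class = "source_profiles")
}

#' Pool habitat samples into source profiles
#'
#' Builds one source profile per habitat group by pooling its samples.
#' The default pools raw counts (consistent with a no-rarefaction
#' workflow); `pool = "rarefy"` subsamples every sample to the smallest
#' library size first so deep samples do not dominate.
#'
#' @param table An [rsv_table()].
#' @param habitats Habitat groups to use as sources (default all).
#' @param pool `"sum"` or `"rarefy"`.
#' @param seed Seed for rarefaction draws.
#' @return A [source_profiles()].
#' @export
pool_sources <- function(table, habitats = NULL, pool = c("sum", "rarefy"),
                         seed = 1) {
  pool <- match.arg(pool)
  stopifnot(inherits(table, "rsv_table"))
  counts <- table$counts[!table$is_control, , drop = FALSE]
  hab <- table$habitat[rownames(counts)]
  habitats <- habitats %||% sort(unique(hab))
  counts <- counts[hab %in% habitats, , drop = FALSE]
  hab <- hab[hab %in% habitats]
  if (pool == "rarefy") {
    depth <- min(rowSums(counts))
    counts <- with_seed(seed, vegan::rrarefy(counts, depth))
  }
  pooled <- rowsum(counts, hab)
  source_profiles(pooled[habitats, , drop = FALSE])
}

fit_sink_one <- function(train, sink_counts, cfg, seed_id) {
  tokens <- rep.int(seq_along(sink_counts), sink_counts) - 1L
  v_names <- c(colnames(train), "Unknown")
  restart_means <- matrix(NA_real_, cfg$n_restarts, length(v_names),
                          dimnames = list(NULL, v_names))
  for (r in seq_len(cfg$n_restarts)) {
    draws <- with_seed(substream_seed(cfg$seed, paste0(seed_id, "#", r)),
                       st_gibbs(tokens, train, cfg$alpha_known,
                                cfg$alpha_unknown, cfg$beta, cfg$burn_in,
                                cfg$n_draws, cfg$thin, cfg$track_training,
                                identical(cfg$init %||% "known", "known")))
    restart_means[r, ] <- colMeans(draws)
  }
  list(proportions = colMeans(restart_means),
       sd = apply(restart_means, 2, sd))
}

#' Apportion one sink community among known sources plus Unknown
#'
#' Collapsed Gibbs sampling over per-sequence source assignments: each of
#' the sink's sequences carries a latent label over the known sources and
#' an Unknown source with no training data. Mixing proportions are the
#' posterior mean of the per-source assignment fractions over retained
#' draws, averaged across independent restarts; the across-restart
#' standard deviation quantifies Monte-Carlo spread. Deterministic given
#' `cfg$seed`.
#'
#' @param sources A [source_profiles()].
#' @param sink_counts Named taxon count vector aligned with
#'   `sources$taxa`; total >= 1.
#' @param cfg A [sampler_config()].
#' @return List of class `source_proportions`: `proportions` (named,
#'   sums to 1, includes `"Unknown"`), `sd`, `n_reads`.
#' @export
fit_sink <- function(sources, sink_counts, cfg = sampler_config()) {
  stopifnot(inherits(sources, "source_profiles"),
            inherits(cfg, "sampler_config"))
  if (!is.null(names(sink_counts))) {
    if (!setequal(names(sink_counts), sources$taxa))
      stop("sink taxa do not match source taxa")
    sink_counts <- sink_counts[sources$taxa]
  } else if (length(sink_counts) != length(sources$taxa)) {
    stop("sink vector length != number of source taxa")
  }
  if (sum(sink_counts) < 1) stop("sink has no sequences")
  fit <- fit_sink_one(t(sources$counts), as.integer(round(sink_counts)),
                      cfg, "sink")
  structure(list(proportions = fit$proportions, sd = fit$sd,
                 n_reads = sum(sink_counts)),
            class = "source_proportions")
}

#' @export
print.source_proportions <- function(x, ...) {
  p <- sprintf("%s %.3f (sd %.3f)", names(x$proportions), x$proportions,
               x$sd)
  cat("Source proportions:", paste(p, collapse = ", "), "\n")
  invisible(x)
}

#' Apportion several sink samples
#'
#' Independent [fit_sink()] runs per sink, each with its own deterministic
#' substream derived from `cfg$seed` and the sink name, so adding or
#' removing a sink never changes the others' results.
#'
#' @param sources A [source_profiles()].
#' @param sink_table Sinks x taxa count matrix (sink rownames, taxon
#'   colnames aligned with the sources).
#' @param cfg A [sampler_config()].
#' @return data.frame: one row per sink, mean proportion per source and
#'   `Unknown`, plus `<source>_sd` columns.
#' @export
fit_all <- function(sources, sink_table, cfg = sampler_config()) {
  sink_table <- as.matrix(sink_table)
  if (nrow(sink_table) == 0)
    return(data.frame(sink = character(0)))
  if (!is.null(colnames(sink_table))) {
    if (!setequal(colnames(sink_table), sources$taxa))
      stop("sink taxa do not match source taxa")
    sink_table <- sink_table[, sources$taxa, drop = FALSE]
  }
  train <- t(sources$counts)
  v_names <- c(sources$sources, "Unknown")
  sink_ids <- rownames(sink_table) %||% paste0("sink", seq_len(nrow(sink_table)))
  rows <- lapply(seq_len(nrow(sink_table)), function(i) {
    fit <- fit_sink_one(train, as.integer(sink_table[i, ]), cfg, sink_ids[i])
    c(fit$proportions, setNames(fit$sd, paste0(v_names, "_sd")))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(sink = sink_ids), out, row.names = NULL)
}

#' Leave-one-out validation of source separability
#'
#' Holds out each source-labelled sample in turn, rebuilds the pooled
#' source profiles from the remaining samples, and fits the held-out
#' sample as a sink. The per-environment mean proportion assigned back to
#' the sample's own environment ("self-assignment") measures how
#' identifiable the sources are.
#'
#' @param sample_counts Samples x taxa count matrix.
#' @param envs Environment label per sample (>= 2 environments).
#' @param cfg A [sampler_config()].
#' @return List of class `loo_validation`: `confusion` (env x env+Unknown
#'   mean proportions) and `self_assignment` (named vector).
#' @export
loo_validate <- function(sample_counts, envs, cfg = sampler_config()) {
  sample_counts <- as.matrix(sample_counts)
  envs <- as.character(envs)
  stopifnot(nrow(sample_counts) == length(envs))
  env_lv <- sort(unique(envs))
  if (length(env_lv) < 2) stop("need at least 2 source environments")
  v_names <- c(env_lv, "Unknown")
  acc <- matrix(0, length(env_lv), length(v_names),
                dimnames = list(env_lv, v_names))
  n_per <- setNames(rep(0, length(env_lv)), env_lv)
  ids <- rownames(sample_counts) %||% paste0("s", seq_len(nrow(sample_counts)))
  for (i in seq_len(nrow(sample_counts))) {
    rest <- sample_counts[-i, , drop = FALSE]
    rest_env <- envs[-i]
    pooled <- rowsum(rest, rest_env)
    avail <- rownames(pooled)[rowSums(pooled) > 0]
    if (length(avail) < 1) next
    if (!envs[i] %in% avail)
      warning("environment ", envs[i], " has a single sample; ",
              "its held-out fit has no same-environment source")
    train <- t(pooled[avail, , drop = FALSE])
    fit <- fit_sink_one(train, as.integer(sample_counts[i, ]), cfg,
                        paste0("loo:", ids[i]))
    p <- setNames(rep(0, length(v_names)), v_names)
    p[c(avail, "Unknown")] <- fit$proportions
    acc[envs[i], ] <- acc[envs[i], ] + p
    n_per[envs[i]] <- n_per[envs[i]] + 1
  }
  confusion <- sweep(acc, 1, pmax(n_per, 1), "/")
  structure(list(confusion = confusion,
                 self_assignment = setNames(confusion[cbind(env_lv, env_lv)],
                                            env_lv)),
            class = "loo_validation")
}

#' @export
print.loo_validation <- function(x, ...) {
  cat("Leave-one-out source validation (rows = held-out environment):\n")
  print(round(x$confusion, 3))
  invisible(x)
}
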