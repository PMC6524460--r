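# small, well-separated three-source fixture
make_sources <- function(n_taxa = 60, depth = 5000) {
  p <- matrix(0.2 / n_taxa, 3, n_taxa,
              dimnames = list(c("A", "B", "C"), paste0("t", seq_len(n_taxa))))
  blocks <- split(seq_len(n_taxa), rep(1:3, length.out = n_taxa))
  for (j in 1:3) p[j, blocks[[j]]] <- 0.8 / length(blocks[[j]])
  source_profiles(round(depth * p / rowSums(p)))
}

fast_cfg <- function(seed = 1)
  sampler_config(n_restarts = 3, burn_in = 50, n_draws = 10, thin = 5,
                 seed = seed)

test_that("proportions are a simplex and the sampler is seed-deterministic", {
  srcs <- make_sources()
  set.seed(99)
  sink <- as.integer(rmultinom(1, 800, rep(1 / 60, 60))[, 1])
  names(sink) <- srcs$taxa
  f1 <- fit_sink(srcs, sink, fast_cfg(7))
  f2 <- fit_sink(srcs, sink, fast_cfg(7))
  expect_equal(sum(f1$proportions), 1, tolerance = 1e-9)
  expect_true(all(f1$proportions >= 0))
  expect_identical(f1$proportions, f2$proportions)  # bit-for-bit
  f3 <- fit_sink(srcs, sink, fast_cfg(8))
  expect_false(identical(f1$proportions, f3$proportions))
})

test_that("a sink equal to one source is assigned to it", {
  # disjoint sources: nothing else can explain any of the sink
  counts <- matrix(0L, 3, 60,
                   dimnames = list(c("A", "B", "C"), paste0("t", 1:60)))
  for (j in 1:3) counts[j, ((j - 1) * 20 + 1):(j * 20)] <- 250L
  srcs <- source_profiles(counts)
  f <- fit_sink(srcs, srcs$counts["A", ], fast_cfg())
  expect_gte(f$proportions[["A"]], 0.95)
  # with overlapping sources the shared background is split, but the true
  # source still dominates
  ov <- make_sources()
  fo <- fit_sink(ov, ov$counts["A", ], fast_cfg())
  expect_gt(fo$proportions[["A"]], 0.85)
})

test_that("a sink on taxa unseen in any source goes to Unknown", {
  srcs <- make_sources(n_taxa = 60)
  counts <- cbind(srcs$counts,
                  matrix(0L, 3, 10,
                         dimnames = list(NULL, paste0("novel", 1:10))))
  srcs2 <- source_profiles(counts)
  sink <- setNames(rep(0L, 70), colnames(counts))
  sink[paste0("novel", 1:10)] <- 80L
  f <- fit_sink(srcs2, sink, fast_cfg())
  expect_gte(f$proportions[["Unknown"]], 0.90)
})

test_that("source relabeling leaves the estimates invariant", {
  srcs <- make_sources()
  set.seed(5)
  sink <- as.integer(rmultinom(1, 600,
                               colSums(srcs$counts) / sum(srcs$counts))[, 1])
  names(sink) <- srcs$taxa
  cfg <- sampler_config(n_restarts = 8, burn_in = 50, n_draws = 10,
                        thin = 5, seed = 3)
  f <- fit_sink(srcs, sink, cfg)
  perm <- source_profiles(srcs$counts[c("C", "A", "B"), ])
  fp <- fit_sink(perm, sink, cfg)
  # column order changes which RNG draw feeds which label, so agreement is
  # to Monte-Carlo precision, not bit-for-bit
  expect_equal(fp$proportions[names(f$proportions)], f$proportions,
               tolerance = 0.05)
})

test_that("identical sink samples give equal fits; empty input empty output", {
  srcs <- make_sources()
  set.seed(12)
  sink <- as.integer(rmultinom(1, 500, rep(1 / 60, 60))[, 1])
  tab <- rbind(a = sink, b = sink)
  colnames(tab) <- srcs$taxa
  res <- fit_all(srcs, tab, fast_cfg())
  # different substreams, same data: agreement within Monte-Carlo spread
  mc <- max(res$A_sd, res$B_sd, res$C_sd, res$Unknown_sd, 0.01)
  expect_lt(max(abs(as.numeric(res[1, 2:5]) - as.numeric(res[2, 2:5]))),
            4 * mc)
  expect_equal(nrow(fit_all(srcs, matrix(0L, 0, 60), fast_cfg())), 0)
})

test_that("deeper sinks recover a fixed mixture more accurately", {
  srcs <- make_sources(depth = 20000)
  p_mix <- as.vector((0.5 * srcs$counts["A", ] + 0.3 * srcs$counts["B", ] +
                        0.2 * srcs$counts["C", ]) / sum(srcs$counts["A", ]))
  truth <- c(0.5, 0.3, 0.2, 0)
  mae <- vapply(c(200, 2000), function(depth) {
    set.seed(31)
    tab <- t(vapply(1:4, function(i)
      as.integer(rmultinom(1, depth, p_mix)[, 1]), integer(60)))
    colnames(tab) <- srcs$taxa
    res <- fit_all(srcs, tab, fast_cfg())
    mean(abs(sweep(as.matrix(res[, c("A", "B", "C", "Unknown")]), 2,
                   truth)))
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("leave-one-out validation separates distinct sources", {
  set.seed(77)
  srcs <- make_sources()
  p <- sweep(srcs$counts, 1, rowSums(srcs$counts), "/")
  counts <- do.call(rbind, lapply(1:3, function(j)
    t(rmultinom(3, 3000, p[j, ]))))
  rownames(counts) <- paste0(rep(c("A", "B", "C"), each = 3), 1:3)
  colnames(counts) <- srcs$taxa
  envs <- rep(c("A", "B", "C"), each = 3)
  loo <- loo_validate(counts, envs, fast_cfg())
  expect_gte(mean(loo$self_assignment), 0.8)

  # two identical source environments split the assignment evenly
  counts2 <- do.call(rbind, lapply(1:2, function(j)
    t(rmultinom(3, 3000, p[1, ]))))
  rownames(counts2) <- paste0(rep(c("X", "Y"), each = 3), 1:3)
  colnames(counts2) <- srcs$taxa
  loo2 <- loo_validate(counts2, rep(c("X", "Y"), each = 3), fast_cfg())
  expect_equal(unname(loo2$self_assignment), c(0.5, 0.5), tolerance = 0.15)
})

test_that("degenerate inputs are rejected", {
  srcs <- make_sources()
  expect_error(fit_sink(srcs, setNames(rep(0L, 60), srcs$taxa), fast_cfg()),
               "no sequences")
  bad <- setNames(rep(1L, 5), paste0("x", 1:5))
  expect_error(fit_sink(srcs, bad, fast_cfg()), "match")
  expect_error(source_profiles(matrix(0, 2, 3,
                                      dimnames = list(c("a", "b"),
                                                      c("x", "y", "z")))),
               "all-zero")
})
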