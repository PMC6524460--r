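test_that("negative-control filtering removes exactly the contaminants", {
  # control all-zero: nothing removed, control column dropped
  m <- rbind(s1 = c(5L, 3L, 0L), s2 = c(1L, 0L, 2L), nc = c(0L, 0L, 0L))
  colnames(m) <- paste0("r", 1:3)
  tab <- toy_table(m, habitat = c("a", "a", "control"),
                   is_control = c(s1 = FALSE, s2 = FALSE, nc = TRUE))
  out <- remove_control_rsvs(tab)
  expect_equal(ncol(out$counts), 3)
  expect_equal(nrow(out$counts), 2)
  expect_length(attr(out, "removed_rsvs"), 0)

  # RSV present in control and samples vanishes everywhere
  m[3, 2] <- 7L
  tab2 <- toy_table(m, habitat = c("a", "a", "control"),
                    is_control = c(s1 = FALSE, s2 = FALSE, nc = TRUE))
  out2 <- remove_control_rsvs(tab2)
  expect_equal(colnames(out2$counts), c("r1", "r3"))
  expect_equal(attr(out2, "removed_rsvs"), "r2")

  # no controls: unchanged with warning
  tab3 <- toy_table(m[1:2, ], habitat = c("a", "a"))
  expect_warning(out3 <- remove_control_rsvs(tab3), "no negative-control")
  expect_identical(out3$counts, tab3$counts)

  # simulator: exactly the planted contaminants are dropped
  com <- suppressWarnings(gen_community_tables(31, n_contaminants = 7))
  filt <- remove_control_rsvs(com$table)
  expect_setequal(attr(filt, "removed_rsvs"), com$truth$contaminant_rsvs)
})

test_that("alpha diversity matches closed forms and a direct oracle", {
  uni <- matrix(c(25, 25, 25, 25), 1, dimnames = list("u", paste0("r", 1:4)))
  a <- alpha_diversity(uni)
  expect_equal(a$observed, 4L)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$inv_simpson, 4.0, tolerance = 1e-12)

  single <- matrix(17, 1, dimnames = list("s", "r1"))
  a1 <- alpha_diversity(single)
  expect_equal(a1$observed, 1L)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$inv_simpson, 1)

  counts <- c(10, 20, 70)
  p <- counts / sum(counts)
  a2 <- alpha_diversity(matrix(counts, 1,
                               dimnames = list("m", paste0("r", 1:3))))
  expect_equal(a2$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(a2$inv_simpson, 1 / sum(p^2), tolerance = 1e-12)

  # empty sample flagged degenerate
  z <- alpha_diversity(rbind(a = c(0, 0), b = c(1, 1)))
  expect_true(z$degenerate[1])
  expect_true(is.na(z$shannon[1]))

  # invariants on simulated data
  com <- suppressWarnings(gen_community_tables(5))
  av <- alpha_diversity(com$table)
  expect_true(all(av$shannon <= log(av$observed) + 1e-9))
  expect_true(all(av$inv_simpson <= av$observed + 1e-9))
  expect_true(all(av$inv_simpson >= 1))
})

test_that("Bray-Curtis on relative abundances hits hand values", {
  m <- rbind(s1 = c(10, 10, 0), s2 = c(5, 5, 10), s3 = c(10, 10, 0),
             s4 = c(0, 0, 7))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s3"], 0)           # identical profiles
  expect_equal(d["s1", "s4"], 1)           # disjoint supports
  # p1 = (.5,.5,0), p2 = (.25,.25,.5) -> 0.5
  expect_equal(d["s1", "s2"], 0.5)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "zero-total")
})

test_that("PCoA recovers planted geometry", {
  # three points at mutual distance 1: equilateral triangle, two equal
  # positive eigenvalues
  d3 <- stats::as.dist(matrix(1, 3, 3) - diag(3))
  ord <- pcoa(d3, n_axes = 2)
  ev <- ord$eigenvalues[ord$eigenvalues > 1e-10]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_equal(as.vector(dist(ord$coordinates)), rep(1, 3),
               tolerance = 1e-9)

  # planted 2-D configuration is recovered up to rotation
  set.seed(11)
  pts <- cbind(rnorm(8), rnorm(8))
  ord2 <- pcoa(dist(pts), n_axes = 2)
  expect_equal(as.vector(dist(ord2$coordinates)), as.vector(dist(pts)),
               tolerance = 1e-8)

  # duplicated sample lands on coincident coordinates
  pts2 <- rbind(pts, pts[1, ])
  ord3 <- pcoa(dist(pts2), n_axes = 2)
  expect_equal(ord3$coordinates[9, ], ord3$coordinates[1, ],
               tolerance = 1e-9)
  expect_warning(pcoa(d3, n_axes = 5), "padding")
})

test_that("group comparison gates on normality and runs post hocs", {
  set.seed(4)
  # clearly non-normal pooled residuals + separated groups -> KW + Dunn
  v <- c(rexp(15, 1), rexp(15, 1) + 40, rexp(15, 1) + 80)
  g <- rep(c("a", "b", "c"), each = 15)
  res <- compare_alpha_groups(v, g)
  expect_equal(res$method, "kruskal-wallis")
  expect_lt(res$p_value, 0.05)
  expect_s3_class(res$posthoc, "data.frame")
  expect_true(all(res$posthoc$adjusted_p >= res$posthoc$p_value - 1e-12))
  expect_true(all(res$posthoc$adjusted_p <= 1))

  # normal residuals -> ANOVA (+ Tukey when significant)
  vn <- c(rnorm(20, 0), rnorm(20, 5))
  gn <- rep(c("a", "b"), each = 20)
  resn <- compare_alpha_groups(vn, gn)
  expect_equal(resn$method, "anova")
  expect_lt(resn$p_value, 0.05)

  # exact small case: ranks fully separated
  r2 <- compare_alpha_groups(c(1, 2, 3, 101, 102, 103),
                             rep(c("lo", "hi"), each = 3))
  expect_lt(r2$p_value, 0.05)

  # single-member groups are excluded with a warning
  expect_warning(compare_alpha_groups(c(v, 1), c(g, "solo")), "single-member")
  # Bonferroni with one pair leaves p unchanged
  d1 <- dunn_test(c(1, 5, 2, 8, 9, 7), rep(c("x", "y"), each = 3))
  expect_equal(d1$adjusted_p, d1$p_value)
})

test_that("null omnibus p-values are approximately uniform", {
  set.seed(21)
  ps <- replicate(200, {
    v <- rnorm(16)
    compare_alpha_groups(v, rep(c("a", "b"), each = 8))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("differential abundance recovers planted shifts without FP", {
  # identical groups: nothing significant
  set.seed(8)
  m <- matrix(rpois(16 * 30, 20), 16, 30,
              dimnames = list(paste0("s", 1:16), paste0("r", 1:30)))
  tab <- toy_table(m, habitat = rep(c("a", "b"), each = 8))
  res0 <- differential_abundance(tab, "a", "b")
  expect_false(any(res0$significant, na.rm = TRUE))
  # BH adjustment equals the hand step-up rule on the same p-values
  p <- res0$p_value
  o <- order(p)
  byhand <- rep(NA_real_, length(p))
  byhand[o] <- rev(cummin(rev(p[o] * length(p[!is.na(p)]) /
                                 seq_along(p))))[seq_along(p)]
  expect_equal(res0$adjusted_p, pmin(byhand, 1))

  # planted 10-fold shifts in 5 RSVs, expectation over seeds
  hits <- 0; fps <- 0
  for (sd in 1:8) {
    com <- suppressWarnings(gen_community_tables(
      100 + sd, habitats = c("a", "b"), n_samples_per = 8,
      depth_range = c(30000, 50000), n_contaminants = 0,
      share_profiles = TRUE, n_rsvs = 100, theta = 10000,
      effect = list(habitat_a = "a", habitat_b = "b", n = 5, fold = 10,
                    band = c(2e-4, 8e-4))))
    res <- differential_abundance(com$table, "a", "b")
    sig <- res$rsv[which(res$significant)]
    hits <- hits + length(intersect(sig, com$truth$effect_rsvs))
    fps <- fps + length(setdiff(sig, com$truth$effect_rsvs))
  }
  expect_gte(hits / 8, 4)     # >= 4 of 5 planted RSVs recovered on average
  expect_lte(fps / 8, 0.5)    # false positives rare at FDR 0.05
})

test_that("constant RSVs are skipped as NA", {
  m <- matrix(10L, 6, 3, dimnames = list(paste0("s", 1:6), paste0("r", 1:3)))
  m[, 2] <- c(1L, 2L, 3L, 30L, 40L, 50L)
  m[, 3] <- 0L  # never observed: constant zero relative abundance
  tab <- toy_table(m, habitat = rep(c("a", "b"), each = 3))
  res <- differential_abundance(tab, "a", "b")
  expect_true(is.na(res$p_value[3]))
  expect_false(res$significant[3] %in% TRUE)
  expect_false(is.na(res$p_value[2]))
})
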