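# Enrichment pipeline: mask fidelity, score algebra, normalization, ANOVA,
# cohort-level recovery of the designed recruitment level.

test_that("reference mask captures strain sites and excludes background", {
  sc <- make_scene(scene_spec(width = 160, height = 160, n_filaments = 5,
                              photon_noise = FALSE, read_sigma = 0, seed = 12))
  mask <- build_reference_mask(sc$rfp)
  sm <- sc$truth$strain_mask
  er_sm <- erode(sm, 1)
  expect_gt(sum(er_sm), 0)
  # the eroded true strain region lies inside the pipeline mask
  expect_gte(sum(mask & er_sm) / sum(er_sm), 0.99)
  # and the mask stays out of the structure-free region (beyond a small
  # dilation of the true filaments that absorbs the blur halo)
  off <- !dilate_mask(sc$truth$filament_mask, 3)
  expect_lte(sum(mask & off) / sum(off), 0.01)
})

test_that("degenerate or all-small reference channels give an empty mask", {
  const <- as_image(matrix(42, 64, 64), 16L)
  expect_false(any(build_reference_mask(const)))
  expect_error(measure_enrichment(const, const,
                                  build_reference_mask(const)), "empty mask")
})

test_that("the erosion step tightens the mask but preserves rank order", {
  sc <- make_scene(scene_spec(width = 128, height = 128, n_filaments = 5,
                              seed = 33))
  with_er <- build_reference_mask(sc$rfp, mask_params(erode_iterations = 1))
  without <- build_reference_mask(sc$rfp, mask_params(erode_iterations = 0))
  expect_lt(sum(with_er), sum(without))
  # scores differ between modes but rank order over rho is preserved
  mean_scores <- function(p) vapply(c(0, 1), function(rho) {
    mean(vapply(1:3, function(s) {
      s2 <- make_scene(scene_spec(width = 128, height = 128, n_filaments = 5,
                                  enrichment_rho = rho, seed = 600 + s))
      measure_enrichment(s2$gfp, s2$rfp, build_reference_mask(s2$rfp, p))$score
    }, numeric(1)))
  }, numeric(1))
  m1 <- mean_scores(mask_params(erode_iterations = 1))
  m0 <- mean_scores(mask_params(erode_iterations = 0))
  expect_lt(m1[1], m1[2])
  expect_lt(m0[1], m0[2])
})

test_that("score algebra: uniform GFP, offset invariance, scale equivariance", {
  set.seed(61)
  for (i in 1:50) {
    nr <- sample(24:40, 1); nc <- sample(24:40, 1)
    rfp <- matrix(runif(nr * nc, 50, 500), nr, nc)
    gfp <- matrix(runif(nr * nc, 10, 800), nr, nc)
    mask <- random_mask(nr, nc, 0.3)
    if (!any(mask) || all(mask)) next
    m <- measure_enrichment(gfp, rfp, mask)
    # uniform offset cancels
    mo <- measure_enrichment(gfp + 123.4, rfp, mask)
    expect_lt(abs(mo$score - m$score), 1e-9)
    # scaling is exactly equivariant
    ms <- measure_enrichment(gfp * 3.25, rfp, mask)
    expect_equal(ms$score, 3.25 * m$score, tolerance = 1e-12)
  }
  # spatially uniform GFP scores exactly 0
  rfp <- matrix(runif(900, 100, 400), 30, 30)
  mask <- random_mask(30, 30, 0.4)
  u <- measure_enrichment(matrix(55, 30, 30), rfp, mask)
  expect_equal(u$score, 0)
  # GFP identical to RFP with RFP ~ 0 outside the mask: score ~ 1
  rfp2 <- matrix(0.001, 30, 30); rfp2[mask] <- 300
  g2 <- measure_enrichment(rfp2, rfp2, mask)
  expect_equal(g2$score, 1, tolerance = 1e-2)
})

test_that("measurement rejects mismatched shapes and zero reference signal", {
  gfp <- matrix(1, 10, 10); rfp <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  expect_error(measure_enrichment(gfp, matrix(1, 9, 10), mask), "dimensions")
  expect_error(measure_enrichment(gfp, rfp, mask), "RFP_i")
})

test_that("per-trial normalization sets the reference mean to exactly 1", {
  tab <- data.frame(trial = c(1, 1, 1, 1, 2, 2, 2),
                    group = c("WT", "WT", "mut", "mut", "WT", "mut", "mut"),
                    score = c(0.2, 0.4, 0.1, 0.2, 0.8, 0.2, 0.6))
  out <- normalize_scores(tab, "WT")
  expect_equal(out$score_norm[1:2], c(2 / 3, 4 / 3))
  for (tr in unique(out$trial))
    expect_equal(mean(out$score_norm[out$trial == tr & out$group == "WT"]), 1,
                 tolerance = 1e-12)
  # per-trial scaling: mutant rows divided by their own trial's WT mean
  expect_equal(out$score_norm[out$trial == 2 & out$group == "mut"],
               c(0.2, 0.6) / 0.8)
  # errors name the offending trial
  expect_error(normalize_scores(data.frame(trial = 3, group = "mut", score = 1),
                                "WT"), "3")
  z <- data.frame(trial = 1, group = c("WT", "WT"), score = c(-1, 1))
  expect_error(normalize_scores(z, "WT"), "0")
})

test_that("one-way ANOVA matches the hand-derived closed form and a permutation oracle", {
  tab <- data.frame(group = rep(c("a", "b"), each = 3),
                    score = c(1, 2, 3, 4, 5, 6))
  r <- compare_groups(tab, value = "score")
  # SS_between = 13.5, SS_within = 4, F = 13.5 / (4/4) = 13.5 on (1, 4) df
  expect_equal(r$F, 13.5, tolerance = 1e-12)
  expect_equal(unname(r$df), c(1, 4))
  expect_equal(r$p, stats::pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$summary$mean, c(2, 5))

  # permutation oracle on a moderate sample
  set.seed(71)
  y <- c(rnorm(12, 0), rnorm(12, 0.9))
  tb <- data.frame(group = rep(c("x", "z"), each = 12), score = y)
  ref <- compare_groups(tb, value = "score")
  fstat <- function(yy, g) {
    m <- tapply(yy, g, mean); n <- tapply(yy, g, length)
    gm <- mean(yy)
    ssb <- sum(n * (m - gm)^2)
    ssw <- sum((yy - ave(yy, g))^2)
    (ssb / 1) / (ssw / (length(yy) - 2))
  }
  g <- tb$group
  perm <- replicate(10000, fstat(sample(y), g))
  p_perm <- mean(perm >= ref$F)
  mc_err <- 3 * sqrt(ref$p * (1 - ref$p) / 10000) + 2e-3
  expect_lt(abs(p_perm - ref$p), mc_err + 0.01)

  # degenerate: identical constants in every group
  dg <- data.frame(group = rep(c("a", "b"), each = 2), score = c(1, 1, 2, 2))
  rd <- compare_groups(dg, value = "score")
  expect_true(rd$degenerate)
  expect_equal(rd$F, Inf)
  expect_error(compare_groups(data.frame(group = "a", score = 1)), "2 groups")
  expect_error(compare_groups(data.frame(group = c("a", "a", "b"),
                                         score = 1:3)), "at least 2 values")
})

test_that("cohort experiment recovers the designed recruitment gradient", {
  mk_cohort <- function(rhos, n_per, size = 128, seed0 = 0) {
    imgs <- list()
    for (gi in seq_along(rhos)) for (k in seq_len(n_per)) {
      sc <- make_scene(scene_spec(width = size, height = size, n_filaments = 5,
                                  enrichment_rho = rhos[gi],
                                  seed = seed0 + gi * 100 + k))
      imgs[[length(imgs) + 1]] <- list(gfp = sc$gfp, rfp = sc$rfp, trial = 1,
                                       group = paste0("rho_", rhos[gi]),
                                       image = paste0("g", gi, "k", k))
    }
    imgs
  }
  exp1 <- run_enrichment_experiment(mk_cohort(c(1, 0), 5), mask_params(),
                                    reference_group = "rho_1")
  agg <- tapply(exp1$scores$score_norm, exp1$scores$group, mean)
  expect_equal(unname(agg["rho_1"]), 1, tolerance = 1e-12)
  expect_lt(unname(agg["rho_0"]), 0.3)
  expect_lt(exp1$stats$p, 0.01)

  # graded groups come out in strict rank order
  exp2 <- run_enrichment_experiment(mk_cohort(c(0, 0.5, 1), 4, seed0 = 5000),
                                    reference_group = "rho_1")
  m <- tapply(exp2$scores$score_norm, exp2$scores$group, mean)
  expect_true(m[["rho_0"]] < m[["rho_0.5"]] &&
              m[["rho_0.5"]] < m[["rho_1"]])

  # single group: normalization works, ANOVA is skipped with a message
  expect_message(
    exp3 <- run_enrichment_experiment(mk_cohort(1, 3, size = 96, seed0 = 900),
                                      reference_group = "rho_1"),
    "skipped")
  expect_null(exp3$stats)
  expect_equal(mean(exp3$scores$score_norm), 1, tolerance = 1e-12)

  # determinism of the full pipeline
  exp1b <- run_enrichment_experiment(mk_cohort(c(1, 0), 5), mask_params(),
                                     reference_group = "rho_1")
  expect_identical(exp1$scores, exp1b$scores)
})
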