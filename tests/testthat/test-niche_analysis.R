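test_that("usage profiles are normalized category proportions", {
  ds <- build_dataset(
    presence_cats = list(BM = list(depth = rep(2L, 10))),
    pa_cats = list(breeding = list()))
  up <- usage_profile(ds, "BM", "depth")
  expect_equal(up$P, c(0, 1, 0))
  expect_equal(up$R, 3L)

  ds2 <- build_dataset(
    presence_cats = list(BF = list(depth = cats_from_counts(c(5, 3, 2)))))
  expect_equal(usage_profile(ds2, "BF", "depth")$P, c(0.5, 0.3, 0.2))
  expect_error(usage_profile(ds2, "NBM", "depth"), "no presence records")

  ds2$records$depth[] <- NA
  expect_error(usage_profile(ds2, "BF", "depth"), "no non-missing values")
})

test_that("Levins breadth hits its closed-form anchors", {
  expect_equal(levins_width(rep(1 / 3, 3)), 3)
  expect_equal(levins_width(c(1, 0, 0)), 1)
  expect_equal(levins_width(c(0.5, 0.3, 0.2)), 1 / 0.38)
  expect_equal(round(levins_width(c(0.5, 0.3, 0.2)), 4), 2.6316)
  expect_error(levins_width(c(0.5, 0.4)), "summing to 1")
})

test_that("breadth is permutation invariant and bounded in [1, R] (property)", {
  set.seed(201)
  for (rep in 1:100) {
    R <- sample(2:8, 1)
    P <- as.vector(stats::rmultinom(1, 60, runif(R) + 0.05)) / 60
    B <- levins_width(P)
    expect_gte(B, 1 - 1e-12)
    expect_lte(B, R + 1e-12)
    expect_equal(levins_width(P[sample(R)]), B)
  }
})

test_that("aggregate group breadth averages per-factor breadths", {
  # uniform use of every category of both factors -> aggregate B = 3
  ds <- build_dataset(
    presence_cats = list(NBM = list(depth = cats_from_counts(c(4, 4, 4)),
                                    substrate = cats_from_counts(c(4, 4, 4)))))
  nw <- group_niche_width(ds, "NBM", exclude_factors = character())
  expect_equal(nw$aggregate_B, 3)
  expect_equal(unname(nw$per_factor_B), c(3, 3))
  # complete concentration -> aggregate B = 1
  ds1 <- build_dataset(presence_cats = list(NBF = list(depth = rep(1L, 8),
                                                       substrate = rep(3L, 8))))
  expect_equal(group_niche_width(ds1, "NBF",
                                 exclude_factors = character())$aggregate_B, 1)
  # harmonic aggregation is an available alternative and differs in general
  ds3 <- build_dataset(
    presence_cats = list(BM = list(depth = cats_from_counts(c(6, 1, 1)),
                                   substrate = cats_from_counts(c(3, 3, 2)))))
  m <- group_niche_width(ds3, "BM", exclude_factors = character())
  h <- group_niche_width(ds3, "BM", exclude_factors = character(),
                         aggregation = "harmonic")
  expect_lt(h$aggregate_B, m$aggregate_B)
})

test_that("directional Levins overlap matches direct arithmetic", {
  expect_equal(levins_overlap(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3)), 1)
  expect_equal(levins_overlap(c(1, 0, 0), c(0, 0.5, 0.5)), 0)
  expect_equal(levins_overlap(c(1, 0, 0), c(0.5, 0.5, 0)), 0.5)
  expect_equal(levins_overlap(c(0.5, 0.5, 0), c(1, 0, 0)), 1.0)
  expect_error(levins_overlap(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("overlap is symmetric exactly when concentrations match (property)", {
  set.seed(202)
  for (rep in 1:100) {
    R <- sample(2:6, 1)
    Pi <- as.vector(stats::rmultinom(1, 40, runif(R) + 0.05)) / 40
    Pk <- as.vector(stats::rmultinom(1, 40, runif(R) + 0.05)) / 40
    expect_gte(levins_overlap(Pi, Pk), 0)
    # simultaneous category permutation leaves the index unchanged
    perm <- sample(R)
    expect_equal(levins_overlap(Pi[perm], Pk[perm]), levins_overlap(Pi, Pk))
    if (abs(sum(Pi^2) - sum(Pk^2)) < 1e-12)
      expect_equal(levins_overlap(Pi, Pk), levins_overlap(Pk, Pi))
  }
  # and a constructed equal-concentration pair
  Pi <- c(0.5, 0.3, 0.2); Pk <- c(0.2, 0.3, 0.5)
  expect_equal(levins_overlap(Pi, Pk), levins_overlap(Pk, Pi))
})

test_that("identical groups overlap at 100% and disjoint groups at 0%", {
  same <- list(depth = cats_from_counts(c(3, 4, 3)),
               substrate = cats_from_counts(c(5, 2, 3)))
  ds <- build_dataset(presence_cats = list(BM = same, BF = same,
                                           NBM = same, NBF = same))
  ov <- overlap_matrix(ds, exclude_factors = character())
  expect_equal(ov$O_sym_pct[upper.tri(ov$O_sym_pct)], rep(100, 6))
  expect_equal(unname(diag(ov$O_dir)), rep(1, 4), tolerance = 0)

  ds2 <- build_dataset(
    presence_cats = list(BM = list(depth = rep(1L, 6), substrate = rep(1L, 6)),
                         BF = list(depth = rep(3L, 6), substrate = rep(2L, 6))))
  ov2 <- overlap_matrix(ds2, groups = c("BM", "BF"),
                        exclude_factors = character())
  expect_equal(ov2$O_sym_pct["BM", "BF"], 0)
})

test_that("label resampling is deterministic and null under identical records", {
  ds <- simulate_dataset(seed = 41, n_pseudo = 20)
  a <- resample_null(ds, n_resamples = 5, seed = 99)
  b <- resample_null(ds, n_resamples = 5, seed = 99)
  expect_identical(a, b)
  expect_length(a, 5)

  # when every presence record is identical, any relabelling reproduces
  # the observed matrix exactly (the identity-permutation invariant)
  same <- list(depth = rep(2L, 1), substrate = rep(3L, 1))
  ds_const <- build_dataset(presence_cats = list(
    BM = lapply(same, rep, 10), BF = lapply(same, rep, 10),
    NBM = lapply(same, rep, 10), NBF = lapply(same, rep, 10)))
  obs <- overlap_matrix(ds_const, exclude_factors = character())
  nul <- resample_null(ds_const, n_resamples = 3, seed = 1,
                       exclude_factors = character())
  for (m in nul) expect_equal(m, obs$O_sym_pct)
})

test_that("the paired-t summary reproduces hand-computed toys", {
  # 3-pair toy with differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641
  obs <- matrix(0, 3, 3); nul <- matrix(0, 3, 3)
  obs[upper.tri(obs)] <- c(11, 12, 13)
  nul[upper.tri(nul)] <- c(10, 10, 10)
  obs <- obs + t(obs); nul <- nul + t(nul)
  sig <- overlap_significance(obs, nul)
  expect_equal(sig$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(sig$t_stat, 4), 3.4641)
  expect_identical(sig$df, 2L)
  # agreement with the standard paired t-test as an independent cross-check
  tt <- t.test(c(11, 12, 13), c(10, 10, 10), paired = TRUE)
  expect_equal(sig$t_stat, abs(unname(tt$statistic)))
  expect_equal(sig$p_value, tt$p.value)
})

test_that("a null identical to the observed matrix gives t = 0, p = 1", {
  ref <- reference_overlaps()
  sig <- overlap_significance(ref$observed, ref$observed)
  expect_equal(sig$t_stat, 0)
  expect_equal(sig$p_value, 1)
  # zero-variance nonzero differences are a degenerate statistic
  shifted <- ref$observed + 5
  expect_error(overlap_significance(shifted, ref$observed), "degenerate")
})

test_that("multiple resamples are averaged and yield a permutation p", {
  ds <- simulate_dataset(seed = 43, n_pseudo = 20)
  obs <- overlap_matrix(ds)
  nulls <- resample_null(ds, n_resamples = 19, seed = 3)
  sig <- overlap_significance(obs, nulls)
  ut <- upper.tri(obs$O_sym_pct)
  manual_null <- Reduce(`+`, nulls)[ut] / 19
  expect_equal(sig$pairs_null, manual_null)
  expect_true(sig$perm_p >= 0 && sig$perm_p <= 1)
  null_means <- vapply(nulls, function(m) mean(m[ut]), numeric(1))
  expect_equal(sig$perm_p, mean(null_means <= mean(obs$O_sym_pct[ut])))
})
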