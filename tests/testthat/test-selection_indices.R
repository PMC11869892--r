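# Worked electivity example used throughout: r = (8,1,1), p = (5,3,2)
# ri/pi = (1.6, 1/3, 0.5), sum = 2.4333..., Wi = (0.65753, 0.13699, 0.20548)
# Ei = (0.32719, -0.41746, -0.23729)
wi_worked <- c(1.6, 1 / 3, 0.5) / sum(c(1.6, 1 / 3, 0.5))
ei_worked <- (wi_worked - 1 / 3) / (wi_worked + 1 / 3)

test_that("Vanderploeg Wi matches direct arithmetic", {
  expect_equal(vanderploeg_wi(c(1, 1, 1), c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(vanderploeg_wi(c(8, 1, 1), c(5, 3, 2)), wi_worked)
  expect_equal(round(vanderploeg_wi(c(8, 1, 1), c(5, 3, 2)), 4),
               c(0.6575, 0.1370, 0.2055))
  expect_equal(vanderploeg_wi(c(0, 5), c(3, 3)), c(0, 1))
})

test_that("Wi flags unavailable-but-used categories and degenerate input", {
  expect_error(vanderploeg_wi(c(1, 2, 3), c(1, 0, 2)), "zero availability")
  expect_error(vanderploeg_wi(c(0, 0, 0), c(1, 1, 1)), "degenerate")
  expect_error(vanderploeg_wi(c(1, 2), c(1)), "equal length")
  # never-offered, never-used category drops out as NA; rest renormalizes
  wi <- vanderploeg_wi(c(2, 0, 2), c(2, 0, 2))
  expect_true(is.na(wi[2]))
  expect_equal(wi[c(1, 3)], c(0.5, 0.5))
})

test_that("Wi sums to one over informative categories (property)", {
  set.seed(101)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    p <- rpois(k, 5) + 1
    r <- rpois(k, 3)
    if (all(r == 0)) r[1] <- 1
    wi <- vanderploeg_wi(r, p)
    expect_equal(sum(wi, na.rm = TRUE), 1, tolerance = 1e-12)
    expect_true(all(wi >= 0, na.rm = TRUE))
  }
})

test_that("Scavia Ei reproduces its endpoint identities and worked values", {
  expect_equal(scavia_ei(rep(1 / 3, 3)), rep(0, 3))
  expect_equal(scavia_ei(rep(1 / 5, 5)), rep(0, 5))
  expect_equal(scavia_ei(c(1, 0, 0)), c(0.5, -1, -1))
  expect_equal(scavia_ei(wi_worked), ei_worked)
  expect_equal(round(scavia_ei(wi_worked), 3), c(0.327, -0.417, -0.237))
})

test_that("Ei respects its attainable range and is increasing in Wi", {
  set.seed(102)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    w <- as.vector(stats::rmultinom(1, 50, runif(k) + 0.1)) / 50
    ei <- scavia_ei(w, n = k)
    expect_true(all(ei >= -1 - 1e-12))
    expect_true(all(ei <= (1 - 1 / k) / (1 + 1 / k) + 1e-12))
  }
  w <- seq(0, 1, by = 0.05)
  expect_false(is.unsorted(scavia_ei(w, n = 4), strictly = TRUE))
})

test_that("the preference rubric classifies including its boundaries", {
  expect_identical(classify_ei(c(0, -1, 1, 0.3272, -0.5, 0.099, -0.099)),
                   c("random", "no_selection", "strong_preference",
                     "selection", "avoidance", "random", "random"))
  # boundary +/-0.1 goes to the adjacent non-random class
  expect_identical(classify_ei(c(0.1, -0.1)), c("selection", "avoidance"))
  expect_identical(classify_ei(NA), "no_data")
  expect_error(classify_ei(1.5), "outside")
})

test_that("category permutation permutes Wi and Ei identically", {
  set.seed(103)
  for (rep in 1:50) {
    k <- sample(3:6, 1)
    r <- rpois(k, 4) + 1
    p <- rpois(k, 6) + 1
    perm <- sample(k)
    expect_equal(vanderploeg_wi(r[perm], p[perm]), vanderploeg_wi(r, p)[perm])
    expect_equal(scavia_ei(vanderploeg_wi(r[perm], p[perm])),
                 scavia_ei(vanderploeg_wi(r, p))[perm])
  }
})

test_that("selection_table composes counts, Wi, Ei and classes", {
  ds <- build_dataset(
    presence_cats = list(BM = list(depth = cats_from_counts(c(8, 1, 1)))),
    pa_cats = list(breeding = list(depth = cats_from_counts(c(5, 3, 2)))))
  tab <- selection_table(ds, groups = "BM", exclude_factors = character())
  dep <- tab[tab$factor == "depth", ]
  expect_equal(dep$r, c(8, 1, 1))
  expect_equal(dep$p, c(5, 3, 2))
  expect_equal(dep$Wi, wi_worked)
  expect_equal(dep$Ei, ei_worked)
  expect_identical(dep$class, c("selection", "avoidance", "avoidance"))
  # substrate: all presences and pseudo-absences in category 1
  sub <- tab[tab$factor == "substrate", ]
  expect_equal(sub$r, c(10, 0, 0))
  expect_true(is.na(sub$Wi[2]) && is.na(sub$Wi[3]))
  expect_identical(sub$class[2:3], c("no_data", "no_data"))
  expect_equal(sub$Ei[1], 0.5)  # Wi = 1 against n = 3 factor levels
})

test_that("selection_table matches season-specific availability and flags aspect", {
  ds <- simulate_dataset(seed = 31, n_pseudo = 30)
  tab <- selection_table(ds)
  expect_true(all(tab$excluded == (tab$factor == "aspect")))
  # availability columns repeat the season-matched pseudo-absence counts
  pa <- ds$records[ds$records$point_class == "pseudo_absence" &
                     ds$records$season == "breeding", ]
  p_alt <- tabulate(bin_value(ds$scheme$altitude, pa$altitude), 3)
  expect_equal(tab$p[tab$group == "BM" & tab$factor == "altitude"], p_alt)
  # Wi sums to 1 within every group x factor
  sums <- tapply(tab$Wi, paste(tab$group, tab$factor),
                 function(v) sum(v, na.rm = TRUE))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("an empty requested group is skipped with a warning", {
  ds <- build_dataset(
    presence_cats = list(BM = list(depth = cats_from_counts(c(3, 3, 3)))),
    pa_cats = list(breeding = list(depth = cats_from_counts(c(3, 3, 3)))))
  expect_warning(tab <- selection_table(ds, groups = c("BM", "NBF")),
                 "NBF")
  expect_identical(unique(tab$group), "BM")
})
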