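# Z-score normalization, one-way ANOVA, Tukey HSD and reagent ranking.

test_that("z-scores have per-group mean 0 and sd 1; degenerate groups give 0", {
  rec <- make_records(7)
  rec$halide <- c(rep("Brc1ccccc1", 4), rep("Brc1ccc(C)cc1", 3))
  rec$outcome <- c(10, 40, 70, 90, 50, 50, 50)
  z <- zscore_normalize(rec)
  g1 <- z$z[1:4]
  expect_equal(mean(g1), 0, tolerance = 1e-9)
  expect_equal(stats::sd(g1), 1, tolerance = 1e-9)
  # zero-variance group maps to exactly 0
  expect_identical(z$z[5:7], rep(0, 3))
  # hand-computed two-point group: sample sd of {0, 100} is 70.71...
  rec2 <- make_records(2)
  rec2$outcome <- c(0, 100)
  z2 <- zscore_normalize(rec2)
  expect_equal(z2$z, c(-0.7071068, 0.7071068), tolerance = 1e-6)
})

test_that("singleton groups get z = 0 and grouping is pluggable", {
  rec <- make_records(3)
  rec$halide <- c("Brc1ccccc1", "Brc1ccc(C)cc1", "Brc1ccc(C)cc1")
  rec$outcome <- c(42, 10, 90)
  z <- zscore_normalize(rec)
  expect_identical(z$z[1], 0)
  z_custom <- zscore_normalize(rec, grouping = function(r) rep("all", nrow(r)))
  expect_equal(mean(z_custom$z), 0, tolerance = 1e-9)
  expect_error(zscore_normalize(rec, grouping = "plate"), "grouping")
})

test_that("ANOVA trivial cases: identical groups, degenerate separation, k < 2", {
  a <- anova_oneway(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(a$F, 0, tolerance = 1e-12)
  expect_equal(a$p, 1, tolerance = 1e-12)
  expect_false(a$significant)

  d <- anova_oneway(list(A = c(0, 0, 0), B = c(10, 10, 10)))
  expect_true(d$degenerate)
  expect_true(d$significant)
  expect_equal(d$p, 0)

  k1 <- anova_oneway(list(A = c(1, 2, 3)))
  expect_false(k1$testable)
  expect_false(k1$significant)
})

test_that("ANOVA and Tukey match the textbook oracle on small instances", {
  set.seed(101)
  cases <- list()
  for (k in 2:4) {
    for (rep_i in 1:6) {
      sizes <- sample(2:6, k, replace = TRUE)
      g <- lapply(sizes, function(n) round(stats::rnorm(n, sd = 2), 3))
      names(g) <- LETTERS[seq_len(k)]
      cases[[length(cases) + 1]] <- g
    }
  }
  for (g in cases) {
    a_pkg <- anova_oneway(g)
    a_or <- oracle_anova(g)
    expect_equal(a_pkg$F, a_or$F, tolerance = 1e-8)
    expect_equal(a_pkg$p, a_or$p, tolerance = 1e-8)
    expect_equal(a_pkg$df_between, a_or$df1)
    expect_equal(a_pkg$df_within, a_or$df2)
    t_pkg <- tukey_hsd(g)
    expect_lt(tukey_p_gap(t_pkg, oracle_tukey(g)), 1e-8)
  }
})

test_that("balanced two-group Tukey equals the two-sided t-test (q = t*sqrt(2))", {
  set.seed(7)
  g <- list(A = stats::rnorm(6), B = stats::rnorm(6, mean = 1))
  tk <- tukey_hsd(g)
  tt <- stats::t.test(g$A, g$B, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey flags a planted shifted level against both others", {
  set.seed(42)
  g <- list(A = stats::rnorm(15), B = stats::rnorm(15),
            C = stats::rnorm(15, mean = 3))
  tk <- tukey_hsd(g)
  involving_c <- tk[tk$level1 == "C" | tk$level2 == "C", ]
  expect_true(all(involving_c$significant))
  ab <- tk[tk$level1 != "C" & tk$level2 != "C", ]
  expect_false(any(ab$significant))
  # equal means: adjusted p near 1
  same <- tukey_hsd(list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4)))
  expect_gt(same$p_adj, 0.99)
})

test_that("ranking labels planted outliers and is antisymmetric", {
  set.seed(9)
  g <- list(good = stats::rnorm(30, 2), ref1 = stats::rnorm(30),
            ref2 = stats::rnorm(30), bad = stats::rnorm(30, -2))
  rk <- rank_reagents(g, category = "ligand")
  expect_identical(rk$entries$level[1], "good")
  expect_identical(rk$entries$class[rk$entries$level == "good"], "best")
  expect_identical(rk$entries$class[rk$entries$level == "bad"], "worst")
  # mirror dataset: best and worst swap exactly
  g_neg <- lapply(g, function(v) -v)
  rk_neg <- rank_reagents(g_neg, category = "ligand")
  expect_identical(rk_neg$entries$level, rev(rk$entries$level))
  cls <- rk$entries$class
  cls_neg <- rk_neg$entries$class[match(rk$entries$level,
                                        rk_neg$entries$level)]
  swap <- c(best = "worst", worst = "best", neutral = "neutral")
  expect_identical(unname(swap[cls]), cls_neg)
})

test_that("a non-significant category yields all-neutral labels", {
  set.seed(13)
  g <- list(A = stats::rnorm(20), B = stats::rnorm(20), C = stats::rnorm(20))
  rk <- rank_reagents(g)
  expect_false(rk$anova$significant)
  expect_true(all(rk$entries$class == "neutral"))
})

test_that("levels below min_n are reported as insufficient data", {
  set.seed(5)
  g <- list(A = stats::rnorm(30, 2), B = stats::rnorm(30), C = stats::rnorm(3))
  rk <- rank_reagents(g, min_n = 5)
  expect_identical(rk$entries$class[rk$entries$level == "C"],
                   "insufficient data")
})

test_that("rankings are invariant to location/scale of raw outcomes", {
  set.seed(21)
  rec <- make_records(60, catalyst_metal = "Pd(OAc)2")
  rec$base <- rep(c("A", "B", "C"), 20)
  rec$outcome <- 50 + 10 * (rec$base == "A") + stats::rnorm(60, 0, 5)
  run <- function(r) {
    z <- zscore_normalize(r)$z
    v <- r$base
    rank_reagents(split(z, v), category = "base")
  }
  rk1 <- run(rec)
  rec2 <- rec
  rec2$outcome <- 3 + 2 * rec$outcome  # same group, affine transform
  rk2 <- run(rec2)
  expect_equal(rk1$anova$p, rk2$anova$p, tolerance = 1e-9)
  expect_equal(rk1$entries$mean_z, rk2$entries$mean_z, tolerance = 1e-9)
  expect_identical(rk1$entries$class, rk2$entries$class)
})

test_that("mean_z ties break by n then level name, deterministically", {
  g <- list(bb = c(1, -1), aa = c(1, -1, 0), cc = c(0.5, -0.5))
  rk <- rank_reagents(g, min_n = 1)
  expect_identical(rk$entries$level, c("aa", "bb", "cc"))
})
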