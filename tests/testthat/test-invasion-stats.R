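# Invasion statistics: normalization, threshold, counts, KDE, group tests.

test_that("min-normalization shifts each organoid independently", {
  t1 <- data.frame(organoid_id = "A", distance_um = c(-12, -3, 40))
  expect_equal(normalize_distances(t1)$normalized_distance_um, c(0, 9, 52))

  t2 <- data.frame(organoid_id = "A", distance_um = 7)
  expect_equal(normalize_distances(t2)$normalized_distance_um, 0)

  t3 <- data.frame(organoid_id = c("A", "A", "B", "B"),
                   distance_um = c(-5, 5, 10, 30))
  expect_equal(normalize_distances(t3)$normalized_distance_um,
               c(0, 10, 0, 20))
})

test_that("normalization is idempotent and keeps the raw column", {
  t3 <- data.frame(organoid_id = c("A", "A", "B"),
                   distance_um = c(-5, 5, 10))
  n1 <- normalize_distances(t3)
  n2 <- normalize_distances(n1)
  expect_identical(n1, n2)
  expect_true("distance_um" %in% names(n1))
})

test_that("the worked invasion example gives threshold 15.75 and counts (2, 0)", {
  tab <- toy_invasion_table()
  thr <- invasion_threshold(tab, "reference")
  # type-7 quantiles: Q3(A) = 22.5, Q3(B) = 9
  expect_equal(thr, 15.75)
  counts <- count_invading(tab, thr)
  expect_equal(counts$n_invading[counts$organoid_id == "A"], 2)
  expect_equal(counts$n_invading[counts$organoid_id == "B"], 0)
})

test_that("threshold edge cases behave", {
  one <- data.frame(organoid_id = "A", group = "ref",
                    distance_um = c(0, 0, 0, 0))
  expect_equal(invasion_threshold(one, "ref"), 0)

  same <- data.frame(organoid_id = rep(c("A", "B", "C"), each = 4),
                     group = "ref", distance_um = rep(c(0, 10, 20, 30), 3))
  expect_equal(invasion_threshold(same, "ref"), 22.5)

  expect_error(invasion_threshold(one, "missing"), "reference group")
})

test_that("threshold never decreases when a maximal cell is added", {
  set.seed(31)
  for (rep in 1:20) {
    tab <- data.frame(
      organoid_id = rep(c("A", "B", "C"), each = 10),
      group = "ref", distance_um = rexp(30, 1 / 20))
    thr0 <- invasion_threshold(tab, "ref")
    extra <- data.frame(organoid_id = "A", group = "ref",
                        distance_um = max(tab$distance_um) + 1)
    thr1 <- invasion_threshold(rbind(tab, extra), "ref")
    expect_gte(thr1, thr0)
  }
})

test_that("invading counts are order-invariant, consistent and bounded", {
  set.seed(5)
  tab <- data.frame(
    organoid_id = rep(c("A", "B", "C", "D"), each = 25),
    group = rep(c("g1", "g2"), each = 50),
    distance_um = rexp(100, 1 / 15))
  thr <- 10
  c1 <- count_invading(tab, thr)
  c2 <- count_invading(tab[sample(nrow(tab)), ], thr)
  expect_identical(c1, c2)
  expect_true(all(c1$n_invading <= c1$n_cells))
  # group totals equal the sum of their organoids
  expect_equal(sum(c1$n_invading[c1$group == "g1"]),
               sum(normalize_distances(tab[tab$group == "g1", ])
                   $normalized_distance_um > thr))
  # extreme thresholds
  expect_true(all(count_invading(tab, Inf)$n_invading == 0))
  cts <- count_invading(tab, -1)
  expect_identical(cts$n_invading, cts$n_cells)
})

test_that("KDE curves integrate to one and find planted modes", {
  set.seed(9)
  kd <- kde_profile(rexp(200, 1 / 30))
  area <- sum(diff(kd$x) * (kd$density[-1] + kd$density[-nrow(kd)]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)

  # single repeated value with fixed bandwidth = one Gaussian
  kd2 <- kde_profile(rep(25, 10), bandwidth = 4)
  expect_equal(kd2$density, dnorm(kd2$x, 25, 4), tolerance = 1e-3)

  # two point masses, small bandwidth: modes at 0 and 100
  kd3 <- kde_profile(c(rep(0, 50), rep(100, 50)), bandwidth = 2)
  dens <- kd3$density
  pk_idx <- which(diff(sign(diff(dens))) == -2) + 1
  pk_idx <- pk_idx[dens[pk_idx] > 0.05 * max(dens)]   # ignore tail ripple
  expect_equal(sort(kd3$x[pk_idx]), c(0, 100), tolerance = 2)

  expect_error(kde_profile(numeric(0)), "empty")
})

test_that("per-organoid KDE profiles share one grid and unit areas", {
  tab <- normalize_distances(data.frame(
    organoid_id = rep(c("A", "B"), each = 30),
    distance_um = c(rexp(30, 1 / 10), rexp(30, 1 / 40))))
  kd <- kde_profile(tab)
  sp <- split(kd, kd$organoid_id)
  expect_equal(sp$A$x, sp$B$x)
  for (d in sp) {
    area <- sum(diff(d$x) * (d$density[-1] + d$density[-nrow(d)]) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }
})

test_that("two-group comparison matches the t-test conventions", {
  r <- compare_two_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(3)
  r2 <- compare_two_groups(c(0, 0, 0, 0) + rnorm(4, sd = 1e-6),
                           c(10, 10, 10, 10) + rnorm(4, sd = 1e-6))
  expect_lt(r2$p_value, 1e-4)
  expect_equal(r2$stars, "****")

  a <- rnorm(8); b <- rnorm(8, 1)
  ra <- compare_two_groups(a, b); rb <- compare_two_groups(b, a)
  expect_equal(ra$statistic, -rb$statistic)
  expect_equal(ra$p_value, rb$p_value)

  # degenerate equal constants
  rz <- compare_two_groups(c(5, 5), c(5, 5))
  expect_equal(rz$p_value, 1)
  expect_true(rz$degenerate)

  expect_error(compare_two_groups(1, c(1, 2)), "n >= 2")
})

test_that("ANOVA + Tukey matches the independent reference implementation", {
  set.seed(17)
  for (rep in 1:50) {
    k <- sample(3:4, 1)
    groups <- lapply(seq_len(k), function(i)
      rnorm(sample(4:8, 1), mean = runif(1, 0, 2)))
    names(groups) <- paste0("g", seq_len(k))
    mine <- compare_multi_groups(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(names(groups), lengths(groups))))
    fit <- aov(y ~ g, data = df)
    ref_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    expect_equal(mine$p_value, ref_p, tolerance = 1e-8)
    tk <- TukeyHSD(fit)$g
    ref <- tk[, "p adj"]
    mine_p <- setNames(mine$pairwise$adjusted_p, mine$pairwise$pair)
    expect_lt(max(abs(mine_p[names(ref)] - ref)), 1e-4)
  }
})

test_that("with two groups Tukey reduces to the pooled t test", {
  set.seed(23)
  for (rep in 1:10) {
    a <- rnorm(6); b <- rnorm(5, 0.8)
    tukey_p <- compare_multi_groups(list(a = a, b = b))$pairwise$adjusted_p
    t_p <- t.test(a, b, var.equal = TRUE)$p.value
    expect_equal(tukey_p, t_p, tolerance = 1e-6)
  }
})

test_that("identical groups give F = 0 and all adjusted p = 1", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- compare_multi_groups(g)
  expect_equal(r$statistic, 0)
  expect_true(all(r$pairwise$adjusted_p == 1))
  expect_error(compare_multi_groups(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("star labels reproduce the caption bands", {
  expect_equal(p_stars(c(1e-5, 5e-4, 3e-3, 0.02, NA)),
               c("****", "***", "**", "ns", NA))
})
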