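test_that("aridity split uses the < 0.2 / >= 0.2 convention and is total", {
  x <- simulate_traits(n = 8, seed = 71)
  x$aridity_index <- c(0.1, 0.15, 0.19, 0.05, 0.2, 0.3, 0.45, 0.21)
  g <- split_groups(x, "aridity")
  expect_named(g, c("arid", "semi_arid"))
  expect_identical(nrow(g$arid), 4L)
  expect_identical(nrow(g$semi_arid), 4L)         # 0.2 itself is semi-arid
  expect_true(all(g$arid$aridity_index < 0.2))

  x$aridity_index[1] <- NA
  expect_message(g2 <- split_groups(x, "aridity", min_n = 3), "1 record")
  expect_identical(nrow(g2$arid) + nrow(g2$semi_arid), 7L)
})

test_that("an expected group that is too small is an error naming it", {
  x <- simulate_traits(n = 10, seed = 72)
  x$life_form <- "woody"
  expect_error(split_groups(x, "life_form"), "herbaceous")
  expect_warning(g <- split_groups(x, "life_form", drop_empty = TRUE), "herbaceous")
  expect_named(g, "woody")

  x2 <- simulate_traits(n = 100, group_effects = c(woody = 0.6, herbaceous = 1),
                        seed = 73)
  x2 <- x2[c(which(x2$life_form == "woody")[1:60],
             which(x2$life_form == "herbaceous")[1:40]), ]
  g2 <- split_groups(x2, "life_form")
  expect_identical(vapply(g2, nrow, integer(1)), c(woody = 60L, herbaceous = 40L))
})

test_that("Duncan's test separates what it should and only that", {
  # identical replicate vectors share a letter
  v <- rnorm(20)
  d0 <- duncan_mrt(list(a = v, b = v))
  expect_identical(unique(tidy(d0)$letters), "a")

  # means 0, 0.01, 10 with sd 0.1: first two share, third distinct
  set.seed(74)
  mk <- function(mu) mu + 0.1 * scale(rnorm(50))[, 1]
  d <- duncan_mrt(list(lo1 = mk(0), lo2 = mk(0.01), hi = mk(10)))
  tb <- tidy(d)
  expect_identical(tb$letters[tb$item == "hi"], "a")
  expect_identical(tb$letters[tb$item %in% c("lo1", "lo2")], c("b", "b"))
})

test_that("Duncan letters are invariant to item order and location shifts", {
  set.seed(75)
  samples <- random_duncan_problem(k = 6)
  base <- tidy(duncan_mrt(samples))
  perm <- tidy(duncan_mrt(samples[sample(names(samples))]))
  expect_identical(base, perm)
  shifted <- tidy(duncan_mrt(lapply(samples, function(v) v + 100)))
  expect_identical(shifted$letters, base$letters)
  expect_identical(shifted$item, base$item)
})

test_that("two-item Duncan reduces to the studentized-range two-group test", {
  set.seed(76)
  for (rep in 1:20) {
    samples <- random_duncan_problem(k = 2, n_min = 5, n_max = 15)
    d <- duncan_mrt(samples)
    tb <- tidy(d)
    ns <- lengths(samples)
    vars <- vapply(samples, var, numeric(1))
    mse <- sum((ns - 1) * vars) / sum(ns - 1)
    n_h <- 2 / sum(1 / ns)
    q_obs <- abs(diff(vapply(samples, mean, numeric(1)))) / sqrt(mse / n_h)
    p_range <- stats::ptukey(q_obs, nmeans = 2, df = sum(ns - 1),
                             lower.tail = FALSE)
    expect_identical(tb$letters[1] != tb$letters[2], unname(p_range < 0.05))
  }
})

test_that("Duncan groupings agree with an independent step-down reference", {
  set.seed(77)
  for (rep in 1:25) {
    samples <- random_duncan_problem(k = 5)
    got <- letters_shared(tidy(duncan_mrt(samples)))
    ref <- oracle_duncan_shared(samples)
    expect_identical(got, ref)
  }
})

test_that("the Welch test matches a hand computation and its conventions", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_ttest(a, b)
  # hand Welch formula: se = sqrt(va/4 + vb/4), both variances 5/3
  se <- sqrt(5 / 3 / 4 + 5 / 3 / 4)
  expect_equal(w$statistic, -1 / se, tolerance = 1e-12)   # = -1.0954
  expect_equal(w$df, 6, tolerance = 1e-12)
  expect_equal(w$p_value, 2 * stats::pt(-1 / se, 6), tolerance = 1e-12)

  v <- rnorm(10)
  w0 <- welch_ttest(v, v)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)

  # huge separation
  set.seed(78)
  expect_lt(welch_ttest(rnorm(1000), rnorm(1000, 5))$p_value, 1e-10)

  # antisymmetry
  set.seed(79)
  x <- rnorm(15); y <- rnorm(12, 1)
  expect_equal(welch_ttest(x, y)$statistic, -welch_ttest(y, x)$statistic)
  expect_equal(welch_ttest(x, y)$p_value, welch_ttest(y, x)$p_value)

  # zero variance in both with equal means -> p = 1 convention
  expect_message(wc <- welch_ttest(rep(2, 5), rep(2, 5)), "degenerate")
  expect_equal(wc$p_value, 1)
})

test_that("planted group differences are recovered with direction and significance", {
  x <- simulate_traits(n = 120, rho_in = 0.9, rho_out = 0,
                       group_effects = c(A = 1, B = 0.9 / 2.7), seed = 80)
  # group A: rho_in 0.9; group B: rho_in 0.3
  cmp <- compare_group_ptns(x, "life_form", B = 80, seed = 81)
  gl <- glance(cmp)
  expect_gt(gl$edge_density[gl$group == "A"], gl$edge_density[gl$group == "B"])
  t_dens <- dplyr::filter(tidy(cmp), parameter == "edge_density")
  expect_lt(t_dens$p_value, 0.05)
  expect_gt(t_dens$statistic * sign(t_dens$mean_a - t_dens$mean_b), 0)
  # per-group letters exist for all 16 traits
  expect_identical(nrow(tidy(cmp$groups$A$duncan_degree)), 16L)
})

test_that("a single-group comparison degrades to a warning, not an error", {
  x <- simulate_traits(n = 40, seed = 82)
  x$life_form <- "woody"
  w <- capture_warnings(cmp <- compare_group_ptns(x, "life_form", B = 10, seed = 83))
  expect_true(any(grepl("only one group", w)))
  expect_named(cmp$groups, "woody")
  expect_identical(nrow(cmp$tests), 0L)
})
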