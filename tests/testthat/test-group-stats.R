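# Gated two-group tests, ANCOVA, grand averages, interval/band masks.

fake_table <- function(n, delta = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, data.frame(
    participant_id = sprintf("S%03d", 1:(2 * n)),
    main_group = rep(c("HC", "MCI"), each = n),
    age = rnorm(2 * n, 72, 6),
    sex = sample(c("M", "F"), 2 * n, replace = TRUE),
    education = rnorm(2 * n, 12, 4),
    y = c(rnorm(n, 0, sd), rnorm(n, delta, sd))
  ))
}

test_that("identical groups give t = 0, p = 1 and no transform", {
  d <- fake_table(40, seed = 2)
  d$y <- rep(d$y[1:40], 2)
  r <- compare_two_groups(d, "y")
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-9)
  expect_equal(r$test, "t")
})

test_that("Welch is used exactly when Levene rejects", {
  set.seed(3)
  d <- fake_table(100, seed = 3)
  d$y <- c(rnorm(100, 0, 1), rnorm(100, 0, 6))
  r <- compare_two_groups(d, "y")
  expect_lt(r$levene_p, 0.05)
  expect_equal(r$test, "Welch-t")
  d2 <- fake_table(100, seed = 4)
  r2 <- compare_two_groups(d2, "y")
  expect_gt(r2$levene_p, 0.05)
  expect_equal(r2$test, "t")
})

test_that("skewed positive data are log transformed before testing", {
  set.seed(5)
  d <- fake_table(80, seed = 5)
  d$y <- exp(rnorm(160, 0, 1))   # log-normal: Shapiro rejects, log fixes
  r <- compare_two_groups(d, "y")
  expect_true(r$transformed)
  # equivalent direct test on the log scale
  ref <- t.test(log(d$y) ~ d$main_group, var.equal = r$test == "t")
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
})

test_that("a real location shift is detected with high power", {
  hits <- vapply(1:20, function(s) {
    compare_two_groups(fake_table(100, delta = 0.5, seed = s), "y")$p < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("ANCOVA without covariates collapses to the pooled t test", {
  d <- fake_table(60, delta = 0.4, seed = 6)
  a <- ancova_groups(d, "y", covariates = character(0))
  r <- t.test(y ~ main_group, data = d, var.equal = TRUE)
  expect_equal(a$omnibus$p, r$p.value, tolerance = 1e-6)
  expect_null(a$contrasts)
})

test_that("ANCOVA adjusts for a confounded covariate", {
  set.seed(77)
  n <- 150
  d <- fake_table(n, seed = 7)
  # age differs between groups and drives y; no true group effect
  d$age <- d$age + rep(c(0, 4), each = n)
  d$y <- 0.3 * d$age + rnorm(2 * n, sd = 0.5)
  raw <- compare_two_groups(d, "y")
  adj <- ancova_groups(d, "y")
  expect_lt(raw$p, 0.01)       # spurious difference without adjustment
  expect_gt(adj$omnibus$p, 0.01)
})

test_that("four-group ANCOVA reports 6 Bonferroni contrasts = min(1, 6p)", {
  set.seed(8)
  n <- 30
  d <- data.frame(
    subgroup = rep(c("CN", "SCD", "aMCI", "naMCI"), each = n),
    age = rnorm(4 * n, 72, 6),
    sex = sample(c("M", "F"), 4 * n, replace = TRUE),
    education = rnorm(4 * n, 12, 4)
  )
  d$y <- rnorm(4 * n) + (d$subgroup == "aMCI") * 1.5
  a <- ancova_groups(d, "y", group_col = "subgroup")
  expect_equal(nrow(a$contrasts), 6)
  expect_equal(a$contrasts$p_adj, pmin(1, 6 * a$contrasts$p),
               tolerance = 1e-9)
  expect_true(all(a$contrasts$p_adj >= a$contrasts$p))
  expect_lt(a$omnibus$p, 0.01)
})

test_that("grand averages are pointwise group means, order-invariant", {
  curves <- rbind(rep(0.4, 50), rep(0.6, 50), rep(1, 50))
  g <- c("HC", "HC", "MCI")
  ga <- grand_average_curves(curves, g)
  expect_equal(unname(ga["HC", ]), rep(0.5, 50))
  expect_equal(unname(ga["MCI", ]), rep(1, 50))
  perm <- c(3, 1, 2)
  expect_equal(grand_average_curves(curves[perm, ], g[perm]), ga)
})

test_that("interval comparison uses seven 100 ms bins of 25 samples", {
  set.seed(9)
  time <- epoch_axis()
  n <- 30
  curves <- matrix(runif(2 * n * 250, 0.4, 0.6), 2 * n, 250)
  g <- rep(c("HC", "MCI"), each = n)
  r <- interval_comparison(curves, time, g)
  expect_equal(nrow(r$intervals), 7)
  expect_true(all(r$intervals$n_samples == 25))
  expect_length(r$mask, 250)
  # identical groups: nothing significant after chance level
  expect_lt(sum(r$intervals$p < 0.05), 3)
  # constructed beta-coupling deficit in one group
  eff <- curves
  sel <- time >= 0 & time < 700
  eff[g == "MCI", sel] <- eff[g == "MCI", sel] - 0.08
  r2 <- interval_comparison(eff, time, g)
  expect_true(all(r2$intervals$p < 0.05))
  expect_gt(mean(r2$mask[sel]), 0.8)
})

test_that("band comparison flags only the bands carrying the effect", {
  set.seed(10)
  freq <- (0:128) * FS / 256
  n <- 40
  base <- matrix(runif(2 * n * 129, 0.5, 0.7), 2 * n, 129)
  g <- rep(c("HC", "MCI"), each = n)
  # lower coupling only in 16-23 Hz for the second group
  sel <- freq >= 16 & freq < 23
  eff <- base
  eff[g == "MCI", sel] <- eff[g == "MCI", sel] - 0.1
  r <- band_comparison(eff, freq, g)
  expect_equal(nrow(r$bands), 7)
  sig <- r$bands$variable[r$bands$p < 0.05]
  expect_true(all(c("middle_beta", "high_beta") %in% sig))
  expect_false(any(c("theta", "low_alpha", "high_alpha") %in% sig))
  # the seven ranges partition 4-30 Hz without gaps
  b <- comparison_bands()
  edges <- unlist(b)
  expect_equal(min(edges), 4)
  expect_equal(max(edges), 30)
  los <- vapply(b, `[`, 0, 1)
  his <- vapply(b, `[`, 0, 2)
  expect_equal(unname(sort(los)[-1]), unname(sort(his)[-7]))
})
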