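# Diversity statistics: factorial ANOVA, correlation, Tukey-Kramer
# comparison, stacked histogram.

test_that("two-way ANOVA reproduces the brute-force SS decomposition", {
  set.seed(21)
  for (rep in 1:5) {
    df <- expand.grid(accession = paste0("a", 1:4),
                      position = c("base", "middle", "tip"),
                      replicate = 1:3)
    df$sd <- rnorm(nrow(df), 120, 10) +
      rep(rnorm(4, 0, 6), times = 9)[as.integer(df$accession)]
    res <- two_way_anova(df)
    want <- oracle_two_way_ss(df$sd, df$accession, df$position)
    expect_equal(res$ss, as.numeric(want), tolerance = 1e-9)
    # balanced data: Type II equals the sequential decomposition
    res1 <- two_way_anova(df, type = 1)
    expect_equal(res$ss, res1$ss, tolerance = 1e-9)
    # total SS is conserved
    expect_equal(sum(res$ss), sum((df$sd - mean(df$sd))^2),
                 tolerance = 1e-9)
  }
})

test_that("null two-way data give tiny F and p near 1", {
  df <- expand.grid(accession = paste0("a", 1:3),
                    position = c("base", "middle", "tip"), replicate = 1:2)
  # all cell means equal; tiny jitter supplies residual variance
  df$sd <- 100 + rep(c(-1, 1), each = 9) * 0.5
  res <- two_way_anova(df)
  expect_true(all(res$F[1:3] < 1e-10, na.rm = TRUE))
  expect_true(all(res$p[1:3] > 0.999, na.rm = TRUE))
  expect_true(all(res$signif[1:3] == "n.s."))
  # empty cell refuses the interaction model
  bad <- df[!(df$accession == "a1" & df$position == "tip"), ]
  expect_error(two_way_anova(bad), "empty")
})

test_that("injected main effects are detected without fake interaction", {
  set.seed(33)
  df <- expand.grid(accession = paste0("a", sprintf("%02d", 1:10)),
                    position = c("base", "middle", "tip"),
                    replicate = 1:3)
  acc_eff <- seq(-15, 15, length.out = 10)
  pos_eff <- c(base = -1.3, middle = -2.3, tip = 3.7)
  df$sd <- 128 + acc_eff[as.integer(df$accession)] +
    pos_eff[as.character(df$position)] + rnorm(nrow(df), 0, 3)
  res <- two_way_anova(df)
  expect_equal(res$signif[1], "**")
  expect_equal(res$signif[2], "**")
  expect_gt(res$p[3], 0.01)
})

test_that("one-way ANOVA matches its oracle and the two-group t test", {
  set.seed(5)
  y <- rnorm(30, 50, 4)
  g <- rep(c("x", "y", "z"), each = 10)
  res <- one_way_anova(y, g)
  want <- oracle_one_way_ss(y, g)
  expect_equal(res$ss, as.numeric(want), tolerance = 1e-9)
  # two groups: F = t^2
  y2 <- y[1:20]; g2 <- g[1:20]
  res2 <- one_way_anova(y2, g2)
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(res2$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p[1], tt$p.value, tolerance = 1e-10)
  # identical group means: F ~ 0
  flat <- one_way_anova(rep(c(1, 2), 10), rep(c("u", "v"), each = 10))
  expect_lt(flat$F[1], 1e-20)
  expect_error(one_way_anova(y, rep("x", 30)), "two groups")
})

test_that("type-I error of the factorial ANOVA is calibrated at 5%", {
  # 1000 null panels: rejection rate must sit in 0.05 +/- 0.02
  set.seed(777)
  alpha_hits <- matrix(FALSE, 1000, 3)
  df0 <- expand.grid(accession = paste0("a", 1:6),
                     position = c("base", "middle", "tip"),
                     replicate = 1:3)
  for (i in 1:1000) {
    df0$sd <- rnorm(nrow(df0), 128, 10)
    p <- two_way_anova(df0)$p[1:3]
    alpha_hits[i, ] <- p < 0.05
  }
  rates <- colMeans(alpha_hits)
  for (r in rates) {
    expect_gte(r, 0.03)
    expect_lte(r, 0.07)
  }
})

test_that("Pearson correlation matches the closed form", {
  up <- correlation_sd_la(1:10, 2 * (1:10) + 3)
  expect_equal(up$R, 1)
  down <- correlation_sd_la(1:10, -0.5 * (1:10))
  expect_equal(down$R, -1)
  ct <- correlation_sd_la(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(ct$R, 0.6)
  t_oracle <- 0.6 * sqrt((4 - 2) / (1 - 0.36))
  expect_equal(ct$t, t_oracle)
  expect_equal(ct$p, 2 * pt(t_oracle, df = 2, lower.tail = FALSE))
  expect_equal(ct$signif, "n.s.")
  expect_error(correlation_sd_la(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Tukey-Kramer agrees with TukeyHSD and a worked example", {
  # textbook-style 3-group design with unequal n
  y <- c(18, 20, 21, 22, 24,          # g1, n=5
         24, 26, 27, 29,              # g2, n=4
         30, 31, 33, 34, 35, 36)      # g3, n=6
  g <- rep(c("g1", "g2", "g3"), c(5, 4, 6))
  res <- tukey_groups(y, g)
  expect_equal(nrow(res$pairs), 3L)
  # independent route: stats::TukeyHSD on the same fit
  hsd <- TukeyHSD(aov(y ~ factor(g)))$`factor(g)`
  expect_equal(res$pairs$p_adj[1], hsd["g2-g1", "p adj"], tolerance = 1e-9)
  expect_equal(res$pairs$p_adj[2], hsd["g3-g1", "p adj"], tolerance = 1e-9)
  expect_equal(abs(res$pairs$diff[3]), abs(hsd["g3-g2", "diff"]))
  # hand-computed q for the g2-g1 pair: q = |diff| / sqrt(MSE/2(1/5+1/4))
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (15 - 3)
  q12 <- abs(mean(y[6:9]) - mean(y[1:5])) / sqrt(mse / 2 * (1 / 5 + 1 / 4))
  expect_equal(res$pairs$q[1], q12)
  expect_true(all(res$pairs$significant))
})

test_that("Tukey handles identical groups, singletons and 15 groups", {
  none <- tukey_groups(rep(c(5, 6), 6), rep(c("u", "v"), each = 6))
  expect_false(any(none$pairs$significant))
  expect_warning(tukey_groups(c(1, 2, 3, 9, 4), c("a", "a", "b", "b", "c")),
                 "single member")
  set.seed(2)
  y <- rnorm(45, 128, 12)
  g <- rep(sprintf("or%02d", 1:15), each = 3)
  res <- tukey_groups(y, g)
  expect_equal(nrow(res$pairs), choose(15, 2))
  expect_equal(nrow(res$pairs), 105L)
  expect_true(all(res$pairs$p_adj >= 0 & res$pairs$p_adj <= 1))
})

test_that("Tukey on two groups matches the t-test decision", {
  set.seed(9)
  for (rep in 1:20) {
    y <- rnorm(16, 0, 1) + rep(c(0, runif(1, 0, 1.5)), each = 8)
    g <- rep(c("u", "v"), each = 8)
    tk <- tukey_groups(y, g)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(tk$pairs$significant[1], tt$p.value < 0.05)
    expect_equal(tk$pairs$p_adj[1], tt$p.value, tolerance = 1e-9)
  }
})

test_that("stacked histogram conserves counts over shared bins", {
  set.seed(4)
  v <- runif(90, 93, 166)
  g <- sample(sprintf("or%02d", 1:15), 90, replace = TRUE)
  h <- origin_histogram(v, g, bin_width = 5)
  expect_equal(sum(h$counts), 90)
  expect_equal(as.integer(rowSums(h$counts)), h$totals)
  # single group: stacked equals plain histogram
  h1 <- origin_histogram(v, rep("all", 90), bin_width = 5)
  expect_equal(h1$totals, h$totals)
  expect_equal(ncol(h1$counts), 1L)
  expect_error(origin_histogram(v, g, bin_width = 0), "positive")
})
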