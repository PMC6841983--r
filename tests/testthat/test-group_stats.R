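mk_records <- function(values, groups, regions) {
  metrics_record(data.frame(image = paste0("img", seq_along(values)),
                            group = groups, region = regions,
                            db = 1.5, lambda_mean = values,
                            density_pct = 10))
}

test_that("metrics records validate shape and flag out-of-range db", {
  df <- data.frame(image = c("a", "a", "b"), group = "H",
                   region = c("whole", "macula", "whole"),
                   db = c(1.5, 1.4, 1.6), lambda_mean = 0.4, density_pct = 10)
  expect_s3_class(metrics_record(df), "metrics_records")
  df$db[1] <- 2.7
  expect_warning(metrics_record(df), "outside")
  expect_error(metrics_record(df[, -4]), "missing column")
  df2 <- df[c(1, 1, 3), ]
  expect_error(suppressWarnings(metrics_record(df2)), "duplicate")
})

test_that("region t-test matches the pooled-variance closed form", {
  rec <- mk_records(c(1, 2, 3, 4, 5, 6), "H",
                    rep(c("macula", "optic_disc"), each = 3))
  res <- region_ttest(rec, "lambda_mean")
  # hand computation: diff -3, pooled var 1, se = sqrt(2/3), df = 4
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$p_value, 2 * pt(-3.674, 4), tolerance = 1e-3)
  # identical samples: t = 0, p = 1
  rec0 <- mk_records(c(1, 2, 3, 1, 2, 3), "H",
                     rep(c("macula", "optic_disc"), each = 3))
  res0 <- region_ttest(rec0, "lambda_mean")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # Welch variant differs under unequal variances
  recv <- mk_records(c(1, 1.1, 0.9, 4, 9, -1), "H",
                     rep(c("macula", "optic_disc"), each = 3))
  expect_false(isTRUE(all.equal(
    region_ttest(recv, "lambda_mean", variant = "student")$p_value,
    region_ttest(recv, "lambda_mean", variant = "welch")$p_value)))
  expect_error(region_ttest(rec[1:3, ], "lambda_mean"), "two region")
})

test_that("one-way ANOVA matches the between/within decomposition", {
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("H", "G", "DR"), each = 3)
  rec <- mk_records(vals, g, "whole")
  res <- anova_oneway(rec, "lambda_mean")
  # textbook decomposition computed independently
  gm <- mean(vals)
  means <- tapply(vals, g, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - means[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate constant layouts resolve to no-effect or full separation", {
  rec <- mk_records(rep(0, 12), rep(c("H", "G", "DR"), each = 4), "whole")
  res <- anova_oneway(rec, "lambda_mean")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(length(unique(res$letters)) == 1)
  rec2 <- mk_records(c(rep(0, 8), rep(10, 4)),
                     rep(c("H", "G", "DR"), each = 4), "whole")
  res2 <- anova_oneway(rec2, "lambda_mean")
  expect_equal(res2$p_value, 0)
  expect_equal(length(unique(res2$letters[c("H", "G")])), 1)
  expect_false(res2$letters[["DR"]] %in% res2$letters[c("H", "G")])
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(31)
  for (i in 1:8) {
    y <- rnorm(24, mean = rep(c(0, 0.5, 1), each = 8))
    g <- factor(rep(c("A", "B", "C"), each = 8))
    rec <- mk_records(y, as.character(g), "whole")
    res <- anova_oneway(rec, "lambda_mean")
    un <- pairwise.t.test(y, g, p.adjust.method = "none", pool.sd = TRUE)$p.value
    unvec <- c("B-A" = un["B", "A"], "C-A" = un["C", "A"], "C-B" = un["C", "B"])
    adj <- setNames(res$posthoc$p_adj, res$posthoc$pair)
    expect_true(all(adj[names(unvec)] >= unvec - 1e-10))
  }
})

test_that("compact letters are deterministic and reproduce the a/ab/b pattern", {
  means <- c(DR = 0.37, G = 0.34, H = 0.33)
  pairs <- c("G-DR", "H-DR", "H-G")
  letters <- compact_letters(pairs, c(FALSE, TRUE, FALSE), means)
  expect_equal(letters[["DR"]], "a")
  expect_equal(letters[["G"]], "ab")
  expect_equal(letters[["H"]], "b")
  expect_identical(letters, compact_letters(pairs, c(FALSE, TRUE, FALSE), means))
  # groups sharing a letter are exactly the non-significant pairs
  all_ns <- compact_letters(pairs, c(FALSE, FALSE, FALSE), means)
  expect_equal(unname(all_ns), rep("a", 3))
})

test_that("two-way ANOVA isolates a shifted cell and a true interaction", {
  regions <- rep(rep(c("macula", "optic_disc"), each = 4), 3)
  groups <- rep(c("H", "G", "DR"), each = 8)
  # all cells identical
  rec <- mk_records(rep(1, 24), groups, regions)
  res <- anova_twoway(rec, "lambda_mean")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(length(unique(res$letters)), 1)
  # one cell 10 SDs away: that cell alone gets its own letter
  set.seed(77)
  y <- rnorm(24, sd = 1)
  y[regions == "macula" & groups == "DR"] <- y[regions == "macula" & groups == "DR"] + 10
  rec2 <- mk_records(y, groups, regions)
  res2 <- anova_twoway(rec2, "lambda_mean")
  shifted <- "macula:DR"
  others <- setdiff(names(res2$letters), shifted)
  expect_false(res2$letters[[shifted]] %in% res2$letters[others])
  expect_equal(length(unique(res2$letters[others])), 1)
  # interaction power under the stated generator: cells (0,0,0,0,0,5), n=4
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    yy <- rnorm(24, sd = 1)
    yy[regions == "macula" & groups == "DR"] <-
      yy[regions == "macula" & groups == "DR"] + 5
    anova_twoway(mk_records(yy, groups, regions), "lambda_mean")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(anova_twoway(mk_records(rep(1, 8), rep(c("H", "G"), each = 4),
                                       "whole"), "lambda_mean"), "cell")
})
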