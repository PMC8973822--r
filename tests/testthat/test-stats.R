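test_that("group summaries follow the order-statistic conventions", {
  rec <- data.frame(genotype_label = "WT", comarker = "PM",
                    pearson_r = c(1, 2, 3, 4, 5))
  s <- summarize_groups(rec)
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  one <- summarize_groups(data.frame(genotype_label = "WT", comarker = "PM",
                                     pearson_r = 0.5))
  expect_true(all(unlist(one[c("min", "q1", "median", "q3", "max")]) == 0.5))
  # 30 draws against an independently sorted-array computation
  set.seed(9)
  x <- rnorm(30)
  s30 <- summarize_groups(data.frame(genotype_label = "g", comarker = "ER",
                                     pearson_r = x))
  xs <- sort(x)
  lin <- function(p) {  # type-7: linear interpolation of order statistics
    h <- (length(xs) - 1) * p
    xs[floor(h) + 1] + (h - floor(h)) * (xs[floor(h) + 2] - xs[floor(h) + 1])
  }
  expect_equal(s30$q1, lin(0.25), tolerance = 1e-12)
  expect_equal(s30$median, lin(0.5), tolerance = 1e-12)
  expect_equal(s30$q3, lin(0.75), tolerance = 1e-12)
  expect_true(s30$q1 <= s30$median && s30$median <= s30$q3)
  expect_equal(nrow(summarize_groups(rec[0, ])), 0)
})

test_that("Welch ANOVA matches the long-hand formula oracle and oneway.test", {
  set.seed(31)
  g <- list(a = rnorm(31, 0, 1), b = rnorm(33, 0.4, 2.5), c = rnorm(30, 0.8, 0.6))
  w <- welch_anova(g)
  o <- welch_oracle(g)
  expect_equal(w$F, o$F, tolerance = 1e-12)
  expect_equal(w$df2, o$df2, tolerance = 1e-12)
  expect_equal(w$p.value, o$p, tolerance = 1e-12)
  ow <- oneway.test(v ~ k, data.frame(v = unlist(g),
                                      k = rep(names(g), lengths(g))))
  expect_equal(w$F, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(w$p.value, ow$p.value, tolerance = 1e-10)
})

test_that("Welch ANOVA degenerates correctly", {
  # identical group means with nonzero variance: F = 0, p = 1
  x <- c(-1, 0, 1)
  w <- welch_anova(list(a = x, b = x + 0, c = 2 * x))
  expect_equal(w$F, 0); expect_equal(w$p.value, 1)
  # k = 2 reduces to the squared Welch t statistic
  set.seed(5)
  g2 <- list(a = rnorm(20, 0, 1), b = rnorm(25, 0.5, 3))
  w2 <- welch_anova(g2)
  tt <- t.test(g2$a, g2$b)
  expect_equal(w2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w2$p.value, tt$p.value, tolerance = 1e-10)
  expect_error(welch_anova(list(a = rnorm(5))), "at least 2 groups")
  expect_error(welch_anova(list(a = rep(1, 5), b = rnorm(5))), "zero within-group")
})

test_that("Welch ANOVA is location-scale invariant", {
  set.seed(6)
  g <- lapply(1:4, function(i) rnorm(20 + i, i / 4, i))
  w1 <- welch_anova(g)
  g2 <- lapply(g, function(x) 3.1 * x - 7)
  w2 <- welch_anova(g2)
  expect_equal(w1$F, w2$F, tolerance = 1e-11)
  expect_equal(w1$df2, w2$df2, tolerance = 1e-11)
  expect_equal(w1$p.value, w2$p.value, tolerance = 1e-11)
})

test_that("the formula interface matches the list interface", {
  set.seed(61)
  d <- data.frame(r = rnorm(60), g = rep(c("x", "y", "z"), each = 20))
  expect_equal(welch_anova(r ~ g, data = d)$F,
               welch_anova(split(d$r, d$g))$F, tolerance = 1e-12)
})

test_that("Games-Howell reduces to the Welch t-test at k = 2", {
  set.seed(13)
  g2 <- list(a = rnorm(28, 0, 1), b = rnorm(34, 0.6, 2))
  gh <- games_howell(g2)
  tt <- t.test(g2$a, g2$b)
  expect_equal(gh$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
  # identical samples: t = 0, p_adj = 1
  same <- games_howell(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$t, 0); expect_equal(same$p_adj, 1)
})

test_that("Games-Howell adjustment is conservative for k > 2", {
  set.seed(14)
  g <- list(a = rnorm(30), b = rnorm(32, 0.3, 2), c = rnorm(31, 0.5, 0.7),
            d = rnorm(29, 0.1, 1.4))
  gh <- games_howell(g)
  for (i in seq_len(nrow(gh))) {
    praw <- 2 * pt(gh$t[i], gh$df[i], lower.tail = FALSE)
    expect_gte(gh$p_adj[i] + 1e-12, praw)
  }
  expect_true(all(gh$q >= 0))
  expect_equal(gh$q, sqrt(2) * gh$t, tolerance = 1e-12)
  # stars agree with p_adj
  expect_equal(gh$stars, as.character(cut(gh$p_adj,
    c(-Inf, 0.001, 0.01, 0.05, Inf), c("***", "**", "*", "ns"), right = FALSE)))
})

test_that("Games-Howell versus-reference mode validates the reference", {
  set.seed(15)
  g <- list(WT = rnorm(30), m1 = rnorm(30, 1), m2 = rnorm(30, 2))
  gh <- games_howell(g, reference = "WT")
  expect_equal(nrow(gh), 2)
  expect_true(all(gh$group_i == "WT"))
  expect_equal(nrow(games_howell(g, reference = "all-pairs")), 3)
  expect_error(games_howell(g, reference = "missing"), "not present")
})

test_that("compare_to_wt enforces design gates", {
  set.seed(16)
  rec <- data.frame(
    genotype_label = rep(c("WT", "mut"), each = 35),
    comarker = "PM",
    pearson_r = c(rnorm(35, 0.9, 0.05), rnorm(35, -0.2, 0.2)))
  res <- compare_to_wt(rec, min_cells = 30)
  expect_s3_class(res, "coloc_wt_test")
  expect_lt(res$comarkers$PM$posthoc$p_adj, 0.001)
  expect_error(compare_to_wt(rec, wt_label = "nope"), "not present")
  expect_error(compare_to_wt(rec, min_cells = 40), "below 40 cells")
  rec_small <- rec[rec$genotype_label == "WT", ]
  expect_error(compare_to_wt(rec_small, min_cells = 30), "at least 2 genotypes")
})
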