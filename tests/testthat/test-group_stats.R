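test_that("normal groups route parametric and null data stays non-significant", {
  gd <- generate_group_data(list(a = list(n = 15, dist = "normal", mean = 0, sd = 1),
                                 b = list(n = 15, dist = "normal", mean = 0, sd = 1),
                                 c = list(n = 15, dist = "normal", mean = 0, sd = 1)),
                            seed = 101)
  res <- route_and_compare(gd$data)
  expect_equal(res$route, "parametric")
  expect_equal(res$procedure, "one-way ANOVA + Tukey-Kramer")
  expect_gt(glance(res)$p_value, 0.05)
  expect_true(all(res$shapiro$normal))
})

test_that("an exponential group flips the route to Kruskal-Wallis + Dunn", {
  gd <- generate_group_data(list(a = list(n = 30, dist = "normal", mean = 5, sd = 1),
                                 b = list(n = 30, dist = "normal", mean = 5, sd = 1),
                                 c = list(n = 30, dist = "exponential", rate = 0.2)),
                            seed = 7)
  res <- route_and_compare(gd$data)
  expect_equal(res$route, "nonparametric")
  expect_match(res$procedure, "Dunn")
  expect_false(all(res$shapiro$normal))
  # route is a pure function of the per-group screen
  res2 <- route_and_compare(gd$data)
  expect_identical(res$route, res2$route)
})

test_that("a 5-sigma effect is detected with adjusted p < 0.001", {
  gd <- generate_group_data(list(lo = list(n = 20, dist = "normal", mean = 0, sd = 1),
                                 hi = list(n = 20, dist = "normal", mean = 5, sd = 1)),
                            seed = 23)
  res <- route_and_compare(gd$data)
  expect_lt(tidy(res)$p_adj[1], 0.001)
  expect_true(tidy(res)$stars[1] %in% c("***", "****"))
})

test_that("relabeling groups permutes the post hoc table without changing p-values", {
  gd <- generate_group_data(list(a = list(n = 12, dist = "normal", mean = 0, sd = 1),
                                 b = list(n = 12, dist = "normal", mean = 1, sd = 1),
                                 c = list(n = 12, dist = "normal", mean = 2, sd = 1)),
                            seed = 31)
  res1 <- route_and_compare(gd$data)
  relabeled <- dplyr::mutate(gd$data, group = dplyr::recode(group, a = "z", b = "y", c = "x"))
  res2 <- route_and_compare(relabeled)
  expect_equal(sort(unname(res1$posthoc$p_adj)), sort(unname(res2$posthoc$p_adj)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(glance(res1)$p_value, glance(res2)$p_value)
})

test_that("star thresholds follow the four caption levels", {
  p <- c(0.2, 0.04, 0.009, 0.0009, 0.00009)
  expect_equal(neuroquant:::p_stars(p), c("ns", "*", "**", "***", "****"))
})

test_that("Holm-Sidak adjustment is a monotone step-down Sidak", {
  p <- c(0.01, 0.04, 0.03)
  adj <- neuroquant:::holm_sidak_adjust(p)
  # smallest p adjusted with m = 3, next with m = 2, largest with m = 1
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.03)^2, adj[1]))
  expect_true(all(diff(adj[order(p)]) >= 0))
  # selected on the parametric branch; normal-quantile fixture passes the
  # Shapiro screen by construction
  d <- data.frame(value = c(qnorm(ppoints(15)), qnorm(ppoints(15)) + 3),
                  group = rep(c("a", "b"), each = 15))
  res <- route_and_compare(d, posthoc = "holm-sidak")
  expect_match(res$procedure, "Holm-Sidak")
  expect_lt(tidy(res)$p_adj[1], 0.001)
})

test_that("Dunn z statistics agree with the rank-sum definition on a tie-free fixture", {
  vals <- c(1, 3, 5, 7, 2, 4, 6, 8, 10, 12, 14, 16)
  grp <- rep(c("a", "b", "c"), each = 4)
  d <- neuroquant:::dunn_test(vals, grp, p_adjust = "none")
  r <- rank(vals)
  mr <- tapply(r, grp, mean)
  N <- 12
  se <- sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 4))
  expect_equal(d$estimate[d$comparison == "a - b"],
               unname((mr["a"] - mr["b"]) / se), tolerance = 1e-12)
  expect_equal(d$p_raw, 2 * pnorm(-abs(d$estimate)), tolerance = 1e-12)
})

test_that("two-way designs report main effects, interaction and Tukey tables", {
  gd <- tidyr::expand_grid(condition = c("SCN", "SCN-AC", "SCN-AC-LN"),
                           day = c(1, 7, 14), rep = 1:5)
  set.seed(3)
  gd$value <- with(gd, as.numeric(factor(condition)) * 2 + day * 0.1 + rnorm(nrow(gd)))
  res <- route_and_compare(gd, design = "two-way")
  expect_equal(res$omnibus$term, c("condition", "day", "condition:day"))
  expect_lt(res$omnibus$p_value[1], 0.001)
  expect_true(any(grepl(":", res$posthoc$term)))
  expect_match(res$procedure, "two-way ANOVA")
})

test_that("small or degenerate groups are rejected with clear errors", {
  bad <- data.frame(value = c(1, 2, 3, 4), group = c("a", "a", "a", "b"))
  expect_error(route_and_compare(bad), class = "nq_validation_error")
  one <- data.frame(value = 1:5, group = "a")
  expect_error(route_and_compare(one), class = "nq_validation_error")
})

test_that("identical constant groups produce no rejection", {
  const <- data.frame(value = rep(5, 30), group = rep(c("a", "b", "c"), each = 10))
  res <- route_and_compare(const)
  expect_equal(res$route, "nonparametric")  # constant data cannot pass the screen
  expect_gte(glance(res)$p_value, 0.05)
})

test_that("empirical type-I error sits near alpha for normal and heavy-tailed nulls", {
  # 600 reps at module level; the 2000-rep study runs in the acceptance suite
  r <- type_i_error_check(n_groups = 3, n = 10, reps = 600, seed = 2)
  expect_gt(r$rejection_rate, 0.03)
  expect_lt(r$rejection_rate, 0.07)
  r2 <- type_i_error_check(n_groups = 3, n = 10, reps = 600,
                           rdist = function(n) stats::rt(n, df = 3), seed = 2)
  expect_gt(r2$rejection_rate, 0.03)
  expect_lt(r2$rejection_rate, 0.07)
  expect_error(type_i_error_check(reps = 100), class = "nq_validation_error")
})
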