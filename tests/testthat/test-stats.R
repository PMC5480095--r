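test_that("per-well aggregation averages fields and tracks ND exclusions", {
  tbl <- tibble::tibble(
    well_id = rep(c("A1", "A2"), each = 4),
    field = rep(1:4, 2),
    m1 = c(rep(5, 4), 1, 2, 3, NA),
    m2 = c(rep(NA_real_, 4), rep(1, 4))
  )
  ws <- aggregate_per_well(tbl)
  a1m1 <- ws[ws$well_id == "A1" & ws$metric == "m1", ]
  expect_equal(a1m1$mean, 5)
  a2m1 <- ws[ws$well_id == "A2" & ws$metric == "m1", ]
  expect_equal(a2m1$mean, 2)
  expect_equal(a2m1$n_used, 3)
  expect_equal(a2m1$n_nd, 1)
  # a well with all-ND fields stays ND
  a1m2 <- ws[ws$well_id == "A1" & ws$metric == "m2", ]
  expect_true(is.na(a1m2$mean))
  # permuting field order changes nothing
  ws2 <- aggregate_per_well(tbl[sample(nrow(tbl)), ])
  expect_equal(dplyr::arrange(ws, well_id, metric),
               dplyr::arrange(ws2, well_id, metric))
})

test_that("Shapiro-Wilk wraps cleanly and flags degenerate groups", {
  set.seed(23)
  d <- tibble::tibble(v = c(rnorm(20), rep(1, 10)),
                      g = rep(c("a", "b"), c(20, 10)))
  sh <- shapiro_by_group(d, v, g)
  expect_equal(nrow(sh), 2)
  expect_false(is.na(sh$shapiro_p[sh$group == "a"]))
  expect_true(is.na(sh$shapiro_p[sh$group == "b"])) # identical values
  ref <- stats::shapiro.test(d$v[d$g == "a"])
  expect_equal(sh$shapiro_w[sh$group == "a"], ref$statistic[[1]])
})

test_that("Kruskal-Wallis is zero for identical groups and matches base R", {
  d0 <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                       g = rep(c("a", "b", "c"), each = 3))
  expect_equal(kruskal_wallis(d0, v, g)$kruskal_h, 0)
  set.seed(24)
  d <- tibble::tibble(v = rnorm(30), g = rep(letters[1:3], 10))
  kw <- kruskal_wallis(d, v, g)
  ref <- stats::kruskal.test(d$v, factor(d$g))
  expect_equal(kw$kruskal_h, ref$statistic[[1]])
  expect_equal(kw$kruskal_p, ref$p.value)
  expect_error(kruskal_wallis(d[d$g == "a", ], v, g), ">= 2 groups")
})

test_that("two-group Steel agrees with the exact Wilcoxon rank-sum test", {
  set.seed(25)
  for (i in 1:3) {
    d <- tibble::tibble(v = c(rnorm(6), rnorm(6, 1.2)),
                        g = rep(c("ctrl", "trt"), each = 6))
    st <- steel_test(d, v, g, control = "ctrl", n_perm = 20000)
    w <- stats::wilcox.test(v ~ g, data = d, exact = TRUE)
    expect_lt(abs(st$p_adjusted - w$p.value), 0.01)
  }
})

test_that("a 5-SD shifted treatment reaches the strong-significance tier", {
  set.seed(26)
  d <- tibble::tibble(
    v = c(rnorm(6), rnorm(6), rnorm(6, 5)),
    g = rep(c("ctrl", "a", "c"), each = 6)
  )
  st <- steel_test(d, v, g, control = "ctrl", n_perm = 1e5)
  expect_lt(st$p_adjusted[st$comparison == "c - ctrl"], 0.005)
  expect_true(all(st$p_adjusted >= st$p_unadjusted - 1e-9))
  # the normal approximation agrees on which comparison stands out
  stn <- steel_test(d, v, g, control = "ctrl", method = "normal")
  expect_equal(which.min(stn$p_adjusted), which.min(st$p_adjusted))
})

test_that("Dunn all-pairs flags only the shifted group's pairs", {
  d0 <- tibble::tibble(v = c(1:6, 1:6) + 0.01 * rnorm(12),
                       g = rep(c("a", "b"), each = 6))
  set.seed(27)
  dn0 <- dunn_all_pairs(tibble::tibble(v = rnorm(12),
                                       g = rep(c("a", "b"), each = 6)), v, g)
  expect_lt(abs(dn0$statistic), 2)
  expect_gt(dn0$p_adjusted, 0.05)
  d <- tibble::tibble(v = c(rnorm(6), rnorm(6), rnorm(6, 5)),
                      g = rep(c("a", "b", "c"), each = 6))
  dn <- dunn_all_pairs(d, v, g)
  sig <- dn$p_adjusted < 0.05
  expect_identical(sort(dn$comparison[sig]), c("a - c", "b - c"))
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted - 1e-9))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(28)
  d <- tibble::tibble(v = rlnorm(24), g = rep(letters[1:4], each = 6))
  f <- function(x) exp(x / 2) + x^3 / 100
  d2 <- dplyr::mutate(d, v = f(v))
  expect_equal(kruskal_wallis(d, v, g), kruskal_wallis(d2, v, g))
  expect_equal(dunn_all_pairs(d, v, g), dunn_all_pairs(d2, v, g))
  set.seed(1); s1 <- steel_test(d, v, g, control = "a", n_perm = 500)
  set.seed(1); s2 <- steel_test(d2, v, g, control = "a", n_perm = 500)
  expect_equal(s1$statistic, s2$statistic)
  expect_equal(s1$p_adjusted, s2$p_adjusted)
})

test_that("post-hoc tests run only when the omnibus gate rejects", {
  d0 <- tibble::tibble(v = rep(c(1, 2, 3, 4, 5, 6), 3),
                       g = rep(c("ctrl", "a", "b"), each = 6))
  gc0 <- compare_groups(d0, v, g, control = "ctrl")
  expect_null(gc0$posthoc) # identical groups: no gate rejection
  expect_equal(nrow(generics::tidy(gc0)), 0)
  set.seed(29)
  d1 <- tibble::tibble(v = c(rnorm(6), rnorm(6), rnorm(6, 6)),
                       g = rep(c("ctrl", "a", "b"), each = 6))
  gc1 <- compare_groups(d1, v, g, control = "ctrl", metric = "demo",
                        n_perm = 1e5)
  expect_false(is.null(gc1$posthoc))
  td <- generics::tidy(gc1)
  expect_true(all(c("metric", "comparison", "p_adjusted", "tier")
                  %in% names(td)))
  expect_identical(td$tier[td$comparison == "b - ctrl"], "**")
  gl <- generics::glance(gc1)
  expect_true(gl$posthoc_performed)
  expect_gte(gl$n_significant, 1)
  # without a control the all-pairs procedure is chosen
  gc2 <- compare_groups(d1, v, g)
  expect_s3_class(gc2$posthoc, "dunn_test")
})

test_that("significance tiers follow the two-star convention", {
  expect_identical(neurohcs:::significance_tier(c(0.06, 0.04, 0.004, NA)),
                   c("ns", "*", "**", NA))
})
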