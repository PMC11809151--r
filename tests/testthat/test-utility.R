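test_that("identical tables give zero marginal differences everywhere", {
  d <- small_cohort(200, seed = 51)$data
  mc <- compare_marginals(d, d)
  expect_true(all(mc$diff == 0))
  expect_true(all(mc$pct_diff == 0))
})

test_that("marginal counts match a hand tally on a 6-row toy", {
  obs <- data.frame(g = factor(c("a", "a", "b", "b", "b", NA)),
                    x = c(1, 2, 3, 4, 5, 6))
  syn <- data.frame(g = factor(c("a", "b", "b", NA, NA, "a"),
                               levels = c("a", "b")),
                    x = c(1, 1, 2, 6, 6, 6))
  mc <- compare_marginals(obs, syn)
  g <- mc[mc$variable == "g", ]
  expect_identical(g$observed_n[g$category == "a"], 2L)
  expect_identical(g$synthetic_n[g$category == "a"], 2L)
  expect_identical(g$observed_n[g$category == "b"], 3L)
  expect_identical(g$synthetic_n[g$category == "b"], 2L)
  expect_identical(g$observed_n[g$category == "NA"], 1L)
  expect_identical(g$synthetic_n[g$category == "NA"], 2L)
  # counts sum to table sizes (invariant), for every variable
  sums <- aggregate(cbind(observed_n, synthetic_n) ~ variable, mc, sum)
  expect_true(all(sums$observed_n == 6))
  expect_true(all(sums$synthetic_n == 6))
})

test_that("synthetic-only categories are reported with observed count 0", {
  obs <- data.frame(g = factor(c("a", "a", "b")))
  syn <- data.frame(g = factor(c("a", "zzz", "b")))
  mc <- compare_marginals(obs, syn)
  row <- mc[mc$category == "zzz", ]
  expect_identical(row$observed_n, 0L)
  expect_identical(row$synthetic_n, 1L)
})

test_that("continuous bins come from observed quartiles and cover synthetic", {
  obs <- data.frame(x = c(1:100 + 0.0))
  syn <- data.frame(x = c(rep(50, 50), -500, 500))
  mc <- compare_marginals(obs, syn)
  expect_identical(sum(mc$observed_n), 100L)
  expect_identical(sum(mc$synthetic_n), 52L)  # extremes binned, not dropped
})

test_that("compare_marginals is symmetric up to count-column swap", {
  a <- small_cohort(150, seed = 52)$data
  b <- small_cohort(150, seed = 53)$data
  # restrict to categorical columns: continuous breaks come from the first
  # argument by design
  cats <- names(a)[sapply(a, is.factor)]
  m1 <- compare_marginals(a[cats], b[cats])
  m2 <- compare_marginals(b[cats], a[cats])
  m2o <- m2[order(m2$variable, m2$category), ]
  m1o <- m1[order(m1$variable, m1$category), ]
  expect_identical(m1o$observed_n, m2o$synthetic_n)
  expect_identical(m1o$synthetic_n, m2o$observed_n)
})

test_that("ci_overlap arithmetic: identical, disjoint, partial, degenerate", {
  expect_equal(ci_overlap(c(0, 1), c(0, 1)), 1)
  expect_equal(ci_overlap(c(0, 1), c(2, 3)), 0)
  expect_equal(ci_overlap(c(0, 2), c(1, 3)), 0.5)   # mean(1/2, 1/2)
  expect_equal(ci_overlap(c(1, 1), c(1, 1)), 1)     # equal points
  expect_equal(ci_overlap(c(1, 1), c(2, 2)), 0)     # distinct points
  expect_error(ci_overlap(c(2, 1), c(0, 1)))
})

test_that("fitting the same data twice gives identical fits, overlap 1", {
  d <- small_cohort(600, seed = 54)$data
  cmp <- fit_glm_both(depression_17 ~ mat_dep + matage, "binomial", d, d)
  expect_equal(cmp$estimate_obs, cmp$estimate_syn)
  expect_equal(cmp$ci_overlap, rep(1, nrow(cmp)))
  # z * SE = estimate to machine precision
  expect_equal(cmp$z_obs * cmp$se_obs, cmp$estimate_obs, tolerance = 1e-12)
  expect_overlap_unit(cmp$ci_overlap)
})

test_that("fit_glm_both is row-order invariant", {
  d <- small_cohort(500, seed = 55)$data
  s <- small_cohort(500, seed = 56)$data
  cmp1 <- fit_glm_both(depression_17 ~ mat_dep + gender, "binomial", d, s)
  set.seed(1); perm <- sample(nrow(d))
  cmp2 <- fit_glm_both(depression_17 ~ mat_dep + gender, "binomial",
                       d[perm, ], s[rev(seq_len(nrow(s))), ])
  expect_equal(cmp1$estimate_obs, cmp2$estimate_obs, tolerance = 1e-10)
  expect_equal(cmp1$estimate_syn, cmp2$estimate_syn, tolerance = 1e-10)
})

test_that("both fits recover a shared logistic truth (b1 = 0.4) at n = 20000", {
  gen <- function(seed) {
    set.seed(seed)
    n <- 20000
    x <- rnorm(n)
    data.frame(x = x,
               y = factor(ifelse(runif(n) < plogis(-1 + 0.4 * x), "yes", "no"),
                          levels = c("no", "yes")))
  }
  cmp <- fit_glm_both(y ~ x, "binomial", gen(61), gen(62))
  b <- cmp[cmp$term == "x", ]
  expect_lt(abs(b$estimate_obs - 0.4), 3 * b$se_obs)
  expect_lt(abs(b$estimate_syn - 0.4), 3 * b$se_syn)
  expect_lt(abs(b$estimate_obs - b$estimate_syn),
            3 * sqrt(b$se_obs^2 + b$se_syn^2))
  expect_gt(b$ci_overlap, 0)
})

test_that("missing formula variables raise a named contract error", {
  d <- data.frame(y = factor(c("a", "b")), x = c(1, 2))
  expect_error(fit_glm_both(y ~ x + ghost, "binomial", d, d), "ghost")
})

test_that("comparison plots build without error", {
  d <- small_cohort(300, seed = 57)$data
  rel <- synthesize(d, seed = 58)
  mc <- compare_marginals(d, rel)
  p1 <- plot_marginals(mc, variables = c("gender", "mated"))
  expect_s3_class(p1, "ggplot")
  cmp <- fit_glm_both(depression_17 ~ mat_dep + gender, "binomial", d, rel)
  p2 <- plot_coefficients(cmp)
  expect_s3_class(p2, "ggplot")
})
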