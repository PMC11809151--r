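test_that("marginal resampling: constant column, support, and proportions", {
  expect_identical(sample_marginal(c(5, 5, 5), 4, seed = 1), rep(5, 4))
  expect_error(sample_marginal(c(1, 2), 0), "positive")

  # 30% missing column: synthetic NA share within 3 binomial SEs of 0.30
  x <- c(rep(NA, 300), rnorm(700))
  s <- sample_marginal(x, 10000, seed = 2)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(is.na(s)) - 0.30), 3 * se)
  expect_true(all(s[!is.na(s)] %in% x))

  # 50/50 categorical: chi-square GOF against the observed marginal
  g <- factor(rep(c("A", "B"), each = 50))
  sg <- sample_marginal(g, 10000, seed = 3)
  p <- suppressWarnings(chisq.test(table(sg), p = c(0.5, 0.5)))$p.value
  expect_gt(p, 0.001)
})

test_that("pure leaves reproduce a deterministic target exactly", {
  x <- factor(rep(c("0", "1"), each = 10))
  y <- ifelse(x == "0", 10, 20)
  syn_x <- factor(sample(c("0", "1"), 50, TRUE), levels = levels(x))
  out <- cart_synthesize_column(y, data.frame(x = x), data.frame(x = syn_x),
                                controls = list(minbucket = 1, cp = 1e-8),
                                seed = 4)
  expect_identical(out, ifelse(syn_x == "0", 10, 20))
})

test_that("depth-1 CART matches the exhaustive single-split oracle", {
  # several toys, 6-10 rows, distinct split gains
  cases <- list(
    list(x = c(1, 2, 3, 4, 5, 6), y = c(2.1, 1.9, 2.0, 10.2, 9.8, 10.0)),
    list(x = c(10, 20, 30, 40, 50, 60, 70, 80),
         y = c(5, 6, 5.5, 6.2, 30, 31, 29, 30.5)),
    list(x = c(1, 1.5, 2, 8, 9, 10, 11, 12, 13, 14),
         y = c(0.2, 0.1, 0.4, 7, 7.2, 6.9, 7.4, 7.1, 7.3, 6.8))
  )
  for (cs in cases) {
    oracle <- best_single_split(cs$x, cs$y, minbucket = 1)
    fit <- fit_cart_column(cs$y, data.frame(x = cs$x),
                           controls = list(minbucket = 1, cp = 1e-8,
                                           maxdepth = 1))
    expect_length(fit$donors, 2)
    left_leaf <- names(fit$donors)[1]
    members_left <- which(fit$leaf == as.integer(left_leaf))
    expect_identical(members_left, oracle$members_left)
    expect_identical(sort(fit$donors[[1]]), oracle$donors_left)
    expect_identical(sort(fit$donors[[2]]), oracle$donors_right)
  }
})

test_that("every observed row maps to one leaf with non-empty donors", {
  d <- small_cohort(300)$data
  keep <- complete.cases(d[c("mat_dep", "matage", "mated")])
  fit <- fit_cart_column(d$mat_dep[keep],
                         d[keep, c("matage", "mated")])
  expect_length(fit$leaf, sum(keep))
  expect_true(all(lengths(fit$donors) > 0))
  expect_setequal(unique(fit$leaf), as.integer(names(fit$donors)))
})

test_that("CART conditional means track the observed ones at n = 5000", {
  set.seed(31)
  n <- 5000
  x <- factor(sample(c("lo", "hi"), n, TRUE))
  y <- ifelse(x == "lo", 2, 8) + rnorm(n)
  syn_x <- factor(sample(c("lo", "hi"), n, TRUE), levels = levels(x))
  ys <- cart_synthesize_column(y, data.frame(x = x), data.frame(x = syn_x),
                               seed = 5)
  for (lev in levels(x)) {
    m_obs <- mean(y[x == lev])
    sd_obs <- sd(y[x == lev])
    m_syn <- mean(ys[syn_x == lev])
    expect_lt(abs(m_syn - m_obs), 3 * sd_obs / sqrt(sum(syn_x == lev)))
  }
})

test_that("out-of-range synthetic predictors are routed, never an error", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 2, 2, 9, 9, 9)
  out <- cart_synthesize_column(y, data.frame(x = x),
                                data.frame(x = c(-100, 100)),
                                controls = list(minbucket = 1, cp = 1e-8),
                                seed = 6)
  expect_identical(out, c(2, 9))
})

test_that("norm family: zero-noise limit and linear recovery", {
  x <- seq(1, 10, length.out = 30)
  y <- 2 * x
  xs <- data.frame(x = c(2.5, 7.25))
  out <- parametric_synthesize_column(y, data.frame(x = x), xs, "norm",
                                      seed = 7)
  expect_equal(out, c(5, 14.5), tolerance = 1e-8)
})

test_that("logit family: null model reproduces the marginal rate", {
  set.seed(41)
  n <- 4000
  x <- rnorm(n)
  y <- factor(ifelse(runif(n) < 0.5, "yes", "no"), levels = c("no", "yes"))
  out <- parametric_synthesize_column(y, data.frame(x = x),
                                      data.frame(x = rnorm(n)), "logit",
                                      seed = 8)
  rate_obs <- mean(y == "yes")
  se <- sqrt(rate_obs * (1 - rate_obs) / n)
  expect_lt(abs(mean(out == "yes") - rate_obs), 3 * se)
})

test_that("logit family preserves a known logistic model (b0=-1, b1=0.5)", {
  set.seed(43)
  n <- 20000
  x <- rnorm(n)
  y <- factor(ifelse(runif(n) < plogis(-1 + 0.5 * x), "yes", "no"),
              levels = c("no", "yes"))
  ys <- parametric_synthesize_column(y, data.frame(x = x),
                                     data.frame(x = x), "logit", seed = 9)
  refit <- glm(ys ~ x, family = binomial())
  sm <- summary(refit)$coefficients
  expect_lt(abs(sm[1, 1] - (-1)), 3 * sm[1, 2])
  expect_lt(abs(sm[2, 1] - 0.5), 3 * sm[2, 2])
})

test_that("polytomous family reproduces class composition", {
  set.seed(44)
  n <- 3000
  x <- rnorm(n)
  lev <- c("a", "b", "c")
  p <- cbind(plogis(-x), 0.5, plogis(x))
  y <- factor(apply(p, 1, function(r) sample(lev, 1, prob = r)), levels = lev)
  ys <- parametric_synthesize_column(y, data.frame(x = x),
                                     data.frame(x = x), "polytomous",
                                     seed = 10)
  for (l in lev) {
    r <- mean(y == l)
    expect_lt(abs(mean(ys == l) - r), 3 * sqrt(r * (1 - r) / n))
  }
})

test_that("a degenerate parametric fit falls back to donor sampling", {
  # single-class target: multinom cannot fit, donor sampling takes over
  y <- factor(rep("only", 12), levels = c("only", "unused"))
  x <- data.frame(x = rnorm(12))
  expect_warning(
    out <- parametric_synthesize_column(y, x, data.frame(x = rnorm(5)),
                                        "polytomous", seed = 11),
    "falling back")
  expect_identical(as.character(out), rep("only", 5))
})

test_that("smoothing: identity at bandwidth 0, fewer exact matches, moments", {
  set.seed(51)
  x <- rnorm(20000, 10, 2)
  expect_identical(apply_smoothing(x, bandwidth = 0), x)

  sm <- apply_smoothing(x, seed = 12)
  share_before <- mean(x %in% x)               # trivially 1
  share_after <- mean(sm %in% x)
  expect_lt(share_after, share_before)

  bw <- bw.nrd0(x)
  # convolution identity: var after = var before + bw^2 (clipping negligible)
  expect_lt(abs(mean(sm) - mean(x)), 3 * bw / sqrt(length(x)))
  expect_lt(abs(var(sm) - (var(x) + bw^2)),
            3 * sqrt(2 / (length(x) - 1)) * var(x))
  # clipped to the observed range, NA untouched
  x2 <- c(NA, x)
  sm2 <- apply_smoothing(x2, seed = 13)
  expect_true(is.na(sm2[1]))
  expect_gte(min(sm2, na.rm = TRUE), min(x))
  expect_lte(max(sm2, na.rm = TRUE), max(x))

  expect_warning(apply_smoothing(rep(1, 5)), "constant")
})

test_that("rules: smoking example, identity, and order-independence", {
  d <- data.frame(
    ever_smoked = factor(c("never", "past", "current", "never", NA)),
    amount_day = c(3, 10, 20, 5, 7),
    other = 1:5
  )
  out <- apply_rules(d, list(list(when = "ever_smoked == 'never'",
                                  target = "amount_day", value = 0)))
  expect_identical(out$amount_day, c(0, 10, 20, 0, 7))  # NA row untouched
  expect_identical(out$other, d$other)

  expect_identical(apply_rules(d, list()), d)

  r1 <- list(when = "ever_smoked == 'never'", target = "amount_day", value = 0)
  r2 <- list(when = "ever_smoked == 'current'", target = "other", value = -1)
  expect_identical(apply_rules(apply_rules(d, list(r1)), list(r2)),
                   apply_rules(apply_rules(d, list(r2)), list(r1)))
})

test_that("an all-sample plan keeps marginals but destroys association", {
  set.seed(61)
  n <- 4000
  a <- factor(sample(c("x", "y"), n, TRUE))
  b <- factor(ifelse(a == "x", sample(c("p", "q"), n, TRUE, c(0.9, 0.1)),
                     sample(c("p", "q"), n, TRUE, c(0.1, 0.9))))
  d <- data.frame(a = a, b = b)
  plan <- synthesis_plan(table_schema(d), method = "sample")
  plan$method[] <- "sample"
  rel <- synthesize(d, plan)
  s <- release_table(rel, false_data = FALSE)
  for (v in c("a", "b")) {
    p <- mean(d[[v]] == levels(d[[v]])[1])
    expect_lt(abs(mean(s[[v]] == levels(d[[v]])[1]) - p),
              3 * sqrt(p * (1 - p) / n))
  }
  # Cramer's V of the synthetic pair is near the independence bound
  tab <- table(s$a, s$b)
  v <- sqrt(suppressWarnings(chisq.test(tab)$statistic) / n)
  expect_lt(v, 0.05)
  # whereas the observed pair is strongly associated
  v_obs <- sqrt(suppressWarnings(chisq.test(table(d$a, d$b))$statistic) / n)
  expect_gt(v_obs, 0.5)
})

test_that("synthesis is deterministic and support-contained", {
  d <- small_cohort(300)$data
  r1 <- synthesize(d, seed = 14)
  r2 <- synthesize(d, seed = 14)
  expect_identical(release_table(r1), release_table(r2))
  s <- release_table(r1, false_data = FALSE)
  for (nm in names(d)) {
    obs_vals <- d[[nm]][!is.na(d[[nm]])]
    syn_vals <- s[[nm]][!is.na(s[[nm]])]
    expect_true(all(as.character(syn_vals) %in% as.character(obs_vals)),
                label = paste("support containment for", nm))
  }
})

test_that("the execution trace never reads a not-yet-synthesised predictor", {
  d <- small_cohort(250)$data
  rel <- synthesize(d, seed = 15)
  trace <- rel$provenance$trace
  seen <- character()
  for (v in names(trace)) {
    expect_true(all(trace[[v]] %in% seen),
                label = paste("predictors of", v, "synthesised before it"))
    seen <- c(seen, v)
  }
})

test_that("missingness relations survive synthesis of the fixture", {
  sim <- simulate_cohort(cohort_sim_config(n = 4000, seed = 16))
  d <- sim$data
  rel <- synthesize(d, seed = 17)
  s <- release_table(rel, false_data = FALSE)
  # NA share preserved per column within 4 binomial SEs
  for (nm in names(d)) {
    p <- mean(is.na(d[[nm]]))
    if (p == 0) {
      expect_equal(mean(is.na(s[[nm]])), 0)
    } else {
      expect_lt(abs(mean(is.na(s[[nm]])) - p),
                4 * sqrt(p * (1 - p) / nrow(d)),
                label = paste("NA share of", nm))
    }
  }
  # MAR structure: msoc missing more often for low education, in both tables
  gap_obs <- mean(is.na(d$msoc[d$mated == "CSE/None"])) -
    mean(is.na(d$msoc[d$mated != "CSE/None"]))
  gap_syn <- mean(is.na(s$msoc[s$mated == "CSE/None"])) -
    mean(is.na(s$msoc[s$mated != "CSE/None"]))
  expect_gt(gap_obs, 0)
  expect_gt(gap_syn, 0)
})

test_that("rules and smoothing are honoured by the full engine", {
  d <- small_cohort(500, seed = 22)$data
  plan <- synthesis_plan(
    table_schema(d),
    smoothing = c("bwt", "parity"),  # smoothing a rule target: rule wins
    rules = list(list(when = "gender == 'Male'", target = "parity",
                      value = 0)),
    seed = 18
  )
  rel <- synthesize(d, plan)
  s <- release_table(rel, false_data = FALSE)
  expect_true(all(s$parity[s$gender == "Male"] == 0))
  # smoothed column leaves the observed support but stays in range
  expect_lt(mean(s$bwt[!is.na(s$bwt)] %in% d$bwt), 0.5)
  expect_gte(min(s$bwt, na.rm = TRUE), min(d$bwt, na.rm = TRUE))
  expect_lte(max(s$bwt, na.rm = TRUE), max(d$bwt, na.rm = TRUE))
})
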