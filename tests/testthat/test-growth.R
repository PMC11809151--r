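test_that("wide_to_long expands completely and drops missing occasions", {
  w <- data.frame(id = c(1, 2), female = c(0, 1),
                  age_1 = c(7, 7.1), age_2 = c(9, 9.2), age_3 = c(11, 10.9),
                  h_1 = c(120, 122), h_2 = c(130, 131), h_3 = c(140, 138))
  long <- wide_to_long(w, paste0("h_", 1:3), paste0("age_", 1:3))
  expect_equal(nrow(long), 6)
  expect_setequal(names(long), c("id", "occasion", "age", "value", "female"))

  w2 <- w; w2$h_2[1] <- NA
  long2 <- wide_to_long(w2, paste0("h_", 1:3), paste0("age_", 1:3))
  expect_equal(nrow(long2), 5)
  # the absent pair is exactly (id 1, occasion 2)
  pairs <- expand.grid(id = c(1, 2), occasion = 1:3)
  present <- paste(long2$id, long2$occasion)
  absent <- setdiff(paste(pairs$id, pairs$occasion), present)
  expect_identical(absent, "1 2")
})

test_that("wide_to_long rejects duplicated ids and unbalanced stubs", {
  w <- data.frame(id = c(1, 1), age_1 = c(7, 8), h_1 = c(120, 125))
  expect_error(wide_to_long(w, "h_1", "age_1"), "duplicated ids")
  expect_error(wide_to_long(w, c("h_1", "h_2"), "age_1"), "pair up")
})

test_that("long -> wide round trip reproduces the panel", {
  p <- simulate_height_panel(panel_sim_config(n = 50, seed = 71,
                                              miss_prob = 0.2))
  w <- p$data
  long <- wide_to_long(w, paste0("height_", 1:8), paste0("age_", 1:8))
  expect_equal(nrow(long), sum(!is.na(w[paste0("height_", 1:8)])))
  back <- long_to_wide(long, value_prefix = "height_", age_prefix = "age_")
  for (k in 1:8) {
    obs_mask <- !is.na(w[[paste0("height_", k)]])
    expect_equal(back[[paste0("height_", k)]][match(w$id[obs_mask], back$id)],
                 w[[paste0("height_", k)]][obs_mask])
  }
})

test_that("noise-free quadratic data is recovered essentially exactly", {
  # y = 150 + 5(a-12) - 0.2(a-12)^2, no random effects, no residual noise
  cfg <- panel_sim_config(n = 60, seed = 72,
                          fixed = c(intercept = 150, age = 5, age2 = -0.2,
                                    female = 0, female_age = 0,
                                    female_age2 = 0),
                          re_cov = matrix(0, 3, 3), resid_sd = 0,
                          miss_prob = 0)
  p <- simulate_height_panel(cfg)
  # heights are rounded to 0.1 on output; regenerate exact values for the
  # deterministic-limit check
  long <- wide_to_long(p$data, paste0("height_", 1:8), paste0("age_", 1:8))
  a <- long$age - 12
  long$value <- 150 + 5 * a - 0.2 * a^2
  fit <- fit_quadratic_growth(long)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["intercept"]), 150, tolerance = 1e-6)
  expect_equal(unname(est["age"]), 5, tolerance = 1e-6)
  expect_equal(unname(est["age2"]), -0.2, tolerance = 1e-6)
  expect_true(all(fit$random$estimate < 1e-4))
})

test_that("fixed effects are recovered within 3 SE on one fixture panel", {
  cfg <- panel_sim_config(n = 1200, seed = 73)
  p <- simulate_height_panel(cfg)
  long <- wide_to_long(p$data, paste0("height_", 1:8), paste0("age_", 1:8))
  fit <- fit_quadratic_growth(long, sex_interaction = TRUE)
  truth <- cfg$fixed
  names(truth)[names(truth) == "intercept"] <- "intercept"
  for (tm in fit$fixed$term) {
    row <- fit$fixed[fit$fixed$term == tm, ]
    expect_lt(abs(row$estimate - truth[[tm]]), 3 * row$se,
              label = paste("recovery of", tm))
  }
  expect_true(all(fit$random$estimate[grep("^var_", fit$random$term)] >= 0))
  expect_gte(fit$n_obs, fit$n)
  expect_true(all(fit$fixed$ci_lo <= fit$fixed$estimate &
                    fit$fixed$estimate <= fit$fixed$ci_hi))
})

test_that("age centring changes parameters but not the fitted curve", {
  p <- simulate_height_panel(panel_sim_config(n = 400, seed = 74))
  long <- wide_to_long(p$data, paste0("height_", 1:8), paste0("age_", 1:8))
  f12 <- fit_quadratic_growth(long, center_age = 12)
  f0 <- fit_quadratic_growth(long, center_age = 0)
  ages <- seq(7, 18, by = 0.5)
  expect_equal(predict(f12, ages), predict(f0, ages), tolerance = 0.05)
  expect_false(isTRUE(all.equal(f12$fixed$estimate[1], f0$fixed$estimate[1])))
})

test_that("compare_growth_estimates: identity and sampling-noise contract", {
  p <- simulate_height_panel(panel_sim_config(n = 500, seed = 75))
  long <- wide_to_long(p$data, paste0("height_", 1:8), paste0("age_", 1:8))
  fit <- fit_quadratic_growth(long)
  cmp <- compare_growth_estimates(fit, fit)
  fx <- cmp[cmp$type == "fixed", ]
  expect_true(all(fx$difference == 0))
  expect_true(all(fx$ci_overlap == 1))

  p2 <- simulate_height_panel(panel_sim_config(n = 500, seed = 76))
  long2 <- wide_to_long(p2$data, paste0("height_", 1:8), paste0("age_", 1:8))
  fit2 <- fit_quadratic_growth(long2)
  cmp2 <- compare_growth_estimates(fit, fit2)
  fx2 <- cmp2[cmp2$type == "fixed", ]
  se1 <- fit$fixed$se; se2 <- fit2$fixed$se
  expect_true(all(abs(fx2$difference) < 3 * sqrt(se1^2 + se2^2)))
})

test_that("mismatched specifications are a contract error", {
  p <- simulate_height_panel(panel_sim_config(n = 200, seed = 77))
  long <- wide_to_long(p$data, paste0("height_", 1:8), paste0("age_", 1:8))
  f1 <- fit_quadratic_growth(long)
  f2 <- fit_quadratic_growth(long, sex_interaction = TRUE)
  expect_error(compare_growth_estimates(f1, f2), "different parameter sets")
})

test_that("fewer than 3 distinct ages is rejected", {
  long <- data.frame(id = rep(1:10, 2), occasion = rep(1:2, each = 10),
                     age = rep(c(8, 12), each = 10), value = rnorm(20, 140))
  expect_error(fit_quadratic_growth(long), "3 distinct ages")
})

test_that("trajectory plot builds for observed-vs-synthetic fits", {
  p <- simulate_height_panel(panel_sim_config(n = 300, seed = 78))
  long <- wide_to_long(p$data, paste0("height_", 1:8), paste0("age_", 1:8))
  f <- fit_quadratic_growth(long, sex_interaction = TRUE)
  pl <- plot_trajectories(list(observed = f, synthetic = f))
  expect_s3_class(pl, "ggplot")
})
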