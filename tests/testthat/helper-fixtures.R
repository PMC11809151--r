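# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk.

# three-variable toy in the canonical age/sex/height shape
toy_ash <- function(n = 40, seed = 11) {
  set.seed(seed)
  data.frame(
    age = round(rnorm(n, 40, 10), 1),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    height = round(rnorm(n, 170, 8), 1)
  )
}

# brute-force oracle: best single split of a regression tree by SS decrease,
# scanning candidate thresholds left to right (midpoints of sorted unique x)
best_single_split <- function(x, y, minbucket = 1) {
  xs <- sort(unique(x))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  ss <- function(v) sum((v - mean(v))^2)
  best <- NULL
  for (cut in cuts) {
    left <- y[x < cut]; right <- y[x >= cut]
    if (length(left) < minbucket || length(right) < minbucket) next
    gain <- ss(y) - (ss(left) + ss(right))
    if (is.null(best) || gain > best$gain + 1e-12)
      best <- list(cut = cut, gain = gain,
                   members_left = which(x < cut),
                   donors_left = sort(left), donors_right = sort(right))
  }
  best
}

small_cohort <- function(n = 400, seed = 21)
  simulate_cohort(cohort_sim_config(n = n, seed = seed))

expect_overlap_unit <- function(x) {
  expect_true(all(x >= 0 & x <= 1, na.rm = TRUE))
}
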