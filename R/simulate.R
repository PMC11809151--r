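## Ground-truth fixture generators. These emulate the *structure* of a
## birth-cohort analysis dataset (a cross-sectional depression analysis
## table and a wide height panel), with every generating parameter chosen
## here and recorded in a truth record — no restricted cohort estimates are
## imitated numerically. Because the truth is known, every downstream stage
## (synthesis, SDC, utility, growth modelling) can be tested quantitatively
## without any external data.

#' Configuration for the cohort fixture
#'
#' Defines the generating model for a 15-variable cross-sectional analysis
#' table: sociodemographic confounders, a bounded integer depression-score
#' exposure (0-30, binomial-logit, so its support is realistic for CART
#' donor sampling), a binary outcome from a logistic model, and MAR
#' missingness driven by observed covariates.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param exposure_betas Named numeric: logit-scale effects on the per-point
#'   probability of the 0-30 exposure score (`intercept` plus covariate
#'   effects).
#' @param outcome_betas Named numeric: logistic model of the binary outcome
#'   (`intercept`, `mat_dep` per score point, covariate effects).
#' @param missingness List of MAR specs `list(target =, logit = <expression
#'   string>)` passed to [inject_missingness()]; `NULL` for the defaults,
#'   `list()` for complete data.
#' @return A `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 5000L, seed = 1L,
                              exposure_betas = NULL,
                              outcome_betas = NULL,
                              missingness = NULL) {
  stopifnot(n >= 1L)
  if (is.null(exposure_betas))
    exposure_betas <- c(intercept = stats::qlogis(0.20),
                        housing_council = 0.30, mated_low = 0.25,
                        mated_high = -0.15, matage = -0.015)
  if (is.null(outcome_betas))
    outcome_betas <- c(intercept = -2.7, mat_dep = 0.08, female = 0.5,
                       matage = -0.01, mated_low = 0.25, mated_high = -0.15,
                       housing_council = 0.20, ethnic_nonwhite = 0.10)
  if (is.null(missingness))
    missingness <- default_cohort_missingness()
  probs <- list(
    gender = c(Male = 0.5, Female = 0.5),
    ethnic = c(White = 0.95, `Non-white` = 0.05),
    mated = c(`CSE/None` = 0.30, `O-level` = 0.45, `A-level/Degree` = 0.25),
    housing = c(`Owned/mortgaged` = 0.70, `Council/rented` = 0.25,
                Other = 0.05),
    marital = c(Married = 0.75, Cohabiting = 0.17, Single = 0.08),
    soc = c(I = 0.07, II = 0.30, III = 0.35, IV = 0.20, V = 0.08),
    pregSize = c(Singleton = 0.985, Twin = 0.015)
  )
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8)
      stop("infeasible category probabilities for '", nm, "'")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 probs = probs,
                 matage_mean = 28, matage_sd = 5,
                 exposure_betas = exposure_betas,
                 outcome_betas = outcome_betas,
                 missingness = missingness),
            class = "cohort_sim_config")
}

default_cohort_missingness <- function() {
  list(
    list(target = "bwt",
         logit = "-2.2 + 0.5 * (housing == 'Council/rented')"),
    list(target = "gest",
         logit = "-2.2 + 0.5 * (housing == 'Council/rented')"),
    list(target = "pated", logit = "-1.9 + 0.4 * (marital == 'Single')"),
    list(target = "msoc", logit = "-2.0 + 0.5 * (mated == 'CSE/None')"),
    list(target = "psoc", logit = "-1.8 + 0.5 * (mated == 'CSE/None')"),
    list(target = "marital", logit = "-2.6"),
    list(target = "mat_dep",
         logit = "-2.9 + 0.4 * (mated == 'CSE/None')"),
    list(target = "depression_17",
         logit = "-2.4 + 0.3 * (housing == 'Council/rented')")
  )
}

#' Simulate the cohort fixture
#'
#' Draws a complete table from the generating model of a
#' [cohort_sim_config()], then applies its MAR missingness. The result has
#' the 15-variable shape of a typical perinatal-cohort depression analysis:
#' child variables (gender, birthweight, gestation, pregnancy size),
#' maternal sociodemographics (age, education, social class, housing,
#' marital status, ethnicity, parity, partner's education/class), the
#' depression-score exposure and the binary outcome.
#'
#' @param config A [cohort_sim_config()].
#' @return List with `data` (the data frame) and `truth` (the config, i.e.
#'   every generating parameter).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n
  pr <- config$probs
  eb <- config$exposure_betas
  ob <- config$outcome_betas

  d <- with_stream(config$seed, 1L, {
    draw_cat <- function(p) factor(sample(names(p), n, TRUE, prob = p),
                                   levels = names(p))
    gender <- draw_cat(pr$gender)
    ethnic <- draw_cat(pr$ethnic)
    mated <- draw_cat(pr$mated)
    marital <- draw_cat(pr$marital)
    pregSize <- draw_cat(pr$pregSize)
    matage <- round(pmin(45, pmax(16, stats::rnorm(n, config$matage_mean,
                                                   config$matage_sd))), 1)
    # housing depends on education (social gradient)
    p_owned <- stats::plogis(stats::qlogis(pr$housing[["Owned/mortgaged"]]) +
                               0.8 * (mated == "A-level/Degree") -
                               0.8 * (mated == "CSE/None"))
    u <- stats::runif(n)
    housing <- factor(ifelse(u < p_owned, "Owned/mortgaged",
                             ifelse(u < p_owned + (1 - p_owned) * 0.83,
                                    "Council/rented", "Other")),
                      levels = names(pr$housing))
    # partner's education loosely matches mother's
    pated <- ifelse(stats::runif(n) < 0.55, as.character(mated),
                    sample(names(pr$mated), n, TRUE, prob = pr$mated))
    pated <- factor(pated, levels = names(pr$mated))
    msoc <- draw_cat(pr$soc)
    psoc <- ifelse(stats::runif(n) < 0.4, as.character(msoc),
                   sample(names(pr$soc), n, TRUE, prob = pr$soc))
    psoc <- factor(psoc, levels = names(pr$soc))
    parity <- pmin(stats::rpois(n, 0.9), 4)
    gest <- round(pmin(43, pmax(25, stats::rnorm(n, 39.4, 1.9))), 1)
    bwt <- round(3.40 + 0.19 * (gest - 39.4) + 0.12 * (gender == "Male") -
                   0.90 * (pregSize == "Twin") + stats::rnorm(n, 0, 0.45), 3)

    eta_exp <- eb[["intercept"]] +
      eb[["housing_council"]] * (housing == "Council/rented") +
      eb[["mated_low"]] * (mated == "CSE/None") +
      eb[["mated_high"]] * (mated == "A-level/Degree") +
      eb[["matage"]] * (matage - config$matage_mean)
    mat_dep <- stats::rbinom(n, 30L, stats::plogis(eta_exp))

    eta_out <- ob[["intercept"]] + ob[["mat_dep"]] * mat_dep +
      ob[["female"]] * (gender == "Female") +
      ob[["matage"]] * (matage - config$matage_mean) +
      ob[["mated_low"]] * (mated == "CSE/None") +
      ob[["mated_high"]] * (mated == "A-level/Degree") +
      ob[["housing_council"]] * (housing == "Council/rented") +
      ob[["ethnic_nonwhite"]] * (ethnic == "Non-white")
    depression_17 <- factor(ifelse(stats::runif(n) < stats::plogis(eta_out),
                                   "Yes", "No"), levels = c("No", "Yes"))

    data.frame(gender, bwt, gest, ethnic, matage, mated, pated, msoc, psoc,
               housing, marital, parity = as.numeric(parity), pregSize,
               mat_dep = as.numeric(mat_dep), depression_17)
  })

  if (length(config$missingness))
    d <- inject_missingness(d, config$missingness,
                            seed = derive_stream_seed(config$seed, 2L))
  list(data = d, truth = config)
}

#' Configuration for the height-panel fixture
#'
#' Generating model for a wide repeated-measures panel: per-individual
#' heights at (jittered) target ages follow a quadratic growth curve with
#' correlated random intercept and random linear and quadratic age slopes,
#' optional female offsets, and Gaussian residual noise. Age is centred at
#' `center_age` in the truth parameterisation.
#'
#' @param n Number of individuals.
#' @param occasions Number of measurement occasions (>= 3; default 8).
#' @param target_ages Nominal ages in years, one per occasion (default 8
#'   ages spanning 7-18).
#' @param fixed Named numeric truth: `intercept` (cm at `center_age`),
#'   `age` (cm/year), `age2` (cm/year^2), `female`, `female_age`,
#'   `female_age2`.
#' @param re_cov 3x3 symmetric PSD covariance of the random (intercept, age,
#'   age2) effects.
#' @param resid_sd Residual standard deviation (cm).
#' @param age_jitter_sd SD of the per-(individual, occasion) age jitter
#'   (years).
#' @param miss_prob Probability each occasion's measurement is missing.
#' @param center_age Centring age of the truth parameterisation.
#' @param seed Integer seed.
#' @return A `panel_sim_config`.
#' @export
panel_sim_config <- function(n = 2000L, occasions = 8L,
                             target_ages = NULL,
                             fixed = c(intercept = 150, age = 5.5,
                                       age2 = -0.25, female = 0.5,
                                       female_age = -1.0,
                                       female_age2 = -0.2),
                             re_cov = NULL, resid_sd = 2.5,
                             age_jitter_sd = 0.25, miss_prob = 0.10,
                             center_age = 12, seed = 1L) {
  stopifnot(occasions >= 3L, n >= 1L, resid_sd >= 0, miss_prob >= 0,
            miss_prob <= 1)
  if (is.null(target_ages))
    target_ages <- seq(7, 18, length.out = occasions)
  stopifnot(length(target_ages) == occasions)
  if (is.null(re_cov)) {
    re_cov <- matrix(c(40.0, 1.00, -0.40,
                       1.00, 0.50,  0.05,
                       -0.40, 0.05, 0.02), 3, 3, byrow = TRUE)
  }
  if (!isSymmetric(unname(re_cov)) || any(eigen(re_cov,
                                                symmetric = TRUE,
                                                only.values = TRUE)$values <
                                          -1e-8))
    stop("random-effect covariance must be symmetric positive semi-definite")
  structure(list(n = as.integer(n), occasions = as.integer(occasions),
                 target_ages = as.numeric(target_ages),
                 fixed = fixed, re_cov = re_cov, resid_sd = resid_sd,
                 age_jitter_sd = age_jitter_sd, miss_prob = miss_prob,
                 center_age = center_age, seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate the wide height panel
#'
#' @param config A [panel_sim_config()].
#' @return List with `data` (wide data frame: `id`, `female`, paired
#'   `age_k`/`height_k` columns) and `truth` (the config).
#' @export
simulate_height_panel <- function(config = panel_sim_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  n <- config$n; K <- config$occasions
  fx <- config$fixed

  with_stream(config$seed, 3L, {
    female <- stats::rbinom(n, 1L, 0.5)
    ## correlated random effects via Cholesky-like factorisation (eigen to
    ## tolerate semi-definite matrices)
    ev <- eigen(config$re_cov, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)
    re <- matrix(stats::rnorm(n * 3), n, 3) %*% t(L)

    wide <- data.frame(id = seq_len(n), female = female)
    for (k in seq_len(K)) {
      age <- round(config$target_ages[k] +
                     stats::rnorm(n, 0, config$age_jitter_sd), 2)
      a <- age - config$center_age
      mu <- (fx[["intercept"]] + re[, 1]) +
        (fx[["age"]] + re[, 2]) * a +
        (fx[["age2"]] + re[, 3]) * a^2 +
        female * (fx[["female"]] + fx[["female_age"]] * a +
                    fx[["female_age2"]] * a^2)
      height <- mu + stats::rnorm(n, 0, config$resid_sd)
      if (config$miss_prob > 0)
        height[stats::runif(n) < config$miss_prob] <- NA
      wide[[paste0("age_", k)]] <- age
      wide[[paste0("height_", k)]] <- round(height, 1)
    }
    list(data = wide, truth = config)
  })
}

#' Inject MAR missingness into a table
#'
#' Sets cells of each target column to missing with probability
#' `plogis(logit)`, where `logit` is an R expression (given as a string)
#' over *other observed* columns — missing at random by construction. A
#' mechanism referencing the target's own value (missing not at random) is
#' rejected.
#'
#' @param table Data frame.
#' @param mechanism List of specs `list(target = <column>, logit =
#'   <expression string>)`.
#' @param seed Integer seed.
#' @return The table with missingness applied.
#' @export
inject_missingness <- function(table, mechanism, seed = 1L) {
  stopifnot(is.data.frame(table))
  for (i in seq_along(mechanism)) {
    sp <- mechanism[[i]]
    used <- intersect(all.vars(str2lang(sp$logit)), names(table))
    if (sp$target %in% used)
      stop("missingness mechanism for '", sp$target,
           "' references the target's own value (MNAR not supported)")
    unknown <- setdiff(all.vars(str2lang(sp$logit)), names(table))
    if (length(unknown))
      stop("missingness mechanism for '", sp$target,
           "' references unknown column(s): ",
           paste(unknown, collapse = ", "))
  }
  with_stream(seed, 4L, {
    for (sp in mechanism) {
      eta <- eval(str2lang(sp$logit), envir = table, enclos = baseenv())
      eta <- rep_len(eta, nrow(table))
      hit <- stats::runif(nrow(table)) < stats::plogis(eta)
      table[[sp$target]][hit] <- NA
    }
    table
  })
}
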