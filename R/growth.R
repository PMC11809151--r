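## Longitudinal validation: wide<->long reshaping and multilevel quadratic
## growth-curve fits. Panels are synthesised strictly in WIDE format (one
## row per individual) so within-individual relations survive synthesis;
## the long format is only an analysis representation.

#' Reshape a wide repeated-measures panel to long format
#'
#' Produces one row per non-missing (individual, occasion) pair with the
#' occasion's age and measurement value. Occasions whose measurement is
#' missing are dropped; a missing age with a non-missing value drops the
#' pair too (no usable time axis).
#'
#' @param table Wide data frame, one row per individual.
#' @param value_stubs Character vector of measurement column names, one per
#'   occasion, in occasion order.
#' @param age_columns Character vector of per-occasion age column names,
#'   same length and order as `value_stubs`.
#' @param id Name of the unique identifier column (default `"id"`).
#' @param carry Names of individual-level columns to carry into the long
#'   table (default: all columns other than id, values and ages).
#' @return Long data frame with columns `id`, `occasion`, `age`, `value`,
#'   plus the carried columns.
#' @export
wide_to_long <- function(table, value_stubs, age_columns, id = "id",
                         carry = NULL) {
  stopifnot(is.data.frame(table))
  if (length(value_stubs) != length(age_columns))
    stop("value_stubs and age_columns must pair up one per occasion")
  if (!(id %in% names(table))) stop("id column '", id, "' not found")
  if (anyDuplicated(table[[id]]))
    stop("duplicated ids in wide input; one row per individual required")
  if (is.null(carry))
    carry <- setdiff(names(table), c(id, value_stubs, age_columns))

  parts <- lapply(seq_along(value_stubs), function(k) {
    out <- data.frame(id = table[[id]],
                      occasion = k,
                      age = as.numeric(table[[age_columns[k]]]),
                      value = as.numeric(table[[value_stubs[k]]]),
                      stringsAsFactors = FALSE)
    names(out)[1] <- id
    cbind(out, table[carry])
  })
  long <- do.call(rbind, parts)
  long <- long[!is.na(long$value) & !is.na(long$age), , drop = FALSE]
  long <- long[order(long[[id]], long$occasion), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Reshape a long panel back to wide format
#'
#' Inverse of [wide_to_long()] up to occasion ordering; pairs absent from
#' the long table come back as `NA`.
#'
#' @param long Long data frame with `id`, `occasion`, `age`, `value` columns.
#' @param id Identifier column name.
#' @param value_prefix,age_prefix Prefixes for the per-occasion columns.
#' @return Wide data frame, one row per individual.
#' @export
long_to_wide <- function(long, id = "id", value_prefix = "value_",
                         age_prefix = "age_") {
  occ <- sort(unique(long$occasion))
  ids <- unique(long[[id]])
  carry <- setdiff(names(long), c(id, "occasion", "age", "value"))
  wide <- data.frame(id = ids, stringsAsFactors = FALSE)
  names(wide)[1] <- id
  for (cv in carry)
    wide[[cv]] <- long[[cv]][match(ids, long[[id]])]
  for (k in occ) {
    sub <- long[long$occasion == k, , drop = FALSE]
    idx <- match(ids, sub[[id]])
    wide[[paste0(age_prefix, k)]] <- sub$age[idx]
    wide[[paste0(value_prefix, k)]] <- sub$value[idx]
  }
  wide
}

#' Fit a multilevel quadratic growth model
#'
#' Linear mixed model of a repeated measure on age centred at `center_age`
#' (default 12 years): fixed intercept, age and age-squared — plus a female
#' main effect and both interactions when `sex_interaction` — with
#' correlated (unstructured) random intercept and random age and
#' age-squared slopes per individual. Estimated by maximum likelihood (not
#' REML) so fits on datasets of different size remain comparable; fixed
#' effects carry Wald standard errors, confidence intervals and p-values.
#'
#' Random-effect (co)variances are reported as point estimates without
#' standard errors: Wald SEs for variance components are unreliable near the
#' boundary and lme4 intentionally does not produce them.
#'
#' @param long Long data frame (see [wide_to_long()]).
#' @param outcome,age,id Column names of the measurement, the age in years,
#'   and the individual identifier.
#' @param center_age Years subtracted from age before fitting (default 12).
#' @param sex_interaction Add female main effect and female-by-age terms.
#' @param sex Column name of the 0/1 female indicator.
#' @param conf_level Confidence level for Wald intervals.
#' @return A `growth_fit`: list with `fixed` (data frame: term, estimate,
#'   se, z, ci_lo, ci_hi, p), `random` (data frame: term, estimate),
#'   `n` individuals, `n_obs` observations, `center_age`, `converged`,
#'   and the underlying `model`.
#' @export
fit_quadratic_growth <- function(long, outcome = "value", age = "age",
                                 id = "id", center_age = 12,
                                 sex_interaction = FALSE, sex = "female",
                                 conf_level = 0.95) {
  need <- c(outcome, age, id, if (sex_interaction) sex)
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols))
    stop("long table lacks column(s): ", paste(missing_cols, collapse = ", "))
  d <- data.frame(.y. = as.numeric(long[[outcome]]),
                  .a. = as.numeric(long[[age]]) - center_age,
                  .id. = long[[id]])
  if (sex_interaction) d$.f. <- as.numeric(long[[sex]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(round(d$.a., 6))) < 3L)
    stop("need at least 3 distinct ages for a quadratic growth model")
  d$.a2. <- d$.a.^2

  form <- if (sex_interaction)
    .y. ~ .a. + .a2. + .f. + .f.:.a. + .f.:.a2. + (.a. + .a2. | .id.)
  else
    .y. ~ .a. + .a2. + (.a. + .a2. | .id.)

  ctl <- lme4::lmerControl(calc.derivs = FALSE,
                           check.conv.singular = "ignore")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = FALSE, control = ctl)))
  converged <- is.null(fit@optinfo$conv$lme4$code)
  if (!converged) {
    # retry from a simpler optimiser configuration
    ctl2 <- lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    fit2 <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(form, data = d, REML = FALSE, control = ctl2))),
      error = function(e) NULL)
    if (!is.null(fit2) && is.null(fit2@optinfo$conv$lme4$code)) {
      fit <- fit2; converged <- TRUE
    }
  }

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  label <- c(`(Intercept)` = "intercept", .a. = "age", .a2. = "age2",
             .f. = "female", `.a.:.f.` = "female_age",
             `.a2.:.f.` = "female_age2")
  fixed <- data.frame(
    term = unname(label[names(est)]),
    estimate = unname(est), se = unname(se), z = unname(z),
    ci_lo = unname(est - zq * se), ci_hi = unname(est + zq * se),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )

  vc <- lme4::VarCorr(fit)
  vm <- vc$.id.
  resid_var <- attr(vc, "sc")^2
  rn <- c("(Intercept)" = "intercept", ".a." = "age", ".a2." = "age2")
  random <- data.frame(
    term = c(paste0("var_", rn[rownames(vm)]),
             "cov_intercept_age", "cov_intercept_age2", "cov_age_age2",
             "var_residual"),
    estimate = c(diag(vm), vm["(Intercept)", ".a."],
                 vm["(Intercept)", ".a2."], vm[".a.", ".a2."], resid_var),
    stringsAsFactors = FALSE
  )
  rownames(random) <- NULL

  structure(
    list(fixed = fixed, random = random,
         n = length(unique(d$.id.)), n_obs = nrow(d),
         center_age = center_age, sex_interaction = sex_interaction,
         conf_level = conf_level, converged = converged, model = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> quadratic growth model (ML), age centred at ",
      x$center_age, "\n  n = ", x$n, " individuals, n_obs = ", x$n_obs,
      if (!x$converged) "  [did not converge]", "\n", sep = "")
  fx <- x$fixed
  fx[-1] <- lapply(fx[-1], function(v) signif(v, 4))
  print.data.frame(fx, row.names = FALSE)
  cat("random effects:\n")
  rd <- x$random; rd$estimate <- signif(rd$estimate, 4)
  print.data.frame(rd, row.names = FALSE)
  invisible(x)
}

#' Predict the population-mean trajectory from a growth fit
#'
#' @param object A `growth_fit`.
#' @param ages Numeric vector of ages (years, uncentred).
#' @param female For sex-interaction fits, 0 or 1.
#' @param ... Unused.
#' @return Numeric vector of predicted mean values at `ages`.
#' @export
predict.growth_fit <- function(object, ages, female = 0, ...) {
  a <- ages - object$center_age
  co <- stats::setNames(object$fixed$estimate, object$fixed$term)
  out <- co["intercept"] + co["age"] * a + co["age2"] * a^2
  if (object$sex_interaction)
    out <- out + female * (co["female"] + co["female_age"] * a +
                             co["female_age2"] * a^2)
  unname(out)
}

#' Compare growth-model estimates from two datasets
#'
#' Lines up the fixed effects (and random-effect estimates) of two
#' [fit_quadratic_growth()] fits — typically observed vs synthetic — and
#' reports differences, the ratio of standard errors, and the symmetrised
#' confidence-interval overlap per fixed effect.
#'
#' @param fit_obs,fit_syn `growth_fit` objects with the same specification.
#' @return A data frame with one row per parameter.
#' @export
compare_growth_estimates <- function(fit_obs, fit_syn) {
  stopifnot(inherits(fit_obs, "growth_fit"), inherits(fit_syn, "growth_fit"))
  if (!identical(fit_obs$fixed$term, fit_syn$fixed$term))
    stop("fits have different parameter sets: {",
         paste(fit_obs$fixed$term, collapse = ", "), "} vs {",
         paste(fit_syn$fixed$term, collapse = ", "), "}")
  fo <- fit_obs$fixed; fs <- fit_syn$fixed
  fixed <- data.frame(
    term = fo$term, type = "fixed",
    estimate_obs = fo$estimate, estimate_syn = fs$estimate,
    difference = fs$estimate - fo$estimate,
    se_ratio = fs$se / fo$se,
    ci_overlap = mapply(function(a, b, c, d) ci_overlap(c(a, b), c(c, d)),
                        fo$ci_lo, fo$ci_hi, fs$ci_lo, fs$ci_hi),
    stringsAsFactors = FALSE
  )
  ro <- fit_obs$random; rs <- fit_syn$random
  random <- data.frame(
    term = ro$term, type = "random",
    estimate_obs = ro$estimate, estimate_syn = rs$estimate,
    difference = rs$estimate - ro$estimate,
    se_ratio = NA_real_, ci_overlap = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(fixed, random)
}
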