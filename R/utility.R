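## Utility validation: do the synthetic data reproduce the observed
## marginals and the observed model coefficients?

#' Compare marginal distributions of observed and synthetic tables
#'
#' Tallies every variable on shared category definitions computed from the
#' observed table: categorical variables on their observed level set (NA as
#' its own category, synthetic-only categories reported with observed count
#' 0 — a synthesis bug signal), continuous variables binned on
#' observed-data quartile breaks extended to cover any synthetic value.
#'
#' @param observed Data frame of observed data.
#' @param synthetic Data frame or `synthetic_release`.
#' @param bins Number of quantile bins for continuous variables (default 4).
#' @return A `marginal_comparison`: data frame with columns `variable`,
#'   `category`, `observed_n`, `synthetic_n`, `diff` (synthetic − observed
#'   count) and `pct_diff` (difference in within-table percentage shares).
#' @export
compare_marginals <- function(observed, synthetic, bins = 4L) {
  synthetic <- as_plain_table(synthetic)
  observed <- as_plain_table(observed)
  if (!setequal(names(observed), names(synthetic)))
    stop("observed and synthetic tables must share a column set")
  synthetic <- synthetic[names(observed)]

  res <- lapply(names(observed), function(nm) {
    o <- observed[[nm]]; s <- synthetic[[nm]]
    if (is.numeric(o)) {
      br <- unique(stats::quantile(o, probs = seq(0, 1, length.out = bins + 1L),
                                   na.rm = TRUE))
      if (length(br) < 3L) {
        oc <- factor(o); sc <- factor(s, levels = levels(oc))
        cats <- sort(unique(c(levels(oc), as.character(unique(s[!is.na(s)])))))
        oc <- factor(as.character(o), levels = cats)
        sc <- factor(as.character(s), levels = cats)
      } else {
        br[1L] <- -Inf; br[length(br)] <- Inf
        oc <- cut(o, br); sc <- cut(s, br)
        cats <- levels(oc)
      }
    } else {
      o <- as.character(o); s <- as.character(s)
      cats <- unique(c(if (is.factor(observed[[nm]]))
        levels(observed[[nm]]) else sort(unique(o[!is.na(o)])),
        sort(unique(s[!is.na(s)]))))
      oc <- factor(o, levels = cats)
      sc <- factor(s, levels = cats)
    }
    lev <- c(levels(oc), "NA")
    on <- c(table(oc), `NA` = sum(is.na(oc)))
    sn <- c(table(sc), `NA` = sum(is.na(sc)))
    data.frame(variable = nm, category = lev,
               observed_n = as.integer(on), synthetic_n = as.integer(sn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$diff <- out$synthetic_n - out$observed_n
  n_obs <- nrow(observed); n_syn <- nrow(synthetic)
  out$pct_diff <- 100 * (out$synthetic_n / n_syn - out$observed_n / n_obs)
  structure(out, n_observed = n_obs, n_synthetic = n_syn,
            class = c("marginal_comparison", "data.frame"))
}

#' @export
print.marginal_comparison <- function(x, ...) {
  cat("<marginal_comparison> ", length(unique(x$variable)), " variables, ",
      attr(x, "n_observed"), " observed vs ", attr(x, "n_synthetic"),
      " synthetic rows\n", sep = "")
  cat("  max |percentage-point difference| per cell: ",
      sprintf("%.2f", max(abs(x$pct_diff))), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("  ... ", nrow(x) - 12, " more rows\n", sep = "")
  invisible(x)
}

#' Symmetrised confidence-interval overlap
#'
#' The shared length of two intervals as a fraction of each interval's own
#' width, averaged: 1 for identical intervals, 0 for disjoint ones. Two
#' zero-width intervals overlap fully iff they are the same point; a
#' zero-width interval against a proper interval scores 1 on its own side
#' iff the point lies inside the other interval.
#'
#' @param interval_obs,interval_syn Numeric length-2 vectors `c(lower,
#'   upper)` with `lower <= upper`.
#' @return A fraction in \[0, 1\].
#' @export
ci_overlap <- function(interval_obs, interval_syn) {
  stopifnot(length(interval_obs) == 2L, length(interval_syn) == 2L)
  if (anyNA(interval_obs) || anyNA(interval_syn)) return(NA_real_)
  stopifnot(interval_obs[1] <= interval_obs[2],
            interval_syn[1] <= interval_syn[2])
  ov <- max(0, min(interval_obs[2], interval_syn[2]) -
              max(interval_obs[1], interval_syn[1]))
  w1 <- diff(interval_obs); w2 <- diff(interval_syn)
  inside <- max(interval_obs[1], interval_syn[1]) <=
    min(interval_obs[2], interval_syn[2])
  f1 <- if (w1 == 0) as.numeric(inside) else ov / w1
  f2 <- if (w2 == 0) as.numeric(inside) else ov / w2
  mean(c(f1, f2))
}

#' Fit the same GLM to observed and synthetic data and compare
#'
#' Fits an identical model specification separately to the complete cases of
#' the observed and the synthetic table and reports, per coefficient, both
#' estimates with standard errors, z-values (estimate/SE — a common scale
#' across coefficients), Wald 95% confidence intervals and their symmetrised
#' overlap. A fit that fails to converge marks its entries unavailable (NA)
#' rather than dropping them.
#'
#' @param formula Model formula, e.g. `outcome ~ exposure + covariates`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param observed Data frame of observed data.
#' @param synthetic Data frame or `synthetic_release`.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return A `model_comparison`: data frame with one row per coefficient.
#' @export
fit_glm_both <- function(formula, family = c("gaussian", "binomial"),
                         observed, synthetic, conf_level = 0.95) {
  family <- match.arg(family)
  synthetic <- as_plain_table(synthetic)
  observed <- as_plain_table(observed)
  vars <- all.vars(formula)
  missing_o <- setdiff(vars, names(observed))
  missing_s <- setdiff(vars, names(synthetic))
  if (length(missing_o) || length(missing_s))
    stop("formula variables absent: observed {",
         paste(missing_o, collapse = ", "), "}, synthetic {",
         paste(missing_s, collapse = ", "), "}")

  fit_one <- function(dat) {
    dat <- dat[stats::complete.cases(dat[vars]), vars, drop = FALSE]
    fit <- tryCatch(
      stats::glm(formula, data = dat,
                 family = if (family == "binomial") stats::binomial()
                 else stats::gaussian()),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    k <- length(stats::coef(fit))
    if (nrow(dat) < 10L * k)
      warning("fewer than 10 complete cases per fitted parameter (",
              nrow(dat), " rows, ", k, " parameters)", call. = FALSE)
    if (family == "binomial" && !fit$converged) return(NULL)
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               stringsAsFactors = FALSE)
  }

  co <- fit_one(observed)
  cs <- fit_one(synthetic)
  if (is.null(co) && is.null(cs))
    stop("model did not converge on either table")
  terms <- if (!is.null(co)) co$term else cs$term
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  grab <- function(tab, terms) {
    if (is.null(tab))
      return(data.frame(estimate = rep(NA_real_, length(terms)),
                        se = NA_real_))
    tab[match(terms, tab$term), c("estimate", "se")]
  }
  o <- grab(co, terms); s <- grab(cs, terms)
  out <- data.frame(
    term = terms,
    estimate_obs = o$estimate, se_obs = o$se, z_obs = o$estimate / o$se,
    ci_lo_obs = o$estimate - zq * o$se, ci_hi_obs = o$estimate + zq * o$se,
    estimate_syn = s$estimate, se_syn = s$se, z_syn = s$estimate / s$se,
    ci_lo_syn = s$estimate - zq * s$se, ci_hi_syn = s$estimate + zq * s$se,
    stringsAsFactors = FALSE
  )
  out$ci_overlap <- mapply(function(a, b, c, d)
    ci_overlap(c(a, b), c(c, d)),
    out$ci_lo_obs, out$ci_hi_obs, out$ci_lo_syn, out$ci_hi_syn)
  structure(out, family = family, formula = deparse(formula),
            class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ", attr(x, "family"), " fit: ",
      attr(x, "formula"), "\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print.data.frame(df[c("term", "estimate_obs", "z_obs",
                        "estimate_syn", "z_syn", "ci_overlap")])
  invisible(x)
}
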