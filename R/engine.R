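## Sequential conditional synthesis engine.
##
## Column i of the synthetic table is generated from a model of the observed
## target given its observed predictors, evaluated at the already-synthesised
## predictor rows. The first visited variable is marginal resampling; later
## variables use CART leaf donor sampling (default) or parametric draws.
## Each column consumes its own RNG stream derived from (plan seed, column
## position) so that editing downstream columns of a plan leaves upstream
## columns bit-identical.

derive_stream_seed <- function(seed, index) {
  # deterministic per-column substream; kept below 2^31 - 1
  as.integer((as.double(seed) * 48271 + as.double(index) * 100003) %% 2147483629)
}

with_stream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_stream_seed(seed, index))
  expr
}

#' Marginal resampling of a column
#'
#' Draws `m` values uniformly with replacement from the observed column,
#' missing markers included, so the synthetic marginal (including the NA
#' share) is an iid resample of the observed one.
#'
#' @param observed_column Vector (numeric or factor/character), possibly with
#'   `NA`.
#' @param m Number of synthetic values to draw; must be positive.
#' @param seed Integer seed for this draw.
#' @return A vector of length `m` of the same type as the input.
#' @export
sample_marginal <- function(observed_column, m, seed = 1L) {
  if (length(observed_column) == 0L) stop("observed column is empty")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    stop("m must be a positive count")
  with_stream(seed, 0L,
    observed_column[sample.int(length(observed_column), m, replace = TRUE)])
}

## --- predictor design -----------------------------------------------------

## Continuous predictors containing NA are split into (mean-filled value,
## missingness indicator factor) so both tree and parametric fits stay
## well-defined while the missingness pattern remains informative.
## Categorical predictors carry NA as an explicit level. Fill values and
## level sets come from the observed data and are reused verbatim for the
## synthetic rows, so train and predict designs always align.
build_design_spec <- function(predictors_obs, schema) {
  spec <- list()
  for (nm in names(predictors_obs)) {
    col <- predictors_obs[[nm]]
    if (is.factor(col) || is.character(col)) {
      lev <- if (is.factor(col)) levels(col) else sort(unique(col[!is.na(col)]))
      spec[[nm]] <- list(type = "cat", levels = lev, has_na = anyNA(col))
    } else {
      fill <- mean(col, na.rm = TRUE)
      if (!is.finite(fill)) fill <- 0
      spec[[nm]] <- list(type = "num", fill = fill, has_na = anyNA(col))
    }
  }
  spec
}

apply_design_spec <- function(data, spec) {
  out <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    col <- data[[nm]]
    if (s$type == "cat") {
      f <- factor(as.character(col), levels = s$levels)
      if (s$has_na) {
        f <- addNA(f, ifany = FALSE)
        levels(f)[is.na(levels(f))] <- ".NA."
        f[is.na(f)] <- ".NA."
      } else {
        # unseen level or unexpected NA routed to the modal level
        if (anyNA(f) && length(s$levels)) f[is.na(f)] <- s$levels[1L]
      }
      out[[nm]] <- f
    } else {
      x <- as.numeric(col)
      if (s$has_na) {
        ind <- factor(ifelse(is.na(x), "miss", "obs"), levels = c("obs", "miss"))
        x[is.na(x)] <- s$fill
        out[[nm]] <- x
        out[[paste0(nm, "._miss")]] <- ind
      } else {
        x[is.na(x)] <- s$fill
        out[[nm]] <- x
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
}

## --- CART -----------------------------------------------------------------

#' Fit a CART column model with leaf donor sets
#'
#' Fits a classification or regression tree of the target on the predictors
#' and records, for every leaf, the observed target values ("donors") that
#' fell into it. Synthetic values are later drawn uniformly from the donor
#' set of the leaf a synthetic row is routed to, so the synthetic conditional
#' distribution is the empirical conditional distribution at the leaf.
#'
#' @param target Observed target column (numeric or factor).
#' @param predictors_obs Data frame of observed predictor columns.
#' @param controls List with `minbucket` and `cp` (see [synthesis_plan()]).
#' @return An object of class `cart_column_fit` with elements `tree` (the
#'   rpart fit), `leaf` (integer node id per observed row), `donors` (named
#'   list of donor vectors per leaf) and `design_spec`.
#' @export
fit_cart_column <- function(target, predictors_obs,
                            controls = list(minbucket = 5, cp = 1e-8)) {
  stopifnot(nrow(predictors_obs) == length(target))
  spec <- build_design_spec(predictors_obs, NULL)
  X <- apply_design_spec(predictors_obs, spec)
  df <- cbind(.y. = target, X)
  method <- if (is.factor(target)) "class" else "anova"
  ctl <- rpart::rpart.control(
    minbucket = controls$minbucket %||% 5,
    minsplit = max(2L, 2L * (controls$minbucket %||% 5)),
    cp = controls$cp %||% 1e-8,
    maxdepth = controls$maxdepth %||% 30,
    xval = 0
  )
  tree <- rpart::rpart(.y. ~ ., data = df, method = method, control = ctl)
  leaf <- as.integer(row.names(tree$frame))[tree$where]
  donors <- split(target, leaf)
  stopifnot(all(lengths(donors) > 0L))
  structure(list(tree = tree, leaf = leaf, donors = donors,
                 design_spec = spec, method = method),
            class = "cart_column_fit")
}

## Route new rows to leaves. rpart's predict() does not expose node ids, so
## the standard device is to overwrite each node's fitted value with its own
## node number and predict "vector". Surrogate/default-branch routing is
## inherited from rpart, so out-of-range synthetic predictor values never
## error.
route_to_leaf <- function(fit, newdata) {
  stopifnot(fit$method == "anova")
  X <- apply_design_spec(newdata, fit$design_spec)
  tr <- fit$tree
  tr$frame$yval <- as.numeric(row.names(tr$frame))
  as.integer(predict(tr, newdata = X, type = "vector"))
}

#' Synthesise one column by CART donor sampling
#'
#' @param target Observed target column.
#' @param predictors_obs Data frame of observed predictor columns (same
#'   length as `target`).
#' @param predictors_syn Data frame of already-synthesised predictor rows;
#'   columns must match `predictors_obs` by name and kind.
#' @param controls CART controls (`minbucket`, `cp`).
#' @param seed Integer seed for the donor draws.
#' @return Synthetic column of length `nrow(predictors_syn)`; values are a
#'   subset of the observed target values.
#' @export
cart_synthesize_column <- function(target, predictors_obs, predictors_syn,
                                   controls = list(minbucket = 5, cp = 1e-8),
                                   seed = 1L) {
  stopifnot(nrow(predictors_obs) == length(target))
  if (!setequal(names(predictors_obs), names(predictors_syn)))
    stop("synthetic predictors do not match observed predictors by name")
  predictors_syn <- predictors_syn[names(predictors_obs)]
  m <- nrow(predictors_syn)
  if (ncol(predictors_obs) == 0L ||
      length(unique(target[!is.na(target)])) < 2L)
    return(sample_marginal(target, m, seed))
  fit <- fit_cart_column(target, predictors_obs, controls)

  if (fit$method == "class") {
    ## leaf routing via predicted class probabilities: with default priors a
    ## leaf's probability vector is its class proportions, so drawing the
    ## class from it is exactly a uniform donor draw within the leaf
    X <- apply_design_spec(predictors_syn, fit$design_spec)
    p <- predict(fit$tree, newdata = X, type = "prob")
    return(with_stream(seed, 0L, {
      idx <- vapply(seq_len(m), function(i)
        sample.int(ncol(p), 1L, prob = p[i, ]), integer(1))
      factor(colnames(p)[idx], levels = levels(target),
             ordered = is.ordered(target))
    }))
  }

  leaves <- route_to_leaf(fit, predictors_syn)
  with_stream(seed, 0L, {
    res <- rep(NA_real_, m)
    for (i in seq_len(m)) {
      d <- fit$donors[[as.character(leaves[i])]]
      j <- if (length(d) == 1L) 1L else sample.int(length(d), 1L)
      res[i] <- d[j]
    }
    res
  })
}

## --- parametric methods ---------------------------------------------------

#' Synthesise one column by a parametric model
#'
#' Fits the named family on the observed data and draws synthetic values at
#' the synthetic predictor rows: `norm` draws linear predictor + Gaussian
#' residual noise, `logit`/`polytomous` draw the class from the per-row
#' predicted probabilities. A singular or separated fit falls back to
#' marginal donor sampling for the column, with a warning.
#'
#' @inheritParams cart_synthesize_column
#' @param family One of `"norm"` (continuous), `"logit"` (binary),
#'   `"polytomous"` (nominal/ordinal).
#' @return Synthetic column of length `nrow(predictors_syn)`.
#' @export
parametric_synthesize_column <- function(target, predictors_obs, predictors_syn,
                                         family = c("norm", "logit", "polytomous"),
                                         seed = 1L) {
  family <- match.arg(family)
  stopifnot(nrow(predictors_obs) == length(target))
  if (family == "norm" && !is.numeric(target))
    stop("family 'norm' requires a continuous target")
  if (family == "logit" && !(is.factor(target) && nlevels(target) == 2L))
    stop("family 'logit' requires a binary (2-level factor) target")
  if (family == "polytomous" && !is.factor(target))
    stop("family 'polytomous' requires a categorical target")
  predictors_syn <- predictors_syn[names(predictors_obs)]
  spec <- build_design_spec(predictors_obs, NULL)
  Xo <- apply_design_spec(predictors_obs, spec)
  Xs <- apply_design_spec(predictors_syn, spec)
  m <- nrow(Xs)

  fallback <- function(msg) {
    warning("parametric fit failed for column (", msg,
            "); falling back to marginal donor sampling", call. = FALSE)
    sample_marginal(target, m, seed)
  }

  tryCatch({
    if (family == "norm") {
      fit <- stats::lm(.y. ~ ., data = cbind(.y. = target, Xo))
      sigma <- sqrt(sum(stats::residuals(fit)^2) /
                      max(1L, stats::df.residual(fit)))
      mu <- unname(suppressWarnings(stats::predict(fit, newdata = Xs)))
      with_stream(seed, 0L, mu + stats::rnorm(m, 0, sigma))
    } else if (family == "logit") {
      fit <- suppressWarnings(
        stats::glm(.y. ~ ., data = cbind(.y. = target, Xo),
                   family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, newdata = Xs, type = "response"))
      if (anyNA(p)) stop("NA predicted probabilities")
      with_stream(seed, 0L,
        factor(levels(target)[1L + stats::rbinom(m, 1L, p)],
               levels = levels(target), ordered = is.ordered(target)))
    } else {
      fit <- suppressWarnings(
        nnet::multinom(.y. ~ ., data = cbind(.y. = target, Xo),
                       trace = FALSE, maxit = 200))
      p <- stats::predict(fit, newdata = Xs, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)  # 2-level degenerate case
      colnames(p) <- levels(droplevels(target))[seq_len(ncol(p))]
      if (anyNA(p)) stop("NA predicted probabilities")
      with_stream(seed, 0L, {
        idx <- vapply(seq_len(m), function(i)
          sample.int(ncol(p), 1L, prob = p[i, ]), integer(1))
        factor(colnames(p)[idx], levels = levels(target),
               ordered = is.ordered(target))
      })
    }
  }, error = function(e) fallback(conditionMessage(e)))
}

## --- smoothing and rules --------------------------------------------------

#' Gaussian-kernel smoothing of a synthetic continuous column
#'
#' Jitters each non-missing value with Gaussian noise whose standard
#' deviation is the normal-reference bandwidth of the column (Silverman's
#' rule via [stats::bw.nrd0()]) unless an explicit bandwidth is given, then
#' clips to the observed range. Smoothing breaks exact value matches with
#' the observed data, lowering disclosure risk for continuous variables.
#'
#' @param column Numeric vector (synthetic values, `NA` allowed).
#' @param bandwidth Kernel standard deviation; `NULL` (default) uses
#'   `bw.nrd0` on the non-missing values. `0` is the identity.
#' @param clip_range Length-2 numeric: values are clipped into this interval
#'   (normally the observed column's range).
#' @param seed Integer seed.
#' @return Numeric vector of the same length; `NA`s untouched.
#' @export
apply_smoothing <- function(column, bandwidth = NULL,
                            clip_range = range(column, na.rm = TRUE),
                            seed = 1L) {
  if (!is.numeric(column)) stop("smoothing applies to continuous columns only")
  ok <- !is.na(column)
  vals <- column[ok]
  if (length(unique(vals)) < 2L) {
    warning("constant column: smoothing skipped", call. = FALSE)
    return(column)
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(vals)
  if (bandwidth == 0) return(column)
  out <- column
  with_stream(seed, 0L, {
    out[ok] <- vals + stats::rnorm(length(vals), 0, bandwidth)
  })
  out[ok] <- pmin(pmax(out[ok], clip_range[1L]), clip_range[2L])
  out
}

#' Apply deterministic rules to a table
#'
#' Each rule forces `target` to `value` on the rows where the predicate
#' `when` (an R expression over earlier-synthesised variables, given as a
#' string) evaluates to `TRUE`. Rows where the predicate is `NA` (e.g. it
#' references a missing value) are left untouched: missing matches no level.
#'
#' @param table A data frame.
#' @param rules List of `list(when =, target =, value =)` rules, applied in
#'   order.
#' @return The table with rules applied.
#' @export
apply_rules <- function(table, rules) {
  for (r in rules) {
    hit <- eval(str2lang(r$when), envir = table, enclos = baseenv())
    hit <- !is.na(hit) & hit
    if (any(hit)) {
      col <- table[[r$target]]
      if (is.factor(col)) {
        val <- as.character(r$value)
        if (!is.na(val) && !(val %in% levels(col)))
          levels(col) <- c(levels(col), val)
        col[hit] <- val
        table[[r$target]] <- col
      } else {
        table[[r$target]][hit] <- r$value
      }
    }
  }
  table
}

## --- the sequential driver ------------------------------------------------

#' Sequentially synthesise a table
#'
#' Runs the full engine: validates the plan, visits each variable in order,
#' synthesises it conditional on the already-synthesised predictors, then
#' applies rules and smoothing, and wraps the result with provenance as a
#' [synthetic_release] (pre-disclosure-control).
#'
#' Missing data are propagated: categorical targets carry `NA` as an
#' explicit level of the column model, so the missingness pattern is
#' synthesised jointly with the values; continuous targets are synthesised
#' in two stages (a missingness indicator by the column's method, then
#' values modelled on the observed non-missing rows), keeping relations
#' between missingness and other variables.
#'
#' @param observed Data frame of observed data.
#' @param plan A [synthesis_plan()]; defaults to the all-CART default plan
#'   over the inferred schema.
#' @param seed Optional integer overriding the plan's seed.
#' @return A `synthetic_release` object (see [new_synthetic_release()]).
#' @examples
#' obs <- data.frame(age = rnorm(200, 50, 8),
#'                   sex = factor(sample(c("F", "M"), 200, TRUE)))
#' rel <- synthesize(obs, seed = 42)
#' release_table(rel)[1:3, ]
#' @export
synthesize <- function(observed, plan = NULL, seed = NULL) {
  stopifnot(is.data.frame(observed), nrow(observed) >= 1L)
  schema <- table_schema(observed)
  if (is.null(plan)) plan <- synthesis_plan(schema)
  if (!is.null(seed)) plan$seed <- as.integer(seed)
  viol <- validate_plan(plan, schema)
  if (length(viol))
    stop("invalid synthesis plan:\n  ", paste(viol, collapse = "\n  "))

  observed <- conform_to_schema(observed, schema)
  n <- nrow(observed)
  syn <- as.data.frame(lapply(observed, function(col) col[rep(NA_integer_, n)]),
                       optional = TRUE)
  names(syn) <- names(observed)
  trace <- list()

  for (i in seq_along(plan$visit_sequence)) {
    var <- plan$visit_sequence[i]
    kind <- schema[[var]]$kind
    method <- plan$method[[var]]
    preds <- colnames(plan$predictor_matrix)[plan$predictor_matrix[var, ]]
    preds <- intersect(plan$visit_sequence[seq_len(i - 1L)], preds)
    trace[[var]] <- preds
    col_seed <- derive_stream_seed(plan$seed, i)

    res <- tryCatch(
      synthesize_one_column(observed, syn, var, kind, method, preds,
                            plan$cart_controls, col_seed),
      error = function(e)
        stop("synthesis failed for column '", var, "': ",
             conditionMessage(e), call. = FALSE)
    )
    syn[[var]] <- res
  }

  if (length(plan$rules)) syn <- apply_rules(syn, plan$rules)

  for (sv in plan$smoothing) {
    if (!is.numeric(syn[[sv]])) next
    syn[[sv]] <- apply_smoothing(
      syn[[sv]],
      clip_range = range(observed[[sv]], na.rm = TRUE),
      seed = derive_stream_seed(plan$seed, ncol(observed) + match(sv, names(syn)))
    )
  }
  # re-assert rules so forced exact values (e.g. a hard 0) survive smoothing
  if (length(plan$rules) && length(plan$smoothing))
    syn <- apply_rules(syn, plan$rules)

  new_synthetic_release(
    table = syn,
    provenance = list(
      seed = plan$seed,
      plan_digest = plan_digest(plan),
      n_observed = n,
      n_before_sdc = n,
      n_removed = 0L,
      sdc_applied = FALSE,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      trace = trace
    )
  )
}

## One column of the sequential pass. `obs_target` models are always fitted
## on observed (target, predictors) and evaluated at the synthetic predictor
## rows.
synthesize_one_column <- function(observed, syn, var, kind, method, preds,
                                  controls, col_seed) {
  n <- nrow(observed)
  obs_y <- observed[[var]]
  if (method == "sample" || length(preds) == 0L)
    return(sample_marginal(obs_y, n, col_seed))

  px_obs <- observed[preds]
  px_syn <- syn[preds]

  if (is_categorical_kind(kind)) {
    y <- obs_y
    has_na <- anyNA(y)
    if (has_na) {
      y <- addNA(y, ifany = FALSE)
      levels(y)[is.na(levels(y))] <- ".NA."
      y[is.na(y)] <- ".NA."
    }
    out <- switch(method,
      cart = cart_synthesize_column(y, px_obs, px_syn, controls, col_seed),
      logit = parametric_synthesize_column(y, px_obs, px_syn,
                                           if (nlevels(droplevels(y)) > 2L)
                                             "polytomous" else "logit",
                                           col_seed),
      polytomous = parametric_synthesize_column(y, px_obs, px_syn,
                                                "polytomous", col_seed),
      stop("method '", method, "' not valid for categorical target"))
    out <- factor(as.character(out), levels = levels(y))
    if (has_na) {
      res <- factor(ifelse(out == ".NA.", NA, as.character(out)),
                    levels = setdiff(levels(y), ".NA."),
                    ordered = is.ordered(obs_y))
    } else {
      res <- factor(as.character(out), levels = levels(obs_y),
                    ordered = is.ordered(obs_y))
    }
    return(res)
  }

  ## continuous: two-stage when the observed column has missing values
  if (anyNA(obs_y)) {
    ind_obs <- factor(ifelse(is.na(obs_y), "miss", "obs"),
                      levels = c("obs", "miss"))
    ind_syn <- switch(method,
      cart = cart_synthesize_column(ind_obs, px_obs, px_syn, controls,
                                    derive_stream_seed(col_seed, 1L)),
      norm = parametric_synthesize_column(ind_obs, px_obs, px_syn, "logit",
                                          derive_stream_seed(col_seed, 1L)),
      stop("method '", method, "' not valid for continuous target"))
    keep <- !is.na(obs_y)
    fill <- ind_syn == "obs"
    vals <- rep(NA_real_, n)
    if (any(fill)) {
      vals[fill] <- synthesize_continuous_values(
        obs_y[keep], px_obs[keep, , drop = FALSE],
        px_syn[fill, , drop = FALSE], method, controls,
        derive_stream_seed(col_seed, 2L))
    }
    return(vals)
  }
  synthesize_continuous_values(obs_y, px_obs, px_syn, method, controls,
                               col_seed)
}

synthesize_continuous_values <- function(y, px_obs, px_syn, method, controls,
                                         seed) {
  if (nrow(px_syn) == 0L) return(numeric(0))
  switch(method,
    cart = cart_synthesize_column(y, px_obs, px_syn, controls, seed),
    norm = parametric_synthesize_column(y, px_obs, px_syn, "norm", seed),
    stop("method '", method, "' not valid for continuous target"))
}
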