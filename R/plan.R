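#' Build a synthesis plan
#'
#' The plan is the declarative contract the synthesis engine executes: the
#' order in which variables are visited, the per-variable method, which
#' earlier variables predict each target, which continuous variables are
#' smoothed after synthesis, deterministic rules, the seed, and the CART
#' fitting controls.
#'
#' Defaults mirror common practice for sequential synthesis: the visit
#' sequence is the column order of the schema, the first variable is drawn by
#' marginal resampling (`sample`) and every later variable by CART
#' conditional on all earlier variables. Synthesising the analysis exposure
#' and outcome last can preserve their relations more faithfully; use
#' `outcome_last` to move named variables to the end of the default sequence.
#'
#' @param schema A [table_schema()] (or a data frame, from which one is
#'   inferred).
#' @param visit_sequence Character vector: a permutation of the schema's
#'   variable names. Defaults to schema order (after `outcome_last` is
#'   applied).
#' @param method Named character vector mapping variables to one of
#'   `"sample"`, `"cart"`, `"norm"`, `"logit"`, `"polytomous"`. Unnamed
#'   scalar recycles to all non-first variables. The first visited variable
#'   always uses `"sample"`.
#' @param predictor_matrix Logical matrix (targets in rows, predictors in
#'   columns, dimnames = variable names). `TRUE` marks a predictor. Defaults
#'   to "all strictly earlier variables".
#' @param smoothing Character vector of continuous variables to jitter with a
#'   Gaussian kernel after synthesis.
#' @param rules List of rules, each `list(when = <predicate string over
#'   earlier variables>, target = <variable>, value = <forced value>)`.
#' @param seed Integer seed; every column draws from its own stream derived
#'   from `(seed, column position)`.
#' @param cart_controls List with `minbucket` (minimum leaf size, default 5)
#'   and `cp` (complexity threshold, default 1e-8).
#' @param outcome_last Character vector of variables (typically exposure and
#'   outcome) moved, in the given order, to the end of the default visit
#'   sequence. Ignored when `visit_sequence` is supplied explicitly.
#'
#' @return An object of class `synthesis_plan`.
#' @seealso [validate_plan()], [synthesize()]
#' @export
synthesis_plan <- function(schema,
                           visit_sequence = NULL,
                           method = NULL,
                           predictor_matrix = NULL,
                           smoothing = character(),
                           rules = list(),
                           seed = 1L,
                           cart_controls = list(minbucket = 5, cp = 1e-8),
                           outcome_last = NULL) {
  if (is.data.frame(schema)) schema <- table_schema(schema)
  vars <- names(schema)
  if (is.null(visit_sequence)) {
    visit_sequence <- vars
    if (!is.null(outcome_last)) {
      visit_sequence <- c(setdiff(vars, outcome_last),
                          intersect(outcome_last, vars))
    }
  }
  visit_sequence <- as.character(visit_sequence)

  if (is.null(method)) method <- "cart"
  if (length(method) == 1L && is.null(names(method)))
    method <- stats::setNames(rep(method, length(vars)), vars)
  full <- stats::setNames(rep("cart", length(vars)), vars)
  full[names(method)[names(method) %in% vars]] <-
    method[names(method) %in% vars]
  if (length(visit_sequence) && visit_sequence[1L] %in% vars)
    full[visit_sequence[1L]] <- "sample"
  method <- full

  if (is.null(predictor_matrix)) {
    predictor_matrix <- default_predictor_matrix(vars, visit_sequence)
  }

  cc <- list(minbucket = 5, cp = 1e-8)
  cc[names(cart_controls)] <- cart_controls

  structure(
    list(schema = schema,
         visit_sequence = visit_sequence,
         method = method,
         predictor_matrix = predictor_matrix,
         smoothing = as.character(smoothing),
         rules = rules,
         seed = as.integer(seed),
         cart_controls = cc),
    class = "synthesis_plan"
  )
}

default_predictor_matrix <- function(vars, visit_sequence) {
  pm <- matrix(FALSE, length(vars), length(vars),
               dimnames = list(vars, vars))
  pos <- match(vars, visit_sequence)
  for (tg in vars) for (pr in vars) {
    if (!is.na(pos[match(tg, vars)]) && !is.na(pos[match(pr, vars)]) &&
        pos[match(pr, vars)] < pos[match(tg, vars)]) {
      pm[tg, pr] <- TRUE
    }
  }
  pm
}

#' @export
print.synthesis_plan <- function(x, ...) {
  cat("<synthesis_plan> ", length(x$visit_sequence), " variables, seed ",
      x$seed, "\n", sep = "")
  cat("  visit order: ", paste(x$visit_sequence, collapse = " -> "), "\n",
      sep = "")
  shown <- x$method[x$visit_sequence]
  cat("  methods:     ", paste(unique(shown), collapse = ", "), "\n", sep = "")
  if (length(x$smoothing))
    cat("  smoothing:   ", paste(x$smoothing, collapse = ", "), "\n", sep = "")
  if (length(x$rules))
    cat("  rules:       ", length(x$rules), "\n", sep = "")
  invisible(x)
}

#' Validate a synthesis plan against a table schema
#'
#' Checks every structural invariant the engine relies on and returns the
#' violations as a character vector (empty when the plan is valid). Unknown
#' variable names yield named violations rather than errors, so a plan read
#' from a config file can be diagnosed in full.
#'
#' Checked invariants:
#' * the visit sequence is a permutation of the schema's variable names;
#' * the predictor matrix only marks predictors strictly earlier in the
#'   visit sequence (lower-triangular under the visit order);
#' * the first visited variable uses method `sample`;
#' * every method is legal for the variable's kind;
#' * every rule's predicate references only variables earlier in the visit
#'   sequence than its target.
#'
#' Rule chaining (a rule's target feeding a later rule's predicate) is legal
#' but surfaced as a note in the `"notes"` attribute of the result.
#'
#' @param plan A [synthesis_plan()].
#' @param schema A [table_schema()]; defaults to the plan's own schema.
#' @return Character vector of violations (length zero iff the plan is
#'   valid), with attribute `"notes"` carrying non-fatal observations.
#' @export
validate_plan <- function(plan, schema = plan$schema) {
  stopifnot(inherits(plan, "synthesis_plan"))
  if (is.data.frame(schema)) schema <- table_schema(schema)
  vars <- names(schema)
  v <- character()
  notes <- character()

  vs <- plan$visit_sequence
  unknown <- setdiff(vs, vars)
  if (length(unknown))
    v <- c(v, paste0("visit_sequence: unknown variable(s) ",
                     paste(unknown, collapse = ", ")))
  missing_vars <- setdiff(vars, vs)
  if (length(missing_vars))
    v <- c(v, paste0("visit_sequence: schema variable(s) not visited: ",
                     paste(missing_vars, collapse = ", ")))
  if (anyDuplicated(vs))
    v <- c(v, paste0("visit_sequence: duplicated variable(s) ",
                     paste(unique(vs[duplicated(vs)]), collapse = ", ")))

  pos <- stats::setNames(match(vs, vs), vs)  # position in visit order

  pm <- plan$predictor_matrix
  if (!is.matrix(pm) || is.null(dimnames(pm))) {
    v <- c(v, "predictor_matrix: must be a named logical matrix")
  } else {
    for (tg in intersect(rownames(pm), vs)) {
      preds <- colnames(pm)[which(pm[tg, ])]
      bad <- preds[!(preds %in% vs) | match(preds, vs) >= match(tg, vs)]
      bad <- bad[!is.na(bad)]
      if (length(bad))
        v <- c(v, paste0("predictor_matrix: non-lower-triangular - '", tg,
                         "' uses predictor(s) not strictly earlier: ",
                         paste(bad, collapse = ", ")))
    }
    pm_unknown <- setdiff(rownames(pm), vars)
    if (length(pm_unknown))
      v <- c(v, paste0("predictor_matrix: unknown variable(s) ",
                       paste(pm_unknown, collapse = ", ")))
  }

  if (length(vs)) {
    first <- vs[1L]
    if (!identical(unname(plan$method[first]), "sample"))
      v <- c(v, paste0("method: first visited variable '", first,
                       "' must use method 'sample'"))
  }

  legal <- list(continuous = c("sample", "cart", "norm"),
                binary     = c("sample", "cart", "logit", "polytomous"),
                nominal    = c("sample", "cart", "polytomous"),
                ordinal    = c("sample", "cart", "polytomous"))
  for (nm in intersect(names(plan$method), vars)) {
    kind <- schema[[nm]]$kind
    if (!(plan$method[[nm]] %in% legal[[kind]]))
      v <- c(v, paste0("method: '", plan$method[[nm]], "' is not valid for ",
                       kind, " variable '", nm, "'"))
  }
  m_unknown <- setdiff(names(plan$method), vars)
  if (length(m_unknown))
    v <- c(v, paste0("method: unknown variable(s) ",
                     paste(m_unknown, collapse = ", ")))

  forced <- character()  # rule targets seen so far, for chain detection
  for (i in seq_along(plan$rules)) {
    r <- plan$rules[[i]]
    if (!is.list(r) || is.null(r$when) || is.null(r$target)) {
      v <- c(v, paste0("rule ", i, ": must have 'when', 'target' and 'value'"))
      next
    }
    if (!(r$target %in% vars)) {
      v <- c(v, paste0("rule ", i, ": unknown target '", r$target, "'"))
      next
    }
    pred_vars <- tryCatch(all.vars(str2lang(r$when)), error = function(e) NULL)
    if (is.null(pred_vars)) {
      v <- c(v, paste0("rule ", i, ": unparseable predicate '", r$when, "'"))
      next
    }
    pred_vars <- intersect(pred_vars, vars)
    late <- pred_vars[is.na(match(pred_vars, vs)) |
                        match(pred_vars, vs) >= match(r$target, vs)]
    if (length(late))
      v <- c(v, paste0("rule ", i, ": rule ordering - predicate variable(s) ",
                       paste(late, collapse = ", "),
                       " not earlier than target '", r$target, "'"))
    chained <- intersect(pred_vars, forced)
    if (length(chained))
      notes <- c(notes, paste0("rule ", i, ": chains on forced variable(s) ",
                               paste(chained, collapse = ", ")))
    forced <- c(forced, r$target)
  }

  structure(v, notes = notes)
}

#' Serialise a synthesis plan to YAML
#'
#' The schema travels with the plan so a config file is self-contained. The
#' predictor matrix is stored sparsely as a per-target list of predictors.
#'
#' @param plan A [synthesis_plan()].
#' @param path File path to write; when `NULL` the YAML string is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
write_plan <- function(plan, path = NULL) {
  pm <- plan$predictor_matrix
  predictors <- lapply(rownames(pm), function(tg) colnames(pm)[pm[tg, ]])
  names(predictors) <- rownames(pm)
  obj <- list(
    schema = lapply(unclass(plan$schema), function(v) {
      list(name = v$name, kind = v$kind, levels = as.list(v$levels),
           missing_allowed = v$missing_allowed)
    }),
    visit_sequence = as.list(plan$visit_sequence),
    method = as.list(plan$method),
    predictors = lapply(predictors, as.list),
    smoothing = as.list(plan$smoothing),
    rules = plan$rules,
    seed = plan$seed,
    cart_controls = plan$cart_controls
  )
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a synthesis plan from YAML
#'
#' @param path Path to a YAML file produced by [write_plan()] (or written by
#'   hand in the same shape).
#' @return A [synthesis_plan()].
#' @export
read_plan <- function(path) {
  obj <- yaml::read_yaml(path)
  schema <- table_schema(lapply(obj$schema, function(v) {
    variable_schema(v$name, v$kind, unlist(v$levels),
                    isTRUE(v$missing_allowed))
  }))
  vars <- names(schema)
  pm <- matrix(FALSE, length(vars), length(vars),
               dimnames = list(vars, vars))
  for (tg in names(obj$predictors))
    pm[tg, unlist(obj$predictors[[tg]])] <- TRUE
  synthesis_plan(
    schema,
    visit_sequence = unlist(obj$visit_sequence),
    method = unlist(obj$method),
    predictor_matrix = pm,
    smoothing = unlist(obj$smoothing) %||% character(),
    rules = obj$rules %||% list(),
    seed = obj$seed %||% 1L,
    cart_controls = obj$cart_controls %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Digest of a synthesis plan
#'
#' md5 of the plan's canonical JSON serialisation; recorded in release
#' provenance so a released file can be traced to the exact plan that
#' produced it.
#'
#' @param plan A [synthesis_plan()].
#' @return A 32-character hex string.
#' @export
plan_digest <- function(plan) {
  pm <- plan$predictor_matrix
  canon <- list(
    schema = lapply(unclass(plan$schema), function(v)
      list(v$name, v$kind, v$levels, v$missing_allowed)),
    visit_sequence = plan$visit_sequence,
    method = as.list(plan$method),
    predictors = lapply(rownames(pm), function(tg) colnames(pm)[pm[tg, ]]),
    smoothing = plan$smoothing,
    rules = plan$rules,
    seed = plan$seed,
    cart_controls = plan$cart_controls
  )
  json <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}
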