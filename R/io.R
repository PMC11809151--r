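## File I/O (CSV and Stata .dta), release packaging and the guideline audit.

#' Read a rectangular dataset
#'
#' Reads CSV or Stata `.dta` into a schema-conformant data frame: labelled
#' Stata columns become factors over their label set, all Stata missing
#' codes (including extended codes) collapse to `NA`, character CSV columns
#' become factors, and empty strings in a CSV are read as missing.
#'
#' @param path File path.
#' @param format `"csv"` or `"dta"`; guessed from the file extension when
#'   omitted.
#' @return A data frame.
#' @export
read_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", dta = "dta",
                     stop("unknown extension '", ext,
                          "': pass format = 'csv' or 'dta' explicitly"))
  }
  format <- match.arg(format, c("csv", "dta"))
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE,
                      na.strings = c("NA", "")),
      error = function(e) stop("cannot parse '", path, "' as CSV: ",
                               conditionMessage(e)))
    for (nm in names(df))
      if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    df
  } else {
    df <- tryCatch(haven::read_dta(path),
                   error = function(e) stop("cannot parse '", path,
                                            "' as Stata .dta: ",
                                            conditionMessage(e)))
    df <- as.data.frame(lapply(df, function(col) {
      if (inherits(col, "haven_labelled")) {
        haven::as_factor(col)  # tagged/extended missing -> NA
      } else {
        as.vector(haven::zap_missing(col))
      }
    }), optional = TRUE, stringsAsFactors = FALSE)
    for (nm in names(df))
      if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    df
  }
}

#' Write a dataset
#'
#' @param data Data frame.
#' @param path Output path; format from the extension unless given.
#' @param format `"csv"` or `"dta"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, format = NULL) {
  if (is.null(format))
    format <- match.arg(tolower(tools::file_ext(path)), c("csv", "dta"))
  if (format == "csv") {
    utils::write.csv(data, path, row.names = FALSE, na = "")
  } else {
    out <- data
    names(out) <- make.names(names(out))
    ## factors are exported as labelled integers (value labels = levels);
    ## dta version 14: modern Stata, and unrestricted variable naming
    haven::write_dta(out, path, version = 14)
  }
  invisible(path)
}

#' Write a synthetic release to disk
#'
#' Exports the release in the requested formats with the `FALSE_DATA`
#' marker as the first column and categorical values as labels, and writes
#' two sidecars: `<basename>_provenance.json` (seed, plan digest, SDC
#' counts, disclosure report) and `<basename>_README.txt` (the disclaimer).
#' A release that has not passed disclosure control, or whose supplied audit
#' failed, is refused unless `force = TRUE`.
#'
#' @param release A `synthetic_release`.
#' @param basename Output path prefix (no extension).
#' @param formats Subset of `c("csv", "dta")`.
#' @param audit Optional [release_audit()] report for the refusal gate.
#' @param force Write even when the gate fails (logged in the provenance).
#' @return Character vector of files written, invisibly.
#' @export
write_release <- function(release, basename, formats = c("csv", "dta"),
                          audit = NULL, force = FALSE) {
  stopifnot(inherits(release, "synthetic_release"))
  formats <- match.arg(formats, c("csv", "dta"), several.ok = TRUE)
  if (nrow(release$table) == 0L)
    stop("refusing to write an empty release")
  if (!isTRUE(release$provenance$sdc_applied) && !force)
    stop("release has not passed disclosure control (apply_sdc); ",
         "use force = TRUE to override")
  if (!is.null(audit) && !isTRUE(audit$overall)) {
    if (!force)
      stop("release audit failed (",
           paste(audit$checks$id[!audit$checks$pass], collapse = ", "),
           "); refusing to write. Use force = TRUE to override")
    release$provenance$forced_past_failed_audit <- TRUE
    message("writing release despite failed audit (force = TRUE)")
  }

  tab <- release_table(release, false_data = TRUE)
  files <- character()
  for (fm in formats) {
    f <- paste0(basename, ".", fm)
    write_table(tab, f, fm)
    files <- c(files, f)
  }
  prov <- release$provenance
  prov$trace <- NULL  # column-level trace is an in-memory diagnostic
  pj <- paste0(basename, "_provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, pretty = TRUE)
  rd <- paste0(basename, "_README.txt")
  writeLines(c("SYNTHETIC DATA - NOT REAL OBSERVATIONS", "", release$disclaimer),
             rd)
  invisible(c(files, pj, rd))
}

#' Audit a synthetic release against the release guidelines
#'
#' Runs the pre-release checklist for synthetic cohort data:
#' * `minimisation` — the release has fewer than 50 variables (excluding
#'   `FALSE_DATA`); when a model specification is given, columns outside it
#'   are noted as candidates for removal;
#' * `no_replicated_uniques` — zero synthetic rows replicate unique observed
#'   rows, and the manual spot check returns 0;
#' * `marginals_compared` — a marginal comparison was generated (attached to
#'   the report);
#' * `model_compared` — when `model_spec` is given, the substantive model
#'   refits on both tables (attached); otherwise marked skipped, not failed;
#' * `false_data_flag` — first exported column is the constant `FALSE_DATA`;
#' * `disclaimer` — the disclaimer text accompanies the release;
#' * `provenance` — seed and plan digest are recorded so the generating
#'   script/run can be published alongside the data.
#'
#' @param observed Data frame of observed data from the same synthesis run.
#' @param release A `synthetic_release`.
#' @param model_spec Optional formula of the substantive analysis.
#' @param family GLM family for `model_spec` (default binomial).
#' @return A `release_audit_report`: list with `checks` (data frame id /
#'   pass / detail), `overall`, and the generated comparison objects.
#' @export
release_audit <- function(observed, release, model_spec = NULL,
                          family = "binomial") {
  stopifnot(inherits(release, "synthetic_release"))
  tab <- release_table(release, false_data = TRUE)
  checks <- list()
  note <- function(id, pass, detail)
    data.frame(id = id, pass = pass, detail = detail,
               stringsAsFactors = FALSE)

  nvar <- ncol(tab) - 1L
  extra <- character()
  if (!is.null(model_spec))
    extra <- setdiff(setdiff(names(tab), "FALSE_DATA"), all.vars(model_spec))
  checks$minimisation <- note(
    "minimisation", nvar < 50L,
    paste0(nvar, " variables (< 50 required)",
           if (length(extra)) paste0("; not in analysis model: ",
                                     paste(extra, collapse = ", "))))

  rep_u <- find_replicated_uniques(observed, release)
  manual <- manual_check_sample(observed, release, k = 10L,
                                seed = release$provenance$seed %||% 1L)
  checks$no_replicated_uniques <- note(
    "no_replicated_uniques",
    rep_u$n_replicated_uniques == 0L && manual == 0L,
    paste0(rep_u$n_replicated_uniques, " replicated unique(s); manual check ",
           manual))

  marg <- compare_marginals(observed, release)
  checks$marginals_compared <- note(
    "marginals_compared", TRUE,
    paste0("max |pct diff| ", sprintf("%.2f", max(abs(marg$pct_diff)))))

  model_cmp <- NULL
  if (is.null(model_spec)) {
    checks$model_compared <- note("model_compared", NA,
                                  "skipped: no model specification given")
  } else {
    model_cmp <- tryCatch(
      fit_glm_both(model_spec, family, observed, release),
      error = function(e) NULL)
    checks$model_compared <- note(
      "model_compared", !is.null(model_cmp),
      if (is.null(model_cmp)) "model comparison failed"
      else paste0("min CI overlap ",
                  sprintf("%.2f", min(model_cmp$ci_overlap, na.rm = TRUE))))
  }

  checks$false_data_flag <- note(
    "false_data_flag",
    names(tab)[1L] == "FALSE_DATA" && all(tab$FALSE_DATA == "FALSE_DATA"),
    "constant FALSE_DATA column placed first")

  checks$disclaimer <- note(
    "disclaimer",
    is.character(release$disclaimer) && nzchar(release$disclaimer),
    "disclaimer text present")

  prov <- release$provenance
  checks$provenance <- note(
    "provenance",
    !is.null(prov$seed) && !is.null(prov$plan_digest),
    paste0("seed ", prov$seed %||% "?", ", digest ",
           substr(prov$plan_digest %||% "?", 1, 8)))

  checks <- do.call(rbind, checks)
  rownames(checks) <- NULL
  overall <- all(checks$pass[!is.na(checks$pass)])
  structure(list(checks = checks, overall = overall,
                 marginals = marg, model = model_cmp,
                 disclosure = rep_u),
            class = "release_audit_report")
}

#' @export
print.release_audit_report <- function(x, ...) {
  cat("<release_audit_report> overall: ",
      if (x$overall) "PASS" else "FAIL", "\n", sep = "")
  st <- ifelse(is.na(x$checks$pass), "skip",
               ifelse(x$checks$pass, "pass", "FAIL"))
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%-4s] %-22s %s\n", st[i], x$checks$id[i],
                x$checks$detail[i]))
  invisible(x)
}
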