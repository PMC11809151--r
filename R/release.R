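#' Recommended disclaimer accompanying released synthetic data
#'
#' Fixed text written alongside every release and embedded in the release
#' object, telling users the data are synthetic and unfit for research use.
#'
#' @format A length-one character vector.
#' @export
synthetic_data_disclaimer <- paste(
  "These are synthesised ALSPAC datasets, and are not suitable for research",
  "purposes. The relations between variables are unlikely to be maintained",
  "perfectly, so there is the risk when using these synthesised datasets",
  "that results may differ from the true data. Only the actual, observed,",
  "ALSPAC data should be used for formal research and analyses reported in",
  "published work.")

#' Construct a synthetic release
#'
#' A `synthetic_release` bundles a synthetic table with its provenance (seed,
#' plan digest, row counts before/after disclosure control, timestamp) and
#' the release disclaimer. The table is stored without the `FALSE_DATA`
#' marker; [release_table()] prepends it on demand and every on-disk export
#' carries it as the first column.
#'
#' @param table Data frame of synthetic rows.
#' @param provenance Named list; at least `seed`, `plan_digest`,
#'   `n_before_sdc`, `n_removed`.
#' @param disclaimer Release disclaimer text.
#' @return An object of class `synthetic_release`.
#' @export
new_synthetic_release <- function(table, provenance,
                                  disclaimer = synthetic_data_disclaimer) {
  stopifnot(is.data.frame(table))
  if ("FALSE_DATA" %in% names(table)) {
    stopifnot(all(table$FALSE_DATA == "FALSE_DATA"))
    table$FALSE_DATA <- NULL
  }
  structure(list(table = table, provenance = provenance,
                 disclaimer = disclaimer),
            class = "synthetic_release")
}

#' Extract the table of a synthetic release
#'
#' @param release A `synthetic_release`.
#' @param false_data Prepend the constant `FALSE_DATA` marker column
#'   (default `TRUE`, the released form).
#' @return A data frame; when `false_data` is `TRUE` its first column is
#'   named `FALSE_DATA` with every value `"FALSE_DATA"`.
#' @export
release_table <- function(release, false_data = TRUE) {
  stopifnot(inherits(release, "synthetic_release"))
  tab <- release$table
  if (false_data)
    tab <- cbind(FALSE_DATA = rep("FALSE_DATA", nrow(tab)), tab,
                 stringsAsFactors = FALSE)
  tab
}

#' @export
as.data.frame.synthetic_release <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  release_table(x, false_data = TRUE)
}

#' @export
print.synthetic_release <- function(x, ...) {
  p <- x$provenance
  cat("<synthetic_release> ", nrow(x$table), " rows x ", ncol(x$table),
      " variables (+ FALSE_DATA)\n", sep = "")
  cat("  seed ", p$seed, ", plan digest ", substr(p$plan_digest, 1, 8),
      "...\n", sep = "")
  cat("  SDC: ", if (isTRUE(p$sdc_applied))
    paste0(p$n_removed, " replicated unique(s) removed of ", p$n_before_sdc)
    else "not yet applied", "\n", sep = "")
  invisible(x)
}
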