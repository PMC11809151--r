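## Statistical disclosure control: replicated-unique detection and removal,
## top/bottom coding, and the manual spot check.

## Canonical row keys: categorical values as labels, continuous values
## rendered at full precision ("%.17g") so comparison is bitwise, NA as a
## dedicated sentinel. Missing markers are part of the key.
row_keys <- function(df) {
  df <- df[setdiff(names(df), "FALSE_DATA")]
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.17g", col)
    } else {
      out <- as.character(col)
    }
    out[is.na(col)] <- "\x01NA\x01"
    out
  })
  do.call(paste, c(cols, sep = "\x1f"))
}

as_plain_table <- function(x) {
  if (inherits(x, "synthetic_release")) release_table(x, false_data = FALSE)
  else x[setdiff(names(x), "FALSE_DATA")]
}

#' Find synthetic rows replicating unique observed rows
#'
#' A synthetic row is flagged when its full value combination (missing
#' markers included) occurs exactly once in the observed table: such rows
#' would reveal a real participant's unique record and must be removed
#' before release. The replicated share is reported as a percentage of the
#' observed sample size.
#'
#' @param observed Data frame of observed data.
#' @param synthetic Data frame or `synthetic_release` of synthetic data
#'   (`FALSE_DATA` is ignored for comparison).
#' @return A `disclosure_report`: list with `n_synthetic_before`,
#'   `n_replicated_uniques`, `pct_replicated` (of observed n),
#'   `removed_row_indices`, and per-row logical `flags`.
#' @export
find_replicated_uniques <- function(observed, synthetic) {
  observed <- as_plain_table(observed)
  synthetic <- as_plain_table(synthetic)
  extra_syn <- setdiff(names(synthetic), names(observed))
  extra_obs <- setdiff(names(observed), names(synthetic))
  if (length(extra_syn) || length(extra_obs))
    stop("column sets differ: only in synthetic {",
         paste(extra_syn, collapse = ", "), "}; only in observed {",
         paste(extra_obs, collapse = ", "), "}")
  synthetic <- synthetic[names(observed)]

  obs_keys <- row_keys(observed)
  syn_keys <- row_keys(synthetic)
  once <- names(which(table(obs_keys) == 1L))
  flags <- syn_keys %in% once

  structure(
    list(n_synthetic_before = nrow(synthetic),
         n_replicated_uniques = sum(flags),
         pct_replicated = 100 * sum(flags) / nrow(observed),
         removed_row_indices = which(flags),
         flags = flags),
    class = "disclosure_report"
  )
}

#' @export
print.disclosure_report <- function(x, ...) {
  cat("<disclosure_report> ", x$n_replicated_uniques,
      " replicated unique(s) among ", x$n_synthetic_before,
      " synthetic rows (", sprintf("%.2f", x$pct_replicated),
      "% of the observed sample)\n", sep = "")
  invisible(x)
}

#' Apply statistical disclosure control to a synthetic table
#'
#' Removes every synthetic row flagged as a replicated unique, optionally
#' top/bottom-codes continuous columns at stated quantiles (values beyond a
#' quantile are replaced by the quantile value), and re-checks that the
#' result contains zero replicated uniques, iterating if coding created new
#' ones. This is the release gate: the returned data always satisfies
#' `find_replicated_uniques(observed, .)$n_replicated_uniques == 0`.
#'
#' @param synthetic Data frame or `synthetic_release`.
#' @param observed Data frame of observed data (needed for flagging and the
#'   re-check).
#' @param report Optional `disclosure_report` from
#'   [find_replicated_uniques()] on the same pair; computed when omitted.
#' @param top_bottom Optional named list: per continuous column a numeric
#'   vector `c(lower, upper)` of quantile probabilities (use `NA` to skip a
#'   side), e.g. `list(bwt = c(0.01, 0.99))`.
#' @return Same class as `synthetic`: the cleaned table, or a release with
#'   updated provenance (`n_removed`, `sdc_applied`).
#' @export
apply_sdc <- function(synthetic, observed, report = NULL, top_bottom = NULL) {
  is_release <- inherits(synthetic, "synthetic_release")
  tab <- as_plain_table(synthetic)
  if (is.null(report)) report <- find_replicated_uniques(observed, tab)
  stopifnot(inherits(report, "disclosure_report"),
            length(report$flags) == nrow(tab))

  n_before <- nrow(tab)
  removed <- sum(report$flags)
  tab <- tab[!report$flags, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("disclosure control removed every synthetic row; ",
         "re-synthesise (different seed/method) before release")

  for (nm in names(top_bottom)) {
    if (!is.numeric(tab[[nm]])) next
    q <- top_bottom[[nm]]
    # type = 1 (inverse CDF): the bound is an actually-observed value
    lo <- if (!is.na(q[1]))
      stats::quantile(tab[[nm]], q[1], na.rm = TRUE, type = 1) else -Inf
    hi <- if (length(q) > 1 && !is.na(q[2]))
      stats::quantile(tab[[nm]], q[2], na.rm = TRUE, type = 1) else Inf
    tab[[nm]] <- pmin(pmax(tab[[nm]], lo), hi)
  }

  ## re-check: top/bottom coding can itself create replicated uniques
  repeat {
    chk <- find_replicated_uniques(observed, tab)
    if (chk$n_replicated_uniques == 0L) break
    removed <- removed + chk$n_replicated_uniques
    tab <- tab[!chk$flags, , drop = FALSE]
    if (nrow(tab) == 0L)
      stop("disclosure control removed every synthetic row after coding")
  }
  rownames(tab) <- NULL

  if (is_release) {
    synthetic$table <- tab
    synthetic$provenance$n_before_sdc <- n_before
    synthetic$provenance$n_removed <-
      (synthetic$provenance$n_removed %||% 0L) + removed
    synthetic$provenance$sdc_applied <- TRUE
    synthetic
  } else {
    tab
  }
}

#' Manual spot check for replicated uniques
#'
#' Draws `k` rows at random from the observed rows that are unique within
#' the observed table and counts how many exactly match a synthetic row that
#' is unique within the synthetic table — the sanity check performed by hand
#' after disclosure control, which must return 0 on released data.
#'
#' @param observed Data frame of observed data.
#' @param synthetic Data frame or `synthetic_release`.
#' @param k Number of observed unique rows to check (default 10).
#' @param seed Integer seed for the row draw.
#' @return Integer match count.
#' @export
manual_check_sample <- function(observed, synthetic, k = 10L, seed = 1L) {
  stopifnot(k >= 1L)
  observed <- as_plain_table(observed)
  synthetic <- as_plain_table(synthetic)
  obs_keys <- row_keys(observed)
  syn_keys <- row_keys(synthetic)
  obs_unique <- obs_keys[!(duplicated(obs_keys) |
                             duplicated(obs_keys, fromLast = TRUE))]
  syn_unique <- syn_keys[!(duplicated(syn_keys) |
                             duplicated(syn_keys, fromLast = TRUE))]
  if (length(obs_unique) == 0L) return(0L)
  if (k > length(obs_unique)) {
    warning("only ", length(obs_unique),
            " unique observed rows; checking all of them", call. = FALSE)
    k <- length(obs_unique)
  }
  picked <- with_stream(seed, 0L,
                        obs_unique[sample.int(length(obs_unique), k)])
  sum(picked %in% syn_unique)
}
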