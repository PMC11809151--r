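## Comparison graphics: grouped count bars per variable, coefficient
## dot-plot on the z scale, and growth-trajectory curves.

#' Plot observed vs synthetic marginal distributions
#'
#' Grouped bar chart of per-category counts, one facet per variable, with
#' missing values shown as their own "NA" bar.
#'
#' @param comparison A [compare_marginals()] result.
#' @param variables Optional subset of variables to show.
#' @return A ggplot object.
#' @export
plot_marginals <- function(comparison, variables = NULL) {
  stopifnot(inherits(comparison, "marginal_comparison"))
  df <- as.data.frame(comparison)
  if (!is.null(variables)) df <- df[df$variable %in% variables, ]
  long <- rbind(
    data.frame(df[c("variable", "category")], count = df$observed_n,
               data = "observed"),
    data.frame(df[c("variable", "category")], count = df$synthetic_n,
               data = "synthetic")
  )
  long$category <- factor(long$category, levels = unique(df$category))
  ggplot2::ggplot(long, ggplot2::aes(x = category, y = count,
                                     fill = data)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::scale_fill_manual(values = c(observed = "#1f4e79",
                                          synthetic = "#74a9cf")) +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot observed vs synthetic model coefficients on the z scale
#'
#' Dot plot of per-coefficient z-values (estimate / SE) for the observed and
#' the synthetic fit; the common scale makes coefficients comparable across
#' terms.
#'
#' @param comparison A [fit_glm_both()] result.
#' @param drop_intercept Hide the intercept row (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_coefficients <- function(comparison, drop_intercept = TRUE) {
  stopifnot(inherits(comparison, "model_comparison"))
  df <- as.data.frame(comparison)
  if (drop_intercept) df <- df[df$term != "(Intercept)", ]
  long <- rbind(
    data.frame(term = df$term, z = df$z_obs, data = "observed"),
    data.frame(term = df$term, z = df$z_syn, data = "synthetic")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = z, y = term,
                                     colour = data)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3, position = ggplot2::position_dodge(0.4)) +
    ggplot2::scale_colour_manual(values = c(observed = "#1f4e79",
                                            synthetic = "#74a9cf")) +
    ggplot2::labs(x = "z value", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted mean growth trajectories
#'
#' Population-mean curves from one or more growth fits (e.g. observed vs
#' synthetic), by sex when the fits include the interaction.
#'
#' @param fits Named list of `growth_fit` objects (names become curve
#'   labels).
#' @param ages Ages at which to evaluate the curves.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fits, ages = seq(7, 18, by = 0.25)) {
  if (inherits(fits, "growth_fit")) fits <- list(fit = fits)
  rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (f$sex_interaction) {
      for (fem in 0:1)
        rows[[paste(nm, fem)]] <- data.frame(
          data = nm, sex = if (fem) "female" else "male", age = ages,
          value = predict(f, ages, female = fem))
    } else {
      rows[[nm]] <- data.frame(data = nm, sex = "all", age = ages,
                               value = predict(f, ages))
    }
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = age, y = value,
                                   colour = data,
                                   linetype = sex)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "age (years)", y = "predicted mean",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("category", "count", "data", "term", "z", "age",
                         "value", "sex", "variable"))
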