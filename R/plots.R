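#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class-specific real-parameter estimates of a fitted model
#'
#' Dot-and-interval plot of back-transformed survival, recapture and
#' movement estimates for every sex-by-age(-by-state) cell.
#'
#' @param object An `ms_fit`.
#' @param chat Overdispersion factor for the intervals.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_fit <- function(object, chat = 1, ...) {
  est <- dplyr::bind_rows(lapply(c("phi", "p", "psi"), function(par) {
    real_estimates(object, par, chat = chat)
  }))
  est$cell <- paste0(est$sex, ".", est$age,
                     ifelse(est$param == "psi", "", paste0(".", est$state)))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$cell)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lcl, xmax = .data$ucl)) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "probability", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot a ranked candidate set
#'
#' Akaike weights by model, ordered by QAICc.
#'
#' @param object An `ms_candidates`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_candidates <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_bw()
}

#' Predicted response to an annual covariate
#'
#' Curve of a back-transformed parameter against one standardized annual
#' covariate, holding the factor cell fixed (other covariates at 0, their
#' standardized mean).
#'
#' @param fit An `ms_fit`.
#' @param covariate Covariate name, e.g. `"soi"` or `"density"`.
#' @param param `"phi"`, `"p"` or `"psi"`.
#' @param sex,age,state Factor cell to evaluate.
#' @param range Covariate range (standardized units).
#' @param chat Overdispersion factor for the confidence band.
#' @return A ggplot.
#' @export
plot_effect <- function(fit, covariate, param = "phi",
                        sex = "female", age = "ASY", state = "F",
                        range = c(-2, 2), chat = 1) {
  grid <- tibble(sex = sex, age = age, state = state)
  grid <- tidyr::expand_grid(grid,
                             !!covariate := seq(range[1], range[2],
                                                length.out = 101))
  est <- real_estimates(fit, param, newdata = grid, chat = chat)
  ggplot2::ggplot(est, ggplot2::aes(x = .data[[covariate]],
                                    y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lcl, ymax = .data$ucl),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(covariate, " (standardized)"),
                  y = paste(param, "estimate")) +
    ggplot2::theme_bw()
}
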