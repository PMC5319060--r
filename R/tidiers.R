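#' Tidy a TRE report into per-landmark rows
#'
#' @param x a \code{tre_report}
#' @param ... unused
#' @return tibble with id, category, group, error_mm
#' @export
tidy.tre_report <- function(x, ...) x$per_landmark

#' One-row TRE summary
#'
#' @param x a \code{tre_report}
#' @param ... unused
#' @return tibble with overall, surface and internal mean TREs (mm)
#' @export
glance.tre_report <- function(x, ...) {
  s <- x$summary
  get <- function(g, col) {
    v <- s[[col]][s$group == g]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(n_landmarks = get("overall", "n"),
                 mean_tre_mm = get("overall", "mean_tre_mm"),
                 surface_tre_mm = get("surface", "mean_tre_mm"),
                 internal_tre_mm = get("internal", "mean_tre_mm"),
                 max_tre_mm = get("overall", "max_tre_mm"))
}

#' Tidy a coupling fit into its evaluation trace
#'
#' @param x a \code{coupling_fit}
#' @param ... unused
#' @return tibble of evaluated (k_tumor, k_vessel, objective, stage)
#' @export
tidy.coupling_fit <- function(x, ...) x$trace

#' One-row summary of a coupling fit
#'
#' @param x a \code{coupling_fit}
#' @param ... unused
#' @return tibble with the estimates, objective and evaluation counts
#' @export
glance.coupling_fit <- function(x, ...) {
  tibble::tibble(k_tumor = x$params$k_tumor, k_vessel = x$params$k_vessel,
                 objective = x$objective, n_evals = x$n_evals,
                 n_failed = x$n_failed)
}

#' Plot per-landmark registration errors
#'
#' Dot plot of per-landmark TRE (mm) grouped by landmark category.
#'
#' @param object a \code{tre_report}
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.tre_report <- function(object, ...) {
  df <- object$per_landmark
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$error_mm)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "red3") +
    ggplot2::labs(x = NULL, y = "target registration error (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the coupling-calibration objective landscape
#'
#' Grid evaluations as a log-log tile map with the refinement path and the
#' final estimate overlaid.
#'
#' @param object a \code{coupling_fit}
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.coupling_fit <- function(object, ...) {
  tr <- object$trace
  grid <- tr[tr$stage == "grid", ]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$k_tumor, y = .data$k_vessel)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$objective))) +
    ggplot2::geom_path(data = tr[tr$stage == "refine", ], color = "white") +
    ggplot2::annotate("point", x = object$params$k_tumor,
                      y = object$params$k_vessel, color = "red", size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "k tumor (N/m)", y = "k vessel (N/m)",
                  fill = "log10 SSE") +
    ggplot2::theme_minimal()
}
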