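## ggplot2 views of run records.

#' Plot the seta-level force profile
#'
#' The three measurement points (substrate reaction, summed anchor-point
#' force, driver constraint force) against time; compression positive,
#' adhesion negative.
#'
#' @param object a [run_protocol()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.seta_run <- function(object, ...) {
  df <- object$seta |>
    dplyr::select("time_ns", "f_sub", "f_ap", "f_driver") |>
    tidyr_longer()
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$force,
                                   colour = .data$measurement)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(f_sub = "#c0392b", f_ap = "#27ae60", f_driver = "#2980b9"),
      labels = c(f_sub = "substrate", f_ap = "anchor points",
                 f_driver = "driver nodes")) +
    ggplot2::labs(x = "time (ns)", y = "force (nN)", colour = NULL,
                  title = "Seta force profile (compression +, adhesion -)") +
    ggplot2::theme_minimal()
}

## minimal pivot (avoids a tidyr dependency for one reshape)
tidyr_longer <- function(df) {
  long <- lapply(c("f_sub", "f_ap", "f_driver"), function(v)
    tibble::tibble(time_ns = df$time_ns, measurement = v,
                   force = df[[v]]))
  dplyr::bind_rows(long)
}

#' Plot per-spatula contact profiles
#'
#' @param run a [run_protocol()] result.
#' @return a ggplot (one facet per spatula).
#' @export
plot_contact_profiles <- function(run) {
  ggplot2::ggplot(run$spatula,
                  ggplot2::aes(.data$time_ns, .data$contacts,
                               colour = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~spatula, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = "contact points", colour = NULL,
                  title = "Spatula-substrate contacts") +
    ggplot2::theme_minimal()
}

#' Plot tip/pad displacement profiles
#'
#' Mean tip and pad coordinates per spatula along X (surface-parallel,
#' toward spatula 1) and Y (surface normal).
#'
#' @param run a [run_protocol()] result.
#' @param axis `"x"` or `"y"`.
#' @return a ggplot (one facet per spatula).
#' @export
plot_displacement_profiles <- function(run, axis = c("y", "x")) {
  axis <- match.arg(axis)
  cols <- if (axis == "y") c("tip_y", "pad_y") else c("tip_x", "pad_x")
  long <- dplyr::bind_rows(lapply(cols, function(v)
    tibble::tibble(time_ns = run$spatula$time_ns,
                   spatula = run$spatula$spatula,
                   group = sub("_[xy]$", "", v),
                   pos = run$spatula[[v]])))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ns, .data$pos,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~spatula, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = sprintf("%s position (nm)",
                                               toupper(axis)),
                  colour = NULL,
                  title = "Tip/pad displacement profiles") +
    ggplot2::theme_minimal()
}
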