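## ggplot2 autoplot() methods for the package's result types.

#' @exportS3Method ggplot2::autoplot
autoplot.fes2d <- function(object, mfep = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s_hat, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$F)) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
    ggplot2::labs(x = expression(hat(s)), y = expression(z ~ (ring(A)^2))) +
    ggplot2::theme_minimal()
  if (!is.null(mfep)) {
    p <- p + ggplot2::geom_path(
      data = mfep,
      ggplot2::aes(x = .data$s_hat_center, y = .data$z_at_min),
      colour = "yellow", linewidth = 1
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.fes1d <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "CV", y = "F (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mfep_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_hat_center, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(hat(s)), y = expression(Delta * G ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.block_error_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$block_size, y = .data$mean_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "block size", y = "mean error (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eds_run <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$time_ps, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "rmsd to target (Å)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.metad_run <- function(object, ...) {
  y <- if (all(is.na(object$cv_log$s_hat))) "s" else "s_hat"
  ggplot2::ggplot(object$cv_log, ggplot2::aes(
    x = .data$time_ps,
    y = .data[[y]]
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (ps)", y = y) +
    ggplot2::theme_minimal()
}
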