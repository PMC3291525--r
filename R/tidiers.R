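# broom-style tidiers and ggplot2 autoplot methods

#' @method tidy arma_fit
#' @export
tidy.arma_fit <- function(x, ...) {
  tibble(term = c(paste0("alpha", seq_along(x$alpha)),
                  paste0("beta", seq_along(x$beta))),
         estimate = c(x$alpha, x$beta))
}

#' @method glance arma_fit
#' @export
glance.arma_fit <- function(x, ...) {
  tibble(order = x$order,
         n_cycles = x$n_cycles,
         resid_var_fraction = x$resid_var_fraction,
         lambda_alt_re = Re(x$lambda_alt_hat),
         lambda_alt_im = Im(x$lambda_alt_hat),
         s_s1s2 = x$s_s1s2_hat,
         s_dyn = x$s_dyn_hat,
         condition_number = x$condition_number)
}

#' @method tidy eigen_summary
#' @export
tidy.eigen_summary <- function(x, ...) {
  tibble(eigenvalue = seq_along(x$eigvals),
         re = Re(x$eigvals), im = Im(x$eigvals),
         modulus = Mod(x$eigvals),
         negligible = x$negligible)
}

#' @method glance eigen_summary
#' @export
glance.eigen_summary <- function(x, ...) {
  tibble(lambda_alt_re = Re(x$lambda_alt),
         lambda_alt_im = Im(x$lambda_alt),
         lambda_mem_re = Re(x$lambda_mem),
         tau_mem_beats = x$tau_mem_beats,
         tau_mem_ms = x$tau_mem_ms)
}

#' @method tidy transfer_fn
#' @export
tidy.transfer_fn <- function(x, ...) {
  dplyr::bind_rows(
    tibble(type = "pole", re = Re(x$poles), im = Im(x$poles)),
    tibble(type = "zero", re = Re(x$zeros), im = Im(x$zeros)))
}

#' @method tidy onset_prediction
#' @export
tidy.onset_prediction <- function(x, ...) {
  tibble(predictor = x$predictor, slope = x$slope,
         intercept = x$intercept, cutoff = x$cutoff,
         onset = x$onset, n_points = x$n_points)
}

#' Bode plot of one or more transfer functions
#'
#' @param object a `transfer_fn`.
#' @param ... further named `transfer_fn` objects overlaid for comparison
#'   (e.g. eigen vs ARMA vs DFT).
#' @param freqs frequency grid (beat^-1) for rational transfer functions.
#' @return A ggplot with gain (dB) and phase (rad) facets over per-beat
#'   frequency.
#' @method autoplot transfer_fn
#' @export
autoplot.transfer_fn <- function(object, ..., freqs = seq(0.005, 0.5,
                                                          by = 0.005)) {
  tfs <- c(list(object), list(...))
  names(tfs) <- vapply(seq_along(tfs), function(i) {
    nm <- names(tfs)[i]
    if (!is.null(nm) && nzchar(nm)) nm else tfs[[i]]$source
  }, "")
  df <- purrr::imap_dfr(tfs, function(tf, nm) {
    fr <- if (tf$source == "dft") frequency_response(tf)
          else frequency_response(tf, freqs)
    fr$which <- nm
    fr
  })
  long <- tidyr::pivot_longer(df, c("gain_db", "phase_rad"),
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$f_per_beat, y = .data$value,
                               colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(gain_db = "gain (dB)",
                            phase_rad = "phase (rad)"))) +
    ggplot2::labs(x = expression(f ~ (beat^-1)), y = NULL,
                  colour = "source") +
    ggplot2::theme_minimal()
}

#' Plot a restitution curve
#' @param object a `restitution_curve`.
#' @param ... unused.
#' @return A ggplot of APD vs DI.
#' @method autoplot restitution_curve
#' @export
autoplot.restitution_curve <- function(object, ...) {
  df <- object[is.finite(object$di_ms), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$di_ms, y = .data$apd_ms)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "DI (ms)", y = "APD (ms)",
                  title = sprintf("%s restitution", attr(object, "kind"))) +
    ggplot2::theme_minimal()
}

#' Plot tracked alternans-eigenvalue estimates
#' @param object a `track_result`.
#' @param predictor x-axis: `"beat"` (window centre) or `"bcl"`.
#' @param ... unused.
#' @return A ggplot with the `lambda_alt = -1` onset line.
#' @method autoplot track_result
#' @export
autoplot.track_result <- function(object, predictor = c("beat", "bcl"),
                                  ...) {
  predictor <- match.arg(predictor)
  x <- if (predictor == "beat") "window_center_beat" else "mean_bcl_ms"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$lambda_alt)) +
    ggplot2::geom_hline(yintercept = -1, linetype = 2, colour = "red") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = if (predictor == "beat") "window centre (beat)"
          else "window mean BCL (ms)",
      y = expression(lambda[alt])) +
    ggplot2::theme_minimal()
}

#' Plot a beat series
#' @param object a `beat_series`.
#' @param ... unused.
#' @return A ggplot of CL, APD and DI vs beat.
#' @method autoplot beat_series
#' @export
autoplot.beat_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("beat", "cl_ms", "apd_ms", "di_ms")],
    c("cl_ms", "apd_ms", "di_ms"),
    names_to = "interval", values_to = "ms")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beat, y = .data$ms,
                                     colour = .data$interval)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "beat", y = "interval (ms)", colour = NULL) +
    ggplot2::theme_minimal()
}
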