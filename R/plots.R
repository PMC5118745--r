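#' Plot a Bland-Altman analysis
#'
#' Scatter of per-pair differences against means with the bias and the
#' 1.96 SD limits of agreement as horizontal lines.
#'
#' @param object a [bland_altman()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "mean of true and measured",
                  y = "true - measured",
                  title = sprintf("Bland-Altman: bias %.2f, LoA width %.2f",
                                  object$bias, object$loa_width)) +
    ggplot2::theme_minimal()
}

#' Plot an annotated record
#'
#' A short stretch of the (filtered) SCG with the annotated AO, AC and MO
#' fiducials overlaid, plus the per-beat systolic-time-interval series.
#'
#' @param object an `sti_annotation` from [annotate_record()].
#' @param what `"sti"` (per-beat PEP/LVET/QS2 series) or `"template"`
#'   (initial SCG template with its landmarks).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sti_annotation <- function(object, what = c("sti", "template"), ...) {
  what <- match.arg(what)
  if (what == "sti") {
    df <- tidyr::pivot_longer(
      dplyr::select(tibble::as_tibble(object$beats),
                    "beat", "pep_ms", "lvet_ms", "qs2_ms"),
      cols = -"beat", names_to = "interval", values_to = "ms")
    ggplot2::ggplot(stats::na.omit(df),
                    ggplot2::aes(x = .data$beat, y = .data$ms,
                                 colour = .data$interval)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "beat", y = "interval (ms)",
                    title = "Systolic time intervals per beat") +
      ggplot2::theme_minimal()
  } else {
    tpl <- object$init$scg_template
    lm <- tpl$landmarks
    fs <- object$fs
    df <- tibble::tibble(t_ms = (seq_along(tpl$wave) - 1) / fs * 1000,
                         wave = tpl$wave)
    marks <- tibble::tibble(
      fiducial = c("AO", "AC", "MO"),
      t_ms = (c(lm$ao, lm$ac, lm$mo) - 1) / fs * 1000,
      wave = tpl$wave[c(lm$ao, lm$ac, lm$mo)]
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$wave)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(data = marks, ggplot2::aes(colour = .data$fiducial),
                          size = 2) +
      ggplot2::labs(x = "time in segment (ms)", y = "SCG template",
                    title = "Initial template with landmarks") +
      ggplot2::theme_minimal()
  }
}
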