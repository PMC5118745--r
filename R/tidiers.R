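#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an annotated record
#'
#' One row per beat: fiducial indices, systolic time intervals and flags.
#'
#' @param x an `sti_annotation` from [annotate_record()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sti_annotation <- function(x, ...) {
  tibble::as_tibble(x$beats)
}

#' @rdname tidy.sti_annotation
#' @export
glance.sti_annotation <- function(x, ...) {
  b <- x$beats
  ann <- !is.na(b$ac)
  rr <- diff(b$r) / x$fs
  tibble::tibble(
    n_beats = nrow(b),
    n_annotated = sum(ann),
    n_flagged = sum(b$flagged),
    hr_bpm = 60 / stats::median(rr),
    pep_ms = mean(b$pep_ms[ann]),
    lvet_ms = mean(b$lvet_ms[ann]),
    qs2_ms = mean(b$qs2_ms[ann])
  )
}

#' Tidy a Bland-Altman analysis
#'
#' `tidy()` returns the per-pair means and differences; `glance()` the
#' bias, limits of agreement and LoA width.
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, loa_low = x$loa_low,
                 loa_high = x$loa_high, loa_width = x$loa_width, n = x$n)
}
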