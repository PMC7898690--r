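#' Postcontrast T1-map sampling scheme
#'
#' An ordered set of postcontrast T1-map acquisition times: a first and a
#' last map plus `n_additional` interior maps equally spaced between them.
#' Times are minutes after the start of contrast injection; each map
#' carries a single effective time stamp (its k-space-center time).
#'
#' @param first Time of the first postcontrast map (min), positive.
#' @param last Time of the last map (min), greater than `first`.
#' @param n_additional Number of equally spaced interior maps (>= 0).
#' @return An object of class `sampling_scheme` with a `times` vector of
#'   length `n_additional + 2`.
#' @examples
#' make_scheme(4.333, 30, 0)   # the two-map protocol
#' make_scheme(4.333, 30, 5)   # "continuous" seven-map scanning
#' @export
make_scheme <- function(first = 4.333, last = 30, n_additional = 0) {
  stopifnot(is.numeric(first), is.numeric(last), is.numeric(n_additional))
  if (first <= 0) stop("`first` must be positive.", call. = FALSE)
  if (last <= first) stop("`last` must exceed `first`.", call. = FALSE)
  if (n_additional < 0 || n_additional != round(n_additional)) {
    stop("`n_additional` must be a non-negative integer.", call. = FALSE)
  }
  times <- seq(first, last, length.out = n_additional + 2)
  structure(
    list(times = times, first = first, last = last,
         n_additional = as.integer(n_additional)),
    class = "sampling_scheme"
  )
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme> %d maps at %s min\n",
              length(x$times), paste(format(x$times, digits = 4), collapse = ", ")))
  invisible(x)
}
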