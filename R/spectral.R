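#' Raw periodogram of a series
#'
#' Classical discrete-Fourier periodogram `I(f_j) = |X(f_j)|^2 / n` at the
#' Fourier frequencies `f_j = j/n`, `j = 1 .. floor(n/2)` cycles per
#' sample.  The series is demeaned internally; missing values are filled
#' with the series mean first (adequate for peak screening, documented in
#' the methods vignette).  No tapering or smoothing is applied.
#'
#' @param x series-like object with at least 4 non-missing values.
#' @return a data frame of class `periodogram` with columns `frequency`
#'   (strictly increasing, in (0, 0.5]) and `power` (non-negative).
#' @examples
#' pg <- periodogram(cos(2 * pi * (0:479) / 24))
#' pg$frequency[which.max(pg$power)]  # 1/24
#' @export
periodogram <- function(x) {
  v <- series_values(x)
  keep <- is.finite(v)
  if (sum(keep) < 4L) stop("periodogram requires at least 4 non-missing values")
  v[!keep] <- mean(v[keep])
  v <- v - mean(v)
  n <- length(v)
  pw <- Mod(stats::fft(v))^2 / n
  j <- seq_len(floor(n / 2))
  out <- data.frame(frequency = j / n, power = pw[j + 1L])
  class(out) <- c("periodogram", "data.frame")
  out
}

#' Candidate periodic frequencies from a periodogram
#'
#' Ranks local maxima of the periodogram by power and returns the top
#' `top_n` together with their implied periods (`1/frequency`, in
#' samples).  Ties in power are broken in favour of the lower frequency.
#' An optional frequency window restricts the screen, mirroring visual
#' inspection of one region of the periodogram.
#'
#' @param p a [periodogram()].
#' @param top_n number of candidates to return (`>= 1`).
#' @param min_frequency,max_frequency frequency window for the screen,
#'   cycles per sample.
#' @return data frame with columns `frequency`, `power`, `period`, ordered
#'   by decreasing power.
#' @export
peak_candidates <- function(p, top_n, min_frequency = 0, max_frequency = 0.5) {
  stopifnot(inherits(p, "periodogram"))
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1)
    stop("`top_n` must be at least 1")
  sel <- p$frequency >= min_frequency & p$frequency <= max_frequency
  fr <- p$frequency[sel]
  pw <- p$power[sel]
  if (length(pw) == 0L) return(data.frame(frequency = numeric(0),
                                          power = numeric(0),
                                          period = numeric(0)))
  padded <- c(-Inf, pw, -Inf)
  is_peak <- pw > padded[seq_along(pw)] & pw >= padded[seq_along(pw) + 2L]
  fr <- fr[is_peak]
  pw <- pw[is_peak]
  ord <- order(-pw, fr)
  take <- utils::head(ord, n = as.integer(top_n))
  data.frame(frequency = fr[take], power = pw[take], period = 1 / fr[take])
}

#' Write a periodogram as a two-column CSV
#'
#' @param p a [periodogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_periodogram_csv <- function(p, path) {
  stopifnot(inherits(p, "periodogram"))
  utils::write.csv(as.data.frame(p)[, c("frequency", "power")], path,
                   row.names = FALSE)
  invisible(path)
}
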