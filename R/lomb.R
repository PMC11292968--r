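#' Lomb-Scargle periodogram of an emergence series
#'
#' Classical normalized Lomb-Scargle power over a grid of periods, using
#' observed bins only (missing bins simply drop out; no imputation).  For
#' angular frequency `w` and mean-centred counts `y` at observed times
#' `t`,
#' \deqn{P(w) = \frac{1}{2 s^2}\left[
#'   \frac{(\sum y \cos w(t-\tau))^2}{\sum \cos^2 w(t-\tau)} +
#'   \frac{(\sum y \sin w(t-\tau))^2}{\sum \sin^2 w(t-\tau)}\right]}
#' with `tan(2 w tau) = sum(sin 2wt) / sum(cos 2wt)` and `s^2` the sample
#' variance.  The peak significance uses the Horne-Baliunas style estimate
#' of the number of independent frequencies, `M = 2 n_obs` scaled by the
#' fraction of the Nyquist range scanned: `p = 1 - (1 - exp(-Z))^M`.  This
#' approximates the p-values of the classical periodogram packages; it is
#' intended for decision-making at `alpha = 0.05`, not for exact p parity.
#'
#' @param series An [emergence_series()].
#' @param scan_min,scan_max Period scan range, in bin units (days for
#'   daily series, hours for hourly): 3-35 days is the standard
#'   circasemilunar visualization range, 15-40 h the circadian one.
#' @param oversampling Frequency oversampling factor (grid step
#'   `1 / (span * oversampling)`).
#' @return A list of class `periodogram` with elements `method` (`"LS"`),
#'   `period_grid`, `statistic` (power), `best_period`, `p_value`,
#'   `n_obs`.
#' @export
lomb_scargle <- function(series, scan_min, scan_max, oversampling = 4) {
  stopifnot(inherits(series, "emergence_series"))
  if (!(scan_min > 0 && scan_min < scan_max))
    stop("need 0 < scan_min < scan_max", call. = FALSE)
  y <- series$counts
  t <- series_index(series)
  obs <- !is.na(y)
  if (sum(obs) < 8)
    stop("fewer than 8 observed bins: periodogram unreliable",
         call. = FALSE)
  t <- t[obs]
  y <- y[obs]
  y <- y - mean(y)
  s2 <- sum(y^2) / (length(y) - 1)

  span <- diff(range(t))
  step <- 1 / (span * oversampling)
  freqs <- seq(1 / scan_max, 1 / scan_min, by = step)
  power <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  if (s2 == 0) power[] <- 0

  best <- which.max(power)
  z <- power[best]
  f_ny <- 0.5 / stats::median(diff(sort(t)))
  m <- max(1, 2 * length(t) * (1 / scan_min - 1 / scan_max) / f_ny)
  # p = 1 - (1 - e^-Z)^M, computed to stay accurate for tiny e^-Z
  p <- -expm1(m * log1p(-exp(-z)))
  p <- min(max(p, 0), 1)
  structure(
    list(method = "LS", period_grid = rev(1 / freqs),
         statistic = rev(power), best_period = 1 / freqs[best],
         p_value = p, n_obs = length(t)),
    class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %s: best period %.4g (p = %.3g, %d bins)\n",
              x$method, x$best_period, x$p_value, x$n_obs))
  invisible(x)
}
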