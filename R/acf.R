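#' Autocorrelation of an emergence series with missing bins
#'
#' Pairwise-complete sample autocorrelation: the lag-l numerator sums over
#' all bin pairs `(t, t + l)` with both bins observed, using the overall
#' observed mean, and is normalized by the lag-0 (variance) term, so lag 0
#' is exactly 1.  This matches the usual missing-value autocorrelation of
#' count series with `NA` passed through rather than imputed.
#'
#' @param series An [emergence_series()].
#' @param max_lag Maximum lag in bins (`< length(series)`).
#' @return Numeric vector of correlations at lags `0..max_lag` (named).
#' @export
autocorrelate <- function(series, max_lag) {
  stopifnot(inherits(series, "emergence_series"))
  y <- series$counts
  n <- length(y)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0 || max_lag >= n)
    stop("`max_lag` must be in [0, length - 1]", call. = FALSE)
  obs <- !is.na(y)
  if (!any(obs))
    stop("all bins missing: autocorrelation undefined", call. = FALSE)
  yc <- y - mean(y[obs])
  denom <- sum(yc[obs]^2)
  if (denom == 0)
    stop("zero variance: autocorrelation undefined", call. = FALSE)
  r <- vapply(0:max_lag, function(l) {
    a <- yc[seq_len(n - l)]
    b <- yc[seq_len(n - l) + l]
    sum(a * b, na.rm = TRUE) / denom
  }, numeric(1))
  names(r) <- 0:max_lag
  r
}
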