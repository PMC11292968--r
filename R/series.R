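#' Construct an emergence-count series
#'
#' Binned counts of emerged adults, daily (`bin_width = 24`) or hourly
#' (`bin_width = 1`), with missing bins carried as `NA`.  Daily series
#' derived from T-cycles longer than 24 h have `NA` exactly on the solar
#' days without a light-to-dark transition.
#'
#' @param counts Numeric vector of non-negative integer counts; `NA` marks
#'   missing bins.
#' @param bin_width Bin width in hours (24 for daily, 1 for hourly).
#' @param start_index Index (day or hour number) of the first bin.
#' @param alignment `"solar_day"` for laboratory-time series,
#'   `"zeitgeber_time"` after ZT alignment.
#' @param regime Optional [light_regime()] the series was recorded under.
#' @param label Free-text series label (replicate/year).
#' @return An object of class `emergence_series`.
#' @export
emergence_series <- function(counts, bin_width = 24, start_index = 0,
                             alignment = c("solar_day", "zeitgeber_time"),
                             regime = NULL, label = "") {
  alignment <- match.arg(alignment)
  if (length(counts) < 1L) stop("`counts` must have length >= 1", call. = FALSE)
  counts <- as.numeric(counts)
  obs <- counts[!is.na(counts)]
  if (any(obs < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(obs != round(obs))) stop("counts must be integers", call. = FALSE)
  if (!is.null(regime)) stopifnot(inherits(regime, "light_regime"))
  structure(
    list(counts = counts, bin_width = as.numeric(bin_width),
         start_index = as.numeric(start_index), alignment = alignment,
         regime = regime, label = as.character(label)),
    class = "emergence_series")
}

#' @export
print.emergence_series <- function(x, ...) {
  cat(sprintf(
    "<emergence_series> '%s': %d bins of %g h from %s %g (%d missing, total %g)\n",
    x$label, length(x$counts), x$bin_width,
    if (x$bin_width == 24) "day" else "hour",
    x$start_index, sum(is.na(x$counts)), sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.emergence_series <- function(x) length(x$counts)

# Bin indices (day or hour numbers) of an emergence series.
series_index <- function(x) x$start_index + seq_along(x$counts) - 1

#' Assign emergence events to 24-h solar days
#'
#' Each event is credited to the solar (24-h) day containing the most recent
#' light-to-dark transition at or before the event, because emergence
#' happens right before lights-off.  Under T-cycles longer than 24 h some
#' solar days contain no light-to-dark transition; those days carry no
#' information and are masked `NA`.
#'
#' @param events Data frame with columns `time` (hours since experiment
#'   start) and `count` (positive integers), sorted by time.
#' @param regime A [light_regime()] with `mode = "LD"`.
#' @param n_days Number of solar days the output series spans (days
#'   `0 .. n_days - 1`).
#' @return A daily [emergence_series()] of length `n_days`.
#' @export
assign_to_solar_days <- function(events, regime, n_days) {
  stopifnot(inherits(regime, "light_regime"))
  if (regime$mode != "LD")
    stop("day assignment requires an LD regime (unsupported regime)",
         call. = FALSE)
  if (!all(c("time", "count") %in% names(events)))
    stop("`events` needs columns `time` and `count`", call. = FALSE)
  if (nrow(events) && any(events$count <= 0))
    stop("event counts must be positive", call. = FALSE)
  n_days <- as.integer(n_days)
  onsets <- dark_onsets(regime, n_days * 24)
  onset_day <- floor(onsets / 24)
  counts <- rep(NA_real_, n_days)
  has_onset <- unique(onset_day[onset_day >= 0 & onset_day < n_days])
  counts[has_onset + 1L] <- 0
  if (nrow(events)) {
    # index of most recent dark onset at or before each event
    i <- findInterval(events$time, onsets)
    keep <- i >= 1L
    if (any(keep)) {
      d <- onset_day[i[keep]]
      ok <- d >= 0 & d < n_days
      tab <- tapply(events$count[keep][ok], d[ok], sum)
      counts[as.integer(names(tab)) + 1L] <- counts[as.integer(names(tab)) + 1L] +
        as.numeric(tab)
    }
  }
  emergence_series(counts, bin_width = 24, start_index = 0,
                   regime = regime, label = "")
}

#' Window a daily series to the free-running analysis window
#'
#' The circasemilunar analysis window drops the first 30 days of the
#' experimental phase (emergence there is developmentally predetermined and
#' partial peaks would bias the estimate) and keeps days 31 to 112
#' inclusive: 82 days.  Shorter inputs are right-padded with `NA` to day
#' 112.
#'
#' @param series A daily [emergence_series()] starting at day 31 or
#'   earlier.
#' @param first_day,last_day Window bounds in the series' day numbering.
#' @return An [emergence_series()] of exactly
#'   `last_day - first_day + 1` bins (82 by default).
#' @export
window_semilunar <- function(series, first_day = 31, last_day = 112) {
  stopifnot(inherits(series, "emergence_series"))
  if (series$bin_width != 24)
    stop("windowing is defined for daily series", call. = FALSE)
  if (series$start_index > first_day)
    stop("series starts after day ", first_day,
         "; cannot recover the analysis window", call. = FALSE)
  idx <- series_index(series)
  want <- first_day:last_day
  pos <- match(want, idx)
  counts <- ifelse(is.na(pos), NA_real_, series$counts[pos])
  emergence_series(counts, bin_width = 24, start_index = first_day,
                   alignment = series$alignment, regime = series$regime,
                   label = series$label)
}

#' Align an hourly series to zeitgeber time
#'
#' Circularly shifts hourly bins so that the midpoint of the dark phase
#' maps to ZT 0 (middle of the night defines zeitgeber time 0).  The total
#' count is conserved.
#'
#' @param series An hourly [emergence_series()].
#' @param regime The [light_regime()] supplying lights-on phase; defaults
#'   to the regime attached to the series.
#' @return An hourly series with `alignment = "zeitgeber_time"`.
#' @export
zt_align <- function(series, regime = series$regime) {
  stopifnot(inherits(series, "emergence_series"))
  if (series$bin_width != 1)
    stop("ZT alignment is defined for hourly series", call. = FALSE)
  if (is.null(regime))
    stop("a light regime with a known lights-on phase is required",
         call. = FALSE)
  if (series$alignment == "zeitgeber_time") return(series)
  shift <- floor(mid_dark(regime)) %% 24
  n <- length(series$counts)
  # bin at absolute hour h moves to ZT (h - shift); rotate left by `shift`
  new <- series$counts[((seq_len(n) - 1 + shift) %% n) + 1]
  emergence_series(new, bin_width = 1, start_index = series$start_index,
                   alignment = "zeitgeber_time", regime = regime,
                   label = series$label)
}

#' Fold an hourly series into a phase profile
#'
#' Sums counts per phase bin over all cycles of `fold_period` hours,
#' skipping missing bins; the grand total is conserved.  Folding at 24 h
#' gives the diel emergence profile used to read off the phase of
#' emergence (e.g. a peak at ZT 18).
#'
#' @param series Hourly [emergence_series()].
#' @param fold_period Positive integer number of hours to fold at.
#' @return Named numeric vector of length `fold_period`; element `j`
#'   sums counts at hours congruent to `j - 1` modulo `fold_period`.
#' @export
hourly_profile <- function(series, fold_period = 24) {
  stopifnot(inherits(series, "emergence_series"))
  if (series$bin_width != 1)
    stop("profiles are defined for hourly series", call. = FALSE)
  fold_period <- as.integer(fold_period)
  if (is.na(fold_period) || fold_period <= 0)
    stop("`fold_period` must be a positive integer number of hours",
         call. = FALSE)
  phase <- series_index(series) %% fold_period
  out <- vapply(0:(fold_period - 1), function(j)
    sum(series$counts[phase == j], na.rm = TRUE), numeric(1))
  names(out) <- 0:(fold_period - 1)
  out
}
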