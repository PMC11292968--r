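#' Configuration for the emergence simulator
#'
#' Parameters of the generative population model used to produce
#' ground-truth emergence series under each clock architecture.
#'
#' Under the counter architecture the circasemilunar period equals
#' `counter_target_C` circadian cycles; the free-running count defaults to
#' 13 (free-running periods of 12-13 days are shorter than the entrained
#' 15-day period), while the entrained count is 15.  The oscillator
#' architecture has a fixed intrinsic period `oscillator_period_days`
#' regardless of the diel cycle.  The beat architecture emerges where a
#' circadian and a circatidal oscillation (tidal period `beat_k / 2`, with
#' `beat_k` the lunar-day length in hours) peak together.
#'
#' @param hypothesis `"counter"`, `"oscillator"` or `"beat"`.
#' @param n_individuals Number of midges in the population.
#' @param n_days Length of the experimental phase in days (default 113
#'   covers days 0-112 so the day 31-112 analysis window is complete).
#' @param counter_target_C Circadian cycles counted per semilunar cycle.
#' @param oscillator_period_days Intrinsic circasemilunar oscillator
#'   period, days.
#' @param beat_k Lunar-day length in hours (24.8 entrained).
#' @param circadian_intrinsic_period Free-running circadian period, hours.
#' @param entrainment_range Lower/upper bound (hours) of the circadian
#'   range of entrainment; half-open `[lower, upper)`, so the default
#'   `c(20, 28)` places a 28-h cycle outside (emergence is arrhythmic at
#'   T = 28 and 30 h).
#' @param ll_phase_diffusion_sd Per-day standard deviation (hours) of
#'   circadian phase drift between individuals in constant conditions;
#'   0 keeps the population synchronized, > 0 desynchronizes it.
#' @param emergence_gate_width Width (hours) of the circadian emergence
#'   window ending at the light-to-dark transition.
#' @param readiness_sd Standard deviation (days) of developmental
#'   readiness around each semilunar cohort peak.
#' @param first_peak_day Day of the first cohort peak.
#' @param count_noise `"poisson"` resamples each bin count Poisson with
#'   the deterministic count as mean; `"none"` keeps raw tallies.
#' @param seed Integer RNG seed; simulation is deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(hypothesis = c("counter", "oscillator", "beat"),
                       n_individuals = 400, n_days = 113,
                       counter_target_C = 13, oscillator_period_days = 15,
                       beat_k = 24.8, circadian_intrinsic_period = 24.5,
                       entrainment_range = c(20, 28),
                       ll_phase_diffusion_sd = 0,
                       emergence_gate_width = 2, readiness_sd = 1.5,
                       first_peak_day = 5,
                       count_noise = c("poisson", "none"), seed = 1) {
  hypothesis <- match.arg(hypothesis)
  count_noise <- match.arg(count_noise)
  stopifnot(n_individuals >= 1, n_days >= 1, counter_target_C >= 1,
            oscillator_period_days > 0, beat_k > 0,
            circadian_intrinsic_period > 0,
            length(entrainment_range) == 2,
            entrainment_range[1] < entrainment_range[2],
            ll_phase_diffusion_sd >= 0, emergence_gate_width > 0,
            readiness_sd >= 0)
  structure(
    list(hypothesis = hypothesis,
         n_individuals = as.integer(n_individuals),
         n_days = as.integer(n_days),
         counter_target_C = counter_target_C,
         oscillator_period_days = oscillator_period_days,
         beat_k = beat_k,
         circadian_intrinsic_period = circadian_intrinsic_period,
         entrainment_range = as.numeric(entrainment_range),
         ll_phase_diffusion_sd = ll_phase_diffusion_sd,
         emergence_gate_width = emergence_gate_width,
         readiness_sd = readiness_sd,
         first_peak_day = first_peak_day,
         count_noise = count_noise,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Effective circadian period under a light regime
#'
#' Under an LD cycle the circadian clock locks to the smallest integer
#' multiple `m * T` of the cycle length that falls inside its range of
#' entrainment (frequency demultiplication: under LD 6:6 it entrains to
#' every second cycle and keeps a 24-h period).  If no multiple falls in
#' range the clock cannot entrain and the effective period is undefined
#' (`NULL`).  In constant conditions the clock free-runs at its intrinsic
#' period.
#'
#' @param regime A [light_regime()].
#' @param config A [sim_config()] supplying the entrainment range and
#'   intrinsic period.
#' @return Period in hours, or `NULL` when the regime is outside the range
#'   of entrainment.  The range is half-open `[lower, upper)`.
#' @examples
#' cfg <- sim_config()
#' effective_circadian_period(light_regime(12), cfg)  # 24 (m = 2)
#' effective_circadian_period(light_regime(30), cfg)  # NULL
#' @export
effective_circadian_period <- function(regime, config) {
  stopifnot(inherits(regime, "light_regime"), inherits(config, "sim_config"))
  if (regime$mode != "LD") return(config$circadian_intrinsic_period)
  rng <- config$entrainment_range
  m <- seq_len(ceiling(rng[2] / regime$cycle_length_T))
  cand <- m * regime$cycle_length_T
  ok <- cand >= rng[1] & cand < rng[2]
  if (!any(ok)) return(NULL)
  min(cand[ok])
}

#' Circasemilunar period predicted by a clock architecture
#'
#' Counter: `C` circadian cycles, i.e. `C * effective_period / 24` days --
#' undefined when the circadian clock cannot entrain.  Oscillator: the
#' intrinsic period, independent of the diel cycle.  Beat: the envelope
#' period of superimposed circadian and circatidal oscillations,
#' `T * k / (2 |T - k|)` hours (see [beat_period()]).
#'
#' @param hypothesis `"counter"`, `"oscillator"` or `"beat"`.
#' @param regime A [light_regime()].
#' @param config A [sim_config()].
#' @return Predicted period in days, or `NULL` where undefined.
#' @examples
#' cfg <- sim_config(counter_target_C = 15)
#' expected_semilunar_period("counter", light_regime(26), cfg)  # 16.25
#' @export
expected_semilunar_period <- function(hypothesis = c("counter", "oscillator",
                                                     "beat"),
                                      regime, config) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(regime, "light_regime"), inherits(config, "sim_config"))
  switch(hypothesis,
    counter = {
      tc <- effective_circadian_period(regime, config)
      if (is.null(tc)) NULL else config$counter_target_C * tc / 24
    },
    oscillator = config$oscillator_period_days,
    beat = beat_period(regime$cycle_length_T, config$beat_k))
}

# Is the circadian clock of the population synchronized under this regime?
circadian_synchronized <- function(regime, config) {
  if (regime$mode == "LD")
    !is.null(effective_circadian_period(regime, config))
  else
    config$ll_phase_diffusion_sd == 0
}

# Developmental readiness times (hours) for a cohort-structured population:
# mixed-age cohorts cluster every `tau_sl` days; NULL `tau_sl` means no
# semilunar structure (uniform readiness, arrhythmic output).
readiness_times <- function(config, tau_sl) {
  horizon <- config$n_days * 24
  n <- config$n_individuals
  if (is.null(tau_sl)) return(stats::runif(n, 0, horizon))
  peaks <- seq(config$first_peak_day, config$n_days, by = tau_sl)
  pk <- peaks[sample.int(length(peaks), n, replace = TRUE)]
  days <- pmax(0, pk + stats::rnorm(n, 0, config$readiness_sd))
  days * 24
}

# Snap readiness times to circadian emergence gates. Gates sit at the end
# of a window of width `gate_width` closing at a light-to-dark transition
# (entrained) or at the free-running circadian phase (constant conditions).
gate_times <- function(readiness, regime, config) {
  horizon <- config$n_days * 24
  tc <- effective_circadian_period(regime, config)
  if (regime$mode == "LD") {
    onsets <- dark_onsets(regime, horizon + 2 * tc)
    stride <- max(1L, round(tc / regime$cycle_length_T))
    gates <- onsets[seq(1L, length(onsets), by = stride)]
  } else {
    gates <- seq(tc, horizon + 2 * tc, by = tc)
  }
  gi <- pmin(findInterval(readiness, gates) + 1L, length(gates))
  gates[gi] - stats::runif(length(readiness), 0, config$emergence_gate_width)
}

# Emergence times when the population's circadian clocks have drifted out
# of phase: each individual keeps a private uniform circadian phase.
desync_times <- function(readiness, config) {
  tc <- config$circadian_intrinsic_period
  phase <- stats::runif(length(readiness), 0, tc)
  readiness + ((phase - readiness) %% tc)
}

sim_emergence_times <- function(config, regime) {
  sync <- circadian_synchronized(regime, config)
  tau_sl <- switch(config$hypothesis,
    counter = if (sync) expected_semilunar_period("counter", regime, config)
              else NULL,
    oscillator = config$oscillator_period_days,
    stop("internal: beat handled separately"))
  readiness <- readiness_times(config, tau_sl)
  if (is.null(tau_sl) && !sync) return(readiness)      # fully arrhythmic
  if (sync) gate_times(readiness, regime, config)
  else desync_times(readiness, config)                 # daily rhythm only
}

# Beat architecture: emergence propensity is the thresholded product of a
# circadian oscillation (effective circadian period) and a circatidal
# oscillation (period k/2 for a lunar day of k hours); each factor is
# rectified above `threshold` so the gate opens only near the oscillation
# peak, and individuals emerge where the two gates coincide, which recurs
# with the beat period T*k/(2|T-k|) hours.
sim_emergence_times_beat <- function(config, regime, tidal_amplitude = 1,
                                     threshold = 0.5) {
  if (regime$mode == "LD" &&
      isTRUE(all.equal(regime$cycle_length_T, config$beat_k)))
    stop("beat period undefined: T equals the lunar-day length k",
         call. = FALSE)
  if (!circadian_synchronized(regime, config)) {
    horizon <- config$n_days * 24
    return(stats::runif(config$n_individuals, 0, horizon))
  }
  tc <- effective_circadian_period(regime, config)
  horizon <- config$n_days * 24
  t <- seq(0.5, horizon - 0.5, by = 1)
  anchor <- if (regime$mode == "LD") dark_onsets(regime, horizon)[1] else 0
  gate <- function(x) pmax(0, x - threshold) / (1 - threshold)
  circ <- cos(2 * pi * (t - anchor) / tc)
  tidal <- cos(2 * pi * (t - anchor) / (config$beat_k / 2))
  w <- gate(circ) * gate((1 - tidal_amplitude) + tidal_amplitude * tidal)
  pick <- sample.int(length(t), config$n_individuals, replace = TRUE, prob = w)
  t[pick] + stats::runif(config$n_individuals, -0.5, 0.5)
}

#' Simulate a population emergence experiment
#'
#' Generates one emergence event per individual.  Individuals carry a
#' developmental readiness time drawn from mixed-age cohorts clustered
#' every predicted semilunar period, and emerge at the first circadian
#' gate (a window ending at the light-to-dark transition, or their
#' free-running phase in constant conditions) after readiness.  When the
#' architecture predicts no rhythm (counter outside the range of
#' entrainment, or any architecture with a desynchronized circadian clock)
#' readiness is uniform and the output is arrhythmic -- that is a valid
#' scientific outcome, not an error.  Counts are binned hourly and, under
#' LD, assigned to solar days via [assign_to_solar_days()]; in constant
#' conditions daily bins are plain 24-h bins.  Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param regime A [light_regime()].
#' @param tidal_amplitude Amplitude in `[0, 1]` of the circatidal
#'   component of the beat architecture (1 = full beat; 0 degenerates to a
#'   pure circadian rhythm with no semilunar structure).
#' @return A list with elements `daily` and `hourly`
#'   ([emergence_series()]), `events` (data frame of emergence times),
#'   `config` and `regime`.
#' @export
simulate_population <- function(config, regime, tidal_amplitude = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(regime, "light_regime"))
  with_seed(config$seed, {
    times <- if (config$hypothesis == "beat")
      sim_emergence_times_beat(config, regime, tidal_amplitude)
    else
      sim_emergence_times(config, regime)
    horizon <- config$n_days * 24
    times <- sort(times[times >= 0 & times < horizon])
    events <- data.frame(time = times, count = rep(1L, length(times)))

    hourly_counts <- tabulate(floor(times) + 1L, nbins = horizon)
    lab <- sprintf("%s_T%g_seed%d", config$hypothesis,
                   if (regime$mode == "LD") regime$cycle_length_T else NA,
                   config$seed)
    if (regime$mode != "LD")
      lab <- sprintf("%s_%s_seed%d", config$hypothesis, regime$mode,
                     config$seed)

    daily <- if (regime$mode == "LD") {
      # the census happens in the light phase after emergence, so the
      # day-assignment events sit just after the gate the midges used
      census <- data.frame(time = times + config$emergence_gate_width,
                           count = events$count)
      assign_to_solar_days(census, regime, config$n_days)
    } else {
      emergence_series(tabulate(floor(times / 24) + 1L,
                                nbins = config$n_days),
                       bin_width = 24, start_index = 0, regime = regime)
    }
    daily$label <- lab
    hourly <- emergence_series(hourly_counts, bin_width = 1,
                               start_index = 0, regime = regime,
                               label = lab)
    if (config$count_noise == "poisson") {
      daily$counts <- noisy_counts(daily$counts)
      hourly$counts <- noisy_counts(hourly$counts)
    }
    list(daily = daily, hourly = hourly, events = events,
         config = config, regime = regime)
  })
}

#' @rdname simulate_population
#' @export
simulate_beat_population <- function(config, regime, tidal_amplitude = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hypothesis != "beat")
    stop("`config$hypothesis` must be \"beat\"", call. = FALSE)
  simulate_population(config, regime, tidal_amplitude = tidal_amplitude)
}

# Poisson resampling of binned counts, preserving the missing mask.
noisy_counts <- function(counts) {
  obs <- !is.na(counts)
  counts[obs] <- stats::rpois(sum(obs), counts[obs])
  counts
}
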