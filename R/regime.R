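#' Describe a diel light regime (T-cycle)
#'
#' A light regime is the diel cycle an emergence experiment runs under: a
#' light-dark (LD) cycle of total length `cycle_length_T` hours, constant
#' light (LL) or constant darkness (DD).  LD 6:6 is encoded as
#' `cycle_length_T = 12, light_fraction = 0.5`; LD 13:13 as
#' `cycle_length_T = 26, light_fraction = 0.5`; and so on.
#'
#' @param cycle_length_T Total cycle length T in hours (> 0).
#' @param light_fraction Fraction of the cycle spent in light, in `[0, 1]`.
#'   Ignored for `mode = "LL"` or `"DD"`.
#' @param mode One of `"LD"`, `"LL"`, `"DD"`.
#' @param phase_origin Clock time (hours since experiment start) of the
#'   first lights-on.
#' @param vibration Logical; whether tidal vibration entrainment is on.
#'   Free-running circasemilunar experiments have `vibration = FALSE`.
#' @return An object of class `light_regime`.
#' @examples
#' light_regime(26)            # LD 13:13
#' light_regime(12)            # LD 6:6
#' light_regime(mode = "LL")
#' @export
light_regime <- function(cycle_length_T = 24, light_fraction = 0.5,
                         mode = c("LD", "LL", "DD"), phase_origin = 0,
                         vibration = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(cycle_length_T) || length(cycle_length_T) != 1L ||
      !is.finite(cycle_length_T) || cycle_length_T <= 0)
    stop("`cycle_length_T` must be a single positive number of hours",
         call. = FALSE)
  if (!is.numeric(light_fraction) || length(light_fraction) != 1L ||
      light_fraction < 0 || light_fraction > 1)
    stop("`light_fraction` must be in [0, 1]", call. = FALSE)
  structure(
    list(cycle_length_T = as.numeric(cycle_length_T),
         light_fraction = as.numeric(light_fraction),
         mode = mode,
         phase_origin = as.numeric(phase_origin),
         vibration = isTRUE(vibration)),
    class = "light_regime")
}

#' @export
print.light_regime <- function(x, ...) {
  if (x$mode == "LD") {
    half <- x$cycle_length_T * c(x$light_fraction, 1 - x$light_fraction)
    cat(sprintf("<light_regime> LD %g:%g (T = %g h), lights-on at h %g%s\n",
                half[1], half[2], x$cycle_length_T, x$phase_origin,
                if (x$vibration) ", tidal vibration" else ""))
  } else {
    cat(sprintf("<light_regime> %s%s\n", x$mode,
                if (x$vibration) ", tidal vibration" else ""))
  }
  invisible(x)
}

# Times (hours since start) of light-to-dark transitions up to `horizon`.
# Emergence is referenced to lights-off: midges emerge right before the
# light-dark transition, so day assignment and circadian gating both key on
# dark onsets, never on dark-to-light transitions.
dark_onsets <- function(regime, horizon) {
  stopifnot(inherits(regime, "light_regime"))
  if (regime$mode != "LD")
    stop("dark onsets are undefined for mode ", regime$mode, call. = FALSE)
  first <- regime$phase_origin + regime$light_fraction * regime$cycle_length_T
  if (horizon < first) return(numeric(0))
  seq(first, horizon, by = regime$cycle_length_T)
}

# Midpoint of the dark phase, as clock hours (used for ZT alignment;
# middle of the night defines zeitgeber time 0).
mid_dark <- function(regime) {
  if (regime$mode != "LD")
    stop("mid-dark is undefined for mode ", regime$mode, call. = FALSE)
  regime$phase_origin +
    regime$cycle_length_T * (regime$light_fraction +
                               (1 - regime$light_fraction) / 2)
}
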