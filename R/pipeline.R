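#' T-cycle experiment recipe
#'
#' End-to-end analysis of the period-versus-T-cycle experiment: each daily
#' series is windowed to days 31-112, periods are estimated
#' ([estimate_periods()], one BH family), significant series with
#' T in `fit_t` become period observations, and the three clock
#' architectures are compared by AICc.  Input is either a list of recorded
#' daily series (with attached LD regimes) or, when `series = NULL`, a
#' simulated experiment generated from `sim` at the given T-cycle lengths
#' and replicate counts.
#'
#' @param series Named list of daily [emergence_series()] (regimes
#'   attached), or `NULL` to simulate.
#' @param sim A [sim_config()] template used when simulating (its seed is
#'   re-derived per replicate from `seed`).
#' @param t_cycles,replicates T-cycle lengths (hours) and replicate counts
#'   used when simulating; defaults mirror the experimental design (five
#'   series at T = 24 including the constant-light control, three at 22
#'   and 26, one at 28 and 30).
#' @param fit_t T values whose significant periods enter the model
#'   comparison (only T-cycles inside the circadian range of entrainment
#'   yield free-running periods).
#' @param alpha Significance level on BH-adjusted q-values.
#' @param seed Master seed for the simulated branch.
#' @param out_dir Optional directory; when given, the report is written as
#'   delimited text plus a JSON twin.
#' @return A list of class `clock_report`: `experiment`, `periods` (the
#'   per-series table), `observations` (significant rows used for
#'   fitting), `comparison` (a `hypothesis_comparison`, or `NULL`),
#'   `status` (0 = success, 4 = no rhythmic series), `config`, `seed`.
#' @export
run_tcycle <- function(series = NULL, sim = sim_config(),
                       t_cycles = c(22, 24, 26, 28, 30),
                       replicates = c(3, 5, 3, 1, 1),
                       fit_t = c(22, 24, 26), alpha = 0.05, seed = 1,
                       out_dir = NULL) {
  if (is.null(series)) {
    stopifnot(length(t_cycles) == length(replicates))
    series <- list()
    i <- 0L
    for (j in seq_along(t_cycles)) {
      for (r in seq_len(replicates[j])) {
        i <- i + 1L
        cfg <- sim
        cfg$seed <- derive_seed(seed, i)
        pop <- simulate_population(cfg, light_regime(t_cycles[j]))
        series[[pop$daily$label]] <- pop$daily
      }
    }
  }
  if (!length(series)) stop("no input series (usage error)", call. = FALSE)
  windowed <- lapply(series, window_semilunar)
  periods <- estimate_periods(windowed, alpha = alpha)
  obs <- periods[periods$significant & periods$T %in% fit_t, , drop = FALSE]
  comparison <- NULL
  status <- 0L
  if (nrow(obs) == 0L) {
    status <- 4L
  } else {
    comparison <- tryCatch(compare_hypotheses(obs),
                           error = function(e) { status <<- 4L; NULL })
  }
  report <- structure(
    list(experiment = "tcycle", periods = periods, observations = obs,
         comparison = comparison, status = status,
         config = list(t_cycles = t_cycles, replicates = replicates,
                       fit_t = fit_t, alpha = alpha,
                       sim = if (is.null(series)) unclass(sim) else NULL),
         seed = seed),
    class = "clock_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Frequency-demultiplication recipe (LD 6:6 versus LD 12:12)
#'
#' Simulates (or accepts) hourly and daily emergence under T = 12 h
#' (LD 6:6) and T = 24 h, estimates the circadian period of each hourly
#' series (Lomb-Scargle; series longer than the JTK limit proceed
#' LS-only) and the circasemilunar period of each windowed daily series,
#' and flags frequency demultiplication when the LD 6:6 circadian period
#' stays near 24 h while the circasemilunar period stays within 2 days of
#' the LD 12:12 value.
#'
#' @param inputs Optional list with elements `hourly12`, `hourly24`
#'   (hourly series, ZT-aligned or with regimes attached) and `daily12`,
#'   `daily24`; `NULL` simulates from `sim`.
#' @inheritParams run_tcycle
#' @param circadian_scan Circadian scan range in hours.
#' @return A `clock_report` with `circadian` and `semilunar` tables and a
#'   logical `demultiplication` flag.
#' @export
run_demultiplication <- function(inputs = NULL, sim = sim_config(),
                                 circadian_scan = c(20, 28), alpha = 0.05,
                                 seed = 1, out_dir = NULL) {
  if (is.null(inputs)) {
    mk <- function(T, i) {
      cfg <- sim
      cfg$seed <- derive_seed(seed, i)
      simulate_population(cfg, light_regime(T))
    }
    p12 <- mk(12, 1L)
    p24 <- mk(24, 2L)
    inputs <- list(hourly12 = zt_align(p12$hourly),
                   hourly24 = zt_align(p24$hourly),
                   daily12 = p12$daily, daily24 = p24$daily)
  }
  need <- c("hourly12", "hourly24", "daily12", "daily24")
  if (!all(need %in% names(inputs)))
    stop("inputs must provide ", paste(need, collapse = ", "),
         " (usage error)", call. = FALSE)
  circ <- estimate_periods(inputs[c("hourly12", "hourly24")],
                           scan = circadian_scan, alpha = alpha)
  semi <- estimate_periods(lapply(inputs[c("daily12", "daily24")],
                                  window_semilunar), alpha = alpha)
  tau12 <- circ$tau[1]
  demult <- isTRUE(circ$significant[1]) && abs(tau12 - 24) <= 1 &&
    abs(semi$tau[1] - semi$tau[2]) <= 2
  report <- structure(
    list(experiment = "ld66", circadian = circ, semilunar = semi,
         demultiplication = demult,
         status = if (any(circ$significant) || any(semi$significant))
           0L else 4L,
         config = list(circadian_scan = circadian_scan, alpha = alpha),
         seed = seed),
    class = "clock_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Constant-light desynchronization recipe
#'
#' Simulates (or accepts) hourly and daily emergence under constant light
#' and an LD 12:12 control, and reports the significance of the circadian
#' and circasemilunar rhythms in both conditions.  Hourly series longer
#' than the JTK length limit are analyzed with the Lomb-Scargle
#' periodogram alone.  The discriminating outcome: a counter clock loses
#' both rhythms when the circadian clock desynchronizes, an independent
#' oscillator keeps the circasemilunar rhythm.
#'
#' @param inputs Optional list with `hourly_ll`, `hourly_ld`, `daily_ll`,
#'   `daily_ld`; `NULL` simulates from `sim`.
#' @param ll_diffusion Per-day circadian phase-drift SD (hours) applied to
#'   the simulated LL branch.
#' @inheritParams run_demultiplication
#' @return A `clock_report` with `circadian` and `semilunar` tables
#'   (conditions LL and LD).
#' @export
run_ll <- function(inputs = NULL, sim = sim_config(), ll_diffusion = 3,
                   circadian_scan = c(20, 28), alpha = 0.05, seed = 1,
                   out_dir = NULL) {
  if (is.null(inputs)) {
    cfg_ll <- sim
    cfg_ll$ll_phase_diffusion_sd <- ll_diffusion
    cfg_ll$seed <- derive_seed(seed, 1L)
    cfg_ld <- sim
    cfg_ld$seed <- derive_seed(seed, 2L)
    pll <- simulate_population(cfg_ll, light_regime(mode = "LL"))
    pld <- simulate_population(cfg_ld, light_regime(24))
    inputs <- list(hourly_ll = pll$hourly, hourly_ld = zt_align(pld$hourly),
                   daily_ll = pll$daily, daily_ld = pld$daily)
  }
  need <- c("hourly_ll", "hourly_ld", "daily_ll", "daily_ld")
  if (!all(need %in% names(inputs)))
    stop("inputs must provide ", paste(need, collapse = ", "),
         " (usage error)", call. = FALSE)
  circ <- estimate_periods(inputs[c("hourly_ll", "hourly_ld")],
                           scan = circadian_scan, alpha = alpha)
  semi <- estimate_periods(lapply(inputs[c("daily_ll", "daily_ld")],
                                  window_semilunar), alpha = alpha)
  report <- structure(
    list(experiment = "ll", circadian = circ, semilunar = semi,
         status = if (any(circ$significant) || any(semi$significant))
           0L else 4L,
         config = list(ll_diffusion = ll_diffusion,
                       circadian_scan = circadian_scan, alpha = alpha),
         seed = seed),
    class = "clock_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.clock_report <- function(x, ...) {
  cat(sprintf("<clock_report> experiment '%s' (seed %s, status %d)\n",
              x$experiment, x$seed, x$status))
  for (nm in intersect(c("periods", "circadian", "semilunar"), names(x))) {
    cat(nm, ":\n", sep = "")
    tab <- x[[nm]]
    tab$tau <- round(tab$tau, 3)
    for (cc in c("ls_p", "jtk_p", "p", "q"))
      tab[[cc]] <- signif(tab[[cc]], 3)
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$comparison)) print(x$comparison)
  if (isTRUE(x$status == 4L)) cat("outcome: no rhythmic series\n")
  if (!is.null(x$demultiplication))
    cat("frequency demultiplication:", x$demultiplication, "\n")
  invisible(x)
}

#' Write a report as delimited text plus a JSON twin
#'
#' Every report embeds its full resolved configuration and seed, so
#' re-running the embedded configuration reproduces it exactly.
#'
#' @param report A `clock_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "clock_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in intersect(c("periods", "circadian", "semilunar"),
                       names(report))) {
    utils::write.table(report[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  if (!is.null(report$comparison))
    utils::write.table(report$comparison$table,
                       file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  twin <- report
  twin$comparison <- if (!is.null(report$comparison))
    report$comparison$table else NULL
  for (nm in c("periods", "circadian", "semilunar", "observations"))
    if (!is.null(twin[[nm]])) attr(twin[[nm]], "estimates") <- NULL
  jsonlite::write_json(unclass(twin),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}
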