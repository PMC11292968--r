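#' Beat period of superimposed circadian and circatidal oscillations
#'
#' Two oscillations with the diel period `T` and the tidal period `k / 2`
#' (half a lunar day of `k` hours) drift in and out of phase; their
#' coincidences recur with the beat period `T * k / (2 |T - k|)` hours.
#'
#' @param T Diel cycle length in hours.
#' @param k Lunar-day length in hours (24.8 when entrained).
#' @return Beat period in days.
#' @examples
#' beat_period(24, 24.8)  # 15.5 days
#' @export
beat_period <- function(T, k) {
  if (any(T <= 0) || any(k <= 0))
    stop("`T` and `k` must be positive", call. = FALSE)
  if (any(abs(T - k) < .Machine$double.eps^0.5 * pmax(T, k)))
    stop("beat period undefined: T equals k (period diverges)",
         call. = FALSE)
  T * k / (2 * abs(T - k)) / 24
}

new_hypothesis_fit <- function(name, params, obs, predictions, n_coef,
                               n_params_p) {
  residuals <- obs$tau - predictions
  rss <- sum(residuals^2)
  n <- nrow(obs)
  list(name = name, params = params, obs = obs,
       predictions = predictions, residuals = residuals, rss = rss,
       rse = sqrt(rss / (n - n_coef)), df_residual = n - n_coef,
       n_params_p = n_params_p, n = n)
}

check_obs <- function(obs, min_n) {
  if (!all(c("T", "tau") %in% names(obs)))
    stop("observations need columns `T` and `tau`", call. = FALSE)
  if ("significant" %in% names(obs)) obs <- obs[isTRUE_vec(obs$significant), ]
  if (nrow(obs) < min_n)
    stop("need at least ", min_n, " (significant) observations",
         call. = FALSE)
  obs
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Fit the day-counter model to period-versus-T data
#'
#' A counter goes through a fixed number of circadian steps, so the
#' circasemilunar period is linear in T-cycle length: ordinary least
#' squares of `tau` (days) on `T` (hours).  The slope expected when 15
#' entrained cycles are counted is 15/24 = 0.625 days per hour.
#'
#' @param obs Data frame of period observations with columns `T` (hours)
#'   and `tau` (days); rows with a `significant` column set to `FALSE`
#'   are dropped (only rhythmic series carry period information).
#' @return A `hypothesis_fit` list: `params` (`intercept`, `slope`,
#'   `slope_p`), predictions, residuals (`tau - prediction`), `rse`,
#'   `n_params_p` (3: intercept, slope, error SD).
#' @export
fit_counter <- function(obs) {
  obs <- check_obs(obs, 3L)
  if (length(unique(obs$T)) < 2L)
    stop("all T identical: slope is not identifiable", call. = FALSE)
  fit <- stats::lm(tau ~ T, data = obs)
  sm <- summary(fit)
  co <- stats::coef(sm)
  out <- new_hypothesis_fit(
    "counter",
    list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
         slope_p = unname(co[2, 4])),
    obs, unname(stats::fitted(fit)), n_coef = 2L, n_params_p = 3L)
  out$lm <- fit
  structure(out, class = "hypothesis_fit")
}

#' Fit the independent-oscillator model
#'
#' An autonomous circasemilunar oscillator is unaffected by T-cycle
#' length, so every observation is predicted by the mean observed period
#' (an intercept-only regression).
#'
#' @inheritParams fit_counter
#' @return A `hypothesis_fit` with `params = list(mean_tau)` and
#'   `n_params_p = 2` (mean, error SD).
#' @export
fit_oscillator <- function(obs) {
  obs <- check_obs(obs, 2L)
  m <- mean(obs$tau)
  structure(
    new_hypothesis_fit("oscillator", list(mean_tau = m), obs,
                       rep(m, nrow(obs)), n_coef = 1L, n_params_p = 2L),
    class = "hypothesis_fit")
}

#' Fit the beat model by nonlinear least squares over k
#'
#' Minimizes the residual sum of squares of [beat_period()] predictions
#' over the lunar-day length `k`.  The objective has poles wherever `k`
#' equals an observed `T`, so instead of an unguarded Gauss-Newton the
#' search runs a Brent minimization inside each subinterval of
#' `(k_lower, k_upper)` delimited by the observed `T` values and keeps the
#' best minimum; the result is compared against `k_start` so the returned
#' objective never exceeds the starting one.
#'
#' @inheritParams fit_counter
#' @param k_start Starting/reference value of `k` in hours.
#' @param k_lower,k_upper Search bounds for `k` in hours.
#' @return A `hypothesis_fit` with `params` (`k`, `k_se`, `k_p`) and
#'   `n_params_p = 2` (k, error SD).
#' @export
fit_beat <- function(obs, k_start = 24.8, k_lower = 12, k_upper = 40) {
  obs <- check_obs(obs, 2L)
  rss_at <- function(k) sum((obs$tau - beat_period(obs$T, k))^2)
  cuts <- sort(unique(c(k_lower, obs$T[obs$T > k_lower & obs$T < k_upper],
                        k_upper)))
  eps <- 1e-4
  cand <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i] + eps
    hi <- cuts[i + 1L] - eps
    if (hi <= lo) next
    cand[[length(cand) + 1L]] <- stats::optimize(rss_at, c(lo, hi),
                                                 tol = 1e-9)
  }
  if (!length(cand))
    stop("beat fit failed to converge: empty search domain", call. = FALSE)
  vals <- vapply(cand, function(o) o$objective, numeric(1))
  k_hat <- cand[[which.min(vals)]]$minimum
  if (!any(abs(obs$T - k_start) < eps) && rss_at(k_start) < min(vals))
    k_hat <- k_start
  pred <- beat_period(obs$T, k_hat)
  out <- new_hypothesis_fit("beat", list(k = k_hat), obs, pred,
                            n_coef = 1L, n_params_p = 2L)
  # Wald standard error from the linearized model at k_hat
  h <- 1e-5
  grad <- (beat_period(obs$T, k_hat + h) - beat_period(obs$T, k_hat - h)) /
    (2 * h)
  jj <- sum(grad^2)
  if (jj > 0 && out$df_residual > 0) {
    se <- out$rse / sqrt(jj)
    out$params$k_se <- se
    out$params$k_p <- 2 * stats::pt(-abs(k_hat / se), df = out$df_residual)
  } else {
    out$params$k_se <- NA_real_
    out$params$k_p <- NA_real_
  }
  structure(out, class = "hypothesis_fit")
}

#' @export
print.hypothesis_fit <- function(x, ...) {
  cat(sprintf("<hypothesis_fit> %s: rse = %.4g on %d df; params: %s\n",
              x$name, x$rse, x$df_residual,
              paste(sprintf("%s = %.4g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' Gaussian log-likelihood of a least-squares fit,
#' `lnL = -n/2 (log(2 pi) + log(rss / n) + 1)`, and
#' `AICc = -2 lnL + 2 p + 2 p (p + 1) / (n - p - 1)`, with `p` the number
#' of estimated parameters *including* the error standard deviation
#' (counter 3, oscillator 2, beat 2) -- the convention under which the
#' criterion values of standard `lm()`/`nls()` fits are reproduced.
#'
#' @param fit A `hypothesis_fit`.
#' @param n Sample size shared by the model comparison (defaults to the
#'   fit's own n).
#' @return The AICc value.
#' @export
aicc <- function(fit, n = fit$n) {
  p <- fit$n_params_p
  if (n - p - 1 <= 0)
    stop("AICc undefined: n <= p + 1", call. = FALSE)
  if (fit$rss <= 0)
    stop("degenerate likelihood: residual sum of squares is zero",
         call. = FALSE)
  loglik <- -n / 2 * (log(2 * pi) + log(fit$rss / n) + 1)
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights
#'
#' Relative likelihoods `w_i = exp(-D_i / 2) / sum_j exp(-D_j / 2)` with
#' `D_i = AICc_i - min(AICc)`; computed on the differences so the result
#' is numerically stable for large spreads.
#'
#' @param aiccs Numeric vector of (finite) AICc values.
#' @return Weights summing to 1, in input order.
#' @examples
#' akaike_weights(c(32.70, 38.35, 62.51))
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) < 1L || any(!is.finite(aiccs)))
    stop("AICc values must be finite", call. = FALSE)
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare counter, oscillator and beat fits on one observation set
#'
#' Fits all three clock architectures to the same (T, tau) observations,
#' computes residual standard errors, AICc on the shared sample size and
#' Akaike weights, and ranks models by ascending AICc (ties broken by
#' fewer parameters, then name).  A model whose fit fails (rank
#' deficiency, degenerate likelihood, non-convergence) is reported with
#' the error message instead of aborting the other fits.
#'
#' @inheritParams fit_counter
#' @param k_start Starting lunar-day length for the beat fit, hours.
#' @return A list of class `hypothesis_comparison`: `table` (data frame
#'   with `hypothesis`, `model`, `rse`, `aicc`, `weight`, ranked), `fits`
#'   (named list of `hypothesis_fit` or error messages), `n`.
#' @export
compare_hypotheses <- function(obs, k_start = 24.8) {
  fitters <- list(counter = fit_counter, oscillator = fit_oscillator,
                  beat = function(o) fit_beat(o, k_start = k_start))
  fits <- lapply(fitters, function(f) tryCatch(f(obs), error = identity))
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok))
    stop("no hypothesis could be fitted: ",
         conditionMessage(fits[[1]]), call. = FALSE)
  n <- unique(vapply(fits[ok], function(f) f$n, numeric(1)))
  stopifnot(length(n) == 1L)
  aics <- vapply(names(fits), function(nm) {
    if (!ok[[nm]]) return(NA_real_)
    tryCatch(aicc(fits[[nm]], n = n), error = function(e) NA_real_)
  }, numeric(1))
  w <- rep(NA_real_, length(aics))
  fin <- is.finite(aics)
  if (any(fin)) w[fin] <- akaike_weights(aics[fin])
  tab <- data.frame(
    hypothesis = names(fits),
    model = c(counter = "lm(tau ~ T)", oscillator = "lm(tau ~ 1)",
              beat = "nls(tau ~ beat(T, k))")[names(fits)],
    rse = vapply(names(fits), function(nm)
      if (ok[[nm]]) fits[[nm]]$rse else NA_real_, numeric(1)),
    aicc = aics, weight = w,
    n_params = vapply(names(fits), function(nm)
      if (ok[[nm]]) fits[[nm]]$n_params_p else NA_integer_, numeric(1)),
    error = vapply(names(fits), function(nm)
      if (ok[[nm]]) NA_character_ else conditionMessage(fits[[nm]]),
      character(1)),
    row.names = NULL)
  tab <- tab[order(is.na(tab$aicc), tab$aicc, tab$n_params,
                   tab$hypothesis), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, n = n),
            class = "hypothesis_comparison")
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  cat(sprintf("Model comparison on %d period observations:\n", x$n))
  tab <- x$table
  tab$rse <- round(tab$rse, 3)
  tab$aicc <- round(tab$aicc, 2)
  tab$weight <- signif(tab$weight, 3)
  print(tab[, c("hypothesis", "model", "rse", "aicc", "weight")],
        row.names = FALSE)
  invisible(x)
}
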