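#' Integrate Lomb-Scargle and JTK period calls meta2d-style
#'
#' The integrated period is the arithmetic mean of the periods reported by
#' the available methods; method p-values are combined by Fisher's method
#' (`X = -2 * sum(log p)` against a chi-square with `2 * n_methods`
#' degrees of freedom).  With a single method the period and p pass
#' through unchanged.
#'
#' @param ls Lomb-Scargle `periodogram` (required).
#' @param jtk JTK `periodogram`, or `NULL` when the method was unavailable
#'   (e.g. series longer than its length limit).
#' @return A list of class `period_estimate`: `ls`, `jtk`,
#'   `tau_integrated`, `p_fisher`, and placeholders `q_bh`/`significant`
#'   filled in by the family-level wrapper [estimate_periods()].
#' @export
integrate_meta2d <- function(ls, jtk = NULL) {
  stopifnot(inherits(ls, "periodogram"), ls$method == "LS")
  if (!is.null(jtk)) stopifnot(inherits(jtk, "periodogram"))
  periods <- c(ls$best_period, jtk$best_period)
  ps <- c(ls$p_value, jtk$p_value)
  if (length(ps) == 1L) {
    p <- ps
  } else {
    x <- -2 * sum(log(ps))
    p <- stats::pchisq(x, df = 2 * length(ps), lower.tail = FALSE)
  }
  structure(
    list(ls = ls, jtk = jtk, tau_integrated = mean(periods),
         p_fisher = p, q_bh = NA_real_, significant = NA),
    class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("<period_estimate> tau = %.4g, p = %.3g%s\n",
              x$tau_integrated, x$p_fisher,
              if (!is.na(x$q_bh)) sprintf(", q = %.3g (%s)", x$q_bh,
                                          if (isTRUE(x$significant))
                                            "significant" else "n.s.")
              else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Estimate the period of one emergence series
#'
#' Runs the Lomb-Scargle periodogram and, when the series is short enough,
#' the JTK-style scan over the integration range, then combines them with
#' [integrate_meta2d()].  Default scan ranges follow the standard
#' analysis: 3-20 days for daily (circasemilunar) series, 20-28 hours for
#' hourly (circadian) series.
#'
#' @param series An [emergence_series()].
#' @param scan Length-2 period range in bin units; `NULL` picks the
#'   layout default.
#' @param jtk_max_length Series longer than this use the Lomb-Scargle
#'   estimate alone.
#' @param oversampling Lomb-Scargle oversampling factor.
#' @return A `period_estimate` (see [integrate_meta2d()]).
#' @export
estimate_period <- function(series, scan = NULL, jtk_max_length = 1000,
                            oversampling = 4) {
  stopifnot(inherits(series, "emergence_series"))
  if (is.null(scan))
    scan <- if (series$bin_width == 24) c(3, 20) else c(20, 28)
  ls <- lomb_scargle(series, scan[1], scan[2], oversampling = oversampling)
  jtk <- jtk_cycle(series, scan[1], scan[2], jtk_max_length = jtk_max_length)
  integrate_meta2d(ls, jtk)
}

#' Estimate periods for a family of series with BH correction
#'
#' All series passed in one call form one multiple-testing family: their
#' Fisher-combined p-values are Benjamini-Hochberg adjusted together and a
#' series is called rhythmic when its q-value falls below `alpha`.
#'
#' @param series_list List of [emergence_series()].
#' @param scan,jtk_max_length,oversampling Passed to [estimate_period()].
#' @param alpha Significance level on the adjusted q-values (default
#'   0.05).
#' @return A data frame with one row per series: `label`, `T` (cycle
#'   length of an attached LD regime, else `NA`), `ls_period`, `ls_p`,
#'   `jtk_period`, `jtk_p`, `tau`, `p`, `q`, `significant`.  The
#'   underlying `period_estimate` objects are attached as attribute
#'   `"estimates"`.
#' @export
estimate_periods <- function(series_list, scan = NULL,
                             jtk_max_length = 1000, oversampling = 4,
                             alpha = 0.05) {
  stopifnot(length(series_list) >= 1L)
  ests <- lapply(series_list, estimate_period, scan = scan,
                 jtk_max_length = jtk_max_length,
                 oversampling = oversampling)
  p <- vapply(ests, function(e) e$p_fisher, numeric(1))
  q <- bh_adjust(p)
  for (i in seq_along(ests)) {
    ests[[i]]$q_bh <- q[i]
    ests[[i]]$significant <- q[i] < alpha
  }
  tab <- data.frame(
    label = vapply(series_list, function(s)
      if (nzchar(s$label)) s$label else NA_character_, character(1)),
    T = vapply(series_list, function(s) {
      if (!is.null(s$regime) && s$regime$mode == "LD")
        s$regime$cycle_length_T else NA_real_
    }, numeric(1)),
    ls_period = vapply(ests, function(e) e$ls$best_period, numeric(1)),
    ls_p = vapply(ests, function(e) e$ls$p_value, numeric(1)),
    jtk_period = vapply(ests, function(e)
      if (is.null(e$jtk)) NA_real_ else e$jtk$best_period, numeric(1)),
    jtk_p = vapply(ests, function(e)
      if (is.null(e$jtk)) NA_real_ else e$jtk$p_value, numeric(1)),
    tau = vapply(ests, function(e) e$tau_integrated, numeric(1)),
    p = p, q = q, significant = q < alpha,
    row.names = NULL)
  attr(tab, "estimates") <- ests
  tab
}
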