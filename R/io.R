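#' Read emergence series from delimited text
#'
#' Files carry a header row, a first column `day` (daily layout) or `hour`
#' (hourly layout), and one series per remaining column.  Comma or tab
#' separation is auto-detected; `NA`, `NaN` and empty cells mark missing
#' bins.  Gaps in the index column become missing bins.  A sidecar
#' key-value file (`<path>.regime.yaml`) can record the light regime per
#' series column (fields of [light_regime()], keyed by column name or under
#' `default`).
#'
#' @param path Path to the delimited text file.
#' @param layout `"daily"` or `"hourly"`.
#' @param regime_file Optional sidecar path; defaults to
#'   `<path>.regime.yaml` when that file exists.
#' @return A named list of [emergence_series()], one per count column.
#' @export
read_series <- function(path, layout = c("daily", "hourly"),
                        regime_file = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", "NaN", ""),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expected an index column plus at least one count column",
         call. = FALSE)
  idx <- df[[1L]]
  if (anyNA(idx) || any(diff(idx) <= 0))
    stop("bin indices must be strictly increasing", call. = FALSE)
  full <- seq(idx[1L], idx[length(idx)])
  pos <- match(full, idx)

  regimes <- read_regime_sidecar(path, regime_file)
  bw <- if (layout == "daily") 24 else 1
  out <- lapply(names(df)[-1L], function(lab) {
    counts <- df[[lab]][pos]
    obs <- counts[!is.na(counts)]
    if (any(obs < 0))
      stop("negative count in series '", lab, "'", call. = FALSE)
    reg <- regimes[[lab]]
    if (is.null(reg)) reg <- regimes[["default"]]
    emergence_series(counts, bin_width = bw, start_index = idx[1L],
                     regime = reg, label = lab)
  })
  names(out) <- names(df)[-1L]
  out
}

read_regime_sidecar <- function(path, regime_file = NULL) {
  if (is.null(regime_file)) {
    cand <- paste0(path, ".regime.yaml")
    if (file.exists(cand)) regime_file <- cand else return(list())
  }
  raw <- yaml::read_yaml(regime_file)
  lapply(raw, function(r) do.call(light_regime, r))
}

#' Write emergence series to delimited text
#'
#' Inverse of [read_series()]: writes one index column (`day` or `hour`)
#' plus one column per series, `NA` for missing bins, so that a
#' read-write-read cycle is bit-exact.  All series must share bin width,
#' start index and length.
#'
#' @param series A single [emergence_series()] or a named list of them.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sep = ",") {
  if (inherits(series, "emergence_series")) {
    series <- stats::setNames(list(series),
                              if (nzchar(series$label)) series$label else "series")
  }
  bw <- unique(vapply(series, function(s) s$bin_width, numeric(1)))
  st <- unique(vapply(series, function(s) s$start_index, numeric(1)))
  n <- unique(vapply(series, length, integer(1)))
  if (length(bw) != 1L || length(st) != 1L || length(n) != 1L)
    stop("all series must share bin width, start index and length",
         call. = FALSE)
  df <- data.frame(idx = st + seq_len(n) - 1)
  names(df) <- if (bw == 24) "day" else "hour"
  for (lab in names(series)) df[[lab]] <- series[[lab]]$counts
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Write a light-regime sidecar file
#'
#' @param regimes Named list of [light_regime()] objects (names are series
#'   column labels, or `default` to apply to all).
#' @param path Path of the series file the sidecar belongs to; the sidecar
#'   is written to `<path>.regime.yaml`.
#' @return The sidecar path, invisibly.
#' @export
write_regime_sidecar <- function(regimes, path) {
  stopifnot(all(vapply(regimes, inherits, logical(1), "light_regime")))
  out <- paste0(path, ".regime.yaml")
  yaml::write_yaml(lapply(regimes, unclass), out)
  invisible(out)
}
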