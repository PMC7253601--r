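# Sensorgram preprocessing: reference-baseline subtraction, per-phase
# Savitzky-Golay smoothing, and interstep (offset-continuity) alignment.
# None of these steps changes segment lengths or time stamps.

split_sensors <- function(set) {
  stopifnot(all(c("sensor_id", "phase", "t_s", "response") %in% names(set)))
  split(seq_len(nrow(set)), set$sensor_id)
}

#' Subtract the averaged secondary baseline from every sensor
#'
#' Averages the secondary-baseline segment pointwise across all sensors in
#' the set, summarises it as a linear trend in time, and subtracts that
#' trend (extrapolated over the full trace) from every sensor. This zeroes
#' a shared constant baseline exactly and removes common-mode linear drift;
#' sensor-specific step artifacts are handled later by
#' [interstep_align()].
#'
#' @param set A `sensorgram_set` tibble (see [simulate_set()] or
#'   [read_sensorgrams()]).
#' @return The set with adjusted `response`; phase labels, segment lengths
#'   and time stamps untouched.
#' @export
subtract_reference_baseline <- function(set) {
  idx <- split_sensors(set)
  base_traces <- lapply(idx, function(i) {
    sel <- set$phase[i] == "secondary_baseline"
    if (!any(sel)) {
      stop(sprintf("sensor '%s' has no secondary_baseline segment",
                   set$sensor_id[i][1]), call. = FALSE)
    }
    list(t = set$t_s[i][sel], y = set$response[i][sel])
  })
  n_min <- min(vapply(base_traces, function(b) length(b$y), integer(1)))
  ymat <- vapply(base_traces, function(b) b$y[seq_len(n_min)],
                 numeric(n_min))
  tvec <- base_traces[[1]]$t[seq_len(n_min)]
  ybar <- if (is.matrix(ymat)) rowMeans(ymat) else ymat
  trend <- if (n_min >= 2L) {
    lm(ybar ~ tvec)
  } else {
    NULL
  }
  correction <- if (is.null(trend)) {
    rep(ybar[1], nrow(set))
  } else {
    cf <- coef(trend)
    cf[1] + cf[2] * set$t_s
  }
  set$response <- set$response - correction
  set
}

largest_odd_window <- function(n, polyorder) {
  w <- if (n %% 2L == 0L) n - 1L else n
  if (w <= polyorder) return(NA_integer_)
  w
}

#' Savitzky-Golay smoothing of a sensorgram set
#'
#' Applies a Savitzky-Golay filter to each phase segment of each sensor
#' independently, so no information leaks across phase boundaries. Segments
#' shorter than the window use the largest valid odd window (with a
#' warning); segments too short for the polynomial order are left
#' untouched. Polynomials up to `polyorder` are reproduced exactly, so
#' constant and linear segments pass through unchanged.
#'
#' @param set A `sensorgram_set` tibble.
#' @param window Odd filter window length in samples (default 11).
#' @param polyorder Polynomial order, < `window` (default 3).
#' @return The set with smoothed `response`.
#' @export
smooth_savgol <- function(set, window = 11L, polyorder = 3L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  idx <- split_sensors(set)
  for (i in idx) {
    for (ph in unique(set$phase[i])) {
      j <- i[set$phase[i] == ph]
      n <- length(j)
      w <- window
      if (n < w) {
        w <- largest_odd_window(n, polyorder)
        if (is.na(w)) next
        warning(sprintf(
          "segment '%s'/%s shorter than window; using window %d",
          set$sensor_id[j][1], ph, w
        ), call. = FALSE)
      }
      set$response[j] <- signal::sgolayfilt(set$response[j],
                                            p = polyorder, n = w)
    }
  }
  set
}

#' Interstep alignment by offset continuity
#'
#' Removes piecewise-constant interstep artifacts: each phase of each
#' sensor is shifted by a constant so that its first sample coincides with
#' the last sample of the preceding phase. In particular the dissociation
#' start equals the association end exactly afterwards, which is the
#' alignment the 1:1 model assumes.
#'
#' @param set A `sensorgram_set` tibble with phases in schedule order.
#' @return The set with aligned `response`.
#' @export
interstep_align <- function(set) {
  idx <- split_sensors(set)
  for (i in idx) {
    phases <- unique(set$phase[i])
    if (length(phases) < 2L) next
    for (k in 2L:length(phases)) {
      prev <- i[set$phase[i] == phases[k - 1L]]
      cur <- i[set$phase[i] == phases[k]]
      if (length(prev) == 0L || length(cur) == 0L) {
        stop(sprintf("sensor '%s' has an empty phase",
                     set$sensor_id[i][1]), call. = FALSE)
      }
      offset <- set$response[cur[1]] - set$response[prev[length(prev)]]
      set$response[cur] <- set$response[cur] - offset
    }
  }
  set
}

#' Standard preprocessing pipeline
#'
#' Savitzky-Golay smoothing, then reference-baseline subtraction, then
#' interstep alignment — the preprocessing applied before [global_fit_1to1()].
#' Each step can be toggled.
#'
#' @param set A `sensorgram_set` tibble.
#' @param smooth,reference_subtract,align Logical toggles.
#' @param window,polyorder Savitzky-Golay settings (see [smooth_savgol()]).
#' @return The preprocessed set.
#' @export
preprocess_set <- function(set, smooth = TRUE, reference_subtract = TRUE,
                           align = TRUE, window = 11L, polyorder = 3L) {
  if (smooth) set <- smooth_savgol(set, window, polyorder)
  if (reference_subtract) set <- subtract_reference_baseline(set)
  if (align) set <- interstep_align(set)
  set
}
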