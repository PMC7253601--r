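# Pseudo-first-order segment fits and the global 1:1 Langmuir fit.

segment_data <- function(trace, phase) {
  sel <- trace$phase == phase
  if (!any(sel)) {
    stop(sprintf("trace has no '%s' segment", phase), call. = FALSE)
  }
  t <- trace$t_s[sel]
  list(t = t - t[1], y = trace$response[sel])
}

new_segment_fit <- function(y0, A, rate, rate_se = NA_real_,
                            residual_sd = NA_real_, converged = FALSE,
                            n = NA_integer_) {
  structure(
    list(y0 = y0, A = A, rate = rate, rate_se = rate_se,
         residual_sd = residual_sd, converged = converged, n = n),
    class = "segment_fit"
  )
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf(
    "<segment_fit> rate = %.4g /s (se %.2g), A = %.4g, Y0 = %.4g, converged = %s\n",
    x$rate, x$rate_se, x$A, x$y0, x$converged
  ))
  invisible(x)
}

# Shared machinery for the two exponential segment fits.
# form = "rise": Y = Y0 + A (1 - exp(-k t));  "decay": Y = Y0 + A exp(-k t)
fit_exponential_segment <- function(t, y, form) {
  n <- length(y)
  if (n < 10L) stop("segment must contain >= 10 samples", call. = FALSE)
  span <- diff(range(y))
  # degenerate flat segment: no decay/rise to fit
  if (span <= 1e-10 * max(1, abs(mean(y)))) {
    return(new_segment_fit(y0 = mean(y), A = 0, rate = 0, rate_se = 0,
                           residual_sd = sd(y), converged = TRUE, n = n))
  }
  head_y <- mean(head(y, max(3L, n %/% 50L)))
  tail_y <- mean(tail(y, max(3L, n %/% 50L)))
  if (form == "rise") {
    y0_0 <- head_y
    a_0 <- tail_y - head_y
    frac <- (y - head_y) / ifelse(a_0 == 0, 1, a_0)
  } else {
    y0_0 <- tail_y
    a_0 <- head_y - tail_y
    frac <- 1 - (y - tail_y) / ifelse(a_0 == 0, 1, a_0)
  }
  i63 <- which(frac >= 0.632)[1]
  k_0 <- if (!is.na(i63) && t[i63] > 0) 1 / t[i63] else 5 / max(t)
  dat <- data.frame(t = t, y = y)
  formula <- if (form == "rise") {
    y ~ y0 + A * (1 - exp(-k * t))
  } else {
    y ~ y0 + A * exp(-k * t)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      formula, data = dat,
      start = list(y0 = y0_0, A = a_0, k = k_0),
      lower = c(-Inf, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_segment_fit(y0 = y0_0, A = a_0, rate = NA_real_,
                           converged = FALSE, n = n))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  new_segment_fit(
    y0 = unname(cf["y0"]), A = unname(cf["A"]), rate = unname(cf["k"]),
    rate_se = se, residual_sd = sd(residuals(fit)),
    converged = fit$convInfo$isConv, n = n
  )
}

#' Fit the association segment of one sensorgram
#'
#' Nonlinear least-squares fit of the pseudo-first-order rising exponential
#' `Y = Y0 + A (1 - exp(-k_obs t))` to the association segment, with time
#' re-zeroed at the segment start. The fitted rate is the observed rate
#' constant `k_obs = k_a C + k_d`.
#'
#' @param trace A single sensorgram (tibble with `phase`, `t_s`,
#'   `response`).
#' @return A `segment_fit` with fields `y0`, `A`, `rate` (`k_obs`),
#'   `rate_se`, `residual_sd`, `converged`, `n`. On non-convergence `rate`
#'   is `NA` and `converged` is `FALSE`.
#' @export
fit_association <- function(trace) {
  d <- segment_data(trace, "association")
  fit_exponential_segment(d$t, d$y, "rise")
}

#' Fit the dissociation segment of one sensorgram
#'
#' Nonlinear least-squares fit of the decaying exponential
#' `Y = Y0 + A exp(-k_d t)` to the dissociation segment, with time
#' re-zeroed at the segment start.
#'
#' @inheritParams fit_association
#' @return A `segment_fit`; `rate` is the dissociation rate constant
#'   `k_d` (1/s).
#' @export
fit_dissociation <- function(trace) {
  d <- segment_data(trace, "dissociation")
  fit_exponential_segment(d$t, d$y, "decay")
}

#' Association rate constant from k_obs, k_d and concentration
#'
#' The pseudo-first-order relation `k_obs = k_a C + k_d` inverted:
#' `k_a = (k_obs - k_d) / C`.
#'
#' @param k_obs Observed association rate (1/s).
#' @param k_d Dissociation rate constant (1/s).
#' @param conc Analyte concentration in molar (> 0).
#' @return `k_a` in 1/M/s. `k_obs == k_d` returns 0 with a warning (no
#'   detectable association); `k_obs < k_d` is unphysical and errors.
#' @export
#' @examples
#' derive_ka(1.0281, 0.0281, 1e-6) # 1e6
derive_ka <- function(k_obs, k_d, conc) {
  stopifnot(is.finite(k_obs), is.finite(k_d), is.finite(conc))
  if (conc <= 0) stop("conc must be > 0", call. = FALSE)
  if (k_obs < k_d) {
    stop("k_obs < k_d: no binding signal (negative rate is unphysical)",
         call. = FALSE)
  }
  if (k_obs == k_d) {
    warning("k_obs equals k_d: no detectable association", call. = FALSE)
    return(0)
  }
  (k_obs - k_d) / conc
}

#' Equilibrium dissociation constant from the rate constants
#'
#' `K_d = k_d / k_a`.
#'
#' @param k_a Association rate constant (1/M/s, > 0).
#' @param k_d Dissociation rate constant (1/s, >= 0).
#' @return `K_d` in molar; 0 (with a warning) when `k_d` is 0.
#' @export
#' @examples
#' derive_equilibrium_kd(1e6, 0.0281) * 1e9 # 28.1 nM
derive_equilibrium_kd <- function(k_a, k_d) {
  stopifnot(is.finite(k_a), is.finite(k_d))
  if (k_a <= 0) stop("k_a must be > 0", call. = FALSE)
  if (k_d < 0) stop("k_d must be >= 0", call. = FALSE)
  if (k_d == 0) {
    warning("k_d is 0: no measurable dissociation", call. = FALSE)
    return(0)
  }
  k_d / k_a
}

# Model responses for one sensor under shared (ka, kd) and its Rmax.
# ta: association times (re-zeroed); td: dissociation times (re-zeroed);
# t_assoc: association phase duration.
model_1to1 <- function(ka, kd, rmax, conc, ta, td, t_assoc) {
  kobs <- ka * conc + kd
  req <- rmax * conc / (conc + kd / ka)
  ya <- req * (1 - exp(-kobs * ta))
  rend <- req * (1 - exp(-kobs * t_assoc))
  yd <- rend * exp(-kd * td)
  c(ya, yd)
}

# numerical jacobian of the stacked residual vector (central differences)
numeric_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

#' Global 1:1 Langmuir fit across a concentration series
#'
#' Fits association and dissociation segments of all positive-concentration
#' sensors jointly, sharing one association rate constant `k_a` and one
#' dissociation rate constant `k_d` across sensors while giving each
#' sensor its own `R_max`. `K_d = k_d / k_a` by construction. Each segment
#' also carries a per-sensor nuisance baseline offset (the `Y0` of the
#' segment equations), which is zero on clean data and absorbs the
#' residual interstep offsets that single-sample alignment leaves on noisy
#' traces. Rates are optimised on a log10 scale by Levenberg-Marquardt
#' least squares; initial values come from per-trace segment fits (`k_d`
#' from the highest-concentration dissociation, `k_a` from the slope of
#' the k_obs versus concentration line). Each sensor is re-zeroed on the mean of its
#' secondary baseline before fitting, so run [preprocess_set()] first on
#' noisy data.
#'
#' Standard errors are 1-SE values from the fit covariance (delta method
#' for the back-transformed rates and for `K_d`); `R2` is the coefficient
#' of determination pooled over all fitted association and dissociation
#' points.
#'
#' @param set A preprocessed `sensorgram_set` tibble containing at least
#'   two distinct positive concentrations.
#' @return An object of class `bli_fit`: list with `k_a`, `k_a_se`, `k_d`,
#'   `k_d_se`, `K_d` (molar), `K_d_se`, `Kd_nM`, `R_max` (named per
#'   sensor), `k_obs` (tibble per concentration: per-trace fit and
#'   model-implied), `R2`, `n_sensors`, `converged`, `message`.
#' @export
global_fit_1to1 <- function(set) {
  idx <- split_sensors(set)
  concs <- vapply(idx, function(i) set$conc_nM[i][1], numeric(1))
  pos <- names(idx)[concs > 0]
  if (length(unique(concs[concs > 0])) < 2L) {
    stop("need at least 2 distinct positive concentrations", call. = FALSE)
  }

  sensors <- lapply(pos, function(id) {
    i <- idx[[id]]
    trace <- set[i, , drop = FALSE]
    base <- trace$response[trace$phase == "secondary_baseline"]
    y0 <- if (length(base) > 0) mean(base) else 0
    a <- segment_data(trace, "association")
    d <- segment_data(trace, "dissociation")
    t_assoc <- min(trace$t_s[trace$phase == "dissociation"]) -
      min(trace$t_s[trace$phase == "association"])
    list(
      id = id, conc = trace$conc_nM[1] * 1e-9,
      ta = a$t, ya = a$y - y0, td = d$t, yd = d$y - y0,
      t_assoc = t_assoc, trace = trace
    )
  })
  names(sensors) <- pos

  # initial values from per-trace segment fits
  seg_assoc <- lapply(sensors, function(s) fit_association(s$trace))
  kobs_fit <- vapply(seg_assoc, function(f) f$rate, numeric(1))
  conc_M <- vapply(sensors, function(s) s$conc, numeric(1))
  top <- which.max(conc_M)
  kd_0 <- fit_dissociation(sensors[[top]]$trace)$rate
  if (!is.finite(kd_0) || kd_0 <= 0) kd_0 <- 1e-2
  ok <- is.finite(kobs_fit)
  ka_0 <- if (sum(ok) >= 2L) {
    sl <- coef(lm(kobs_fit[ok] ~ conc_M[ok]))[2]
    if (is.finite(sl) && sl > 0) unname(sl) else kd_0 / 1e-7
  } else {
    kd_0 / 1e-7
  }
  kd_ka <- kd_0 / ka_0
  rmax_0 <- vapply(sensors, function(s) {
    amp <- max(s$ya) - min(s$ya[1], 0)
    occ <- s$conc / (s$conc + kd_ka)
    max(amp / max(occ, 1e-6), 1e-6)
  }, numeric(1))

  # parameters: log10(ka), log10(kd), per-sensor R_max, then per-sensor
  # baseline offsets Y0 for the association and dissociation segments (the
  # Y0 terms of the segment equations; they absorb residual interstep
  # offsets left by single-sample alignment and are ~0 on clean data)
  ns <- length(sensors)
  yobs <- unlist(lapply(sensors, function(s) c(s$ya, s$yd)),
                 use.names = FALSE)
  resid_fn <- function(par) {
    ka <- 10^par[1]
    kd <- 10^par[2]
    rmax <- par[2 + seq_len(ns)]
    y0a <- par[2 + ns + seq_len(ns)]
    y0d <- par[2 + 2 * ns + seq_len(ns)]
    yhat <- unlist(lapply(seq_len(ns), function(i) {
      s <- sensors[[i]]
      m <- model_1to1(ka, kd, rmax[i], s$conc, s$ta, s$td, s$t_assoc)
      m + rep(c(y0a[i], y0d[i]), c(length(s$ta), length(s$td)))
    }), use.names = FALSE)
    yobs - yhat
  }
  par0 <- c(log10(ka_0), log10(kd_0), rmax_0, rep(0, 2 * ns))
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = c(-Inf, -Inf, rep(0, ns), rep(-Inf, 2 * ns)),
    control = minpack.lm::nls.lm.control(maxiter = 400)
  )
  converged <- fit$info %in% 1:4
  par <- unname(fit$par)
  ka <- 10^par[1]
  kd <- 10^par[2]
  rmax <- setNames(par[2 + seq_len(ns)], pos)

  # covariance of the parameters at the optimum
  res <- resid_fn(par)
  dof <- length(res) - length(par)
  s2 <- sum(res^2) / max(dof, 1L)
  J <- numeric_jacobian(resid_fn, par)
  covmat <- tryCatch(s2 * solve(crossprod(J)),
                     error = function(e) matrix(NA_real_, length(par),
                                                length(par)))
  ln10 <- log(10)
  ka_se <- ka * ln10 * sqrt(covmat[1, 1])
  kd_se <- kd * ln10 * sqrt(covmat[2, 2])
  kD <- kd / ka
  kD_se <- kD * ln10 *
    sqrt(covmat[1, 1] + covmat[2, 2] - 2 * covmat[1, 2])

  sst <- sum((yobs - mean(yobs))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_

  # fitted association amplitude at the top concentration, and the pooled
  # residual noise: together they say whether any binding signal rises
  # above background at all
  s_top <- sensors[[top]]
  kobs_top <- ka * s_top$conc + kd
  amp_top <- rmax[top] * s_top$conc / (s_top$conc + kD) *
    (1 - exp(-kobs_top * s_top$t_assoc))
  residual_sd <- sqrt(sum(res^2) / max(length(res) - length(par), 1L))

  structure(
    list(
      k_a = ka, k_a_se = ka_se, k_d = kd, k_d_se = kd_se,
      K_d = kD, K_d_se = kD_se, Kd_nM = kD * 1e9,
      R_max = rmax,
      signal_amplitude = unname(amp_top), residual_sd = residual_sd,
      k_obs = tibble::tibble(
        sensor_id = pos, conc_nM = conc_M * 1e9,
        k_obs_trace = unname(kobs_fit),
        k_obs_model = ka * conc_M + kd
      ),
      R2 = r2, n_sensors = length(pos),
      converged = converged, message = fit$message
    ),
    class = "bli_fit"
  )
}

#' @export
print.bli_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<bli_fit> k_a = %.4g /M/s (se %.2g), k_d = %.4g /s (se %.2g)\n",
           "          K_d = %.4g nM (se %.2g), R2 = %.4f, %d sensors, converged = %s\n"),
    x$k_a, x$k_a_se, x$k_d, x$k_d_se, x$Kd_nM, x$K_d_se * 1e9, x$R2,
    x$n_sensors, x$converged
  ))
  invisible(x)
}

#' Two-stage kinetic estimate (k_obs regression route)
#'
#' The classical per-trace route: fit `k_obs` for each concentration with
#' [fit_association()], fit `k_d` from the highest-concentration
#' dissociation, derive `k_a = (k_obs - k_d)/C` per trace
#' ([derive_ka()]) and average, then `K_d = k_d / k_a`
#' ([derive_equilibrium_kd()]). Serves as an independent cross-check of
#' [global_fit_1to1()].
#'
#' @param set A preprocessed `sensorgram_set` tibble.
#' @return List with `k_a`, `k_d`, `K_d` (molar), `Kd_nM` and the
#'   per-concentration `k_obs` tibble.
#' @export
two_stage_fit <- function(set) {
  idx <- split_sensors(set)
  concs <- vapply(idx, function(i) set$conc_nM[i][1], numeric(1))
  pos <- names(idx)[concs > 0]
  if (length(pos) < 2L) {
    stop("need at least 2 positive concentrations", call. = FALSE)
  }
  traces <- lapply(pos, function(id) set[idx[[id]], , drop = FALSE])
  conc_M <- concs[pos] * 1e-9
  kobs <- vapply(traces, function(tr) fit_association(tr)$rate, numeric(1))
  kd <- fit_dissociation(traces[[which.max(conc_M)]])$rate
  ka_each <- mapply(function(ko, cc) derive_ka(ko, kd, cc), kobs, conc_M)
  ka <- mean(ka_each)
  list(
    k_a = ka, k_d = kd, K_d = derive_equilibrium_kd(ka, kd),
    Kd_nM = derive_equilibrium_kd(ka, kd) * 1e9,
    k_obs = tibble::tibble(sensor_id = pos, conc_nM = concs[pos],
                           k_obs = unname(kobs))
  )
}

#' Categorical binding call from a kinetic fit
#'
#' Scales an interaction into the three categories used for cross-species
#' binding matrices: strong (`++`) for a converged fit with
#' `K_d < 250 nM`, weak (`+`) for a converged fit with `K_d` up to the
#' highest assayed protein concentration (default 3 uM), and none (`-`)
#' otherwise. A fit whose fitted top-concentration amplitude does not rise
#' above the residual noise floor (`min_signal_sd` standard deviations) is
#' called `"none"` regardless of its nominal `K_d`: that is an interaction
#' showing no binding greater than the negative controls, where the
#' reported rate constants are not identifiable.
#'
#' @param fit A `bli_fit` (possibly unconverged).
#' @param max_assay_conc Highest assay concentration in molar (default
#'   3e-6).
#' @param strong_threshold Strong/weak cut-off in molar (default 250e-9).
#' @param min_signal_sd Signal-above-background requirement: the fitted
#'   association amplitude at the top concentration must exceed this many
#'   residual SDs (default 5; a fitted amplitude is an extreme-value-prone
#'   quantity, so a conventional 3-SD rule admits occasional false
#'   positives under pure background noise).
#' @return Character scalar: `"strong"`, `"weak"` or `"none"`. Render with
#'   [binding_symbol()].
#' @export
classify_binding <- function(fit, max_assay_conc = 3e-6,
                             strong_threshold = 250e-9,
                             min_signal_sd = 5) {
  stopifnot(inherits(fit, "bli_fit"))
  if (!isTRUE(fit$converged) || !is.finite(fit$K_d)) return("none")
  if (!is.null(fit$signal_amplitude) && !is.null(fit$residual_sd) &&
      is.finite(fit$signal_amplitude) && is.finite(fit$residual_sd) &&
      fit$signal_amplitude < min_signal_sd * fit$residual_sd) {
    return("none")
  }
  if (fit$K_d < strong_threshold) return("strong")
  if (fit$K_d <= max_assay_conc) return("weak")
  "none"
}

#' Render a binding call as its table symbol
#'
#' @param call Character vector of `"none"`, `"weak"`, `"strong"`.
#' @return `"-"`, `"+"` or `"++"` respectively.
#' @export
binding_symbol <- function(call) {
  unname(c(none = "-", weak = "+", strong = "++")[call])
}
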