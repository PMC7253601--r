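# Synthetic biolayer-interferometry sensorgrams under a 1:1 Langmuir model.

PHASES <- c("primary_baseline", "loading", "secondary_baseline",
            "association", "dissociation")

#' Ground-truth kinetic parameters for a 1:1 interaction
#'
#' @param k_a Association rate constant (1/M/s), > 0.
#' @param k_d Dissociation rate constant (1/s), >= 0.
#' @param R_max Maximal response at analyte saturation (response units),
#'   >= 0. Default 1.
#' @return Object of class `kinetic_params` with derived `K_d = k_d / k_a`
#'   (molar).
#' @export
#' @examples
#' kinetic_params(k_a = 1e6, k_d = 0.0281)$K_d # 28.1 nM
kinetic_params <- function(k_a, k_d, R_max = 1) {
  stopifnot(is.finite(k_a), is.finite(k_d), is.finite(R_max))
  if (k_a <= 0) stop("k_a must be > 0", call. = FALSE)
  if (k_d < 0) stop("k_d must be >= 0", call. = FALSE)
  if (R_max < 0) stop("R_max must be >= 0", call. = FALSE)
  structure(
    list(k_a = k_a, k_d = k_d, R_max = R_max, K_d = k_d / k_a),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> k_a = %.4g /M/s, k_d = %.4g /s, K_d = %.4g nM, R_max = %.3g\n",
    x$k_a, x$k_d, x$K_d * 1e9, x$R_max
  ))
  invisible(x)
}

#' Octet-style phase schedule
#'
#' Phase durations in seconds for the five biosensor steps, defaulting to
#' the optimised protocol: primary baseline 60 s, DNA loading 150 s,
#' secondary baseline 180 s, association 180 s, dissociation 270 s.
#'
#' @param primary_baseline,loading,secondary_baseline,association,dissociation
#'   Phase durations in seconds (> 0).
#' @param dt Sampling interval in seconds (default 0.2).
#' @return Object of class `phase_schedule`.
#' @export
phase_schedule <- function(primary_baseline = 60, loading = 150,
                           secondary_baseline = 180, association = 180,
                           dissociation = 270, dt = 0.2) {
  durations <- c(
    primary_baseline = primary_baseline, loading = loading,
    secondary_baseline = secondary_baseline, association = association,
    dissociation = dissociation
  )
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all phase durations must be positive", call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(durations = durations, dt = dt), class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("<phase_schedule> ",
      paste(sprintf("%s %gs", names(x$durations), x$durations),
            collapse = ", "),
      sprintf(" (dt = %gs)\n", x$dt), sep = "")
  invisible(x)
}

#' Instrument noise model for simulated sensorgrams
#'
#' @param gaussian_sd Per-sample Gaussian noise SD (response units).
#' @param step_offset_sd SD of the random offset injected at each phase
#'   boundary (response units); emulates interstep artifacts.
#' @param drift_rate Common-mode linear drift (response units per second).
#' @return Object of class `noise_model`. All-zero (the default of
#'   `noise_model(0, 0, 0)`) means noiseless.
#' @export
noise_model <- function(gaussian_sd = 0.01, step_offset_sd = 0.02,
                        drift_rate = 0) {
  stopifnot(gaussian_sd >= 0, step_offset_sd >= 0, drift_rate >= 0)
  structure(
    list(gaussian_sd = gaussian_sd, step_offset_sd = step_offset_sd,
         drift_rate = drift_rate),
    class = "noise_model"
  )
}

#' Simulate one BLI sensorgram
#'
#' Generates a response-vs-time trace across the five protocol phases under
#' pseudo-first-order 1:1 binding. During association the mean signal
#' (above the load level) is `R_eq * (1 - exp(-k_obs * t))` with
#' `k_obs = k_a * C + k_d` and `R_eq = R_max * C / (C + K_d)`; dissociation
#' decays from the association endpoint as `exp(-k_d * t)`. Baselines are
#' flat; loading is a saturating ramp to `load_level` (its shape carries no
#' kinetic information). Gaussian noise, per-phase step offsets and
#' common-mode drift are added per the `noise` model. Zero concentration
#' yields zero mean binding signal.
#'
#' @param params A [kinetic_params()] object.
#' @param conc_nM Analyte concentration in nM (>= 0; 0 marks a reference
#'   sensor).
#' @param schedule A [phase_schedule()].
#' @param noise A [noise_model()]; use `noise_model(0, 0, 0)` for a
#'   noiseless trace.
#' @param seed Integer seed for the noise realisation.
#' @param sensor_id Sensor label.
#' @param load_level Response level reached by the loading step (default 1).
#' @return A tibble with columns `sensor_id`, `conc_nM`, `is_reference`,
#'   `phase`, `t_s` (absolute time, seconds) and `response`.
#' @export
simulate_sensorgram <- function(params, conc_nM, schedule = phase_schedule(),
                                noise = noise_model(), seed = 1L,
                                sensor_id = sprintf("S_%gnM", conc_nM),
                                load_level = 1) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "phase_schedule"),
            inherits(noise, "noise_model"))
  if (!is.finite(conc_nM) || conc_nM < 0) {
    stop("conc_nM must be finite and >= 0", call. = FALSE)
  }
  conc <- conc_nM * 1e-9
  bounds <- cumsum(schedule$durations)
  total <- bounds[length(bounds)]
  t_s <- seq(0, total, by = schedule$dt)
  phase_i <- findInterval(t_s, c(0, bounds), rightmost.closed = TRUE)
  phase_i[phase_i > 5L] <- 5L
  starts <- c(0, bounds[-length(bounds)])
  t_rel <- t_s - starts[phase_i]

  k_obs <- params$k_a * conc + params$k_d
  r_eq <- if (conc > 0) {
    params$R_max * conc / (conc + params$K_d)
  } else {
    0
  }
  t_assoc <- schedule$durations[["association"]]
  r_end <- r_eq * (1 - exp(-k_obs * t_assoc))

  mean_resp <- numeric(length(t_s))
  for (p in seq_along(PHASES)) {
    sel <- phase_i == p
    tr <- t_rel[sel]
    mean_resp[sel] <- switch(
      PHASES[p],
      primary_baseline = rep(0, sum(sel)),
      loading = load_level *
        (1 - exp(-5 * tr / schedule$durations[["loading"]])),
      secondary_baseline = rep(load_level, sum(sel)),
      association = load_level + r_eq * (1 - exp(-k_obs * tr)),
      dissociation = load_level + r_end * exp(-params$k_d * tr)
    )
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  steps <- c(0, rnorm(4L, 0, noise$step_offset_sd))
  response <- mean_resp +
    steps[phase_i] +
    noise$drift_rate * t_s +
    rnorm(length(t_s), 0, noise$gaussian_sd)

  tibble::tibble(
    sensor_id = sensor_id,
    conc_nM = conc_nM,
    is_reference = conc_nM == 0,
    phase = PHASES[phase_i],
    t_s = t_s,
    response = response
  )
}

#' Simulate a concentration series of sensorgrams
#'
#' One sensorgram per (concentration, replicate) plus one zero-concentration
#' reference sensor, all sharing one schedule and ground truth. Per-member
#' noise realisations use deterministic sub-seeds derived from `seed`, so
#' re-runs are bit-identical.
#'
#' @param params A [kinetic_params()] object.
#' @param concs_nM Distinct positive concentrations in nM; default is the
#'   two-fold dilution series 1000, 500, 250, 125, 62.5, 31.3.
#' @param schedule A [phase_schedule()].
#' @param noise A [noise_model()].
#' @param replicates Replicates per concentration (default 1).
#' @param seed Integer master seed.
#' @return A `sensorgram_set`: tibble of stacked sensorgrams with
#'   attributes `params`, `schedule`, `noise` and `seed`.
#' @export
simulate_set <- function(params,
                         concs_nM = c(1000, 500, 250, 125, 62.5, 31.3),
                         schedule = phase_schedule(), noise = noise_model(),
                         replicates = 1L, seed = 1L) {
  stopifnot(length(concs_nM) >= 1L, replicates >= 1L)
  if (any(concs_nM <= 0)) {
    stop("concs_nM must all be positive (the reference is added internally)",
         call. = FALSE)
  }
  if (anyDuplicated(concs_nM)) {
    stop("concs_nM must be distinct", call. = FALSE)
  }
  members <- expand.grid(rep = seq_len(replicates), conc = concs_nM,
                         KEEP.OUT.ATTRS = FALSE)
  members <- rbind(members, data.frame(rep = 1L, conc = 0))
  traces <- lapply(seq_len(nrow(members)), function(i) {
    conc <- members$conc[i]
    rep_i <- members$rep[i]
    sub_seed <- (as.numeric(seed) * 10007 + i * 7919) %% .Machine$integer.max
    id <- if (conc == 0) {
      sprintf("REF_r%d", rep_i)
    } else {
      sprintf("S%02d_%gnM_r%d", match(conc, concs_nM), conc, rep_i)
    }
    simulate_sensorgram(params, conc, schedule, noise, seed = sub_seed,
                        sensor_id = id)
  })
  out <- do.call(rbind, traces)
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "noise") <- noise
  attr(out, "seed") <- seed
  class(out) <- c("sensorgram_set", class(out))
  out
}
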