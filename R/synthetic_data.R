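# Synthetic running-gait generator.
#
# Produces cohorts, a full-factorial trial design (participants x surfaces x
# speed classes x sides x stances), and per-stance 1000 Hz time-synchronized
# vertical force + tri-axial accelerometer/gyroscope signals at shank, hip,
# and sacrum, with closed-form latent force features.
#
# Force model: a raised half-sine active component (amplitude growing with
# speed) plus a gamma-shaped early impact transient (amplitude growing with
# foot strike angle above a threshold, so forefoot strikes carry no impact
# peak). Accelerations follow Newton's second law at the COM placements:
# with all noise terms zero, mass * (vertical accel + 1 g) * g0 reproduces
# the force series exactly during stance.

#' Cohort and signal-generation configuration
#'
#' Defaults mirror a typical overground running protocol: 74 participants,
#' 2 surfaces,
#' 3 self-selected speed classes, 2 sides, 5 stances per cell (4440 trials),
#' sampled at 1000 Hz. Anthropometric distributions, speed-class means, and
#' waveform gains are generator choices documented in the methods vignette.
#'
#' @param n_participants cohort size.
#' @param surfaces character vector of surface labels.
#' @param speed_classes named list, each `c(mean =, sd =)` in m/s.
#' @param sides character vector of sides.
#' @param stances_per_cell stances per participant x surface x speed x side.
#' @param fs sampling rate (Hz).
#' @param mass,height,age named vectors `c(mean, sd, min)` for truncated
#'   normal draws (kg, m, years).
#' @param leg_length_ratio leg length as a fraction of height `c(mean, sd)`.
#' @param prop_female probability a participant is female.
#' @param fsa participant-mean foot strike angle distribution `c(mean, sd)`
#'   (radians).
#' @param fsa_trial_sd,speed_trial_sd within-participant trial SDs.
#' @param active_base,active_speed_gain active-peak amplitude model, in body
#'   weights: `BW * (active_base + active_speed_gain * speed)`.
#' @param impact_fsa_gain,impact_fsa0 impact amplitude model, in body
#'   weights: `BW * max(0, impact_fsa_gain * (fsa - impact_fsa0))`.
#' @param surface_impact_mult named multiplier on the impact amplitude per
#'   surface (default 1 for both: no surface effect).
#' @param amp_sd SD of the participant-level log-normal amplitude
#'   multipliers (impact and active drawn independently).
#' @param contact_time_map `c(t_ref, v_ref, slope)`: contact time (s) is
#'   `t_ref + slope * (speed - v_ref)`, floored at 0.15 s.
#' @param impact_peak_frac impact-transient peak time as a fraction of
#'   stance.
#' @param impact_shape gamma shape of the impact transient.
#' @param quiet_prefix_s,suffix_s duration of the quiet-standing prefix and
#'   post-stance (flight) suffix (s).
#' @param noise list of noise magnitudes: `accel_sd` (g), `ripple_amp` (g),
#'   `ripple_hz`, `gyro_sd` (rad/s), `gyro_amp` (rad/s), `force_sd` (N).
#'   Set all to zero for noiseless Newtonian-consistent data.
#' @param shank_gain scale of shank vertical acceleration relative to COM.
#' @param shank_spike_gain impact spike amplitude at the shank, in g per
#'   body-weight of impact amplitude.
#' @param ap_amp amplitude (g) of the biphasic anteroposterior channel.
#' @param misalignment named list placement -> 3x3 rotation applied to the
#'   sensor signals (default `NULL`: identity alignment).
#' @param seed master seed controlling every draw.
#' @return object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_participants = 74,
                          surfaces = c("floor", "track"),
                          speed_classes = list(
                            slowest = c(mean = 2.7, sd = 0.25),
                            typical = c(mean = 3.3, sd = 0.30),
                            fastest = c(mean = 4.2, sd = 0.45)),
                          sides = c("left", "right"),
                          stances_per_cell = 5,
                          fs = 1000,
                          mass = c(mean = 66, sd = 12, min = 40),
                          height = c(mean = 1.70, sd = 0.09, min = 1.40),
                          age = c(mean = 28, sd = 12, min = 18),
                          leg_length_ratio = c(mean = 0.53, sd = 0.02),
                          prop_female = 42 / 74,
                          fsa = c(mean = 0.15, sd = 0.12),
                          fsa_trial_sd = 0.03,
                          speed_trial_sd = 0.10,
                          active_base = 1.4,
                          active_speed_gain = 0.25,
                          impact_fsa_gain = 3.0,
                          impact_fsa0 = 0.0,
                          surface_impact_mult = c(floor = 1, track = 1),
                          amp_sd = 0.08,
                          contact_time_map = c(t_ref = 0.35, v_ref = 2.5,
                                               slope = -0.052),
                          impact_peak_frac = 0.13,
                          impact_shape = 4,
                          quiet_prefix_s = 0.30,
                          suffix_s = 0.10,
                          noise = list(accel_sd = 0.03, ripple_amp = 0.15,
                                       ripple_hz = 8, gyro_sd = 0.01,
                                       gyro_amp = 1.5, force_sd = 2),
                          shank_gain = 1.0,
                          shank_spike_gain = 8,
                          ap_amp = 0.3,
                          misalignment = NULL,
                          seed = 20231025L) {
  cfg <- list(n_participants = n_participants, surfaces = surfaces,
              speed_classes = speed_classes, sides = sides,
              stances_per_cell = stances_per_cell, fs = fs,
              mass = mass, height = height, age = age,
              leg_length_ratio = leg_length_ratio,
              prop_female = prop_female, fsa = fsa,
              fsa_trial_sd = fsa_trial_sd, speed_trial_sd = speed_trial_sd,
              active_base = active_base,
              active_speed_gain = active_speed_gain,
              impact_fsa_gain = impact_fsa_gain, impact_fsa0 = impact_fsa0,
              surface_impact_mult = surface_impact_mult, amp_sd = amp_sd,
              contact_time_map = contact_time_map,
              impact_peak_frac = impact_peak_frac,
              impact_shape = impact_shape,
              quiet_prefix_s = quiet_prefix_s, suffix_s = suffix_s,
              noise = noise, shank_gain = shank_gain,
              shank_spike_gain = shank_spike_gain, ap_amp = ap_amp,
              misalignment = misalignment, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 0 || cfg$stances_per_cell < 0) {
    stop("counts must be >= 0")
  }
  if (cfg$fs <= 0) stop("sampling rate must be positive")
  for (nm in c("mass", "height", "age")) {
    if (cfg[[nm]]["sd"] < 0) {
      stop("configuration error: negative SD for ", nm)
    }
  }
  for (sc in cfg$speed_classes) {
    if (sc["sd"] < 0 || sc["mean"] <= 0) {
      stop("configuration error: invalid speed class parameters")
    }
  }
  bad <- vapply(cfg$noise, function(x) x < 0, logical(1))
  if (any(bad)) stop("noise magnitudes must be >= 0")
  invisible(cfg)
}

rtruncnorm1 <- function(n, mean, sd, min = -Inf) {
  if (sd < 0) stop("configuration error: SD < 0")
  x <- stats::rnorm(n, mean, sd)
  while (any(x < min)) {
    k <- x < min
    x[k] <- stats::rnorm(sum(k), mean, sd)
  }
  x
}

#' Generate a cohort of participant profiles
#'
#' Anthropometrics are drawn from truncated normal distributions; each
#' participant also receives latent log-normal amplitude multipliers for the
#' impact and active force components and a participant-mean foot strike
#' angle. Deterministic for a fixed master seed.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per participant: `id`, `mass` (kg),
#'   `height` (m), `leg_length` (m), `sex`, `age` (years), `mean_fsa` (rad),
#'   `act_mult`, `imp_mult`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_participants
  if (n == 0) {
    return(data.frame(id = character(0), mass = numeric(0),
                      height = numeric(0), leg_length = numeric(0),
                      sex = character(0), age = numeric(0),
                      mean_fsa = numeric(0), act_mult = numeric(0),
                      imp_mult = numeric(0), stringsAsFactors = FALSE))
  }
  set.seed(config$seed)
  height <- rtruncnorm1(n, config$height["mean"], config$height["sd"],
                        config$height["min"])
  ratio <- pmin(pmax(stats::rnorm(n, config$leg_length_ratio["mean"],
                                  config$leg_length_ratio["sd"]), 0.4), 0.6)
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    mass = rtruncnorm1(n, config$mass["mean"], config$mass["sd"],
                       config$mass["min"]),
    height = height,
    leg_length = ratio * height,
    sex = ifelse(stats::runif(n) < config$prop_female, "F", "M"),
    age = round(rtruncnorm1(n, config$age["mean"], config$age["sd"],
                            config$age["min"])),
    mean_fsa = stats::rnorm(n, config$fsa["mean"], config$fsa["sd"]),
    act_mult = exp(stats::rnorm(n, 0, config$amp_sd)),
    imp_mult = exp(stats::rnorm(n, 0, config$amp_sd)),
    stringsAsFactors = FALSE)
}

#' Generate the full-factorial trial design
#'
#' One row per participant x surface x speed class x side x stance. Trial
#' speed is drawn around the participant-and-class mean; trial foot strike
#' angle around the participant mean. Deterministic for a fixed master seed.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the matching [cohort_config()].
#' @return data.frame of trial conditions with a unique `stance_id`, and a
#'   per-trial `seed` used for signal synthesis.
#' @export
generate_trial_conditions <- function(cohort, config = cohort_config()) {
  validate_cohort_config(config)
  if (nrow(cohort) == 0) stop("cohort is empty")
  grid <- expand.grid(stance_index = seq_len(config$stances_per_cell),
                      side = config$sides,
                      speed_class = names(config$speed_classes),
                      surface = config$surfaces,
                      participant_id = cohort$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(grid) == 0) {
    grid$speed <- numeric(0); grid$fsa <- numeric(0)
    grid$stance_id <- character(0); grid$seed <- integer(0)
    return(grid)
  }
  set.seed(config$seed + 1L)
  # participant-level speed offsets keep classes ordered within runner
  sp_off <- stats::rnorm(nrow(cohort), 0, 0.15)
  names(sp_off) <- cohort$id
  cls_mean <- vapply(config$speed_classes, function(x) x[["mean"]],
                     numeric(1))
  mu <- cls_mean[grid$speed_class] + sp_off[grid$participant_id]
  grid$speed <- pmax(stats::rnorm(nrow(grid), mu, config$speed_trial_sd),
                     1.5)
  pfsa <- cohort$mean_fsa
  names(pfsa) <- cohort$id
  grid$fsa <- stats::rnorm(nrow(grid), pfsa[grid$participant_id],
                           config$fsa_trial_sd)
  grid$stance_id <- sprintf("%s_%s_%s_%s_s%d", grid$participant_id,
                            grid$surface, grid$speed_class, grid$side,
                            grid$stance_index)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  grid[, c("stance_id", "participant_id", "surface", "speed_class",
           "speed", "side", "fsa", "stance_index", "seed")]
}

contact_time_for_speed <- function(speed, config) {
  m <- config$contact_time_map
  pmax(m[["t_ref"]] + m[["slope"]] * (speed - m[["v_ref"]]), 0.15)
}

# gamma-shaped unit pulse peaking at t = tp with shape k
impact_pulse <- function(t, tp, k) {
  p <- numeric(length(t))
  pos <- t > 0
  p[pos] <- (t[pos] / tp)^k * exp(k * (1 - t[pos] / tp))
  p
}

#' Synthesize one stance of vertical GRF with closed-form latent features
#'
#' Force = active + impact. The active component is a raised half-sine of
#' amplitude `mass * g0 * (active_base + active_speed_gain * speed) *
#' act_mult`; the impact component is a gamma-shaped transient peaking at
#' `impact_peak_frac` of stance with amplitude
#' `mass * g0 * max(0, impact_fsa_gain * (fsa - impact_fsa0)) *
#' surface_mult * imp_mult`. Gaussian force-plate noise (if configured) is
#' added and the series clipped at zero. Latent features are computed from
#' the noiseless composite.
#'
#' @param condition one row of [generate_trial_conditions()].
#' @param participant the matching cohort row.
#' @param config the [cohort_config()].
#' @param noise logical; add force-plate noise (uses the current RNG
#'   stream).
#' @return list with `force` (N, one value per stance sample), `time` (s),
#'   `latent` ([grf_features()] from the noiseless model), `contact_time`,
#'   and the component amplitudes `a_active`, `a_impact`.
#' @export
synthesize_vgrf <- function(condition, participant, config = cohort_config(),
                            noise = TRUE) {
  if (participant$mass <= 0) stop("generation error: non-positive mass")
  tc <- contact_time_for_speed(condition$speed, config)
  if (tc <= 0) stop("generation error: non-positive contact time")
  fs <- config$fs
  n <- round(tc * fs)
  t <- (seq_len(n) - 1) / fs
  bw <- participant$mass * GRAVITY
  a_active <- bw * (config$active_base +
                    config$active_speed_gain * condition$speed) *
    participant$act_mult
  surf_mult <- config$surface_impact_mult[[condition$surface]] %||% 1
  a_impact <- bw * max(0, config$impact_fsa_gain *
                          (condition$fsa - config$impact_fsa0)) *
    surf_mult * participant$imp_mult
  tp <- config$impact_peak_frac * tc
  active <- a_active * sin(pi * t / tc)
  impact <- a_impact * impact_pulse(t, tp, config$impact_shape)
  clean <- active + impact
  force <- clean
  if (noise && config$noise$force_sd > 0) {
    force <- force + stats::rnorm(n, 0, config$noise$force_sd)
  }
  force <- pmax(force, 0)
  latent <- latent_features(clean, t, a_active, a_impact, tp, tc, config)
  list(force = force, time = t, latent = latent, contact_time = tc,
       a_active = a_active, a_impact = a_impact)
}

# latent features from the noiseless composite series; the first peak uses
# the same high-frequency reconstruction rule as the extractor so latent
# and measured definitions coincide
latent_features <- function(clean, t, a_active, a_impact, tp, tc, config) {
  fs <- config$fs
  n <- length(clean)
  k <- config$impact_shape
  fp <- NA_real_; fp_time <- NA_real_; lr <- NA_real_
  if (a_impact > 0) {
    pk <- hif_first_peak(clean, fs)
    if (!is.null(pk)) {
      fp <- pk$magnitude
      fp_time <- pk$time
      lr <- loading_rate(clean, fp_time, fs)
    }
  }
  # impact residue at mid-stance is closed-form and negligible by design
  x_mid <- (tc / 2) / tp
  sp <- a_active + a_impact * x_mid^k * exp(k * (1 - x_mid))
  # stance average: half-sine mean 2A/pi plus gamma-pulse closed-form mean
  pulse_int <- tp * exp(k) * k^(-(k + 1)) *
    (gamma(k + 1) * stats::pgamma(k * tc / tp, k + 1))
  avg <- 2 * a_active / pi + a_impact * pulse_int / tc
  grf_features(first_peak = fp, first_peak_time = fp_time,
               loading_rate = lr, second_peak = sp, average = avg,
               time_series = clean, fs = fs)
}

#' Synthesize per-placement IMU signals consistent with a force series
#'
#' Builds raw (primary/secondary) tri-axial accelerometer and gyroscope
#' series at the shank, hip, and sacrum, with a quiet-standing prefix and a
#' flight suffix around the stance. In the unrotated sensor frame +y is
#' longitudinal (up during quiet standing), +x anteroposterior, +z right.
#' COM placements (hip, sacrum) obey Newton's second law: the vertical
#' specific force during stance is `force / (mass * g0)` in g. The shank
#' adds a sharp impact spike (primary channel clipped at +/-16 g so the
#' 15.5 g saturation-fusion rule is exercisable). Gyroscope signals are
#' dominated by a mediolateral (z) oscillation during stance for segment
#' coordinate-system extraction.
#'
#' @param condition,participant,config as in [synthesize_vgrf()].
#' @param force stance force series from [synthesize_vgrf()].
#' @return list with `time`, per-placement `imu` (each a list with `primary`,
#'   `secondary`, `gyro`: n x 3 matrices in g and rad/s), `force_padded`
#'   (force on the shared time base), and `stance_range` (first/last stance
#'   sample on that base).
#' @export
synthesize_accelerations <- function(condition, participant, force,
                                     config = cohort_config()) {
  fs <- config$fs
  n_pre <- round(config$quiet_prefix_s * fs)
  n_st <- length(force)
  n_post <- round(config$suffix_s * fs)
  n <- n_pre + n_st + n_post
  t_all <- (seq_len(n) - 1) / fs
  stance <- (n_pre + 1):(n_pre + n_st)
  bw <- participant$mass * GRAVITY
  nz <- config$noise
  tc <- n_st / fs

  # vertical specific force in g: 1 during quiet standing, F/(m g0) during
  # stance, 0 in flight
  ay_com <- c(rep(1, n_pre), force / bw, rep(0, n_post))

  t_st <- (seq_len(n_st) - 1) / fs
  ap <- numeric(n)
  ap[stance] <- -config$ap_amp * sin(2 * pi * t_st / tc)

  ripple <- function() {
    r <- numeric(n)
    if (nz$ripple_amp > 0) {
      r[stance] <- nz$ripple_amp * sin(2 * pi * nz$ripple_hz * t_st) *
        sin(pi * t_st / tc)
    }
    r
  }
  wnoise <- function(sd) {
    if (sd > 0) c(rep(0, n_pre), stats::rnorm(n_st + n_post, 0, sd))
    else numeric(n)
  }
  gyro_base <- function() {
    g <- matrix(0, n, 3)
    if (nz$gyro_amp > 0) {
      g[stance, 3] <- nz$gyro_amp * sin(2 * pi * t_st / (1.4 * tc))
    }
    if (nz$gyro_sd > 0) {
      g[-seq_len(n_pre), ] <- g[-seq_len(n_pre), ] +
        stats::rnorm((n_st + n_post) * 3, 0, nz$gyro_sd)
    }
    g
  }

  tp <- config$impact_peak_frac * tc
  spike_amp <- config$shank_spike_gain *
    max(0, config$impact_fsa_gain * (condition$fsa - config$impact_fsa0))
  spike <- numeric(n)
  if (spike_amp > 0) {
    spike[stance] <- spike_amp * impact_pulse(t_st, tp, 12)
  }

  make_placement <- function(vert, extra_y = 0) {
    acc <- cbind(ap + wnoise(nz$accel_sd),
                 vert + extra_y + ripple() + wnoise(nz$accel_sd),
                 wnoise(nz$accel_sd))
    list(accel = acc, gyro = gyro_base())
  }

  placements <- list(
    shank = make_placement(c(rep(1, n_pre),
                             config$shank_gain * (force / bw - 1) + 1,
                             rep(0, n_post)), extra_y = spike),
    hip = make_placement(ay_com),
    sacrum = make_placement(ay_com))

  out <- lapply(names(placements), function(pl) {
    p <- placements[[pl]]
    R <- NULL
    if (!is.null(config$misalignment)) R <- config$misalignment[[pl]]
    if (!is.null(R)) {
      stopifnot(is_rotation_matrix(R))
      p$accel <- p$accel %*% t(R)
      p$gyro <- p$gyro %*% t(R)
    }
    primary <- pmin(pmax(p$accel, -16), 16)
    list(primary = primary, secondary = p$accel, gyro = p$gyro)
  })
  names(out) <- names(placements)

  force_padded <- c(rep(0, n_pre), force, rep(0, n_post))
  list(time = t_all, imu = out, force_padded = force_padded,
       stance_range = c(n_pre + 1L, n_pre + n_st))
}

#' Generate a complete synthetic dataset
#'
#' One `synthetic_stance` per trial condition: paired 1000 Hz force and IMU
#' signals plus closed-form latent features and condition metadata.
#' Reproducible bit-for-bit for a fixed master seed.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, a CSV fixture set is
#'   written via [write_dataset_csv()].
#' @return object of class `synthetic_dataset`: list with `cohort`,
#'   `conditions`, `stances` (list of `synthetic_stance`), `config`.
#' @export
generate_dataset <- function(config = cohort_config(), out_dir = NULL) {
  cohort <- generate_cohort(config)
  conditions <- if (nrow(cohort) > 0) {
    generate_trial_conditions(cohort, config)
  } else {
    data.frame()
  }
  stances <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    part <- cohort[cohort$id == cond$participant_id, ]
    set.seed(cond$seed)
    vg <- synthesize_vgrf(cond, part, config)
    im <- synthesize_accelerations(cond, part, vg$force, config)
    stances[[i]] <- structure(
      list(stance_id = cond$stance_id, condition = cond,
           participant = part, time = im$time, force = im$force_padded,
           imu = im$imu, stance_range = im$stance_range,
           latent = vg$latent, contact_time = vg$contact_time,
           seed = cond$seed, fs = config$fs),
      class = "synthetic_stance")
  }
  ds <- structure(list(cohort = cohort, conditions = conditions,
                       stances = stances, config = config),
                  class = "synthetic_dataset")
  if (!is.null(out_dir)) write_dataset_csv(ds, out_dir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic running dataset: %d participants, ",
                     "%d stances at %g Hz\n"),
              nrow(x$cohort), length(x$stances), x$config$fs))
  invisible(x)
}

#' Write a dataset as a plain-text CSV fixture set
#'
#' One time-series CSV per stance (`time_s`, `force_N`, then per-placement
#' `ax/ay/az` in g and `gx/gy/gz` in rad/s), plus `participants.csv`,
#' `conditions.csv`, and a JSON manifest with the seeds and configuration.
#'
#' @param dataset a `synthetic_dataset`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_dataset_csv <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$cohort, file.path(out_dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$conditions, file.path(out_dir, "conditions.csv"),
                   row.names = FALSE)
  for (st in dataset$stances) {
    tab <- data.frame(time_s = st$time, force_N = st$force)
    for (pl in names(st$imu)) {
      a <- st$imu[[pl]]$primary
      g <- st$imu[[pl]]$gyro
      cols <- data.frame(a[, 1], a[, 2], a[, 3], g[, 1], g[, 2], g[, 3])
      names(cols) <- paste0(pl, "_", c("ax", "ay", "az", "gx", "gy", "gz"))
      tab <- cbind(tab, cols)
    }
    utils::write.csv(tab, file.path(out_dir,
                                    paste0(st$stance_id, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = dataset$config$seed,
    n_participants = dataset$config$n_participants,
    n_stances = length(dataset$stances),
    fs = dataset$config$fs,
    stance_seeds = stats::setNames(
      as.list(dataset$conditions$seed),
      dataset$conditions$stance_id))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
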