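# Registry of the 27 single-accelerometer vGRF estimation methods, their
# capability matrix, and the four estimator families:
#   DIRECT   -- F(t) = mass * acceleration (with a method-specific cutoff);
#   PEAK_REG -- OLS of a discrete force feature on the peak of the selected
#               acceleration signal plus anthropometrics;
#   RATE_REG -- same, on the peak acceleration rate (loading-rate methods);
#   TS_BASIS -- sine-basis expansion of the body-weight-normalized force
#               series with basis coefficients regressed on signal features;
#   NN       -- small fully connected network mapping resampled stance
#               acceleration channels (plus mass and contact time) to the
#               force series.
# Trainable families are fitted with gold-standard force-plate features as
# targets inside a leave-one-participant-out harness.

feature_caps <- function(first_peak = "none", loading_rate = "none",
                         second_peak = "none", average = "none",
                         time_series = "none") {
  c(first_peak = first_peak, loading_rate = loading_rate,
    second_peak = second_peak, average = average,
    time_series = time_series)
}

method_spec <- function(name, placement, family, selector = "y",
                        frame = "SCS", cutoff = NULL, capabilities,
                        designs = list(), xynorm = FALSE,
                        report = "features") {
  structure(list(name = name, placement = placement, family = family,
                 input_selector = selector, input_frame = frame,
                 cutoff = cutoff, capabilities = capabilities,
                 designs = designs, xynorm = xynorm, report = report),
            class = "method_spec")
}

#' Build the registry of 27 estimation methods
#'
#' Returns the full method set: 5 shank, 6 hip, and 16 sacrum methods, with
#' a capability matrix recording, per vGRF feature, whether the method was
#' designed to estimate it or whether the feature is derived from the
#' method's estimated time series. Regression design rows are defaults
#' visible in each spec and overridable.
#'
#' @return named list of 27 `method_spec` objects.
#' @export
build_registry <- function() {
  pk_design <- "~ a_pk * mass"
  rate_design <- "~ a_rate * mass"
  higgins_fp <- "~ a_pk + mass + height + leg_length"
  higgins_lr <- "~ a_rate + mass + height + leg_length"
  veras <- function(name, placement, selector) {
    method_spec(name, placement, "RATE_REG", selector,
                capabilities = feature_caps(loading_rate = "designed",
                                            second_peak = "designed"),
                designs = list(loading_rate = rate_design,
                               second_peak = pk_design))
  }
  wundersitz <- function(name, cutoff) {
    method_spec(name, "sacrum", "DIRECT", "res", cutoff = cutoff,
                capabilities = feature_caps(second_peak = "designed"),
                report = "max")
  }
  day <- function(name, cutoff) {
    method_spec(name, "sacrum", "DIRECT", "y", cutoff = cutoff,
                capabilities = feature_caps(first_peak = "derived",
                                            loading_rate = "derived",
                                            second_peak = "designed",
                                            average = "derived",
                                            time_series = "designed"),
                report = "series")
  }
  kim <- function(name) {
    method_spec(name, "sacrum", "TS_BASIS", "y",
                capabilities = feature_caps(first_peak = "derived",
                                            loading_rate = "derived",
                                            second_peak = "derived",
                                            average = "derived",
                                            time_series = "designed"),
                report = "series")
  }
  pogson <- function(name, xynorm) {
    method_spec(name, "sacrum", "NN", "xyz", xynorm = xynorm,
                capabilities = feature_caps(first_peak = "derived",
                                            loading_rate = "derived",
                                            second_peak = "derived",
                                            average = "derived",
                                            time_series = "designed"),
                report = "series")
  }
  specs <- list(
    # ---- shank (5) ----
    method_spec("Charry", "shank", "PEAK_REG", "y",
                capabilities = feature_caps(second_peak = "designed"),
                designs = list(second_peak = pk_design)),
    method_spec("Thiel", "shank", "DIRECT", "res",
                capabilities = feature_caps(second_peak = "designed"),
                report = "max"),
    veras("Veras shank res", "shank", "res"),
    veras("Veras shank y", "shank", "y"),
    method_spec("Higgins shank", "shank", "PEAK_REG", "res",
                capabilities = feature_caps(first_peak = "designed",
                                            loading_rate = "designed"),
                designs = list(first_peak = higgins_fp,
                               loading_rate = higgins_lr)),
    # ---- hip (6) ----
    method_spec("Neugebauer", "hip", "PEAK_REG", "res",
                capabilities = feature_caps(second_peak = "designed"),
                designs = list(second_peak = structure(pk_design,
                                                       log_target = TRUE))),
    method_spec("Meyer", "hip", "DIRECT", "y",
                capabilities = feature_caps(second_peak = "designed"),
                report = "max"),
    method_spec("Kiernan hip", "hip", "PEAK_REG", "y",
                capabilities = feature_caps(first_peak = "designed",
                                            second_peak = "designed"),
                designs = list(first_peak = pk_design,
                               second_peak = pk_design)),
    veras("Veras hip res", "hip", "res"),
    veras("Veras hip y", "hip", "y"),
    method_spec("Higgins hip", "hip", "PEAK_REG", "res",
                capabilities = feature_caps(first_peak = "designed",
                                            loading_rate = "designed"),
                designs = list(first_peak = higgins_fp,
                               loading_rate = higgins_lr)),
    # ---- sacrum (16) ----
    method_spec("Gurchiek", "sacrum", "DIRECT", "y", cutoff = NULL,
                capabilities = feature_caps(first_peak = "derived",
                                            loading_rate = "derived",
                                            second_peak = "derived",
                                            average = "designed",
                                            time_series = "designed"),
                report = "series"),
    kim("Kim acceleration"),
    kim("Kim displacement"),
    method_spec("Kiernan sacrum", "sacrum", "PEAK_REG", "y",
                capabilities = feature_caps(first_peak = "designed",
                                            second_peak = "designed"),
                designs = list(first_peak = pk_design,
                               second_peak = pk_design)),
    veras("Veras sacrum res", "sacrum", "res"),
    veras("Veras sacrum y", "sacrum", "y"),
    day("Day 5 Hz", 5), day("Day 10 Hz", 10), day("Day 30 Hz", 30),
    wundersitz("Wundersitz 10 Hz", 10),
    wundersitz("Wundersitz 15 Hz", 15),
    wundersitz("Wundersitz 20 Hz", 20),
    wundersitz("Wundersitz 25 Hz", 25),
    wundersitz("Wundersitz raw", NULL),
    pogson("Pogson", xynorm = FALSE),
    pogson("Pogson xynorm", xynorm = TRUE))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Capability matrix of the registry
#'
#' @param registry output of [build_registry()].
#' @return data.frame: method, placement, family, and one column per vGRF
#'   feature with values "designed", "derived", or "none".
#' @export
registry_capabilities <- function(registry = build_registry()) {
  rows <- lapply(registry, function(s) {
    data.frame(method = s$name, placement = s$placement, family = s$family,
               t(s$capabilities), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract per-method scalar input features from stance acceleration
#'
#' Computes the inputs consumed by the regression and basis families: the
#' peak of the selected signal, the secant rate of change over 20-80% of
#' the onset-to-peak interval, the signal mean, the contact time, and the
#' vertical displacement excursion from double integration with per-stance
#' linear velocity detrending.
#'
#' @param accel stance-window n x 3 gravity-free acceleration matrix (g).
#' @param fs sampling rate (Hz).
#' @param selector "y" (vertical axis), "res" (resultant with gravity
#'   re-added on the vertical axis), or "xyz".
#' @return list with `a_pk` (g), `a_rate` (g/s), `a_mean` (g),
#'   `contact_time` (s), `disp` (m).
#' @export
extract_input_features <- function(accel, fs = 1000, selector = "y") {
  accel <- as.matrix(accel)
  n <- nrow(accel)
  sel <- select_signal(accel, selector)
  if (is.matrix(sel)) sel <- sqrt(rowSums(sel^2))
  ipk <- which.max(sel)
  a_pk <- sel[ipk]
  a_rate <- 0
  if (ipk > 2) {
    t_pk <- (ipk - 1) / fs
    tt <- (seq_len(n) - 1) / fs
    f20 <- stats::approx(tt, sel, xout = 0.2 * t_pk)$y
    f80 <- stats::approx(tt, sel, xout = 0.8 * t_pk)$y
    a_rate <- (f80 - f20) / (0.6 * t_pk)
  }
  # vertical displacement excursion (m): double integration of the
  # gravity-free vertical channel with linear velocity detrending
  dt <- 1 / fs
  av <- accel[, 2] * GRAVITY
  vel <- cumsum(av) * dt
  tt <- (seq_len(n) - 1) * dt
  vel <- vel - stats::lm.fit(cbind(1, tt), vel)$fitted.values
  pos <- cumsum(vel) * dt
  list(a_pk = a_pk, a_rate = a_rate, a_mean = mean(sel),
       contact_time = n / fs, disp = max(pos) - min(pos))
}

# selected signal: vertical channel, gravity-re-added resultant, or the
# full 3-channel matrix
select_signal <- function(accel, selector) {
  switch(selector,
         y = accel[, 2],
         res = {
           a <- accel
           a[, 2] <- a[, 2] + 1
           sqrt(rowSums(a^2))
         },
         xyz = accel,
         stop("unknown input selector: ", selector))
}

#' Direct Newtonian force estimate
#'
#' F(t) = mass * g0 * (a_sel(t) + 1 g), where `a_sel` is the vertical
#' gravity-free channel (selector "y"), or the magnitude of the
#' acceleration with gravity re-added on the vertical axis (selector
#' "res"), after the method's low-pass cutoff. Methods with `report =
#' "max"` return only the second peak (the series maximum); `report =
#' "series"` methods return the series and its designed/derived features.
#'
#' @param spec a `method_spec` with `family = "DIRECT"`.
#' @param accel stance-window n x 3 gravity-free acceleration matrix (g).
#' @param mass participant mass (kg).
#' @param fs sampling rate (Hz).
#' @return `estimate_record` list: `features` (named numeric) and `series`
#'   (N, or `NULL`).
#' @export
estimate_direct <- function(spec, accel, mass, fs = 1000) {
  if (mass <= 0) stop("non-positive mass")
  accel <- as.matrix(accel)
  if (!is.null(spec$cutoff)) accel <- lowpass_filter(accel, fs, spec$cutoff)
  force <- if (spec$input_selector == "y") {
    mass * GRAVITY * (accel[, 2] + 1)
  } else {
    a <- accel
    a[, 2] <- a[, 2] + 1
    mass * GRAVITY * sqrt(rowSums(a^2))
  }
  if (identical(spec$report, "max")) {
    return(estimate_record(spec, c(second_peak = max(force))))
  }
  feats <- derive_features_from_series(force, fs)
  vals <- unlist(feats[c("first_peak", "loading_rate", "second_peak",
                         "average")])
  estimate_record(spec, vals, series = force)
}

estimate_record <- function(spec, features, series = NULL) {
  caps <- spec$capabilities
  keep <- names(features)[names(features) %in%
                            names(caps)[caps != "none"]]
  structure(list(method = spec$name, features = features[keep],
                 series = series), class = "estimate_record")
}

#' Derive discrete vGRF features from an estimated force series
#'
#' Applies the gold-standard feature operations (HiF first peak, loading
#' rate, second peak, average) to an estimated stance force series.
#'
#' @param series estimated stance force series (N).
#' @param fs sampling rate (Hz).
#' @return list with `first_peak`, `first_peak_time`, `loading_rate`,
#'   `second_peak`, `average`.
#' @export
derive_features_from_series <- function(series, fs = 1000) {
  if (length(series) < 10) stop("estimated series shorter than 10 samples")
  fp <- hif_first_peak(series, fs)
  list(first_peak = if (is.null(fp)) NA_real_ else fp$magnitude,
       first_peak_time = if (is.null(fp)) NA_real_ else fp$time,
       loading_rate = loading_rate(series,
                                   if (is.null(fp)) NULL else fp$time, fs),
       second_peak = second_peak(series,
                                 if (is.null(fp)) NULL else fp$index),
       average = average_force(series))
}

# assemble the regression design frame for one stance record
design_frame <- function(record, selector, fs) {
  feats <- extract_input_features(record$accel, fs, selector)
  data.frame(a_pk = feats$a_pk, a_rate = feats$a_rate,
             a_mean = feats$a_mean, contact_time = feats$contact_time,
             disp = feats$disp, mass = record$mass,
             height = record$height, leg_length = record$leg_length,
             age = record$age,
             sex_num = as.numeric(record$sex == "M"))
}

#' Fit a peak/rate regression method
#'
#' Ordinary least squares of each designed gold-standard feature on the
#' method's design row (default: peak acceleration or peak acceleration
#' rate, mass, and their interaction; the Higgins forms add height and leg
#' length). The Neugebauer second-peak model is fitted on the log target
#' and back-transformed at prediction.
#'
#' @param spec a `method_spec` with family "PEAK_REG" or "RATE_REG".
#' @param training list of stance records (see [prepare_stance_inputs()]).
#' @param fs sampling rate (Hz).
#' @return `trained_method` with per-feature `lm` fits.
#' @export
fit_peak_regression <- function(spec, training, fs = 1000) {
  if (length(unique(vapply(training, `[[`, character(1),
                           "participant"))) < 2) {
    stop("peak regression needs at least 2 training participants")
  }
  X <- do.call(rbind, lapply(training, design_frame,
                             selector = spec$input_selector, fs = fs))
  fits <- list()
  for (feature in names(spec$designs)) {
    design <- spec$designs[[feature]]
    log_target <- isTRUE(attr(design, "log_target"))
    y <- vapply(training, function(r) r$gold[[feature]], numeric(1))
    ok <- is.finite(y)
    if (sum(ok) <= length(all.vars(stats::as.formula(design))) + 1) {
      stop("underdetermined design for feature ", feature,
           ": ", sum(ok), " usable training stances")
    }
    dat <- X[ok, , drop = FALSE]
    dat$.y <- if (log_target) log(y[ok]) else y[ok]
    fit <- stats::lm(stats::as.formula(paste(".y", design)), data = dat)
    if (anyNA(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design for ", spec$name, "/", feature,
           "; collinear columns: ", paste(bad, collapse = ", "))
    }
    fits[[feature]] <- list(fit = fit, log_target = log_target)
  }
  trained_method(spec, fits,
                 unique(vapply(training, `[[`, character(1),
                               "participant")))
}

predict_peak_regression <- function(trained, record, fs = 1000) {
  X <- design_frame(record, trained$spec$input_selector, fs)
  vals <- vapply(names(trained$fits), function(feature) {
    f <- trained$fits[[feature]]
    p <- unname(stats::predict(f$fit, newdata = X))
    if (f$log_target) exp(p) else p
  }, numeric(1))
  estimate_record(trained$spec, vals)
}

sine_basis <- function(L, K) {
  tau <- seq(0, 1, length.out = L)
  outer(tau, seq_len(K), function(t, k) sin(k * pi * t))
}

kim_features <- function(record, spec, fs) {
  feats <- extract_input_features(record$accel, fs, "y")
  if (spec$name == "Kim displacement") {
    c(disp = feats$disp, contact_time = feats$contact_time)
  } else {
    c(a_pk = feats$a_pk, a_mean = feats$a_mean,
      contact_time = feats$contact_time)
  }
}

#' Fit a sine-basis time-series method
#'
#' Each training stance's force series, normalized to body weight and
#' resampled to `L` points, is projected onto `K` sine basis functions
#' sin(k * pi * tau); each basis coefficient is then regressed on the
#' method's scalar inputs (peak and mean sacral acceleration plus contact
#' time, or displacement excursion plus contact time). Prediction
#' reconstructs the normalized series and rescales by body weight and the
#' stance duration.
#'
#' @param spec a `method_spec` with family "TS_BASIS".
#' @param training list of stance records.
#' @param K number of sine basis functions (must be < `L`).
#' @param L normalized series length.
#' @param fs sampling rate (Hz).
#' @return `trained_method` with the basis and coefficient maps.
#' @export
fit_ts_basis <- function(spec, training, K = 10, L = 100, fs = 1000) {
  if (K >= L) stop("K must be smaller than the series length L")
  B <- sine_basis(L, K)
  Z <- do.call(rbind, lapply(training, kim_features, spec = spec, fs = fs))
  if (nrow(Z) < ncol(Z) + 2) stop("too few training stances for basis fit")
  C <- vapply(training, function(r) {
    y <- resample_series(r$force, L) / (r$mass * GRAVITY)
    qr.solve(B, y)
  }, numeric(K))
  C <- if (K == 1) matrix(C, ncol = 1) else t(C)
  beta <- stats::lm.fit(cbind(1, Z), C)$coefficients
  beta[is.na(beta)] <- 0     # aliased (collinear) input columns drop out
  trained_method(spec, list(B = B, beta = beta, K = K, L = L),
                 unique(vapply(training, `[[`, character(1),
                               "participant")))
}

predict_ts_basis <- function(trained, record, fs = 1000) {
  f <- trained$fits
  z <- kim_features(record, trained$spec, fs)
  chat <- as.vector(c(1, z) %*% f$beta)
  series_bw <- as.vector(f$B %*% chat)
  n <- nrow(record$accel)
  series <- resample_series(series_bw, n) * record$mass * GRAVITY
  feats <- derive_features_from_series(series, fs)
  vals <- unlist(feats[c("first_peak", "loading_rate", "second_peak",
                         "average")])
  estimate_record(trained$spec, vals, series = series)
}

nn_inputs <- function(record, spec, L) {
  A <- as.matrix(record$accel)
  ch <- list(resample_series(A[, 1], L), resample_series(A[, 2], L),
             resample_series(A[, 3], L))
  if (spec$xynorm) {
    # x and y channels scaled to unit peak absolute value per stance
    for (j in 1:2) {
      pk <- max(abs(ch[[j]]))
      if (pk > 0) ch[[j]] <- ch[[j]] / pk
    }
  }
  c(ch[[1]], ch[[2]], ch[[3]], record$mass, nrow(A) / 1000)
}

#' Fit a neural-network time-series method
#'
#' A fully connected network (two tanh hidden layers of 32 units) maps the
#' three stance acceleration channels resampled to `L` points, plus mass
#' and contact time, to the `L`-point force series in body weights. The
#' "xynorm" variant first scales the x and y input channels to unit peak
#' absolute value per stance. Training is full-batch Adam with a fixed
#' epoch budget and seeded initialization (deterministic given the seed).
#'
#' @param spec a `method_spec` with family "NN".
#' @param training list of stance records (at least 10).
#' @param seed integer seed.
#' @param L normalized series length.
#' @param epochs training epochs.
#' @param hidden hidden-layer widths.
#' @param fs sampling rate (Hz).
#' @return `trained_method` with network weights and input scalings.
#' @export
fit_nn <- function(spec, training, seed = 1L, L = 100, epochs = 300,
                   hidden = c(32, 32), fs = 1000) {
  if (length(training) < 10) {
    stop("network training needs at least 10 stances")
  }
  X <- t(vapply(training, nn_inputs, numeric(3 * L + 2), spec = spec,
                L = L))
  Y <- t(vapply(training, function(r) {
    resample_series(r$force, L) / (r$mass * GRAVITY)
  }, numeric(L)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  net <- mlp_fit(Xs, Y, hidden = hidden, epochs = epochs, seed = seed)
  trained_method(spec, list(net = net, mu = mu, sd = sdv, L = L),
                 unique(vapply(training, `[[`, character(1),
                               "participant")),
                 seed = seed)
}

predict_nn <- function(trained, record, fs = 1000) {
  f <- trained$fits
  x <- nn_inputs(record, trained$spec, f$L)
  xs <- (x - f$mu) / f$sd
  series_bw <- as.vector(mlp_predict(f$net, matrix(xs, nrow = 1)))
  n <- nrow(record$accel)
  series <- resample_series(series_bw, n) * record$mass * GRAVITY
  feats <- derive_features_from_series(series, fs)
  vals <- unlist(feats[c("first_peak", "loading_rate", "second_peak",
                         "average")])
  estimate_record(trained$spec, vals, series = series)
}

trained_method <- function(spec, fits, participants, seed = NA_integer_) {
  structure(list(spec = spec, fits = fits,
                 train_participants = participants, seed = seed),
            class = "trained_method")
}

#' Fit any trainable method
#'
#' Dispatches on the spec's family; DIRECT methods need no fitting and
#' return a trivial trained wrapper.
#'
#' @param spec a `method_spec`.
#' @param training list of stance records.
#' @param seed seed for stochastic (network) training.
#' @param ... passed to the family fitter.
#' @return a `trained_method`.
#' @export
fit_method <- function(spec, training, seed = 1L, ...) {
  switch(spec$family,
         DIRECT = trained_method(spec, NULL, character(0)),
         PEAK_REG = ,
         RATE_REG = fit_peak_regression(spec, training, ...),
         TS_BASIS = fit_ts_basis(spec, training, ...),
         NN = fit_nn(spec, training, seed = seed, ...),
         stop("unknown family: ", spec$family))
}

#' Apply a trained method to one stance record
#'
#' @param trained a `trained_method`.
#' @param record a stance record from [prepare_stance_inputs()].
#' @param fs sampling rate (Hz).
#' @return an `estimate_record`.
#' @export
predict_method <- function(trained, record, fs = 1000) {
  switch(trained$spec$family,
         DIRECT = estimate_direct(trained$spec, record$accel, record$mass,
                                  fs),
         PEAK_REG = ,
         RATE_REG = predict_peak_regression(trained, record, fs),
         TS_BASIS = predict_ts_basis(trained, record, fs),
         NN = predict_nn(trained, record, fs))
}

#' Prepare per-stance method inputs from a synthetic dataset
#'
#' Runs the gold-standard feature extractor on each stance's force series
#' and the IMU chain on each required placement, producing the flat stance
#' records consumed by the estimator families and the LOO harness.
#'
#' @param dataset a `synthetic_dataset`.
#' @param placements placements to process.
#' @param cutoff IMU low-pass cutoff (Hz) or `NULL`.
#' @param beta Madgwick gain.
#' @return list of stance records; each holds `stance_id`, `participant`,
#'   condition covariates, anthropometrics, per-placement stance
#'   acceleration, the gold `grf_features`, and the gold stance force
#'   series.
#' @export
prepare_stance_inputs <- function(dataset,
                                  placements = c("shank", "hip", "sacrum"),
                                  cutoff = 50, beta = 0.1) {
  lapply(dataset$stances, function(st) {
    gold <- extract_features(st$force, st$fs)
    accels <- lapply(placements, function(pl) {
      process_stance_imu(st, pl, frame = "SCS", cutoff = cutoff,
                         beta = beta, bounds = gold$bounds)$stance_accel
    })
    names(accels) <- placements
    list(stance_id = st$stance_id,
         participant = st$condition$participant_id,
         surface = st$condition$surface, speed = st$condition$speed,
         fsa = st$condition$fsa, side = st$condition$side,
         mass = st$participant$mass, height = st$participant$height,
         leg_length = st$participant$leg_length,
         sex = st$participant$sex, age = st$participant$age,
         accels = accels, gold = gold, force = gold$time_series,
         fs = st$fs)
  })
}

# view of a record for one placement (the accel the method consumes)
record_for <- function(record, placement) {
  record$accel <- record$accels[[placement]]
  if (is.null(record$accel)) {
    stop("record lacks processed accel for placement ", placement)
  }
  record
}

#' Leave-one-participant-out estimation for all methods
#'
#' For each participant, trainable methods are fitted on every other
#' participant's stances and applied to the held-out participant; DIRECT
#' methods are applied without fitting. A method that cannot be fitted on
#' some fold (too little data) is skipped for that fold with a warning.
#'
#' @param records stance records from [prepare_stance_inputs()].
#' @param registry method registry (default [build_registry()]).
#' @param seed integer; per-fold training seeds are derived from it.
#' @param nn_epochs epochs for the network family.
#' @param keep_fits keep the per-fold `trained_method` objects (memory
#'   permitting); useful for auditing fold isolation.
#' @return list with `estimates` (data.frame: stance_id, participant,
#'   method, feature, value), `series` (nested list method -> stance_id ->
#'   estimated series), `folds` (participant -> training participants),
#'   and (when `keep_fits`) `fits` (participant -> method -> fit).
#' @export
loo_estimate_all <- function(records, registry = build_registry(),
                             seed = 1L, nn_epochs = 300,
                             keep_fits = FALSE) {
  participants <- unique(vapply(records, `[[`, character(1),
                                "participant"))
  if (length(participants) < 3) {
    stop("leave-one-out needs at least 3 participants")
  }
  rows <- list()
  series <- list()
  folds <- list()
  fits <- list()
  for (fold_i in seq_along(participants)) {
    p <- participants[fold_i]
    hold <- Filter(function(r) r$participant == p, records)
    train <- Filter(function(r) r$participant != p, records)
    folds[[p]] <- setdiff(participants, p)
    for (spec in registry) {
      train_pl <- lapply(train, record_for, placement = spec$placement)
      trained <- tryCatch(
        if (spec$family == "NN") {
          fit_method(spec, train_pl, seed = seed + fold_i,
                     epochs = nn_epochs)
        } else {
          fit_method(spec, train_pl, seed = seed + fold_i)
        },
        error = function(e) {
          warning("skipping ", spec$name, " for fold ", p, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(trained)) next
      stopifnot(!p %in% trained$train_participants)
      if (keep_fits) fits[[p]][[spec$name]] <- trained
      for (r in hold) {
        est <- predict_method(trained, record_for(r, spec$placement),
                              r$fs)
        vals <- est$features
        if (length(vals) > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            stance_id = r$stance_id, participant = p,
            method = spec$name, feature = names(vals),
            value = unname(vals), stringsAsFactors = FALSE)
        }
        if (!is.null(est$series)) {
          series[[spec$name]][[r$stance_id]] <- est$series
        }
      }
    }
  }
  estimates <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(stance_id = character(0), participant = character(0),
               method = character(0), feature = character(0),
               value = numeric(0))
  rownames(estimates) <- NULL
  out <- list(estimates = estimates, series = series, folds = folds)
  if (keep_fits) out$fits <- fits
  out
}
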