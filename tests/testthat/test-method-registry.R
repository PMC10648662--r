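# Method registry: capability matrix, input features, estimator families,
# and the leave-one-participant-out harness.

test_that("registry reproduces the published method set cell-for-cell", {
  reg <- build_registry()
  expect_length(reg, 27)
  caps <- registry_capabilities(reg)
  expect_equal(sum(caps$placement == "shank"), 5)
  expect_equal(sum(caps$placement == "hip"), 6)
  expect_equal(sum(caps$placement == "sacrum"), 16)

  # literal capability fixture: designed (D), derived (d), none (.)
  expect_capabilities_match(caps, capability_fixture())
  # the counts quoted for sacrum capabilities
  expect_equal(sum(caps$placement == "sacrum" & caps$second_peak != "none"),
               16)
  expect_equal(sum(caps$placement == "sacrum" & caps$time_series != "none"),
               8)
})

test_that("input features match closed forms", {
  fs <- 1000
  # constant 1 g vertical: peak = mean = 1, rate = 0
  accel <- cbind(0, rep(1, 200), 0)
  f <- extract_input_features(accel, fs, "y")
  expect_equal(f$a_pk, 1)
  expect_equal(f$a_mean, 1)
  expect_equal(f$a_rate, 0)
  expect_equal(f$contact_time, 0.2)

  # triangular pulse peaking at 5 g mid-stance: secant of the rising limb
  n <- 201
  tri <- c(seq(0, 5, length.out = 101), seq(5, 0, length.out = 100)[-1])
  f2 <- extract_input_features(cbind(0, tri, 0), fs, "y")
  expect_equal(f2$a_pk, 5)
  tpk <- 100 / fs
  expect_equal(f2$a_rate, (tri[81] - tri[21]) / (0.6 * tpk),
               tolerance = 1e-9)

  # sine acceleration: displacement excursion 2 a g0 / (2 pi f)^2
  fr <- 10
  amp <- 0.5
  t <- (0:999) / fs
  f3 <- extract_input_features(cbind(0, amp * sin(2 * pi * fr * t), 0),
                               fs, "y")
  expect_equal(f3$disp, 2 * amp * GRAVITY / (2 * pi * fr)^2,
               tolerance = 0.02)
})

test_that("direct estimation inverts the generator and orders cutoffs", {
  reg <- build_registry()
  ds <- ds_noiseless()
  st <- ds$stances[[1]]
  pr <- process_stance_imu(st, "sacrum", cutoff = NULL, beta = 0)
  truth <- st$force[pr$bounds$start:(pr$bounds$end - 1)]
  est <- estimate_direct(reg[["Gurchiek"]], pr$stance_accel,
                         st$participant$mass, st$fs)
  expect_equal(est$series, truth, tolerance = 1e-12)
  expect_equal(unname(est$features["second_peak"]), max(truth),
               tolerance = 1e-12)
  expect_equal(unname(est$features["average"]), mean(truth),
               tolerance = 1e-12)

  # zero gravity-free accel: estimate is body weight throughout
  flat <- matrix(0, 300, 3)
  bw_est <- estimate_direct(reg[["Gurchiek"]], flat, 70, 1000)
  expect_equal(unique(round(bw_est$series, 9)), 70 * GRAVITY)

  # on an impact-rich stance, heavier smoothing attenuates the sharp peak
  # (5 Hz < 30 Hz < raw; exact monotonicity across every adjacent cutoff
  # pair is not a theorem for finite windows, see the methods vignette)
  fs <- 1000
  n2 <- 300
  tt2 <- (0:(n2 - 1)) / fs
  Tc <- n2 / fs
  ay <- -1 + 2.2 * sin(pi * tt2 / Tc) +
    3 * exp(-((tt2 - 0.12 * Tc) / 0.008)^2)
  accel_imp <- cbind(0, ay, 0)
  peaks <- vapply(c("Day 5 Hz", "Day 10 Hz", "Day 30 Hz"), function(m) {
    unname(estimate_direct(reg[[m]], accel_imp, 70,
                           fs)$features["second_peak"])
  }, numeric(1))
  raw_peak <- max(70 * GRAVITY * (ay + 1))
  expect_lt(peaks["Day 5 Hz"], peaks["Day 30 Hz"])
  expect_lt(peaks["Day 10 Hz"], peaks["Day 30 Hz"])
  expect_lt(peaks["Day 30 Hz"], raw_peak)
  expect_error(estimate_direct(reg[["Gurchiek"]], flat, -1, 1000), "mass")
})

test_that("peak regression recovers exact and noisy coefficients", {
  fs <- 1000
  reg <- build_registry()
  spec <- reg[["Kiernan sacrum"]]
  make_rec <- function(ipeak, mass, id, yfun) {
    accel <- cbind(0, ipeak * sin(pi * (0:199) / 199), 0)
    a_pk <- max(accel[, 2])
    list(participant = id, mass = mass, height = 1.7, leg_length = 0.9,
         sex = "F", age = 30, accel = accel,
         gold = list(first_peak = yfun(a_pk, mass),
                     second_peak = yfun(a_pk, mass)),
         force = NULL, fs = fs)
  }
  yfun <- function(a, m) 2 + 3 * a            # exact linear model
  set.seed(10)
  recs <- mapply(make_rec, runif(30, 0.5, 3), runif(30, 50, 90),
                 rep(sprintf("P%d", 1:6), 5),
                 MoreArgs = list(yfun = yfun), SIMPLIFY = FALSE)
  fit <- fit_peak_regression(spec, recs, fs)
  co <- coef(fit$fits$second_peak$fit)
  expect_equal(unname(co[1:2]), c(2, 3), tolerance = 1e-8)
  expect_equal(unname(co[3:4]), c(0, 0), tolerance = 1e-8)

  # gaussian noise sigma = 50: coefficients within 3 SE of truth
  set.seed(11)
  recs_n <- mapply(
    make_rec, runif(300, 0.5, 3), runif(300, 50, 90),
    rep(sprintf("P%d", 1:10), 30),
    MoreArgs = list(yfun = function(a, m) 100 + 400 * a + 5 * m +
                      rnorm(1, 0, 50)),
    SIMPLIFY = FALSE)
  fit_n <- fit_peak_regression(spec, recs_n, fs)
  sm <- summary(fit_n$fits$second_peak$fit)$coefficients
  expect_lt(abs(sm["a_pk", "Estimate"] - 400) / sm["a_pk", "Std. Error"],
            3)
  expect_lt(abs(sm["mass", "Estimate"] - 5) / sm["mass", "Std. Error"], 3)

  # log-target back-transformation (Neugebauer form)
  nspec <- reg[["Neugebauer"]]
  recs_l <- mapply(make_rec, runif(40, 0.5, 3), runif(40, 50, 90),
                   rep(sprintf("P%d", 1:8), 5),
                   MoreArgs = list(yfun = function(a, m) exp(1 + 0.5 * a)),
                   SIMPLIFY = FALSE)
  fit_l <- fit_peak_regression(nspec, recs_l, fs)
  pred <- predict_method(fit_l, recs_l[[1]], fs)
  expect_equal(unname(pred$features["second_peak"]),
               recs_l[[1]]$gold$second_peak, tolerance = 1e-6)

  expect_error(fit_peak_regression(spec, recs[1], fs), "participants")
})

test_that("sine-basis family represents, shrinks, and shapes correctly", {
  fs <- 1000
  reg <- build_registry()
  spec <- reg[["Kim acceleration"]]
  L <- 100
  tau <- seq(0, 1, length.out = L)
  mass <- 70
  make_rec <- function(alpha, id) {
    accel <- cbind(0, alpha * sin(pi * tau), 0)
    a_pk <- max(accel[, 2])
    # exact 2-term sine series with coefficients linear in a_pk
    y_bw <- (1 + a_pk) * sin(pi * tau) + 0.1 * a_pk * sin(2 * pi * tau)
    list(participant = id, mass = mass, height = 1.7, leg_length = 0.9,
         sex = "F", age = 30, accel = accel, gold = list(),
         force = y_bw * mass * GRAVITY, fs = fs)
  }
  set.seed(12)
  recs <- mapply(make_rec, runif(25, 0.5, 3),
                 rep(sprintf("P%d", 1:5), 5), SIMPLIFY = FALSE)
  fit <- fit_ts_basis(spec, recs, K = 5, L = L, fs = fs)
  pred <- predict_method(fit, recs[[1]], fs)
  expect_lt(sqrt(mean((pred$series - recs[[1]]$force)^2)) /
              (mass * GRAVITY), 1e-6)

  # K = 1: predictions are half-sine arcs, zero at both ends
  fit1 <- fit_ts_basis(spec, recs, K = 1, L = L, fs = fs)
  p1 <- predict_method(fit1, recs[[1]], fs)
  expect_equal(p1$series[1], 0, tolerance = 1e-8)
  expect_equal(p1$series[L], 0, tolerance = 1e-8)
  shape <- p1$series / max(p1$series)
  expect_equal(shape, sin(pi * tau) / max(sin(pi * tau)),
               tolerance = 1e-6)

  # pointwise variance of in-sample predictions never exceeds the target
  recs_h <- mapply(function(alpha, id) {
    r <- make_rec(alpha, id)
    set.seed(nchar(id) + round(alpha * 100))
    r$force <- r$force + rnorm(L, 0, 40)     # heterogeneous targets
    r
  }, runif(25, 0.5, 3), rep(sprintf("P%d", 1:5), 5), SIMPLIFY = FALSE)
  fit_h <- fit_ts_basis(spec, recs_h, K = 8, L = L, fs = fs)
  preds <- vapply(recs_h, function(r) predict_method(fit_h, r, fs)$series,
                  numeric(L))
  targets <- vapply(recs_h, function(r) {
    resample_series(r$force, L)
  }, numeric(L))
  # regressing basis coefficients on features projects them, so predicted
  # series can never be pointwise more variable than the basis-projected
  # targets; aggregate variance also shrinks against the raw targets
  B <- accelGRF:::sine_basis(L, 8)
  proj <- apply(targets, 2, function(y) B %*% qr.solve(B, y))
  v_pred <- apply(preds, 1, var)
  v_proj <- apply(proj, 1, var)
  v_targ <- apply(targets, 1, var)
  expect_true(all(v_pred <= v_proj * (1 + 1e-8) + 1e-8))
  expect_lt(mean(v_pred), mean(v_targ))

  expect_error(fit_ts_basis(spec, recs, K = 100, L = 100), "smaller")
})

test_that("network family is deterministic, normalizes, and can overfit", {
  fs <- 1000
  reg <- build_registry()
  spec <- reg[["Pogson"]]
  specx <- reg[["Pogson xynorm"]]
  set.seed(20)
  recs <- lapply(1:20, function(i) {
    st <- one_stance(fsa = runif(1, -0.1, 0.35), speed = runif(1, 2.6, 4.4),
                     seed = 600 + i, noise = TRUE)
    n <- length(st$force)
    accel <- cbind(0.3 * sin(2 * pi * (0:(n - 1)) / n),
                   st$force / (70 * GRAVITY) - 1,
                   rnorm(n, 0, 0.02))
    list(participant = sprintf("P%d", (i %% 5) + 1), mass = 70,
         height = 1.7, leg_length = 0.9, sex = "F", age = 30,
         accel = accel, gold = list(), force = st$force, fs = fs)
  })
  fit_a <- fit_nn(spec, recs, seed = 33, epochs = 50)
  fit_b <- fit_nn(spec, recs, seed = 33, epochs = 50)
  expect_identical(fit_a$fits$net$layers, fit_b$fits$net$layers)

  # capacity: 20 stances can be overfitted to < 0.1 BW training RMSE
  fit_o <- fit_nn(spec, recs, seed = 33, epochs = 800)
  rmse <- vapply(recs, function(r) {
    p <- predict_method(fit_o, r, fs)
    sqrt(mean((p$series - r$force)^2)) / (70 * GRAVITY)
  }, numeric(1))
  expect_lt(mean(rmse), 0.1)

  # xynorm scales the x and y input channels to unit peak per stance
  xin <- accelGRF:::nn_inputs(recs[[1]], specx, 100)
  expect_equal(max(abs(xin[1:100])), 1, tolerance = 1e-9)
  expect_equal(max(abs(xin[101:200])), 1, tolerance = 1e-9)
  expect_error(fit_nn(spec, recs[1:5], seed = 1), "at least 10")
})

test_that("derived features reduce to the gold operations", {
  st <- one_stance(fsa = 0.3)
  gold <- extract_features(st$force)
  d <- derive_features_from_series(gold$time_series)
  expect_equal(d$first_peak, gold$first_peak)
  expect_equal(d$second_peak, gold$second_peak)
  expect_equal(d$average, gold$average)
  expect_equal(d$loading_rate, gold$loading_rate)
  flat <- rep(700, 300)
  d2 <- derive_features_from_series(flat)
  expect_true(is.na(d2$first_peak))
  hs <- 2 * 70 * GRAVITY * sin(pi * (0:299) / 299)
  expect_equal(derive_features_from_series(hs)$average,
               4 * 70 * GRAVITY / pi, tolerance = 0.01)
  expect_error(derive_features_from_series(rep(1, 5)), "10 samples")
})

test_that("LOO harness trains without leakage and respects families", {
  records <- records_small()
  reg <- build_registry()[c("Gurchiek", "Kiernan sacrum",
                            "Kim acceleration")]
  loo <- suppressWarnings(loo_estimate_all(records, reg, seed = 5,
                                           keep_fits = TRUE))
  participants <- unique(vapply(records, `[[`, character(1),
                                "participant"))
  # leakage audit: every fold excludes its own participant
  for (p in participants) {
    expect_false(p %in% loo$folds[[p]])
    expect_setequal(loo$folds[[p]], setdiff(participants, p))
    for (m in c("Kiernan sacrum", "Kim acceleration")) {
      expect_false(p %in% loo$fits[[p]][[m]]$train_participants)
    }
  }
  # 4 folds produce 4 distinct fitted parameter sets per trainable method
  co <- vapply(participants, function(p) {
    coef(loo$fits[[p]][["Kiernan sacrum"]]$fits$second_peak$fit)[1]
  }, numeric(1))
  expect_equal(length(unique(co)), 4)

  # DIRECT estimates are identical whether or not LOO is used
  rec1 <- records[[1]]
  rec1$accel <- rec1$accels$sacrum
  direct <- estimate_direct(reg[["Gurchiek"]], rec1$accel, rec1$mass,
                            rec1$fs)
  got <- loo$estimates[loo$estimates$stance_id == rec1$stance_id &
                         loo$estimates$method == "Gurchiek" &
                         loo$estimates$feature == "average", "value"]
  expect_equal(got, unname(direct$features["average"]))
  expect_error(loo_estimate_all(records[1:4], reg),
               "at least 3 participants")
})
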