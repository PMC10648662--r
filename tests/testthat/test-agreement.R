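# Agreement statistics: errors, t-tests with FDR, variance components,
# RC/LOA identities, condition-effect models, bias surfaces.

toy_gold <- function() {
  data.frame(stance_id = c("s1", "s2"), participant = c("P1", "P2"),
             surface = "floor", speed = 3.3, fsa = 0.1,
             feature = "second_peak", value = c(1700, 1600),
             stringsAsFactors = FALSE)
}

test_that("errors are estimate minus gold, RMSE for series", {
  est <- data.frame(stance_id = c("s1", "s2"), participant = c("P1", "P2"),
                    method = "m", feature = "second_peak",
                    value = c(1800, 1600), stringsAsFactors = FALSE)
  gold <- toy_gold()
  gs <- list(s1 = rep(1000, 100), s2 = rep(900, 100))
  ser <- list(m = list(s1 = rep(1050, 100), s2 = rep(900, 100)))
  err <- compute_errors(est, gold, ser, gs)
  e1 <- err[err$method == "m" & err$feature == "second_peak", ]
  expect_equal(e1$error[e1$stance_id == "s1"], 100)
  expect_equal(e1$error[e1$stance_id == "s2"], 0)
  ets <- err[err$method == "m" & err$feature == "time_series", ]
  expect_equal(ets$error[ets$stance_id == "s1"], 50)   # constant offset
  expect_equal(ets$error[ets$stance_id == "s2"], 0)
  ref <- err[err$method == "reference", ]
  expect_true(all(ref$error == 0))
  expect_true(all(c("speed", "surface", "fsa") %in% names(err)))
  est_bad <- est
  est_bad$stance_id <- c("s1", "zzz")
  expect_error(compute_errors(est_bad, gold), "absent")
})

test_that("t-tests and the BH correction match the step-up oracle", {
  set.seed(21)
  sym <- data.frame(method = "m", participant = "P1", stance_id = "x",
                    feature = "f", estimate = NA, gold = NA,
                    error = c(-3, 3, -2, 2, -1, 1))
  tt <- ttest_fdr(sym)
  expect_gt(tt$p, 0.99)

  # BH flags equal the literal step-up rule on random p-vectors
  for (i in 1:100) {
    m <- sample(5:40, 1)
    p <- runif(m)^sample(1:3, 1)   # mix of uniform-ish and small p
    flags <- p.adjust(p, "BH") <= 0.05
    expect_equal(unname(flags), bh_stepup(p, 0.05),
                 label = paste("p-vector", i))
  }

  # a single test: adjusted p equals the raw p
  one <- data.frame(method = "m", participant = "P1", stance_id = "x",
                    feature = "f", estimate = NA, gold = NA,
                    error = rnorm(20, 1))
  t1 <- ttest_fdr(one)
  expect_equal(t1$p_adj, t1$p)

  # zero-variance cell flagged degenerate with undefined p
  zv <- data.frame(method = "m", participant = "P1", stance_id = "x",
                   feature = "f", estimate = NA, gold = NA,
                   error = rep(2, 10))
  tz <- ttest_fdr(zv)
  expect_true(tz$degenerate)
  expect_true(is.na(tz$p))
})

test_that("RC and LOA identities hold exactly", {
  expect_equal(rc_from_sigma(0), 0)
  expect_equal(rc_from_sigma(10), 28.3)
  expect_equal(rc_from_sigma(1), 2.83)
  expect_error(rc_from_sigma(-1), ">= 0")
  expect_equal(loa_from_components(0, 0, 0, 0), 0)
  expect_equal(loa_from_components(0, 3, 0, 4), 9.8)
  # symmetric under swapping reference and method components
  expect_equal(loa_from_components(3, 0, 4, 0),
               loa_from_components(0, 3, 0, 4))
  expect_error(loa_from_components(-1, 0, 0, 0), ">= 0")
  # 2.83 is 2 * sqrt(2) rounded to two decimals: the difference of two
  # replicates has SD sigma * sqrt(2), doubled for the 95% range
  expect_lt(abs(rc_from_sigma(1) - 2 * sqrt(2)) / (2 * sqrt(2)), 0.002)
})

test_that("linked-replicates fit: degenerate, equivariant, recovering", {
  # all-zero errors: all variance estimates vanish
  zero <- sim_linked_errors(4, 3, c(A = 0, B = 0), c(A = 0, B = 0),
                            c(A = 0, B = 0), b_sd = 0, d_sd = 0, seed = 2)
  vc0 <- fit_linked_replicates(zero, "second_peak", "error")
  expect_true(all(abs(c(vc0$components$tau, vc0$components$sigma)) < 1e-8))

  err <- sim_linked_errors(20, 6, c(A = 10, B = -5), c(A = 5, B = 8),
                           c(A = 10, B = 14), seed = 3)
  vc1 <- suppressWarnings(fit_linked_replicates(err, "second_peak",
                                                "error"))
  err2 <- err
  err2$error <- 2 * err$error
  vc2 <- suppressWarnings(fit_linked_replicates(err2, "second_peak",
                                                "error"))
  # doubling all errors doubles every estimated SD and intercept
  expect_equal(vc2$components$sigma, 2 * vc1$components$sigma,
               tolerance = 1e-6)
  expect_equal(vc2$components$tau, 2 * vc1$components$tau,
               tolerance = 1e-6)
  expect_equal(vc2$components$a, 2 * vc1$components$a, tolerance = 1e-6)
  expect_equal(vc2$participant_sd, 2 * vc1$participant_sd,
               tolerance = 1e-6)
  expect_error(fit_linked_replicates(err[err$participant %in%
                                           c("P01", "P02"), ],
                                     "second_peak", "error"),
               "participants")
})

test_that("variance components agree with an independent lme4 fit", {
  skip_if_not_installed("lme4")
  err <- sim_linked_errors(40, 10, a = c(A = 10, B = -5),
                           tau = c(A = 12, B = 6), sig = c(A = 10, B = 10),
                           b_sd = 15, d_sd = 12, seed = 5)
  vc <- suppressWarnings(fit_linked_replicates(err, "second_peak",
                                               "error"))
  d <- err
  d$dA <- as.numeric(d$method == "A")
  d$dB <- as.numeric(d$method == "B")
  d$trial <- paste(d$participant, sub(".*_t", "", d$stance_id))
  m <- suppressMessages(lme4::lmer(
    error ~ method - 1 + (1 | participant) + (0 + dA | participant) +
      (0 + dB | participant) + (1 | trial),
    data = d, REML = TRUE))
  v4 <- as.data.frame(lme4::VarCorr(m))
  tauA4 <- v4$sdcor[!is.na(v4$var1) & v4$var1 == "dA"]
  comp <- vc$components
  expect_equal(comp$tau[comp$method == "A"], tauA4, tolerance = 0.02)
  expect_equal(comp$a[comp$method == "A"],
               unname(lme4::fixef(m)[["methodA"]]), tolerance = 0.01)
  expect_equal(vc$trial_sd, v4$sdcor[v4$grp == "trial"][1],
               tolerance = 0.02)
})

test_that("measurement formulation estimates reference components", {
  set.seed(31)
  P <- 12; Tn <- 6
  gold_rows <- list()
  for (p in 1:P) {
    truth <- 1600 + rnorm(1, 0, 150) + rnorm(Tn, 0, 80)
    gold_rows[[p]] <- data.frame(
      stance_id = sprintf("P%02d_t%d", p, 1:Tn),
      participant = sprintf("P%02d", p), surface = "floor", speed = 3.3,
      fsa = 0.1, feature = "second_peak", value = truth,
      stringsAsFactors = FALSE)
  }
  gold <- do.call(rbind, gold_rows)
  est <- data.frame(stance_id = gold$stance_id,
                    participant = gold$participant, method = "mock",
                    feature = "second_peak",
                    value = gold$value + 50 + rnorm(nrow(gold), 0, 30),
                    stringsAsFactors = FALSE)
  err <- compute_errors(est, gold)
  vc <- suppressWarnings(agreement_by_method(err, "second_peak",
                                             "measurement"))
  s <- summarize_agreement(vc)
  expect_equal(s$bias, 50, tolerance = 0.5)     # absolute: bias near +50 N
  expect_gt(vc$sigma0, 0)                        # reference varies by trial
  expect_equal(s$loa,
               1.96 * sqrt(vc$tau0^2 + s$tau^2 + vc$sigma0^2 + s$sigma^2),
               tolerance = 1e-9)
  expect_equal(s$rc, 2.83 * s$sigma, tolerance = 1e-12)
})

test_that("condition model recovers injected speed slopes and coding", {
  set.seed(41)
  P <- 25; Tn <- 12
  rows <- list()
  for (p in 1:P) {
    v <- rnorm(Tn, 3.3, 0.5)
    fsa <- rnorm(Tn, 0.15, 0.1)
    surf <- rep(c("floor", "track"), length.out = Tn)
    e <- 50 * (v - 3.3) + rnorm(1, 0, 15) + rnorm(Tn, 0, 20)
    rows[[p]] <- data.frame(method = "m", participant = sprintf("P%d", p),
                            stance_id = sprintf("P%d_t%d", p, 1:Tn),
                            feature = "second_peak", estimate = NA,
                            gold = NA, error = e, speed = v,
                            surface = surf, fsa = fsa,
                            stringsAsFactors = FALSE)
  }
  err <- do.call(rbind, rows)
  ce <- fit_condition_model(err, "second_peak", "m")
  expect_lt(abs(ce$speed["est"] - 50) / ce$speed["se"], 3)
  expect_lte(ce$speed["p"], 0.05)

  # floor rows coded 0: intercept is the floor-condition mean bias
  set.seed(42)
  rows2 <- lapply(1:10, function(p) {
    surf <- rep(c("floor", "track"), each = 4)
    data.frame(method = "m", participant = sprintf("P%d", p),
               stance_id = sprintf("P%d_t%d", p, 1:8),
               feature = "average", estimate = NA, gold = NA,
               error = 10 + 5 * (surf == "track") + rnorm(8, 0, 0.5),
               speed = 3.3, surface = surf, fsa = 0.1,
               stringsAsFactors = FALSE)
  })
  err2 <- do.call(rbind, rows2)
  expect_warning(ce2 <- fit_condition_model(err2, "average", "m"),
                 "constant")
  floor_mean <- mean(err2$error[err2$surface == "floor"])
  expect_equal(unname(ce2$intercept["est"]), floor_mean, tolerance = 0.05)
  expect_equal(unname(ce2$surface["est"]), 5, tolerance = 0.5)
})

test_that("bias surfaces evaluate the linear form on the grid", {
  eff <- structure(list(method = "m", feature = "second_peak",
                        intercept = c(est = 10, se = 1, p = 0.01),
                        speed = c(est = -20, se = 2, p = 0.01),
                        surface = c(est = 0, se = 1, p = 0.9),
                        fsa = c(est = 100, se = 30, p = 0.01), n = 100),
                   class = "condition_effects")
  sg <- seq(2.5, 5, length.out = 50)
  fg <- seq(-0.2, 0.4, length.out = 50)
  surf <- predict_bias_surface(eff, sg, fg)
  expect_equal(dim(surf), c(50, 50))
  expect_equal(surf[3, 7], 10 - 20 * sg[3] + 100 * fg[7])
  expect_equal(attr(surf, "strike_bands"),
               c(FFS_MFS = -0.03, MFS_RFS = 0.14))
  # zero slopes: constant surface at the intercept
  eff0 <- eff
  eff0$speed["est"] <- 0
  eff0$fsa["est"] <- 0
  s0 <- predict_bias_surface(eff0, sg, fg)
  expect_true(all(s0 == 10))
  expect_error(predict_bias_surface(eff, numeric(0), fg), "empty")
})

test_that("mock-method coverage: ~95% of fresh errors inside bias +/- LOA", {
  set.seed(51)
  P <- 40; Tn <- 15
  tau_true <- 30; sig_true <- 60; bias_true <- 25
  sim_p <- function(P, Tn) {
    u <- rnorm(P, 0, tau_true)
    do.call(rbind, lapply(1:P, function(p) {
      data.frame(method = "mock", participant = sprintf("P%d", p),
                 stance_id = sprintf("P%d_t%d", p, 1:Tn), feature = "f",
                 estimate = NA, gold = NA,
                 error = bias_true + u[p] + rnorm(Tn, 0, sig_true),
                 stringsAsFactors = FALSE)
    }))
  }
  fitdat <- sim_p(P, Tn)
  class(fitdat) <- c("error_table", "data.frame")
  vc <- fit_linked_replicates(fitdat, "f", "error")
  s <- summarize_agreement(vc)
  expect_equal(s$bias, bias_true, tolerance = 0.4)  # within 10 N
  expect_equal(s$rc, 2.83 * s$sigma, tolerance = 1e-12)
  fresh <- sim_p(120, 15)
  inside <- abs(fresh$error - s$bias) <= s$loa
  expect_lt(abs(mean(inside) - 0.95), 0.025)
})
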