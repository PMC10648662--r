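# Shared fixtures and independent oracles. Everything is generated in code;
# small datasets are memoized so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

zero_noise <- function() {
  list(accel_sd = 0, ripple_amp = 0, ripple_hz = 8, gyro_sd = 0,
       gyro_amp = 0, force_sd = 0)
}

# noiseless 2-participant dataset (Newtonian-exact signals)
ds_noiseless <- function() memoize("ds_noiseless", {
  generate_dataset(cohort_config(n_participants = 2, sides = "left",
                                 stances_per_cell = 1,
                                 noise = zero_noise(), seed = 404L))
})

# small noisy dataset for estimator / agreement tests
ds_small <- function() memoize("ds_small", {
  generate_dataset(cohort_config(n_participants = 4, sides = "left",
                                 stances_per_cell = 2, seed = 99L))
})

records_small <- function() memoize("records_small", {
  prepare_stance_inputs(ds_small())
})

# stance records restricted to one placement (the `accel` the families use)
records_for_placement <- function(records, placement) {
  lapply(records, function(r) {
    r$accel <- r$accels[[placement]]
    r
  })
}

# one mid-foot-ish stance force series + condition for feature tests
one_stance <- function(fsa = 0.30, speed = 3.3, mass = 70, seed = 1,
                       noise = FALSE) {
  cfg <- if (noise) cohort_config() else cohort_config(noise = zero_noise())
  part <- data.frame(id = "P1", mass = mass, height = 1.75,
                     leg_length = 0.92, sex = "F", age = 30,
                     mean_fsa = fsa, act_mult = 1, imp_mult = 1)
  cond <- data.frame(stance_id = "P1_s1", participant_id = "P1",
                     surface = "floor", speed_class = "typical",
                     speed = speed, side = "left", fsa = fsa,
                     stance_index = 1, seed = seed)
  set.seed(seed)
  synthesize_vgrf(cond, part, cfg, noise = noise)
}

# ---- independent oracles ----

# direct O(n^2) discrete Fourier transform (independent of stats::fft)
brute_dft <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  W <- exp(-2i * pi * outer(j, j) / n)
  as.vector(W %*% x)
}

brute_idft <- function(X) {
  n <- length(X)
  j <- 0:(n - 1)
  W <- exp(2i * pi * outer(j, j) / n)
  Re(as.vector(W %*% X)) / n
}

# plain-loop local maxima with the plateau-takes-first-sample rule
oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      # scan over a possible plateau
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j < n && x[j + 1] < x[i]) out <- c(out, i)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# brute-force spectral-split first peak (same rule set, independent path)
oracle_hif_first_peak <- function(force, fs = 1000, cutoff = 10,
                                  gate = 0.05, min_rel = 0.05) {
  n <- length(force)
  X <- brute_dft(force)
  freq <- (0:(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)
  X[freq < cutoff] <- 0
  hif <- brute_idft(X)
  cand <- oracle_local_maxima(hif)
  cand <- cand[cand > gate * (n - 1) + 1 & cand < n]
  cand <- cand[hif[cand] >= min_rel * max(force)]
  if (length(cand) == 0) return(NULL)
  list(index = cand[1], magnitude = force[cand[1]])
}

oracle_second_peak <- function(force, first_idx = NULL) {
  if (is.null(first_idx) || is.na(first_idx)) return(max(force))
  cand <- oracle_local_maxima(force)
  cand <- cand[cand > first_idx]
  if (length(cand) == 0) return(max(force))
  max(force[cand])
}

# literal Benjamini-Hochberg step-up rule
bh_stepup <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= (seq_len(m) / m) * q)
  flags <- rep(FALSE, m)
  if (length(k) > 0) flags[ord[seq_len(max(k))]] <- TRUE
  flags
}

# simulate the linked-replicates generating model directly
sim_linked_errors <- function(P, Tn, a, tau, sig, b_sd = 20, d_sd = 15,
                              feature = "second_peak", seed = 1) {
  set.seed(seed)
  methods <- names(a)
  b <- stats::rnorm(P, 0, b_sd)
  rows <- list()
  for (p in seq_len(P)) {
    D <- stats::rnorm(Tn, 0, d_sd)
    C <- stats::setNames(stats::rnorm(length(methods), 0, tau), methods)
    for (m in methods) {
      e <- stats::rnorm(Tn, 0, sig[m])
      rows[[length(rows) + 1]] <- data.frame(
        method = m, participant = sprintf("P%02d", p),
        stance_id = sprintf("P%02d_t%02d", p, seq_len(Tn)),
        feature = feature, estimate = NA_real_, gold = NA_real_,
        error = a[m] + b[p] + C[m] + D + e, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_table", "data.frame")
  out
}

# literal transcription of the published method capability table:
# D = designed, d = derived from an estimated time series, . = none
capability_fixture <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
method              placement fp lr sp av ts
Charry              shank     .  .  D  .  .
Thiel               shank     .  .  D  .  .
'Veras shank res'   shank     .  D  D  .  .
'Veras shank y'     shank     .  D  D  .  .
'Higgins shank'     shank     D  D  .  .  .
Neugebauer          hip       .  .  D  .  .
Meyer               hip       .  .  D  .  .
'Kiernan hip'       hip       D  .  D  .  .
'Veras hip res'     hip       .  D  D  .  .
'Veras hip y'       hip       .  D  D  .  .
'Higgins hip'       hip       D  D  .  .  .
Gurchiek            sacrum    d  d  d  D  D
'Kim acceleration'  sacrum    d  d  d  d  D
'Kim displacement'  sacrum    d  d  d  d  D
'Kiernan sacrum'    sacrum    D  .  D  .  .
'Veras sacrum res'  sacrum    .  D  D  .  .
'Veras sacrum y'    sacrum    .  D  D  .  .
'Day 5 Hz'          sacrum    d  d  D  d  D
'Day 10 Hz'         sacrum    d  d  D  d  D
'Day 30 Hz'         sacrum    d  d  D  d  D
'Wundersitz 10 Hz'  sacrum    .  .  D  .  .
'Wundersitz 15 Hz'  sacrum    .  .  D  .  .
'Wundersitz 20 Hz'  sacrum    .  .  D  .  .
'Wundersitz 25 Hz'  sacrum    .  .  D  .  .
'Wundersitz raw'    sacrum    .  .  D  .  .
Pogson              sacrum    d  d  d  d  D
'Pogson xynorm'     sacrum    d  d  d  d  D")
}

expect_capabilities_match <- function(caps, fixture) {
  code <- c(D = "designed", d = "derived", "." = "none")
  testthat::expect_setequal(caps$method, fixture$method)
  for (i in seq_len(nrow(fixture))) {
    row <- caps[caps$method == fixture$method[i], ]
    testthat::expect_equal(row$placement, fixture$placement[i],
                           label = fixture$method[i])
    got <- unname(unlist(row[c("first_peak", "loading_rate", "second_peak",
                               "average", "time_series")]))
    want <- unname(code[unlist(fixture[i, c("fp", "lr", "sp", "av",
                                            "ts")])])
    testthat::expect_equal(got, want, label = fixture$method[i])
  }
}

quat_angle_deg <- function(q1, q2) {
  d <- abs(sum(q1 * q2))
  2 * acos(min(1, d)) * 180 / pi
}
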