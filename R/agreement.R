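# Method-agreement statistics for linked replicates.
#
# Every trial is measured by all methods and by the gold-standard force
# plate, so trial-level variation is shared across methods. Measurements
# (or errors) enter a crossed mixed-effects model
#
#   y[m, p, t] = a[m] + b[p] + C[m, p] + D[p, t] + e[m, p, t]
#
# with fixed method intercepts a, random participant effects b, a
# method x participant interaction C ~ N(0, tau_m^2), shared
# participant x trial effects D, and method-specific residuals
# e ~ N(0, sigma_m^2). From the fitted components:
#
#   RC_m  = 2.83 * sigma_m                         (repeatability)
#   LOA_m = 1.96 * sqrt(tau_0^2 + tau_m^2 + sigma_0^2 + sigma_m^2)
#
# where tau_0, sigma_0 are the gold-standard (reference) components. The
# default "measurement" formulation enters the reference rows as their own
# method so tau_0/sigma_0 are estimated; the "error" formulation models
# errors directly with the reference components pinned at 0.

REFERENCE_METHOD <- "reference"

#' Per-trial errors relative to the gold standard
#'
#' Discrete features: estimate - gold. Time series: RMSE over stance after
#' resampling the estimate to the gold length (gold reference RMSE is 0).
#' Reference rows (the gold standard measured against itself) are emitted
#' for every stance x feature so the linked-replicates model can estimate
#' the reference variance components.
#'
#' @param estimates data.frame from [loo_estimate_all()] (`$estimates`).
#' @param gold data.frame with columns `stance_id`, `participant`,
#'   `feature`, `value`, and condition covariates `speed`, `surface`,
#'   `fsa`.
#' @param series optional nested list (method -> stance_id -> estimated
#'   series) used to build time-series RMSE rows.
#' @param gold_series optional named list stance_id -> gold stance series.
#' @return data.frame of class `error_table`: `method`, `participant`,
#'   `stance_id`, `feature`, `estimate`, `gold`, `error`, plus covariates.
#' @export
compute_errors <- function(estimates, gold, series = NULL,
                           gold_series = NULL) {
  key <- paste(gold$stance_id, gold$feature)
  gmap <- stats::setNames(gold$value, key)
  meta_cols <- intersect(c("participant", "speed", "surface", "fsa"),
                         names(gold))
  meta <- gold[!duplicated(gold$stance_id),
               c("stance_id", meta_cols), drop = FALSE]

  est <- estimates[estimates$feature != "time_series", , drop = FALSE]
  ekey <- paste(est$stance_id, est$feature)
  missing_ids <- setdiff(est$stance_id, gold$stance_id)
  if (length(missing_ids) > 0) {
    stop("estimates reference stances absent from the gold table: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  est$gold <- unname(gmap[ekey])
  est$error <- est$value - est$gold
  names(est)[names(est) == "value"] <- "estimate"

  rows <- est[, c("method", "participant", "stance_id", "feature",
                  "estimate", "gold", "error")]

  # time-series rows: per-trial RMSE, reference RMSE identically 0
  if (!is.null(series) && length(series) > 0) {
    ts_rows <- list()
    for (m in names(series)) {
      for (sid in names(series[[m]])) {
        gs <- gold_series[[sid]]
        if (is.null(gs)) next
        es <- series[[m]][[sid]]
        if (length(es) != length(gs)) {
          es <- resample_series(es, length(gs))
        }
        rmse <- sqrt(mean((es - gs)^2))
        ts_rows[[length(ts_rows) + 1]] <- data.frame(
          method = m,
          participant = meta$participant[match(sid, meta$stance_id)],
          stance_id = sid, feature = "time_series", estimate = rmse,
          gold = 0, error = rmse, stringsAsFactors = FALSE)
      }
    }
    if (length(ts_rows) > 0) rows <- rbind(rows, do.call(rbind, ts_rows))
  }

  # reference rows: the gold standard measured against itself
  ref <- gold[, c("stance_id", "feature", "value")]
  ref <- ref[is.finite(ref$value), , drop = FALSE]
  ref_rows <- data.frame(method = REFERENCE_METHOD,
                         participant = meta$participant[
                           match(ref$stance_id, meta$stance_id)],
                         stance_id = ref$stance_id, feature = ref$feature,
                         estimate = ref$value, gold = ref$value, error = 0,
                         stringsAsFactors = FALSE)
  if (!is.null(gold_series) && length(gold_series) > 0) {
    sid <- names(gold_series)
    ref_ts <- data.frame(method = REFERENCE_METHOD,
                         participant = meta$participant[
                           match(sid, meta$stance_id)],
                         stance_id = sid, feature = "time_series",
                         estimate = 0, gold = 0, error = 0,
                         stringsAsFactors = FALSE)
    ref_rows <- rbind(ref_rows, ref_ts)
  }
  rows <- rbind(rows, ref_rows)
  rows <- rows[is.finite(rows$error), , drop = FALSE]
  extra <- setdiff(meta_cols, "participant")
  for (cn in extra) {
    rows[[cn]] <- meta[[cn]][match(rows$stance_id, meta$stance_id)]
  }
  rownames(rows) <- NULL
  class(rows) <- c("error_table", "data.frame")
  rows
}

#' One-sample t-tests with Benjamini-Hochberg FDR correction
#'
#' Tests each method x feature mean error against 0 and flags cells that
#' remain significant after a Benjamini-Hochberg false-discovery-rate
#' correction across the whole family of tests at level `q`.
#'
#' @param errors an `error_table` (reference rows are ignored).
#' @param q FDR level (default 0.05).
#' @return data.frame: `method`, `feature`, `n`, `mean_error`, `t`, `p`,
#'   `p_adj`, `significant`. Zero-variance cells get `NA` p-values and are
#'   flagged in `degenerate`.
#' @export
ttest_fdr <- function(errors, q = 0.05) {
  errors <- errors[errors$method != REFERENCE_METHOD, , drop = FALSE]
  cells <- unique(errors[, c("method", "feature")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    e <- errors$error[errors$method == cells$method[i] &
                        errors$feature == cells$feature[i]]
    e <- e[is.finite(e)]
    if (length(e) < 2 || stats::sd(e) < 1e-12) {
      return(data.frame(method = cells$method[i],
                        feature = cells$feature[i], n = length(e),
                        mean_error = mean(e), t = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(e)
    data.frame(method = cells$method[i], feature = cells$feature[i],
               n = length(e), mean_error = mean(e),
               t = unname(tt$statistic), p = tt$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj <= q
  rownames(out) <- NULL
  out
}

#' Fit the linked-replicates variance-components model
#'
#' REML fit (via nlme) of the crossed random-effects model with a fixed
#' intercept per method, a shared participant effect, a per-method
#' method x participant interaction variance tau_m^2 (diagonal
#' participant-level covariance), a shared participant x trial effect, and
#' per-method residual variances sigma_m^2 (varIdent). On non-convergence
#' the response is rescaled once and the model refitted.
#'
#' @param errors an `error_table`.
#' @param feature which feature's rows to model.
#' @param formulation "measurement" (default) enters reference rows as
#'   their own method so the reference components tau_0, sigma_0 are
#'   estimated; "error" models errors with reference components pinned at
#'   0.
#' @param methods optional character vector restricting the fit to a
#'   subset of methods (the reference is retained automatically in the
#'   measurement formulation). [agreement_by_method()] uses this to fit
#'   each method paired with the reference.
#' @return object of class `variance_components`: data.frame `components`
#'   (method, a, bias, tau, sigma), scalars `participant_sd`, `trial_sd`,
#'   `tau0`, `sigma0`, the fitted `model`, and `formulation`.
#' @export
fit_linked_replicates <- function(errors, feature,
                                  formulation = c("measurement", "error"),
                                  methods = NULL) {
  formulation <- match.arg(formulation)
  d <- errors[errors$feature == feature, , drop = FALSE]
  if (!is.null(methods)) {
    keep_m <- if (formulation == "measurement") {
      c(methods, REFERENCE_METHOD)
    } else {
      methods
    }
    d <- d[d$method %in% keep_m, , drop = FALSE]
  }
  if (formulation == "error") {
    d <- d[d$method != REFERENCE_METHOD, , drop = FALSE]
    d$y <- d$error
  } else {
    d$y <- d$estimate
  }
  d <- d[is.finite(d$y), , drop = FALSE]
  if (formulation == "measurement" && length(unique(d$method)) < 2) {
    stop("linked-replicates model needs at least 2 methods ",
         "(including the reference)")
  }
  if (nrow(d) == 0) stop("no usable rows for feature ", feature)
  if (length(unique(d$participant)) < 3) {
    stop("linked-replicates model needs at least 3 participants")
  }
  d$method <- factor(d$method)
  d$participant <- factor(d$participant)
  # within-participant replicate index, shared across methods for the same
  # trial (this is what links the replicates)
  d$trial_f <- factor(stats::ave(as.character(d$stance_id), d$participant,
                                 FUN = function(s) {
                                   as.integer(factor(s,
                                                     levels = unique(s)))
                                 }))

  all_methods <- levels(d$method)
  # degenerate short-circuit: no variation anywhere
  if (stats::sd(d$y) < 1e-12) {
    comp <- data.frame(method = all_methods,
                       a = rep(mean(d$y), length(all_methods)),
                       bias = 0, tau = 0, sigma = 0,
                       stringsAsFactors = FALSE)
    return(structure(list(components = comp, participant_sd = 0,
                          trial_sd = 0, tau0 = 0, sigma0 = 0,
                          model = NULL, formulation = formulation,
                          feature = feature),
                     class = "variance_components"))
  }

  # methods without internal variation (e.g. the reference entered as
  # per-trial time-series RMSE, identically 0) have tau = sigma = 0 by
  # construction and cannot sit in a variance stratum; pin them. Methods
  # with too few rows are dropped with NA components.
  scale_all <- stats::sd(d$y)
  m_sd <- tapply(d$y, d$method, stats::sd)
  m_n <- tapply(d$y, d$method, length)
  pinned <- all_methods[m_sd[all_methods] < 1e-10 * scale_all]
  sparse <- setdiff(all_methods[m_n[all_methods] < 3], pinned)
  if (length(sparse) > 0) {
    warning("dropping method(s) with fewer than 3 usable trials: ",
            paste(sparse, collapse = ", "), call. = FALSE)
  }
  methods <- setdiff(all_methods, c(pinned, sparse))
  if (length(methods) < 1) stop("no methods with estimable variation")
  dm <- droplevels(d[d$method %in% methods, , drop = FALSE])

  # standardize the response for the optimizer; components are rescaled on
  # the way out
  scale_fac <- stats::sd(dm$y)
  center <- mean(dm$y)
  dm$ys <- (dm$y - center) / scale_fac

  single <- length(methods) == 1
  fit_once <- function(opt) {
    if (single) {
      # one estimable method: the trial effect is confounded with the
      # residual and the interaction with the participant effect; fit
      # participant + residual and report them as tau/sigma
      nlme::lme(ys ~ 1, random = ~ 1 | participant,
                data = dm, method = "REML",
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 500,
                                           niterEM = 100, opt = opt,
                                           returnObject = FALSE))
    } else {
      nlme::lme(ys ~ method - 1,
                random = list(participant = nlme::pdBlocked(list(
                  nlme::pdIdent(~1),
                  nlme::pdDiag(~ method - 1),
                  nlme::pdIdent(~ trial_f - 1)))),
                weights = nlme::varIdent(form = ~ 1 | method),
                data = dm, method = "REML",
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 500,
                                           niterEM = 100, opt = opt,
                                           returnObject = FALSE))
    }
  }
  fit <- tryCatch(fit_once("nlminb"), error = function(e) e)
  if (inherits(fit, "error")) {
    fit <- tryCatch(fit_once("optim"), error = function(e) e)
    if (inherits(fit, "error")) {
      stop("linked-replicates model failed to converge: ",
           conditionMessage(fit))
    }
  }

  sigma_base <- fit$sigma * scale_fac
  vw <- fit$modelStruct$varStruct
  rel <- rep(1, length(methods))
  names(rel) <- methods
  if (!is.null(vw)) {
    cc <- stats::coef(vw, unconstrained = FALSE, allCoef = TRUE)
    rel[names(cc)] <- cc
  }
  sigma_m <- sigma_base * rel[methods]

  # participant-level SDs from the pdBlocked structure, in response units
  vc <- nlme::VarCorr(fit)
  sdcol <- suppressWarnings(as.numeric(vc[, "StdDev"])) * scale_fac
  names(sdcol) <- rownames(vc)
  if (single) {
    tau_m <- stats::setNames(sdcol[["(Intercept)"]], methods)
    b_sd <- 0
  } else {
    tau_m <- sdcol[paste0("method", methods)]
    names(tau_m) <- methods
    b_sd <- sdcol[["(Intercept)"]]
  }
  trial_names <- grep("^trial_f", names(sdcol), value = TRUE)
  trial_sd <- if (length(trial_names) > 0) unname(sdcol[trial_names[1]])
              else 0

  a <- nlme::fixef(fit) * scale_fac
  if (single) {
    names(a) <- methods
  } else {
    names(a) <- sub("^method", "", names(a))
  }
  a <- a[methods] + center

  # fold pinned and dropped methods back in
  for (m in pinned) {
    a[m] <- mean(d$y[d$method == m])
    tau_m[m] <- 0
    sigma_m[m] <- 0
  }
  for (m in sparse) {
    a[m] <- NA_real_
    tau_m[m] <- NA_real_
    sigma_m[m] <- NA_real_
  }
  methods <- all_methods

  if (formulation == "measurement") {
    if (!REFERENCE_METHOD %in% methods) {
      stop("measurement formulation requires reference rows")
    }
    tau0 <- unname(tau_m[REFERENCE_METHOD])
    sigma0 <- unname(sigma_m[REFERENCE_METHOD])
    bias <- a - a[REFERENCE_METHOD]
  } else {
    tau0 <- 0
    sigma0 <- 0
    bias <- a
  }
  keep <- setdiff(methods, REFERENCE_METHOD)
  comp <- data.frame(method = keep, a = unname(a[keep]),
                     bias = unname(bias[keep]), tau = unname(tau_m[keep]),
                     sigma = unname(sigma_m[keep]),
                     stringsAsFactors = FALSE)
  structure(list(components = comp, participant_sd = unname(b_sd),
                 trial_sd = trial_sd, tau0 = tau0, sigma0 = sigma0,
                 model = fit, formulation = formulation,
                 feature = feature),
            class = "variance_components")
}

#' Variance components per method, each paired with the reference
#'
#' The limits-of-agreement formula combines one method's components with
#' the gold standard's, so each method can be modeled jointly with the
#' reference alone. This pairwise strategy is the standard practice for
#' Bland-Altman comparisons against a gold standard and is far more robust
#' than one joint fit across dozens of methods. In the error formulation
#' (no reference rows) all requested methods are fitted jointly instead.
#'
#' @param errors an `error_table`.
#' @param feature feature to model.
#' @param formulation see [fit_linked_replicates()].
#' @param methods methods to include (default: all present).
#' @return a merged `variance_components`; methods whose pair fit fails
#'   get NA components with a warning.
#' @export
agreement_by_method <- function(errors, feature,
                                formulation = c("measurement", "error"),
                                methods = NULL) {
  formulation <- match.arg(formulation)
  if (formulation == "error") {
    return(fit_linked_replicates(errors, feature, formulation, methods))
  }
  present <- unique(errors$method[errors$feature == feature])
  if (is.null(methods)) methods <- setdiff(present, REFERENCE_METHOD)
  comps <- list()
  tau0 <- NA_real_; sigma0 <- NA_real_
  for (m in methods) {
    vc <- tryCatch(
      fit_linked_replicates(errors, feature, formulation, methods = m),
      error = function(e) {
        warning("agreement fit failed for ", m, "/", feature, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(vc)) {
      comps[[m]] <- data.frame(method = m, a = NA_real_, bias = NA_real_,
                               tau = NA_real_, sigma = NA_real_,
                               tau0 = NA_real_, sigma0 = NA_real_,
                               stringsAsFactors = FALSE)
    } else {
      row <- vc$components[vc$components$method == m, , drop = FALSE]
      row$tau0 <- vc$tau0
      row$sigma0 <- vc$sigma0
      comps[[m]] <- row
      if (is.na(tau0)) { tau0 <- vc$tau0; sigma0 <- vc$sigma0 }
    }
  }
  comp <- do.call(rbind, comps)
  rownames(comp) <- NULL
  structure(list(components = comp, participant_sd = NA_real_,
                 trial_sd = NA_real_,
                 tau0 = if (is.na(tau0)) 0 else tau0,
                 sigma0 = if (is.na(sigma0)) 0 else sigma0,
                 model = NULL, formulation = formulation,
                 feature = feature),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("linked-replicates variance components (%s formulation)\n",
              x$formulation))
  cat(sprintf("  participant SD %.3g, trial SD %.3g, tau0 %.3g, ",
              x$participant_sd, x$trial_sd, x$tau0))
  cat(sprintf("sigma0 %.3g\n", x$sigma0))
  print(x$components, digits = 4)
  invisible(x)
}

#' Repeatability coefficient from a residual SD
#'
#' RC = 2.83 * sigma: the largest absolute difference expected between two
#' measurements on the same participant under identical circumstances
#' (2.83 is 1.96 * sqrt(2) rounded to two decimals).
#'
#' @param sigma_method method residual SD (>= 0).
#' @return repeatability coefficient, same units.
#' @export
rc_from_sigma <- function(sigma_method) {
  if (any(sigma_method < 0)) stop("sigma must be >= 0")
  2.83 * sigma_method
}

#' Limits of agreement from variance components
#'
#' LOA = 1.96 * sqrt(tau0^2 + tau_m^2 + sigma0^2 + sigma_m^2): the
#' half-width of the interval expected to contain 95% of future errors for
#' the method, combining reference and method interaction and residual
#' components.
#'
#' @param tau0,tau_m,sigma0,sigma_m component SDs (>= 0).
#' @return LOA half-width, same units.
#' @export
loa_from_components <- function(tau0, tau_m, sigma0, sigma_m) {
  if (any(c(tau0, tau_m, sigma0, sigma_m) < 0)) {
    stop("variance-component SDs must be >= 0")
  }
  1.96 * sqrt(tau0^2 + tau_m^2 + sigma0^2 + sigma_m^2)
}

#' Summarize agreement per method for one feature
#'
#' Combines the variance components with the t-test/FDR table into the
#' bias / RC / LOA summary for one feature.
#'
#' @param vc a `variance_components`.
#' @param tests output of [ttest_fdr()] (optional).
#' @return data.frame: method, bias, rc, loa, tau, sigma, n, p, p_adj,
#'   significant.
#' @export
summarize_agreement <- function(vc, tests = NULL) {
  comp <- vc$components
  tau0 <- comp$tau0 %||% rep(vc$tau0, nrow(comp))
  sigma0 <- comp$sigma0 %||% rep(vc$sigma0, nrow(comp))
  ok <- is.finite(comp$tau) & is.finite(comp$sigma)
  loa <- rep(NA_real_, nrow(comp))
  loa[ok] <- loa_from_components(tau0[ok], comp$tau[ok], sigma0[ok],
                                 comp$sigma[ok])
  rc <- rep(NA_real_, nrow(comp))
  rc[ok] <- rc_from_sigma(comp$sigma[ok])
  out <- data.frame(method = comp$method, feature = vc$feature %||% NA,
                    bias = comp$bias, rc = rc, loa = loa,
                    tau = comp$tau, sigma = comp$sigma,
                    stringsAsFactors = FALSE)
  if (!is.null(tests)) {
    tf <- tests[tests$feature == (vc$feature %||% tests$feature[1]), ,
                drop = FALSE]
    idx <- match(out$method, tf$method)
    out$n <- tf$n[idx]
    out$p <- tf$p[idx]
    out$p_adj <- tf$p_adj[idx]
    out$significant <- tf$significant[idx]
  }
  out
}

#' Condition-effect mixed model for one method x feature
#'
#' Augments the error model with fixed effects of running speed (m/s),
#' surface (0 = floor, 1 = track), and foot strike angle (radians), with a
#' random participant intercept. Wald p-values use the normal
#' approximation. Constant covariates are dropped with a warning.
#'
#' @param errors an `error_table` with covariate columns.
#' @param feature,method the cell to model.
#' @return object of class `condition_effects`: coefficients, SEs,
#'   p-values, and metadata.
#' @export
fit_condition_model <- function(errors, feature, method) {
  d <- errors[errors$feature == feature & errors$method == method, ,
              drop = FALSE]
  if (nrow(d) < 4) stop("too few rows for a condition model")
  needed <- c("speed", "surface", "fsa")
  if (!all(needed %in% names(d))) {
    stop("condition covariates missing from the error table")
  }
  d$surface_track <- as.numeric(d$surface == "track")
  terms <- c(speed = "speed", surface = "surface_track", fsa = "fsa")
  keep <- vapply(terms, function(v) {
    length(unique(d[[v]])) > 1
  }, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(terms)[!keep], collapse = ", "), call. = FALSE)
  }
  rhs <- paste(terms[keep], collapse = " + ")
  if (rhs == "") stop("no non-constant covariates to model")
  d$participant <- factor(d$participant)
  fit <- nlme::lme(stats::as.formula(paste("error ~", rhs)),
                   random = ~ 1 | participant, data = d, method = "REML",
                   control = nlme::lmeControl(opt = "optim",
                                              returnObject = TRUE))
  tt <- summary(fit)$tTable
  coefs <- tt[, "Value"]
  ses <- tt[, "Std.Error"]
  pz <- 2 * stats::pnorm(-abs(coefs / ses))
  get <- function(nm) {
    if (nm %in% names(coefs)) {
      c(est = unname(coefs[nm]), se = unname(ses[nm]),
        p = unname(pz[nm]))
    } else {
      c(est = NA_real_, se = NA_real_, p = NA_real_)
    }
  }
  structure(list(method = method, feature = feature,
                 intercept = get("(Intercept)"),
                 speed = get("speed"),
                 surface = get("surface_track"),
                 fsa = get("fsa"),
                 n = nrow(d), model = fit),
            class = "condition_effects")
}

#' @export
print.condition_effects <- function(x, ...) {
  cat(sprintf("condition effects for %s / %s (n = %d)\n", x$method,
              x$feature, x$n))
  for (nm in c("intercept", "speed", "surface", "fsa")) {
    v <- x[[nm]]
    cat(sprintf("  %-9s %9.3f (SE %8.3f, p = %.3g)%s\n", nm, v["est"],
                v["se"], v["p"],
                if (!is.na(v["p"]) && v["p"] <= 0.05) " *" else ""))
  }
  invisible(x)
}

#' Predicted bias surface over speed and foot strike angle
#'
#' Evaluates bias(v, theta) = intercept + beta_speed * v + beta_fsa *
#' theta on a grid (surface fixed at floor), annotated with the rear-,
#' mid-, and fore-foot strike bands at 0.14 and -0.03 rad.
#'
#' @param effects a `condition_effects`.
#' @param speed_grid,fsa_grid numeric grids (non-empty).
#' @return matrix (length(speed_grid) x length(fsa_grid)) with the grids
#'   and strike bands as attributes.
#' @export
predict_bias_surface <- function(effects, speed_grid, fsa_grid) {
  if (length(speed_grid) == 0 || length(fsa_grid) == 0) {
    stop("empty prediction grid")
  }
  b0 <- effects$intercept["est"]
  bs <- effects$speed["est"]
  bf <- effects$fsa["est"]
  if (is.na(bs)) bs <- 0
  if (is.na(bf)) bf <- 0
  surf <- outer(speed_grid, fsa_grid,
                function(v, th) b0 + bs * v + bf * th)
  dimnames(surf) <- list(speed = signif(speed_grid, 6),
                         fsa = signif(fsa_grid, 6))
  attr(surf, "speed_grid") <- speed_grid
  attr(surf, "fsa_grid") <- fsa_grid
  attr(surf, "strike_bands") <- c(FFS_MFS = -0.03, MFS_RFS = 0.14)
  surf
}
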