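# End-to-end orchestration: simulate -> process -> extract -> train /
# estimate -> agreement -> report, as one configured, seeded, reproducible
# run with CSV/JSON artifacts.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()]; defaults to a desk-scale design
#'   (6 participants, 2 surfaces, 3 speeds, 1 side, 2 stances per cell).
#' @param methods optional character vector restricting the registry by
#'   method name.
#' @param features features to summarize.
#' @param formulation agreement formulation (see
#'   [fit_linked_replicates()]).
#' @param nn_epochs training epochs for the network family.
#' @param bias_threshold methods with |bias| below this (per feature, in
#'   the feature's units) get condition-effect models; `Inf` fits all.
#' @param seed run seed (estimation folds; the cohort seed lives in
#'   `cohort`).
#' @param out_dir optional output directory for the run artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(n_participants = 6,
                                              sides = "left",
                                              stances_per_cell = 2),
                       methods = NULL,
                       features = grf_feature_names(),
                       formulation = "measurement",
                       nn_epochs = 300,
                       bias_threshold = Inf,
                       seed = 1L,
                       out_dir = NULL) {
  structure(list(cohort = cohort, methods = methods, features = features,
                 formulation = formulation, nn_epochs = nn_epochs,
                 bias_threshold = bias_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

gold_feature_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    vals <- c(first_peak = r$gold$first_peak,
              loading_rate = r$gold$loading_rate,
              second_peak = r$gold$second_peak,
              average = r$gold$average)
    data.frame(stance_id = r$stance_id, participant = r$participant,
               surface = r$surface, speed = r$speed, fsa = r$fsa,
               feature = names(vals), value = unname(vals),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full estimation and agreement pipeline
#'
#' Generates (or accepts) a synthetic dataset, extracts gold-standard
#' features, runs the leave-one-participant-out estimation for every
#' registry method, computes errors, fits the linked-replicates model per
#' feature, and (optionally) writes summary tables, condition-effect
#' coefficients, and a run manifest.
#'
#' @param config a [run_config()].
#' @param dataset optional pre-generated `synthetic_dataset` (bypasses
#'   simulation).
#' @return list of class `pipeline_run`: `gold`, `estimates`, `errors`,
#'   `tests`, `summaries` (per feature), `condition_effects`, `counts`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  if (is.null(dataset)) dataset <- generate_dataset(config$cohort)
  if (length(dataset$stances) == 0) stop("stage simulate: empty dataset")

  records <- prepare_stance_inputs(dataset)
  gold <- gold_feature_table(records)
  gold_series <- stats::setNames(lapply(records, `[[`, "force"),
                                 vapply(records, `[[`, character(1),
                                        "stance_id"))

  registry <- build_registry()
  if (!is.null(config$methods)) {
    missing <- setdiff(config$methods, names(registry))
    if (length(missing) > 0) {
      stop("unknown method(s): ", paste(missing, collapse = ", "))
    }
    registry <- registry[config$methods]
  }
  loo <- loo_estimate_all(records, registry, seed = config$seed,
                          nn_epochs = config$nn_epochs)
  errors <- compute_errors(loo$estimates, gold, loo$series, gold_series)
  tests <- ttest_fdr(errors)

  summaries <- list()
  cond <- list()
  for (feature in config$features) {
    if (!any(errors$feature == feature &
               errors$method != REFERENCE_METHOD)) next
    vc <- agreement_by_method(errors, feature,
                              formulation = config$formulation)
    summ <- summarize_agreement(vc, tests)
    summaries[[feature]] <- summ
    best <- summ$method[abs(summ$bias) <= config$bias_threshold]
    for (m in best) {
      ce <- tryCatch(fit_condition_model(errors, feature, m),
                     error = function(e) NULL)
      if (!is.null(ce)) {
        cond[[length(cond) + 1]] <- data.frame(
          method = m, feature = feature,
          intercept = ce$intercept["est"],
          speed = ce$speed["est"], speed_p = ce$speed["p"],
          surface = ce$surface["est"], surface_p = ce$surface["p"],
          fsa = ce$fsa["est"], fsa_p = ce$fsa["p"],
          stringsAsFactors = FALSE)
      }
    }
  }
  cond_tab <- if (length(cond) > 0) do.call(rbind, cond) else NULL
  if (!is.null(cond_tab)) rownames(cond_tab) <- NULL

  manifest <- list(seed = config$seed,
                   cohort_seed = config$cohort$seed,
                   n_participants = config$cohort$n_participants,
                   n_stances = length(dataset$stances),
                   n_estimates = nrow(loo$estimates),
                   features = names(summaries),
                   formulation = config$formulation)
  run <- structure(list(gold = gold, estimates = loo$estimates,
                        errors = errors, tests = tests,
                        summaries = summaries,
                        condition_effects = cond_tab,
                        folds = loo$folds,
                        counts = c(stances = length(dataset$stances),
                                   estimates = nrow(loo$estimates)),
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run: %d stances, %d estimate rows, %d features\n",
              x$counts["stances"], x$counts["estimates"],
              length(x$summaries)))
  invisible(x)
}

# manifest hash: md5 of the serialized manifest, stamped on every output
manifest_hash <- function(manifest) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# manifest_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write run artifacts to a directory
#'
#' Emits `gold_features.csv`, `estimates.csv`, `errors.csv`, one
#' `summary_<feature>.csv` per feature, `condition_effects.csv`, the
#' `report.md` ranking, and `manifest.json`. Every CSV carries the run
#' manifest hash as a leading comment line (read back with
#' `comment.char = "#"`).
#'
#' @param run a `pipeline_run`.
#' @param out_dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_run <- function(run, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  hash <- manifest_hash(run$manifest)
  run$manifest$hash <- hash
  write_stamped_csv(run$gold, file.path(out_dir, "gold_features.csv"),
                    hash)
  write_stamped_csv(run$estimates, file.path(out_dir, "estimates.csv"),
                    hash)
  write_stamped_csv(run$errors, file.path(out_dir, "errors.csv"), hash)
  write_stamped_csv(run$tests, file.path(out_dir, "ttests.csv"), hash)
  for (feature in names(run$summaries)) {
    write_stamped_csv(run$summaries[[feature]],
                      file.path(out_dir,
                                paste0("summary_", feature, ".csv")),
                      hash)
  }
  if (!is.null(run$condition_effects)) {
    write_stamped_csv(run$condition_effects,
                      file.path(out_dir, "condition_effects.csv"), hash)
  }
  writeLines(write_report(run$summaries), file.path(out_dir, "report.md"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a human-readable agreement report
#'
#' Ranks methods per feature by absolute bias (ties broken by RC then
#' LOA); the ranking is invariant to the row order of the input tables.
#'
#' @param summaries named list of per-feature summary data.frames
#'   ([summarize_agreement()]).
#' @return character vector of markdown lines.
#' @export
write_report <- function(summaries) {
  if (length(summaries) == 0) stop("no summaries to report")
  lines <- c("# vGRF estimation agreement report", "")
  for (feature in names(summaries)) {
    s <- summaries[[feature]]
    s <- s[order(abs(s$bias), s$rc, s$loa, s$method), , drop = FALSE]
    lines <- c(lines, paste0("## ", feature), "",
               "| rank | method | bias | RC | LOA | sig |",
               "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(s))) {
      sig <- if (isTRUE(s$significant[i])) "*" else ""
      lines <- c(lines, sprintf("| %d | %s | %+.2f | %.2f | %.2f | %s |",
                                i, s$method[i], s$bias[i], s$rc[i],
                                s$loa[i], sig))
    }
    lines <- c(lines, "")
  }
  lines
}
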