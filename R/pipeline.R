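# End-to-end orchestration: generate or ingest event data, process,
# summarize, fit, classify, and write plain CSV/JSON reports from a
# single YAML configuration with one global seed.

#' Validate a pipeline run configuration
#'
#' Checks the configuration (a list, typically from YAML) before any
#' work is done; all schema violations are reported together with their
#' field paths.
#'
#' @param config configuration list (see [run_pipeline()]).
#' @return The validated config, invisibly; errors on violations.
#' @export
validate_config <- function(config) {
  errs <- character()
  note <- function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg))
  mode <- config$mode %||% NA_character_
  if (!identical(mode, "simulate") && !identical(mode, "ingest")) {
    note("mode", "must be 'simulate' or 'ingest'")
  }
  if (identical(mode, "simulate")) {
    if (is.null(config$seed)) note("seed", "required in simulate mode")
    if (is.null(config$design$doses)) note("design.doses", "required in simulate mode")
    ty <- config$design$model$type %||% NA_character_
    if (!ty %in% c("hill", "iffl", "kinetics")) {
      note("design.model.type", "must be 'hill', 'iffl' or 'kinetics'")
    }
  }
  if (identical(mode, "ingest")) {
    files <- config$inputs$files
    if (is.null(files) || length(files) == 0L) {
      note("inputs.files", "at least one input file or glob required")
    } else {
      found <- unlist(lapply(files, function(g) Sys.glob(g)))
      if (length(found) == 0L) note("inputs.files", "no files match")
    }
  }
  if (is.null(config$output_dir)) note("output_dir", "required")
  fits <- config$analysis$fit %||% character()
  if (!all(fits %in% c("hill", "iffl"))) {
    note("analysis.fit", "entries must be 'hill' or 'iffl'")
  }
  if (length(errs)) {
    stop_param("invalid run configuration:\n  %s", paste(errs, collapse = "\n  "))
  }
  invisible(config)
}

config_model <- function(design) {
  ty <- design$model$type
  if (ty == "hill") {
    do.call(hill_params, design$model$params)
  } else if (ty == "iffl") {
    do.call(iffl_params, design$model$params)
  } else {
    p <- do.call(kinetic_params, design$model$kinetics %||% list())
    s <- do.call(scenario, design$model$scenario %||% list())
    list(params = p, scenario = s, aba = design$model$aba %||% 0)
  }
}

process_tables <- function(tables, processing) {
  channel <- processing$channel %||% "fl1_a"
  lapply(tables, function(tab) {
    tab <- clean_events(tab)
    if (isTRUE(processing$gate)) {
      tab <- gate_anomalies(tab, window = processing$window %||% 5,
                            mad_threshold = processing$mad_threshold %||% 5)
    }
    size_normalize(tab, channel = channel)
  })
}

summaries_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    m <- s$metadata
    data.frame(alpha = m$alpha %||% NA_real_, aba = m$aba %||% NA_real_,
               timepoint = m$timepoint %||% NA_real_,
               median = s$median, q1 = s$q1, q3 = s$q3, cv = s$cv,
               n_events = s$n_events, n_gated = m$n_gated %||% 0L)
  })
  do.call(rbind, rows)
}

write_report_csv <- function(df, path) {
  # fixed %.15g formatting keeps reruns byte-identical across platforms
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
}

#' Write / read a dose-response curve as CSV
#'
#' Plain-text interchange for fitted curves: columns `dose`, `median`,
#' `q1`, `q3`, `n_events`, `condition`.
#'
#' @param curve a [dose_response_curve()].
#' @param path file path.
#' @return `path` invisibly (write); a list of curves, one per
#'   condition (read).
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  df$condition <- attr(curve, "condition")
  write_report_csv(df, path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  conds <- unique(df$condition %||% "curve")
  lapply(setNames(conds, conds), function(cd) {
    d <- df[df$condition == cd, , drop = FALSE]
    dose_response_curve(d$dose, d$median,
                        q1 = d$q1 %||% NA_real_, q3 = d$q3 %||% NA_real_,
                        n_events = d$n_events %||% NA_integer_,
                        condition = cd)
  })
}

#' Run the full analysis pipeline from one configuration
#'
#' In `simulate` mode, generates a dose series of event-level
#' populations from the configured forward model (steady-state Hill,
#' IFFL, or the mechanistic kinetic model), processes them with the
#' standard cytometry steps (dialect correction, optional anomaly
#' gating, size normalization), summarizes each dose, fits the
#' requested response models, classifies the dose-response shape, and
#' writes `summaries.csv`, `fits.json`, `classification.json` and
#' `run_log.json` to the output directory. In `ingest` mode the event
#' tables are read from CSV/FCS files instead.
#'
#' The single global seed is expanded deterministically into per-stage
#' seeds, so a rerun with the same configuration is byte-identical in
#' its CSV outputs.
#'
#' @param config path to a YAML configuration or an equivalent list.
#'   Fields: `mode` (simulate/ingest), `seed`, `output_dir`,
#'   `generator` ([population_spec()] fields), `design` (`doses`,
#'   `model$type` plus model parameters), `processing` (`channel`,
#'   `gate`, `window`, `mad_threshold`), `analysis` (`fit`, `classify`,
#'   `rel_tol`, `bootstrap`), `inputs` (`files`, ingest mode).
#' @return Invisibly, a list with `summaries`, `curve`, `fits`,
#'   `classification` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  channel <- config$processing$channel %||% "fl1_a"
  if (identical(config$mode, "simulate")) {
    gen <- config$generator %||% list()
    gen$seed <- derive_seed(config$seed, 1L)
    spec <- do.call(population_spec, gen)
    doses <- as.numeric(config$design$doses)
    model <- config_model(config$design)
    tables <- generate_dose_series(spec, doses, model)
  } else {
    files <- unlist(lapply(config$inputs$files, Sys.glob))
    tables <- lapply(files, read_events, format = config$inputs$format %||% NULL)
    names(tables) <- basename(files)
  }

  processed <- process_tables(tables, config$processing %||% list())
  summaries <- lapply(processed, summarize_population,
                      channel = paste0(channel, "_norm"))
  sum_df <- summaries_table(summaries)
  sum_path <- file.path(out_dir, "summaries.csv")
  write_report_csv(sum_df, sum_path)

  curve <- curve_from_summaries(summaries, condition = config$condition %||% "run")

  fits <- list()
  for (model_name in config$analysis$fit %||% character()) {
    fit <- if (model_name == "hill") {
      fit_hill(curve, weights = config$analysis$weights %||% "none")
    } else {
      suppressWarnings(fit_iffl(curve,
                                weights = config$analysis$weights %||% "none",
                                normalize = config$analysis$normalize %||% TRUE))
    }
    bs <- config$analysis$bootstrap %||% list()
    if (isTRUE(bs$enabled)) {
      fit <- bootstrap_uncertainty(processed, model = model_name,
                                   n_boot = bs$n_boot %||% 200L,
                                   seed = derive_seed(config$seed %||% 1L, 2L),
                                   channel = paste0(channel, "_norm"))
    }
    fits[[model_name]] <- fit
  }
  fits_path <- file.path(out_dir, "fits.json")
  jsonlite::write_json(lapply(fits, function(f) {
    jsonlite::fromJSON(fit_to_json(f))
  }), fits_path, auto_unbox = TRUE, digits = NA)

  classification <- NULL
  if (isTRUE(config$analysis$classify %||% TRUE)) {
    classification <- classify_response(curve$dose, curve$median,
                                        rel_tol = config$analysis$rel_tol %||% 0.05)
    jsonlite::write_json(list(classification = classification,
                              rel_tol = config$analysis$rel_tol %||% 0.05),
                         file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE)
  }

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(list(
    package = "mapkrewire",
    version = as.character(utils::packageVersion("mapkrewire")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed %||% NA_integer_,
    config = config), log_path, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(summaries = summaries, curve = curve, fits = fits,
                 classification = classification,
                 paths = list(summaries = sum_path, fits = fits_path,
                              log = log_path)))
}
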