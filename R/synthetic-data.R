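#' Specification of a simulated cytometry population
#'
#' Describes one acquisition read of a yeast population on a flow
#' cytometer. Cell size (FSC-A proxy) and intracellular reporter
#' concentration are both log-normal — strictly positive and
#' right-skewed, as cytometry scatter and expression data are — and a
#' cell's fluorescence is size times concentration plus
#' autofluorescence, which is what makes raw fluorescence strongly
#' size-correlated and motivates forward-scatter normalization.
#' CVs are converted internally to log-space sigma via
#' `sqrt(log(1 + cv^2))`; medians map to the log-mean.
#'
#' @param n_events events per read (default 10000, one standard read).
#' @param size_median median FSC-A (arbitrary instrument units).
#' @param size_cv coefficient of variation of cell size.
#' @param conc_median median reporter concentration (arbitrary units).
#' @param conc_cv coefficient of variation of concentration.
#' @param autofluorescence additive background fluorescence (units of
#'   the fluorescence channel).
#' @param noise_frac measurement noise SD as a fraction of each event's
#'   signal (default 0.01).
#' @param vyb_offset_sd SD of the additive instrument baseline noise in
#'   the `vyb` dialect (can push low events negative); the `accuri`
#'   dialect instead floors values at 0.
#' @param read_duration acquisition duration in seconds; event times are
#'   uniform over it.
#' @param instrument_dialect `"accuri"` (zero-floored) or `"vyb"`
#'   (baseline-subtracted, negative values possible).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_events = 10000L,
                            size_median = 5e4,
                            size_cv = 0.35,
                            conc_median = 0.02,
                            conc_cv = 0.25,
                            autofluorescence = 30,
                            noise_frac = 0.01,
                            vyb_offset_sd = 20,
                            read_duration = 60,
                            instrument_dialect = c("accuri", "vyb"),
                            seed = 1L) {
  instrument_dialect <- match.arg(instrument_dialect)
  if (!is.numeric(n_events) || n_events < 1) stop_param("`n_events` must be >= 1")
  check_number(size_median, "size_median", min = 0, strict_min = TRUE)
  check_number(conc_median, "conc_median", min = 0, strict_min = TRUE)
  check_number(size_cv, "size_cv", min = 0)
  check_number(conc_cv, "conc_cv", min = 0)
  check_number(autofluorescence, "autofluorescence", min = 0)
  check_number(noise_frac, "noise_frac", min = 0)
  check_number(read_duration, "read_duration", min = 0, strict_min = TRUE)
  structure(list(n_events = as.integer(n_events), size_median = size_median,
                 size_cv = size_cv, conc_median = conc_median,
                 conc_cv = conc_cv, autofluorescence = autofluorescence,
                 noise_frac = noise_frac, vyb_offset_sd = vyb_offset_sd,
                 read_duration = read_duration,
                 instrument_dialect = instrument_dialect,
                 seed = as.integer(seed)),
            class = "population_spec")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Construct an event table: a data.frame of per-event measurements with
# shared acquisition metadata carried as attributes.
event_table <- function(df, metadata = list()) {
  stopifnot(is.data.frame(df))
  meta <- modifyList(list(strain = NA_character_, alpha = NA_real_,
                          aba = NA_real_, timepoint = NA_real_,
                          dialect = NA_character_), metadata)
  structure(df, class = c("event_table", "data.frame"), metadata = meta)
}

#' Acquisition metadata of an event table
#' @param x an `event_table`.
#' @return Named list (strain, alpha, aba, timepoint, dialect, ...).
#' @export
events_metadata <- function(x) attr(x, "metadata")

#' @export
print.event_table <- function(x, ...) {
  m <- events_metadata(x)
  cat(sprintf("<event_table> %d events, dialect=%s, alpha=%s uM, aba=%s uM, t=%s min\n",
              nrow(x), m$dialect, format(m$alpha), format(m$aba),
              format(m$timepoint)))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more events\n", nrow(x) - 4L))
  invisible(x)
}

#' Generate one simulated cytometry population
#'
#' Draws `n_events` cells with log-normal size and concentration, sets
#' fluorescence to `size * concentration + autofluorescence` plus
#' proportional measurement noise, then applies the instrument dialect:
#' `accuri` floors negative values at 0, `vyb` adds baseline noise and
#' can report negative values. Identical specs (including seed) give
#' bit-identical tables.
#'
#' @param spec a [population_spec()].
#' @param response_scale multiplier (>= 0) on the concentration median;
#'   1 is the untreated steady state, values < 1 emulate degradation.
#' @param metadata named list merged into the table's metadata.
#' @return An `event_table` with columns `fsc_a`, `fl1_a`, `t_acquire`.
#' @examples
#' tab <- generate_population(population_spec(n_events = 1000, seed = 7))
#' summary(tab$fl1_a)
#' @export
generate_population <- function(spec, response_scale = 1, metadata = list()) {
  stopifnot(inherits(spec, "population_spec"))
  check_number(response_scale, "response_scale", min = 0)
  n <- spec$n_events
  with_seed(spec$seed, {
    size <- rlnorm(n, meanlog = log(spec$size_median),
                   sdlog = cv_to_sdlog(spec$size_cv))
    conc <- if (response_scale == 0) numeric(n) else {
      rlnorm(n, meanlog = log(spec$conc_median * response_scale),
             sdlog = cv_to_sdlog(spec$conc_cv))
    }
    signal <- size * conc + spec$autofluorescence
    fl <- signal + rnorm(n, 0, spec$noise_frac * signal)
    if (spec$instrument_dialect == "vyb") {
      fl <- fl + rnorm(n, 0, spec$vyb_offset_sd)
    } else {
      fl <- pmax(fl, 0)
    }
    t_acq <- sort(runif(n, 0, spec$read_duration))
    df <- data.frame(fsc_a = size, fl1_a = fl, t_acquire = t_acq)
    event_table(df, modifyList(list(dialect = spec$instrument_dialect),
                               metadata))
  })
}

#' Generate a dose series of simulated populations
#'
#' Applies a steady-state response model as the forward model: at each
#' dose the concentration median is scaled by `model(dose) / model(0)`,
#' so the untreated population defines scale 1. The model can be a
#' [hill_params()]/[iffl_params()] object or a `list(params =
#' kinetic_params, scenario = scenario)` pair, in which case the
#' steady-state total reporter from the kinetic model supplies the
#' response.
#'
#' @param spec a [population_spec()]; per-dose seeds are derived
#'   deterministically from `spec$seed`.
#' @param doses non-negative doses (uM alpha-factor).
#' @param model response model (see Description).
#' @param metadata named list merged into each table's metadata.
#' @return Named list of `event_table`s, one per dose.
#' @export
generate_dose_series <- function(spec, doses, model, metadata = list()) {
  stopifnot(inherits(spec, "population_spec"))
  if (any(doses < 0)) stop_param("doses must be non-negative")
  scale_fun <- dose_scale_function(model)
  base <- scale_fun(0)
  if (base == 0) stop_param("model response at dose 0 is zero; cannot normalize")
  out <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    sp <- spec
    sp$seed <- derive_seed(spec$seed, i)
    out[[i]] <- generate_population(
      sp, response_scale = scale_fun(doses[i]) / base,
      metadata = modifyList(list(alpha = doses[i]), metadata))
  }
  names(out) <- format(doses, trim = TRUE)
  out
}

dose_scale_function <- function(model) {
  if (inherits(model, "hill_params") || inherits(model, "iffl_params")) {
    function(x) model_response(x, model)
  } else if (is.list(model) && inherits(model$params, "kinetic_params")) {
    s <- model$scenario %||% scenario()
    aba <- model$aba %||% 0
    function(x) steady_state(model$params, s,
                             list(alpha = x, aba = aba))[["total"]]
  } else {
    stop_param("`model` must be hill/iffl params or list(params=, scenario=)")
  }
}

#' Generate an induction time course of simulated populations
#'
#' Runs the kinetic model from its untreated steady state with the given
#' inputs applied at time 0 and emits one population per requested time,
#' with the concentration median following the simulated total-reporter
#' trajectory.
#'
#' @param spec a [population_spec()]; per-timepoint seeds are derived
#'   from `spec$seed`.
#' @param kinetics a [kinetic_params()] object.
#' @param times sampling times in minutes, starting at 0.
#' @param scen a [scenario()] object.
#' @param inputs list with `alpha` and `aba` (uM), applied at time 0.
#' @param metadata named list merged into each table's metadata.
#' @return Named list of `event_table`s, one per time point.
#' @export
generate_timecourse <- function(spec, kinetics, times,
                                scen = scenario(),
                                inputs = list(alpha = 10, aba = 0),
                                metadata = list()) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(kinetics, "kinetic_params"))
  traj <- simulate_kinetics(kinetics, scen, inputs, times)
  if (traj$total[1] <= 0) stop_param("initial reporter level is zero")
  scale <- traj$total / traj$total[1]
  out <- vector("list", length(times))
  for (i in seq_along(times)) {
    sp <- spec
    sp$seed <- derive_seed(spec$seed, i)
    out[[i]] <- generate_population(
      sp, response_scale = scale[i],
      metadata = modifyList(list(timepoint = times[i],
                                 alpha = inputs$alpha %||% 0,
                                 aba = inputs$aba %||% 0), metadata))
  }
  names(out) <- format(times, trim = TRUE)
  out
}
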