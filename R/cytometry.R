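# Event processing: dialect-specific zero/offset correction, anomaly
# gating on FSC-A vs acquisition time, size normalization, and
# population summaries.

fluor_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("fsc_a", "t_acquire"))
}

#' Dialect-specific zero/offset correction of raw events
#'
#' Prepares raw cytometry values for log-scale analysis. For the Accuri
#' dialect (hard zero floor) any fluorescence value equal to 0 is
#' converted to 1. For the VYB dialect (baseline-subtracted, values may
#' be negative) every fluorescence channel is shifted by the absolute
#' value of the lowest value in the batch plus 1, so the minimum maps
#' to 1. The batch is the table itself by default; pass `batch_min` (a
#' named per-channel vector of minima from the full acquisition day) to
#' share one offset across files.
#'
#' @param table an `event_table` whose metadata names the dialect.
#' @param batch_min optional named numeric vector of per-channel batch
#'   minima overriding the per-table minima (VYB only).
#' @return The corrected `event_table`; row count unchanged.
#' @examples
#' tab <- generate_population(population_spec(n_events = 500, seed = 1))
#' cleaned <- clean_events(tab)
#' @export
clean_events <- function(table, batch_min = NULL) {
  stopifnot(inherits(table, "event_table"))
  dialect <- events_metadata(table)$dialect
  chans <- fluor_columns(table)
  if (identical(dialect, "accuri")) {
    for (ch in chans) table[[ch]][table[[ch]] == 0] <- 1
  } else if (identical(dialect, "vyb")) {
    for (ch in chans) {
      lo <- if (!is.null(batch_min) && ch %in% names(batch_min)) {
        batch_min[[ch]]
      } else {
        min(table[[ch]])
      }
      table[[ch]] <- table[[ch]] + abs(lo) + 1
    }
  } else {
    stop_param("unknown instrument dialect '%s'", format(dialect))
  }
  table
}

#' Remove acquisition anomalies by FSC-A versus time
#'
#' Flags transient disturbances (bubbles, clogs) as events whose FSC-A
#' deviates from a centered running median — computed over the `k`
#' nearest events by acquisition time, where `k` approximates the event
#' rate times `window` — by more than `mad_threshold` robust standard
#' deviations (1.4826 x MAD of the deviations). Gating is an optional
#' step: the source procedure inspected these plots by eye.
#'
#' @param table an `event_table` with a `t_acquire` column.
#' @param window sliding-window width in seconds (default 5).
#' @param mad_threshold robust-SD multiplier (default 5); `Inf` is the
#'   identity.
#' @return Filtered `event_table`; the number of removed events is
#'   recorded in `events_metadata(x)$n_gated`.
#' @export
gate_anomalies <- function(table, window = 5, mad_threshold = 5) {
  stopifnot(inherits(table, "event_table"))
  if (!"t_acquire" %in% names(table)) stop_param("`t_acquire` column required")
  n <- nrow(table)
  ord <- order(table$t_acquire)
  x <- table$fsc_a[ord]
  duration <- diff(range(table$t_acquire))
  if (window >= duration) {
    warning("window exceeds the read duration; using a single global window")
    med <- rep(median(x), n)
  } else {
    k <- max(3L, round(n * window / duration))
    if (k %% 2L == 0L) k <- k + 1L
    k <- min(k, if (n %% 2L == 1L) n else n - 1L)
    med <- runmed(x, k, endrule = "median")
  }
  dev <- x - med
  rsd <- 1.4826 * median(abs(dev))
  keep_sorted <- if (is.infinite(mad_threshold)) rep(TRUE, n) else {
    if (rsd == 0) dev == 0 else abs(dev) <= mad_threshold * rsd
  }
  keep <- logical(n)
  keep[ord] <- keep_sorted
  out <- table[keep, , drop = FALSE]
  meta <- events_metadata(table)
  meta$n_gated <- sum(!keep)
  event_table(as.data.frame(out), meta)
}

#' Normalize fluorescence by cell size
#'
#' Divides each event's fluorescence by its FSC-A value, removing the
#' component of fluorescence variation driven by cell volume. Adds a
#' `<channel>_norm` column; original columns are retained.
#'
#' @param table a cleaned `event_table` (all FSC-A values positive).
#' @param channel fluorescence column to normalize (default `"fl1_a"`).
#' @return The `event_table` with an added normalized column.
#' @export
size_normalize <- function(table, channel = "fl1_a") {
  stopifnot(inherits(table, "event_table"))
  if (!channel %in% names(table)) stop_param("channel '%s' not present", channel)
  if (any(table$fsc_a <= 0)) {
    stop_param("FSC-A must be positive for all events; run clean_events()/gate_anomalies() first")
  }
  table[[paste0(channel, "_norm")]] <- table[[channel]] / table$fsc_a
  table
}

#' Summarize one population
#'
#' Median, interquartile range and coefficient of variation (sd/mean,
#' linear scale) of a chosen channel. Quantiles use R's default linear
#' interpolation (type 7).
#'
#' @param table an `event_table` with at least one event.
#' @param channel column to summarize (default the size-normalized
#'   `"fl1_a_norm"`).
#' @return An object of class `population_summary`: list with `median`,
#'   `q1`, `q3`, `cv`, `n_events`, `channel`, and the table's metadata.
#' @export
summarize_population <- function(table, channel = "fl1_a_norm") {
  stopifnot(inherits(table, "event_table"))
  if (nrow(table) == 0L) stop_param("cannot summarize an empty population")
  if (!channel %in% names(table)) stop_param("channel '%s' not present", channel)
  x <- table[[channel]]
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  mu <- mean(x)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 cv = if (mu == 0) NA_real_ else sd(x) / mu,
                 n_events = nrow(table), channel = channel,
                 metadata = events_metadata(table)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s: median=%.4g IQR=[%.4g, %.4g] CV=%.3f n=%d\n",
              x$channel, x$median, x$q1, x$q3, x$cv, x$n_events))
  invisible(x)
}

#' Fold change between untreated and treated populations
#'
#' Oriented as untreated over treated, so that kinase-directed
#' degradation yields values greater than 1 (an "x-fold drop").
#'
#' @param untreated,treated `population_summary` objects for the same
#'   channel.
#' @return List with `fold` (untreated median / treated median) and
#'   `log10_fold`.
#' @export
fold_change <- function(untreated, treated) {
  stopifnot(inherits(untreated, "population_summary"),
            inherits(treated, "population_summary"))
  if (!identical(untreated$channel, treated$channel)) {
    stop_param("summaries are for different channels")
  }
  if (treated$median <= 0) stop_param("treated median must be positive")
  f <- untreated$median / treated$median
  list(fold = f, log10_fold = log10(f))
}

#' Percent reduction of population CV by size normalization
#'
#' `100 * (1 - cv_norm / cv_raw)` for the same events summarized on the
#' raw and the size-normalized channel; quantifies how much of the
#' fluorescence variability is explained by cell size.
#'
#' @param raw `population_summary` on the raw fluorescence channel.
#' @param normalized `population_summary` on the normalized channel.
#' @return Percent CV reduction.
#' @export
cv_reduction <- function(raw, normalized) {
  stopifnot(inherits(raw, "population_summary"),
            inherits(normalized, "population_summary"))
  if (is.na(raw$cv) || raw$cv == 0) stop_param("raw CV is zero or undefined")
  100 * (1 - normalized$cv / raw$cv)
}
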