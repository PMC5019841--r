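# Constrained nonlinear least-squares estimation of the Hill and IFFL
# dose-response models from per-dose medians (the quantity plotted in a
# dose-response panel), with deterministic multistart, parameter
# sharing across conditions, and event-level bootstrap uncertainty.

#' Dose-response curve container
#'
#' @param doses unique non-negative doses (uM).
#' @param medians size-normalized median fluorescence, one per dose.
#' @param q1,q3 optional per-dose quartiles (used for `inv_iqr` weights).
#' @param n_events optional events per dose.
#' @param condition label for the condition (strain/treatment).
#' @return A `dose_response_curve` data frame.
#' @export
dose_response_curve <- function(doses, medians, q1 = NA_real_, q3 = NA_real_,
                                n_events = NA_integer_, condition = "curve") {
  if (any(doses < 0)) stop_param("doses must be non-negative")
  if (anyDuplicated(doses)) stop_param("doses must be unique")
  if (length(doses) != length(medians)) stop_param("doses/medians length mismatch")
  ord <- order(doses)
  structure(data.frame(dose = doses, median = medians, q1 = q1, q3 = q3,
                       n_events = n_events)[ord, , drop = FALSE],
            class = c("dose_response_curve", "data.frame"),
            condition = condition)
}

#' Build a dose-response curve from population summaries
#'
#' @param summaries list of `population_summary` objects whose metadata
#'   records the dose in `alpha`.
#' @param condition condition label.
#' @return A [dose_response_curve()].
#' @export
curve_from_summaries <- function(summaries, condition = "curve") {
  dose_response_curve(
    doses = vapply(summaries, function(s) s$metadata$alpha, numeric(1)),
    medians = vapply(summaries, function(s) s$median, numeric(1)),
    q1 = vapply(summaries, function(s) s$q1, numeric(1)),
    q3 = vapply(summaries, function(s) s$q3, numeric(1)),
    n_events = vapply(summaries, function(s) s$n_events, integer(1)),
    condition = condition)
}

fit_result <- function(model, params, shared = character(), rss, converged,
                       unidentifiable = FALSE, degenerate_de = FALSE,
                       uncertainty = NULL, n_boot = 0L, seed = NA_integer_,
                       n_failed = 0L) {
  structure(list(model = model, params = params, shared = shared,
                 rss = rss, converged = converged,
                 unidentifiable = unidentifiable,
                 degenerate_de = degenerate_de,
                 uncertainty = uncertainty, n_boot = n_boot, seed = seed,
                 n_failed = n_failed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s rss=%.6g converged=%s\n",
              x$model, x$rss, x$converged))
  for (cond in names(x$params)) {
    p <- x$params[[cond]]
    cat(sprintf("  %s: %s\n", cond,
                paste(sprintf("%s=%.6g", names(unclass(p))[1:min(6, length(unclass(p)))],
                              unlist(unclass(p))[1:min(6, length(unclass(p)))]),
                      collapse = "  ")))
  }
  if (length(x$shared)) cat("  shared:", paste(x$shared, collapse = ", "), "\n")
  if (x$unidentifiable) cat("  WARNING: fit flagged unidentifiable\n")
  if (!is.null(x$uncertainty)) {
    cat(sprintf("  bootstrap 95%% intervals (n_boot=%d):\n", x$n_boot))
    print(x$uncertainty)
  }
  invisible(x)
}

hill_bounds <- list(lower = c(A = 0, B = 0, C = 1e-8, n = 1e-2),
                    upper = c(A = Inf, B = Inf, C = Inf, n = 10))
iffl_bounds <- list(lower = c(hill_bounds$lower, D = 0, E = 0),
                    upper = c(hill_bounds$upper, D = Inf, E = Inf))

curve_weights <- function(curve, weights) {
  if (weights == "inv_iqr") {
    iqr <- curve$q3 - curve$q1
    if (any(!is.finite(iqr)) || any(iqr <= 0)) {
      stop_param("inv_iqr weighting requires positive finite IQRs at every dose")
    }
    1 / iqr
  } else {
    rep(1, nrow(curve))
  }
}

# Deterministic multistart grid (DESIGN: A from the minimum median, B
# from the span times the trial C, C in {0.1,1,10}, n in {1,2,4}, and
# for the IFFL model D,E in {0.01,0.1,1}).
start_grid <- function(curve, model) {
  a0 <- max(min(curve$median), 0)
  span <- max(max(curve$median) - min(curve$median), 1e-6 * max(abs(curve$median), 1))
  starts <- list()
  for (C0 in c(0.1, 1, 10)) for (n0 in c(1, 2, 4)) {
    base <- c(A = a0, B = span * C0, C = C0, n = n0)
    if (model == "hill") {
      starts[[length(starts) + 1L]] <- base
    } else {
      for (D0 in c(0.01, 0.1, 1)) for (E0 in c(0.01, 0.1, 1)) {
        starts[[length(starts) + 1L]] <- c(base, D = D0, E = E0)
      }
    }
  }
  starts
}

model_predict <- function(par, x, model) {
  xn <- x^par[["n"]]
  hill <- par[["A"]] + par[["B"]] * xn / (1 + par[["C"]] * xn)
  if (model == "hill") return(hill)
  (hill - par[["A"]]) * (1 + par[["E"]] * x) / (1 + par[["D"]] * x) + par[["A"]]
}

run_nlslm <- function(par0, resid_fun, lower, upper) {
  fit <- try(suppressWarnings(
    minpack.lm::nls.lm(par = par0, fn = resid_fun, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(par = fit$par, rss = sum(fit$fvec^2), info = fit$info)
}

best_fit <- function(starts, resid_fun, lower, upper) {
  best <- NULL
  for (par0 in starts) {
    res <- run_nlslm(par0, resid_fun, lower, upper)
    if (is.null(res)) next
    if (is.null(best) || res$rss < best$rss) best <- res
  }
  best
}

is_flat_curve <- function(medians) {
  span <- max(medians) - min(medians)
  span <= 1e-10 * max(abs(medians), 1)
}

#' Fit the Hill dose-response model to one curve
#'
#' Bounded Levenberg-Marquardt least squares on per-dose medians
#' (`A, B >= 0`, `C > 0`, `0 < n <= 10`), best-of over a deterministic
#' multistart grid. A curve with no dose dependence is flagged
#' unidentifiable rather than silently fitted.
#'
#' @param curve a [dose_response_curve()] with at least 4 distinct doses.
#' @param weights `"none"` (default) or `"inv_iqr"` (residuals weighted
#'   by 1/IQR).
#' @param start optional named start vector `c(A, B, C, n)`; when given,
#'   multistart is skipped (used by the bootstrap refits).
#' @return A `fit_result` whose `params` hold one [hill_params()] per
#'   condition.
#' @export
fit_hill <- function(curve, weights = c("none", "inv_iqr"), start = NULL) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "dose_response_curve"))
  if (nrow(curve) < 4L) stop_param("need at least 4 distinct doses to fit 4 parameters")
  cond <- attr(curve, "condition")
  if (is_flat_curve(curve$median)) {
    p <- hill_params(A = mean(curve$median), B = 0, C = 1, n = 1)
    return(fit_result("hill", setNames(list(p), cond), rss = 0,
                      converged = FALSE, unidentifiable = TRUE))
  }
  w <- curve_weights(curve, weights)
  resid_fun <- function(par) w * (model_predict(par, curve$dose, "hill") - curve$median)
  starts <- if (is.null(start)) start_grid(curve, "hill") else list(start)
  best <- best_fit(starts, resid_fun, hill_bounds$lower, hill_bounds$upper)
  if (is.null(best)) stop_param("all starts failed for the Hill fit")
  p <- hill_params(best$par[["A"]], best$par[["B"]], best$par[["C"]], best$par[["n"]])
  fit_result("hill", setNames(list(p), cond), rss = best$rss,
             converged = best$info %in% 1:3)
}

#' Joint Hill fits with parameters shared across conditions
#'
#' Minimizes the concatenated residuals of several dose-response curves
#' in a single optimization, with the named parameters constrained to a
#' common value across conditions — `shared = "C"` ties the saturation
#' coefficient between a feedback strain and its control, the scheme
#' used when comparing rewired and control pathway outputs.
#'
#' @param curves list of [dose_response_curve()] objects (>= 2).
#' @param shared character subset of `c("A", "B", "C", "n")`.
#' @param weights as in [fit_hill()].
#' @return A `fit_result` with one [hill_params()] per condition; shared
#'   parameters are numerically identical across conditions.
#' @export
fit_hill_joint <- function(curves, shared = "C",
                           weights = c("none", "inv_iqr")) {
  weights <- match.arg(weights)
  if (length(curves) < 2L) stop_param("need at least 2 curves for a joint fit")
  if (!all(shared %in% c("A", "B", "C", "n"))) {
    stop_param("shared parameters must be among A, B, C, n")
  }
  conds <- vapply(seq_along(curves), function(i) {
    attr(curves[[i]], "condition") %||% paste0("curve", i)
  }, character(1))
  if (anyDuplicated(conds)) conds <- make.unique(conds)
  free <- setdiff(c("A", "B", "C", "n"), shared)
  k <- length(curves)

  # parameter vector layout: shared params once, then free params per curve
  pack <- function(per_curve) {
    c(if (length(shared)) per_curve[[1]][shared] else NULL,
      unlist(lapply(per_curve, function(p) p[free])))
  }
  unpack <- function(theta) {
    sh <- if (length(shared)) setNames(theta[seq_along(shared)], shared) else NULL
    rest <- if (length(shared)) theta[-seq_len(length(shared))] else theta
    lapply(seq_len(k), function(i) {
      fr <- setNames(rest[(i - 1) * length(free) + seq_along(free)], free)
      c(sh, fr)[c("A", "B", "C", "n")]
    })
  }
  ws <- lapply(curves, curve_weights, weights = weights)
  resid_fun <- function(theta) {
    pars <- unpack(theta)
    unlist(lapply(seq_len(k), function(i) {
      ws[[i]] * (model_predict(pars[[i]], curves[[i]]$dose, "hill") -
                   curves[[i]]$median)
    }))
  }
  lower <- pack(rep(list(hill_bounds$lower), k))
  upper <- pack(rep(list(hill_bounds$upper), k))

  starts <- list()
  grids <- lapply(curves, start_grid, model = "hill")
  for (j in seq_along(grids[[1]])) {
    starts[[j]] <- pack(lapply(grids, `[[`, j))
  }
  best <- best_fit(starts, resid_fun, lower, upper)
  if (is.null(best)) stop_param("all starts failed for the joint Hill fit")
  pars <- unpack(best$par)
  plist <- setNames(lapply(pars, function(v) {
    hill_params(v[["A"]], v[["B"]], v[["C"]], v[["n"]])
  }), conds)
  fit_result("hill", plist, shared = shared, rss = best$rss,
             converged = best$info %in% 1:3)
}

#' Fit the IFFL (band-pass) dose-response model to one curve
#'
#' As [fit_hill()] with the additional inhibitory-arm parameters
#' `D, E >= 0`. Medians are first normalized to the untreated (zero
#' dose) condition, the convention used for band-pass dose-response
#' data; disable with `normalize = FALSE`. A fit with `D` and `E`
#' nearly equal is flagged `degenerate_de`: the inhibitory factor is
#' then indistinguishable from 1 and the data are effectively Hill.
#'
#' @param curve a [dose_response_curve()] with at least 6 distinct
#'   doses; sampling beyond the empirical peak is recommended.
#' @param weights as in [fit_hill()].
#' @param normalize divide medians by the zero-dose median first.
#' @param start optional named start vector `c(A, B, C, n, D, E)`.
#' @return A `fit_result` holding one [iffl_params()].
#' @export
fit_iffl <- function(curve, weights = c("none", "inv_iqr"),
                     normalize = TRUE, start = NULL) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "dose_response_curve"))
  if (nrow(curve) < 6L) stop_param("need at least 6 distinct doses to fit 6 parameters")
  cond <- attr(curve, "condition")
  if (normalize) {
    i0 <- which(curve$dose == 0)
    if (length(i0) != 1L || curve$median[i0] <= 0) {
      stop_param("normalization requires a positive median at dose 0")
    }
    sc <- curve$median[i0]
    curve$median <- curve$median / sc
    curve$q1 <- curve$q1 / sc
    curve$q3 <- curve$q3 / sc
  }
  if (is_flat_curve(curve$median)) {
    p <- iffl_params(A = mean(curve$median), B = 0, C = 1, n = 1, D = 0, E = 0)
    return(fit_result("iffl", setNames(list(p), cond), rss = 0,
                      converged = FALSE, unidentifiable = TRUE))
  }
  w <- curve_weights(curve, weights)
  resid_fun <- function(par) w * (model_predict(par, curve$dose, "iffl") - curve$median)
  starts <- if (is.null(start)) start_grid(curve, "iffl") else list(start)
  best <- best_fit(starts, resid_fun, iffl_bounds$lower, iffl_bounds$upper)
  if (is.null(best)) stop_param("all starts failed for the IFFL fit")
  pr <- best$par
  degen <- abs(pr[["D"]] - pr[["E"]]) <= 1e-3 * max(pr[["D"]], pr[["E"]], 1)
  if (degen) {
    warning("fitted D and E are nearly equal; inhibitory arm unidentifiable (data look Hill-like)")
  }
  p <- iffl_params(pr[["A"]], pr[["B"]], pr[["C"]], pr[["n"]], pr[["D"]], pr[["E"]])
  fit_result("iffl", setNames(list(p), cond), rss = best$rss,
             converged = best$info %in% 1:3, degenerate_de = degen)
}

#' Bootstrap parameter uncertainty from event-level data
#'
#' Resamples events with replacement within each dose, recomputes the
#' per-dose medians, and refits the model; reports percentile 2.5/97.5
#' intervals per parameter. Refits start from the full-data point
#' estimate. The study itself reports no fit uncertainties, so this is
#' the package's own uncertainty procedure.
#'
#' @param tables named list of processed `event_table`s, one per dose
#'   (names or metadata `alpha` give the dose); the summarized channel
#'   must be present (default `"fl1_a_norm"`).
#' @param model `"hill"` or `"iffl"`.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed; intervals are reproducible.
#' @param channel event column to summarize.
#' @param weights,normalize passed to the fit.
#' @return The full-data `fit_result` augmented with an `uncertainty`
#'   matrix (rows 2.5%/97.5%, columns parameters), `n_boot`, `seed` and
#'   the bootstrap failure count.
#' @export
bootstrap_uncertainty <- function(tables, model = c("hill", "iffl"),
                                  n_boot = 200L, seed = 1L,
                                  channel = "fl1_a_norm",
                                  weights = "none", normalize = TRUE) {
  model <- match.arg(model)
  if (n_boot < 100L) stop_param("n_boot must be >= 100")
  doses <- vapply(tables, function(t) events_metadata(t)$alpha, numeric(1))
  if (anyNA(doses)) doses <- as.numeric(names(tables))
  if (anyNA(doses)) stop_param("cannot determine doses from metadata or names")

  make_curve <- function(meds) {
    dose_response_curve(doses, meds, condition = "bootstrap")
  }
  full_meds <- vapply(tables, function(t) median(t[[channel]]), numeric(1))
  full_fit <- if (model == "hill") {
    fit_hill(make_curve(full_meds), weights = weights)
  } else {
    fit_iffl(make_curve(full_meds), weights = weights, normalize = normalize)
  }
  start <- unlist(unclass(full_fit$params[[1]])[
    if (model == "hill") c("A", "B", "C", "n") else c("A", "B", "C", "n", "D", "E")])

  boot_pars <- with_seed(seed, {
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      meds <- vapply(tables, function(t) {
        x <- t[[channel]]
        median(x[sample.int(length(x), replace = TRUE)])
      }, numeric(1))
      fit <- try(suppressWarnings(
        if (model == "hill") {
          fit_hill(make_curve(meds), weights = weights, start = start)
        } else {
          fit_iffl(make_curve(meds), weights = weights,
                   normalize = normalize, start = start)
        }), silent = TRUE)
      out[[b]] <- if (inherits(fit, "try-error")) NULL else {
        unlist(unclass(fit$params[[1]])[names(start)])
      }
    }
    out
  })
  ok <- !vapply(boot_pars, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    stop_param("bootstrap refits failed for %.0f%% of replicates", 100 * mean(!ok))
  }
  mat <- do.call(rbind, boot_pars[ok])
  ci <- apply(mat, 2, quantile, probs = c(0.025, 0.975), type = 7)
  full_fit$uncertainty <- ci
  full_fit$n_boot <- as.integer(n_boot)
  full_fit$seed <- as.integer(seed)
  full_fit$n_failed <- sum(!ok)
  full_fit
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path optional output path; when `NULL` a JSON string is
#'   returned.
#' @return `path` invisibly, or a JSON string.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(model = fit$model,
              params = lapply(fit$params, unclass),
              shared = fit$shared, rss = fit$rss,
              converged = fit$converged,
              unidentifiable = fit$unidentifiable,
              degenerate_de = fit$degenerate_de,
              n_boot = fit$n_boot, seed = fit$seed,
              n_failed = fit$n_failed)
  if (!is.null(fit$uncertainty)) {
    obj$uncertainty <- as.list(as.data.frame(fit$uncertainty))
  }
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
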