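#' Steady-state Hill dose-response parameters
#'
#' Parameters of the saturating dose-response model
#' \deqn{Y(x) = A + \frac{B x^n}{1 + C x^n}}
#' used to describe pathway output (size-normalized median fluorescence)
#' as a function of pheromone dose \eqn{x} (micromolar alpha-factor).
#' `A` is the uninduced baseline, `B/C` the induced span at saturating
#' dose, and `n` the apparent Hill coefficient.
#'
#' @param A baseline signal at zero dose (normalized-fluorescence units),
#'   `A >= 0`.
#' @param B response numerator coefficient (signal per uM^n), `B >= 0`.
#' @param C saturation coefficient (per uM^n), `C > 0`.
#' @param n apparent Hill coefficient (dimensionless), `n > 0`.
#' @return An object of class `hill_params`.
#' @examples
#' p <- hill_params(A = 0.1, B = 1, C = 1, n = 2)
#' hill_response(c(0, 1, 100), p)
#' @export
hill_params <- function(A, B, C, n) {
  check_number(A, "A", min = 0)
  check_number(B, "B", min = 0)
  check_number(C, "C", min = 0, strict_min = TRUE)
  check_number(n, "n", min = 0, strict_min = TRUE)
  structure(list(A = A, B = B, C = C, n = n), class = "hill_params")
}

#' Incoherent feed-forward (band-pass) dose-response parameters
#'
#' Parameters of the phenomenological hybrid incoherent feed-forward loop
#' model
#' \deqn{Y(x) = A + \frac{B x^n}{1 + C x^n} \cdot \frac{1 + E x}{1 + D x}}
#' in which the activating arm is the Hill term and the
#' post-translational degradation arm contributes the rational factor
#' `(1 + E x)/(1 + D x)`. With `D > E` the factor decays with dose and an
#' interior maximum (band-pass response) can arise; with `D = E` the
#' model reduces exactly to [hill_params()].
#'
#' By default the degradation factor multiplies only the induced Hill
#' term, on the grounds that the baseline `A` represents dose-independent
#' background signal; set `baseline_modulated = TRUE` for the alternative
#' grouping `(A + Hill) * factor`.
#'
#' @inheritParams hill_params
#' @param D inhibitory-arm saturation coefficient (per uM), `D >= 0`.
#' @param E inhibitory-arm residual coefficient (per uM), `E >= 0`.
#' @param baseline_modulated logical; apply the `(1+Ex)/(1+Dx)` factor to
#'   the baseline `A` as well as the induced term (default `FALSE`).
#' @return An object of class `iffl_params`.
#' @examples
#' p <- iffl_params(A = 0, B = 1, C = 1, n = 2, D = 1, E = 0)
#' bandpass_peak(p)
#' @export
iffl_params <- function(A, B, C, n, D, E, baseline_modulated = FALSE) {
  base <- hill_params(A, B, C, n)
  check_number(D, "D", min = 0)
  check_number(E, "E", min = 0)
  structure(c(unclass(base),
              list(D = D, E = E,
                   baseline_modulated = isTRUE(baseline_modulated))),
            class = "iffl_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill dose-response: Y = A + B*x^n/(1 + C*x^n)\n"))
  cat(sprintf("  A=%.4g  B=%.4g  C=%.4g  n=%.4g  (max = A + B/C = %.4g)\n",
              x$A, x$B, x$C, x$n, x$A + x$B / x$C))
  invisible(x)
}

#' @export
print.iffl_params <- function(x, ...) {
  cat("IFFL dose-response: Y = A + [B*x^n/(1 + C*x^n)] * (1 + E*x)/(1 + D*x)\n")
  cat(sprintf("  A=%.4g  B=%.4g  C=%.4g  n=%.4g  D=%.4g  E=%.4g\n",
              x$A, x$B, x$C, x$n, x$D, x$E))
  pk <- bandpass_peak(x)
  if (is.na(pk)) cat("  monotone (no interior peak)\n")
  else cat(sprintf("  interior peak at x = %.4g uM\n", pk))
  invisible(x)
}

#' Evaluate the Hill dose-response model
#'
#' @param x dose(s) in uM, `x >= 0`. Vectorized.
#' @param p a [hill_params()] object.
#' @return Signal values, same length as `x`.
#' @export
hill_response <- function(x, p) {
  stopifnot(inherits(p, "hill_params"))
  if (any(x < 0)) stop_param("doses must be non-negative")
  xn <- x^p$n
  p$A + p$B * xn / (1 + p$C * xn)
}

#' Evaluate the incoherent feed-forward (band-pass) dose-response model
#'
#' @param x dose(s) in uM, `x >= 0`. Vectorized.
#' @param p an [iffl_params()] object.
#' @return Signal values, same length as `x`.
#' @export
iffl_response <- function(x, p) {
  stopifnot(inherits(p, "iffl_params"))
  if (any(x < 0)) stop_param("doses must be non-negative")
  xn <- x^p$n
  hill <- p$B * xn / (1 + p$C * xn)
  fac <- (1 + p$E * x) / (1 + p$D * x)
  if (isTRUE(p$baseline_modulated)) (p$A + hill) * fac else p$A + hill * fac
}

# Dispatch helper used by the generator and the pipeline.
model_response <- function(x, p) {
  if (inherits(p, "iffl_params")) iffl_response(x, p)
  else if (inherits(p, "hill_params")) hill_response(x, p)
  else stop_param("unsupported response model of class '%s'", class(p)[1])
}

#' Maximal pathway activation of a fitted Hill model
#'
#' The saturating-dose limit `A + B/C` of [hill_response()].
#'
#' @param p a [hill_params()] object.
#' @return The limiting signal at infinite dose.
#' @export
max_activation <- function(p) {
  stopifnot(inherits(p, "hill_params"))
  if (p$C == 0) stop_param("C must be positive to define a saturation limit")
  p$A + p$B / p$C
}

#' Percent reduction in maximal activation between two fitted curves
#'
#' Quantifies how strongly a synthetic negative-feedback connection damps
#' pathway output: `100 * (1 - max_fb / max_ctrl)`. By default the
#' comparison uses the induced span `B/C` (baseline autofluorescence is
#' not counted as pathway activation); set `include_baseline = TRUE` to
#' compare `A + B/C` instead.
#'
#' @param feedback [hill_params()] fit for the feedback strain.
#' @param control [hill_params()] fit for the untargeted-kinase control.
#' @param include_baseline logical; include baseline `A` in the maxima.
#' @return Percent reduction (positive when feedback lowers the maximum).
#' @export
percent_reduction <- function(feedback, control, include_baseline = FALSE) {
  stopifnot(inherits(feedback, "hill_params"), inherits(control, "hill_params"))
  span <- function(p) if (include_baseline) max_activation(p) else p$B / p$C
  mc <- span(control)
  if (mc == 0) stop_param("control maximal activation is zero")
  100 * (1 - span(feedback) / mc)
}

#' Locate the interior band-pass peak of an IFFL dose-response
#'
#' Searches for an interior maximum of [iffl_response()] on a wide
#' log-spaced dose grid and refines it with golden-section optimization.
#' A monotone response (e.g. `D = E`) has no interior peak.
#'
#' @param p an [iffl_params()] object.
#' @param lower,upper search interval in uM.
#' @param n_grid number of log-spaced grid points used for bracketing.
#' @return The peak dose in uM, or `NA_real_` when the response has no
#'   interior maximum.
#' @export
bandpass_peak <- function(p, lower = 1e-6, upper = 1e6, n_grid = 4000L) {
  stopifnot(inherits(p, "iffl_params"))
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  y <- iffl_response(grid, p)
  i <- which.max(y)
  if (i == 1L || i == n_grid) return(NA_real_)
  # require a genuine interior maximum, not a saturating plateau
  y0 <- iffl_response(0, p)
  yinf <- y[n_grid]
  tol <- 1e-10 * max(abs(y), 1)
  if (y[i] <= max(y0, yinf) + tol) return(NA_real_)
  opt <- optimize(function(x) iffl_response(x, p),
                  interval = c(grid[i - 1L], grid[i + 1L]),
                  maximum = TRUE, tol = 1e-12)
  opt$maximum
}

#' Classify a sampled dose-response curve
#'
#' Labels a sampled curve as `"bandpass"` (an interior dose exceeds both
#' endpoints), `"amplifier"` (the highest dose carries the maximum and
#' exceeds the baseline), or `"flat"`. Comparisons use a tolerance of
#' `rel_tol * max(signal)` so that sampling noise does not create
#' spurious interior maxima.
#'
#' @param doses sorted non-negative doses (uM) including 0; at least 5.
#' @param signal response values, one per dose.
#' @param rel_tol relative tolerance for "exceeds" (default 0.05).
#' @return One of `"amplifier"`, `"bandpass"`, `"flat"`.
#' @export
classify_response <- function(doses, signal, rel_tol = 0.05) {
  if (length(doses) != length(signal)) stop_param("doses and signal lengths differ")
  if (length(doses) < 5L) stop_param("need at least 5 dose points")
  if (is.unsorted(doses, strictly = TRUE)) stop_param("doses must be sorted and unique")
  if (doses[1] != 0) stop_param("dose series must include 0")
  eps <- rel_tol * max(abs(signal))
  k <- length(signal)
  interior <- signal[-c(1L, k)]
  if (max(interior) > signal[1] + eps && max(interior) > signal[k] + eps) {
    return("bandpass")
  }
  if (signal[k] >= max(signal) - eps && signal[k] > signal[1] + eps) {
    return("amplifier")
  }
  "flat"
}

#' Serialize response-model parameters to JSON
#'
#' @param p a [hill_params()] or [iffl_params()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
params_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "hill_params") || inherits(p, "iffl_params"))
  obj <- c(list(model = if (inherits(p, "iffl_params")) "iffl" else "hill"),
           unclass(p))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Read response-model parameters from JSON
#'
#' @param json a file path or JSON string produced by [params_to_json()].
#' @return A [hill_params()] or [iffl_params()] object.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  switch(obj$model %||% "hill",
    hill = hill_params(obj$A, obj$B, obj$C, obj$n),
    iffl = iffl_params(obj$A, obj$B, obj$C, obj$n, obj$D, obj$E,
                       baseline_modulated = obj$baseline_modulated %||% FALSE),
    stop_param("unknown model '%s' in JSON", obj$model))
}
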