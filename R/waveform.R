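#' Curvature and twist of a supercoil from pitch and diameter
#'
#' A supercoiled filament centerline is a circular helix of radius
#' `r = D / 2` and reduced rise `h = P / (2 * pi)`; its Frenet curvature
#' and torsion (here called twist) are `kappa = r / (r^2 + h^2)` and
#' `tau = h / (r^2 + h^2)`.  The straight limit `D = 0` gives
#' `kappa = 0, tau = 2 * pi / P`; the circle limit `P -> 0` gives
#' `kappa = 1 / r, tau = 0`.  Handedness is not observable from a single
#' 2D projection, so `tau` is reported positive (right-handed) by default;
#' flip the sign from independent metadata if known.
#'
#' @param P Supercoil pitch (micrometers), > 0. Vectorized.
#' @param D Supercoil diameter (micrometers), >= 0. Vectorized.
#' @return Data frame with columns `kappa` and `tau` (1/micrometer).
#' @examples
#' curvature_twist(2.0, 0.5)   # kappa 1.526, tau 1.943
#' @export
curvature_twist <- function(P, D) {
  if (any(!is.finite(P)) || any(P <= 0)) stop("'P' must be positive", call. = FALSE)
  if (any(!is.finite(D)) || any(D < 0)) stop("'D' must be >= 0", call. = FALSE)
  r <- D / 2
  h <- P / (2 * pi)
  s <- r^2 + h^2
  data.frame(kappa = r / s, tau = h / s)
}

#' Pitch and diameter from curvature and twist
#'
#' Algebraic inverse of [curvature_twist()]: `r = kappa / (kappa^2 +
#' tau^2)`, `h = tau / (kappa^2 + tau^2)`.
#'
#' @param kappa Curvature (1/micrometer), >= 0. Vectorized.
#' @param tau Twist (1/micrometer). Vectorized.
#' @return Data frame with columns `P` and `D` (micrometers).
#' @export
pitch_diameter <- function(kappa, tau) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("'kappa' must be >= 0", call. = FALSE)
  }
  s <- kappa^2 + tau^2
  if (any(s == 0)) stop("kappa and tau cannot both be zero", call. = FALSE)
  data.frame(P = 2 * pi * tau / s, D = 2 * kappa / s)
}

#' Waveform trace constructor
#'
#' A digitized filament centerline from a fluorescence image: the
#' projected lateral displacement `x` sampled along the axial coordinate
#' `s` (both micrometers).
#'
#' @param s Strictly increasing axial positions (micrometers).
#' @param x Lateral displacements (micrometers).
#' @param id Filament identifier.
#' @return Object of class `waveform_trace` (a data frame `s`, `x` with an
#'   `id` attribute).
#' @export
waveform_trace <- function(s, x, id = "filament") {
  s <- as.numeric(s); x <- as.numeric(x)
  if (length(s) != length(x) || length(s) < 4L) {
    stop("'s' and 'x' must be equal-length numeric vectors (>= 4 points)",
         call. = FALSE)
  }
  if (any(diff(s) <= 0)) stop("'s' must be strictly increasing", call. = FALSE)
  structure(data.frame(s = s, x = x), id = as.character(id),
            class = c("waveform_trace", "data.frame"))
}

# profiled least squares of x ~ A sin(2 pi s / P + phi) + x0 at fixed P:
# linear in (a, b, x0) with a sin + b cos
.sine_fit <- function(s, x, P) {
  X <- cbind(sin(2 * pi * s / P), cos(2 * pi * s / P), 1)
  fit <- stats::lm.fit(X, x)
  rss <- sum(fit$residuals^2)
  list(P = P, amp = sqrt(fit$coefficients[1]^2 + fit$coefficients[2]^2),
       phase = atan2(fit$coefficients[2], fit$coefficients[1]),
       offset = fit$coefficients[3], rss = rss)
}

#' Measure supercoil pitch and diameter from a projected centerline
#'
#' Fits `x(s) = (D / 2) * sin(2 * pi * s / P + phi0) + x0` by least
#' squares.  The period enters nonlinearly, so the fit multi-starts on a
#' dense grid of candidate periods (avoiding the local minima of the sine
#' objective) and polishes the best candidate with a 1D optimizer.
#'
#' @param trace A [waveform_trace()] (or data frame with columns `s`, `x`).
#' @param noise_floor Amplitude (micrometers) below which the trace is
#'   treated as straight and the pitch flagged indeterminate (default
#'   0.05).
#' @return List: `P` (pitch, micrometers; `NA` when indeterminate), `D`
#'   (diameter = twice the fitted amplitude), `residual` (root mean square
#'   fit residual), `indeterminate` (logical).  Errors if the trace spans
#'   less than one period of the best fit.
#' @export
measure_pitch_diameter <- function(trace, noise_floor = 0.05) {
  s <- trace$s; x <- trace$x
  span <- diff(range(s))
  if (span <= 0) stop("degenerate trace", call. = FALSE)
  # candidate periods from twice the sampling step up to twice the span
  p_lo <- max(4 * stats::median(diff(s)), span / 50)
  grid <- exp(seq(log(p_lo), log(2 * span), length.out = 200L))
  rss <- vapply(grid, function(P) .sine_fit(s, x, P)$rss, numeric(1))
  best <- grid[which.min(rss)]
  lo <- best / 1.3; hi <- best * 1.3
  opt <- stats::optimize(function(P) .sine_fit(s, x, P)$rss, c(lo, hi),
                         tol = 1e-10)
  fit <- .sine_fit(s, x, opt$minimum)
  resid <- sqrt(fit$rss / length(s))
  if (fit$amp < noise_floor) {
    return(list(P = NA_real_, D = 2 * fit$amp, residual = resid,
                indeterminate = TRUE))
  }
  if (fit$P > span) {
    stop(sprintf("trace spans %.3g um, less than one period of the fitted pitch %.3g um",
                 span, fit$P), call. = FALSE)
  }
  list(P = unname(fit$P), D = unname(2 * fit$amp), residual = resid,
       indeterminate = FALSE)
}

#' Per-strain waveform summary
#'
#' Measures each trace with [measure_pitch_diameter()], converts each
#' per-trace (P, D) to (kappa, tau) before averaging, and aggregates.
#'
#' @param traces List of [waveform_trace()] objects (one strain).
#' @param ... Passed to [measure_pitch_diameter()].
#' @return List with `per_trace` (data frame: id, P, D, kappa, tau,
#'   residual) and `summary` (data frame of mean and sd for P, D, kappa,
#'   tau over determinate traces; sd is 0 for a single trace).
#' @export
waveform_summary <- function(traces, ...) {
  if (inherits(traces, "waveform_trace")) traces <- list(traces)
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  rows <- lapply(traces, function(tr) {
    m <- measure_pitch_diameter(tr, ...)
    kt <- if (m$indeterminate) data.frame(kappa = NA_real_, tau = NA_real_)
          else curvature_twist(m$P, m$D)
    data.frame(id = attr(tr, "id") %||% "filament", P = m$P, D = m$D,
               kappa = kt$kappa, tau = kt$tau, residual = m$residual)
  })
  per_trace <- do.call(rbind, rows)
  ok <- per_trace[!is.na(per_trace$P), ]
  agg <- function(f) vapply(ok[c("P", "D", "kappa", "tau")], f, numeric(1))
  sdv <- if (nrow(ok) > 1) agg(stats::sd) else agg(function(v) 0)
  list(per_trace = per_trace,
       summary = data.frame(stat = c("mean", "sd"),
                            rbind(agg(mean), sdv), row.names = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write waveform trace CSV
#'
#' Column contract: `filament_id`, `s_um`, `x_um`.
#'
#' @param path CSV path.
#' @return `read_trace_csv`: list of [waveform_trace()]; `write_trace_csv`:
#'   `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filament_id", "s_um", "x_um")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$filament_id), function(d) {
    d <- d[order(d$s_um), ]
    waveform_trace(d$s_um, d$x_um, id = d$filament_id[1])
  })
}

#' @param traces List of [waveform_trace()] objects.
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "waveform_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(filament_id = attr(tr, "id"), s_um = tr$s, x_um = tr$x)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
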