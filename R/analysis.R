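#' Detect per-stimulus responses in a voltage trace
#'
#' A stimulus is scored as a response ("fired") when the cell-1 membrane
#' potential crosses `spike_threshold` upward within the stimulus window
#' `[times[i], times[i+1])` (the last window extends one inter-pulse
#' period).  Spikes in this Morris--Lecar regime overshoot 0 mV while
#' subthreshold responses stay well below it, so the default threshold is
#' 0 mV.  The latency is the time from pulse onset to the first threshold
#' crossing (linear interpolation between samples).
#'
#' @param trace a `sim_trace` covering all pulses of `train`.
#' @param train the [pulse_train()] that generated the trace.
#' @param spike_threshold spike-detection threshold (mV).
#' @return A data frame of class `response_series` with columns `stim`,
#'   `time_ms` (pulse onset), `fired`, `latency_ms` (NA when not fired).
#' @examples
#' \donttest{
#' run <- run_habituation(mcell_params(ag_max = 41.5), count = 10, step = 0.05)
#' detect_responses(run$trace, run$train)
#' }
#' @export
detect_responses <- function(trace, train, spike_threshold = 0) {
  stopifnot(inherits(trace, "sim_trace"), inherits(train, "pulse_train"))
  onsets <- stimulus_times(train)
  if (length(onsets) == 0) {
    return(structure(data.frame(stim = integer(0), time_ms = numeric(0),
                                fired = logical(0), latency_ms = numeric(0)),
                     class = c("response_series", "data.frame"),
                     train = train))
  }
  period <- 1000 / train$frequency
  t <- trace$t_ms
  if (max(t) < onsets[length(onsets)] + period - 1e-6) {
    stop("trace does not cover the last stimulus window")
  }
  keep <- t >= onsets[1] - 1e-9 & t <= onsets[length(onsets)] + period
  if (max(diff(t[keep])) > 1 + 1e-9) {
    stop("trace sampling too coarse to localize spike crossings within 1 ms")
  }
  v <- trace$v1
  up <- which(v[-length(v)] < spike_threshold & v[-1] >= spike_threshold)
  cross_t <- t[up] + (spike_threshold - v[up]) / (v[up + 1] - v[up]) *
    (t[up + 1] - t[up])
  win <- findInterval(cross_t, c(onsets, onsets[length(onsets)] + period))
  win[win < 1 | win > length(onsets)] <- NA
  fired <- seq_along(onsets) %in% win
  latency <- rep(NA_real_, length(onsets))
  hit <- !is.na(win)
  if (any(hit)) {
    first <- tapply(cross_t[hit], win[hit], min)
    idx <- as.integer(names(first))
    latency[idx] <- as.numeric(first) - onsets[idx]
  }
  structure(data.frame(stim = seq_along(onsets), time_ms = onsets,
                       fired = fired, latency_ms = latency),
            class = c("response_series", "data.frame"), train = train)
}

#' Faithfulness of the response to repeated stimuli
#'
#' The fraction of stimuli that evoke an action potential, counted over
#' stimuli whose onset lies in `[window_start, window_end)`.  Faithfulness
#' ranges from 0 (no response) to 1 (full response); higher Faithfulness
#' corresponds to lower habituation.  The standard analysis windows at a
#' 20 s stimulation onset are the initial interval 20--30 s and the stable
#' interval 40--70 s.
#'
#' @param series a `response_series` from [detect_responses()].
#' @param window_start,window_end analysis window (ms); stimuli with onset
#'   in `[window_start, window_end)` are counted.
#' @return Fraction in \[0, 1\].
#' @examples
#' s <- structure(data.frame(stim = 1:10, time_ms = 20000 + 0:9 * 1000,
#'                           fired = rep(c(TRUE, FALSE), 5),
#'                           latency_ms = NA),
#'                class = c("response_series", "data.frame"))
#' faithfulness(s, 20000, 30000)
#' @export
faithfulness <- function(series, window_start, window_end) {
  stopifnot(inherits(series, "response_series"))
  sel <- series$time_ms >= window_start & series$time_ms < window_end
  if (!any(sel)) stop("window contains no stimuli")
  mean(series$fired[sel])
}

#' Suprathreshold area per stimulus window
#'
#' For each stimulus i, the area `A_i` under the cell-1 voltage trace above
#' `area_threshold`, integrated by the trapezoidal rule on the stored trace
#' grid over `[times[i], times[i+1])`.  The default threshold, -30 mV, sits
#' between the resting potential (about -34 mV) and the spike peak, so that
#' subthreshold responses contribute small positive areas and spikes very
#' large ones; the resulting return maps are insensitive to the exact
#' threshold choice.
#'
#' @param trace a `sim_trace`.
#' @param train the [pulse_train()] used.
#' @param area_threshold area threshold (mV).
#' @return Numeric vector of areas `A_i` (mV ms, >= 0), one per stimulus.
#' @export
response_areas <- function(trace, train, area_threshold = -30) {
  stopifnot(inherits(trace, "sim_trace"), inherits(train, "pulse_train"))
  onsets <- stimulus_times(train)
  if (length(onsets) == 0) return(numeric(0))
  period <- 1000 / train$frequency
  t <- trace$t_ms
  h <- pmax(trace$v1 - area_threshold, 0)
  # cumulative trapezoid, then difference across window edges
  seg <- diff(t) * (h[-1] + h[-length(h)]) / 2
  cum <- c(0, cumsum(seg))
  at <- function(x) {
    # cumulative integral up to time x (x is a grid point up to round-off)
    i <- findInterval(x, t)
    i <- pmin(pmax(i, 1), length(t))
    cum[i]
  }
  as.numeric(at(onsets + period) - at(onsets))
}

#' One-dimensional return map of suprathreshold areas
#'
#' Consecutive-area pairs `(A_i, A_{i+1})` restricted to stimuli whose
#' onset falls in the analysis window (default 100--300 s after the first
#' pulse, discarding the transient).  Because spike areas exceed
#' subthreshold areas by orders of magnitude, areas are log10-transformed
#' for classification and plotting.
#'
#' @param areas per-stimulus areas from [response_areas()].
#' @param train the [pulse_train()] used.
#' @param window analysis window (ms) relative to the first pulse onset.
#' @param log log10-transform the areas (errors if any selected area is 0,
#'   which signals a misconfigured area threshold).
#' @return Data frame with columns `i`, `A_i`, `A_next` (log10 values in
#'   `logA_i`, `logA_next` when `log = TRUE`).
#' @export
return_map <- function(areas, train, window = c(100000, 300000), log = TRUE) {
  stopifnot(inherits(train, "pulse_train"))
  onsets <- stimulus_times(train)
  if (length(areas) != length(onsets)) {
    stop("areas and stimulus count differ")
  }
  rel <- onsets - train$onset
  sel <- which(rel >= window[1] & rel < window[2])
  if (length(sel) < 2) stop("analysis window covers fewer than 2 stimuli")
  i <- sel[-length(sel)]
  out <- data.frame(i = i, A_i = areas[i], A_next = areas[i + 1])
  if (log) {
    if (any(out$A_i <= 0 | out$A_next <= 0)) {
      stop("zero suprathreshold area in the analysis window; ",
           "lower area_threshold so subthreshold responses are captured")
    }
    out$logA_i <- log10(out$A_i)
    out$logA_next <- log10(out$A_next)
  }
  out
}

#' Classify the stationary response pattern
#'
#' Classifies the asymptotic response of the cell to periodic stimulation
#' into the five return-map types, in order of increasing excitability:
#' `subthreshold_fixed_point` (the cell stops responding and subthreshold
#' areas settle on a fixed point), `subthreshold_periodic` (sparse but
#' periodic action potentials, firing fraction <= 0.5), `irregular`
#' (aperiodic, potentially chaotic response), `suprathreshold_periodic`
#' (spikes skipped sparsely but periodically, firing fraction > 0.5), and
#' `suprathreshold_fixed_point` (faithful firing to every stimulus).
#'
#' The firing sequence over the analysis window is called periodic when
#' some period `p <= period_max` repeats exactly; the deterministic model
#' at fixed step size makes exact repetition well-defined.
#'
#' @param series a `response_series`.
#' @param areas per-stimulus areas from [response_areas()].
#' @param window analysis window (ms) relative to the first pulse onset;
#'   must contain at least 20 stimuli.
#' @param tolerances list with `period_max` (maximum period tested, default
#'   10) and `area_sd_log` (maximum standard deviation of log10 areas for
#'   a silent pattern to count as a fixed point, default 0.05).
#' @return One of the five class labels (character), with attributes
#'   `firing_fraction` and `period` (NA when aperiodic).
#' @export
classify_pattern <- function(series, areas, window = c(100000, 300000),
                             tolerances = list(period_max = 10,
                                               area_sd_log = 0.05)) {
  stopifnot(inherits(series, "response_series"))
  period_max <- tolerances$period_max %||% 10
  area_sd_log <- tolerances$area_sd_log %||% 0.05
  rel <- series$time_ms - series$time_ms[1]
  sel <- rel >= window[1] & rel < window[2]
  if (sum(sel) < 20) {
    stop("analysis window contains fewer than 20 stimuli")
  }
  fired <- series$fired[sel]
  f <- mean(fired)
  label <- function(lab, p = NA_integer_) {
    structure(lab, firing_fraction = f, period = p)
  }
  if (f == 1) return(label("suprathreshold_fixed_point", 1L))
  if (f == 0) {
    a <- areas[which(sel)]
    if (any(a <= 0) || sd(log10(a)) <= area_sd_log) {
      return(label("subthreshold_fixed_point", 1L))
    }
    return(label("irregular"))
  }
  p <- firing_period(fired, period_max)
  if (is.na(p)) return(label("irregular"))
  if (f <= 0.5) label("subthreshold_periodic", p) else
    label("suprathreshold_periodic", p)
}

firing_period <- function(x, period_max) {
  n <- length(x)
  for (p in seq_len(min(period_max, n - 1))) {
    if (all(x[seq_len(n - p)] == x[seq_len(n - p) + p])) return(p)
  }
  NA_integer_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Firing boundary scan in the slow ([Ca], E_net) plane
#'
#' For each grid point of the rectangle `region` in the slow
#' (calcium, adaptation) plane, the fast variables are frozen at their
#' quasi-steady values `(v0, n0)`, the slow variables are set to the grid
#' values, and a single stimulus pulse is delivered immediately; the grid
#' point is marked "fired" if the cell spikes.  The fired set (the
#' "jump-up region") lies left of a boundary curve running from the lower
#' left to the upper right of the plane: lower calcium and higher
#' adaptation make the cell fire.
#'
#' The default region \[3, 3.2\] x \[0.9, 1.2\] at increment 0.01 covers the
#' slow-variable excursion during 1 Hz stimulation.
#'
#' @param params an [mcell_params()] object.
#' @param region `c(Ca_min, Ca_max, E_min, E_max)`.
#' @param increment grid spacing in both coordinates.
#' @param v0,n0 frozen fast variables; default taken from
#'   [quasi_steady_state()] of `params` (reference values: `(-34.32,
#'   0.00427)` dominant/communal-like, `(-34.322, 0.00429)`
#'   subordinate-like).
#' @param amplitude,width stimulus pulse parameters.
#' @param spike_threshold spike-detection threshold (mV).
#' @param sim_duration post-pulse simulation time (ms) used to detect the
#'   spike.
#' @param step integrator step (ms).
#' @return An object of class `jumpup_grid`: list with `Ca`, `E_net` (grid
#'   axes), `fired` (logical matrix, rows = Ca, columns = E_net), and
#'   `boundary` (per-Ca smallest firing E_net, NA where no grid E fires).
#' @export
jump_up_grid <- function(params, region = c(3, 3.2, 0.9, 1.2),
                         increment = 0.01, v0 = NULL, n0 = NULL,
                         amplitude = 4.5, width = 20, spike_threshold = 0,
                         sim_duration = 300, step = 0.01) {
  stopifnot(inherits(params, "mcell_params"))
  if (is.null(v0) || is.null(n0)) {
    qs <- quasi_steady_state(params, step = max(step, 0.01))
    if (is.null(v0)) v0 <- qs[["v1"]]
    if (is.null(n0)) n0 <- qs[["n1"]]
  }
  Ca_grid <- seq(region[1], region[2], by = increment)
  E_grid <- seq(region[3], region[4], by = increment)
  # the synaptic variable rests at its fixed point alpha*s_inf/(alpha*s_inf
  # + beta), not at s_inf; near the firing boundary the difference matters
  s_inf <- activation_curves(v0, params)$s_inf
  s0 <- params$alpha * s_inf / (params$alpha * s_inf + params$beta)
  train <- pulse_train(onset = 0, frequency = 1, count = 1,
                       amplitude = amplitude, width = width)
  fired <- matrix(NA, nrow = length(Ca_grid), ncol = length(E_grid),
                  dimnames = list(Ca = format(Ca_grid), E_net = format(E_grid)))
  for (j in seq_along(Ca_grid)) {
    for (k in seq_along(E_grid)) {
      cs <- circuit_state(cell_state(v = v0, n = n0, Ca = Ca_grid[j],
                                     s = s0, E_net = E_grid[k]))
      tr <- integrate_circuit(cs, params, train, t_end = sim_duration,
                              step = step, sample_by = 0.5, fine_window = 0)
      fired[j, k] <- count_upward_crossings(tr$t_ms, tr$v1, spike_threshold,
                                            0, sim_duration) > 0
    }
  }
  boundary_idx <- apply(fired, 1, function(row) {
    w <- which(row)
    if (length(w)) min(w) else NA_integer_
  })
  # frontier must climb from lower-left to upper-right; tolerate single-cell
  # jitter, flag anything worse as a detection bug
  fin <- boundary_idx[!is.na(boundary_idx)]
  if (length(fin) > 1 && any(diff(fin) < -1)) {
    stop("jump-up frontier is non-monotone beyond one grid cell")
  }
  structure(list(Ca = Ca_grid, E_net = E_grid, fired = fired,
                 boundary = data.frame(
                   Ca = Ca_grid,
                   E_min = ifelse(is.na(boundary_idx), NA_real_,
                                  E_grid[boundary_idx]))),
            class = "jumpup_grid",
            v0 = v0, n0 = n0, amplitude = amplitude, width = width)
}

#' @export
print.jumpup_grid <- function(x, ...) {
  cat(sprintf("jump-up grid: %d x %d points, %d fired\n",
              length(x$Ca), length(x$E_net), sum(x$fired)))
  invisible(x)
}

#' Project a trajectory into the slow ([Ca], E_net) plane
#'
#' Sample the cell-1 slow variables at each stimulus onset, labelled by
#' whether that stimulus evoked a spike.  Overlaying these triples on a
#' [jump_up_grid()] boundary shows how the slow drift carries the cell out
#' of (and, for subordinate-like cells, back into) the firing region.
#'
#' @param trace a `sim_trace`.
#' @param train the [pulse_train()] used.
#' @param series the matching `response_series`.
#' @return Data frame with columns `stim`, `time_ms`, `Ca`, `E_net`,
#'   `fired`.
#' @export
slow_projection <- function(trace, train, series) {
  stopifnot(inherits(trace, "sim_trace"), inherits(train, "pulse_train"),
            inherits(series, "response_series"))
  onsets <- stimulus_times(train)
  idx <- findInterval(onsets + 1e-9, trace$t_ms)
  if (any(abs(trace$t_ms[idx] - onsets) > 0.5)) {
    stop("trace samples do not align with stimulus onsets")
  }
  data.frame(stim = seq_along(onsets), time_ms = onsets,
             Ca = trace$Ca1[idx], E_net = trace$E_net1[idx],
             fired = series$fired)
}

#' Faithfulness scan over stimulation frequency and a second parameter
#'
#' Run the full habituation protocol over a grid of stimulation
#' frequencies crossed with either `ag_max` values (social-phenotype axis)
#' or stimulus amplitudes, and measure Faithfulness in each analysis
#' window.  Each grid cell is initialized at its own quasi-steady state
#' (cached per parameter set).  Failures in individual cells are recorded
#' as NA and the scan continues.
#'
#' @param params baseline [mcell_params()]; `ag_max` is overridden when
#'   scanning the `ag_max` axis.
#' @param frequencies stimulation frequency grid (Hz).
#' @param ag_max_values grid for the `ag_max` axis (default
#'   `seq(40.5, 44.5, by = 0.25)`); set to `NULL` to scan amplitude
#'   instead.
#' @param amplitude_values grid for the amplitude axis (used when
#'   `ag_max_values` is `NULL`; default `seq(3, 6, by = 0.25)`).
#' @param windows named list of analysis windows (ms).
#' @param amplitude pulse amplitude used on the `ag_max` axis.
#' @param width pulse width (ms).
#' @param onset stimulation onset (ms).
#' @param t_end run end (ms); default covers the last window.
#' @param step integrator step (ms).
#' @return Tidy data frame with columns `frequency`, `ag_max` or
#'   `amplitude`, `window`, `faithfulness`.
#' @export
faithfulness_scan <- function(params = mcell_params(),
                              frequencies = c(0.1, 0.2, 0.5, 1, 2, 5),
                              ag_max_values = seq(40.5, 44.5, by = 0.25),
                              amplitude_values = NULL,
                              windows = list(initial = c(20000, 30000),
                                             stable = c(40000, 70000)),
                              amplitude = 4.5, width = 20, onset = 20000,
                              t_end = NULL, step = 0.01) {
  stopifnot(inherits(params, "mcell_params"))
  axis_ag <- !is.null(ag_max_values)
  if (!axis_ag && is.null(amplitude_values)) {
    amplitude_values <- seq(3, 6, by = 0.25)
  }
  yvals <- if (axis_ag) ag_max_values else amplitude_values
  if (is.null(t_end)) t_end <- max(vapply(windows, max, numeric(1)))
  qss_cache <- new.env(parent = emptyenv())
  qss_for <- function(p) {
    key <- format(p$ag_max, digits = 15)
    if (is.null(qss_cache[[key]])) {
      qss_cache[[key]] <- quasi_steady_state(p, step = step)
    }
    qss_cache[[key]]
  }
  rows <- list()
  for (y in yvals) {
    p <- if (axis_ag) mcell_params_override(params, ag_max = y) else params
    amp <- if (axis_ag) amplitude else y
    init <- tryCatch(qss_for(p), error = function(e) e)
    for (fr in frequencies) {
      vals <- rep(NA_real_, length(windows))
      if (!inherits(init, "error")) {
        count <- ceiling((t_end - onset) * fr / 1000)
        res <- tryCatch({
          run <- run_habituation(p, frequency = fr, count = count,
                                 amplitude = amp, width = width,
                                 onset = onset, t_end = t_end, step = step,
                                 init = init, sample_by = 1, fine_window = 0)
          vapply(windows, function(w) {
            faithfulness(run$series, w[1], w[2])
          }, numeric(1))
        }, error = function(e) {
          warning(sprintf("scan cell (freq %g, %g) failed: %s", fr, y,
                          conditionMessage(e)), call. = FALSE)
          rep(NA_real_, length(windows))
        })
        vals <- res
      }
      rows[[length(rows) + 1]] <- data.frame(
        frequency = fr, y = y, window = names(windows),
        faithfulness = vals)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2] <- if (axis_ag) "ag_max" else "amplitude"
  rownames(out) <- NULL
  out
}

mcell_params_override <- function(params, ...) {
  p <- unclass(params)
  dots <- list(...)
  p[names(dots)] <- dots
  validate_params(p)
  structure(p, class = "mcell_params")
}

#' Plot a jump-up grid
#'
#' Fired/silent grid points in the slow ([Ca], E_net) plane with the
#' boundary curve; pass a [slow_projection()] result to overlay a
#' trajectory.
#'
#' @param x a `jumpup_grid`.
#' @param projection optional data frame from [slow_projection()].
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.jumpup_grid <- function(x, projection = NULL, ...) {
  pts <- expand.grid(Ca = x$Ca, E_net = x$E_net)
  fired <- as.vector(x$fired)
  graphics::plot(pts$Ca, pts$E_net, pch = ifelse(fired, 16, 1),
                 col = ifelse(fired, "tomato3", "grey70"),
                 cex = 0.6, xlab = "[Ca]", ylab = "E_net", ...)
  ok <- !is.na(x$boundary$E_min)
  graphics::lines(x$boundary$Ca[ok], x$boundary$E_min[ok], lwd = 2)
  if (!is.null(projection)) {
    graphics::lines(projection$Ca, projection$E_net, col = "grey30")
    graphics::points(projection$Ca, projection$E_net,
                     pch = ifelse(projection$fired, 17, 2), cex = 0.8,
                     col = "navy")
  }
  invisible(x)
}
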