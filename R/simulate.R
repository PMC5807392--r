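#' Integrate the circuit under a pulse protocol
#'
#' Fixed-step classical fourth-order Runge--Kutta integration of the ten
#' circuit equations.  Pulse edges are forced grid points, so no integration
#' step ever straddles a drive discontinuity; within each continuous segment
#' the step is `step` (shortened evenly on the final partial step of a
#' segment).
#'
#' The returned trace is sampled on a coarse grid (`sample_by`, default
#' 1 ms) everywhere, refined to `fine_by` (default 0.1 ms) within
#' `fine_window` ms around each pulse onset so that spike latencies and
#' suprathreshold areas are resolved precisely where they matter.
#'
#' @param initial a `circuit_state` (or named 10-vector) at time 0.
#' @param params an [mcell_params()] object.
#' @param train a [pulse_train()], or `NULL` for stimulus-free relaxation.
#' @param t_end end time (ms, >= 0); `t_end = 0` returns the initial state.
#' @param step integrator step (ms, <= 0.1; default 0.01).
#' @param sample_by coarse trace sampling interval (ms).
#' @param fine_by fine sampling interval near pulses (ms); set `NULL` (or
#'   `fine_window = 0`) to disable refinement.
#' @param fine_window half-width (ms) of the refined window around each
#'   pulse onset.
#' @return A data frame of class `sim_trace` with columns `t_ms`,
#'   `v1, n1, Ca1, s1, E_net1, v2, n2, Ca2, s2, E_net2`, `drive1`; the
#'   protocol, step and calcium-clamp count are attached as attributes.
#' @examples
#' p <- mcell_params(ag_max = 41.5)
#' st <- circuit_state(cell_state(-30, 0.01, 3, 1e-4, 1))
#' tr <- integrate_circuit(st, p, t_end = 100, step = 0.05)
#' tail(tr$v1, 1)
#' @export
integrate_circuit <- function(initial, params, train = NULL, t_end,
                              step = 0.01, sample_by = 1, fine_by = 0.1,
                              fine_window = 50) {
  stopifnot(inherits(params, "mcell_params"))
  if (!is.finite(t_end) || t_end < 0) stop("t_end must be >= 0")
  if (!is.finite(step) || step <= 0 || step > 0.1) {
    stop("step must lie in (0, 0.1] ms")
  }
  y0 <- as_state_vector(initial)

  if (is.null(train)) {
    onsets <- numeric(0)
    width <- 1
    amplitude <- 0
  } else {
    stopifnot(inherits(train, "pulse_train"))
    if (step > train$width) stop("integrator step exceeds the pulse width")
    onsets <- stimulus_times(train)
    width <- train$width
    amplitude <- train$amplitude
  }

  ts <- unique(c(seq(0, t_end, by = sample_by), t_end))
  if (length(onsets) && !is.null(fine_by) && fine_window > 0) {
    fine <- lapply(onsets[onsets - fine_window <= t_end & onsets + fine_window >= 0],
                   function(on) {
                     seq(max(0, on - fine_window), min(t_end, on + fine_window),
                         by = fine_by)
                   })
    ts <- c(ts, unlist(fine))
  }
  ts <- sort(ts)
  ts <- ts[c(TRUE, diff(ts) > 1e-9)]

  res <- .rk4_integrate(unname(y0), unclass(params), onsets, width,
                        amplitude, 0, t_end, step, ts)
  bad <- !is.finite(res$state)
  if (any(bad)) stop("non-finite state values in trace")

  out <- as.data.frame(res$state)
  names(out) <- state_names
  out <- cbind(t_ms = res$time, out, drive1 = res$drive)
  structure(out,
            class = c("sim_trace", "data.frame"),
            train = train, step = step, sample_by = sample_by,
            ca_clamped = res$ca_clamped)
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("circuit trace: %d samples over %g ms (step %g ms)\n",
              nrow(x), max(x$t_ms), attr(x, "step")))
  if (isTRUE(attr(x, "ca_clamped") > 0)) {
    cat(sprintf("  [Ca] round-off clamped to 0 at %g integration steps\n",
                attr(x, "ca_clamped")))
  }
  NextMethod()
}

final_state <- function(trace) {
  y <- as.numeric(trace[nrow(trace), state_names])
  structure(setNames(y, state_names), class = "circuit_state")
}

#' Quasi-steady state of the circuit
#'
#' Relax the circuit with zero drive for `relax_duration` ms (default 20 s,
#' the reference initialization) from a generic resting start and return
#' the final state.  Errors if the state is still drifting at the end
#' (maximum derivative magnitude above `tol`), which signals a parameter
#' set without a stimulus-free equilibrium in this basin.
#'
#' @param params an [mcell_params()] object.
#' @param relax_duration relaxation time (ms).
#' @param step integrator step (ms).
#' @param tol drift tolerance on the maximum absolute derivative at the end
#'   of relaxation (per-ms units of each variable).
#' @param initial optional starting `circuit_state`; the default starts at
#'   `v = -30`, `n = n_inf(-30)`, `Ca = 3`, `s = s_inf(-30)`, `E_net = 1`.
#' @return A `circuit_state` with attribute `residual` (max |derivative|).
#' @examples
#' qs <- quasi_steady_state(mcell_params(ag_max = 41.5), step = 0.05)
#' round(qs[["v1"]], 2)
#' @export
quasi_steady_state <- function(params, relax_duration = 20000, step = 0.01,
                               tol = 0.01, initial = NULL) {
  stopifnot(inherits(params, "mcell_params"))
  if (is.null(initial)) {
    ac <- activation_curves(-30, params)
    initial <- circuit_state(cell_state(v = -30, n = ac$n_inf, Ca = 3,
                                        s = ac$s_inf, E_net = 1))
  }
  tr <- integrate_circuit(initial, params, train = NULL,
                          t_end = relax_duration, step = step,
                          sample_by = relax_duration)
  st <- final_state(tr)
  resid <- max(abs(circuit_derivatives(st, params)))
  if (resid > tol) {
    stop(sprintf(paste0("state still drifting after %g ms of relaxation ",
                        "(max |derivative| = %.3g > %g): no quasi-steady ",
                        "state reached"), relax_duration, resid, tol))
  }
  attr(st, "residual") <- resid
  st
}

#' Run a habituation protocol end to end
#'
#' Initialize at the quasi-steady state, deliver a periodic pulse train,
#' and detect per-stimulus responses.  This is the standard protocol run:
#' 40 pulses of amplitude 4.5 at 1 or 0.2 Hz beginning at 20 s.
#'
#' @param params an [mcell_params()] object.
#' @param frequency stimulation frequency (Hz).
#' @param count number of pulses.
#' @param amplitude pulse amplitude.
#' @param width pulse width (ms); see [calibrate_pulse_width()].
#' @param onset time of the first pulse (ms).
#' @param t_end end of simulation (ms); default covers the last response
#'   window, `onset + count * 1000/frequency`.
#' @param step integrator step (ms).
#' @param spike_threshold spike-detection threshold (mV), see
#'   [detect_responses()].
#' @param area_threshold area threshold (mV), see [response_areas()].
#' @param init optional precomputed initial `circuit_state` (e.g. a cached
#'   [quasi_steady_state()]).
#' @param ... further arguments to [integrate_circuit()] (`sample_by`,
#'   `fine_by`, `fine_window`).
#' @return A list of class `habituation_run`: `trace` (a `sim_trace`),
#'   `series` (a `response_series` with per-stimulus fired flags,
#'   latencies and suprathreshold areas), `train`, `params`.
#' @examples
#' \donttest{
#' run <- run_habituation(mcell_params(ag_max = 41.5), frequency = 1,
#'                        count = 40, step = 0.05)
#' sum(run$series$fired)
#' }
#' @export
run_habituation <- function(params, frequency = 1, count = 40,
                            amplitude = 4.5, width = 20, onset = 20000,
                            t_end = NULL, step = 0.01, spike_threshold = 0,
                            area_threshold = -30, init = NULL, ...) {
  train <- pulse_train(onset = onset, frequency = frequency, count = count,
                       amplitude = amplitude, width = width)
  if (is.null(t_end)) t_end <- onset + count * 1000 / frequency
  if (is.null(init)) init <- quasi_steady_state(params, step = step)
  trace <- integrate_circuit(init, params, train, t_end = t_end,
                             step = step, ...)
  series <- detect_responses(trace, train, spike_threshold = spike_threshold)
  series$area <- response_areas(trace, train, area_threshold = area_threshold)
  structure(list(trace = trace, series = series, train = train,
                 params = params),
            class = "habituation_run")
}

#' @export
print.habituation_run <- function(x, ...) {
  cat(sprintf("habituation run: ag_max = %g, %d pulses at %g Hz; %d/%d fired\n",
              x$params$ag_max, x$train$count, x$train$frequency,
              sum(x$series$fired), nrow(x$series)))
  invisible(x)
}

#' Calibrate the stimulus pulse width
#'
#' The model delivers a depolarizing current pulse of amplitude 4.5 per
#' stimulus, but the pulse duration is a free parameter and the circuit's
#' phenotypes are extremely sensitive to it (all the qualitative structure
#' lives in a band of a few hundredths of a millisecond around 1.96 ms at
#' the default amplitude).  This routine selects the smallest candidate
#' width for which the qualitative phenotypes hold:
#'
#' 1. the subordinate-like model fires exactly one action potential to the
#'    first pulse from its quasi-steady state;
#' 2. the dominant-like model responds to at least one of the first ten
#'    1 Hz stimuli and to none after stimulus 10;
#' 3. the subordinate-like model responds intermittently and aperiodically
#'    (firing fraction strictly between 0 and 1, no exact period <= 10)
#'    over the stationary 100--300 s window at 1 Hz;
#' 4. at 0.2 Hz the spread of stable-window Faithfulness across the three
#'    phenotypes is smaller than at 1 Hz.
#'
#' Checks are run cheapest-first and a candidate is abandoned at its first
#' failure, so the search is far cheaper than four full protocols per
#' candidate.
#'
#' @param params_subordinate subordinate-like parameters
#'   (default `ag_max = 43.5`).
#' @param params_dominant dominant-like parameters (default `ag_max = 41.5`).
#' @param params_communal communal-like parameters (default
#'   `ag_max = 42.2`), used in the frequency-spread check.
#' @param candidates candidate widths (ms), ascending.
#' @param amplitude pulse amplitude.
#' @param step integrator step (ms).
#' @param spike_threshold spike-detection threshold (mV).
#' @return The selected width (ms), with the evaluation of all candidates
#'   up to the selected one attached as attribute `table`.  Errors if no
#'   candidate elicits the single first-pulse spike, or if none satisfies
#'   all four phenotype conditions.
#' @examples
#' \donttest{
#' calibrate_pulse_width()
#' }
#' @export
calibrate_pulse_width <- function(params_subordinate = mcell_params(ag_max = 43.5),
                                  params_dominant = mcell_params(ag_max = 41.5),
                                  params_communal = mcell_params(ag_max = 42.2),
                                  candidates = seq(1.95, 1.99, by = 5e-4),
                                  amplitude = 4.5, step = 0.01,
                                  spike_threshold = 0) {
  if (is.unsorted(candidates, strictly = TRUE)) {
    stop("candidate widths must be ascending")
  }
  phen <- list(dominant = params_dominant, communal = params_communal,
               subordinate = params_subordinate)
  qs <- lapply(phen, quasi_steady_state, step = step)
  onset <- 20000
  run_phen <- function(nm, frequency, count, w, t_end = NULL) {
    run_habituation(phen[[nm]], frequency = frequency, count = count,
                    amplitude = amplitude, width = w, onset = onset,
                    t_end = t_end, step = step, init = qs[[nm]],
                    spike_threshold = spike_threshold,
                    sample_by = 1, fine_window = 0)
  }
  any_single <- FALSE
  rows <- list()
  for (w in candidates) {
    row <- data.frame(width = w, single_spike = NA, dominant_stops = NA,
                      subordinate_irregular = NA, freq_spread_shrinks = NA)
    ok <- local({
      tr1 <- pulse_train(onset = onset, frequency = 1, count = 1,
                         amplitude = amplitude, width = w)
      trace1 <- integrate_circuit(qs$subordinate, params_subordinate, tr1,
                                  t_end = onset + 1000, step = step,
                                  sample_by = 1, fine_window = 0)
      n_spikes <- count_upward_crossings(trace1$t_ms, trace1$v1,
                                         spike_threshold, onset, onset + 1000)
      row$single_spike <<- n_spikes == 1
      if (n_spikes != 1) return(FALSE)
      any_single <<- TRUE

      dom <- run_phen("dominant", 1, 40, w)
      fired <- dom$series$fired
      row$dominant_stops <<- any(fired[1:10]) && !any(fired[11:40])
      if (!row$dominant_stops) return(FALSE)

      sub <- run_phen("subordinate", 1, 300, w, t_end = onset + 301000)
      rel <- sub$series$time_ms - onset
      x <- sub$series$fired[rel >= 100000 & rel < 300000]
      f <- mean(x)
      row$subordinate_irregular <<- f > 0 && f < 1 &&
        is.na(firing_period(as.integer(x), 10))
      if (!row$subordinate_irregular) return(FALSE)

      f_at <- function(freq) {
        vapply(names(phen), function(nm) {
          r <- run_phen(nm, freq, ceiling(50 * freq), w, t_end = 70000)
          faithfulness(r$series, 40000, 70000)
        }, numeric(1))
      }
      row$freq_spread_shrinks <<-
        diff(range(f_at(0.2))) < diff(range(f_at(1)))
      row$freq_spread_shrinks
    })
    rows[[length(rows) + 1]] <- row
    if (isTRUE(ok)) {
      tab <- do.call(rbind, rows)
      return(structure(w, table = tab))
    }
  }
  if (!any_single) {
    stop("no candidate width elicits exactly one spike to the first pulse; ",
         "check the model equations or the amplitude")
  }
  stop("no candidate width satisfies all calibration phenotypes")
}

count_upward_crossings <- function(t, v, threshold, t_from, t_to) {
  keep <- t >= t_from & t < t_to
  t <- t[keep]; v <- v[keep]
  if (length(v) < 2) return(0L)
  sum(v[-length(v)] < threshold & v[-1] >= threshold)
}

#' Plot a simulation trace
#'
#' Voltage of the stimulated cell over time with the drive shown underneath;
#' quick visual check of a protocol run.
#'
#' @param x a `sim_trace`.
#' @param window optional `c(from, to)` time window (ms).
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sim_trace <- function(x, window = NULL, ...) {
  d <- x
  if (!is.null(window)) d <- d[d$t_ms >= window[1] & d$t_ms <= window[2], ]
  graphics::plot(d$t_ms / 1000, d$v1, type = "l", xlab = "time (s)",
                 ylab = "v (mV)", ...)
  if (any(d$drive1 > 0)) {
    on <- range(d$v1)
    graphics::lines(d$t_ms / 1000,
                    min(d$v1) + d$drive1 / max(d$drive1) * 0.05 * diff(on),
                    col = "grey50")
  }
  invisible(x)
}
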