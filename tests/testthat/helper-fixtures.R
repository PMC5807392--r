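# Build synthetic sim_trace objects without running the integrator, and
# cache the expensive reference runs so several tests can share them.

make_trace <- function(t, v1, train = NULL, Ca1 = 3, E_net1 = 1) {
  n <- length(t)
  df <- data.frame(t_ms = t, v1 = v1, n1 = 0, Ca1 = Ca1, s1 = 0, E_net1 = E_net1,
                   v2 = -34, n2 = 0, Ca2 = 3, s2 = 0, E_net2 = 1, drive1 = 0)
  structure(df, class = c("sim_trace", "data.frame"),
            train = train, step = NA_real_, sample_by = diff(t[1:2]))
}

make_series <- function(time_ms, fired, latency_ms = ifelse(fired, 5, NA)) {
  structure(data.frame(stim = seq_along(time_ms), time_ms = time_ms,
                       fired = fired, latency_ms = latency_ms),
            class = c("response_series", "data.frame"))
}

# gaussian bump spike shape riding on a resting potential
inject_spike <- function(v, t, center, peak = 40, width = 4) {
  v + (peak - v) * exp(-(t - center)^2 / (2 * width^2))
}

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

qss_for <- function(ag_max, step = 0.01) {
  cached(sprintf("qss_%g_%g", ag_max, step),
         quasi_steady_state(mcell_params(ag_max = ag_max), step = step))
}

# reference habituation run shared by the acceptance tests; 300 s protocol
long_run <- function(ag_max, frequency = 1, width = calibrated_width()) {
  cached(sprintf("long_%g_%g_%g", ag_max, frequency, width), {
    run_habituation(mcell_params(ag_max = ag_max), frequency = frequency,
                    count = ceiling(300000 * frequency / 1000),
                    amplitude = 4.5, width = width, onset = 20000,
                    t_end = 20000 + 300000 + 1000 / frequency,
                    init = qss_for(ag_max), sample_by = 1, fine_window = 0)
  })
}

calibrated_width <- function() {
  cached("width", as.numeric(calibrate_pulse_width()))
}
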