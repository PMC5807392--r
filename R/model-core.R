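#' Single-cell state
#'
#' Bundle the five dynamical variables of one model M-cell: membrane
#' potential `v` (mV), potassium gating variable `n`, intracellular calcium
#' concentration `Ca`, synaptic activation fraction `s`, and the
#' activity-dependent adaptation variable `E_net`.
#'
#' @param v membrane potential (mV).
#' @param n potassium-gate open fraction, in \[0, 1\].
#' @param Ca intracellular calcium concentration (model units, >= 0).
#' @param s synaptic activation fraction, in \[0, 1\].
#' @param E_net activity-dependent net excitation (> 0).
#' @return A named numeric vector of class `cell_state`.
#' @examples
#' cell_state(v = -34.32, n = 0.00427, Ca = 3.05, s = 2e-4, E_net = 0.964)
#' @export
cell_state <- function(v, n, Ca, s, E_net) {
  x <- c(v = v, n = n, Ca = Ca, s = s, E_net = E_net)
  if (!all(is.finite(x))) stop("cell state must be finite")
  if (n < 0 || n > 1) stop("n must lie in [0, 1]")
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (Ca < 0) stop("Ca must be >= 0")
  if (E_net <= 0) stop("E_net must be > 0")
  structure(x, class = "cell_state")
}

#' Two-cell circuit state
#'
#' The coupled circuit holds exactly two cells.  Stimulus routing is fixed:
#' cell 1 receives the depolarizing pulse train, cell 2 receives no direct
#' stimulus; each cell receives synaptic input gated by the *other* cell's
#' synaptic variable.
#'
#' @param cell1,cell2 `cell_state` objects (cell 2 defaults to a copy of
#'   cell 1, the symmetric rest configuration).
#' @return A named numeric vector of length 10 of class `circuit_state`,
#'   ordered `v1, n1, Ca1, s1, E_net1, v2, n2, Ca2, s2, E_net2`.
#' @examples
#' cs <- circuit_state(cell_state(-30, 0.01, 3, 1e-4, 1))
#' cs["v1"]
#' @export
circuit_state <- function(cell1, cell2 = cell1) {
  stopifnot(inherits(cell1, "cell_state"), inherits(cell2, "cell_state"))
  x <- c(unclass(cell1), unclass(cell2))
  names(x) <- c("v1", "n1", "Ca1", "s1", "E_net1",
                "v2", "n2", "Ca2", "s2", "E_net2")
  structure(x, class = "circuit_state")
}

state_names <- c("v1", "n1", "Ca1", "s1", "E_net1",
                 "v2", "n2", "Ca2", "s2", "E_net2")

as_state_vector <- function(state) {
  x <- unclass(state)
  if (is.null(names(x))) {
    if (length(x) != 10) stop("circuit state must have 10 components")
    names(x) <- state_names
  } else {
    if (!all(state_names %in% names(x))) {
      stop("circuit state is missing components: ",
           paste(setdiff(state_names, names(x)), collapse = ", "))
    }
    x <- x[state_names]
  }
  if (!all(is.finite(x))) stop("circuit state must be finite")
  x
}

#' Voltage-dependent activation curves
#'
#' Evaluate the steady-state gating curves and the potassium-gate time
#' constant at a membrane potential: the instantaneous calcium-channel
#' activation `m_inf(v) = 0.5 (1 + tanh((v - v1)/v2))`, the potassium-gate
#' target `n_inf(v) = 0.5 (1 + tanh((v - v3)/v4))` with time constant
#' `tau_n(v) = 1 / cosh((v - v3)/(2 v4))`, and the synaptic activation
#' target `s_inf(v) = 1 / (1 + exp(-(v - theta_s)/sigma_s))`.
#'
#' @param v membrane potential (mV); vectorized.
#' @param params an [mcell_params()] object.
#' @return A list with numeric components `m_inf`, `n_inf`, `tau_n`,
#'   `s_inf`, each the length of `v`.
#' @examples
#' activation_curves(-1.2, mcell_params())$m_inf  # 0.5 at the half-activation
#' @export
activation_curves <- function(v, params) {
  stopifnot(inherits(params, "mcell_params"))
  list(
    m_inf = 0.5 * (1 + tanh((v - params$v1) / params$v2)),
    n_inf = 0.5 * (1 + tanh((v - params$v3) / params$v4)),
    tau_n = 1 / cosh((v - params$v3) / (2 * params$v4)),
    s_inf = 1 / (1 + exp(-(v - params$theta_s) / params$sigma_s))
  )
}

#' Membrane currents of one cell
#'
#' Evaluate the four intrinsic ionic currents and the cross-cell synaptic
#' current at a given cell state.  Sign convention follows the current
#' balance equation `C dv/dt = -I_Ca - I_K - I_L - I_KCa - I_syn + I_app`:
#' positive values are outward.  The synaptic current is gated by the
#' *other* cell's synaptic variable `other_s`.
#'
#' @param state a `cell_state` (or named vector with `v`, `n`, `Ca`).
#' @param other_s synaptic activation fraction of the other M-cell.
#' @param params an [mcell_params()] object.
#' @return A named list `I_Ca`, `I_K`, `I_KCa`, `I_L`, `I_syn`.
#' @examples
#' st <- cell_state(v = -84, n = 0.1, Ca = 5, s = 0, E_net = 1)
#' membrane_currents(st, other_s = 0, mcell_params())$I_K  # zero driving force
#' @export
membrane_currents <- function(state, other_s, params) {
  stopifnot(inherits(params, "mcell_params"))
  v <- state[["v"]]; n <- state[["n"]]; Ca <- max(state[["Ca"]], 0)
  m_inf <- 0.5 * (1 + tanh((v - params$v1) / params$v2))
  list(
    I_Ca  = params$g_Ca * m_inf * (v - params$v_Ca),
    I_K   = params$g_K * n * (v - params$v_K),
    I_KCa = params$g_KCa * (Ca / (Ca + params$k1)) * (v - params$v_K),
    I_L   = params$g_L * (v - params$v_L),
    I_syn = params$g_syn * (v - params$v_syn) * other_s
  )
}

#' Calcium-regulated target of the adaptation variable
#'
#' The slow adaptation variable `E_net` relaxes (with time constant `rho`)
#' toward `ag_max / (Ca + k2)`: intracellular calcium reciprocally
#' modulates the maximal net excitation of the cell.  The target is
#' strictly decreasing in `Ca` and equals `ag_max / k2` at `Ca = 0`.
#'
#' @param Ca calcium concentration (>= 0); vectorized.
#' @param params an [mcell_params()] object.
#' @return Numeric target value(s) of `E_net`.
#' @examples
#' net_excitation_target(0, mcell_params(ag_max = 40))  # 40/40 = 1
#' @export
net_excitation_target <- function(Ca, params) {
  stopifnot(inherits(params, "mcell_params"))
  if (any(Ca < 0)) stop("Ca must be >= 0")
  params$ag_max / (Ca + params$k2)
}

#' Vector field of the coupled two-cell circuit
#'
#' Time derivatives of all ten state variables under instantaneous drive
#' currents `drive1` (cell 1) and `drive2` (cell 2).  The applied current of
#' cell i is `I_app = I0 + drive_i + w_M * E_net_i`; the calcium balance is
#' `dCa/dt = eps * (-mu * I_Ca - k_Ca * Ca)`; the adaptation variable
#' relaxes toward [net_excitation_target()] with time constant `rho`.
#'
#' This pure-R evaluation is the reference definition of the model; the
#' compiled integrator implements the same equations and is checked against
#' it in the test-suite.
#'
#' @param state a `circuit_state` (or named 10-vector).
#' @param params an [mcell_params()] object.
#' @param drive1,drive2 instantaneous pulse currents to cells 1 and 2
#'   (0 when off-pulse).
#' @return Named numeric vector of the ten time derivatives (per ms).
#' @examples
#' cs <- circuit_state(cell_state(-34.32, 0.00427, 3.05, 2e-4, 0.964))
#' circuit_derivatives(cs, mcell_params(ag_max = 41.5), 0, 0)
#' @export
circuit_derivatives <- function(state, params, drive1 = 0, drive2 = 0) {
  stopifnot(inherits(params, "mcell_params"))
  y <- as_state_vector(state)
  if (y[["Ca1"]] < -1e-9 || y[["Ca2"]] < -1e-9) {
    stop("invalid state: negative calcium concentration")
  }
  one_cell <- function(v, n, Ca, s, E, other_s, drive) {
    Ca <- max(Ca, 0)
    ac <- activation_curves(v, params)
    cur <- membrane_currents(c(v = v, n = n, Ca = Ca), other_s, params)
    I_app <- params$I0 + drive + params$w_M * E
    c(
      dv = (-cur$I_Ca - cur$I_K - cur$I_L - cur$I_KCa - cur$I_syn + I_app) /
        params$C,
      dn = params$phi * (ac$n_inf - n) / ac$tau_n,
      dCa = params$eps * (-params$mu * cur$I_Ca - params$k_Ca * Ca),
      ds = params$alpha * ac$s_inf * (1 - s) - params$beta * s,
      dE = (net_excitation_target(Ca, params) - E) / params$rho
    )
  }
  d1 <- one_cell(y[["v1"]], y[["n1"]], y[["Ca1"]], y[["s1"]], y[["E_net1"]],
                 other_s = y[["s2"]], drive = drive1)
  d2 <- one_cell(y[["v2"]], y[["n2"]], y[["Ca2"]], y[["s2"]], y[["E_net2"]],
                 other_s = y[["s1"]], drive = drive2)
  setNames(c(d1, d2), state_names)
}
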