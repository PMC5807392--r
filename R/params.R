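#' Model parameters for the M-cell circuit
#'
#' Construct the full parameter set of the two-cell M-cell circuit model.
#' Defaults are the reference values for the modified Morris--Lecar
#' M-cell with calcium-dependent potassium current and calcium-regulated
#' adaptation; any subset can be overridden by name.
#'
#' Units: voltages in mV, time in ms, capacitance and conductances in the
#' model's dimensionless units (capacitance 1 means dv/dt is in mV/ms).
#' `rho` is the relaxation time constant of the adaptation variable `E_net`
#' in ms, so the default 8400 gives a ~8.4 s adaptation time scale.
#'
#' `ag_max`, the maximal net excitation, is the social-phenotype control
#' parameter: 41.5 (dominant-like), 42.2 (communal-like), 43.5
#' (subordinate-like).  The default is the communal-like value.
#'
#' `s2` is carried along as an inert constant from the reference parameter
#' table; it enters no equation and is exposed only so that configurations
#' round-trip losslessly.
#'
#' @param ag_max maximal net excitation (phenotype control parameter).
#' @param ... named overrides of any other parameter; see Details.
#' @return An object of class `mcell_params`: a named list of numeric
#'   parameters.
#' @examples
#' p <- mcell_params(ag_max = 41.5)
#' p$g_Ca
#' @export
mcell_params <- function(ag_max = 42.2, ...) {
  p <- list(
    g_Ca = 4, g_KCa = 0.25, g_K = 8, g_L = 2,
    eps = 0.00033,
    v_Ca = 120, v_K = -84, v_L = -60,
    k1 = 10, k2 = 40,
    theta_s = 0,
    v1 = -1.2, v2 = 18, v3 = 12, v4 = 17,
    k_Ca = 1, mu = 0.2, C = 1, phi = 0.23,
    alpha = 10, beta = 0.08,
    g_syn = 0.5, v_syn = -50,
    s2 = 0.029,        # inert constant from the reference parameter table
    sigma_s = 4,
    I0 = 40.5, w_M = 0.5,
    rho = 8400,
    ag_max = ag_max
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "mcell_params")
}

#' @export
print.mcell_params <- function(x, ...) {
  cat("M-cell circuit parameters (ag_max =", x$ag_max, ")\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "))
  }
  pos <- c("C", "eps", "rho", "k1", "k2", "k_Ca", "alpha", "beta", "phi",
           "sigma_s", "ag_max")
  low <- vapply(pos, function(nm) p[[nm]] <= 0, logical(1))
  if (any(low)) {
    stop("parameter(s) must be strictly positive: ",
         paste(pos[low], collapse = ", "))
  }
  nn <- c("g_Ca", "g_KCa", "g_K", "g_L", "g_syn")
  neg <- vapply(nn, function(nm) p[[nm]] < 0, logical(1))
  if (any(neg)) {
    stop("conductance(s) must be nonnegative: ", paste(nn[neg], collapse = ", "))
  }
  invisible(p)
}

#' Phenotype-labelled parameter sets
#'
#' Convenience constructor mapping a social-phenotype label to its
#' `ag_max` value: dominant-like 41.5, communal-like 42.2,
#' subordinate-like 43.5.
#'
#' @param phenotype one of `"dominant"`, `"communal"`, `"subordinate"`.
#' @param ... further overrides passed to [mcell_params()].
#' @return An `mcell_params` object.
#' @examples
#' phenotype_params("subordinate")$ag_max
#' @export
phenotype_params <- function(phenotype = c("communal", "dominant",
                                           "subordinate"), ...) {
  phenotype <- match.arg(phenotype)
  ag <- c(dominant = 41.5, communal = 42.2, subordinate = 43.5)[[phenotype]]
  mcell_params(ag_max = ag, ...)
}
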