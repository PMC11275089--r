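#' Hodgkin-Huxley membrane parameters
#'
#' Constructs and validates the parameter set of a single membrane
#' compartment. Defaults are the squid-axon constants in the modern (rest
#' near -65 mV) convention, with a membrane capacitance of 0.5 uF/cm2.
#'
#' @param Cm Membrane capacitance, uF/cm2. Must be > 0.
#' @param gNa Peak sodium conductance, mS/cm2.
#' @param gK Peak potassium conductance, mS/cm2.
#' @param gL Leak conductance, mS/cm2.
#' @param ENa Sodium reversal potential, mV.
#' @param EK Potassium reversal potential, mV.
#' @param EL Leak reversal potential, mV.
#'
#' @return An object of class `hh_parameters` (a named list).
#' @examples
#' p <- hh_parameters()
#' p$Cm
#' @export
hh_parameters <- function(Cm = 0.5, gNa = 120, gK = 36, gL = 0.3,
                          ENa = 50, EK = -77, EL = -54.387) {
  p <- list(Cm = Cm, gNa = gNa, gK = gK, gL = gL, ENa = ENa, EK = EK, EL = EL)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("hh_parameters: '", nm, "' must be a finite numeric scalar")
  }
  if (Cm <= 0) stop("hh_parameters: Cm must be > 0")
  if (gNa < 0 || gK < 0 || gL < 0)
    stop("hh_parameters: conductances must be >= 0")
  structure(p, class = "hh_parameters")
}

# Threshold below which the removable singularities of the alpha_m / alpha_n
# expressions are replaced by their analytic limits.
.hh_sing_eps <- 1e-7

#' Voltage-dependent gating rate constants
#'
#' Evaluates the six first-order rate constants (alpha/beta for the m, h and
#' n gates) at membrane potential `V`, using the standard squid-axon
#' expressions in the -65 mV resting convention. The removable singularities
#' of `alpha_m` (at V = -40 mV) and `alpha_n` (at V = -55 mV) are evaluated
#' by their analytic limits.
#'
#' @param V Membrane potential, mV. May be a vector; all values must be
#'   finite.
#'
#' @return A list of class `hh_rates` with components `alpha_m`, `beta_m`,
#'   `alpha_h`, `beta_h`, `alpha_n`, `beta_n` (ms^-1), each the same length
#'   as `V`.
#' @examples
#' rate_constants(-65)
#' rate_constants(-40)$alpha_m # analytic limit, exactly 1
#' @export
rate_constants <- function(V) {
  if (!is.numeric(V) || length(V) < 1L || any(!is.finite(V)))
    stop("rate_constants: V must be finite numeric")
  xm <- V + 40
  am <- ifelse(abs(xm) < .hh_sing_eps, 1.0, 0.1 * xm / (1 - exp(-xm / 10)))
  xn <- V + 55
  an <- ifelse(abs(xn) < .hh_sing_eps, 0.1, 0.01 * xn / (1 - exp(-xn / 10)))
  structure(list(
    alpha_m = am,
    beta_m  = 4 * exp(-(V + 65) / 18),
    alpha_h = 0.07 * exp(-(V + 65) / 20),
    beta_h  = 1 / (1 + exp(-(V + 35) / 10)),
    alpha_n = an,
    beta_n  = 0.125 * exp(-(V + 65) / 80)
  ), class = "hh_rates")
}

#' Gating state constructor
#'
#' @param m,h,n Gating probabilities in \[0, 1\].
#' @return A list of class `gating_state`.
#' @export
gating_state <- function(m, h, n) {
  g <- list(m = m, h = h, n = n)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("gating_state: '", nm, "' must lie in [0, 1]")
  }
  structure(g, class = "gating_state")
}

#' Steady-state gating variables at a clamped potential
#'
#' The fixed point x_inf = alpha / (alpha + beta) of each gating ODE at a
#' clamped membrane potential.
#'
#' @inheritParams rate_constants
#' @return A `gating_state` with components `m`, `h`, `n`.
#' @examples
#' steady_state_gating(-65)
#' @export
steady_state_gating <- function(V) {
  r <- rate_constants(V)
  gating_state(
    m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    n = r$alpha_n / (r$alpha_n + r$beta_n)
  )
}

#' Membrane state constructor
#'
#' @param V Membrane potential, mV (finite).
#' @param gating A `gating_state` (or list with `m`, `h`, `n`).
#' @return A list of class `membrane_state` with fields `V` and `gating`.
#' @export
membrane_state <- function(V, gating) {
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("membrane_state: V must be a finite scalar")
  if (!inherits(gating, "gating_state"))
    gating <- gating_state(gating$m, gating$h, gating$n)
  structure(list(V = V, gating = gating), class = "membrane_state")
}

#' Ionic current densities of one compartment
#'
#' Sodium, potassium and leak current densities at the given state:
#' `INa = gNa * m^3 * h * (V - ENa)`, `IK = gK * n^4 * (V - EK)`,
#' `IL = gL * (V - EL)`. Positive values are outward.
#'
#' @param state A `membrane_state`.
#' @param params An `hh_parameters` object.
#' @return Named numeric vector `c(INa, IK, IL)`, uA/cm2.
#' @examples
#' ionic_currents(init_resting_state(), hh_parameters())
#' @export
ionic_currents <- function(state, params = hh_parameters()) {
  stopifnot(inherits(state, "membrane_state"), inherits(params, "hh_parameters"))
  V <- state$V
  g <- state$gating
  c(
    INa = params$gNa * g$m^3 * g$h * (V - params$ENa),
    IK  = params$gK * g$n^4 * (V - params$EK),
    IL  = params$gL * (V - params$EL)
  )
}

#' Membrane-potential derivative with an added user capacitance
#'
#' The compartment membrane equation
#' `dV/dt = (I_ext - INa - IK - IL) / (Cm + C_user)`, where `C_user` is the
#' capacitance added in parallel to the membrane by the dielectric element
#' (zero when no element is present).
#'
#' @param state A `membrane_state`.
#' @param I_ext Applied current density, uA/cm2.
#' @param params An `hh_parameters` object.
#' @param C_user Added capacitance, uF/cm2, >= 0.
#' @return dV/dt in mV/ms.
#' @examples
#' membrane_derivative(init_resting_state(), I_ext = 6.5)
#' @export
membrane_derivative <- function(state, I_ext, params = hh_parameters(),
                                C_user = 0) {
  if (!is.numeric(C_user) || length(C_user) != 1L || !is.finite(C_user) ||
      C_user < 0)
    stop("membrane_derivative: C_user must be a finite scalar >= 0")
  Ctot <- params$Cm + C_user
  if (Ctot <= 0) stop("membrane_derivative: Cm + C_user must be > 0")
  ii <- ionic_currents(state, params)
  (I_ext - ii[["INa"]] - ii[["IK"]] - ii[["IL"]]) / Ctot
}

#' Resting state of a compartment
#'
#' Returns the conventional resting state: V = -65 mV with gating variables
#' at their steady-state values for that potential. The residual ionic
#' current at -65 mV is small (< 0.005 uA/cm2 with default parameters), so
#' an unstimulated simulation started here drifts by well under 1 mV.
#'
#' @param params An `hh_parameters` object (unused for the potential itself,
#'   accepted for interface symmetry and future parameterisations).
#' @return A `membrane_state`.
#' @export
init_resting_state <- function(params = hh_parameters()) {
  stopifnot(inherits(params, "hh_parameters"))
  membrane_state(V = -65, gating = steady_state_gating(-65))
}

# Euler update of gating variables toward their voltage-dependent targets;
# clamped to [0, 1] because forward Euler can overshoot at coarse dt.
.gating_step <- function(m, h, n, rates, dt) {
  list(
    m = pmin(pmax(m + dt * (rates$alpha_m * (1 - m) - rates$beta_m * m), 0), 1),
    h = pmin(pmax(h + dt * (rates$alpha_h * (1 - h) - rates$beta_h * h), 0), 1),
    n = pmin(pmax(n + dt * (rates$alpha_n * (1 - n) - rates$beta_n * n), 0), 1)
  )
}
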