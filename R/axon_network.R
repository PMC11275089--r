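#' Dielectric element configuration
#'
#' Describes the skin-applied dielectric device as a lumped circuit element
#' at one axon node: a capacitor in parallel with the membrane
#' (`C_user`), an impressed current generator opposing depolarization, or
#' both. The generator has two laws: `"proportional"` injects
#' `-kappa * max(V - V_rest, 0)` (kappa in mS/cm2, opposing depolarization
#' only), `"constant_opposition"` injects `-kappa * Is(t)` (kappa a
#' dimensionless fraction of the instantaneous stimulus).
#'
#' @param mode One of `"none"`, `"capacitive"`, `"current_generator"`,
#'   `"both"`.
#' @param C_user Added capacitance, uF/cm2, >= 0.
#' @param kappa Opposition gain (mS/cm2 for the proportional law, a
#'   dimensionless fraction for the constant-opposition law), >= 0.
#' @param generator_law `"proportional"` or `"constant_opposition"`.
#' @param epsilon_r Optional relative dielectric constant of the device
#'   material, in \[2, 5\]; metadata only (reported, never converted to a
#'   capacitance, as no device geometry is modelled).
#'
#' @return An object of class `dielectric_config`.
#' @examples
#' dielectric_config()                 # frozen defaults, mode "both"
#' dielectric_config(mode = "none")
#' @export
dielectric_config <- function(mode = c("both", "none", "capacitive",
                                       "current_generator"),
                              C_user = 0.5, kappa = 0.15,
                              generator_law = c("proportional",
                                                "constant_opposition"),
                              epsilon_r = NULL) {
  mode <- match.arg(mode)
  generator_law <- match.arg(generator_law)
  if (!is.numeric(C_user) || length(C_user) != 1L || !is.finite(C_user) ||
      C_user < 0)
    stop("dielectric_config: C_user must be a finite scalar >= 0")
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 0)
    stop("dielectric_config: kappa must be a finite scalar >= 0")
  if (!is.null(epsilon_r)) {
    if (!is.numeric(epsilon_r) || length(epsilon_r) != 1L ||
        epsilon_r < 2 || epsilon_r > 5)
      stop("dielectric_config: epsilon_r must lie in [2, 5]")
  }
  structure(list(mode = mode, C_user = C_user, kappa = kappa,
                 generator_law = generator_law, epsilon_r = epsilon_r),
            class = "dielectric_config")
}

#' Axon geometry and coupling configuration
#'
#' @param n_nodes Number of serial compartments; an odd integer of at
#'   least 3, so that a median node exists. Default 9.
#' @param g_axial Inter-node coupling conductance, mS/cm2.
#' @param dielectric_node 1-based index of the node carrying the dielectric
#'   element; defaults to the median node.
#' @param stimulus_node Default stimulus site: a 1-based node index, or
#'   `"all"` to apply the stimulus as a current density along the whole
#'   axon (the default; see the package vignette for the rationale).
#'
#' @return An object of class `axon_config`.
#' @examples
#' axon_config()          # 9 nodes, dielectric element at node 5
#' @export
axon_config <- function(n_nodes = 9, g_axial = 0.5, dielectric_node = NULL,
                        stimulus_node = "all") {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L ||
      n_nodes != round(n_nodes) || n_nodes < 3)
    stop("axon_config: n_nodes must be an integer >= 3")
  if (n_nodes %% 2 == 0)
    stop("axon_config: n_nodes must be odd (a median node must exist)")
  n_nodes <- as.integer(n_nodes)
  if (!is.numeric(g_axial) || g_axial < 0 || !is.finite(g_axial))
    stop("axon_config: g_axial must be a finite scalar >= 0")
  if (is.null(dielectric_node)) dielectric_node <- (n_nodes + 1L) %/% 2L
  if (!is.numeric(dielectric_node) || dielectric_node != round(dielectric_node) ||
      dielectric_node < 1 || dielectric_node > n_nodes)
    stop("axon_config: dielectric_node must be a node index in 1..",
         n_nodes)
  .check_stim_node(stimulus_node, n_nodes, "axon_config")
  structure(list(n_nodes = n_nodes, g_axial = g_axial,
                 dielectric_node = as.integer(dielectric_node),
                 stimulus_node = stimulus_node),
            class = "axon_config")
}

.check_stim_node <- function(node, n_nodes, where) {
  if (identical(node, "all")) return(invisible(node))
  if (!is.numeric(node) || length(node) != 1L || node != round(node) ||
      node < 1 || node > n_nodes)
    stop(where, ": stimulus node must be \"all\" or an index in 1..", n_nodes)
  invisible(node)
}

#' Stimulus protocol
#'
#' A constant-current step of density `amplitude` applied between `t_on`
#' and `t_off`, either at one node or along the whole axon.
#'
#' @param amplitude Current density Is, uA/cm2.
#' @param t_on,t_off Stimulus window, ms; `t_off` may be `Inf` (sustained
#'   for the whole run, the default).
#' @param node `"all"` (default), a 1-based node index, or `NULL` to defer
#'   to the axon configuration's `stimulus_node`.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(amplitude = 6.5)
#' @export
stimulus_protocol <- function(amplitude = 6.5, t_on = 0, t_off = Inf,
                              node = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude))
    stop("stimulus_protocol: amplitude must be a finite scalar")
  if (!is.numeric(t_on) || t_on < 0 || !is.numeric(t_off) || t_off <= t_on)
    stop("stimulus_protocol: need t_off > t_on >= 0")
  structure(list(amplitude = amplitude, t_on = t_on, t_off = t_off,
                 node = node),
            class = "stimulus_protocol")
}

#' Assemble a validated axon model
#'
#' Chains `n_nodes` Hodgkin-Huxley compartments with axial coupling and
#' places the dielectric element at the configured node. Every node is
#' initialized at rest. The dielectric node carries the added capacitance
#' `C_user` only when the mode includes a capacitive component.
#'
#' @param axon An `axon_config`.
#' @param membrane An `hh_parameters` object.
#' @param dielectric A `dielectric_config`.
#' @return An object of class `axon_model` with the per-node total
#'   capacitance vector `Ctot`, the resting state, and copies of all
#'   configurations.
#' @examples
#' model <- build_axon()
#' model$Ctot
#' @export
build_axon <- function(axon = axon_config(), membrane = hh_parameters(),
                       dielectric = dielectric_config()) {
  stopifnot(inherits(axon, "axon_config"), inherits(membrane, "hh_parameters"),
            inherits(dielectric, "dielectric_config"))
  n <- axon$n_nodes
  Ctot <- rep(membrane$Cm, n)
  if (dielectric$mode %in% c("capacitive", "both"))
    Ctot[axon$dielectric_node] <- membrane$Cm + dielectric$C_user
  rest <- init_resting_state(membrane)
  state <- list(
    V = rep(rest$V, n),
    m = rep(rest$gating$m, n),
    h = rep(rest$gating$h, n),
    n = rep(rest$gating$n, n)
  )
  structure(list(axon = axon, membrane = membrane, dielectric = dielectric,
                 Ctot = Ctot, v_rest = rest$V, init_state = state),
            class = "axon_model")
}

#' Impressed current of the dielectric element
#'
#' The current density injected by the device's generator component at the
#' dielectric node. Modes without a generator contribute zero. The
#' proportional law opposes depolarization only:
#' `-kappa * max(V_node - V_rest, 0)`; the constant-opposition law injects
#' `-kappa * Is_now` regardless of the local potential.
#'
#' @param V_node Potential at the dielectric node, mV.
#' @param V_rest Resting potential, mV.
#' @param Is_now Instantaneous stimulus current density, uA/cm2.
#' @param cfg A `dielectric_config`.
#' @return Current density, uA/cm2 (<= 0 for kappa >= 0).
#' @examples
#' dielectric_current(-55, -65, 6.5, dielectric_config(kappa = 0.2))
#' @export
dielectric_current <- function(V_node, V_rest, Is_now, cfg) {
  stopifnot(inherits(cfg, "dielectric_config"))
  if (!(cfg$mode %in% c("current_generator", "both"))) return(0)
  if (cfg$generator_law == "proportional") {
    -cfg$kappa * max(V_node - V_rest, 0)
  } else {
    -cfg$kappa * Is_now
  }
}

# Per-node stimulus vector at time t (ms).
.stimulus_vector <- function(stim, axon, t) {
  n <- axon$n_nodes
  on <- (t >= stim$t_on) && (t < stim$t_off)
  out <- numeric(n)
  if (!on) return(out)
  node <- if (is.null(stim$node)) axon$stimulus_node else stim$node
  if (identical(node, "all")) out[] <- stim$amplitude else out[node] <- stim$amplitude
  out
}

#' Advance the network state by one forward-Euler step
#'
#' Reference single-step update of the whole axon: each node receives its
#' stimulus, axial coupling `g_axial * (V_prev - V) + g_axial * (V_next - V)`
#' with sealed (reflecting) ends, and the dielectric generator current at
#' the dielectric node; gating variables follow their kinetic equations and
#' are clamped to \[0, 1\] after the step. `simulate_axon()` runs the same
#' update in compiled code.
#'
#' @param state List with numeric vectors `V`, `m`, `h`, `n` (length
#'   `n_nodes`).
#' @param t Current time, ms (used to gate the stimulus window).
#' @param model An `axon_model`.
#' @param stim A `stimulus_protocol`.
#' @param dt Time step, ms, > 0.
#' @return The updated state list.
#' @examples
#' model <- build_axon()
#' st <- step_network(model$init_state, 0, model, stimulus_protocol(), 0.01)
#' @export
step_network <- function(state, t, model, stim, dt) {
  stopifnot(inherits(model, "axon_model"), inherits(stim, "stimulus_protocol"))
  if (!is.numeric(dt) || dt <= 0) stop("step_network: dt must be > 0")
  ax <- model$axon
  p <- model$membrane
  n <- ax$n_nodes
  V <- state$V
  r <- rate_constants(V)
  INa <- p$gNa * state$m^3 * state$h * (V - p$ENa)
  IK <- p$gK * state$n^4 * (V - p$EK)
  IL <- p$gL * (V - p$EL)
  Iax <- numeric(n)
  if (n > 1) {
    Iax[1] <- ax$g_axial * (V[2] - V[1])
    Iax[n] <- ax$g_axial * (V[n - 1] - V[n])
    if (n > 2) {
      i <- 2:(n - 1)
      Iax[i] <- ax$g_axial * (V[i - 1] - V[i]) + ax$g_axial * (V[i + 1] - V[i])
    }
  }
  Ist <- .stimulus_vector(stim, ax, t)
  Is_now <- if ((t >= stim$t_on) && (t < stim$t_off)) stim$amplitude else 0
  Idl <- numeric(n)
  Idl[ax$dielectric_node] <- dielectric_current(V[ax$dielectric_node],
                                                model$v_rest, Is_now,
                                                model$dielectric)
  Vnew <- V + dt * (Ist + Iax + Idl - INa - IK - IL) / model$Ctot
  if (any(!is.finite(Vnew)))
    stop("step_network: non-finite membrane potential after update at t = ", t)
  g <- .gating_step(state$m, state$h, state$n, r, dt)
  list(V = Vnew, m = g$m, h = g$h, n = g$n)
}

#' Simulate the axon
#'
#' Integrates the full multi-compartment system with forward Euler at fixed
#' step `dt`, recording the membrane potential of every node at every step.
#' Deterministic: identical configurations give bit-identical traces.
#'
#' @param model An `axon_model` from [build_axon()].
#' @param stim A `stimulus_protocol`.
#' @param duration Total simulated time, ms.
#' @param dt Time step, ms.
#' @return An object of class `simulation_trace`: list with `dt`, `times`
#'   (ms, length T+1 including t = 0), `V` (n_nodes x (T+1) matrix, mV),
#'   `v_rest`, and `configs` (copies of all input configurations).
#' @examples
#' model <- build_axon(dielectric = dielectric_config(mode = "none"))
#' tr <- simulate_axon(model, stimulus_protocol(6.5), duration = 50)
#' dim(tr$V)
#' @export
simulate_axon <- function(model, stim = stimulus_protocol(),
                          duration = 500, dt = 0.01) {
  stopifnot(inherits(model, "axon_model"), inherits(stim, "stimulus_protocol"))
  if (!is.numeric(duration) || duration <= 0)
    stop("simulate_axon: duration must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("simulate_axon: dt must be > 0")
  ax <- model$axon
  node <- if (is.null(stim$node)) ax$stimulus_node else stim$node
  .check_stim_node(node, ax$n_nodes, "simulate_axon")
  stim_all <- identical(node, "all")
  n_steps <- as.integer(round(duration / dt))
  st <- model$init_state
  diel <- model$dielectric
  use_gen <- diel$mode %in% c("current_generator", "both")
  res <- cpp_simulate_axon(
    V0 = st$V, m0 = st$m, h0 = st$h, n0 = st$n,
    gNa = model$membrane$gNa, gK = model$membrane$gK, gL = model$membrane$gL,
    ENa = model$membrane$ENa, EK = model$membrane$EK, EL = model$membrane$EL,
    Ctot = model$Ctot, g_axial = ax$g_axial,
    stim_amplitude = stim$amplitude, stim_t_on = stim$t_on,
    stim_t_off = stim$t_off,
    stim_all = stim_all, stim_node = if (stim_all) 1L else as.integer(node),
    use_generator = use_gen,
    proportional = identical(diel$generator_law, "proportional"),
    kappa = diel$kappa, dielectric_node = ax$dielectric_node,
    v_rest = model$v_rest, dt = dt, n_steps = n_steps
  )
  structure(list(
    dt = dt,
    times = seq(0, by = dt, length.out = n_steps + 1L),
    V = res$V,
    v_rest = model$v_rest,
    final_gating = list(m = res$m, h = res$h, n = res$n),
    gating_range = res$gating_range,
    configs = list(axon = ax, membrane = model$membrane, dielectric = diel,
                   stimulus = stim, duration = duration, dt = dt)
  ), class = "simulation_trace")
}

#' Write / read a voltage trace as CSV
#'
#' The CSV has a header `time_ms, v_node_1, ..., v_node_N` and one row per
#' recorded time point.
#'
#' @param trace A `simulation_trace`.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a list with `times`, `V` (node x time matrix) and `dt`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "simulation_trace"))
  df <- data.frame(time_ms = trace$times, t(trace$V))
  names(df) <- c("time_ms", paste0("v_node_", seq_len(nrow(trace$V))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, check.names = TRUE)
  if (names(df)[1] != "time_ms" ||
      !all(grepl("^v_node_[0-9]+$", names(df)[-1])))
    stop("read_trace_csv: unexpected header in ", path)
  times <- df$time_ms
  dt <- if (length(times) > 1) times[2] - times[1] else NA_real_
  list(times = times, V = t(as.matrix(df[, -1, drop = FALSE])), dt = dt)
}
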