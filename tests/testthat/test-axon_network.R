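test_that("configuration constructors reject invalid geometry", {
  expect_error(axon_config(n_nodes = 8), "odd")
  expect_error(axon_config(n_nodes = 2), "3")
  expect_error(axon_config(n_nodes = 3, dielectric_node = 4), "node index")
  expect_error(axon_config(stimulus_node = 12), "all")
  expect_error(dielectric_config(C_user = -1), "C_user")
  expect_error(dielectric_config(kappa = -0.1), "kappa")
  expect_error(dielectric_config(epsilon_r = 1.5), "epsilon_r")
  expect_error(stimulus_protocol(t_on = 5, t_off = 5), "t_off")
  ok <- dielectric_config(epsilon_r = 3.2)
  expect_equal(ok$epsilon_r, 3.2)
})

test_that("default axon places the dielectric element at the median node", {
  model <- build_axon()
  expect_equal(model$axon$n_nodes, 9L)
  expect_equal(model$axon$dielectric_node, 5L)
  # C_user adds to the membrane capacitance only at the dielectric node
  expect_equal(model$Ctot[5], 0.5 + 0.5)
  expect_equal(model$Ctot[-5], rep(0.5, 8))
  none <- build_axon(dielectric = dielectric_config(mode = "none"))
  expect_equal(none$Ctot, rep(0.5, 9))
  gen_only <- build_axon(dielectric = dielectric_config(mode = "current_generator"))
  expect_equal(gen_only$Ctot, rep(0.5, 9))
})

test_that("dielectric generator current follows its stated laws", {
  cfg <- dielectric_config(mode = "both", kappa = 0.2)
  expect_equal(dielectric_current(-65, -65, 6.5, cfg), 0)
  expect_equal(dielectric_current(-55, -65, 6.5, cfg), -2.0)
  # hyperpolarized node: proportional law opposes depolarization only
  expect_equal(dielectric_current(-80, -65, 6.5, cfg), 0)
  cfg_none <- dielectric_config(mode = "none")
  expect_equal(dielectric_current(-20, -65, 6.5, cfg_none), 0)
  cfg_cap <- dielectric_config(mode = "capacitive", kappa = 5)
  expect_equal(dielectric_current(-20, -65, 6.5, cfg_cap), 0)
  cfg_const <- dielectric_config(mode = "current_generator", kappa = 0.4,
                                 generator_law = "constant_opposition")
  expect_equal(dielectric_current(-65, -65, 6.5, cfg_const), -2.6)
})

test_that("single network step respects locality and axial symmetry", {
  model <- build_axon(dielectric = dielectric_config(mode = "none"))
  st0 <- model$init_state
  # uniform potential, no stimulus: every node moves identically
  st1 <- step_network(st0, 0, model, stimulus_protocol(amplitude = 0), 0.01)
  expect_equal(diff(range(st1$V)), 0)
  # injection at node 1 changes only node 1 in the first step
  st2 <- step_network(st0, 0, model,
                      stimulus_protocol(amplitude = 6.5, node = 1), 0.01)
  expect_gt(abs(st2$V[1] - st0$V[1]), 0.1)
  expect_equal(st2$V[-1], st1$V[-1], tolerance = 1e-12)
  expect_error(step_network(st0, 0, model, stimulus_protocol(), dt = 0),
               "dt")
})

test_that("one step matches an independently hand-rolled few-node oracle", {
  set.seed(7)
  p <- hh_parameters()
  ax <- axon_config(n_nodes = 3, g_axial = 0.37, dielectric_node = 2)
  model <- build_axon(ax, p, dielectric_config(mode = "none"))
  for (rep in 1:20) {
    st <- list(V = runif(3, -80, 30), m = runif(3), h = runif(3),
               n = runif(3))
    stim <- stimulus_protocol(amplitude = 4.2, node = 1)
    got <- step_network(st, 0, model, stim, 0.01)
    want <- oracle_three_node_step(st$V, st$m, st$h, st$n, p, 0.37,
                                   model$Ctot, c(4.2, 0, 0), 0.01)
    expect_equal(got$V, want$V, tolerance = 1e-10)
    expect_equal(got$m, want$m, tolerance = 1e-10)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$n, want$n, tolerance = 1e-10)
  }
})

test_that("compiled integrator reproduces the R reference step exactly", {
  model <- build_axon() # mode "both": capacitor + generator at node 5
  stim <- stimulus_protocol(amplitude = 6.5)
  dt <- 0.01
  n_steps <- 400L
  tr <- simulate_axon(model, stim, duration = n_steps * dt, dt = dt)
  st <- model$init_state
  for (k in seq_len(n_steps))
    st <- step_network(st, (k - 1) * dt, model, stim, dt)
  expect_equal(tr$V[, n_steps + 1L], st$V, tolerance = 1e-12)
  expect_equal(tr$final_gating$m, st$m, tolerance = 1e-12)
  expect_equal(tr$final_gating$h, st$h, tolerance = 1e-12)
  expect_equal(tr$final_gating$n, st$n, tolerance = 1e-12)
})

test_that("simulation is deterministic and satisfies trace invariants", {
  model <- build_axon()
  tr1 <- simulate_axon(model, duration = 60)
  tr2 <- simulate_axon(model, duration = 60)
  expect_identical(tr1$V, tr2$V)
  expect_equal(nrow(tr1$V), 9)
  expect_true(all(is.finite(tr1$V)))
  expect_equal(unique(round(diff(tr1$times), 12)), 0.01)
  expect_true(all(tr1$gating_range >= 0 & tr1$gating_range <= 1))
})

test_that("unstimulated axon stays within 1 mV of rest", {
  model <- build_axon(dielectric = dielectric_config(mode = "none"))
  tr <- simulate_axon(model, stimulus_protocol(amplitude = 0),
                      duration = 200)
  expect_lt(max(abs(tr$V + 65)), 1)
  expect_equal(sum(summarize_trace(tr)$count), 0)
})

test_that("axial coupling conserves charge with sealed ends", {
  # with all channel conductances zero and no stimulus, the only current is
  # axial; back it out of one Euler step and check it sums to zero
  p <- hh_parameters(gNa = 0, gK = 0, gL = 0)
  model <- build_axon(axon_config(g_axial = 0.8), p,
                      dielectric_config(mode = "none"))
  set.seed(11)
  for (rep in 1:25) {
    st <- model$init_state
    st$V <- runif(9, -80, 40)
    dt <- 0.01
    nxt <- step_network(st, 0, model, stimulus_protocol(amplitude = 0), dt)
    i_axial <- (nxt$V - st$V) * model$Ctot / dt
    expect_lt(abs(sum(i_axial)), 1e-9)
  }
})

test_that("spike count responds monotonically to stimulus strength", {
  model <- build_axon(dielectric = dielectric_config(mode = "none"))
  counts <- vapply(c(0, 2, 6.5), function(a) {
    tr <- simulate_axon(model, stimulus_protocol(amplitude = a),
                        duration = 500)
    summarize_trace(tr)$count[5]
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gte(counts[3], 2)
})

test_that("added capacitance never increases the local peak depolarization", {
  peaks <- vapply(c(0, 0.5, 1.0), function(cu) {
    model <- build_axon(dielectric = dielectric_config(mode = "capacitive",
                                                       C_user = cu))
    tr <- simulate_axon(model, duration = 300)
    max(tr$V[5, ])
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("trace CSV round-trips and rejects malformed headers", {
  model <- build_axon()
  tr <- simulate_axon(model, duration = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$times, tr$times, tolerance = 1e-12)
  expect_equal(back$V, tr$V, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$dt, tr$dt, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,volts", "0,1"), bad)
  expect_error(read_trace_csv(bad), "header")
})

test_that("numerical blow-up raises an instability error naming the step", {
  model <- build_axon(axon_config(g_axial = 1e6),
                      dielectric = dielectric_config(mode = "none"))
  expect_error(
    simulate_axon(model, stimulus_protocol(amplitude = 1e8), duration = 500,
                  dt = 1),
    "instability.*step")
})
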