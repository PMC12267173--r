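# Small networks and short horizons keep these checks fast; the integrator
# scheme is identical at every scale.

test_that("zero coupling decouples the network: only the stimulated neuron moves", {
  g <- build_ring(10, directed = TRUE)
  res <- simulate_network(g, synapse_spec("RS", g = 0), stimulus_spec("sine"),
                          sim = sim_config(t_total = 100))
  expect_gt(length(res$spikes[[1]]), 0)
  for (i in 2:10) {
    expect_length(res$spikes[[i]], 0)
    expect_lt(max(abs(res$V[i, ] + 65)), 1)
  }
})

test_that("compiled and pure-R engines produce the same trajectories", {
  cases <- list(
    list(graph = build_ring(6, directed = TRUE), syn = synapse_spec("RS")),
    list(graph = build_ring(6, directed = TRUE), syn = synapse_spec("HS", g = 8)),
    list(graph = build_ring(6, directed = FALSE), syn = synapse_spec("ES")))
  for (cs in cases) {
    a <- simulate_network(cs$graph, cs$syn, stimulus_spec("sine"),
                          sim = sim_config(t_total = 30), engine = "cpp")
    b <- simulate_network(cs$graph, cs$syn, stimulus_spec("sine"),
                          sim = sim_config(t_total = 30), engine = "r")
    expect_lt(max(abs(a$V - b$V)), 1e-9)
  }
})

test_that("a single driven neuron matches an independent deSolve RK4 integration", {
  f <- function(t, y, parms) {
    am <- 0.1 * (y[1] + 40) / (1 - exp(-(y[1] + 40) / 10))
    bm <- 4 * exp(-(y[1] + 65) / 18)
    ah <- 0.07 * exp(-(y[1] + 65) / 20)
    bh <- 1 / (exp(-(y[1] + 35) / 10) + 1)
    an <- 0.01 * (y[1] + 55) / (1 - exp(-(y[1] + 55) / 10))
    bn <- 0.125 * exp(-(y[1] + 65) / 80)
    I <- 60 * sin(0.1 * pi * t) + 30
    dv <- 120 * y[2]^3 * y[3] * (50 - y[1]) + 36 * y[4]^4 * (-77 - y[1]) +
      0.3 * (-54.5 - y[1]) + I
    list(c(dv, am * (1 - y[2]) - bm * y[2], ah * (1 - y[3]) - bh * y[3],
           an * (1 - y[4]) - bn * y[4]))
  }
  ref <- deSolve::rk4(unlist(resting_state()), times = seq(0, 100, 0.01), f,
                      parms = NULL)
  g2 <- network_graph(2, data.frame(src = 1, dst = 2, directed = TRUE))
  mine <- simulate_network(g2, synapse_spec("HS", g = 0), stimulus_spec("sine"),
                           sim = sim_config(t_total = 100))
  expect_lt(max(abs(ref[, "v"] - mine$V[1, ])), 1e-8)
})

test_that("with tau = 0 the buffered chemical coupling equals instantaneous coupling", {
  for (kind in c("HS", "RS")) {
    g <- build_ring(5, directed = TRUE)
    arcs <- cbind(g$edges$src, g$edges$dst)
    gval <- if (kind == "HS") 8 else 0.1
    mine <- simulate_network(g, synapse_spec(kind, g = gval, tau = 0),
                             stimulus_spec("sine"),
                             sim = sim_config(t_total = 40))
    live <- oracle_sim_live(5, arcs, kind, g = gval, vthresh = -52, vrev = 0,
                            iext_fun = function(t) 60 * sin(0.1 * pi * t) + 30,
                            t_total = 40)
    expect_lt(max(abs(mine$V - live)), 1e-8)
  }
})

test_that("halving the step changes the trajectory by far less than 0.5 mV (RK4 convergence)", {
  # measured on smooth vector fields (single neuron, then gap-junction
  # coupling); the chemical Heaviside gate is discontinuous by design and
  # its switch times, not the solver order, bound the step sensitivity there
  g <- build_ring(4, directed = FALSE)
  a <- simulate_network(g, synapse_spec("ES"), stimulus_spec("sine"),
                        sim = sim_config(dt = 0.01, t_total = 60))
  b <- simulate_network(g, synapse_spec("ES"), stimulus_spec("sine"),
                        sim = sim_config(dt = 0.005, t_total = 60,
                                         record_stride = 2))
  expect_lt(max(abs(a$V - b$V)), 0.5)
  g1 <- network_graph(2, data.frame(src = 1, dst = 2, directed = TRUE))
  c1 <- simulate_network(g1, synapse_spec("HS", g = 0), stimulus_spec("sine"),
                         sim = sim_config(dt = 0.01, t_total = 100))
  c2 <- simulate_network(g1, synapse_spec("HS", g = 0), stimulus_spec("sine"),
                         sim = sim_config(dt = 0.005, t_total = 100,
                                          record_stride = 2))
  expect_lt(max(abs(c1$V[1, ] - c2$V[1, ])), 0.01)
})

test_that("gating variables stay inside [0,1] on every recorded sample", {
  g <- build_ring(8, directed = TRUE)
  res <- simulate_network(g, synapse_spec("RS"), stimulus_spec("sine"),
                          sim = sim_config(t_total = 120), engine = "r")
  fin <- res$final_state
  expect_true(all(fin$m >= 0 & fin$m <= 1))
  expect_true(all(fin$h >= 0 & fin$h <= 1))
  expect_true(all(fin$n >= 0 & fin$n <= 1))
  # spot-check along the way with the step-level API
  st <- lapply(resting_state(), rep, 8)
  names(st) <- c("v", "m", "h", "n")
  arcs <- cbind(build_ring(8)$edges$src, build_ring(8)$edges$dst)
  for (k in 1:500) {
    iext <- matrix(0, 8, 3)
    iext[1, ] <- sine_wave((k - 1) * 0.01 + c(0, 0.005, 0.01))
    st <- step_network(st, arcs, synapse_spec("RS"), numeric(8), iext,
                       dt = 0.01)
    expect_true(all(st$m >= 0 & st$m <= 1 & st$h >= 0 & st$h <= 1 &
                      st$n >= 0 & st$n <= 1))
  }
})

test_that("electrical edge currents cancel pairwise and keep a symmetric pair exactly synchronous", {
  # conservation at the current level, over simulated states
  g <- build_ring(6, directed = FALSE)
  res <- simulate_network(g, synapse_spec("ES"), stimulus_spec("sine"),
                          sim = sim_config(t_total = 50))
  v <- res$V[, seq(1, ncol(res$V), by = 500)]
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges$src[e]; j <- g$edges$dst[e]
    expect_identical(electrical_current(v[i, ], v[j, ], 0.1) +
                       electrical_current(v[j, ], v[i, ], 0.1),
                     rep(0, ncol(v)))
  }
  # two identically driven, symmetrically coupled neurons never diverge
  arcs <- rbind(c(1L, 2L), c(2L, 1L))
  st <- lapply(resting_state(), rep, 2)
  names(st) <- c("v", "m", "h", "n")
  worst <- 0
  for (k in 1:2000) {
    iext <- matrix(sine_wave((k - 1) * 0.01 + c(0, 0.005, 0.01)),
                   nrow = 2, ncol = 3, byrow = TRUE)
    st <- step_network(st, arcs, synapse_spec("ES"), numeric(2), iext, dt = 0.01)
    worst <- max(worst, abs(st$v[1] - st$v[2]))
  }
  expect_lt(worst, 1e-6)
})

test_that("one RK4 step is consistent with four Euler substeps at dt/4", {
  st <- lapply(resting_state(), rep, 3)
  names(st) <- c("v", "m", "h", "n")
  st$v <- c(-60, -65, -70)  # off-equilibrium
  arcs <- cbind(build_ring(3)$edges$src, build_ring(3)$edges$dst)
  sp <- synapse_spec("RS")
  iext <- matrix(0, 3, 3); iext[1, ] <- 40
  rk <- step_network(st, arcs, sp, numeric(3), iext, dt = 0.01)
  eu <- st
  for (i in 1:4) eu <- step_network(eu, arcs, sp, numeric(3), iext,
                                    dt = 0.0025, integrator = "euler")
  expect_lt(max(abs(rk$v - eu$v)), 5e-4)  # O(dt^2) agreement
  expect_false(isTRUE(all.equal(rk$v, st$v)))
})

test_that("a diverging run aborts naming the neuron and time", {
  g2 <- network_graph(2, data.frame(src = 1, dst = 2, directed = TRUE))
  huge <- stimulus_spec("sine", amplitude = 0, offset = 1e7)
  expect_error(
    simulate_network(g2, synapse_spec("HS", g = 0), huge,
                     sim = sim_config(t_total = 1)),
    "divergence at neuron 1")
})

test_that("graph/synapse compatibility is enforced", {
  expect_error(simulate_network(build_ring(5, directed = TRUE),
                                synapse_spec("ES")),
               "undirected")
  expect_error(simulate_network(build_ring(5, directed = FALSE),
                                synapse_spec("RS")),
               "directed")
})

test_that("the square-wave two-neuron validation drives full spikes through each synapse", {
  for (kind in c("HS", "ES", "RS")) {
    d <- demo_two_neuron(kind)
    expect_gt(length(d$spikes[[1]]), 0)
    expect_gt(length(d$spikes[[2]]), 0)
    expect_gt(max(d$V[1, ]), 0)
    expect_gt(max(d$V[2, ]), 0)
  }
})

test_that("first-spike times are non-decreasing with ring distance in a directed chain", {
  res <- simulate_network(build_ring(10, directed = TRUE), synapse_spec("RS"),
                          stimulus_spec("sine"), sim = sim_config(t_total = 150))
  fs <- vapply(res$spikes, function(s) if (length(s)) s[1] else NA_real_,
               numeric(1))
  fired <- which(!is.na(fs))
  expect_true(1 %in% fired)
  # the fired set is a contiguous stretch from neuron 1 outward
  expect_equal(fired, seq_len(length(fired)))
  expect_true(all(diff(fs[fired]) >= 0))
})

test_that("deterministic reruns are bit-identical; noise seeds distinguish runs", {
  g <- build_ring(5, directed = TRUE)
  a <- simulate_network(g, synapse_spec("RS"), stimulus_spec("sine"),
                        sim = sim_config(t_total = 20))
  b <- simulate_network(g, synapse_spec("RS"), stimulus_spec("sine"),
                        sim = sim_config(t_total = 20))
  expect_identical(a$V, b$V)
  n1 <- simulate_network(g, synapse_spec("RS"),
                         stimulus_spec("sine_plus_noise", seed = 1),
                         sim = sim_config(t_total = 20))
  n1b <- simulate_network(g, synapse_spec("RS"),
                          stimulus_spec("sine_plus_noise", seed = 1),
                          sim = sim_config(t_total = 20))
  n2 <- simulate_network(g, synapse_spec("RS"),
                         stimulus_spec("sine_plus_noise", seed = 2),
                         sim = sim_config(t_total = 20))
  expect_identical(n1$V, n1b$V)
  expect_false(identical(n1$V, n2$V))
})
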