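#' Integration settings
#'
#' Fixed-step integration settings for [simulate_network()].  The defaults
#' (classic RK4, dt = 0.01 ms, 300 ms total) are the study conditions for
#' the 100-neuron runs; the two-neuron validation uses `t_total = 100`.
#'
#' @param dt integration step, ms, > 0.
#' @param t_total total simulated time, ms, >= `dt`.
#' @param integrator `"rk4"` or `"euler"`.
#' @param record_stride record every `record_stride`-th step (1 = full
#'   resolution); must divide the step count.
#' @param seed RNG seed passed to seedless noise stimuli.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, t_total = 300,
                       integrator = c("rk4", "euler"),
                       record_stride = 1L, seed = NULL) {
  integrator <- match.arg(integrator)
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(t_total), length(t_total) == 1, t_total >= dt)
  record_stride <- as.integer(record_stride)
  stopifnot(record_stride >= 1)
  structure(list(dt = dt, t_total = t_total, integrator = integrator,
                 record_stride = record_stride, seed = seed),
            class = "sim_config")
}

# Network derivative field used by the pure-R engine and by step_network():
# HH ionic terms plus stimulus plus synaptic currents.  `gate_count[i]` is
# the number of open chemical afferents of neuron i (from delayed voltages);
# `arcs` is a 2-column matrix of directed arcs (undirected edges expanded).
network_derivs <- function(v, m, h, n, arcs, synapse, gate_count, i_ext, hh) {
  i_tot <- i_ext
  if (synapse$kind == "HS") {
    i_tot <- i_tot + synapse$g * gate_count
  } else if (synapse$kind == "RS") {
    drive <- if (synapse$rs_sign_literal) v - synapse$v_rev else synapse$v_rev - v
    i_tot <- i_tot + synapse$g * gate_count * drive
  } else if (nrow(arcs)) {
    ies <- synapse$g * (v[arcs[, 1]] - v[arcs[, 2]])
    acc <- rowsum(ies, group = arcs[, 2])
    i_tot[as.integer(rownames(acc))] <- i_tot[as.integer(rownames(acc))] + acc[, 1]
  }
  r <- rate_constants(v)
  list(dv = (hh$g_na * m^3 * h * (hh$e_na - v) + hh$g_k * n^4 * (hh$e_k - v) +
               hh$g_l * (hh$e_l - v) + i_tot) / hh$c_m,
       dm = r$alpha_m * (1 - m) - r$beta_m * m,
       dh = r$alpha_h * (1 - h) - r$beta_h * h,
       dn = r$alpha_n * (1 - n) - r$beta_n * n)
}

#' Advance the whole network by one step
#'
#' One fixed-step update (RK4 or forward Euler) of all neurons, with the
#' chemical gates and the noise part of the stimulus held constant over the
#' step.  This is the R reference for the compiled core and the building
#' block of `simulate_network(engine = "r")`.
#'
#' @param state list of numeric vectors `v`, `m`, `h`, `n` (one entry per
#'   neuron).
#' @param arcs 2-column integer matrix of directed arcs `(src, dst)`;
#'   undirected edges must already be expanded into both directions.
#' @param synapse a [synapse_spec()].
#' @param gate_count numeric vector: open chemical afferents per neuron,
#'   computed by the caller from the delayed presynaptic voltages (ignored
#'   for ES).
#' @param i_ext external current per neuron: a matrix with one row per
#'   neuron and 3 columns (values at `t`, `t + dt/2`, `t + dt`), or a single
#'   column reused for all substages.
#' @param hh an [hh_params()].
#' @param dt step, ms.
#' @param integrator `"rk4"` or `"euler"`.
#' @return The updated state list.
#' @export
step_network <- function(state, arcs, synapse, gate_count, i_ext,
                         hh = hh_params(), dt = 0.01,
                         integrator = c("rk4", "euler")) {
  integrator <- match.arg(integrator)
  nn <- length(state$v)
  if (is.null(dim(i_ext))) i_ext <- matrix(i_ext, nrow = nn, ncol = 3)
  if (ncol(i_ext) == 1) i_ext <- i_ext[, c(1, 1, 1), drop = FALSE]
  f <- function(v, m, h, n, sub)
    network_derivs(v, m, h, n, arcs, synapse, gate_count, i_ext[, sub], hh)
  if (integrator == "euler") {
    k1 <- f(state$v, state$m, state$h, state$n, 1)
    return(list(v = state$v + dt * k1$dv, m = state$m + dt * k1$dm,
                h = state$h + dt * k1$dh, n = state$n + dt * k1$dn))
  }
  k1 <- f(state$v, state$m, state$h, state$n, 1)
  k2 <- f(state$v + dt / 2 * k1$dv, state$m + dt / 2 * k1$dm,
          state$h + dt / 2 * k1$dh, state$n + dt / 2 * k1$dn, 2)
  k3 <- f(state$v + dt / 2 * k2$dv, state$m + dt / 2 * k2$dm,
          state$h + dt / 2 * k2$dh, state$n + dt / 2 * k2$dn, 2)
  k4 <- f(state$v + dt * k3$dv, state$m + dt * k3$dm,
          state$h + dt * k3$dh, state$n + dt * k3$dn, 3)
  list(v = state$v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv),
       m = state$m + dt / 6 * (k1$dm + 2 * k2$dm + 2 * k3$dm + k4$dm),
       h = state$h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh),
       n = state$n + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn))
}

# Pure-R mirror of the compiled core: same substep stimulus sampling, same
# held-per-step delayed gates and noise.  Used for small cross-check runs.
sim_engine_r <- function(state0, arcs, synapse, delay_steps, iext_half,
                         iext_step, stim_node, hh, dt, nsteps, integrator,
                         record_stride) {
  nn <- length(state0$v)
  chem <- synapse$kind %in% c("HS", "RS")
  hlen <- delay_steps + 1L
  hist <- matrix(state0$v, nrow = nn, ncol = hlen)
  head <- 1L
  nrec <- nsteps %/% record_stride + 1L
  vrec <- matrix(NA_real_, nn, nrec)
  vrec[, 1] <- state0$v
  rec <- 2L
  st <- state0
  gate <- numeric(nn)
  for (k in seq_len(nsteps) - 1L) {
    if (chem) {
      vdel <- hist[, (head %% hlen) + 1L]
      open <- vdel[arcs[, 1]] > synapse$v_thresh
      gate <- tabulate(arcs[open, 2], nbins = nn)
    }
    nz <- if (length(iext_step)) iext_step[k + 1L] else 0
    iext <- matrix(0, nn, 3)
    iext[stim_node, ] <- iext_half[2L * k + c(1L, 2L, 3L)] + nz
    st <- step_network(st, arcs, synapse, gate, iext, hh, dt, integrator)
    if (any(!is.finite(st$v)) || any(abs(st$v) > 150))
      stop(sprintf("divergence at neuron %d, t = %.4f ms",
                   which(!is.finite(st$v) | abs(st$v) > 150)[1], (k + 1) * dt),
           call. = FALSE)
    if (chem) {
      head <- (head %% hlen) + 1L
      hist[, head] <- st$v
    }
    if ((k + 1L) %% record_stride == 0 && rec <= nrec) {
      vrec[, rec] <- st$v
      rec <- rec + 1L
    }
  }
  list(V = vrec, final = st)
}

#' Simulate a coupled Hodgkin-Huxley network
#'
#' Integrates the delay-coupled network on a fixed time grid.  Every neuron
#' follows the HH membrane equation; the stimulated node additionally
#' receives the external stimulus, and every neuron receives the algebraic
#' sum of its afferent synaptic currents (delayed chemical gating via
#' internal ring buffers pre-filled with the initial potential).  All
#' neurons start at the common resting state `resting_state(v0)`.
#'
#' Graphs and synapses must be compatible: electrical synapses require
#' undirected edges, chemical synapses directed edges.
#'
#' @param graph a [network_graph()].
#' @param synapse a [synapse_spec()].
#' @param stimulus a [stimulus_spec()] applied to the stimulated node.
#' @param hh an [hh_params()].
#' @param sim a [sim_config()].
#' @param engine `"cpp"` (compiled core, default) or `"r"` (pure-R
#'   reference, for small cross-check runs).
#' @param v0 common initial membrane potential, mV.
#' @param spike_threshold,refractory spike detection settings passed to
#'   [detect_spikes()].
#' @return An object of class `hh_sim`: list with `time` (ms), `V` (matrix,
#'   neurons x samples, mV), `spikes` (list of spike-time vectors, ms),
#'   the echoed `graph`/`synapse`/`stimulus`/`hh`/`sim` and a `config_hash`.
#' @examples
#' \donttest{
#' g <- build_ring(10, directed = TRUE)
#' res <- simulate_network(g, synapse_spec("RS"), stimulus_spec("sine"),
#'                         sim = sim_config(t_total = 50))
#' res
#' }
#' @export
simulate_network <- function(graph, synapse, stimulus = stimulus_spec("none"),
                             hh = hh_params(), sim = sim_config(),
                             engine = c("cpp", "r"), v0 = -65,
                             spike_threshold = 0, refractory = 2) {
  engine <- match.arg(engine)
  stopifnot(inherits(graph, "network_graph"), inherits(synapse, "synapse_spec"),
            inherits(stimulus, "stimulus_spec"), inherits(hh, "hh_params"),
            inherits(sim, "sim_config"))
  directed <- graph$edges$directed
  if (synapse$kind == "ES" && any(directed))
    stop("configuration error: electrical synapses need undirected edges",
         call. = FALSE)
  if (synapse$kind != "ES" && any(!directed))
    stop("configuration error: chemical synapses need directed edges",
         call. = FALSE)

  nsteps <- as.integer(round(sim$t_total / sim$dt))
  if (nsteps < 1) stop("`t_total` must cover at least one step", call. = FALSE)
  if (nsteps %% sim$record_stride != 0)
    stop("`record_stride` must divide the number of steps", call. = FALSE)
  dt <- sim$dt
  delay_steps <- if (synapse$kind == "ES") 0L else as.integer(round(synapse$tau / dt))

  # Resolve the stimulus: noise sampling interval defaults to the
  # integration step, seed falls back to the sim seed.
  stimulus$noise_sample_dt <- stimulus$noise_sample_dt %||% dt
  stimulus$seed <- stimulus$seed %||% sim$seed

  times_half <- (0:(2L * nsteps)) * (dt / 2)
  if (stimulus$waveform == "sine_plus_noise") {
    det <- stimulus
    det$waveform <- "sine"
    iext_half <- render_stimulus(det, times_half)
    # one noise draw per noise_sample_dt, held constant over each step
    nsam <- floor(nsteps * dt / stimulus$noise_sample_dt + 1e-9) + 1
    draws <- noise_samples(nsam, stimulus)
    step_t <- (seq_len(nsteps) - 1L) * dt
    iext_step <- draws[pmin(floor(step_t / stimulus$noise_sample_dt + 1e-9) + 1, nsam)]
  } else {
    iext_half <- render_stimulus(stimulus, times_half)
    iext_step <- numeric(0)
  }

  g0 <- steady_state_gating(v0)
  state0 <- list(v = rep(v0, graph$n), m = rep(unname(g0["m"]), graph$n),
                 h = rep(unname(g0["h"]), graph$n), n = rep(unname(g0["n"]), graph$n))
  arcs <- graph_arcs(graph)
  kind_code <- match(synapse$kind, c("ES", "HS", "RS")) - 1L

  core <- if (engine == "cpp") {
    sim_core_cpp(state0$v, state0$m, state0$h, state0$n,
                 as.integer(arcs[, 1]), as.integer(arcs[, 2]),
                 kind_code, synapse$g, synapse$v_thresh, synapse$v_rev,
                 synapse$rs_sign_literal, delay_steps,
                 iext_half, iext_step, graph$stimulated_node,
                 unlist(hh[c("c_m", "g_na", "g_k", "g_l", "e_na", "e_k", "e_l")]),
                 dt, nsteps, sim$integrator == "rk4", sim$record_stride)
  } else {
    sim_engine_r(state0, arcs, synapse, delay_steps, iext_half, iext_step,
                 graph$stimulated_node, hh, dt, nsteps, sim$integrator,
                 sim$record_stride)
  }

  V <- core$V
  rownames(V) <- paste0("neuron_", seq_len(graph$n))
  time <- (0:(nsteps %/% sim$record_stride)) * (dt * sim$record_stride)
  rec_dt <- dt * sim$record_stride
  spikes <- lapply(seq_len(graph$n), function(i)
    detect_spikes(V[i, ], rec_dt, threshold = spike_threshold,
                  refractory = refractory))
  meta <- list(synapse = unclass(synapse), stimulus = unclass(stimulus),
               hh = unclass(hh), sim = unclass(sim), n = graph$n,
               edges = graph$edges, stim_node = graph$stimulated_node)
  structure(list(time = time, V = V, spikes = spikes, graph = graph,
                 synapse = synapse, stimulus = stimulus, hh = hh, sim = sim,
                 final_state = core$final, config_hash = config_hash(meta)),
            class = "hh_sim")
}

#' @export
print.hh_sim <- function(x, ...) {
  nsp <- vapply(x$spikes, length, integer(1))
  cat("<hh_sim> ", x$graph$n, " neurons, ", max(x$time), " ms (",
      x$synapse$kind, " coupling, ", x$stimulus$waveform, " stimulus)\n",
      sep = "")
  cat("  neurons spiking: ", sum(nsp > 0), "/", x$graph$n,
      "; total spikes: ", sum(nsp), "\n", sep = "")
  cat("  config ", x$config_hash, "\n", sep = "")
  invisible(x)
}

#' Two-neuron validation run
#'
#' The square-wave validation experiment: neuron 1 is driven by the 10
#' uA/cm^2, 20 ms-period square wave for 100 ms and is coupled to neuron 2
#' by a single synapse (directed for chemical kinds, undirected for
#' electrical).  With a working synapse both neurons produce full action
#' potentials.
#'
#' The network study's coupling strength (0.1) is kept for the ES and RS
#' demos.  For HS — whose current is the bare amplitude `g` — the default is
#' 10 uA/cm^2: a constant 0.1 uA/cm^2 is far below the HH firing threshold
#' current (about 6 uA/cm^2), so a demonstration of suprathreshold
#' transmission needs an amplitude above it.
#'
#' @param kind `"ES"`, `"HS"` or `"RS"`.
#' @param g coupling strength; `NULL` picks the defaults described above.
#' @param t_total duration, ms.
#' @param ... passed to [simulate_network()].
#' @return An `hh_sim` for the two neurons.
#' @export
demo_two_neuron <- function(kind = c("HS", "ES", "RS"), g = NULL,
                            t_total = 100, ...) {
  kind <- match.arg(kind)
  g <- g %||% if (kind == "HS") 10 else 0.1
  graph <- if (kind == "ES") {
    network_graph(2, data.frame(src = 1, dst = 2, directed = FALSE))
  } else {
    network_graph(2, data.frame(src = 1, dst = 2, directed = TRUE))
  }
  simulate_network(graph, synapse_spec(kind, g = g),
                   stimulus_spec("square"),
                   sim = sim_config(t_total = t_total), ...)
}
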