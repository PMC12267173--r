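#' Experiment configuration
#'
#' Full configuration of the comparative experiment grid: three synapse
#' models (ES, HS, RS) by two topologies (ring, hub-augmented NW
#' small-world) by two stimuli (noise-free sine, sine plus Gaussian white
#' noise), on a 100-neuron network simulated for 300 ms at dt = 0.01 ms
#' with only neuron 1 stimulated.  Every argument defaults to the study
#' condition, so `experiment_config()` with no arguments describes the
#' whole reference grid.
#'
#' Noise conditions are replicated over `noise_seeds` (10 fixed seeds by
#' default) and summarized by the mean over replicates.
#'
#' @param n_neurons network size.
#' @param synapses,topologies,stimuli condition axes (subsets of the
#'   defaults) — `topologies` from `"ring"`, `"nw"`; `stimuli` from
#'   `"sine"`, `"sine_noise"`.
#' @param hh an [hh_params()].
#' @param g,v_thresh,v_rev,tau,rs_sign_literal synapse settings shared by
#'   all three kinds (see [synapse_spec()]).
#' @param hub_k,hub_targets NW hub shortcut count and optional explicit
#'   target set (see [build_nw_hub()]).
#' @param amplitude,offset,omega sine stimulus settings.
#' @param noise_mean,noise_sd,noise_sample_dt noise settings (see
#'   [stimulus_spec()]).
#' @param dt,t_total,integrator,record_stride integration settings.
#' @param noise_seeds integer vector of noise replicate seeds.
#' @param pairs correlation pairs (see [default_pairs()]).
#' @param burn_in_ms initial window discarded before correlating.
#' @param reference_neuron latency reference.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_neurons = 100,
                              synapses = c("ES", "HS", "RS"),
                              topologies = c("ring", "nw"),
                              stimuli = c("sine", "sine_noise"),
                              hh = hh_params(),
                              g = 0.1, v_thresh = -52, v_rev = 0, tau = 1,
                              rs_sign_literal = FALSE,
                              hub_k = 24, hub_targets = NULL,
                              amplitude = 60, offset = 30, omega = 0.1 * pi,
                              noise_mean = 0, noise_sd = 20,
                              noise_sample_dt = NULL,
                              dt = 0.01, t_total = 300, integrator = "rk4",
                              record_stride = 1L,
                              noise_seeds = 101:110,
                              pairs = default_pairs(),
                              burn_in_ms = 0,
                              reference_neuron = 1) {
  synapses <- match.arg(synapses, several.ok = TRUE)
  topologies <- match.arg(topologies, several.ok = TRUE)
  stimuli <- match.arg(stimuli, several.ok = TRUE)
  stopifnot(inherits(hh, "hh_params"))
  if (!is.numeric(tau) || tau < 0)
    stop("constraint violation: `tau` must be >= 0", call. = FALSE)
  if (!is.numeric(g) || g < 0)
    stop("constraint violation: `g` must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("constraint violation: `noise_sd` must be >= 0", call. = FALSE)
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 2)
  if (any(unlist(pairs) < 1 | unlist(pairs) > n_neurons))
    stop("constraint violation: correlation pair outside 1..n_neurons",
         call. = FALSE)
  if (reference_neuron < 1 || reference_neuron > n_neurons)
    stop("constraint violation: `reference_neuron` outside 1..n_neurons",
         call. = FALSE)
  cfg <- list(n_neurons = n_neurons, synapses = synapses,
              topologies = topologies, stimuli = stimuli, hh = hh, g = g,
              v_thresh = v_thresh, v_rev = v_rev, tau = tau,
              rs_sign_literal = rs_sign_literal, hub_k = as.integer(hub_k),
              hub_targets = hub_targets, amplitude = amplitude,
              offset = offset, omega = omega, noise_mean = noise_mean,
              noise_sd = noise_sd, noise_sample_dt = noise_sample_dt,
              dt = dt, t_total = t_total, integrator = integrator,
              record_stride = as.integer(record_stride),
              noise_seeds = as.integer(noise_seeds), pairs = pairs,
              burn_in_ms = burn_in_ms,
              reference_neuron = as.integer(reference_neuron))
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config> ", x$n_neurons, " neurons, ",
      length(x$synapses) * length(x$topologies) * length(x$stimuli),
      " conditions (", paste(x$synapses, collapse = "/"), " x ",
      paste(x$topologies, collapse = "/"), " x ",
      paste(x$stimuli, collapse = "/"), ")\n", sep = "")
  cat("  g =", x$g, " tau =", x$tau, "ms  dt =", x$dt, "ms  T =",
      x$t_total, "ms\n")
  invisible(x)
}

config_keys <- function() names(formals(experiment_config))

#' Parse an experiment configuration file
#'
#' Reads a YAML key/value file into an [experiment_config()].  Every key is
#' optional — an empty file yields the full reference configuration — and
#' unknown keys are rejected by name.  HH membrane parameters go under a
#' nested `hh:` block (keys of [hh_params()]).
#'
#' A potassium conductance above 100 mS/cm^2 is accepted but triggers a
#' warning: such a shunt clamps the membrane near E_K and suppresses firing
#' altogether.
#'
#' @param path path to a YAML file.
#' @return An `experiment_config`.
#' @export
parse_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration file must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$hh)) {
    if (!is.list(raw$hh)) stop("`hh` must be a mapping", call. = FALSE)
    bad <- setdiff(names(raw$hh), names(formals(hh_params)))
    if (length(bad))
      stop("unknown hh parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    raw$hh <- do.call(hh_params, raw$hh)
    if (raw$hh$g_k > 100)
      warning("g_k = ", raw$hh$g_k,
              " mS/cm^2: a potassium shunt this strong holds the membrane ",
              "near E_K and suppresses firing", call. = FALSE)
  }
  do.call(experiment_config, raw)
}

grid_stimulus <- function(cfg, stimulus, seed = NULL) {
  stimulus_spec(if (stimulus == "sine") "sine" else "sine_plus_noise",
                amplitude = cfg$amplitude, offset = cfg$offset,
                omega = cfg$omega, noise_mean = cfg$noise_mean,
                noise_sd = cfg$noise_sd, seed = seed,
                noise_sample_dt = cfg$noise_sample_dt)
}

grid_graph <- function(cfg, synapse_kind, topology) {
  directed <- synapse_kind != "ES"
  if (topology == "ring")
    build_ring(cfg$n_neurons, directed = directed)
  else
    build_nw_hub(cfg$n_neurons, hub = 1, k = cfg$hub_k, directed = directed,
                 targets = cfg$hub_targets)
}

#' Run the full experiment grid
#'
#' Simulates every condition of the configuration (synapse x topology x
#' stimulus), replicating noise conditions over the configured seeds, and
#' computes per-run correlation tables and first-spike latencies.  A failing
#' condition is recorded with its error message without aborting the rest of
#' the grid.
#'
#' @param config an [experiment_config()].
#' @param engine integrator engine, as in [simulate_network()].
#' @param keep_traces logical; retain the full voltage matrices (memory!).
#' @param out_dir optional directory: per-run voltage traces are written as
#'   wide CSV (`t_ms`, `V_1` ... `V_n`) tagged with the config hash.
#' @param verbose logical; report condition progress via [message()].
#' @return An object of class `hh_grid`: list of per-run records (each with
#'   `synapse`, `topology`, `stimulus`, `seed`, `cor`, `latency`,
#'   `config_hash`, optionally `result`/`error`) plus the configuration.
#' @seealso [summarize_grid()]
#' @export
run_experiment_grid <- function(config = experiment_config(), engine = "cpp",
                                keep_traces = FALSE, out_dir = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- list()
  for (syn in config$synapses) {
    for (topo in config$topologies) {
      for (stim in config$stimuli) {
        seeds <- if (stim == "sine") NA_integer_ else config$noise_seeds
        for (seed in seeds) {
          label <- paste(syn, topo, stim,
                         if (!is.na(seed)) paste0("seed", seed) else "det",
                         sep = "_")
          if (verbose) message("running ", label)
          rec <- list(synapse = syn, topology = topo, stimulus = stim,
                      seed = if (is.na(seed)) NULL else seed, label = label)
          rec <- tryCatch({
            graph <- grid_graph(config, syn, topo)
            sp <- synapse_spec(syn, g = config$g, v_thresh = config$v_thresh,
                               tau = config$tau, v_rev = config$v_rev,
                               rs_sign_literal = config$rs_sign_literal)
            st <- grid_stimulus(config, stim,
                                seed = if (is.na(seed)) NULL else seed)
            res <- simulate_network(graph, sp, st, hh = config$hh,
                                    sim = sim_config(dt = config$dt,
                                                     t_total = config$t_total,
                                                     integrator = config$integrator,
                                                     record_stride = config$record_stride),
                                    engine = engine)
            rec$cor <- correlation_table(res, config$pairs, config$burn_in_ms)
            rec$latency <- tryCatch(
              first_spike_latency(res, config$reference_neuron),
              error = function(e) NULL)
            rec$config_hash <- res$config_hash
            if (!is.null(out_dir)) {
              f <- file.path(out_dir, paste0("traces_", label, ".csv"))
              write_traces_csv(res, f)
            }
            if (keep_traces) rec$result <- res
            rec
          }, error = function(e) {
            rec$error <- conditionMessage(e)
            rec
          })
          runs[[label]] <- rec
        }
      }
    }
  }
  structure(list(runs = runs, config = config), class = "hh_grid")
}

#' @export
print.hh_grid <- function(x, ...) {
  ok <- vapply(x$runs, function(r) is.null(r$error), logical(1))
  cat("<hh_grid> ", length(x$runs), " runs (", sum(!ok), " failed)\n", sep = "")
  invisible(x)
}

#' Write voltage traces as wide CSV
#'
#' Columns `t_ms`, `V_1` ... `V_n`; the first line is a comment naming the
#' config hash that produced the run.
#'
#' @param result an `hh_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(result, path) {
  stopifnot(inherits(result, "hh_sim"))
  df <- data.frame(t_ms = result$time, t(result$V))
  names(df) <- c("t_ms", paste0("V_", seq_len(result$graph$n)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", result$config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Summarize an experiment grid
#'
#' Assembles the per-synapse synchrony tables (one row per topology x
#' stimulus condition, one column per neuron pair) and a latency summary.
#' Noise conditions report the mean correlation over the replicate seeds;
#' cells whose correlation is undefined in every replicate stay `NA`, and
#' failed conditions are marked missing rather than fabricated.
#'
#' @param grid an `hh_grid` from [run_experiment_grid()].
#' @param probe_neurons neurons whose first-spike latency (relative to the
#'   configured reference) is tabulated; defaults to 25, 50 and 100 clipped
#'   to the network size.
#' @return A list with `correlation` (named list of data frames, one per
#'   synapse model) and `latency` (long data frame).
#' @export
summarize_grid <- function(grid, probe_neurons = NULL) {
  stopifnot(inherits(grid, "hh_grid"))
  cfg <- grid$config
  probe_neurons <- probe_neurons %||% unique(pmin(c(25L, 50L, 100L), cfg$n_neurons))
  plabs <- vapply(cfg$pairs, pair_label, character(1))
  conditions <- expand.grid(stimulus = cfg$stimuli, topology = cfg$topologies,
                            stringsAsFactors = FALSE)[, c("topology", "stimulus")]
  cor_tables <- list()
  lat_rows <- list()
  for (syn in cfg$synapses) {
    tab <- data.frame(condition = paste(conditions$topology,
                                        conditions$stimulus, sep = "_"))
    for (pl in plabs) tab[[pl]] <- NA_real_
    for (ci in seq_len(nrow(conditions))) {
      topo <- conditions$topology[ci]
      stim <- conditions$stimulus[ci]
      sel <- Filter(function(r) is.null(r$error) && r$synapse == syn &&
                      r$topology == topo && r$stimulus == stim, grid$runs)
      if (!length(sel)) next
      for (pl in plabs) {
        vals <- vapply(sel, function(r) r$cor$r[r$cor$pair == pl], numeric(1))
        tab[ci, pl] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      }
      for (nb in probe_neurons) {
        lats <- vapply(sel, function(r) {
          if (is.null(r$latency)) return(NA_real_)
          r$latency$latency_ms[r$latency$neuron == nb]
        }, numeric(1))
        lat_rows[[length(lat_rows) + 1]] <- data.frame(
          synapse = syn, topology = topo, stimulus = stim, neuron = nb,
          latency_ms = if (all(is.na(lats))) NA_real_ else mean(lats, na.rm = TRUE),
          n_missing = sum(is.na(lats)), n_runs = length(lats))
      }
    }
    cor_tables[[syn]] <- tab
  }
  list(correlation = cor_tables, latency = do.call(rbind, lat_rows))
}

#' Write grid summary tables as CSV
#'
#' One synchrony-table CSV per synapse model plus a latency CSV, each tagged
#' with the configuration hash in a leading comment line.
#'
#' @param grid an `hh_grid`.
#' @param dir output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_grid_outputs <- function(grid, dir) {
  stopifnot(inherits(grid, "hh_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  smry <- summarize_grid(grid)
  hash <- config_hash(unclass(grid$config))
  paths <- character(0)
  for (syn in names(smry$correlation)) {
    p <- file.path(dir, paste0("correlation_", syn, ".csv"))
    con <- file(p, "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    write.csv(smry$correlation[[syn]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "latency.csv")
  con <- file(p, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(smry$latency, con, row.names = FALSE)
  close(con)
  invisible(c(paths, p))
}
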