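# A desk-scale configuration: the full condition grid on a small network
# with a short horizon, so orchestration logic is exercised quickly.
small_config <- function(...) {
  experiment_config(n_neurons = 20, t_total = 40, hub_k = 4,
                    noise_seeds = c(101L, 102L),
                    pairs = list(c(1L, 5L), c(2L, 8L)), ...)
}

test_that("the default configuration is the full reference grid", {
  cfg <- experiment_config()
  expect_equal(cfg$n_neurons, 100L)
  expect_equal(cfg$t_total, 300)
  expect_equal(cfg$dt, 0.01)
  expect_equal(cfg$g, 0.1)
  expect_equal(cfg$v_thresh, -52)
  expect_equal(cfg$tau, 1)
  expect_equal(cfg$hub_k, 24L)
  expect_equal(cfg$noise_sd, 20)
  expect_equal(length(cfg$noise_seeds), 10L)
  expect_equal(length(cfg$synapses) * length(cfg$topologies) * length(cfg$stimuli), 12L)
  expect_equal(cfg$pairs, default_pairs())
})

test_that("an empty YAML file parses to the default configuration", {
  p <- tempfile(fileext = ".yml")
  on.exit(unlink(p))
  writeLines("", p)
  cfg <- parse_config(p)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$n_neurons, experiment_config()$n_neurons)
  expect_equal(cfg$hh, experiment_config()$hh)
})

test_that("config files override defaults, reject unknown keys and bad values", {
  p <- tempfile(fileext = ".yml")
  on.exit(unlink(p))
  writeLines(c("tau: 0.5", "n_neurons: 50", "hh:", "  g_k: 40"), p)
  cfg <- parse_config(p)
  expect_equal(cfg$tau, 0.5)
  expect_equal(cfg$n_neurons, 50L)
  expect_equal(cfg$hh$g_k, 40)

  writeLines("not_a_key: 1", p)
  expect_error(parse_config(p), "unknown configuration key")
  writeLines("tau: -1", p)
  expect_error(parse_config(p), "constraint violation")
  writeLines(c("hh:", "  g_k: 360"), p)
  expect_warning(cfg360 <- parse_config(p), "suppresses firing")
  expect_equal(cfg360$hh$g_k, 360)
})

test_that("the experiment grid covers all conditions, replicates noise seeds and persists tables", {
  cfg <- small_config()
  out <- tempfile()
  on.exit(unlink(out, recursive = TRUE))
  grid <- run_experiment_grid(cfg)
  # 6 deterministic runs + 6 noise conditions x 2 seeds
  expect_length(grid$runs, 18)
  expect_true(all(vapply(grid$runs, function(r) is.null(r$error), logical(1))))
  smry <- summarize_grid(grid)
  expect_named(smry$correlation, c("ES", "HS", "RS"))
  for (tab in smry$correlation) {
    expect_equal(nrow(tab), 4)
    expect_equal(names(tab), c("condition", "r_1_5", "r_2_8"))
    expect_true(all(is.na(unlist(tab[-1])) | abs(unlist(tab[-1])) <= 1))
  }
  paths <- write_grid_outputs(grid, out)
  expect_length(list.files(out, pattern = "^correlation_.*csv$"), 3)
  expect_true(file.exists(file.path(out, "latency.csv")))
  first <- readLines(file.path(out, "latency.csv"), n = 1)
  expect_match(first, "^# config_hash: [0-9a-f]+$")
  back <- read.csv(file.path(out, "correlation_RS.csv"), comment.char = "#")
  expect_equal(back$condition,
               c("ring_sine", "ring_sine_noise", "nw_sine", "nw_sine_noise"))
})

test_that("deterministic conditions are reproducible run-to-run", {
  cfg <- small_config(stimuli = "sine")
  g1 <- run_experiment_grid(cfg)
  g2 <- run_experiment_grid(cfg)
  for (lab in names(g1$runs))
    expect_equal(g1$runs[[lab]]$cor$r, g2$runs[[lab]]$cor$r, tolerance = 0)
})

test_that("a failing condition is recorded without aborting the grid", {
  cfg <- small_config(stimuli = "sine")
  # amplitude large enough to blow up the first neuron
  cfg$amplitude <- 1e7
  grid <- run_experiment_grid(cfg)
  expect_length(grid$runs, 6)
  errs <- vapply(grid$runs, function(r) !is.null(r$error), logical(1))
  expect_true(all(errs))
  expect_match(grid$runs[[1]]$error, "divergence")
  smry <- summarize_grid(grid)
  expect_true(all(is.na(unlist(smry$correlation$RS[-1]))))
})

test_that("voltage trace CSVs round-trip through the wide format", {
  res <- simulate_network(build_ring(4, directed = TRUE), synapse_spec("RS"),
                          stimulus_spec("sine"), sim = sim_config(t_total = 5))
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_traces_csv(res, p)
  expect_match(readLines(p, n = 1), res$config_hash)
  df <- read.csv(p, comment.char = "#")
  expect_equal(names(df), c("t_ms", paste0("V_", 1:4)))
  expect_equal(df$V_1, unname(res$V[1, ]), tolerance = 1e-6)
  expect_equal(df$t_ms, res$time, tolerance = 1e-9)
})
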