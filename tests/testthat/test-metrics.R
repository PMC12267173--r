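test_that("spike detection finds interpolated upward crossings with a refractory gap", {
  dt <- 0.1
  t <- seq(0, 50, by = dt)
  v <- rep(-65, length(t))
  bump <- function(v, at, width = 1) {
    v[abs(t - at) <= width] <- 30
    v
  }
  v2 <- bump(bump(v, 10), 30)
  sp <- detect_spikes(v2, dt)
  expect_length(sp, 2)
  expect_equal(sp, c(9, 29), tolerance = 0.2)

  expect_length(detect_spikes(rep(-65, 100), dt), 0)
  # downward-only crossing is not a spike
  down <- c(rep(30, 10), rep(-65, 90))
  expect_length(detect_spikes(down, dt), 0)
  # refractory merging: two crossings 1 ms apart with refractory 2 ms
  vr <- rep(-65, length(t))
  vr[t >= 10 & t < 10.3] <- 30
  vr[t >= 11 & t < 11.3] <- 30
  expect_length(detect_spikes(vr, dt, refractory = 2), 1)
  expect_length(detect_spikes(vr, dt, refractory = 0.5), 2)
  expect_error(detect_spikes(numeric(0), dt), "invalid input")
})

test_that("pearson_r reproduces hand-computed and degenerate cases", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_error(pearson_r(x, c(2, 2, 2)), "zero variance")
  expect_error(pearson_r(x, c(1, 2)), "equal length")
})

test_that("pearson_r agrees with a brute-force oracle and stats::cor on random input", {
  set.seed(42)
  for (n in c(5, 50, 1000)) {
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
})

test_that("correlation is affine-invariant up to the sign of the scalings", {
  set.seed(7)
  x <- rnorm(100)
  y <- rnorm(100)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(2 * x + 3, 0.5 * y - 1), r, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * x + 3, 0.5 * y - 1), -r, tolerance = 1e-12)
})

test_that("correlation tables flag undefined cells instead of zeroing them", {
  g <- build_ring(10, directed = TRUE)
  res <- simulate_network(g, synapse_spec("HS"), stimulus_spec("sine"),
                          sim = sim_config(t_total = 60))
  # neurons far downstream of a subthreshold chain keep a tiny drift trace;
  # a self-pair is exactly 1
  tab <- correlation_table(res, pairs = list(c(1L, 1L), c(1L, 6L)))
  expect_equal(tab$r[1], 1.0)
  expect_true(all(tab$defined == !is.na(tab$r)))
  # constant traces have no defined correlation
  res0 <- res
  res0$V[6, ] <- -65
  tab0 <- correlation_table(res0, pairs = list(c(1L, 6L)))
  expect_false(tab0$defined[1])
  expect_true(is.na(tab0$r[1]))
  expect_error(correlation_table(res, pairs = list(c(1L, 99L))), "outside")
})

test_that("latency is zero at the reference, missing for silent neurons, monotone on a chain", {
  res <- simulate_network(build_ring(10, directed = TRUE), synapse_spec("RS"),
                          stimulus_spec("sine"), sim = sim_config(t_total = 150))
  lat <- first_spike_latency(res)
  expect_equal(lat$latency_ms[1], 0)
  fired <- which(!is.na(lat$latency_ms))
  expect_true(all(diff(lat$latency_ms[fired]) >= 0))

  dec <- simulate_network(build_ring(5, directed = TRUE),
                          synapse_spec("RS", g = 0), stimulus_spec("sine"),
                          sim = sim_config(t_total = 60))
  ldec <- first_spike_latency(dec)
  expect_true(all(is.na(ldec$latency_ms[2:5])))
  expect_false(any(ldec$latency_ms[2:5] == 0, na.rm = TRUE))
  # silent reference is an error, not a zero
  expect_error(first_spike_latency(dec, reference = 3), "invalid reference")
})
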