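# Independent reference implementations used as oracles.  These deliberately
# avoid the package's own code paths (aside from trivially shared constants)
# so that agreement is informative.

# Brute-force two-pass Pearson correlation with explicit loops.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in 1:n) { mx <- mx + x[i]; my <- my + y[i] }
  mx <- mx / n; my <- my / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in 1:n) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

oracle_rates <- function(v) {
  list(am = if (abs(v + 40) < 1e-7) 1 else 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10)),
       bm = 4 * exp(-(v + 65) / 18),
       ah = 0.07 * exp(-(v + 65) / 20),
       bh = 1 / (exp(-(v + 35) / 10) + 1),
       an = if (abs(v + 55) < 1e-7) 0.1 else 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10)),
       bn = 0.125 * exp(-(v + 65) / 80))
}

# Naive fixed-step RK4 network simulator with *instantaneous* chemical
# coupling: the gate is read from the live presynaptic voltage at the start
# of each step, with no delay-buffer machinery at all.  Used to check that
# the buffered integrator at tau = 0 collapses to instantaneous coupling.
oracle_sim_live <- function(n, arcs, kind, g, vthresh, vrev, iext_fun,
                            stim = 1, dt = 0.01, t_total = 50) {
  r0 <- oracle_rates(-65)
  y <- list(v = rep(-65, n),
            m = rep(r0$am / (r0$am + r0$bm), n),
            h = rep(r0$ah / (r0$ah + r0$bh), n),
            n = rep(r0$an / (r0$an + r0$bn), n))
  nsteps <- round(t_total / dt)
  vout <- matrix(NA_real_, n, nsteps + 1)
  vout[, 1] <- y$v
  f <- function(v, m, h, nn, gate, iext) {
    itot <- numeric(n)
    itot[stim] <- iext
    for (a in seq_len(nrow(arcs))) {
      s <- arcs[a, 1]; d <- arcs[a, 2]
      if (kind == "ES") {
        itot[d] <- itot[d] + g * (v[s] - v[d])
      } else if (gate[s]) {
        itot[d] <- itot[d] + if (kind == "HS") g else g * (vrev - v[d])
      }
    }
    dv <- numeric(n); dm <- numeric(n); dh <- numeric(n); dn <- numeric(n)
    for (i in 1:n) {
      rr <- oracle_rates(v[i])
      dv[i] <- 120 * m[i]^3 * h[i] * (50 - v[i]) + 36 * nn[i]^4 * (-77 - v[i]) +
        0.3 * (-54.5 - v[i]) + itot[i]
      dm[i] <- rr$am * (1 - m[i]) - rr$bm * m[i]
      dh[i] <- rr$ah * (1 - h[i]) - rr$bh * h[i]
      dn[i] <- rr$an * (1 - nn[i]) - rr$bn * nn[i]
    }
    list(dv = dv, dm = dm, dh = dh, dn = dn)
  }
  for (k in 0:(nsteps - 1)) {
    gate <- y$v > vthresh            # live presynaptic voltage, step start
    i0 <- iext_fun(k * dt); i1 <- iext_fun((k + 0.5) * dt); i2 <- iext_fun((k + 1) * dt)
    k1 <- f(y$v, y$m, y$h, y$n, gate, i0)
    k2 <- f(y$v + dt / 2 * k1$dv, y$m + dt / 2 * k1$dm, y$h + dt / 2 * k1$dh,
            y$n + dt / 2 * k1$dn, gate, i1)
    k3 <- f(y$v + dt / 2 * k2$dv, y$m + dt / 2 * k2$dm, y$h + dt / 2 * k2$dh,
            y$n + dt / 2 * k2$dn, gate, i1)
    k4 <- f(y$v + dt * k3$dv, y$m + dt * k3$dm, y$h + dt * k3$dh,
            y$n + dt * k3$dn, gate, i2)
    y$v <- y$v + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    y$m <- y$m + dt / 6 * (k1$dm + 2 * k2$dm + 2 * k3$dm + k4$dm)
    y$h <- y$h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    y$n <- y$n + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn)
    vout[, k + 2] <- y$v
  }
  vout
}
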