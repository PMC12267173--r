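#' Synapse specification
#'
#' Describes one of the three coupling models used throughout the package:
#'
#' * `"ES"` — electrical synapse (gap junction): bidirectional ohmic coupling
#'   `I = g (V_pre - V_post)`.
#' * `"HS"` — Hansel chemical synapse: the postsynaptic cell receives the
#'   constant current `g` whenever the delayed presynaptic potential exceeds
#'   `v_thresh` (Heaviside gating), else nothing.
#' * `"RS"` — Rabinovich chemical synapse: like HS but the delivered current
#'   also scales with the gap between the postsynaptic potential and the
#'   synaptic reversal potential, `I = g (v_rev - V_post) H(...)`, so the
#'   drive is self-limiting as the target depolarizes towards `v_rev`
#'   (a postsynaptic feedback mechanism).
#'
#' Chemical synapses are strictly unidirectional (presynaptic to
#' postsynaptic) and act on the presynaptic potential delayed by `tau` ms.
#' The Heaviside gate opens only when the threshold is strictly exceeded
#' (`H(0) = 0`); the tie has measure zero on any simulated trajectory.
#'
#' With `rs_sign_literal = TRUE` the RS current is flipped to
#' `g (V_post - v_rev) H(...)`, a hyperpolarizing variant retained for
#' comparison; the default depolarizing convention is the one under which
#' threshold-gated excitation can propagate.
#'
#' @param kind `"ES"`, `"HS"` or `"RS"`.
#' @param g coupling strength, >= 0.  mS/cm^2 for ES and RS; for HS the
#'   Heaviside gate is dimensionless so `g` acts directly as a current
#'   amplitude in uA/cm^2.  Default 0.1 (the network study condition).
#' @param v_thresh synaptic threshold, mV (chemical kinds only).
#' @param tau transmission delay, ms, >= 0 (chemical kinds only; forced to 0
#'   for ES).  Default 1 ms.
#' @param v_rev synaptic reversal potential, mV (RS only).  Default 0 mV.
#' @param rs_sign_literal logical; flip the RS sign convention (see above).
#' @return An object of class `synapse_spec`.
#' @examples
#' synapse_spec("RS")
#' @export
synapse_spec <- function(kind = c("ES", "HS", "RS"), g = 0.1, v_thresh = -52,
                         tau = 1, v_rev = 0, rs_sign_literal = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(g), length(g) == 1, is.finite(g),
            is.numeric(v_thresh), length(v_thresh) == 1, is.finite(v_thresh),
            is.numeric(tau), length(tau) == 1, is.finite(tau),
            is.numeric(v_rev), length(v_rev) == 1, is.finite(v_rev),
            is.logical(rs_sign_literal), length(rs_sign_literal) == 1)
  if (g < 0) stop("coupling strength `g` must be >= 0", call. = FALSE)
  if (tau < 0) stop("transmission delay `tau` must be >= 0", call. = FALSE)
  if (kind == "ES") tau <- 0
  structure(list(kind = kind, g = g, v_thresh = v_thresh, tau = tau,
                 v_rev = v_rev, rs_sign_literal = rs_sign_literal),
            class = "synapse_spec")
}

#' @export
print.synapse_spec <- function(x, ...) {
  cat("<synapse_spec>", x$kind, " g =", x$g, "\n")
  if (x$kind != "ES")
    cat("  v_thresh =", x$v_thresh, "mV  tau =", x$tau, "ms",
        if (x$kind == "RS") paste(" v_rev =", x$v_rev, "mV"), "\n")
  invisible(x)
}

check_finite <- function(..., what = "inputs") {
  vals <- c(...)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop(what, " must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Electrical (gap-junction) coupling current
#'
#' `I = g (v_pre - v_post)`, uA/cm^2.  Antisymmetric under exchange of the
#' endpoints, so the summed current over the two ends of an undirected edge
#' is exactly zero: gap junctions redistribute charge, they do not inject it.
#'
#' @param v_pre,v_post membrane potentials, mV.
#' @param g coupling conductance, mS/cm^2.
#' @return Current density, uA/cm^2.
#' @examples
#' electrical_current(-40, -65, g = 0.1)  # 2.5
#' @export
electrical_current <- function(v_pre, v_post, g = 0.1) {
  check_finite(v_pre, v_post, g)
  g * (v_pre - v_post)
}

#' Hansel synapse current
#'
#' Constant-amplitude threshold-gated current: `g` while the delayed
#' presynaptic potential strictly exceeds the threshold, 0 otherwise.  The
#' output is two-valued by construction.
#'
#' @param v_pre_delayed presynaptic membrane potential `tau` ms ago, mV.
#' @param spec a [synapse_spec()] with `kind = "HS"`.
#' @return Current density, uA/cm^2 (either 0 or `spec$g`).
#' @export
hansel_current <- function(v_pre_delayed, spec = synapse_spec("HS")) {
  stopifnot(inherits(spec, "synapse_spec"))
  if (spec$kind != "HS") stop("`spec` must have kind \"HS\"", call. = FALSE)
  check_finite(v_pre_delayed)
  spec$g * as.numeric(v_pre_delayed > spec$v_thresh)
}

#' Rabinovich synapse current
#'
#' Threshold-gated current with postsynaptic feedback:
#' `g (v_rev - v_post)` while the delayed presynaptic potential exceeds the
#' threshold, 0 otherwise (sign flipped when `spec$rs_sign_literal`).  The
#' magnitude is bounded by `g * |v_rev - v_post|` and vanishes at the
#' reversal point.
#'
#' @param v_post postsynaptic membrane potential, mV.
#' @param v_pre_delayed presynaptic membrane potential `tau` ms ago, mV.
#' @param spec a [synapse_spec()] with `kind = "RS"`.
#' @return Current density, uA/cm^2.
#' @examples
#' rabinovich_current(-65, 0, synapse_spec("RS"))  # 6.5
#' @export
rabinovich_current <- function(v_post, v_pre_delayed, spec = synapse_spec("RS")) {
  stopifnot(inherits(spec, "synapse_spec"))
  if (spec$kind != "RS") stop("`spec` must have kind \"RS\"", call. = FALSE)
  check_finite(v_post, v_pre_delayed)
  gate <- as.numeric(v_pre_delayed > spec$v_thresh)
  drive <- if (spec$rs_sign_literal) v_post - spec$v_rev else spec$v_rev - v_post
  spec$g * drive * gate
}

#' Delayed-voltage ring buffer
#'
#' A small history buffer of past membrane potentials sampled every `dt` ms,
#' used to realise the `V_pre(t - tau)` term of the chemical synapse models.
#' Before the buffer has accumulated `tau` ms of history, lookups return the
#' initial membrane potential `init` (the network integrator pre-fills its
#' buffers with the resting potential in the same way).
#'
#' The compiled integrator keeps its own internal buffers; this R-level
#' object exposes the same semantics for testing and for external analyses.
#'
#' @param horizon maximum lag ever looked up, ms.
#' @param dt sample spacing, ms, > 0.
#' @param init value reported before history accumulates, mV.
#' @return An object of class `delay_buffer`.
#' @seealso [buffer_push()], [delayed_lookup()]
#' @export
delay_buffer <- function(horizon, dt, init = -65) {
  stopifnot(is.numeric(horizon), length(horizon) == 1, horizon >= 0,
            is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(init), length(init) == 1, is.finite(init))
  structure(list(values = numeric(0), horizon = horizon, dt = dt, init = init),
            class = "delay_buffer")
}

#' Append a sample to a delay buffer
#'
#' @param buffer a [delay_buffer()].
#' @param v the current membrane potential sample, mV.
#' @return The updated buffer (functional update; reassign the result).
#' @export
buffer_push <- function(buffer, v) {
  stopifnot(inherits(buffer, "delay_buffer"))
  check_finite(v)
  keep <- ceiling(buffer$horizon / buffer$dt) + 1L
  buffer$values <- tail(c(buffer$values, v), keep)
  buffer
}

#' Look up a delayed membrane potential
#'
#' Returns the stored potential `tau` ms before the most recent pushed
#' sample, linearly interpolated between grid samples when `tau` is not a
#' multiple of `dt`.  Lag 0 returns the current sample exactly; lags reaching
#' beyond the accumulated history return the buffer's initial value.
#'
#' @param buffer a [delay_buffer()].
#' @param tau lag, ms, with `0 <= tau <= horizon`.
#' @return Membrane potential, mV.
#' @examples
#' b <- delay_buffer(horizon = 0.1, dt = 0.01)
#' b <- buffer_push(b, -65); b <- buffer_push(b, -55)
#' delayed_lookup(b, 0)      # -55 (current sample)
#' delayed_lookup(b, 0.005)  # -60 (midpoint interpolation)
#' @export
delayed_lookup <- function(buffer, tau) {
  stopifnot(inherits(buffer, "delay_buffer"),
            is.numeric(tau), length(tau) == 1, is.finite(tau), tau >= 0)
  if (tau > buffer$horizon + 1e-12)
    stop("configuration error: lag `tau` exceeds the buffer horizon",
         call. = FALSE)
  nv <- length(buffer$values)
  if (nv == 0) return(buffer$init)
  # most recent sample sits at relative time (nv - 1) * dt
  tq <- (nv - 1) * buffer$dt - tau
  if (tq < -1e-12) return(buffer$init)
  j <- tq / buffer$dt + 1
  i <- floor(j)
  w <- j - i
  if (i >= nv) return(buffer$values[nv])
  if (i < 1) return((1 - (j)) * buffer$init + j * buffer$values[1])
  (1 - w) * buffer$values[i] + w * buffer$values[i + 1]
}
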