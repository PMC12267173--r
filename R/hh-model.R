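#' Hodgkin-Huxley membrane parameters
#'
#' Container for the classic squid-axon membrane constants of the
#' Hodgkin-Huxley (HH) model: capacitance, maximal channel conductances and
#' reversal potentials.  The defaults are the canonical HH values at 6.3 C
#' shifted so that rest sits near -65 mV; in particular the potassium
#' conductance defaults to 36 mS/cm^2, the only value consistent with the
#' resting gating point (0.05293, 0.5961, 0.3177) used throughout this
#' package.  Conductances an order of magnitude larger clamp the membrane to
#' E_K and silence the model (see [parse_config()], which warns in that case).
#'
#' @param c_m membrane capacitance (uF/cm^2), > 0.
#' @param g_na,g_k,g_l maximal sodium, potassium and leak conductances
#'   (mS/cm^2), >= 0.
#' @param e_na,e_k,e_l sodium, potassium and leak reversal potentials (mV).
#' @return An object of class `hh_params`.
#' @examples
#' hh_params()
#' hh_params(g_k = 360)  # accepted, but suppresses firing
#' @export
hh_params <- function(c_m = 1, g_na = 120, g_k = 36, g_l = 0.3,
                      e_na = 50, e_k = -77, e_l = -54.5) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  p <- list(c_m = num1(c_m, "c_m"), g_na = num1(g_na, "g_na"),
            g_k = num1(g_k, "g_k"), g_l = num1(g_l, "g_l"),
            e_na = num1(e_na, "e_na"), e_k = num1(e_k, "e_k"),
            e_l = num1(e_l, "e_l"))
  if (p$c_m <= 0) stop("membrane capacitance `c_m` must be positive", call. = FALSE)
  if (p$g_na < 0 || p$g_k < 0 || p$g_l < 0)
    stop("conductances must be non-negative", call. = FALSE)
  structure(p, class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("<hh_params>  C =", x$c_m, "uF/cm^2\n")
  cat("  g_Na =", x$g_na, " g_K =", x$g_k, " g_L =", x$g_l, "mS/cm^2\n")
  cat("  E_Na =", x$e_na, " E_K =", x$e_k, " E_L =", x$e_l, "mV\n")
  invisible(x)
}

#' Voltage-dependent channel transition rates
#'
#' Evaluates the six HH opening/closing rates (1/ms) at membrane potential
#' `v` (mV).  The activation rates `alpha_m` and `alpha_n` have removable
#' singularities at -40 mV and -55 mV; both are evaluated by their analytic
#' limits (1.0 and 0.1) within 1e-7 mV of the singular point, keeping the
#' functions continuous there.
#'
#' The inactivation closing rate uses the sigmoid form
#' `beta_h = 1 / (exp(-(v + 35)/10) + 1)`.
#'
#' @param v membrane potential(s), mV; must be finite.
#' @return A list with numeric components `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, each the length of `v`.
#' @examples
#' rate_constants(-65)
#' rate_constants(-40)$alpha_m  # limit value 1.0
#' @export
rate_constants <- function(v) {
  if (!is.numeric(v) || length(v) == 0 || any(!is.finite(v)))
    stop("`v` must be finite membrane potential(s) in mV", call. = FALSE)
  xm <- v + 40
  am <- ifelse(abs(xm) < 1e-7, 1.0, 0.1 * xm / (1 - exp(-xm / 10)))
  xn <- v + 55
  an <- ifelse(abs(xn) < 1e-7, 0.1, 0.01 * xn / (1 - exp(-xn / 10)))
  list(alpha_m = am,
       beta_m  = 4 * exp(-(v + 65) / 18),
       alpha_h = 0.07 * exp(-(v + 65) / 20),
       beta_h  = 1 / (exp(-(v + 35) / 10) + 1),
       alpha_n = an,
       beta_n  = 0.125 * exp(-(v + 65) / 80))
}

#' Steady-state gating values
#'
#' The voltage-clamp fixed points `x_inf = alpha/(alpha + beta)` of the three
#' gating variables.  At the resting potential -65 mV these are
#' (m, h, n) = (0.05293, 0.5961, 0.3177) to four significant figures, the
#' initial state used for every simulation in this package.
#'
#' @inheritParams rate_constants
#' @return For scalar `v`, a named numeric vector `c(m, h, n)`; for vector
#'   `v`, a matrix with columns `m`, `h`, `n`.
#' @examples
#' steady_state_gating(-65)
#' @export
steady_state_gating <- function(v) {
  r <- rate_constants(v)
  out <- cbind(m = r$alpha_m / (r$alpha_m + r$beta_m),
               h = r$alpha_h / (r$alpha_h + r$beta_h),
               n = r$alpha_n / (r$alpha_n + r$beta_n))
  if (length(v) == 1) out[1, ] else out
}

#' Resting neuron state
#'
#' A neuron state (`v`, `m`, `h`, `n`) with the gating variables at their
#' steady-state values for the given membrane potential.
#'
#' @param v membrane potential, mV (default -65, the resting potential).
#' @return A list with components `v`, `m`, `h`, `n`.
#' @export
resting_state <- function(v = -65) {
  g <- steady_state_gating(v)
  list(v = v, m = unname(g["m"]), h = unname(g["h"]), n = unname(g["n"]))
}

#' Hodgkin-Huxley derivative field
#'
#' Right-hand side of the four-dimensional HH membrane equation
#' `C dV/dt = g_Na m^3 h (E_Na - V) + g_K n^4 (E_K - V) + g_L (E_L - V) + I`
#' together with the first-order gating kinetics
#' `dx/dt = alpha_x (1 - x) - beta_x x`.  `i_total` is the total injected
#' current density (external stimulus plus synaptic input, summed by the
#' caller).
#'
#' All inputs may be vectors of equal length (one entry per neuron).
#'
#' @param state list with numeric components `v`, `m`, `h`, `n`; the gating
#'   values must lie in `[0, 1]`.
#' @param i_total total current density, uA/cm^2; must be finite.
#' @param params an [hh_params()] object.
#' @return A list with components `dv` (mV/ms) and `dm`, `dh`, `dn` (1/ms).
#' @examples
#' hh_derivatives(resting_state(), i_total = 0)
#' @export
hh_derivatives <- function(state, i_total = 0, params = hh_params()) {
  v <- state$v; m <- state$m; h <- state$h; n <- state$n
  if (any(m < 0 | m > 1 | h < 0 | h > 1 | n < 0 | n > 1))
    stop("invalid state: gating variable outside [0, 1]", call. = FALSE)
  if (!is.numeric(i_total) || any(!is.finite(i_total)))
    stop("`i_total` must be finite", call. = FALSE)
  r <- rate_constants(v)
  ionic <- params$g_na * m^3 * h * (params$e_na - v) +
    params$g_k * n^4 * (params$e_k - v) +
    params$g_l * (params$e_l - v)
  list(dv = (ionic + i_total) / params$c_m,
       dm = r$alpha_m * (1 - m) - r$beta_m * m,
       dh = r$alpha_h * (1 - h) - r$beta_h * h,
       dn = r$alpha_n * (1 - n) - r$beta_n * n)
}
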