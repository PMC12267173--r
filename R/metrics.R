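#' Detect spikes in a voltage trace
#'
#' Spike times are the upward crossings of `threshold` (linearly
#' interpolated between samples), with successive spikes forced to be at
#' least `refractory` ms apart.  Downward crossings are ignored.
#'
#' @param v voltage trace, mV, uniformly sampled.
#' @param dt sample spacing, ms.
#' @param threshold crossing threshold, mV (default 0: the action-potential
#'   overshoot, well above any subthreshold response).
#' @param refractory minimum spike separation, ms.
#' @return Numeric vector of spike times, ms (possibly empty).
#' @examples
#' t <- seq(0, 50, 0.1)
#' v <- -65 + 100 * (abs(t - 10) < 0.5)
#' detect_spikes(v, 0.1)
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 2) {
  if (!is.numeric(v) || length(v) < 2)
    stop("invalid input: need a voltage trace with at least two samples",
         call. = FALSE)
  stopifnot(is.numeric(dt), dt > 0)
  i <- which(v[-length(v)] <= threshold & v[-1] > threshold)
  if (!length(i)) return(numeric(0))
  times <- (i - 1) * dt + dt * (threshold - v[i]) / (v[i + 1] - v[i])
  keep <- times[1]
  for (tt in times[-1]) if (tt - keep[length(keep)] >= refractory) keep <- c(keep, tt)
  keep
}

#' Pearson correlation coefficient
#'
#' The normalized covariance
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`, the synchrony statistic applied to pairs of
#' membrane-potential traces.  A zero-variance input has no defined
#' correlation and raises an error rather than silently returning 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return The correlation, in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))  # 0.98198
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 2 || any(!is.finite(x)) || any(!is.finite(y)))
    stop("`x` and `y` must be finite numeric vectors of equal length >= 2",
         call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc^2)
  sy <- sum(yc^2)
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  r <- sum(xc * yc) / sqrt(sx * sy)
  max(-1, min(1, r))
}

#' Neuron pairs of the synchrony tables
#'
#' The four neuron pairs whose trace correlations quantify network
#' synchrony, in fixed column order: (1,25), (15,30), (20,35), (5,45).
#'
#' @return A list of 4 integer pairs.
#' @export
default_pairs <- function() list(c(1L, 25L), c(15L, 30L), c(20L, 35L), c(5L, 45L))

pair_label <- function(p) paste0("r_", p[1], "_", p[2])

#' Pairwise trace correlations of a simulation
#'
#' Pearson correlation of the recorded membrane-potential traces for each
#' requested neuron pair, over the full recorded window by default
#' (`burn_in_ms` discards an initial transient).  A pair involving a
#' constant (never-depolarized) trace has no defined correlation and is
#' flagged rather than zeroed.
#'
#' @param result an `hh_sim` from [simulate_network()].
#' @param pairs list of integer pairs (default [default_pairs()]).
#' @param burn_in_ms initial window to discard, ms.
#' @return A data frame with columns `pair`, `i`, `j`, `r`, `defined`.
#' @export
correlation_table <- function(result, pairs = default_pairs(), burn_in_ms = 0) {
  stopifnot(inherits(result, "hh_sim"))
  keep <- result$time >= burn_in_ms
  out <- lapply(pairs, function(p) {
    if (any(p < 1 | p > result$graph$n))
      stop("pair index outside 1..n", call. = FALSE)
    r <- tryCatch(pearson_r(result$V[p[1], keep], result$V[p[2], keep]),
                  error = function(e) NA_real_)
    data.frame(pair = pair_label(p), i = p[1], j = p[2], r = r,
               defined = !is.na(r))
  })
  do.call(rbind, out)
}

#' First-spike latency relative to a reference neuron
#'
#' For each neuron, the time of its first detected spike and the latency
#' relative to the reference neuron's first spike (the study's
#' propagation-delay measure).  Neurons that never spike are reported as
#' missing (`NA`), never as zero; a silent reference neuron is an error.
#'
#' @param result an `hh_sim` from [simulate_network()].
#' @param reference reference neuron index (default the stimulated node).
#' @return A data frame with columns `neuron`, `first_spike_ms`,
#'   `latency_ms`; the reference index is stored in
#'   `attr(, "reference")`.
#' @export
first_spike_latency <- function(result, reference = NULL) {
  stopifnot(inherits(result, "hh_sim"))
  reference <- reference %||% result$graph$stimulated_node
  stopifnot(reference >= 1, reference <= result$graph$n)
  fs <- vapply(result$spikes, function(s) if (length(s)) s[1] else NA_real_,
               numeric(1))
  if (is.na(fs[reference]))
    stop("invalid reference: reference neuron produced no spikes", call. = FALSE)
  out <- data.frame(neuron = seq_len(result$graph$n), first_spike_ms = fs,
                    latency_ms = fs - fs[reference])
  attr(out, "reference") <- as.integer(reference)
  out
}
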