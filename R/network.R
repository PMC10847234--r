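#' Simulation time grid
#'
#' A uniform closed grid `[0, t_end]` with step `dt`.  Spike times are
#' reported at grid points unless sub-grid interpolation is requested in
#' [simulate_forward()].
#'
#' @param t_end Window length T in ms (> 0).
#' @param dt Grid step in ms (> 0); `t_end` must be an integer multiple.
#' @return An object of class `time_grid` with fields `t_end`, `dt`,
#'   `times` (the grid points) and `n` (number of points).
#' @export
time_grid <- function(t_end = 25, dt = 0.1) {
  stopifnot(is.numeric(t_end), t_end > 0, is.numeric(dt), dt > 0)
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-9) {
    abort("`t_end` must be an integer multiple of `dt`.")
  }
  structure(
    list(t_end = t_end, dt = dt, times = (0:n_steps) * dt, n = n_steps + 1L),
    class = "time_grid"
  )
}

#' Network parameters: per-synapse weights and delays
#'
#' Container for a feed-forward architecture given by `layer_sizes`, with
#' one weight matrix and one congruent delay matrix per non-input layer.
#' Matrix `l` has shape `layer_sizes[l] x layer_sizes[l + 1]`
#' (presynaptic rows, postsynaptic columns).  Delays must lie in
#' `[0, d_max]` of the accompanying [neuron_config()].
#'
#' @param layer_sizes Integer vector of neuron counts per layer (>= 2 layers,
#'   all sizes >= 1).
#' @param weights List of weight matrices, one per non-input layer.
#' @param delays List of delay matrices, congruent with `weights`.
#' @param config A [neuron_config()] (used to validate the delay bound).
#' @return An object of class `network_params`.
#' @seealso [init_network()] for seeded random initialization.
#' @export
network_params <- function(layer_sizes, weights, delays, config = neuron_config()) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    abort("`layer_sizes` needs at least two layers, all with >= 1 neuron.")
  }
  n_conn <- length(layer_sizes) - 1L
  if (length(weights) != n_conn || length(delays) != n_conn) {
    abort("`weights` and `delays` must each hold one matrix per non-input layer.")
  }
  for (l in seq_len(n_conn)) {
    expect_dim <- c(layer_sizes[l], layer_sizes[l + 1])
    if (!identical(dim(weights[[l]]), as.integer(expect_dim)) ||
        !identical(dim(delays[[l]]), as.integer(expect_dim))) {
      abort(sprintf(
        "layer %d: weights and delays must both be %d x %d matrices.",
        l + 1, expect_dim[1], expect_dim[2]
      ))
    }
    if (any(!is.finite(weights[[l]])) || any(!is.finite(delays[[l]]))) {
      abort(sprintf("layer %d: non-finite parameter values.", l + 1))
    }
    if (any(delays[[l]] < 0) || any(delays[[l]] > config$d_max)) {
      abort(sprintf("layer %d: delays must lie in [0, d_max = %g].",
                    l + 1, config$d_max))
    }
  }
  structure(
    list(layer_sizes = layer_sizes, weights = weights, delays = delays),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> architecture %s\n",
              paste(x$layer_sizes, collapse = "-")))
  n_par <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("  %d weights + %d delays\n", n_par, n_par))
  invisible(x)
}

#' Seeded random initialization of weights and delays
#'
#' Weights are drawn uniformly from a positive range scaled so a
#' postsynaptic neuron's expected peak potential under average input is
#' roughly `1.5 * theta`: with about half the inputs active and an average
#' kernel overlap of about half the peak, the draw is
#' `U(0, 6 * theta / n_pre)` per synapse (mean `3 * theta / n_pre`,
#' so `n_pre * mean * 0.5 * 0.5 * 2 = 1.5 theta`), keeping fresh networks
#' responsive without saturating.  Delays are drawn uniformly from
#' `[0, d_max / 2]`, leaving headroom for delay learning in both directions.
#'
#' @param layer_sizes Integer vector of neuron counts per layer.
#' @param config A [neuron_config()].
#' @param seed Integer RNG seed.
#' @param w_scale Optional override for the upper weight bound per layer
#'   (recycled); default `6 * theta / n_pre`.
#' @return A [network_params()] object.
#' @export
init_network <- function(layer_sizes, config = neuron_config(), seed = 1L,
                         w_scale = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  n_conn <- length(layer_sizes) - 1L
  if (!is.null(w_scale)) w_scale <- rep_len(w_scale, n_conn)
  set.seed(seed)
  weights <- vector("list", n_conn)
  delays <- vector("list", n_conn)
  for (l in seq_len(n_conn)) {
    n_pre <- layer_sizes[l]
    n_post <- layer_sizes[l + 1]
    hi <- if (is.null(w_scale)) 6 * config$theta / n_pre else w_scale[l]
    weights[[l]] <- matrix(runif(n_pre * n_post, 0, hi), n_pre, n_post)
    delays[[l]] <- matrix(runif(n_pre * n_post, 0, config$d_max / 2),
                          n_pre, n_post)
  }
  network_params(layer_sizes, weights, delays, config)
}

#' Membrane potential of one SRM neuron
#'
#' Sums the delayed, weighted kernel responses of one postsynaptic neuron:
#' `V(t) = sum_i w_i * K(t - t_i - d_i)`.  Silent presynaptic neurons
#' (`NA` spike time) contribute zero.  The value depends only on the time
#' differences, so shifting all spike times and `t` together leaves it
#' unchanged.
#'
#' @param t Evaluation time(s) in ms (vectorized).
#' @param pre_spikes Presynaptic spike times in ms, `NA` for silent.
#' @param weights Synaptic weights, same length as `pre_spikes`.
#' @param delays Synaptic delays in ms, same length as `pre_spikes`.
#' @param config A [neuron_config()].
#' @return Potential at each `t`.
#' @export
membrane_potential <- function(t, pre_spikes, weights, delays, config) {
  n <- length(pre_spikes)
  if (length(weights) != n || length(delays) != n) {
    abort("`pre_spikes`, `weights` and `delays` must have equal length.")
  }
  active <- which(!is.na(pre_spikes))
  if (!length(active)) return(numeric(length(t)))
  # offsets: |t| x |active|
  arg <- outer(t, pre_spikes[active] + delays[active], "-")
  drop(psp_kernel(arg, config) %*% weights[active])
}

#' Simulate a forward pass through the network
#'
#' Event-level simulation of a feed-forward SRM network under the
#' at-most-one-spike constraint.  Layer by layer, each neuron's membrane
#' potential is accumulated on the time grid from the (delayed) spikes of
#' the previous layer; its spike time is the first grid point where the
#' potential reaches `theta`, after which the neuron is frozen.  Neurons
#' that never cross within the window are silent (`NA`).
#'
#' With `interpolate = TRUE` the crossing time is refined by linear
#' interpolation between the last sub-threshold grid point and the crossing
#' point, making spike time a locally smooth function of the parameters
#' (used by the gradient checker); the potential at an interpolated
#' crossing is `theta` by construction.
#'
#' @param input_spikes Numeric vector of input spike times in ms (`NA` =
#'   silent), length `layer_sizes[1]`.
#' @param params A [network_params()].
#' @param config A [neuron_config()].
#' @param grid A [time_grid()].
#' @param interpolate Refine crossings below the grid resolution
#'   (default `FALSE`: spike times are grid points, fully deterministic).
#' @return An object of class `srm_record`: a list with per-layer
#'   `times` (spike time or `NA`), `v_trace` (potential on the grid,
#'   `n_time x n_neuron`, `NULL` for the input layer), `v_at_spike`
#'   (potential at the detected crossing) and `v_max` (maximum potential
#'   over the window).
#' @export
simulate_forward <- function(input_spikes, params, config = neuron_config(),
                             grid = time_grid(), interpolate = FALSE) {
  sizes <- params$layer_sizes
  if (length(input_spikes) != sizes[1]) {
    abort(sprintf("expected %d input spike times, got %d.",
                  sizes[1], length(input_spikes)))
  }
  input_spikes <- as.numeric(input_spikes)
  if (any(input_spikes < 0, na.rm = TRUE)) {
    abort("input spike times must be >= 0 (or NA for silent).")
  }
  tg <- grid$times
  n_t <- grid$n
  L <- length(sizes)
  times <- vector("list", L)
  v_trace <- vector("list", L)
  v_at_spike <- vector("list", L)
  v_max <- vector("list", L)
  times[[1]] <- input_spikes

  for (l in 2:L) {
    W <- params$weights[[l - 1]]
    D <- params$delays[[l - 1]]
    n_post <- sizes[l]
    V <- matrix(0, n_t, n_post)
    pre_t <- times[[l - 1]]
    for (i in which(!is.na(pre_t))) {
      arg <- outer(tg - pre_t[i], D[i, ], "-")
      V <- V + psp_kernel(arg, config) *
        matrix(W[i, ], n_t, n_post, byrow = TRUE)
    }
    t_l <- rep(NA_real_, n_post)
    v_at <- rep(NA_real_, n_post)
    for (j in seq_len(n_post)) {
      idx <- which(V[, j] >= config$theta)[1]
      if (!is.na(idx)) {
        if (interpolate && idx > 1) {
          v0 <- V[idx - 1, j]
          v1 <- V[idx, j]
          t_l[j] <- tg[idx - 1] + grid$dt * (config$theta - v0) / (v1 - v0)
          v_at[j] <- config$theta
        } else {
          t_l[j] <- tg[idx]
          v_at[j] <- V[idx, j]
        }
      }
    }
    times[[l]] <- t_l
    v_trace[[l]] <- V
    v_at_spike[[l]] <- v_at
    v_max[[l]] <- apply(V, 2, max)
  }

  structure(
    list(times = times, v_trace = v_trace, v_at_spike = v_at_spike,
         v_max = v_max, grid = grid, interpolated = interpolate),
    class = "srm_record"
  )
}

#' @export
print.srm_record <- function(x, ...) {
  L <- length(x$times)
  cat("<srm_record>\n")
  for (l in seq_len(L)) {
    t <- x$times[[l]]
    cat(sprintf("  layer %d: %d/%d fired; times: %s\n", l,
                sum(!is.na(t)), length(t),
                paste(ifelse(is.na(t), "-", sprintf("%.2f", t)),
                      collapse = " ")))
  }
  invisible(x)
}

#' Spike times of the output layer
#'
#' @param record An `srm_record` from [simulate_forward()].
#' @return Numeric vector of output spike times (`NA` = silent).
#' @export
output_times <- function(record) {
  record$times[[length(record$times)]]
}
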