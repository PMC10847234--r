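#' Surrogate-gradient configuration
#'
#' Controls how the ill-posed derivative of spike time with respect to
#' membrane voltage is evaluated during backpropagation.
#'
#' In `capped_gaussian` mode (the default, and the method this package
#' exists for) the magnitude is a Gaussian in the distance of the
#' at-crossing potential from threshold, capped near threshold:
#' `exp(-2 (V - theta)^2 / tau_sg)` when `|V - theta| > m`, and the
#' constant cap `exp(-2 m^2 / tau_sg)` when `|V - theta| <= m`.  The two
#' branches agree at `|V - theta| = m`, so the function is continuous,
#' strictly positive, and bounded by the cap — slow threshold crossings can
#' no longer blow the gradient up.
#'
#' In `linearized` mode the classical spike-time linearization is used
#' instead: `dt/dV = -1 / (dV/dt)` at the crossing.  This is exact up to
#' the linear approximation but explodes when the potential crosses
#' threshold slowly; it is kept for comparison studies and as the mode
#' under which analytic gradients match finite differences.
#'
#' @param m Cap half-width in potential units, `0 < m < 1`.
#' @param tau_sg Surrogate temperature (potential units squared, > 0).
#' @param mode `"capped_gaussian"` or `"linearized"`.
#' @param eps Degeneracy floor for `linearized` mode: a crossing slope with
#'   magnitude below `eps` is reported as a degenerate (exploding-gradient)
#'   crossing rather than inverted.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(m = 0.3, tau_sg = 1.0,
                             mode = c("capped_gaussian", "linearized"),
                             eps = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(m), m > 0, m < 1, is.numeric(tau_sg), tau_sg > 0,
            is.numeric(eps), eps > 0)
  structure(list(m = m, tau_sg = tau_sg, mode = mode, eps = eps),
            class = "surrogate_config")
}

#' Training configuration
#'
#' @param eta_w Weight learning rate (>= 0).
#' @param eta_d Delay learning rate (>= 0); ignored when
#'   `weight_only = TRUE`.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling shuffling (and nothing else).
#' @param weight_only If `TRUE`, delays are frozen and only weights learn
#'   (the weight-only ablation of the method).
#' @param silent_boost Additive weight increment applied to all incoming
#'   synapses of a neuron that failed to fire during a sample, nudging
#'   silent neurons back into the responsive regime.
#' @param silent_margin A silent output neuron enters the loss with the
#'   surrogate spike time `t_end + silent_margin` (ms), so silence is
#'   penalized as an extreme late spike.
#' @param eta_decay Multiplicative per-epoch decay applied to both learning
#'   rates by [srm_fit()] (1 = constant rates); annealing stabilizes the
#'   late phase of online spike-time learning.
#' @return An object of class `train_config`.
#' @export
train_config <- function(eta_w = 0.02, eta_d = 0.1, epochs = 100, seed = 1L,
                         weight_only = FALSE, silent_boost = 0.05,
                         silent_margin = 3, eta_decay = 1) {
  stopifnot(eta_w >= 0, eta_d >= 0, epochs >= 0, silent_boost >= 0,
            silent_margin >= 0, eta_decay > 0, eta_decay <= 1)
  structure(
    list(eta_w = eta_w, eta_d = if (weight_only) 0 else eta_d,
         epochs = as.integer(epochs), seed = as.integer(seed),
         weight_only = isTRUE(weight_only), silent_boost = silent_boost,
         silent_margin = silent_margin, eta_decay = eta_decay),
    class = "train_config"
  )
}

#' Temporal mean-squared-error loss
#'
#' `E = 1/2 * sum_k (t_k_actual - t_k_desired)^2` over the output neurons.
#' Silent actual spikes (`NA`) are an error here: the caller must apply the
#' silent-neuron policy (substitute the surrogate late time) first, so that
#' silence is never silently dropped from the loss.
#'
#' @param actual Actual output spike times in ms (no `NA` allowed).
#' @param desired Desired output spike times in ms.
#' @return Scalar loss.
#' @export
temporal_mse <- function(actual, desired) {
  if (length(actual) != length(desired)) {
    abort("`actual` and `desired` must have equal length.")
  }
  if (anyNA(actual) || anyNA(desired)) {
    abort(paste0(
      "silent (NA) spike times reached the loss; apply the silent-neuron ",
      "policy before calling `temporal_mse()`."
    ))
  }
  0.5 * sum((actual - desired)^2)
}

#' Capped-Gaussian surrogate for |dt/dV|
#'
#' The bounded replacement for the spike-time derivative magnitude:
#' `exp(-2 (V - theta)^2 / tau_sg)` for `|V - theta| > m`, capped at
#' `exp(-2 m^2 / tau_sg)` for `|V - theta| <= m`.  Returns the magnitude
#' only; backpropagation applies it with a negative sign so that the update
#' direction matches the linearized rule (an upward crossing has
#' `dt/dV < 0`: more drive, earlier spike).
#'
#' @param v_at_spike Membrane potential(s) at the detected crossing.
#' @param config A [neuron_config()] (supplies `theta`).
#' @param sg A [surrogate_config()] in `capped_gaussian` mode.
#' @return Positive value(s) bounded by `exp(-2 m^2 / tau_sg)`.
#' @export
surrogate_dtdv <- function(v_at_spike, config, sg = surrogate_config()) {
  if (sg$mode != "capped_gaussian") {
    abort("`surrogate_dtdv()` requires `mode = \"capped_gaussian\"`.")
  }
  dev <- abs(v_at_spike - config$theta)
  ifelse(dev > sg$m,
         exp(-2 * dev^2 / sg$tau_sg),
         exp(-2 * sg$m^2 / sg$tau_sg))
}

#' Linearized spike-time derivative dt/dV
#'
#' The classical linearization: around a detected threshold crossing the
#' potential is treated as linear in time, giving
#' `dt/dV = -1 / sum_i w_i * dK/dt(t_spike - t_i - d_i)`.
#' When the crossing slope's magnitude falls below `sg$eps` the crossing is
#' degenerate (the potential grazes the threshold) and the resulting
#' gradient would explode; this is reported as an error of class
#' `delayprop_degenerate_crossing`, not masked.
#'
#' @param pre_spikes Presynaptic spike times (ms, `NA` = silent).
#' @param weights_col Incoming weights of the crossing neuron.
#' @param delays_col Incoming delays of the crossing neuron.
#' @param t_spike Detected crossing time (ms).
#' @param config A [neuron_config()].
#' @param sg A [surrogate_config()] (supplies the degeneracy floor `eps`).
#' @return A scalar, negative at an ordinary upward crossing.
#' @export
linearized_dtdv <- function(pre_spikes, weights_col, delays_col, t_spike,
                            config, sg = surrogate_config(mode = "linearized")) {
  slope <- sum(weights_col *
                 psp_kernel_deriv(t_spike - pre_spikes - delays_col, config),
               na.rm = TRUE)
  if (abs(slope) < sg$eps) {
    abort(
      sprintf(paste0(
        "degenerate threshold crossing at t = %.3f ms: |dV/dt| = %.3g < %g; ",
        "the linearized spike-time gradient explodes here."
      ), t_spike, abs(slope), sg$eps),
      class = "delayprop_degenerate_crossing"
    )
  }
  -1 / slope
}

# dt/dV for every neuron of layer l (0 for silent neurons), applying the
# sign convention: the propagated derivative is negative at a crossing.
layer_dtdv <- function(record, params, l, config, sg) {
  t_l <- record$times[[l]]
  out <- numeric(length(t_l))
  fired <- which(!is.na(t_l))
  if (!length(fired)) return(out)
  if (sg$mode == "capped_gaussian") {
    out[fired] <- -surrogate_dtdv(record$v_at_spike[[l]][fired], config, sg)
  } else {
    t_pre <- record$times[[l - 1]]
    W <- params$weights[[l - 1]]
    D <- params$delays[[l - 1]]
    for (j in fired) {
      out[j] <- linearized_dtdv(t_pre, W[, j], D[, j], t_l[j], config, sg)
    }
  }
  out
}

#' Output-layer error terms
#'
#' `delta_k = dt/dV * (t_k_actual - t_k_desired)` for every output neuron;
#' silent output neurons get exactly 0 (their learning pressure comes from
#' the silent-neuron policy, not from a spike-time gradient).
#'
#' @param record An `srm_record` from [simulate_forward()].
#' @param desired Desired output spike times (ms).
#' @param params A [network_params()].
#' @param config A [neuron_config()].
#' @param sg A [surrogate_config()].
#' @return Numeric vector `delta` over output neurons.
#' @export
output_deltas <- function(record, desired, params, config,
                          sg = surrogate_config()) {
  t_o <- output_times(record)
  if (length(desired) != length(t_o)) {
    abort("`desired` length must match the output layer size.")
  }
  L <- length(record$times)
  dtdv <- layer_dtdv(record, params, L, config, sg)
  err <- ifelse(is.na(t_o), 0, t_o - desired)
  dtdv * err
}

#' Hidden-layer error terms
#'
#' Backpropagates upstream error terms through spike times:
#' `delta_j = dt_j/dV * sum_k delta_k * w_jk * xi_jk`, where
#' `xi_jk = psp_delay_deriv(t_k - t_j - d_jk)` couples neuron `j`'s spike
#' time to downstream neuron `k`'s potential at its crossing.  Silent
#' neurons (in either layer) contribute — and receive — exactly 0.
#'
#' @param record An `srm_record`.
#' @param params A [network_params()].
#' @param upstream_deltas `delta` vector of layer `l + 1`.
#' @param l Hidden layer index (2 .. number of layers - 1).
#' @param config A [neuron_config()].
#' @param sg A [surrogate_config()].
#' @return Numeric vector `delta` over layer `l` neurons.
#' @export
hidden_deltas <- function(record, params, upstream_deltas, l, config,
                          sg = surrogate_config()) {
  L <- length(record$times)
  if (l < 2 || l >= L) {
    abort(sprintf("`l` must be a hidden layer index in [2, %d].", L - 1))
  }
  t_j <- record$times[[l]]
  t_k <- record$times[[l + 1]]
  W <- params$weights[[l]]    # n_j x n_k
  D <- params$delays[[l]]
  # offsets t_k - t_j - d_jk; NA rows/cols (silent) yield xi = 0
  arg <- outer(-t_j, t_k, "+") - D
  XI <- psp_delay_deriv(arg, config)
  upstream <- ifelse(is.na(t_k), 0, upstream_deltas)
  back <- drop((W * XI) %*% upstream)
  dtdv <- layer_dtdv(record, params, l, config, sg)
  dtdv * back
}

#' Weight and delay gradients of the temporal loss
#'
#' Assembles the full gradient set from per-layer error terms:
#' `dE/dw_ij = delta_j * K(t_j - t_i - d_ij)` and
#' `dE/dd_ij = delta_j * w_ij * xi(t_j - t_i - d_ij)`.
#' Entries touching a silent pre- or postsynaptic neuron are exactly 0, as
#' is any kernel evaluated at a non-positive offset (causality).
#'
#' @param record An `srm_record`.
#' @param params A [network_params()].
#' @param deltas List of `delta` vectors, one per non-input layer (as
#'   produced by [output_deltas()] and [hidden_deltas()]).
#' @param config A [neuron_config()].
#' @return An object of class `gradient_set`: list with `dE_dw`, `dE_dd`
#'   (lists of matrices congruent with `params`) and the `deltas`.
#' @export
srm_gradients <- function(record, params, deltas, config) {
  L <- length(record$times)
  dE_dw <- vector("list", L - 1)
  dE_dd <- vector("list", L - 1)
  for (l in 2:L) {
    t_pre <- record$times[[l - 1]]
    t_post <- record$times[[l]]
    D <- params$delays[[l - 1]]
    W <- params$weights[[l - 1]]
    arg <- outer(-t_pre, t_post, "+") - D   # t_post - t_pre - d
    Kmat <- psp_kernel(arg, config)
    XI <- psp_delay_deriv(arg, config)
    d_l <- ifelse(is.na(t_post), 0, deltas[[l - 1]])
    d_row <- matrix(d_l, nrow(W), ncol(W), byrow = TRUE)
    dE_dw[[l - 1]] <- Kmat * d_row
    dE_dd[[l - 1]] <- W * XI * d_row
  }
  structure(list(dE_dw = dE_dw, dE_dd = dE_dd, deltas = deltas),
            class = "gradient_set")
}

#' Full backward pass
#'
#' Convenience wrapper: output error terms, hidden error terms down the
#' stack, then the gradient set.
#'
#' @inheritParams output_deltas
#' @return A `gradient_set` (see [srm_gradients()]).
#' @export
backprop <- function(record, desired, params, config,
                     sg = surrogate_config()) {
  L <- length(record$times)
  deltas <- vector("list", L - 1)
  deltas[[L - 1]] <- output_deltas(record, desired, params, config, sg)
  if (L > 2) {
    for (l in (L - 1):2) {
      deltas[[l - 1]] <- hidden_deltas(record, params, deltas[[l]], l,
                                       config, sg)
    }
  }
  srm_gradients(record, params, deltas, config)
}

#' One online training step
#'
#' One forward pass, one backward pass, one in-place parameter update:
#' `w <- w - eta_w * dE/dw`, `d <- d - eta_d * dE/dd`, with delays clamped
#' to `[0, d_max]` after the update and the delay update skipped entirely
#' under `weight_only`.  The silent-neuron policy is applied around the
#' update: silent output neurons enter the loss with surrogate time
#' `t_end + silent_margin`, and every non-input neuron that stayed silent
#' has all incoming weights boosted by `silent_boost` so it can re-enter
#' the responsive regime on later samples.
#'
#' @param input_times Input spike-time vector (ms, `NA` = silent).
#' @param desired_times Desired output spike times (ms).
#' @param params A [network_params()].
#' @param config A [neuron_config()].
#' @param sg A [surrogate_config()].
#' @param tc A [train_config()].
#' @param grid A [time_grid()].
#' @param interpolate Passed to [simulate_forward()].
#' @return List with `params` (updated), `loss` (pre-update), and the
#'   forward `record`.
#' @export
fit_one_sample <- function(input_times, desired_times, params,
                           config = neuron_config(),
                           sg = surrogate_config(),
                           tc = train_config(),
                           grid = time_grid(), interpolate = FALSE) {
  record <- simulate_forward(input_times, params, config, grid, interpolate)
  actual <- output_times(record)
  filled <- ifelse(is.na(actual), grid$t_end + tc$silent_margin, actual)
  loss <- temporal_mse(filled, desired_times)

  grads <- backprop(record, desired_times, params, config, sg)
  L <- length(params$layer_sizes)
  for (l in seq_len(L - 1)) {
    step_w <- tc$eta_w * grads$dE_dw[[l]]
    if (any(!is.finite(step_w))) {
      abort(sprintf("non-finite weight update in layer %d.", l + 1))
    }
    params$weights[[l]] <- params$weights[[l]] - step_w
    if (!tc$weight_only && tc$eta_d > 0) {
      step_d <- tc$eta_d * grads$dE_dd[[l]]
      if (any(!is.finite(step_d))) {
        abort(sprintf("non-finite delay update in layer %d.", l + 1))
      }
      params$delays[[l]] <- pmin(pmax(params$delays[[l]] - step_d, 0),
                                 config$d_max)
    }
    # silent-neuron boost: every incoming weight of a non-firing neuron
    # that is actually required to fire.  Hidden neurons always carry
    # downstream demand; a silent output neuron is only revived when its
    # desired time asks for a spike strictly inside the window — a
    # non-target trained toward the window edge is silent by design.
    if (tc$silent_boost > 0 && (tc$eta_w > 0 || tc$eta_d > 0)) {
      silent_j <- which(is.na(record$times[[l + 1]]))
      if (l + 1 == L) {
        silent_j <- silent_j[desired_times[silent_j] < grid$t_end]
      }
      if (length(silent_j)) {
        params$weights[[l]][, silent_j] <-
          params$weights[[l]][, silent_j] + tc$silent_boost
      }
    }
  }
  list(params = params, loss = loss, record = record)
}
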