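#' Spike Response Model neuron configuration
#'
#' Bundles the membrane constants of the SRM neuron used throughout the
#' package: the membrane time constant `tau_m`, the synaptic time constant
#' `tau_s`, the firing threshold `theta`, and the delay bound `d_max`.
#' The derived quantities `beta = tau_m / tau_s` and the normalization
#' constant `v_norm` (which scales the postsynaptic-potential kernel so its
#' maximum equals 1) are computed on construction.
#'
#' `tau_m` must strictly exceed `tau_s`: the kernel is a difference of
#' exponentials and its normalization is only defined for `beta > 1`.
#'
#' @param tau_m Membrane time constant in ms (> 0).
#' @param tau_s Synaptic time constant in ms (> 0, < `tau_m`).
#' @param theta Firing threshold in potential units (> 0).
#' @param d_max Upper bound for synaptic delays in ms (>= 0).
#'
#' @return An object of class `neuron_config`: a list with fields `tau_m`,
#'   `tau_s`, `theta`, `d_max`, `beta`, `v_norm`.
#'
#' @examples
#' cfg <- neuron_config(tau_m = 4, tau_s = 2)
#' cfg$v_norm # 4: with beta = 2 the normalization is beta^2 / (beta - 1)
#' @export
neuron_config <- function(tau_m = 10, tau_s = 2.5, theta = 1, d_max = 10) {
  stopifnot(
    is.numeric(tau_m), length(tau_m) == 1, is.finite(tau_m), tau_m > 0,
    is.numeric(tau_s), length(tau_s) == 1, is.finite(tau_s), tau_s > 0,
    is.numeric(theta), length(theta) == 1, is.finite(theta), theta > 0,
    is.numeric(d_max), length(d_max) == 1, is.finite(d_max), d_max >= 0
  )
  structure(
    list(
      tau_m = tau_m, tau_s = tau_s, theta = theta, d_max = d_max,
      beta = tau_m / tau_s, v_norm = psp_vnorm(tau_m, tau_s)
    ),
    class = "neuron_config"
  )
}

#' @export
print.neuron_config <- function(x, ...) {
  cat(sprintf(
    "<neuron_config> tau_m = %g ms, tau_s = %g ms, theta = %g, d_max = %g ms\n",
    x$tau_m, x$tau_s, x$theta, x$d_max
  ))
  cat(sprintf("  beta = %g, v_norm = %g (kernel peak scaled to 1)\n",
              x$beta, x$v_norm))
  invisible(x)
}

#' PSP normalization constant
#'
#' Computes the constant that scales the double-exponential postsynaptic
#' potential kernel to a peak value of 1:
#' `v_norm = beta^(beta / (beta - 1)) / (beta - 1)` with
#' `beta = tau_m / tau_s`.
#'
#' @inheritParams neuron_config
#' @return A positive scalar.
#' @examples
#' psp_vnorm(4, 2)           # 4
#' psp_vnorm(8, 2)           # 4^(4/3)/3
#' @export
psp_vnorm <- function(tau_m, tau_s) {
  if (!is.numeric(tau_m) || !is.numeric(tau_s) ||
      !is.finite(tau_m) || !is.finite(tau_s) || tau_s <= 0 || tau_m <= tau_s) {
    abort("`tau_m` must strictly exceed `tau_s` > 0 (beta > 1) for the PSP normalization to be defined.")
  }
  beta <- tau_m / tau_s
  beta^(beta / (beta - 1)) / (beta - 1)
}

#' Postsynaptic potential kernel
#'
#' The causal double-exponential kernel
#' `K(x) = v_norm * (exp(-x / tau_m) - exp(-x / tau_s))` for `x > 0` and
#' exactly 0 for `x <= 0`.  With `v_norm` from [psp_vnorm()] the kernel's
#' maximum over positive offsets is exactly 1, attained at
#' [psp_peak_time()].
#'
#' `NA` offsets (a silent presynaptic neuron) evaluate to 0: a neuron that
#' never fired contributes no potential.
#'
#' @param x Time offset(s) in ms; vector or matrix.
#' @param config A [neuron_config()].
#' @return Potential value(s), same shape as `x`.
#' @export
psp_kernel <- function(x, config) {
  out <- numeric(length(x))
  dim(out) <- dim(x)
  p <- which(x > 0)
  if (length(p)) {
    out[p] <- config$v_norm * (exp(-x[p] / config$tau_m) - exp(-x[p] / config$tau_s))
  }
  out
}

#' Time derivative of the PSP kernel
#'
#' `dK/dx = v_norm * (-exp(-x/tau_m)/tau_m + exp(-x/tau_s)/tau_s)` for
#' `x > 0`, 0 for `x <= 0` (and for `NA`, i.e. silent inputs).  Positive on
#' the kernel's rising edge, zero at the peak, negative on the decay.
#'
#' @inheritParams psp_kernel
#' @return Potential-per-ms value(s), same shape as `x`.
#' @export
psp_kernel_deriv <- function(x, config) {
  out <- numeric(length(x))
  dim(out) <- dim(x)
  p <- which(x > 0)
  if (length(p)) {
    out[p] <- config$v_norm *
      (-exp(-x[p] / config$tau_m) / config$tau_m +
         exp(-x[p] / config$tau_s) / config$tau_s)
  }
  out
}

#' Derivative of the PSP kernel with respect to the synaptic delay
#'
#' For a synapse evaluated at offset `delta = t_post - t_pre - d`, the
#' derivative of `K(delta)` with respect to the delay `d` is `-dK/dx`:
#' `v_norm * (exp(-delta/tau_m)/tau_m - exp(-delta/tau_s)/tau_s)` for
#' `delta > 0`, 0 otherwise.  This is the per-synapse factor in the delay
#' gradient.
#'
#' @param delta Offset(s) `t_post - t_pre - d` in ms; vector or matrix.
#' @param config A [neuron_config()].
#' @return Value(s), same shape as `delta`; identically
#'   `-psp_kernel_deriv(delta, config)`.
#' @export
psp_delay_deriv <- function(delta, config) {
  -psp_kernel_deriv(delta, config)
}

#' Time offset at which the PSP kernel peaks
#'
#' The kernel maximum sits at
#' `x* = tau_m * tau_s / (tau_m - tau_s) * log(tau_m / tau_s)`.
#'
#' @param config A [neuron_config()].
#' @return Peak offset in ms.
#' @export
psp_peak_time <- function(config) {
  config$tau_m * config$tau_s / (config$tau_m - config$tau_s) * log(config$beta)
}
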