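test_that("temporal MSE evaluates the squared spike-time error", {
  expect_identical(temporal_mse(c(3, 5), c(3, 5)), 0)
  expect_equal(temporal_mse(c(3, 5), c(2, 5)), 0.5)
  expect_equal(temporal_mse(c(2, 5), c(3, 5)), temporal_mse(c(3, 5), c(2, 5)))
  expect_error(temporal_mse(c(NA, 5), c(2, 5)), "silent")
  expect_error(temporal_mse(c(1, 2), c(1, 2, 3)))
})

test_that("capped-Gaussian surrogate matches its two branches and is continuous", {
  cfg <- neuron_config()
  sg <- surrogate_config(m = 0.3, tau_sg = 1)
  # cap branch at V = theta
  expect_equal(surrogate_dtdv(cfg$theta, cfg, sg), exp(-0.18),
               tolerance = 1e-12)
  # Gaussian branch
  sg2 <- surrogate_config(m = 0.5, tau_sg = 1)
  expect_equal(surrogate_dtdv(cfg$theta + 1, cfg, sg2), exp(-2),
               tolerance = 1e-12)
  # continuity at the branch point |V - theta| = m
  for (m in c(0.1, 0.3, 0.5, 0.9)) {
    for (tau_sg in c(0.5, 1, 2)) {
      sgi <- surrogate_config(m = m, tau_sg = tau_sg)
      at_m <- surrogate_dtdv(cfg$theta + m, cfg, sgi)
      just_out <- surrogate_dtdv(cfg$theta + m + 1e-9, cfg, sgi)
      expect_equal(at_m, exp(-2 * m^2 / tau_sg), tolerance = 1e-12)
      expect_equal(just_out, at_m, tolerance = 1e-6)
    }
  }
})

test_that("surrogate output is positive and bounded by its cap", {
  cfg <- neuron_config()
  vs <- seq(-5, 10, by = 0.01)
  for (m in c(0.2, 0.5)) {
    sg <- surrogate_config(m = m, tau_sg = 1.5)
    out <- surrogate_dtdv(vs, cfg, sg)
    cap <- exp(-2 * m^2 / sg$tau_sg)
    expect_true(all(out > 0))
    expect_true(all(out <= cap + 1e-15))
    # the cap is attained exactly on |V - theta| <= m
    at_cap <- abs(vs - cfg$theta) <= m
    expect_equal(out == cap, at_cap)
  }
})

test_that("linearized dt/dV is negative at an upward crossing and flags degeneracy", {
  cfg <- neuron_config()
  p <- chain_net(w = 2, d = 0)
  rec <- simulate_forward(0, p, cfg, time_grid())
  t_o <- output_times(rec)
  val <- linearized_dtdv(0, 2, 0, t_o, cfg)
  expect_lt(val, 0)
  # near-zero slope is reported, not inverted
  expect_error(
    linearized_dtdv(0, 1e-12, 0, 5, cfg),
    class = "delayprop_degenerate_crossing"
  )
})

test_that("linearized dt/dV agrees with a perturbation oracle on the trace", {
  # shifting the potential up by dv moves the crossing by about dv * dt/dV
  cfg <- neuron_config()
  grid <- fine_grid
  w <- 2; d <- 0
  p <- chain_net(w = w, d = d)
  rec <- simulate_forward(0, p, cfg, grid, interpolate = TRUE)
  t0 <- output_times(rec)
  dtdv <- linearized_dtdv(0, w, d, t0, cfg)
  dv <- 1e-4
  # raising the threshold by dv is the same as lowering V by dv
  cfg_hi <- neuron_config(theta = cfg$theta + dv)
  t1 <- output_times(simulate_forward(0, p, cfg_hi, grid, interpolate = TRUE))
  expect_equal((t1 - t0) / dv, -dtdv, tolerance = 1e-2)
})

test_that("output deltas vanish at the target and scale with the error", {
  net <- small_net()
  rec <- simulate_forward(net$input, net$params, default_cfg, time_grid())
  t_o <- output_times(rec)
  expect_true(all(!is.na(t_o)))
  sg <- surrogate_config()
  d0 <- output_deltas(rec, t_o, net$params, default_cfg, sg)
  expect_equal(d0, c(0, 0))
  d1 <- output_deltas(rec, t_o - 1, net$params, default_cfg, sg)
  d2 <- output_deltas(rec, t_o - 2, net$params, default_cfg, sg)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("deltas on a 1-1-1 chain match the hand-expanded product form", {
  cfg <- neuron_config()
  sg <- surrogate_config(mode = "linearized")
  p <- chain_net(w = 2, d = 0.5, sizes = c(1, 1, 1))
  rec <- simulate_forward(0, p, cfg, time_grid())
  t_h <- rec$times[[2]]
  t_o <- rec$times[[3]]
  expect_false(is.na(t_o))
  t_d <- t_o - 2

  # hand expansion with the same chain rule, written out term by term
  dtdv_o <- -1 / (2 * psp_kernel_deriv(t_o - t_h - 0.5, cfg))
  delta_o_hand <- dtdv_o * (t_o - t_d)
  xi_oh <- psp_delay_deriv(t_o - t_h - 0.5, cfg)
  dtdv_h <- -1 / (2 * psp_kernel_deriv(t_h - 0 - 0.5, cfg))
  delta_h_hand <- dtdv_h * delta_o_hand * 2 * xi_oh

  delta_o <- output_deltas(rec, t_d, p, cfg, sg)
  delta_h <- hidden_deltas(rec, p, delta_o, 2, cfg, sg)
  expect_equal(delta_o, delta_o_hand, tolerance = 1e-12)
  expect_equal(delta_h, delta_h_hand, tolerance = 1e-12)

  # zero upstream error backpropagates to zero
  expect_equal(hidden_deltas(rec, p, 0, 2, cfg, sg), 0)
})

test_that("gradient entries touching silent neurons or acausal offsets are zero", {
  cfg <- neuron_config()
  p <- init_network(c(3, 4, 2), cfg, seed = 2)
  # silence input 2 entirely
  rec <- simulate_forward(c(0, NA, 5), p, cfg, time_grid())
  grads <- backprop(rec, c(10, 15), p, cfg, surrogate_config())
  expect_equal(grads$dE_dw[[1]][2, ], rep(0, 4))
  expect_equal(grads$dE_dd[[1]][2, ], rep(0, 4))
  # acausal pair: presynaptic spike after the postsynaptic crossing
  t_h <- rec$times[[2]]
  t_o <- rec$times[[3]]
  for (i in seq_along(t_h)) {
    for (j in seq_along(t_o)) {
      if (!is.na(t_h[i]) && !is.na(t_o[j]) &&
          t_o[j] - t_h[i] - p$delays[[2]][i, j] <= 0) {
        expect_identical(grads$dE_dw[[2]][i, j], 0)
      }
    }
  }
})

test_that("exact output times are a fixed point: zero gradients, no update", {
  net <- small_net()
  rec <- simulate_forward(net$input, net$params, default_cfg, time_grid())
  t_o <- output_times(rec)
  grads <- backprop(rec, t_o, net$params, default_cfg, surrogate_config())
  for (l in 1:2) {
    expect_true(all(grads$dE_dw[[l]] == 0))
    expect_true(all(grads$dE_dd[[l]] == 0))
  }
  res <- fit_one_sample(net$input, t_o, net$params, default_cfg,
                        surrogate_config(),
                        train_config(eta_w = 0.05, eta_d = 0.1,
                                     silent_boost = 0.05))
  expect_equal(res$params$weights, net$params$weights)
  expect_equal(res$params$delays, net$params$delays)
  expect_identical(res$loss, 0)
})

test_that("zero learning rates leave parameters untouched but report the loss", {
  net <- small_net()
  res <- fit_one_sample(net$input, net$desired, net$params, default_cfg,
                        surrogate_config(),
                        train_config(eta_w = 0, eta_d = 0))
  expect_identical(res$params$weights, net$params$weights)
  expect_identical(res$params$delays, net$params$delays)
  expect_gt(res$loss, 0)
})

test_that("delays stay clamped to [0, d_max] after updates", {
  cfg <- neuron_config(d_max = 10)
  p <- chain_net(w = 2, d = 0.05)
  # desired far in the future pushes the delay up; desired at 0 pushes down
  for (target in c(0.1, 24)) {
    q <- p
    for (i in 1:50) {
      res <- fit_one_sample(0, target, q, cfg, surrogate_config(),
                            train_config(eta_w = 0, eta_d = 2))
      q <- res$params
      expect_gte(q$delays[[1]][1, 1], 0)
      expect_lte(q$delays[[1]][1, 1], cfg$d_max)
    }
  }
})

test_that("weight-only mode never changes the delays", {
  net <- small_net()
  tc <- train_config(eta_w = 0.05, eta_d = 0.5, weight_only = TRUE)
  expect_identical(tc$eta_d, 0)
  res <- fit_one_sample(net$input, net$desired, net$params, default_cfg,
                        surrogate_config(), tc)
  expect_identical(res$params$delays, net$params$delays)
  expect_false(identical(res$params$weights, net$params$weights))
})

test_that("delay-only updates drive a single synapse toward the desired time", {
  cfg <- neuron_config()
  p <- chain_net(w = 2, d = 0)
  t0 <- output_times(simulate_forward(0, p, cfg, time_grid()))
  target <- t0 + 3  # reachable purely by increasing the delay
  losses <- numeric(40)
  q <- p
  for (i in seq_along(losses)) {
    res <- fit_one_sample(0, target, q, cfg, surrogate_config(),
                          train_config(eta_w = 0, eta_d = 0.3))
    q <- res$params
    losses[i] <- res$loss
  }
  expect_lt(losses[40], losses[1] / 10)
  t_end <- output_times(simulate_forward(0, q, cfg, time_grid()))
  expect_lt(abs(t_end - target), abs(t0 - target))
})

test_that("silent non-input neurons receive the incoming-weight boost", {
  cfg <- neuron_config(theta = 100)  # nothing can fire
  p <- init_network(c(2, 3, 2), cfg, seed = 1, w_scale = 0.01)
  tc <- train_config(eta_w = 0.05, eta_d = 0.1, silent_boost = 0.25)
  res <- fit_one_sample(c(0, 1), c(10, 15), p, cfg, surrogate_config(), tc)
  expect_equal(res$params$weights[[1]], p$weights[[1]] + 0.25)
  expect_equal(res$params$weights[[2]], p$weights[[2]] + 0.25)
})

test_that("silent outputs targeted at the window edge are not boosted", {
  cfg <- neuron_config(theta = 100)
  p <- init_network(c(2, 3, 2), cfg, seed = 1, w_scale = 0.01)
  tc <- train_config(eta_w = 0.05, eta_d = 0.1, silent_boost = 0.25)
  grid <- time_grid()
  # output 1 demanded inside the window, output 2 "kept silent" at t_end
  res <- fit_one_sample(c(0, 1), c(10, grid$t_end), p, cfg,
                        surrogate_config(), tc, grid)
  expect_equal(res$params$weights[[2]][, 1], p$weights[[2]][, 1] + 0.25)
  expect_equal(res$params$weights[[2]][, 2], p$weights[[2]][, 2])
  # hidden neurons always carry demand
  expect_equal(res$params$weights[[1]], p$weights[[1]] + 0.25)
})

test_that("analytic gradients match finite differences on a small net", {
  net <- small_net(seed = 11)
  report <- gradcheck(net$params, net$input, net$desired,
                      default_cfg, grid = fine_grid)
  expect_true(report$comparable)
  expect_gte(report$fraction_within_tol, 0.95)
  # every parameter block of the architecture is reported
  expect_setequal(paste(report$blocks$layer, report$blocks$param),
                  c("2 w", "2 d", "3 w", "3 d"))
})

test_that("gradcheck agrees trivially on an all-silent network", {
  p <- network_params(c(2, 2), list(matrix(0, 2, 2)),
                      list(matrix(1, 2, 2)), default_cfg)
  report <- gradcheck(p, c(0, 1), c(10, 12), default_cfg, grid = fine_grid)
  expect_true(report$comparable)
  expect_equal(report$fraction_within_tol, 1)
  expect_equal(sum(report$blocks$max_rel_err), 0)
})

test_that("gradcheck declares surrogate mode non-comparable", {
  net <- small_net()
  report <- gradcheck(net$params, net$input, net$desired, default_cfg,
                      sg = surrogate_config(mode = "capped_gaussian"),
                      grid = fine_grid)
  expect_false(report$comparable)
  expect_true(is.na(report$fraction_within_tol))
})
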