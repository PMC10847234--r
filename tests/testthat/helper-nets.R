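# Shared fixtures: small seeded networks and samples built in code.

default_cfg <- neuron_config()

# A 3-4-2 network with inputs and targets that produce spikes everywhere
# under the default constants (verified in the simulation tests).
small_net <- function(seed = 2) {
  list(
    params = init_network(c(3, 4, 2), default_cfg, seed = seed),
    input = c(0, 2, 5),
    desired = c(12, 18)
  )
}

# A 1-1 chain driven hard enough to fire: single synapse, adjustable delay.
chain_net <- function(w = 2, d = 0, sizes = c(1, 1)) {
  n <- length(sizes)
  network_params(
    sizes,
    weights = lapply(seq_len(n - 1), function(l) matrix(w, 1, 1)),
    delays = lapply(seq_len(n - 1), function(l) matrix(d, 1, 1)),
    default_cfg
  )
}

fine_grid <- time_grid(t_end = 25, dt = 0.01)
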