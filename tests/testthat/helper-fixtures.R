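# Shared fixtures: small parameter sets and substrates used across tests.

# plain scanner with no pausing, isomerization or detachment
free_runner <- function(v = 300) {
  enzyme_params("runner", v_pre = v, v_post = 0.75 * v)
}

# enzyme that always pauses at Chi for an (almost) fixed duration d and
# always commits: gamma with a large shape concentrates the dwell at d
fixed_pauser <- function(d, v = 300, p_commit = 1, shape = 400) {
  enzyme_params("pauser", v_pre = v, v_post = 0.75 * v, p_pause = 1,
                pause_shape = shape, pause_scale = d / shape,
                p_commit = p_commit)
}

chi_free_substrate <- function(L = 6000) substrate_spec(L)

one_chi_substrate <- function(L = 6000, chi = 4588)
  substrate_spec(L, chi_positions = chi)

quiet_trace_cfg <- function(noise = 0) trace_config(noise_sd_bp = noise)
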