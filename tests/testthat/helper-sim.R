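# Shared fixture builders. "quiet" configs strip noise, autofluorescence,
# spillover and doublets so generator identities are exact.

quiet_cfg <- function(seed = 1, n_cells = 200, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed, n_cells = n_cells, noise_cv = 0, autofl_mu = -Inf,
    bg_mu = -Inf, doublet_fraction = 0, p_transfected = 1,
    mixing = spillover_matrix(), quantize = FALSE
  )
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# single-colour / vector control configs built on an arbitrary base config
control_cfgs <- function(base) {
  list(
    vector = modifyList_cfg(base, list(p_transfected = 0)),
    donor = modifyList_cfg(base, list(
      acceptor_rate = 0, marker_rate = 0,
      dimer_fraction_vehicle = 0, dimer_fraction_max = 0
    )),
    acceptor = modifyList_cfg(base, list(
      donor_rate = 0, marker_rate = 0,
      dimer_fraction_vehicle = 0, dimer_fraction_max = 0
    ))
  )
}

modifyList_cfg <- function(cfg, changes) {
  cfg[names(changes)] <- changes
  fretquant:::validate_sim_config(cfg)
}

image_fields_for <- function(cfg, n_fields = 3) {
  lapply(simulate_image_fields(cfg, n_fields), `[[`, "field")
}

# drop attributes (e.g. the recorded correction variant) for raw comparisons
unclass_attr <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
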