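# Parameter set with every reaction switched off except the overrides,
# for closed-form single-reaction checks.
decay_only_params <- function(...) {
  zero <- list(k1 = 0, k2 = 0, k3 = 0, Gc = 0, k4 = 0, k5 = 0, k6 = 0,
               k9 = 0, k7 = 0, k10 = 0, k8 = 0, k11 = 0, k12 = 0,
               k13 = 0, k14 = 0, k15 = 0, k16 = 0, d = 0)
  over <- list(...)
  zero[names(over)] <- over
  do.call(eco_params, zero)
}

# Random nonnegative state spanning the magnitudes the model visits.
random_state <- function() {
  v <- 10^stats::runif(9, -3, 9) * stats::rbinom(9, 1, 0.8)
  eco_state(c1 = v[1], c2 = v[2], AHL1 = v[3], AHL2 = v[4], C1 = v[5],
            C2 = v[6], preRes1 = v[7], Res1 = v[8], Res2 = v[9])
}

# Independent drift oracle: per-reaction accumulation loop over the
# stoichiometry, never calling eco_drift.
accumulate_drift <- function(state, params) {
  a <- eco_propensities(state, params)
  S <- eco_stoichiometry()
  out <- stats::setNames(numeric(9), eco_species())
  for (j in 1:18) out <- out + S[, j] * a[[j]]
  out
}
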