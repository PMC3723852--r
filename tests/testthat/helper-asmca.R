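# shared fixtures: default parameters and the drug-free resting equilibrium
default_params <- asm_parameters()
resting_eq <- find_equilibrium(default_params)

# a seeded generator of valid random states
random_state <- function() {
  asm_state(c = runif(1, 0, 1.5), c_s = runif(1, 1, 300),
            phi = runif(1), s = runif(1), p_eff = runif(1, 0, 2),
            ryr_leak = runif(1, 0, 19), serca_eff = runif(1))
}

random_targets <- function() {
  drug_targets(agonist = runif(1, 0, 2), ryacaf = runif(1) > 0.5,
               cpa = runif(1) > 0.5, external_ca = runif(1) > 0.5)
}
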