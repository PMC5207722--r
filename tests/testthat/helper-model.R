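# shared objects for the test-suite; everything is generated in code
kin_default <- sigb_kinetics()
op_default <- sigb_operon()

# unstressed steady state, reused across files
ss_unstressed <- steady_state(kin_default, op_default, 0)

random_state <- function(seed) {
  with_seed <- function(s, expr) {
    set.seed(s); expr
  }
  with_seed(seed, sigb_state(setNames(runif(9, 0, 2), sigb_species())))
}
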