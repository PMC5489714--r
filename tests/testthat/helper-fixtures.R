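# Shared fixture helpers: coupling problems on the built-in toys.

toy_problem <- function(name, product = "EX_P", level = 0.5) {
  fx <- make_toy(name)
  build_coupling_problem(fx$net, fx$config, product, level)
}

# residual of the mass balance and extra rows for a witness flux
flux_residuals <- function(net, witness) {
  as.numeric(net$S %*% witness[net$rxns$id])
}
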