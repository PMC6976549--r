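{
  "rates": { "type": "constant", "lambda": 0.8, "mu": 0.2 },
  "tree": { "newick": "inst/extdata/example_tree.nwk" },
  "sampling": { "scheme": "n", "m_p": 1 },
  "numerics": { "ode_tol": 1e-10, "seed": 1 }
}
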