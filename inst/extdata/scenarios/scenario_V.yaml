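id: V
rho_genetic: -0.5
weights: [0.7, 1.3]
trait1:
  var_gca: 1
  var_gca_x_loc: 0.91
  var_sca: 0.33
  var_sca_x_loc: 0.52
  var_error: 4.28
trait2:
  var_gca: 1
  var_gca_x_loc: 0.91
  var_sca: 0.33
  var_sca_x_loc: 0.52
  var_error: 4.28

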