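id: wheat_goal1
rho_genetic: -0.40
weights: [1, 0.12]
trait1:
  var_gca: 5.7
  var_gca_x_loc: 5.19
  var_sca: 1.88
  var_sca_x_loc: 2.94
  var_error: 24.37
trait2:
  var_gca: 0.08
  var_gca_x_loc: 0.02
  var_sca: 0.01
  var_sca_x_loc: 0
  var_error: 0.09

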