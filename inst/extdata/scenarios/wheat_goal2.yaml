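id: wheat_goal2
rho_genetic: -0.18
weights: [1, 0.12]
trait1:
  var_gca: 5.7
  var_gca_x_loc: 5.19
  var_sca: 1.88
  var_sca_x_loc: 2.94
  var_error: 24.37
trait2:
  var_gca: 23.54
  var_gca_x_loc: 1.58
  var_sca: 0.64
  var_sca_x_loc: 0.25
  var_error: 6.9

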