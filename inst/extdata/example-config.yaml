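# Example run configuration. Unset keys fall back to the model defaults
# (0.05 mm mesh, a = 0.0375, b = 3 um/s, N = 10, 35 days, 8 um load,
# mu = 0.3, stock material table).
implant: D
element_size: 0.1
days: 35
load:
  top_displacement: 8
interface:
  mode: coulomb_penalty
  friction_coefficient: 0.3
diffusivity: calibrate
output_dir: healing-out
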