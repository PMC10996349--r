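# Reference isotropic DC conductivities (S/m) for all model scales.
# Head-scale tissues, capillary-voxel compartments, and BBB ultrastructure
# channels. Values may be overridden by supplying a modified copy of this
# file to conductivity_table().
version: 1
conductivities_S_per_m:
  scalp: 0.465
  fat: 0.025
  skull: 0.01
  csf: 0.8
  gray_matter: 0.276
  white_matter: 0.126
  electrode: 5.9e+7
  parenchyma: 0.276
  lumen: 0.7
  astrocytic_channel: 1.5
  endothelial_cleft_channel: 1.5
  basement_membrane: 0.3
  glycocalyx: 0.3
  insulating_membrane: 1.0e-5
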