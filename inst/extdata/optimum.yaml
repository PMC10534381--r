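# Reference (optimum) device configuration: four electrodes at +-2.0 V,
# 40 um channel width, buffer inlet 850 um/s, cell inlet 134 um/s.
geometry:
  channel_width_um: 40
  n_electrodes: 4
drive:
  amplitude_V: 2.0
flow:
  v_blood_um_s: 134
  v_buffer_um_s: 850
mesh_level: fine
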