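{
  "radius_um": 50,
  "height_um": 20,
  "pi_mode": "approx3",
  "actin_uM": 3,
  "arp_uM": 0.09,
  "cp_uM": 0.015,
  "tail_subunit_fraction": 0.5,
  "max_tail_length_um": 60,
  "tail_cross_section_um2": 12,
  "mean_comet_length_um": 63,
  "measured_tail_fraction": 0.57
}
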