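{
  "weights": {
    "gauss1": -0.035579,
    "gauss2": -0.005156,
    "repulsion": 0.840245,
    "hydrophobic": -0.035069,
    "hbond": -0.587439
  },
  "radii": {"C": 1.9, "N": 1.8, "O": 1.7, "S": 2.0, "P": 2.1,
            "F": 1.5, "Cl": 1.8, "Br": 2.0, "I": 2.2},
  "gauss1_width": 0.5, "gauss2_offset": 3.0, "gauss2_width": 2.0,
  "hydrophobic_good": 0.5, "hydrophobic_bad": 1.5,
  "hbond_good": -0.7, "hbond_bad": 0.0,
  "cutoff": 8.0,
  "chpi_kernel": {"depth_fraction": 0.45, "breadth_factor": 1.3333333333333333,
                  "cutoff": 8.0},
  "chpi_params_h": {"e": 0.29, "r0": 3.58, "c": 0.85},
  "chpi_params_c": {"e": 0.26, "r0": 4.49, "c": 0.75}
}
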