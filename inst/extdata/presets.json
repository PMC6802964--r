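{
  "_comment": "Named parameter presets for the synthetic-data generators. Event kinetics are in molecules and seconds; cameras are in AU, um and seconds. Presets are data, not code.",
  "cameras": {
    "endocytosis": {
      "pixel_size": 0.1,
      "frame_interval": 0.05,
      "psf_sigma": 0.09,
      "single_fluorophore_intensity": 52.7333333,
      "read_noise_sd": 2,
      "shot_noise": true,
      "baseline_offset": 20
    },
    "single_molecule": {
      "pixel_size": 0.1,
      "frame_interval": 0.015873016,
      "psf_sigma": 0.09,
      "single_fluorophore_intensity": 263.6666667,
      "read_noise_sd": 2,
      "shot_noise": true,
      "baseline_offset": 20
    }
  },
  "calibration": {
    "excitation_scale": 0.2
  },
  "events": {
    "myo1": {
      "kinetics": {
        "rise_rate": 10.1833165,
        "peak_molecules": 45,
        "plateau_duration": 5.2358204,
        "fall_rate": 10.7522124,
        "scission_mode": "none"
      },
      "jitter": {
        "duration_cv": 0.199258,
        "peak_cv": 0.2,
        "start_sd": 0.5
      },
      "trace": {
        "pre_pad_s": 4,
        "post_pad_s": 5
      },
      "camera": "endocytosis"
    },
    "cam1": {
      "kinetics": {
        "rise_rate": 20.347661,
        "peak_molecules": 90,
        "plateau_duration": 1.950154,
        "fall_rate": 19.494311,
        "scission_mode": "none"
      },
      "jitter": {
        "duration_cv": 0.137792,
        "peak_cv": 0.2,
        "start_sd": 0.5
      },
      "trace": {
        "pre_pad_s": 4,
        "post_pad_s": 5
      },
      "camera": "endocytosis"
    },
    "myo1_S742A": {
      "kinetics": {
        "rise_rate": 10.1833165,
        "peak_molecules": 45,
        "plateau_duration": 3.6958204,
        "fall_rate": 10.7522124,
        "scission_mode": "none"
      },
      "jitter": {
        "duration_cv": 0.206298,
        "peak_cv": 0.2,
        "start_sd": 0.5
      },
      "trace": {
        "pre_pad_s": 4,
        "post_pad_s": 5
      },
      "camera": "endocytosis"
    },
    "cam2": {
      "kinetics": {
        "rise_rate": 5.0847458,
        "peak_molecules": 30,
        "plateau_duration": 2.0,
        "fall_rate": 10.0,
        "scission_mode": "abrupt",
        "scission_offset": 7.4
      },
      "jitter": {
        "duration_cv": 0.15,
        "peak_cv": 0.2,
        "start_sd": 0.5
      },
      "trace": {
        "pre_pad_s": 4,
        "post_pad_s": 6
      },
      "camera": "endocytosis"
    }
  },
  "two_color": {
    "myo1_cam1": {
      "channel_a": "myo1",
      "channel_b": "cam1",
      "offset_b": 0.0,
      "offset_b_sd": 0.3
    },
    "cam1_cam2": {
      "channel_a": "cam1",
      "channel_b": "cam2",
      "offset_b": 4.0,
      "offset_b_sd": 1.0
    }
  },
  "single_molecule": {
    "on_rate_density": 0.12,
    "off_rate": 7.8,
    "diffusion_coefficient": 0.03,
    "field_um": 12.8,
    "duration_s": 20,
    "camera": "single_molecule"
  },
  "titrations": {
    "cam1_titration": {
      "model": {
        "K1": 0.005,
        "K2": 0.68,
        "dF1": 23.025,
        "dF2": 23.025,
        "F0": 0.5,
        "reporter_total": 0.5
      },
      "ligand_uM": [
        0,
        0.1,
        0.2,
        0.35,
        0.5,
        0.7,
        1.0,
        1.4,
        2.0,
        3.0,
        5.0,
        10.0
      ],
      "noise_cv": 0.02
    },
    "cam2_titration": {
      "model": {
        "K1": 0.005,
        "K2": 1.1,
        "dF1": 9.49,
        "dF2": 22.15,
        "F0": 0.5,
        "reporter_total": 0.5
      },
      "ligand_uM": [
        0,
        0.1,
        0.2,
        0.35,
        0.5,
        0.7,
        1.0,
        1.4,
        2.0,
        3.0,
        5.0,
        10.0
      ],
      "noise_cv": 0.02
    },
    "pca_titration": {
      "model": {
        "pCa50": 5.87,
        "hill_n": 2.0,
        "Ymax": 46.05,
        "Ymin": 5.0
      },
      "pca": [
        4.5,
        4.93,
        5.36,
        5.79,
        6.21,
        6.64,
        7.07,
        7.5
      ],
      "noise_cv": 0.02
    }
  },
  "transients": {
    "ca_release": {
      "amplitudes": [
        0.4,
        0.4,
        0.4
      ],
      "rates": [
        137,
        12.9,
        2.0
      ],
      "offset": 0.05,
      "duration_s": 2.5,
      "dense_until_s": 0.12,
      "dense_dt_s": 0.0002,
      "sparse_dt_s": 0.005,
      "noise_sd": 0.004
    }
  },
  "forster": {
    "cypet_ypet_R0_nm": 5.301
  }
}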