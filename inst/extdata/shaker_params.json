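{
  "registry_version": "1.0",
  "units": {
    "amplitude": "1/ms at 0 mV",
    "charge": "elementary charge e",
    "gV_coeffs": "polynomial in V (mV), coefficients ordered degree 5 .. constant"
  },
  "models": {
    "zha_a": {
      "rates": {
        "alpha": {"amplitude": 0.1219, "charge": 0.6232},
        "beta":  {"amplitude": 0.0342, "charge": -0.0207}
      },
      "g0": 0.9717,
      "gV_coeffs": [-1.9823e-10, -1.4013e-9, 1.0424e-6, -1.8204e-5, -1.3480e-3, 0.07696],
      "extras": {}
    },
    "zha_d": {
      "rates": {
        "alpha":   {"amplitude": 2.1605, "charge": 1.9760},
        "beta":    {"amplitude": 0.0558, "charge": -0.0108},
        "gamma":   {"amplitude": 0.2642, "charge": 0.2080},
        "delta":   {"amplitude": 0.1103, "charge": -0.5311},
        "k_alpha": {"amplitude": 0.3505, "charge": 0.0138},
        "k_beta":  {"amplitude": 0.5253, "charge": -0.0203}
      },
      "g0": 1.3011,
      "gV_coeffs": [3.4123e-11, 6.8293e-10, -7.6790e-8, -1.0646e-8, -2.4698e-4, 0.04219],
      "extras": {"theta": 8.8660}
    },
    "bps": {
      "rates": {
        "alpha0": {"amplitude": 0.2761, "charge": 0.7467},
        "beta0":  {"amplitude": 1.2647, "charge": 0.2082},
        "alpha1": {"amplitude": 1.6095, "charge": 1.4896},
        "beta1":  {"amplitude": 0.1061, "charge": 0.1316},
        "alpha2": {"amplitude": 1.6809, "charge": 0.7891},
        "beta2":  {"amplitude": 0.2955, "charge": 2.1390},
        "alpha3": {"amplitude": 2.0483, "charge": 0.8988},
        "beta3":  {"amplitude": 0.8917, "charge": 0.3814},
        "alpha4": {"amplitude": 1.8216, "charge": 0.8376},
        "beta4":  {"amplitude": 0.3384, "charge": 0.2731}
      },
      "charge_note": "beta charges are the published positive-magnitude backward charges delta0..delta4; the model builder applies them with a negative sign",
      "g0": 0.9386,
      "gV_coeffs": [-1.2009e-11, -1.5047e-9, 7.1616e-8, 2.3240e-6, -3.2463e-4, 0.03649],
      "extras": {}
    },
    "ss": {
      "rates": {
        "alpha":   {"amplitude": 1.0859, "charge": 0.8288},
        "beta":    {"amplitude": 0.1415, "charge": -1.1574},
        "gamma":   {"amplitude": 2.2983, "charge": 0.0160},
        "delta":   {"amplitude": 1.3948, "charge": -0.1893},
        "epsilon": {"amplitude": 1.3100, "charge": 0.0639},
        "zeta":    {"amplitude": 0.5676, "charge": -0.0584},
        "alphaN1": {"amplitude": 4.5890, "charge": 0.0771},
        "betaN1":  {"amplitude": 0.1965, "charge": -0.0779},
        "alphaN":  {"amplitude": 1.9438, "charge": 0.6513},
        "betaN":   {"amplitude": 0.1431, "charge": -0.6569},
        "c":       {"amplitude": 0.0054, "charge": 0.0980},
        "d":       {"amplitude": 0.3853, "charge": 0},
        "c1":      {"amplitude": 0.1680, "charge": 0},
        "d1":      {"amplitude": 3.9279, "charge": -0.3678},
        "c2":      {"amplitude": 0.8233, "charge": 0},
        "d2":      {"amplitude": 9.9927, "charge": 0}
      },
      "g0": 0.9119,
      "gV_coeffs": [-2.9371e-11, -3.6458e-10, 9.4630e-8, -2.0430e-6, -1.0250e-4, 0.03638],
      "extras": {}
    }
  }
}
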