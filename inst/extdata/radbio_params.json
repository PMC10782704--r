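{
  "_comment": "Placeholder radiobiological parameters for methodological testing only -- NOT clinically validated. alpha/beta = 3 Gy for normal tissues; tumour set targets 1-year local control of brain metastases. Edit or replace for any real analysis.",
  "PTV": {
    "type": "tumor",
    "alpha_beta": 10,
    "tcd50": 24,
    "gamma50": 1.5,
    "a": -10
  },
  "brain_minus_GTV": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 60,
    "m": 0.15,
    "n": 0.25
  },
  "brainstem": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 65,
    "m": 0.14,
    "n": 0.16
  },
  "opt_chiasm": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 65,
    "m": 0.14,
    "n": 0.25
  },
  "opt_nerve_L": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 65,
    "m": 0.14,
    "n": 0.25
  },
  "opt_nerve_R": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 65,
    "m": 0.14,
    "n": 0.25
  },
  "lens_L": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 18,
    "m": 0.27,
    "n": 0.04
  },
  "lens_R": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 18,
    "m": 0.27,
    "n": 0.04
  },
  "spinal_cord": {
    "type": "oar",
    "alpha_beta": 3,
    "td50": 66.5,
    "m": 0.175,
    "n": 0.05,
    "exclude": true
  }
}
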