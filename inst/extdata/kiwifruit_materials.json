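{
  "skin": {
    "E": 10.233,
    "sigma_y": 0.514,
    "nu": 0.30,
    "density": 0.99,
    "density_alt": 0.551,
    "symmetry": "isotropic"
  },
  "core": {
    "E": 4.499,
    "Et": 1.381,
    "sigma_y": 1.306,
    "nu": 0.30,
    "density": 1.154,
    "symmetry": "isotropic"
  },
  "flesh_axial": {
    "E": 2.305,
    "Et": 0.967,
    "sigma_y": 0.491,
    "nu": 0.40,
    "density": 1.248,
    "symmetry": "isotropic"
  },
  "flesh_radial": {
    "E": 1.346,
    "Et": 0.642,
    "sigma_y": 0.292,
    "nu": 0.40,
    "density": 1.248,
    "symmetry": "isotropic"
  },
  "flesh": {
    "symmetry": "transverse",
    "E_axial": 2.305,
    "E_radial": 1.346,
    "Et_axial": 0.967,
    "Et_radial": 0.642,
    "sigma_y_axial": 0.491,
    "sigma_y_radial": 0.292,
    "nu": 0.40,
    "density": 1.248
  }
}
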